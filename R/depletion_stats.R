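# Gene-level depletion statistics for condition contrasts.
#
# Guide log2 fold changes feed two gene-level summaries: a signed score (the
# median of the gene's guide lfc values) and a robust-rank-aggregation (RRA)
# significance layer. RRA converts each guide's lfc to a rank percentile u,
# and scores a gene with k guides by the minimum, over the sorted u(j) below
# the percentile threshold alpha, of the Beta(j, k - j + 1) CDF at u(j) —
# the probability that the j-th of k uniform order statistics is that small.
# Significance comes from permuting percentile assignments to gene slots;
# depletion uses u, enrichment uses the reversed percentiles.

#' Configuration for a pairwise condition contrast
#'
#' @param treatment condition label of the treated samples (e.g. `"Ci"`).
#' @param control condition label of the control (e.g. `"mock"`).
#' @param pseudocount added to normalized counts before the log ratio
#'   (default 1).
#' @param alpha rank-percentile threshold in (0, 1] for RRA (default 0.25).
#' @param n_permutations permutation draws for the null (default 10000).
#' @param seed RNG seed used for the permutations.
#' @return a `contrast_config` list.
#' @export
contrast_config <- function(treatment, control, pseudocount = 1,
                            alpha = 0.25, n_permutations = 10000L, seed = 1L) {
  stopifnot(pseudocount > 0, alpha > 0, alpha <= 1, n_permutations >= 100L)
  structure(list(treatment = treatment, control = control,
                 pseudocount = pseudocount, alpha = alpha,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "contrast_config")
}

#' Per-guide log2 fold changes and rank percentiles
#'
#' Computes `lfc = log2((norm_treat + pc) / (norm_ctrl + pc))` for every
#' included guide — single-target guides targeting a CDS-like feature;
#' multi-target and intergenic guides are excluded from gene-level
#' statistics. Rank percentiles (average ranks for ties) are computed over
#' the included guides, ascending for the depletion tail (`u`) and
#' descending for the enrichment tail (`u_pos`).
#'
#' @param norm a `normalized_counts` with pooled condition columns.
#' @param lib the `guide_library` (for gene assignment and exclusion flags).
#' @param cfg a [contrast_config()].
#' @return data.frame with one row per (guide, targeted gene): `spacer`,
#'   `gene`, `lfc`, `u`, `u_pos`. The attribute `n_included` records the
#'   number of distinct guides ranked.
#' @export
guide_lfc <- function(norm, lib, cfg) {
  stopifnot(inherits(norm, "normalized_counts"), inherits(cfg, "contrast_config"))
  cond <- norm$samples$condition
  tcol <- which(cond == cfg$treatment)
  ccol <- which(cond == cfg$control)
  if (length(tcol) != 1L || length(ccol) != 1L) {
    stop("conditions '", cfg$treatment, "' and '", cfg$control,
         "' must each map to exactly one (pooled) column", call. = FALSE)
  }
  idx <- library_gene_index(lib)
  idx <- idx[!idx$multi_target & idx$target_class == "cds_rule_pass", , drop = FALSE]
  if (!nrow(idx)) stop("no included guides (single-target, CDS-targeting)", call. = FALSE)
  spacers <- unique(idx$spacer)
  m <- norm$matrix
  hit <- match(spacers, rownames(m))
  if (anyNA(hit)) stop("library spacers missing from the count matrix", call. = FALSE)
  pc <- cfg$pseudocount
  lfc <- log2((m[hit, tcol] + pc) / (m[hit, ccol] + pc))
  n <- length(lfc)
  u <- rank(lfc, ties.method = "average") / n
  u_pos <- rank(-lfc, ties.method = "average") / n
  pos <- match(idx$spacer, spacers)
  out <- data.frame(spacer = idx$spacer, gene = idx$gene,
                    lfc = lfc[pos], u = u[pos], u_pos = u_pos[pos],
                    stringsAsFactors = FALSE)
  attr(out, "n_included") <- n
  out
}

#' Signed gene depletion score
#'
#' The score of a gene is the median of its included guides' log2 fold
#' changes; negative scores mean guide loss (gene inhibition is costly).
#'
#' @param stats guide table from [guide_lfc()].
#' @return data.frame with `gene`, `n_guides`, `score`.
#' @export
gene_depletion_score <- function(stats) {
  if (!nrow(stats)) {
    return(data.frame(gene = character(0), n_guides = integer(0),
                      score = numeric(0)))
  }
  sp <- split(stats$lfc, stats$gene)
  data.frame(gene = names(sp),
             n_guides = lengths(sp),
             score = vapply(sp, stats::median, numeric(1L)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' RRA rho score for a vector of rank percentiles
#'
#' @param u percentiles in (0, 1].
#' @param alpha threshold; percentiles above it are ignored. If no
#'   percentile falls below `alpha` the score is 1.
#' @return the rho score (minimum Beta order-statistic CDF value).
#' @export
rra_rho <- function(u, alpha = 0.25) {
  u <- sort(u)
  k <- length(u)
  j <- which(u <= alpha)
  if (!length(j)) return(1)
  min(stats::pbeta(u[j], j, k - j + 1L))
}

# vectorized rho over columns of a k x n matrix of percentiles
#' @keywords internal
#' @noRd
.rra_rho_matrix <- function(U, alpha) {
  k <- nrow(U)
  U <- apply(U, 2L, sort.int)
  if (k == 1L) U <- matrix(U, nrow = 1L)
  B <- stats::pbeta(U, seq_len(k), k - seq_len(k) + 1L)
  B[U > alpha] <- Inf
  rho <- Reduce(pmin, lapply(seq_len(k), function(j) B[j, ]))
  rho[is.infinite(rho)] <- 1
  rho
}

#' RRA significance by permutation
#'
#' For every gene, the observed rho score in each tail is compared with a
#' null distribution obtained by drawing the gene's number of percentile
#' slots, without replacement, from the pool of all included-guide
#' percentiles (`n_permutations` draws, shared across genes with the same
#' guide count). The p-value is `(1 + #{null <= observed}) /
#' (n_permutations + 1)`; FDRs are Benjamini-Hochberg within each tail.
#'
#' @param stats guide table from [guide_lfc()].
#' @param cfg a [contrast_config()]; its `seed` fixes the permutation RNG.
#' @return data.frame with `gene`, `n_guides`, `rho_neg`, `p_neg`,
#'   `fdr_neg`, `rho_pos`, `p_pos`, `fdr_pos`.
#' @export
rra_significance <- function(stats, cfg) {
  stopifnot(inherits(cfg, "contrast_config"))
  # percentile pools over distinct guides (a guide spanning two genes still
  # contributes one slot to the pool)
  d <- stats[!duplicated(stats$spacer), , drop = FALSE]
  pool_neg <- d$u
  pool_pos <- d$u_pos
  by_gene_u <- split(stats$u, stats$gene)
  by_gene_up <- split(stats$u_pos, stats$gene)
  genes <- names(by_gene_u)
  k <- lengths(by_gene_u)
  if (any(k > length(pool_neg))) {
    stop("a gene has more guides than the guide pool", call. = FALSE)
  }
  rho_neg <- vapply(by_gene_u, rra_rho, numeric(1L), alpha = cfg$alpha)
  rho_pos <- vapply(by_gene_up, rra_rho, numeric(1L), alpha = cfg$alpha)
  nperm <- cfg$n_permutations
  p_neg <- numeric(length(genes))
  p_pos <- numeric(length(genes))
  .with_seed(cfg$seed, {
    for (kk in sort(unique(k))) {
      null_neg <- sort.int(.rra_null(pool_neg, kk, nperm, cfg$alpha))
      null_pos <- sort.int(.rra_null(pool_pos, kk, nperm, cfg$alpha))
      sel <- which(k == kk)
      p_neg[sel] <- (1 + findInterval(rho_neg[sel], null_neg)) / (nperm + 1)
      p_pos[sel] <- (1 + findInterval(rho_pos[sel], null_pos)) / (nperm + 1)
    }
  })
  data.frame(gene = genes, n_guides = as.integer(k),
             rho_neg = rho_neg, p_neg = p_neg,
             fdr_neg = stats::p.adjust(p_neg, "BH"),
             rho_pos = rho_pos, p_pos = p_pos,
             fdr_pos = stats::p.adjust(p_pos, "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @keywords internal
#' @noRd
.rra_null <- function(pool, k, nperm, alpha) {
  U <- vapply(seq_len(nperm), function(i) sample(pool, k), numeric(k))
  if (k == 1L) U <- matrix(U, nrow = 1L)
  .rra_rho_matrix(U, alpha)
}

#' Gene scores with RRA significance for one contrast
#'
#' Wrapper combining [guide_lfc()], [gene_depletion_score()] and
#' [rra_significance()]. The score definition (median guide log2 fold
#' change) and the permutation seed are recorded as attributes
#' `score_definition` and `seed` and written into the output header by
#' [write_gene_scores()].
#'
#' @param norm a `normalized_counts` with pooled condition columns.
#' @param lib the `guide_library`.
#' @param cfg a [contrast_config()].
#' @return data.frame with `gene`, `n_guides`, `score`, `rho_neg`, `p_neg`,
#'   `fdr_neg`, `rho_pos`, `p_pos`, `fdr_pos`.
#' @export
gene_scores <- function(norm, lib, cfg) {
  gs <- guide_lfc(norm, lib, cfg)
  sc <- gene_depletion_score(gs)
  sig <- rra_significance(gs, cfg)
  out <- merge(sc, sig[setdiff(names(sig), "n_guides")], by = "gene", sort = TRUE)
  attr(out, "score_definition") <- "median gRNA log2 fold change (treatment vs control)"
  attr(out, "seed") <- cfg$seed
  attr(out, "contrast") <- paste(cfg$treatment, "vs", cfg$control)
  out
}

#' @rdname gene_scores
#' @param scores result of [gene_scores()].
#' @param path output TSV path.
#' @export
write_gene_scores <- function(scores, path) {
  hdr <- .tsv_header(seed = attr(scores, "seed"),
                     extra = c(paste0("contrast=", attr(scores, "contrast")),
                               paste0("score_definition=",
                                      attr(scores, "score_definition"))))
  write_tsv_file(scores, path, header_lines = hdr)
}
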