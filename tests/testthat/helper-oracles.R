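# Independent brute-force oracles and tiny random-input generators.
# These deliberately avoid the package's interval machinery: windows are
# enumerated by sliding over explicit strand strings, and feature overlap is
# decided by per-base set intersection.

rc_string <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

random_dna <- function(L, gc = 0.4, n_frac = 0) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  s <- sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = p)
  if (n_frac > 0) {
    k <- rbinom(1, L, n_frac)
    if (k > 0) s[sample.int(L, k)] <- "N"
  }
  paste(s, collapse = "")
}

random_annotated_genome <- function(L = NULL, n_feat = NULL, circular = NULL,
                                    n_frac = 0) {
  if (is.null(L)) L <- sample(200:2000, 1)
  if (is.null(circular)) circular <- runif(1) < 0.5
  if (is.null(n_feat)) n_feat <- sample(0:6, 1)
  feats <- NULL
  if (n_feat > 0) {
    start <- sample(0:(L - 2), n_feat, replace = TRUE)
    len <- pmin(sample(30:300, n_feat, replace = TRUE), L - start)
    feats <- data.frame(
      locus_tag = sprintf("F%02d", seq_len(n_feat)),
      gene_name = NA_character_,
      kind = sample(c("CDS", "CDS", "CDS", "rRNA", "tRNA"), n_feat, replace = TRUE),
      strand = sample(c("+", "-"), n_feat, replace = TRUE),
      start = start, end = start + pmax(len, 1L),
      stringsAsFactors = FALSE)
  }
  annotated_genome(sprintf("rnd_%d", sample.int(1e6, 1)),
                   random_dna(L, n_frac = n_frac), circular, feats)
}

# Brute-force designer: slide a 23-nt window over each explicit strand
# string; classify against features by per-base membership.
oracle_design <- function(genome, rna_rule = "cds") {
  L <- genome$length
  circ <- genome$circular
  feats <- genome$features[genome$features$kind != "intergenic", , drop = FALSE]
  feat_bases <- lapply(seq_len(nrow(feats)), function(i)
    seq.int(feats$start[i], feats$end[i] - 1L))
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") genome$sequence else rc_string(genome$sequence)
    s2 <- if (circ) paste0(s, s) else s
    n_starts <- if (circ) L else L - 22L
    if (n_starts < 1) next
    j <- seq_len(n_starts)
    win <- substring(s2, j, j + 22L)
    ok <- substr(win, 22L, 23L) == "GG" & !grepl("N", win, fixed = TRUE)
    for (jj in j[ok]) {
      j0 <- jj - 1L                                  # 0-based start on this strand
      gstart <- if (strand == "+") j0 else L - 1L - j0
      fp <- if (strand == "+") (gstart + 0:19) else (gstart - 0:19)
      fp <- if (circ) fp %% L else fp
      stopifnot(all(fp >= 0 & fp < L))
      ovl <- vapply(feat_bases, function(b) length(intersect(fp, b)), integer(1))
      touched <- which(ovl > 0)
      if (!length(touched)) {
        cls <- "intergenic"; tgt <- "."
      } else {
        pass <- vapply(touched, function(fi) {
          if (feats$kind[fi] == "CDS" || rna_rule == "cds") {
            strand != feats$strand[fi]
          } else TRUE
        }, logical(1))
        if (any(pass)) {
          cls <- "cds_rule_pass"
          ord <- touched[pass]
          tgt <- paste(sprintf("%s:%d", feats$locus_tag[ord], ovl[ord]),
                       collapse = ";")
        } else {
          cls <- "rejected"; tgt <- NA_character_
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        strand = strand, start = gstart,
        spacer = substr(win[jj], 1L, 20L), pam = substr(win[jj], 21L, 23L),
        target_class = cls, targets = tgt, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(strand = character(0), start = integer(0),
                      spacer = character(0), pam = character(0),
                      target_class = character(0), targets = character(0)))
  }
  do.call(rbind, rows)  # includes rejected rows; callers filter
}

# canonical key for comparing guide sets (target list order-insensitive)
guide_key <- function(df) {
  tgt <- vapply(df$targets, function(t) {
    if (is.na(t) || t == ".") return(".")
    paste(sort(strsplit(t, ";", fixed = TRUE)[[1]]), collapse = ";")
  }, character(1))
  sort(paste(df$strand, df$start, df$spacer, df$pam, df$target_class, tgt,
             sep = "|"))
}

# simulate at the counting layer and score one contrast (shared by tests)
neutral_guide_table <- function(n_genes, guides_per_gene, depth, seed,
                                dispersion = 0.01) {
  genes <- sprintf("N%04d", seq_len(n_genes))
  lib <- simulate_library(genes, guides_per_gene, fixed_guides = TRUE, seed = seed)
  truth <- simulate_truth(genes, n_costly = 0, n_essential = 0, seed = seed + 1)
  cfg <- sim_config(n_genes = n_genes, guides_per_gene = guides_per_gene,
                    reads_per_replicate = depth / 4, replicates = 4L,
                    dispersion = dispersion, seed = seed + 2)
  cm <- simulate_screen_counts(lib, truth, cfg)
  list(lib = lib, truth = truth,
       norm = median_ratio_normalize(pool_replicates(cm)))
}
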