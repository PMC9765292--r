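# Genome-wide gRNA library design for CRISPRi.
#
# A candidate is every genomic position (either strand) where a 20-nt spacer
# is immediately followed, 3' on the same strand, by an NGG PAM. Retention
# follows the CRISPRi rule for coding sequences: transcriptional interference
# in a CDS requires the spacer to base-pair with the coding (nontemplate)
# strand, i.e. the protospacer must lie on the strand opposite the CDS.
# Candidates wholly inside intergenic regions are kept on both strands.
#
# Coordinate convention for candidates: `start` is the genome (+ strand)
# coordinate of the protospacer's 5'-most base *as read on its own strand* —
# the leftmost protospacer base for "+" guides, the rightmost for "-" guides.
# Reading 23 nt 5'->3' from `start` on `strand` always reproduces
# spacer + PAM (see [extract_protospacer()]).

#' Enumerate all spacer+PAM candidate sites
#'
#' Scans both strands of the genome for 20-nt windows immediately followed by
#' an NGG PAM. Circular genomes include origin-spanning windows. Any window
#' (spacer or PAM) containing `N` is skipped.
#'
#' @param genome an [annotated_genome()].
#' @return data.frame with columns `strand`, `start`, `spacer`, `pam`, sorted
#'   by (strand, start, spacer). A genome too short to fit spacer+PAM yields
#'   zero rows.
#' @export
enumerate_candidates <- function(genome) {
  stopifnot(inherits(genome, "annotated_genome"))
  L <- genome$length
  plus <- .scan_strand(genome$sequence, L, genome$circular, "+")
  minus <- .scan_strand(.revcomp(genome$sequence), L, genome$circular, "-")
  out <- rbind(plus, minus)
  out <- out[order(out$strand, out$start, out$spacer), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @keywords internal
#' @noRd
.scan_strand <- function(strand_seq, L, circular, strand) {
  empty <- data.frame(strand = character(0), start = integer(0),
                      spacer = character(0), pam = character(0),
                      stringsAsFactors = FALSE)
  if (L < 23L && !circular) return(empty)
  if (L == 0L) return(empty)
  ext <- if (circular) paste0(strand_seq, substr(strand_seq, 1L, 22L)) else strand_seq
  n <- nchar(ext)
  if (n < 23L) return(empty)
  ch <- strsplit(ext, "", fixed = TRUE)[[1L]]
  # 1-based spacer start positions on this strand's string
  j_max <- if (circular) min(L, n - 22L) else n - 22L
  j <- seq_len(j_max)
  ok <- ch[j + 21L] == "G" & ch[j + 22L] == "G"
  nN <- cumsum(c(0L, ch == "N"))
  ok <- ok & (nN[j + 23L] - nN[j]) == 0L
  j <- j[ok]
  if (!length(j)) return(empty)
  spacer <- substring(ext, j, j + 19L)
  pam <- substring(ext, j + 20L, j + 22L)
  start0 <- if (strand == "+") j - 1L else (L - 1L) - (j - 1L)
  data.frame(strand = strand, start = as.integer(start0),
             spacer = spacer, pam = pam, stringsAsFactors = FALSE)
}

# genomic footprint of the 20-nt protospacer, as 0-based half-open
# sub-interval(s); circular sites may split at the origin
#' @keywords internal
#' @noRd
.protospacer_intervals <- function(strand, start, L, circular) {
  lo <- ifelse(strand == "+", start, start - 19L)
  hi <- lo + 20L
  idx <- rep.int(seq_along(lo), 1L)
  out <- data.frame(site = idx, lo = lo, hi = hi)
  if (!circular) return(out)
  out$lo <- out$lo %% L
  wrap <- out$lo + 20L > L
  if (!any(wrap)) {
    out$hi <- out$lo + 20L
    return(out)
  }
  w <- out[wrap, , drop = FALSE]
  nw <- out[!wrap, , drop = FALSE]
  nw$hi <- nw$lo + 20L
  part1 <- data.frame(site = w$site, lo = w$lo, hi = L)
  part2 <- data.frame(site = w$site, lo = 0L, hi = (w$lo + 20L) %% L)
  rbind(nw, part1, part2)
}

#' Re-extract spacer+PAM from the genome at a recorded locus
#'
#' Reads 23 nt 5'->3' from `start` on `strand` (wrapping the origin on
#' circular genomes) and returns them; the first 20 nt are the spacer, the
#' last 3 the PAM. Used to verify the locus/sequence invariant.
#'
#' @param genome an [annotated_genome()].
#' @param strand `"+"` or `"-"` (vectorized).
#' @param start 0-based coordinate of the protospacer's 5'-most base
#'   (vectorized).
#' @return character vector of 23-nt sequences.
#' @export
extract_protospacer <- function(genome, strand, start) {
  L <- genome$length
  ch <- strsplit(genome$sequence, "", fixed = TRUE)[[1L]]
  vapply(seq_along(start), function(i) {
    pos <- if (strand[i] == "+") start[i] + 0:22 else start[i] - 0:22
    if (genome$circular) pos <- pos %% L
    if (any(pos < 0L | pos >= L)) {
      stop("protospacer window outside linear genome", call. = FALSE)
    }
    s <- paste(ch[pos + 1L], collapse = "")
    if (strand[i] == "-") s <- chartr("ACGTN", "TGCAN", s)
    s
  }, character(1L))
}

#' Apply CDS/intergenic retention rules to candidate sites
#'
#' A candidate overlapping (by >= 1 protospacer base) a CDS-like feature on
#' strand `s` is retained for that feature iff its protospacer lies on the
#' opposite strand, so that the spacer base-pairs with the coding strand.
#' Candidates overlapping no annotated feature are intergenic and retained on
#' either strand. Candidates that overlap features but pass for none are
#' rejected. Retained guides sharing a spacer sequence are flagged
#' `multi_target` with their copy number.
#'
#' @param sites candidate data.frame from [enumerate_candidates()].
#' @param genome an [annotated_genome()]; its CDS/rRNA/tRNA features are used.
#' @param rna_rule how rRNA/tRNA loci are treated: `"cds"` (default) applies
#'   the coding-strand rule; `"both_strands"` retains guides on either strand.
#' @return a `guide_library` object: list with `guides` (data.frame `spacer`,
#'   `pam`, `strand`, `start`, `targets`, `target_class`, `multi_target`,
#'   `copies`), `genome_id`, `genome_length`, `circular`, `n_candidates`,
#'   `n_rejected`, `rna_rule`.
#' @export
apply_retention_rules <- function(sites, genome, rna_rule = c("cds", "both_strands")) {
  rna_rule <- match.arg(rna_rule)
  stopifnot(inherits(genome, "annotated_genome"))
  L <- genome$length
  n <- nrow(sites)
  feats <- genome$features[genome$features$kind != "intergenic", , drop = FALSE]
  targets <- rep.int(".", n)
  target_class <- rep.int("intergenic", n)
  if (n && nrow(feats)) {
    iv <- .protospacer_intervals(sites$strand, sites$start, L, genome$circular)
    ir_c <- IRanges::IRanges(iv$lo + 1L, iv$hi)
    ir_f <- IRanges::IRanges(feats$start + 1L, feats$end)
    hits <- IRanges::findOverlaps(ir_c, ir_f)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    if (length(qh)) {
      ov <- pmin(BiocGenerics::end(ir_c)[qh], BiocGenerics::end(ir_f)[sh]) -
        pmax(BiocGenerics::start(ir_c)[qh], BiocGenerics::start(ir_f)[sh]) + 1L
      pr <- data.frame(site = iv$site[qh], feat = sh, ov = ov)
      # wrapped candidates/features can hit the same pair twice: sum overlap
      key <- paste(pr$site, pr$feat)
      agg <- rowsum(pr$ov, key)
      first <- !duplicated(key)
      pr <- data.frame(site = pr$site[first], feat = pr$feat[first],
                       ov = as.vector(agg[match(key[first], rownames(agg))]))
      fk <- feats$kind[pr$feat]
      fs <- feats$strand[pr$feat]
      cand_strand <- sites$strand[pr$site]
      use_cds_rule <- fk == "CDS" | rna_rule == "cds"
      pass <- ifelse(use_cds_rule, cand_strand != fs, TRUE)
      overlapped <- unique(pr$site)
      target_class[overlapped] <- "rejected"
      pass_pr <- pr[pass, , drop = FALSE]
      if (nrow(pass_pr)) {
        lab <- paste0(feats$locus_tag[pass_pr$feat], ":", pass_pr$ov)
        tgt <- tapply(lab, pass_pr$site, paste, collapse = ";")
        ids <- as.integer(names(tgt))
        target_class[ids] <- "cds_rule_pass"
        targets[ids] <- as.vector(tgt)
      }
    }
  }
  keep <- target_class != "rejected"
  guides <- data.frame(spacer = sites$spacer[keep], pam = sites$pam[keep],
                       strand = sites$strand[keep], start = sites$start[keep],
                       targets = targets[keep], target_class = target_class[keep],
                       stringsAsFactors = FALSE)
  guides <- guides[order(guides$strand, guides$start, guides$spacer), , drop = FALSE]
  cp <- table(guides$spacer)
  guides$copies <- as.integer(cp[guides$spacer])
  guides$multi_target <- guides$copies > 1L
  guides <- guides[c("spacer", "pam", "strand", "start", "targets",
                     "target_class", "multi_target", "copies")]
  rownames(guides) <- NULL
  structure(list(guides = guides, genome_id = genome$id, genome_length = L,
                 circular = genome$circular, n_candidates = n,
                 n_rejected = sum(!keep), rna_rule = rna_rule),
            class = "guide_library")
}

#' Design a CRISPRi guide library for a genome
#'
#' One-call wrapper: [enumerate_candidates()] then [apply_retention_rules()].
#'
#' @inheritParams apply_retention_rules
#' @param genome an [annotated_genome()].
#' @return a `guide_library`.
#' @export
design_guides <- function(genome, rna_rule = c("cds", "both_strands")) {
  apply_retention_rules(enumerate_candidates(genome), genome, rna_rule)
}

#' @export
print.guide_library <- function(x, ...) {
  cat(sprintf("<guide_library> %s (%s bp): %d guides retained (%d candidates, %d rejected)\n",
              x$genome_id, format(x$genome_length, big.mark = ","),
              nrow(x$guides), x$n_candidates, x$n_rejected))
  print(table(x$guides$target_class))
  invisible(x)
}

#' Guide-to-gene index of a library
#'
#' Expands the `targets` column into long format: one row per (guide row,
#' targeted locus tag) with the protospacer overlap in bases.
#'
#' @param lib a `guide_library`.
#' @return data.frame with columns `guide_row`, `spacer`, `multi_target`,
#'   `target_class`, `gene`, `overlap`.
#' @export
library_gene_index <- function(lib) {
  g <- lib$guides
  has <- which(g$target_class == "cds_rule_pass")
  if (!length(has)) {
    return(data.frame(guide_row = integer(0), spacer = character(0),
                      multi_target = logical(0), target_class = character(0),
                      gene = character(0), overlap = integer(0)))
  }
  parts <- strsplit(g$targets[has], ";", fixed = TRUE)
  nrep <- lengths(parts)
  flat <- unlist(parts, use.names = FALSE)
  gene <- sub(":[0-9]+$", "", flat)
  ov <- as.integer(sub("^.*:", "", flat))
  data.frame(guide_row = rep.int(has, nrep),
             spacer = rep.int(g$spacer[has], nrep),
             multi_target = rep.int(g$multi_target[has], nrep),
             target_class = rep.int(g$target_class[has], nrep),
             gene = gene, overlap = ov, stringsAsFactors = FALSE)
}

#' Library density statistics
#'
#' Guide count, median guides per CDS (zeros included; even counts use the
#' midpoint convention of [stats::median()]), mean genome spacing and a
#' per-feature coverage table.
#'
#' @param lib a `guide_library`.
#' @param genome the [annotated_genome()] the library was designed on.
#' @return list with `n_guides`, `median_guides_per_cds`, `mean_spacing_bp`
#'   (= `round(genome length / n_guides)`) and `coverage` (data.frame
#'   `locus_tag`, `kind`, `n_guides`).
#' @export
library_stats <- function(lib, genome) {
  n_guides <- nrow(lib$guides)
  if (n_guides == 0L) {
    stop("empty guide library: spacing undefined (division by zero)", call. = FALSE)
  }
  idx <- library_gene_index(lib)
  feats <- genome$features[genome$features$kind != "intergenic", , drop = FALSE]
  cov_n <- integer(nrow(feats))
  if (nrow(idx)) {
    tb <- table(idx$gene)
    m <- match(feats$locus_tag, names(tb))
    cov_n <- ifelse(is.na(m), 0L, as.integer(tb[m]))
  }
  coverage <- data.frame(locus_tag = feats$locus_tag, kind = feats$kind,
                         n_guides = cov_n, stringsAsFactors = FALSE)
  cds_counts <- coverage$n_guides[coverage$kind == "CDS"]
  list(n_guides = n_guides,
       median_guides_per_cds = if (length(cds_counts)) stats::median(cds_counts) else NA_real_,
       mean_spacing_bp = round(genome$length / n_guides),
       coverage = coverage)
}

#' Write a guide library to TSV (and optionally BED)
#'
#' The TSV carries the library metadata as `#key=value` comment lines and one
#' row per retained guide; [read_library()] inverts it losslessly. The BED6
#' track records the 20-nt protospacer footprints under the 0-based half-open
#' convention (origin-wrapping footprints emit two lines).
#'
#' @param lib a `guide_library`.
#' @param path output TSV path.
#' @param bed_path optional BED6 output path.
#' @return invisibly, the TSV path.
#' @export
write_library <- function(lib, path, bed_path = NULL) {
  meta <- sprintf("%s=%s",
                  c("genome_id", "genome_length", "circular", "n_candidates",
                    "n_rejected", "rna_rule"),
                  c(lib$genome_id, lib$genome_length, lib$circular,
                    lib$n_candidates, lib$n_rejected, lib$rna_rule))
  g <- lib$guides[c("spacer", "pam", "strand", "start", "targets",
                    "target_class", "multi_target", "copies")]
  write_tsv_file(g, path, header_lines = meta, na = ".")
  if (!is.null(bed_path)) {
    if (nrow(g)) {
      iv <- .protospacer_intervals(g$strand, g$start, lib$genome_length, lib$circular)
      bed <- data.frame(chrom = lib$genome_id, start = iv$lo, end = iv$hi,
                        name = g$spacer[iv$site], score = 0L,
                        strand = g$strand[iv$site])
      bed <- bed[order(bed$start, bed$end), , drop = FALSE]
    } else {
      bed <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                        name = character(0), score = integer(0), strand = character(0))
    }
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a guide library written by [write_library()]
#'
#' @param path TSV path.
#' @return a `guide_library`.
#' @export
read_library <- function(path) {
  if (!file.exists(path)) stop("library file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", meta_lines), "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  g <- read_tsv_file(path, na = "\1")  # keep '.' literal in targets
  expected <- c("spacer", "pam", "strand", "start", "targets", "target_class",
                "multi_target", "copies")
  if (!identical(names(g), expected)) {
    stop("malformed library table: expected columns ",
         paste(expected, collapse = ", "), call. = FALSE)
  }
  g$start <- as.integer(g$start)
  g$copies <- as.integer(g$copies)
  g$multi_target <- as.logical(g$multi_target)
  g$targets <- as.character(g$targets)
  g$spacer <- as.character(g$spacer)
  structure(list(guides = g, genome_id = unname(meta["genome_id"]),
                 genome_length = as.integer(meta["genome_length"]),
                 circular = as.logical(meta["circular"]),
                 n_candidates = as.integer(meta["n_candidates"]),
                 n_rejected = as.integer(meta["n_rejected"]),
                 rna_rule = unname(meta["rna_rule"])),
            class = "guide_library")
}
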