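# Amplicon read counting for pooled screens.
#
# Spacers are recovered from raw reads by exact matching of the two constant
# anchor sequences that flank the 20-nt spacer in the amplicon; both read
# orientations are tried. Failures are tallied per sample as `unassigned`,
# so assigned + unassigned always equals the number of reads processed.

#' Define the amplicon structure used for spacer extraction
#'
#' @param upstream constant DNA immediately 5' of the spacer (>= 8 nt, no N).
#' @param downstream constant DNA immediately 3' of the spacer (>= 8 nt, no N).
#' @param expected_length expected amplicon length in bp (metadata only;
#'   default 219).
#' @return an `amplicon_schema` object.
#' @export
amplicon_schema <- function(upstream, downstream, expected_length = 219L) {
  upstream <- .validate_dna(upstream, "upstream anchor")
  downstream <- .validate_dna(downstream, "downstream anchor")
  if (nchar(upstream) < 8L || nchar(downstream) < 8L) {
    stop("anchors must be at least 8 nt", call. = FALSE)
  }
  if (grepl("N", upstream, fixed = TRUE) || grepl("N", downstream, fixed = TRUE)) {
    stop("anchors must not contain N", call. = FALSE)
  }
  structure(list(upstream = upstream, downstream = downstream,
                 expected_length = as.integer(expected_length)),
            class = "amplicon_schema")
}

#' Extract 20-nt spacers from reads
#'
#' Locates the upstream anchor (exactly, or with at most `max_mismatch`
#' mismatches), requires the downstream anchor exactly 20 nt further on, and
#' returns the intervening spacer. Reads failing in the given orientation are
#' retried reverse-complemented.
#'
#' @param reads character vector of read sequences.
#' @param schema an [amplicon_schema()].
#' @param max_mismatch mismatches tolerated per anchor (0, the default, or 1).
#' @return character vector the length of `reads`; `NA` where no spacer was
#'   recovered.
#' @export
extract_spacers <- function(reads, schema, max_mismatch = 0L) {
  stopifnot(inherits(schema, "amplicon_schema"), max_mismatch %in% c(0L, 1L))
  if (!length(reads)) return(character(0))
  reads <- toupper(reads)
  res <- .extract_oriented(reads, schema, max_mismatch)
  miss <- is.na(res)
  if (any(miss)) {
    res[miss] <- .extract_oriented(.revcomp(reads[miss]), schema, max_mismatch)
  }
  res
}

#' @keywords internal
#' @noRd
.extract_oriented <- function(reads, schema, max_mismatch) {
  up <- schema$upstream
  dn <- schema$downstream
  nu <- nchar(up)
  nd <- nchar(dn)
  if (max_mismatch == 0L) {
    pos <- regexpr(up, reads, fixed = TRUE)  # first exact occurrence
    sp_start <- as.integer(pos) + nu
    sp <- substr(reads, sp_start, sp_start + 19L)
    down <- substr(reads, sp_start + 20L, sp_start + 19L + nd)
    ok <- pos > 0L & nchar(sp) == 20L & down == dn
    return(ifelse(ok, sp, NA_character_))
  }
  ss <- Biostrings::DNAStringSet(reads)
  m <- Biostrings::vmatchPattern(up, ss, max.mismatch = max_mismatch)
  vapply(seq_along(reads), function(i) {
    starts <- BiocGenerics::start(m[[i]])
    for (s in starts) {
      sp_start <- s + nu
      sp <- substr(reads[i], sp_start, sp_start + 19L)
      if (nchar(sp) != 20L) next
      down <- substr(reads[i], sp_start + 20L, sp_start + 19L + nd)
      if (nchar(down) == nd &&
          .hamming(down, dn) <= max_mismatch &&
          !grepl("N", sp, fixed = TRUE)) {
        return(sp)
      }
    }
    NA_character_
  }, character(1L))
}

#' @keywords internal
#' @noRd
.hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1L]] != strsplit(b, "", fixed = TRUE)[[1L]])
}

#' @keywords internal
#' @noRd
.library_spacers <- function(lib) {
  if (inherits(lib, "guide_library")) unique(lib$guides$spacer) else unique(lib)
}

#' Build a count matrix (one sample) from recovered spacers
#' @keywords internal
#' @noRd
.count_one <- function(spacers, lib_spacers) {
  hit <- match(spacers, lib_spacers)
  counts <- tabulate(hit[!is.na(hit)], nbins = length(lib_spacers))
  list(counts = counts, unassigned = sum(is.na(hit)))
}

#' Count library spacers in amplicon FASTQ samples
#'
#' Reads each sample's FASTQ file(s), extracts spacers with
#' [extract_spacers()], and matches them exactly to the library. Extracted
#' spacers absent from the library count as unassigned, as do reads where no
#' spacer was recovered. Multi-target guides are counted here (their
#' exclusion happens at the statistics layer).
#'
#' @param sample_sheet data.frame with columns `sample`, `condition`,
#'   `replicate`, `fastq` (path).
#' @param lib a `guide_library` (or character vector of spacers).
#' @param schema an [amplicon_schema()].
#' @param max_mismatch passed to [extract_spacers()].
#' @return a `count_matrix`: list with `counts` (guides x samples integer
#'   matrix, rownames = spacers), `samples` (the sample sheet) and
#'   `unassigned` (per-sample count).
#' @export
count_reads <- function(sample_sheet, lib, schema, max_mismatch = 0L) {
  needed <- c("sample", "condition", "fastq")
  if (!all(needed %in% names(sample_sheet))) {
    stop("sample sheet needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (!"replicate" %in% names(sample_sheet)) sample_sheet$replicate <- "1"
  spacers <- .library_spacers(lib)
  ns <- nrow(sample_sheet)
  counts <- matrix(0L, nrow = length(spacers), ncol = ns,
                   dimnames = list(spacers, sample_sheet$sample))
  unassigned <- stats::setNames(integer(ns), sample_sheet$sample)
  for (i in seq_len(ns)) {
    fp <- sample_sheet$fastq[i]
    if (!file.exists(fp)) stop("FASTQ not found: ", fp, call. = FALSE)
    reads <- if (file.size(fp) == 0L) character(0) else
      as.character(Biostrings::readDNAStringSet(fp, format = "fastq"))
    if (!length(reads)) {
      warning("sample '", sample_sheet$sample[i], "' has no reads",
              call. = FALSE)
      next
    }
    got <- extract_spacers(reads, schema, max_mismatch)
    one <- .count_one(got, spacers)
    counts[, i] <- one$counts
    unassigned[i] <- one$unassigned
  }
  count_matrix(counts, sample_sheet[c("sample", "condition", "replicate")],
               unassigned)
}

#' Construct a count matrix object
#'
#' @param counts non-negative integer matrix, guides as rows (rownames =
#'   spacers), samples as columns.
#' @param samples data.frame with columns `sample`, `condition`, `replicate`
#'   matching the matrix columns.
#' @param unassigned per-sample count of reads not matching any library
#'   spacer (default 0).
#' @return a `count_matrix`.
#' @export
count_matrix <- function(counts, samples, unassigned = NULL) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (!"replicate" %in% names(samples)) samples$replicate <- "1"
  stopifnot(nrow(samples) == ncol(counts))
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(unassigned)) unassigned <- stats::setNames(integer(ncol(counts)), samples$sample)
  colnames(counts) <- samples$sample
  structure(list(counts = counts, samples = samples,
                 unassigned = unassigned),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d guides x %d samples; %s assigned reads, %s unassigned\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ","),
              format(sum(x$unassigned), big.mark = ",")))
  invisible(x)
}

#' Pool replicate counts by condition
#'
#' Raw counts of replicates of the same condition are summed elementwise
#' (pooling precedes normalization in this pipeline).
#'
#' @param cm a `count_matrix`.
#' @return a `count_matrix` with one column per condition.
#' @export
pool_replicates <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  cond <- cm$samples$condition
  if (any(is.na(cond) | !nzchar(cond))) stop("unknown condition label", call. = FALSE)
  conds <- unique(cond)
  pooled <- vapply(conds, function(cc)
    rowSums(cm$counts[, cond == cc, drop = FALSE]), numeric(nrow(cm$counts)))
  pooled <- matrix(as.integer(pooled), nrow = nrow(cm$counts),
                   dimnames = list(rownames(cm$counts), conds))
  samples <- data.frame(sample = conds, condition = conds, replicate = "pooled",
                        stringsAsFactors = FALSE)
  unassigned <- vapply(conds, function(cc) sum(cm$unassigned[cond == cc]), numeric(1L))
  count_matrix(pooled, samples, unassigned)
}

#' Median-ratio normalization
#'
#' Size factor of sample j is the median over guides of `c_ij / g_i`, where
#' `g_i` is the geometric mean of guide i across samples, computed over
#' guides with nonzero counts in every sample. Normalized counts are raw
#' counts divided by the sample's size factor.
#'
#' @param cm a `count_matrix` (>= 2 samples).
#' @return a `normalized_counts` object: list with `matrix`, `size_factors`,
#'   `samples`.
#' @export
median_ratio_normalize <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  m <- cm$counts
  if (ncol(m) < 2L) stop("need at least 2 samples to normalize", call. = FALSE)
  all_nz <- rowSums(m > 0) == ncol(m)
  if (!any(all_nz)) {
    stop("no guide has nonzero counts in all samples; ",
         "filter low-coverage guides before normalizing", call. = FALSE)
  }
  ref <- m[all_nz, , drop = FALSE]
  lg <- rowMeans(log(ref))
  size_factors <- apply(ref, 2L, function(col) stats::median(exp(log(col) - lg)))
  structure(list(matrix = sweep(m, 2L, size_factors, "/"),
                 size_factors = size_factors, samples = cm$samples),
            class = "normalized_counts")
}

#' Write / read a count matrix as TSV
#'
#' First column `spacer`, one column per sample; the per-sample unassigned
#' totals travel as a comment line.
#'
#' @param cm a `count_matrix`.
#' @param path file path.
#' @param header_lines extra comment lines.
#' @return `path` invisibly (write) or a `count_matrix` (read).
#' @export
write_counts <- function(cm, path, header_lines = NULL) {
  meta <- c(header_lines,
            paste0("unassigned=", paste(sprintf("%s:%d", names(cm$unassigned),
                                                as.integer(cm$unassigned)),
                                        collapse = ",")),
            paste0("condition=", paste(sprintf("%s:%s", cm$samples$sample,
                                               cm$samples$condition),
                                       collapse = ",")),
            paste0("replicate=", paste(sprintf("%s:%s", cm$samples$sample,
                                               cm$samples$replicate),
                                       collapse = ",")))
  df <- data.frame(spacer = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_file(df, path, header_lines = meta)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#(unassigned|condition|replicate)=", lines, value = TRUE)
  parse_map <- function(key) {
    ln <- grep(paste0("^#", key, "="), meta_lines, value = TRUE)
    if (!length(ln)) return(NULL)
    items <- strsplit(sub(paste0("^#", key, "="), "", ln[1L]), ",", fixed = TRUE)[[1L]]
    kv <- strsplit(items, ":", fixed = TRUE)
    stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  }
  df <- read_tsv_file(path, na = "\1")
  m <- as.matrix(df[-1L])
  storage.mode(m) <- "integer"
  rownames(m) <- df$spacer
  sn <- colnames(m)
  cond <- parse_map("condition")
  repl <- parse_map("replicate")
  una <- parse_map("unassigned")
  samples <- data.frame(sample = sn,
                        condition = if (is.null(cond)) sn else unname(cond[sn]),
                        replicate = if (is.null(repl)) "1" else unname(repl[sn]),
                        stringsAsFactors = FALSE)
  unassigned <- if (is.null(una)) stats::setNames(integer(length(sn)), sn) else
    stats::setNames(as.integer(una[sn]), sn)
  count_matrix(m, samples, unassigned)
}
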