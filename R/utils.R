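# Internal helpers shared across modules.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' @keywords internal
#' @noRd
.revcomp <- function(x) {
  # vectorized reverse complement over character strings (A/C/G/T/N)
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @keywords internal
#' @noRd
.validate_dna <- function(x, what = "sequence") {
  x <- toupper(x)
  bad <- setdiff(unique(strsplit(x, "", fixed = TRUE)[[1]]), DNA_ALPHABET)
  if (length(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N}: %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  x
}

#' Write a data frame as a tab-separated table
#'
#' Plain TSV writer used for every tabular artifact of the pipeline. Optional
#' `header_lines` are emitted as `#`-prefixed comments before the column
#' header so run metadata (version, seed) travels with the file.
#'
#' @param df data.frame to write.
#' @param path output file path.
#' @param header_lines character vector of comment lines (without the leading
#'   `#`), or `NULL`.
#' @param na string used for missing values (default `"."`).
#' @return `path`, invisibly.
#' @export
write_tsv_file <- function(df, path, header_lines = NULL, na = ".") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header_lines) && length(header_lines)) {
    writeLines(paste0("#", header_lines), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = na)
  invisible(path)
}

#' Read a tab-separated table written by [write_tsv_file()]
#'
#' @param path file path.
#' @param na string interpreted as missing (default `"."`).
#' @return data.frame.
#' @export
read_tsv_file <- function(path, na = ".") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    na.strings = na, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "")
}

#' @keywords internal
#' @noRd
.pkg_version <- function() {
  as.character(utils::packageVersion("crispriscreen"))
}

#' @keywords internal
#' @noRd
.tsv_header <- function(seed = NULL, extra = character(0)) {
  h <- sprintf(" crispriscreen v%s", .pkg_version())
  if (!is.null(seed)) h <- c(h, sprintf(" seed=%d", as.integer(seed)))
  c(h, paste0(" ", extra))[nzchar(c(h, paste0(" ", extra)))]
}

#' @keywords internal
#' @noRd
.with_seed <- function(seed, code) {
  # evaluate `code` under a fixed RNG state, restoring the caller's state
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}
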