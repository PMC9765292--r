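# Genome-weighted COG functional profiles of screen hits.
#
# Each gene carries at most one COG category (the highest-scoring
# assignment). A screen's profile reports, per category, the number of hit
# genes divided by the number of genome genes in that category — a
# percentage weighted by genome composition, so small categories are not
# drowned out by large ones.

COG_CATEGORIES <- strsplit("ABCDEFGHIJKLMNOPQRSTUVWXYZ", "")[[1L]]

#' Construct a COG assignment table
#'
#' @param assignments data.frame with columns `gene` and `category` (single
#'   COG letter). Duplicate rows with the same category collapse; duplicates
#'   with conflicting categories are an error.
#' @return a `cog_table`: list with `assignments` and `genome_totals`
#'   (named integer vector per category).
#' @export
cog_table <- function(assignments) {
  stopifnot(all(c("gene", "category") %in% names(assignments)))
  a <- unique(assignments[c("gene", "category")])
  a$gene <- as.character(a$gene)
  a$category <- as.character(a$category)
  if (nrow(a)) {
    bad <- setdiff(a$category, COG_CATEGORIES)
    if (length(bad)) {
      stop("unknown COG categories: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    dup <- a$gene[duplicated(a$gene)]
    if (length(dup)) {
      stop("conflicting COG categories for: ",
           paste(unique(dup), collapse = ", "), call. = FALSE)
    }
  }
  totals <- table(a$category)
  structure(list(assignments = a,
                 genome_totals = stats::setNames(as.integer(totals), names(totals))),
            class = "cog_table")
}

#' Read a COG assignment TSV (columns `gene`, `category`)
#'
#' @param path file path.
#' @return a `cog_table`.
#' @export
load_cog_table <- function(path) {
  if (!file.exists(path)) stop("COG table not found: ", path, call. = FALSE)
  body <- grep("^\\s*(#|$)", readLines(path, warn = FALSE),
               value = TRUE, invert = TRUE)
  if (!length(body)) {
    return(cog_table(data.frame(gene = character(0), category = character(0))))
  }
  cog_table(read_tsv_file(path))
}

#' @rdname load_cog_table
#' @param cog a `cog_table`.
#' @export
write_cog_table <- function(cog, path) {
  write_tsv_file(cog$assignments, path)
}

#' Genome-weighted COG profile of screen hit lists
#'
#' For each screen (and for the union of all screens, reported as
#' `"combined"`) and each COG category, counts the distinct hit genes in the
#' category and divides by the genome total, times 100. Hit genes without an
#' assignment are reported under the explicit `unassigned` category (whose
#' genome total, and hence weighted percentage, is unknown and reported as
#' `NA`). Categories with a genome total of zero are omitted.
#'
#' @param hit_lists named list of character vectors of hit genes, one per
#'   screen (set semantics: duplicates ignored).
#' @param cog a `cog_table`.
#' @return data.frame `screen`, `category`, `hits`, `genome_total`,
#'   `weighted_pct`.
#' @export
profile_hits <- function(hit_lists, cog) {
  stopifnot(inherits(cog, "cog_table"))
  if (is.null(names(hit_lists)) || any(!nzchar(names(hit_lists)))) {
    stop("hit_lists must be a named list", call. = FALSE)
  }
  lists <- c(hit_lists, list(combined = unique(unlist(hit_lists, use.names = FALSE))))
  cats <- names(cog$genome_totals)
  one <- function(screen, genes) {
    genes <- unique(as.character(genes))
    assigned <- cog$assignments$category[match(genes, cog$assignments$gene)]
    hits <- vapply(cats, function(cc) sum(assigned == cc, na.rm = TRUE), integer(1L))
    total <- as.integer(cog$genome_totals[cats])
    df <- data.frame(screen = screen, category = cats, hits = hits,
                     genome_total = total,
                     weighted_pct = 100 * hits / total,
                     stringsAsFactors = FALSE)
    n_un <- sum(is.na(assigned))
    rbind(df, data.frame(screen = screen, category = "unassigned",
                         hits = n_un, genome_total = NA_integer_,
                         weighted_pct = NA_real_, stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, Map(one, names(lists), lists))
  rownames(out) <- NULL
  out
}
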