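# Reporter (beta-Gal / luciferase) screen scoring and the transformation
# rate of the spontaneous-transformation screen.
#
# Each picked clone carries one gRNA and a comX-promoter luciferase fusion.
# Its promoter activity is summarized as specific Lux activity: RLU divided
# by OD600 at each timepoint, summed over the time course. Gene-level
# evidence combines the mean log2 fold change of specific activity over the
# gene's selected guides with the library-normalized count of distinct
# selected guides.

#' Specific luciferase activity of a time series
#'
#' `sum(rlu / od600)` over timepoints with `od600 >= od_floor`; the floor
#' excludes early near-blank wells where the ratio explodes.
#'
#' @param ts data.frame with columns `od600` and `rlu` (a `t` column, if
#'   present, must be strictly increasing).
#' @param od_floor minimum OD600 for a timepoint to be included
#'   (default 0.01).
#' @return non-negative scalar.
#' @export
specific_lux <- function(ts, od_floor = 0.01) {
  stopifnot(all(c("od600", "rlu") %in% names(ts)))
  if ("t" %in% names(ts) && is.unsorted(ts$t, strictly = TRUE)) {
    stop("timepoints must be strictly increasing", call. = FALSE)
  }
  if (any(ts$rlu < 0)) stop("negative RLU", call. = FALSE)
  keep <- ts$od600 >= od_floor
  if (!any(keep)) stop("no timepoint at or above the OD floor", call. = FALSE)
  n_drop <- sum(!keep)
  if (n_drop) message(n_drop, " timepoint(s) below OD floor excluded")
  sum(ts$rlu[keep] / ts$od600[keep])
}

#' Log2 fold change of a clone's specific Lux activity vs a reference
#'
#' @param clone_ts,reference_ts time series as in [specific_lux()].
#' @param od_floor passed to [specific_lux()].
#' @return `log2(specLux_clone / specLux_reference)`.
#' @export
clone_fold_change <- function(clone_ts, reference_ts, od_floor = 0.01) {
  ref <- specific_lux(reference_ts, od_floor)
  if (ref <= 0) stop("reference specific activity is zero", call. = FALSE)
  cl <- specific_lux(clone_ts, od_floor)
  if (cl <= 0) stop("clone specific activity is zero", call. = FALSE)
  log2(cl / ref)
}

#' Fold changes for all clones of a long-format time-series table
#'
#' @param timeseries long data.frame `clone_id`, `t`, `od600`, `rlu`.
#' @param clones clone sheet data.frame with columns `clone_id`, `spacer`.
#' @param reference_clone `clone_id` of the no-gRNA reference strain.
#' @param od_floor passed to [specific_lux()].
#' @return `clones` with a `log2fc` column appended.
#' @export
reporter_fold_changes <- function(timeseries, clones,
                                  reference_clone = "reference",
                                  od_floor = 0.01) {
  stopifnot(all(c("clone_id", "t", "od600", "rlu") %in% names(timeseries)))
  sp <- split(timeseries[c("t", "od600", "rlu")], timeseries$clone_id)
  if (!reference_clone %in% names(sp)) {
    stop("reference clone '", reference_clone, "' absent from time series",
         call. = FALSE)
  }
  ref <- sp[[reference_clone]]
  clones$log2fc <- vapply(as.character(clones$clone_id), function(id) {
    if (!id %in% names(sp)) stop("no time series for clone ", id, call. = FALSE)
    clone_fold_change(sp[[id]], ref, od_floor)
  }, numeric(1L))
  clones
}

#' Gene-level reporter screen summary
#'
#' Aggregates clone fold changes per targeted gene. Selected spacers are
#' counted once per gene even when re-isolated in several clones (their fold
#' changes are averaged per spacer first). The normalized count divides the
#' number of distinct selected spacers by the number of library guides
#' targeting the gene, removing the gene-size bias. A gene is `antagonist`
#' when both cutoffs are strictly exceeded; `agonist` mirrors the rule on
#' the negative side (an extension beyond the published antagonist cutoffs,
#' flagged by the `class` value itself); otherwise `unclassified`.
#'
#' @param clones data.frame `clone_id`, `spacer`, `log2fc` (from
#'   [reporter_fold_changes()]).
#' @param lib the `guide_library` (gene assignment; multi-target spacers are
#'   excluded).
#' @param count_cutoff normalized-count cutoff (default 0.02).
#' @param fc_cutoff mean log2 fold-change cutoff (default 0.5).
#' @return data.frame `gene`, `n_selected_guides`, `n_library_guides`,
#'   `normalized_count`, `mean_log2fc`, `class`; attribute `unmapped` lists
#'   clone spacers not resolvable to a gene.
#' @export
summarize_reporter_genes <- function(clones, lib, count_cutoff = 0.02,
                                     fc_cutoff = 0.5) {
  stopifnot(all(c("spacer", "log2fc") %in% names(clones)))
  idx <- library_gene_index(lib)
  idx <- idx[!idx$multi_target, , drop = FALSE]
  # average duplicate isolates of the same spacer
  per_spacer <- stats::aggregate(log2fc ~ spacer, data = clones, FUN = mean)
  hit <- idx[idx$spacer %in% per_spacer$spacer, , drop = FALSE]
  unmapped <- setdiff(per_spacer$spacer, hit$spacer)
  lib_per_gene <- table(idx$gene)
  if (nrow(hit)) {
    hit$log2fc <- per_spacer$log2fc[match(hit$spacer, per_spacer$spacer)]
    n_sel <- tapply(hit$spacer, hit$gene, function(s) length(unique(s)))
    mfc <- tapply(hit$log2fc, hit$gene, mean)
    genes <- names(n_sel)
    n_lib <- as.integer(lib_per_gene[genes])
    out <- data.frame(gene = genes,
                      n_selected_guides = as.integer(n_sel),
                      n_library_guides = n_lib,
                      normalized_count = as.integer(n_sel) / n_lib,
                      mean_log2fc = as.vector(mfc),
                      row.names = NULL, stringsAsFactors = FALSE)
    if (any(out$normalized_count > 1)) {
      warning("normalized count above 1: clone sheet and library disagree",
              call. = FALSE)
    }
    out$class <- ifelse(out$normalized_count > count_cutoff &
                          out$mean_log2fc > fc_cutoff, "antagonist",
                        ifelse(out$normalized_count > count_cutoff &
                                 out$mean_log2fc < -fc_cutoff, "agonist",
                               "unclassified"))
    out <- out[order(out$gene), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out <- data.frame(gene = character(0), n_selected_guides = integer(0),
                      n_library_guides = integer(0),
                      normalized_count = numeric(0), mean_log2fc = numeric(0),
                      class = character(0), stringsAsFactors = FALSE)
  }
  attr(out, "unmapped") <- unmapped
  out
}

#' Transformation rate from selective / total CFU counts
#'
#' `rate = (cfu_selective * dilution_selective) / (cfu_total *
#' dilution_total)`. Zero selective colonies give `NA` (the "not detected"
#' convention); zero total colonies are an error.
#'
#' @param cfu_selective,cfu_total colony counts (vectorized).
#' @param dilution_selective,dilution_total dilution factors (>= 1) applied
#'   to the respective plates.
#' @return data.frame `cfu_selective`, `cfu_total`, `dilution_selective`,
#'   `dilution_total`, `rate`, `detected`.
#' @export
transformation_rate <- function(cfu_selective, cfu_total,
                                dilution_selective = 1, dilution_total = 1) {
  stopifnot(all(cfu_selective >= 0), all(cfu_total >= 0),
            all(dilution_selective >= 1), all(dilution_total >= 1))
  if (any(cfu_total == 0)) stop("total CFU count of zero", call. = FALSE)
  n <- max(length(cfu_selective), length(cfu_total))
  cfu_selective <- rep_len(cfu_selective, n)
  cfu_total <- rep_len(cfu_total, n)
  dilution_selective <- rep_len(dilution_selective, n)
  dilution_total <- rep_len(dilution_total, n)
  rate <- (cfu_selective * dilution_selective) / (cfu_total * dilution_total)
  rate[cfu_selective == 0] <- NA_real_
  data.frame(cfu_selective = cfu_selective, cfu_total = cfu_total,
             dilution_selective = dilution_selective,
             dilution_total = dilution_total,
             rate = rate, detected = cfu_selective > 0)
}
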