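# Cross-condition regression of gene scores and residual outlier calling.
#
# Gene scores from the library-only contrast (x, e.g. Ci vs mock) and the
# competence-induced contrast (y, e.g. Ci+C vs mock) are highly correlated:
# most fitness effects are shared. Genes whose cost is specific to one
# condition fall off the regression line; they are called by standardized
# residuals beyond +/- 2.5 and confirmed against the direct contrast
# (Ci vs Ci+C).

#' Ordinary least-squares fit of y-scores on x-scores
#'
#' @param x numeric vector of gene scores (library-only contrast).
#' @param y numeric vector of gene scores (competence-induced contrast),
#'   same genes and order as `x`.
#' @return a `score_regression` list: `slope`, `intercept`, `r_squared`,
#'   `sigma_hat` (residual standard deviation), `residual_df` (= n - 2),
#'   `n`.
#' @export
fit_score_regression <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 genes to fit the regression", call. = FALSE)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("all y scores identical: R-squared undefined", call. = FALSE)
  fit <- stats::lm(y ~ x)
  e <- stats::residuals(fit)
  sse <- sum(e^2)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = 1 - sse / sst,
                 sigma_hat = sqrt(sse / (n - 2L)),
                 residual_df = n - 2L, n = n),
            class = "score_regression")
}

#' @export
print.score_regression <- function(x, ...) {
  cat(sprintf("<score_regression> y = %.4f + %.4f x; R^2 = %.4f; sigma = %.4f (df = %d)\n",
              x$intercept, x$slope, x$r_squared, x$sigma_hat, x$residual_df))
  invisible(x)
}

#' Standardized residuals of a score regression
#'
#' Residuals divided by their estimated standard deviation. The default is
#' the internally studentized form, which corrects each residual for its
#' leverage `h_i = 1/n + (x_i - xbar)^2 / sum((x_j - xbar)^2)`:
#' `r_i = e_i / (sigma_hat * sqrt(1 - h_i))`. `type = "simple"` divides by
#' `sigma_hat` alone; at genome scale (n in the thousands) the two are
#' practically identical.
#'
#' @param fit a `score_regression` from [fit_score_regression()].
#' @param x,y the data the fit was computed on.
#' @param type `"studentized"` (default) or `"simple"`.
#' @return numeric vector of standardized residuals.
#' @export
standardized_residuals <- function(fit, x, y, type = c("studentized", "simple")) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "score_regression"), length(x) == length(y))
  n <- length(x)
  if (n <= 2L) stop("need more than 2 points", call. = FALSE)
  e <- y - (fit$intercept + fit$slope * x)
  # a (numerically) perfect fit has no residual scale: all residuals are 0
  if (fit$sigma_hat < sqrt(.Machine$double.eps) * stats::sd(y)) {
    return(rep(0, n))
  }
  if (type == "simple") return(e / fit$sigma_hat)
  h <- 1 / n + (x - mean(x))^2 / sum((x - mean(x))^2)
  e / (fit$sigma_hat * sqrt(1 - h))
}

#' Classify residual outliers
#'
#' Strictly below `-cutoff` is `depleted`, strictly above `+cutoff` is
#' `enriched`, everything else (ties at the cutoff included) is `neutral`.
#'
#' @param std_residual numeric vector of standardized residuals.
#' @param cutoff positive threshold (default 2.5).
#' @return character vector of classes.
#' @export
classify_outliers <- function(std_residual, cutoff = 2.5) {
  stopifnot(cutoff > 0)
  ifelse(std_residual < -cutoff, "depleted",
         ifelse(std_residual > cutoff, "enriched", "neutral"))
}

#' Regression-residual outlier calls across two contrasts
#'
#' Inner-joins two gene-score tables by gene, fits the OLS regression of the
#' competence-induced scores on the library-only scores, computes
#' standardized residuals and classifies outliers.
#'
#' @param scores_x gene-score table of the library-only contrast (columns
#'   `gene`, `score`; e.g. Ci vs mock).
#' @param scores_y gene-score table of the competence-induced contrast
#'   (e.g. Ci+C vs mock).
#' @param cutoff residual cutoff (default 2.5).
#' @param residual_type passed to [standardized_residuals()].
#' @return data.frame `gene`, `x`, `y`, `fitted`, `residual`,
#'   `std_residual`, `class`, with attributes `fit` (the
#'   `score_regression`) and `dropped` (genes present in only one table).
#' @export
competence_residuals <- function(scores_x, scores_y, cutoff = 2.5,
                                 residual_type = c("studentized", "simple")) {
  residual_type <- match.arg(residual_type)
  common <- intersect(scores_x$gene, scores_y$gene)
  dropped <- union(setdiff(scores_x$gene, common), setdiff(scores_y$gene, common))
  if (length(common) < 3L) stop("fewer than 3 genes shared between contrasts", call. = FALSE)
  x <- scores_x$score[match(common, scores_x$gene)]
  y <- scores_y$score[match(common, scores_y$gene)]
  fit <- fit_score_regression(x, y)
  fitted <- fit$intercept + fit$slope * x
  r <- standardized_residuals(fit, x, y, residual_type)
  out <- data.frame(gene = common, x = x, y = y, fitted = fitted,
                    residual = y - fitted, std_residual = r,
                    class = classify_outliers(r, cutoff),
                    stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  attr(out, "dropped") <- dropped
  attr(out, "cutoff") <- cutoff
  attr(out, "residual_type") <- residual_type
  out
}

#' Confirm residual calls against the direct contrast
#'
#' A `depleted` call is confirmed when the gene's depletion-tail FDR in the
#' direct treatment-vs-treatment contrast (e.g. Ci+C vs Ci) is at most
#' `fdr_cutoff`; `enriched` calls use the enrichment tail. Neutral genes get
#' `NA`. Genes absent from the direct contrast are unconfirmed, with a
#' warning.
#'
#' @param calls result of [competence_residuals()].
#' @param direct gene-score table of the direct contrast (from
#'   [gene_scores()]).
#' @param fdr_cutoff FDR threshold (default 0.05).
#' @return `calls` with a logical `confirmed_by_direct` column added.
#' @export
confirm_direct <- function(calls, direct, fdr_cutoff = 0.05) {
  m <- match(calls$gene, direct$gene)
  absent <- is.na(m) & calls$class != "neutral"
  if (any(absent)) {
    warning(sum(absent), " called gene(s) absent from the direct contrast; ",
            "marked unconfirmed", call. = FALSE)
  }
  fdr <- ifelse(calls$class == "depleted", direct$fdr_neg[m],
                ifelse(calls$class == "enriched", direct$fdr_pos[m], NA_real_))
  confirmed <- ifelse(calls$class == "neutral", NA,
                      !is.na(fdr) & fdr <= fdr_cutoff)
  calls$confirmed_by_direct <- confirmed
  calls
}
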