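# Accuracy metrics and agreement analysis between estimated and measured GFR.

.check_pair <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    stop("predicted and actual lengths differ", call. = FALSE)
  }
  if (length(predicted) == 0) stop("empty input", call. = FALSE)
}

#' Root mean square error
#'
#' \eqn{RMSE = \sqrt{\frac{1}{n}\sum (y_{pred} - y_{actual})^2}}
#'
#' @param predicted,actual Numeric vectors of equal nonzero length.
#' @return A single non-negative number.
#' @export
rmse <- function(predicted, actual) {
  .check_pair(predicted, actual)
  sqrt(mean((predicted - actual)^2))
}

#' Mean absolute error
#'
#' \eqn{MAE = \frac{1}{n}\sum |y_{pred} - y_{actual}|}
#'
#' @inheritParams rmse
#' @return A single non-negative number; always `<=` the RMSE of the same pair.
#' @export
mae <- function(predicted, actual) {
  .check_pair(predicted, actual)
  mean(abs(predicted - actual))
}

#' Bland--Altman agreement analysis
#'
#' Computes the bias (mean of the paired differences `predicted - actual`)
#' and the limits of agreement `bias +/- multiplier * SD(differences)`, with
#' the sample standard deviation (n - 1 denominator) and the conventional
#' multiplier 1.96.  Also returns the per-pair plotting coordinates: the mean
#' of the two methods against their difference.
#'
#' @inheritParams rmse
#' @param multiplier Width of the limits of agreement in SD units.
#' @return A list with `bias`, `loa_low`, `loa_high`, `sd`, `n` and `pairs`
#'   (a data frame with columns `mean` and `difference`).
#' @export
#' @examples
#' ba <- bland_altman(c(31, 29, 31, 29), c(30, 30, 30, 30))
#' c(ba$bias, ba$loa_low, ba$loa_high)
bland_altman <- function(predicted, actual, multiplier = 1.96) {
  .check_pair(predicted, actual)
  if (length(predicted) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- predicted - actual
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - multiplier * s,
       loa_high = bias + multiplier * s, sd = s, n = length(d),
       pairs = data.frame(mean = (predicted + actual) / 2, difference = d))
}

#' Mean and quartiles of a vector
#'
#' Summary in the `mean (P25--P75)` convention; percentiles use linear
#' interpolation between order statistics (`stats::quantile` type 7).
#'
#' @param values Nonempty numeric vector.
#' @return Named numeric vector `c(mean, p25, p75)`.
#' @export
summary_stats <- function(values) {
  if (length(values) == 0) stop("empty input", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  c(mean = mean(values), p25 = q[1], p75 = q[2])
}

#' Per-method accuracy report against measured GFR
#'
#' Evaluates every estimation equation plus the tree-selector dispatch on a
#' labelled cohort, comparing to measured GFR on the 1.73 m^2-normalised
#' scale.  One row per method: RMSE, MAE, Bland--Altman bias and limits of
#' agreement, and the mean/P25/P75 of the method's estimates.  Equations
#' whose inputs are absent from the cohort get NA metrics.
#'
#' @param cohort A labelled cohort with a `split` column (see
#'   [label_cohort()] and [split_cohort()]).
#' @param selector A fitted `egfr_selector` (or `egfr_tree`).
#' @param split Which rows to evaluate: `"test"` (default), `"train"` or
#'   `"all"`.
#' @param multiplier Limits-of-agreement multiplier, passed to
#'   [bland_altman()].
#' @return Data frame with 14 rows (13 equations + `tree_selector`) and
#'   columns `method`, `label`, `rmse`, `mae`, `bias`, `loa_low`, `loa_high`,
#'   `mean`, `p25`, `p75`, `n`.  The per-pair Bland--Altman data of all
#'   methods is attached as attribute `"pairs"`.
#' @export
comparison_report <- function(cohort, selector, split = c("test", "train", "all"),
                              multiplier = 1.96) {
  split <- match.arg(split)
  if (is.null(cohort$sgfr_norm)) {
    stop("cohort has no sgfr_norm; run label_cohort() first", call. = FALSE)
  }
  rows <- if (split == "all" || is.null(cohort$split)) rep(TRUE, nrow(cohort))
          else cohort$split == split
  if (!any(rows)) stop("empty evaluation split '", split, "'", call. = FALSE)
  eval_cohort <- cohort[rows, , drop = FALSE]
  actual <- eval_cohort$sgfr_norm

  est <- estimate_all(eval_cohort)
  est <- cbind(est, tree_selector = dispatch_estimate(selector, eval_cohort)$egfr)

  methods <- colnames(est)
  pair_frames <- list()
  report <- do.call(rbind, lapply(methods, function(m) {
    pred <- est[, m]
    if (anyNA(pred)) {
      return(data.frame(method = m, label = egfr_equation_label(m),
                        rmse = NA_real_, mae = NA_real_, bias = NA_real_,
                        loa_low = NA_real_, loa_high = NA_real_,
                        mean = NA_real_, p25 = NA_real_, p75 = NA_real_,
                        n = 0L))
    }
    ba <- bland_altman(pred, actual, multiplier)
    ss <- summary_stats(pred)
    pair_frames[[m]] <<- data.frame(method = m, ba$pairs)
    data.frame(method = m, label = egfr_equation_label(m),
               rmse = rmse(pred, actual), mae = mae(pred, actual),
               bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
               mean = ss[["mean"]], p25 = ss[["p25"]], p75 = ss[["p75"]],
               n = length(pred))
  }))
  attr(report, "pairs") <- do.call(rbind, c(pair_frames, make.row.names = FALSE))
  report
}
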