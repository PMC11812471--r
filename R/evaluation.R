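# -- validation-side evaluation ----------------------------------------------
#
# Confusion metrics, stratified error-rate tables (risk group x age bin x
# sex), conformal validity curves, quintile occupancy fractions, and the
# population-projection arithmetic. "Undecided" conformal point labels
# count as prediction errors for both classes: the tool reports a binary
# disease status, so refusing to call one is a miss.

#' Sensitivity, specificity and confusion counts
#'
#' @param predictions character vector of point labels (`"case"`,
#'   `"control"`, or `"undecided"`, which counts as an error against
#'   either truth).
#' @param truth character vector of true labels, same length.
#' @return list of class `confusion_metrics`: `sensitivity` = tp/(tp+fn),
#'   `specificity` = tn/(tn+fp), `counts` (tp, fp, tn, fn). A metric whose
#'   class is absent from `truth` is `NA` (undefined), never 0.
#' @export
confusion_metrics <- function(predictions, truth) {
  stopifnot(length(predictions) == length(truth))
  predictions <- as.character(predictions)
  truth <- check_labels(truth)
  tp <- sum(truth == "case" & predictions == "case")
  fn <- sum(truth == "case" & predictions != "case")
  tn <- sum(truth == "control" & predictions == "control")
  fp <- sum(truth == "control" & predictions != "control")
  sens <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0L) tn / (tn + fp) else NA_real_
  structure(list(sensitivity = sens, specificity = spec,
                 counts = c(tp = tp, fp = fp, tn = tn, fn = fn)),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("sensitivity %.1f%%, specificity %.1f%% (tp=%d fp=%d tn=%d fn=%d)\n",
              100 * x$sensitivity, 100 * x$specificity,
              x$counts["tp"], x$counts["fp"], x$counts["tn"], x$counts["fn"]))
  invisible(x)
}

#' Default age bins for stratified error tables
#'
#' \code{[50,60], (60,70], (70,80], (80,95]} — the first bin is closed on
#' the left so ages at the lower cohort bound are covered.
#'
#' @return numeric vector of bin edges c(50, 60, 70, 80, 95).
#' @export
default_age_bins <- function() c(50, 60, 70, 80, 95)

bin_ages <- function(ages, age_bins) {
  cut(ages, breaks = age_bins, include.lowest = TRUE, right = TRUE)
}

pool_groups <- function(risk_groups, scheme) {
  if (scheme == "per_group") {
    factor(risk_groups, levels = 1:5)
  } else {
    factor(ifelse(risk_groups == 1L, "1",
                  ifelse(risk_groups <= 3L, "2-3", "4-5")),
           levels = c("1", "2-3", "4-5"))
  }
}

#' Prediction-error rates stratified by risk group, age bin and sex
#'
#' The error rate of a stratum is the fraction of its members whose point
#' label differs from the truth (`"undecided"` always counts as wrong).
#' Strata smaller than `min_n` are flagged; empty strata are emitted with
#' `n = 0` and `NA` error rate.
#'
#' @param predictions,truth character vectors of point labels and true
#'   labels.
#' @param risk_groups integer risk groups 1-5.
#' @param ages,sexes covariate vectors, aligned.
#' @param age_bins bin edges covering the cohort age range (default
#'   [default_age_bins()]).
#' @param min_n strata smaller than this are flagged as unstable
#'   (default 73, the smallest subgroup size reported for the emulated
#'   analysis).
#' @param group_scheme `"pooled"` (risk groups \{1\}, \{2,3\}, \{4,5\};
#'   default) or `"per_group"`.
#' @param by_sex set `FALSE` to pool the sexes.
#' @return data.frame of class `stratified_error_table`: risk_group,
#'   age_bin, sex, n, n_wrong, error_rate, flagged_small.
#' @export
stratified_error_rates <- function(predictions, truth, risk_groups, ages,
                                   sexes, age_bins = default_age_bins(),
                                   min_n = 73L,
                                   group_scheme = c("pooled", "per_group"),
                                   by_sex = TRUE) {
  group_scheme <- match.arg(group_scheme)
  n <- length(truth)
  stopifnot(length(predictions) == n, length(risk_groups) == n,
            length(ages) == n, length(sexes) == n)
  if (any(ages < min(age_bins) | ages > max(age_bins))) {
    stop("age bins do not cover the cohort age range", call. = FALSE)
  }
  wrong <- as.character(predictions) != as.character(truth)
  g <- pool_groups(as.integer(risk_groups), group_scheme)
  a <- bin_ages(ages, age_bins)
  s <- if (by_sex) factor(as.character(sexes)) else factor(rep("all", n))
  cells <- expand.grid(risk_group = levels(g), age_bin = levels(a),
                       sex = levels(s), KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  key <- interaction(g, a, s, drop = FALSE)
  n_tab <- table(key)
  wrong_tab <- tapply(wrong, key, sum)
  cell_key <- interaction(factor(cells$risk_group, levels = levels(g)),
                          factor(cells$age_bin, levels = levels(a)),
                          factor(cells$sex, levels = levels(s)))
  cells$n <- as.integer(n_tab[as.character(cell_key)])
  nw <- wrong_tab[as.character(cell_key)]
  cells$n_wrong <- ifelse(is.na(nw), 0L, as.integer(nw))
  cells$error_rate <- ifelse(cells$n > 0L, cells$n_wrong / cells$n, NA_real_)
  cells$flagged_small <- cells$n < min_n
  structure(cells, class = c("stratified_error_table", "data.frame"))
}

#' Empirical conformal validity curve
#'
#' For each significance level on the grid and each true class, the
#' empirical error is the fraction of that class's individuals whose
#' true-label conformal p-value is at or below the level (exactly the rate
#' at which the prediction set excludes the truth). For a valid Mondrian
#' conformal predictor this curve lies on or below the diagonal.
#'
#' @param p_case,p_control conformal p-value vectors (from
#'   [predict.mccp()] output).
#' @param truth character vector of true labels.
#' @param eps_grid significance levels in (0, 1).
#' @return data.frame: epsilon, class, n, empirical_error.
#' @export
validity_curve <- function(p_case, p_control, truth,
                           eps_grid = c(0.05, 0.1, 0.2, 0.3)) {
  truth <- check_labels(truth)
  if (any(eps_grid <= 0 | eps_grid >= 1)) {
    stop("eps_grid must lie strictly inside (0, 1)", call. = FALSE)
  }
  p_true <- ifelse(truth == "case", p_case, p_control)
  do.call(rbind, lapply(eps_grid, function(eps) {
    do.call(rbind, lapply(MCCP_CLASSES, function(cl) {
      sel <- truth == cl
      data.frame(epsilon = eps, class = cl, n = sum(sel),
                 empirical_error = mean(p_true[sel] <= eps),
                 stringsAsFactors = FALSE)
    }))
  }))
}

#' Fraction of a cohort in given risk groups
#'
#' @param risk_groups integer risk groups 1-5.
#' @param groups_of_interest default the two highest quintiles, c(4, 5).
#' @return fraction of individuals whose group is in
#'   `groups_of_interest`.
#' @export
quintile_fraction <- function(risk_groups, groups_of_interest = c(4L, 5L)) {
  if (length(risk_groups) == 0L) stop("empty cohort", call. = FALSE)
  mean(risk_groups %in% groups_of_interest)
}

#' Project a cohort fraction onto a population count
#'
#' `round(fraction * base_count)`: e.g. if 27% of late-stage patients sit
#' in the two highest risk quintiles and 300,000 people in a region are
#' blind or visually impaired due to the disease, about 81,000 of them
#' fall into those quintiles.
#'
#' @param fraction real in [0, 1].
#' @param base_count non-negative population count.
#' @return projected count, rounded to the nearest integer.
#' @export
population_projection <- function(fraction, base_count) {
  stopifnot(is.finite(fraction), fraction >= 0, fraction <= 1,
            is.finite(base_count), base_count >= 0)
  round(fraction * base_count)
}

#' Overall error rate from a stratified table
#'
#' Stratum-size-weighted mean of stratum error rates; equals the plain
#' overall error rate when the strata partition the cohort.
#'
#' @param tab a `stratified_error_table`.
#' @return fraction.
#' @export
overall_error_rate <- function(tab) {
  keep <- tab$n > 0L
  sum(tab$n[keep] * tab$error_rate[keep]) / sum(tab$n[keep])
}
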