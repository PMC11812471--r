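# -- PRS engine --------------------------------------------------------------
#
# PRS_i = sum_j d_ij * w_j / w-bar: risk-allele dosages weighted by effect
# size, summed, divided by the panel mean effect size, so the score reads
# as "number of risk alleles of average effect". Risk groups are quintiles
# of a reference PRS distribution.

#' Construct a dosage matrix
#'
#' Individuals by panel variants risk-allele dosage counts. `NA` encodes a
#' missing call (variant absent from the genotype file or uncalled).
#'
#' @param dosage integer matrix with values in \{0, 1, 2\} or `NA`.
#' @param individual_ids row identifiers.
#' @param variant_rsids column identifiers, aligned to the panel.
#' @return A list of class `dosage_matrix` with elements `dosage`,
#'   `individual_ids`, `variant_rsids`.
#' @export
dosage_matrix <- function(dosage, individual_ids, variant_rsids) {
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != length(individual_ids) ||
      ncol(dosage) != length(variant_rsids)) {
    stop("dosage dimensions do not match identifier lengths", call. = FALSE)
  }
  vals <- dosage[!is.na(dosage)]
  if (length(vals) > 0L && !all(vals %in% 0:2)) {
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  }
  storage.mode(dosage) <- "integer"
  dimnames(dosage) <- list(individual_ids, variant_rsids)
  structure(list(dosage = dosage,
                 individual_ids = as.character(individual_ids),
                 variant_rsids = as.character(variant_rsids)),
            class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("dosage_matrix: %d individuals x %d variants, %d missing calls\n",
              nrow(x$dosage), ncol(x$dosage), sum(is.na(x$dosage))))
  invisible(x)
}

check_alignment <- function(matrix, panel) {
  if (!identical(matrix$variant_rsids, panel$rsid)) {
    stop("dosage matrix columns are not aligned with the panel", call. = FALSE)
  }
}

#' Strong-effect variant quality control
#'
#' A PRS loses predictive power if a strong-effect variant drops out of the
#' genotyping assay, whereas isolated weak variants matter little. This
#' check flags every panel variant whose oriented odds ratio is at least
#' `or_threshold` and whose missing-call fraction exceeds `max_missing`.
#'
#' @param matrix a [dosage_matrix()] aligned to `panel`.
#' @param panel a `variant_panel`.
#' @param or_threshold oriented odds ratio at or above which a variant
#'   counts as strong-effect (default 1.3).
#' @param max_missing tolerated missing-call fraction per variant
#'   (default 0.05).
#' @return A list of class `qc_report`: `per_variant` (data.frame: rsid,
#'   odds_ratio, missing_fraction, strong, flagged), `strong_effect_flags`
#'   (rsids), `pass`.
#' @export
qc_strong_effect <- function(matrix, panel, or_threshold = 1.3,
                             max_missing = 0.05) {
  stopifnot(inherits(matrix, "dosage_matrix"), inherits(panel, "variant_panel"))
  check_alignment(matrix, panel)
  miss_frac <- colMeans(is.na(matrix$dosage))
  strong <- panel$odds_ratio >= or_threshold
  flagged <- strong & miss_frac > max_missing
  per_variant <- data.frame(rsid = panel$rsid,
                            odds_ratio = panel$odds_ratio,
                            missing_fraction = unname(miss_frac),
                            strong = strong, flagged = flagged,
                            stringsAsFactors = FALSE)
  structure(list(per_variant = per_variant,
                 strong_effect_flags = panel$rsid[flagged],
                 pass = !any(flagged),
                 or_threshold = or_threshold, max_missing = max_missing),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %s (%d strong-effect variant(s) flagged at OR >= %.2f, missing > %.0f%%)\n",
              if (x$pass) "PASS" else "FAIL", length(x$strong_effect_flags),
              x$or_threshold, 100 * x$max_missing))
  if (length(x$strong_effect_flags) > 0L) {
    cat("flagged:", paste(x$strong_effect_flags, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Compute weighted polygenic risk scores
#'
#' For individual i, `PRS_i = (sum_j d_ij * w_j) / w-bar` with `w_j` the
#' panel effect weights and `w-bar` their mean. Missing dosages are
#' handled per `missing_policy`: `"impute_freq"` substitutes the
#' Hardy-Weinberg expectation `2 f_j` (requires the panel `freq` column);
#' `"zero"` treats them as zero risk alleles (biases the score downward;
#' a warning is emitted when missing calls are present).
#'
#' @param matrix a [dosage_matrix()] aligned to `panel`.
#' @param panel a `variant_panel` with positive mean effect weight.
#' @param missing_policy `"impute_freq"` or `"zero"`. Default uses
#'   frequency imputation when the panel carries frequencies, else zero.
#' @return data.frame of class `prs_table`: id, prs, n_missing.
#' @export
compute_prs <- function(matrix, panel,
                        missing_policy = c("auto", "impute_freq", "zero")) {
  stopifnot(inherits(matrix, "dosage_matrix"), inherits(panel, "variant_panel"))
  check_alignment(matrix, panel)
  missing_policy <- match.arg(missing_policy)
  has_freq <- all(is.finite(panel$freq))
  if (missing_policy == "auto") {
    missing_policy <- if (has_freq) "impute_freq" else "zero"
  }
  if (missing_policy == "impute_freq" && !has_freq) {
    stop("missing_policy 'impute_freq' requires panel risk-allele frequencies",
         call. = FALSE)
  }
  wbar <- mean(panel$effect_weight)
  if (!is.finite(wbar) || wbar <= 0) {
    stop("panel mean effect weight must be positive", call. = FALSE)
  }
  d <- matrix$dosage
  miss <- is.na(d)
  n_missing <- as.integer(rowSums(miss))
  if (any(miss)) {
    if (missing_policy == "zero") {
      warning("missing dosages treated as zero risk alleles; ",
              "the PRS is biased downward for affected individuals",
              call. = FALSE)
      fill <- matrix(0, nrow(d), ncol(d))
    } else {
      fill <- matrix(rep(2 * panel$freq, each = nrow(d)), nrow(d), ncol(d))
    }
    d <- ifelse(miss, fill, d)
  }
  prs <- as.vector(d %*% panel$effect_weight) / wbar
  structure(data.frame(id = matrix$individual_ids, prs = prs,
                       n_missing = n_missing, stringsAsFactors = FALSE),
            class = c("prs_table", "data.frame"))
}

#' Derive quintile thresholds from a reference PRS distribution
#'
#' Cut points at the empirical 20/40/60/80th percentiles (linear
#' interpolation between order statistics, `stats::quantile` type 7).
#'
#' @param reference_prs numeric vector of at least 5 reference scores.
#' @return A `quintile_thresholds` object (four ascending cuts).
#' @export
derive_quintile_thresholds <- function(reference_prs) {
  reference_prs <- reference_prs[is.finite(reference_prs)]
  if (length(reference_prs) < 5L) {
    stop("need at least 5 finite reference PRS values", call. = FALSE)
  }
  cuts <- unname(stats::quantile(reference_prs, probs = c(0.2, 0.4, 0.6, 0.8),
                                 type = 7))
  quintile_thresholds(cuts)
}

#' Construct quintile thresholds
#'
#' @param cuts four strictly ascending reals c1 < c2 < c3 < c4 partitioning
#'   the PRS axis into risk groups 1-5.
#' @return numeric vector of class `quintile_thresholds`.
#' @export
quintile_thresholds <- function(cuts) {
  cuts <- as.numeric(cuts)
  if (length(cuts) != 4L || any(!is.finite(cuts)) || any(diff(cuts) <= 0)) {
    stop("quintile thresholds must be four strictly ascending finite values",
         call. = FALSE)
  }
  structure(cuts, class = "quintile_thresholds")
}

#' Published AMD PRS quintile thresholds
#'
#' The reference quintile cut points of the consortium PRS distribution:
#' group 1 PRS <= 25.3, group 2 (25.3, 29.9], group 3 (29.9, 34.5],
#' group 4 (34.5, 39.1], group 5 > 39.1.
#'
#' @return A `quintile_thresholds` object `c(25.3, 29.9, 34.5, 39.1)`.
#' @export
amd_quintile_thresholds <- function() {
  quintile_thresholds(c(25.3, 29.9, 34.5, 39.1))
}

#' Assign PRS values to risk groups 1-5
#'
#' Intervals are closed on the right: group 1 iff `prs <= c1`, group k in
#' 2-4 iff `c_{k-1} < prs <= c_k`, group 5 iff `prs > c4` — matching the
#' published convention that a PRS of exactly 25.3 is group 1 and 25.31 is
#' group 2.
#'
#' @param prs numeric vector of PRS values.
#' @param thresholds a `quintile_thresholds` object.
#' @return integer vector of risk groups in 1..5.
#' @export
assign_risk_group <- function(prs, thresholds = amd_quintile_thresholds()) {
  stopifnot(inherits(thresholds, "quintile_thresholds"))
  findInterval(prs, as.numeric(thresholds), left.open = TRUE) + 1L
}

#' Score a dosage matrix: PRS plus risk groups
#'
#' Convenience wrapper chaining [compute_prs()] and [assign_risk_group()].
#'
#' @inheritParams compute_prs
#' @param thresholds a `quintile_thresholds` object, or `NULL` to derive
#'   quintiles from this cohort's own PRS distribution.
#' @return data.frame of class `prs_table`: id, prs, n_missing, risk_group.
#' @export
score_cohort <- function(matrix, panel, thresholds = amd_quintile_thresholds(),
                         missing_policy = c("auto", "impute_freq", "zero")) {
  tab <- compute_prs(matrix, panel, missing_policy = missing_policy)
  if (is.null(thresholds)) thresholds <- derive_quintile_thresholds(tab$prs)
  tab$risk_group <- assign_risk_group(tab$prs, thresholds)
  attr(tab, "thresholds") <- thresholds
  tab
}

#' Write a PRS table to TSV
#'
#' @param tab a `prs_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_prs_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
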