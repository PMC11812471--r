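# -- variant panel -----------------------------------------------------------
#
# A variant panel is the curated list of independent GWAS lead variants used
# to build the weighted PRS. Each record carries the risk allele, the
# per-risk-allele odds ratio and its additive-scale effect weight
# (beta = ln OR after orientation). The panel-level mean effect weight
# (w-bar) is the divisor of the PRS, so that the score reads as "number of
# risk alleles of average effect".

PANEL_COLUMNS <- c("rsid", "chrom", "pos", "ref", "alt", "risk_allele",
                   "odds_ratio", "locus")

#' Construct a variant panel from a data frame
#'
#' Validates a table of risk variants, orients every record to its risk
#' allele (protective odds ratios < 1 are flipped to the other allele and
#' inverted), computes the per-variant effect weight as the natural log of
#' the oriented odds ratio, and stores the panel mean effect weight.
#'
#' @param df data.frame with columns `rsid`, `chrom`, `pos`, `ref`, `alt`,
#'   `risk_allele`, `odds_ratio`, `locus` and optionally `freq` (risk-allele
#'   frequency after orientation, used by the `"impute_freq"` missing-data
#'   policy of [compute_prs()]).
#' @param weight_scale `"log_or"` (default) weights variants by ln(OR);
#'   `"or"` weights by the raw oriented odds ratio. The log scale is the
#'   additive effect-size scale consistent with summing weighted risk
#'   alleles.
#' @return An object of class `variant_panel`: the validated, risk-oriented
#'   data frame with an `effect_weight` column and attributes
#'   `mean_effect_weight` and `weight_scale`.
#' @seealso [load_panel()], [apply_exclusions()], [orient_to_risk()]
#' @export
variant_panel <- function(df, weight_scale = c("log_or", "or")) {
  weight_scale <- match.arg(weight_scale)
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(PANEL_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("panel table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) stop("panel must contain at least one variant", call. = FALSE)
  df$odds_ratio <- as.numeric(df$odds_ratio)
  bad_or <- which(!is.finite(df$odds_ratio) | df$odds_ratio <= 0)
  if (length(bad_or) > 0L) {
    stop("non-positive or unparseable odds ratio for rsid(s): ",
         paste(df$rsid[bad_or], collapse = ", "), call. = FALSE)
  }
  dup <- df$rsid[duplicated(df$rsid)]
  if (length(dup) > 0L) {
    stop("duplicate rsid(s) in panel: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_risk <- which(df$risk_allele != df$ref & df$risk_allele != df$alt)
  if (length(bad_risk) > 0L) {
    stop("risk_allele is neither ref nor alt for rsid(s): ",
         paste(df$rsid[bad_risk], collapse = ", "), call. = FALSE)
  }
  df <- orient_to_risk(df)
  df$effect_weight <- if (weight_scale == "log_or") log(df$odds_ratio) else df$odds_ratio
  if (!"freq" %in% names(df)) df$freq <- NA_real_
  rownames(df) <- NULL
  structure(df,
            class = c("variant_panel", "data.frame"),
            mean_effect_weight = mean(df$effect_weight),
            weight_scale = weight_scale)
}

#' Orient variant records to their risk allele
#'
#' Records with an odds ratio below 1 describe a protective allele; the
#' risk allele is then the *other* allele of the pair, with odds ratio equal
#' to the reciprocal. Orientation makes all weights non-negative and the
#' PRS monotone in every dosage. Idempotent.
#'
#' @param df data.frame with at least `ref`, `alt`, `risk_allele`,
#'   `odds_ratio` columns (one or more rows).
#' @return The same data frame with every row oriented so `odds_ratio >= 1`.
#' @export
orient_to_risk <- function(df) {
  flip <- df$odds_ratio < 1
  if (any(flip)) {
    other <- ifelse(df$risk_allele == df$ref, df$alt, df$ref)
    df$risk_allele[flip] <- other[flip]
    df$odds_ratio[flip] <- 1 / df$odds_ratio[flip]
    if ("freq" %in% names(df)) df$freq[flip] <- 1 - df$freq[flip]
  }
  if ("effect_weight" %in% names(df)) df$effect_weight <- log(df$odds_ratio)
  df
}

#' Panel mean effect weight
#'
#' @param panel a `variant_panel`.
#' @return The arithmetic mean of the member effect weights (w-bar).
#' @export
mean_effect_weight <- function(panel) {
  stopifnot(inherits(panel, "variant_panel"))
  mean(panel$effect_weight)
}

#' Load a risk-variant panel from a TSV file
#'
#' The panel file is tab-separated with header columns `rsid`, `chrom`,
#' `pos`, `ref`, `alt`, `risk_allele`, `odds_ratio`, `locus` and an optional
#' `freq` column. Effect weights are computed on load and protective
#' variants are flipped to risk orientation (see [orient_to_risk()]).
#'
#' @param path path to the panel TSV.
#' @inheritParams variant_panel
#' @return A `variant_panel`.
#' @export
load_panel <- function(path, weight_scale = c("log_or", "or")) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  if ("pos" %in% names(df)) df$pos <- as.integer(df$pos)
  if ("freq" %in% names(df)) df$freq <- as.numeric(df$freq)
  variant_panel(df, weight_scale = match.arg(weight_scale))
}

#' Load an exclusion list from a TSV file
#'
#' @param path TSV with header columns `rsid` and `reason`.
#' @return A data.frame of class `exclusion_list`.
#' @export
load_exclusions <- function(path) {
  if (!file.exists(path)) stop("exclusion file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", stringsAsFactors = FALSE)
  exclusion_list(df$rsid, df$reason)
}

#' Construct an exclusion list
#'
#' @param rsids character vector of variant identifiers to drop.
#' @param reason character vector (recycled) documenting why.
#' @return data.frame of class `exclusion_list` with columns `rsid`, `reason`.
#' @export
exclusion_list <- function(rsids, reason = "unspecified") {
  if (anyDuplicated(rsids)) {
    stop("duplicate rsid(s) in exclusion list: ",
         paste(unique(rsids[duplicated(rsids)]), collapse = ", "),
         call. = FALSE)
  }
  structure(data.frame(rsid = as.character(rsids),
                       reason = rep_len(as.character(reason), length(rsids)),
                       stringsAsFactors = FALSE),
            class = c("exclusion_list", "data.frame"))
}

#' Remove excluded variants from a panel
#'
#' Drops every excluded rsid and recomputes the panel mean effect weight on
#' the survivors. An excluded rsid that is not in the panel is a hard
#' error: it signals a panel/exclusion-list mismatch rather than a no-op.
#'
#' @param panel a `variant_panel`.
#' @param excl an `exclusion_list` (or character vector of rsids).
#' @return A new `variant_panel` without the excluded variants.
#' @export
apply_exclusions <- function(panel, excl) {
  stopifnot(inherits(panel, "variant_panel"))
  rsids <- if (is.data.frame(excl)) excl$rsid else as.character(excl)
  if (length(rsids) == 0L) return(panel)
  absent <- setdiff(rsids, panel$rsid)
  if (length(absent) > 0L) {
    stop("excluded rsid(s) not present in panel: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  keep <- !(panel$rsid %in% rsids)
  variant_panel(as.data.frame(panel)[keep, , drop = FALSE],
                weight_scale = attr(panel, "weight_scale"))
}

#' The five low-coverage variants excluded from the 52-variant panel
#'
#' Five GWAS lead variants are dropped from the 52-variant AMD panel
#' because they cannot be genotyped reliably on the diagnostic assay:
#' rs187328863 (a secondary CFH signal), rs114092250 (PRLR/SPEF2),
#' rs10781182 (MIR6130/RORB), rs67538026 (CNN2) and rs201459901 (C20orf85).
#'
#' @return An `exclusion_list` with the five rsids.
#' @export
amd_exclusions <- function() {
  exclusion_list(
    c("rs187328863", "rs114092250", "rs10781182", "rs67538026",
      "rs201459901"),
    reason = "low coverage on diagnostic genotyping panel")
}

#' @export
print.variant_panel <- function(x, ...) {
  cat(sprintf("variant_panel: %d variants, mean effect weight %.4f (%s scale)\n",
              nrow(x), attr(x, "mean_effect_weight"), attr(x, "weight_scale")))
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... and %d more\n", nrow(x) - 10L))
  invisible(x)
}
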