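# -- synthetic cohort generation ---------------------------------------------
#
# Genotypes are drawn under Hardy-Weinberg equilibrium (dosage ~
# Binomial(2, f_j), variants independent: the panel holds independent GWAS
# signals, so LD adds nothing testable). Disease status follows a logistic
# liability model on the ln-OR scale with age and sex covariates; cohorts
# with exact case/control totals are obtained by stratified resampling of a
# simulated pool.

#' Construct a disease model for cohort simulation
#'
#' The generative model is additive-logistic:
#' \deqn{P(case) = logit^{-1}(b_0 + \sum_j d_{ij} \beta_j +
#'   b_{age}(age_i - age_{ref}) + b_{sex} 1[sex_i = F])}
#' with dosages \eqn{d_{ij}} counting risk alleles, \eqn{\beta_j} the
#' per-allele log odds ratios, ages from a truncated normal and sex a
#' balanced binary covariate.
#'
#' @param panel a `variant_panel`; `variant_log_ors` and
#'   `risk_allele_freqs` default to the panel's ln(OR) weights and `freq`
#'   column.
#' @param intercept log-odds of disease at zero risk alleles, reference age
#'   and male sex.
#' @param variant_log_ors numeric vector aligned to the panel.
#' @param age_effect log-odds per year of age above `age_ref`.
#' @param sex_effect log-odds added for female sex.
#' @param age_ref reference age in years.
#' @param age_mean,age_sd,age_min,age_max truncated-normal age
#'   distribution (years).
#' @param risk_allele_freqs risk-allele frequencies in (0, 1), aligned to
#'   the panel.
#' @return A list of class `disease_model`.
#' @export
disease_model <- function(panel,
                          intercept = NULL,
                          variant_log_ors = log(panel$odds_ratio),
                          age_effect = 0.08,
                          sex_effect = 0.10,
                          age_ref = 75,
                          age_mean = 75, age_sd = 10,
                          age_min = 50, age_max = 95,
                          risk_allele_freqs = panel$freq) {
  stopifnot(inherits(panel, "variant_panel"))
  p <- nrow(panel)
  if (length(variant_log_ors) != p || length(risk_allele_freqs) != p) {
    stop("variant_log_ors and risk_allele_freqs must align with the panel",
         call. = FALSE)
  }
  if (any(!is.finite(risk_allele_freqs)) ||
      any(risk_allele_freqs <= 0) || any(risk_allele_freqs >= 1)) {
    stop("risk allele frequencies must lie strictly inside (0, 1)",
         call. = FALSE)
  }
  if (is.null(intercept)) {
    # centre the genetic load: an average-genotype individual of reference
    # age has P(case) = 0.5, which keeps simulated pools roughly balanced
    intercept <- -sum(2 * risk_allele_freqs * variant_log_ors) - sex_effect / 2
  }
  structure(list(intercept = intercept,
                 variant_log_ors = variant_log_ors,
                 age_effect = age_effect,
                 sex_effect = sex_effect,
                 age_ref = age_ref,
                 age_mean = age_mean, age_sd = age_sd,
                 age_min = age_min, age_max = age_max,
                 risk_allele_freqs = risk_allele_freqs,
                 rsids = panel$rsid),
            class = "disease_model")
}

#' Simulate risk-allele dosages under Hardy-Weinberg equilibrium
#'
#' Each dosage is an independent Binomial(2, f_j) draw, f_j the risk-allele
#' frequency of panel variant j.
#'
#' @param panel a `variant_panel`.
#' @param n number of individuals.
#' @param freqs risk-allele frequencies aligned to the panel; defaults to
#'   the panel `freq` column.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param ids individual identifiers (default `ind00001`...).
#' @return A [dosage_matrix()] of `n` individuals by `nrow(panel)` variants.
#' @export
simulate_genotypes <- function(panel, n, freqs = panel$freq, seed = 1L,
                               ids = NULL) {
  stopifnot(inherits(panel, "variant_panel"), n >= 1)
  p <- nrow(panel)
  if (length(freqs) != p) {
    stop("freqs must align with the panel", call. = FALSE)
  }
  if (any(!is.finite(freqs)) || any(freqs <= 0) || any(freqs >= 1)) {
    stop("allele frequencies must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (is.null(ids)) ids <- sprintf("ind%05d", seq_len(n))
  d <- withr::with_seed(seed, {
    matrix(stats::rbinom(n * p, size = 2L, prob = rep(freqs, each = n)),
           nrow = n, ncol = p)
  })
  dosage_matrix(d, individual_ids = ids, variant_rsids = panel$rsid)
}

truncnorm_inv <- function(u, mean, sd, lo, hi) {
  # inverse-CDF sampling of the truncated normal: deterministic, no rejection
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

#' Simulate phenotypes for a dosage matrix
#'
#' Ages come from the model's truncated normal, sex is Bernoulli(`p_female`)
#' and case/control status is a Bernoulli draw from the logistic liability
#' model (see [disease_model()]).
#'
#' @param dosages a [dosage_matrix()].
#' @param panel the `variant_panel` the dosages were simulated from.
#' @param model a `disease_model` aligned to the panel.
#' @param seed integer seed.
#' @param p_female probability of female sex (default balanced).
#' @return A list of class `simulated_cohort` with elements `dosages`,
#'   `phenotypes` (data.frame: id, status, age, sex), `model`, `seed`.
#' @export
simulate_phenotypes <- function(dosages, panel, model, seed = 1L,
                                p_female = 0.5) {
  stopifnot(inherits(dosages, "dosage_matrix"),
            inherits(model, "disease_model"))
  p <- ncol(dosages$dosage)
  if (length(model$variant_log_ors) != p) {
    stop("disease model is not aligned with the dosage matrix", call. = FALSE)
  }
  n <- nrow(dosages$dosage)
  pheno <- withr::with_seed(seed, {
    age <- truncnorm_inv(stats::runif(n), model$age_mean, model$age_sd,
                         model$age_min, model$age_max)
    sex <- ifelse(stats::runif(n) < p_female, "F", "M")
    eta <- model$intercept +
      as.vector(dosages$dosage %*% model$variant_log_ors) +
      model$age_effect * (age - model$age_ref) +
      model$sex_effect * (sex == "F")
    status <- ifelse(stats::runif(n) < stats::plogis(eta), "case", "control")
    data.frame(id = dosages$individual_ids, status = status,
               age = round(age, 1), sex = sex, stringsAsFactors = FALSE)
  })
  structure(list(dosages = dosages, phenotypes = pheno,
                 model = model, seed = seed),
            class = "simulated_cohort")
}

subset_cohort <- function(cohort, idx) {
  d <- cohort$dosages
  structure(list(
    dosages = dosage_matrix(d$dosage[idx, , drop = FALSE],
                            individual_ids = d$individual_ids[idx],
                            variant_rsids = d$variant_rsids),
    phenotypes = cohort$phenotypes[idx, , drop = FALSE],
    model = cohort$model, seed = cohort$seed),
    class = "simulated_cohort")
}

resample_case_control <- function(cohort, n_case, n_control, seed) {
  status <- cohort$phenotypes$status
  cases <- which(status == "case")
  controls <- which(status == "control")
  idx <- withr::with_seed(seed, {
    c(sample(cases, n_case, replace = length(cases) < n_case),
      sample(controls, n_control, replace = length(controls) < n_control))
  })
  out <- subset_cohort(cohort, idx)
  # resampling may duplicate individuals; re-key ids so they stay unique
  out$dosages$individual_ids <- sprintf("%s_%05d", out$dosages$individual_ids,
                                        seq_along(idx))
  out$phenotypes$id <- out$dosages$individual_ids
  rownames(out$phenotypes) <- NULL
  out
}

#' IAMDGC-like training and validation cohorts
#'
#' Generates the package's reference synthetic cohorts: a training cohort
#' of 1,667 cases / 1,148 controls and a validation cohort of 14,209 cases
#' / 16,566 controls, the case/control totals of the European-ancestry
#' AMD consortium cohorts the pipeline emulates. Genotypes cover the
#' 47-variant diagnostic panel ([synthetic_panel_47()]: two strong loci,
#' 45 weak); case/control totals are met by stratified resampling from
#' simulated pools.
#'
#' @param seed integer root seed; all stage seeds derive from it.
#' @param n_train_pool,n_valid_pool pool sizes the cohorts are resampled
#'   from. Defaults are sized so both strata overshoot their targets with
#'   near-certainty under the preset model.
#' @return A list with elements `train` and `valid` (each a
#'   `simulated_cohort`), `panel` (the 47-variant panel) and `model`.
#' @export
make_iamdgc_preset <- function(seed = 1L, n_train_pool = 6000L,
                               n_valid_pool = 42000L) {
  panel <- synthetic_panel_47()
  model <- disease_model(panel)
  sizes <- iamdgc_cohort_sizes()
  train_pool <- simulate_phenotypes(
    simulate_genotypes(panel, n_train_pool, seed = seed * 8L + 1L),
    panel, model, seed = seed * 8L + 2L)
  valid_pool <- simulate_phenotypes(
    simulate_genotypes(panel, n_valid_pool, seed = seed * 8L + 3L),
    panel, model, seed = seed * 8L + 4L)
  list(train = resample_case_control(train_pool, sizes[["train_cases"]],
                                     sizes[["train_controls"]],
                                     seed = seed * 8L + 5L),
       valid = resample_case_control(valid_pool, sizes[["valid_cases"]],
                                     sizes[["valid_controls"]],
                                     seed = seed * 8L + 6L),
       panel = panel, model = model)
}

#' Case/control totals of the emulated consortium cohorts
#'
#' @return Named integer vector: `train_cases`, `train_controls`,
#'   `valid_cases`, `valid_controls`.
#' @export
iamdgc_cohort_sizes <- function() {
  c(train_cases = 1667L, train_controls = 1148L,
    valid_cases = 14209L, valid_controls = 16566L)
}

#' @export
print.simulated_cohort <- function(x, ...) {
  tab <- table(x$phenotypes$status)
  cat(sprintf("simulated_cohort: %d individuals x %d variants (%s)\n",
              nrow(x$phenotypes), ncol(x$dosages$dosage),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Write cohort phenotypes to TSV
#'
#' Columns: id, status, age, sex.
#'
#' @param cohort a `simulated_cohort` (or its phenotype data.frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(cohort, path) {
  pheno <- if (inherits(cohort, "simulated_cohort")) cohort$phenotypes else cohort
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a phenotype TSV
#'
#' @param path TSV with columns id, status, age, sex.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("id", "status", "age", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("phenotype table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df$id <- as.character(df$id)
  df
}
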