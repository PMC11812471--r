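# shared fixtures and independent oracles

# three-variant toy panel with hand-checkable weights
toy_panel <- function(or = c(exp(0.5), exp(1.0), exp(1.5)),
                      freq = c(0.2, 0.4, 0.5)) {
  freq <- rep_len(freq, length(or))
  variant_panel(data.frame(
    rsid = paste0("rsT", seq_along(or)),
    chrom = "1", pos = 100L * seq_along(or),
    ref = "A", alt = "G", risk_allele = "G",
    odds_ratio = or, locus = "TOY", freq = freq,
    stringsAsFactors = FALSE))
}

# brute-force per-individual, per-variant PRS oracle (no linear algebra)
prs_oracle <- function(dosage, weights, freqs = NULL,
                       policy = c("impute_freq", "zero")) {
  policy <- match.arg(policy)
  wbar <- mean(weights)
  out <- numeric(nrow(dosage))
  for (i in seq_len(nrow(dosage))) {
    s <- 0
    for (j in seq_len(ncol(dosage))) {
      d <- dosage[i, j]
      if (is.na(d)) {
        d <- if (policy == "impute_freq") 2 * freqs[j] else 0
      }
      s <- s + d * weights[j]
    }
    out[i] <- s / wbar
  }
  out
}

# brute-force conformal p-value: count ties/exceedances per fold with a loop
conformal_p_oracle <- function(model, features, y) {
  x <- amdprs:::scale_features(model, features)
  out <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    p_folds <- numeric(model$k)
    for (f in seq_len(model$k)) {
      p_case <- stats::plogis(model$folds[[f]]$coefs[1] +
                                sum(x[i, ] * model$folds[[f]]$coefs[-1]))
      p_y <- if (y == "case") p_case else 1 - p_case
      a <- if (model$nonconformity == "prob") 1 - p_y else (1 - p_y) - p_y
      cal <- model$folds[[f]]$calib[[y]]
      p_folds[f] <- (sum(cal >= a) + 1) / (length(cal) + 1)
    }
    out[i] <- mean(p_folds)
  }
  out
}

# hand-built single-fold MCCP model with known calibration scores
manual_mccp <- function(calib_case, calib_control,
                        coefs = c(0, 1, 0, 0), k = 1L) {
  structure(list(
    k = k,
    folds = rep(list(list(coefs = coefs,
                          calib = list(case = sort(calib_case),
                                       control = sort(calib_control)))), k),
    centre = c(prs = 0, age = 0, sex = 0),
    spread = c(prs = 1, age = 1, sex = 1),
    lambda = 0, nonconformity = "prob",
    classes = c("case", "control"), seed = 0L,
    n_train = length(calib_case) + length(calib_control),
    class_counts = c(length(calib_case), length(calib_control))),
    class = "mccp")
}

# small labelled feature set with a clean PRS signal, for conformal tests
toy_training <- function(n = 120L, seed = 7L) {
  withr::with_seed(seed, {
    status <- rep(c("case", "control"), length.out = n)
    prs <- stats::rnorm(n, mean = ifelse(status == "case", 38, 32), sd = 4)
    data.frame(prs = prs,
               age = stats::runif(n, 50, 95),
               sex = sample(c("F", "M"), n, replace = TRUE),
               status = status, stringsAsFactors = FALSE)
  })
}

# fit-and-predict on the IAMDGC-like preset for one seed
preset_run <- function(seed, epsilon = 0.2, k = 5L) {
  pre <- make_iamdgc_preset(seed = seed)
  tr <- compute_prs(pre$train$dosages, pre$panel)
  va <- compute_prs(pre$valid$dosages, pre$panel)
  feat_tr <- data.frame(prs = tr$prs, age = pre$train$phenotypes$age,
                        sex = pre$train$phenotypes$sex)
  feat_va <- data.frame(prs = va$prs, age = pre$valid$phenotypes$age,
                        sex = pre$valid$phenotypes$sex)
  model <- fit_mccp(feat_tr, pre$train$phenotypes$status, k = k, seed = seed)
  pred <- predict(model, feat_va, epsilon = epsilon)
  list(preset = pre, model = model, pred = pred,
       truth = pre$valid$phenotypes$status,
       feat_va = feat_va, prs_va = va, prs_tr = tr)
}
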