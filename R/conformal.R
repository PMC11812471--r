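# -- Mondrian cross-conformal prediction -------------------------------------
#
# Disease status is predicted from (PRS, age, sex) with k-fold Mondrian
# cross-conformal prediction: the taxonomy is the true class label, so
# calibration scores are kept per class and the conformal guarantee is
# class-conditional — each class's error rate is controlled at the chosen
# significance level regardless of class balance (and hence robust to the
# case/control ratio differing between training and deployment).
#
# Underlying classifier: L2-regularized logistic regression on
# standardized features. Nonconformity alpha(x, y) = 1 - P_hat(y | x)
# (probability score) or the margin P_hat(other | x) - P_hat(y | x).
# Per-fold p-values use the standard conformal count
#   p = (#{calibration scores of class y >= alpha} + 1) / (n_cal_y + 1)
# and folds are combined by arithmetic mean.

MCCP_CLASSES <- c("case", "control")

encode_features <- function(features) {
  need <- c("prs", "age", "sex")
  miss <- setdiff(need, names(features))
  if (length(miss) > 0L) {
    stop("feature table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sex <- features$sex
  sex_num <- if (is.numeric(sex)) as.numeric(sex) else as.numeric(sex == "F")
  cbind(prs = as.numeric(features$prs), age = as.numeric(features$age),
        sex = sex_num)
}

check_labels <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), MCCP_CLASSES)
  if (length(bad) > 0L) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         " (expected 'case'/'control')", call. = FALSE)
  }
  labels
}

fit_ridge_logistic <- function(x, y01, lambda) {
  fit <- glmnet::glmnet(x, y01, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  as.numeric(stats::coef(fit))  # (intercept, prs, age, sex)
}

prob_case <- function(coefs, x) {
  as.vector(stats::plogis(coefs[1L] + x %*% coefs[-1L]))
}

nonconformity_scores <- function(p_case, labels, score = c("prob", "margin")) {
  score <- match.arg(score)
  p_true <- ifelse(labels == "case", p_case, 1 - p_case)
  switch(score,
         prob = 1 - p_true,
         margin = (1 - p_true) - p_true)
}

#' Fit a Mondrian cross-conformal disease-status model
#'
#' Splits the training data into `k` stratified folds. For each fold, an
#' L2-regularized logistic classifier is fitted on the other `k - 1` folds
#' and the held-out fold supplies calibration nonconformity scores, stored
#' per true class (the Mondrian taxonomy). Features are standardized with
#' constants computed on the full training set.
#'
#' @param features data.frame with columns `prs`, `age`, `sex` (`"F"`/`"M"`
#'   or numeric 0/1 with female = 1).
#' @param labels character vector of `"case"`/`"control"`, aligned to
#'   `features`.
#' @param k number of folds (>= 2; default 5).
#' @param seed integer seed controlling the fold assignment.
#' @param lambda ridge penalty of the underlying classifier (default 1e-3,
#'   i.e. weak regularization on standardized features).
#' @param nonconformity `"prob"` (alpha = 1 - P(y|x), default) or
#'   `"margin"`.
#' @return An object of class `mccp`: fold coefficient vectors, per-fold
#'   per-class calibration score multisets, scaling constants, seed.
#' @export
fit_mccp <- function(features, labels, k = 5L, seed = 1L, lambda = 1e-3,
                     nonconformity = c("prob", "margin")) {
  nonconformity <- match.arg(nonconformity)
  labels <- check_labels(labels)
  x_raw <- encode_features(features)
  n <- nrow(x_raw)
  if (length(labels) != n) {
    stop("features and labels have different lengths", call. = FALSE)
  }
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  counts <- table(factor(labels, levels = MCCP_CLASSES))
  if (any(counts < k)) {
    stop("each class needs at least k members so every calibration fold ",
         "contains both classes; got ",
         paste(names(counts), counts, sep = "=", collapse = ", "),
         call. = FALSE)
  }
  centre <- colMeans(x_raw)
  spread <- apply(x_raw, 2L, stats::sd)
  spread[spread == 0] <- 1
  x <- sweep(sweep(x_raw, 2L, centre), 2L, spread, "/")
  fold <- integer(n)
  fold <- withr::with_seed(seed, {
    f <- integer(n)
    for (cl in MCCP_CLASSES) {
      idx <- which(labels == cl)
      f[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    f
  })
  y01 <- as.integer(labels == "case")
  folds <- lapply(seq_len(k), function(i) {
    tr <- fold != i
    coefs <- fit_ridge_logistic(x[tr, , drop = FALSE], y01[tr], lambda)
    cal <- which(!tr)
    p_cal <- prob_case(coefs, x[cal, , drop = FALSE])
    alpha <- nonconformity_scores(p_cal, labels[cal], nonconformity)
    list(coefs = coefs,
         calib = list(case = sort(alpha[labels[cal] == "case"]),
                      control = sort(alpha[labels[cal] == "control"])))
  })
  structure(list(k = k, folds = folds,
                 centre = centre, spread = spread,
                 lambda = lambda, nonconformity = nonconformity,
                 classes = MCCP_CLASSES, seed = seed,
                 n_train = n,
                 class_counts = as.integer(counts)),
            class = "mccp")
}

#' @export
print.mccp <- function(x, ...) {
  cat(sprintf(
    "mccp: %d-fold Mondrian cross-conformal model (%s nonconformity)\n",
    x$k, x$nonconformity))
  cat(sprintf("trained on %d individuals (case=%d, control=%d), seed %d\n",
              x$n_train, x$class_counts[1L], x$class_counts[2L], x$seed))
  invisible(x)
}

scale_features <- function(model, features) {
  x <- encode_features(features)
  sweep(sweep(x, 2L, model$centre), 2L, model$spread, "/")
}

fold_p_values <- function(model, alpha, class) {
  # alpha: n x k matrix of per-fold nonconformity scores;
  # mean over folds of (#\{calibration scores >= alpha\} + 1) / (n + 1)
  p <- matrix(0, nrow = nrow(alpha), ncol = model$k)
  for (i in seq_len(model$k)) {
    s <- model$folds[[i]]$calib[[class]]
    n_cal <- length(s)
    ge <- n_cal - findInterval(alpha[, i], s, left.open = TRUE)
    p[, i] <- (ge + 1) / (n_cal + 1)
  }
  rowMeans(p)
}

fold_alphas <- function(model, x, class) {
  a <- vapply(seq_len(model$k), function(i) {
    p_case <- prob_case(model$folds[[i]]$coefs, x)
    p_y <- if (class == "case") p_case else 1 - p_case
    if (model$nonconformity == "prob") 1 - p_y else (1 - p_y) - p_y
  }, numeric(nrow(x)))
  matrix(a, nrow = nrow(x), ncol = model$k)
}

#' Conformal p-value for a hypothesized label
#'
#' For each fold, the nonconformity of `x` under label `y` is ranked
#' against that fold's calibration scores of class `y`:
#' `p_fold = (#\{scores >= alpha\} + 1) / (n_cal + 1)`; the returned
#' p-value is the arithmetic mean over folds and always lies in (0, 1].
#'
#' @param model a fitted `mccp` model.
#' @param features data.frame with columns `prs`, `age`, `sex` (one row
#'   per individual).
#' @param y hypothesized label, `"case"` or `"control"`.
#' @return numeric vector of conformal p-values.
#' @export
conformal_p <- function(model, features, y) {
  stopifnot(inherits(model, "mccp"))
  y <- match.arg(y, MCCP_CLASSES)
  x <- scale_features(model, features)
  fold_p_values(model, fold_alphas(model, x, y), y)
}

#' Predict disease status with conformal guarantees
#'
#' Returns, per individual, the per-class conformal p-values, the
#' prediction set at significance `epsilon` (every label whose p-value
#' exceeds `epsilon`; possibly empty or both), a point label (the label
#' with the larger p-value; exact ties give `"undecided"`), and
#' `prob_affected`, the underlying classifiers' estimated P(case | x)
#' averaged over folds.
#'
#' @param object a fitted `mccp` model.
#' @param newdata data.frame with columns `prs`, `age`, `sex` (and
#'   optionally `id`, propagated to the output).
#' @param epsilon significance level in (0, 1); default 0.2.
#' @param ... unused.
#' @return data.frame of class `conformal_prediction`: id, p_case,
#'   p_control, label_set (comma-separated, `""` if empty), point_label,
#'   prob_affected, epsilon.
#' @export
predict.mccp <- function(object, newdata, epsilon = 0.2, ...) {
  if (epsilon <= 0 || epsilon >= 1) {
    stop("epsilon must lie strictly between 0 and 1", call. = FALSE)
  }
  ids <- if ("id" %in% names(newdata)) as.character(newdata$id)
         else sprintf("obs%05d", seq_len(nrow(newdata)))
  x <- scale_features(object, newdata)
  p_case <- fold_p_values(object, fold_alphas(object, x, "case"), "case")
  p_control <- fold_p_values(object, fold_alphas(object, x, "control"),
                             "control")
  prob_affected <- rowMeans(matrix(vapply(seq_len(object$k), function(i) {
    prob_case(object$folds[[i]]$coefs, x)
  }, numeric(nrow(x))), nrow = nrow(x)))
  in_set <- cbind(case = p_case > epsilon, control = p_control > epsilon)
  label_set <- apply(in_set, 1L, function(r) {
    paste(MCCP_CLASSES[r], collapse = ",")
  })
  point_label <- ifelse(p_case > p_control, "case",
                        ifelse(p_control > p_case, "control", "undecided"))
  structure(data.frame(id = ids, p_case = p_case, p_control = p_control,
                       label_set = label_set, point_label = point_label,
                       prob_affected = prob_affected, epsilon = epsilon,
                       stringsAsFactors = FALSE),
            class = c("conformal_prediction", "data.frame"))
}

#' Serialize a fitted MCCP model to JSON
#'
#' Versioned plain-text serialization: fold coefficients, scaling
#' constants, calibration score arrays, seed and configuration.
#'
#' @param model a fitted `mccp` model.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mccp <- function(model, path) {
  stopifnot(inherits(model, "mccp"))
  doc <- list(format = "amdprs-mccp", version = 1L,
              k = model$k, lambda = model$lambda,
              nonconformity = model$nonconformity,
              classes = model$classes, seed = model$seed,
              n_train = model$n_train, class_counts = model$class_counts,
              centre = as.list(model$centre), spread = as.list(model$spread),
              folds = lapply(model$folds, function(f) {
                list(coefs = f$coefs, calib = f$calib)
              }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized MCCP model
#'
#' @param path path to a JSON file written by [write_mccp()].
#' @return An `mccp` model.
#' @export
read_mccp <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) NULL)
  if (!identical(doc$format, "amdprs-mccp")) {
    stop("not an amdprs MCCP model file: ", path, call. = FALSE)
  }
  folds <- lapply(seq_len(doc$k), function(i) {
    f <- if (is.data.frame(doc$folds)) {
      list(coefs = doc$folds$coefs[[i]], calib = list(
        case = doc$folds$calib$case[[i]],
        control = doc$folds$calib$control[[i]]))
    } else doc$folds[[i]]
    list(coefs = as.numeric(f$coefs),
         calib = list(case = as.numeric(f$calib$case),
                      control = as.numeric(f$calib$control)))
  })
  structure(list(k = doc$k, folds = folds,
                 centre = stats::setNames(as.numeric(doc$centre),
                                          names(doc$centre)),
                 spread = stats::setNames(as.numeric(doc$spread),
                                          names(doc$spread)),
                 lambda = doc$lambda, nonconformity = doc$nonconformity,
                 classes = doc$classes, seed = doc$seed,
                 n_train = doc$n_train,
                 class_counts = as.integer(doc$class_counts)),
            class = "mccp")
}

#' Write conformal predictions to TSV
#'
#' @param pred a `conformal_prediction` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pred, path) {
  utils::write.table(as.data.frame(pred), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
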