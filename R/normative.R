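# Control-referenced normative modelling: per feature, an ordinary
# least-squares fit (Gaussian identity-link GLM) of the feature on age and
# sex in the control cohort. Patient deviations are expressed as residuals
# standardized by the control residual mean and SD (Z-scores). Many
# features share one design matrix, so all fits are a single QR solve.

#' Fit per-feature normative models on controls
#'
#' Fits `feature ~ age + sex` by ordinary least squares, independently per
#' feature, and stores for each feature the coefficients and the control
#' residual mean and SD used later for Z-scoring. Sex is coded with
#' `female` as baseline. Optionally adds a quadratic age term.
#'
#' @param features Numeric matrix (controls x features) or data frame;
#'   column names identify features.
#' @param ages Numeric vector of ages in years, one per control.
#' @param sexes Character vector, `"male"`/`"female"`, one per control.
#' @param age2 Add an `age^2` term (default `FALSE`).
#' @return A `normative_model`: list with `coefficients`
#'   (terms x features), `residual_mean`, `residual_sd`, `features`,
#'   `age_range`, `terms`.
#' @export
fit_normative_model <- function(features, ages, sexes, age2 = FALSE) {
  y <- as.matrix(features)
  if (is.null(colnames(y)))
    colnames(y) <- sprintf("feature_%d", seq_len(ncol(y)))
  n <- nrow(y)
  if (length(ages) != n || length(sexes) != n)
    stop("ages/sexes must match the number of control rows", call. = FALSE)
  if (!all(sexes %in% c("male", "female")))
    stop("sex must be 'male' or 'female'", call. = FALSE)
  if (length(unique(sexes)) < 2L)
    stop("degenerate design: only one sex represented in controls",
         call. = FALSE)
  x <- cbind(intercept = 1, age = ages, sex_male = as.numeric(sexes == "male"))
  if (age2) x <- cbind(x, age2 = ages^2)
  if (n < ncol(x) + 3L)
    stop("too few controls: need at least ", ncol(x) + 3L, call. = FALSE)
  qrx <- qr(x)
  if (qrx$rank < ncol(x))
    stop("degenerate design: rank-deficient (constant age?)", call. = FALSE)
  beta <- qr.coef(qrx, y)
  resid <- y - x %*% beta
  res_sd <- apply(resid, 2L, sd)
  if (any(res_sd <= .Machine$double.eps^0.5 * pmax(1, apply(y, 2, sd))))
    stop("feature constant in controls (zero residual SD): ",
         paste(colnames(y)[res_sd <= .Machine$double.eps^0.5 *
                             pmax(1, apply(y, 2, sd))][1:3], collapse = ", "),
         call. = FALSE)
  structure(list(coefficients = beta,
                 residual_mean = colMeans(resid),
                 residual_sd = res_sd,
                 features = colnames(y),
                 age_range = range(ages),
                 terms = colnames(x)),
            class = "normative_model")
}

#' Predicted feature values for a subject
#'
#' @param model A `normative_model`.
#' @param age Age in years.
#' @param sex `"male"` or `"female"`.
#' @return Named numeric vector of model predictions, one per feature.
#' @export
predict_normative <- function(model, age, sex) {
  stopifnot(inherits(model, "normative_model"))
  x <- c(1, age, as.numeric(sex == "male"))
  if ("age2" %in% model$terms) x <- c(x, age^2)
  drop(x %*% model$coefficients)
}

#' Age/sex-adjusted residuals for a subject's feature vector
#'
#' @inheritParams predict_normative
#' @param values Named or ordered numeric vector of feature values matching
#'   the model's features.
#' @param warn_extrapolation Warn when `age` falls outside the control age
#'   range (the model extrapolates rather than refusing).
#' @return Numeric vector of residuals (observed minus predicted).
#' @export
residuals_normative <- function(model, values, age, sex,
                                warn_extrapolation = TRUE) {
  if (length(values) != length(model$features))
    stop("value vector does not match model features", call. = FALSE)
  if (warn_extrapolation &&
      (age < model$age_range[1L] || age > model$age_range[2L]))
    warning(sprintf("age %.2f outside control range [%.2f, %.2f]: extrapolating",
                    age, model$age_range[1L], model$age_range[2L]),
            call. = FALSE)
  as.numeric(values) - predict_normative(model, age, sex)
}

#' Z-score a subject's feature vector against the normative model
#'
#' `z = ((value - predicted) - control_residual_mean) / control_residual_sd`
#' per feature, so control training Z-scores have sample mean 0 and SD 1
#' by construction.
#'
#' @inheritParams residuals_normative
#' @return Numeric vector of Z-scores, one per feature.
#' @export
zscore_features <- function(model, values, age, sex,
                            warn_extrapolation = TRUE) {
  r <- residuals_normative(model, values, age, sex, warn_extrapolation)
  (r - model$residual_mean) / model$residual_sd
}

#' Z-score a single feature value
#'
#' Scalar convenience wrapper around [zscore_features()].
#'
#' @inheritParams predict_normative
#' @param feature Feature name (or index) in the model.
#' @param value Observed value.
#' @return Scalar Z-score.
#' @export
zscore_patient <- function(model, feature, value, age, sex) {
  idx <- if (is.character(feature)) match(feature, model$features)
         else as.integer(feature)
  if (is.na(idx)) stop("unknown feature: ", feature, call. = FALSE)
  x <- c(1, age, as.numeric(sex == "male"))
  if ("age2" %in% model$terms) x <- c(x, age^2)
  pred <- drop(x %*% model$coefficients[, idx])
  unname(((value - pred) - model$residual_mean[idx]) / model$residual_sd[idx])
}

#' Abnormal-node burden from a Z-score vector
#'
#' Counts entries strictly outside `±threshold`, in total and per
#' direction.
#'
#' @param z Finite numeric vector of Z-scores (named by parcel, ideally).
#' @param threshold Positive threshold (default 2).
#' @return List with `n_abnormal_total`, `n_above`, `n_below`, `threshold`.
#' @export
abnormal_burden <- function(z, threshold = 2) {
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  bad <- !is.finite(z)
  if (any(bad))
    stop("non-finite Z-scores at: ",
         paste(if (!is.null(names(z))) names(z)[bad] else which(bad),
               collapse = ", "), call. = FALSE)
  n_above <- sum(z > threshold)
  n_below <- sum(z < -threshold)
  list(n_abnormal_total = n_above + n_below, n_above = n_above,
       n_below = n_below, threshold = threshold)
}

#' Serialize a normative model to JSON
#' @param model A `normative_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_normative_model <- function(model, path) {
  jsonlite::write_json(
    list(terms = model$terms, features = model$features,
         coefficients = as.data.frame(model$coefficients),
         residual_mean = model$residual_mean,
         residual_sd = model$residual_sd,
         age_range = model$age_range),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
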