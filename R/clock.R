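#' Fit an elastic-net Cox proportional-hazards model
#'
#' Minimizes the negative log partial likelihood (Breslow ties) plus the
#' elastic-net penalty. The penalty strength is chosen at the minimum of
#' `n_folds`-fold cross-validated partial-likelihood deviance with a seeded
#' fold assignment. Covariates are standardized internally; coefficients are
#' reported on the original scale, with exact zeros kept so the returned
#' coefficient map covers every candidate covariate.
#'
#' @param X Numeric matrix (or data.frame) of covariates with column names.
#' @param time Follow-up times in years (> 0).
#' @param event 0/1 event indicator (1 = death).
#' @param spec An [enet_spec()].
#' @return A list of class `cox_fit` with elements `coefficients`, `lambda`,
#'   `alpha`, `ties_method` and `converged`.
#' @export
fit_cox_elastic_net <- function(X, time, event, spec = enet_spec()) {
  stopifnot(inherits(spec, "enet_spec"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("covariates must be named")
  if (anyNA(X) || any(!is.finite(X))) stop("covariates contain missing or non-finite values")
  if (length(time) != nrow(X) || length(event) != nrow(X)) stop("length mismatch")
  if (any(time <= 0)) stop("times must be positive")
  n_events <- sum(event == 1)
  if (n_events == 0) stop("no events; cannot fit a Cox model")
  if (n_events < 20) {
    warning(sprintf("only %d events; penalized Cox fit may be unstable", n_events))
  }
  y <- survival::Surv(time, event)
  foldid <- make_folds(nrow(X), spec$n_folds, spec$seed)
  cv <- glmnet::cv.glmnet(X, y, family = "cox", alpha = spec$alpha,
                          lambda = spec$lambda_grid, foldid = foldid,
                          type.measure = "deviance",
                          standardize = spec$standardize)
  b <- as.numeric(stats::coef(cv, s = "lambda.min"))
  names(b) <- colnames(X)
  structure(list(coefficients = b, lambda = cv$lambda.min, alpha = spec$alpha,
                 ties_method = "breslow", converged = TRUE),
            class = "cox_fit")
}

# Unpenalized-limit Cox elastic net at a fixed lambda (no CV); used where the
# penalty value itself is part of the experiment.
cox_enet_at <- function(X, time, event, alpha, lambda, standardize = TRUE) {
  X <- as.matrix(X)
  y <- survival::Surv(time, event)
  lam <- sort(unique(c(lambda, lambda + c(4, 2, 1, 0.5) * max(lambda, 0.1))),
              decreasing = TRUE)
  fit <- glmnet::glmnet(X, y, family = "cox", alpha = alpha, lambda = lam,
                        standardize = standardize, thresh = 1e-12, maxit = 1e6)
  b <- as.numeric(stats::coef(fit, s = lambda, exact = FALSE))
  names(b) <- colnames(X)
  b
}

#' Cox linear predictor
#'
#' Computes `X beta` per sample for a [clock_model()] or `cox_fit` (no
#' intercept; the Cox model has none). Every model covariate must be present
#' as a column of `X`.
#'
#' @param model A [clock_model()] or `cox_fit`.
#' @param X `data.frame` or matrix whose columns include the model covariates.
#' @return Numeric vector of linear predictor values.
#' @export
linear_predictor <- function(model, X) {
  beta <- model$coefficients
  missing <- setdiff(names(beta), colnames(as.data.frame(X)))
  if (length(missing) > 0) {
    stop("covariate(s) missing from X: ", paste(missing, collapse = ", "))
  }
  Xm <- as.matrix(as.data.frame(X)[, names(beta), drop = FALSE])
  if (!is.numeric(Xm)) stop("covariates must be numeric")
  as.numeric(Xm %*% beta)
}

#' Calibrate a Cox linear predictor into units of years
#'
#' Chooses the affine transform whose output has the same mean and variance
#' as chronological age in the training data: `slope = sd(age) / sd(lp)`,
#' `intercept = mean(age) - slope * mean(lp)` (sample SDs, n-1 denominator).
#'
#' @param lp_train Linear predictor values on the training samples.
#' @param age_train Chronological ages (years) of the same samples.
#' @return A list of class `calibration` with `intercept`, `slope`,
#'   `train_age_mean`, `train_age_sd`.
#' @export
calibrate_to_age <- function(lp_train, age_train) {
  if (length(lp_train) != length(age_train)) stop("length mismatch")
  keep <- !is.na(lp_train) & !is.na(age_train)
  lp <- lp_train[keep]; age <- age_train[keep]
  if (stats::sd(lp) == 0) stop("linear predictor has zero variance")
  if (stats::sd(age) == 0) stop("age has zero variance")
  slope <- stats::sd(age) / stats::sd(lp)
  intercept <- mean(age) - slope * mean(lp)
  structure(list(intercept = intercept, slope = slope,
                 train_age_mean = mean(age), train_age_sd = stats::sd(age)),
            class = "calibration")
}

#' Apply a calibrated clock
#'
#' Returns `calib_intercept + calib_slope * linear_predictor(model, X)`:
#' the DNAm mortality-clock estimate in units of years.
#'
#' @inheritParams linear_predictor
#' @param model A [clock_model()].
#' @return Numeric vector of clock values (years).
#' @export
apply_clock <- function(model, X) {
  stopifnot(inherits(model, "clock_model"))
  model$calib_intercept + model$calib_slope * linear_predictor(model, X)
}

#' Train and calibrate a mortality clock in one step
#'
#' Convenience wrapper: fits [fit_cox_elastic_net()] on the supplied
#' covariates, then calibrates the training linear predictor to the supplied
#' ages with [calibrate_to_age()].
#'
#' @inheritParams fit_cox_elastic_net
#' @param age Chronological ages (years) of the training samples.
#' @return A [clock_model()]; the underlying `cox_fit` and `calibration` are
#'   attached as attributes `"cox_fit"` and `"calibration"`.
#' @export
train_clock <- function(X, time, event, age, spec = enet_spec()) {
  fit <- fit_cox_elastic_net(X, time, event, spec)
  lp <- linear_predictor(fit, X)
  cal <- calibrate_to_age(lp, age)
  model <- clock_model(covariate_names = names(fit$coefficients),
                       coefficients = fit$coefficients,
                       calib_intercept = cal$intercept,
                       calib_slope = cal$slope)
  attr(model, "cox_fit") <- fit
  attr(model, "calibration") <- cal
  model
}

#' The published GrimAge2 coefficient model
#'
#' Returns the 12-covariate mortality clock as published: ten DNAm surrogate
#' biomarkers (ADM, B2M, cystatin C, GDF-15, leptin, logCRP, logA1C, PAI-1,
#' TIMP-1 and smoking pack-years), chronological age and female sex, with the
#' printed Cox coefficients and the year-scale calibration
#' `years = -61.03936 + 8.271105 * lp`. Users supply the ten DNAm component
#' values (the per-CpG weights behind them were not published) plus `Age` and
#' `Female` as columns when applying the model.
#'
#' @return A [clock_model()] with 12 covariates.
#' @examples
#' m <- grimage2_model()
#' m$coefficients[["Female"]]
#' @export
grimage2_model <- function() {
  clock_model(
    covariate_names = c("DNAmADM", "DNAmB2M", "DNAmCystatinC", "DNAmGDF15",
                        "DNAmLeptin", "DNAmlogCRP", "DNAmlogA1C", "DNAmPAI1",
                        "DNAmTIMP1", "DNAmPACKYRS", "Age", "Female"),
    coefficients = c(DNAmADM = 0.00609,
                     DNAmB2M = 2.79e-07,
                     DNAmCystatinC = 4.08e-06,
                     DNAmGDF15 = 0.00035,
                     DNAmLeptin = -2.03e-05,
                     DNAmlogCRP = 1.90266,
                     DNAmlogA1C = 0.40359,
                     DNAmPAI1 = 0.02941,
                     DNAmTIMP1 = 3.67e-06,
                     DNAmPACKYRS = 0.00014,
                     Age = 0.02676,
                     Female = -0.14212),
    calib_intercept = -61.03936,
    calib_slope = 8.271105)
}

#' Published training winsorization bounds for CRP and A1C
#'
#' The raw-scale ranges of the winsorized training analytes: C-reactive
#' protein in mg/L and hemoglobin A1C in percent. Use with [apply_bounds()]
#' to clamp new analyte measurements into the training range.
#'
#' @return Named list of `c(lo, hi)` bounds.
#' @examples
#' b <- grimage2_winsor_bounds()
#' apply_bounds(100, b$CRP[1], b$CRP[2])  # 54.01
#' @export
grimage2_winsor_bounds <- function() {
  list(CRP = c(0.14, 54.01), A1C = c(4.7, 10))
}

#' Age acceleration: residualize a DNAm measure on chronological age
#'
#' Ordinary least-squares residuals of `dnam ~ 1 + age`. A positive value
#' means the DNAm measure is higher than expected for the chronological age.
#' Residuals have mean zero and zero sample covariance with age.
#'
#' @param dnam Numeric vector of DNAm clock or surrogate values.
#' @param age Chronological ages (years), same length; must vary.
#' @return Numeric vector of residuals (years, for a year-scaled clock).
#' @export
age_acceleration <- function(dnam, age) {
  if (length(dnam) != length(age)) stop("length mismatch")
  if (sum(stats::complete.cases(dnam, age)) < 3) stop("need at least 3 paired values")
  if (stats::sd(age, na.rm = TRUE) == 0) stop("age is constant; cannot residualize")
  stats::resid(stats::lm(dnam ~ age, na.action = stats::na.exclude))
}

#' Cox deviance residuals from a fixed linear predictor
#'
#' Computes the "excess mortality risk" score: the Breslow cumulative
#' baseline hazard is estimated from `(time, event)` with risk scores
#' `exp(lp)`, giving martingale residuals
#' `m_i = event_i - Lambda0(t_i) * exp(lp_i)` (which sum to zero), and the
#' signed square-root deviance transform
#' `d_i = sign(m_i) * sqrt(-2 * (m_i + event_i * log(event_i - m_i)))`.
#'
#' Unlike `residuals()` on a fitted Cox model, the linear predictor here is
#' supplied, so a clock trained elsewhere can be scored on a test cohort.
#'
#' @param time Follow-up times (> 0).
#' @param event 0/1 event indicator.
#' @param lp Linear predictor (log relative hazard), same length.
#' @return Numeric vector of deviance residuals; the martingale residuals
#'   are attached as attribute `"martingale"`. With no events at all the
#'   baseline hazard is identically zero and a zero vector is returned with
#'   a warning.
#' @export
mortality_res <- function(time, event, lp) {
  n <- length(time)
  if (length(event) != n || length(lp) != n) stop("length mismatch")
  if (any(time <= 0)) stop("times must be positive")
  if (all(event == 0)) {
    warning("no events: baseline hazard is zero, all residuals are 0")
    out <- rep(0, n)
    attr(out, "martingale") <- rep(0, n)
    return(out)
  }
  risk <- exp(lp)
  etimes <- sort(unique(time[event == 1]))
  d <- vapply(etimes, function(t) sum(event == 1 & time == t), numeric(1))
  denom <- vapply(etimes, function(t) sum(risk[time >= t]), numeric(1))
  H0 <- cumsum(d / denom)                      # Breslow cumulative baseline hazard
  idx <- findInterval(time, etimes)            # last event time <= t_i
  Lam <- c(0, H0)[idx + 1L]
  mart <- event - Lam * risk
  inner <- mart + ifelse(event == 1, log(event - mart), 0)
  dev <- sign(mart) * sqrt(pmax(-2 * inner, 0))
  attr(dev, "martingale") <- mart
  dev
}
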