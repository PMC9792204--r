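#' Cox association of an exposure with a time-to-event outcome
#'
#' Fits a proportional-hazards model of the outcome on the exposure plus
#' adjustment covariates and returns the log hazard ratio per unit exposure
#' with its standard error. When `cluster` labels are supplied (pedigrees or
#' repeated measures), the Huber sandwich cluster-robust standard error is
#' reported instead of the model-based one.
#'
#' @param time Follow-up times (> 0).
#' @param event 0/1 event indicator (>= 10 events required).
#' @param exposure Numeric exposure of interest.
#' @param covariates Optional `data.frame` of adjustment covariates.
#' @param cluster Optional vector of cluster labels.
#' @param label Stratum label for the result.
#' @return A [stratum_association()] of kind `"cox"`; the hazard ratio
#'   `exp(estimate)` is attached as attribute `"hr"`.
#' @export
cox_association <- function(time, event, exposure, covariates = NULL,
                            cluster = NULL, label = "all") {
  if (sum(event == 1) < 10) stop("need at least 10 events")
  dat <- data.frame(.time = time, .event = event, .exposure = exposure)
  rhs <- ".exposure"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    dat <- cbind(dat, covariates)
    rhs <- paste(c(rhs, names(covariates)), collapse = " + ")
  }
  if (!is.null(cluster)) dat$.cluster <- cluster
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs))
  fit <- tryCatch(
    if (is.null(cluster)) {
      survival::coxph(fml, data = dat, ties = "breslow")
    } else {
      survival::coxph(fml, data = dat, ties = "breslow", cluster = .cluster,
                      robust = TRUE)
    },
    warning = function(w) {
      if (grepl("converge|infinite|Loglik", conditionMessage(w))) {
        stop("Cox model did not converge cleanly: ", conditionMessage(w))
      }
      suppressWarnings(if (is.null(cluster)) {
        survival::coxph(fml, data = dat, ties = "breslow")
      } else {
        survival::coxph(fml, data = dat, ties = "breslow", cluster = .cluster,
                        robust = TRUE)
      })
    })
  sm <- summary(fit)$coefficients
  est <- sm[".exposure", "coef"]
  se <- if (is.null(cluster)) sm[".exposure", "se(coef)"] else sm[".exposure", "robust se"]
  out <- stratum_association(label, est, se, n = nrow(dat), kind = "cox")
  attr(out, "hr") <- exp(est)
  out
}

#' Logistic association of an exposure with a binary outcome
#'
#' Returns the log odds ratio per unit exposure with its standard error from
#' a logistic regression adjusted for optional covariates.
#'
#' @param outcome 0/1 outcome; both classes must be present.
#' @param exposure Numeric exposure of interest; must vary.
#' @param covariates Optional `data.frame` of adjustment covariates.
#' @param label Stratum label for the result.
#' @return A [stratum_association()] of kind `"logistic"`; the odds ratio
#'   `exp(estimate)` is attached as attribute `"or"`.
#' @export
logistic_association <- function(outcome, exposure, covariates = NULL,
                                 label = "all") {
  if (length(unique(stats::na.omit(outcome))) < 2) {
    stop("outcome has a single class; odds ratio undefined")
  }
  if (stats::sd(exposure, na.rm = TRUE) == 0) {
    stop("exposure is constant; effect is unidentifiable (infinite se)")
  }
  dat <- data.frame(.outcome = outcome, .exposure = exposure)
  rhs <- ".exposure"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    dat <- cbind(dat, covariates)
    rhs <- paste(c(rhs, names(covariates)), collapse = " + ")
  }
  fml <- stats::as.formula(paste(".outcome ~", rhs))
  fit <- stats::glm(fml, data = dat, family = stats::binomial())
  sm <- summary(fit)$coefficients
  est <- sm[".exposure", "Estimate"]
  se <- sm[".exposure", "Std. Error"]
  if (!is.finite(se) || se > 100) {
    stop("standard error is effectively infinite (separation?)")
  }
  out <- stratum_association(label, est, se, n = nrow(dat), kind = "logistic")
  attr(out, "or") <- exp(est)
  out
}

#' Comorbidity index: count of age-related conditions
#'
#' Row-wise sum of 0/1 condition indicators, with missing indicators
#' excluded from the sum; the number of non-missing indicators contributing
#' to each sum is reported alongside.
#'
#' @param conditions `data.frame` or matrix of 0/1 (or `NA`) indicator
#'   columns, one per age-related condition.
#' @return A `data.frame` with `index` (the count) and `n_conditions` (how
#'   many indicators were non-missing for that sample).
#' @export
comorbidity_index <- function(conditions) {
  x <- as.matrix(conditions)
  bad <- which(!is.na(x) & !(x %in% c(0, 1)))
  if (length(bad) > 0) {
    stop("condition indicators must be 0/1 or missing; found ", x[bad[1]])
  }
  data.frame(index = as.integer(rowSums(x, na.rm = TRUE)),
             n_conditions = as.integer(rowSums(!is.na(x))))
}

#' HOMA-IR insulin-resistance score
#'
#' Homeostatic model assessment of insulin resistance:
#' `(FPI x FPG) / 22.5`, where FPI is fasting plasma insulin (mU/l) and FPG
#' is fasting plasma glucose (mmol/l). Higher scores indicate greater
#' insulin resistance.
#'
#' @param fpi Fasting plasma insulin, mU/l (>= 0).
#' @param fpg Fasting plasma glucose, mmol/l (>= 0).
#' @return Numeric score(s).
#' @examples
#' homa_ir(22.5, 1)  # 1
#' @export
homa_ir <- function(fpi, fpg) {
  if (any(fpi < 0, na.rm = TRUE) || any(fpg < 0, na.rm = TRUE)) {
    stop("fasting insulin and glucose must be non-negative")
  }
  fpi * fpg / 22.5
}
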