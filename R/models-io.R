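#' Construct a Stage-1 surrogate model
#'
#' Holds everything needed to apply a fitted DNAm surrogate of a plasma
#' analyte: per-CpG weights, age and sex weights, intercept, the winsorization
#' bounds learned on the training analyte, whether the analyte was
#' log-transformed, and the mean/SD of the in-sample predictions (used by
#' [scale_surrogate()] so one scaled unit equals one training SD).
#'
#' @param name Analyte name (e.g. `"CRP"`).
#' @param cpg_weights Named numeric vector of CpG weights (may be empty for
#'   an intercept-only model).
#' @param age_weight,female_weight,intercept Scalars.
#' @param winsor_lo,winsor_hi Optional training winsorization bounds.
#' @param log_transformed Was the analyte modeled on the natural-log scale?
#' @param train_mean,train_sd Mean and SD of in-sample predictions
#'   (`train_sd > 0`).
#' @param cpg_means Optional named vector of training mean beta values for
#'   the model CpGs, used to impute missing betas at prediction time.
#' @return An object of class `surrogate_model`.
#' @export
surrogate_model <- function(name, cpg_weights, age_weight, female_weight,
                            intercept, winsor_lo = NULL, winsor_hi = NULL,
                            log_transformed = FALSE, train_mean, train_sd,
                            cpg_means = NULL) {
  cpg_weights <- unlist(cpg_weights)
  if (length(cpg_weights) > 0 && is.null(names(cpg_weights))) {
    stop("cpg_weights must be named by CpG ID")
  }
  if (!is.finite(train_sd) || train_sd <= 0) stop("train_sd must be > 0")
  stopifnot(is.finite(age_weight), is.finite(female_weight), is.finite(intercept))
  structure(list(name = as.character(name),
                 cpg_weights = cpg_weights,
                 age_weight = as.numeric(age_weight),
                 female_weight = as.numeric(female_weight),
                 intercept = as.numeric(intercept),
                 winsor_lo = if (is.null(winsor_lo)) NULL else as.numeric(winsor_lo),
                 winsor_hi = if (is.null(winsor_hi)) NULL else as.numeric(winsor_hi),
                 log_transformed = isTRUE(log_transformed),
                 train_mean = as.numeric(train_mean),
                 train_sd = as.numeric(train_sd),
                 cpg_means = cpg_means),
            class = "surrogate_model")
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat(sprintf("<surrogate_model> DNAm%s%s: %d CpGs + age + sex; train mean %.4g, sd %.4g\n",
              if (x$log_transformed) "log" else "", x$name,
              length(x$cpg_weights), x$train_mean, x$train_sd))
  invisible(x)
}

#' Construct a Stage-2 mortality clock model
#'
#' A clock is an elastic-net Cox coefficient vector over named covariates
#' plus an affine calibration taking the Cox linear predictor (a log relative
#' hazard) into units of years.
#'
#' @param covariate_names Ordered character vector of covariate names.
#' @param coefficients Named numeric vector of Cox coefficients covering
#'   exactly `covariate_names`.
#' @param calib_intercept,calib_slope Calibration constants; `calib_slope > 0`.
#' @return An object of class `clock_model`.
#' @export
clock_model <- function(covariate_names, coefficients, calib_intercept,
                        calib_slope) {
  covariate_names <- as.character(covariate_names)
  coefficients <- unlist(coefficients)
  if (!setequal(names(coefficients), covariate_names) ||
      length(coefficients) != length(covariate_names)) {
    stop("coefficients must cover every covariate name exactly once")
  }
  if (!is.finite(calib_slope) || calib_slope <= 0) stop("calib_slope must be > 0")
  structure(list(covariate_names = covariate_names,
                 coefficients = coefficients[covariate_names],
                 calib_intercept = as.numeric(calib_intercept),
                 calib_slope = as.numeric(calib_slope)),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("<clock_model> %d covariates; years = %.5f + %.6f * lp\n",
              length(x$covariate_names), x$calib_intercept, x$calib_slope))
  invisible(x)
}

surrogate_required <- c("name", "cpg_weights", "age_weight", "female_weight",
                        "intercept", "log_transformed", "train_mean", "train_sd")
surrogate_optional <- c("winsor_lo", "winsor_hi", "cpg_means")
clock_required <- c("covariate_names", "coefficients", "calib_intercept",
                    "calib_slope")

#' Write a surrogate or clock model to JSON
#'
#' Models round-trip losslessly through a fixed JSON dialect: a `"type"`
#' discriminator (`"surrogate"` or `"clock"`) plus the model fields. Reals
#' are written at full precision.
#'
#' @param model A [surrogate_model()] or [clock_model()].
#' @param path Output path.
#' @seealso [read_model()]
#' @export
write_model <- function(model, path) {
  if (inherits(model, "surrogate_model")) {
    body <- unclass(model)
    body <- body[!vapply(body, is.null, logical(1))]
    # weight maps must stay JSON objects even at length 1 (auto_unbox would
    # otherwise drop the CpG name)
    for (f in c("cpg_weights", "cpg_means")) {
      if (!is.null(body[[f]])) body[[f]] <- as.list(body[[f]])
    }
    obj <- c(list(type = "surrogate"), body)
  } else if (inherits(model, "clock_model")) {
    obj <- c(list(type = "clock"), unclass(model))
    obj$coefficients <- as.list(obj$coefficients)
  } else {
    stop("model must be a surrogate_model or clock_model")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a surrogate or clock model from JSON
#'
#' Unknown fields produce a warning and are dropped; missing required fields
#' are an error; a file that is not valid JSON is a parse error.
#'
#' @param path Path to a model JSON written by [write_model()].
#' @return A [surrogate_model()] or [clock_model()].
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$type) || !obj$type %in% c("surrogate", "clock")) {
    stop("model file lacks a valid 'type' field ('surrogate' or 'clock')")
  }
  required <- if (obj$type == "surrogate") surrogate_required else clock_required
  optional <- if (obj$type == "surrogate") surrogate_optional else character(0)
  missing <- setdiff(required, names(obj))
  if (length(missing) > 0) {
    stop("model file missing required field(s): ", paste(missing, collapse = ", "))
  }
  unknown <- setdiff(names(obj), c("type", required, optional))
  if (length(unknown) > 0) {
    warning("ignoring unknown model field(s): ", paste(unknown, collapse = ", "))
  }
  if (obj$type == "surrogate") {
    surrogate_model(name = obj$name,
                    cpg_weights = unlist(obj$cpg_weights),
                    age_weight = obj$age_weight,
                    female_weight = obj$female_weight,
                    intercept = obj$intercept,
                    winsor_lo = obj$winsor_lo,
                    winsor_hi = obj$winsor_hi,
                    log_transformed = obj$log_transformed,
                    train_mean = obj$train_mean,
                    train_sd = obj$train_sd,
                    cpg_means = if (is.null(obj$cpg_means)) NULL else unlist(obj$cpg_means))
  } else {
    clock_model(covariate_names = obj$covariate_names,
                coefficients = unlist(obj$coefficients),
                calib_intercept = obj$calib_intercept,
                calib_slope = obj$calib_slope)
  }
}
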