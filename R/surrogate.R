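#' Elastic-net hyperparameter specification
#'
#' @param alpha Mixing parameter in \[0, 1\] between ridge (0) and lasso (1).
#'   Default 0.5, the usual convention for methylation clocks.
#' @param n_folds Number of cross-validation folds (>= 2); default 10.
#' @param lambda_grid Optional decreasing numeric vector of penalty values;
#'   `NULL` lets the solver construct its own path.
#' @param seed Integer seed controlling the fold assignment, so that
#'   cross-validation is fully reproducible.
#' @param standardize Standardize predictors internally before penalizing
#'   (coefficients are always reported on the original scale).
#' @return A list of class `enet_spec`.
#' @export
enet_spec <- function(alpha = 0.5, n_folds = 10, lambda_grid = NULL,
                      seed = 1L, standardize = TRUE) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (!is.null(lambda_grid) && any(lambda_grid <= 0)) stop("lambda_grid must be positive")
  structure(list(alpha = alpha, n_folds = as.integer(n_folds),
                 lambda_grid = lambda_grid, seed = as.integer(seed),
                 standardize = isTRUE(standardize)),
            class = "enet_spec")
}

# Deterministic near-equal-size fold assignment: shuffle once with the seed.
make_folds <- function(n, k, seed) {
  if (k > n) stop(sprintf("n_folds (%d) exceeds the number of samples (%d)", k, n))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

#' Winsorize the upper tail at a scaled-value threshold
#'
#' Extreme values are defined on the raw scale as those observations whose
#' scaled values (z-scores against the raw mean and SD) exceed `z_max`; they
#' are replaced by the largest observation whose scaled value is still
#' `<= z_max` (the raw value "closest to" the threshold from below). The
#' lower tail is left untouched; the returned `lo` is the observed minimum,
#' stored so prediction-time inputs can be clamped into the training range.
#'
#' @param x Numeric vector (>= 3 values).
#' @param z_max Threshold on the scaled values; default 6.
#' @return List with `x` (winsorized vector), `lo`, `hi`.
#' @examples
#' winsorize_scaled(c(1, 2, 3, 2, 1000))$hi
#' @export
winsorize_scaled <- function(x, z_max = 6) {
  obs <- x[!is.na(x)]
  if (length(obs) < 3) stop("need at least 3 values to winsorize")
  s <- stats::sd(obs)
  if (is.na(s) || s == 0) {
    return(list(x = x, lo = obs[1], hi = obs[1]))
  }
  z <- (obs - mean(obs)) / s
  hi <- max(obs[z <= z_max])
  x[!is.na(x) & x > hi] <- hi
  list(x = x, lo = min(obs), hi = hi)
}

#' Clamp values into stored winsorization bounds
#'
#' Re-applies training bounds at prediction time.
#'
#' @param x Numeric vector.
#' @param lo,hi Bounds with `lo <= hi`.
#' @return `pmin(pmax(x, lo), hi)`.
#' @examples
#' apply_bounds(100, 0.14, 54.01)  # published CRP bounds -> 54.01
#' @export
apply_bounds <- function(x, lo, hi) {
  if (lo > hi) stop("lo must not exceed hi")
  pmin(pmax(x, lo), hi)
}

#' Natural-log transform a positive vector
#'
#' @param x Positive numeric vector; names (sample IDs) are kept and used in
#'   error messages.
#' @return `log(x)` elementwise.
#' @export
log_transform <- function(x) {
  bad <- which(!is.na(x) & x <= 0)
  if (length(bad) > 0) {
    who <- if (!is.null(names(x))) names(x)[bad[1]] else paste("position", bad[1])
    stop(sprintf("log transform requires positive values; offending sample: %s (%g)",
                 who, x[bad[1]]))
  }
  log(x)
}

# Shared elastic-net gaussian solver; lambda may be 0 (unpenalized).
enet_gaussian <- function(X, y, alpha, lambda, standardize = TRUE) {
  fit <- glmnet::glmnet(X, y, family = "gaussian", alpha = alpha,
                        lambda = lambda, standardize = standardize,
                        thresh = 1e-12, maxit = 1e6)
  b <- as.numeric(stats::coef(fit, s = min(lambda)))
  names(b) <- c("(Intercept)", colnames(X))
  b
}

#' Fit a Stage-1 DNAm surrogate of a plasma analyte
#'
#' Regresses a (winsorized, log-transformed) plasma analyte on all CpG beta
#' values plus chronological age and sex with an elastic-net penalty. The
#' penalty strength is chosen at the minimum of `n_folds`-fold
#' cross-validated error with a seeded fold assignment, so fits are
#' reproducible. Age and sex enter as penalized candidates alongside the
#' CpGs. The mean and SD of the in-sample predictions are stored so
#' downstream effect sizes can be reported per training SD.
#'
#' Samples with a missing target or any missing candidate predictor are
#' dropped listwise for this target.
#'
#' @param m A [methylation_matrix()].
#' @param pheno Phenotype `data.frame` aligned with `m` (see
#'   [align_samples()]), containing `age`, `female` and the target column.
#' @param target Name of the analyte column in `pheno`.
#' @param spec An [enet_spec()].
#' @param winsorize Apply [winsorize_scaled()] to the raw target (default
#'   TRUE); the learned bounds are stored in the model.
#' @param log Natural-log the (winsorized) target (default TRUE).
#' @param winsor_z Threshold for winsorization; default 6.
#' @return A [surrogate_model()].
#' @export
fit_surrogate <- function(m, pheno, target, spec = enet_spec(),
                          winsorize = TRUE, log = TRUE, winsor_z = 6) {
  stopifnot(inherits(spec, "enet_spec"))
  for (col in c("age", "female", target)) {
    if (!col %in% names(pheno)) stop("phenotype table lacks column '", col, "'")
  }
  if (nrow(m) != nrow(pheno) || !identical(rownames(m), pheno$sample_id)) {
    stop("methylation matrix and phenotype table are not aligned; call align_samples()")
  }
  y_raw <- pheno[[target]]
  X_all <- cbind(unclass(m), age = pheno$age, female = pheno$female)
  keep <- !is.na(y_raw) & stats::complete.cases(X_all)
  if (sum(keep) < 50) {
    stop(sprintf("target '%s' has %d usable samples; need at least 50", target, sum(keep)))
  }
  y <- y_raw[keep]
  if (stats::sd(y) == 0) stop("target '", target, "' is constant")
  X <- X_all[keep, , drop = FALSE]

  lo <- hi <- NULL
  if (winsorize) {
    w <- winsorize_scaled(y, z_max = winsor_z)
    y <- w$x; lo <- w$lo; hi <- w$hi
  }
  if (log) {
    names(y) <- pheno$sample_id[keep]
    y <- log_transform(y)
  }

  foldid <- make_folds(length(y), spec$n_folds, spec$seed)
  cv <- glmnet::cv.glmnet(X, y, family = "gaussian", alpha = spec$alpha,
                          lambda = spec$lambda_grid, foldid = foldid,
                          standardize = spec$standardize)
  b <- as.numeric(stats::coef(cv, s = "lambda.min"))
  names(b) <- c("(Intercept)", colnames(X))
  cpg_w <- b[colnames(m)]
  cpg_w <- cpg_w[cpg_w != 0]

  pred <- as.numeric(b[1] + X %*% b[-1])
  pred_sd <- stats::sd(pred)
  # full shrinkage leaves constant predictions; store unit scale so
  # scale_surrogate stays well-defined
  if (pred_sd == 0) pred_sd <- 1
  model <- surrogate_model(
    name = target,
    cpg_weights = cpg_w,
    age_weight = b[["age"]],
    female_weight = b[["female"]],
    intercept = b[["(Intercept)"]],
    winsor_lo = lo, winsor_hi = hi,
    log_transformed = log,
    train_mean = mean(pred),
    train_sd = pred_sd,
    cpg_means = if (length(cpg_w) > 0) colMeans(m[keep, names(cpg_w), drop = FALSE],
                                                na.rm = TRUE) else NULL)
  attr(model, "lambda") <- cv$lambda.min
  model
}

#' Apply a surrogate model to new samples
#'
#' Computes `intercept + sum(w_cpg * beta) + age_weight * age +
#' female_weight * female` per sample. Every model CpG must be present in
#' the matrix; missing beta values are imputed with the stored training mean
#' for that CpG when the model carries one, otherwise they are an error.
#'
#' @param model A [surrogate_model()].
#' @param m A [methylation_matrix()].
#' @param pheno Aligned phenotype `data.frame` with `age` and `female`.
#' @return Named numeric vector of DNAm surrogate values, one per sample.
#' @export
predict_surrogate <- function(model, m, pheno) {
  stopifnot(inherits(model, "surrogate_model"))
  cpgs <- names(model$cpg_weights)
  absent <- setdiff(cpgs, colnames(m))
  if (length(absent) > 0) {
    stop("methylation matrix lacks model CpG(s): ",
         paste(utils::head(absent, 10), collapse = ", "))
  }
  if (length(cpgs) > 0) {
    B <- unclass(m)[, cpgs, drop = FALSE]
    if (anyNA(B)) {
      if (is.null(model$cpg_means)) {
        stop("missing beta values for model CpGs and no training means stored")
      }
      for (j in seq_along(cpgs)) {
        nas <- is.na(B[, j])
        if (any(nas)) B[nas, j] <- model$cpg_means[[cpgs[j]]]
      }
    }
    contrib <- as.numeric(B %*% model$cpg_weights)
  } else {
    contrib <- rep(0, nrow(m))
  }
  out <- model$intercept + contrib +
    model$age_weight * pheno$age + model$female_weight * pheno$female
  names(out) <- rownames(m)
  out
}

#' Scale surrogate values to training-SD units
#'
#' One unit of the scaled surrogate corresponds to one standard deviation of
#' the DNAm surrogate in the training data.
#'
#' @param x Numeric vector of surrogate values.
#' @param model The [surrogate_model()] carrying `train_mean` / `train_sd`.
#' @return `(x - train_mean) / train_sd`.
#' @export
scale_surrogate <- function(x, model) {
  if (!is.finite(model$train_sd) || model$train_sd <= 0) stop("train_sd must be > 0")
  (x - model$train_mean) / model$train_sd
}
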