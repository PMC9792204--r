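#' Ground-truth parameters for cohort simulation
#'
#' Defines the generative model the two-stage clock assumes: a handful of
#' causal CpGs per analyte whose methylation carries the analyte signal, a
#' proportional-hazards mortality process driven by the (standardized)
#' analyte signals, age, sex and smoking, a Weibull baseline hazard, and a
#' target censoring fraction. Defaults mirror the training-cohort scale the
#' clock was designed for: mean age 66.1 (SD 9.06) and roughly 13% deaths.
#'
#' @param analytes Analyte names. The first is treated as CRP-like
#'   (lognormal, right-skewed, stored in mg/L-like units); the second as
#'   A1C-like (percent scale).
#' @param n_causal Causal CpGs per analyte; default 20.
#' @param signal_r2 Fraction of analyte variance explained by the CpG/age/sex
#'   signal; default 0.8.
#' @param cox_beta Named log-hazard coefficients on the mortality drivers:
#'   one entry per analyte (per SD of its true signal), plus `age` (per SD
#'   of age), `female` and `packyrs` (per pack-year).
#' @param weibull_shape,weibull_scale Weibull baseline hazard parameters
#'   (shape > 1 gives an age-increasing hazard); scale in years.
#' @param censor_rate Target censored fraction in \[0, 1); default 0.87
#'   (roughly 13% deaths).
#' @param seed Integer seed; all simulation randomness derives from it.
#' @return A list of class `sim_truth`.
#' @export
sim_truth <- function(analytes = c("CRP", "A1C"), n_causal = 20,
                      signal_r2 = 0.8,
                      cox_beta = c(CRP = 0.35, A1C = 0.25, age = 0.5,
                                   female = -0.2, packyrs = 0.01),
                      weibull_shape = 1.5, weibull_scale = 80,
                      censor_rate = 0.87, seed = 1L) {
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must lie in [0, 1)")
  if (!all(is.finite(cox_beta))) stop("cox_beta must be finite")
  if (signal_r2 <= 0 || signal_r2 >= 1) stop("signal_r2 must lie in (0, 1)")
  structure(list(analytes = analytes, n_causal = as.integer(n_causal),
                 signal_r2 = signal_r2, cox_beta = cox_beta,
                 weibull_shape = weibull_shape, weibull_scale = weibull_scale,
                 censor_rate = censor_rate, seed = as.integer(seed),
                 causal_cpgs = NULL, signals = NULL, lp = NULL),
            class = "sim_truth")
}

#' Simulate a methylation cohort with known analyte structure
#'
#' Generates a samples x CpGs beta matrix and a phenotype table with the
#' statistical structure the two training stages assume:
#' \itemize{
#'   \item ages drawn normal and affinely standardized so the empirical mean
#'     and SD equal `age_mean` / `age_sd` exactly;
#'   \item `female ~ Bernoulli(0.5)`; smoking pack-years zero-inflated;
#'   \item CpG betas are `plogis(base + age effect + causal loading + noise)`,
#'     guaranteed in (0, 1), with each analyte loading on its own set of
#'     `n_causal` CpGs through a per-sample latent factor;
#'   \item each analyte is (on the log scale for the CRP-like analyte) a
#'     linear combination of its causal CpG betas plus small age and sex
#'     effects plus Gaussian noise sized so the signal explains
#'     `signal_r2` of the variance.
#' }
#' The returned truth records the causal CpG IDs and weights, the per-sample
#' true analyte signals and the mortality log-hazard `lp`, enabling
#' parameter-recovery tests.
#'
#' @param n Samples (>= 50); default 1833, the training-cohort scale.
#' @param p CpGs (>= 10); default 1030.
#' @param truth A [sim_truth()].
#' @param age_mean,age_sd Empirical age mean/SD in years; defaults 66.1
#'   and 9.06.
#' @return List with `m` ([methylation_matrix()]), `pheno` (`data.frame`
#'   including survival columns from [simulate_survival()]) and the
#'   completed `truth`.
#' @export
simulate_cohort <- function(n = 1833, p = 1030, truth = sim_truth(),
                            age_mean = 66.1, age_sd = 9.06) {
  stopifnot(inherits(truth, "sim_truth"))
  if (n < 50) stop("need n >= 50")
  if (p < 10) stop("need p >= 10")
  set.seed(truth$seed)

  age <- stats::rnorm(n)
  age <- age_mean + age_sd * (age - mean(age)) / stats::sd(age)
  female <- stats::rbinom(n, 1, 0.5)
  age_std <- (age - age_mean) / age_sd

  smoker <- stats::rbinom(n, 1, 0.45)
  packyrs <- smoker * stats::rgamma(n, shape = 2, scale = 10)

  cpg_ids <- sprintf("cg%08d", seq_len(p))
  sample_ids <- sprintf("S%04d", seq_len(n))
  base <- stats::rnorm(p, 0, 1.2)          # logit-scale CpG baselines
  age_slope <- stats::rnorm(p, 0, 0.25)    # per SD of age

  logit <- outer(rep(1, n), base) + outer(age_std, age_slope) +
    matrix(stats::rnorm(n * p, 0, 0.3), n, p)

  # causal sets are disjoint across analytes; cap their size so they fit
  k <- min(truth$n_causal, floor(p / (2 * length(truth$analytes))))
  if (k < 1) stop("too few CpGs for one causal CpG per analyte")
  causal <- list()
  signals <- matrix(NA_real_, n, length(truth$analytes),
                    dimnames = list(sample_ids, truth$analytes))
  free <- seq_len(p)
  for (a in truth$analytes) {
    ids <- sample(free, k)
    free <- setdiff(free, ids)
    load <- stats::runif(k, 0.8, 1.6) * sample(c(-1, 1), k, replace = TRUE)
    z <- stats::rnorm(n)
    logit[, ids] <- logit[, ids] + outer(z, load)
    causal[[a]] <- list(cpgs = cpg_ids[ids], weights = load)
  }
  beta <- stats::plogis(logit)
  sat <- mean(beta < 1e-4 | beta > 1 - 1e-4)
  if (sat > 0.05) {
    stop(sprintf("effect sizes saturate the beta scale (%.1f%% of values at the boundary); reduce loadings", 100 * sat))
  }
  dimnames(beta) <- list(sample_ids, cpg_ids)

  # True analyte signal = linear combination of the causal CpG *betas*; this
  # is what Stage 1 can in principle recover from methylation alone.
  pheno <- data.frame(sample_id = sample_ids, age = age, female = female,
                      packyrs = packyrs, stringsAsFactors = FALSE)
  for (a in truth$analytes) {
    ids <- causal[[a]]$cpgs
    s <- as.numeric(beta[, ids, drop = FALSE] %*% causal[[a]]$weights)
    s_std <- (s - mean(s)) / stats::sd(s)
    signals[, a] <- s_std
    core <- s_std + 0.1 * age_std + 0.05 * female
    noise_sd <- stats::sd(core) * sqrt(1 / truth$signal_r2 - 1)
    y <- core + stats::rnorm(n, 0, noise_sd)
    if (a == truth$analytes[1]) {
      pheno[[a]] <- exp(0.7 + 0.9 * y)           # CRP-like, right-skewed (mg/L)
    } else {
      pheno[[a]] <- exp(log(5.7) + 0.08 * y)     # A1C-like (%), mildly skewed
    }
  }

  cb <- truth$cox_beta
  lp <- rep(0, n)
  for (a in truth$analytes) lp <- lp + cb[[a]] * signals[, a]
  lp <- lp + cb[["age"]] * age_std + cb[["female"]] * female +
    cb[["packyrs"]] * packyrs
  truth$causal_cpgs <- causal
  truth$signals <- signals
  truth$lp <- as.numeric(lp)

  surv <- simulate_survival(truth$lp, truth, seed = truth$seed + 1L)
  pheno$time <- surv$time
  pheno$event <- surv$event

  list(m = methylation_matrix(beta), pheno = validate_phenotypes(pheno),
       truth = truth)
}

#' Simulate proportional-hazards survival outcomes
#'
#' Event times follow a Weibull baseline with hazard multiplied by
#' `exp(lp)`; censoring is independent uniform on `(0, c_max)` with `c_max`
#' solved numerically so the expected event fraction matches
#' `1 - censor_rate` for the realized event-time sample. With
#' `censor_rate = 0` every subject is an event.
#'
#' @param lp Finite log relative hazards, one per subject.
#' @param truth A [sim_truth()] supplying the Weibull baseline and
#'   `censor_rate`.
#' @param seed Seed for this draw; defaults to `truth$seed + 1`.
#' @return `data.frame` with `time` (years) and `event` (0/1).
#' @export
simulate_survival <- function(lp, truth = sim_truth(), seed = truth$seed + 1L) {
  if (any(!is.finite(lp))) stop("linear predictor must be finite")
  if (truth$censor_rate >= 1) stop("censor_rate must be < 1")
  set.seed(seed)
  n <- length(lp)
  u <- stats::runif(n)
  T <- truth$weibull_scale * (-log(u) / exp(lp))^(1 / truth$weibull_shape)
  if (truth$censor_rate == 0) {
    return(data.frame(time = T, event = rep(1L, n)))
  }
  target <- 1 - truth$censor_rate
  pevent <- function(cmax) mean(pmax(0, 1 - T / cmax)) - target
  upper <- max(T) * 2
  while (pevent(upper) < 0 && upper < max(T) * 1e6) upper <- upper * 10
  cmax <- stats::uniroot(pevent, c(min(T) * 1e-6, upper))$root
  C <- stats::runif(n, 0, cmax)
  data.frame(time = pmin(T, C), event = as.integer(T <= C))
}
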