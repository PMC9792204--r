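#' Biweight midcorrelation
#'
#' Robust correlation weighting observations by Tukey's biweight around the
#' median: `u_i = (x_i - med(x)) / (c * MAD(x))` with the unscaled median
#' absolute deviation, weights `w_i = (1 - u_i^2)^2 * 1[|u_i| < 1]`, and
#'
#' `bicor = sum(wx wy (x - med)(y - med)) /
#'   sqrt(sum(wx^2 (x - med)^2) * sum(wy^2 (y - med)^2))`.
#'
#' Observations further than `c` MADs from the median get zero weight, which
#' makes the statistic insensitive to gross outliers. When a MAD is zero
#' (more than half the values tied at the median) the SD is used in its
#' place, with a warning.
#'
#' @param x,y Numeric vectors; pairwise-complete observations are used
#'   (>= 3 required).
#' @param c Tuning constant; default 9.
#' @return Correlation in \[-1, 1\].
#' @examples
#' bicor(1:10, (1:10)^1)   # 1
#' @export
bicor <- function(x, y, c = 9) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 paired non-missing observations")
  ux <- bicor_u(x, c)
  uy <- bicor_u(y, c)
  wx <- (1 - ux^2)^2 * (abs(ux) < 1)
  wy <- (1 - uy^2)^2 * (abs(uy) < 1)
  dx <- x - stats::median(x)
  dy <- y - stats::median(y)
  num <- sum(wx * wy * dx * dy)
  den <- sqrt(sum((wx * dx)^2) * sum((wy * dy)^2))
  if (den == 0) stop("zero robust variance; correlation undefined")
  max(-1, min(1, num / den))
}

bicor_u <- function(v, c) {
  med <- stats::median(v)
  s <- stats::mad(v, constant = 1)
  if (s == 0) {
    warning("MAD is zero; falling back to the standard deviation")
    s <- stats::sd(v)
    if (s == 0) stop("vector is constant; correlation undefined")
  }
  (v - med) / (c * s)
}

#' Fisher z-transform of a correlation
#'
#' Variance-stabilizing transform used to pool correlations across strata:
#' `z = atanh(r)` with variance `1 / (n - 3)`.
#'
#' @param r Correlation with `|r| < 1`.
#' @param n Number of paired observations (>= 4).
#' @return List with `z` and `var`.
#' @export
fisher_z <- function(r, n) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1 for the Fisher transform")
  if (any(n < 4)) stop("need n >= 4")
  list(z = atanh(r), var = 1 / (n - 3))
}

#' One stratum of an association analysis
#'
#' @param label Stratum label (e.g. cohort/race/sex cell).
#' @param estimate Effect on the analysis scale: log hazard ratio, log odds
#'   ratio, regression beta, or a correlation for `kind = "bicor"`.
#' @param se Standard error (> 0); ignored for `kind = "bicor"`, whose
#'   pooling variance comes from `n` via [fisher_z()].
#' @param n Stratum sample size (>= 3).
#' @param kind One of `"cox"`, `"logistic"`, `"linear"`, `"bicor"`.
#' @return A list of class `stratum_association`.
#' @export
stratum_association <- function(label, estimate, se, n,
                                kind = c("cox", "logistic", "linear", "bicor")) {
  kind <- match.arg(kind)
  if (kind != "bicor" && (!is.finite(se) || se <= 0)) stop("se must be > 0")
  if (n < 3) stop("n must be >= 3")
  structure(list(label = as.character(label), estimate = as.numeric(estimate),
                 se = as.numeric(se), n = as.integer(n), kind = kind),
            class = "stratum_association")
}

#' Inverse-variance fixed-effect meta-analysis
#'
#' Pools per-stratum estimates with weights `w_i = 1 / se_i^2`:
#' pooled estimate `sum(w b) / sum(w)`, standard error `1 / sqrt(sum(w))`,
#' `Z = estimate / se` and a two-sided normal p-value. Strata of kind
#' `"bicor"` are pooled on the Fisher-z scale with variance `1/(n-3)` and
#' the pooled estimate is back-transformed to a correlation for reporting
#' (its `se` and `z` remain on the z scale).
#'
#' @param strata List of [stratum_association()] objects (all the same
#'   kind), or a `data.frame` with columns `estimate`, `se`, optionally
#'   `n`, `kind`, `label`.
#' @return A list of class `meta_result` with `estimate`, `se`, `z`, `p`,
#'   `kind` and the per-stratum records.
#' @export
fixed_effect_meta <- function(strata) {
  strata <- as_strata(strata)
  if (length(strata) < 1) stop("need at least one stratum")
  kind <- unique(vapply(strata, `[[`, character(1), "kind"))
  if (length(kind) > 1) stop("strata mix kinds: ", paste(kind, collapse = ", "))
  est <- vapply(strata, `[[`, numeric(1), "estimate")
  if (kind == "bicor") {
    ns <- vapply(strata, `[[`, numeric(1), "n")
    fz <- fisher_z(est, ns)
    b <- fz$z; v <- fz$var
  } else {
    se <- vapply(strata, `[[`, numeric(1), "se")
    if (any(se <= 0)) stop("every stratum needs se > 0")
    b <- est; v <- se^2
  }
  w <- 1 / v
  pooled <- sum(w * b) / sum(w)
  se_pooled <- 1 / sqrt(sum(w))
  z <- pooled / se_pooled
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(estimate = if (kind == "bicor") tanh(pooled) else pooled,
                 se = se_pooled, z = z, p = p, kind = kind, strata = strata),
            class = "meta_result")
}

as_strata <- function(strata) {
  if (is.data.frame(strata)) {
    strata <- lapply(seq_len(nrow(strata)), function(i) {
      stratum_association(
        label = if ("label" %in% names(strata)) strata$label[i] else as.character(i),
        estimate = strata$estimate[i],
        se = if ("se" %in% names(strata)) strata$se[i] else 1,
        n = if ("n" %in% names(strata)) strata$n[i] else 3L,
        kind = if ("kind" %in% names(strata)) strata$kind[i] else "linear")
    })
  }
  if (inherits(strata, "stratum_association")) strata <- list(strata)
  stopifnot(all(vapply(strata, inherits, logical(1), "stratum_association")))
  strata
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result> %d strata (%s): estimate %.4g, se %.4g, Z %.3f, p %.3g\n",
              length(x$strata), x$kind, x$estimate, x$se, x$z, x$p))
  invisible(x)
}

#' Stouffer's sample-size-weighted meta-analysis
#'
#' Combines per-stratum Z statistics weighted by the square root of the
#' stratum sample size: `Z = sum(sqrt(n_i) z_i) / sqrt(sum(n_i))`, with a
#' two-sided normal p-value. Used where effect sizes cannot be harmonized
#' across cohorts (e.g. comorbidity counts).
#'
#' @param z Numeric vector of per-stratum Z statistics.
#' @param n Integer vector of per-stratum sample sizes (>= 1).
#' @return List with `z` (combined) and `p`.
#' @export
stouffer_meta <- function(z, n) {
  if (length(z) == 0) stop("need at least one stratum")
  if (length(z) != length(n)) stop("length mismatch")
  if (any(n < 1)) stop("sample sizes must be >= 1")
  Z <- sum(sqrt(n) * z) / sqrt(sum(n))
  list(z = Z, p = 2 * stats::pnorm(-abs(Z)))
}
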