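#' EWAS of a numeric trait by per-CpG correlation screening
#'
#' For each CpG, methylation outliers are masked at six SDs
#' ([mask_extreme_values()]), the Pearson correlation with the trait is
#' computed over complete pairs, and a Student-t p-value with
#' `df = pairs - 2` is reported together with the signed normal-equivalent
#' Z. CpGs with fewer than `min_pairs` usable pairs are emitted with missing
#' statistics.
#'
#' @param m A [methylation_matrix()].
#' @param trait Numeric trait, one value per row of `m`.
#' @param min_pairs Minimum complete pairs per CpG; default 10.
#' @param adjust Optional multiple-testing adjustment column: `"none"`
#'   (default, matching the convention of reporting unadjusted P),
#'   `"bonferroni"` or `"BH"`.
#' @return `data.frame` ordered by CpG ID with columns `cpg`, `n`,
#'   `estimate` (r), `z`, `p` (and `p_adj` when requested).
#' @export
ewas_numeric_trait <- function(m, trait, min_pairs = 10,
                               adjust = c("none", "bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  if (length(trait) != nrow(m)) stop("trait length must match sample count")
  cpgs <- sort(colnames(m))
  res <- vapply(cpgs, function(id) {
    x <- mask_extreme_values(unclass(m)[, id])
    keep <- !is.na(x) & !is.na(trait)
    n <- sum(keep)
    if (n < min_pairs) return(c(n = n, r = NA, z = NA, p = NA))
    if (stats::sd(x[keep]) == 0 || stats::sd(trait[keep]) == 0) {
      return(c(n = n, r = NA, z = NA, p = NA))
    }
    r <- stats::cor(x[keep], trait[keep])
    df <- n - 2
    tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df)
    z <- sign(r) * stats::qnorm(pmax(p / 2, .Machine$double.xmin), lower.tail = FALSE)
    c(n = n, r = r, z = z, p = p)
  }, numeric(4))
  out <- data.frame(cpg = cpgs, n = as.integer(res["n", ]),
                    estimate = res["r", ], z = res["z", ], p = res["p", ],
                    row.names = NULL)
  if (adjust != "none") out$p_adj <- stats::p.adjust(out$p, method = adjust)
  out
}

#' EWAS of a censored outcome by per-CpG Cox regression
#'
#' Fits one proportional-hazards model per CpG, with the CpG's methylation
#' (outlier-masked at six SDs) as exposure and the covariate set chosen by
#' `model`:
#' \describe{
#'   \item{I}{age and sex (columns `age`, `female`)}
#'   \item{II}{Model I plus smoking pack-years (`packyrs`)}
#'   \item{III}{Model I plus blood-cell composition columns (`cell_cols`)}
#' }
#'
#' @param m A [methylation_matrix()].
#' @param time,event Survival outcome, one value per row of `m`.
#' @param pheno Aligned phenotype `data.frame` supplying the covariates.
#' @param model `"I"`, `"II"` or `"III"`.
#' @param cell_cols Character vector of blood-cell covariate column names
#'   (required for Model III).
#' @param min_pairs Minimum usable samples per CpG; default 10.
#' @return `data.frame` ordered by CpG ID with columns `cpg`, `n`,
#'   `estimate` (log HR per unit beta), `se`, `z`, `p`.
#' @export
ewas_cox <- function(m, time, event, pheno, model = c("I", "II", "III"),
                     cell_cols = NULL, min_pairs = 10) {
  model <- match.arg(model)
  covars <- c("age", "female")
  if (model == "II") covars <- c(covars, "packyrs")
  if (model == "III") {
    if (is.null(cell_cols) || length(cell_cols) == 0) {
      stop("Model III requires blood-cell covariate names in cell_cols")
    }
    covars <- c(covars, cell_cols)
  }
  missing <- setdiff(covars, names(pheno))
  if (length(missing) > 0) {
    stop("phenotype table lacks covariate(s) for Model ", model, ": ",
         paste(missing, collapse = ", "))
  }
  Z <- as.matrix(pheno[, covars, drop = FALSE])
  cpgs <- sort(colnames(m))
  res <- vapply(cpgs, function(id) {
    x <- mask_extreme_values(unclass(m)[, id])
    keep <- !is.na(x) & stats::complete.cases(Z) & !is.na(time) & !is.na(event)
    n <- sum(keep)
    if (n < min_pairs || sum(event[keep] == 1) < 2 || stats::sd(x[keep]) == 0) {
      return(c(n = n, b = NA, se = NA, z = NA, p = NA))
    }
    fit <- tryCatch(
      survival::coxph(survival::Surv(time[keep], event[keep]) ~
                        cbind(x[keep], Z[keep, , drop = FALSE]),
                      ties = "breslow"),
      error = function(e) NULL)
    if (is.null(fit)) return(c(n = n, b = NA, se = NA, z = NA, p = NA))
    sm <- summary(fit)$coefficients
    c(n = n, b = sm[1, "coef"], se = sm[1, "se(coef)"], z = sm[1, "z"],
      p = sm[1, "Pr(>|z|)"])
  }, numeric(5))
  data.frame(cpg = cpgs, n = as.integer(res["n", ]), estimate = res["b", ],
             se = res["se", ], z = res["z", ], p = res["p", ], row.names = NULL)
}
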