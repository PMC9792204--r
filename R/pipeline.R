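#' Read a plain-text run configuration
#'
#' Parses a `key: value` file (one pair per line, `#` comments allowed) into
#' a named list. Values that parse as numbers are converted; `true`/`false`
#' become logicals; everything else stays character.
#'
#' @param path Path to the config file.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse config line: '", ln, "'")
    key <- m[2]; val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
      else if (tolower(val) %in% c("true", "false")) tolower(val) == "true"
      else val
  }
  structure(out, class = "run_config")
}

cfg_get <- function(config, key, default = NULL) {
  if (!is.null(config[[key]])) config[[key]] else default
}

cfg_require <- function(config, keys, command) {
  missing <- keys[vapply(keys, function(k) is.null(config[[k]]), logical(1))]
  if (length(missing) > 0) {
    stop(sprintf("command '%s' requires config key(s): %s", command,
                 paste(missing, collapse = ", ")))
  }
}

spec_from_config <- function(config) {
  enet_spec(alpha = cfg_get(config, "alpha", 0.5),
            n_folds = cfg_get(config, "folds", 10),
            seed = cfg_get(config, "seed", 1))
}

write_provenance <- function(config, command, outputs, dir) {
  inputs <- unlist(config[grepl("^(meth|pheno|model|table|strata)$", names(config))])
  sums <- if (length(inputs) > 0) as.list(tools::md5sum(inputs[file.exists(inputs)])) else list()
  rec <- list(command = command, config = unclass(config),
              seed = cfg_get(config, "seed", 1),
              package_version = as.character(utils::packageVersion("grimage2")),
              r_version = as.character(getRversion()),
              input_md5 = sums, outputs = outputs)
  jsonlite::write_json(rec, file.path(dir, paste0(command, ".provenance.json")),
                       auto_unbox = TRUE, digits = NA)
}

#' Run one pipeline command
#'
#' Single entry point tying the stages together. Commands:
#' \describe{
#'   \item{simulate}{write a simulated cohort (`out_prefix` + `meth.csv`,
#'     `pheno.csv`, `truth.json`); keys: `n`, `p`, `seed`, `out_prefix`.}
#'   \item{train-surrogate}{fit a Stage-1 surrogate; keys: `meth`, `pheno`,
#'     `target`, `out`, optional `alpha`, `folds`, `seed`, `log`, `winsor_z`.}
#'   \item{train-clock}{predict the configured surrogates, fit the Cox clock
#'     on them plus age/female (and `packyrs` when present), calibrate to
#'     age, write clock JSON; keys: `meth`, `pheno`, `surrogates`
#'     (comma-separated model files), `out`.}
#'   \item{apply-clock}{apply a clock JSON (or `grimage2_published`) to a
#'     covariate table; keys: `model`, `table`, `out`.}
#'   \item{accel}{age-acceleration residuals of a column against `age`;
#'     keys: `table`, `column`, `out`.}
#'   \item{ewas}{per-CpG screen; keys: `meth`, `pheno`, `out`, and either
#'     `trait` (numeric-trait EWAS) or `model` I/II/III (Cox EWAS).}
#'   \item{meta}{pool a strata table (columns `estimate`, `se`, `n`, `kind`);
#'     keys: `strata`, `scheme` (`fixed`/`stouffer`), `out`.}
#' }
#' Every run writes a provenance JSON (config echo, seed, versions, input
#' checksums) next to its outputs. On failure, partially written outputs of
#' the failing run are removed.
#'
#' @param config A `run_config` (or plain named list).
#' @param command One of the commands above.
#' @return Invisibly, a character vector of the files written.
#' @export
run_pipeline <- function(config, command = c("simulate", "train-surrogate",
                                             "train-clock", "apply-clock",
                                             "accel", "ewas", "meta")) {
  command <- match.arg(command)
  outputs <- character(0)
  run <- function() {
    switch(command,
      "simulate" = {
        cfg_require(config, "out_prefix", command)
        truth <- sim_truth(seed = cfg_get(config, "seed", 1),
                           censor_rate = cfg_get(config, "censor_rate", 0.87))
        sim <- simulate_cohort(n = cfg_get(config, "n", 1833),
                               p = cfg_get(config, "p", 1030),
                               truth = truth,
                               age_mean = cfg_get(config, "age_mean", 66.1),
                               age_sd = cfg_get(config, "age_sd", 9.06))
        pre <- config$out_prefix
        dir.create(dirname(paste0(pre, "x")), showWarnings = FALSE, recursive = TRUE)
        outputs <<- paste0(pre, c("meth.csv", "pheno.csv", "truth.json"))
        write_methylation(sim$m, outputs[1])
        write_phenotypes(sim$pheno, outputs[2])
        tr <- sim$truth
        jsonlite::write_json(
          list(seed = tr$seed, analytes = tr$analytes,
               causal_cpgs = tr$causal_cpgs, cox_beta = as.list(tr$cox_beta),
               weibull_shape = tr$weibull_shape, weibull_scale = tr$weibull_scale,
               censor_rate = tr$censor_rate, lp = tr$lp),
          outputs[3], auto_unbox = TRUE, digits = NA)
      },
      "train-surrogate" = {
        cfg_require(config, c("meth", "pheno", "target", "out"), command)
        dat <- align_samples(read_methylation(config$meth),
                             read_phenotypes(config$pheno))
        model <- fit_surrogate(dat$m, dat$p, config$target,
                               spec = spec_from_config(config),
                               winsorize = cfg_get(config, "winsorize", TRUE),
                               log = cfg_get(config, "log", TRUE),
                               winsor_z = cfg_get(config, "winsor_z", 6))
        outputs <<- config$out
        write_model(model, config$out)
      },
      "train-clock" = {
        cfg_require(config, c("meth", "pheno", "surrogates", "out"), command)
        dat <- align_samples(read_methylation(config$meth),
                             read_phenotypes(config$pheno))
        paths <- trimws(strsplit(config$surrogates, ",")[[1]])
        X <- data.frame(row.names = dat$p$sample_id)
        for (pth in paths) {
          sm <- read_model(pth)
          X[[paste0("DNAm", if (sm$log_transformed) "log" else "", sm$name)]] <-
            predict_surrogate(sm, dat$m, dat$p)
        }
        X$Age <- dat$p$age
        X$Female <- dat$p$female
        if ("packyrs" %in% names(dat$p) && !anyNA(dat$p$packyrs)) {
          X$PACKYRS <- dat$p$packyrs
        }
        model <- train_clock(X, dat$p$time, dat$p$event, dat$p$age,
                             spec = spec_from_config(config))
        outputs <<- config$out
        write_model(model, config$out)
      },
      "apply-clock" = {
        cfg_require(config, c("model", "table", "out"), command)
        model <- if (identical(config$model, "grimage2_published")) {
          grimage2_model()
        } else read_model(config$model)
        tab <- utils::read.table(config$table, header = TRUE, sep = ",",
                                 check.names = FALSE)
        tab$clock_years <- apply_clock(model, tab)
        outputs <<- config$out
        utils::write.table(tab, config$out, sep = ",", quote = FALSE,
                           row.names = FALSE)
      },
      "accel" = {
        cfg_require(config, c("table", "column", "out"), command)
        tab <- utils::read.table(config$table, header = TRUE, sep = ",",
                                 check.names = FALSE)
        if (!all(c(config$column, "age") %in% names(tab))) {
          stop("table needs columns '", config$column, "' and 'age'")
        }
        tab$accel <- age_acceleration(tab[[config$column]], tab$age)
        outputs <<- config$out
        utils::write.table(tab, config$out, sep = ",", quote = FALSE,
                           row.names = FALSE)
      },
      "ewas" = {
        cfg_require(config, c("meth", "pheno", "out"), command)
        dat <- align_samples(read_methylation(config$meth),
                             read_phenotypes(config$pheno))
        res <- if (!is.null(config$trait)) {
          ewas_numeric_trait(dat$m, dat$p[[config$trait]])
        } else {
          cfg_require(config, "model", command)
          ewas_cox(dat$m, dat$p$time, dat$p$event, dat$p, model = config$model,
                   cell_cols = if (is.null(config$cells)) NULL
                               else trimws(strsplit(config$cells, ",")[[1]]))
        }
        outputs <<- config$out
        utils::write.table(res, config$out, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      },
      "meta" = {
        cfg_require(config, c("strata", "out"), command)
        tab <- utils::read.table(config$strata, header = TRUE, sep = "\t",
                                 check.names = FALSE)
        scheme <- cfg_get(config, "scheme", "fixed")
        res <- if (scheme == "stouffer") {
          st <- stouffer_meta(tab$z, tab$n)
          data.frame(estimate = NA, se = NA, z = st$z, p = st$p)
        } else {
          fe <- fixed_effect_meta(tab)
          data.frame(estimate = fe$estimate, se = fe$se, z = fe$z, p = fe$p)
        }
        outputs <<- config$out
        utils::write.table(res, config$out, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      })
    out_dir <- dirname(outputs[1])
    write_provenance(config, command, outputs, out_dir)
  }
  tryCatch(run(), error = function(e) {
    existing <- outputs[file.exists(outputs)]
    if (length(existing) > 0) unlink(existing)
    stop(e)
  })
  invisible(outputs)
}
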