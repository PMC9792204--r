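test_that("cohort simulation is deterministic and respects the beta range", {
  tr <- sim_truth(n_causal = 6, seed = 14)
  a <- simulate_cohort(n = 120, p = 30, truth = tr)
  b <- simulate_cohort(n = 120, p = 30, truth = tr)
  expect_identical(unclass(a$m), unclass(b$m))
  expect_identical(a$pheno, b$pheno)
  expect_identical(a$truth$lp, b$truth$lp)

  expect_true(all(a$m > 0 & a$m < 1))
  expect_equal(mean(a$pheno$age), 66.1, tolerance = 1e-12)
  expect_equal(sd(a$pheno$age), 9.06, tolerance = 1e-12)
  expect_true(all(a$pheno$female %in% c(0, 1)))
  expect_true(all(a$pheno$packyrs >= 0))
  expect_true(all(a$pheno$CRP > 0))
  # CRP-like analyte is right-skewed on the raw scale
  crp <- a$pheno$CRP
  expect_gt(mean((crp - mean(crp))^3) / sd(crp)^3, 1)
})

test_that("analytes track their causal-CpG linear combination", {
  sim <- simulate_cohort(n = 500, p = 100, truth = sim_truth(seed = 15))
  for (an in c("CRP", "A1C")) {
    cc <- sim$truth$causal_cpgs[[an]]
    s <- as.numeric(unclass(sim$m)[, cc$cpgs] %*% cc$weights)
    y <- if (an == "CRP") log(sim$pheno[[an]]) else sim$pheno[[an]]
    expect_gt(cor(y, s), 0.7)
    expect_equal(unname(cor(s, sim$truth$signals[, an])), 1, tolerance = 1e-12)
  }
})

test_that("parameter guards on the generator", {
  expect_error(sim_truth(censor_rate = 1), "censor_rate")
  expect_error(sim_truth(signal_r2 = 1.2), "signal_r2")
  expect_error(simulate_cohort(n = 10, p = 30), "n >= 50")
  expect_error(simulate_cohort(n = 60, p = 5), "p >= 10")
  expect_error(simulate_survival(c(0, NA), sim_truth()), "finite")
  # default settings must not saturate the beta scale
  expect_silent(simulate_cohort(n = 60, p = 12,
                                truth = sim_truth(n_causal = 3, seed = 16)))
})

test_that("survival generator hits the target event fraction and null/effect behavior", {
  tr <- sim_truth(seed = 17, censor_rate = 0.87)
  lp <- rnorm(800, 0, 0.4)
  s <- simulate_survival(lp, tr, seed = 18)
  expect_true(abs(mean(s$event) - 0.13) <= 0.05)
  expect_true(all(s$time > 0))

  # censor_rate = 0 -> everyone is an event
  tr0 <- sim_truth(seed = 17, censor_rate = 0)
  s0 <- simulate_survival(lp, tr0, seed = 18)
  expect_true(all(s0$event == 1))

  # equal hazards: two random halves are indistinguishable by logrank
  trn <- sim_truth(seed = 19, censor_rate = 0.5)
  sn <- simulate_survival(rep(0, 1000), trn, seed = 20)
  set.seed(21)
  grp <- sample(rep(0:1, 500))
  lr <- survival::survdiff(survival::Surv(sn$time, sn$event) ~ grp)
  expect_gt(1 - pchisq(lr$chisq, 1), 0.01)

  # a log-2 hazard shift is recovered by unpenalized Cox within 15%
  grp2 <- rep(0:1, each = 1000)
  tr2 <- sim_truth(seed = 22, censor_rate = 0.5)
  s2 <- simulate_survival(log(2) * grp2, tr2, seed = 23)
  fit <- survival::coxph(survival::Surv(s2$time, s2$event) ~ grp2,
                         ties = "breslow")
  expect_lt(abs(coef(fit) - log(2)) / log(2), 0.15)
})

test_that("end-to-end: surrogate -> clock -> acceleration recovers the mortality signal", {
  sim <- simulate_cohort(n = 1200, p = 150,
                         truth = sim_truth(seed = 24, censor_rate = 0.75))
  spec <- enet_spec(seed = 25, n_folds = 5)
  crp <- fit_surrogate(sim$m, sim$pheno, "CRP", spec)
  a1c <- fit_surrogate(sim$m, sim$pheno, "A1C", spec)
  X <- data.frame(DNAmlogCRP = predict_surrogate(crp, sim$m, sim$pheno),
                  DNAmlogA1C = predict_surrogate(a1c, sim$m, sim$pheno),
                  Age = sim$pheno$age, Female = sim$pheno$female,
                  PACKYRS = sim$pheno$packyrs)
  ck <- train_clock(X, sim$pheno$time, sim$pheno$event, sim$pheno$age,
                    enet_spec(seed = 26, n_folds = 5))
  yrs <- apply_clock(ck, X)
  expect_equal(mean(yrs), mean(sim$pheno$age), tolerance = 1e-9 * 66)
  expect_equal(sd(yrs), sd(sim$pheno$age), tolerance = 1e-9 * 9)

  accel <- age_acceleration(yrs, sim$pheno$age)
  a <- cox_association(sim$pheno$time, sim$pheno$event, accel,
                       covariates = data.frame(age = sim$pheno$age,
                                               female = sim$pheno$female))
  expect_gt(a$estimate, 0)
  expect_lt(2 * pnorm(-abs(a$estimate / a$se)), 0.01)
})
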