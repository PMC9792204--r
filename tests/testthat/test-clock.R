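grim_row <- function(logcrp = 0, loga1c = 0, age = 0, female = 0, pack = 0) {
  data.frame(DNAmADM = 0, DNAmB2M = 0, DNAmCystatinC = 0, DNAmGDF15 = 0,
             DNAmLeptin = 0, DNAmlogCRP = logcrp, DNAmlogA1C = loga1c,
             DNAmPAI1 = 0, DNAmTIMP1 = 0, DNAmPACKYRS = pack,
             Age = age, Female = female)
}

test_that("packaged 12-covariate clock reproduces its printed constants", {
  g <- grimage2_model()
  expect_length(g$covariate_names, 12)
  expect_equal(g$coefficients[["Female"]], -0.14212)
  expect_equal(g$coefficients[["Age"]], 0.02676)
  expect_equal(g$coefficients[["DNAmlogCRP"]], 1.90266)
  expect_equal(g$calib_intercept, -61.03936)
  expect_equal(g$calib_slope, 8.271105)

  # hand arithmetic: Age 65, Female 1, all DNAm terms zero
  expect_equal(linear_predictor(g, grim_row(age = 65, female = 1)),
               0.02676 * 65 - 0.14212)
  expect_equal(linear_predictor(g, grim_row(age = 65, female = 1)), 1.59728)

  # calibration maps lp = 0 to the printed intercept, unit slope to the printed slope
  expect_equal(apply_clock(g, grim_row()), -61.03936)
  expect_equal(apply_clock(g, grim_row(age = 65, female = 1)),
               -61.03936 + 8.271105 * 1.59728, tolerance = 1e-12)

  # two samples differing only in Female
  both <- rbind(grim_row(age = 70, female = 1), grim_row(age = 70, female = 0))
  d <- diff(apply_clock(g, both))
  expect_equal(d, -8.271105 * (-0.14212), tolerance = 1e-12)
})

test_that("linear predictor is linear and checks covariate names", {
  g <- grimage2_model()
  expect_equal(linear_predictor(g, grim_row()), 0)
  x1 <- grim_row(logcrp = 1); x2 <- grim_row(logcrp = 3)
  expect_equal(linear_predictor(g, x2) - linear_predictor(g, x1),
               1.90266 * 2, tolerance = 1e-12)
  expect_error(linear_predictor(g, data.frame(Age = 65)), "Female")
})

test_that("calibration matches training age moments exactly", {
  set.seed(3)
  lp <- rnorm(500)
  lp <- (lp - mean(lp)) / sd(lp)        # standardized linear predictor
  age <- rnorm(500, 66, 9)
  cal <- calibrate_to_age(lp, age)
  expect_equal(cal$intercept, mean(age), tolerance = 1e-9)
  expect_equal(cal$slope, sd(age), tolerance = 1e-9)
  out <- cal$intercept + cal$slope * lp
  expect_equal(mean(out), mean(age), tolerance = 1e-9 * abs(mean(age)))
  expect_equal(sd(out), sd(age), tolerance = 1e-9 * sd(age))
  expect_error(calibrate_to_age(rep(1, 10), age[1:10]), "zero variance")
  expect_error(calibrate_to_age(lp[1:10], rep(66, 10)), "zero variance")
})

test_that("clock output is affine in every covariate", {
  g <- grimage2_model()
  base <- grim_row(logcrp = 0.5, loga1c = 0.2, age = 66, female = 1, pack = 10)
  y0 <- apply_clock(g, base)
  for (nm in g$covariate_names) {
    bumped <- base
    bumped[[nm]] <- bumped[[nm]] + 1
    expect_lt(abs((apply_clock(g, bumped) - y0) -
                    g$calib_slope * g$coefficients[[nm]]), 1e-10)
  }
})

test_that("penalized Cox at lambda = 0 matches the unpenalized partial-likelihood solver", {
  d <- sim_cox_data(500, c(0.6, -0.4), censor = 0.5, seed = 13)
  b <- grimage2:::cox_enet_at(d$X, d$time, d$event, alpha = 0.5, lambda = 0)
  oracle <- survival::coxph(survival::Surv(d$time, d$event) ~ d$X,
                            ties = "breslow")
  expect_equal(unname(b), unname(coef(oracle)), tolerance = 1e-4)
})

test_that("Cox elastic net shrinks fully at huge lambda and ignores sample order", {
  d <- sim_cox_data(300, c(0.5, -0.3), censor = 0.5, seed = 17)
  spec <- enet_spec(seed = 4, n_folds = 5, lambda_grid = c(100, 50))
  fit <- fit_cox_elastic_net(d$X, d$time, d$event, spec)
  expect_true(all(fit$coefficients == 0))
  expect_true(fit$converged)
  expect_identical(fit$ties_method, "breslow")

  # at a fixed penalty the solution does not depend on sample order
  set.seed(8)
  perm <- sample(nrow(d$X))
  b1 <- grimage2:::cox_enet_at(d$X, d$time, d$event, alpha = 0.5, lambda = 0.05)
  b2 <- grimage2:::cox_enet_at(d$X[perm, ], d$time[perm], d$event[perm],
                               alpha = 0.5, lambda = 0.05)
  expect_equal(b1, b2, tolerance = 1e-10)

  spec2 <- enet_spec(seed = 4, n_folds = 5)
  expect_error(fit_cox_elastic_net(d$X, d$time, rep(0, 300), spec2), "no events")
  Xbad <- d$X; Xbad[1, 1] <- NA
  expect_error(fit_cox_elastic_net(Xbad, d$time, d$event, spec2), "missing")
})

test_that("Cox fit recovers simulation truth at moderate scale", {
  d <- sim_cox_data(2000, c(1, -0.8), censor = 0.6, seed = 19)
  fit <- fit_cox_elastic_net(d$X, d$time, d$event, enet_spec(seed = 1, n_folds = 5))
  expect_lt(abs(fit$coefficients[["x1"]] - 1) / 1, 0.15)
  expect_lt(abs(fit$coefficients[["x2"]] + 0.8) / 0.8, 0.15)
})

test_that("age acceleration residuals are OLS residuals on age", {
  set.seed(23)
  age <- runif(100, 50, 90)
  expect_equal(age_acceleration(age, age), rep(0, 100),
               tolerance = 1e-10, ignore_attr = TRUE)

  clockv <- 5 + 0.9 * age + rnorm(100, 0, 3)
  acc <- age_acceleration(clockv, age)
  expect_equal(sum(acc), 0, tolerance = 1e-9)
  expect_equal(sum(acc * (age - mean(age))), 0, tolerance = 1e-8)

  # independent normal-equations oracle
  A <- cbind(1, age)
  res_oracle <- clockv - A %*% solve(crossprod(A), crossprod(A, clockv))
  expect_equal(unname(acc), as.numeric(res_oracle), tolerance = 1e-9)

  expect_error(age_acceleration(clockv, rep(70, 100)), "constant")
})

test_that("deviance residuals match independent oracles", {
  set.seed(29)
  n <- 20
  time <- round(rexp(n, 0.2), 2) + 0.05
  event <- rbinom(n, 1, 0.5)
  lp <- rnorm(n, 0, 0.7)
  dev <- mortality_res(time, event, lp)

  # naive textbook double-loop oracle
  expect_equal(as.numeric(dev), deviance_oracle(time, event, lp), tolerance = 1e-8)

  # survival-package oracle: Cox model with the lp as a fixed offset
  fit <- survival::coxph(survival::Surv(time, event) ~ offset(lp),
                         ties = "breslow")
  expect_equal(as.numeric(dev),
               unname(residuals(fit, type = "deviance")), tolerance = 1e-8)
  expect_equal(unname(attr(dev, "martingale")),
               unname(residuals(fit, type = "martingale")), tolerance = 1e-8)

  # martingale residuals sum to zero when events exist
  expect_equal(sum(attr(dev, "martingale")), 0, tolerance = 1e-9)

  # censored observation before the first event has residual 0
  t2 <- c(0.01, time); e2 <- c(0, event); l2 <- c(0, lp)
  expect_equal(mortality_res(t2, e2, l2)[1], 0)

  # all-censored input: zero vector with warning
  expect_warning(z <- mortality_res(time, rep(0, n), lp), "no events")
  expect_equal(as.numeric(z), rep(0, n))
})

test_that("train_clock produces a calibrated clock whose training mean/sd equal age", {
  d <- sim_cox_data(400, c(0.5, -0.3), censor = 0.6, seed = 31)
  age <- rnorm(400, 66, 9)
  ck <- train_clock(d$X, d$time, d$event, age, enet_spec(seed = 6, n_folds = 5))
  yrs <- apply_clock(ck, d$X)
  expect_equal(mean(yrs), mean(age), tolerance = 1e-9 * abs(mean(age)))
  expect_equal(sd(yrs), sd(age), tolerance = 1e-9 * sd(age))
})
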