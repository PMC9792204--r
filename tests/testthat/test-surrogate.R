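test_that("winsorization caps the upper tail at the largest in-threshold value", {
  x <- c(1, 2, 3, 4, 5)
  w <- winsorize_scaled(x)
  expect_identical(w$x, x)          # all |z| <= 6
  expect_equal(w$lo, 1)
  expect_equal(w$hi, 5)

  # one gross outlier: hi is the largest raw value with z <= 6, outlier capped
  y <- c(rnorm(200, 1, 0.1), 1000)
  w2 <- winsorize_scaled(y)
  z <- (y - mean(y)) / sd(y)
  expect_equal(w2$hi, max(y[z <= 6]))
  expect_equal(max(w2$x), w2$hi)
  expect_identical(w2$x[-201], y[-201])

  # rank order of non-extreme values is never changed
  expect_identical(rank(w2$x[-201]), rank(y[-201]))

  # sd = 0 degenerate branch
  cst <- winsorize_scaled(rep(2, 5))
  expect_identical(cst$x, rep(2, 5))
  expect_equal(cst$lo, 2)
  expect_equal(cst$hi, 2)
})

test_that("published training bounds clamp raw analytes", {
  b <- grimage2_winsor_bounds()
  expect_equal(apply_bounds(100, b$CRP[1], b$CRP[2]), 54.01)
  expect_equal(apply_bounds(0.05, b$CRP[1], b$CRP[2]), 0.14)
  expect_equal(apply_bounds(12, b$A1C[1], b$A1C[2]), 10)
  expect_equal(apply_bounds(5.6, b$A1C[1], b$A1C[2]), 5.6)
  expect_equal(apply_bounds(1e6, b$CRP[1], b$CRP[2]), 54.01)
  expect_error(apply_bounds(1, 2, 1), "lo")
})

test_that("log transform is the elementwise natural log with named errors", {
  expect_equal(log_transform(1), 0)
  expect_equal(log_transform(exp(1)), 1)
  crp <- c(0.14, 1.7, 54.01)
  expect_equal(log_transform(crp), c(log(0.14), log(1.7), log(54.01)))
  expect_error(log_transform(c(a = 1, b = -2)), "b")
})

test_that("elastic net at lambda = 0 matches the normal-equations solution", {
  set.seed(11)
  n <- 200; p <- 5
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
  y <- 2 + X %*% c(1, -0.5, 0, 0.25, 2) + rnorm(n, 0, 0.5)
  b <- grimage2:::enet_gaussian(X, as.numeric(y), alpha = 0.5,
                                lambda = c(1, 0.3, 0.1, 0.03, 0.01, 0))
  ols <- solve(crossprod(cbind(1, X)), crossprod(cbind(1, X), y))
  expect_equal(unname(b), as.numeric(ols), tolerance = 1e-6)
})

test_that("surrogate fitting is deterministic, shrinks fully at huge lambda, and recovers signal", {
  sim <- simulate_cohort(n = 250, p = 50, truth = sim_truth(n_causal = 8, seed = 21))
  spec <- enet_spec(seed = 5, n_folds = 5)
  m1 <- fit_surrogate(sim$m, sim$pheno, "CRP", spec)
  m2 <- fit_surrogate(sim$m, sim$pheno, "CRP", spec)
  expect_identical(m1$cpg_weights, m2$cpg_weights)
  expect_identical(attr(m1, "lambda"), attr(m2, "lambda"))

  # forcing a gigantic penalty gives an intercept-only model
  big <- fit_surrogate(sim$m, sim$pheno, "CRP",
                       enet_spec(seed = 5, n_folds = 5,
                                 lambda_grid = c(1e6, 9e5)))
  expect_length(big$cpg_weights, 0)
  expect_equal(big$age_weight, 0)
  expect_equal(big$female_weight, 0)

  # prediction on training samples reproduces the stored scale stats
  pred <- predict_surrogate(m1, sim$m, sim$pheno)
  expect_equal(mean(pred), m1$train_mean, tolerance = 1e-9)
  expect_equal(sd(pred), m1$train_sd, tolerance = 1e-9)
  sc <- scale_surrogate(pred, m1)
  expect_equal(mean(sc), 0, tolerance = 1e-9)
  expect_equal(sd(sc), 1, tolerance = 1e-9)

  # and tracks the simulated true analyte signal
  expect_gt(cor(pred, sim$truth$signals[, "CRP"]), 0.8)
})

test_that("nonzero CpG count trends down along increasing penalty", {
  sim <- simulate_cohort(n = 150, p = 40, truth = sim_truth(n_causal = 6, seed = 31))
  y <- log(sim$pheno$CRP)
  X <- cbind(unclass(sim$m), age = sim$pheno$age, female = sim$pheno$female)
  lams <- c(0.5, 0.05, 0.005)
  fit <- glmnet::glmnet(X, y, alpha = 0.5, lambda = lams, standardize = TRUE)
  nz <- sapply(lams, function(l) sum(as.numeric(coef(fit, s = l))[-1] != 0))
  expect_true(all(diff(nz) >= 0))  # fewer active weights at stronger penalty
})

test_that("surrogate prediction rules for missing data are enforced", {
  sim <- simulate_cohort(n = 120, p = 30, truth = sim_truth(n_causal = 5, seed = 41))
  mod <- fit_surrogate(sim$m, sim$pheno, "CRP", enet_spec(seed = 2, n_folds = 5))
  skip_if(length(mod$cpg_weights) == 0)

  # absent CpG column -> error naming it
  drop <- names(mod$cpg_weights)[1]
  m2 <- sim$m[, setdiff(colnames(sim$m), drop)]
  expect_error(predict_surrogate(mod, methylation_matrix(m2), sim$pheno), drop)

  # missing beta imputed from stored training means
  m3 <- unclass(sim$m)
  m3[1, drop] <- NA
  p3 <- predict_surrogate(mod, methylation_matrix(m3), sim$pheno)
  manual <- predict_surrogate(mod, sim$m, sim$pheno)
  delta <- mod$cpg_weights[[drop]] * (mod$cpg_means[[drop]] - sim$m[1, drop])
  expect_equal(p3[[1]], manual[[1]] + delta, tolerance = 1e-12)

  # intercept-only model predicts a constant
  const <- surrogate_model("x", numeric(0), 0, 0, 3.5, train_mean = 3.5,
                           train_sd = 1)
  expect_equal(unname(predict_surrogate(const, sim$m, sim$pheno)),
               rep(3.5, nrow(sim$m)))

  # single-CpG hand example: w = 2, beta = 0.5, no demographics -> 1.0
  one <- surrogate_model("x", c(cgA = 2), 0, 0, 0, train_mean = 0, train_sd = 1)
  mm <- methylation_matrix(matrix(0.5, 1, 1), "s1", "cgA")
  expect_equal(unname(predict_surrogate(one, mm, data.frame(age = 70, female = 1))), 1)
})

test_that("fit_surrogate rejects unusable inputs", {
  sim <- simulate_cohort(n = 60, p = 12, truth = sim_truth(n_causal = 3, seed = 51))
  ph <- sim$pheno
  ph$flat <- 1
  expect_error(fit_surrogate(sim$m, ph, "flat", enet_spec(n_folds = 5)), "constant")
  expect_error(fit_surrogate(sim$m, ph, "CRP", enet_spec(n_folds = 100)), "n_folds")
  ph$sparse <- c(ph$CRP[1:10], rep(NA, 50))
  expect_error(fit_surrogate(sim$m, ph, "sparse", enet_spec(n_folds = 5)), "at least 50")
})
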