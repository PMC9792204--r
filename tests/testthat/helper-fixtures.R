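# Shared fixtures and independent oracles for the test suite.

# Small random beta matrix with IDs.
tiny_meth <- function(n = 20, p = 10, seed = 42) {
  set.seed(seed)
  methylation_matrix(matrix(runif(n * p, 0.05, 0.95), n, p),
                     sample_ids = sprintf("S%03d", seq_len(n)),
                     cpg_ids = sprintf("cg%08d", seq_len(p)))
}

tiny_pheno <- function(n = 20, seed = 43) {
  set.seed(seed)
  data.frame(sample_id = sprintf("S%03d", seq_len(n)),
             age = round(runif(n, 45, 85), 1),
             female = rbinom(n, 1, 0.5),
             time = round(rexp(n, 0.1) + 0.1, 3),
             event = rbinom(n, 1, 0.4),
             stringsAsFactors = FALSE)
}

# Independent deviance-residual oracle: naive O(n^2) textbook formula.
deviance_oracle <- function(time, event, lp) {
  n <- length(time)
  risk <- exp(lp)
  Lam <- numeric(n)
  ets <- sort(unique(time[event == 1]))
  for (i in seq_len(n)) {
    tot <- 0
    for (tj in ets[ets <= time[i]]) {
      dj <- sum(time == tj & event == 1)
      rj <- sum(risk[time >= tj])
      tot <- tot + dj / rj
    }
    Lam[i] <- tot
  }
  m <- event - Lam * risk
  sign(m) * sqrt(-2 * (m + ifelse(event == 1, log(event - m), 0)))
}

# Direct-formula biweight midcorrelation, written independently of bicor().
bicor_oracle <- function(x, y, c = 9) {
  mx <- median(x); my <- median(y)
  madx <- median(abs(x - mx)); mady <- median(abs(y - my))
  ux <- (x - mx) / (c * madx); uy <- (y - my) / (c * mady)
  wx <- ifelse(abs(ux) < 1, (1 - ux^2)^2, 0)
  wy <- ifelse(abs(uy) < 1, (1 - uy^2)^2, 0)
  sum(wx * wy * (x - mx) * (y - my)) /
    sqrt(sum((wx * (x - mx))^2) * sum((wy * (y - my))^2))
}

# Proportional-hazards data with known log-HR vector beta.
sim_cox_data <- function(n, beta, censor = 0.6, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * length(beta)), n, length(beta),
              dimnames = list(NULL, paste0("x", seq_along(beta))))
  lp <- as.numeric(X %*% beta)
  T <- (-log(runif(n)) / exp(lp))^(1 / 1.5) * 10
  C <- runif(n, 0, quantile(T, 1 - censor) * 2.5)
  list(X = X, time = pmin(T, C), event = as.integer(T <= C), lp = lp)
}
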