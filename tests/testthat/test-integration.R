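test_that("e^beta - 1 effects and the diagnostic cutoffs", {
  set.seed(71)
  n <- 100
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
             x4 = rnorm(n), x5 = rnorm(n))
  # counts follow the generator's convention (exp(mu) - 1), so the +1
  # pseudocount recovers mu without bias
  y_counts <- simulate_expression(X, beta0 = 3,
                                  betas = c(log(2), 0, 0, 0, 0),
                                  sigma = 0.2, seed = 171)
  fit <- fit_integration(X, y_counts, pseudocount = 1)
  # n = 100, k = 5: leverage cutoff 2k/n = 0.100, influence 4/94
  expect_equal(fit$leverage_cutoff, 0.1)
  expect_equal(fit$influence_cutoff, 4 / 94, tolerance = 1e-12)
  # beta = ln 2 -> effect ~ 1.0 (a 100 % increase per unit)
  i1 <- match("x1", fit$terms)
  expect_lt(abs(fit$effects[i1] - 1.0), 0.2)
  # a zero coefficient has effect ~ 0
  i2 <- match("x2", fit$terms)
  expect_lt(abs(fit$effects[i2]), 0.1)
  # identity of the transform, exactly
  expect_equal(fit$effects, exp(fit$betas) - 1)
})

test_that("rank deficiency and tiny n are rejected", {
  X <- cbind(a = 1:20, b = (1:20) * 2)
  expect_error(fit_integration(X, rexp(20)),
               class = "epicmml_validation_error")
  expect_error(fit_integration(cbind(a = 1:3), rexp(3)),
               class = "epicmml_validation_error")
})

test_that("the exclusion rule removes a planted high-influence outlier", {
  set.seed(72)
  n <- 80
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  y <- exp(1 + 0.5 * X[, "x1"] + rnorm(n, 0, 0.2))
  # plant one extreme-leverage, extreme-influence point
  X[1, ] <- c(8, 8)
  y[1] <- exp(12)
  fit <- fit_integration(X, y)
  expect_true("1" %in% fit$excluded$id)
  # the rule-compliant fit is closer to truth than the naive fit
  naive <- epicmml:::ols_fit(cbind(1, X), log(y + 1))
  expect_lt(abs(fit$betas[2] - 0.5), abs(naive$beta[2] - 0.5))
})

test_that("lmg shares: sum to R2, orthogonal split, k=2 closed form, brute force", {
  set.seed(73)
  # orthogonal centered covariates: share_j = marginal R2
  n <- 64
  x1 <- rep(c(-1, 1), n / 2)
  x2 <- rep(c(-1, -1, 1, 1), n / 4)
  y <- 2 * x1 + 1 * x2 + rnorm(n, 0, 0.5)
  sh <- lmg_shares(cbind(x1 = x1, x2 = x2), y)
  r2_1 <- summary(lm(y ~ x1))$r.squared
  r2_2 <- summary(lm(y ~ x2))$r.squared
  expect_equal(as.numeric(sh), c(r2_1, r2_2), tolerance = 1e-9)
  expect_equal(sum(sh), attr(sh, "r2"), tolerance = 1e-12)
  # correlated k = 2: explicit two-ordering average
  X <- cbind(a = rnorm(50), b = rnorm(50))
  X[, "b"] <- X[, "b"] + 0.7 * X[, "a"]
  yy <- X %*% c(1, 0.5) + rnorm(50, 0, 0.3)
  sh2 <- lmg_shares(X, yy)
  r2 <- function(f) summary(lm(yy ~ f))$r.squared
  want_a <- 0.5 * (r2(X[, "a"]) +
                     (r2(X) - r2(X[, "b"])))
  expect_equal(as.numeric(sh2["a"]), want_a, tolerance = 1e-10)
  # k <= 5 all-orderings brute force
  for (k in 3:5) {
    Xk <- matrix(rnorm(40 * k), 40, k)
    Xk[, 1] <- Xk[, 1] + 0.5 * Xk[, 2]
    yk <- Xk %*% runif(k, -1, 1) + rnorm(40, 0, 0.4)
    got <- lmg_shares(Xk, yk)
    expect_equal(as.numeric(got), lmg_brute(Xk, yk), tolerance = 1e-10)
    expect_equal(sum(got), attr(got, "r2"), tolerance = 1e-9)
    expect_true(all(got >= -1e-12))
  }
})

test_that("duplicated covariates split their joint contribution equally", {
  set.seed(74)
  x <- rnorm(60)
  y <- 2 * x + rnorm(60, 0, 0.3)
  sh <- lmg_shares(cbind(a = x, b = x + rnorm(60, 0, 1e-9)), y)
  expect_equal(as.numeric(sh["a"]), as.numeric(sh["b"]), tolerance = 1e-4)
})

test_that("exact lmg equals seeded ordering subsampling within Monte-Carlo error", {
  set.seed(75)
  X <- matrix(rnorm(80 * 6), 80, 6)
  X[, 2] <- X[, 2] + 0.6 * X[, 1]
  y <- X %*% c(1, 0.5, 0.2, 0, 0, -0.3) + rnorm(80, 0, 0.5)
  exact <- lmg_shares(X, y)
  approx <- lmg_shares(X, y, exact_max = 2, n_orderings = 4000, seed = 5)
  expect_lt(max(abs(exact - approx)), 0.02)
  expect_error(lmg_shares(matrix(rnorm(240 * 12), 240, 12), rnorm(240)),
               class = "epicmml_validation_error")
})

test_that("relative importance report ranks shares and normalizes percentages", {
  set.seed(76)
  X <- cbind(big = rnorm(100), small = rnorm(100))
  y_counts <- simulate_expression(X, beta0 = 3, betas = c(1.5, 0.1),
                                  sigma = 0.3, seed = 176)
  fit <- fit_integration(X, y_counts)
  rep <- relative_importance_report(fit)
  expect_equal(rep$covariate[1], "big")
  expect_equal(sum(rep$share_pct), 100, tolerance = 1e-6)
  # single covariate gets 100 % of R2
  fit1 <- fit_integration(cbind(only = rnorm(50)), rexp(50))
  rep1 <- relative_importance_report(fit1)
  expect_equal(rep1$share_pct, 100, tolerance = 1e-6)
})

test_that("planted betas are recovered through the full fit-exclude-refit path", {
  # a study-scale design: occupancy percentages, methylation percent,
  # binary presence covariates, with the generator's default effects
  set.seed(77)
  n <- 400
  X <- cbind(active_occ = 100 * rbeta(n, 0.4, 1.2),
             inactive_occ = 100 * rbeta(n, 0.4, 1.2),
             mc_pct = 100 * ifelse(runif(n) < 0.3, 0, rbeta(n, 2, 2)),
             hmc_present = rbinom(n, 1, 0.5),
             enh_present = rbinom(n, 1, 0.2))
  truth <- c(0.02, -0.01, 0.02, 0, 0.4)
  y <- simulate_expression(X, beta0 = 2, betas = truth, sigma = 0.5,
                           seed = 78)
  fit <- fit_integration(X, y)
  for (i in seq_along(truth)) {
    j <- i + 1  # skip intercept
    expect_lt(abs(fit$betas[j] - truth[i]), 3.5 * fit$se[j],
              label = fit$terms[j])
  }
  # with a dominant planted enhancer effect, enh_present tops the ranking
  y2 <- simulate_expression(X, beta0 = 2,
                            betas = c(0.005, 0, 0.005, 0, 2),
                            sigma = 0.5, seed = 79)
  fit2 <- fit_integration(X, y2)
  expect_equal(relative_importance_report(fit2)$covariate[1],
               "enh_present")
})
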