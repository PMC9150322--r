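test_that("survival_dataset materializes elementwise interactions", {
  dat <- make_cox_data(n = 30, q = 2, p = 4, interactions = TRUE)
  expect_equal(ncol(dat$U), 8)
  expect_equal(colnames(dat$U)[1:4], paste0("E1:G", 1:4))
  expect_equal(dat$U[, "E2:G3"], dat$E[, "E2"] * dat$X[, "G3"])
  expect_error(survival_dataset(c(1, -1), c(1, 0),
                                matrix(0, 2, 1), matrix(0, 2, 1)),
               "positive")
  expect_error(survival_dataset(c(1, 2), c(1, 2),
                                matrix(0, 2, 1), matrix(0, 2, 1)),
               "0/1")
})

test_that("null Cox fit reproduces martingale residuals and identities", {
  dat <- make_cox_data(n = 80, q = 2, alpha = c(0.7, -0.4), seed = 3)
  nf <- fit_null_cox(dat)
  # score equation at the MLE
  expect_lt(abs(sum(nf$m)), 1e-6)
  # independent oracle: coxph's own Breslow martingale residuals
  cp <- survival::coxph(survival::Surv(dat$time, dat$status) ~ dat$E,
                        ties = "breslow")
  expect_equal(nf$m, unname(residuals(cp, type = "martingale")),
               tolerance = 1e-8)
  expect_equal(nf$c, rowSums(nf$P))
  expect_equal(nf$V, t(nf$V))
  # residual range: m <= 1 overall, censored subjects nonpositive
  expect_true(all(nf$m <= 1))
  expect_true(all(nf$m[dat$status == 0] <= 0))
  expect_error(fit_null_cox(time = 1:3, status = c(0, 0, 0),
                            E = matrix(rnorm(3))),
               "event")
})

test_that("V is PSD off the indicator directions on random instances", {
  for (seed in 1:4) {
    dat <- make_cox_data(n = 40, q = 2, alpha = c(0.5, 0.2), seed = seed)
    nf <- fit_null_cox(dat)
    ev <- eigen((nf$V + t(nf$V)) / 2, symmetric = TRUE,
                only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(abs(ev)))
  }
})

test_that("null fit Breslow machinery matches a hand-computed example", {
  # 3 subjects, one binary covariate, all events, times 1 < 2 < 3,
  # x = (1, 0, 1).  With b the partial-likelihood MLE:
  #   score: [e^b/(2e^b+1) - ... ] solved below by uniroot, then
  #   Breslow increments 1/S0(t_j) and martingale residuals by hand.
  tt <- c(1, 2, 3); dd <- c(1, 1, 1); x <- c(1, 0, 1)
  score <- function(b) {
    s1 <- 2 * exp(b) + 1; s2 <- exp(b) + 1; s3 <- exp(b)
    (1 - 2 * exp(b) / s1) + (0 - exp(b) / s2) + (1 - 1)
  }
  b <- uniroot(score, c(-5, 5), tol = 1e-12)$root
  h <- c(1 / (2 * exp(b) + 1), 1 / (exp(b) + 1), 1 / exp(b))
  ch <- c(exp(b) * h[1], sum(h[1:2]), exp(b) * sum(h))
  nf <- fit_null_cox(time = tt, status = dd, E = matrix(x, ncol = 1))
  expect_equal(nf$alpha, b, tolerance = 1e-6)
  expect_equal(nf$dLambda0, h, tolerance = 1e-6)
  expect_equal(nf$m, 1 - ch, tolerance = 1e-6)
})

test_that("penalized Cox wrapper is deterministic and drops constants", {
  dat <- make_cox_data(n = 100, q = 2, p = 8, alpha = c(1, 0),
                       beta = c(1.2, rep(0, 7)), seed = 5)
  design <- cbind(dat$E, dat$X, const = rep(2, dat$n))
  expect_warning(
    fit <- fit_penalized_cox(dat$time, dat$status, design,
                             penalty = "lasso", folds = 5, seed = 9),
    "constant")
  expect_false("const" %in% names(fit$coef))
  fit2 <- suppressWarnings(
    fit_penalized_cox(dat$time, dat$status, design, penalty = "lasso",
                      folds = 5, seed = 9))
  expect_identical(fit$coef, fit2$coef)
  # the injected strong signal survives selection
  expect_true(fit$coef["G1"] != 0)
})

test_that("ridge treats duplicated columns symmetrically", {
  dat <- make_cox_data(n = 90, q = 1, p = 2, beta = c(1, 0), seed = 7)
  design <- cbind(a = dat$X[, 1], b = dat$X[, 1], c = dat$X[, 2])
  fit <- fit_penalized_cox(dat$time, dat$status, design,
                           penalty = "ridge", folds = 5, seed = 2,
                           thresh = 1e-14)
  expect_lt(abs(fit$coef[["a"]] - fit$coef[["b"]]), 1e-6)
})

test_that("prognostic index is the named linear predictor", {
  model <- list(coef = c(a = 0.5, b = -2))
  nd <- cbind(b = c(1, 0), a = c(2, 4))   # order must not matter
  expect_equal(prognostic_index(model, nd), c(0.5 * 2 - 2, 0.5 * 4))
  expect_error(prognostic_index(model, cbind(a = 1)), "lacks")
})

test_that("vectorized univariate Cox scan matches coxph Wald statistics", {
  dat <- make_cox_data(n = 120, q = 1, p = 6, beta = c(1, -0.8, 0, 0, 0, 0),
                       seed = 11)
  scan <- univariate_cox_scan(dat$time, dat$status, dat$X)
  for (j in c(1, 2, 5)) {
    cp <- summary(survival::coxph(
      survival::Surv(dat$time, dat$status) ~ dat$X[, j],
      ties = "breslow"))
    expect_equal(scan$coef[j], unname(cp$coefficients[1, "coef"]),
                 tolerance = 1e-4)
    expect_equal(scan$z[j], unname(cp$coefficients[1, "z"]),
                 tolerance = 1e-3)
  }
})

test_that("Breslow log partial likelihood agrees with coxph", {
  dat <- make_cox_data(n = 70, q = 2, alpha = c(0.6, -0.3), seed = 13)
  cp <- survival::coxph(survival::Surv(dat$time, dat$status) ~ dat$E,
                        ties = "breslow")
  eta <- as.numeric(dat$E %*% coef(cp))
  expect_equal(cox_loglik(dat$time, dat$status, eta), cp$loglik[2],
               tolerance = 1e-8)
  expect_equal(cox_loglik(dat$time, dat$status, rep(0, dat$n)),
               cp$loglik[1], tolerance = 1e-8)
})
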