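test_that("interaction blocks are environment-major elementwise products", {
  dat <- make_cox_data(n = 4, q = 2, p = 3, seed = 1)
  R <- interaction_block(dat$E, dat$X, c("G1", "G3"))
  expect_equal(colnames(R), c("E1:G1", "E1:G3", "E2:G1", "E2:G3"))
  expect_equal(unname(R[, "E1:G3"]), unname(dat$E[, 1] * dat$X[, 3]))
  expect_equal(unname(R[, "E2:G1"]), unname(dat$E[, 2] * dat$X[, 1]))
  # q = 1: block equals the gene columns scaled by the E column
  R1 <- interaction_block(dat$E[, 1, drop = FALSE], dat$X, c("G1", "G2"))
  expect_equal(unname(R1), unname(dat$E[, 1] * dat$X[, 1:2]))
  # l = q * g
  big <- make_cox_data(n = 10, q = 5, p = 9, seed = 2)
  expect_equal(ncol(interaction_block(big$E, big$X, paste0("G", 1:9))),
               45)
  expect_error(interaction_block(dat$E, dat$X, character(0)), "empty")
})

test_that("unsupervised weights follow the Beta(1,25) density formula", {
  set.seed(3)
  R <- matrix(rnorm(40 * 6) * rep(c(1, 2, 0.5, 1, 3, 1), each = 40),
              40, 6)
  W <- unsupervised_weights(R)
  v <- apply(R, 2, var) / sum(apply(R, 2, var))
  expect_equal(sum(v), 1)
  expect_equal(W, (25 * (1 - v)^24)^2, tolerance = 1e-12,
               ignore_attr = TRUE)
  # v -> 0 limit gives sqrt(W) -> 25
  expect_equal(dbeta(0, 1, 25), 25)
  # single-column fallback
  expect_message(W1 <- unsupervised_weights(matrix(rnorm(20), 20, 1)),
                 "W = 1")
  expect_equal(W1, 1)
  expect_error(unsupervised_weights(matrix(0, 10, 3)), "zero variance")
})

test_that("SKAT statistic equals its brute-force evaluation", {
  set.seed(4)
  m <- rnorm(6); R <- matrix(rnorm(18), 6, 3); W <- runif(3, 0.5, 2)
  Qb <- 0
  for (j in 1:3) {
    acc <- 0
    for (i in 1:6) acc <- acc + R[i, j] * m[i]
    Qb <- Qb + (W[j] * acc)^2
  }
  expect_equal(skat_statistic(m, R, W), Qb, tolerance = 1e-10)
  expect_equal(skat_statistic(rep(0, 6), R, W), 0)
  # W = I, single column: Q = (r'm)^2
  r <- R[, 1, drop = FALSE]
  expect_equal(skat_statistic(m, r, 1), sum(r * m)^2)
})

test_that("SKAT covariance matches the naive matrix formula", {
  dat <- make_cox_data(n = 35, q = 2, p = 4, alpha = c(0.5, -0.2),
                       seed = 6)
  nf <- fit_null_cox(dat)
  R <- interaction_block(dat$E, dat$X, paste0("G", 1:3))
  w <- runif(ncol(R), 0.2, 2)
  got <- skat_covariance(R, w, nf)
  V <- diag(nf$c) - nf$P %*% t(nf$P)
  E <- dat$E
  Mv <- V - V %*% E %*% solve(t(E) %*% V %*% E) %*% t(E) %*% V
  naive <- diag(w) %*% t(R) %*% Mv %*% R %*% diag(w)
  expect_equal(got$Sigma, naive, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(got$Sigma, t(got$Sigma), tolerance = 1e-12)
  # W = 0 collapses everything
  z <- skat_covariance(R, rep(0, ncol(R)), nf)
  expect_true(all(z$Sigma == 0))
  expect_length(z$eigenvalues, 0)
  # projection property: shifting R by E-plane columns changes nothing
  B <- matrix(rnorm(2 * ncol(R)), 2, ncol(R))
  got2 <- skat_covariance(R + E %*% B, w, nf)
  expect_equal(got2$Sigma, got$Sigma, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("weighted chi-square tails match closed forms", {
  # chi^2_1 95th percentile
  expect_equal(weighted_chisq_tail(1, qchisq(0.95, 1))$p, 0.05,
               tolerance = 1e-4)
  # equal weights = chi^2_3 survival on a grid
  for (q in seq(0.5, 14, length.out = 10))
    expect_equal(weighted_chisq_tail(c(1, 1, 1), q)$p,
                 pchisq(q, 3, lower.tail = FALSE), tolerance = 1e-5)
  expect_equal(weighted_chisq_tail(c(2, 0.3), 0)$p, 1)
  deg <- weighted_chisq_tail(numeric(0), 5)
  expect_equal(deg$p, 0)
  expect_true(deg$degenerate)
})

test_that("moment-matching fallback is itself a sane approximation", {
  # the Liu tail is only used when quadrature fails; check it directly
  for (q in c(2, 6, 12))
    expect_equal(ogscreen:::liu_tail(c(1, 1, 1), q),
                 pchisq(q, 3, lower.tail = FALSE), tolerance = 1e-6)
  lam <- c(3, 1, 0.5, 0.1)
  for (q in c(2, 8, 20))
    expect_lt(abs(ogscreen:::liu_tail(lam, q) -
                  weighted_chisq_tail(lam, q)$p), 0.03)
})

test_that("group p-values are invariant to weight rescaling", {
  dat <- make_cox_data(n = 40, q = 2, p = 5, alpha = c(0.4, 0.1),
                       seed = 8)
  nf <- fit_null_cox(dat)
  R <- interaction_block(dat$E, dat$X, paste0("G", 1:4))
  w <- unsupervised_weights(R)
  p_of <- function(w) {
    Q <- skat_statistic(nf$m, R, w)
    ev <- skat_covariance(R, w, nf)$eigenvalues
    weighted_chisq_tail(ev, Q)$p
  }
  p1 <- p_of(w)
  for (cc in c(1e-3, 7, 1e4))
    expect_equal(p_of(cc * w), p1, tolerance = 1e-8)
})

test_that("permuted covariates give roughly uniform group p-values", {
  # sanity: under row permutation p-values should not pile up near 0
  dat <- make_cox_data(n = 90, q = 2, p = 12, alpha = c(0.5, -0.5),
                       beta = c(rep(0.8, 3), rep(0, 9)), seed = 10)
  set.seed(77)
  ps <- replicate(40, {
    pi_r <- sample.int(dat$n)
    Ep <- dat$E[pi_r, , drop = FALSE]; Xp <- dat$X[pi_r, , drop = FALSE]
    nf <- fit_null_cox(time = dat$time, status = dat$status, E = Ep)
    skat_group_pvalue(nf, Ep, Xp, paste0("G", 1:4))$p
  })
  expect_lte(mean(ps < 0.05), 0.15)
})
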