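## SKAT variance-component test for a block of G-E interaction columns
## under the null Cox model (environment only), with Beta(1,25)-density
## unsupervised weights and Davies/Imhof weighted-chi-square tails.

#' Interaction block of one candidate pathway
#'
#' Returns the `N x l` matrix of interaction columns (`l = q * g` for `g`
#' pathway genes), environment-major ordered, entries the elementwise
#' products of the parent columns.
#'
#' @param E N x q environment matrix.
#' @param X N x p expression matrix (column-named).
#' @param genes Character vector of pathway genes (subset of
#'   `colnames(X)`).
#' @return N x (q * length(genes)) matrix with `Ej:Gk` column names.
#' @export
interaction_block <- function(E, X, genes) {
  if (length(genes) == 0L) stop("empty pathway")
  build_interactions(E, X, genes = genes)
}

#' Unsupervised Beta(1,25)-density interaction weights
#'
#' With `v_i` the share of column i in the total sample variance of the
#' block, the square root of the weight is the Beta(1, 25) density at
#' `v_i`: `sqrt(W_ii) = 25 (1 - v_i)^24`.  For a single-column block the
#' density at `v = 1` is zero, which would make the group untestable, so
#' the weight falls back to 1 (with a message).
#'
#' @param R Interaction block from [interaction_block()].
#' @return Numeric vector of diagonal weights `W_ii` (the squared
#'   densities).
#' @export
unsupervised_weights <- function(R) {
  R <- as.matrix(R)
  n <- nrow(R)
  vars <- (colSums(R^2) - n * colMeans(R)^2) / (n - 1)
  tot <- sum(vars)
  if (tot <= 0) stop("all interaction columns have zero variance")
  v <- vars / tot
  w_sqrt <- stats::dbeta(v, 1, 25)         # = 25 (1 - v)^24 on [0, 1)
  if (ncol(R) == 1L) {
    message("single-column group: Beta(1,25) weight degenerates; ",
            "using W = 1")
    w_sqrt <- 1
  }
  w_sqrt^2
}

#' SKAT statistic for a weighted interaction block
#'
#' `Q = m' R W W R' m = || W R' m ||^2`, with `m` the martingale residuals
#' of the null Cox fit and `W` the diagonal weight matrix.
#'
#' @param m Martingale residual vector.
#' @param R N x l interaction block.
#' @param W Diagonal weights: vector of length l (the `W_ii`), or an
#'   l x l diagonal matrix.
#' @return Nonnegative scalar Q.
#' @export
skat_statistic <- function(m, R, W) {
  R <- as.matrix(R)
  w <- if (is.matrix(W)) diag(W) else as.numeric(W)
  if (length(w) != ncol(R)) stop("W has wrong length")
  if (length(m) != nrow(R)) stop("m has wrong length")
  s <- w * as.numeric(crossprod(R, m))
  sum(s^2)
}

#' Null covariance of the weighted interaction score and its eigenvalues
#'
#' `Sigma = W R' (V - V E (E'VE)^{-1} E' V) R W`, the covariance of
#' `W R' m` under the null of no interaction effects, where `V = diag(c) -
#' P P'` comes from the null Cox fit.  Eigenvalues are from a symmetric
#' decomposition, truncated below `1e-10 * lambda_max`.
#'
#' @param R N x l interaction block.
#' @param W Diagonal weights (vector or diagonal matrix).
#' @param null A [fit_null_cox()] result.
#' @return List with `Sigma` (l x l) and `eigenvalues` (descending,
#'   truncated).
#' @export
skat_covariance <- function(R, W, null) {
  stopifnot(inherits(null, "NullCoxFit"))
  R <- as.matrix(R)
  w <- if (is.matrix(W)) diag(W) else as.numeric(W)
  E <- null$E
  VR <- null$c * R - null$P %*% crossprod(null$P, R)
  VE <- null$c * E - null$P %*% crossprod(null$P, E)
  EVE <- crossprod(E, VE)
  cn <- kappa(EVE, exact = TRUE)
  if (!is.finite(cn) || cn > 1e12)
    stop("E'VE is numerically singular (condition number ",
         format(cn, digits = 3), ")")
  EVR <- crossprod(VE, R)                  # E'V R  (q x l)
  core <- crossprod(R, VR) - crossprod(EVR, solve(EVE, EVR))
  Sigma <- w * t(w * core)                 # W %*% core %*% W, symmetrized
  Sigma <- (Sigma + t(Sigma)) / 2
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > 1e-10 * max(ev, 0)]
  list(Sigma = Sigma, eigenvalues = ev)
}

imhof_integrand <- function(u, lambda, q) {
  theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
  rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
  val <- sin(theta) / (u * rho)
  val[u == 0] <- 0.5 * (sum(lambda) - q)   # limit as u -> 0
  val
}

#' Tail probability of a positively weighted sum of 1-df chi-squares
#'
#' Computes `P(sum_j lambda_j chisq_1j > q_obs)` by adaptive quadrature of
#' the Imhof characteristic-function inversion integral (absolute
#' tolerance 1e-6, integration interval doubled until the analytic tail
#' bound is negligible).  Falls back to Liu-type four-moment matching when
#' the inversion fails.  The result is clipped to `[1e-14, 1]`.
#'
#' @param lambda Nonnegative eigenvalues (zeros are dropped).
#' @param q_obs Observed statistic, `>= 0`.
#' @return List with `p`, `method_used` (`"davies"` or
#'   `"moment-matching"`), and `degenerate` flag.
#' @export
weighted_chisq_tail <- function(lambda, q_obs) {
  lambda <- lambda[lambda > 0]
  if (q_obs < 0) stop("q_obs must be nonnegative")
  if (length(lambda) == 0L) {
    return(list(p = if (q_obs > 0) 0 else 1, method_used = "davies",
                degenerate = TRUE))
  }
  if (q_obs == 0)
    return(list(p = 1, method_used = "davies", degenerate = FALSE))
  # the tail probability is invariant to a common rescaling of the
  # eigenvalues and the statistic; normalize for quadrature conditioning
  sc <- max(lambda)
  lambda <- lambda / sc
  q_obs <- q_obs / sc
  # eigenvalues below 1e-6 of the largest shift the tail probability by
  # O(1e-6); dropping them keeps the quadrature cheap for wide blocks
  lambda <- lambda[lambda > 1e-6]
  # upper limit: analytic bound on the neglected tail.  For any subset S
  # of the eigenvalues, |f(u)| <= u^{-(1 + |S|/2)} / sqrt(prod_S lambda),
  # which integrates to (2/|S|) U^{-|S|/2} / sqrt(prod_S lambda); use the
  # dominant eigenvalues so the bound is not wrecked by near-zero ones,
  # and double U until the bound is negligible
  # upper limit from the analytic tail bound, valid for any eigenvalue
  # subset S: |f(u)| <= u^{-(1 + |S|/2)} / sqrt(prod_S lambda).  Larger
  # thresholds give fewer but larger factors; take the best U over a few
  U_for <- function(thr) {
    dom <- lambda[lambda >= thr]
    ls <- length(dom)
    if (ls == 0L) return(Inf)
    log_pl <- 0.5 * sum(log(dom))
    U <- 1
    repeat {
      # direct envelope integral beyond U
      b_env <- exp(log(2 / ls) - (ls / 2) * log(U) - log_pl)
      # oscillation bound: beyond U the integrand is ~sin(q u / 2 + phi)
      # times a monotone envelope, so the tail is <= (4/q) envelope(U)
      b_osc <- exp(log(4 / max(q_obs, 1e-3)) -
                   (1 + ls / 2) * log(U) - log_pl)
      if (min(b_env, b_osc) < 1e-7 * pi || U > 1e9) break
      U <- U * 2
    }
    U
  }
  U <- min(vapply(c(0.5, 0.1, 1e-2, 1e-3), U_for, numeric(1)))
  # composite Simpson with a step tied to the oscillation frequency
  # (|theta'(u)| <= (sum lambda + q) / 2), refined once as an error check
  freq <- 0.5 * (sum(lambda) + q_obs)
  simpson <- function(npt) {
    npt <- 2L * ceiling(npt / 2)
    u <- seq(0, U, length.out = npt + 1L)
    f <- imhof_integrand(u, lambda, q_obs)
    h <- U / npt
    idx <- seq(2L, npt, by = 2L)
    (h / 3) * (f[1] + f[npt + 1L] + 4 * sum(f[idx]) +
               2 * sum(f[seq(3L, npt - 1L, by = 2L)]))
  }
  npt <- min(max(1000, ceiling(U * freq * 40 / (2 * pi))), 2^21)
  p <- tryCatch({
    i1 <- simpson(npt)
    i2 <- simpson(2L * npt)
    if (abs(i1 - i2) > 1e-6 * pi) NA_real_ else 0.5 + i2 / pi
  }, error = function(e) NA_real_)
  method <- "davies"
  if (!is.na(p) && (p < -1e-4 || p > 1 + 1e-4)) p <- NA_real_
  if (is.na(p)) {
    p <- liu_tail(lambda, q_obs)
    method <- "moment-matching"
  }
  list(p = min(max(p, 1e-14), 1), method_used = method,
       degenerate = FALSE)
}

## Liu-Tang-Zhang four-moment chi-square approximation (fallback).
liu_tail <- function(lambda, q_obs) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    df <- a^2 - 2 * delta
  } else {
    a <- 1 / s1
    delta <- 0
    df <- a^2
  }
  mu_q <- c1; sigma_q <- sqrt(2 * c2)
  t_star <- (q_obs - mu_q) / sigma_q
  q_chi <- t_star * sqrt(2 * (df + 2 * delta)) + df + delta
  stats::pchisq(q_chi, df = df, ncp = delta, lower.tail = FALSE)
}

#' SKAT p-value for one candidate pathway's G-E interaction block
#'
#' Composes [interaction_block()], [unsupervised_weights()],
#' [skat_statistic()], [skat_covariance()] and [weighted_chisq_tail()].
#'
#' @param null A [fit_null_cox()] result.
#' @param E,X Covariate matrices (rows aligned with the null fit).
#' @param genes Pathway gene names.
#' @param group_id Optional label carried into the result.
#' @return Object of class `SkatResult`: `Q`, `eigenvalues`, `p`,
#'   `method_used`, `group_id`, `l`.
#' @export
skat_group_pvalue <- function(null, E, X, genes, group_id = NA_character_) {
  R <- interaction_block(E, X, genes)
  W <- unsupervised_weights(R)
  Q <- skat_statistic(null$m, R, W)
  cov <- skat_covariance(R, W, null)
  tail <- weighted_chisq_tail(cov$eigenvalues, Q)
  structure(list(Q = Q, eigenvalues = cov$eigenvalues, p = tail$p,
                 method_used = tail$method_used, group_id = group_id,
                 l = ncol(R)),
            class = "SkatResult")
}

#' @export
print.SkatResult <- function(x, ...) {
  cat("SkatResult", if (!is.na(x$group_id)) paste0(" [", x$group_id, "]"),
      ": Q = ", signif(x$Q, 5), ", l = ", x$l, ", p = ",
      format(x$p, digits = 4), " (", x$method_used, ")\n", sep = "")
  invisible(x)
}
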