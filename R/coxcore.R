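#' Assemble a survival dataset with environment, gene and interaction blocks
#'
#' @param time Positive observed times (event or censoring).
#' @param status Event indicator, 1 = event, 0 = censored.
#' @param E N x q numeric matrix of environmental/clinical covariates
#'   (column-named; default names `E1..Eq`).
#' @param X N x p numeric expression matrix (column-named; default
#'   `G1..Gp`).
#' @param interactions If `TRUE` (default) materialize the N x (q*p)
#'   interaction block `U`, ordered environment-major
#'   (`E1:G1 ... E1:Gp, E2:G1, ...`) with `Ej:Gk` column names.
#' @return Object of class `SurvivalDataset` with fields `time`, `status`,
#'   `E`, `X`, `U` (or `NULL`), `n`, `q`, `p`.
#' @export
survival_dataset <- function(time, status, E, X, interactions = TRUE) {
  time <- as.numeric(time); status <- as.numeric(status)
  E <- as.matrix(E); X <- as.matrix(X)
  n <- length(time)
  if (length(status) != n || nrow(E) != n || nrow(X) != n)
    stop("time, status, E and X must have a common number of rows")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("times must be positive and finite")
  if (!all(status %in% c(0, 1))) stop("status must be 0/1")
  if (ncol(E) > 0L && is.null(colnames(E)))
    colnames(E) <- paste0("E", seq_len(ncol(E)))
  if (is.null(colnames(X))) colnames(X) <- paste0("G", seq_len(ncol(X)))
  U <- if (isTRUE(interactions) && ncol(E) > 0L)
    build_interactions(E, X) else NULL
  structure(list(time = time, status = status, E = E, X = X, U = U,
                 n = n, q = ncol(E), p = ncol(X)),
            class = "SurvivalDataset")
}

#' @export
print.SurvivalDataset <- function(x, ...) {
  cat("SurvivalDataset: n = ", x$n, ", q = ", x$q, " environments, p = ",
      x$p, " genes (", round(100 * mean(x$status == 0), 1),
      "% censored)\n", sep = "")
  invisible(x)
}

#' Environment-major interaction design
#'
#' Columns are elementwise products `Ej * Gk`, ordered
#' `E1:G1 ... E1:Gp, E2:G1, ..., Eq:Gp`.
#'
#' @param E N x q environment matrix.
#' @param X N x p expression matrix.
#' @param genes Optional subset of `colnames(X)` to use (in the given
#'   order); default all genes.
#' @return N x (q * length(genes)) matrix with `Ej:Gk` column names.
#' @export
build_interactions <- function(E, X, genes = NULL) {
  E <- as.matrix(E); X <- as.matrix(X)
  if (is.null(colnames(E))) colnames(E) <- paste0("E", seq_len(ncol(E)))
  if (is.null(colnames(X))) colnames(X) <- paste0("G", seq_len(ncol(X)))
  if (!is.null(genes)) {
    miss <- setdiff(genes, colnames(X))
    if (length(miss))
      stop("genes absent from expression matrix: ",
           paste(utils::head(miss, 5L), collapse = ", "))
    X <- X[, genes, drop = FALSE]
  }
  if (ncol(X) == 0L) stop("no genes to interact")
  q <- ncol(E); p <- ncol(X)
  U <- matrix(0, nrow(E), q * p)
  for (j in seq_len(q))
    U[, ((j - 1L) * p + 1L):(j * p)] <- E[, j] * X
  colnames(U) <- as.vector(t(outer(colnames(E), colnames(X),
                                   paste, sep = ":")))
  U
}

#' Null Cox model fit with martingale residuals and baseline machinery
#'
#' Fits the Cox model on the environmental covariates only (Breslow ties),
#' then assembles the quantities the SKAT test needs: Breslow
#' baseline-hazard increments at the `nu` distinct event times, the
#' N x nu matrix `P` with `p_ij = at-risk(i, t_(j)) * exp(e_i' alpha) *
#' dLambda0(t_(j))`, cumulative hazards `c = rowSums(P)`, martingale
#' residuals `m = status - c`, and `V = diag(c) - P P'`.
#'
#' @param data A [survival_dataset()], or `NULL` when `time`, `status`,
#'   `E` are given directly.
#' @param time,status,E Alternative direct inputs.
#' @return Object of class `NullCoxFit` with fields `alpha`, `m`,
#'   `hazard_times`, `dLambda0`, `P`, `c`, `V`, `E`, `n`, `nu`.
#' @export
fit_null_cox <- function(data = NULL, time = NULL, status = NULL,
                         E = NULL) {
  if (!is.null(data)) {
    stopifnot(inherits(data, "SurvivalDataset"))
    time <- data$time; status <- data$status; E <- data$E
  }
  E <- as.matrix(E)
  if (sum(status) < 1) stop("the null Cox fit requires at least one event")
  if (qr(E)$rank < ncol(E)) stop("E must have full column rank")
  fit <- survival::coxph(survival::Surv(time, status) ~ E,
                         ties = "breslow",
                         control = survival::coxph.control(iter.max = 50))
  if (!is.null(fit$info) && isTRUE(fit$info$flag > 0))
    stop("null Cox fit did not converge")
  alpha <- unname(stats::coef(fit))
  if (anyNA(alpha)) stop("null Cox fit produced NA coefficients")
  risk <- as.numeric(exp(E %*% alpha))
  tev <- sort(unique(time[status == 1]))
  nu <- length(tev)
  # Breslow: dLambda0(t_(j)) = d_j / sum_{l at risk} exp(eta_l)
  dj <- vapply(tev, function(s) sum(status == 1 & time == s), numeric(1))
  S0 <- vapply(tev, function(s) sum(risk[time >= s]), numeric(1))
  dL <- dj / S0
  at_risk <- outer(time, tev, ">=")            # N x nu
  P <- at_risk * (risk %o% dL)
  cc <- rowSums(P)
  m <- status - cc
  V <- diag(cc) - tcrossprod(P)
  structure(list(alpha = alpha, m = m, hazard_times = tev, dLambda0 = dL,
                 P = P, c = cc, V = V, E = E, n = length(time), nu = nu),
            class = "NullCoxFit")
}

#' @export
print.NullCoxFit <- function(x, ...) {
  cat("NullCoxFit: n = ", x$n, ", ", x$nu, " distinct event times\n",
      "  alpha-hat: ", paste(signif(x$alpha, 4), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

## Event-stratified fold assignment so every CV fold sees events.
stratified_folds <- function(status, nfolds) {
  folds <- integer(length(status))
  for (s in c(0, 1)) {
    idx <- which(status == s)
    if (length(idx))
      folds[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  folds
}

#' Ridge- or Lasso-penalized Cox regression with CV-selected penalty
#'
#' Thin wrapper around [glmnet::cv.glmnet()] (partial-likelihood deviance,
#' `lambda.min` rule) with event-stratified folds and a deterministic
#' seed.  All-constant columns are dropped with a warning.  Columns may be
#' exempted from the penalty via `unpenalized`.
#'
#' @param time,status Survival outcome.
#' @param design Named numeric matrix of covariates.
#' @param penalty `"lasso"` or `"ridge"`.
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed controlling the fold assignment.
#' @param unpenalized Optional character vector of column names left
#'   unpenalized.
#' @param ... Further arguments passed to [glmnet::cv.glmnet()] (e.g.
#'   `thresh`).
#' @return Object of class `FinalModel`: named `coef` on the original
#'   covariate scale, `lambda`, `penalty`, plus the underlying cv.glmnet
#'   fit.  Use [prognostic_index()] for test-set scores.
#' @export
fit_penalized_cox <- function(time, status, design,
                              penalty = c("lasso", "ridge"),
                              folds = 10L, seed = 1L,
                              unpenalized = NULL, ...) {
  penalty <- match.arg(penalty)
  design <- as.matrix(design)
  if (is.null(colnames(design)))
    colnames(design) <- paste0("V", seq_len(ncol(design)))
  if (sum(status) < 2) stop("need at least two events")
  keep <- apply(design, 2, function(z) stats::sd(z) > 0)
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " all-constant column(s): ",
            paste(utils::head(colnames(design)[!keep], 5L),
                  collapse = ", "))
    design <- design[, keep, drop = FALSE]
  }
  if (ncol(design) == 0L) stop("design has no usable column")
  pf <- rep(1, ncol(design))
  if (!is.null(unpenalized))
    pf[colnames(design) %in% unpenalized] <- 0
  y <- survival::Surv(time, status)
  set.seed(seed)
  foldid <- stratified_folds(status, folds)
  alpha <- if (penalty == "lasso") 1 else 0
  cv <- glmnet::cv.glmnet(design, y, family = "cox", alpha = alpha,
                          foldid = foldid, penalty.factor = pf,
                          lambda.min.ratio = 1e-2, nlambda = 100,
                          standardize = TRUE, ...)
  beta <- as.numeric(stats::coef(cv, s = "lambda.min"))
  names(beta) <- colnames(design)
  structure(list(coef = beta, lambda = cv$lambda.min, penalty = penalty,
                 cv = cv, features = colnames(design)),
            class = "FinalModel")
}

#' @export
print.FinalModel <- function(x, ...) {
  cat("FinalModel (", x$penalty, "): ", sum(x$coef != 0), " of ",
      length(x$coef), " coefficients nonzero, lambda = ",
      signif(x$lambda, 4), "\n", sep = "")
  invisible(x)
}

#' Prognostic-index scores of a fitted model on new data
#'
#' PI_i = covariate row i times the coefficient vector, matched by column
#' name; model features absent from `newdata` are an error.
#'
#' @param model A `FinalModel` (or any list with a named `coef` vector).
#' @param newdata Matrix of covariates with column names.
#' @return Numeric vector of PI scores.
#' @export
prognostic_index <- function(model, newdata) {
  beta <- model$coef
  miss <- setdiff(names(beta), colnames(newdata))
  if (length(miss))
    stop("newdata lacks model feature(s): ",
         paste(utils::head(miss, 5L), collapse = ", "))
  as.numeric(as.matrix(newdata)[, names(beta), drop = FALSE] %*% beta)
}

#' Univariate Cox Wald screening statistics, vectorized across columns
#'
#' For every column of `design` fits the single-covariate Cox model by
#' Newton iterations on the Breslow partial likelihood (all columns in
#' parallel via risk-set reverse cumulative sums) and returns Wald
#' z-statistics and two-sided p-values.  This is the ranking engine of the
#' SIS-Lasso comparator.
#'
#' @param time,status Survival outcome.
#' @param design N x p covariate matrix.
#' @param iter Newton iterations (default 8).
#' @return Data frame with `feature`, `coef`, `z`, `p`.
#' @export
univariate_cox_scan <- function(time, status, design, iter = 8L) {
  design <- as.matrix(design)
  if (is.null(colnames(design)))
    colnames(design) <- paste0("V", seq_len(ncol(design)))
  n <- length(time); p <- ncol(design)
  ord <- order(time)
  tt <- time[ord]; dd <- status[ord]
  Xs <- design[ord, , drop = FALSE]
  # risk set of row i (ascending time) = rows i..n, extended to tie starts
  first_idx <- match(tt, tt)             # first row of each tie group
  ev <- which(dd == 1)
  ev_first <- first_idx[ev]
  revcum <- function(M) {
    M <- apply(M[n:1, , drop = FALSE], 2, cumsum)
    M[n:1, , drop = FALSE]
  }
  beta <- rep(0, p)
  for (it in seq_len(iter)) {
    eta <- sweep(Xs, 2, beta, "*")
    eta <- sweep(eta, 2, apply(eta, 2, max), "-")   # guard overflow
    Ee <- exp(eta)
    S0 <- revcum(Ee)
    S1 <- revcum(Xs * Ee)
    S2 <- revcum(Xs * Xs * Ee)
    r0 <- S0[ev_first, , drop = FALSE]
    xbar <- S1[ev_first, , drop = FALSE] / r0
    U <- colSums(Xs[ev, , drop = FALSE] - xbar)
    I <- colSums(S2[ev_first, , drop = FALSE] / r0 - xbar^2)
    step <- ifelse(I > 1e-12, U / I, 0)
    step <- pmin(pmax(step, -2), 2)      # damped for stability
    beta <- beta + step
  }
  # final information at beta for the Wald statistic
  eta <- sweep(Xs, 2, beta, "*")
  eta <- sweep(eta, 2, apply(eta, 2, max), "-")
  Ee <- exp(eta)
  S0 <- revcum(Ee); S1 <- revcum(Xs * Ee); S2 <- revcum(Xs * Xs * Ee)
  r0 <- S0[ev_first, , drop = FALSE]
  xbar <- S1[ev_first, , drop = FALSE] / r0
  I <- colSums(S2[ev_first, , drop = FALSE] / r0 - xbar^2)
  z <- ifelse(I > 1e-12, beta * sqrt(I), 0)
  data.frame(feature = colnames(design), coef = beta, z = z,
             p = 2 * stats::pnorm(-abs(z)),
             row.names = NULL, stringsAsFactors = FALSE)
}
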