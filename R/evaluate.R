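## Performance measures and the replicate benchmark harness with Oracle,
## SIS-Lasso and Ordinary-Lasso comparators.

#' Root mean squared error over the full coefficient vector
#'
#' `sqrt(mean((theta - theta_hat)^2))` over all `S` model coefficients;
#' unselected features contribute `theta_hat = 0`.
#'
#' @param theta_hat,theta_true Equal-length numeric vectors.
#' @return Scalar RMSE.
#' @export
rmse <- function(theta_hat, theta_true) {
  if (length(theta_hat) != length(theta_true))
    stop("coefficient vectors differ in length")
  sqrt(mean((theta_true - theta_hat)^2))
}

#' Selection sensitivity, specificity, interaction coverage and size
#'
#' Over a common feature universe: `sen = |selected & true| / |true|`,
#' `spe = |unselected & untrue| / |untrue|`, `p_int` the proportion of
#' the true interaction pairs contained in the selected interactions,
#' `size = |selected|`.
#'
#' @param selected Character vector of selected feature names.
#' @param true_support Character vector of truly effective features.
#' @param universe All feature names.
#' @param true_interactions True interaction pair names (subset of
#'   `true_support`).
#' @return List `p_int`, `sen`, `spe`, `size`.
#' @export
selection_metrics <- function(selected, true_support, universe,
                              true_interactions) {
  selected <- intersect(selected, universe)
  untrue <- setdiff(universe, true_support)
  sel_int <- selected[grepl(":", selected, fixed = TRUE)]
  list(p_int = if (length(true_interactions))
         mean(true_interactions %in% sel_int) else NA_real_,
       sen = if (length(true_support))
         mean(true_support %in% selected) else NA_real_,
       spe = if (length(untrue))
         mean(!untrue %in% selected) else NA_real_,
       size = length(selected))
}

#' Harrell's concordance index of a prognostic index
#'
#' Among usable pairs (the earlier observed time is an event), the
#' fraction where the higher PI has the shorter survival; PI ties count
#' one half.
#'
#' @param PI Prognostic-index scores.
#' @param time,status Survival outcome.
#' @return Concordance in `[0, 1]`, or `NA` (with a warning) when no
#'   pair is usable.
#' @export
harrell_cindex <- function(PI, time, status) {
  n <- length(PI)
  if (n < 2L) stop("need at least two subjects")
  num <- 0; den <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (time[i] == time[j]) next
      a <- if (time[i] < time[j]) i else j    # earlier
      b <- if (time[i] < time[j]) j else i
      if (status[a] != 1) next                # earlier must be an event
      den <- den + 1
      if (PI[a] > PI[b]) num <- num + 1
      else if (PI[a] == PI[b]) num <- num + 0.5
    }
  }
  if (den == 0) { warning("no usable pair"); return(NA_real_) }
  num / den
}

#' IPCW cumulative/dynamic time-dependent AUC at a horizon
#'
#' Cases are subjects with an event by the horizon, weighted
#' `1 / G(t^-)`; controls are subjects still at risk past the horizon,
#' weighted `1 / G(horizon)`; `G` is the Kaplan-Meier survivor of the
#' censoring distribution.  PI ties count one half, so the statistic is
#' invariant under strictly increasing transforms of PI.
#'
#' @param PI Prognostic-index scores.
#' @param time,status Survival outcome.
#' @param horizon Evaluation time; default the median observed event
#'   time.
#' @return AUC in `[0, 1]`, or `NA` (with a warning) if there is no case
#'   or no control.
#' @export
td_auc <- function(PI, time, status, horizon = NULL) {
  if (is.null(horizon)) {
    ev <- time[status == 1]
    if (length(ev) == 0) { warning("no events"); return(NA_real_) }
    horizon <- stats::median(ev)
  }
  G <- censoring_km(time, status)
  case <- which(time <= horizon & status == 1)
  ctrl <- which(time > horizon)
  if (length(case) == 0 || length(ctrl) == 0) {
    warning("no case or no control at the horizon")
    return(NA_real_)
  }
  wc <- 1 / pmax(G(time[case]), 1e-8)
  wk <- rep(1 / pmax(G(horizon, left = FALSE), 1e-8), length(ctrl))
  cmp <- outer(PI[case], PI[ctrl],
               function(a, b) (a > b) + 0.5 * (a == b))
  sum((wc %o% wk) * cmp) / (sum(wc) * sum(wk))
}

#' Test-set deviance, Cox test and log-rank test of a prognostic index
#'
#' Fits the univariate Cox model with PI as the only covariate on the
#' test data: `cox_test_p` is its Wald p-value, `deviance` is
#' `2 * (loglik_null - loglik_PI)` (more negative = better prediction).
#' `lr_test_p` is the log-rank p-value between the groups split at the
#' median PI.
#'
#' @param PI Prognostic-index scores on the test set.
#' @param time,status Test-set outcome.
#' @return List `deviance`, `cox_test_p`, `lr_test_p`.
#' @export
test_set_tests <- function(PI, time, status) {
  if (stats::sd(PI) == 0) {
    warning("constant PI")
    return(list(deviance = 0, cox_test_p = 1, lr_test_p = 1))
  }
  fit <- survival::coxph(survival::Surv(time, status) ~ PI,
                         ties = "breslow")
  dev <- 2 * (fit$loglik[1] - fit$loglik[2])
  z <- stats::coef(fit) / sqrt(diag(fit$var))
  cox_p <- as.numeric(2 * stats::pnorm(-abs(z)))
  grp <- PI > stats::median(PI)
  lr_p <- if (length(unique(grp)) < 2L) 1 else {
    sd <- survival::survdiff(survival::Surv(time, status) ~ grp)
    as.numeric(1 - stats::pchisq(sd$chisq, df = 1))
  }
  list(deviance = dev, cox_test_p = cox_p, lr_test_p = lr_p)
}

## ---- comparator fits -------------------------------------------------

## Embed a named coefficient vector into the full feature universe.
embed_theta <- function(coefs, universe) {
  th <- stats::setNames(numeric(length(universe)), universe)
  common <- intersect(names(coefs), universe)
  th[common] <- coefs[common]
  th
}

full_design <- function(data) cbind(data$E, data$X, data$U)

fit_oracle <- function(data, truth, seed) {
  Z <- full_design(data)[, truth$support, drop = FALSE]
  y <- survival::Surv(data$time, data$status)
  fit <- tryCatch(
    survival::coxph(y ~ Z, ties = "breslow",
                    control = survival::coxph.control(iter.max = 50)),
    warning = function(w) NULL, error = function(e) NULL)
  coefs <- if (!is.null(fit) && !anyNA(stats::coef(fit)) &&
               max(abs(stats::coef(fit))) < 50) {
    stats::setNames(as.numeric(stats::coef(fit)), colnames(Z))
  } else {
    # near-unpenalized ridge fallback for non-convergent fits
    g <- glmnet::glmnet(Z, y, family = "cox", alpha = 0,
                        lambda = c(1, 0.1, 1e-2, 1e-4),
                        standardize = TRUE)
    stats::setNames(as.numeric(stats::coef(g, s = 1e-4)), colnames(Z))
  }
  structure(list(coef = coefs, lambda = 0, penalty = "none",
                 features = colnames(Z)), class = "FinalModel")
}

fit_ordinary_lasso <- function(data, seed, folds = 10L) {
  fit_penalized_cox(data$time, data$status, full_design(data),
                    penalty = "lasso", folds = folds, seed = seed)
}

fit_sis_lasso <- function(data, seed, folds = 10L) {
  Z <- full_design(data)
  scan <- univariate_cox_scan(data$time, data$status, Z)
  keep_n <- floor(data$n / log(data$n))
  ord <- order(scan$p, -abs(scan$z))
  keep <- scan$feature[ord][seq_len(min(keep_n, nrow(scan)))]
  fit_penalized_cox(data$time, data$status, Z[, keep, drop = FALSE],
                    penalty = "lasso", folds = folds, seed = seed)
}

evaluate_model <- function(model, sim, universe, true_int) {
  truth <- sim$truth
  selected <- names(model$coef)[model$coef != 0]
  sel <- selection_metrics(selected, truth$support, universe, true_int)
  theta_hat <- embed_theta(model$coef, universe)
  test <- sim$test
  PI <- prognostic_index(model, full_design(test))
  tst <- test_set_tests(PI, test$time, test$status)
  data.frame(rmse = rmse(theta_hat, truth$theta[universe]),
             p_int = sel$p_int, sen = sel$sen, spe = sel$spe,
             model_size = sel$size, deviance = tst$deviance,
             c_index = harrell_cindex(PI, test$time, test$status),
             td_auc = td_auc(PI, test$time, test$status),
             cox_test_p = tst$cox_test_p, lr_test_p = tst$lr_test_p)
}

#' Replicate benchmark of OGS against Oracle, SIS-Lasso, Ordinary-Lasso
#'
#' Per replicate: simulate a training/test cohort pair, fit each
#' requested method on the training data, evaluate all measures on the
#' test data; then aggregate across replicates by the median (and
#' additionally the mean for RMSE).  Per-replicate seeds derive from the
#' master seed.  Method failures on single replicates are recorded as
#' missing and excluded from the aggregates with a count.
#'
#' @param config A [sim_config()].
#' @param methods Subset of `oracle`, `sis_lasso`, `ordinary_lasso`,
#'   `ogs_ridge`, `ogs_lasso`.
#' @param replicates Number of simulation replicates.
#' @param seed Integer master seed.
#' @param folds CV folds used by every penalized fit.
#' @param I Permutation replicates inside OGS.
#' @param nlambda,lambda_min_ratio Step-1 path controls for OGS.
#' @param verbose Print per-replicate progress.
#' @return Object of class `BenchmarkReport`: `per_replicate` (long data
#'   frame), `summary` (median per method and metric, plus `rmse_mean`),
#'   `failures`.
#' @export
run_benchmark <- function(config,
                          methods = c("oracle", "sis_lasso",
                                      "ordinary_lasso", "ogs_lasso"),
                          replicates = 30L, seed = 1L, folds = 10L,
                          I = 30L, nlambda = 100L,
                          lambda_min_ratio = 1e-3, verbose = FALSE) {
  methods <- match.arg(methods,
                       c("oracle", "sis_lasso", "ordinary_lasso",
                         "ogs_ridge", "ogs_lasso"),
                       several.ok = TRUE)
  universe <- feature_names(config)
  truth0 <- true_parameters(config)
  true_int <- names(truth0$eta)[truth0$eta != 0]
  rows <- list()
  failures <- stats::setNames(integer(length(methods)), methods)
  for (r in seq_len(replicates)) {
    rs <- derive_seed(seed, paste0("replicate-", r))
    sim <- simulate_dataset(config, seed = rs)
    for (mth in methods) {
      res <- tryCatch({
        model <- switch(mth,
          oracle = fit_oracle(sim$train, sim$truth,
                              derive_seed(rs, "oracle")),
          sis_lasso = fit_sis_lasso(sim$train, derive_seed(rs, "sis"),
                                    folds = folds),
          ordinary_lasso = fit_ordinary_lasso(
            sim$train, derive_seed(rs, "ordinary"), folds = folds),
          ogs_ridge = run_ogs(sim$train, config$pathways,
                              penalty = "ridge", I = I, folds = folds,
                              seed = derive_seed(rs, "ogs"),
                              nlambda = nlambda,
                              lambda_min_ratio = lambda_min_ratio)$model,
          ogs_lasso = run_ogs(sim$train, config$pathways,
                              penalty = "lasso", I = I, folds = folds,
                              seed = derive_seed(rs, "ogs"),
                              nlambda = nlambda,
                              lambda_min_ratio = lambda_min_ratio)$model)
        cbind(data.frame(replicate = r, method = mth,
                         stringsAsFactors = FALSE),
              evaluate_model(model, sim, universe, true_int))
      }, error = function(e) {
        warning("replicate ", r, ", method ", mth, " failed: ",
                conditionMessage(e))
        NULL
      })
      if (is.null(res)) failures[mth] <- failures[mth] + 1L
      else rows[[length(rows) + 1L]] <- res
      if (verbose)
        message("replicate ", r, " ", mth, " done")
    }
  }
  per_rep <- do.call(rbind, rows)
  metric_cols <- setdiff(colnames(per_rep), c("replicate", "method"))
  summ <- do.call(rbind, lapply(split(per_rep, per_rep$method),
                                function(df) {
    out <- data.frame(method = df$method[1], stringsAsFactors = FALSE)
    for (mc in metric_cols)
      out[[mc]] <- stats::median(df[[mc]], na.rm = TRUE)
    out$rmse_mean <- mean(df$rmse, na.rm = TRUE)
    out
  }))
  rownames(summ) <- NULL
  structure(list(per_replicate = per_rep, summary = summ,
                 failures = failures, replicates = replicates,
                 config = config),
            class = "BenchmarkReport")
}

#' @export
print.BenchmarkReport <- function(x, ...) {
  cat("BenchmarkReport: ", x$replicates, " replicate(s), censoring ",
      "target ", x$config$censor_target, "\n", sep = "")
  print(x$summary, digits = 4)
  if (any(x$failures > 0)) {
    cat("failures:\n"); print(x$failures[x$failures > 0])
  }
  invisible(x)
}
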