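## Overlapping group-lasso Cox regression (step 1 of the OGS pipeline).
## The latent-effect expansion duplicates the columns of overlapping genes
## so the overlapping group penalty becomes an ordinary (disjoint) group
## penalty on the expanded design; the C++ FISTA path solver does the rest.

cox_sort_info <- function(time, status) {
  ord <- order(time)
  tt <- time[ord]
  first <- match(tt, tt)                     # first row of each tie group
  last <- length(tt) + 1L - match(rev(tt), rev(tt))[length(tt):1]
  list(ord = ord, delta = as.numeric(status[ord]),
       tie_first = as.integer(first - 1L),
       tie_last = as.integer(last - 1L))
}

#' Breslow Cox log partial likelihood of a linear predictor
#'
#' @param time,status Survival outcome.
#' @param eta Linear predictor, same length.
#' @return Log partial likelihood (scalar).
#' @export
cox_loglik <- function(time, status, eta) {
  si <- cox_sort_info(time, status)
  -.cox_negloglik(eta[si$ord], si$delta, si$tie_first, si$tie_last)
}

#' Overlapping group-lasso Cox regression for candidate pathway selection
#'
#' Fits the Cox model with the environmental covariates unpenalized plus
#' the latent-effect expanded gene design `X %*% S` under a group-lasso
#' penalty with one block per pathway (group weights `sqrt(group size)`).
#' The penalty level is chosen by k-fold cross-validated partial-likelihood
#' deviance (Verweij & van Houwelingen form, minimum rule) over a
#' log-spaced path from `lambda_max` down.  Columns are standardized
#' internally; coefficients are returned on the original scale.
#'
#' @param data A [survival_dataset()].
#' @param pathways A [pathway_collection()] over (a subset of) the genes
#'   of `data$X`.
#' @param folds CV folds, stratified by event status (default 10).
#' @param nlambda,lambda_min_ratio Path resolution (defaults 100, 1e-3).
#' @param lambda Optional fixed penalty grid overriding the automatic
#'   path (decreasing).
#' @param seed Integer seed for the fold assignment.
#' @param max_iter,tol Solver controls per path point.
#' @return Object of class `OverlapGroupCoxFit`: `M_main` (selected group
#'   names at the CV-chosen penalty), `alpha` (environment coefficients),
#'   `gamma` (latent coefficients, named `group.gene`), `beta` (collapsed
#'   gene coefficients), `lambda`, `lambda_seq`, `cvm`, `expansion`.
#' @export
fit_overlap_group_cox <- function(data, pathways, folds = 10L,
                                  nlambda = 100L, lambda_min_ratio = 1e-3,
                                  lambda = NULL, seed = 1L,
                                  max_iter = 500L, tol = 1e-5) {
  stopifnot(inherits(data, "SurvivalDataset"),
            inherits(pathways, "PathwayCollection"))
  expansion <- build_expansion(pathways)
  miss <- setdiff(expansion$genes, colnames(data$X))
  if (length(miss))
    stop("pathway genes absent from the expression matrix: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  gene_idx <- match(expansion$column_index$gene, colnames(data$X))
  Z <- cbind(data$E, data$X[, gene_idx, drop = FALSE])
  nunpen <- ncol(data$E)
  ctr <- colMeans(Z)
  scl <- apply(Z, 2, stats::sd)
  scl[scl == 0] <- 1
  Zs <- scale(Z, center = ctr, scale = scl)

  grp <- expansion$column_index$group
  grp_rle <- rle(grp)
  if (!identical(sort(unique(grp)), sort(grp_rle$values)) ||
      length(grp_rle$values) != pathways$G)
    stop("latent columns are not contiguous by group")
  grp_end <- cumsum(grp_rle$lengths)
  grp_start <- grp_end - grp_rle$lengths + 1L
  grp_mult <- sqrt(grp_rle$lengths)

  si <- cox_sort_info(data$time, data$status)
  Xs <- Zs[si$ord, , drop = FALSE]
  lam_in <- if (is.null(lambda)) numeric(0) else as.numeric(lambda)
  full <- .grplasso_cox_path(Xs, si$delta, si$tie_first, si$tie_last,
                             nunpen, as.integer(grp_start - 1L),
                             as.integer(grp_end - 1L), grp_mult,
                             lam_in, as.integer(nlambda),
                             lambda_min_ratio, as.integer(max_iter), tol)
  lam_seq <- as.numeric(full$lambda)

  # Verweij & van Houwelingen cross-validated partial-likelihood deviance
  set.seed(seed)
  foldid <- stratified_folds(data$status, folds)
  cvm <- rep(0, length(lam_seq))
  for (k in seq_len(folds)) {
    tr <- which(foldid != k)
    si_tr <- cox_sort_info(data$time[tr], data$status[tr])
    fit_k <- .grplasso_cox_path(Zs[tr, , drop = FALSE][si_tr$ord, ,
                                                       drop = FALSE],
                                si_tr$delta, si_tr$tie_first,
                                si_tr$tie_last, nunpen,
                                as.integer(grp_start - 1L),
                                as.integer(grp_end - 1L), grp_mult,
                                lam_seq, length(lam_seq),
                                lambda_min_ratio, as.integer(max_iter),
                                tol)
    eta_full <- Zs %*% fit_k$beta            # n x nlambda
    for (l in seq_along(lam_seq)) {
      ll_full <- cox_loglik(data$time, data$status, eta_full[, l])
      ll_tr <- cox_loglik(data$time[tr], data$status[tr],
                          eta_full[tr, l])
      cvm[l] <- cvm[l] - 2 * (ll_full - ll_tr)
    }
  }
  best <- which.min(cvm)
  coef_std <- full$beta[, best]
  coef_orig <- coef_std / scl
  alpha <- coef_orig[seq_len(nunpen)]
  names(alpha) <- colnames(data$E)
  gamma <- coef_orig[-seq_len(nunpen)]
  names(gamma) <- paste(expansion$column_index$group,
                        expansion$column_index$gene, sep = ".")
  nz_norm <- vapply(seq_along(grp_start), function(g)
    sqrt(sum(gamma[grp_start[g]:grp_end[g]]^2)), numeric(1))
  M_main <- grp_rle$values[nz_norm > 0]
  structure(list(M_main = M_main, alpha = alpha, gamma = gamma,
                 beta = collapse_latent(unname(gamma), expansion),
                 lambda = lam_seq[best], lambda_seq = lam_seq,
                 lambda_max = full$lambda_max, cvm = cvm,
                 expansion = expansion, folds = folds),
            class = "OverlapGroupCoxFit")
}

#' @export
print.OverlapGroupCoxFit <- function(x, ...) {
  cat("OverlapGroupCoxFit: ", length(x$M_main), " group(s) selected at ",
      "lambda = ", signif(x$lambda, 4), "\n", sep = "")
  if (length(x$M_main))
    cat("  M_main: ", paste(x$M_main, collapse = ", "), "\n", sep = "")
  invisible(x)
}
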