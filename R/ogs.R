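## The four-step OGS pipeline: overlapping group-lasso pathway selection,
## SKAT group p-values, permutation-calibrated threshold, penalized final
## model.

#' Permutation-calibrated interaction-selection threshold
#'
#' Each replicate draws one permutation `pi` of the subject index, forms
#' the permuted data `{Y_i, e_pi(i), x_pi(i)}` (one shared permutation for
#' E and X, outcomes fixed), refits the null Cox model on the permuted E,
#' recomputes all candidate-group SKAT p-values, and records their
#' minimum `tau_r`.  The cutoff is `C_int = median(tau_1..tau_I)`.
#'
#' @param data A [survival_dataset()].
#' @param pathways A [pathway_collection()].
#' @param M_main Character vector of candidate group names (step 1
#'   output).
#' @param I Number of permutation replicates (default 30).
#' @param seed Integer seed; results are deterministic given it.
#' @param max_retries Replicates whose null refit fails are redrawn, at
#'   most this many times each (default 5).
#' @return List with `tau` (length I), `C_int`, and `retries`.
#' @export
permutation_threshold <- function(data, pathways, M_main, I = 30L,
                                  seed = 1L, max_retries = 5L) {
  stopifnot(inherits(data, "SurvivalDataset"))
  if (length(M_main) < 1L) stop("M_main must contain at least one group")
  if (I < 1L) stop("I must be >= 1")
  set.seed(seed)
  tau <- numeric(I)
  retries <- 0L
  for (r in seq_len(I)) {
    for (attempt in seq_len(max_retries + 1L)) {
      pi_r <- sample.int(data$n)
      Ep <- data$E[pi_r, , drop = FALSE]
      Xp <- data$X[pi_r, , drop = FALSE]
      res <- tryCatch({
        null_p <- fit_null_cox(time = data$time, status = data$status,
                               E = Ep)
        vapply(M_main, function(g)
          skat_group_pvalue(null_p, Ep, Xp, pathways$members[[g]],
                            group_id = g)$p, numeric(1))
      }, error = function(e) NULL)
      if (!is.null(res)) break
      retries <- retries + 1L
      if (attempt > max_retries)
        stop("permutation replicate ", r, " failed after ", max_retries,
             " retries")
    }
    tau[r] <- min(res)
  }
  list(tau = tau, C_int = stats::median(tau), retries = retries)
}

#' Select interaction groups against the permutation cutoff
#'
#' Strict rule: group `b` is selected iff `p_b < C_int`.
#'
#' @param group_pvalues Named vector of candidate-group p-values.
#' @param C_int Cutoff from [permutation_threshold()].
#' @return Character vector of selected group names (`M_int`).
#' @export
select_interaction_groups <- function(group_pvalues, C_int) {
  if (any(group_pvalues < 0 | group_pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  names(group_pvalues)[which(group_pvalues < C_int)]
}

#' Run the full OGS gene-environment interaction selection pipeline
#'
#' Step 1 selects candidate pathways by overlapping group-lasso Cox
#' regression ([fit_overlap_group_cox()]).  Step 2 computes each
#' candidate's SKAT interaction p-value on the original data.  Step 3
#' calibrates the cutoff `C_int` by covariate permutation
#' ([permutation_threshold()]).  Step 4 fits the final Ridge- or
#' Lasso-penalized Cox model on all environmental columns, the
#' (deduplicated) genes of the candidate pathways, and the interaction
#' columns of the groups passing the cutoff.
#'
#' @param data A [survival_dataset()].
#' @param pathways A [pathway_collection()].
#' @param penalty `"lasso"` or `"ridge"` for the final model.
#' @param I Permutation replicates (default 30).
#' @param folds CV folds for steps 1 and 4 (default 10).
#' @param seed Integer master seed (steps 1, 3 and 4 use derived
#'   substreams; same seed implies identical output).
#' @param nlambda,lambda_min_ratio Step-1 path controls.
#' @param penalize_environment Penalize the E columns in step 4 (default
#'   `TRUE`; set `FALSE` to exempt them).
#' @return List with `selection` (class `OgsSelection`: `M_main`, `A`,
#'   `group_pvalues`, `tau`, `C_int`, `M_int`, `selected_genes`,
#'   `selected_interactions`, `I`, `early_stop`) and `model` (a
#'   `FinalModel`; E-only when step 1 selects nothing).
#' @export
run_ogs <- function(data, pathways, penalty = c("lasso", "ridge"),
                    I = 30L, folds = 10L, seed = 1L, nlambda = 100L,
                    lambda_min_ratio = 1e-3,
                    penalize_environment = TRUE) {
  penalty <- match.arg(penalty)
  stopifnot(inherits(data, "SurvivalDataset"),
            inherits(pathways, "PathwayCollection"))

  step1 <- fit_overlap_group_cox(data, pathways, folds = folds,
                                 nlambda = nlambda,
                                 lambda_min_ratio = lambda_min_ratio,
                                 seed = derive_seed(seed, "step1"))
  M_main <- step1$M_main
  unpen <- if (penalize_environment) NULL else colnames(data$E)

  if (length(M_main) == 0L) {
    model <- fit_penalized_cox(data$time, data$status, data$E,
                               penalty = penalty, folds = folds,
                               seed = derive_seed(seed, "step4"),
                               unpenalized = unpen)
    selection <- structure(
      list(M_main = character(0), A = 0L,
           group_pvalues = numeric(0), tau = numeric(0), C_int = NA_real_,
           M_int = character(0), selected_genes = character(0),
           selected_interactions = character(0), I = I,
           early_stop = TRUE, step1 = step1),
      class = "OgsSelection")
    return(list(selection = selection, model = model))
  }

  null0 <- fit_null_cox(data)
  pvals <- vapply(M_main, function(g)
    skat_group_pvalue(null0, data$E, data$X, pathways$members[[g]],
                      group_id = g)$p, numeric(1))

  perm <- permutation_threshold(data, pathways, M_main, I = I,
                                seed = derive_seed(seed, "step3"))
  M_int <- select_interaction_groups(pvals, perm$C_int)

  genes_main <- unique(unlist(pathways$members[M_main],
                              use.names = FALSE))
  design <- cbind(data$E, data$X[, genes_main, drop = FALSE])
  int_cols <- character(0)
  if (length(M_int)) {
    genes_int <- unique(unlist(pathways$members[M_int],
                               use.names = FALSE))
    Ublk <- build_interactions(data$E, data$X, genes = genes_int)
    int_cols <- colnames(Ublk)
    design <- cbind(design, Ublk)
  }
  model <- fit_penalized_cox(data$time, data$status, design,
                             penalty = penalty, folds = folds,
                             seed = derive_seed(seed, "step4"),
                             unpenalized = unpen)
  selection <- structure(
    list(M_main = M_main, A = length(M_main), group_pvalues = pvals,
         tau = perm$tau, C_int = perm$C_int, M_int = M_int,
         selected_genes = genes_main, selected_interactions = int_cols,
         I = I, early_stop = FALSE, step1 = step1),
    class = "OgsSelection")
  list(selection = selection, model = model)
}

#' @export
print.OgsSelection <- function(x, ...) {
  cat("OgsSelection: A = ", x$A, " candidate group(s)", sep = "")
  if (x$early_stop) {
    cat(" — early stop, main-effects-only model\n")
    return(invisible(x))
  }
  cat(", C_int = ", format(x$C_int, digits = 4), ", |M_int| = ",
      length(x$M_int), "\n", sep = "")
  if (length(x$M_int))
    cat("  M_int: ", paste(x$M_int, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Serialize an OGS run to TSV/JSON files
#'
#' Writes `selection.tsv` (feature, type E/G/GxE, group, coefficient),
#' `group_pvalues.tsv`, and `run_metadata.json` (seed, lambdas, C_int,
#' tau list) to `outdir`.
#'
#' @param result A [run_ogs()] result.
#' @param outdir Output directory (created if needed).
#' @param seed The seed used for the run, recorded in the metadata.
#' @return `outdir`, invisibly.
#' @export
write_ogs_results <- function(result, outdir, seed = NA_integer_) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sel <- result$selection
  coefs <- result$model$coef
  feat <- names(coefs)
  type <- ifelse(grepl(":", feat, fixed = TRUE), "GxE",
                 ifelse(feat %in% sel$selected_genes, "G", "E"))
  grp_of <- function(f) {
    g <- sub(".*:", "", f)
    hits <- if (sel$A)
      sel$M_main[vapply(sel$M_main, function(b)
        g %in% sel$step1$expansion$column_index$gene[
          sel$step1$expansion$column_index$group == b], logical(1))]
    else character(0)
    if (length(hits)) paste(hits, collapse = ";") else NA_character_
  }
  utils::write.table(
    data.frame(feature = feat, type = type,
               group = vapply(feat, grp_of, character(1)),
               coefficient = unname(coefs), stringsAsFactors = FALSE),
    file.path(outdir, "selection.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(group = names(sel$group_pvalues),
               p = unname(sel$group_pvalues)),
    file.path(outdir, "group_pvalues.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed, package_version = as.character(
           utils::packageVersion("ogscreen")),
         lambda_step1 = sel$step1$lambda,
         lambda_step4 = result$model$lambda, C_int = sel$C_int,
         tau = sel$tau, M_main = sel$M_main, M_int = sel$M_int),
    file.path(outdir, "run_metadata.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}

## Deterministic 31-bit substream seed from a master seed and a label,
## so that each stochastic component draws from its own stream.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 2654435761)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
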