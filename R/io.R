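## File formats: expression TSV (samples x genes), clinical CSV with
## survival outcome and environmental covariates, GMT gene sets.

#' Read an expression + clinical file pair into a survival dataset
#'
#' Expression: samples x genes, first column the sample id, header row of
#' gene ids, tab-separated.  Clinical: CSV with the sample id in the
#' first column plus time, status and environment columns.  The two are
#' inner-joined on sample id (drop counts reported); rows with missing
#' outcome or environment values are rejected with a named report — no
#' silent imputation.  A transposed expression matrix (genes in rows) is
#' detected by an id-overlap heuristic and rejected with guidance.
#'
#' @param expression_path Path to the expression TSV.
#' @param clinical_path Path to the clinical CSV.
#' @param env Character vector of environment column names.
#' @param time,status Clinical column names for the outcome (defaults
#'   `"time"`, `"status"`).
#' @return A [survival_dataset()] (interaction block materialized only
#'   when `interactions = TRUE`).
#' @param interactions Materialize the q x p interaction block (default
#'   `FALSE`; it can be large).
#' @export
read_dataset <- function(expression_path, clinical_path, env,
                         time = "time", status = "status",
                         interactions = FALSE) {
  expr <- utils::read.delim(expression_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  clin <- utils::read.csv(clinical_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids_e <- as.character(expr[[1]])
  ids_c <- as.character(clin[[1]])
  if (length(intersect(ids_e, ids_c)) == 0 &&
      length(intersect(colnames(expr)[-1], ids_c)) > 0)
    stop("expression matrix appears transposed (sample ids found in ",
         "its header); provide samples in rows and genes in columns")
  missing_cols <- setdiff(c(time, status, env), colnames(clin))
  if (length(missing_cols))
    stop("clinical table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  common <- intersect(ids_e, ids_c)
  if (length(common) == 0) stop("no sample id shared between the files")
  dropped <- (length(ids_e) - length(common)) +
             (length(ids_c) - length(common))
  if (dropped > 0)
    message("read_dataset: dropped ", length(ids_e) - length(common),
            " expression and ", length(ids_c) - length(common),
            " clinical sample(s) absent from the other file")
  expr <- expr[match(common, ids_e), , drop = FALSE]
  clin <- clin[match(common, ids_c), , drop = FALSE]
  X <- as.matrix(expr[, -1, drop = FALSE])
  if (!is.numeric(X)) stop("non-numeric expression values")
  rownames(X) <- common
  E <- if (length(env)) as.matrix(clin[, env, drop = FALSE])
       else matrix(numeric(0), length(common), 0)
  if (length(env) && !is.numeric(E))
    stop("non-numeric environment values")
  tt <- as.numeric(clin[[time]])
  ss <- as.numeric(clin[[status]])
  bad <- !stats::complete.cases(E) | is.na(tt) | is.na(ss)
  if (any(bad))
    stop("missing outcome/environment values for sample(s): ",
         paste(utils::head(common[bad], 5L), collapse = ", "),
         " — impute or remove them upstream")
  if (!all(ss %in% c(0, 1)))
    stop("status column must be 0/1; offending sample(s): ",
         paste(utils::head(common[!ss %in% c(0, 1)], 5L),
               collapse = ", "))
  survival_dataset(tt, ss, E, X, interactions = interactions)
}

#' Export a survival dataset in the formats [read_dataset()] reads
#'
#' Writes `<prefix>_clinical.csv` (id, time, status, E columns) and
#' `<prefix>_expression.tsv` (samples x genes), with full-precision
#' numbers so a read-back reproduces the matrices bitwise.
#'
#' @param data A [survival_dataset()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"cohort"`).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(data, dir, prefix = "cohort") {
  stopifnot(inherits(data, "SurvivalDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- if (!is.null(rownames(data$X))) rownames(data$X)
         else paste0("S", seq_len(data$n))
  num <- function(v) vapply(v, function(z) sprintf("%.17g", z),
                            character(1))
  clin <- data.frame(id = ids, time = num(data$time),
                     status = data$status,
                     stringsAsFactors = FALSE)
  for (j in colnames(data$E)) clin[[j]] <- num(data$E[, j])
  cpath <- file.path(dir, paste0(prefix, "_clinical.csv"))
  utils::write.csv(clin, cpath, row.names = FALSE, quote = FALSE)
  expr <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (j in colnames(data$X)) expr[[j]] <- num(data$X[, j])
  epath <- file.path(dir, paste0(prefix, "_expression.tsv"))
  utils::write.table(expr, epath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(clinical = cpath, expression = epath))
}

#' Export a full simulated cohort (data, pathways, truth)
#'
#' Writes train/test clinical CSVs and expression TSVs, the group layout
#' as GMT, and the true nonzero coefficients as TSV — the same formats
#' the real-data path reads.
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dataset(sim$train, dir, "train")
  write_dataset(sim$test, dir, "test")
  write_gmt(sim$config$pathways, file.path(dir, "pathways.gmt"))
  th <- sim$truth$theta[sim$truth$theta != 0]
  utils::write.table(
    data.frame(feature = names(th), effect = unname(th)),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}

write_run_metadata <- function(path, config_list, seed) {
  jsonlite::write_json(
    c(list(seed = seed,
           package_version = as.character(
             utils::packageVersion("ogscreen")),
           r_version = R.version.string,
           timestamp = format(Sys.time(), tz = "UTC")),
      config_list),
    path, auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  invisible(path)
}
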