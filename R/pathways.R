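#' Construct a collection of (possibly overlapping) gene pathways
#'
#' A `PathwayCollection` stores named gene groups that may share genes.
#' It is the grouping structure consumed by the latent-effect expansion
#' ([build_expansion()]) and by the overlapping group-lasso Cox fit.
#'
#' @param members Named list; each element is a character vector of gene
#'   identifiers belonging to one group.  Duplicate genes within a single
#'   group are an error (use [read_gmt()] for tolerant file input, which
#'   deduplicates with a warning).
#' @param genes Optional master gene universe (character).  Defaults to the
#'   union of all members, in first-appearance order.
#' @return An object of class `PathwayCollection` with fields
#'   `group_names`, `members`, `genes`, `p` (number of unique genes) and
#'   `G` (number of groups).
#' @export
pathway_collection <- function(members, genes = NULL) {
  if (length(members) == 0L) stop("at least one group is required")
  if (is.null(names(members)) || anyNA(names(members)) ||
      any(names(members) == ""))
    names(members) <- paste0("group", seq_along(members))
  if (anyDuplicated(names(members)))
    stop("group names must be unique")
  members <- lapply(members, as.character)
  for (g in names(members)) {
    if (length(members[[g]]) == 0L)
      stop("group '", g, "' is empty")
    if (anyDuplicated(members[[g]]))
      stop("group '", g, "' contains duplicated genes: ",
           paste(unique(members[[g]][duplicated(members[[g]])]),
                 collapse = ", "))
  }
  all_genes <- unique(unlist(members, use.names = FALSE))
  if (is.null(genes)) {
    genes <- all_genes
  } else {
    genes <- as.character(genes)
    missing <- setdiff(all_genes, genes)
    if (length(missing))
      stop("groups reference genes absent from the master list: ",
           paste(utils::head(missing, 5L), collapse = ", "))
  }
  structure(list(group_names = names(members),
                 members = members,
                 genes = genes,
                 p = length(genes),
                 G = length(members)),
            class = "PathwayCollection")
}

#' @export
print.PathwayCollection <- function(x, ...) {
  sizes <- lengths(x$members)
  cat("PathwayCollection: ", x$G, " groups over ", x$p, " genes\n",
      "  group sizes: min ", min(sizes), ", median ",
      stats::median(sizes), ", max ", max(sizes), "\n", sep = "")
  invisible(x)
}

#' Latent-effect expansion of an overlapping group structure
#'
#' Rewrites the gene coefficient vector as `beta = S %*% gamma`, where
#' `gamma` stacks one latent coefficient per (group, gene) membership.  The
#' binary map `S` (p x d, `d = sum of group sizes`) has one 1 per column;
#' the row of a gene carries one 1 for every group containing it, so
#' multiplying by a latent vector sums, per gene, the latent effects of all
#' groups it belongs to.  Penalizing `gamma` group-by-group turns an
#' overlapping group penalty into an ordinary (disjoint) one.
#'
#' @param pathways A [pathway_collection()].
#' @return An object of class `ExpansionMap`: sparse binary `S`
#'   (genes x latent columns), `d`, and `column_index`, a data frame with
#'   one row per latent column giving its `group` and `gene`.  Latent
#'   columns are ordered group-by-group, genes in within-group order.
#' @export
build_expansion <- function(pathways) {
  stopifnot(inherits(pathways, "PathwayCollection"))
  gene_idx <- match(unlist(pathways$members, use.names = FALSE),
                    pathways$genes)
  if (anyNA(gene_idx)) {
    bad <- unlist(pathways$members, use.names = FALSE)[is.na(gene_idx)]
    stop("unknown gene(s) in groups: ",
         paste(utils::head(unique(bad), 5L), collapse = ", "))
  }
  d <- length(gene_idx)
  grp <- rep(pathways$group_names, lengths(pathways$members))
  S <- Matrix::sparseMatrix(i = gene_idx, j = seq_len(d), x = 1,
                            dims = c(pathways$p, d),
                            dimnames = list(pathways$genes, NULL))
  structure(list(S = S, d = d,
                 column_index = data.frame(
                   group = grp,
                   gene = pathways$genes[gene_idx],
                   stringsAsFactors = FALSE),
                 group_names = pathways$group_names,
                 genes = pathways$genes),
            class = "ExpansionMap")
}

#' @export
print.ExpansionMap <- function(x, ...) {
  cat("ExpansionMap: ", length(x$genes), " genes -> ", x$d,
      " latent effects in ", length(x$group_names), " groups\n", sep = "")
  invisible(x)
}

#' Collapse latent coefficients to gene coefficients
#'
#' Computes `beta = S %*% gamma`: each gene coefficient is the sum of the
#' latent effects of every group containing that gene.
#'
#' @param gamma Numeric vector of latent coefficients, length `d`.
#' @param expansion An [build_expansion()] result.
#' @return Named numeric vector of gene coefficients, length `p`.
#' @export
collapse_latent <- function(gamma, expansion) {
  stopifnot(inherits(expansion, "ExpansionMap"))
  if (length(gamma) != expansion$d)
    stop("gamma has length ", length(gamma), " but the expansion has ",
         expansion$d, " latent columns")
  beta <- as.numeric(expansion$S %*% gamma)
  names(beta) <- expansion$genes
  beta
}

#' Chain-overlap gene group layout
#'
#' Builds a pathway collection in which groups occupy consecutive gene
#' indices and each group overlaps only its successor: group `j + 1` starts
#' `overlaps[j]` genes before group `j` ends.  This is the layout used by
#' the simulation engine's 25-group structure.
#'
#' @param sizes Integer vector of group sizes.
#' @param overlaps Integer vector, length `length(sizes) - 1`, of shared
#'   gene counts between consecutive groups; each must be smaller than both
#'   adjacent group sizes.
#' @param gene_prefix Prefix for generated gene names (default `"G"`,
#'   giving `G1`, `G2`, ...).
#' @return A [pathway_collection()] whose unique gene count is
#'   `sum(sizes) - sum(overlaps)`.
#' @export
chain_layout <- function(sizes, overlaps, gene_prefix = "G") {
  sizes <- as.integer(sizes); overlaps <- as.integer(overlaps)
  if (length(overlaps) != length(sizes) - 1L)
    stop("need exactly length(sizes) - 1 overlaps")
  if (any(sizes <= 0L)) stop("group sizes must be positive")
  if (any(overlaps < 0L)) stop("overlaps must be nonnegative")
  for (j in seq_along(overlaps))
    if (overlaps[j] >= min(sizes[j], sizes[j + 1L]))
      stop("overlap ", j, " (", overlaps[j],
           ") must be smaller than both adjacent group sizes")
  starts <- integer(length(sizes))
  starts[1L] <- 1L
  if (length(sizes) > 1L)
    for (j in 2L:length(sizes))
      starts[j] <- starts[j - 1L] + sizes[j - 1L] - overlaps[j - 1L]
  ends <- starts + sizes - 1L
  p <- ends[length(ends)]
  stopifnot(p == sum(sizes) - sum(overlaps))
  members <- lapply(seq_along(sizes), function(j)
    paste0(gene_prefix, starts[j]:ends[j]))
  names(members) <- paste0("group", seq_along(sizes))
  pathway_collection(members, genes = paste0(gene_prefix, seq_len(p)))
}

#' The simulation study's 25-group overlapping layout
#'
#' Group sizes (3,3,3,6,6,6,9,9,9,15,15,15,24,24,24,36,36,36,45,45,45,
#' 60,60,60,38) with consecutive-pair overlaps
#' (1,1,0,2,2,0,3,3,0,5,5,0,8,8,0,12,12,0,15,15,0,20,20,0): 500 unique
#' genes carrying 632 latent effects.  Group 7 spans G22-G30 and group 13
#' spans G78-G101.
#'
#' @return A [pathway_collection()] with 25 groups over genes `G1..G500`.
#' @export
simulation_layout <- function() {
  sizes <- c(3, 3, 3, 6, 6, 6, 9, 9, 9, 15, 15, 15, 24, 24, 24,
             36, 36, 36, 45, 45, 45, 60, 60, 60, 38)
  overlaps <- c(1, 1, 0, 2, 2, 0, 3, 3, 0, 5, 5, 0, 8, 8, 0,
                12, 12, 0, 15, 15, 0, 20, 20, 0)
  chain_layout(sizes, overlaps)
}

#' Restrict a pathway collection to a gene universe
#'
#' Drops genes absent from `universe` (with a message reporting how many),
#' removes groups emptied by the filtering, and optionally pools the genes
#' of `universe` that belong to no surviving group into one extra group.
#'
#' @param pathways A [pathway_collection()].
#' @param universe Character vector of genes to keep (e.g. the columns of
#'   an expression matrix).
#' @param ungrouped `"discard"` (default) or `"pool"`: what to do with
#'   universe genes not covered by any group.
#' @return A filtered [pathway_collection()].
#' @export
filter_pathways <- function(pathways, universe,
                            ungrouped = c("discard", "pool")) {
  stopifnot(inherits(pathways, "PathwayCollection"))
  ungrouped <- match.arg(ungrouped)
  universe <- as.character(universe)
  members <- lapply(pathways$members, function(m) m[m %in% universe])
  dropped_genes <- sum(lengths(pathways$members)) - sum(lengths(members))
  keep <- lengths(members) > 0L
  if (dropped_genes > 0L || any(!keep))
    message("filter_pathways: dropped ", dropped_genes,
            " gene membership(s) and ", sum(!keep), " emptied group(s)")
  members <- members[keep]
  if (length(members) == 0L) stop("no group survives the gene filter")
  covered <- unique(unlist(members, use.names = FALSE))
  if (ungrouped == "pool") {
    rest <- setdiff(universe, covered)
    if (length(rest)) members[["ungrouped"]] <- rest
    pathway_collection(members, genes = universe)
  } else {
    pathway_collection(members, genes = universe[universe %in% covered])
  }
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated format: `set_name<TAB>description<TAB>gene1...`.
#' Descriptions are discarded; duplicate genes within a set are removed
#' with a warning.  Filtering against an expression universe is done
#' separately by [filter_pathways()].
#'
#' @param path Path to a GMT file.
#' @return A [pathway_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  members <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    nms[i] <- fields[1L]
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("GMT set '", fields[1L], "' contains duplicated genes; ",
              "deduplicated")
      genes <- unique(genes)
    }
    members[[i]] <- genes
  }
  names(members) <- nms
  pathway_collection(members)
}

#' Write a pathway collection to a GMT file
#'
#' @param pathways A [pathway_collection()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  stopifnot(inherits(pathways, "PathwayCollection"))
  lines <- vapply(pathways$group_names, function(g)
    paste(c(g, "na", pathways$members[[g]]), collapse = "\t"),
    character(1L))
  writeLines(lines, path)
  invisible(path)
}
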