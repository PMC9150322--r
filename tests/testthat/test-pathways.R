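test_that("latent-effect expansion matches hand-enumerated memberships", {
  # two disjoint groups: S is a permutation-like 3x3 binary matrix
  pw <- pathway_collection(list(a = c("g1", "g2"), b = "g3"))
  ex <- build_expansion(pw)
  expect_equal(ex$d, 3)
  expect_true(all(Matrix::colSums(ex$S) == 1))
  expect_true(all(Matrix::rowSums(ex$S) == 1))

  # overlapping groups: the shared gene's row carries two 1s
  pw2 <- pathway_collection(list(a = c("g1", "g2"), b = c("g2", "g3")))
  ex2 <- build_expansion(pw2)
  expect_equal(ex2$d, 4)
  expect_equal(as.numeric(Matrix::rowSums(ex2$S)[ "g2" ]), 2)
  expect_equal(ex2$column_index$gene, c("g1", "g2", "g2", "g3"))

  # summing latent-column counts per group reproduces the input sizes
  pw3 <- chain_layout(c(4, 6, 5), c(2, 1))
  ex3 <- build_expansion(pw3)
  expect_equal(as.integer(table(ex3$column_index$group)[pw3$group_names]),
               c(4L, 6L, 5L))

  expect_error(
    build_expansion(pathway_collection(list(a = c("g1", "gX")),
                                       genes = c("g1", "g2"))),
    "gX")
})

test_that("collapse_latent sums group-specific effects per gene", {
  pw <- pathway_collection(list(a = c("g1", "g2"), b = c("g2", "g3")))
  ex <- build_expansion(pw)
  expect_equal(unname(collapse_latent(c(1, 1, 2, 2), ex)), c(1, 3, 2))
  expect_equal(unname(collapse_latent(rep(0, 4), ex)), rep(0, 3))
  expect_error(collapse_latent(1:3, ex), "length")

  # single group containing all genes: S is the identity
  pw1 <- pathway_collection(list(all = paste0("g", 1:5)))
  ex1 <- build_expansion(pw1)
  expect_equal(unname(collapse_latent(5:1, ex1)), 5:1)
})

test_that("collapse_latent equals a naive double-loop product", {
  set.seed(42)
  for (rep in 1:5) {
    G <- sample(2:5, 1)
    genes <- paste0("g", 1:8)
    members <- lapply(seq_len(G), function(i)
      sample(genes, sample(2:6, 1)))
    names(members) <- paste0("grp", seq_len(G))
    pw <- pathway_collection(members, genes = genes)
    ex <- build_expansion(pw)
    gamma <- rnorm(ex$d)
    naive <- numeric(pw$p)
    for (k in seq_len(pw$p))
      for (c in seq_len(ex$d))
        naive[k] <- naive[k] + as.numeric(ex$S[k, c]) * gamma[c]
    expect_equal(unname(collapse_latent(gamma, ex)), naive)
  }
})

test_that("chain layout places genes and overlaps as specified", {
  pw <- simulation_layout()
  expect_equal(pw$G, 25)
  expect_equal(pw$p, 500)
  expect_equal(build_expansion(pw)$d, 632)
  expect_equal(pw$members$group7, paste0("G", 22:30))
  expect_equal(pw$members$group13, paste0("G", 78:101))
  expect_true(all(c("G22", "G24", "G26") %in% pw$members$group7))
  expect_true(all(c("G78", "G83", "G88") %in% pw$members$group13))

  # disjoint consecutive blocks when all overlaps are zero
  pw0 <- chain_layout(c(3, 2, 4), c(0, 0))
  expect_equal(pw0$members$group2, c("G4", "G5"))
  expect_equal(pw0$p, 9)

  expect_error(chain_layout(c(3, 3), c(3)), "smaller")
  expect_error(chain_layout(c(3, 3), c(1, 1)), "overlaps")
})

test_that("GMT files round-trip and malformed input is rejected", {
  pw <- chain_layout(c(4, 5, 3), c(1, 1))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(pw, path)
  back <- read_gmt(path)
  expect_equal(back$members, pw$members)
  expect_equal(back$p, pw$p)

  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines("only_name\tdesc", bad)
  expect_error(read_gmt(bad), "line 1")

  dup <- withr::local_tempfile(fileext = ".gmt")
  writeLines("s1\tna\tg1\tg2\tg1", dup)
  expect_warning(got <- read_gmt(dup), "duplicated")
  expect_equal(got$members$s1, c("g1", "g2"))
})

test_that("filter_pathways drops absent genes and can pool the rest", {
  pw <- pathway_collection(list(a = c("g1", "g2", "gZ"), b = c("gY")))
  expect_message(flt <- filter_pathways(pw, c("g1", "g2", "g3")),
                 "dropped")
  expect_equal(flt$group_names, "a")
  expect_equal(flt$members$a, c("g1", "g2"))

  expect_message(
    pooled <- filter_pathways(pw, c("g1", "g2", "g3"), ungrouped = "pool"))
  expect_true("ungrouped" %in% pooled$group_names)
  expect_equal(pooled$members$ungrouped, "g3")
})
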