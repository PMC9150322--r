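test_that("rmse follows its definition", {
  th <- rnorm(10)
  expect_equal(rmse(th, th), 0)
  e <- rep(0, 3005); e[17] <- 1
  expect_equal(rmse(e, rep(0, 3005)), sqrt(1 / 3005))
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(rmse(a, b), rmse(2 * b - a, b))   # sign-flipped errors
  expect_error(rmse(1:3, 1:4), "length")
})

test_that("selection metrics count as set algebra and as confusion table", {
  ints <- paste0("E1:g", 1:6)
  univ <- c(paste0("f", 1:2999), ints)
  truth <- c(paste0("f", 1:85), ints)
  sel <- c(truth, paste0("f", 101:109))   # truth plus 9 false positives
  m <- selection_metrics(sel, truth, univ, ints)
  expect_equal(m$sen, 1)
  expect_equal(m$spe, 2905 / 2914)
  expect_equal(m$size, 100)
  # confusion-matrix cross-check
  tp <- sum(sel %in% truth); fp <- sum(!sel %in% truth)
  fn <- sum(!truth %in% sel); tn <- 3005 - tp - fp - fn
  expect_equal(m$sen, tp / (tp + fn))
  expect_equal(m$spe, tn / (tn + fp))

  empty <- selection_metrics(character(0), truth, univ, ints)
  expect_equal(empty$sen, 0)
  expect_equal(empty$spe, 1)
  all_right <- selection_metrics(truth, truth, univ, ints)
  expect_equal(all_right$p_int, 1)
})

test_that("Harrell c-index counts usable pairs correctly", {
  # perfect anti-monotone PI on uncensored data
  t <- c(5, 3, 9, 1, 7); d <- rep(1, 5)
  expect_equal(harrell_cindex(-t, t, d), 1)
  expect_equal(harrell_cindex(t, t, d), 0)
  # hand-enumerated example with one censored subject:
  # times 1..5, status (1,1,0,1,1), PI (5,1,3,2,4)
  # usable pairs: (1,2)(1,3)(1,4)(1,5)(2,3)(2,4)(2,5)(4,5);
  # concordant: the four involving subject 1 only -> 4/8
  expect_equal(harrell_cindex(c(5, 1, 3, 2, 4), 1:5, c(1, 1, 0, 1, 1)),
               0.5)
  # against survival::concordance on censoring-free data (no ties)
  set.seed(4)
  tt <- rexp(40); pi <- rnorm(40)
  ours <- harrell_cindex(pi, tt, rep(1, 40))
  ref <- survival::concordance(survival::Surv(tt, rep(1, 40)) ~ pi)
  expect_equal(ours, 1 - ref$concordance, tolerance = 1e-12)
  # antisymmetry on censoring-free data
  expect_equal(harrell_cindex(-pi, tt, rep(1, 40)), 1 - ours)
})

test_that("time-dependent AUC behaves like an IPCW rank statistic", {
  set.seed(6)
  t <- rexp(100); d <- rep(1, 100)
  # perfectly separating PI, no censoring
  expect_equal(td_auc(-t, t, d), 1)
  # invariant under strictly increasing transforms
  pi <- rnorm(100)
  t2 <- rexp(100, exp(pi)); c2 <- runif(100, 0, quantile(t2, 0.8))
  tt <- pmin(t2, c2); dd <- as.numeric(t2 <= c2)
  expect_equal(td_auc(pi, tt, dd), td_auc(exp(pi), tt, dd))
  # uninformative PI hovers near 1/2
  set.seed(8)
  aucs <- replicate(40, {
    n <- 150
    p0 <- rnorm(n); t0 <- rexp(n); c0 <- runif(n, 0, quantile(t0, 0.8))
    td_auc(p0, pmin(t0, c0), as.numeric(t0 <= c0))
  })
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se + 5e-3)
})

test_that("test-set summaries follow the univariate PI Cox model", {
  set.seed(9)
  n <- 120
  pi <- rnorm(n)
  t0 <- rexp(n, exp(1.5 * pi)); c0 <- runif(n, 0, quantile(t0, 0.85))
  tt <- pmin(t0, c0); dd <- as.numeric(t0 <= c0)
  res <- test_set_tests(pi, tt, dd)
  expect_lt(res$deviance, 0)             # informative PI improves fit
  expect_lt(res$cox_test_p, 1e-4)
  expect_lt(res$lr_test_p, 1e-3)
  # median split differs by at most one subject
  grp <- pi > median(pi)
  expect_lte(abs(sum(grp) - sum(!grp)), 1)
  expect_warning(cst <- test_set_tests(rep(1, n), tt, dd), "constant")
  expect_equal(cst$cox_test_p, 1)
})

test_that("the benchmark harness aggregates per-replicate metrics", {
  cfg <- small_sim_config()
  bm <- run_benchmark(cfg, methods = c("oracle", "ordinary_lasso"),
                      replicates = 2, seed = 3, folds = 4, I = 4,
                      nlambda = 15)
  expect_s3_class(bm, "BenchmarkReport")
  expect_setequal(unique(bm$per_replicate$method),
                  c("oracle", "ordinary_lasso"))
  expect_equal(nrow(bm$per_replicate), 4)
  expect_true(all(c("rmse", "sen", "spe", "c_index", "td_auc",
                    "rmse_mean") %in% colnames(bm$summary)))
  orc <- bm$summary[bm$summary$method == "oracle", ]
  expect_equal(orc$sen, 1)               # oracle carries the true model
  expect_equal(orc$p_int, 1)
  # single-replicate aggregation equals that replicate's values
  bm1 <- run_benchmark(cfg, methods = "oracle", replicates = 1,
                       seed = 3, folds = 4)
  expect_equal(bm1$summary$c_index, bm1$per_replicate$c_index)
  # replicate-order invariance of the medians
  expect_equal(median(bm$per_replicate$sen[bm$per_replicate$method ==
                                             "ordinary_lasso"]),
               bm$summary$sen[bm$summary$method == "ordinary_lasso"])
})
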