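# Small in-code fixtures shared across test files.

# Cox survival data with q environment columns, p gene columns and an
# optional known signal; returns a SurvivalDataset.
make_cox_data <- function(n = 100, q = 2, p = 10, alpha = NULL,
                          beta = NULL, eta_pairs = NULL,
                          censor_q = 0.8, seed = 1,
                          interactions = FALSE) {
  set.seed(seed)
  E <- matrix(rnorm(n * q), n, q, dimnames = list(NULL, paste0("E", 1:q)))
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("G", 1:p)))
  lp <- rep(0, n)
  if (!is.null(alpha)) lp <- lp + as.numeric(E %*% alpha)
  if (!is.null(beta)) lp <- lp + as.numeric(X %*% beta)
  if (!is.null(eta_pairs))
    for (k in seq_len(nrow(eta_pairs)))
      lp <- lp + eta_pairs$effect[k] *
        E[, eta_pairs$env[k]] * X[, eta_pairs$gene[k]]
  t0 <- rexp(n, exp(lp))
  cc <- runif(n, 0, quantile(t0, censor_q))
  survival_dataset(pmin(t0, cc), as.numeric(t0 <= cc), E, X,
                   interactions = interactions)
}

# A small config for simulator tests that keeps p tiny: two overlapping
# groups, one effective, one interaction.
small_sim_config <- function(n_train = 150, n_test = 60,
                             censor_target = 0.3) {
  pw <- chain_layout(c(5, 5, 4), c(1, 0))
  sim_config(n_train = n_train, n_test = n_test,
             alpha = c(0.8, -0.5), ar_E = 0.3, ar_X = 0.5,
             pathways = pw,
             effective_groups = "group1", latent_effects = 1.5,
             interactions = data.frame(env = "E1", gene = "G2",
                                       effect = 1, group = "group1",
                                       stringsAsFactors = FALSE),
             baseline_rate = 10, censor_target = censor_target)
}

# Null-model config (no effects anywhere), used by calibration tests.
null_sim_config <- function(n_train = 150, n_test = 50, p_groups = 3,
                            censor_target = 0.3) {
  pw <- chain_layout(rep(4, p_groups), rep(0, p_groups - 1))
  sim_config(n_train = n_train, n_test = n_test, alpha = c(0, 0),
             ar_E = 0.3, ar_X = 0.5, pathways = pw,
             effective_groups = character(0),
             latent_effects = numeric(0),
             interactions = data.frame(env = character(0),
                                       gene = character(0),
                                       effect = numeric(0),
                                       group = character(0),
                                       stringsAsFactors = FALSE),
             baseline_rate = 10, censor_target = censor_target)
}
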