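# Independent oracles and small fixtures shared across tests. Everything
# here recomputes quantities from first principles, without touching the
# package's own estimators.

# A 4-gene, 2-drug toy study with hand-chosen intensities so every fold
# change is known in closed form. One treated and one control sample per
# group; drug A at two doses, one time-point.
tiny_study <- function() {
  genes <- c("g1", "g2", "g3", "g4")
  meta <- tibble::tibble(
    sample_id = c("t_low", "t_high", "ctrl", "b_t", "b_ctrl"),
    drug = c("A", "A", "A", "B", "B"),
    dose = c("low", "high", "control", "middle", "control"),
    time_days = c(3L, 3L, 3L, 7L, 7L),
    is_control = c(FALSE, FALSE, TRUE, FALSE, TRUE))
  intens <- cbind(
    t_low = c(3.0, 1.0, 2.0, 4.0),
    t_high = c(6.0, 0.5, 2.0, 8.0),
    ctrl = c(2.0, 2.0, 2.0, 2.0),
    b_t = c(2.0, 2.0, 10.0, 1.0),
    b_ctrl = c(2.0, 2.0, 2.0, 4.0))
  rownames(intens) <- genes
  expression_study(intens, meta)
}

# Full factorial single-drug study builder for regrouping tests: every
# (dose, time) cell with matched controls, deterministic intensities.
factorial_study <- function(drugs = c("D1", "D2"), fold = 4) {
  doses <- c("low", "middle", "high")
  times <- c(3L, 7L, 14L, 28L)
  genes <- sprintf("g%02d", 1:10)
  meta <- list()
  cols <- list()
  for (d in drugs) {
    for (t in times) {
      sid <- paste0(d, "_ctrl_", t)
      meta[[sid]] <- tibble::tibble(sample_id = sid, drug = d,
                                    dose = "control", time_days = t,
                                    is_control = TRUE)
      cols[[sid]] <- rep(2, 10)
      for (do in doses) {
        sid2 <- paste0(d, "_", do, "_", t)
        meta[[sid2]] <- tibble::tibble(sample_id = sid2, drug = d, dose = do,
                                       time_days = t, is_control = FALSE)
        x <- rep(2, 10)
        x[1:3] <- 2 * fold   # genes g01-g03 always strongly up
        cols[[sid2]] <- x
      }
    }
  }
  intens <- do.call(cbind, cols)
  rownames(intens) <- genes
  expression_study(intens, dplyr::bind_rows(meta))
}

# Exhaustive enumeration of the collapsed author-topic posterior over all
# K^N topic assignment vectors of a tiny corpus. Returns per-token marginal
# P(z_i = k | w). Implemented directly from the Dirichlet-multinomial
# marginal, independent of the sampler.
enumerate_collapsed_posterior <- function(token_author, token_word,
                                          n_authors, V, alpha, beta) {
  N <- length(token_word)
  K <- length(alpha)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), N)))
  logw <- apply(grid, 1, function(z) {
    n_ak <- matrix(0, n_authors, K)
    n_kw <- matrix(0, K, V)
    for (i in seq_len(N)) {
      n_ak[token_author[i], z[i]] <- n_ak[token_author[i], z[i]] + 1
      n_kw[z[i], token_word[i]] <- n_kw[z[i], token_word[i]] + 1
    }
    n_k <- rowSums(n_kw)
    N_a <- rowSums(n_ak)
    sum(lgamma(sum(alpha)) - lgamma(N_a + sum(alpha))) +
      sum(lgamma(t(n_ak) + alpha) - lgamma(alpha)) +
      sum(lgamma(V * beta) - lgamma(n_k + V * beta)) +
      sum(lgamma(n_kw + beta) - lgamma(beta))
  })
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  marg <- matrix(0, N, K)
  for (i in seq_len(N)) {
    for (k in seq_len(K)) marg[i, k] <- sum(w[grid[, i] == k])
  }
  marg
}

# Direct summation sKL oracle.
skl_oracle <- function(p, q) {
  s <- 0
  for (k in seq_along(p)) {
    s <- s + p[k] * log(p[k] / q[k]) + q[k] * log(q[k] / p[k])
  }
  s
}

# Exact hypergeometric upper-tail oracle by explicit binomial summation.
hyper_tail_oracle <- function(universe, set_size, list_size, overlap) {
  ks <- overlap:min(set_size, list_size)
  sum(choose(set_size, ks) * choose(universe - set_size, list_size - ks)) /
    choose(universe, list_size)
}

# Hand-rolled information criteria from a log-likelihood.
aic_oracle <- function(ll, k) 2 * k - 2 * ll
bic_oracle <- function(ll, k, n) k * log(n) - 2 * ll

# Module spec with one dose-driven and one time-driven drug, used by the
# reduction-logic tests.
two_mode_modules <- function(n_genes = 300L, genes_per_module = 40L) {
  tibble::tibble(
    module = 1:2,
    drugs = list("DRUG01", "DRUG02"),
    genes = list(1:genes_per_module,
                 (genes_per_module + 1):(2 * genes_per_module)),
    dose_profile = c("increasing", "flat"),
    time_profile = c("flat", "increasing"),
    max_log2_fc = c(2.5, 2.5))
}

# One seeded run of the pipeline from simulated study to reduction verdict
# for a single drug; returns the verdict string.
reduction_verdict_for_drug <- function(drug, modules, seed, K = 6,
                                       iterations = 200, n_genes = 300L) {
  sim <- simulate_tg_study(n_drugs = 2L, n_genes = n_genes,
                           modules = modules, seed = seed)
  fc <- apply_deg_filter(compute_fold_changes(sim$study))
  corpus <- suppressWarnings(discretize_to_counts(fc))
  model <- att_train(corpus, K = K, iterations = iterations, burn_in = 50,
                     optimize_interval = 10, seed = seed, average_last = 10)
  sim_mat <- pairwise_skl(model)
  design <- build_pair_design(sim_mat, drug)
  fits <- lapply(c("dose_and_time", "dose_only", "time_only"),
                 function(v) suppressWarnings(fit_skl_glm(design, v)))
  attr(compare_glm_variants(fits), "verdict")
}
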