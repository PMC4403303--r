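# Training, point estimates, held-out perplexity, model selection.

test_that("training is bit-reproducible under a fixed seed", {
  sim <- simulate_att_corpus(K = 3, V = 40, n_authors = 20,
                             tokens_per_doc = 25, seed = 10)
  m1 <- att_train(sim$corpus, K = 3, iterations = 60, burn_in = 20, seed = 4)
  m2 <- att_train(sim$corpus, K = 3, iterations = 60, burn_in = 20, seed = 4)
  expect_identical(m1$theta, m2$theta)
  expect_identical(m1$phi_smoothed, m2$phi_smoothed)
  expect_identical(m1$alpha, m2$alpha)
  expect_identical(m1$log_lik, m2$log_lik)
})

test_that("theta and phi rows are normalized to 1e-9", {
  sim <- simulate_att_corpus(K = 4, V = 60, n_authors = 15,
                             tokens_per_doc = 30, seed = 2)
  m <- att_train(sim$corpus, K = 4, iterations = 80, burn_in = 20, seed = 2)
  expect_true(all(abs(rowSums(m$theta) - 1) < 1e-9))
  expect_true(all(abs(rowSums(m$phi_smoothed) - 1) < 1e-9))
  expect_true(all(m$phi_smoothed > 0))
  # raw rows sum to one over their support (all topics occupied here)
  occupied <- rowSums(m$phi_raw) > 0
  expect_true(all(abs(rowSums(m$phi_raw[occupied, , drop = FALSE]) - 1) < 1e-9))
})

test_that("a separable corpus yields disjoint raw supports per topic", {
  # two disjoint vocabularies used by two disjoint document sets
  set.seed(77)
  half <- matrix(0L, 10, 40)
  for (d in 1:10) {
    half[d, sample(1:20, 8)] <- sample(1:3, 8, replace = TRUE)
  }
  other <- matrix(0L, 10, 40)
  for (d in 1:10) {
    other[d, 20 + sample(1:20, 8)] <- sample(1:3, 8, replace = TRUE)
  }
  corpus <- count_corpus(rbind(half, other))
  m <- att_train(corpus, K = 2, iterations = 150, burn_in = 30, seed = 6)
  support <- m$phi_raw > 0
  # each topic's support lies within one vocabulary half (label swap ok)
  in_first <- rowSums(support[, 1:20]) / rowSums(support)
  expect_true(all(pmin(in_first, 1 - in_first) < 0.15))
  expect_true(abs(in_first[1] - in_first[2]) > 0.7)
})

test_that("the likelihood trace stabilizes after burn-in", {
  sim <- simulate_att_corpus(K = 3, V = 50, n_authors = 25,
                             tokens_per_doc = 40, seed = 12)
  m <- att_train(sim$corpus, K = 3, iterations = 500, burn_in = 50, seed = 12)
  tail_ll <- m$log_lik[451:500]   # last 10% of sweeps
  trend <- lm(tail_ll ~ seq_along(tail_ll))
  slope <- summary(trend)$coefficients[2, ]
  # slope indistinguishable from noise at ~3 SE
  expect_lt(abs(slope["Estimate"]), 3 * slope["Std. Error"] + 1e-8)
})

test_that("zero-token authors fall back to the prior mean", {
  corpus <- count_corpus(matrix(c(2L, 1L), 1, 2,
                                dimnames = list("d1", c("a", "b"))),
                         doc_author = 1L, author_ids = c("act", "idle"))
  s <- initialize_state(corpus, K = 2, seed = 1)
  expect_warning(theta <- estimate_theta(s, c("act", "idle")), "no tokens")
  expect_equal(unname(theta["idle", ]), s$alpha / sum(s$alpha))
  expect_equal(rowSums(theta), c(act = 1, idle = 1))
})

test_that("raw phi keeps exact zeros and point masses", {
  corpus <- count_corpus(matrix(c(3L, 0L, 0L, 2L), 2, 2,
                                dimnames = list(c("d1", "d2"), c("a", "b"))))
  s <- initialize_state(corpus, K = 1, seed = 1)
  phi <- estimate_phi(s, smoothed = FALSE)
  expect_equal(unname(phi[1, ]), c(3, 2) / 5)
  # single token on one gene -> point mass
  c2 <- count_corpus(matrix(1L, 1, 1, dimnames = list("d", "g")))
  s2 <- initialize_state(c2, K = 1, seed = 1)
  expect_equal(unname(estimate_phi(s2, smoothed = FALSE)[1, ]), 1)
  # smoothed mode is strictly positive even for unseen genes
  expect_true(all(estimate_phi(s, smoothed = TRUE) > 0))
})

test_that("uniform topic-gene distributions give perplexity exactly V", {
  sim <- simulate_att_corpus(K = 2, V = 25, n_authors = 6,
                             tokens_per_doc = 20, seed = 9)
  m <- att_train(sim$corpus, K = 2, iterations = 30, burn_in = 10, seed = 9)
  m$phi_smoothed[] <- 1 / 25
  heldout <- simulate_att_corpus(K = 2, V = 25, n_authors = 4,
                                 tokens_per_doc = 15, seed = 10)$corpus
  expect_equal(held_out_perplexity(m, heldout, seed = 1), 25,
               tolerance = 1e-12)
})

test_that("perplexity matches a hand-evaluated formula on a tiny document", {
  sim <- simulate_att_corpus(K = 2, V = 4, n_authors = 3,
                             tokens_per_doc = 10, seed = 21)
  m <- att_train(sim$corpus, K = 2, iterations = 30, burn_in = 10, seed = 21)
  # make both topics share one known gene distribution: the mixture then
  # equals p regardless of the folded-in theta
  p <- c(0.4, 0.3, 0.2, 0.1)
  m$phi_smoothed[1, ] <- p
  m$phi_smoothed[2, ] <- p
  held <- count_corpus(matrix(c(2L, 1L, 0L, 0L), 1, 4,
                              dimnames = list("h", colnames(m$phi_smoothed))))
  expected <- exp(-(2 * log(0.4) + log(0.3)) / 3)
  expect_equal(held_out_perplexity(m, held, seed = 5), expected,
               tolerance = 1e-10)
})

test_that("out-of-vocabulary held-out genes are dropped with a warning", {
  sim <- simulate_att_corpus(K = 2, V = 10, n_authors = 5,
                             tokens_per_doc = 10, seed = 31)
  m <- att_train(sim$corpus, K = 2, iterations = 20, burn_in = 5, seed = 31)
  held <- count_corpus(matrix(c(2L, 3L), 1, 2,
                              dimnames = list("h", c("gene_0001", "NOVEL"))))
  expect_warning(p <- held_out_perplexity(m, held, seed = 1), "vocabulary")
  expect_true(is.finite(p) && p > 0)
})

test_that("cross-validated selection reports the grid and a single winner", {
  sim <- simulate_att_corpus(K = 2, V = 30, n_authors = 12,
                             tokens_per_doc = 20, seed = 17)
  res <- select_num_topics(sim$corpus, K_grid = c(2, 4), folds = 4,
                           iterations = 40, burn_in = 10, seed = 17)
  expect_equal(res$K, c(2L, 4L))
  expect_equal(sum(res$recommended), 1L)
  expect_equal(res$K[res$recommended],
               res$K[which.min(res$mean_perplexity)])
  expect_true(all(res$mean_perplexity > 0))
  expect_error(select_num_topics(sim$corpus, integer(0)), "K_grid")
  # leave-one-out: folds equal to the number of documents is accepted
  res_loo <- select_num_topics(sim$corpus, K_grid = 2, folds = 12,
                               iterations = 20, burn_in = 5, seed = 3)
  expect_equal(nrow(res_loo), 1L)
})

test_that("model round trip through a directory preserves the estimates", {
  sim <- simulate_att_corpus(K = 3, V = 20, n_authors = 8,
                             tokens_per_doc = 15, seed = 23)
  m <- att_train(sim$corpus, K = 3, iterations = 40, burn_in = 10, seed = 23)
  dir <- withr::local_tempdir()
  write_att_model(m, dir)
  m2 <- read_att_model(dir)
  expect_equal(unname(m2$theta), unname(m$theta), tolerance = 1e-12)
  expect_equal(unname(m2$phi_raw), unname(m$phi_raw), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(m2$alpha, m$alpha, tolerance = 1e-12)
  expect_equal(m2$K, m$K)
})

test_that("tidy and glance summarize a fitted model", {
  sim <- simulate_att_corpus(K = 2, V = 15, n_authors = 6,
                             tokens_per_doc = 12, seed = 25)
  m <- att_train(sim$corpus, K = 2, iterations = 30, burn_in = 10, seed = 25)
  td <- tidy(m)
  expect_equal(nrow(td), 6 * 2)
  expect_true(all(abs(tapply(td$probability, td$author, sum) - 1) < 1e-9))
  raw <- tidy(m, matrix = "phi_raw")
  expect_true(all(raw$probability > 0))
  g <- glance(m)
  expect_equal(g$K, 2L)
  expect_equal(g$n_authors, 6L)
})
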