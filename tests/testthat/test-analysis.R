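# Symmetric KL similarity, ranking, topic/gene reports, enrichment.

make_sim <- function(scores, ids) {
  dimnames(scores) <- list(ids, ids)
  structure(list(scores = scores, feature_ids = ids),
            class = "similarity_matrix")
}

test_that("sKL is a symmetric premetric and matches the direct formula", {
  p <- c(0.5, 0.5)
  q <- c(0.9, 0.1)
  expect_equal(skl_divergence(p, q), skl_oracle(p, q), tolerance = 1e-12)
  expect_equal(skl_divergence(p, q), 0.8788898, tolerance = 1e-6)

  set.seed(314)
  for (i in 1:200) {
    k <- sample(2:12, 1)
    a <- rgamma(k, 1) + 1e-6
    b <- rgamma(k, 1) + 1e-6
    a <- a / sum(a)
    b <- b / sum(b)
    expect_gte(skl_divergence(a, b), 0)
    expect_equal(skl_divergence(a, b), skl_divergence(b, a),
                 tolerance = 1e-12)
    expect_equal(skl_divergence(a, a), 0)
  }

  expect_error(skl_divergence(c(0.5, 0.5), c(1, 0)), "smoothed")
  expect_error(skl_divergence(c(0.5, 0.5), c(0.2, 0.2)), "sum to 1")
  expect_error(skl_divergence(c(0.5, 0.5), c(0.3, 0.3, 0.4)), "length")
})

test_that("pairwise sKL equals element-wise recomputation", {
  set.seed(41)
  theta <- matrix(rgamma(5 * 6, 1) + 0.01, 5, 6)
  theta <- theta / rowSums(theta)
  rownames(theta) <- paste0("f", 1:5)
  sim <- pairwise_skl(theta)
  expect_equal(diag(sim$scores), setNames(rep(0, 5), paste0("f", 1:5)))
  expect_equal(sim$scores, t(sim$scores))
  for (i in 1:5) {
    for (j in 1:5) {
      expect_equal(sim$scores[i, j],
                   skl_divergence(theta[i, ], theta[j, ]),
                   tolerance = 1e-9)
    }
  }
  # identical rows score exactly zero
  theta2 <- rbind(theta, theta[1, ])
  rownames(theta2) <- c(rownames(theta), "f1copy")
  expect_equal(pairwise_skl(theta2)$scores["f1", "f1copy"], 0)
})

test_that("similarity ranking is ascending, self-free and tie-stable", {
  # scores in the style of a published drug-similarity table
  ids <- c("Acetaminophen", "Bromobenzene", "Phenacetin", "Coumarin")
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- 3.04238
  m[1, 3] <- m[3, 1] <- 4.47157
  m[1, 4] <- m[4, 1] <- 6.03134
  m[2, 3] <- m[3, 2] <- 5
  m[2, 4] <- m[4, 2] <- 5
  m[3, 4] <- m[4, 3] <- 5
  sim <- make_sim(m, ids)
  rk <- rank_similar(sim, "Acetaminophen", top_n = 10)
  expect_equal(rk$feature, c("Bromobenzene", "Phenacetin", "Coumarin"))
  expect_equal(rk$skl[1], 3.04238)
  expect_false("Acetaminophen" %in% rk$feature)
  expect_equal(nrow(rk), 3)  # min(top_n, n - 1)

  # all-equal scores fall back to feature-id order
  rk2 <- rank_similar(sim, "Coumarin", top_n = 2)
  expect_equal(rk2$feature, c("Bromobenzene", "Phenacetin"))

  expect_error(rank_similar(sim, "Aspirin"), "unknown feature")
})

test_that("top_topics reproduces a known theta row ordering", {
  K <- 200
  row <- rep((1 - 0.366 - 0.091 - 0.07) / 197, K)
  row[161] <- 0.366
  row[197] <- 0.091
  row[164] <- 0.07
  theta <- rbind(t47 = row / sum(row))
  tt <- top_topics(theta, "t47", n = 3)
  expect_equal(tt$topic, c(161L, 197L, 164L))
  expect_equal(tt$probability, c(0.366, 0.091, 0.07), tolerance = 1e-9)

  # uniform row: ties break toward the smallest topic index
  uni <- rbind(u = rep(1 / 6, 6))
  expect_equal(top_topics(uni, "u", n = 3)$topic, 1:3)
  # point mass
  pm <- rbind(p = c(0, 1, 0))
  expect_equal(top_topics(pm, "p", n = 1),
               tibble::tibble(topic = 2L, probability = 1))
  expect_warning(res <- top_topics(uni, "u", n = 10), "exceeds K")
  expect_equal(nrow(res), 6)
})

test_that("top_genes returns the positive support, ordered and truncated", {
  phi <- matrix(0, 2, 6, dimnames = list(NULL, paste0("g", 1:6)))
  phi[1, 1:4] <- c(0.4, 0.3, 0.2, 0.1)
  phi[2, 5] <- 1
  tg <- top_genes(phi, 1)
  expect_equal(nrow(tg), 4)   # exactly the positive-support size
  expect_equal(tg$gene[1], "g1")
  expect_true(all(diff(tg$probability) <= 0))
  expect_equal(nrow(top_genes(phi, 1, max_n = 2)), 2)
  expect_equal(top_genes(phi, 2)$gene, "g5")   # point mass

  phi_empty <- rbind(phi, 0)
  empty <- top_genes(phi_empty, 3)
  expect_equal(nrow(empty), 0)
  expect_true(isTRUE(attr(empty, "empty_topic")))
  expect_error(top_genes(phi, 9), "out of range")
})

test_that("gene-list export writes one file per topic plus a manifest", {
  sim <- simulate_att_corpus(K = 3, V = 30, n_authors = 10,
                             tokens_per_doc = 20, seed = 19)
  m <- att_train(sim$corpus, K = 3, iterations = 40, burn_in = 10, seed = 19)
  dir <- withr::local_tempdir()
  manifest <- export_gene_lists(m, out_path = dir)
  expect_equal(nrow(manifest), 3)
  for (r in seq_len(nrow(manifest))) {
    path <- file.path(dir, manifest$file[r])
    expect_true(file.exists(path))
    genes <- readLines(path)
    expect_equal(length(genes), manifest$n_genes[r])
    expect_setequal(genes, top_genes(m, manifest$topic[r])$gene)
  }
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  # topic filter -> exactly one list file
  dir2 <- withr::local_tempdir()
  m2 <- export_gene_lists(m, topics = 2, out_path = dir2)
  expect_equal(m2$topic, 2)
  expect_equal(list.files(dir2), c("manifest.tsv", "topic_002.txt"))
})

test_that("hypergeometric enrichment matches the exact tail oracle", {
  sets <- list(S = paste0("g", 1:5))
  hits <- c(paste0("g", 1:4), "g10")      # overlap 4 of list 5
  res <- enrich_gene_sets(hits, sets, universe_size = 20)
  expect_equal(res$p_value, 76 / 15504, tolerance = 1e-12)
  expect_equal(res$p_value, hyper_tail_oracle(20, 5, 5, 4), tolerance = 1e-14)
  expect_equal(res$overlap, 4L)
  # single set: BH FDR equals the p-value
  expect_equal(res$fdr, res$p_value)

  # zero overlap: upper tail from >= 0 is exactly 1
  res0 <- enrich_gene_sets(paste0("x", 1:3),
                           list(S = paste0("g", 1:4)), universe_size = 50)
  expect_equal(res0$p_value, 1)

  # p-values in (0, 1] and BH monotone after sorting
  set.seed(63)
  sets_many <- lapply(1:8, function(i) paste0("g", sample(1:100, 10)))
  names(sets_many) <- paste0("S", 1:8)
  resm <- enrich_gene_sets(paste0("g", 1:15), sets_many, universe_size = 100)
  expect_true(all(resm$p_value > 0 & resm$p_value <= 1))
  expect_true(all(diff(resm$fdr) >= -1e-12))
  expect_error(enrich_gene_sets(character(0), sets, 20), "empty")
})

test_that("GMT files round-trip through read_gmt", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3",
               "setB\tanother\tg2\tg4"), path)
  sets <- read_gmt(path)
  expect_equal(names(sets), c("setA", "setB"))
  expect_equal(sets$setA, c("g1", "g2", "g3"))
  expect_equal(sets$setB, c("g2", "g4"))
})

test_that("drugs sharing a planted module are mutual sKL nearest neighbors", {
  shared_modules <- tibble::tibble(
    module = 1:2,
    drugs = list(c("DRUG01", "DRUG02"), "DRUG03"),
    genes = list(1:40, 41:80),
    dose_profile = c("increasing", "increasing"),
    time_profile = c("flat", "flat"),
    max_log2_fc = c(2.5, 2.5))
  wins <- 0L
  for (seed in 1:10) {
    sim <- simulate_tg_study(n_drugs = 3, n_genes = 200,
                             modules = shared_modules, seed = seed)
    fc <- apply_deg_filter(compute_fold_changes(sim$study))
    corpus <- suppressWarnings(discretize_to_counts(fc))
    drug_corpus <- regroup_by_feature(corpus, "drug")
    m <- att_train(drug_corpus, K = 4, iterations = 120, burn_in = 30,
                   seed = seed)
    s <- pairwise_skl(m)
    nn1 <- rank_similar(s, "DRUG01", 1)$feature
    nn2 <- rank_similar(s, "DRUG02", 1)$feature
    if (nn1 == "DRUG02" && nn2 == "DRUG01") wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})
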