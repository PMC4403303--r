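rdirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Simulate a corpus from the author-topic generative model
#'
#' Topic-gene distributions are drawn from a symmetric Dirichlet(beta),
#' per-author topic weights from Dirichlet(alpha), and each document's
#' tokens by ancestral sampling: topic from the author's weights, gene from
#' the topic. This is exactly the model the collapsed Gibbs sampler
#' inverts, so it supplies ground truth for recovery tests.
#'
#' @param K,V numbers of topics and genes.
#' @param n_authors number of authors; each contributes `docs_per_author`
#'   documents of `tokens_per_doc` tokens.
#' @param docs_per_author,tokens_per_doc document layout.
#' @param alpha Dirichlet concentration over topics: scalar (symmetric) or
#'   length-K vector (asymmetric).
#' @param beta symmetric Dirichlet concentration over genes.
#' @param seed integer seed.
#' @return list with `corpus` (a `count_corpus`) and `truth` (a
#'   `planted_truth`: `true_phi`, `true_theta`, `true_alpha`).
#' @export
simulate_att_corpus <- function(K, V, n_authors, docs_per_author = 1L,
                                tokens_per_doc = 50L, alpha = 1, beta = 0.05,
                                seed = 1L) {
  if (K < 1 || V < 1 || n_authors < 1 || docs_per_author < 1 ||
      tokens_per_doc < 1) {
    abort("all sizes must be >= 1")
  }
  if (any(alpha <= 0) || beta <= 0) abort("alpha and beta must be positive")
  if (length(alpha) == 1) alpha <- rep(alpha, K)
  if (length(alpha) != K) abort("alpha must be scalar or length K")

  set.seed(seed)
  phi <- rdirichlet(K, rep(beta, V))
  theta <- rdirichlet(n_authors, alpha)

  D <- n_authors * docs_per_author
  doc_author <- rep(seq_len(n_authors), each = docs_per_author)
  counts <- matrix(0L, D, V)
  for (d in seq_len(D)) {
    zs <- sample.int(K, tokens_per_doc, replace = TRUE,
                     prob = theta[doc_author[d], ])
    for (k in unique(zs)) {
      nw <- rmultinom(1, sum(zs == k), phi[k, ])[, 1]
      counts[d, ] <- counts[d, ] + nw
    }
  }
  genes <- sprintf("gene_%04d", seq_len(V))
  colnames(counts) <- genes
  doc_ids <- sprintf("doc_%04d", seq_len(D))
  author_ids <- sprintf("author_%04d", seq_len(n_authors))
  corpus <- new_count_corpus(counts = Matrix::Matrix(counts, sparse = TRUE),
                             doc_ids = doc_ids, doc_author = doc_author,
                             author_ids = author_ids,
                             feature_level = "treatment")
  truth <- structure(list(true_phi = phi, true_theta = theta,
                          true_alpha = alpha),
                     class = "planted_truth")
  list(corpus = corpus, truth = truth)
}

#' Default planted-module specification for a simulated dose-time study
#'
#' Each module is a block of genes activated by one or more drugs, with a
#' dose profile (`"increasing"`: log fold change grows with dose rank;
#' `"flat"`: same at every dose) and a time profile (same choices over the
#' four durations).
#'
#' @param n_drugs number of drugs in the study.
#' @param n_genes vocabulary size.
#' @param genes_per_module module size (default 40).
#' @return tibble with one row per module: `module`, `drugs` (list-col),
#'   `genes` (list-col), `dose_profile`, `time_profile`, `max_log2_fc`.
#' @export
default_module_spec <- function(n_drugs, n_genes, genes_per_module = 40L) {
  n_modules <- n_drugs
  starts <- floor(seq(1, n_genes - genes_per_module + 1,
                      length.out = n_modules))
  tibble(
    module = seq_len(n_modules),
    drugs = lapply(seq_len(n_modules), function(i) sprintf("DRUG%02d", i)),
    genes = lapply(starts, function(s) s:(s + genes_per_module - 1L)),
    dose_profile = rep("increasing", n_modules),
    time_profile = rep("flat", n_modules),
    max_log2_fc = rep(2.5, n_modules))
}

profile_weight <- function(profile, rank, n_levels) {
  switch(profile,
         flat = 1,
         increasing = rank / n_levels,
         abort(paste0("unknown profile: ", profile)))
}

#' Simulate a factorial repeated-dose toxicogenomic study
#'
#' Emulates the statistical structure of an in vivo repeated-dose design:
#' each drug is profiled at three dose levels and four durations (3, 7, 14,
#' 28 days) with concurrent per-time controls. Control intensities are
#' log-normal around a common baseline; for treated samples, genes in a
#' drug's planted modules are multiplied by a fold change determined by the
#' module's dose and time profiles, and every sample gets multiplicative
#' log-normal noise. Only module genes at sufficiently activated
#' dose/time combinations exceed the 1.5 differential-expression cutoff, so
#' the planted modules are the ground-truth latent processes.
#'
#' @param n_drugs number of drugs (default 5; each gets 12 treatments).
#' @param n_genes vocabulary size (default 500).
#' @param modules module specification tibble, see [default_module_spec()].
#' @param noise_sd standard deviation of log2 multiplicative noise
#'   (default 0.15).
#' @param n_replicates animals per group (default 3).
#' @param baseline mean log2 control intensity (default 7, arbitrary
#'   expression units).
#' @param seed integer seed.
#' @return list with `study` (an `expression_study`) and `truth`
#'   (a `planted_truth` carrying the module spec and design metadata).
#' @export
simulate_tg_study <- function(n_drugs = 5L, n_genes = 500L, modules = NULL,
                              noise_sd = 0.15, n_replicates = 3L,
                              baseline = 7, seed = 1L) {
  if (n_drugs < 1 || n_genes < 1 || n_replicates < 1) {
    abort("all sizes must be >= 1")
  }
  modules <- modules %||% default_module_spec(n_drugs, n_genes)
  if (any(lengths(modules$genes) == 0)) abort("empty gene module in spec")
  set.seed(seed)

  drugs <- sprintf("DRUG%02d", seq_len(n_drugs))
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  gene_base <- 2^(baseline + rnorm(n_genes, 0, 0.5))  # per-gene baseline

  design <- tidyr::expand_grid(drug = drugs, dose = DOSE_LEVELS,
                               time_days = TIME_DAYS)
  # log2 fold-change map: gene x treatment
  lfc <- matrix(0, n_genes, nrow(design))
  for (m in seq_len(nrow(modules))) {
    g <- modules$genes[[m]]
    for (ti in seq_len(nrow(design))) {
      if (!design$drug[ti] %in% modules$drugs[[m]]) next
      wd <- profile_weight(modules$dose_profile[m],
                           match(design$dose[ti], DOSE_LEVELS), 3L)
      wt <- profile_weight(modules$time_profile[m],
                           match(design$time_days[ti], TIME_DAYS), 4L)
      lfc[g, ti] <- lfc[g, ti] + modules$max_log2_fc[m] * wd * wt
    }
  }

  meta <- list()
  cols <- list()
  for (d in drugs) {
    for (t in TIME_DAYS) {
      for (r in seq_len(n_replicates)) {
        sid <- sprintf("%s_ctrl_%dd_r%d", d, t, r)
        meta[[sid]] <- tibble(sample_id = sid, drug = d, dose = "control",
                              time_days = t, is_control = TRUE)
        cols[[sid]] <- gene_base * 2^rnorm(n_genes, 0, noise_sd)
      }
    }
  }
  for (ti in seq_len(nrow(design))) {
    for (r in seq_len(n_replicates)) {
      sid <- sprintf("%s_%s_%dd_r%d", design$drug[ti], design$dose[ti],
                     design$time_days[ti], r)
      meta[[sid]] <- tibble(sample_id = sid, drug = design$drug[ti],
                            dose = design$dose[ti],
                            time_days = design$time_days[ti],
                            is_control = FALSE)
      cols[[sid]] <- gene_base * 2^(lfc[, ti] + rnorm(n_genes, 0, noise_sd))
    }
  }
  intensities <- do.call(cbind, cols)
  rownames(intensities) <- genes
  study <- expression_study(intensities, dplyr::bind_rows(meta))
  truth <- structure(list(modules = modules, design = design,
                          log2_fc = lfc, genes = genes, noise_sd = noise_sd),
                     class = "planted_truth")
  list(study = study, truth = truth)
}

#' Align estimated topics with planted topics
#'
#' Resolves label switching: finds the one-to-one topic assignment
#' minimizing the summed total-variation distance between estimated and
#' true topic-gene rows — exhaustively for K <= 8, greedily (best available
#' match per true topic, in order of best distance) for larger K.
#'
#' @param estimated_phi,true_phi topic-by-gene stochastic matrices over the
#'   same vocabulary; `estimated_phi` may have more rows, in which case the
#'   unmatched extras are flagged.
#' @return list with `permutation` (index into `estimated_phi` rows for
#'   each true topic), `tv_distances` (per matched topic), `mean_tv`,
#'   `method` (`"exhaustive"` or `"greedy"`), `unmatched` (extra estimated
#'   rows).
#' @export
align_topics <- function(estimated_phi, true_phi) {
  if (ncol(estimated_phi) != ncol(true_phi)) {
    abort("estimated and true phi must share a vocabulary")
  }
  K_true <- nrow(true_phi)
  K_est <- nrow(estimated_phi)
  if (K_est < K_true) abort("estimated phi has fewer topics than the truth")

  # pairwise total-variation distances: true k (rows) x estimated j (cols)
  tv <- matrix(0, K_true, K_est)
  for (k in seq_len(K_true)) {
    tv[k, ] <- 0.5 * rowSums(abs(sweep(estimated_phi, 2, true_phi[k, ])))
  }

  if (K_est <= 8) {
    perms <- all_permutations(K_est)
    best <- NULL
    best_total <- Inf
    for (i in seq_len(nrow(perms))) {
      assign <- perms[i, seq_len(K_true)]
      total <- sum(tv[cbind(seq_len(K_true), assign)])
      if (total < best_total) {
        best_total <- total
        best <- assign
      }
    }
    perm <- best
    method <- "exhaustive"
  } else {
    # repeatedly take the globally best remaining (true, estimated) match
    perm <- integer(K_true)
    tvw <- tv
    for (step in seq_len(K_true)) {
      idx <- which(tvw == min(tvw), arr.ind = TRUE)[1, ]
      perm[idx[1]] <- idx[2]
      tvw[idx[1], ] <- Inf
      tvw[, idx[2]] <- Inf
    }
    method <- "greedy"
  }
  d <- numeric(K_true)
  for (k in seq_len(K_true)) {
    d[k] <- 0.5 * sum(abs(estimated_phi[perm[k], ] - true_phi[k, ]))
  }
  list(permutation = perm, tv_distances = d, mean_tv = mean(d),
       method = method, unmatched = setdiff(seq_len(K_est), perm))
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
  dimnames(out) <- NULL
  out
}
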