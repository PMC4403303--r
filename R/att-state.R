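#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_tile geom_point
#'   geom_col labs scale_fill_gradient facet_wrap theme_minimal
#' @export
ggplot2::autoplot

# Expand a count corpus into flat token arrays (0-based for the C++ core).
# Tokens are ordered by document, then by gene index within document, so a
# sweep visits them in document order as the sampler contract requires.
corpus_tokens <- function(corpus) {
  tm <- Matrix::summary(corpus$counts)
  ord <- order(tm$i, tm$j)
  reps <- as.integer(tm$x[ord])
  doc <- rep.int(tm$i[ord], reps)
  word <- rep.int(tm$j[ord], reps)
  list(doc = as.integer(doc) - 1L,
       word = as.integer(word) - 1L,
       author = corpus$doc_author[doc] - 1L)
}

#' Initialize the collapsed Gibbs sampler state
#'
#' Every token gets a topic drawn uniformly at random; the author-topic and
#' topic-gene count tables are tallied from those assignments. The
#' asymmetric prior starts symmetric at `alpha0 / K` per topic.
#'
#' @param corpus a `count_corpus`.
#' @param K number of latent biological processes (topics), >= 1.
#' @param alpha0 total concentration of the topic prior; each component
#'   starts at `alpha0 / K`. Default 50, a common collapsed-LDA choice.
#' @param beta0 symmetric concentration of the topic-gene prior (default
#'   0.01).
#' @param seed integer seed; same seed, same state.
#' @return an `att_state`.
#' @export
initialize_state <- function(corpus, K, alpha0 = 50, beta0 = 0.01, seed = 1L) {
  stopifnot(inherits(corpus, "count_corpus"))
  if (K < 1) abort("K must be >= 1")
  if (alpha0 <= 0 || beta0 <= 0) abort("alpha0 and beta0 must be positive")
  if (sum(corpus$counts) == 0) abort("corpus has no tokens")
  tok <- corpus_tokens(corpus)
  N <- length(tok$word)
  A <- length(corpus$author_ids)
  V <- length(corpus$vocabulary)

  set.seed(seed)
  z <- sample.int(K, N, replace = TRUE) - 1L
  if (K == 1L) z <- rep(0L, N)

  n_ak <- matrix(0L, A, K)
  n_kw <- matrix(0L, K, V)
  for (i in seq_len(N)) {
    n_ak[tok$author[i] + 1L, z[i] + 1L] <- n_ak[tok$author[i] + 1L, z[i] + 1L] + 1L
    n_kw[z[i] + 1L, tok$word[i] + 1L] <- n_kw[z[i] + 1L, tok$word[i] + 1L] + 1L
  }

  structure(list(z = z, tokens = tok,
                 n_ak = n_ak, n_kw = n_kw, n_k = rowSums(n_kw),
                 alpha = rep(alpha0 / K, K), beta = beta0, K = as.integer(K),
                 n_authors = A, n_vocab = V, rng_seed = as.integer(seed)),
            class = "att_state")
}

#' @export
print.att_state <- function(x, ...) {
  cat(sprintf("att_state: %d tokens, %d authors, %d genes, K = %d\n",
              length(x$z), x$n_authors, x$n_vocab, x$K))
  invisible(x)
}

# Recount oracle: tally count tables directly from z and compare. Used by
# tests and by gibbs_sweep's consistency guard.
recount_state <- function(state) {
  n_ak <- matrix(0L, state$n_authors, state$K)
  n_kw <- matrix(0L, state$K, state$n_vocab)
  for (i in seq_along(state$z)) {
    a <- state$tokens$author[i] + 1L
    k <- state$z[i] + 1L
    w <- state$tokens$word[i] + 1L
    n_ak[a, k] <- n_ak[a, k] + 1L
    n_kw[k, w] <- n_kw[k, w] + 1L
  }
  list(n_ak = n_ak, n_kw = n_kw, n_k = rowSums(n_kw))
}

check_state_consistency <- function(state) {
  rc <- recount_state(state)
  if (!identical(unname(rc$n_ak), unname(state$n_ak)) ||
      !identical(unname(rc$n_kw), unname(state$n_kw)) ||
      !all(rc$n_k == state$n_k)) {
    abort("att_state count tables are inconsistent with topic assignments")
  }
  invisible(TRUE)
}

#' Run collapsed Gibbs sweeps over all tokens
#'
#' Resamples every token's topic once per sweep from its collapsed full
#' conditional, updating the count tables incrementally. Randomness comes
#' from R's RNG, so wrap in `set.seed()` for reproducibility.
#'
#' @param state an `att_state`.
#' @param nsweeps number of full passes (default 1).
#' @param check if `TRUE`, verify count-table consistency before sweeping.
#' @return the updated `att_state`.
#' @export
gibbs_sweep <- function(state, nsweeps = 1L, check = FALSE) {
  stopifnot(inherits(state, "att_state"))
  if (check) check_state_consistency(state)
  out <- cpp_gibbs_sweeps(state$z, state$tokens$author, state$tokens$word,
                          state$n_ak, state$n_kw, as.integer(state$n_k),
                          state$alpha, state$beta, as.integer(nsweeps))
  state$z <- out$z
  state$n_ak <- out$n_ak
  state$n_kw <- out$n_kw
  state$n_k <- as.numeric(out$n_k)
  state
}

#' Collapsed joint log-likelihood log p(w, z)
#'
#' The Dirichlet-multinomial marginal of the author-topic model with the
#' topic proportions and topic-gene distributions integrated out; recorded
#' per sweep as the convergence diagnostic.
#'
#' @param state an `att_state`.
#' @return scalar log-likelihood in nats.
#' @export
joint_log_lik <- function(state) {
  a_tot <- sum(state$alpha)
  N_a <- rowSums(state$n_ak)
  ll_theta <- state$n_authors * lgamma(a_tot) - sum(lgamma(N_a + a_tot)) +
    sum(lgamma(sweep(state$n_ak, 2, state$alpha, "+"))) -
    state$n_authors * sum(lgamma(state$alpha))
  V <- state$n_vocab
  ll_phi <- state$K * lgamma(V * state$beta) -
    sum(lgamma(state$n_k + V * state$beta)) +
    sum(lgamma(state$n_kw + state$beta)) -
    state$K * V * lgamma(state$beta)
  ll_theta + ll_phi
}

#' Learn the asymmetric topic prior by Minka's fixed point
#'
#' Maximum-likelihood update of the Dirichlet concentration vector of the
#' author-topic Dirichlet-multinomial, iterated to convergence:
#' alpha_k <- alpha_k * (sum_a digamma(n_ak + alpha_k) - A digamma(alpha_k)) /
#'            (sum_a digamma(N_a + sum(alpha)) - A digamma(sum(alpha))).
#'
#' @param state an `att_state` (or, for direct use, pass `counts`).
#' @param counts optional author-by-topic count matrix overriding
#'   `state$n_ak`; lets the update be applied to any Dirichlet-multinomial
#'   table.
#' @param tol relative-change convergence tolerance (default 1e-6).
#' @param max_iter inner iteration cap (default 1000).
#' @param floor smallest admissible component (default 1e-8); components
#'   falling below are clamped.
#' @return the state with `alpha` updated (or, with `counts`, the alpha
#'   vector itself).
#' @export
optimize_alpha <- function(state = NULL, counts = NULL, tol = 1e-6,
                           max_iter = 1000L, floor = 1e-8) {
  n_ak <- counts %||% state$n_ak
  alpha <- if (is.null(state)) rep(1, ncol(n_ak)) else state$alpha
  if (all(n_ak == 0)) {
    warn("all author-topic counts are zero; alpha left unchanged")
    return(if (is.null(counts)) state else alpha)
  }
  A <- nrow(n_ak)
  N_a <- rowSums(n_ak)
  for (iter in seq_len(max_iter)) {
    a_tot <- sum(alpha)
    denom <- sum(digamma(N_a + a_tot)) - A * digamma(a_tot)
    num <- colSums(digamma(sweep(n_ak, 2, alpha, "+"))) - A * digamma(alpha)
    alpha_new <- alpha * num / denom
    alpha_new[!is.finite(alpha_new) | alpha_new < floor] <- floor
    delta <- max(abs(alpha_new - alpha) / alpha)
    alpha <- alpha_new
    if (delta < tol) break
  }
  if (is.null(counts) && !is.null(state)) {
    state$alpha <- alpha
    state
  } else {
    alpha
  }
}

#' Point estimate of the author-topic distribution P(Z | feature)
#'
#' `theta[a, k] = (n_ak + alpha_k) / (N_a + sum(alpha))`; rows sum to one. An
#' author with no tokens gets the prior mean with a warning.
#'
#' @param state an `att_state`.
#' @param author_ids optional row names.
#' @return author-by-topic stochastic matrix.
#' @export
estimate_theta <- function(state, author_ids = NULL) {
  N_a <- rowSums(state$n_ak)
  if (any(N_a == 0)) {
    warn(sprintf("%d author(s) have no tokens; their rows equal the prior mean",
                 sum(N_a == 0)))
  }
  theta <- sweep(state$n_ak, 2, state$alpha, "+") / (N_a + sum(state$alpha))
  rownames(theta) <- author_ids
  colnames(theta) <- paste0("topic_", seq_len(state$K))
  theta
}

#' Point estimate of the topic-gene distribution P(Ge | Z)
#'
#' Smoothed mode: `phi[k, w] = (n_kw + beta) / (n_k + V beta)`, strictly
#' positive, used for perplexity. Raw mode: `phi[k, w] = n_kw / n_k` with
#' exact zeros for genes never assigned to the topic — the sparse support
#' from which per-process gene lists are read. A raw-mode topic with no
#' tokens is returned as all-zero and flagged in the `"empty_topics"`
#' attribute.
#'
#' @param state an `att_state`.
#' @param smoothed `TRUE` (default) for the smoothed estimate.
#' @param vocabulary optional column names.
#' @return topic-by-gene matrix.
#' @export
estimate_phi <- function(state, smoothed = TRUE, vocabulary = NULL) {
  V <- state$n_vocab
  if (smoothed) {
    phi <- (state$n_kw + state$beta) / (state$n_k + V * state$beta)
  } else {
    phi <- state$n_kw / ifelse(state$n_k > 0, state$n_k, 1)
    attr(phi, "empty_topics") <- which(state$n_k == 0)
  }
  colnames(phi) <- vocabulary
  rownames(phi) <- paste0("topic_", seq_len(state$K))
  phi
}

#' Gibbs sweeps with per-token occupancy tracing
#'
#' Runs `nsweeps` collapsed sweeps and records, after each sweep, which
#' topic every token occupies. Returns the long-run per-token topic
#' frequencies plus batch means for Monte-Carlo standard errors — the
#' machinery for validating the sampler against exhaustive enumeration of
#' the collapsed posterior on tiny corpora.
#'
#' @param state an `att_state`.
#' @param nsweeps number of sweeps.
#' @param nbatches number of batches for batch-means standard errors
#'   (default 100).
#' @return list with `freq` (token-by-topic occupancy proportions),
#'   `se` (token-by-topic batch-means standard errors) and the final
#'   `state`.
#' @export
gibbs_sweep_traced <- function(state, nsweeps, nbatches = 100L) {
  stopifnot(inherits(state, "att_state"))
  out <- cpp_gibbs_sweeps_traced(state$z, state$tokens$author,
                                 state$tokens$word, state$n_ak, state$n_kw,
                                 as.integer(state$n_k), state$alpha,
                                 state$beta, as.integer(nsweeps),
                                 as.integer(nbatches))
  freq <- out$freq / nsweeps
  # batch_mean: nbatches x (N*K); batch-means SE of each token-topic mean
  bm <- out$batch_mean
  se_flat <- apply(bm, 2, sd) / sqrt(nrow(bm))
  se <- matrix(se_flat, nrow = length(state$z), ncol = state$K, byrow = TRUE)
  state$z <- out$z
  state$n_ak <- out$n_ak
  state$n_kw <- out$n_kw
  state$n_k <- as.numeric(out$n_k)
  list(freq = freq, se = se, state = state)
}
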