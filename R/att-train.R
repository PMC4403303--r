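#' Fit the asymmetric author-topic model by collapsed Gibbs sampling
#'
#' Runs `iterations` full Gibbs sweeps from a random seeded initialization.
#' After `burn_in` sweeps the asymmetric Dirichlet prior on the per-author
#' topic distribution is re-optimized every `optimize_interval` sweeps by
#' Minka's fixed point, so prevalent processes receive more prior mass —
#' the asymmetry that stabilizes the model against the choice of K. Point
#' estimates are taken from the final state (optionally averaged over the
#' last thinned samples); the collapsed joint log-likelihood is recorded
#' every sweep as a convergence trace.
#'
#' @param corpus a `count_corpus`.
#' @param K number of latent biological processes.
#' @param iterations total Gibbs sweeps (default 3000).
#' @param burn_in sweeps before prior optimization starts (default 200).
#' @param optimize_interval sweeps between prior updates (default 10);
#'   `0` disables optimization (symmetric fixed prior).
#' @param alpha0,beta0 initial concentrations, as in [initialize_state()].
#' @param seed integer seed; fixed seed gives bit-identical estimates.
#' @param average_last if > 0, average theta/phi point estimates over this
#'   many final samples thinned at `optimize_interval`; default 0 (final
#'   sample only).
#' @param n_chains number of independent seeded chains; the chain with the
#'   highest mean joint log-likelihood over its final sweeps is kept
#'   (default 1). Restarts guard against the sampler settling in a poor
#'   mode where planted processes merge.
#' @return an `att_model` with elements `theta`, `phi_smoothed`, `phi_raw`,
#'   `alpha`, `beta`, `K`, `log_lik` (per-sweep trace), `author_ids`,
#'   `vocabulary`, `feature_level`.
#' @export
att_train <- function(corpus, K, iterations = 3000L, burn_in = 200L,
                      optimize_interval = 10L, alpha0 = 50, beta0 = 0.01,
                      seed = 1L, average_last = 0L, n_chains = 1L) {
  stopifnot(inherits(corpus, "count_corpus"))
  if (n_chains > 1L) {
    fits <- lapply(seq_len(n_chains), function(ch) {
      att_train(corpus, K, iterations = iterations, burn_in = burn_in,
                optimize_interval = optimize_interval, alpha0 = alpha0,
                beta0 = beta0, seed = seed + 999983L * (ch - 1L),
                average_last = average_last, n_chains = 1L)
    })
    score <- vapply(fits, function(f) {
      mean(utils::tail(f$log_lik, max(1L, iterations %/% 10L)))
    }, numeric(1))
    return(fits[[which.max(score)]])
  }
  state <- initialize_state(corpus, K, alpha0 = alpha0, beta0 = beta0,
                            seed = seed)
  log_lik <- numeric(iterations)
  acc <- NULL
  n_acc <- 0L
  for (it in seq_len(iterations)) {
    state <- gibbs_sweep(state)
    if (optimize_interval > 0 && it > burn_in && it %% optimize_interval == 0) {
      state <- optimize_alpha(state)
    }
    log_lik[it] <- joint_log_lik(state)
    if (average_last > 0 &&
        it > iterations - average_last * max(optimize_interval, 1L) &&
        it %% max(optimize_interval, 1L) == 0) {
      th <- estimate_theta(state)
      ph <- estimate_phi(state, smoothed = TRUE)
      if (is.null(acc)) acc <- list(theta = th * 0, phi = ph * 0)
      acc$theta <- acc$theta + th
      acc$phi <- acc$phi + ph
      n_acc <- n_acc + 1L
    }
  }
  theta <- suppressWarnings(estimate_theta(state, corpus$author_ids))
  phi_s <- estimate_phi(state, smoothed = TRUE, vocabulary = corpus$vocabulary)
  if (!is.null(acc) && n_acc > 0) {
    theta <- acc$theta / n_acc
    dimnames(theta) <- list(corpus$author_ids,
                            paste0("topic_", seq_len(state$K)))
    phi_s <- acc$phi / n_acc
    dimnames(phi_s) <- list(paste0("topic_", seq_len(state$K)),
                            corpus$vocabulary)
  }
  phi_r <- estimate_phi(state, smoothed = FALSE, vocabulary = corpus$vocabulary)
  structure(list(theta = theta, phi_smoothed = phi_s, phi_raw = phi_r,
                 alpha = state$alpha, beta = state$beta, K = state$K,
                 log_lik = log_lik, author_ids = corpus$author_ids,
                 vocabulary = corpus$vocabulary,
                 feature_level = corpus$feature_level,
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 optimize_interval = as.integer(optimize_interval),
                 seed = as.integer(seed), final_state = state),
            class = "att_model")
}

#' @export
print.att_model <- function(x, ...) {
  cat(sprintf(
    "att_model (%s level): K = %d topics, %d authors, %d genes, %d sweeps\n",
    x$feature_level, x$K, nrow(x$theta), ncol(x$phi_smoothed), x$iterations))
  cat(sprintf("  alpha in [%.3g, %.3g], beta = %g, final log-lik %.2f\n",
              min(x$alpha), max(x$alpha), x$beta,
              x$log_lik[length(x$log_lik)]))
  invisible(x)
}

#' Tidy the per-author topic distribution of a fitted model
#'
#' @param x an `att_model`.
#' @param matrix which distribution to tidy: `"theta"` (default,
#'   author-topic), `"phi"` (smoothed topic-gene) or `"phi_raw"` (sparse
#'   topic-gene; zero entries dropped).
#' @param ... unused.
#' @return a long tibble.
#' @export
tidy.att_model <- function(x, matrix = c("theta", "phi", "phi_raw"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "theta") {
    m <- x$theta
    out <- tibble(author = rep(rownames(m), ncol(m)),
                  topic = rep(seq_len(ncol(m)), each = nrow(m)),
                  probability = as.vector(m))
    return(dplyr::arrange(out, .data$author, .data$topic))
  }
  m <- if (matrix == "phi") x$phi_smoothed else x$phi_raw
  out <- tibble(topic = rep(seq_len(nrow(m)), ncol(m)),
                gene = rep(colnames(m), each = nrow(m)),
                probability = as.vector(m))
  if (matrix == "phi_raw") out <- out[out$probability > 0, ]
  dplyr::arrange(out, .data$topic, dplyr::desc(.data$probability))
}

#' One-row summary of a fitted author-topic model
#'
#' @param x an `att_model`.
#' @param ... unused.
#' @return a one-row tibble with K, dimensions, final log-likelihood and
#'   prior summary.
#' @export
glance.att_model <- function(x, ...) {
  tibble(K = x$K, n_authors = nrow(x$theta),
         n_genes = ncol(x$phi_smoothed),
         feature_level = x$feature_level,
         iterations = x$iterations,
         log_lik = x$log_lik[length(x$log_lik)],
         alpha_sum = sum(x$alpha),
         alpha_max_ratio = max(x$alpha) / min(x$alpha),
         beta = x$beta)
}

#' Plot the convergence trace of a fitted model
#'
#' @param object an `att_model`.
#' @param ... unused.
#' @return a ggplot of the per-sweep collapsed joint log-likelihood.
#' @export
autoplot.att_model <- function(object, ...) {
  df <- tibble(sweep = seq_along(object$log_lik), log_lik = object$log_lik)
  ggplot(df, aes(x = .data$sweep, y = .data$log_lik)) +
    geom_line(colour = "steelblue") +
    labs(x = "Gibbs sweep", y = "joint log-likelihood",
         title = sprintf("Convergence trace (K = %d, %s level)",
                         object$K, object$feature_level)) +
    theme_minimal()
}

#' Held-out perplexity by fold-in Gibbs sampling
#'
#' Freezes the trained smoothed topic-gene distribution, infers the topic
#' proportions of each held-out document by Gibbs sampling over that
#' document's tokens, then evaluates
#' exp(-sum_tokens log sum_k theta_dk phi_kw / N). Lower is better; a model
#' that spreads phi uniformly over V genes scores exactly V. Held-out genes
#' absent from the training vocabulary are dropped with a warning.
#'
#' Two evaluation protocols are offered. `"fold_in"` infers theta from the
#' whole held-out document and scores the same tokens; it is simple and
#' matches the closed-form examples, but because every scored token also
#' informed theta it rewards extra topics and is unsuitable for choosing K.
#' `"completion"` (document completion) splits each held-out document's
#' tokens in half, infers theta from one half and scores only the other,
#' giving an honest out-of-sample estimate; [select_num_topics()] uses it.
#'
#' @param model an `att_model`.
#' @param heldout a `count_corpus` of held-out documents.
#' @param fold_in_sweeps Gibbs sweeps for the fold-in (default 100).
#' @param seed integer seed for the fold-in sampler (and the token split
#'   under `"completion"`).
#' @param method `"fold_in"` (default) or `"completion"`.
#' @return held-out perplexity (positive scalar).
#' @export
held_out_perplexity <- function(model, heldout, fold_in_sweeps = 100L,
                                seed = 1L,
                                method = c("fold_in", "completion")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "att_model"), inherits(heldout, "count_corpus"))
  keep <- heldout$vocabulary %in% model$vocabulary
  if (!all(keep)) {
    warn(sprintf("dropping %d held-out gene(s) absent from the training vocabulary",
                 sum(!keep)))
  }
  counts <- heldout$counts[, keep, drop = FALSE]
  word_map <- match(heldout$vocabulary[keep], model$vocabulary)
  doc_tot <- Matrix::rowSums(counts)
  counts <- counts[doc_tot > 0, , drop = FALSE]
  if (!nrow(counts) || sum(counts) == 0) abort("held-out corpus has no usable tokens")

  tm <- Matrix::summary(counts)
  ord <- order(tm$i, tm$j)
  reps <- as.integer(tm$x[ord])
  token_doc <- rep.int(as.integer(tm$i[ord]), reps) - 1L
  token_word <- rep.int(word_map[as.integer(tm$j[ord])], reps) - 1L
  D <- nrow(counts)
  K <- model$K
  N <- length(token_doc)

  set.seed(seed)
  if (method == "completion") {
    # split each document's tokens: infer theta on one half, score the other
    eval_mask <- logical(N)
    for (d in seq_len(D) - 1L) {
      idx <- which(token_doc == d)
      n_eval <- floor(length(idx) / 2)
      if (n_eval > 0) eval_mask[sample(idx, n_eval)] <- TRUE
    }
    if (!any(eval_mask)) abort("held-out documents are too short for completion scoring")
    est_doc <- token_doc[!eval_mask]
    est_word <- token_word[!eval_mask]
    score_doc <- token_doc[eval_mask]
    score_word <- token_word[eval_mask]
  } else {
    est_doc <- score_doc <- token_doc
    est_word <- score_word <- token_word
  }

  Ne <- length(est_doc)
  z <- sample.int(K, Ne, replace = TRUE) - 1L
  n_dk <- matrix(0L, D, K)
  for (i in seq_len(Ne)) {
    n_dk[est_doc[i] + 1L, z[i] + 1L] <- n_dk[est_doc[i] + 1L, z[i] + 1L] + 1L
  }
  fit <- cpp_fold_in(z, est_doc, est_word, n_dk, model$phi_smoothed,
                     model$alpha, as.integer(fold_in_sweeps))
  theta_d <- sweep(fit$n_dk, 2, model$alpha, "+") /
    (rowSums(fit$n_dk) + sum(model$alpha))

  # per-token predictive probability sum_k theta_dk phi_kw
  pred <- theta_d %*% model$phi_smoothed  # D x V_train
  ll <- sum(log(pred[cbind(score_doc + 1L, score_word + 1L)]))
  exp(-ll / length(score_doc))
}

#' Choose the number of latent processes by cross-validated perplexity
#'
#' Documents are split into seeded folds; for each candidate K a model is
#' trained on the remaining folds and scored by document-completion
#' held-out perplexity on the left-out fold (see
#' [held_out_perplexity()] for why completion scoring, not plain fold-in,
#' is required here). The recommended K minimizes the mean perplexity,
#' with ties broken toward the smaller (more parsimonious) K.
#'
#' @param corpus a `count_corpus` with at least `folds` documents.
#' @param K_grid integer vector of candidate topic counts.
#' @param folds number of cross-validation folds (default 10).
#' @param iterations,burn_in,optimize_interval,alpha0,beta0 passed to
#'   [att_train()].
#' @param fold_in_sweeps passed to [held_out_perplexity()].
#' @param seed integer seed governing fold assignment and all model fits.
#' @return a tibble with one row per K: `K`, `mean_perplexity`,
#'   `sd_perplexity`, `recommended`.
#' @export
select_num_topics <- function(corpus, K_grid, folds = 10L,
                              iterations = 200L, burn_in = 50L,
                              optimize_interval = 10L, alpha0 = 50,
                              beta0 = 0.01, fold_in_sweeps = 50L, seed = 1L) {
  stopifnot(inherits(corpus, "count_corpus"))
  if (!length(K_grid)) abort("K_grid must be non-empty")
  D <- nrow(corpus$counts)
  if (D < folds) abort("corpus has fewer documents than folds")
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(folds), D))

  subset_corpus <- function(idx) {
    new_count_corpus(counts = corpus$counts[idx, , drop = FALSE],
                     doc_ids = corpus$doc_ids[idx],
                     doc_author = seq_along(idx),
                     author_ids = corpus$doc_ids[idx],
                     feature_level = corpus$feature_level)
  }

  res <- purrr::map_dfr(sort(unique(as.integer(K_grid))), function(K) {
    perp <- vapply(seq_len(folds), function(f) {
      train_idx <- which(fold_of != f)
      test_idx <- which(fold_of == f)
      fit <- att_train(subset_corpus(train_idx), K,
                       iterations = iterations, burn_in = burn_in,
                       optimize_interval = optimize_interval,
                       alpha0 = alpha0, beta0 = beta0,
                       seed = seed + 1000L * K + f)
      held_out_perplexity(fit, subset_corpus(test_idx),
                          fold_in_sweeps = fold_in_sweeps,
                          seed = seed + 2000L * K + f,
                          method = "completion")
    }, numeric(1))
    tibble(K = K, mean_perplexity = mean(perp), sd_perplexity = sd(perp))
  })
  best <- which(res$mean_perplexity == min(res$mean_perplexity))[1]
  res$recommended <- seq_len(nrow(res)) == best
  res
}

#' Save a fitted model as a directory of plain-text files
#'
#' Writes `theta.tsv`, `phi_smoothed.tsv`, `phi_raw.tsv` (sparse triples),
#' `hyper.json` and `loglik.tsv`.
#'
#' @param model an `att_model`.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_att_model <- function(model, dir) {
  stopifnot(inherits(model, "att_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(data.frame(author = rownames(model$theta), model$theta,
                         check.names = FALSE),
              file.path(dir, "theta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(topic = rownames(model$phi_smoothed),
                         model$phi_smoothed, check.names = FALSE),
              file.path(dir, "phi_smoothed.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  nz <- which(model$phi_raw > 0, arr.ind = TRUE)
  write.table(data.frame(topic = nz[, 1], gene = colnames(model$phi_raw)[nz[, 2]],
                         probability = model$phi_raw[nz]),
              file.path(dir, "phi_raw.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(alpha = model$alpha, beta = model$beta, K = model$K,
         seed = model$seed, iterations = model$iterations,
         burn_in = model$burn_in, optimize_interval = model$optimize_interval,
         feature_level = model$feature_level),
    file.path(dir, "hyper.json"), auto_unbox = TRUE, digits = NA)
  write.table(data.frame(sweep = seq_along(model$log_lik),
                         log_lik = model$log_lik),
              file.path(dir, "loglik.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' Read a model directory written by [write_att_model()]
#'
#' @param dir model directory.
#' @return an `att_model` (without the sampler state).
#' @export
read_att_model <- function(dir) {
  for (f in c("theta.tsv", "phi_smoothed.tsv", "phi_raw.tsv", "hyper.json")) {
    if (!file.exists(file.path(dir, f))) abort(paste0("model directory is missing ", f))
  }
  hyper <- jsonlite::read_json(file.path(dir, "hyper.json"), simplifyVector = TRUE)
  th <- read.delim(file.path(dir, "theta.tsv"), check.names = FALSE)
  theta <- as.matrix(th[, -1, drop = FALSE])
  rownames(theta) <- th$author
  ph <- read.delim(file.path(dir, "phi_smoothed.tsv"), check.names = FALSE)
  phi_s <- as.matrix(ph[, -1, drop = FALSE])
  rownames(phi_s) <- ph$topic
  raw <- read.delim(file.path(dir, "phi_raw.tsv"), check.names = FALSE)
  phi_r <- matrix(0, nrow(phi_s), ncol(phi_s), dimnames = dimnames(phi_s))
  phi_r[cbind(raw$topic, match(raw$gene, colnames(phi_s)))] <- raw$probability
  ll <- if (file.exists(file.path(dir, "loglik.tsv"))) {
    read.delim(file.path(dir, "loglik.tsv"))$log_lik
  } else numeric(0)
  structure(list(theta = theta, phi_smoothed = phi_s, phi_raw = phi_r,
                 alpha = hyper$alpha, beta = hyper$beta, K = hyper$K,
                 log_lik = ll, author_ids = rownames(theta),
                 vocabulary = colnames(phi_s),
                 feature_level = hyper$feature_level,
                 iterations = hyper$iterations, burn_in = hyper$burn_in,
                 optimize_interval = hyper$optimize_interval,
                 seed = hyper$seed),
            class = "att_model")
}
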