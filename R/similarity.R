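#' Symmetric Kullback-Leibler divergence between two distributions
#'
#' sKL(p, q) = sum_k p_k log(p_k / q_k) + q_k log(q_k / p_k), in nats.
#' Zero iff p = q; symmetric; non-negative; the triangle inequality is not
#' guaranteed. Both vectors must be strictly positive — use the smoothed
#' author-topic estimate, which the Dirichlet prior keeps off the boundary.
#'
#' @param p,q probability vectors of equal length, each summing to one
#'   within 1e-9, all components > 0.
#' @return non-negative scalar divergence in nats.
#' @export
skl_divergence <- function(p, q) {
  if (length(p) != length(q)) abort("p and q must have the same length")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9) {
    abort("p and q must each sum to 1 (tolerance 1e-9)")
  }
  if (any(p <= 0) || any(q <= 0)) {
    abort("p and q must be strictly positive; use the smoothed theta estimate")
  }
  sum(p * log(p / q) + q * log(q / p))
}

#' Pairwise symmetric KL divergence between feature topic distributions
#'
#' @param theta author-by-topic stochastic matrix (rows strictly positive),
#'   e.g. `model$theta`, or an `att_model`.
#' @return a `similarity_matrix`: symmetric feature-by-feature matrix of
#'   sKL scores with zero diagonal.
#' @export
pairwise_skl <- function(theta) {
  if (inherits(theta, "att_model")) theta <- theta$theta
  if (any(theta <= 0)) abort("theta rows must be strictly positive")
  ids <- rownames(theta) %||% paste0("feature_", seq_len(nrow(theta)))
  # sKL(p,q) = sum (p-q) (log p - log q), vectorized over all pairs
  lt <- log(theta)
  a <- rowSums(theta * lt)                       # sum p log p
  cross <- theta %*% t(lt)                       # [i,j] = sum p_i log p_j
  scores <- outer(a, rep(1, length(a))) + outer(rep(1, length(a)), a) -
    cross - t(cross)
  scores[scores < 0] <- 0                        # numerical floor at exact 0
  diag(scores) <- 0
  scores <- (scores + t(scores)) / 2
  dimnames(scores) <- list(ids, ids)
  structure(list(scores = scores, feature_ids = ids),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  off <- x$scores[upper.tri(x$scores)]
  cat(sprintf("similarity_matrix: %d features; sKL range [%.3f, %.3f] nats\n",
              length(x$feature_ids),
              if (length(off)) min(off) else NA, if (length(off)) max(off) else NA))
  invisible(x)
}

#' @export
tidy.similarity_matrix <- function(x, ...) {
  idx <- which(upper.tri(x$scores), arr.ind = TRUE)
  tibble(feature_i = x$feature_ids[idx[, 1]],
         feature_j = x$feature_ids[idx[, 2]],
         skl = x$scores[idx])
}

#' Heatmap of a pairwise similarity matrix
#'
#' @param object a `similarity_matrix`.
#' @param ... unused.
#' @return a ggplot tile plot of sKL scores.
#' @export
autoplot.similarity_matrix <- function(object, ...) {
  df <- tidyr::expand_grid(feature_i = object$feature_ids,
                           feature_j = object$feature_ids)
  df$skl <- as.vector(t(object$scores))
  ggplot(df, aes(x = .data$feature_j, y = .data$feature_i, fill = .data$skl)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "firebrick") +
    labs(x = NULL, y = NULL, fill = "sKL (nats)") +
    theme_minimal()
}

#' Rank the features most similar to a query feature
#'
#' Low sKL means similar topic usage, so the list is sorted ascending; the
#' query itself is excluded and ties are broken by feature ID.
#'
#' @param sim a `similarity_matrix`.
#' @param feature_id query feature.
#' @param top_n maximum list length (default 10).
#' @return tibble with columns `feature`, `skl`, `rank`.
#' @export
rank_similar <- function(sim, feature_id, top_n = 10L) {
  stopifnot(inherits(sim, "similarity_matrix"))
  if (!feature_id %in% sim$feature_ids) {
    abort(paste0("unknown feature: ", feature_id))
  }
  scores <- sim$scores[feature_id, ]
  others <- setdiff(sim$feature_ids, feature_id)
  ord <- others[order(scores[others], others)]
  out <- head(ord, top_n)
  tibble(feature = out, skl = unname(scores[out]), rank = seq_along(out))
}

#' Top latent processes for one feature
#'
#' @param theta author-by-topic matrix or `att_model`.
#' @param feature_id row to report.
#' @param n number of processes (default 3); capped at K with a warning.
#' @return tibble `topic`, `probability`, descending; ties go to the
#'   smaller topic index.
#' @export
top_topics <- function(theta, feature_id, n = 3L) {
  if (inherits(theta, "att_model")) theta <- theta$theta
  if (!feature_id %in% rownames(theta)) {
    abort(paste0("unknown feature: ", feature_id))
  }
  K <- ncol(theta)
  if (n > K) {
    warn(sprintf("n = %d exceeds K = %d; returning all topics", n, K))
    n <- K
  }
  p <- theta[feature_id, ]
  ord <- order(-p, seq_len(K))[seq_len(n)]
  tibble(topic = ord, probability = unname(p[ord]))
}

#' Genes with positive probability in one latent process
#'
#' Reads the raw (unsmoothed) topic-gene estimate, whose support is the set
#' of genes actually assigned to the process — typically a small fraction
#' of the vocabulary.
#'
#' @param phi_raw topic-by-gene raw matrix or `att_model`.
#' @param topic topic index.
#' @param max_n optional truncation.
#' @return tibble `gene`, `probability`, descending probability with ties
#'   by gene ID; an empty topic yields an empty tibble with attribute
#'   `empty_topic = TRUE`.
#' @export
top_genes <- function(phi_raw, topic, max_n = NULL) {
  if (inherits(phi_raw, "att_model")) phi_raw <- phi_raw$phi_raw
  if (topic < 1 || topic > nrow(phi_raw)) {
    abort(sprintf("topic index %d out of range 1..%d", topic, nrow(phi_raw)))
  }
  p <- phi_raw[topic, ]
  genes <- colnames(phi_raw) %||% paste0("gene_", seq_along(p))
  keep <- which(p > 0)
  out <- tibble(gene = genes[keep], probability = unname(p[keep]))
  out <- out[order(-out$probability, out$gene), ]
  if (!is.null(max_n)) out <- head(out, max_n)
  if (!nrow(out)) attr(out, "empty_topic") <- TRUE
  out
}

#' Export per-process gene lists for external annotation
#'
#' Writes one plain-text gene list per latent process (one gene ID per
#' line, descending probability) plus a `manifest.tsv` mapping topic to
#' file and support size — the files one would upload to an annotation
#' service such as DAVID.
#'
#' @param model an `att_model`.
#' @param topics integer vector of topics (default: all).
#' @param out_path output directory.
#' @return invisibly, the manifest tibble.
#' @export
export_gene_lists <- function(model, topics = NULL, out_path) {
  stopifnot(inherits(model, "att_model"))
  topics <- topics %||% seq_len(model$K)
  dir.create(out_path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_path)) abort(paste0("cannot create directory ", out_path))
  manifest <- purrr::map_dfr(topics, function(k) {
    genes <- top_genes(model, k)
    fname <- sprintf("topic_%03d.txt", k)
    writeLines(genes$gene, file.path(out_path, fname))
    tibble(topic = k, file = fname, n_genes = nrow(genes),
           empty = nrow(genes) == 0L)
  })
  write.table(manifest, file.path(out_path, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line — name, description, then member gene
#' IDs, tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors of gene IDs.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  sets <- lapply(lines, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(lines, `[[`, "", 1L)
  sets[lengths(sets) > 0]
}

#' Hypergeometric gene-set enrichment of a gene list
#'
#' Local stand-in for a web annotation service: for each gene set the
#' upper-tail hypergeometric p-value of the overlap with the query list is
#' computed against a fixed universe, with Benjamini-Hochberg correction
#' across sets.
#'
#' @param gene_list character vector of query gene IDs (non-empty).
#' @param gene_sets named list of character vectors (e.g. [read_gmt()]).
#' @param universe_size number of genes in the universe; defaults should be
#'   the corpus vocabulary size. Must be >= `length(gene_list)`.
#' @return tibble `set`, `set_size`, `overlap`, `p_value`, `fdr`, sorted by
#'   p-value.
#' @export
enrich_gene_sets <- function(gene_list, gene_sets, universe_size) {
  gene_list <- unique(gene_list)
  if (!length(gene_list)) abort("gene_list is empty")
  if (!length(gene_sets)) abort("gene_sets is empty")
  if (universe_size < length(gene_list)) {
    abort("universe_size must be at least the gene-list size")
  }
  res <- purrr::imap_dfr(gene_sets, function(members, nm) {
    m <- length(unique(members))
    ov <- length(intersect(gene_list, members))
    p <- phyper(ov - 1, m, universe_size - m, length(gene_list),
                lower.tail = FALSE)
    tibble(set = nm, set_size = m, overlap = ov, p_value = p)
  })
  res$fdr <- p.adjust(res$p_value, method = "BH")
  dplyr::arrange(res, .data$p_value, .data$set)
}
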