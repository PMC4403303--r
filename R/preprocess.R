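#' Compute the treatment fold-change matrix
#'
#' For every unique (drug, dose, time) treatment the per-gene ratio of mean
#' treated intensity to mean concurrent-control intensity is computed.
#' Down-regulation is stored with the reciprocal-signed convention: a ratio
#' r >= 1 is stored as r, a ratio r < 1 as -1/r, so the stored magnitude is
#' always max(r, 1/r) and the sign gives the direction. Controls are matched
#' on (drug, time); all matching control samples are pooled.
#'
#' @param study an [expression_study()].
#' @param aggregate how replicate intensities are combined before the ratio:
#'   `"arithmetic"` (default) or `"geometric"` mean.
#' @return a `fold_change_matrix`: genes x treatments, with a `treatments`
#'   design tibble attached.
#' @export
compute_fold_changes <- function(study, aggregate = c("arithmetic", "geometric")) {
  stopifnot(inherits(study, "expression_study"))
  aggregate <- match.arg(aggregate)
  meta <- study$sample_meta
  treated <- meta[!meta$is_control, ]
  combos <- unique(treated[, c("drug", "dose", "time_days")])
  combos <- combos[order(combos$drug,
                         match(combos$dose, DOSE_LEVELS),
                         combos$time_days), ]
  keys <- treatment_key(combos$drug, combos$dose, combos$time_days)

  avg <- function(mat) {
    if (aggregate == "arithmetic") rowMeans(mat) else exp(rowMeans(log(mat)))
  }

  values <- matrix(0, nrow(study$intensities), nrow(combos),
                   dimnames = list(rownames(study$intensities), keys))
  for (i in seq_len(nrow(combos))) {
    t_ids <- meta$sample_id[!meta$is_control &
                            meta$drug == combos$drug[i] &
                            meta$dose == combos$dose[i] &
                            meta$time_days == combos$time_days[i]]
    c_ids <- meta$sample_id[meta$is_control &
                            meta$drug == combos$drug[i] &
                            meta$time_days == combos$time_days[i]]
    if (!length(c_ids)) {
      abort(sprintf("treatment %s has no matching control samples", keys[i]))
    }
    r <- avg(study$intensities[, t_ids, drop = FALSE]) /
         avg(study$intensities[, c_ids, drop = FALSE])
    values[, i] <- ifelse(r >= 1, r, -1 / r)
  }

  structure(list(values = values,
                 treatments = tibble(key = keys, drug = combos$drug,
                                     dose = combos$dose,
                                     time_days = combos$time_days),
                 genes = rownames(values)),
            class = "fold_change_matrix")
}

#' @export
print.fold_change_matrix <- function(x, ...) {
  cat(sprintf("fold_change_matrix: %d genes x %d treatments (%d drugs); %.1f%% zero\n",
              nrow(x$values), ncol(x$values), length(unique(x$treatments$drug)),
              100 * mean(x$values == 0)))
  invisible(x)
}

#' Zero out genes below the differential-expression cutoff
#'
#' Entries whose absolute fold change is strictly greater than `threshold`
#' are differentially expressed and kept; everything else is set to exactly
#' zero, marking the gene as not differentially expressed for that
#' treatment. Idempotent.
#'
#' @param fc a `fold_change_matrix`.
#' @param threshold positive fold-change cutoff, default 1.5; must be >= 1
#'   since stored magnitudes are >= 1 by construction.
#' @return the filtered `fold_change_matrix`.
#' @export
apply_deg_filter <- function(fc, threshold = 1.5) {
  stopifnot(inherits(fc, "fold_change_matrix"))
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 1) {
    abort("threshold must be a single number >= 1")
  }
  fc$values[abs(fc$values) <= threshold] <- 0
  fc
}

#' Discretize a filtered fold-change matrix into a token-count corpus
#'
#' Each treatment becomes a document and each differentially expressed gene
#' contributes round(scale * |fold change|) tokens (half-to-even rounding).
#' Documents left without any tokens are dropped with a warning. At this
#' stage each document is its own author (treatment-level grouping).
#'
#' @param fc a DEG-filtered `fold_change_matrix`.
#' @param scale positive multiplier applied to |fold change| before
#'   rounding; default 1.
#' @param signed_tokens if `TRUE`, up- and down-regulation emit distinct
#'   `GENE_up` / `GENE_dn` vocabulary entries; default `FALSE` (magnitude
#'   only).
#' @return a `count_corpus` with `feature_level = "treatment"`.
#' @export
discretize_to_counts <- function(fc, scale = 1.0, signed_tokens = FALSE) {
  stopifnot(inherits(fc, "fold_change_matrix"))
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0) {
    abort("scale must be a single positive number")
  }
  if (signed_tokens) {
    up <- fc$values
    up[up < 0] <- 0
    dn <- -fc$values
    dn[dn < 0] <- 0
    vals <- rbind(up, dn)
    rownames(vals) <- c(paste0(fc$genes, "_up"), paste0(fc$genes, "_dn"))
  } else {
    vals <- abs(fc$values)
  }
  counts <- round(scale * vals)  # zero stays zero: round(0) == 0
  counts <- t(counts)            # documents x genes
  mode(counts) <- "integer"

  empty <- rowSums(counts) == 0L
  if (any(empty)) {
    warn(sprintf("dropping %d document(s) with no tokens: %s",
                 sum(empty), paste(rownames(counts)[empty], collapse = ", ")))
    counts <- counts[!empty, , drop = FALSE]
  }
  if (!nrow(counts)) abort("no document has any tokens after discretization")

  new_count_corpus(
    counts = Matrix::Matrix(counts, sparse = TRUE),
    doc_ids = rownames(counts),
    doc_author = seq_len(nrow(counts)),
    author_ids = rownames(counts),
    feature_level = "treatment"
  )
}

new_count_corpus <- function(counts, doc_ids, doc_author, author_ids,
                             feature_level) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  dimnames(counts) <- list(doc_ids, colnames(counts))
  structure(list(counts = counts,
                 vocabulary = colnames(counts),
                 doc_ids = doc_ids,
                 doc_author = as.integer(doc_author),
                 author_ids = author_ids,
                 feature_level = feature_level),
            class = "count_corpus")
}

#' @export
print.count_corpus <- function(x, ...) {
  cat(sprintf(
    "count_corpus (%s level): %d documents, %d authors, %d genes, %d tokens\n",
    x$feature_level, nrow(x$counts), length(x$author_ids),
    ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Regroup corpus documents under treatment, drug or dose-time authors
#'
#' Documents (treatments) are untouched; only the author of each document
#' changes: at `"treatment"` level each document authors itself, at
#' `"drug"` level all treatments of a drug share one author, and at
#' `"time_dose"` level all treatments with the same (dose, time) pair share
#' one author, giving the 12 dose-time combinations of a full 3-dose,
#' 4-duration design.
#'
#' @param corpus a `count_corpus` whose document IDs are treatment keys.
#' @param feature_level `"treatment"`, `"drug"` or `"time_dose"`.
#' @return the regrouped `count_corpus`.
#' @export
regroup_by_feature <- function(corpus,
                               feature_level = c("treatment", "drug", "time_dose")) {
  stopifnot(inherits(corpus, "count_corpus"))
  feature_level <- match.arg(feature_level)
  design <- parse_treatment_key(corpus$doc_ids)
  author_of_doc <- switch(feature_level,
    treatment = design$key,
    drug = design$drug,
    time_dose = paste0(design$dose, "|", design$time_days, "d"))
  author_ids <- sort(unique(author_of_doc))
  new_count_corpus(counts = corpus$counts,
                   doc_ids = corpus$doc_ids,
                   doc_author = match(author_of_doc, author_ids),
                   author_ids = author_ids,
                   feature_level = feature_level)
}

#' Tidy a count corpus into a long tibble
#'
#' @param x a `count_corpus`.
#' @param ... unused.
#' @return tibble with columns `document`, `author`, `gene`, `count`
#'   (nonzero cells only).
#' @export
tidy.count_corpus <- function(x, ...) {
  tm <- Matrix::summary(x$counts)
  tibble(document = x$doc_ids[tm$i],
         author = x$author_ids[x$doc_author[tm$i]],
         gene = x$vocabulary[tm$j],
         count = as.integer(tm$x))[order(tm$i, tm$j), ]
}

#' Write a count corpus to a directory of plain-text files
#'
#' Writes `counts.tsv` (document, gene, count triples), `vocab.txt` and
#' `authors.tsv` (doc_id, author_id, feature level).
#'
#' @param corpus a `count_corpus`.
#' @param dir output directory, created if needed.
#' @return invisibly, `dir`.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "count_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tm <- Matrix::summary(corpus$counts)
  write.table(data.frame(doc_id = corpus$doc_ids[tm$i],
                         gene = corpus$vocabulary[tm$j],
                         count = as.integer(tm$x)),
              file.path(dir, "counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(corpus$vocabulary, file.path(dir, "vocab.txt"))
  authors <- data.frame(doc_id = corpus$doc_ids,
                        author_id = corpus$author_ids[corpus$doc_author],
                        feature_level = corpus$feature_level)
  write.table(authors, file.path(dir, "authors.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a count corpus written by [write_corpus()]
#'
#' @param dir corpus directory.
#' @return a `count_corpus`.
#' @export
read_corpus <- function(dir) {
  for (f in c("counts.tsv", "vocab.txt", "authors.tsv")) {
    if (!file.exists(file.path(dir, f))) {
      abort(paste0("corpus directory is missing ", f))
    }
  }
  triples <- read.delim(file.path(dir, "counts.tsv"), check.names = FALSE)
  vocab <- readLines(file.path(dir, "vocab.txt"))
  authors <- read.delim(file.path(dir, "authors.tsv"), check.names = FALSE)
  doc_ids <- authors$doc_id
  author_ids <- sort(unique(authors$author_id))
  counts <- Matrix::sparseMatrix(
    i = match(triples$doc_id, doc_ids),
    j = match(triples$gene, vocab),
    x = triples$count,
    dims = c(length(doc_ids), length(vocab)),
    dimnames = list(doc_ids, vocab))
  new_count_corpus(counts = counts, doc_ids = doc_ids,
                   doc_author = match(authors$author_id, author_ids),
                   author_ids = author_ids,
                   feature_level = authors$feature_level[1])
}

#' Write / read a fold-change matrix as TSV
#'
#' Genes as rows, treatment keys as columns.
#'
#' @param fc a `fold_change_matrix`.
#' @param path TSV path.
#' @return invisibly, `path` (write) or a `fold_change_matrix` (read).
#' @export
write_fold_changes <- function(fc, path) {
  stopifnot(inherits(fc, "fold_change_matrix"))
  df <- data.frame(gene = fc$genes, fc$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fold_changes
#' @export
read_fold_changes <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  df <- read.delim(path, check.names = FALSE, row.names = 1)
  values <- as.matrix(df)
  design <- parse_treatment_key(colnames(values))
  structure(list(values = values, treatments = design,
                 genes = rownames(values)),
            class = "fold_change_matrix")
}

#' Construct a count corpus directly from a document-gene count matrix
#'
#' @param counts non-negative integer matrix, documents in rows (rownames
#'   become document IDs), genes in columns (colnames become the
#'   vocabulary); every document must have at least one token.
#' @param doc_author integer vector mapping each document to its author
#'   index; default: each document authors itself.
#' @param author_ids author identifiers; required when `doc_author` is
#'   given.
#' @param feature_level grouping level label (default `"treatment"`).
#' @return a `count_corpus`.
#' @export
count_corpus <- function(counts, doc_author = NULL, author_ids = NULL,
                         feature_level = "treatment") {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers")
  }
  if (any(rowSums(counts) == 0)) {
    abort("every document must have at least one token")
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("doc_%04d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("gene_%04d", seq_len(ncol(counts)))
  }
  if (is.null(doc_author)) {
    doc_author <- seq_len(nrow(counts))
    author_ids <- rownames(counts)
  } else if (is.null(author_ids)) {
    abort("author_ids is required when doc_author is supplied")
  }
  if (length(doc_author) != nrow(counts) ||
      any(doc_author < 1) || any(doc_author > length(author_ids))) {
    abort("doc_author must map every document to an author index")
  }
  mode(counts) <- "integer"
  new_count_corpus(counts = Matrix::Matrix(counts, sparse = TRUE),
                   doc_ids = rownames(counts),
                   doc_author = doc_author, author_ids = author_ids,
                   feature_level = feature_level)
}
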