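#' Assemble an expression study from intensities and sample metadata
#'
#' Bundles a gene-by-sample intensity matrix with the design metadata of a
#' repeated-dose study: each treated sample carries a drug, a dose level and
#' a duration, and every (drug, time) stratum has concurrent control samples.
#'
#' @param intensities numeric matrix, genes in rows (unique rownames),
#'   samples in columns (colnames = sample IDs). All values must be > 0.
#' @param sample_meta data frame with columns `sample_id`, `drug`, `dose`
#'   (one of low/middle/high/control, case-insensitive), `time_days`
#'   (one of 3, 7, 14, 28) and `is_control` (logical). A `dose` of
#'   `"control"` and `is_control = TRUE` are equivalent markers.
#' @return an `expression_study` object.
#' @export
expression_study <- function(intensities, sample_meta) {
  intensities <- as.matrix(intensities)
  if (is.null(rownames(intensities)) || anyDuplicated(rownames(intensities))) {
    abort("intensities must have unique gene rownames")
  }
  if (is.null(colnames(intensities))) {
    abort("intensities must have sample IDs as colnames")
  }
  meta <- as_tibble(sample_meta)
  required <- c("sample_id", "drug", "dose", "time_days", "is_control")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    abort(paste0("sample_meta lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  meta$dose <- tolower(as.character(meta$dose))
  meta$is_control <- meta$is_control | meta$dose == "control"
  meta$time_days <- as.integer(meta$time_days)
  if (!all(meta$dose %in% c(DOSE_LEVELS, "control"))) {
    abort("dose must be one of low, middle, high, control")
  }
  if (!setequal(meta$sample_id, colnames(intensities))) {
    abort("sample_meta$sample_id must match colnames(intensities)")
  }
  meta <- meta[match(colnames(intensities), meta$sample_id), ]
  if (any(!is.finite(intensities)) || any(intensities <= 0)) {
    bad <- which(!is.finite(intensities) | intensities <= 0, arr.ind = TRUE)[1, ]
    abort(sprintf("non-positive intensity for gene '%s' in sample '%s'",
                  rownames(intensities)[bad[1]], colnames(intensities)[bad[2]]))
  }
  treated <- meta[!meta$is_control, ]
  ctrl <- meta[meta$is_control, ]
  combos <- unique(treated[, c("drug", "dose", "time_days")])
  for (i in seq_len(nrow(combos))) {
    has_ctrl <- any(ctrl$drug == combos$drug[i] &
                    ctrl$time_days == combos$time_days[i])
    if (!has_ctrl) {
      abort(sprintf("treatment %s has no matching control samples",
                    treatment_key(combos$drug[i], combos$dose[i],
                                  combos$time_days[i])))
    }
  }
  structure(list(intensities = intensities, sample_meta = meta),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  meta <- x$sample_meta
  cat(sprintf(
    "expression_study: %d genes x %d samples (%d treated, %d control), %d drugs\n",
    nrow(x$intensities), ncol(x$intensities), sum(!meta$is_control),
    sum(meta$is_control), length(unique(meta$drug))))
  invisible(x)
}

#' Read an expression study from TSV files
#'
#' @param expr_path gene-by-sample TSV: first column gene IDs, header row of
#'   sample IDs.
#' @param meta_path sample metadata TSV with columns `sample_id`, `drug`,
#'   `dose`, `time_days`, `is_control`.
#' @return an `expression_study`.
#' @export
read_expression_study <- function(expr_path, meta_path) {
  if (!file.exists(expr_path)) abort(paste0("no such file: ", expr_path))
  if (!file.exists(meta_path)) abort(paste0("no such file: ", meta_path))
  expr <- read.delim(expr_path, check.names = FALSE, row.names = 1)
  meta <- read.delim(meta_path, check.names = FALSE)
  meta$is_control <- as.logical(meta$is_control)
  expression_study(as.matrix(expr), meta)
}

#' Write an expression study to TSV files
#'
#' @param study an `expression_study`.
#' @param expr_path,meta_path output paths.
#' @return invisibly, the study.
#' @export
write_expression_study <- function(study, expr_path, meta_path) {
  df <- data.frame(gene = rownames(study$intensities), study$intensities,
                   check.names = FALSE)
  write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(study$sample_meta, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(study)
}
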