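#' Read a pipeline configuration from YAML or JSON
#'
#' @param path configuration file; `.yaml`/`.yml` or `.json`.
#' @return a named list, as accepted by [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("no such config file: ", path))
  if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

default_pipeline_config <- function() {
  list(
    expr = NULL, meta = NULL, gmt = NULL, out = "toxitopic_run",
    threshold = 1.5, scale = 1.0,
    levels = c("treatment", "drug", "time_dose"),
    K = list(treatment = 200L, drug = 100L, time_dose = 100L),
    iterations = 3000L, burn_in = 200L, optimize_interval = 10L,
    alpha0 = 50, beta0 = 0.01, seed = 7L,
    top_n = 10L, glm_family = "gaussian", glm_scopes = NULL)
}

log_msg <- function(con, ...) {
  msg <- sprintf(...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full corpus-to-comparison pipeline
#'
#' Orchestrates the whole analysis: read the expression study, compute and
#' filter fold changes, discretize into a corpus, fit one author-topic
#' model per requested feature level (treatment, drug, dose-time), compute
#' pairwise sKL similarity and ranked reports per level, and — where a
#' scope is available — fit and compare the three sKL reduction models.
#' Every output lands under one run directory with a manifest recording the
#' configuration, seed and output files; rerunning with the same
#' configuration and seed reproduces the run exactly.
#'
#' @param config named list (see `read_pipeline_config()`); unspecified
#'   entries fall back to defaults. Required: `expr` and `meta` paths.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(default_pipeline_config(), config)
  for (f in c("expr", "meta")) {
    if (is.null(cfg[[f]])) abort(paste0("config entry '", f, "' is required"))
    if (!file.exists(cfg[[f]])) {
      abort(paste0("pipeline aborted at stage 'input': no such file: ", cfg[[f]]))
    }
  }
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(cfg$out, "run.log"), open = "wt")
  on.exit(close(logf), add = TRUE)
  failed_marker <- file.path(cfg$out, "FAILED")
  file.create(failed_marker)
  manifest <- list(config = cfg, outputs = character(0))
  add_output <- function(path) {
    manifest$outputs <<- c(manifest$outputs, path)
  }

  stage <- function(name, expr) {
    log_msg(logf, "[%s] start", name)
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline aborted at stage '%s': %s", name,
                    conditionMessage(e)))
    })
  }

  study <- stage("preprocess", read_expression_study(cfg$expr, cfg$meta))
  log_msg(logf, "defaults in effect: threshold=%g scale=%g family=%s sKL log base=e (nats)",
          cfg$threshold, cfg$scale, cfg$glm_family)
  fc <- stage("preprocess", {
    fc <- compute_fold_changes(study)
    fc <- apply_deg_filter(fc, threshold = cfg$threshold)
    write_fold_changes(fc, file.path(cfg$out, "fold_changes.tsv"))
    fc
  })
  add_output("fold_changes.tsv")
  corpus <- stage("preprocess", discretize_to_counts(fc, scale = cfg$scale))
  write_corpus(corpus, file.path(cfg$out, "corpus_treatment"))
  add_output("corpus_treatment")

  sims <- list()
  for (level in cfg$levels) {
    lvl_corpus <- stage("regroup", regroup_by_feature(corpus, level))
    if (level != "treatment") {
      write_corpus(lvl_corpus, file.path(cfg$out, paste0("corpus_", level)))
      add_output(paste0("corpus_", level))
    }
    K <- cfg$K[[level]] %||% 100L
    log_msg(logf, "[train] level=%s K=%d iterations=%d", level, K, cfg$iterations)
    model <- stage("train",
      att_train(lvl_corpus, K = K, iterations = cfg$iterations,
                burn_in = cfg$burn_in,
                optimize_interval = cfg$optimize_interval,
                alpha0 = cfg$alpha0, beta0 = cfg$beta0, seed = cfg$seed))
    mdir <- file.path(cfg$out, paste0("model_", level))
    write_att_model(model, mdir)
    add_output(paste0("model_", level))

    sim <- stage("similarity", pairwise_skl(model))
    write.table(data.frame(feature = sim$feature_ids, sim$scores,
                           check.names = FALSE),
                file.path(cfg$out, paste0("skl_", level, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    add_output(paste0("skl_", level, ".tsv"))
    sims[[level]] <- sim

    reports <- purrr::map_dfr(model$author_ids, function(a) {
      tt <- top_topics(model, a, n = min(3L, model$K))
      tt$feature <- a
      tt
    })
    write.table(reports[, c("feature", "topic", "probability")],
                file.path(cfg$out, paste0("top_topics_", level, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    add_output(paste0("top_topics_", level, ".tsv"))

    stage("gene lists",
          export_gene_lists(model,
                            out_path = file.path(cfg$out,
                                                 paste0("gene_lists_", level))))
    add_output(paste0("gene_lists_", level))
  }

  scopes <- cfg$glm_scopes
  if (is.null(scopes)) {
    scopes <- character(0)
    if ("treatment" %in% names(sims)) {
      design <- parse_treatment_key(sims$treatment$feature_ids)
      counts <- table(design$drug)
      scopes <- names(counts)[counts >= 3]
    }
    if ("time_dose" %in% names(sims)) scopes <- c(scopes, "time_dose_model")
  }
  if (length(scopes)) {
    glm_rows <- purrr::map_dfr(scopes, function(sc) {
      sim <- if (identical(sc, "time_dose_model")) sims$time_dose else sims$treatment
      res <- stage("glm", {
        d <- build_pair_design(sim, sc)
        fits <- lapply(c("dose_and_time", "dose_only", "time_only"),
                       function(v) fit_skl_glm(d, v, family = cfg$glm_family))
        compare_glm_variants(fits)
      })
      g <- glance(res)
      wide <- tidyr::pivot_wider(
        as_tibble(res)[, c("variant", "adj_r_squared", "aic", "bic")],
        names_from = "variant",
        values_from = c("adj_r_squared", "aic", "bic"))
      dplyr::bind_cols(g[, c("scope", "verdict")], wide)
    })
    write.table(glm_rows, file.path(cfg$out, "glm_comparison.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    add_output("glm_comparison.tsv")
  }

  cfg_path <- file.path(cfg$out, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest$config_hash <- unname(tools::md5sum(cfg_path))
  manifest$seed <- cfg$seed
  jsonlite::write_json(manifest, file.path(cfg$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  add_output("config.json")
  file.remove(failed_marker)
  log_msg(logf, "[done] %d outputs under %s", length(manifest$outputs), cfg$out)
  invisible(manifest)
}
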