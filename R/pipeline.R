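#' Pipeline configuration
#'
#' Exactly one knowledge-base source must be given: either `kb_path` (a sif
#' or GraphML file) or `kb_config` (a [synthetic_kb_config()], in which case
#' the generated knowledge base is written alongside the other outputs).
#' Focus genes come either from a packaged agent group or from a GMT file.
#'
#' @param kb_path path to a knowledge-base file.
#' @param kb_format file format for `kb_path`.
#' @param kb_config a [synthetic_kb_config()].
#' @param agent agent group for the packaged focus-gene sets
#'   (`"platinum"`, `"taxane"`, `"platinum/taxane"`), ignored when
#'   `focus_gmt` is given.
#' @param focus_gmt optional GMT file; its first set is used.
#' @param analysis an [analysis_config()].
#' @param out_dir output directory (created if missing).
#' @param seed global seed; stage seeds are derived from it by a fixed rule
#'   so stages can be re-run in isolation.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(kb_path = NULL, kb_format = "sif",
                            kb_config = NULL,
                            agent = "platinum", focus_gmt = NULL,
                            analysis = analysis_config(),
                            out_dir = "cipnnet-run", seed = 1) {
  if (is.null(kb_path) == is.null(kb_config)) {
    stop("specify exactly one knowledge-base source: kb_path or kb_config")
  }
  structure(list(kb_path = kb_path, kb_format = kb_format,
                 kb_config = kb_config, agent = agent,
                 focus_gmt = focus_gmt, analysis = analysis,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

# fixed fan-out of the global seed to per-stage seeds (kept below 2^31)
stage_seed <- function(seed, stage) {
  (as.integer(seed) * 1009L + stage) %% 2147483647L
}

#' Run the full analysis pipeline
#'
#' Generates or loads the knowledge base, runs the core analysis for the
#' selected focus genes, scores the networks, reports hubs for the top
#' network, fits the log-log power-law diagnostic, and writes
#' `networks.json`, `hubs.tsv`, `fit.json`, `exclusions.tsv` and a run
#' manifest (`manifest.json`: configuration, package version, seed and MD5
#' of every output). Outputs contain no timestamps, so a rerun with the same
#' configuration reproduces them byte-for-byte.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`kb`, `result`,
#'   `hubs`, `fit`, file paths).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop("config must be built with pipeline_config()")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  if (!is.null(config$kb_path)) {
    if (!file.exists(config$kb_path)) {
      stop("knowledge-base stage: file not found: ", config$kb_path)
    }
    kb <- load_kb(config$kb_path, format = config$kb_format)
    truth <- NULL
  } else {
    kbc <- config$kb_config
    kbc$seed <- stage_seed(config$seed, 1L)
    sim <- generate_kb(kbc)
    kb <- sim$kb
    truth <- sim$truth
    paths$kb <- file.path(config$out_dir, "kb.tsv")
    save_kb(kb, paths$kb, format = "sif")
    paths$truth <- file.path(config$out_dir, "ground_truth.tsv")
    save_ground_truth(truth, paths$truth)
  }

  focus <- if (!is.null(config$focus_gmt)) {
    read_gmt(config$focus_gmt)[[1]]
  } else {
    focus_genes_for_agent(cipn_focus_gene_sets(), config$agent)
  }

  result <- core_analysis(kb, focus, config$analysis)

  paths$networks <- file.path(config$out_dir, "networks.json")
  nets_json <- lapply(result$networks, function(nt) {
    list(genes = nt$genes, focus_genes = nt$focus_genes,
         n = nt$n, n_f = nt$n_f, p_value = nt$p_value, score = nt$score,
         significant = nt$significant,
         provenance = nt$provenance)
  })
  jsonlite::write_json(
    list(kb = kb$name, N = result$N, K = result$K, networks = nets_json),
    paths$networks, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  hubs <- if (length(result$networks) > 0) {
    top <- result$networks[[1]]
    find_hubs(count_connections(kb, top$genes),
              min_connections = config$analysis$hub_min_connections,
              focus = top$focus_genes)
  } else {
    find_hubs(integer(), config$analysis$hub_min_connections)
  }
  paths$hubs <- file.path(config$out_dir, "hubs.tsv")
  utils::write.table(as.data.frame(hubs), paths$hubs, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  fit <- tryCatch({
    degs <- if (length(result$networks) > 0) {
      unname(count_connections(kb, result$networks[[1]]$genes))
    } else degree_sequence(kb)
    if (length(unique(degs[degs >= 1])) < 3) degs <- degree_sequence(kb)
    loglog_powerlaw_fit(degs)
  }, error = function(e) NULL)
  paths$fit <- file.path(config$out_dir, "fit.json")
  jsonlite::write_json(
    if (is.null(fit)) list(error = "insufficient data") else
      list(slope = fit$slope, intercept = fit$intercept,
           r_squared = fit$r_squared, mode = fit$mode),
    paths$fit, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  paths$exclusions <- file.path(config$out_dir, "exclusions.tsv")
  utils::write.table(result$excluded, paths$exclusions, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "cipnnet",
    version = as.character(utils::packageVersion("cipnnet")),
    seed = config$seed,
    agent = if (is.null(config$focus_gmt)) config$agent else NULL,
    focus_gmt = config$focus_gmt,
    kb_source = if (!is.null(config$kb_path)) config$kb_path else "synthetic",
    kb_config = if (!is.null(config$kb_config)) {
      c <- unclass(config$kb_config)
      c$relation_weights <- as.list(c$relation_weights)
      c
    } else NULL,
    analysis = unclass(config$analysis),
    outputs = lapply(paths, function(p) unname(tools::md5sum(p))))
  paths$manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  invisible(list(kb = kb, truth = truth, result = result, hubs = hubs,
                 fit = fit, paths = paths))
}
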