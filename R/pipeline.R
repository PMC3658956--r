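# End-to-end orchestration: simulate/load -> QC -> network -> MCL ->
# enrichment -> profiles/activation, with one global seed fanned out to
# per-stage seeds by fixed offsets and a manifest of every artifact.

PIPELINE_KEYS <- list(
  top = c("seed", "outdir", "input", "simulation", "qc", "network",
          "cluster", "enrichment", "activation"),
  input = c("matrix", "samples", "term_map", "gmt"),
  qc = c("enabled", "min_group_size"),
  network = c("threshold", "min_group_size", "zero_variance_policy", "chunk_size"),
  cluster = c("inflation", "expansion", "self_loop_policy", "prune_threshold",
              "convergence_eps", "max_iterations", "min_cluster_size", "weighted"),
  enrichment = c("method", "alpha", "fdr_scope"),
  activation = c("n_permutations", "alpha"))

#' Validate a pipeline configuration
#'
#' Reads a YAML (or JSON) file, rejects unknown keys (all offenders are
#' listed), checks that exactly one of an `input` block (paths to matrix,
#' sample sheet, term map) and a `simulation` block (compendium settings)
#' is supplied, and fills defaults: correlation threshold 0.52, MCL
#' inflation 1.8, QC on.
#'
#' @param config path to a YAML/JSON file, or an equivalent named list.
#' @return validated config list of class `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_immunet("config must be a file path or a list")
  offenders <- character(0)
  chk <- function(block, allowed, prefix = "") {
    bad <- setdiff(names(block), allowed)
    if (length(bad) > 0) offenders <<- c(offenders, paste0(prefix, bad))
  }
  chk(config, PIPELINE_KEYS$top)
  for (b in c("input", "qc", "network", "cluster", "enrichment", "activation")) {
    if (!is.null(config[[b]])) {
      chk(config[[b]], PIPELINE_KEYS[[b]], paste0(b, "."))
    }
  }
  if (!is.null(config$simulation)) {
    chk(config$simulation, names(formals(compendium_config)), "simulation.")
  }
  if (length(offenders) > 0) {
    stop_immunet("unknown config key(s): %s", paste(offenders, collapse = ", "))
  }
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulation)
  if (has_input == has_sim) {
    stop_immunet("supply exactly one of 'input' and 'simulation'")
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$outdir <- config$outdir %||% "immunet_run"
  config$qc <- utils::modifyList(list(enabled = TRUE, min_group_size = 3),
                                 config$qc %||% list())
  config$network <- do.call(wgcn_params, config$network %||% list())
  config$cluster <- do.call(mcl_params, config$cluster %||% list())
  config$enrichment <- utils::modifyList(
    list(method = "fisher", alpha = 0.05, fdr_scope = "per_cluster"),
    config$enrichment %||% list())
  config$activation <- utils::modifyList(
    list(n_permutations = 1000, alpha = 0.05), config$activation %||% list())
  class(config) <- "pipeline_config"
  config
}

#' Run the full meta-analysis pipeline
#'
#' Executes simulate/load, QC, network construction, MCL clustering,
#' cluster enrichment, and per-cluster profiles and activation calls,
#' persisting every intermediate artifact under the configured output
#' directory. Re-running with an identical config reproduces byte-identical
#' artifacts; a manifest (JSON) lists every file with its md5 digest.
#'
#' @param config a [validate_config()] result, a config list, or a path.
#' @param outdir optional override of the configured output directory.
#' @return the manifest list, invisibly. Main in-memory results are in its
#'   `results` element (edges, clusters, enrichment, activation).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  if (!is.null(outdir)) config$outdir <- outdir
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(config$outdir, f)
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  artifacts <- character(0)

  # --- data ---------------------------------------------------------------
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    sim$seed <- sim$seed %||% config$seed
    cc <- do.call(compendium_config, sim)
    comp <- generate_compendium(cc)
    mat <- comp$matrix; samples <- comp$samples; term_map <- comp$term_map
    log_stage("simulate", "%d probesets x %d arrays, %d datasets, seed %d",
              nrow(mat), ncol(mat), cc$n_datasets, cc$seed)
  } else {
    comp <- NULL
    mat <- read_expression_matrix(config$input$matrix)
    samples <- read_sample_sheet(config$input$samples, mat,
                                 config$qc$min_group_size)
    ann <- read_annotation_sources(config$input$term_map, config$input$gmt)
    term_map <- ann$term_map
    log_stage("load", "%d probesets x %d arrays", nrow(mat), ncol(mat))
  }
  write_expression_matrix(mat, path("matrix.tsv"))
  write_sample_sheet(samples, path("samples.tsv"))
  artifacts <- c(artifacts, "matrix.tsv", "samples.tsv")

  # --- qc -----------------------------------------------------------------
  if (isTRUE(config$qc$enabled)) {
    report <- qc_metrics(mat)
    write_results(report, path("qc_report.tsv"))
    artifacts <- c(artifacts, "qc_report.tsv")
    filtered <- qc_filter(mat, samples, report, config$qc$min_group_size)
    log_stage("qc", "%d of %d arrays kept", ncol(filtered$matrix), ncol(mat))
    mat <- filtered$matrix; samples <- filtered$samples
  }

  # --- network ------------------------------------------------------------
  edges <- network_from_compendium(mat, samples, config$network)
  write_edge_list(edges, path("edges.txt"))
  artifacts <- c(artifacts, "edges.txt")
  log_stage("network", "%d edges at threshold %.2f (of %d probesets)",
            nrow(edges), config$network$threshold, nrow(mat))

  # --- cluster ------------------------------------------------------------
  clusters <- run_mcl(edges, config$cluster)
  write_results(clusters, path("clusters.tsv"))
  artifacts <- c(artifacts, "clusters.tsv")
  n_cl <- length(unique(stats::na.omit(clusters$cluster)))
  log_stage("cluster", "%d clusters (inflation %.2f)", n_cl,
            config$cluster$inflation)

  # --- annotate -----------------------------------------------------------
  enrichment <- enrich_clusters(clusters, term_map, background = rownames(mat),
                                method = config$enrichment$method,
                                fdr_scope = config$enrichment$fdr_scope)
  write_results(enrichment, path("enrichment.tsv"))
  artifacts <- c(artifacts, "enrichment.tsv")
  log_stage("annotate", "%d (cluster, term) rows, %d below q %.2f",
            nrow(enrichment), sum(enrichment$q < config$enrichment$alpha),
            config$enrichment$alpha)

  # --- profiles and activation --------------------------------------------
  prof_rows <- list(); act_rows <- list()
  for (cl in seq_len(n_cl)) {
    members <- cluster_members(clusters, cl)
    prof <- cluster_profile(mat, samples, members)
    prof$cluster <- cl
    prof_rows[[cl]] <- prof
    act <- activation_calls(mat, samples, members,
                            n_permutations = config$activation$n_permutations,
                            seed = config$seed + 1000L + cl,
                            alpha = config$activation$alpha)
    if (nrow(act) > 0) {
      act$cluster <- cl
      act_rows[[cl]] <- act
    }
  }
  profiles <- do.call(rbind, prof_rows) %||% data.frame()
  activation <- do.call(rbind, act_rows) %||% data.frame()
  write_results(profiles, path("profiles.tsv"))
  write_results(activation, path("activation.tsv"))
  artifacts <- c(artifacts, "profiles.tsv", "activation.tsv")
  log_stage("profile", "%d clusters profiled, %d activation calls",
            n_cl, sum(activation$activated %||% logical(0)))

  # --- manifest -----------------------------------------------------------
  digests <- tools::md5sum(file.path(config$outdir, artifacts))
  manifest <- list(
    tool = sprintf("immunet %s", as.character(utils::packageVersion("immunet"))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = config_echo(config),
    files = data.frame(file = artifacts, md5 = unname(digests),
                       stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest$results <- list(matrix = mat, samples = samples, edges = edges,
                           clusters = clusters, enrichment = enrichment,
                           profiles = profiles, activation = activation,
                           compendium = comp)
  invisible(manifest)
}

config_echo <- function(config) {
  keep <- config[intersect(names(config), PIPELINE_KEYS$top)]
  lapply(keep, function(x) if (is.list(x)) unclass(x) else x)
}
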