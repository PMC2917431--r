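#' Build and validate a pipeline configuration
#'
#' A run configuration ties the stages together: input paths (or the
#' synthetic-benchmark parameters that replace them), the resolution-sweep
#' settings, the similarity measures to score, the homogeneity threshold
#' and reporting size, the metric registry subset, and the AUC evaluation
#' range.  Validation happens here, before any stage runs.
#'
#' @param config A named list or the path to a YAML file with (a subset
#'   of) the fields below.
#' @return A validated config list of class `"run_config"`.
#'
#' @section Fields:
#' * `outdir` (required): output directory, created if absent.
#' * `seed`: integer master seed (default 1).
#' * `edges`: edge-list TSV path; omit to simulate instead.
#' * `simulate`: list of [generate_planted_network()] /
#'   [generate_annotations()] / [generate_growth_profiles()] parameter
#'   overrides (`fidelity` default 0.9, `effect_size` 1, `noise_sd` 0.5).
#' * `annotations`, `ontology`, `growth`: input paths (required for the
#'   measures that use them when `edges` is given).
#' * `sweep`: list `log_min` (-1), `log_max` (3), `step` (0.1),
#'   `warm_start` (TRUE).
#' * `measures`: subset of `c("G", "C")` when simulating (default both);
#'   with file inputs also `"M"` if a flat annotation TSV is supplied via
#'   `flat_annotations`.
#' * `threshold` (0.3), `min_size` (4).
#' * `metrics`: metric names (default [metric_registry()]).
#' * `auc_range`: length-2 numeric (default `c(0, 3)`).
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$outdir)) stop("config requires an 'outdir'")
  defaults <- list(seed = 1L,
                   sweep = list(log_min = -1, log_max = 3, step = 0.1,
                                warm_start = TRUE),
                   measures = c("G", "C"), threshold = 0.3, min_size = 4,
                   metrics = metric_registry(), auc_range = c(0, 3))
  for (f in names(defaults)) {
    if (is.null(config[[f]])) config[[f]] <- defaults[[f]]
  }
  for (f in names(defaults$sweep)) {
    if (is.null(config$sweep[[f]])) config$sweep[[f]] <- defaults$sweep[[f]]
  }
  with(config$sweep, stopifnot(log_min < log_max, step > 0))
  stopifnot(config$threshold >= 0, config$min_size >= 1,
            length(config$auc_range) == 2)
  bad <- setdiff(config$metrics, metric_registry())
  if (length(bad)) stop("unknown metrics in config: ",
                        paste(bad, collapse = ", "))
  simulating <- is.null(config$edges)
  if (!simulating) {
    if ("G" %in% config$measures &&
        (is.null(config$annotations) || is.null(config$ontology))) {
      stop("measure G requires 'annotations' and 'ontology' paths")
    }
    if ("M" %in% config$measures && is.null(config$flat_annotations)) {
      stop("measure M requires a 'flat_annotations' path")
    }
    if ("C" %in% config$measures && is.null(config$growth)) {
      stop("measure C requires a 'growth' path")
    }
  } else {
    if (is.null(config$simulate)) config$simulate <- list()
    sim_defaults <- list(fidelity = 0.9, effect_size = 1, noise_sd = 0.5,
                         missing_fraction = 0)
    for (f in names(sim_defaults)) {
      if (is.null(config$simulate[[f]])) {
        config$simulate[[f]] <- sim_defaults[[f]]
      }
    }
  }
  structure(config, class = c("run_config", "list"))
}

#' Run the full analysis pipeline
#'
#' Executes the staged pipeline — simulate (optional) / build, resolution
#' sweep, similarity scoring, homogeneity calls, community topology, and
#' predictor evaluation — writing every stage's output as a CSV in
#' `outdir`, plus a `manifest.json` recording the package version, the
#' configuration and its file hash, and per-stage row counts.  With the
#' same configuration (including seed) a rerun writes identical partition
#' and call tables.
#'
#' @param config A `"run_config"`, or anything [run_config()] accepts.
#' @param quiet Suppress per-stage messages.
#' @return The output directory path, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- run_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  counts <- list()

  # --- build / simulate -----------------------------------------------
  if (is.null(config$edges)) {
    sim <- config$simulate
    net_args <- sim[intersect(names(sim),
                              c("n_coarse", "fine_per_coarse", "fine_size",
                                "p_fine", "p_coarse", "p_between"))]
    gen <- stage("simulate", do.call(generate_planted_network,
                                     c(net_args, list(seed = config$seed))))
    net <- gen$network
    st <- gen$structure
    ann <- stage("simulate", propagate_annotations(generate_annotations(
      st, fidelity = sim$fidelity, seed = config$seed + 1L)))
    gm <- stage("simulate", generate_growth_profiles(
      st, effect_size = sim$effect_size, noise_sd = sim$noise_sd,
      missing_fraction = sim$missing_fraction, seed = config$seed + 2L))
    write_labels_csv(st, file.path(config$outdir, "planted_labels.csv"))
  } else {
    net <- stage("build", read_edge_tsv(config$edges, keep_lcc = TRUE))
    ann <- if ("G" %in% config$measures) {
      stage("build", propagate_annotations(read_annotation_tsv(
        config$annotations, read_obo(config$ontology))))
    }
    gm <- if ("C" %in% config$measures) {
      stage("build", read_growth_csv(config$growth))
    }
  }
  flat_ann <- if ("M" %in% config$measures &&
                  !is.null(config$flat_annotations)) {
    df <- read.delim(config$flat_annotations, stringsAsFactors = FALSE)
    tapply(df$term, df$protein, unique, simplify = FALSE)
  }
  write_edge_tsv(net, file.path(config$outdir, "edges.tsv"))
  ns <- network_summary(net)
  say("network: %d nodes, %d edges, mean degree %.2f", ns$n_nodes,
      ns$n_edges, ns$mean_degree)
  counts$n_nodes <- ns$n_nodes
  counts$n_edges <- ns$n_edges

  # --- sweep ----------------------------------------------------------
  sw <- stage("sweep", potts_sweep(
    net, log_min = config$sweep$log_min, log_max = config$sweep$log_max,
    step = config$sweep$step, seed = config$seed,
    warm_start = config$sweep$warm_start))
  utils::write.csv(as.data.frame(sw),
                   file.path(config$outdir, "partitions.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(summary(sw), file.path(config$outdir, "energies.csv"),
                   row.names = FALSE, quote = FALSE)
  say("sweep: %d grid points, %d-%d communities",
      length(sw$log_lambda), min(sw$n_communities), max(sw$n_communities))
  counts$n_grid <- length(sw$log_lambda)

  # --- similarity + homogeneity --------------------------------------
  ez <- list()
  for (m in config$measures) {
    es <- stage("similarity", switch(m,
      G = edge_similarity(net, "G", ann, seed = config$seed),
      M = edge_similarity(net, "M", flat_ann, seed = config$seed),
      C = edge_similarity(net, "C", gm, seed = config$seed)))
    sim_df <- cbind(measure = m, es$values)
    utils::write.csv(sim_df,
                     file.path(config$outdir,
                               sprintf("similarity_%s.csv", m)),
                     row.names = FALSE, quote = FALSE)
    ez[[m]] <- stage("similarity", zscore_edges(es))
  }
  calls <- stage("homogeneity", call_communities(
    sw, net, ez, threshold = config$threshold,
    min_size = config$min_size))
  utils::write.csv(calls, file.path(config$outdir, "community_calls.csv"),
                   row.names = FALSE, quote = FALSE)
  summ <- sweep_summary(calls)
  utils::write.csv(summ, file.path(config$outdir, "sweep_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  say("homogeneity: %d calls across %d resolutions", nrow(calls),
      length(unique(calls$log_lambda)))
  counts$n_calls <- nrow(calls)

  # --- topology + evaluation -----------------------------------------
  mets <- stage("topology", sweep_metrics(sw, net, config$metrics,
                                          min_size = config$min_size))
  utils::write.csv(mets, file.path(config$outdir, "community_metrics.csv"),
                   row.names = FALSE, quote = FALSE)
  aucs <- stage("evaluate", metric_aucs(mets, calls,
                                        measure = config$measures[[1]],
                                        min_size = config$min_size))
  utils::write.csv(aucs, file.path(config$outdir, "metric_aucs.csv"),
                   row.names = FALSE, quote = FALSE)
  ranking <- stage("evaluate", metric_ranking(aucs, config$auc_range))
  utils::write.csv(ranking, file.path(config$outdir, "metric_ranking.csv"),
                   row.names = FALSE, quote = FALSE)
  say("evaluation: top metric %s (mean AUC %.3f)", ranking$metric[[1]],
      ranking$mean_auc[[1]])
  counts$n_metrics <- length(unique(mets$metric))

  # --- manifest -------------------------------------------------------
  cfg_path <- file.path(config$outdir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  manifest <- list(
    package = "pottsnet",
    version = as.character(utils::packageVersion("pottsnet")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    counts = counts)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(config$outdir)
}
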