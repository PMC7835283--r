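# End-to-end orchestration: one validated config in, every intermediate
# artifact (CSV / GraphML / Newick / JSON manifest) out, fully
# deterministic under a fixed seed.

pipeline_defaults <- function() {
  list(
    input = list(edf = NULL, annotations = NULL, scenario = NULL),
    h2 = list(n_bins = 10L, min_points_per_bin = 10L,
              lag_range_ms = c(-100, 100), lag_step_samples = 1L),
    graph = list(rule = "independent", adjacency_mode = "binary"),
    stats = list(q = 0.05, k = 25L, collapse = "max",
                 control_phase = "baseline"),
    tracts = list(labels = NULL, streamlines = NULL),
    output_dir = NULL,
    seed = 1L
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a config as a named list or as a path to a YAML/JSON file,
#' checks it against the schema (unknown keys are errors), fills defaults
#' and returns the normalized config. Exactly one signal source must be
#' set: either `input$edf` (with `input$annotations`) or
#' `input$scenario` (`"demo"` for the built-in [demo_scenario()], or a
#' [scenario_spec()] when configuring from R).
#'
#' @param config Named list, or path to a YAML or JSON file.
#' @return A validated config list of class `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop_ictalnet(sprintf("config file not found: %s", config),
                    "ictalnet_config_error")
    }
    config <- if (grepl("\\.json$", config)) {
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  defs <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defs))
  if (length(unknown)) {
    stop_ictalnet(sprintf("unknown config key(s): %s",
                          paste(unknown, collapse = ", ")),
                  "ictalnet_config_error")
  }
  cfg <- utils::modifyList(defs, config)
  for (section in c("input", "h2", "graph", "stats", "tracts")) {
    extra <- setdiff(names(cfg[[section]]), names(defs[[section]]))
    if (length(extra)) {
      stop_ictalnet(sprintf("unknown config key(s) in %s: %s", section,
                            paste(extra, collapse = ", ")),
                    "ictalnet_config_error")
    }
  }
  has_edf <- !is.null(cfg$input$edf)
  has_scen <- !is.null(cfg$input$scenario)
  if (has_edf && !is.null(config$input$scenario)) {
    stop_ictalnet("set exactly one of input$edf and input$scenario",
                  "ictalnet_config_error")
  }
  if (has_edf) cfg$input$scenario <- NULL
  if (!has_edf && !has_scen) {
    stop_ictalnet("config must set input$edf or input$scenario",
                  "ictalnet_config_error")
  }
  if (has_edf && is.null(cfg$input$annotations)) {
    stop_ictalnet("EDF input requires input$annotations (sidecar JSON)",
                  "ictalnet_config_error")
  }
  q <- cfg$stats$q
  if (!is.numeric(q) || q <= 0 || q >= 1) {
    stop_ictalnet("stats$q must lie in (0, 1)", "ictalnet_config_error")
  }
  if (!cfg$graph$rule %in% c("independent", "winner_take_all")) {
    stop_ictalnet("graph$rule must be independent or winner_take_all",
                  "ictalnet_config_error")
  }
  if (!cfg$graph$adjacency_mode %in% c("binary", "weighted")) {
    stop_ictalnet("graph$adjacency_mode must be binary or weighted",
                  "ictalnet_config_error")
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

write_num_csv <- function(x, path) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) {
    ifelse(is.na(v), NA, sprintf("%.6f", v))
  })
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full seizure-network pipeline
#'
#' Executes, in order: signal input (EDF + annotations, or the synthetic
#' scenario), per-event h2 coupling matrices, the baseline threshold
#' model, directed event graphs, adjacency matrices, cosine similarity
#' and dendrograms, the similarity distribution, and the phase-change
#' signed-rank statistics — plus streamline counting when a label volume
#' and streamline file are configured. Every intermediate result is
#' written to `output_dir` along with a JSON manifest recording the
#' package version, seed, config hash and artifact list. The run is
#' deterministic: identical config and seed give byte-identical outputs.
#'
#' @param config A [validate_config()] config (list, path, or already
#'   validated).
#' @return The manifest, invisibly (list with `artifacts`, `seed`,
#'   `config_hash`, `version`, and the in-memory `results`).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    validate_config(config)
  out_dir <- cfg$output_dir %||% stop_ictalnet(
    "config must set output_dir", "ictalnet_config_error")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  art <- character()
  put <- function(name) {
    p <- file.path(out_dir, name)
    art <<- c(art, p)
    p
  }

  # --- signal input ----------------------------------------------------
  truth <- NULL
  if (!is.null(cfg$input$edf)) {
    rec <- read_edf(cfg$input$edf)
    ann <- read_annotations(cfg$input$annotations)
  } else {
    spec <- cfg$input$scenario
    if (identical(spec, "demo")) spec <- demo_scenario()
    if (!inherits(spec, "scenario_spec")) {
      stop_ictalnet("input$scenario must be 'demo' or a scenario_spec",
                    "ictalnet_config_error")
    }
    sim <- generate_seizure_scenario(spec, seed = cfg$seed)
    rec <- sim$recording
    ann <- sim$annotations
    truth <- sim$truth
  }
  validate_annotations(ann, rec)

  # --- h2 coupling ------------------------------------------------------
  h2cfg <- h2_config(cfg$h2$n_bins, cfg$h2$min_points_per_bin,
                     cfg$h2$lag_range_ms, cfg$h2$lag_step_samples)
  coupling <- event_coupling(rec, ann, h2cfg, keep_matrices = TRUE)
  mats <- attr(coupling, "matrices")
  write_num_csv(coupling, put("coupling_long.csv"))

  # --- threshold + graphs ----------------------------------------------
  base_idx <- which(ann$phase == "baseline")
  if (length(base_idx) == 0L) {
    stop_ictalnet("pipeline stage 'graphs': no baseline event to fit thresholds",
                  "ictalnet_pipeline_error")
  }
  thr <- fit_baseline(mats[[base_idx[1]]])
  write_num_csv(tidy(thr), put("threshold_model.csv"))
  graphs <- lapply(mats, build_event_graph, thr = thr, rule = cfg$graph$rule)
  edges <- dplyr::bind_rows(lapply(seq_along(graphs), function(i) {
    dplyr::mutate(graphs[[i]]$edges,
                  seizure_id = ann$seizure_id[i], phase = ann$phase[i],
                  .before = 1)
  }))
  write_num_csv(edges, put("event_graph_edges.csv"))
  for (i in seq_along(graphs)) {
    write_graphml(graphs[[i]], put(sprintf("graph_s%d_%s.graphml",
                                           ann$seizure_id[i], ann$phase[i])))
  }

  # --- clustering -------------------------------------------------------
  adjs <- lapply(graphs, to_adjacency, mode = cfg$graph$adjacency_mode)
  sims <- lapply(adjs, cosine_similarity)
  dends <- lapply(sims, agglomerate)
  merges <- dplyr::bind_rows(lapply(seq_along(dends), function(i) {
    dplyr::mutate(tidy(dends[[i]]),
                  seizure_id = ann$seizure_id[i], phase = ann$phase[i],
                  .before = 1)
  }))
  write_num_csv(merges, put("dendrogram_merges.csv"))
  for (i in seq_along(dends)) {
    write_newick(dends[[i]], put(sprintf("dendrogram_s%d_%s.nwk",
                                         ann$seizure_id[i], ann$phase[i])))
  }
  dist_tbl <- similarity_distribution(sims, phases = ann$phase)
  write_num_csv(dist_tbl, put("similarity_distribution.csv"))
  sim_h2 <- similarity_vs_h2(sims, mats)
  write_num_csv(sim_h2, put("similarity_vs_h2.csv"))

  # --- phase statistics -------------------------------------------------
  stats_res <- NULL
  diffs <- pair_differences(coupling,
                            control_phase = cfg$stats$control_phase,
                            collapse = cfg$stats$collapse)
  if (nrow(diffs)) {
    stats_res <- phase_signed_rank(diffs, q = cfg$stats$q)
    write_num_csv(as_tibble(stats_res), put("signed_rank_results.csv"))
    tops <- suppressWarnings(top_pairs(stats_res, diffs, k = cfg$stats$k))
    write_num_csv(tops, put("top_pairs_diffs.csv"))
  }

  # --- structural tracts (optional) ------------------------------------
  tracts <- NULL
  if (!is.null(cfg$tracts$labels) && !is.null(cfg$tracts$streamlines)) {
    vol <- read_label_volume(cfg$tracts$labels)
    sls <- read_tck(cfg$tracts$streamlines)
    tracts <- tract_count_matrix(sls, vol)
    utils::write.csv(as.data.frame(unclass(tracts)),
                     put("tract_counts.csv"))
  }

  manifest <- list(
    package = "ictalnet",
    version = as.character(utils::packageVersion("ictalnet")),
    seed = cfg$seed,
    config_hash = rlang::hash(unclass(cfg)[setdiff(names(cfg), "output_dir")]),
    n_events = nrow(ann),
    artifacts = basename(art)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest$results <- list(recording = rec, annotations = ann,
                           coupling = coupling, threshold = thr,
                           graphs = graphs, similarity = sims,
                           dendrograms = dends, distribution = dist_tbl,
                           stats = stats_res, truth = truth,
                           tracts = tracts)
  invisible(manifest)
}
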