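#' Default pipeline configuration
#'
#' Every stage parameter of [run_pipeline()] with its default. Unknown keys
#' in a user configuration are rejected.
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    seed = NULL,
    out = NULL,
    simulate = list(
      n_spots = 100, n_clones = 20,
      pattern_mix = c(expanded = 0.5, dispersed = 0.5),
      spots_per_clone = 3:8, umis_per_spot = 2,
      error_rates = c(sub = 0.0260, ins = 0.0095, del = 0.0119),
      mean_reads_per_umi = 2, reads_per_clone = NULL
    ),
    demux = list(max_dist = 2, max_adapter_dist = 4),
    annotate = list(min_score = 50),
    correct = list(k = 8, min_jaccard = 0.2, max_cdr3_dist = 10),
    repertoire = list(
      min_len = 5, max_len = 30, min_umi = 1, min_dist = 2,
      require_vj = TRUE, min_expr = 1
    ),
    spatial = list(
      prune_factor = 3.0, spot_min_umi = 5, umi_threshold = 5,
      clonality_threshold = 1, diversity_threshold = 3.0,
      min_clones_diverse = 2
    )
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      abort(paste0("unknown config key: ", full),
        class = "clonospace_config_error"
      )
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
      is.list(user[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Run the full synthetic pipeline
#'
#' Chains simulate -> emit reads -> demultiplex -> orient/split ->
#' annotate -> (V,C)-partitioned consensus correction -> re-annotation ->
#' UMI collapse -> clonotype clustering -> normalisation -> spatial
#' metrics -> spot classification, logging a waterfall of record counts
#' per stage. Deterministic given `config$seed`.
#'
#' @param config A nested list overriding [default_config()], or a path to
#'   a YAML file with the same structure. `seed` is mandatory.
#' @param quiet Suppress per-stage messages.
#' @return A `clonospace_run` list: `bundle`, `reads`, `truth`,
#'   `assignments`, `inserts`, `annotations`, `corrected`,
#'   `annotations_corrected`, `collapsed`, `records`, `clones`,
#'   `normalized`, `graph`, `clone_stats`, `spot_metrics`, `error_pre`,
#'   `error_post`, `waterfall`, `config`.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  if (is.null(cfg$seed)) {
    abort("config$seed is mandatory", class = "clonospace_config_error")
  }
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  stage <- function(name) say(
    "[%s] %s", format(round(difftime(Sys.time(), t0, units = "secs"), 1)), name
  )

  refs <- toy_references()
  sim <- cfg$simulate
  stage("simulate")
  bundle <- simulate_repertoire(
    n_spots = sim$n_spots, n_clones = sim$n_clones,
    pattern_mix = unlist(sim$pattern_mix),
    spots_per_clone = sim$spots_per_clone, umis_per_spot = sim$umis_per_spot,
    error_rates = unlist(sim$error_rates), refs = refs, seed = cfg$seed
  )
  emitted <- emit_reads(bundle,
    mean_reads_per_umi = sim$mean_reads_per_umi,
    reads_per_clone = sim$reads_per_clone
  )
  reads <- emitted$reads

  stage("demux")
  assignments <- demux_reads(reads, bundle$whitelist,
    max_dist = cfg$demux$max_dist,
    max_adapter_dist = cfg$demux$max_adapter_dist
  )

  stage("orient")
  inserts <- orient_and_split(reads, max_dist = cfg$demux$max_adapter_dist)

  stage("annotate")
  annotations <- annotate_inserts(inserts, refs, min_score = cfg$annotate$min_score)

  stage("correct")
  error_pre <- measure_error(
    tibble(read_id = inserts$insert_id, seq = inserts$seq), refs
  )
  corrected <- correct_partitions(
    inserts, annotations,
    k = cfg$correct$k, min_jaccard = cfg$correct$min_jaccard,
    max_cdr3_dist = cfg$correct$max_cdr3_dist
  )
  error_post <- measure_error(corrected[, c("read_id", "seq")], refs)

  stage("re-annotate corrected reads")
  ann2 <- annotate_inserts(
    tibble(insert_id = corrected$read_id, seq = corrected$seq), refs,
    min_score = cfg$annotate$min_score
  )

  stage("repertoire")
  collapsed <- collapse_to_umis(assignments, ann2)
  records <- preprocess_tcr(collapsed,
    min_len = cfg$repertoire$min_len, max_len = cfg$repertoire$max_len,
    min_umi = cfg$repertoire$min_umi, require_vj = cfg$repertoire$require_vj
  )
  clones <- cluster_cdr3(records, min_dist = cfg$repertoire$min_dist)
  normalized <- normalize_tcr(clones, bundle$spot_table,
    min_expr = cfg$repertoire$min_expr
  )

  stage("spatial metrics")
  graph <- delaunay_graph(bundle$spot_table, prune_factor = cfg$spatial$prune_factor)
  clone_stats <- clonality_index(graph, clones)
  spot_metrics <- spot_summaries(clones, bundle$spot_table,
    min_umi = cfg$spatial$spot_min_umi
  ) |>
    classify_spots(clone_stats, clones,
      umi_threshold = cfg$spatial$umi_threshold,
      clonality_threshold = cfg$spatial$clonality_threshold,
      diversity_threshold = cfg$spatial$diversity_threshold,
      min_clones_diverse = cfg$spatial$min_clones_diverse
    )

  waterfall <- tibble(
    stage = c(
      "reads_emitted", "reads_demultiplexed", "inserts", "inserts_annotated",
      "reads_corrected", "records_filtered", "clones"
    ),
    n = c(
      nrow(reads), sum(!is.na(assignments$barcode)), nrow(inserts),
      sum(nzchar(annotations$v_call)), nrow(corrected), nrow(records),
      nrow(clones)
    )
  )
  run <- structure(
    list(
      bundle = bundle, reads = reads, truth = emitted$truth,
      assignments = assignments, inserts = inserts,
      annotations = annotations, corrected = corrected,
      annotations_corrected = ann2, collapsed = collapsed,
      records = records, clones = clones, normalized = normalized,
      graph = graph, clone_stats = clone_stats, spot_metrics = spot_metrics,
      error_pre = error_pre, error_post = error_post,
      waterfall = waterfall, config = cfg
    ),
    class = "clonospace_run"
  )
  if (!is.null(cfg$out)) write_run(run, cfg$out)
  run
}

#' @export
print.clonospace_run <- function(x, ...) {
  cat("<clonospace_run>\n")
  w <- x$waterfall
  cat(paste0("  ", format(w$stage, width = 22), w$n, collapse = "\n"), "\n")
  cat(sprintf(
    "  error rate: %.2f%% -> %.2f%%\n",
    100 * x$error_pre$summary$mean_error, 100 * x$error_post$summary$mean_error
  ))
  invisible(x)
}

#' Write pipeline artifacts to a directory
#'
#' @param run A `clonospace_run`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_airr(run$annotations_corrected, file.path(dir, "airr.tsv"))
  clones_flat <- run$clones |>
    mutate(members = vapply(.data$members, paste, character(1), collapse = ";"))
  readr::write_tsv(clones_flat, file.path(dir, "clones.tsv"), progress = FALSE)
  readr::write_tsv(clone_spot_counts(run$clones),
    file.path(dir, "clone_spot_counts.tsv"),
    progress = FALSE
  )
  readr::write_tsv(run$spot_metrics, file.path(dir, "spot_metrics.tsv"), progress = FALSE)
  readr::write_tsv(run$clone_stats, file.path(dir, "clone_stats.tsv"), progress = FALSE)
  readr::write_tsv(run$graph$edges, file.path(dir, "spot_graph_edges.tsv"), progress = FALSE)
  write_spot_table(run$bundle$spot_table, file.path(dir, "spots.csv"))
  report <- list(
    waterfall = setNames(as.list(run$waterfall$n), run$waterfall$stage),
    error = list(
      pre = as.list(run$error_pre$summary),
      post = as.list(run$error_post$summary)
    )
  )
  jsonlite::write_json(report, file.path(dir, "run_report.json"),
    auto_unbox = TRUE, digits = NA
  )
  cfg <- run$config
  cfg$simulate$reads_per_clone <- cfg$simulate$reads_per_clone %||% "null"
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
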