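## End-to-end pipeline: input -> haplotypes -> network -> metrics -> report.

#' Read a pipeline configuration file
#'
#' YAML or JSON (by extension). Recognized fields: `alignment` and
#' `metadata` paths (FASTA + TSV route), or `incidence` path
#' (counts-only route), or `simulate` (a list of [simulation_params()]
#' arguments); `trim` (list with `drop_leading`, `drop_trailing`),
#' `ambiguity_policy`, `island_aliases` (named list), `max_steps`,
#' `rules`, `outdir`, `seed`.
#'
#' @param path configuration file path.
#' @return The configuration as a named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    ih_stop(sprintf("config file not found: %s", path),
            "islehaps_input_error")
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  for (f in c("alignment", "metadata", "incidence"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      ih_stop(sprintf("config references missing file '%s': %s", f, cfg[[f]]),
              "islehaps_input_error")
  cfg
}

log_stage <- function(con, stage, ...) {
  rec <- c(list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
}

#' Run the colonization-analysis pipeline
#'
#' Executes the full chain for one data set: obtain an alignment
#' (simulated or read from FASTA), trim, collapse into a haplotype table,
#' build the haplotype network, classify and rank haplotypes, compute
#' colonization metrics, and write every artifact plus a run manifest to
#' `config$outdir`. With an `incidence` input the sequence-dependent
#' stages are skipped and metrics are computed directly from the counts.
#'
#' Artifacts: `haplotypes.tsv`, `incidence.tsv`, `network_edges.tsv`,
#' `network.graphml`, `classification.tsv`, `ancestrality.tsv`,
#' `metrics.json`, `manifest.json`, `pipeline.log` (line-delimited JSON,
#' one record per stage). On failure a `.partial` marker file is left in
#' the output directory beside whatever artifacts were completed.
#'
#' @param config a configuration list (see [read_pipeline_config()]) or a
#'   path to a YAML/JSON configuration file.
#' @return Invisibly, a named character vector of artifact paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  outdir <- if (is.null(config$outdir)) "." else config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  partial <- file.path(outdir, ".partial")
  file.create(partial)
  logcon <- file(file.path(outdir, "pipeline.log"), open = "wt")
  on.exit(close(logcon), add = TRUE)
  artifacts <- c(log = file.path(outdir, "pipeline.log"))
  aliases <- if (is.null(config$island_aliases)) default_island_aliases()
             else unlist(config$island_aliases)

  table <- NULL
  net <- NULL
  if (!is.null(config$simulate)) {
    args <- config$simulate
    if (is.null(args$seed) && !is.null(config$seed)) args$seed <- config$seed
    params <- if (identical(args$preset, "galapagos-like"))
      do.call(galapagos_params, args[setdiff(names(args), "preset")])
    else do.call(simulation_params, args)
    ds <- simulate_colonization(params)
    sim_paths <- write_simulated_dataset(ds, file.path(outdir, "simulated"))
    artifacts <- c(artifacts, sim_paths)
    log_stage(logcon, "simulate", n_samples = length(ds$alignment$ids),
              n_events = true_event_count(ds))
    aln <- ds$alignment
    meta <- ds$metadata
  } else if (!is.null(config$alignment)) {
    aln <- read_alignment(config$alignment)
    meta <- read_sample_metadata(config$metadata, island_aliases = aliases)
    log_stage(logcon, "read", n_samples = length(aln$ids),
              length_bp = aln$length)
  } else if (!is.null(config$incidence)) {
    table <- read_incidence(config$incidence)
    log_stage(logcon, "read_incidence", n_haplotypes = nrow(table$counts),
              n_islands = ncol(table$counts))
  } else {
    ih_stop("config needs one of: simulate, alignment(+metadata), incidence",
            "islehaps_input_error")
  }

  if (is.null(table)) {
    if (!is.null(config$trim)) {
      aln <- trim_alignment(aln,
                            drop_leading = config$trim$drop_leading %||% 0L,
                            drop_trailing = config$trim$drop_trailing %||% 0L)
      log_stage(logcon, "trim", length_bp = aln$length)
    }
    policy <- config$ambiguity_policy %||% "exclude"
    table <- collapse_haplotypes(aln, meta, ambiguity_policy = policy,
                                 island_aliases = aliases)
    log_stage(logcon, "collapse", n_haplotypes = nrow(table$haplotypes),
              n_ingroup = sum(table$counts))
  }

  artifacts["haplotypes"] <- file.path(outdir, "haplotypes.tsv")
  write_haplotype_table(table, artifacts[["haplotypes"]])
  artifacts["incidence"] <- file.path(outdir, "incidence.tsv")
  write_incidence(table, artifacts[["incidence"]])

  if (has_sequences(table)) {
    max_steps <- config$max_steps %||% Inf
    net <- build_network(table, max_steps = max_steps)
    artifacts["network_edges"] <- file.path(outdir, "network_edges.tsv")
    write_network_edgelist(net, artifacts[["network_edges"]])
    artifacts["network_graphml"] <- file.path(outdir, "network.graphml")
    write_network_graphml(net, artifacts[["network_graphml"]])
    cls <- classify_nodes(net)
    artifacts["classification"] <- file.path(outdir, "classification.tsv")
    utils::write.table(
      data.frame(haplotype_id = names(cls), class = unname(cls)),
      artifacts[["classification"]], sep = "\t", quote = FALSE,
      row.names = FALSE)
    rank <- ancestrality_rank(net, table)
    artifacts["ancestrality"] <- file.path(outdir, "ancestrality.tsv")
    utils::write.table(rank, artifacts[["ancestrality"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log_stage(logcon, "network",
              n_nodes = nrow(net$nodes), n_edges = nrow(net$edges),
              n_inferred = sum(net$nodes$type == "inferred"))
  } else {
    log_stage(logcon, "network", skipped = "sequence-free input")
  }

  n_occupied <- sum(colSums(table$counts) > 0L)
  # archipelago size: explicit config, else the simulated archipelago,
  # else the islands seen in the data
  n_arch <- config$n_archipelago_islands %||%
    (if (!is.null(config$simulate)) params$n_islands else ncol(table$counts))
  ev <- inferred_events(table, "all")
  maxp <- max_potential(nrow(table$counts), n_arch)
  metrics <- list(
    n_haplotypes = nrow(table$counts),
    n_islands_occupied = n_occupied,
    n_archipelago_islands = n_arch,
    chorological_min = chorological_minimum(n_occupied),
    max_potential = maxp,
    inferred_events = as.list(ev),
    success = if (maxp >= 1L)
      lapply(as.list(ev), function(e) colonization_success(e, maxp)$rounded)
    else NULL)
  artifacts["metrics"] <- file.path(outdir, "metrics.json")
  jsonlite::write_json(metrics, artifacts[["metrics"]], auto_unbox = TRUE,
                       digits = NA)
  log_stage(logcon, "metrics", chorological_min = metrics$chorological_min,
            max_potential = maxp)

  manifest <- list(
    package = "islehaps",
    version = as.character(utils::packageVersion("islehaps")),
    seed = config$seed,
    config_hash = digest_config(config),
    artifacts = as.list(artifacts[sort(names(artifacts))]))
  artifacts["manifest"] <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, artifacts[["manifest"]], auto_unbox = TRUE,
                       digits = NA)
  file.remove(partial)
  invisible(artifacts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable fingerprint of the configuration for the run manifest
digest_config <- function(config) {
  s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                        digits = NA, null = "null", force = TRUE)
  # small polynomial rolling hash of the serialized config; enough to
  # detect drift between runs
  h <- 17
  for (b in utf8ToInt(as.character(s)))
    h <- (h * 131 + b) %% 68719476731
  sprintf("%011.0f", h)
}
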