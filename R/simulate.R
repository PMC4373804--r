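## Forward-time island-colonization simulator with ground-truth event log.
##
## Stepping-stone-style model: one Wright-Fisher deme per island
## (haploid, fixed fecundity), finite-sites mutation on a short mtDNA-like
## locus, and rare uniform migration between islands. Every inter-island
## move is logged, so the true number of colonization events is known and
## the haplotype-sharing inference chain can be validated end to end.

GALAPAGOS_ISLANDS <- c("Española", "Fernandina", "Floreana", "Genovesa",
                       "Isabela", "San Cristóbal", "Santa Cruz",
                       "Santa Fe", "Santiago")

#' Simulation parameters
#'
#' Validated parameter set for [simulate_colonization()].
#'
#' @param island_names character vector of island names.
#' @param founding_island island receiving the single founding
#'   colonization; must be in `island_names`.
#' @param n_generations forward generations simulated.
#' @param deme_size individuals produced per occupied island per
#'   generation.
#' @param migration_prob per-individual per-generation probability of
#'   moving to a uniformly chosen other island.
#' @param mutation_rate per-site per-generation substitution probability.
#' @param seq_length locus length in bp.
#' @param samples_per_island individuals sampled per occupied island at
#'   the end (islands with fewer residents are sampled exhaustively).
#' @param seed integer seed; the run is fully reproducible from it.
#' @return A `sim_params` list.
#' @export
simulation_params <- function(island_names,
                              founding_island = island_names[1],
                              n_generations = 150L,
                              deme_size = 60L,
                              migration_prob = 0.001,
                              mutation_rate = 2e-5,
                              seq_length = 217L,
                              samples_per_island = 13L,
                              seed = 1L) {
  if (length(island_names) < 1L || anyDuplicated(island_names))
    ih_stop("island_names must be non-empty and unique",
            "islehaps_input_error")
  if (!founding_island %in% island_names)
    ih_stop("founding_island must be one of island_names",
            "islehaps_input_error")
  for (p in list(migration_prob, mutation_rate))
    if (!is.numeric(p) || p < 0 || p > 1)
      ih_stop("probabilities must lie in [0, 1]", "islehaps_input_error")
  for (n in list(n_generations, deme_size, seq_length, samples_per_island))
    if (!is_count(n) || n < 1)
      ih_stop("counts must be positive integers", "islehaps_input_error")
  if (!is_count(seed))
    ih_stop("seed must be an integer", "islehaps_input_error")
  structure(
    list(n_islands = length(island_names),
         island_names = as.character(island_names),
         founding_island = founding_island,
         n_generations = as.integer(n_generations),
         deme_size = as.integer(deme_size),
         migration_prob = migration_prob,
         mutation_rate = mutation_rate,
         seq_length = as.integer(seq_length),
         samples_per_island = as.integer(samples_per_island),
         seed = as.integer(seed)),
    class = "sim_params")
}

#' Galapagos-like parameter preset
#'
#' Nine named islands, a 217 bp locus, and roughly 120 sampled
#' individuals, with mutation and migration rates calibrated so that a
#' typical run yields on the order of 10-15 haplotypes dominated by a few
#' widespread interior haplotypes plus single-island tips.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [simulation_params()].
#' @return A `sim_params` list.
#' @export
galapagos_params <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(island_names = GALAPAGOS_ISLANDS,
         founding_island = "Isabela",
         seed = seed),
    list(...))
  do.call(simulation_params, args)
}

# deterministic per-generation sub-seed below 2^31
sub_seed <- function(seed, g) {
  (as.numeric(seed) * 48271 + g * 16807) %% 2147483587
}

#' Simulate island colonization
#'
#' Forward Wright-Fisher simulation: each generation every occupied
#' island produces `deme_size` offspring by copying uniformly chosen
#' parents from its deme; each offspring mutates each site independently
#' with `mutation_rate` (finite sites, recurrent mutation allowed, so
#' homoplasy and network loops can arise); each offspring then emigrates
#' with `migration_prob` to a uniformly chosen other island. Every
#' inter-island move is logged; a move is flagged `novel` — a
#' colonization event — when the haplotype neither originated on the
#' destination island nor had ever been moved there before. At the end `samples_per_island` individuals
#' are drawn without replacement per occupied island.
#'
#' @param params a `sim_params` object.
#' @return A `sim_dataset` list: `alignment` (a `hap_alignment` of the
#'   sampled individuals), `metadata` (sample metadata data.frame),
#'   `event_log` (generation, source_island, dest_island, haplotype_id,
#'   novel), `genealogy` (haplotype_id, parent_id, origin_island,
#'   origin_generation, sequence: a forest rooted at the founding
#'   haplotype), and `params`.
#' @export
simulate_colonization <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  isl <- params$island_names
  L <- params$seq_length

  set.seed(params$seed)
  founder_seq <- paste(sample(UNAMBIGUOUS_BASES, L, replace = TRUE),
                       collapse = "")
  registry <- founder_seq                       # sequence per haplotype id
  genealogy <- data.frame(haplotype_id = 1L, parent_id = NA_integer_,
                          origin_island = params$founding_island,
                          origin_generation = 0L,
                          stringsAsFactors = FALSE)
  # islands where each haplotype has "been": its island of origin plus
  # every island it was ever moved to; a move into any other island is a
  # colonization event
  ever_present <- stats::setNames(
    lapply(isl, function(i) integer(0)), isl)
  ever_present[[params$founding_island]] <- 1L

  demes <- stats::setNames(lapply(isl, function(i) integer(0)), isl)
  demes[[params$founding_island]] <- rep(1L, params$deme_size)

  log_gen <- integer(0); log_src <- character(0); log_dst <- character(0)
  log_hap <- integer(0); log_novel <- logical(0)

  for (g in seq_len(params$n_generations)) {
    set.seed(sub_seed(params$seed, g))

    # reproduction + mutation, island by island in fixed name order
    children <- stats::setNames(vector("list", length(isl)), isl)
    for (i in isl) {
      deme <- demes[[i]]
      if (length(deme) == 0L) next
      kids <- deme[sample.int(length(deme), params$deme_size, replace = TRUE)]
      nmut <- stats::rbinom(params$deme_size, L, params$mutation_rate)
      for (k in which(nmut > 0L)) {
        s <- strsplit(registry[kids[k]], "")[[1]]
        sites <- sample.int(L, nmut[k])
        for (p in sites)
          s[p] <- sample(setdiff(UNAMBIGUOUS_BASES, s[p]), 1L)
        newseq <- paste(s, collapse = "")
        hid <- match(newseq, registry)
        if (is.na(hid)) {
          registry <- c(registry, newseq)
          hid <- length(registry)
          genealogy <- rbind(genealogy, data.frame(
            haplotype_id = hid, parent_id = kids[k],
            origin_island = i, origin_generation = g,
            stringsAsFactors = FALSE))
          ever_present[[i]] <- union(ever_present[[i]], hid)
        }
        kids[k] <- hid
      }
      children[[i]] <- kids
    }

    # migration: each child emigrates with migration_prob; migrants are
    # drawn from the pre-migration snapshot so nobody moves twice per
    # generation
    if (params$migration_prob > 0 && length(isl) > 1L) {
      moves_src <- character(0); moves_dst <- character(0)
      moves_hap <- integer(0)
      for (i in isl) {
        kids <- children[[i]]
        if (length(kids) == 0L) next
        mig <- stats::runif(length(kids)) < params$migration_prob
        if (!any(mig)) next
        dest <- sample(setdiff(isl, i), sum(mig), replace = TRUE)
        moves_src <- c(moves_src, rep(i, sum(mig)))
        moves_dst <- c(moves_dst, dest)
        moves_hap <- c(moves_hap, kids[mig])
        children[[i]] <- kids[!mig]
      }
      for (k in seq_along(moves_hap)) {
        novel <- !(moves_hap[k] %in% ever_present[[moves_dst[k]]])
        log_gen <- c(log_gen, g); log_src <- c(log_src, moves_src[k])
        log_dst <- c(log_dst, moves_dst[k]); log_hap <- c(log_hap, moves_hap[k])
        log_novel <- c(log_novel, novel)
        if (novel)
          ever_present[[moves_dst[k]]] <-
            c(ever_present[[moves_dst[k]]], moves_hap[k])
        children[[moves_dst[k]]] <- c(children[[moves_dst[k]]], moves_hap[k])
      }
    }
    demes <- children
    demes[vapply(demes, is.null, logical(1))] <- list(integer(0))
  }

  # final sampling, without replacement, exhaustive on small demes
  set.seed(sub_seed(params$seed, params$n_generations + 1L))
  ids <- character(0); seqs <- character(0); islands <- character(0)
  for (i in isl) {
    deme <- demes[[i]]
    if (length(deme) == 0L) next
    n <- min(params$samples_per_island, length(deme))
    take <- deme[sample.int(length(deme), n)]
    ids <- c(ids, sprintf("%s_%02d", gsub("[^A-Za-z0-9]", "", i), seq_len(n)))
    seqs <- c(seqs, registry[take])
    islands <- c(islands, rep(i, n))
  }
  alignment <- as_alignment(ids, seqs)
  metadata <- data.frame(sample_id = ids, island = islands,
                         population = islands, species = "simulated",
                         is_outgroup = FALSE, stringsAsFactors = FALSE)
  event_log <- data.frame(generation = log_gen, source_island = log_src,
                          dest_island = log_dst, haplotype_id = log_hap,
                          novel = log_novel, stringsAsFactors = FALSE)
  genealogy$sequence <- registry[genealogy$haplotype_id]
  structure(
    list(alignment = alignment, metadata = metadata, event_log = event_log,
         genealogy = genealogy, params = params),
    class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "Simulated dataset: %d samples on %d island(s), %d haplotype(s) ever arisen, %d logged move(s), %d colonization event(s)\n",
    length(x$alignment$ids), length(unique(x$metadata$island)),
    nrow(x$genealogy), nrow(x$event_log), true_event_count(x)))
  invisible(x)
}

#' True number of colonization events
#'
#' Counts the logged inter-island moves that introduced a haplotype to an
#' island where it had never been present before.
#'
#' @param ds a `sim_dataset`.
#' @return Integer event count.
#' @export
true_event_count <- function(ds) {
  stopifnot(inherits(ds, "sim_dataset"))
  sum(ds$event_log$novel)
}

#' Write a simulated dataset to disk
#'
#' Writes the alignment as FASTA, the metadata and event log as TSV, and
#' the parameters as YAML, all consumable by the io module.
#'
#' @param ds a `sim_dataset`.
#' @param dir output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulated_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    alignment = file.path(dir, "alignment.fasta"),
    metadata = file.path(dir, "metadata.tsv"),
    event_log = file.path(dir, "event_log.tsv"),
    params = file.path(dir, "params.yaml"))
  seqinr::write.fasta(as.list(ds$alignment$seqs), ds$alignment$ids,
                      paths[["alignment"]], as.string = TRUE)
  utils::write.table(ds$metadata, paths[["metadata"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ds$event_log, paths[["event_log"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(ds$params), paths[["params"]])
  invisible(paths)
}

#' Recovery experiment: inferred vs true colonization events
#'
#' Runs the full inference chain (simulate, collapse haplotypes, count
#' inferred events under every sharing rule) over a grid of migration and
#' mutation rates, with seeded replicates per cell, and summarizes how
#' the haplotype-sharing inference tracks the known truth.
#'
#' @param migration_probs numeric vector of migration probabilities.
#' @param mutation_rates numeric vector of per-site mutation rates.
#' @param replicates replicates per grid cell.
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param base_params a `sim_params` object providing all other
#'   parameters (default [galapagos_params()]).
#' @return Data.frame with one row per grid cell: mean true events, mean
#'   inferred events per rule, mean colonization success (headline rule
#'   over haplotypes x (islands - 1)), and mean haplotype count.
#'   Attribute `trend` holds the Spearman correlation between
#'   `migration_prob` and mean success.
#' @export
recovery_experiment <- function(migration_probs, mutation_rates,
                                replicates = 10L, seed = 1L,
                                base_params = galapagos_params()) {
  stopifnot(inherits(base_params, "sim_params"))
  grid <- expand.grid(migration_prob = migration_probs,
                      mutation_rate = mutation_rates,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(ci) {
    res <- vapply(seq_len(replicates), function(r) {
      p <- base_params
      p$migration_prob <- grid$migration_prob[ci]
      p$mutation_rate <- grid$mutation_rate[ci]
      p$seed <- as.integer((as.numeric(seed) * 10007 + ci * 503 + r) %%
                             2147483587)
      ds <- simulate_colonization(p)
      tab <- collapse_haplotypes(ds$alignment, ds$metadata,
                                 island_aliases = character(0))
      ev <- inferred_events(tab, "all")
      maxp <- max_potential(nrow(tab$counts), p$n_islands)
      c(true = true_event_count(ds), ev,
        success = ev[["per_haplotype_spanning"]] / maxp,
        n_haplotypes = nrow(tab$counts))
    }, numeric(6))
    m <- rowMeans(res)
    data.frame(migration_prob = grid$migration_prob[ci],
               mutation_rate = grid$mutation_rate[ci],
               replicates = replicates,
               mean_true_events = m[["true"]],
               mean_shared_count = m[["shared_count"]],
               mean_per_haplotype_spanning = m[["per_haplotype_spanning"]],
               mean_spanning_plus_components = m[["spanning_plus_components"]],
               mean_success = m[["success"]],
               mean_n_haplotypes = m[["n_haplotypes"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "trend") <-
    if (length(unique(out$migration_prob)) > 1L)
      stats::cor(out$migration_prob, out$mean_success, method = "spearman")
    else NA_real_
  out
}
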