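## Colonization metrics: chorological minimum, maximum potential events,
## inferred events from haplotype sharing, colonization success.

#' Chorological minimum number of colonization events
#'
#' The fewest inter-island colonization events consistent with presence
#' data alone: a species occupying n islands needs at least n - 1 events.
#'
#' @param n_islands_occupied number of islands where the species occurs.
#' @return `n_islands_occupied - 1`.
#' @examples
#' chorological_minimum(9)  # 8
#' @export
chorological_minimum <- function(n_islands_occupied) {
  if (!is_count(n_islands_occupied) || n_islands_occupied < 1)
    ih_stop("n_islands_occupied must be a positive integer",
            "islehaps_input_error")
  as.integer(n_islands_occupied) - 1L
}

#' Maximum number of potential colonization events
#'
#' Upper bound from genetics: each of the h haplotypes could in principle
#' have spread from its island of origin to every other of the I largest
#' archipelago islands, giving h * (I - 1) potential events.
#'
#' @param n_haplotypes number of haplotypes observed for the species.
#' @param n_archipelago_islands number of (largest) islands considered.
#' @return `n_haplotypes * (n_archipelago_islands - 1)`.
#' @examples
#' max_potential(12, 12)  # 132
#' @export
max_potential <- function(n_haplotypes, n_archipelago_islands) {
  if (!is_count(n_haplotypes) || n_haplotypes < 1)
    ih_stop("n_haplotypes must be a positive integer",
            "islehaps_input_error")
  if (!is_count(n_archipelago_islands) || n_archipelago_islands < 1)
    ih_stop("n_archipelago_islands must be a positive integer",
            "islehaps_input_error")
  as.integer(n_haplotypes) * (as.integer(n_archipelago_islands) - 1L)
}

INFERRED_RULES <- c("shared_count", "per_haplotype_spanning",
                    "spanning_plus_components")

#' Inferred colonization events from haplotype sharing
#'
#' A haplotype sampled on two or more islands is molecular evidence of
#' inter-island movement, under the assumption that every haplotype
#' originated by mutation on a single island. Three counting rules are
#' implemented and always reported together, since they answer slightly
#' different questions:
#' \describe{
#'   \item{`shared_count`}{number of haplotypes present on >= 2 islands
#'     (the coarsest reading: one event per travelled haplotype).}
#'   \item{`per_haplotype_spanning`}{sum over haplotypes on k >= 2 islands
#'     of (k - 1): the minimum number of arrivals beyond each haplotype's
#'     single island of origin. This is the headline rule.}
#'   \item{`spanning_plus_components`}{`per_haplotype_spanning` plus
#'     (C - 1), where C is the number of connected components of the
#'     island graph whose edges join islands sharing a haplotype; the
#'     extra term counts the events needed to connect island groups that
#'     share no haplotype at all.}
#' }
#'
#' @param table a `hap_table` (sequences not required).
#' @param rule one of `"shared_count"`, `"per_haplotype_spanning"`,
#'   `"spanning_plus_components"`, or `"all"` (default) for a named
#'   vector of all three.
#' @return Integer event count, or a named integer vector when
#'   `rule = "all"`.
#' @export
inferred_events <- function(table, rule = c("all", INFERRED_RULES)) {
  stopifnot(inherits(table, "hap_table"))
  rule <- match.arg(rule)
  if (nrow(table$counts) == 0L)
    ih_stop("empty haplotype table", "islehaps_input_error")
  sets <- island_sets(table)
  k <- lengths(sets)

  shared_count <- sum(k >= 2L)
  per_hap <- sum(pmax(k - 1L, 0L)[k >= 2L])

  # island graph: islands are vertices, shared haplotypes its edges
  occupied <- colnames(table$counts)[colSums(table$counts) > 0L]
  edges <- do.call(rbind, lapply(sets[k >= 2L], function(s)
    t(utils::combn(s, 2L))))
  g <- igraph::graph_from_data_frame(
    if (is.null(edges)) data.frame(from = character(0), to = character(0))
    else data.frame(from = edges[, 1], to = edges[, 2]),
    directed = FALSE, vertices = data.frame(name = occupied))
  n_comp <- igraph::components(g)$no
  spanning_plus <- per_hap + (n_comp - 1L)

  out <- c(shared_count = as.integer(shared_count),
           per_haplotype_spanning = as.integer(per_hap),
           spanning_plus_components = as.integer(spanning_plus))
  if (rule == "all") out else unname(out[rule])
}

#' Colonization success
#'
#' Ratio of inferred to maximum potential colonization events; ranges
#' from 0 (no inter-island colonization detected) to 1 (every haplotype
#' on every island).
#'
#' @param inferred inferred number of colonization events.
#' @param max_potential maximum number of potential events (>= 1).
#' @return List with `ratio` (full precision) and `rounded` (half-up to
#'   3 decimals).
#' @examples
#' colonization_success(11, 33)$rounded  # 0.333
#' @export
colonization_success <- function(inferred, max_potential) {
  if (!is.numeric(inferred) || length(inferred) != 1L || inferred < 0)
    ih_stop("inferred must be a non-negative number", "islehaps_input_error")
  if (!is_count(max_potential) || max_potential < 1)
    ih_stop("max_potential must be a positive integer (ratio undefined at 0)",
            "islehaps_undefined_ratio_error")
  ratio <- inferred / max_potential
  list(ratio = ratio, rounded = round_half_up(ratio, 3))
}

#' Cross-species colonization report
#'
#' Computes the four colonization metrics for each species record and
#' assembles a comparison table sorted by colonization success (high to
#' low). A record supplies either an externally published
#' `inferred_events` count (rule reported as `"external"`) or a
#' `hap_table` in `sharing`, from which all three sharing rules are
#' computed and the `headline_rule` used for the success column.
#'
#' @param records list of records; each a list with fields `species`,
#'   `n_islands_occupied`, `n_archipelago_islands`, `n_haplotypes`, and
#'   either `inferred_events` (count) or `sharing` (a `hap_table`).
#'   Optional `archipelago`.
#' @param headline_rule sharing rule used for the success column when a
#'   record carries a `hap_table`; default `"per_haplotype_spanning"`.
#' @return Data.frame with one row per species: occupancy and haplotype
#'   counts, `chorological_min`, `max_potential`, `inferred_events`,
#'   `rule`, `success` (3-decimal), `success_full`, plus the per-rule
#'   columns for records computed from sharing; sorted by success
#'   descending, species name ascending.
#' @export
species_report <- function(records,
                           headline_rule = "per_haplotype_spanning") {
  stopifnot(headline_rule %in% INFERRED_RULES)
  if (length(records) == 0L) {
    return(data.frame(species = character(0), archipelago = character(0),
                      n_islands_occupied = integer(0),
                      n_archipelago_islands = integer(0),
                      n_haplotypes = integer(0),
                      chorological_min = integer(0),
                      max_potential = integer(0),
                      inferred_events = integer(0),
                      rule = character(0),
                      success = numeric(0), success_full = numeric(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(records, function(rec) {
    for (f in c("species", "n_islands_occupied", "n_archipelago_islands",
                "n_haplotypes"))
      if (is.null(rec[[f]]))
        ih_stop(sprintf("record '%s' is missing field '%s'",
                        if (is.null(rec$species)) "<unnamed>" else rec$species,
                        f),
                "islehaps_validation_error")
    if (rec$n_islands_occupied < 1 ||
        rec$n_islands_occupied > rec$n_archipelago_islands)
      ih_stop(sprintf(
        "record '%s': islands occupied (%d) outside 1..%d",
        rec$species, rec$n_islands_occupied, rec$n_archipelago_islands),
        "islehaps_validation_error")
    maxp <- max_potential(rec$n_haplotypes, rec$n_archipelago_islands)
    if (!is.null(rec$sharing)) {
      tab <- rec$sharing
      stopifnot(inherits(tab, "hap_table"))
      sets <- island_sets(tab)
      if (length(Reduce(union, sets)) != rec$n_islands_occupied)
        ih_stop(sprintf(
          "record '%s': sharing islands do not match n_islands_occupied",
          rec$species), "islehaps_validation_error")
      ev <- inferred_events(tab, "all")
      inferred <- ev[[headline_rule]]
      rule <- headline_rule
    } else if (!is.null(rec$inferred_events)) {
      ev <- c(shared_count = NA_integer_,
              per_haplotype_spanning = NA_integer_,
              spanning_plus_components = NA_integer_)
      inferred <- rec$inferred_events
      rule <- "external"
    } else {
      ih_stop(sprintf(
        "record '%s' needs either 'sharing' or 'inferred_events'",
        rec$species), "islehaps_validation_error")
    }
    if (inferred > maxp)
      ih_stop(sprintf("record '%s': inferred events (%d) exceed maximum (%d)",
                      rec$species, inferred, maxp),
              "islehaps_validation_error")
    succ <- colonization_success(inferred, maxp)
    data.frame(species = rec$species,
               archipelago = if (is.null(rec$archipelago)) NA_character_
                             else rec$archipelago,
               n_islands_occupied = as.integer(rec$n_islands_occupied),
               n_archipelago_islands = as.integer(rec$n_archipelago_islands),
               n_haplotypes = as.integer(rec$n_haplotypes),
               chorological_min = chorological_minimum(rec$n_islands_occupied),
               max_potential = maxp,
               inferred_events = as.integer(inferred),
               rule = rule,
               shared_count = ev[["shared_count"]],
               per_haplotype_spanning = ev[["per_haplotype_spanning"]],
               spanning_plus_components = ev[["spanning_plus_components"]],
               success = succ$rounded,
               success_full = succ$ratio,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  report <- report[order(-report$success_full, report$species), ]
  rownames(report) <- NULL
  report
}

#' Read a species summary table
#'
#' Reads a TSV with columns `species`, `archipelago`,
#' `n_islands_occupied`, `n_archipelago_islands`, `n_haplotypes`,
#' `inferred_events` into the record list consumed by [species_report()].
#'
#' @param path path to a TSV file.
#' @return List of species records.
#' @export
read_species_summary <- function(path) {
  if (!file.exists(path))
    ih_stop(sprintf("species summary not found: %s", path),
            "islehaps_input_error")
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  required <- c("species", "n_islands_occupied", "n_archipelago_islands",
                "n_haplotypes", "inferred_events")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    ih_stop(sprintf("species summary is missing columns: %s",
                    paste(missing_cols, collapse = ", ")),
            "islehaps_input_error")
  lapply(seq_len(nrow(df)), function(i) {
    rec <- as.list(df[i, ])
    rec[!vapply(rec, function(v) is.na(v) || identical(v, ""), logical(1))]
  })
}

#' Write a species report as TSV, JSON or Markdown
#'
#' @param report data.frame from [species_report()].
#' @param path output path.
#' @param format `"tsv"`, `"json"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_species_report <- function(report, path,
                                 format = c("tsv", "json", "markdown")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(report, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "json") {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else {
    cols <- c("species", "archipelago", "n_islands_occupied",
              "n_archipelago_islands", "n_haplotypes", "chorological_min",
              "max_potential", "inferred_events", "rule", "success")
    hdr <- paste0("| ", paste(cols, collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", length(cols)), collapse = "|"), "|")
    body <- apply(report[cols], 1L, function(r)
      paste0("| ", paste(r, collapse = " | "), " |"))
    writeLines(c(hdr, sep, body), path)
  }
  invisible(path)
}
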