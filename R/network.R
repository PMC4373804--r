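## Parsimony haplotype network: single-substitution edges, inferred
## intermediates on multi-step connections, loop (homoplasy) flags.

#' Pairwise substitution distances between haplotypes
#'
#' Hamming distance over aligned haplotype sequences, counting a mismatch
#' only where both sequences carry an unambiguous base (A/C/G/T); sites
#' with gaps, N or IUPAC codes in either sequence are skipped.
#'
#' @param table a `hap_table` carrying sequences.
#' @return Symmetric integer matrix with zero diagonal, dimnames =
#'   haplotype ids.
#' @export
pairwise_distances <- function(table) {
  stopifnot(inherits(table, "hap_table"))
  if (!has_sequences(table))
    ih_stop("haplotype table is sequence-free; distances are unavailable",
            "islehaps_unsupported_error")
  ids <- table$haplotypes$haplotype_id
  chars <- lapply(table$haplotypes$sequence, function(s) strsplit(s, "")[[1]])
  lens <- lengths(chars)
  if (length(unique(lens)) != 1L)
    ih_stop("haplotype sequences have unequal lengths",
            "islehaps_alignment_error")
  n <- length(ids)
  d <- matrix(0L, n, n, dimnames = list(ids, ids))
  unamb <- lapply(chars, function(s) s %in% UNAMBIGUOUS_BASES)
  for (i in seq_len(n)) {
    for (j in seq_len(n)[-seq_len(i)]) {
      ok <- unamb[[i]] & unamb[[j]]
      d[i, j] <- d[j, i] <- sum(chars[[i]][ok] != chars[[j]][ok])
    }
  }
  d
}

#' Build a parsimony haplotype network
#'
#' Minimum-spanning-network construction over observed haplotypes.
#' Candidate pairs are sorted by substitution distance (ties broken by the
#' lexicographic haplotype-id pair). Processing distances in ascending
#' order, a pair is retained when its two haplotypes lie in components
#' that were still separate before the current distance level; all
#' equal-distance alternatives between the same pair of components are
#' retained, so mutational ambiguity shows up as loops rather than being
#' arbitrarily resolved. Each retained k-step connection is expanded into
#' a path through k - 1 inferred intermediate nodes (`m1`, `m2`, ... in
#' creation order) representing unobserved haplotypes; intermediates
#' carry no sequence.
#'
#' @param table a `hap_table` carrying sequences.
#' @param max_steps maximum substitution distance a connection may span;
#'   `Inf` (default) connects everything, appropriate for single-species
#'   data sets whose network is fully connected.
#' @return An object of class `hap_network`: `nodes` (data.frame with
#'   `node_id`, `type` = observed/inferred, `on_cycle`), `edges`
#'   (single-substitution edges after intermediate expansion),
#'   `connections` (retained observed-haplotype pairs with their step
#'   counts), `graph` (the expanded igraph object) and `max_steps`.
#' @export
build_network <- function(table, max_steps = Inf) {
  stopifnot(inherits(table, "hap_table"))
  if (nrow(table$haplotypes) == 0L)
    ih_stop("empty haplotype table", "islehaps_input_error")
  d <- pairwise_distances(table)
  ids <- sort(rownames(d))

  # candidate pairs, sorted by (distance, id pair)
  pairs <- data.frame(from = character(0), to = character(0),
                      steps = integer(0), stringsAsFactors = FALSE)
  if (length(ids) > 1L) {
    idx <- t(utils::combn(ids, 2L))
    pairs <- data.frame(from = idx[, 1], to = idx[, 2],
                        steps = d[idx], stringsAsFactors = FALSE)
    pairs <- pairs[pairs$steps <= max_steps & pairs$steps > 0L, , drop = FALSE]
    pairs <- pairs[order(pairs$steps, pairs$from, pairs$to), , drop = FALSE]
  }

  # union-find over observed haplotypes
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }

  retained <- pairs[0, , drop = FALSE]
  if (nrow(pairs)) for (lvl in unique(pairs$steps)) {
    lv <- pairs[pairs$steps == lvl, , drop = FALSE]
    # component membership frozen at the start of the level, so that all
    # tied minimal connections between two components are kept (-> loops)
    snap <- vapply(ids, find, character(1))
    add <- snap[lv$from] != snap[lv$to]
    if (any(add)) {
      retained <- rbind(retained, lv[add, , drop = FALSE])
      for (k in which(add)) parent[[find(lv$from[k])]] <- find(lv$to[k])
    }
  }

  # expand multi-step connections into paths of inferred intermediates
  edges <- data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE)
  n_inferred <- 0L
  if (nrow(retained)) {
    for (k in seq_len(nrow(retained))) {
      steps <- retained$steps[k]
      if (steps == 1L) {
        path <- c(retained$from[k], retained$to[k])
      } else {
        mids <- paste0("m", n_inferred + seq_len(steps - 1L))
        n_inferred <- n_inferred + steps - 1L
        path <- c(retained$from[k], mids, retained$to[k])
      }
      edges <- rbind(edges, data.frame(from = path[-length(path)],
                                       to = path[-1],
                                       stringsAsFactors = FALSE))
    }
  }
  node_ids <- c(ids, if (n_inferred) paste0("m", seq_len(n_inferred)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = node_ids))

  on_cycle <- rep(FALSE, length(node_ids))
  names(on_cycle) <- node_ids
  if (igraph::ecount(g) > 0L) {
    bic <- igraph::biconnected_components(g)
    for (comp in bic$components) {
      if (length(comp) >= 3L)
        on_cycle[names(comp)] <- TRUE
    }
  }
  nodes <- data.frame(
    node_id = node_ids,
    type = ifelse(node_ids %in% ids, "observed", "inferred"),
    on_cycle = unname(on_cycle),
    stringsAsFactors = FALSE
  )
  structure(
    list(nodes = nodes, edges = edges, connections = retained,
         graph = g, max_steps = max_steps),
    class = "hap_network"
  )
}

#' @export
print.hap_network <- function(x, ...) {
  cat(sprintf(
    "Haplotype network: %d observed + %d inferred nodes, %d single-step edges, %d connection(s)\n",
    sum(x$nodes$type == "observed"), sum(x$nodes$type == "inferred"),
    nrow(x$edges), nrow(x$connections)))
  if (any(x$nodes$on_cycle))
    cat(sprintf("  loops present (homoplasy): %d node(s) on cycles\n",
                sum(x$nodes$on_cycle)))
  invisible(x)
}

#' Classify haplotypes as tip, interior or isolated
#'
#' Node degree in the expanded network (edges toward both observed and
#' inferred neighbours): degree 0 = isolated, 1 = tip, >= 2 = interior.
#' Under coalescent expectations interior haplotypes are older than tips.
#'
#' @param net a `hap_network`.
#' @return Named character vector over observed haplotypes with values
#'   `"tip"`, `"interior"` or `"isolated"`.
#' @export
classify_nodes <- function(net) {
  stopifnot(inherits(net, "hap_network"))
  obs <- net$nodes$node_id[net$nodes$type == "observed"]
  deg <- igraph::degree(net$graph, v = obs)
  stats::setNames(
    ifelse(deg == 0L, "isolated", ifelse(deg == 1L, "tip", "interior")),
    obs)
}

#' Partition observed haplotypes into lineages
#'
#' With `cut = NULL` the lineages are the connected components of the
#' network. An explicit cut severs the listed connections (observed
#' haplotype pairs, including their inferred intermediates) before
#' computing components, e.g. to split a network into geographic lineage
#' groups.
#'
#' @param net a `hap_network`.
#' @param cut NULL, or a two-column data.frame/matrix of observed
#'   haplotype pairs matching rows of `net$connections` (order within a
#'   pair is ignored).
#' @return List of character vectors, each the observed haplotype ids of
#'   one lineage.
#' @export
lineages <- function(net, cut = NULL) {
  stopifnot(inherits(net, "hap_network"))
  g <- net$graph
  if (!is.null(cut)) {
    cut <- as.data.frame(cut, stringsAsFactors = FALSE)
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    conn_keys <- key(net$connections$from, net$connections$to)
    cut_keys <- key(as.character(cut[[1]]), as.character(cut[[2]]))
    miss <- setdiff(cut_keys, conn_keys)
    if (length(miss))
      ih_stop(sprintf("cut connection(s) not in network: %s",
                      paste(miss, collapse = "; ")),
              "islehaps_input_error")
    # rebuild the expanded edge set without the severed connections
    keep <- !(conn_keys %in% cut_keys)
    sub <- net$connections[keep, , drop = FALSE]
    obs <- net$nodes$node_id[net$nodes$type == "observed"]
    edges <- data.frame(from = character(0), to = character(0))
    mcount <- 0L
    if (nrow(sub)) for (k in seq_len(nrow(sub))) {
      steps <- sub$steps[k]
      mids <- if (steps > 1L) paste0("c", mcount + seq_len(steps - 1L))
      mcount <- mcount + max(0L, steps - 1L)
      path <- c(sub$from[k], mids, sub$to[k])
      edges <- rbind(edges, data.frame(from = path[-length(path)],
                                       to = path[-1]))
    }
    g <- igraph::graph_from_data_frame(
      edges, directed = FALSE,
      vertices = data.frame(name = unique(c(obs, edges$from, edges$to))))
  }
  memb <- igraph::components(g)$membership
  obs <- net$nodes$node_id[net$nodes$type == "observed"]
  split(obs, memb[obs])
}

#' Rank haplotypes by coalescent ancestrality criteria
#'
#' Orders haplotypes by three signals of ancestrality, compared
#' lexicographically: (i) fewest substitution steps to the nearest
#' outgroup haplotype (raw pairwise distance, so it is defined even when
#' the outgroup exceeds the network connection limit); (ii) highest
#' number of network connections to other observed ingroup haplotypes;
#' (iii) widest
#' geographic spread (islands occupied, then sample count). Remaining
#' ties are broken by haplotype id and flagged.
#'
#' @param net a `hap_network` built from `table`.
#' @param table the `hap_table` the network was built from (provides
#'   sequences, island counts and outgroup flags).
#' @param outgroup_ids haplotype ids to treat as the outgroup; defaults to
#'   the table's `is_outgroup` haplotypes. With no outgroup the report is
#'   computed without the steps criterion and flagged `"no-outgroup"`.
#' @return Data.frame (one row per non-outgroup haplotype, rank 1 = most
#'   ancestral) with columns `haplotype_id`, `steps_to_outgroup`,
#'   `degree`, `n_islands`, `n_samples`, `rank`, `tied`; attribute
#'   `mode` is `"outgroup"` or `"no-outgroup"`.
#' @export
ancestrality_rank <- function(net, table, outgroup_ids = NULL) {
  stopifnot(inherits(net, "hap_network"), inherits(table, "hap_table"))
  if (is.null(outgroup_ids))
    outgroup_ids <- table$haplotypes$haplotype_id[table$haplotypes$is_outgroup]
  ingroup <- setdiff(net$nodes$node_id[net$nodes$type == "observed"],
                     outgroup_ids)

  if (length(outgroup_ids)) {
    d <- pairwise_distances(table)
    if (!all(outgroup_ids %in% rownames(d)))
      ih_stop("outgroup haplotype(s) missing from the table",
              "islehaps_input_error")
    steps <- apply(d[ingroup, outgroup_ids, drop = FALSE], 1L, min)
    mode <- "outgroup"
  } else {
    steps <- stats::setNames(rep(NA_integer_, length(ingroup)), ingroup)
    mode <- "no-outgroup"
  }

  # degree counts connections toward other observed ingroup haplotypes;
  # the outgroup attachment is already captured by steps_to_outgroup
  conn <- net$connections
  conn <- conn[!(conn$from %in% outgroup_ids) &
                 !(conn$to %in% outgroup_ids), , drop = FALSE]
  degree <- vapply(ingroup, function(h)
    sum(conn$from == h | conn$to == h), integer(1))

  idx <- match(ingroup, rownames(table$counts))
  n_islands <- ifelse(is.na(idx), 0L,
                      rowSums(table$counts > 0L)[idx])
  n_samples <- ifelse(is.na(idx), 0L, rowSums(table$counts)[idx])

  key_steps <- if (mode == "outgroup") steps else rep(0L, length(ingroup))
  ord <- order(key_steps, -degree, -n_islands, -n_samples, ingroup)
  report <- data.frame(
    haplotype_id = ingroup[ord],
    steps_to_outgroup = unname(steps[ord]),
    degree = unname(degree[ord]),
    n_islands = unname(n_islands[ord]),
    n_samples = unname(n_samples[ord]),
    rank = seq_along(ingroup),
    stringsAsFactors = FALSE
  )
  key <- paste(report$steps_to_outgroup, report$degree,
               report$n_islands, report$n_samples)
  report$tied <- key %in% key[duplicated(key)]
  attr(report, "mode") <- mode
  report
}

#' Export the expanded network as an edge list
#'
#' Writes one TSV row per single-substitution edge with columns
#' `node_a`, `node_b`, `inferred_a`, `inferred_b` (whether each endpoint
#' is an inferred intermediate).
#'
#' @param net a `hap_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_edgelist <- function(net, path) {
  stopifnot(inherits(net, "hap_network"))
  inferred <- net$nodes$node_id[net$nodes$type == "inferred"]
  df <- data.frame(node_a = net$edges$from, node_b = net$edges$to,
                   inferred_a = net$edges$from %in% inferred,
                   inferred_b = net$edges$to %in% inferred)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export the expanded network as GraphML
#'
#' @param net a `hap_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  stopifnot(inherits(net, "hap_network"))
  g <- net$graph
  igraph::V(g)$type <- net$nodes$type[match(igraph::V(g)$name,
                                            net$nodes$node_id)]
  igraph::V(g)$on_cycle <- net$nodes$on_cycle[match(igraph::V(g)$name,
                                                    net$nodes$node_id)]
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
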