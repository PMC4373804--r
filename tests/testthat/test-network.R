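test_that("pairwise distances match a brute-force positional count", {
  tab <- table_from_sequences(c("ACGT", "ACGT", "ACGA"),
                              islands = c("A", "B", "C"))
  d <- pairwise_distances(tab)
  expect_equal(unname(diag(d)), c(0L, 0L))
  expect_equal(d["h1", "h2"], 1L, ignore_attr = TRUE)
  expect_true(isSymmetric(d))

  set.seed(11)
  seqs <- random_sequences(8, 30)
  tab2 <- table_from_sequences(seqs)
  d2 <- pairwise_distances(tab2)
  for (i in 1:8) for (j in 1:8) {
    si <- tab2$haplotypes$sequence[tab2$haplotypes$haplotype_id ==
                                     rownames(d2)[i]]
    sj <- tab2$haplotypes$sequence[tab2$haplotypes$haplotype_id ==
                                     rownames(d2)[j]]
    expect_equal(d2[i, j], oracle_hamming(si, sj), ignore_attr = TRUE)
  }

  # ambiguous sites are skipped, not counted: distance ACNT vs ACGA is 1
  tab3 <- table_from_sequences(c("ACTT", "ACGA"), islands = c("A", "B"))
  tab3$haplotypes$sequence[1] <- "ACNT"
  expect_equal(pairwise_distances(tab3)["h1", "h2"], 1L, ignore_attr = TRUE)
  expect_equal(oracle_hamming("ACNT", "ACGA"), 1L)
})

test_that("build_network handles the canonical small cases", {
  # two haplotypes one step apart: single edge, no intermediates
  t1 <- table_from_sequences(c("AAAA", "AAAT"), islands = c("A", "B"))
  n1 <- build_network(t1)
  expect_equal(nrow(n1$edges), 1L)
  expect_equal(sum(n1$nodes$type == "inferred"), 0L)

  # distance three: path through two inferred missing haplotypes
  t2 <- table_from_sequences(c("AAAA", "ATTT"), islands = c("A", "B"))
  n2 <- build_network(t2)
  expect_equal(sum(n2$nodes$type == "inferred"), 2L)
  expect_equal(nrow(n2$edges), 3L)
  expect_equal(n2$connections$steps, 3L)

  # path A-B-C: shortcut A-C at distance 2 must not be added
  t3 <- table_from_sequences(c("AAAA", "AAAT", "AATT"),
                             islands = c("A", "B", "C"))
  n3 <- build_network(t3)
  expect_setequal(conn_key(n3$connections$from, n3$connections$to),
                  c("h1 h2", "h2 h3"))
  cls <- classify_nodes(n3)
  expect_equal(unname(cls[c("h1", "h3")]), c("tip", "tip"))
  expect_equal(unname(cls["h2"]), "interior")
})

test_that("network equals the brute-force minimal-network oracle on random sets", {
  set.seed(23)
  for (rep in 1:40) {
    n <- sample(2:6, 1)
    len <- sample(6:12, 1)
    # cluster sequences around a seed haplotype so small distances occur
    base <- random_sequences(1, len)
    seqs <- unique(c(base, vapply(seq_len(n - 1), function(i) {
      s <- strsplit(base, "")[[1]]
      k <- sample(1:3, 1)
      pos <- sample(len, k)
      for (p in pos) s[p] <- sample(c("A", "C", "G", "T"), 1)
      paste(s, collapse = "")
    }, character(1))))
    tab <- table_from_sequences(seqs)
    max_steps <- sample(c(2, 3, Inf), 1)
    net <- build_network(tab, max_steps = max_steps)
    d <- pairwise_distances(tab)
    want <- oracle_msn_connections(d, max_steps)
    expect_setequal(conn_key(net$connections$from, net$connections$to),
                    conn_key(want$from, want$to))
    # step counts agree too
    got <- net$connections[order(conn_key(net$connections$from,
                                          net$connections$to)), ]
    want <- want[order(conn_key(want$from, want$to)), ]
    expect_equal(got$steps, want$steps, ignore_attr = TRUE)
  }
})

test_that("network structure invariants hold", {
  set.seed(37)
  for (rep in 1:15) {
    seqs <- unique(random_sequences(sample(3:6, 1), 8))
    tab <- table_from_sequences(seqs)
    net <- build_network(tab)
    n_obs <- sum(net$nodes$type == "observed")

    # unlimited steps -> connected, >= n-1 endpoint connections
    comp <- lineages(net)
    expect_length(comp, 1L)
    expect_gte(nrow(net$connections), n_obs - 1L)
    # tree case: exactly n-1 connections iff no node sits on a cycle
    if (!any(net$nodes$on_cycle))
      expect_equal(nrow(net$connections), n_obs - 1L)

    # inferred intermediates = sum(steps - 1) over connections
    expect_equal(sum(net$nodes$type == "inferred"),
                 sum(net$connections$steps - 1L))

    # loop flag vs brute-force cycle search on the expanded graph
    for (v in net$nodes$node_id)
      expect_equal(net$nodes$on_cycle[net$nodes$node_id == v],
                   oracle_on_cycle(v, net$edges),
                   info = paste("node", v, "rep", rep))
  }
})

test_that("network output does not depend on input haplotype order", {
  set.seed(41)
  seqs <- unique(random_sequences(6, 10))
  islands <- paste0("isl", seq_along(seqs))
  tab <- table_from_sequences(seqs, islands = islands)
  net <- build_network(tab)
  # permute input sample order; haplotype labels may change, so compare
  # connection sets through sequences
  perm <- sample(length(seqs))
  tab_p <- table_from_sequences(seqs[perm], islands = islands[perm])
  net_p <- build_network(tab_p)
  seq_of <- function(t) stats::setNames(t$haplotypes$sequence,
                                        t$haplotypes$haplotype_id)
  key <- function(net, t) {
    s <- seq_of(t)
    sort(conn_key(s[net$connections$from], s[net$connections$to]))
  }
  expect_equal(key(net, tab), key(net_p, tab_p))
})

test_that("ties at equal distance are retained as loops and flagged", {
  # four haplotypes on a square: AA, AT, TA, TT with the diagonal absent
  tab <- table_from_sequences(c("AACC", "ATCC", "TACC", "TTCC"))
  net <- build_network(tab)
  # h2-h3 distance 2 ties through both h1 and h4: all four unit edges kept
  expect_equal(nrow(net$connections), 4L)
  expect_true(all(net$nodes$on_cycle))
  cls <- classify_nodes(net)
  expect_true(all(cls == "interior"))
})

test_that("classify_nodes covers star, isolate and mixed topologies", {
  # star: centre AAAA with 6 single-step neighbours
  centre <- "AAAAAAAA"
  leaves <- vapply(1:6, function(i) {
    s <- strsplit(centre, "")[[1]]; s[i] <- "T"; paste(s, collapse = "")
  }, character(1))
  tab <- table_from_sequences(c(centre, leaves))
  net <- build_network(tab)
  cls <- classify_nodes(net)
  expect_equal(sum(cls == "interior"), 1L)
  expect_equal(sum(cls == "tip"), 6L)
  expect_equal(names(cls)[cls == "interior"], "h1")

  # single haplotype -> isolated
  t1 <- table_from_sequences("ACGT")
  expect_equal(unname(classify_nodes(build_network(t1))), "isolated")

  # disconnected pair under max_steps: both isolated
  t2 <- table_from_sequences(c("AAAAAA", "TTTTAA"))
  n2 <- build_network(t2, max_steps = 2)
  expect_equal(unname(classify_nodes(n2)), c("isolated", "isolated"))
  expect_length(lineages(n2), 2L)
})

test_that("lineages partition components and honour explicit cuts", {
  # two disconnected pairs
  t1 <- table_from_sequences(c("AAAAAAAA", "AAAAAAAT",
                               "TTTTTTTT", "TTTTTTTA"))
  n1 <- build_network(t1, max_steps = 3)
  expect_length(lineages(n1), 2L)

  # path of 8, cut the middle connection -> lineages of 4 + 4
  seqs <- vapply(0:7, function(k)
    paste(c(rep("T", k), rep("A", 8 - k)), collapse = ""), character(1))
  t2 <- table_from_sequences(seqs)
  n2 <- build_network(t2)
  expect_length(lineages(n2), 1L)
  mid <- data.frame(from = "h4", to = "h5")
  parts <- lineages(n2, cut = mid)
  expect_equal(sort(unname(lengths(parts))), c(4L, 4L))

  # cutting a connection not in the network errors
  expect_error(lineages(n2, cut = data.frame(from = "h1", to = "h8")),
               class = "islehaps_input_error")
})

test_that("ancestrality ranking prefers few outgroup steps, high degree, wide range", {
  # dominated winner: centre 3 steps from the outgroup, degree 6, on six
  # islands with 53 of 118 samples; all competitors worse on every key
  centre <- strrep("A", 20)
  leaves <- vapply(1:6, function(i) {
    s <- strsplit(centre, "")[[1]]; s[i] <- "C"; paste(s, collapse = "")
  }, character(1))
  og <- paste0(strrep("T", 3), strrep("A", 17))  # 3 steps from centre

  islands <- c("Mainland",
               "I1", "I2", "I3", "I4", "I5", "I6",  # centre everywhere
               paste0("I", 1:6))                    # one leaf each
  seqs <- c(og, rep(centre, 6), leaves)
  counts <- c(1, c(48, 1, 1, 1, 1, 1), rep(1, 6))
  ids <- sprintf("s%02d", seq_along(seqs))
  expanded_ids <- unlist(mapply(function(id, n) paste0(id, "_", seq_len(n)),
                                ids, counts, SIMPLIFY = FALSE))
  expanded_seqs <- rep(seqs, counts)
  expanded_isl <- rep(islands, counts)
  tab <- table_from_sequences(expanded_seqs, islands = expanded_isl,
                              ids = expanded_ids,
                              outgroup = rep(c(TRUE, FALSE),
                                             c(1, length(expanded_ids) - 1)))
  net <- build_network(tab)
  rep_ <- ancestrality_rank(net, tab)
  expect_equal(attr(rep_, "mode"), "outgroup")
  top <- rep_[rep_$rank == 1, ]
  expect_equal(top$degree, 6L)
  expect_equal(top$n_islands, 6L)
  expect_equal(top$steps_to_outgroup, 3L)
  expect_false(top$tied)
  centre_id <- tab$haplotypes$haplotype_id[tab$haplotypes$sequence == centre]
  expect_equal(top$haplotype_id, centre_id)

  # identical-profile haplotypes tie, broken by id and flagged
  t2 <- table_from_sequences(c("AAAA", "AAAT", "AATA"),
                             islands = c("A", "B", "C"))
  n2 <- build_network(t2)
  r2 <- ancestrality_rank(n2, t2)
  expect_equal(attr(r2, "mode"), "no-outgroup")
  tips <- r2[r2$haplotype_id %in% c("h2", "h3"), ]
  expect_true(all(tips$tied))
  expect_equal(tips$haplotype_id[order(tips$rank)], c("h2", "h3"))

  # single haplotype ranks 1 trivially
  t3 <- table_from_sequences("ACGT")
  r3 <- ancestrality_rank(build_network(t3), t3)
  expect_equal(r3$rank, 1L)
})

test_that("low-mutation simulator runs recover the true mutation genealogy", {
  # low rate: substitutions hit unique sites, distances are additive
  # along the genealogy, and the network must be the true tree
  p <- simulation_params(island_names = paste0("isl", 1:4),
                         n_generations = 60L, deme_size = 40L,
                         migration_prob = 0.01, mutation_rate = 8e-6,
                         seq_length = 500L, samples_per_island = 10L,
                         seed = 8L)
  ds <- simulate_colonization(p)
  tab <- collapse_haplotypes(ds$alignment, ds$metadata,
                             island_aliases = character(0))
  gen <- ds$genealogy

  # precondition for additivity: every mutation on the genealogy hit a
  # fresh site (distance to parent == 1 for all derived haplotypes)
  seq_by_id <- stats::setNames(gen$sequence, gen$haplotype_id)
  derived <- gen[!is.na(gen$parent_id), ]
  expect_true(all(vapply(seq_len(nrow(derived)), function(i)
    oracle_hamming(seq_by_id[[as.character(derived$haplotype_id[i])]],
                   seq_by_id[[as.character(derived$parent_id[i])]]) == 1L,
    logical(1))))

  net <- build_network(tab)
  expect_false(any(net$nodes$on_cycle))
  n_obs <- nrow(tab$haplotypes)
  expect_equal(nrow(net$connections), n_obs - 1L)

  # oracle: contract unsampled haplotypes out of the recorded genealogy;
  # sampled pairs are adjacent iff their genealogy path avoids every
  # other sampled haplotype, with steps = path length
  sampled_gid <- gen$haplotype_id[match(tab$haplotypes$sequence,
                                        gen$sequence)]
  parent <- stats::setNames(gen$parent_id, gen$haplotype_id)
  path_to_root <- function(h) {
    out <- h
    while (!is.na(parent[[as.character(h)]])) {
      h <- parent[[as.character(h)]]
      out <- c(out, h)
    }
    out
  }
  gpath <- function(a, b) {
    pa <- path_to_root(a); pb <- path_to_root(b)
    anc <- intersect(pa, pb)[1]
    c(pa[seq_len(which(pa == anc))], rev(pb[seq_len(which(pb == anc) - 1)]))
  }
  want <- character(0); want_steps <- integer(0)
  for (i in seq_along(sampled_gid)) for (j in seq_along(sampled_gid)) {
    if (j <= i) next
    pth <- gpath(sampled_gid[i], sampled_gid[j])
    if (!any(pth[-c(1, length(pth))] %in% sampled_gid)) {
      hi <- tab$haplotypes$haplotype_id[i]
      hj <- tab$haplotypes$haplotype_id[j]
      want <- c(want, conn_key(hi, hj))
      want_steps <- c(want_steps, length(pth) - 1L)
    }
  }
  got_key <- conn_key(net$connections$from, net$connections$to)
  expect_setequal(got_key, want)
  expect_equal(net$connections$steps[match(want, got_key)], want_steps)
})

test_that("network exports write edge lists and GraphML", {
  tab <- table_from_sequences(c("AAAA", "AAAT", "ATTT"),
                              islands = c("A", "B", "C"))
  net <- build_network(tab)
  el <- withr::local_tempfile(fileext = ".tsv")
  write_network_edgelist(net, el)
  df <- read.delim(el)
  expect_equal(names(df), c("node_a", "node_b", "inferred_a", "inferred_b"))
  expect_equal(nrow(df), nrow(net$edges))
  expect_true(any(df$inferred_b | df$inferred_a))

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
})
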