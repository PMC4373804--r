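# Independent brute-force oracles and small fixture builders.
# Everything here is deliberately naive and self-contained so it checks
# the package implementation from a different route.

random_sequences <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# position-by-position mismatch count over unambiguous bases
oracle_hamming <- function(a, b) {
  sa <- strsplit(a, "")[[1]]
  sb <- strsplit(b, "")[[1]]
  n <- 0L
  for (p in seq_along(sa)) {
    ok <- sa[p] %in% c("A", "C", "G", "T") && sb[p] %in% c("A", "C", "G", "T")
    if (ok && sa[p] != sb[p]) n <- n + 1L
  }
  n
}

# hand-rolled BFS connectivity on an edge list (rows of from/to ids)
oracle_connected <- function(a, b, edges) {
  if (a == b) return(TRUE)
  frontier <- a
  seen <- a
  while (length(frontier)) {
    nxt <- character(0)
    for (v in frontier) {
      nb <- c(edges$to[edges$from == v], edges$from[edges$to == v])
      nxt <- c(nxt, setdiff(nb, seen))
    }
    nxt <- unique(nxt)
    if (b %in% nxt) return(TRUE)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  FALSE
}

# minimum-spanning-network characterization: a pair (i, j) is retained
# exactly when no path of strictly shorter retained-irrelevant edges
# connects them, i.e. when i and j are separate in the graph of ALL
# pairs at distance < d(i, j)
oracle_msn_connections <- function(d, max_steps = Inf) {
  ids <- rownames(d)
  out <- data.frame(from = character(0), to = character(0),
                    steps = integer(0), stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      dij <- d[i, j]
      if (dij == 0L || dij > max_steps) next
      shorter <- data.frame(from = character(0), to = character(0))
      for (a in seq_along(ids)) for (b in seq_along(ids)) {
        if (b > a && d[a, b] > 0L && d[a, b] < dij)
          shorter <- rbind(shorter,
                           data.frame(from = ids[a], to = ids[b]))
      }
      if (!oracle_connected(ids[i], ids[j], shorter))
        out <- rbind(out, data.frame(from = ids[i], to = ids[j],
                                     steps = dij))
    }
  }
  out
}

# brute-force "does node v lie on any cycle": v is on a cycle iff two of
# its neighbours are connected by a path that avoids v
oracle_on_cycle <- function(v, edges) {
  nb <- unique(c(edges$to[edges$from == v], edges$from[edges$to == v]))
  if (length(nb) < 2L) return(FALSE)
  rest <- edges[edges$from != v & edges$to != v, , drop = FALSE]
  for (i in seq_along(nb)) for (j in seq_along(nb)) {
    if (j > i && oracle_connected(nb[i], nb[j], rest)) return(TRUE)
  }
  FALSE
}

# unordered connection key for comparing edge/connection sets
conn_key <- function(from, to) {
  paste(pmin(from, to), pmax(from, to))
}

# build a hap_table directly from sequences, one island each by default
table_from_sequences <- function(seqs, islands = NULL, ids = NULL,
                                 outgroup = rep(FALSE, length(seqs))) {
  if (is.null(islands)) islands <- paste0("isl", seq_along(seqs))
  if (is.null(ids)) ids <- paste0("s", seq_along(seqs))
  aln <- as_alignment(ids, seqs)
  meta <- data.frame(sample_id = ids, island = islands,
                     population = islands, species = "test",
                     is_outgroup = outgroup, stringsAsFactors = FALSE)
  collapse_haplotypes(aln, meta, island_aliases = character(0))
}

# incidence hap_table built in memory via a TSV round trip
table_from_counts <- function(m) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  df <- data.frame(haplotype_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  read_incidence(path)
}

write_temp_fasta <- function(ids, seqs, width = NULL) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  lines <- character(0)
  for (i in seq_along(ids)) {
    s <- seqs[i]
    body <- if (is.null(width)) s
            else substring(s, seq(1, nchar(s), width),
                           pmin(seq(1, nchar(s), width) + width - 1, nchar(s)))
    lines <- c(lines, paste0(">", ids[i]), body)
  }
  writeLines(lines, path)
  path
}
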