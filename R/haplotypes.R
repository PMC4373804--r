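## Haplotype table: distinct sequences with per-island sample counts.

new_hap_table <- function(haplotypes, counts, population_counts = NULL) {
  structure(
    list(haplotypes = haplotypes,
         counts = counts,
         population_counts = population_counts),
    class = "hap_table"
  )
}

#' Does a haplotype table carry sequences?
#'
#' Tables read from an incidence matrix are sequence-free; network
#' operations refuse them.
#'
#' @param table a `hap_table`.
#' @return TRUE if every haplotype has a sequence string.
#' @export
has_sequences <- function(table) {
  stopifnot(inherits(table, "hap_table"))
  !anyNA(table$haplotypes$sequence)
}

#' @export
print.hap_table <- function(x, ...) {
  n_out <- sum(x$haplotypes$is_outgroup)
  cat(sprintf("Haplotype table: %d haplotypes (%d outgroup), %d islands, %d samples\n",
              nrow(x$haplotypes), n_out, ncol(x$counts), sum(x$counts)))
  if (!has_sequences(x)) cat("  (sequence-free: built from incidence counts)\n")
  invisible(x)
}

# TRUE where the sequence has a call other than A/C/G/T at that position
ambiguous_sites <- function(seq) {
  !strsplit(seq, "")[[1]] %in% UNAMBIGUOUS_BASES
}

#' Collapse an alignment into a haplotype table
#'
#' Groups identical ingroup sequences into haplotypes and tabulates sample
#' counts per island (and per population). Outgroup samples are collapsed
#' separately and labelled before the ingroup haplotypes (h1, h2, ... for
#' the outgroup, then the ingroup in order of first occurrence); outgroup
#' haplotypes carry no island counts.
#'
#' Ambiguity handling is controlled by `ambiguity_policy`:
#' \describe{
#'   \item{`exclude`}{(default) any sequence containing a gap, `N` or IUPAC
#'     ambiguity code inside the analysis window is dropped, with a warning
#'     listing the samples.}
#'   \item{`collapse_compatible`}{an ambiguous sequence is merged into the
#'     unique unambiguous haplotype it matches at all of its unambiguous
#'     sites; if zero or several haplotypes are compatible the sample is
#'     excluded with a warning.}
#' }
#'
#' @param aln a `hap_alignment`.
#' @param meta metadata data.frame as returned by [read_sample_metadata()];
#'   must contain every alignment sample.
#' @param ambiguity_policy `"exclude"` or `"collapse_compatible"`.
#' @param island_aliases alias map applied to metadata island names if the
#'   metadata has not already been normalized; see
#'   [default_island_aliases()].
#' @return A `hap_table`: `haplotypes` (data.frame with `haplotype_id`,
#'   `sequence`, `is_outgroup`, `n_samples`), `counts` (ingroup haplotype
#'   x island integer matrix) and `population_counts` (haplotype x
#'   population matrix).
#' @export
collapse_haplotypes <- function(aln, meta,
                                ambiguity_policy = c("exclude",
                                                     "collapse_compatible"),
                                island_aliases = default_island_aliases()) {
  stopifnot(inherits(aln, "hap_alignment"))
  ambiguity_policy <- match.arg(ambiguity_policy)
  meta <- as_sample_metadata(meta, island_aliases = island_aliases)
  missing_meta <- setdiff(aln$ids, meta$sample_id)
  if (length(missing_meta))
    ih_stop(sprintf("samples without metadata: %s",
                    paste(missing_meta, collapse = ", ")),
            "islehaps_input_error")
  meta <- meta[match(aln$ids, meta$sample_id), ]

  seqs <- aln$seqs
  is_amb <- vapply(seqs, function(s) any(ambiguous_sites(s)), logical(1),
                   USE.NAMES = FALSE)
  assigned_seq <- seqs          # sequence each sample is counted under
  keep <- rep(TRUE, length(seqs))

  if (any(is_amb)) {
    if (ambiguity_policy == "exclude") {
      keep[is_amb] <- FALSE
      warning(sprintf("excluded %d sample(s) with ambiguous sites: %s",
                      sum(is_amb),
                      paste(aln$ids[is_amb], collapse = ", ")),
              call. = FALSE)
    } else {
      # candidates are the distinct fully resolved sequences, per group
      for (i in which(is_amb)) {
        grp <- if (meta$is_outgroup[i]) meta$is_outgroup & !is_amb
               else !meta$is_outgroup & !is_amb
        cand <- unique(seqs[grp])
        amb <- ambiguous_sites(seqs[i])
        s_res <- strsplit(seqs[i], "")[[1]][!amb]
        compatible <- cand[vapply(cand, function(cs)
          all(strsplit(cs, "")[[1]][!amb] == s_res), logical(1))]
        if (length(compatible) == 1L) {
          assigned_seq[i] <- compatible
        } else {
          keep[i] <- FALSE
          warning(sprintf(
            "sample '%s' is compatible with %d haplotypes; excluded",
            aln$ids[i], length(compatible)), call. = FALSE)
        }
      }
    }
  }
  if (!any(keep))
    ih_stop("all samples excluded by the ambiguity policy",
            "islehaps_empty_result_error")

  meta <- meta[keep, ]
  assigned_seq <- assigned_seq[keep]
  out <- meta$is_outgroup

  # outgroup haplotypes first, then ingroup, each in first-occurrence order
  out_seqs <- unique(assigned_seq[out])
  in_seqs <- setdiff(unique(assigned_seq[!out]), out_seqs)
  all_seqs <- c(out_seqs, in_seqs)
  hap_ids <- paste0("h", seq_along(all_seqs))
  hap_of <- hap_ids[match(assigned_seq, all_seqs)]

  # counts matrix rows: every haplotype with >= 1 ingroup sample
  count_ids <- hap_ids[all_seqs %in% unique(assigned_seq[!out])]
  islands <- sort(unique(meta$island[!out]))
  counts <- matrix(0L, nrow = length(count_ids), ncol = length(islands),
                   dimnames = list(count_ids, islands))
  tb <- table(hap_of[!out], meta$island[!out])
  counts[rownames(tb), colnames(tb)] <- tb

  pops <- sort(unique(meta$population[!out]))
  pop_counts <- matrix(0L, nrow = length(count_ids), ncol = length(pops),
                       dimnames = list(count_ids, pops))
  tbp <- table(hap_of[!out], meta$population[!out])
  pop_counts[rownames(tbp), colnames(tbp)] <- tbp

  n_samples <- as.integer(table(factor(hap_of, levels = hap_ids)))
  haplotypes <- data.frame(
    haplotype_id = hap_ids,
    sequence = all_seqs,
    is_outgroup = all_seqs %in% out_seqs,
    n_samples = n_samples,
    stringsAsFactors = FALSE
  )
  new_hap_table(haplotypes, counts, pop_counts)
}

#' Read a haplotype-by-island incidence matrix
#'
#' Entry point for datasets where only haplotype-by-island sample counts
#' are known (no sequences). The TSV has a first column of haplotype
#' identifiers, remaining columns named by island, and non-negative
#' integer cells.
#'
#' @param path path to a TSV file.
#' @return A sequence-free `hap_table`; operations that need sequences
#'   (distances, network building) refuse it.
#' @export
read_incidence <- function(path) {
  if (!file.exists(path))
    ih_stop(sprintf("incidence file not found: %s", path),
            "islehaps_input_error")
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (ncol(df) < 2L || nrow(df) < 1L)
    ih_stop("incidence matrix needs >= 1 haplotype row and >= 1 island column",
            "islehaps_input_error")
  hap_ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  if (anyNA(m) || any(m < 0) || any(m != round(m)))
    ih_stop("incidence cells must be non-negative integers",
            "islehaps_input_error")
  storage.mode(m) <- "integer"
  rownames(m) <- hap_ids
  m <- m[, colnames(m) != "", drop = FALSE]
  if (any(rowSums(m) < 1L))
    ih_stop("every haplotype must have total count >= 1",
            "islehaps_input_error")
  haplotypes <- data.frame(
    haplotype_id = hap_ids,
    sequence = NA_character_,
    is_outgroup = FALSE,
    n_samples = as.integer(rowSums(m)),
    stringsAsFactors = FALSE
  )
  new_hap_table(haplotypes, m)
}

#' Write a haplotype-by-island incidence matrix
#'
#' Inverse of [read_incidence()]: writes the ingroup counts matrix as TSV.
#'
#' @param table a `hap_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_incidence <- function(table, path) {
  stopifnot(inherits(table, "hap_table"))
  df <- data.frame(haplotype_id = rownames(table$counts),
                   table$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a haplotype table as TSV or JSON
#'
#' @param table a `hap_table`.
#' @param path output path.
#' @param format `"tsv"` (haplotype rows with sequence and island counts)
#'   or `"json"`.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(table, path, format = c("tsv", "json")) {
  stopifnot(inherits(table, "hap_table"))
  format <- match.arg(format)
  hap <- table$haplotypes
  if (format == "tsv") {
    idx <- match(hap$haplotype_id, rownames(table$counts))
    cnt <- table$counts[ifelse(is.na(idx), 1L, idx), , drop = FALSE]
    cnt[is.na(idx), ] <- 0L
    df <- cbind(hap, as.data.frame(cnt, check.names = FALSE))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(haplotypes = hap,
           islands = colnames(table$counts),
           counts = table$counts),
      path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  }
  invisible(path)
}

#' Per-haplotype island occupancy sets
#'
#' @param table a `hap_table`.
#' @return Named list mapping each ingroup haplotype to the character
#'   vector of islands where its count is positive.
#' @export
island_sets <- function(table) {
  stopifnot(inherits(table, "hap_table"))
  apply(table$counts > 0L, 1L, function(r) colnames(table$counts)[r],
        simplify = FALSE)
}
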