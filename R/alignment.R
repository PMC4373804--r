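## Alignment container and FASTA / metadata input.

# Characters accepted in an aligned sequence after uppercasing and U->T:
# the four bases, IUPAC ambiguity codes, gap and N.
ALIGNMENT_ALPHABET <- c("A", "C", "G", "T",
                        "R", "Y", "S", "W", "K", "M",
                        "B", "D", "H", "V", "N", "-")
UNAMBIGUOUS_BASES <- c("A", "C", "G", "T")

new_alignment <- function(ids, seqs) {
  structure(
    list(ids = as.character(ids),
         seqs = as.character(seqs),
         length = if (length(seqs)) nchar(seqs[[1]]) else 0L),
    class = "hap_alignment"
  )
}

#' Read an aligned FASTA file
#'
#' Reads a (wrapped or single-line) FASTA file of pre-aligned nucleotide
#' sequences. Sequences are uppercased and `U` is mapped to `T`. All
#' sequences must have identical length and identifiers must be unique;
#' characters outside the nucleotide alphabet (four bases, IUPAC ambiguity
#' codes, `-`, `N`) raise an error naming the offending record.
#'
#' @param path path to a FASTA file.
#' @return An object of class `hap_alignment`: a list with `ids`
#'   (record identifiers in input order), `seqs` (uppercase sequence
#'   strings) and `length` (alignment length in bp).
#' @seealso [trim_alignment()], [collapse_haplotypes()]
#' @export
read_alignment <- function(path) {
  if (!file.exists(path))
    ih_stop(sprintf("FASTA file not found: %s", path), "islehaps_input_error")
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                       forceDNAtolower = FALSE),
    error = function(e)
      ih_stop(sprintf("cannot parse FASTA file %s: %s", path,
                      conditionMessage(e)),
              "islehaps_input_error"))
  if (length(recs) == 0L)
    ih_stop(sprintf("no sequences in FASTA file: %s", path),
            "islehaps_input_error")
  ids <- vapply(recs, function(r) attr(r, "name"), character(1))
  seqs <- toupper(vapply(recs, as.character, character(1)))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  as_alignment(ids, seqs)
}

#' Construct an alignment from identifiers and sequence strings
#'
#' Programmatic constructor validating the same invariants as
#' [read_alignment()]: equal lengths, unique identifiers, legal alphabet.
#'
#' @param ids character vector of unique sample identifiers.
#' @param seqs character vector of equal-length sequences (uppercased
#'   internally; `U` mapped to `T`).
#' @return A `hap_alignment` object.
#' @export
as_alignment <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- gsub("U", "T", toupper(as.character(seqs)), fixed = TRUE)
  if (length(ids) != length(seqs))
    ih_stop("ids and seqs must have the same length", "islehaps_input_error")
  if (length(ids) == 0L)
    ih_stop("alignment has no records", "islehaps_input_error")
  if (anyDuplicated(ids))
    ih_stop(sprintf("duplicated sample identifiers: %s",
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")),
            "islehaps_input_error")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    ih_stop(sprintf(
      "sequences are not aligned: lengths range %d-%d (first offender: %s)",
      min(lens), max(lens), ids[which(lens != lens[1])[1]]),
      "islehaps_alignment_error")
  bad <- vapply(strsplit(seqs, ""),
                function(s) any(!s %in% ALIGNMENT_ALPHABET), logical(1))
  if (any(bad))
    ih_stop(sprintf("illegal characters in sequence of sample '%s'",
                    ids[which(bad)[1]]),
            "islehaps_input_error")
  new_alignment(ids, seqs)
}

#' @export
print.hap_alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d sequences, %d bp\n", length(x$ids), x$length))
  invisible(x)
}

#' Trim an alignment to its analysis window
#'
#' Drops a fixed number of leading and trailing positions, e.g. to remove
#' low-quality ends of Sanger reads before haplotype calling.
#'
#' @param aln a `hap_alignment`.
#' @param drop_leading number of positions removed from the start.
#' @param drop_trailing number of positions removed from the end.
#' @return A `hap_alignment` of length
#'   `aln$length - drop_leading - drop_trailing` over the same samples.
#' @examples
#' aln <- as_alignment(c("a", "b"), c("ACGTACGT", "ACGTACGA"))
#' trim_alignment(aln, 2, 1)$length
#' @export
trim_alignment <- function(aln, drop_leading = 0L, drop_trailing = 0L) {
  stopifnot(inherits(aln, "hap_alignment"))
  if (!is_count(drop_leading) || !is_count(drop_trailing) ||
      drop_leading < 0 || drop_trailing < 0)
    ih_stop("drop_leading and drop_trailing must be non-negative integers",
            "islehaps_input_error")
  width <- aln$length - drop_leading - drop_trailing
  if (width <= 0)
    ih_stop(sprintf("trim window is empty: %d - %d - %d = %d bp",
                    aln$length, drop_leading, drop_trailing, width),
            "islehaps_input_error")
  new_alignment(aln$ids,
                substr(aln$seqs, drop_leading + 1L, aln$length - drop_trailing))
}

#' Default island alias map
#'
#' Islands joined by a recent land bridge are treated as a single island
#' for colonization counting; the shipped default merges Baltra into
#' Santa Cruz (Galapagos).
#'
#' @return Named character vector mapping alias -> canonical island name.
#' @export
default_island_aliases <- function() {
  c("Baltra" = "Santa Cruz")
}

#' Read a sample metadata table
#'
#' Reads a tab-separated metadata table with required columns
#' `sample_id`, `island`, `population`, `species`, `is_outgroup`.
#' Island and population labels are whitespace-trimmed and island aliases
#' (e.g. land-bridge merges) applied.
#'
#' @param path path to a TSV file.
#' @param island_aliases named character vector mapping alias island names
#'   to canonical ones; applied before any counting. Default
#'   [default_island_aliases()].
#' @return A data.frame with the five required columns; `is_outgroup`
#'   is logical.
#' @export
read_sample_metadata <- function(path, island_aliases = default_island_aliases()) {
  if (!file.exists(path))
    ih_stop(sprintf("metadata file not found: %s", path),
            "islehaps_input_error")
  meta <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                            check.names = FALSE)
  as_sample_metadata(meta, island_aliases = island_aliases)
}

#' Validate and normalize a metadata data.frame
#'
#' @param meta data.frame with columns `sample_id`, `island`, `population`,
#'   `species`, `is_outgroup`.
#' @inheritParams read_sample_metadata
#' @return The validated data.frame with aliases applied.
#' @export
as_sample_metadata <- function(meta, island_aliases = default_island_aliases()) {
  required <- c("sample_id", "island", "population", "species", "is_outgroup")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    ih_stop(sprintf("metadata is missing required columns: %s",
                    paste(missing_cols, collapse = ", ")),
            "islehaps_input_error")
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id))
    ih_stop("metadata contains duplicated sample_id rows",
            "islehaps_input_error")
  meta$island <- apply_island_aliases(normalize_label(meta$island),
                                      island_aliases)
  meta$population <- normalize_label(meta$population)
  meta$species <- normalize_label(meta$species)
  meta$is_outgroup <- as.logical(meta$is_outgroup)
  if (anyNA(meta$is_outgroup))
    ih_stop("is_outgroup must be TRUE/FALSE", "islehaps_input_error")
  meta[required]
}

#' Apply an island alias map to a vector of island names
#'
#' @param islands character vector of island names.
#' @param aliases named character vector, alias -> canonical name.
#' @return Character vector with aliases replaced.
#' @export
apply_island_aliases <- function(islands, aliases = default_island_aliases()) {
  if (length(aliases) == 0L) return(islands)
  hit <- islands %in% names(aliases)
  islands[hit] <- unname(aliases[islands[hit]])
  islands
}
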