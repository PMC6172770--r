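#' Read a FASTA file into a tibble
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning a
#' two-column tibble so sequence sets flow through dplyr pipelines.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  empty <- which(Biostrings::width(set) == 0)
  if (length(empty)) {
    abort(sprintf("FASTA record %d ('%s') has no sequence",
                  empty[1], names(set)[empty[1]]))
  }
  tibble(
    id = sub("\\s.*$", "", names(set)),
    sequence = unname(as.character(set))
  )
}

#' Write sequences to FASTA
#'
#' @param seqs A tibble with columns `id` and `sequence`, or a named
#'   character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) {
    seqs <- tibble(id = names(seqs), sequence = unname(seqs))
  }
  set <- Biostrings::DNAStringSet(setNames(seqs$sequence, seqs$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# Parse one CIGAR string into per-operation lengths and codes.
parse_cigar <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(lens) != length(ops) || length(ops) == 0L) {
    abort(sprintf("malformed CIGAR string '%s'", cigar))
  }
  list(lens = lens, ops = ops)
}

#' Read alignments from a SAM file
#'
#' Parses mapped records from a plain-text SAM file into the alignment
#' record layout used by [filter_alignments()]. Aligned length is the sum
#' of aligned query operations (`M`, `=`, `X`); matches are derived from
#' the `NM` tag as `aligned_len - NM`. Coordinates are converted to
#' 0-based half-open at the parser.
#'
#' @param path Path to a SAM file.
#' @return A tibble with columns `read_id`, `contig_id`, `read_len`,
#'   `aligned_len`, `matches`, `start`, `end`, `strand`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "@"))
  recs <- lapply(body, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L) {
      abort(sprintf("malformed SAM record at line %d", i))
    }
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) == 4L || f[3] == "*") return(NULL)
    cig <- parse_cigar(f[6])
    aligned <- sum(cig$lens[cig$ops %in% c("M", "=", "X")])
    ref_span <- sum(cig$lens[cig$ops %in% c("M", "=", "X", "D", "N")])
    read_len <- sum(cig$lens[cig$ops %in% c("M", "I", "S", "=", "X")])
    nm_field <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    nm <- if (length(nm_field)) as.integer(sub("^NM:i:", "", nm_field[1])) else 0L
    start <- as.integer(f[4]) - 1L
    tibble(
      read_id = f[1], contig_id = f[3],
      read_len = read_len, aligned_len = aligned,
      matches = aligned - nm,
      start = start, end = start + ref_span,
      strand = if (bitwAnd(flag, 16L) == 16L) "-" else "+"
    )
  })
  out <- bind_rows(recs)
  if (nrow(out) == 0L) {
    out <- tibble(
      read_id = character(), contig_id = character(),
      read_len = integer(), aligned_len = integer(), matches = integer(),
      start = integer(), end = integer(), strand = character()
    )
  }
  out
}

#' Read BLAST tabular output
#'
#' Reads an `outfmt 6`-like tab-separated file. The default column order
#' is the standard twelve-column layout; pass `columns` to match other
#' dialects.
#'
#' @param path Path to the tabular file.
#' @param columns Character vector of column names in file order.
#' @return A tibble with the given columns, numeric where standard.
#' @export
read_blast_tab <- function(path,
                           columns = c("qseqid", "sseqid", "pident", "length",
                                       "mismatch", "gapopen", "qstart", "qend",
                                       "sstart", "send", "evalue", "bitscore")) {
  out <- readr::read_tsv(path, col_names = columns, show_col_types = FALSE,
                         progress = FALSE)
  num <- intersect(columns, c("pident", "length", "mismatch", "gapopen",
                              "qstart", "qend", "sstart", "send",
                              "evalue", "bitscore"))
  out[num] <- lapply(out[num], as.numeric)
  out
}

#' Read and write labelled numeric matrices as TSV
#'
#' A samples-by-features matrix is stored with the row labels in the
#' first column (named `sample`).
#'
#' @param path File path.
#' @return `read_tsv_matrix()` returns a numeric matrix with dimnames.
#' @export
read_tsv_matrix <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(tb[, -1, drop = FALSE])
  rownames(m) <- as.character(tb[[1]])
  m
}

#' @rdname read_tsv_matrix
#' @param m A numeric matrix with row and column names.
#' @export
write_tsv_matrix <- function(m, path) {
  tb <- as_tibble(m, rownames = "sample")
  readr::write_tsv(tb, path, progress = FALSE)
  invisible(path)
}

#' Read counts for the seven permafrost-thaw viromes
#'
#' Published per-virome sequencing summaries for the seven palsa, bog and
#' fen viromes (BioProject PRJNA445426): DNA input, total reads, reads
#' assembling into contigs, reads recruited to putative viral contigs,
#' and reads recruited to the 53 well-sampled vOTUs. These printed counts
#' are the input for [summarize_viromes()].
#'
#' @return A tibble with one row per virome.
#' @export
stordalen_virome_counts <- function() {
  path <- system.file("extdata", "stordalen_virome_counts.tsv",
                      package = "thawvir", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
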