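# Minimal k-mer-seeded read mapper for the synthetic test path. Reads
# are located by exact seed lookup and scored as full-length ungapped
# alignments (the generator plants substitutions only); production
# mapping should come from a real aligner via read_sam().

#' Map uniform-length reads onto contigs
#'
#' Seeds each read (and its reverse complement) with exact k-mers at a
#' few offsets, places it on the first seeded diagonal, and scores the
#' full-length ungapped alignment. A candidate placement below 50%
#' identity is discarded and the next seed tried, so host-derived reads
#' that graze a planted protospacer do not produce alignments.
#'
#' @param reads Tibble with `read_id` and `sequence` (all reads the same
#'   length), or a named character vector.
#' @param contigs Tibble with `id` and `sequence`, or a named character
#'   vector.
#' @param k Seed k-mer size.
#' @param max_seeds Maximum seed offsets tried per strand.
#' @return An alignment-record tibble (`read_id`, `contig_id`,
#'   `read_len`, `aligned_len`, `matches`, `start`, `end`, `strand`)
#'   with 0-based half-open contig coordinates.
#' @export
map_reads <- function(reads, contigs, k = 15L, max_seeds = 5L) {
  if (is.character(reads)) {
    reads <- tibble(read_id = names(reads), sequence = unname(reads))
  }
  if (is.character(contigs)) {
    contigs <- tibble(id = names(contigs), sequence = unname(contigs))
  }
  rl <- unique(nchar(reads$sequence))
  if (length(rl) != 1L) abort("map_reads() expects uniform read length")
  if (rl < k) abort("reads shorter than the seed size")

  clen <- nchar(contigs$sequence)
  idx_kmer <- character(0)
  idx_contig <- integer(0)
  idx_pos <- integer(0)
  for (ci in seq_len(nrow(contigs))) {
    km <- seq_kmers(contigs$sequence[ci], k)
    idx_kmer <- c(idx_kmer, km)
    idx_contig <- c(idx_contig, rep.int(ci, length(km)))
    idx_pos <- c(idx_pos, seq_along(km))
  }

  offsets <- unique(floor(seq(1L, rl - k + 1L, length.out = max_seeds)))
  n <- nrow(reads)
  todo <- rep(TRUE, n)
  out <- vector("list", 2L * length(offsets))
  oi <- 0L
  for (strand in c("+", "-")) {
    if (!any(todo)) break
    rs <- if (strand == "+") reads$sequence else revcomp(reads$sequence)
    for (off in offsets) {
      idx <- which(todo)
      if (length(idx) == 0L) break
      seeds <- substr(rs[idx], off, off + k - 1L)
      m <- match(seeds, idx_kmer)
      hit <- which(!is.na(m))
      if (length(hit) == 0L) next
      ci <- idx_contig[m[hit]]
      start <- idx_pos[m[hit]] - off + 1L
      valid <- start >= 1L & start + rl - 1L <= clen[ci]
      hit <- hit[valid]
      if (length(hit) == 0L) next
      ci <- ci[valid]
      start <- start[valid]
      ref <- substring(contigs$sequence[ci], start, start + rl - 1L)
      mm <- count_mismatches(rs[idx[hit]], ref)
      keep <- mm <= rl * 0.5
      if (!any(keep)) next
      oi <- oi + 1L
      st0 <- start[keep] - 1L
      out[[oi]] <- tibble(
        read_id = reads$read_id[idx[hit[keep]]],
        contig_id = contigs$id[ci[keep]],
        read_len = rl,
        aligned_len = rl,
        matches = rl - mm[keep],
        start = st0,
        end = st0 + rl,
        strand = strand
      )
      todo[idx[hit[keep]]] <- FALSE
    }
  }
  res <- bind_rows(out[seq_len(oi)])
  if (nrow(res) == 0L) {
    res <- tibble(
      read_id = character(), contig_id = character(), read_len = integer(),
      aligned_len = integer(), matches = integer(), start = integer(),
      end = integer(), strand = character()
    )
  }
  res
}
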