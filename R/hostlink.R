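# Virus-host prediction: CRISPR array detection on host genomes, exact
# spacer-to-protospacer matching, and nucleotide similarity linkage at
# the 50-bit / 1e-3 / 70% ANI / 2,500 bp thresholds.

# Karlin-Altschul parameters for ungapped match +1 / mismatch -2
# nucleotide scoring (the standard short-match dialect).
KA_LAMBDA <- 1.28
KA_K <- 0.46

#' Find CRISPR arrays in a genome
#'
#' Scans for maximal runs of at least `min_repeats` identical repeat
#' copies separated by spacers, with repeat and spacer lengths inside
#' the given ranges. Seeds on exactly repeated k-mers (k = minimum
#' repeat length), extends each run to the maximal common repeat, and
#' rejects runs whose implied spacers fall outside the range. The scan
#' is deterministic left to right.
#'
#' @param genome A DNA sequence (character scalar) or a tibble with
#'   `host_id`/`id` and `sequence` for several genomes.
#' @param repeat_len_range,spacer_len_range Allowed repeat and spacer
#'   lengths in bp.
#' @param min_repeats Minimum identical repeat copies.
#' @return A tibble with one row per array: `host_id`, `repeat_seq`,
#'   `n_repeats`, `start`, `end` (0-based half-open), and a `spacers`
#'   list-column of tibbles (`spacer`, `start`, `end`).
#' @export
find_crispr_arrays <- function(genome, repeat_len_range = c(23L, 47L),
                               spacer_len_range = c(26L, 50L),
                               min_repeats = 3L) {
  if (is.data.frame(genome)) {
    idcol <- if ("host_id" %in% names(genome)) "host_id" else "id"
    out <- purrr::map2(genome[[idcol]], genome$sequence, function(id, s) {
      res <- find_crispr_arrays(s, repeat_len_range, spacer_len_range,
                                min_repeats)
      if (nrow(res)) res$host_id <- id
      res
    })
    return(bind_rows(out))
  }
  assert_dna(genome, "genome")
  k <- repeat_len_range[1]
  L <- nchar(genome)
  empty <- tibble(host_id = NA_character_, repeat_seq = character(),
                  n_repeats = integer(), start = integer(), end = integer(),
                  spacers = list())[0, ]
  if (L < 2L * k + spacer_len_range[1]) return(empty)

  km <- seq_kmers(genome, k)
  counts <- table(km)
  cand <- names(counts)[counts >= min_repeats]
  if (length(cand) == 0L) return(empty)
  period_min <- repeat_len_range[1] + spacer_len_range[1]
  period_max <- repeat_len_range[2] + spacer_len_range[2]

  gchars <- strsplit(genome, "", fixed = TRUE)[[1]]
  arrays <- list()
  for (kmer in cand) {
    pos <- which(km == kmer)
    # split into maximal runs with period inside the allowed window
    gaps <- diff(pos)
    run_break <- c(TRUE, gaps < period_min | gaps > period_max)
    run_id <- cumsum(run_break)
    for (r in unique(run_id)) {
      p <- pos[run_id == r]
      if (length(p) < min_repeats) next
      # maximal common extension, bounded by the repeat-length cap and
      # by keeping every spacer at or above its minimum length
      max_len <- min(repeat_len_range[2], min(diff(p)) - spacer_len_range[1])
      len <- k
      while (len < max_len && max(p) + len <= L &&
             length(unique(gchars[p + len])) == 1L) {
        len <- len + 1L
      }
      while (len < max_len && min(p) > 1L &&
             length(unique(gchars[p - 1L])) == 1L) {
        p <- p - 1L
        len <- len + 1L
      }
      spacer_lens <- diff(p) - len
      if (any(spacer_lens < spacer_len_range[1]) ||
          any(spacer_lens > spacer_len_range[2])) next
      rep_seq <- substr(genome, p[1], p[1] + len - 1L)
      spacer_tb <- tibble(
        spacer = substring(genome, head(p, -1) + len, p[-1] - 1L),
        start = head(p, -1) + len - 1L,
        end = p[-1] - 1L
      )
      arrays[[length(arrays) + 1L]] <- tibble(
        host_id = NA_character_, repeat_seq = rep_seq,
        n_repeats = length(p),
        start = p[1] - 1L, end = p[length(p)] + len - 1L,
        spacers = list(spacer_tb)
      )
    }
  }
  if (length(arrays) == 0L) return(empty)
  bind_rows(arrays) %>%
    distinct(.data$start, .data$repeat_seq, .keep_all = TRUE) %>%
    arrange(.data$start)
}

#' Match CRISPR spacers against viral contigs
#'
#' Exhaustively reports every occurrence of each spacer on either
#' strand of each contig with at most `max_mismatch` substitutions.
#'
#' @param spacers Named character vector of spacer sequences (or a
#'   tibble with `spacer_id` and `spacer`).
#' @param viral_contigs Tibble with `id` and `sequence`, or a named
#'   character vector.
#' @param max_mismatch Maximum substitutions (default 0: the
#'   high-confidence convention).
#' @return A tibble: `spacer_id`, `spacer`, `contig_id`, `start`, `end`
#'   (0-based half-open, on the forward strand of the contig),
#'   `strand`, `mismatches`.
#' @export
match_spacers <- function(spacers, viral_contigs, max_mismatch = 0L) {
  if (is.data.frame(spacers)) {
    spacers <- setNames(spacers$spacer, spacers$spacer_id)
  }
  if (length(spacers) == 0L) abort("spacers must be non-empty")
  if (is.null(names(spacers))) {
    names(spacers) <- sprintf("spacer_%03d", seq_along(spacers))
  }
  if (is.character(viral_contigs)) {
    viral_contigs <- tibble(id = names(viral_contigs),
                            sequence = unname(viral_contigs))
  }
  short <- nchar(spacers) < 20L
  if (any(short)) {
    warn(sprintf("%d spacer(s) shorter than 20 bp: low specificity",
                 sum(short)))
  }
  subject <- Biostrings::DNAStringSet(
    setNames(viral_contigs$sequence, viral_contigs$id)
  )
  out <- list()
  for (si in seq_along(spacers)) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") spacers[[si]] else revcomp(spacers[[si]])
      hits <- Biostrings::vmatchPattern(pat, subject,
                                        max.mismatch = max_mismatch)
      for (ci in seq_along(subject)) {
        v <- hits[[ci]]
        if (length(v) == 0L) next
        found <- substring(viral_contigs$sequence[ci],
                           IRanges::start(v), IRanges::end(v))
        mm <- vapply(found, function(f) {
          sum(charToRaw(f) != charToRaw(pat))
        }, integer(1), USE.NAMES = FALSE)
        out[[length(out) + 1L]] <- tibble(
          spacer_id = names(spacers)[si],
          spacer = spacers[[si]],
          contig_id = viral_contigs$id[ci],
          start = IRanges::start(v) - 1L,
          end = IRanges::end(v),
          strand = strand,
          mismatches = mm
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble(spacer_id = character(), spacer = character(),
                  contig_id = character(), start = integer(),
                  end = integer(), strand = character(),
                  mismatches = integer()))
  }
  bind_rows(out) %>% arrange(.data$spacer_id, .data$contig_id, .data$start)
}

# Best ungapped local alignment between two sequences: anchor shared
# k-mers, and on each supported diagonal take the maximum-scoring
# subsegment (match +1 / mismatch -2) via a vectorized prefix scan.
best_local_segment <- function(seq_a, seq_b, k = 12L, min_anchors = 2L) {
  la <- nchar(seq_a)
  best <- NULL
  for (strand in c("+", "-")) {
    sb <- if (strand == "+") seq_b else revcomp(seq_b)
    lb <- nchar(sb)
    if (la < k || lb < k) next
    ka <- seq_kmers(seq_a, k)
    kb <- seq_kmers(sb, k)
    hit <- match(kb, ka)
    ok <- which(!is.na(hit))
    if (length(ok) == 0L) next
    diag <- hit[ok] - ok
    tab <- table(diag)
    diags <- as.integer(names(tab)[tab >= min_anchors])
    for (d in diags) {
      start_a <- max(1L, 1L + d)
      end_a <- min(la, lb + d)
      n <- end_a - start_a + 1L
      if (n < k) next
      ra <- charToRaw(substr(seq_a, start_a, end_a))
      rb <- charToRaw(substr(sb, start_a - d, end_a - d))
      sc <- ifelse(ra == rb & ra != charToRaw("N"), 1, -2)
      pre <- cumsum(sc)
      minpre <- cummin(c(0, pre[-n]))
      gain <- pre - minpre
      j <- which.max(gain)
      raw_score <- gain[j]
      if (raw_score <= 0) next
      i <- which(c(0, pre)[seq_len(j)] == minpre[j])[1]  # segment starts at i
      seg_len <- j - i + 1L
      seg_matches <- sum(sc[i:j] == 1)
      if (is.null(best) || raw_score > best$raw_score) {
        best <- list(
          raw_score = raw_score, matches = seg_matches,
          aligned_len = seg_len, ani = seg_matches / seg_len,
          a_start = start_a + i - 2L,  # 0-based
          strand = strand
        )
      }
    }
  }
  best
}

#' Nucleotide similarity linkage between viruses and hosts
#'
#' Finds the best ungapped local alignment for each virus-host pair and
#' emits a link only when all four thresholds pass: bit score at least
#' `min_bitscore`, E value at most `max_evalue`, identity at least
#' `min_ani` over at least `min_len` aligned bp. Bit scores and E
#' values use ungapped Karlin-Altschul statistics for the match +1 /
#' mismatch -2 scoring dialect, and are reported so the thresholds are
#' auditable.
#'
#' @param viral_contigs,host_genomes Tibbles with `id`/`host_id` and
#'   `sequence`, or named character vectors.
#' @param min_bitscore,max_evalue,min_ani,min_len Link thresholds
#'   (defaults 50, 1e-3, 0.70, 2500).
#' @return A tibble of links: `contig_id`, `host_id`,
#'   `evidence = "similarity"`, `bitscore`, `evalue`, `ani`,
#'   `aligned_len`, `strand`.
#' @export
similarity_link <- function(viral_contigs, host_genomes, min_bitscore = 50,
                            max_evalue = 1e-3, min_ani = 0.70,
                            min_len = 2500L) {
  if (is.character(viral_contigs)) {
    viral_contigs <- tibble(id = names(viral_contigs),
                            sequence = unname(viral_contigs))
  }
  if (is.character(host_genomes)) {
    host_genomes <- tibble(host_id = names(host_genomes),
                           sequence = unname(host_genomes))
  }
  if (!"host_id" %in% names(host_genomes)) {
    host_genomes <- rename(host_genomes, host_id = "id")
  }
  out <- list()
  for (vi in seq_len(nrow(viral_contigs))) {
    for (hi in seq_len(nrow(host_genomes))) {
      seg <- best_local_segment(viral_contigs$sequence[vi],
                                host_genomes$sequence[hi])
      if (is.null(seg)) next
      bit <- (KA_LAMBDA * seg$raw_score - log(KA_K)) / log(2)
      ev <- nchar(viral_contigs$sequence[vi]) *
        nchar(host_genomes$sequence[hi]) * 2^(-bit)
      if (bit >= min_bitscore && ev <= max_evalue &&
          seg$ani >= min_ani && seg$aligned_len >= min_len) {
        out[[length(out) + 1L]] <- tibble(
          contig_id = viral_contigs$id[vi],
          host_id = host_genomes$host_id[hi],
          evidence = "similarity",
          bitscore = bit, evalue = ev, ani = seg$ani,
          aligned_len = seg$aligned_len, strand = seg$strand
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble(contig_id = character(), host_id = character(),
                  evidence = character(), bitscore = numeric(),
                  evalue = numeric(), ani = numeric(),
                  aligned_len = integer(), strand = character()))
  }
  bind_rows(out)
}

#' Predict hosts for viral contigs
#'
#' Combines both lines of evidence: CRISPR arrays are detected on the
#' host genomes, their spacers matched against the viral contigs
#' (exact matches by default), and nucleotide similarity linkage is
#' applied at its own thresholds. Links are reported per
#' (contig, host) pair.
#'
#' @param viral_contigs Tibble with `id` and `sequence` (or named
#'   character vector).
#' @param host_genomes Tibble with `host_id` and `sequence` (or named
#'   character vector).
#' @param max_mismatch Maximum spacer mismatches (default 0).
#' @param similarity Run similarity linkage as well (default TRUE).
#' @param ... Threshold overrides passed to [similarity_link()].
#' @return A tibble of host links: `contig_id`, `host_id`, `evidence`
#'   (`"crispr"` or `"similarity"`), plus evidence detail columns.
#' @export
predict_hosts <- function(viral_contigs, host_genomes, max_mismatch = 0L,
                          similarity = TRUE, ...) {
  if (is.character(host_genomes)) {
    host_genomes <- tibble(host_id = names(host_genomes),
                           sequence = unname(host_genomes))
  }
  if (!"host_id" %in% names(host_genomes)) {
    host_genomes <- rename(host_genomes, host_id = "id")
  }
  arrays <- find_crispr_arrays(host_genomes)
  crispr <- tibble(contig_id = character(), host_id = character(),
                   evidence = character(), detail = character())
  if (nrow(arrays)) {
    spacer_tb <- arrays %>%
      select("host_id", "spacers") %>%
      tidyr::unnest("spacers") %>%
      mutate(spacer_id = sprintf("%s_sp%02d", .data$host_id,
                                 row_number()))
    hits <- match_spacers(
      setNames(spacer_tb$spacer, spacer_tb$spacer_id),
      viral_contigs, max_mismatch = max_mismatch
    )
    if (nrow(hits)) {
      crispr <- hits %>%
        left_join(spacer_tb %>% select("spacer_id", "host_id"),
                  by = "spacer_id") %>%
        mutate(
          evidence = "crispr",
          detail = sprintf("%s@%d%s/%dmm", .data$spacer_id, .data$start,
                           .data$strand, .data$mismatches)
        ) %>%
        select("contig_id", "host_id", "evidence", "detail") %>%
        distinct()
    }
  }
  sim <- tibble(contig_id = character(), host_id = character(),
                evidence = character(), detail = character())
  if (similarity) {
    sl <- similarity_link(viral_contigs, host_genomes, ...)
    if (nrow(sl)) {
      sim <- sl %>%
        mutate(detail = sprintf("bit=%.1f,E=%.2g,ani=%.3f,len=%d",
                                .data$bitscore, .data$evalue, .data$ani,
                                .data$aligned_len)) %>%
        select("contig_id", "host_id", "evidence", "detail")
    }
  }
  bind_rows(crispr, sim) %>% arrange(.data$contig_id, .data$host_id)
}
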