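# vOTU dereplication: pairwise ANI and greedy longest-first clustering at
# the 95% identity / 80% length thresholds used for species-level viral
# populations.

# Count identical columns between two equal-length segments; N never
# counts as a match.
segment_matches <- function(sa, sb) {
  ra <- charToRaw(sa)
  rb <- charToRaw(sb)
  sum(ra == rb & ra != charToRaw("N"))
}

# Core ANI engine: k-mer anchored diagonal alignment. Shared k-mers vote
# for a diagonal; on the winning diagonal the maximum-scoring local
# segment (match +1 / mismatch -2) is taken, so partially homologous
# pairs report identity over the aligned stretch only. Indels are out
# of scope (the generator plants substitutions only), so a single
# diagonal carries the whole homologous stretch; on test scales this is
# equivalent to a full DP alignment.
ani_core <- function(seq_a, seq_b, k = 13L, both_strands = TRUE) {
  la <- nchar(seq_a)
  lb <- nchar(seq_b)
  empty <- list(ani = 0, aligned_len = 0L, matches = 0L, strand = "+")
  if (la < k || lb < k) return(empty)

  ka <- seq_kmers(seq_a, k)
  score_orientation <- function(sb, strand) {
    kb <- seq_kmers(sb, k)
    hit <- match(kb, ka)
    ok <- which(!is.na(hit))
    if (length(ok) == 0L) return(NULL)
    diag <- hit[ok] - ok
    tab <- sort(table(diag), decreasing = TRUE)
    best <- as.integer(names(tab))
    # deterministic tie-break: most anchors, then smallest |diagonal|
    best <- best[tab == tab[1]]
    d <- best[order(abs(best), best)][1]
    start_a <- max(1L, 1L + d)
    end_a <- min(la, nchar(sb) + d)
    n <- end_a - start_a + 1L
    if (n < k) return(NULL)
    ra <- charToRaw(substr(seq_a, start_a, end_a))
    rb <- charToRaw(substr(sb, start_a - d, end_a - d))
    eq <- ra == rb & ra != charToRaw("N")
    # maximum-scoring subsegment via a prefix scan (ungapped local
    # alignment restricted to the diagonal)
    sc <- ifelse(eq, 1, -2)
    pre <- cumsum(sc)
    minpre <- cummin(c(0, pre[-n]))
    gain <- pre - minpre
    j <- which.max(gain)
    if (gain[j] <= 0) return(NULL)
    i <- which(c(0, pre)[seq_len(j)] == minpre[j])[1]
    len <- j - i + 1L
    m <- sum(eq[i:j])
    list(ani = m / len, aligned_len = len, matches = m, strand = strand)
  }

  cands <- list(score_orientation(seq_b, "+"))
  if (both_strands) cands <- c(cands, list(score_orientation(revcomp(seq_b), "-")))
  cands <- Filter(Negate(is.null), cands)
  if (length(cands) == 0L) return(empty)
  scores <- vapply(cands, function(x) x$matches, numeric(1))
  cands[[which.max(scores)]]
}

#' Average nucleotide identity between two sequences
#'
#' Computes ANI as the fraction of identical columns over the aligned
#' region, and the aligned fraction relative to the chosen denominator
#' (the shorter sequence by default, the permissive convention for
#' fragmented cluster members).
#'
#' @param seq_a,seq_b DNA sequences (character scalars, alphabet ACGTN).
#' @param k Anchor k-mer size for the alignment engine.
#' @param both_strands Also consider the reverse complement of `seq_b`.
#' @param cov_denominator Length used for `aligned_fraction`: `"shorter"`
#'   (default), `"longer"`, or `"a"` (treat `seq_a` as the reference).
#' @return A one-row tibble with columns `ani`, `aligned_fraction`,
#'   `aligned_len`, `strand`.
#' @examples
#' s <- paste(rep("ACGT", 50), collapse = "")
#' compute_ani(s, s)
#' @export
compute_ani <- function(seq_a, seq_b, k = 13L, both_strands = TRUE,
                        cov_denominator = c("shorter", "longer", "a")) {
  cov_denominator <- match.arg(cov_denominator)
  assert_dna(seq_a, "seq_a")
  assert_dna(seq_b, "seq_b")
  res <- ani_core(seq_a, seq_b, k = k, both_strands = both_strands)
  denom <- switch(cov_denominator,
    shorter = min(nchar(seq_a), nchar(seq_b)),
    longer = max(nchar(seq_a), nchar(seq_b)),
    a = nchar(seq_a)
  )
  tibble(
    ani = res$ani,
    aligned_fraction = res$aligned_len / denom,
    aligned_len = res$aligned_len,
    strand = res$strand
  )
}

#' Cluster contigs into viral populations (vOTUs)
#'
#' Greedy longest-first dereplication: contigs are sorted by length
#' (ties broken by lexicographic id), each contig joins the first
#' existing representative it matches at `min_ani` identity over
#' `min_cov` of the shorter sequence, otherwise it seeds a new vOTU.
#' The representative of each vOTU is therefore its longest member.
#'
#' @param contigs A tibble with columns `id` and `sequence`, or a named
#'   character vector.
#' @param min_ani Minimum average nucleotide identity (default 0.95).
#' @param min_cov Minimum aligned fraction of the shorter contig
#'   (default 0.80).
#' @param min_length Optional minimum contig length; shorter contigs are
#'   dropped before clustering (0 keeps everything).
#' @param k Anchor k-mer size passed to the ANI engine.
#' @return An object of class `votu_set` with elements `votus` (one row
#'   per population), `membership` (one row per contig), and `params`.
#'   See [tidy.votu_set()] and [glance.votu_set()].
#' @export
cluster_contigs <- function(contigs, min_ani = 0.95, min_cov = 0.80,
                            min_length = 0L, k = 13L) {
  if (is.character(contigs)) {
    contigs <- tibble(id = names(contigs), sequence = unname(contigs))
  }
  stopifnot(all(c("id", "sequence") %in% names(contigs)))
  if (anyDuplicated(contigs$id)) {
    abort("duplicate contig ids in input")
  }
  assert_dna(contigs$sequence, "contig sequences")
  contigs <- contigs %>%
    mutate(length = nchar(.data$sequence)) %>%
    filter(.data$length >= min_length) %>%
    arrange(dplyr::desc(.data$length), .data$id)

  n <- nrow(contigs)
  if (n == 0L) abort("no contigs left after length filtering")
  rep_idx <- integer(0)          # indices (into contigs) of representatives
  assignment <- integer(n)       # cluster number per contig
  for (i in seq_len(n)) {
    placed <- FALSE
    for (ci in seq_along(rep_idx)) {
      r <- rep_idx[ci]
      res <- ani_core(contigs$sequence[r], contigs$sequence[i], k = k)
      cov <- res$aligned_len / min(contigs$length[r], contigs$length[i])
      if (res$ani >= min_ani && cov >= min_cov) {
        assignment[i] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_idx <- c(rep_idx, i)
      assignment[i] <- length(rep_idx)
    }
  }

  votu_ids <- sprintf("vOTU_%d", seq_along(rep_idx))
  membership <- tibble(
    contig_id = contigs$id,
    votu_id = votu_ids[assignment],
    is_representative = seq_len(n) %in% rep_idx
  )
  votus <- tibble(
    votu_id = votu_ids,
    representative = contigs$id[rep_idx],
    length = contigs$length[rep_idx],
    n_members = as.integer(table(factor(assignment, seq_along(rep_idx))))
  )
  structure(
    list(
      votus = votus,
      membership = membership,
      representatives = setNames(contigs$sequence[rep_idx], votu_ids),
      params = list(min_ani = min_ani, min_cov = min_cov,
                    min_length = min_length, k = k)
    ),
    class = "votu_set"
  )
}

#' @export
print.votu_set <- function(x, ...) {
  cat(sprintf(
    "<votu_set> %d contigs in %d vOTUs (ANI >= %.2f over %.0f%% of length)\n",
    nrow(x$membership), nrow(x$votus),
    x$params$min_ani, 100 * x$params$min_cov
  ))
  print(x$votus, ...)
  invisible(x)
}

#' Tidy a vOTU clustering
#'
#' @param x A `votu_set` from [cluster_contigs()].
#' @param ... Unused.
#' @return `tidy()` returns the per-contig membership tibble
#'   (`contig_id`, `votu_id`, `is_representative`); `glance()` returns a
#'   one-row summary.
#' @method tidy votu_set
#' @export
tidy.votu_set <- function(x, ...) x$membership

#' @rdname tidy.votu_set
#' @method glance votu_set
#' @export
glance.votu_set <- function(x, ...) {
  tibble(
    n_contigs = nrow(x$membership),
    n_votus = nrow(x$votus),
    n_singletons = sum(x$votus$n_members == 1L),
    mean_length = mean(x$votus$length)
  )
}
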