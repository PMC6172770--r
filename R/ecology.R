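# Community-ecology statistics over the abundance/detection matrix:
# diversity indices, Bray-Curtis PCoA, habitat sharing, collector
# curves, codon-usage profiles, and the contaminant screen.

#' Richness, Shannon diversity, and Pielou evenness
#'
#' Computed on a (detection-masked, total-sum-scaled) abundance vector:
#' richness is the number of nonzero entries, `H' = -sum p log p` over
#' `p > 0` (natural log by default), and Pielou's
#' `J = H' / log(richness)` (defined 0 when richness is 0 or 1).
#'
#' @param x Non-negative abundance vector, or a samples-by-taxa matrix
#'   (one result row per sample).
#' @param base Logarithm base (default natural log, so `H'` is in
#'   nats).
#' @return A tibble with columns `richness`, `shannon`, `pielou` (and
#'   `sample` for matrix input).
#' @export
diversity_indices <- function(x, base = exp(1)) {
  if (is.matrix(x) || is.data.frame(x)) {
    m <- as.matrix(x)
    out <- bind_rows(lapply(seq_len(nrow(m)), function(i) {
      diversity_indices(m[i, ], base = base)
    }))
    out$sample <- rownames(m) %||% as.character(seq_len(nrow(m)))
    return(select(out, "sample", dplyr::everything()))
  }
  if (any(x < 0)) abort("abundances must be non-negative")
  p <- x[x > 0]
  s <- length(p)
  if (s == 0L) return(tibble(richness = 0L, shannon = 0, pielou = 0))
  p <- p / sum(p)
  h <- -sum(p * log(p, base = base))
  tibble(
    richness = s,
    shannon = h,
    pielou = if (s > 1) h / log(s, base = base) else 0
  )
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`; symmetric with zero
#' diagonal. A pair of all-zero samples is defined as 0 with a warning.
#'
#' @param m Non-negative samples-by-taxa matrix.
#' @return A symmetric dissimilarity matrix.
#' @export
bray_curtis <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) abort("bray_curtis() requires non-negative values")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  warned <- FALSE
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      denom <- sum(m[i, ] + m[j, ])
      if (denom == 0) {
        if (!warned) {
          warn("all-zero sample pair: Bray-Curtis defined as 0")
          warned <- TRUE
        }
        next
      }
      d[i, j] <- d[j, i] <- sum(abs(m[i, ] - m[j, ])) / denom
    }
  }
  d
}

#' Principal-coordinate analysis (classical scaling)
#'
#' Double-centers `-D^2 / 2`, eigendecomposes, and scales eigenvectors
#' by the square root of their eigenvalues. Axes are ordered by
#' eigenvalue; the sign convention makes the first nonzero loading of
#' each axis positive. Negative eigenvalues (possible for non-Euclidean
#' dissimilarities such as Bray-Curtis) are excluded from the
#' coordinates and variance fractions but reported.
#'
#' @param d Symmetric dissimilarity matrix with zero diagonal.
#' @return A `pcoa_ordination`: list with `points` (samples x axes),
#'   `eigenvalues` (positive, one per axis), `variance_explained`
#'   (fractions of the positive-eigenvalue total), and
#'   `negative_eigenvalues`.
#' @export
pcoa_ordination <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    abort("dissimilarity matrix must be symmetric")
  }
  n <- nrow(d)
  fit <- suppressWarnings(cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE))
  eig <- fit$eig
  tol <- max(abs(eig)) * 1e-9
  pos <- which(eig > tol)
  pts <- fit$points[, seq_along(pos), drop = FALSE]
  # sign convention: first loading of nonneglible magnitude is positive
  for (ax in seq_len(ncol(pts))) {
    v <- pts[, ax]
    first <- which(abs(v) > max(abs(v)) * 1e-8)[1]
    if (!is.na(first) && v[first] < 0) pts[, ax] <- -v
  }
  colnames(pts) <- paste0("Axis", seq_len(ncol(pts)))
  rownames(pts) <- rownames(d) %||% as.character(seq_len(n))
  structure(
    list(
      points = pts,
      eigenvalues = eig[pos],
      variance_explained = eig[pos] / sum(eig[pos]),
      negative_eigenvalues = eig[eig < -tol]
    ),
    class = "pcoa_ordination"
  )
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  ve <- x$variance_explained
  cat(sprintf(
    "<pcoa_ordination> %d samples, %d axes; axis 1-2 explain %.1f%% + %.1f%%\n",
    nrow(x$points), ncol(x$points),
    100 * ve[1], if (length(ve) > 1) 100 * ve[2] else 0
  ))
  invisible(x)
}

#' Tidy a PCoA ordination
#'
#' @param x A `pcoa_ordination`.
#' @param ... Unused.
#' @return `tidy()` returns one row per (sample, axis) with the score
#'   and the axis's variance fraction; `glance()` a one-row summary.
#' @method tidy pcoa_ordination
#' @export
tidy.pcoa_ordination <- function(x, ...) {
  as_tibble(x$points, rownames = "sample") %>%
    tidyr::pivot_longer(-"sample", names_to = "axis", values_to = "score") %>%
    mutate(variance_explained = x$variance_explained[
      as.integer(sub("Axis", "", .data$axis))
    ])
}

#' @rdname tidy.pcoa_ordination
#' @method glance pcoa_ordination
#' @export
glance.pcoa_ordination <- function(x, ...) {
  ve <- x$variance_explained
  tibble(
    n_samples = nrow(x$points),
    n_axes = ncol(x$points),
    axis1_pct = 100 * ve[1],
    axis2_pct = if (length(ve) > 1) 100 * ve[2] else 0,
    n_negative_eigenvalues = length(x$negative_eigenvalues)
  )
}

#' Collector (species accumulation) curves
#'
#' For each random permutation of sample order, the cumulative count of
#' distinct taxa; the mean curve across permutations flattens as
#' sampling saturates the community.
#'
#' @param presence Logical/0-1 samples-by-taxa matrix.
#' @param n_randomizations Number of sample-order randomizations.
#' @param seed Seed for the permutation stream.
#' @return A `collector_curve`: list with `curves` (tibble
#'   `randomization`, `n_samples`, `richness`) and `mean` (tibble
#'   `n_samples`, `mean_richness`).
#' @export
collectors_curve <- function(presence, n_randomizations = 50L, seed = 1L) {
  stopifnot(n_randomizations >= 1)
  m <- as.matrix(presence) > 0
  n <- nrow(m)
  curves <- with_op_seed(seed, "collector", {
    bind_rows(lapply(seq_len(n_randomizations), function(r) {
      perm <- sample.int(n)
      seen <- apply(m[perm, , drop = FALSE], 2, cummax)
      if (n == 1L) seen <- matrix(seen, nrow = 1)
      tibble(
        randomization = r,
        n_samples = seq_len(n),
        richness = as.integer(rowSums(seen))
      )
    }))
  })
  mean_curve <- curves %>%
    group_by(.data$n_samples) %>%
    summarise(mean_richness = mean(.data$richness), .groups = "drop")
  structure(list(curves = curves, mean = mean_curve),
            class = "collector_curve")
}

#' @export
print.collector_curve <- function(x, ...) {
  cat(sprintf(
    "<collector_curve> %d randomizations of %d samples; final richness %d\n",
    max(x$curves$randomization), max(x$curves$n_samples),
    as.integer(x$curves$richness[which.max(x$curves$n_samples)])
  ))
  invisible(x)
}

#' Habitat sharing of detected taxa
#'
#' Collapses per-sample detections to per-habitat presence and reports
#' the Euler-diagram regions: per-habitat sets, pairwise shared counts,
#' exclusive region sizes (which partition the detected taxa), and the
#' fraction detected in more than one habitat.
#'
#' @param presence Logical/0-1 samples-by-taxa matrix.
#' @param habitats Habitat label per sample (no missing values).
#' @return A `habitat_sharing`: list with `habitat_sets` (named list of
#'   taxa), `pairwise_shared` (matrix of shared counts), `regions`
#'   (tibble `region`, `n`; regions partition the detected taxa),
#'   `multi_habitat_fraction`, and `n_detected`.
#' @export
habitat_sharing <- function(presence, habitats) {
  m <- as.matrix(presence) > 0
  if (length(habitats) != nrow(m) || anyNA(habitats)) {
    abort("every sample needs a habitat label")
  }
  hs <- unique(habitats)
  by_hab <- vapply(hs, function(h) {
    colSums(m[habitats == h, , drop = FALSE]) > 0
  }, logical(ncol(m)))
  taxa <- colnames(m) %||% as.character(seq_len(ncol(m)))
  detected <- rowSums(by_hab) > 0
  habitat_sets <- lapply(setNames(hs, hs), function(h) taxa[by_hab[, h]])
  pairwise <- matrix(0L, length(hs), length(hs), dimnames = list(hs, hs))
  for (i in seq_along(hs)) {
    for (j in seq_along(hs)) {
      pairwise[i, j] <- sum(by_hab[, i] & by_hab[, j])
    }
  }
  pattern <- apply(by_hab, 1, function(row) {
    paste(hs[row], collapse = "&")
  })
  regions <- tibble(region = pattern[detected]) %>%
    dplyr::count(.data$region, name = "n") %>%
    arrange(dplyr::desc(.data$n))
  structure(
    list(
      habitat_sets = habitat_sets,
      pairwise_shared = pairwise,
      regions = regions,
      multi_habitat_fraction = if (any(detected)) {
        sum(rowSums(by_hab) > 1) / sum(detected)
      } else 0,
      n_detected = sum(detected)
    ),
    class = "habitat_sharing"
  )
}

#' @export
print.habitat_sharing <- function(x, ...) {
  cat(sprintf(
    "<habitat_sharing> %d detected taxa; %.0f%% in >1 habitat\n",
    x$n_detected, 100 * x$multi_habitat_fraction
  ))
  print(x$regions, ...)
  invisible(x)
}

#' Codon-usage frequency profile
#'
#' Frequencies over all codons of all coding sequences pooled together;
#' the 64-component vector sums to 1 and feeds [bray_curtis()] and
#' [pcoa_ordination()] for codon-usage ordinations of viruses and
#' their candidate hosts.
#'
#' @param cds_sequences Character vector of in-frame coding sequences
#'   (each length divisible by 3).
#' @return A named numeric vector of 64 codon frequencies.
#' @export
codon_usage_profile <- function(cds_sequences) {
  bad <- which(nchar(cds_sequences) %% 3 != 0)
  if (length(bad)) {
    nm <- names(cds_sequences)[bad[1]] %||% as.character(bad[1])
    abort(sprintf("CDS '%s' has length not divisible by 3", nm))
  }
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(cds_sequences), width = 3, step = 3
  )
  total <- colSums(counts)
  total / sum(total)
}

#' Screen contigs against contaminant references
#'
#' Flags contigs whose best alignment to any reference exceeds
#' `min_ani` identity over at least `min_cov` of the shorter sequence
#' (the laboratory-contaminant screen); removal is the caller's choice.
#'
#' @param contigs Tibble with `id` and `sequence` (or named character
#'   vector).
#' @param reference_set Same layout; may be empty (nothing flagged).
#' @param min_ani Identity threshold (flagging requires `ani >
#'   min_ani`).
#' @param min_cov Minimum aligned fraction of the shorter sequence for
#'   a hit to count.
#' @return A tibble with one row per contig: `contig_id`, `flagged`,
#'   `best_reference`, `ani`, `aligned_fraction`.
#' @export
screen_contaminants <- function(contigs, reference_set, min_ani = 0.95,
                                min_cov = 0.5) {
  if (is.character(contigs)) {
    contigs <- tibble(id = names(contigs), sequence = unname(contigs))
  }
  if (is.character(reference_set)) {
    reference_set <- tibble(id = names(reference_set),
                            sequence = unname(reference_set))
  }
  n_ref <- if (is.null(reference_set)) 0L else nrow(reference_set)
  out <- lapply(seq_len(nrow(contigs)), function(ci) {
    best <- list(ani = 0, frac = 0, ref = NA_character_)
    for (ri in seq_len(n_ref)) {
      res <- ani_core(contigs$sequence[ci], reference_set$sequence[ri])
      frac <- res$aligned_len /
        min(nchar(contigs$sequence[ci]), nchar(reference_set$sequence[ri]))
      if (frac >= min_cov && res$ani > best$ani) {
        best <- list(ani = res$ani, frac = frac, ref = reference_set$id[ri])
      }
    }
    tibble(
      contig_id = contigs$id[ci],
      flagged = best$ani > min_ani,
      best_reference = best$ref,
      ani = best$ani,
      aligned_fraction = best$frac
    )
  })
  bind_rows(out)
}
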