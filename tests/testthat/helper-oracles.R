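# Independent oracles and small fixture builders, kept deliberately
# naive and separate from the package's own algorithms.

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutate_at_rate <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  chars[hit] <- vapply(chars[hit], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  paste(chars, collapse = "")
}

rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Full dynamic-programming alignment oracle: ends-free alignment with
# heavy gap penalties (the synthetic world is substitution-only), ANI
# as identities over aligned (non-gap) columns.
dp_ani <- function(a, b) {
  one_strand <- function(bb) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(bb),
      type = "overlap",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -2
      ),
      gapOpening = 25, gapExtension = 10
    )
    nm <- Biostrings::nmatch(aln)
    nmm <- Biostrings::nmismatch(aln)
    list(ani = if (nm + nmm > 0) nm / (nm + nmm) else 0,
         aligned_len = nm + nmm, matches = nm)
  }
  fwd <- one_strand(b)
  rev <- one_strand(rc(b))
  if (fwd$matches >= rev$matches) fwd else rev
}

# Exhaustive hypergeometric tail: genome A occupies a fixed set of `a`
# PCs out of n; enumerate every b-subset for genome B and count those
# sharing at least cc PCs.
enum_hyper_tail <- function(a, b, cc, n) {
  sets <- utils::combn(n, b)
  in_a <- sets <= a   # wlog A = {1..a}
  mean(colSums(in_a) >= cc)
}

# Independent dense MCL: no pruning, attractor-row cluster extraction
# with overlap merging (distinct formulation from the package's).
ref_mcl <- function(adj, inflation, iters = 60) {
  m <- adj
  diag(m) <- pmax(apply(m, 1, max), 1)  # same loop convention
  m <- apply(m, 2, function(col) col / sum(col))
  for (i in seq_len(iters)) {
    m <- m %*% m
    m <- m^inflation
    m <- apply(m, 2, function(col) col / sum(col))
  }
  attractors <- which(diag(m) > 1e-6)
  clusters <- lapply(attractors, function(r) which(m[r, ] > 1e-6))
  # merge clusters sharing any node
  repeat {
    merged <- FALSE
    if (length(clusters) > 1) {
      for (i in seq_len(length(clusters) - 1)) {
        for (j in (i + 1):length(clusters)) {
          if (length(intersect(clusters[[i]], clusters[[j]]))) {
            clusters[[i]] <- union(clusters[[i]], clusters[[j]])
            clusters[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
    if (!merged) break
  }
  memb <- integer(nrow(adj))
  for (ci in seq_along(clusters)) memb[clusters[[ci]]] <- ci
  # unattracted nodes (none expected) become their own cluster
  loose <- which(memb == 0)
  memb[loose] <- seq_along(loose) + length(clusters)
  memb
}

# Naive sliding-window spacer scan over both strands.
naive_spacer_scan <- function(spacer, contig, max_mismatch = 0) {
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") spacer else rc(spacer)
    pl <- nchar(pat)
    pr <- charToRaw(pat)
    for (s in seq_len(nchar(contig) - pl + 1)) {
      mm <- sum(charToRaw(substr(contig, s, s + pl - 1)) != pr)
      if (mm <= max_mismatch) {
        out[[length(out) + 1]] <- data.frame(
          start = s - 1L, strand = strand, mismatches = mm
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), strand = character(),
                      mismatches = integer()))
  }
  do.call(rbind, out)
}

same_partition <- function(a, b) {
  thawvir:::adjusted_rand(a, b) == 1
}

# A small, fast scenario for pipeline plumbing tests.
tiny_config <- function(seed = 3L, ...) {
  pipeline_config(
    seed = seed,
    community = community_config(
      seed = seed, votus_per_habitat = 4L,
      genome_length_range = c(3000L, 3500L),
      n_reads = 4000L, read_len = 150L,
      host_count = 3L, n_linked_hosts = 2L, host_length = 6000L,
      spacers_per_array = 3L, vc_plan = c(5L, 4L), ...
    ),
    ecology = list(collector_randomizations = 10L)
  )
}
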