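# Shared internal helpers: seeded RNG streams, sequence primitives, and
# small numeric utilities used across modules.

# Derive a 32-bit sub-seed from (master seed, operation name) so every
# simulation stage draws from its own decoupled stream.
op_seed <- function(seed, op) {
  h <- sum(utf8ToInt(op) * seq_along(utf8ToInt(op)))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483647)
}

with_op_seed <- function(seed, op, code) {
  withr::with_seed(op_seed(seed, op), code)
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(len) {
  paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Point-mutate a sequence at the given per-base substitution rate.
# Substitutions always change the base.
mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  hit <- which(runif(n) < rate)
  if (length(hit) == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  chars[hit] <- vapply(chars[hit], function(b) {
    sample(setdiff(DNA_BASES, b), 1L)
  }, character(1))
  paste(chars, collapse = "")
}

# Vectorised Hamming mismatch count between two equal-length string
# vectors; operates on raw bytes so 10^5-read batches stay cheap.
count_mismatches <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) == 0L) return(integer(0))
  w <- nchar(x)
  stopifnot(all(w == nchar(y)), length(unique(w)) == 1L)
  rx <- charToRaw(paste(x, collapse = ""))
  ry <- charToRaw(paste(y, collapse = ""))
  neq <- rx != ry
  as.integer(colSums(matrix(neq, nrow = w[1])))
}

# All k-mers of a sequence with their 1-based start positions.
seq_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  substring(seq, 1:(L - k + 1), k:L)
}

assert_dna <- function(x, what = "sequence") {
  if (length(x) == 0L || any(!nzchar(x))) {
    abort(sprintf("%s must be non-empty", what))
  }
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    abort(sprintf("%s contains characters outside {A,C,G,T,N}", what))
  }
  invisible(x)
}

# Adjusted Rand index between two labellings of the same items.
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}
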