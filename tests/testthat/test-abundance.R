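aln_row <- function(read_id, contig_id, matches, aligned = 100,
                    read_len = 100, start = 0) {
  tibble::tibble(
    read_id = read_id, contig_id = contig_id, read_len = read_len,
    aligned_len = aligned, matches = matches,
    start = start, end = start + aligned, strand = "+"
  )
}

test_that("alignment filtering applies identity and best-hit rules", {
  aln <- dplyr::bind_rows(
    aln_row("r1", "c1", 95),          # retained
    aln_row("r2", "c1", 85),          # below 90%
    aln_row("r3", "c1", 95),          # best hit of r3
    aln_row("r3", "c2", 92)
  )
  out <- filter_alignments(aln)
  expect_equal(out$read_id, c("r1", "r3"))
  expect_equal(out$contig_id[out$read_id == "r3"], "c1")

  bad <- aln_row("r4", "c1", 120)     # matches > aligned_len
  expect_error(filter_alignments(dplyr::bind_rows(aln, bad)), "index 5")
})

test_that("breadth gates detection and abundance follows the formula", {
  # 1,000-bp contig covered over 800 distinct bp -> detected
  covered <- dplyr::bind_rows(lapply(0:7, function(i) {
    aln_row(paste0("r", i), "c1", 100, start = i * 100)
  }))
  res <- detect_and_quantify(covered, c(c1 = 1000), total_bp = 1e6)
  expect_true(res$detected)
  expect_equal(res$breadth, 0.8)

  # 700 bp covered -> not detected, abundance forced to 0
  part <- dplyr::bind_rows(lapply(0:6, function(i) {
    aln_row(paste0("r", i), "c1", 100, start = i * 100)
  }))
  res2 <- detect_and_quantify(part, c(c1 = 1000), total_bp = 1e6)
  expect_false(res2$detected)
  expect_equal(res2$abundance, 0)

  # 10-kb contig, 20,000 mapped bp, 1e8 bp library -> 20 per Gbp
  deep <- dplyr::bind_rows(lapply(seq_len(200), function(i) {
    aln_row(paste0("r", i), "big", 100, start = (i %% 100) * 100)
  }))
  res3 <- detect_and_quantify(deep, c(big = 10000), total_bp = 1e8)
  expect_equal(res3$abundance, 20)
  expect_error(
    detect_and_quantify(deep, c(other = 10000), total_bp = 1e8),
    "absent"
  )
})

test_that("abundance is linear in mapped bp and inverse in length and
           library size", {
  base <- dplyr::bind_rows(lapply(seq_len(80), function(i) {
    aln_row(paste0("r", i), "c", 100, start = (i %% 10) * 100)
  }))
  a1 <- detect_and_quantify(base, c(c = 1000), total_bp = 1e7)$abundance
  a2 <- detect_and_quantify(dplyr::bind_rows(base, base),
                            c(c = 1000), total_bp = 1e7)$abundance
  a3 <- detect_and_quantify(base, c(c = 1000), total_bp = 2e7)$abundance
  expect_equal(a2, 2 * a1)
  expect_equal(a3, a1 / 2)
})

test_that("total-sum scaling normalizes rows and flags zero rows", {
  m <- rbind(s1 = c(2, 2, 4), s2 = c(0, 0, 0))
  expect_warning(out <- total_sum_scale(m), "all-zero")
  expect_equal(unname(out["s1", ]), c(0.25, 0.25, 0.5))
  expect_equal(unname(out["s2", ]), c(0, 0, 0))
  m2 <- matrix(runif(30), 5)
  expect_equal(unname(rowSums(total_sum_scale(m2))), rep(1, 5),
               tolerance = 1e-12)
  expect_error(total_sum_scale(rbind(c(-1, 2))), "non-negative")
})

test_that("virome summaries reproduce the published accounting", {
  vs <- summarize_viromes(stordalen_virome_counts())
  g <- glance(vs)
  expect_equal(round(g$mean_assembled_pct), 19)
  expect_equal(round(g$min_assembled_pct), 5)
  expect_equal(round(g$max_assembled_pct), 32)
  expect_equal(round(g$votu_pct_of_assembled), 10)
  expect_equal(round(g$votu_pct_of_viral), 54)
  expect_equal(round(fold_ratio(vs, "bog_chilled_B", "bog_frozen_B")), 9)

  bad <- stordalen_virome_counts()
  bad$viral_reads[1] <- bad$assembled_reads[1] + 1
  expect_error(summarize_viromes(bad), "ordering")
})
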