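test_that("planted CRISPR arrays are found with exact geometry", {
  viral <- withr::with_seed(41, tibble::tibble(
    genome_id = c("v1", "v2"),
    sequence = c(rand_dna(1200), rand_dna(1200))
  ))
  sim <- simulate_hosts_with_crispr(
    host_count = 1, viral_genomes = viral, spacers_per_array = 5,
    repeat_len = 30, spacer_len = 35, host_length = 6000,
    n_linked = 1, seed = 42
  )
  arrays <- find_crispr_arrays(sim$hosts$sequence[1])
  expect_equal(nrow(arrays), 1)
  expect_equal(arrays$repeat_seq, sim$arrays$repeat_seq)
  expect_equal(arrays$n_repeats, 6)
  sp <- arrays$spacers[[1]]
  expect_equal(nrow(sp), 5)
  expect_setequal(sp$spacer, sim$host_links$spacer)
  # coordinates index back into the host sequence
  expect_equal(
    substring(sim$hosts$sequence[1], sp$start + 1, sp$end),
    sp$spacer
  )
})

test_that("random genomes yield no arrays; short spacers are rejected", {
  g <- withr::with_seed(43, rand_dna(20000))
  expect_equal(nrow(find_crispr_arrays(g)), 0)

  # tandem repeat with 10-bp gaps: spacer below range, rejected
  rep_seq <- withr::with_seed(44, rand_dna(30))
  gaps <- replicate(4, rand_dna(10))
  tandem <- paste0(rand_dna(500),
                   rep_seq, gaps[1], rep_seq, gaps[2], rep_seq, gaps[3],
                   rep_seq, rand_dna(500))
  expect_equal(nrow(find_crispr_arrays(tandem)), 0)
})

test_that("spacer matching reports both strands and respects mismatches", {
  withr::with_seed(45, {
    contig <- rand_dna(3000)
    fwd <- substr(contig, 501, 535)
    rev <- rc(substr(contig, 1201, 1235))
    # one-substitution copy of a third site
    near <- substr(contig, 2001, 2035)
    substr(near, 18, 18) <- setdiff(c("A", "C", "G", "T"),
                                    substr(near, 18, 18))[1]
    spacers <- c(s_fwd = fwd, s_rev = rev, s_near = near)
    hits <- match_spacers(spacers, c(votu1 = contig))
    expect_equal(hits$strand[hits$spacer_id == "s_fwd"], "+")
    expect_equal(hits$start[hits$spacer_id == "s_fwd"], 500)
    expect_equal(hits$strand[hits$spacer_id == "s_rev"], "-")
    expect_false("s_near" %in% hits$spacer_id)
    hits1 <- match_spacers(spacers, c(votu1 = contig), max_mismatch = 1)
    near_hit <- hits1[hits1$spacer_id == "s_near", ]
    expect_equal(near_hit$mismatches, 1L)
    expect_equal(near_hit$start, 2000L)
  })
  expect_warning(
    match_spacers(c(s = "ACGTACGTACGT"), c(v = "ACGTACGTACGTACGT")),
    "specificity"
  )
})

test_that("spacer matching agrees with the sliding-window oracle", {
  withr::with_seed(46, {
    for (mm_max in c(0L, 1L)) {
      contig <- rand_dna(1500)
      spacer <- mutate_at_rate(substr(contig, 700, 734), 0.03)
      oracle <- naive_spacer_scan(spacer, contig, mm_max)
      suppressWarnings(
        hits <- match_spacers(c(s = spacer), c(v = contig), mm_max)
      )
      expect_equal(nrow(hits), nrow(oracle))
      if (nrow(hits)) {
        expect_setequal(
          paste(hits$start, hits$strand, hits$mismatches),
          paste(oracle$start, oracle$strand, oracle$mismatches)
        )
      }
    }
  })
})

test_that("similarity linkage enforces all four thresholds", {
  withr::with_seed(47, {
    virus <- rand_dna(8000)
    backbone <- rand_dna(12000)
    plant <- function(seg, at) {
      paste0(substr(backbone, 1, at), seg,
             substr(backbone, at + 1, nchar(backbone)))
    }
    # 3,000-bp identical shared segment -> link at 100% ANI
    h_good <- plant(substr(virus, 1001, 4000), 5000)
    links <- similarity_link(c(v = virus), c(h = h_good))
    expect_equal(nrow(links), 1)
    expect_gte(links$aligned_len, 2500)
    expect_gt(links$ani, 0.99)
    expect_gte(links$bitscore, 50)
    expect_lte(links$evalue, 1e-3)

    # 2,000 bp at 90% identity: length fails
    h_short <- plant(mutate_at_rate(substr(virus, 1001, 3000), 0.10), 5000)
    expect_equal(nrow(similarity_link(c(v = virus), c(h = h_short))), 0)

    # 2,600 bp at 65% identity: identity fails
    h_weak <- plant(mutate_at_rate(substr(virus, 1001, 3600), 0.35), 5000)
    expect_equal(nrow(similarity_link(c(v = virus), c(h = h_weak))), 0)

    # unrelated host: no link
    expect_equal(nrow(similarity_link(c(v = virus),
                                      c(h = rand_dna(12000)))), 0)
  })
})

test_that("predict_hosts combines CRISPR and similarity evidence", {
  withr::with_seed(48, {
    viral <- tibble::tibble(genome_id = c("v1", "v2"),
                            sequence = c(rand_dna(6000), rand_dna(6000)))
    sim <- simulate_hosts_with_crispr(
      host_count = 2, viral_genomes = viral, spacers_per_array = 4,
      host_length = 9000, n_linked = 1, seed = 49
    )
    hosts <- sim$hosts
    # plant a similarity segment of v2 into the second (link-free) host
    hosts$sequence[2] <- paste0(
      substr(hosts$sequence[2], 1, 4000),
      substr(viral$sequence[2], 1000, 4000),
      substr(hosts$sequence[2], 4001, 9000)
    )
    links <- predict_hosts(
      tibble::tibble(id = viral$genome_id, sequence = viral$sequence),
      hosts
    )
    crispr <- links[links$evidence == "crispr", ]
    expect_setequal(
      paste(crispr$host_id, crispr$contig_id),
      unique(paste(sim$host_links$host_id, sim$host_links$genome_id))
    )
    sim_links <- links[links$evidence == "similarity", ]
    expect_equal(sim_links$host_id, "host_02")
    expect_equal(sim_links$contig_id, "v2")
  })
})
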