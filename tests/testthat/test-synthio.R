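test_that("community realizes configured pools, overlaps and abundances", {
  cfg0 <- community_config(overlap = matrix(0L, 3, 3), seed = 5)
  comm0 <- simulate_community(cfg0)
  expect_equal(nrow(comm0$genomes), 30)
  for (h1 in cfg0$habitats) {
    for (h2 in setdiff(cfg0$habitats, h1)) {
      expect_length(intersect(comm0$pools[[h1]], comm0$pools[[h2]]), 0)
    }
  }

  ov <- matrix(0L, 3, 3, dimnames = list(c("palsa", "bog", "fen"),
                                         c("palsa", "bog", "fen")))
  ov["bog", "fen"] <- ov["fen", "bog"] <- 4L
  cfg <- community_config(overlap = ov, seed = 5)
  comm <- simulate_community(cfg)
  expect_length(intersect(comm$pools$bog, comm$pools$fen), 4)
  expect_length(intersect(comm$pools$palsa, comm$pools$fen), 0)
  expect_equal(nrow(comm$genomes), 26)

  # abundance rows are per-habitat simplexes over the habitat's pool
  expect_equal(unname(rowSums(comm$abundance)), rep(1, 3))
  expect_true(all(comm$abundance[1, setdiff(colnames(comm$abundance),
                                            comm$pools$palsa)] == 0))
})

test_that("invalid overlap requests name the offending pair", {
  ov <- matrix(0L, 3, 3, dimnames = list(c("palsa", "bog", "fen"),
                                         c("palsa", "bog", "fen")))
  ov["palsa", "fen"] <- ov["fen", "palsa"] <- 99L
  expect_error(community_config(overlap = ov), "palsa.*fen")
})

test_that("a fixed seed reproduces the community bit-exactly", {
  cfg <- community_config(seed = 17, votus_per_habitat = 3L,
                          genome_length_range = c(2000L, 2500L))
  a <- simulate_community(cfg)
  b <- simulate_community(cfg)
  expect_identical(a$genomes, b$genomes)
  expect_identical(a$contigs, b$contigs)
  expect_identical(a$abundance, b$abundance)
  # changing only the seed preserves the configured counts
  cfg2 <- community_config(seed = 18, votus_per_habitat = 3L,
                           genome_length_range = c(2000L, 2500L))
  d <- simulate_community(cfg2)
  expect_equal(dim(d$abundance), dim(a$abundance))
  expect_false(identical(d$genomes$sequence, a$genomes$sequence))
})

test_that("error-free reads are exact substrings of their genome", {
  g <- withr::with_seed(1, c(genomeA = rand_dna(3000)))
  sim <- simulate_reads(g, c(genomeA = 1), n_reads = 50, read_len = 100,
                        err_rate = 0, seed = 2)
  for (i in seq_len(50)) {
    r <- sim$reads$sequence[i]
    expect_true(grepl(r, g, fixed = TRUE) || grepl(rc(r), g, fixed = TRUE))
  }
  expect_error(
    simulate_reads(g, c(genomeA = 1), 10, read_len = 4000, seed = 1),
    "shortest genome"
  )
})

test_that("read counts follow abundance x length weighting", {
  gs <- withr::with_seed(2, c(g1 = rand_dna(2000), g2 = rand_dna(2000)))
  sim <- simulate_reads(gs, c(g1 = 0.8, g2 = 0.2), n_reads = 50000,
                        read_len = 100, err_rate = 0, seed = 9)
  n1 <- sum(sim$truth$genome_id == "g1")
  sd3 <- 3 * sqrt(50000 * 0.8 * 0.2)
  expect_lt(abs(n1 - 40000), sd3)
})

test_that("substitution errors land at the configured rate", {
  g <- withr::with_seed(3, c(g = rand_dna(5000)))
  sim <- simulate_reads(g, c(g = 1), n_reads = 2000, read_len = 150,
                        err_rate = 0.05, seed = 4)
  # realign each read to its recorded origin and measure identity
  origin <- substring(g, sim$truth$start + 1, sim$truth$start + 150)
  reads <- ifelse(sim$truth$strand == "+", sim$reads$sequence,
                  rc(sim$reads$sequence))
  mm <- thawvir:::count_mismatches(reads, origin)
  expect_lt(abs(mean(1 - mm / 150) - 0.95), 0.005)
})

test_that("CRISPR hosts carry well-formed arrays traceable to viruses", {
  viral <- withr::with_seed(5, tibble::tibble(
    genome_id = c("v1", "v2", "v3"),
    sequence = vapply(rep(1500, 3), function(l) rand_dna(l), character(1))
  ))
  sim <- simulate_hosts_with_crispr(
    host_count = 2, viral_genomes = viral, spacers_per_array = 5,
    repeat_len = 30, spacer_len = 35, host_length = 5000,
    n_linked = 1, seed = 6
  )
  host <- sim$hosts$sequence[1]
  rep_seq <- sim$arrays$repeat_seq[1]
  # spacers_per_array + 1 identical repeats, spacers all distinct
  n_rep <- length(gregexpr(rep_seq, host, fixed = TRUE)[[1]])
  expect_equal(n_rep, 6)
  expect_equal(nrow(sim$host_links), 5)
  expect_length(unique(sim$host_links$spacer), 5)
  # every truth spacer is verbatim in its viral genome on the recorded strand
  for (i in seq_len(nrow(sim$host_links))) {
    vseq <- viral$sequence[viral$genome_id == sim$host_links$genome_id[i]]
    proto <- if (sim$host_links$strand[i] == "+") {
      sim$host_links$spacer[i]
    } else {
      rc(sim$host_links$spacer[i])
    }
    expect_true(grepl(proto, vseq, fixed = TRUE))
  }
  # the unlinked host shares no spacer-length substring with any virus
  free_host <- sim$hosts$sequence[2]
  host_kmers <- thawvir:::seq_kmers(free_host, 35)
  for (v in viral$sequence) {
    expect_false(any(thawvir:::seq_kmers(v, 35) %in% host_kmers))
  }
})

test_that("gene content realizes the sharing plan exactly", {
  gc <- simulate_gene_content(vc_plan = c(3, 3, 1), families_per_genome = 12,
                              intra_shared = 8, inter_shared = 0, seed = 7)
  counts <- table(gc$proteins$genome_id)
  expect_true(all(counts == 12))
  fams <- split(gc$proteins$family, gc$proteins$genome_id)
  cl <- gc$truth$vc_assignments
  for (i in seq_len(nrow(cl))) {
    for (j in seq_len(nrow(cl))) {
      if (i >= j) next
      shared <- length(intersect(fams[[cl$genome_id[i]]],
                                 fams[[cl$genome_id[j]]]))
      expect_equal(shared,
                   if (cl$cluster[i] == cl$cluster[j]) 8 else 0)
    }
  }
  expect_error(
    simulate_gene_content(c(2, 2), intra_shared = 3, inter_shared = 3),
    "sharing"
  )
})
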