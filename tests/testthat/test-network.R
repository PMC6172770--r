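test_that("hypergeometric tail matches closed-form cases and is symmetric", {
  expect_equal(hypergeom_shared_pc_pvalue(3, 3, 3, 5), 0.1)
  expect_equal(hypergeom_shared_pc_pvalue(4, 2, 0, 9), 1)
  withr::with_seed(31, {
    for (i in 1:20) {
      n <- sample(4:40, 1)
      a <- sample.int(n, 1)
      b <- sample.int(n, 1)
      cc <- sample.int(min(a, b), 1)
      expect_equal(hypergeom_shared_pc_pvalue(a, b, cc, n),
                   hypergeom_shared_pc_pvalue(b, a, cc, n))
    }
  })
  expect_error(hypergeom_shared_pc_pvalue(3, 3, 4, 5), "c <= min")
})

test_that("similarity score uses the corrected -log10(P x T) form", {
  # published comparison count: 2,052 genomes -> T = 2,052 x 2,051
  expect_equal(similarity_score(1e-8, 2052), 8 - log10(2052 * 2051))
  expect_lt(similarity_score(1, 2052), 0)
  # boundary algebra: S >= 1 exactly when P <= 0.1 / T
  t_comp <- 50 * 49
  expect_equal(similarity_score(0.1 / t_comp, 50), 1)
  expect_lt(similarity_score(0.1 / t_comp * 1.01, 50), 1)
  # log-space path survives underflowed tails
  expect_equal(similarity_score(n_genomes = 2052, log10_p = -400),
               400 - log10(2052 * 2051))
  expect_error(similarity_score(0, 2052), "log10_p")
})

test_that("MCL separates disconnected cliques at any inflation", {
  adj <- matrix(0, 8, 8)
  adj[1:4, 1:4] <- 1
  adj[5:8, 5:8] <- 1
  diag(adj) <- 0
  for (infl in c(1.2, 2, 3.6, 5)) {
    memb <- mcl(adj, inflation = infl)
    expect_length(unique(memb), 2)
    expect_length(unique(memb[1:4]), 1)
    expect_length(unique(memb[5:8]), 1)
  }
  # idempotent identity-like input converges immediately to singletons
  memb <- mcl(diag(0, 5), inflation = 2)
  expect_length(unique(memb), 5)
  expect_error(mcl(matrix(runif(9), 3)), "symmetric")
})

test_that("protein clustering applies thresholds and the two-genome rule", {
  proteins <- tibble::tibble(
    protein_id = c("g1_p1", "g1_p2", "g2_p1", "g2_p2", "g3_p1",
                   "g3_p2", "g3_p3"),
    genome_id = c("g1", "g1", "g2", "g2", "g3", "g3", "g3")
  )
  edges <- tibble::tibble(
    qseqid = c("g1_p1", "g1_p2", "g3_p2", "g1_p1", "g2_p2"),
    sseqid = c("g2_p1", "g2_p2", "g3_p3", "g3_p1", "g3_p1"),
    bitscore = c(120, 110, 150, 30, 90),
    evalue = c(1e-30, 1e-25, 1e-40, 1e-30, 1e-2)
  )
  # edge 4 fails bitscore, edge 5 fails evalue; the g3-internal family
  # spans one genome only and is demoted
  pcs <- build_protein_clusters(edges, proteins)
  expect_length(unique(pcs$pcs$pc_id), 2)
  expect_true(all(c("g3_p2", "g3_p3") %in% pcs$singletons$protein_id))
  expect_setequal(names(pcs$profiles), c("g1", "g2", "g3"))
  expect_length(pcs$profiles$g3, 0)

  expect_warning(
    build_protein_clusters(
      dplyr::bind_rows(edges, tibble::tibble(
        qseqid = "g1_p1", sseqid = "g1_p1", bitscore = 500, evalue = 0
      )),
      proteins
    ),
    "self-edge"
  )
})

test_that("planted families are recovered as PCs", {
  gc <- simulate_gene_content(vc_plan = c(4, 3), families_per_genome = 10,
                              intra_shared = 6, seed = 32)
  pcs <- build_protein_clusters(gc$edges, gc$proteins)
  rec <- dplyr::left_join(pcs$pcs, gc$truth$pc_assignments,
                          by = "protein_id")
  # each recovered PC corresponds to exactly one planted family and
  # vice versa (restricted to multi-genome families)
  expect_true(all(tapply(rec$family, rec$pc_id,
                         function(x) length(unique(x))) == 1))
  multi <- gc$proteins |>
    dplyr::group_by(family) |>
    dplyr::filter(dplyr::n_distinct(genome_id) >= 2) |>
    dplyr::ungroup()
  expect_setequal(rec$protein_id, multi$protein_id)
})

test_that("viral-cluster assignment scans 21 inflations and recovers
           planted clusters", {
  gc <- simulate_gene_content(vc_plan = c(4, 4), families_per_genome = 10,
                              intra_shared = 7, seed = 33)
  pcs <- build_protein_clusters(gc$edges, gc$proteins)
  vcs <- assign_viral_clusters(pcs)
  expect_equal(nrow(vcs$grid), 21)
  expect_equal(vcs$grid$inflation, seq(1, 5, by = 0.2))
  expect_true(all(vcs$grid$n_clusters == 2))
  truth <- gc$truth$vc_assignments
  rec <- tidy(vcs)
  joined <- dplyr::left_join(truth, rec, by = "genome_id")
  expect_true(same_partition(joined$cluster, joined$vc_id))
  expect_true(all(rec$class == "clustered"))
})

test_that("profile-less genomes are singletons and do not perturb scores", {
  profiles <- list(
    g1 = paste0("PC_", 1:6),
    g2 = paste0("PC_", 1:6),
    g3 = paste0("PC_", 7:12)
  )
  net <- genome_network(profiles)
  withone <- genome_network(c(profiles, list(g4 = character(0))))
  expect_equal(net$score, withone$score)
  vcs <- assign_viral_clusters(c(profiles, list(g4 = character(0))))
  cls <- setNames(tidy(vcs)$class, tidy(vcs)$genome_id)
  expect_equal(unname(cls["g4"]), "singleton")
  expect_equal(unname(cls["g3"]), "singleton")

  # scores depend only on pc_set contents, not labels
  relabel <- lapply(profiles, function(p) sub("PC_", "FAM", p))
  expect_equal(genome_network(relabel)$score, net$score)
})

test_that("an empty network warns and classifies all genomes singleton", {
  profiles <- list(g1 = "PC_1", g2 = "PC_2", g3 = character(0))
  expect_warning(vcs <- assign_viral_clusters(profiles), "singleton")
  expect_true(all(tidy(vcs)$class == "singleton"))
})
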