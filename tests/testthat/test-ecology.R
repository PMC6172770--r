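test_that("diversity indices match closed forms", {
  u <- diversity_indices(rep(0.1, 10))
  expect_equal(u$shannon, log(10))
  expect_equal(u$pielou, 1)
  expect_equal(u$richness, 10L)

  one <- diversity_indices(c(0, 1, 0))
  expect_equal(one$shannon, 0)
  expect_equal(one$pielou, 0)

  h <- diversity_indices(c(0.5, 0.3, 0.2))$shannon
  expect_equal(h, -(0.5 * log(0.5) + 0.3 * log(0.3) + 0.2 * log(0.2)),
               tolerance = 1e-12)

  zero <- diversity_indices(c(0, 0))
  expect_equal(zero$richness, 0L)

  # invariance to pre-scaling of raw abundances
  x <- c(4, 1, 0, 7, 3)
  expect_equal(diversity_indices(x), diversity_indices(x / sum(x)))
  expect_equal(diversity_indices(x), diversity_indices(x * 1e6))
})

test_that("Bray-Curtis matches arithmetic and the vegan oracle", {
  m <- rbind(a = c(1, 2, 0), b = c(0, 2, 2), c = c(1, 2, 0))
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 3 / 7)
  expect_equal(d["a", "c"], 0)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))

  disjoint <- rbind(x = c(1, 1, 0, 0), y = c(0, 0, 2, 3))
  expect_equal(bray_curtis(disjoint)["x", "y"], 1)

  r <- withr::with_seed(51, matrix(runif(60), 6))
  expect_equal(bray_curtis(r),
               as.matrix(vegan::vegdist(r, method = "bray")),
               ignore_attr = TRUE, tolerance = 1e-12)

  zz <- rbind(a = c(0, 0), b = c(0, 0))
  expect_warning(dz <- bray_curtis(zz), "all-zero")
  expect_equal(dz["a", "b"], 0)
})

test_that("PCoA recovers planted geometry with the stated conventions", {
  # three collinear points: one axis carries all variance
  d3 <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3)
  ord3 <- pcoa_ordination(d3)
  expect_equal(ord3$variance_explained[1], 1)

  # a planted 2-D configuration comes back up to rotation/reflection
  x <- withr::with_seed(52, matrix(rnorm(20), ncol = 2))
  ord <- pcoa_ordination(as.matrix(dist(x)))
  expect_equal(ncol(ord$points), 2)
  pr <- vegan::procrustes(x, ord$points, symmetric = TRUE)
  expect_lt(pr$ss, 1e-8)
  expect_true(all(ord$variance_explained >= 0))
  expect_lte(sum(ord$variance_explained), 1 + 1e-12)

  expect_error(pcoa_ordination(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("collector curves are monotone and hit the known endpoints", {
  # identical samples: flat at the shared richness
  flat <- matrix(1, nrow = 4, ncol = 7)
  cc_flat <- collectors_curve(flat, 20, seed = 53)
  expect_true(all(cc_flat$curves$richness == 7))

  # pairwise-disjoint samples: mean curve exactly linear
  disj <- rbind(c(1, 1, 0, 0, 0, 0), c(0, 0, 1, 1, 0, 0),
                c(0, 0, 0, 0, 1, 1))
  cc_d <- collectors_curve(disj, 25, seed = 54)
  expect_equal(cc_d$mean$mean_richness, c(2, 4, 6))

  pres <- withr::with_seed(55, matrix(runif(6 * 30) < 0.4, nrow = 6))
  cc1 <- collectors_curve(pres, 200, seed = 56)
  expect_true(all(diff(cc1$mean$mean_richness) >= 0))
  by_rand <- split(cc1$curves$richness, cc1$curves$randomization)
  expect_true(all(vapply(by_rand, function(r) all(diff(r) >= 0),
                         logical(1))))
  # every permutation ends at the total richness
  expect_true(all(vapply(by_rand, function(r) r[length(r)],
                         integer(1)) == sum(colSums(pres) > 0)))
  # two seeds agree within Monte-Carlo tolerance at 200 randomizations
  cc2 <- collectors_curve(pres, 200, seed = 57)
  expect_lt(max(abs(cc1$mean$mean_richness - cc2$mean$mean_richness)), 1)
})

test_that("habitat sharing partitions detected taxa", {
  pres <- rbind(
    p1 = c(1, 1, 0, 0, 0), p2 = c(1, 0, 0, 0, 0),
    b1 = c(0, 1, 1, 1, 0), b2 = c(0, 0, 1, 0, 0),
    f1 = c(0, 0, 0, 1, 1)
  )
  colnames(pres) <- paste0("t", 1:5)
  hs <- habitat_sharing(pres, c("palsa", "palsa", "bog", "bog", "fen"))
  expect_equal(hs$pairwise_shared["palsa", "bog"], 1L)  # t2
  expect_equal(hs$pairwise_shared["bog", "fen"], 1L)    # t4
  expect_equal(hs$pairwise_shared["palsa", "fen"], 0L)
  expect_equal(sum(hs$regions$n), hs$n_detected)
  expect_equal(hs$multi_habitat_fraction, 2 / 5)

  all_shared <- matrix(1, 3, 4)
  hs2 <- habitat_sharing(all_shared, c("a", "b", "c"))
  expect_equal(hs2$multi_habitat_fraction, 1)
  expect_error(habitat_sharing(pres, c("palsa", NA, "bog", "bog", "fen")),
               "habitat label")
})

test_that("codon usage profiles are proper frequency vectors", {
  p <- codon_usage_profile("ATGATGATG")
  expect_equal(unname(p["ATG"]), 1)
  expect_equal(sum(p), 1)
  expect_length(p, 64)

  cds <- withr::with_seed(58, vapply(c(300, 600), function(l) {
    rand_dna(l)
  }, character(1)))
  p1 <- codon_usage_profile(cds[1])
  p2 <- codon_usage_profile(cds[2])
  both <- codon_usage_profile(cds)
  expect_equal(sum(both), 1, tolerance = 1e-12)
  # concatenation = length-weighted mean of the parts
  expect_equal(both, (100 * p1 + 200 * p2) / 300, tolerance = 1e-12)

  expect_error(codon_usage_profile(c(good = "ATGATG", bad = "ATGA")),
               "bad")
})

test_that("the contaminant screen flags only true copies", {
  withr::with_seed(59, {
    ref <- rand_dna(2000)
    copied <- ref
    diverged <- mutate_at_rate(ref, 0.10)   # ~90% ANI
    clean <- rand_dna(2000)
    contigs <- c(copy = copied, far = diverged, clean = clean)
    res <- screen_contaminants(contigs, c(ref1 = ref))
    flags <- setNames(res$flagged, res$contig_id)
    expect_true(flags[["copy"]])
    expect_false(flags[["far"]])
    expect_false(flags[["clean"]])
    # empty reference set flags nothing
    none <- screen_contaminants(contigs,
                                tibble::tibble(id = character(),
                                               sequence = character()))
    expect_false(any(none$flagged))
  })
})
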