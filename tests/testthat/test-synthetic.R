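test_that("pure-birth simulation hits the tip target and is reproducible", {
  x <- simulate_bd_chronogram(n_tips = 10, birth = 1, death = 0, seed = 1)
  expect_equal(ape::Ntip(x$phy), 10)
  expect_equal(x$phy$Nnode, 9)  # strictly binary
  expect_equal(nrow(validate_chronogram(x)), 0)
  y <- simulate_bd_chronogram(n_tips = 10, birth = 1, death = 0, seed = 1)
  expect_identical(write_chronogram(x), write_chronogram(y))
})

test_that("tip-count stopping is exact across seeds, with extinction", {
  for (seed in 1:100) {
    x <- simulate_bd_chronogram(n_tips = 12, birth = 0.5, death = 0.2,
                                seed = seed)
    expect_equal(ape::Ntip(x$phy), 12)
    expect_equal(nrow(validate_chronogram(x)), 0)
  }
})

test_that("simulator rejects inconsistent stopping rules and schedules", {
  expect_error(simulate_bd_chronogram(n_tips = 10, duration = 5), "exactly one")
  expect_error(simulate_bd_chronogram(), "exactly one")
  expect_error(simulate_bd_chronogram(n_tips = 10, birth = -1), "non-negative")
  ep <- data.frame(start_age = 5, end_age = 0, birth = 1, death = 0)
  expect_error(simulate_bd_chronogram(n_tips = 10, epochs = ep), "duration")
  bad <- data.frame(start_age = c(5, 2), end_age = c(3, 0),
                    birth = 1, death = 0)
  expect_error(simulate_bd_chronogram(duration = 5, epochs = bad),
               "contiguous")
})

test_that("epoch schedules modulate rates through time", {
  # no speciation allowed in the old half, so every split is younger than 5
  ep <- data.frame(start_age = c(10, 5), end_age = c(5, 0),
                   birth = c(0, 0.8), death = 0)
  x <- simulate_bd_chronogram(duration = 10, epochs = ep, seed = 11)
  internal_ages <- x$age[-seq_len(ape::Ntip(x$phy))]
  expect_true(all(internal_ages[internal_ages < tree_height(x) - 1e-9] < 5))
})

test_that("high extinction exhausts the retry budget with a clear error", {
  expect_error(
    simulate_bd_chronogram(n_tips = 50, birth = 0.01, death = 5, seed = 2,
                           retries = 3),
    "extinct in all 3 attempts")
})

test_that("per-lineage event rate matches the Yule expectation", {
  # events per lineage-Myr, averaged over duration-stopped pure-birth runs,
  # estimates the birth rate
  set.seed(42)
  est <- replicate(500, {
    x <- simulate_bd_chronogram(duration = 3, birth = 1, death = 0,
                                seed = sample.int(1e8, 1))
    (ape::Ntip(x$phy) - 2) / sum(x$phy$edge.length)
  })
  expect_equal(mean(est), 1.0, tolerance = 0.1)
})

test_that("proportions mode labels every tip from the allowed statuses", {
  x <- random_chronogram(10, seed = 3)
  taxa <- assign_categories(x, "proportions",
                            proportions = c(endemic = 0.5, native = 0.5),
                            seed = 1)
  expect_setequal(taxa$species, x$phy$tip.label)
  expect_true(all(taxa$status %in% c("endemic", "native")))
})

test_that("exact-count assignment reproduces the requested composition", {
  x <- random_chronogram(30, seed = 9)
  taxa <- assign_categories(x, counts = c(endemic = 4, native = 20,
                                          exotic = 3, outgroup = 3),
                            seed = 2)
  expect_equal(taxon_counts(taxa),
               c(endemic = 4L, native = 20L, exotic = 3L, outgroup = 3L))
})

test_that("label frequencies follow the proportions binomially", {
  x <- simulate_bd_chronogram(n_tips = 1000, birth = 0.08, death = 0.03,
                              seed = 5)
  p <- c(endemic = 0.1, native = 0.74, exotic = 0.16)
  nseed <- 200
  tot <- c(endemic = 0, native = 0, exotic = 0)
  for (s in seq_len(nseed)) {
    taxa <- assign_categories(x, "proportions", proportions = p, seed = s)
    cnt <- taxon_counts(taxa)
    tot <- tot + cnt[names(p)]
  }
  n <- 1000 * nseed
  for (st in names(p)) {
    sd3 <- 3 * sqrt(n * p[[st]] * (1 - p[[st]]))
    expect_lt(abs(tot[[st]] - n * p[[st]]), sd3)
  }
})

test_that("clade enrichment with strength 1 marks exactly the window clade", {
  # one clade of 4 tips with root age 10; everything else far older
  x <- parse_chronogram(
    "(((a:5,b:5):5,(c:5,d:5):5):90,((e:60,f:60):20,g:80):20);")
  taxa <- assign_categories(x, "clade_enriched",
                            proportions = c(native = 1),
                            target = "endemic", window = c(8, 12),
                            strength = 1, seed = 4)
  endo <- taxa$species[taxa$status == "endemic"]
  expect_setequal(endo, c("a", "b", "c", "d"))
  expect_true(all(taxa$status[!taxa$species %in% endo] == "native"))
})

test_that("an empty enrichment window is an error", {
  x <- t1_tree()
  expect_error(
    assign_categories(x, "clade_enriched", proportions = c(native = 1),
                      target = "endemic", window = c(100, 120), seed = 1),
    "window contains no clade")
})

test_that("synthesized taxonomy is nested and genera are clades", {
  x <- random_chronogram(80, seed = 12)
  taxa <- assign_categories(x, "proportions", seed = 6)
  # nesting: one family per genus, one order per family
  expect_true(all(tapply(taxa$family, taxa$genus,
                         function(v) length(unique(v))) == 1))
  expect_true(all(tapply(taxa$order, taxa$family,
                         function(v) length(unique(v))) == 1))
  # monophyly: the MRCA of a genus with >= 2 tips spans only that genus
  for (g in unique(taxa$genus)) {
    tips <- taxa$species[taxa$genus == g]
    if (length(tips) < 2) next
    v <- ape::getMRCA(x$phy, tips)
    desc <- ape::extract.clade(x$phy, v)$tip.label
    expect_setequal(desc, tips)
  }
})

test_that("synthetic age intervals bracket ages and respect the halfwidth", {
  x <- random_chronogram(40, seed = 8)
  y <- synthesize_age_intervals(x, 0.25, seed = 5)
  internal <- seq.int(ape::Ntip(y$phy) + 1, ape::Ntip(y$phy) + y$phy$Nnode)
  expect_true(all(y$lower[internal] < y$age[internal]))
  expect_true(all(y$upper[internal] > y$age[internal]))
  expect_true(all(y$lower[internal] >= y$age[internal] * 0.75))
  expect_true(all(y$upper[internal] <= y$age[internal] * 1.25))
  z <- synthesize_age_intervals(x, 0.25, seed = 5)
  expect_identical(z$lower, y$lower)
  expect_error(synthesize_age_intervals(x, 0), "between 0 and 1")
  expect_error(synthesize_age_intervals(x, 1), "between 0 and 1")
})

test_that("alignment fixtures have the requested shape and missingness", {
  f <- make_alignment_fixture(c(2, 3, 4), 3, 0, seed = 1)
  expect_equal(vapply(f$alignments, ncol, 0L), c(locus1 = 2L, locus2 = 3L,
                                                 locus3 = 4L))
  expect_equal(ncol(concatenate_loci(f$alignments)$matrix), 9)
  expect_equal(f$realized_missing, 0)
  # realized missingness concentrates around the target across seeds
  fr <- vapply(1:30, function(s)
    make_alignment_fixture(rep(100, 6), 100, 0.59, seed = s)$realized_missing,
    numeric(1))
  expect_lt(abs(mean(fr) - 0.59), 0.05)
  # files are written as valid aligned FASTA
  d <- tempfile(); f2 <- make_alignment_fixture(c(5, 7), 4, 0.3, seed = 2,
                                                dir = d)
  expect_true(all(file.exists(f2$paths)))
  back <- read_fasta_alignment(f2$paths[1])
  expect_equal(dim(back), c(4, 5))
})
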