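graft_taxa <- function() t1_taxa()  # A,B in genus g1; C in g2; all in f1/o1

test_that("attachment levels resolve to the documented nodes", {
  x <- t1_tree()
  taxa <- graft_taxa()
  # two congeners A,B -> their MRCA at age 10
  reqX <- list(species = "X", genus = "g1", family = "f1", order = "o1")
  v <- find_attachment(x, taxa, reqX, "two_congeners")
  expect_equal(x$age[v], 10)
  # one congener C -> its parent, the root at age 40
  reqY <- list(species = "Y", genus = "g2", family = "f1", order = "o1")
  expect_true(is.na(find_attachment(x, taxa, reqY, "two_congeners")))
  v2 <- find_attachment(x, taxa, reqY, "one_congener")
  expect_equal(x$age[v2], 40)
  # family {A,B,C} -> MRCA of all members, the root
  reqZ <- list(species = "Z", genus = "g9", family = "f1", order = "o1")
  v3 <- find_attachment(x, taxa, reqZ, "family")
  expect_equal(x$age[v3], 40)
  # absent rank returns none
  reqW <- list(species = "W", genus = "gX", family = "fX", order = "oX")
  expect_true(is.na(find_attachment(x, taxa, reqW, "order")))
})

test_that("grafting builds polytomies with tip branch length = node age", {
  x <- t1_tree()
  req <- data.frame(species = "X", genus = "g1", family = "f1", order = "o1",
                    status = "native")
  g <- apply_grafts(x, graft_taxa(), req)
  expect_equal(ape::Ntip(g$phy), 4)
  rep <- attr(g, "graft_report")
  expect_equal(rep$level, "two_congeners")
  expect_equal(rep$branch_length, rep$node_age)
  expect_equal(rep$node_age, 10)
  ev <- split_events(g)
  expect_equal(sum(ev$weight), 3)
  expect_equal(ev$weight[ev$age == 10], 2L)
  expect_equal(nrow(validate_chronogram(g)), 0)
})

test_that("escalation stops at the first applicable level", {
  x <- t1_tree()
  # X has two congeners AND a family match; must be placed at level 1
  req <- data.frame(species = "X", genus = "g1", family = "f1", order = "o1")
  g <- apply_grafts(x, graft_taxa(), req)
  expect_equal(attr(g, "graft_report")$level, "two_congeners")
})

test_that("unplaceable species are reported, not fatal", {
  x <- t1_tree()
  req <- data.frame(species = c("X", "Q"),
                    genus = c("g1", "gQ"), family = c("f1", "fQ"),
                    order = c("o1", "oQ"))
  g <- apply_grafts(x, graft_taxa(), req)
  rep <- attr(g, "graft_report")
  expect_equal(rep$level, c("two_congeners", "unplaced"))
  expect_true(is.na(rep$node_age[2]))
  expect_equal(ape::Ntip(g$phy), 4)  # only X added
})

test_that("request validation catches duplicates and label clashes", {
  x <- t1_tree()
  dup <- data.frame(species = c("X", "X"), genus = "g1", family = "f1",
                    order = "o1")
  expect_error(apply_grafts(x, graft_taxa(), dup), "duplicate")
  clash <- data.frame(species = "A", genus = "g1", family = "f1",
                      order = "o1")
  expect_error(apply_grafts(x, graft_taxa(), clash), "already in the tree")
})

test_that("grafting preserves backbone ages, topology and ultrametricity", {
  for (seed in 1:10) {
    x <- random_chronogram(30, seed = seed)
    taxa <- assign_categories(x, "proportions", seed = seed + 50)
    k <- 6
    pick <- taxa[sample(nrow(taxa), k), ]
    req <- data.frame(species = sprintf("new%02d", seq_len(k)),
                      genus = pick$genus, family = pick$family,
                      order = pick$order, status = "native")
    g <- apply_grafts(x, taxa, req)
    rep <- attr(g, "graft_report")
    placed <- sum(rep$level != "unplaced")
    expect_equal(ape::Ntip(g$phy), 30 + placed)
    expect_equal(nrow(validate_chronogram(g)), 0)
    # all original node ages survive unchanged
    expect_true(all(x$age %in% g$age))
    # pruning back to the backbone tips reproduces the backbone
    back <- prune_to_taxa(g, x$phy$tip.label)
    expect_identical(write_chronogram(back), write_chronogram(x))
  }
})

test_that("placement is order-independent under backbone-only attachment", {
  x <- random_chronogram(25, seed = 21)
  taxa <- assign_categories(x, "proportions", seed = 22)
  pick <- taxa[sample(nrow(taxa), 5), ]
  req <- data.frame(species = sprintf("new%d", 1:5), genus = pick$genus,
                    family = pick$family, order = pick$order)
  g1 <- apply_grafts(x, taxa, req)
  g2 <- apply_grafts(x, taxa, req[5:1, ])
  expect_true(ape::all.equal.phylo(g1$phy, g2$phy, use.edge.length = TRUE))
})

test_that("sequential mode lets grafted tips recruit later requests", {
  x <- t1_tree()
  # Y's only congener is X, itself a graft: placeable only sequentially
  req <- data.frame(species = c("X", "Y"),
                    genus = c("g1", "gN"), family = c("f1", "fN"),
                    order = c("o1", "oN"), status = "native",
                    stringsAsFactors = FALSE)
  req$genus[2] <- "g1"  # congener of A, B and (once placed) X
  g_def <- apply_grafts(x, graft_taxa(), req)
  g_seq <- apply_grafts(x, graft_taxa(), req, sequential = TRUE)
  expect_equal(ape::Ntip(g_def$phy), 5)
  expect_equal(ape::Ntip(g_seq$phy), 5)
  # a request whose genus only matches another request
  req2 <- data.frame(species = c("P", "Q"), genus = "g1", family = "f9",
                     order = "o9", status = "native")
  req2$genus <- c("g1", "gP")
  # Q matches nothing on the backbone
  g3 <- apply_grafts(x, graft_taxa(), req2)
  expect_equal(attr(g3, "graft_report")$level[2], "unplaced")
})

test_that("the chronogram series grows monotonically in coverage", {
  x <- random_chronogram(40, seed = 31)
  taxa <- assign_categories(x, "proportions", seed = 32)
  # requests spanning all levels: congeners, family-only, order-only matches
  pick <- taxa[sample(nrow(taxa), 8), ]
  req <- data.frame(species = sprintf("add%d", 1:8),
                    genus = c(pick$genus[1:3], sprintf("zz%d", 1:5)),
                    family = c(pick$family[1:6], "zf1", "zf2"),
                    order = c(pick$order[1:7], "zo1"))
  ser <- chronogram_series(x, taxa, req)
  expect_named(ser, c("congeners2", "congeners1", "family", "order"))
  tipn <- vapply(ser, function(t) ape::Ntip(t$phy), 0L)
  expect_true(all(diff(tipn) >= 0))
  for (t in ser) expect_equal(nrow(validate_chronogram(t)), 0)
})

test_that("an empty request set returns four backbone copies", {
  x <- t1_tree()
  req <- data.frame(species = character(0), genus = character(0),
                    family = character(0), order = character(0))
  ser <- chronogram_series(x, t1_taxa(), req)
  for (t in ser)
    expect_identical(write_chronogram(t), write_chronogram(x))
})
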