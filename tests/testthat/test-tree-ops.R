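test_that("newick I/O enforces the tree invariants", {
  p <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1):0;", p)
  tr <- read_newick(p)
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(max(ape::node.depth.edgelength(tr)), 1)

  writeLines("(A:1,A:1);", p)
  expect_error(read_newick(p), class = "geothermflora_parse_error")

  writeLines("(A,B);", p)
  expect_error(read_newick(p), class = "geothermflora_parse_error") # no lengths

  writeLines("(A:1,(B:1;", p)
  expect_error(read_newick(p), class = "geothermflora_parse_error")

  expect_error(read_newick(file.path(tempdir(), "no-such-file.nwk")),
               class = "geothermflora_parse_error")
})

test_that("write/read round trip preserves topology and lengths to 1e-9", {
  tr <- fixture_tree(40, seed = 7)
  p <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, p)
  tr2 <- read_newick(p)
  m1 <- patristic_matrix(tr)
  m2 <- patristic_matrix(tr2)[rownames(m1), colnames(m1)]
  expect_lt(max(abs(m1 - m2)), 1e-9)
})

test_that("patristic distances match the path-sum and MRCA-depth oracles", {
  p <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:2);", p)
  expect_equal(patristic_matrix(read_newick(p))["A", "B"], 3)

  tr <- fixture_tree(10, seed = 13)
  m <- patristic_matrix(tr)
  for (pair in utils::combn(tr$tip.label, 2, simplify = FALSE)) {
    expect_equal(m[pair[1], pair[2]],
                 oracle_ultra_dist(tr, pair[1], pair[2]), tolerance = 1e-10)
  }
  expect_error(patristic_matrix(tr, c("t01", "nope")),
               class = "geothermflora_lookup_error")
})

test_that("patristic matrix is a metric and satisfies the four-point condition", {
  tr <- fixture_tree(8, seed = 17)
  m <- patristic_matrix(tr)
  expect_true(all(diag(m) == 0))
  expect_equal(m, t(m))
  labs <- rownames(m)
  for (q in utils::combn(labs, 4, simplify = FALSE)) {
    s1 <- m[q[1], q[2]] + m[q[3], q[4]]
    s2 <- m[q[1], q[3]] + m[q[2], q[4]]
    s3 <- m[q[1], q[4]] + m[q[2], q[3]]
    sums <- sort(c(s1, s2, s3))
    expect_lt(sums[3] - sums[2], 1e-9) # two largest sums are equal
  }
  # triangle inequality over all triples
  for (t3 in utils::combn(labs, 3, simplify = FALSE)) {
    expect_lte(m[t3[1], t3[2]],
               m[t3[1], t3[3]] + m[t3[2], t3[3]] + 1e-12)
  }
})

test_that("grafting restores pruned species, preserves geometry, and respects methods", {
  cfg <- small_config(seed = 81)
  d <- gen_dataset(cfg)
  tax <- d$pool
  # prune about a quarter of the pool, keeping every family represented
  keep_one <- function() {
    drop <- character(0)
    left <- table(tax$family)
    for (s in withr::with_seed(9, sample(tax$species))) {
      f <- tax$family[tax$species == s]
      if (left[[f]] > 1 && length(drop) < 12) {
        drop <- c(drop, s)
        left[[f]] <- left[[f]] - 1
      }
    }
    drop
  }
  dropped <- keep_one()
  pruned <- ape::drop.tip(d$tree, dropped)
  m0 <- patristic_matrix(pruned)

  for (method in c("basal_polytomy", "random_within_family",
                   "taxonomy_constrained")) {
    g <- graft_species(pruned, tax, dropped, method = method, seed = 3)
    expect_setequal(g$tip.label, tax$species)
    expect_true(ape::is.ultrametric(g, tol = 1e-6))
    mg <- patristic_matrix(g)[rownames(m0), colnames(m0)]
    expect_lt(max(abs(m0 - mg)), 1e-8) # pre-existing distances preserved
    if (method != "taxonomy_constrained") {
      # each grafted tip's nearest relative is in its own family
      mfull <- patristic_matrix(g)
      for (s in dropped) {
        others <- setdiff(tax$species, s)
        nearest <- others[which.min(mfull[s, others])]
        expect_equal(tax$family[tax$species == nearest],
                     tax$family[tax$species == s])
      }
    }
  }

  # grafting nothing is the identity
  g0 <- graft_species(pruned, tax, character(0), method = "basal_polytomy")
  expect_identical(ape::write.tree(g0), ape::write.tree(pruned))

  # basal polytomy attaches at the family MRCA
  fam <- names(which(table(tax$family[tax$species %in% pruned$tip.label]) >= 2))[1]
  fam_tips <- intersect(tax$species[tax$family == fam], pruned$tip.label)
  g1 <- graft_species(pruned, tibble::tibble(species = "newbie", family = fam,
                                             order = "X") |>
                        dplyr::bind_rows(tax),
                      "newbie", method = "basal_polytomy")
  mrca <- ape::getMRCA(g1, fam_tips)
  parent <- g1$edge[g1$edge[, 2] == which(g1$tip.label == "newbie"), 1]
  expect_equal(parent, mrca)
  expect_true(ape::is.ultrametric(g1, tol = 1e-6))
})

test_that("species whose family and order are absent are reported unplaceable", {
  tr <- fixture_tree(4, seed = 2)
  tax <- tibble::tibble(
    species = c(tr$tip.label, "lost1", "lost2"),
    family = c("F1", "F1", "F2", "F2", "F3", "F3"),
    order = c("O1", "O1", "O1", "O1", "O9", "O9"))
  expect_error(graft_species(tr, tax, c("lost1", "lost2"), "basal_polytomy"),
               "lost1.*lost2", class = "geothermflora_unplaceable")
  # taxonomy_constrained can still place a species whose order is present
  tax2 <- tax
  tax2$order[5:6] <- "O1"
  g <- graft_species(tr, tax2, c("lost1", "lost2"), "taxonomy_constrained")
  expect_setequal(g$tip.label, tax2$species)
  expect_true(ape::is.ultrametric(g, tol = 1e-6))
})

test_that("pair subsampling is exhaustive when small and uniform when large", {
  sp <- sprintf("s%d", 1:5)
  pp <- sample_pairs(sp, max_pairs = 100)
  expect_equal(nrow(pp), 10)
  expect_equal(nrow(unique(pp)), 10)

  expect_equal(nrow(sample_pairs(c("a", "b"), 100)), 1)
  expect_error(sample_pairs("a", 100), class = "geothermflora_invalid_config")

  # uniform inclusion: n = 8 gives 28 pairs; sample 10, check inclusion 10/28
  sp8 <- sprintf("s%d", 1:8)
  reps <- 4000
  seen <- new.env()
  counts <- matrix(0, 8, 8)
  for (r in seq_len(reps)) {
    pr <- sample_pairs(sp8, max_pairs = 10, seed = r)
    expect_equal(nrow(unique(pr)), 10)
    i <- match(pr$a, sp8)
    j <- match(pr$b, sp8)
    counts[cbind(i, j)] <- counts[cbind(i, j)] + 1
  }
  p_incl <- 10 / 28
  se <- sqrt(p_incl * (1 - p_incl) / reps)
  freqs <- counts[upper.tri(counts)] / reps
  expect_true(all(abs(freqs - p_incl) < 3.5 * se))
})
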