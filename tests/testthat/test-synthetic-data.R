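test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_families = 1), class = "geothermflora_invalid_config")
  expect_error(synthetic_config(n_families = -3), class = "geothermflora_invalid_config")
  expect_error(synthetic_config(zone_richness = c(5, 10, 12, 20)),
               class = "geothermflora_invalid_config") # must decrease outward
  expect_error(synthetic_config(n_species = 20, n_obligate = 15, n_facultative = 10,
                                n_families = 10, tips_per_family = c(1, 3),
                                zone_richness = c(5, 4, 3, 2)),
               class = "geothermflora_invalid_config")
  expect_error(synthetic_config(n_families = 10, n_species = 500,
                                tips_per_family = c(1, 9)),
               class = "geothermflora_invalid_config") # unattainable pool size
  expect_error(synthetic_config(clustering_strength = 1.4),
               class = "geothermflora_invalid_config")
})

test_that("backbone tree is ultrametric with monophyletic families of the requested size", {
  cfg <- synthetic_config(seed = 11) # default scale: 60 families, 292 species
  bt <- gen_backbone_tree(cfg)
  expect_equal(length(bt$tree$tip.label), 292)
  expect_true(ape::is.ultrametric(bt$tree, tol = 1e-6))
  expect_equal(length(unique(bt$taxonomy$family)), 60)
  expect_true(all(bt$family_sizes >= 1 & bt$family_sizes <= 9))
  sizes <- table(bt$taxonomy$family)
  expect_equal(sum(sizes), 292)
  for (f in sample(unique(bt$taxonomy$family), 12)) {
    tips <- bt$taxonomy$species[bt$taxonomy$family == f]
    expect_true(length(tips) == 1 || ape::is.monophyletic(bt$tree, tips))
  }
  # every species in exactly one family
  expect_false(anyDuplicated(bt$taxonomy$species) > 0)
})

test_that("a two-family, one-tip-each config gives a 2-tip tree with equal depths", {
  cfg <- synthetic_config(n_families = 2, n_species = 2, tips_per_family = c(1, 1),
                          n_obligate = 0, n_facultative = 0,
                          zone_richness = c(2, 1, 1, 1), seed = 5)
  bt <- gen_backbone_tree(cfg)
  dep <- ape::node.depth.edgelength(bt$tree)
  expect_equal(length(bt$tree$tip.label), 2)
  expect_equal(dep[1], dep[2], tolerance = 1e-12)
})

test_that("generators are deterministic under a fixed seed", {
  d1 <- gen_dataset(small_config(seed = 21))
  d2 <- gen_dataset(small_config(seed = 21))
  expect_identical(ape::write.tree(d1$tree), ape::write.tree(d2$tree))
  expect_identical(d1$pool, d2$pool)
  expect_identical(d1$soil, d2$soil)
  expect_identical(d1$cover, d2$cover)
  d3 <- gen_dataset(small_config(seed = 22))
  expect_false(identical(ape::write.tree(d1$tree), ape::write.tree(d3$tree)))
})

test_that("thermal status assignment honours counts and clustering extremes", {
  cfg <- small_config(seed = 31)
  bt <- gen_backbone_tree(cfg)
  pool <- gen_thermal_status(bt$taxonomy, cfg)
  expect_equal(sum(pool$status == "obligate"), 6)
  expect_equal(sum(pool$status == "facultative"), 8)

  # strength 1, 4 obligates, all families large enough -> one family
  cfg1 <- synthetic_config(n_families = 6, n_species = 30, tips_per_family = c(5, 5),
                           n_obligate = 4, n_facultative = 0,
                           clustering_strength = 1,
                           zone_richness = c(10, 8, 6, 4), seed = 32)
  bt1 <- gen_backbone_tree(cfg1)
  p1 <- gen_thermal_status(bt1$taxonomy, cfg1)
  expect_equal(length(unique(p1$family[p1$status == "obligate"])), 1)

  # zero thermal species
  cfg0 <- synthetic_config(n_families = 6, n_species = 30, tips_per_family = c(5, 5),
                           n_obligate = 0, n_facultative = 0,
                           zone_richness = c(10, 8, 6, 4), seed = 33)
  p0 <- gen_thermal_status(gen_backbone_tree(cfg0)$taxonomy, cfg0)
  expect_true(all(p0$status == "non_thermal"))

  # requesting more thermal species than the pool has errors
  expect_error(gen_thermal_status(bt1$taxonomy[1:3, ], cfg1),
               class = "geothermflora_invalid_config")
})

test_that("with clustering 0 the per-family thermal counts are hypergeometric", {
  cfg <- synthetic_config(n_families = 6, n_species = 30, tips_per_family = c(5, 5),
                          n_obligate = 3, n_facultative = 3,
                          clustering_strength = 0,
                          zone_richness = c(10, 8, 6, 4), seed = 41)
  bt <- gen_backbone_tree(cfg)
  fams <- sort(unique(bt$taxonomy$family))
  reps <- 2000
  counts <- matrix(0, reps, length(fams), dimnames = list(NULL, fams))
  for (r in seq_len(reps)) {
    p <- gen_thermal_status(bt$taxonomy, cfg, seed = 10000 + r)
    tab <- table(factor(p$family[p$status != "non_thermal"], levels = fams))
    counts[r, ] <- as.numeric(tab)
  }
  # E[k_f] = n_thermal * K_f / N = 6 * 5 / 30 = 1 for every family
  expected <- 1
  # var of the hypergeometric count
  v <- 6 * (5 / 30) * (25 / 30) * (24 / 29)
  se <- sqrt(v / reps)
  for (f in fams) {
    expect_lt(abs(mean(counts[, f]) - expected), 3 * se)
  }
})

test_that("zone tables: exact richness, pool containment, planted gradients", {
  cfg <- small_config(seed = 51)
  d <- gen_dataset(cfg)
  rich <- table(d$zones$zone)[c("I", "II", "III", "IV")]
  expect_equal(unname(as.numeric(rich)), c(14, 10, 8, 5))
  expect_true(all(d$zones$species %in% d$pool$species))

  # hotter zones lose non-thermal species first
  th <- d$pool$species[d$pool$status != "non_thermal"]
  frac_non <- vapply(c("I", "II", "III", "IV"), function(z) {
    s <- d$zones$species[d$zones$zone == z]
    mean(!(s %in% th))
  }, 0)
  expect_lt(frac_non[["IV"]], frac_non[["I"]])

  # noise-free pH gradient is monotone down
  grad0 <- default_soil_gradients()
  grad0$noise_sd <- rep(0, nrow(grad0))
  cfg0 <- small_config(seed = 52, soil_gradients = grad0)
  d0 <- gen_dataset(cfg0)
  ph <- tapply(d0$soil$pH, d0$soil$zone, mean)[c("I", "II", "III", "IV")]
  expect_true(all(diff(ph) < 0))
})

test_that("planted cover effects reach the configured rank correlation", {
  cfg <- synthetic_config(n_plots = 200, seed = 61, clustering_strength = 1)
  d <- gen_dataset(cfg)
  ec_sp <- d$effects$species[d$effects$property == "EC"][1]
  rho <- suppressWarnings(
    cor(d$cover[[ec_sp]], d$plots$EC, method = "spearman"))
  expect_gt(rho, 0.5)
})

test_that("dataset files round-trip through the plain-text writers", {
  d <- gen_dataset(small_config(seed = 71))
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  expect_true(all(file.exists(file.path(
    dir, c("tree.nwk", "pool.tsv", "zones.tsv", "soil.tsv", "plots.tsv",
           "cover.tsv", "config.yaml")))))
  d2 <- read_dataset(dir)
  expect_equal(sort(d2$tree$tip.label), sort(d$tree$tip.label))
  expect_equal(as.data.frame(d2$pool), as.data.frame(d$pool))
  expect_equal(d2$config$zone_richness, d$config$zone_richness)
  m1 <- patristic_matrix(d$tree)
  m2 <- patristic_matrix(d2$tree)[rownames(m1), colnames(m1)]
  expect_lt(max(abs(m1 - m2)), 1e-9)
})
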