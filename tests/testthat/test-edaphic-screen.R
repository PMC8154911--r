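test_that("Spearman screen: perfect monotone cases and the exact small-n p", {
  x <- 1:8
  up <- spearman_screen(x, x + 0)
  expect_equal(up$rho, 1)
  # exactly one of the 8! orderings attains rho = 1; the one-tailed 1/8! is
  # doubled for the two-sided test
  expect_equal(up$p_value, 2 / factorial(8), tolerance = 1e-12)
  down <- spearman_screen(1:10, 10:1)
  expect_equal(down$rho, -1)
  expect_error(spearman_screen(rep(1, 8), 1:8),
               class = "geothermflora_invalid_config")
  expect_error(spearman_screen(1:4, 4:1), class = "geothermflora_invalid_config")
  # missing values dropped pairwise
  xm <- c(1:8, NA)
  ym <- c(2 * (1:8), 5)
  expect_equal(spearman_screen(xm, ym)$n_used, 8)
})

test_that("Spearman p-values are calibrated under independence", {
  reps <- 2000
  pv <- withr::with_seed(71, {
    vapply(seq_len(reps), function(i) {
      spearman_screen(stats::rnorm(12), stats::rnorm(12))$p_value
    }, 0)
  })
  for (alpha in c(0.01, 0.05)) {
    se <- sqrt(alpha * (1 - alpha) / reps)
    expect_lt(abs(mean(pv <= alpha) - alpha), 3.5 * se + 0.005)
  }
})

test_that("Hoeffding's D equals the brute-force count formula exactly", {
  withr::with_seed(73, {
    for (i in 1:50) {
      n <- sample(5:30, 1)
      x <- stats::rnorm(n)
      y <- if (i %% 3 == 0) x^2 + stats::rnorm(n, 0, 0.2) else stats::rnorm(n)
      if (i %% 5 == 0) { # inject ties
        x <- round(x, 1)
        y <- round(y, 1)
      }
      expect_equal(hoeffding_d(x, y), oracle_hoeffding_d(x, y),
                   tolerance = 1e-12)
    }
  })
  # maximal dependence: x = y on strict ranks
  expect_equal(hoeffding_d(1:10, 1:10), oracle_hoeffding_d(1:10, 1:10),
               tolerance = 1e-14)
  expect_gt(hoeffding_d(1:10, 1:10), 0.5)
  expect_error(hoeffding_d(1:4, 1:4), class = "geothermflora_invalid_config")
})

test_that("Hoeffding screen detects a parabola that Spearman misses", {
  withr::with_seed(74, {
    x <- seq(-2, 2, length.out = 30) + stats::rnorm(30, 0, 0.05)
    y <- (x - mean(x))^2 + stats::rnorm(30, 0, 0.1)
  })
  ho <- hoeffding_screen(x, y, n_perm = 999, seed = 1)
  sp <- spearman_screen(x, y)
  expect_lte(ho$p_value, 0.01)
  expect_gt(ho$d, 0)
  expect_lt(abs(sp$rho), 0.35)
})

test_that("Hoeffding permutation p is calibrated under independence", {
  reps <- 600
  pv <- withr::with_seed(75, {
    vapply(seq_len(reps), function(i) {
      hoeffding_screen(stats::runif(20), stats::runif(20),
                       n_perm = 99, seed = 5000 + i)$p_value
    }, 0)
  })
  se <- sqrt(0.01 * 0.99 / reps)
  expect_lt(abs(mean(pv <= 0.01) - 0.01), 3.5 * se + 0.002)
  d0 <- withr::with_seed(76, hoeffding_d(stats::runif(50), stats::runif(50)))
  expect_lt(abs(d0), 0.05)
})

test_that("both screens are invariant under strictly increasing transforms", {
  withr::with_seed(77, {
    x <- stats::rlnorm(15)
    y <- stats::rnorm(15)
  })
  expect_equal(hoeffding_d(x, y), hoeffding_d(log(x), exp(y)), tolerance = 1e-12)
  expect_equal(spearman_screen(x, y)$rho,
               spearman_screen(log(x), exp(y))$rho, tolerance = 1e-12)
})

test_that("importance matrix flags the planted association and validates plots", {
  hits <- vapply(1:25, function(s) {
    set.seed(600 + s)
    n <- 12
    ec <- stats::rnorm(n, 2, 1)
    cover <- tibble::tibble(
      plot = sprintf("p%02d", 1:n),
      sp1 = 100 * stats::pnorm(0.95 * as.numeric(scale(ec)) +
                                 sqrt(1 - 0.95^2) * stats::rnorm(n)),
      sp2 = stats::runif(n, 0, 60))
    soil <- tibble::tibble(plot = cover$plot, EC = ec, pH = stats::rnorm(n, 6))
    im <- importance_matrix(cover, soil, alpha = 0.01, n_perm = 199,
                            seed = 900 + s)
    im$important[im$species == "sp1" & im$property == "EC"]
  }, logical(1))
  expect_gt(mean(hits), 0.6) # majority of seeds recover the planted signal

  cover <- tibble::tibble(plot = c("a", "b", "c", "d", "e", "f"),
                          sp1 = c(1, 2, 3, 4, 5, 6))
  soil_bad <- tibble::tibble(plot = c("a", "b", "c", "d", "e", "zz"),
                             EC = 1:6)
  expect_error(importance_matrix(cover, soil_bad),
               class = "geothermflora_invalid_config")
})

test_that("constant columns are excluded and alpha = 0 flags nothing", {
  set.seed(81)
  n <- 10
  cover <- tibble::tibble(plot = sprintf("p%d", 1:n),
                          sp1 = stats::runif(n), sp2 = rep(0, n))
  soil <- tibble::tibble(plot = cover$plot, EC = stats::rnorm(n),
                         flat = rep(7, n))
  expect_warning(expect_warning(
    im <- importance_matrix(cover, soil, alpha = 0, n_perm = 99, seed = 1),
    "sp2"), "flat")
  expect_false(any(im$species == "sp2"))
  expect_false(any(im$property == "flat"))
  expect_false(any(im$important))
})

test_that("with independent cover and soils the importance rate stays near 2*alpha", {
  set.seed(83)
  n <- 12
  cover <- tibble::as_tibble(c(list(plot = sprintf("p%d", 1:n)),
                               stats::setNames(lapply(1:20, function(i) stats::runif(n)),
                                               sprintf("sp%02d", 1:20))))
  soil <- tibble::as_tibble(c(list(plot = cover$plot),
                              stats::setNames(lapply(1:8, function(i) stats::rnorm(n)),
                                              sprintf("pr%d", 1:8))))
  im <- importance_matrix(cover, soil, alpha = 0.01, n_perm = 199, seed = 2)
  rate <- mean(im$important)
  expect_lt(rate, 2 * 0.01 + 3 * sqrt(0.02 * 0.98 / nrow(im)))
})

test_that("the thermophyte aggregation is the exact hypergeometric tail", {
  # 4 thermophytes all important, 4 others not: one-sided p = 1/choose(8,4)
  im <- tibble::tibble(
    species = sprintf("s%d", 1:8),
    property = "EC",
    important = c(rep(TRUE, 4), rep(FALSE, 4)))
  class(im) <- c("geo_importance", class(im))
  st <- tibble::tibble(species = im$species,
                       status = c(rep("obligate", 4), rep("non_thermal", 4)))
  r <- thermophyte_property_test(im, st)
  expect_equal(r$p_value, 1 / choose(8, 4), tolerance = 1e-12)

  # identical importance rates in both strata: p near 1
  im2 <- im
  im2$important <- rep(c(TRUE, FALSE), 4)
  st2 <- tibble::tibble(species = im$species,
                        status = rep(c("facultative", "non_thermal"), each = 4))
  expect_gt(thermophyte_property_test(im2, st2)$p_value, 0.5)

  # agreement with fisher.test's one-sided enrichment p on random tables
  withr::with_seed(85, {
    for (i in 1:50) {
      Ns <- sample(8:30, 1)
      Ks <- sample(2:(Ns - 2), 1)
      sp <- sprintf("s%02d", 1:Ns)
      imp <- sample(c(TRUE, FALSE), Ns, replace = TRUE)
      imr <- tibble::tibble(species = sp, property = "x", important = imp)
      class(imr) <- c("geo_importance", class(imr))
      str <- tibble::tibble(species = sp,
                            status = c(rep("obligate", Ks),
                                       rep("non_thermal", Ns - Ks)))
      got <- thermophyte_property_test(imr, str)$p_value
      tab <- matrix(c(sum(imp[1:Ks]), Ks - sum(imp[1:Ks]),
                      sum(imp[-(1:Ks)]), Ns - Ks - sum(imp[-(1:Ks)])), 2,
                    byrow = TRUE)
      want <- stats::fisher.test(tab, alternative = "greater")$p.value
      expect_equal(got, want, tolerance = 1e-12)
    }
  })
})
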