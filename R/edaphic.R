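# Screening of soil properties limiting species cover: Spearman rank
# correlation for monotone association, Hoeffding's D for general (including
# non-monotone) dependence, an importance matrix over the species x property
# grid, and a Fisher-style aggregation asking which properties matter for
# more thermophytes than chance expects.

drop_pairwise_na <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  list(x = x[ok], y = y[ok], n = sum(ok))
}

#' Spearman correlation screen
#'
#' Rank correlation (mid-ranks for ties) between a species' cover values and
#' a soil property. The p-value is exact (permutation distribution of the
#' rank statistic) for n <= 9 without ties, and the t-approximation
#' otherwise; two-sided.
#'
#' @param cover,property Paired numeric vectors; missing values are dropped
#'   pairwise.
#' @return One-row tibble: `rho`, `p_value`, `n_used`.
#' @export
spearman_screen <- function(cover, property) {
  d <- drop_pairwise_na(cover, property)
  if (d$n < 5L) stop_config("need at least 5 paired observations.")
  if (stats::sd(d$x) == 0 || stats::sd(d$y) == 0) {
    stop_config("rank correlation undefined for a constant column.")
  }
  ct <- suppressWarnings(
    stats::cor.test(d$x, d$y, method = "spearman", exact = d$n <= 9))
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n_used = d$n)
}

#' Hoeffding's D statistic
#'
#' Nonparametric measure of general bivariate dependence, computed from
#' joint and marginal rank counts with mid-rank tie handling and scaled by 30
#' so the statistic lies in about `[-0.5, 1]` (0 under independence, large
#' positive for dependence of any shape, including non-monotone).
#'
#' @param x,y Paired numeric vectors, length >= 5.
#' @return The D statistic (scalar).
#' @export
hoeffding_d <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop_config("x and y must have equal length.")
  if (n < 5L) stop_config("Hoeffding's D is undefined for n < 5.")
  R <- rank(x)
  S <- rank(y)
  Mx <- outer(x, x, "<") + 0.5 * outer(x, x, "==")
  My <- outer(y, y, "<") + 0.5 * outer(y, y, "==")
  hoeffding_d_core(Mx, My, R, S, n)
}

# Core computation given the comparison matrices; reused by the permutation
# loop, where only y's rows/columns are permuted.
hoeffding_d_core <- function(Mx, My, R, S, n) {
  Q <- 1 + colSums(Mx * My) - 0.25 # subtract each point's self-term
  D1 <- sum((Q - 1) * (Q - 2))
  D2 <- sum((R - 1) * (R - 2) * (S - 1) * (S - 2))
  D3 <- sum((R - 2) * (S - 2) * (Q - 1))
  30 * ((n - 2) * (n - 3) * D1 + D2 - 2 * (n - 2) * D3) /
    (n * (n - 1) * (n - 2) * (n - 3) * (n - 4))
}

#' Hoeffding dependence screen with permutation p-value
#'
#' [hoeffding_d()] plus a right-tail permutation p-value obtained by
#' permuting one margin `n_perm` times (add-one formula). Permutation is used
#' instead of the asymptotic approximation of the classical implementation:
#' it is exact in distribution at any n and handles ties without special
#' cases.
#'
#' @param cover,property Paired numeric vectors; missing values dropped
#'   pairwise.
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @return One-row tibble: `d`, `p_value`, `n_used`, `n_perm`.
#' @export
hoeffding_screen <- function(cover, property, n_perm = 9999, seed = NULL) {
  d <- drop_pairwise_na(cover, property)
  if (d$n < 5L) stop_config("need at least 5 paired observations.")
  x <- d$x
  y <- d$y
  n <- d$n
  R <- rank(x)
  S <- rank(y)
  Mx <- outer(x, x, "<") + 0.5 * outer(x, x, "==")
  My <- outer(y, y, "<") + 0.5 * outer(y, y, "==")
  d_obs <- hoeffding_d_core(Mx, My, R, S, n)
  exceed <- with_seed_if(seed, {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      d_b <- hoeffding_d_core(Mx, My[perm, perm], R, S[perm], n)
      if (d_b >= d_obs) hits <- hits + 1L
    }
    hits
  })
  tibble(d = d_obs, p_value = (exceed + 1) / (n_perm + 1),
         n_used = n, n_perm = n_perm)
}

#' Species x property importance matrix
#'
#' Runs both screens for every (species, property) cell of a cover matrix
#' against plot-level soil properties. A property is `important` for a
#' species when either test has `p <= alpha` (no correction across the grid,
#' mirroring the per-cell decision rule; BH q-values over the grid are
#' attached as side information). `direction` is the Spearman sign when the
#' monotone test is the significant one, `"nonmonotone"` when only
#' Hoeffding's test fires.
#'
#' @param cover Wide tibble: `plot` column plus one numeric column per
#'   species (% cover).
#' @param soil Tibble: `plot` column plus one numeric column per property.
#'   Plot sets must match.
#' @param alpha Importance threshold on the per-test p-values.
#' @param n_perm Permutations for the Hoeffding screen.
#' @param seed Optional integer seed.
#' @return A tibble of class `geo_importance`, one row per (species,
#'   property): `spearman_rho`, `spearman_p`, `spearman_q`, `hoeffding_d`,
#'   `hoeffding_p`, `hoeffding_q`, `important`, `direction`.
#' @export
importance_matrix <- function(cover, soil, alpha = 0.01, n_perm = 999,
                              seed = NULL) {
  if (!("plot" %in% names(cover)) || !("plot" %in% names(soil))) {
    stop_config("both tables need a `plot` id column.")
  }
  if (!setequal(cover$plot, soil$plot)) {
    stop_config("plot ids of the cover and soil tables do not match.")
  }
  soil <- soil[match(cover$plot, soil$plot), ]
  species <- setdiff(names(cover), "plot")
  props <- names(soil)[vapply(soil, is.numeric, TRUE)]
  const_sp <- species[vapply(species, function(s) stats::sd(cover[[s]]) == 0, TRUE)]
  const_pr <- props[vapply(props, function(p) stats::sd(soil[[p]]) == 0, TRUE)]
  if (length(const_sp)) {
    warn(paste0("excluding constant cover columns: ",
                paste(const_sp, collapse = ", ")))
    species <- setdiff(species, const_sp)
  }
  if (length(const_pr)) {
    warn(paste0("excluding constant soil properties: ",
                paste(const_pr, collapse = ", ")))
    props <- setdiff(props, const_pr)
  }
  grid <- tidyr::expand_grid(species = species, property = props)
  seeds <- derive_seeds(seed, nrow(grid))
  rows <- purrr::pmap(list(grid$species, grid$property, seeds),
                      function(s, p, sd_i) {
    sp <- spearman_screen(cover[[s]], soil[[p]])
    ho <- hoeffding_screen(cover[[s]], soil[[p]], n_perm = n_perm, seed = sd_i)
    tibble(species = s, property = p,
           spearman_rho = sp$rho, spearman_p = sp$p_value,
           hoeffding_d = ho$d, hoeffding_p = ho$p_value, n_used = sp$n_used)
  })
  out <- bind_rows(rows) |>
    mutate(
      spearman_q = stats::p.adjust(.data$spearman_p, method = "BH"),
      hoeffding_q = stats::p.adjust(.data$hoeffding_p, method = "BH"),
      important = pmin(.data$spearman_p, .data$hoeffding_p) <= alpha,
      direction = dplyr::case_when(
        spearman_p <= alpha & spearman_rho > 0 ~ "+",
        spearman_p <= alpha & spearman_rho < 0 ~ "-",
        hoeffding_p <= alpha ~ "nonmonotone",
        TRUE ~ NA_character_)) |>
    select("species", "property", "spearman_rho", "spearman_p", "spearman_q",
           "hoeffding_d", "hoeffding_p", "hoeffding_q", "n_used",
           "important", "direction")
  class(out) <- c("geo_importance", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' Properties disproportionately important for thermophytes
#'
#' For every soil property, builds the 2 x 2 table (thermophyte vs not) x
#' (important vs not) over the species of an importance matrix and computes
#' the one-sided Fisher exact enrichment probability — the exact
#' hypergeometric tail [p_over()] with N = species tested, K = thermophytes,
#' n = species the property is important for, k = important thermophytes.
#'
#' @param importance A [importance_matrix()] result.
#' @param statuses Tibble with `species` and `status` columns covering the
#'   species tested.
#' @return Tibble per property: `n_species`, `n_thermophyte`, `n_important`,
#'   `k_important_thermophyte`, `p_value`.
#' @export
thermophyte_property_test <- function(importance, statuses) {
  if (!all(c("species", "status") %in% names(statuses))) {
    stop_config("`statuses` needs species and status columns.")
  }
  sp <- unique(importance$species)
  missing <- setdiff(sp, statuses$species)
  if (length(missing)) {
    stop_lookup(paste0("species without a status: ",
                       paste(missing, collapse = ", ")))
  }
  thermal <- statuses$species[statuses$status %in% c("obligate", "facultative")]
  if (!any(sp %in% thermal)) {
    warn("no thermophytes among the species tested; all p-values are 1.")
  }
  importance |>
    as_tibble() |>
    group_by(.data$property) |>
    summarise(
      n_species = dplyr::n_distinct(.data$species),
      n_thermophyte = dplyr::n_distinct(.data$species[.data$species %in% thermal]),
      n_important = sum(.data$important),
      k_important_thermophyte = sum(.data$important &
                                      .data$species %in% thermal),
      .groups = "drop") |>
    mutate(p_value = purrr::pmap_dbl(
      list(.data$n_species, .data$n_thermophyte, .data$n_important,
           .data$k_important_thermophyte),
      function(N, K, n, k) p_over(N, K, n, k))) |>
    arrange(.data$p_value)
}
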