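# Permutation tests for between-zone species-composition overlap.

#' Zone-composition overlap permutation test
#'
#' Tests whether two zones share more (or fewer) species than expected if
#' both were uniform random subsets of the pool. The null overlap is built by
#' drawing, `n_draws` times, independent subsets of sizes `|A|` and `|B|`
#' without replacement from the pool and counting common species (the null
#' mean is the hypergeometric expectation `|A||B|/|pool|`). Both tails use
#' the add-one correction and include ties, so `p_right + p_left >= 1`.
#'
#' @param zone_a,zone_b Character vectors of species, both subsets of `pool`.
#' @param pool Character vector: the species pool the zones were surveyed
#'   from.
#' @param n_draws Number of null draws.
#' @param seed Optional integer seed.
#' @return One-row tibble: `n_a`, `n_b`, `pool_size`, `observed`,
#'   `null_mean`, `null_sd`, `p_right`, `p_left`, `n_draws`.
#' @export
overlap_test <- function(zone_a, zone_b, pool, n_draws = 1000, seed = NULL) {
  zone_a <- unique(zone_a)
  zone_b <- unique(zone_b)
  pool <- unique(pool)
  if (length(zone_a) == 0L || length(zone_b) == 0L) {
    stop_config("both zones must be non-empty.")
  }
  bad <- setdiff(c(zone_a, zone_b), pool)
  if (length(bad)) {
    stop_config(paste0("zone species not in the pool: ",
                       paste(bad, collapse = ", ")))
  }
  a <- length(zone_a)
  b <- length(zone_b)
  P <- length(pool)
  observed <- length(intersect(zone_a, zone_b))
  null <- with_seed_if(seed, {
    vapply(seq_len(n_draws), function(i) {
      x <- sample.int(P, a)
      y <- sample.int(P, b)
      sum(!is.na(match(x, y)))
    }, numeric(1))
  })
  tibble(
    n_a = a, n_b = b, pool_size = P, observed = observed,
    null_mean = mean(null), null_sd = stats::sd(null),
    p_right = (sum(null >= observed) + 1) / (n_draws + 1),
    p_left = (sum(null <= observed) + 1) / (n_draws + 1),
    n_draws = n_draws)
}

#' Pairwise zone-overlap p-value matrices
#'
#' Runs [overlap_test()] for every unordered pair of zones (diagonal
#' included) and collects right- and left-tail p-values into symmetric
#' matrices.
#'
#' @param zones Long tibble with `zone` and `species` columns, or a named
#'   list of species vectors.
#' @param pool Species pool; defaults to the union of the zone sets.
#' @param n_draws Null draws per pair.
#' @param seed Optional integer seed (each pair gets a derived sub-seed).
#' @return A `geo_overlap` object: matrices `observed`, `p_right`, `p_left`,
#'   plus `pool_size` and `n_draws`. See [tidy.geo_overlap()].
#' @export
all_pairs_matrix <- function(zones, pool = NULL, n_draws = 1000, seed = NULL) {
  if (is.data.frame(zones)) {
    if (!all(c("zone", "species") %in% names(zones))) {
      stop_config("`zones` must have zone and species columns.")
    }
    zones <- split(zones$species, zones$zone)
  }
  if (length(zones) < 2L) stop_config("need at least 2 zones.")
  zl <- names(zones)
  pool <- pool %||% unique(unlist(zones))
  k <- length(zones)
  obs <- pr <- pl <- matrix(NA_real_, k, k, dimnames = list(zl, zl))
  seeds <- derive_seeds(seed, k * (k + 1L) / 2L)
  si <- 0L
  for (i in seq_len(k)) {
    for (j in i:k) {
      si <- si + 1L
      res <- overlap_test(zones[[i]], zones[[j]], pool, n_draws = n_draws,
                          seed = seeds[[si]])
      obs[i, j] <- obs[j, i] <- res$observed
      pr[i, j] <- pr[j, i] <- res$p_right
      pl[i, j] <- pl[j, i] <- res$p_left
    }
  }
  structure(list(observed = obs, p_right = pr, p_left = pl,
                 pool_size = length(unique(pool)), n_draws = n_draws),
            class = "geo_overlap")
}

#' @export
print.geo_overlap <- function(x, ...) {
  cat(sprintf("<geo_overlap> %d zones, pool of %d species, %d null draws\n",
              nrow(x$observed), x$pool_size, x$n_draws))
  cat("  right-tail p (more shared species than chance):\n")
  print(round(x$p_right, 4))
  invisible(x)
}
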