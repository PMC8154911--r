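# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an NRI result
#'
#' One row per (tree, replicate) with the observed MPD, null summary, NRI and
#' rank p-value.
#'
#' @param x A `geo_nri` from [nri_procedure()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy geo_nri
#' @export
tidy.geo_nri <- function(x, ...) {
  x$replicates
}

#' One-row summary of an NRI result
#'
#' The cross-tree mean of per-tree median NRI and p-value, with the
#' procedure's settings.
#'
#' @param x A `geo_nri`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance geo_nri
#' @export
glance.geo_nri <- function(x, ...) {
  tibble(nri = x$nri, p_value = x$p_value, group_size = x$group_size,
         pool_size = x$pool_size, trees_used = x$trees_used, reps = x$reps,
         n_draws = x$n_draws, max_pairs = x$max_pairs,
         convention = x$convention, null_model = x$null_model)
}

#' Tidy a zone-overlap matrix
#'
#' One row per unordered zone pair with the observed number of shared
#' species and both tail p-values.
#'
#' @param x A `geo_overlap` from [all_pairs_matrix()].
#' @param ... Unused.
#' @return A tibble: `zone_a`, `zone_b`, `observed`, `p_right`, `p_left`.
#' @method tidy geo_overlap
#' @export
tidy.geo_overlap <- function(x, ...) {
  zl <- rownames(x$observed)
  idx <- which(upper.tri(x$observed, diag = TRUE), arr.ind = TRUE)
  tibble(zone_a = zl[idx[, 1]], zone_b = zl[idx[, 2]],
         observed = x$observed[idx], p_right = x$p_right[idx],
         p_left = x$p_left[idx])
}
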