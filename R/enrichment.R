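# Hypergeometric over/under-representation of taxa within a species group.
#
# The model: a pool of N species contains K members of a taxon; a group of n
# species drawn from the pool contains k of them. p(k) is the hypergeometric
# probability; the over-representation tail P_over sums p(i) for
# i in [k, min(K, n)] and the under-representation tail P_under sums p(i) for
# i in [0, k] (both tails include i = k, so P_over + P_under = 1 + p(k)).

check_enrichment_input <- function(N, K, n, k = NULL) {
  if (any(!is.finite(c(N, K, n))) || any(c(N, K, n) < 0) ||
      any(c(N, K, n) != round(c(N, K, n)))) {
    stop_config("N, K and n must be non-negative integers.")
  }
  if (K > N || n > N) stop_config("need K <= N and n <= N.")
  if (!is.null(k)) {
    if (any(!is.finite(k)) || any(k < 0) || any(k != round(k))) {
      stop_config("k must be a non-negative integer.")
    }
    if (any(k > pmin(K, n))) stop_config("k cannot exceed min(K, n).")
  }
  invisible(TRUE)
}

#' Hypergeometric probability mass
#'
#' `p(k) = choose(K, k) * choose(N - K, n - k) / choose(N, n)`: the
#' probability that a uniform random group of `n` species from a pool of `N`
#' contains exactly `k` of a taxon's `K` members. Computed in log space so it
#' stays stable for pools of hundreds of species. Vectorised over `k`;
#' combinatorially impossible `k` return 0.
#'
#' @param N Pool size. @param K Taxon size in the pool.
#' @param n Group size. @param k Taxon members observed in the group.
#' @return Probability (vector along `k`).
#' @export
hypergeom_pmf <- function(N, K, n, k) {
  check_enrichment_input(N, K, n)
  if (any(!is.finite(k)) || any(k != round(k))) {
    stop_config("k must be integer-valued.")
  }
  out <- numeric(length(k))
  ok <- k >= max(0, n - (N - K)) & k <= min(K, n) & k >= 0
  out[ok] <- exp(lchoose(K, k[ok]) + lchoose(N - K, n - k[ok]) - lchoose(N, n))
  out
}

#' Over-representation tail probability
#'
#' Probability that `k` **or more** of the taxon's species occur in the group
#' by chance: the inclusive sum of `p(i)` for `i` from `k` to `min(K, n)`.
#'
#' @inheritParams hypergeom_pmf
#' @return Probability in (0, 1].
#' @export
p_over <- function(N, K, n, k) {
  check_enrichment_input(N, K, n, k)
  min(1, sum(hypergeom_pmf(N, K, n, seq.int(k, min(K, n)))))
}

#' Under-representation tail probability
#'
#' Probability that `k` **or fewer** of the taxon's species occur in the
#' group by chance: the inclusive sum of `p(i)` for `i` from 0 to `k`.
#'
#' @inheritParams hypergeom_pmf
#' @return Probability in (0, 1].
#' @export
p_under <- function(N, K, n, k) {
  check_enrichment_input(N, K, n, k)
  min(1, sum(hypergeom_pmf(N, K, n, seq.int(0, k))))
}

resolve_group <- function(pool, group) {
  if (length(group) == 1L &&
      group %in% c("obligate", "facultative", "non_thermal", "thermal")) {
    if (!("status" %in% names(pool))) {
      stop_config("`pool` has no status column to resolve the group from.")
    }
    sel <- if (group == "thermal") {
      pool$status %in% c("obligate", "facultative")
    } else {
      pool$status == group
    }
    return(pool$species[sel])
  }
  bad <- setdiff(group, pool$species)
  if (length(bad)) {
    stop_lookup(paste0("group species not in the pool: ",
                       paste(bad, collapse = ", ")))
  }
  group
}

#' Taxon over/under-representation table
#'
#' For every taxon of the chosen rank present in the pool, computes the
#' hypergeometric tails [p_over()] and [p_under()] of its membership in the
#' group, flags raw calls at `alpha` (the primary rule) and attaches
#' Benjamini-Hochberg q-values across the taxa of the rank, with FDR calls at
#' `fdr`. Single-species taxa are reported but flagged `low_power`.
#'
#' @param pool Tibble with `species` and the rank column (`family`, `order`
#'   or `class`); a `status` column lets `group` be given as a status name.
#' @param group Character vector of species in the group, or one of
#'   `"obligate"`, `"facultative"`, `"non_thermal"`, `"thermal"`.
#' @param rank Taxonomic rank to test.
#' @param alpha Raw-call threshold (default 0.05).
#' @param fdr FDR-call threshold on BH q-values (default 0.15).
#' @return A tibble, one row per taxon: `taxon`, `rank`, `N`, `K`, `n`, `k`,
#'   `p_over`, `p_under`, `q_over`, `q_under`, `call`, `call_fdr`,
#'   `low_power`; sorted by `p_over`.
#' @export
enrich_table <- function(pool, group, rank = c("family", "order", "class"),
                         alpha = 0.05, fdr = 0.15) {
  rank <- match.arg(rank)
  if (!all(c("species", rank) %in% names(pool))) {
    stop_config(sprintf("`pool` must have species and %s columns.", rank))
  }
  if (anyDuplicated(pool$species)) stop_config("duplicated species in the pool.")
  group <- resolve_group(pool, group)
  if (length(group) == 0L) {
    warn("empty group: all tail probabilities are 1.")
  }
  pool_size <- nrow(pool)
  group_size <- length(group)
  in_group <- pool$species %in% group

  counts <- pool |>
    mutate(.taxon = .data[[rank]], .in = in_group) |>
    group_by(.data$.taxon) |>
    summarise(K = dplyr::n(), k = sum(.data$.in), .groups = "drop")

  po <- mapply(function(K, k) p_over(pool_size, K, group_size, k),
               counts$K, counts$k)
  pu <- mapply(function(K, k) p_under(pool_size, K, group_size, k),
               counts$K, counts$k)
  qo <- stats::p.adjust(po, method = "BH")
  qu <- stats::p.adjust(pu, method = "BH")

  tibble(
    taxon = counts$.taxon, rank = rank,
    N = pool_size, K = counts$K, n = group_size, k = counts$k,
    p_over = po, p_under = pu, q_over = qo, q_under = qu,
    call = dplyr::case_when(po <= alpha ~ "over",
                            pu <= alpha ~ "under",
                            TRUE ~ "none"),
    call_fdr = dplyr::case_when(qo <= fdr ~ "over",
                                qu <= fdr ~ "under",
                                TRUE ~ "none"),
    low_power = counts$K == 1L) |>
    arrange(.data$p_over, .data$taxon)
}

#' Merge thermal statuses from two survey sources
#'
#' Reconciles two (species, status) tables: a species classified thermal in
#' at least one source is thermal; a species classified non-thermal in both
#' is non-thermal; a species present in only one source keeps that source's
#' status. When one source says obligate and the other facultative, the
#' species has been seen outside heated ground at least once, so the merge
#' resolves to facultative (reported via a message). A thermal label is not
#' downgraded by a non-thermal label from the other source.
#'
#' @param status_a,status_b Tibbles with `species` and `status` columns
#'   (`obligate`/`facultative`/`non_thermal`).
#' @return A tibble `species`, `status` covering the union of species.
#' @export
merge_status_sources <- function(status_a, status_b) {
  for (s in list(status_a, status_b)) {
    if (!all(c("species", "status") %in% names(s))) {
      stop_config("both sources need species and status columns.")
    }
    bad <- setdiff(unique(s$status), c("obligate", "facultative", "non_thermal"))
    if (length(bad)) {
      stop_config(paste0("unknown status values: ", paste(bad, collapse = ", ")))
    }
  }
  m <- full_join(
    select(status_a, "species", a = "status"),
    select(status_b, "species", b = "status"),
    by = "species")
  resolve <- function(a, b) {
    if (is.na(a)) return(b)
    if (is.na(b)) return(a)
    th <- c("obligate", "facultative")
    if (a == b) return(a)
    if (a %in% th && b %in% th) return("facultative") # contradictory labels
    if (a %in% th) return(a) # thermal in >= 1 source -> thermal
    if (b %in% th) return(b)
    "non_thermal"
  }
  out <- m |>
    mutate(status = purrr::map2_chr(.data$a, .data$b, resolve))
  clash <- !is.na(out$a) & !is.na(out$b) &
    out$a %in% c("obligate", "facultative") &
    out$b %in% c("obligate", "facultative") & out$a != out$b
  if (any(clash)) {
    inform(paste0("resolved obligate/facultative contradictions to facultative: ",
                  paste(out$species[clash], collapse = ", ")))
  }
  select(out, "species", "status")
}

#' Biomorph composition test
#'
#' Compares the biomorph (growth-form) spectrum of a species group against
#' the rest of the pool with a two-sided Fisher's exact test per biomorph
#' (2 x 2: in group vs not, this biomorph vs others).
#'
#' @param pool Tibble with `species` and `biomorph` columns.
#' @param group Character vector of species or a status name (see
#'   [enrich_table()]).
#' @return Tibble: `biomorph`, `k` (in group), `K` (in pool), `n`, `N`,
#'   `p_value`.
#' @export
biomorph_test <- function(pool, group) {
  if (!all(c("species", "biomorph") %in% names(pool))) {
    stop_config("`pool` must have species and biomorph columns.")
  }
  group <- resolve_group(pool, group)
  in_group <- pool$species %in% group
  purrr::map_dfr(sort(unique(pool$biomorph)), function(b) {
    is_b <- pool$biomorph == b
    tab <- matrix(c(sum(is_b & in_group), sum(is_b & !in_group),
                    sum(!is_b & in_group), sum(!is_b & !in_group)), 2)
    tibble(biomorph = b, k = sum(is_b & in_group), K = sum(is_b),
           n = sum(in_group), N = nrow(pool),
           p_value = stats::fisher.test(tab)$p.value)
  })
}
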