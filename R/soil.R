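# Soil indices (temperature-depth gradient, weathering ratios), grouped
# nonparametric comparisons and reference-normalised composition profiles.

#' Temperature-depth gradient and its angle
#'
#' Fits the linear temperature-depth model `T(d) = k * d + T15` (temperatures
#' anchored at the 15 cm reference depth). With exactly two measurements the
#' slope is the two-point difference quotient (for the standard 15/50 cm pair,
#' `k = (T50 - T15) / 35`); with more depths it is the least-squares slope.
#' The gradient angle is `alpha = arctan(k)` in degrees.
#'
#' @param depth Depths in cm (>= 2 values, not all equal).
#' @param temperature Temperatures in degrees C at those depths.
#' @return One-row tibble: `k` (degrees C per cm), `alpha_deg`, `n_points`.
#' @export
temp_gradient <- function(depth, temperature) {
  if (length(depth) != length(temperature)) {
    stop_config("depth and temperature must have equal length.")
  }
  ok <- is.finite(depth) & is.finite(temperature)
  if (!all(ok)) stop_config("non-finite depths or temperatures.")
  if (length(depth) < 2L || length(unique(depth)) < 2L) {
    stop_config("need at least two distinct depths.")
  }
  k <- if (length(depth) == 2L) {
    diff(temperature) / diff(depth)
  } else {
    unname(stats::coef(stats::lm(temperature ~ depth))[2])
  }
  tibble(k = k, alpha_deg = atan(k) * 180 / pi, n_points = length(depth))
}

#' Silica-titanium weathering index (STI)
#'
#' `STI = 100 * SiO2 / (SiO2/TiO2 + Al2O3/TiO2 + SiO2/Al2O3)` on oxide mass
#' percentages. Higher values indicate less altered parent material.
#' Vectorised.
#'
#' @param sio2,tio2,al2o3 Oxide mass percentages; `tio2` and `al2o3` must be
#'   positive.
#' @return Numeric vector of index values.
#' @export
sti <- function(sio2, tio2, al2o3) {
  if (any(!is.finite(c(sio2, tio2, al2o3))) || any(c(sio2) < 0)) {
    stop_config("oxide values must be finite and non-negative.")
  }
  if (any(tio2 <= 0) || any(al2o3 <= 0)) {
    stop_config("STI is undefined for TiO2 = 0 or Al2O3 = 0.")
  }
  100 * sio2 / (sio2 / tio2 + al2o3 / tio2 + sio2 / al2o3)
}

#' Silica to sesquioxide ratio
#'
#' `Silica/R2O3 = SiO2 / (Al2O3 + Fe2O3 + TiO2)`; scale-invariant (unchanged
#' when all oxides are multiplied by a constant). Vectorised.
#'
#' @param sio2,al2o3,fe2o3,tio2 Oxide mass percentages.
#' @return Numeric vector of ratio values.
#' @export
silica_r2o3 <- function(sio2, al2o3, fe2o3, tio2) {
  if (any(!is.finite(c(sio2, al2o3, fe2o3, tio2)))) {
    stop_config("oxide values must be finite.")
  }
  denom <- al2o3 + fe2o3 + tio2
  if (any(denom <= 0)) stop_config("Silica/R2O3 undefined: zero denominator.")
  sio2 / denom
}

#' Pairwise Mann-Whitney comparisons between groups
#'
#' One- or two-sided Mann-Whitney (Wilcoxon rank-sum) tests for every
#' unordered pair of groups, with Bonferroni correction over the number of
#' pairwise tests performed (capped at 1). The exact U distribution is used
#' whenever the implementation can (small samples, no ties); otherwise the
#' normal approximation with tie correction. For one-sided tests the
#' alternative is stated for `group1` (the earlier group level) relative to
#' `group2`; the direction must be declared by the caller.
#'
#' @param data A data frame.
#' @param value Name of the numeric column to compare (string).
#' @param group Name of the grouping column (string).
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (group1 vs
#'   group2).
#' @return Tibble per pair: `group1`, `group2`, `n1`, `n2`, `statistic` (U of
#'   group1), `p_value`, `p_bonferroni`.
#' @export
zone_compare <- function(data, value, group, alternative = "two.sided") {
  if (!all(c(value, group) %in% names(data))) {
    stop_config("`value` and `group` must name columns of `data`.")
  }
  g <- data[[group]]
  v <- data[[value]]
  ok <- !is.na(g) & is.finite(v)
  g <- g[ok]
  v <- v[ok]
  levels <- if (is.factor(g)) levels(droplevels(g)) else sort(unique(g))
  if (length(levels) < 2L) stop_config("need at least two groups.")
  sizes <- table(factor(g, levels = levels))
  if (any(sizes < 2L)) {
    stop_config(paste0("every group needs n >= 2; offending: ",
                       paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  pairs <- utils::combn(as.character(levels), 2)
  n_tests <- ncol(pairs)
  out <- purrr::map_dfr(seq_len(n_tests), function(i) {
    g1 <- pairs[1, i]
    g2 <- pairs[2, i]
    wt <- suppressWarnings(
      stats::wilcox.test(v[g == g1], v[g == g2], alternative = alternative))
    tibble(group1 = g1, group2 = g2,
           n1 = sum(g == g1), n2 = sum(g == g2),
           statistic = unname(wt$statistic), p_value = wt$p.value)
  })
  mutate(out, p_bonferroni = pmin(1, .data$p_value * n_tests))
}

#' Per-group summary profiles
#'
#' Median and interquartile range of selected variables within each group
#' (e.g. thermal zone).
#'
#' @param data A data frame.
#' @param group Grouping column name (string).
#' @param vars Character vector of numeric columns to summarise.
#' @return Tibble: `group`, `property`, `n`, `median`, `iqr`.
#' @export
zone_profile <- function(data, group, vars) {
  missing <- setdiff(c(group, vars), names(data))
  if (length(missing)) {
    stop_config(paste0("columns not in `data`: ", paste(missing, collapse = ", ")))
  }
  data |>
    tidyr::pivot_longer(all_of(vars), names_to = "property") |>
    group_by(group = .data[[group]], .data$property) |>
    summarise(n = sum(is.finite(.data$value)),
              median = stats::median(.data$value, na.rm = TRUE),
              iqr = stats::IQR(.data$value, na.rm = TRUE), .groups = "drop")
}

#' Normalise composition profiles to a reference group
#'
#' Per variable and group, the ratio of the group's summary statistic
#' (median by default) to the reference group's. Reference ratios are exactly
#' 1; a zero reference statistic flags the ratio as undefined (`NA`) for that
#' variable. Applying the function to an already-normalised wide table is a
#' no-op on the ratios.
#'
#' @param data A data frame of samples.
#' @param vars Character vector of composition variables.
#' @param group Grouping column name (string).
#' @param reference Reference group label (default `"I"`).
#' @param stat Summary statistic function (default [stats::median]).
#' @return Tibble: `group`, `property`, `value` (group statistic), `ratio`.
#' @export
normalize_to_reference <- function(data, vars, group = "zone",
                                   reference = "I", stat = stats::median) {
  missing <- setdiff(c(group, vars), names(data))
  if (length(missing)) {
    stop_config(paste0("columns not in `data`: ", paste(missing, collapse = ", ")))
  }
  if (!(reference %in% data[[group]])) {
    stop_config(sprintf("reference group '%s' not present.", reference))
  }
  prof <- data |>
    tidyr::pivot_longer(all_of(vars), names_to = "property") |>
    group_by(group = .data[[group]], .data$property) |>
    summarise(value = stat(.data$value[is.finite(.data$value)]),
              .groups = "drop")
  ref <- prof |>
    filter(.data$group == reference) |>
    select("property", ref_value = "value")
  prof |>
    left_join(ref, by = "property") |>
    mutate(ratio = ifelse(.data$ref_value == 0, NA_real_,
                          .data$value / .data$ref_value)) |>
    select("group", "property", "value", "ratio")
}

#' Group soil samples by zone, temperature class or depth
#'
#' Adds a `group` factor column forming an exhaustive, disjoint partition:
#' \describe{
#'   \item{zone}{the existing `zone` column.}
#'   \item{temperature_class}{sample temperature cut at 30/50/80 degrees C,
#'     left-closed (a sample at exactly 30 is "slightly heated"):
#'     non-heated `< 30`, slightly heated `[30, 50)`, moderately heated
#'     `[50, 80)`, hot `>= 80`.}
#'   \item{depth}{sampling depth from `depth_top`: topsoil `[0, 10)`,
#'     subsoil `[10, 50)`, deep `>= 50` cm.}
#' }
#'
#' @param data Soil sample table.
#' @param criterion `"zone"`, `"temperature_class"` or `"depth"`.
#' @return `data` with an added `group` factor column.
#' @export
group_samples <- function(data,
                          criterion = c("zone", "temperature_class", "depth")) {
  criterion <- match.arg(criterion)
  need <- switch(criterion, zone = "zone", temperature_class = "temperature",
                 depth = "depth_top")
  if (!(need %in% names(data))) {
    stop_config(sprintf("criterion '%s' needs column '%s'.", criterion, need))
  }
  if (anyNA(data[[need]])) {
    stop_config(sprintf("missing values in grouping column '%s'.", need))
  }
  grp <- switch(
    criterion,
    zone = factor(data$zone),
    temperature_class = cut(data$temperature,
                            breaks = c(-Inf, 30, 50, 80, Inf), right = FALSE,
                            labels = c("non-heated", "slightly heated",
                                       "moderately heated", "hot")),
    depth = cut(data$depth_top, breaks = c(-Inf, 10, 50, Inf), right = FALSE,
                labels = c("topsoil (0-10 cm)", "subsoil (10-50 cm)",
                           "deep (>= 50 cm)")))
  mutate(data, group = grp)
}
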