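#' Default soil-property gradients for the synthetic generator
#'
#' One row per soil property with the direction of its zone trend, the four
#' zone means (coolest to hottest), the Gaussian noise SD and the physically
#' valid range used for truncation. Defaults emulate a catena from non-heated
#' Andosols to hot, acid-sulfate altered soils: soil organic carbon, sand,
#' silica and pH decrease towards the hot end while electrical conductivity,
#' Eh, clay, and the Al/Fe/Ti oxides increase.
#'
#' Units: `T15` degrees C at 15 cm depth; `pH` unitless; `EC` dS/m; `Eh` mV;
#' `SOC`, oxides and particle-size fractions mass %.
#'
#' @param n_zones Number of thermal zones (means are interpolated if not 4).
#' @return A tibble with columns `property`, `direction`, `zone_means`
#'   (list-column), `noise_sd`, `min`, `max`.
#' @export
default_soil_gradients <- function(n_zones = 4L) {
  g <- tibble::tribble(
    ~property,  ~direction, ~zone_means,              ~noise_sd, ~min, ~max,
    "T15",      "up",       c(16, 40, 64, 92),         3,    -20,  110,
    "pH",       "down",     c(6.3, 6.0, 5.0, 4.2),     0.25,  0,   14,
    "EC",       "up",       c(0.15, 0.5, 1.5, 3.5),    0.2,   0,   Inf,
    "Eh",       "up",       c(420, 450, 520, 560),     40,  -500, 1000,
    "SOC",      "down",     c(12, 9, 4, 1.5),          1,     0,   100,
    "SiO2",     "down",     c(62, 58, 52, 46),         2,     0,   100,
    "TiO2",     "up",       c(0.7, 0.85, 1.0, 1.2),    0.08,  0,   100,
    "Al2O3",    "up",       c(14, 16, 19, 23),         1,     0,   100,
    "Fe2O3",    "up",       c(5, 6, 8, 10),            0.7,   0,   100,
    "pm_clay",  "up",       c(8, 14, 28, 45),          3,     0,   100,
    "pm_sand",  "down",     c(55, 45, 25, 12),         4,     0,   100
  )
  if (n_zones != 4L) {
    g$zone_means <- lapply(g$zone_means, function(m) {
      stats::approx(seq_along(m), m, n = n_zones)$y
    })
  }
  g
}

#' Default planted cover-soil associations
#'
#' Species tokens `"@obligate1"`, `"@facultative1"` and `"@nonthermal1"` are
#' resolved at generation time to the first species of that thermal status in
#' the pool, so the planted signals exist whatever the pool looks like.
#'
#' @return A tibble with columns `species`, `property`, `sign` (+1/-1) and
#'   `strength` (latent Gaussian-copula correlation in `[0, 1]`).
#' @export
default_cover_effects <- function() {
  tibble::tribble(
    ~species,        ~property, ~sign, ~strength,
    "@obligate1",    "EC",       1,    0.95,
    "@facultative1", "pH",      -1,    0.85,
    "@nonthermal1",  "SOC",      1,    0.85
  )
}

#' Configuration for the synthetic survey generator
#'
#' Bundles every knob of the synthetic-data module: the shape of the species
#' pool and its phylogeny, how strongly thermal species cluster into families,
#' zone richness, soil gradients and planted cover-soil correlations. Defaults
#' mirror the scale of a real geothermal-valley flora: 292 species in 60
#' families, 33 facultative and 18 obligate thermophytes, four thermal zones
#' with weakly decreasing richness.
#'
#' @param n_families Number of plant families (monophyletic clades), >= 2.
#' @param n_species Total pool size; must be attainable given `n_families` and
#'   `tips_per_family`. Use `NULL` to keep the randomly drawn family sizes.
#' @param tips_per_family Length-2 integer vector `(min, max)` of species per
#'   family.
#' @param n_obligate,n_facultative Number of obligate / facultative
#'   thermophytes to plant in the pool.
#' @param clustering_strength Probability in `[0, 1]` that each successive
#'   thermal species is drawn from a family that already contains one, rather
#'   than uniformly from the pool. 1 packs thermophytes into the minimal
#'   number of families; 0 assigns them uniformly.
#' @param n_zones Number of thermal zones (labelled with Roman numerals).
#' @param zone_richness Integer vector (length `n_zones`), weakly decreasing:
#'   species richness per zone from coolest to hottest.
#' @param n_pits_per_zone Soil pits dug per zone.
#' @param n_plots Number of 1 m2 vegetation plots carrying cover values.
#' @param zone_alpha Matrix (or list) of per-zone `(min, max)` ranges for the
#'   temperature-depth gradient angle alpha (degrees), coolest zone first.
#' @param soil_gradients See [default_soil_gradients()].
#' @param cover_effects See [default_cover_effects()].
#' @param seed Integer seed; every generator consumes sub-seeds derived from
#'   it, so equal configs give byte-identical data.
#' @return An object of class `geo_config` (a validated list).
#' @export
synthetic_config <- function(n_families = 60L,
                             n_species = 292L,
                             tips_per_family = c(1L, 9L),
                             n_obligate = 18L,
                             n_facultative = 33L,
                             clustering_strength = 0.9,
                             n_zones = 4L,
                             zone_richness = c(24L, 18L, 12L, 6L),
                             n_pits_per_zone = 3L,
                             n_plots = 12L,
                             zone_alpha = rbind(c(4.6, 5.2), c(10, 19),
                                                c(23, 37), c(0, 11)),
                             soil_gradients = default_soil_gradients(n_zones),
                             cover_effects = default_cover_effects(),
                             seed = 1L) {
  n_families <- check_count(n_families, "n_families", min = 2L)
  n_obligate <- check_count(n_obligate, "n_obligate", min = 0L)
  n_facultative <- check_count(n_facultative, "n_facultative", min = 0L)
  n_zones <- check_count(n_zones, "n_zones", min = 1L)
  n_pits_per_zone <- check_count(n_pits_per_zone, "n_pits_per_zone")
  n_plots <- check_count(n_plots, "n_plots")
  clustering_strength <- check_prob(clustering_strength, "clustering_strength")

  if (length(tips_per_family) != 2L || any(tips_per_family < 1L) ||
      tips_per_family[1] > tips_per_family[2]) {
    stop_config("`tips_per_family` must be (min, max) with 1 <= min <= max.")
  }
  tips_per_family <- as.integer(tips_per_family)

  if (!is.null(n_species)) {
    n_species <- check_count(n_species, "n_species", min = n_families)
    lo <- n_families * tips_per_family[1]
    hi <- n_families * tips_per_family[2]
    if (n_species < lo || n_species > hi) {
      stop_config(sprintf(
        "`n_species` = %d unattainable: %d families with %d-%d tips give %d-%d species.",
        n_species, n_families, tips_per_family[1], tips_per_family[2], lo, hi))
    }
    if (n_obligate + n_facultative > n_species) {
      stop_config("n_obligate + n_facultative exceeds the species pool.")
    }
  }

  if (length(zone_richness) != n_zones) {
    stop_config("`zone_richness` must have one entry per zone.")
  }
  zone_richness <- as.integer(zone_richness)
  if (any(zone_richness < 1L)) stop_config("`zone_richness` entries must be >= 1.")
  if (is.unsorted(rev(zone_richness))) {
    stop_config("`zone_richness` must be weakly decreasing from zone I outward.")
  }
  if (!is.null(n_species) && max(zone_richness) > n_species) {
    stop_config("`zone_richness` cannot exceed the pool size.")
  }

  zone_alpha <- as.matrix(zone_alpha)
  if (nrow(zone_alpha) != n_zones || ncol(zone_alpha) != 2L) {
    stop_config("`zone_alpha` must be an n_zones x 2 matrix of (min, max) degrees.")
  }

  req <- c("property", "direction", "zone_means", "noise_sd", "min", "max")
  if (!all(req %in% names(soil_gradients))) {
    stop_config("`soil_gradients` must have columns property, direction, zone_means, noise_sd, min, max.")
  }
  if (!all(soil_gradients$direction %in% c("up", "down", "flat"))) {
    stop_config("gradient `direction` must be one of up/down/flat.")
  }
  if (!all(lengths(soil_gradients$zone_means) == n_zones)) {
    stop_config("each `zone_means` entry must have one mean per zone.")
  }

  if (!all(c("species", "property", "sign", "strength") %in% names(cover_effects))) {
    stop_config("`cover_effects` must have columns species, property, sign, strength.")
  }
  if (!all(cover_effects$property %in% soil_gradients$property)) {
    stop_config("every cover effect must target a generated soil property.")
  }
  if (!all(abs(cover_effects$sign) == 1)) {
    stop_config("cover effect `sign` must be +1 or -1.")
  }
  if (any(cover_effects$strength < 0 | cover_effects$strength > 1)) {
    stop_config("cover effect `strength` must lie in [0, 1].")
  }

  structure(
    list(n_families = n_families, n_species = n_species,
         tips_per_family = tips_per_family, n_obligate = n_obligate,
         n_facultative = n_facultative,
         clustering_strength = clustering_strength, n_zones = n_zones,
         zone_richness = zone_richness, n_pits_per_zone = n_pits_per_zone,
         n_plots = n_plots, zone_alpha = zone_alpha,
         soil_gradients = soil_gradients, cover_effects = cover_effects,
         seed = as.integer(seed)),
    class = "geo_config")
}

#' @export
print.geo_config <- function(x, ...) {
  cat("<geo_config> synthetic geothermal survey\n")
  cat(sprintf("  pool: %s species in %d families (%d-%d tips each)\n",
              x$n_species %||% "free", x$n_families,
              x$tips_per_family[1], x$tips_per_family[2]))
  cat(sprintf("  thermophytes: %d obligate + %d facultative, clustering %.2f\n",
              x$n_obligate, x$n_facultative, x$clustering_strength))
  cat(sprintf("  zones: %d, richness %s\n", x$n_zones,
              paste(x$zone_richness, collapse = " > ")))
  cat(sprintf("  soil: %d properties, %d pits/zone, %d plots; seed %d\n",
              nrow(x$soil_gradients), x$n_pits_per_zone, x$n_plots, x$seed))
  invisible(x)
}

# Write / read a config as YAML (matrices and list-columns flattened).
#' Write a synthetic configuration to YAML
#' @param config A `geo_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "geo_config"))
  x <- unclass(config)
  x$zone_alpha <- lapply(seq_len(nrow(config$zone_alpha)),
                         function(i) as.numeric(config$zone_alpha[i, ]))
  x$soil_gradients <- lapply(seq_len(nrow(config$soil_gradients)), function(i) {
    r <- config$soil_gradients[i, ]
    list(property = r$property, direction = r$direction,
         zone_means = as.numeric(r$zone_means[[1]]),
         noise_sd = r$noise_sd, min = r$min, max = r$max)
  })
  x$cover_effects <- lapply(seq_len(nrow(config$cover_effects)), function(i) {
    as.list(config$cover_effects[i, ])
  })
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a synthetic configuration from YAML
#' @param path YAML file written by [write_config()].
#' @return A validated `geo_config`.
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  sg <- dplyr::bind_rows(lapply(x$soil_gradients, function(r) {
    tibble(property = r$property, direction = r$direction,
           zone_means = list(as.numeric(r$zone_means)),
           noise_sd = r$noise_sd, min = r$min, max = r$max)
  }))
  ce <- dplyr::bind_rows(lapply(x$cover_effects, tibble::as_tibble))
  synthetic_config(
    n_families = x$n_families, n_species = x$n_species,
    tips_per_family = unlist(x$tips_per_family),
    n_obligate = x$n_obligate, n_facultative = x$n_facultative,
    clustering_strength = x$clustering_strength, n_zones = x$n_zones,
    zone_richness = unlist(x$zone_richness),
    n_pits_per_zone = x$n_pits_per_zone, n_plots = x$n_plots,
    zone_alpha = do.call(rbind, x$zone_alpha),
    soil_gradients = sg, cover_effects = ce, seed = x$seed)
}
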