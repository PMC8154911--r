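# Zone compositions, soil tables, plot-level soils and cover matrices with
# the statistical structure the downstream analyses assume.

# Truncated Gaussian by rejection (falls back to clamping for extreme cases).
rtnorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:100) {
    bad <- x < lo | x > hi
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(x, lo), hi)
}

zone_labels <- function(n) as.character(utils::as.roman(seq_len(n)))

# Resolve "@obligate1"-style species tokens against a pool with statuses.
resolve_cover_effects <- function(effects, pool) {
  token <- c("@obligate1" = "obligate", "@facultative1" = "facultative",
             "@nonthermal1" = "non_thermal")
  sp <- effects$species
  for (tk in names(token)) {
    hit <- sp == tk
    if (any(hit)) {
      cand <- pool$species[pool$status == token[[tk]]]
      sp[hit] <- if (length(cand)) cand[1] else NA_character_
    }
  }
  effects$species <- sp
  drop <- is.na(sp) | !(sp %in% pool$species)
  if (any(drop)) {
    warn(sprintf("dropping %d cover effect(s) whose species cannot be resolved.",
                 sum(drop)))
    effects <- effects[!drop, ]
  }
  effects
}

#' Generate zone compositions, soil tables, plot soils and a cover matrix
#'
#' Zone species sets are drawn so that hotter zones lose non-thermal species
#' first: zone I is a uniform sample of the pool; each hotter zone samples
#' from its predecessor's species plus all thermophytes, down-weighting
#' non-thermal candidates by `exp(-1.2 * (zone - 1))`. Soil properties follow
#' the configured per-zone means with truncated Gaussian noise; pit
#' temperature profiles follow the linear temperature-depth model with a
#' per-zone gradient angle. Cover values of nominated species are tied to a
#' soil property through a Gaussian copula at the configured strength (these
#' species are guaranteed to occur in every zone).
#'
#' @param pool Taxonomy tibble with a `status` column
#'   (see [gen_thermal_status()]).
#' @param config A [synthetic_config()].
#' @param seed Overrides `config$seed` when given.
#' @return A list: `zones` (tibble zone/species), `soil` (per-horizon
#'   samples), `plots` (plot-level topsoil properties), `cover` (wide
#'   plot x species tibble, % cover) and `effects` (resolved planted
#'   associations).
#' @export
gen_zone_tables <- function(pool, config, seed = config$seed) {
  stopifnot(inherits(config, "geo_config"))
  if (!all(c("species", "status") %in% names(pool))) {
    stop_config("`pool` needs species and status columns; run gen_thermal_status() first.")
  }
  seeds <- derive_seeds(seed, 4L)
  zl <- zone_labels(config$n_zones)
  thermal <- pool$species[pool$status != "non_thermal"]
  effects <- resolve_cover_effects(config$cover_effects, pool)

  # --- zone species sets ----------------------------------------------------
  sets <- with_seed_if(seeds[[1]], {
    out <- vector("list", config$n_zones)
    for (z in seq_len(config$n_zones)) {
      cand <- if (z == 1L) pool$species else union(out[[z - 1L]], thermal)
      r <- config$zone_richness[z]
      if (r > length(cand)) {
        stop_config(sprintf("zone %s richness %d exceeds its %d candidates.",
                            zl[z], r, length(cand)))
      }
      w <- ifelse(cand %in% thermal, 1, exp(-1.2 * (z - 1L)))
      out[[z]] <- sample(cand, r, prob = w)
      # planted cover-effect species must occur along the whole catena
      for (e in unique(effects$species)) {
        if (!(e %in% out[[z]])) {
          swap <- which(!(out[[z]] %in% effects$species))
          out[[z]][swap[sample.int(length(swap), 1L)]] <- e
        }
      }
    }
    out
  })
  zones <- tibble(zone = rep(zl, lengths(sets)), species = unlist(sets)) |>
    arrange(.data$zone, .data$species)

  grad <- config$soil_gradients
  zmean <- function(prop, z) grad$zone_means[[match(prop, grad$property)]][z]
  grow <- function(prop, z, n) {
    i <- match(prop, grad$property)
    rtnorm(n, grad$zone_means[[i]][z], grad$noise_sd[i], grad$min[i], grad$max[i])
  }
  props <- setdiff(grad$property, "T15")

  # --- per-horizon soil samples --------------------------------------------
  soil <- with_seed_if(seeds[[2]], {
    layers <- cbind(top = c(0, 10, 30), bottom = c(10, 30, 50))
    rows <- list()
    pit_no <- 0L
    for (z in seq_len(config$n_zones)) {
      for (p in seq_len(config$n_pits_per_zone)) {
        pit_no <- pit_no + 1L
        alpha <- stats::runif(1, config$zone_alpha[z, 1], config$zone_alpha[z, 2])
        k <- tan(alpha * pi / 180)
        t15 <- grow("T15", z, 1L)
        mid <- rowMeans(layers)
        df <- tibble(
          pit = sprintf("pit%02d", pit_no), zone = zl[z],
          depth_top = layers[, "top"], depth_bottom = layers[, "bottom"],
          temperature = k * (mid - 15) + t15,
          T15 = t15, T50 = k * 35 + t15, k = k, alpha_deg = alpha)
        for (pr in props) df[[pr]] <- grow(pr, z, nrow(df))
        rows[[pit_no]] <- df
      }
    }
    out <- bind_rows(rows)
    if (all(c("pm_clay", "pm_sand") %in% names(out))) {
      tot <- out$pm_clay + out$pm_sand
      over <- tot > 99
      out$pm_clay[over] <- out$pm_clay[over] * 95 / tot[over]
      out$pm_sand[over] <- out$pm_sand[over] * 95 / tot[over]
      out$pm_silt <- 100 - out$pm_clay - out$pm_sand
    }
    out
  })

  # --- plot-level topsoil properties ---------------------------------------
  plots <- with_seed_if(seeds[[3]], {
    pz <- rep(zl, each = ceiling(config$n_plots / config$n_zones))[seq_len(config$n_plots)]
    df <- tibble(plot = sprintf("plot%02d", seq_len(config$n_plots)), zone = pz)
    zi <- match(pz, zl)
    for (pr in grad$property) {
      i <- match(pr, grad$property)
      df[[pr]] <- rtnorm(length(zi),
                         vapply(zi, function(z) grad$zone_means[[i]][z], 0),
                         grad$noise_sd[i], grad$min[i], grad$max[i])
    }
    df
  })

  # --- cover matrix (Gaussian copula against the target property) ----------
  cover <- with_seed_if(seeds[[4]], {
    present <- lapply(sets, identity)
    names(present) <- zl
    sp_all <- pool$species[pool$species %in% unique(unlist(sets))]
    m <- matrix(0, nrow = nrow(plots), ncol = length(sp_all),
                dimnames = list(plots$plot, sp_all))
    for (s in sp_all) {
      in_plot <- plots$zone %in% zl[vapply(seq_along(sets),
                                           function(z) s %in% sets[[z]], TRUE)]
      eff <- effects[effects$species == s, ]
      if (nrow(eff) >= 1L) {
        eff <- eff[1, ]
        x <- plots[[eff$property]]
        zx <- if (stats::sd(x) > 0) as.numeric(scale(x)) else stats::rnorm(length(x))
        lat <- eff$sign * eff$strength * zx +
          sqrt(1 - eff$strength^2) * stats::rnorm(length(x))
        m[, s] <- round(100 * stats::pnorm(lat), 1)
      } else {
        m[in_plot, s] <- round(stats::rbeta(sum(in_plot), 1.2, 4) * 60, 1)
      }
    }
    bind_cols(tibble(plot = plots$plot), as_tibble(m))
  })

  list(zones = zones, soil = soil, plots = plots, cover = cover,
       effects = effects)
}

#' Generate a complete synthetic survey
#'
#' Runs [gen_backbone_tree()], [gen_thermal_status()] and [gen_zone_tables()]
#' under sub-seeds derived from `config$seed`, so equal configs yield
#' byte-identical datasets.
#'
#' @param config A [synthetic_config()].
#' @return A `geo_dataset`: list with `tree`, `pool` (taxonomy + status),
#'   `zones`, `soil`, `plots`, `cover`, `effects` and the `config`.
#' @export
gen_dataset <- function(config = synthetic_config()) {
  seeds <- derive_seeds(config$seed, 3L)
  bt <- gen_backbone_tree(config, seed = seeds[[1]])
  pool <- gen_thermal_status(bt$taxonomy, config, seed = seeds[[2]])
  zt <- gen_zone_tables(pool, config, seed = seeds[[3]])
  structure(c(list(tree = bt$tree, pool = pool), zt, list(config = config)),
            class = "geo_dataset")
}

#' @export
print.geo_dataset <- function(x, ...) {
  cat("<geo_dataset>\n")
  cat(sprintf("  tree: %d tips; pool: %d species (%d obligate, %d facultative)\n",
              length(x$tree$tip.label), nrow(x$pool),
              sum(x$pool$status == "obligate"),
              sum(x$pool$status == "facultative")))
  cat(sprintf("  zones: %s (richness %s)\n",
              paste(unique(x$zones$zone), collapse = ", "),
              paste(table(x$zones$zone)[unique(x$zones$zone)], collapse = ", ")))
  cat(sprintf("  soil: %d samples in %d pits; cover: %d plots x %d species\n",
              nrow(x$soil), length(unique(x$soil$pit)),
              nrow(x$cover), ncol(x$cover) - 1L))
  invisible(x)
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Emits `tree.nwk`, `pool.tsv`, `zones.tsv`, `soil.tsv`, `plots.tsv`,
#' `cover.tsv` and `config.yaml`.
#'
#' @param dataset A `geo_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "geo_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_newick(dataset$tree, file.path(dir, "tree.nwk"))
  readr::write_tsv(dataset$pool, file.path(dir, "pool.tsv"))
  readr::write_tsv(dataset$zones, file.path(dir, "zones.tsv"))
  readr::write_tsv(dataset$soil, file.path(dir, "soil.tsv"))
  readr::write_tsv(dataset$plots, file.path(dir, "plots.tsv"))
  readr::write_tsv(dataset$cover, file.path(dir, "cover.tsv"))
  write_config(dataset$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#' @param dir Directory containing the dataset files.
#' @return A `geo_dataset`.
#' @export
read_dataset <- function(dir) {
  rd <- function(f) readr::read_tsv(file.path(dir, f), show_col_types = FALSE)
  structure(
    list(tree = read_newick(file.path(dir, "tree.nwk")),
         pool = rd("pool.tsv"), zones = rd("zones.tsv"), soil = rd("soil.tsv"),
         plots = rd("plots.tsv"), cover = rd("cover.tsv"),
         effects = NULL, config = read_config(file.path(dir, "config.yaml"))),
    class = "geo_dataset")
}
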