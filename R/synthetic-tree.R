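# Synthetic backbone phylogeny: a pure-birth tree over families, each family
# tip replaced by a pure-birth subtree of species, rescaled so the whole tree
# is ultrametric with depth 1. Families are monophyletic by construction.

# Draw family sizes within [min, max] and repair them to sum to `total`
# (uniform draws, then random +/-1 adjustments that respect the bounds).
draw_family_sizes <- function(n_families, bounds, total = NULL) {
  span <- bounds[2] - bounds[1] + 1L
  sizes <- bounds[1] + sample.int(span, n_families, replace = TRUE) - 1L
  if (is.null(total)) {
    return(sizes)
  }
  while (sum(sizes) != total) {
    if (sum(sizes) > total) {
      cand <- which(sizes > bounds[1])
      i <- cand[sample.int(length(cand), 1L)]
      sizes[i] <- sizes[i] - 1L
    } else {
      cand <- which(sizes < bounds[2])
      i <- cand[sample.int(length(cand), 1L)]
      sizes[i] <- sizes[i] + 1L
    }
  }
  sizes
}

# Ultrametric pure-birth tree rescaled to a given depth.
yule_tree <- function(n_tips, depth = 1) {
  stopifnot(n_tips >= 2)
  tr <- ape::rphylo(n_tips, birth = 1, death = 0)
  tr$edge.length <- tr$edge.length * (depth / max(ape::node.depth.edgelength(tr)))
  tr
}

# Serialise a phylo to newick, substituting designated tips with pre-built
# subtree blocks (text + its own stem length). Used to splice family subtrees
# into the family backbone at full numeric precision.
newick_with_blocks <- function(phy, blocks = list()) {
  ntip <- length(phy$tip.label)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  elen <- numeric(max(phy$edge))
  elen[phy$edge[, 2]] <- phy$edge.length
  fmt <- function(x) sprintf("%.15g", x)
  rec <- function(v) {
    if (v <= ntip) {
      lab <- phy$tip.label[v]
      if (lab %in% names(blocks)) {
        paste0(blocks[[lab]]$text, ":", fmt(blocks[[lab]]$stem))
      } else {
        paste0(lab, ":", fmt(elen[v]))
      }
    } else {
      inner <- paste(vapply(kids[[as.character(v)]], rec, character(1)),
                     collapse = ",")
      core <- paste0("(", inner, ")")
      if (v == ntip + 1L) core else paste0(core, ":", fmt(elen[v]))
    }
  }
  paste0(rec(ntip + 1L), ";")
}

#' Generate a synthetic backbone phylogeny with taxonomy
#'
#' Simulates a rooted ultrametric tree (depth 1) in which every family is a
#' monophyletic clade: a pure-birth backbone over families whose tips are
#' replaced by pure-birth species subtrees spanning half the family's pendant
#' branch. Families are grouped into orders (blocks of ~3 families) and orders
#' into two classes; each species also receives a biomorph label.
#'
#' @param config A [synthetic_config()].
#' @param seed Overrides `config$seed` when given.
#' @return A list with `tree` (an `ape::phylo`), `taxonomy` (tibble: species,
#'   family, order, class, biomorph) and `family_sizes`.
#' @export
gen_backbone_tree <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "geo_config"))
  with_seed_if(seed, {
    nf <- config$n_families
    sizes <- draw_family_sizes(nf, config$tips_per_family, config$n_species)
    fams <- sprintf("Fam%03d", seq_len(nf))

    backbone <- yule_tree(nf, depth = 1)
    backbone$tip.label <- fams # tip order is the simulation's labelling order
    pend <- backbone$edge.length[match(seq_len(nf), backbone$edge[, 2])]

    species <- vector("list", nf)
    blocks <- list()
    for (f in seq_len(nf)) {
      m <- sizes[f]
      sp <- sprintf("%s_sp%02d", fams[f], seq_len(m))
      species[[f]] <- sp
      if (m == 1L) {
        backbone$tip.label[f] <- sp
      } else {
        sub <- yule_tree(m, depth = pend[f] / 2)
        sub$tip.label <- sp
        txt <- ape::write.tree(sub, digits = 15)
        blocks[[fams[f]]] <- list(text = sub(";$", "", txt),
                                  stem = pend[f] / 2)
      }
    }

    tree <- ape::read.tree(text = newick_with_blocks(backbone, blocks))

    n_orders <- max(1L, ceiling(nf / 3L))
    ord_of_fam <- sprintf("Ord%02d", ceiling(seq_len(nf) / 3L))
    cls_of_ord <- ifelse(seq_len(n_orders) <= ceiling(n_orders / 2),
                         "ClassA", "ClassB")
    taxonomy <- tibble(
      species = unlist(species),
      family = rep(fams, sizes),
      order = rep(ord_of_fam, sizes)
    )
    taxonomy$class <- cls_of_ord[match(taxonomy$order,
                                       sprintf("Ord%02d", seq_len(n_orders)))]
    taxonomy$biomorph <- sample(c("herb", "graminoid", "fern", "shrub"),
                                nrow(taxonomy), replace = TRUE,
                                prob = c(0.55, 0.2, 0.12, 0.13))
    # match tip order for convenience
    taxonomy <- taxonomy[match(tree$tip.label, taxonomy$species), ]

    list(tree = tree, taxonomy = as_tibble(taxonomy), family_sizes = sizes)
  })
}

#' Assign thermal statuses to a species pool
#'
#' Plants `n_obligate + n_facultative` thermal species. Each successive
#' thermal species is drawn, with probability `clustering_strength`, uniformly
#' from the not-yet-thermal species of families that already contain a thermal
#' species, and otherwise uniformly from the whole remaining pool. With
#' strength 1 thermophytes fill one family after another (small clusters of
#' close relatives); with strength 0 the thermal set is a uniform random
#' subset, so per-family thermal counts are hypergeometric. The first
#' `n_obligate` species drawn are labelled obligate, the rest facultative.
#'
#' @param taxonomy Tibble with at least `species` and `family` columns.
#' @param config A [synthetic_config()].
#' @param seed Overrides `config$seed` when given.
#' @return `taxonomy` with a `status` column
#'   (`obligate`/`facultative`/`non_thermal`).
#' @export
gen_thermal_status <- function(taxonomy, config, seed = config$seed) {
  stopifnot(inherits(config, "geo_config"))
  n_th <- config$n_obligate + config$n_facultative
  if (n_th > nrow(taxonomy)) {
    stop_config("requested thermal species exceed the pool size.")
  }
  with_seed_if(seed, {
    fam_of <- stats::setNames(taxonomy$family, taxonomy$species)
    remaining <- taxonomy$species
    picked <- character(0)
    for (i in seq_len(n_th)) {
      thermal_fams <- unique(fam_of[picked])
      cands <- remaining[fam_of[remaining] %in% thermal_fams]
      use_cluster <- length(cands) > 0 &&
        stats::runif(1) <= config$clustering_strength
      pick <- if (use_cluster) {
        cands[sample.int(length(cands), 1L)]
      } else {
        remaining[sample.int(length(remaining), 1L)]
      }
      picked <- c(picked, pick)
      remaining <- setdiff(remaining, pick)
    }
    status <- rep("non_thermal", nrow(taxonomy))
    status[match(picked[seq_len(config$n_obligate)], taxonomy$species)] <- "obligate"
    if (config$n_facultative > 0) {
      fac <- picked[config$n_obligate + seq_len(config$n_facultative)]
      status[match(fac, taxonomy$species)] <- "facultative"
    }
    mutate(taxonomy, status = status)
  })
}
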