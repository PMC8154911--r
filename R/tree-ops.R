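# Newick I/O, grafting of species missing from a backbone tree, patristic
# distances and uniform pair subsampling.

#' Read a rooted phylogeny from a newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' downstream analyses rely on: a single tree, unique tip labels, and branch
#' lengths present and non-negative (patristic distances are undefined
#' without them).
#'
#' @param path Path to a newick file.
#' @return An `ape::phylo`.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) {
                   stop_parse(sprintf("malformed newick in %s: %s", path,
                                      conditionMessage(e)))
                 })
  if (is.null(tr)) stop_parse(sprintf("malformed newick in %s.", path))
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop_parse(sprintf("%s contains %d trees, expected one.",
                                             path, length(tr)))
    tr <- tr[[1]]
  }
  validate_tree(tr, where = path)
  tr
}

validate_tree <- function(tr, where = "tree") {
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup)) {
    stop_parse(sprintf("duplicate tip labels in %s: %s", where,
                       paste(dup, collapse = ", ")))
  }
  if (is.null(tr$edge.length) || anyNA(tr$edge.length)) {
    stop_parse(sprintf("missing branch lengths in %s: patristic distances are undefined.",
                       where))
  }
  if (any(tr$edge.length < 0)) {
    stop_parse(sprintf("negative branch lengths in %s.", where))
  }
  invisible(tr)
}

#' Write a phylogeny to a newick file
#'
#' @param tree An `ape::phylo`.
#' @param path Output path.
#' @param digits Significant digits for branch lengths (default preserves a
#'   depth-1 tree to well below 1e-9 on a round trip).
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, digits = 12) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

# Depth (root-to-node path length) of every node, and the tree height.
node_depths <- function(tree) ape::node.depth.edgelength(tree)

tips_of_clade <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  desc <- phytools::getDescendants(tree, node)
  desc[desc <= ntip]
}

#' Graft missing species onto a backbone phylogeny
#'
#' Adds each species absent from the tree according to one of three rules:
#' \describe{
#'   \item{`basal_polytomy`}{attach at the most recent common ancestor (MRCA)
#'     of the species' family.}
#'   \item{`random_within_family`}{attach at an internal node chosen uniformly
#'     within the family clade (MRCA included).}
#'   \item{`taxonomy_constrained`}{as `basal_polytomy` when the family has
#'     tips in the tree; otherwise attach at the MRCA of the species' order.
#'     This emulates placement against a taxonomic megatree without an
#'     external service.}
#' }
#' The pendant branch always spans from the attachment point to the tree
#' height, so an ultrametric input stays ultrametric; when a family is
#' represented by a single tip, a new node is created halfway down that tip's
#' pendant branch so the family remains monophyletic. Species are processed
#' sequentially, so a species grafted earlier can anchor later ones from the
#' same family.
#'
#' @param tree Backbone `ape::phylo` with branch lengths.
#' @param taxonomy Tibble with `species`, `family` and (for the
#'   taxonomy-constrained method) `order` columns covering both tree tips and
#'   the missing species.
#' @param missing_species Character vector of species to add.
#' @param method One of `"basal_polytomy"`, `"random_within_family"`,
#'   `"taxonomy_constrained"`.
#' @param seed Optional integer seed (only `random_within_family` draws
#'   random numbers).
#' @return The enlarged `ape::phylo`.
#' @export
graft_species <- function(tree, taxonomy, missing_species,
                          method = c("basal_polytomy", "random_within_family",
                                     "taxonomy_constrained"),
                          seed = NULL) {
  method <- match.arg(method)
  validate_tree(tree)
  if (length(missing_species) == 0L) return(tree)
  unknown <- setdiff(missing_species, taxonomy$species)
  if (length(unknown)) {
    stop_lookup(paste0("species missing from the taxonomy: ",
                       paste(unknown, collapse = ", ")))
  }
  already <- intersect(missing_species, tree$tip.label)
  if (length(already)) {
    stop_config(paste0("species already in the tree: ",
                       paste(already, collapse = ", ")))
  }

  fam_of <- stats::setNames(taxonomy$family, taxonomy$species)
  ord_of <- if ("order" %in% names(taxonomy)) {
    stats::setNames(taxonomy$order, taxonomy$species)
  } else {
    stats::setNames(rep(NA_character_, nrow(taxonomy)), taxonomy$species)
  }
  tip_fams <- fam_of[tree$tip.label]
  tip_ords <- ord_of[tree$tip.label]
  need_fam <- fam_of[missing_species]
  need_ord <- ord_of[missing_species]
  unplaceable <- if (method == "taxonomy_constrained") {
    missing_species[!(need_fam %in% tip_fams) & !(need_ord %in% tip_ords)]
  } else {
    missing_species[!(need_fam %in% tip_fams)]
  }
  if (length(unplaceable)) {
    abort(paste0("unplaceable species (family",
                 if (method == "taxonomy_constrained") " and order" else "",
                 " absent from the tree): ",
                 paste(unplaceable, collapse = ", ")),
          class = "geothermflora_unplaceable")
  }

  with_seed_if(seed, {
    for (sp in missing_species) {
      tree <- graft_one(tree, sp, fam_of, ord_of, method)
    }
    tree
  })
}

graft_one <- function(tree, sp, fam_of, ord_of, method) {
  ntip <- length(tree$tip.label)
  dep <- node_depths(tree)
  height <- max(dep[seq_len(ntip)])
  fam_tips <- which(fam_of[tree$tip.label] == fam_of[[sp]])

  attach_at_tip_half <- function(tipnum) {
    el <- tree$edge.length[tree$edge[, 2] == tipnum]
    phytools::bind.tip(tree, sp, edge.length = el / 2,
                       where = tipnum, position = el / 2)
  }
  attach_at_node <- function(node) {
    phytools::bind.tip(tree, sp, edge.length = height - dep[node],
                       where = node, position = 0)
  }

  if (length(fam_tips) == 0L) { # taxonomy_constrained fallback to the order
    ord_tips <- which(ord_of[tree$tip.label] == ord_of[[sp]])
    if (length(ord_tips) == 1L) return(attach_at_tip_half(ord_tips))
    return(attach_at_node(ape::getMRCA(tree, ord_tips)))
  }
  if (length(fam_tips) == 1L) return(attach_at_tip_half(fam_tips))

  mrca <- ape::getMRCA(tree, fam_tips)
  node <- if (method == "random_within_family") {
    cand <- c(mrca, phytools::getDescendants(tree, mrca))
    cand <- cand[cand > ntip]
    cand[sample.int(length(cand), 1L)]
  } else {
    mrca
  }
  attach_at_node(node)
}

#' Patristic distance matrix
#'
#' Sum of branch lengths along the path between every pair of tips,
#' optionally restricted to a subset of species.
#'
#' @param tree An `ape::phylo` with branch lengths.
#' @param species Optional character vector of tips; errors if any is absent.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
patristic_matrix <- function(tree, species = NULL) {
  validate_tree(tree)
  m <- ape::cophenetic.phylo(tree)
  if (is.null(species)) return(m)
  missing <- setdiff(species, rownames(m))
  if (length(missing)) {
    stop_lookup(paste0("species not in the tree: ",
                       paste(missing, collapse = ", ")))
  }
  m[species, species, drop = FALSE]
}

#' Subsample unordered species pairs
#'
#' Returns all `choose(n, 2)` pairs when there are at most `max_pairs` of
#' them, otherwise a uniform sample of `max_pairs` distinct pairs without
#' replacement. This is the pair-subsampling device used to keep mean
#' pairwise distance computations tractable for large groups.
#'
#' @param species Character vector (length >= 2).
#' @param max_pairs Maximum number of pairs to return.
#' @param seed Optional integer seed.
#' @return A tibble with character columns `a` and `b`.
#' @export
sample_pairs <- function(species, max_pairs = 100, seed = NULL) {
  n <- length(species)
  if (n < 2L) stop_config("need at least 2 species to form pairs.")
  if (anyDuplicated(species)) stop_config("`species` contains duplicates.")
  npairs <- choose(n, 2)
  idx <- if (npairs <= max_pairs) {
    seq_len(npairs)
  } else {
    with_seed_if(seed, sample.int(npairs, max_pairs))
  }
  ij <- pair_from_index(idx, n)
  tibble(a = species[ij[, "i"]], b = species[ij[, "j"]])
}
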