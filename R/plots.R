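# ggplot2 graphics for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_hline geom_tile
#'   geom_text geom_line labs scale_fill_gradient2 scale_fill_manual
#'   theme_minimal facet_wrap geom_boxplot
#' @export
ggplot2::autoplot

#' Plot NRI replicates
#'
#' Per-tree replicate NRI values with the per-tree medians and the zero line
#' (values above zero indicate phylogenetic clustering).
#'
#' @param object A `geo_nri`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot geo_nri
#' @export
autoplot.geo_nri <- function(object, ...) {
  reps <- object$replicates
  med <- object$per_tree
  ggplot(reps, aes(x = factor(.data$tree), y = .data$nri)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    geom_point(alpha = 0.6, position = ggplot2::position_jitter(width = 0.08,
                                                                height = 0)) +
    geom_point(data = med, shape = 95, size = 10, colour = "firebrick") +
    labs(x = "tree", y = "NRI",
         title = sprintf("NRI = %.2f, p = %.3g (mean of per-tree medians)",
                         object$nri, object$p_value)) +
    theme_minimal()
}

#' Plot a zone-overlap matrix
#'
#' Tile map of the right-tail (or left-tail) overlap p-values with the
#' observed shared-species counts printed in the cells.
#'
#' @param object A `geo_overlap`.
#' @param tail `"right"` (more similar than chance) or `"left"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot geo_overlap
#' @export
autoplot.geo_overlap <- function(object, tail = c("right", "left"), ...) {
  tail <- match.arg(tail)
  d <- tidy(object)
  d$p <- if (tail == "right") d$p_right else d$p_left
  ggplot(d, aes(x = .data$zone_a, y = .data$zone_b, fill = -log10(.data$p))) +
    geom_tile() +
    geom_text(aes(label = .data$observed), size = 3) +
    scale_fill_gradient2(low = "white", high = "firebrick",
                         name = expression(-log[10](p))) +
    labs(x = NULL, y = NULL,
         title = sprintf("shared species vs %s-tail permutation p", tail)) +
    theme_minimal()
}

#' Plot an edaphic importance matrix
#'
#' Species x property tiles coloured by the direction of significant
#' associations (positive, negative, non-monotone).
#'
#' @param object A `geo_importance` from [importance_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot geo_importance
#' @export
autoplot.geo_importance <- function(object, ...) {
  d <- as_tibble(object)
  d$direction <- ifelse(d$important, d$direction, NA_character_)
  ggplot(d, aes(x = .data$property, y = .data$species,
                fill = .data$direction)) +
    geom_tile(colour = "grey85") +
    scale_fill_manual(values = c(`+` = "#2166ac", `-` = "#b2182b",
                                 nonmonotone = "#f4a582"),
                      na.value = "white", name = "association") +
    labs(x = NULL, y = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a taxon enrichment table
#'
#' Tail probabilities per taxon on a -log10 scale, coloured by the raw call.
#'
#' @param enrichment A tibble from [enrich_table()].
#' @param alpha Reference line (default 0.05).
#' @return A ggplot.
#' @export
plot_enrichment <- function(enrichment, alpha = 0.05) {
  d <- enrichment |>
    mutate(p_best = pmin(.data$p_over, .data$p_under),
           taxon = stats::reorder(.data$taxon, -.data$p_best))
  ggplot(d, aes(x = .data$taxon, y = -log10(.data$p_best),
                colour = .data$call)) +
    geom_point(size = 2) +
    geom_hline(yintercept = -log10(alpha), linetype = 2, colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(over = "#b2182b",
                                            under = "#2166ac",
                                            none = "grey60")) +
    ggplot2::coord_flip() +
    labs(x = NULL, y = expression(-log[10](p)),
         title = "taxon over/under-representation") +
    theme_minimal()
}

#' Plot zone-normalised composition ratios
#'
#' Per-property ratios of each zone's median to the reference zone's median
#' (reference = 1, dashed line).
#'
#' @param ratios Output of [normalize_to_reference()].
#' @return A ggplot.
#' @export
plot_zone_ratios <- function(ratios) {
  ggplot(ratios, aes(x = .data$group, y = .data$ratio, group = .data$property)) +
    geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    geom_line(colour = "grey70") +
    geom_point() +
    facet_wrap(~property, scales = "free_y") +
    labs(x = "zone", y = "ratio to reference zone") +
    theme_minimal()
}
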