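#' @importFrom ggplot2 autoplot ggplot aes geom_segment geom_point geom_bar
#'   geom_histogram labs theme_minimal scale_shape_manual
NULL

#' @export
ggplot2::autoplot

#' @export
tidy.cc_network <- function(x, ...) {
  as_tibble(x$edges)
}

#' @export
glance.cc_network <- function(x, ...) {
  network_stats(x)
}

#' Plot a combined network
#'
#' Fruchterman-Reingold layout (reproducible via `layout_seed`); nodes
#' coloured by species presence, second messengers drawn as squares, edges
#' coloured by species provenance with central-cascade edges emphasised.
#'
#' @param object A `cc_network`.
#' @param layout_seed Seed for the layout RNG.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cc_network <- function(object, layout_seed = 42, ...) {
  g <- as_igraph(object)
  xy <- withr::with_seed(layout_seed, igraph::layout_with_fr(g))
  pos <- tibble(id = igraph::V(g)$name, x = xy[, 1], y = xy[, 2]) |>
    left_join(object$nodes, by = "id")
  seg <- object$edges |>
    left_join(select(pos, "id", "x", "y"), by = c(from = "id")) |>
    rename(x0 = "x", y0 = "y") |>
    left_join(select(pos, "id", "x", "y"), by = c(to = "id")) |>
    mutate(edge_category = ifelse(.data$is_cc_edge, "cc",
                                  .data$species_provenance))
  ggplot() +
    geom_segment(data = seg,
                 aes(x = .data$x0, y = .data$y0, xend = .data$x,
                     yend = .data$y, colour = .data$edge_category),
                 alpha = 0.5) +
    geom_point(data = pos,
               aes(x = .data$x, y = .data$y, fill = .data$species_presence,
                   shape = .data$node_kind),
               size = 2, colour = "grey30") +
    scale_shape_manual(values = c(protein = 21, second_messenger = 22)) +
    labs(x = NULL, y = NULL, colour = "edge", fill = "presence",
         shape = "kind") +
    theme_minimal()
}

#' Plot the concordance class distribution
#'
#' @param object A `concordance_tbl`.
#' @param ... Unused.
#' @return A ggplot bar chart of the four classes.
#' @export
autoplot.concordance_tbl <- function(object, ...) {
  ggplot(object, aes(x = .data$label, fill = .data$label)) +
    geom_bar() +
    labs(x = "concordance class", y = "genes") +
    theme_minimal()
}

#' Histogram of overall concordance scores
#' @param records A `concordance_tbl`.
#' @param binwidth Histogram bin width; default 0.25.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(records, binwidth = 0.25) {
  ggplot(records, aes(x = .data$overall)) +
    geom_histogram(binwidth = binwidth, boundary = 0,
                   fill = "steelblue", colour = "white") +
    labs(x = "overall concordance score", y = "genes") +
    theme_minimal()
}
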