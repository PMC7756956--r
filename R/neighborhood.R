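#' Annotate neighbour degree relative to the central-cascade seed set
#'
#' Breadth-first minimum graph distance from the seed set: CC members are at
#' distance 0, proteins directly interacting with the CC are 1st-degree
#' neighbours, their interactors 2nd-degree, and so on; nodes farther than
#' `max_degree` (or disconnected) are labelled `beyond`. Distances run over
#' the full network including second-messenger nodes, which mediate CC
#' connectivity.
#'
#' @param network A `cc_network`.
#' @param cc_seeds Character vector of seed node ids; every seed must be in
#'   the network.
#' @param max_degree Largest annotated shell; default 3.
#' @return A tibble with columns `id`, `distance` (Inf if unreachable) and
#'   `cc_degree` (factor `cc_member`, `first`, `second`, `third`, ...,
#'   `beyond`).
#' @export
annotate_cc_degrees <- function(network, cc_seeds, max_degree = 3) {
  cc_seeds <- unique(clean_symbols(cc_seeds))
  missing <- setdiff(cc_seeds, network$nodes$id)
  if (length(missing) > 0) {
    abort(paste0("seed(s) not in network: ", paste(missing, collapse = ", ")),
          class = "plateletcc_consistency_error")
  }
  g <- as_igraph(network)
  d <- igraph::distances(g, v = cc_seeds, to = igraph::V(g))
  dmin <- apply(d, 2, min)
  labels <- cc_degree_labels(max_degree)
  lab <- ifelse(dmin > max_degree, "beyond", labels[dmin + 1])
  tibble(
    id = igraph::V(g)$name,
    distance = unname(dmin),
    cc_degree = factor(lab, levels = c(labels, "beyond"))
  ) |>
    arrange(.data$distance, .data$id)
}

cc_degree_labels <- function(max_degree) {
  base <- c("cc_member", "first", "second", "third")
  if (max_degree <= 3) return(base[seq_len(max_degree + 1)])
  c(base, paste0("degree_", 4:max_degree))
}

#' Extract the central cascade plus its neighbours
#'
#' Induced subgraph on nodes at distance at most `max_degree` from the seed
#' set; components containing no seed are dropped entirely.
#'
#' @param network A `cc_network`.
#' @param annotations Output of [annotate_cc_degrees()] covering the network.
#' @param max_degree Shell cut; default 3.
#' @return A `cc_network`.
#' @export
extract_cc_subnetwork <- function(network, annotations, max_degree = 3) {
  missing <- setdiff(network$nodes$id, annotations$id)
  if (length(missing) > 0) {
    abort("annotations do not cover the network",
          class = "plateletcc_consistency_error")
  }
  keep <- annotations$id[annotations$distance <= max_degree]
  induced_subnetwork(network, keep)
}

# Induced subgraph on a node id set.
induced_subnetwork <- function(network, ids) {
  nodes <- filter(network$nodes, .data$id %in% ids)
  edges <- filter(network$edges,
                  .data$from %in% ids, .data$to %in% ids)
  structure(list(nodes = nodes, edges = edges), class = "cc_network")
}
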