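#' Thresholds for the combined-network difference filter
#'
#' A node survives filtering if its interspecies expression difference exceeds
#' `delta_rpkm_min` (default 100 RPKM, approximating the 90th percentile of
#' all differences), if it is expressed solidly (> `exclusive_min_rpkm`,
#' default 10) in one species but not in the other (at most
#' `detection_limit_rpkm`, default 1), or if no ortholog exists in the other
#' species.
#'
#' @param delta_rpkm_min Positive; default 100.
#' @param exclusive_min_rpkm Positive; default 10.
#' @param detection_limit_rpkm Nonnegative; default 1.
#' @return A list classed `filter_thresholds`.
#' @export
filter_thresholds <- function(delta_rpkm_min = 100,
                              exclusive_min_rpkm = 10,
                              detection_limit_rpkm = 1.0) {
  if (!(delta_rpkm_min > exclusive_min_rpkm &&
        exclusive_min_rpkm > detection_limit_rpkm)) {
    abort("need delta_rpkm_min > exclusive_min_rpkm > detection_limit_rpkm",
          class = "plateletcc_config_error")
  }
  structure(
    list(delta_rpkm_min = delta_rpkm_min,
         exclusive_min_rpkm = exclusive_min_rpkm,
         detection_limit_rpkm = detection_limit_rpkm),
    class = "filter_thresholds"
  )
}

#' Cross-species RPKM difference (human minus mouse)
#' @param human_rpkm,mouse_rpkm Nonnegative numeric vectors.
#' @return Signed numeric vector.
#' @export
delta_rpkm <- function(human_rpkm, mouse_rpkm) {
  stopifnot(all(human_rpkm >= 0, na.rm = TRUE),
            all(mouse_rpkm >= 0, na.rm = TRUE))
  human_rpkm - mouse_rpkm
}

#' Apply the clear-difference filter to node expression evidence
#'
#' Categorises each node: `kept_non_ortholog` (no ortholog in the other
#' species -- a genomic presence/absence difference), `kept_exclusive`
#' (solidly expressed in one species, not detected in the other),
#' `kept_delta` (absolute RPKM difference strictly above the threshold), or
#' `dropped`. Reporting precedence is non-ortholog > exclusive > delta.
#'
#' @param expression Tibble with columns `id`, `human_rpkm`, `mouse_rpkm` and
#'   logical `has_ortholog` (NA RPKM is treated as 0).
#' @param thresholds A [filter_thresholds()] object.
#' @return `expression` with an added `filter_category` factor column.
#' @export
passes_difference_filter <- function(expression,
                                     thresholds = filter_thresholds()) {
  h <- expression$human_rpkm %na% 0
  m <- expression$mouse_rpkm %na% 0
  dl <- thresholds$detection_limit_rpkm
  ex <- thresholds$exclusive_min_rpkm
  exclusive <- (h > ex & m <= dl) | (m > ex & h <= dl)
  big_delta <- abs(delta_rpkm(h, m)) > thresholds$delta_rpkm_min
  category <- case_when(
    !expression$has_ortholog ~ "kept_non_ortholog",
    exclusive ~ "kept_exclusive",
    big_delta ~ "kept_delta",
    TRUE ~ "dropped"
  )
  mutate(expression, filter_category = factor(
    category,
    levels = c("kept_non_ortholog", "kept_exclusive", "kept_delta", "dropped")
  ))
}

#' Identify connector nodes between retained nodes
#'
#' A single pass adds every non-retained node adjacent to at least two
#' retained nodes (a bridge between clear differences); no transitive closure
#' is applied.
#'
#' @param network A `cc_network`.
#' @param retained Character vector of retained node ids (subset of the
#'   network's nodes).
#' @return Character vector of connector node ids.
#' @export
add_connectors <- function(network, retained) {
  stopifnot(all(retained %in% network$nodes$id))
  e <- network$edges
  touches <- bind_rows(
    tibble(node = e$from, other = e$to),
    tibble(node = e$to, other = e$from)
  ) |>
    filter(!.data$node %in% retained, .data$other %in% retained) |>
    distinct(.data$node, .data$other) |>
    count(.data$node)
  touches$node[touches$n >= 2]
}

#' Assign Cytoscape-style node and edge attribute categories
#'
#' Fill category encodes where a protein occurs: only in one species'
#' platelet network (ortholog present), only in one species' genome
#' (non-ortholog, drawn as rectangle), shared, or grey for second messengers
#' and proteins not expressed in either species. Border category encodes the
#' direction of a clear expression difference (higher in human / higher in
#' mouse); node size is the absolute RPKM difference. Edge category encodes
#' provenance (both / human / mouse) with central-cascade edges set apart.
#'
#' @param network A `cc_network`.
#' @param expression Tibble with `id`, `human_rpkm`, `mouse_rpkm` (NA treated
#'   as 0); nodes without a row count as unexpressed.
#' @param labels Optional `concordance_tbl`; its `label` is carried along as
#'   an annotation column.
#' @param thresholds A [filter_thresholds()] object.
#' @return A list with `nodes` (id, fill_category, border_category,
#'   size_value, shape, concordance_label) and `edges` (from, to,
#'   edge_category) tibbles.
#' @export
assign_attributes <- function(network, expression, labels = NULL,
                              thresholds = filter_thresholds()) {
  nodes <- network$nodes |>
    left_join(select(expression, "id", "human_rpkm", "mouse_rpkm"), by = "id") |>
    mutate(
      human_rpkm = .data$human_rpkm %na% 0,
      mouse_rpkm = .data$mouse_rpkm %na% 0,
      delta = delta_rpkm(.data$human_rpkm, .data$mouse_rpkm),
      unexpressed = .data$human_rpkm <= thresholds$detection_limit_rpkm &
        .data$mouse_rpkm <= thresholds$detection_limit_rpkm,
      fill_category = case_when(
        .data$node_kind == "second_messenger" ~ "not_expressed_or_messenger",
        .data$unexpressed ~ "not_expressed_or_messenger",
        .data$ortholog_status == "human_specific" ~ "human_genome_only",
        .data$ortholog_status == "mouse_specific" ~ "mouse_genome_only",
        .data$species_presence == "human_only" ~ "human_network_only",
        .data$species_presence == "mouse_only" ~ "mouse_network_only",
        TRUE ~ "shared"
      ),
      has_difference = kept_flag(.data$human_rpkm, .data$mouse_rpkm,
                                 .data$ortholog_status, thresholds),
      border_category = case_when(
        .data$node_kind == "second_messenger" ~ "no_clear_difference",
        .data$has_difference & .data$delta > 0 ~ "higher_human",
        .data$has_difference & .data$delta < 0 ~ "higher_mouse",
        TRUE ~ "no_clear_difference"
      ),
      size_value = abs(.data$delta),
      shape = ifelse(.data$fill_category %in%
                       c("human_genome_only", "mouse_genome_only"),
                     "rectangle", "ellipse")
    ) |>
    select("id", "fill_category", "border_category", "size_value", "shape")
  if (!is.null(labels)) {
    nodes <- left_join(
      nodes,
      tibble(id = labels$symbol, concordance_label = as.character(labels$label)),
      by = "id"
    )
  }
  edges <- network$edges |>
    mutate(edge_category = ifelse(.data$is_cc_edge, "cc",
                                  .data$species_provenance)) |>
    select("from", "to", "edge_category")
  list(nodes = nodes, edges = edges)
}

kept_flag <- function(h, m, ortholog_status, thresholds) {
  cat <- passes_difference_filter(
    tibble(id = seq_along(h), human_rpkm = h, mouse_rpkm = m,
           has_ortholog = !(ortholog_status %in%
                              c("human_specific", "mouse_specific"))),
    thresholds
  )$filter_category
  cat != "dropped"
}

#' Filter a combined network down to its clear cross-species differences
#'
#' Applies [passes_difference_filter()] to every protein node, retains the
#' kept nodes plus single-pass connectors ([add_connectors()]), central-
#' cascade members and second messengers, and returns the induced subgraph.
#'
#' @param network A `cc_network`.
#' @param expression Tibble with `id`, `human_rpkm`, `mouse_rpkm`.
#' @param thresholds A [filter_thresholds()] object.
#' @return A list: `network` (the filtered `cc_network`), `categories` (the
#'   per-node filter categories) and `connectors` (ids added as connectors).
#' @export
filter_difference_network <- function(network, expression,
                                      thresholds = filter_thresholds()) {
  prot <- filter(network$nodes, .data$node_kind == "protein")
  ev <- prot |>
    left_join(select(expression, "id", "human_rpkm", "mouse_rpkm"), by = "id") |>
    mutate(has_ortholog = !(.data$ortholog_status %in%
                              c("human_specific", "mouse_specific"))) |>
    select("id", "human_rpkm", "mouse_rpkm", "has_ortholog")
  categories <- passes_difference_filter(ev, thresholds)
  retained <- categories$id[categories$filter_category != "dropped"]
  connectors <- add_connectors(network, retained)
  keep <- unique(c(
    retained, connectors,
    network$nodes$id[network$nodes$is_cc |
                       network$nodes$node_kind == "second_messenger"]
  ))
  list(
    network = induced_subnetwork(network, keep),
    categories = categories,
    connectors = connectors
  )
}
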