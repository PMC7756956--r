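#' Construct a typed platelet interaction network
#'
#' A `cc_network` holds a node tibble and an undirected edge tibble. Nodes are
#' proteins or non-protein second messengers, with species presence
#' (`human_only` / `mouse_only` / `both`) and ortholog status
#' (`ortholog_pair` / `human_specific` / `mouse_specific`; `NA` for second
#' messengers). Edges carry species provenance, a confidence in \[0, 1\] and a
#' central-cascade membership flag, and are stored with `from <= to`.
#'
#' @param nodes Tibble with at least an `id` column; missing typed columns are
#'   filled with defaults (`protein`, presence `both`, not CC).
#' @param edges Tibble with at least `from` and `to`.
#' @param validate Check edge endpoints against the node set.
#' @return A `cc_network` object.
#' @export
cc_network <- function(nodes, edges, validate = TRUE) {
  nodes <- as_tibble(nodes)
  edges <- as_tibble(edges)
  if (!"id" %in% names(nodes)) abort("nodes need an 'id' column")
  nodes$id <- as.character(nodes$id)
  if (!"node_kind" %in% names(nodes)) nodes$node_kind <- "protein"
  if (!"species_presence" %in% names(nodes)) nodes$species_presence <- "both"
  if (!"ortholog_status" %in% names(nodes)) nodes$ortholog_status <- NA_character_
  if (!"is_cc" %in% names(nodes)) nodes$is_cc <- FALSE
  nodes <- distinct(nodes, .data$id, .keep_all = TRUE)
  if (nrow(edges) == 0) {
    edges <- tibble(from = character(), to = character(),
                    species_provenance = character(), confidence = numeric(),
                    is_cc_edge = logical())
  } else {
    if (!all(c("from", "to") %in% names(edges))) {
      abort("edges need 'from' and 'to' columns")
    }
    edges <- mutate(edges,
      from0 = pmin(as.character(.data$from), as.character(.data$to)),
      to0 = pmax(as.character(.data$from), as.character(.data$to)),
      from = .data$from0, to = .data$to0
    ) |> select(-"from0", -"to0")
    if (!"species_provenance" %in% names(edges)) edges$species_provenance <- "both"
    if (!"confidence" %in% names(edges)) edges$confidence <- 1
    if (!"is_cc_edge" %in% names(edges)) edges$is_cc_edge <- FALSE
    edges <- edges |>
      filter(.data$from != .data$to) |>
      distinct(.data$from, .data$to, .keep_all = TRUE)
  }
  if (validate) {
    missing <- setdiff(unique(c(edges$from, edges$to)), nodes$id)
    if (length(missing) > 0) {
      abort(paste0("edge endpoints not in node set: ",
                   paste(head(missing, 5), collapse = ", ")),
            class = "plateletcc_consistency_error")
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "cc_network")
}

#' @export
print.cc_network <- function(x, ...) {
  np <- sum(x$nodes$node_kind == "protein")
  nm <- sum(x$nodes$node_kind == "second_messenger")
  cat(sprintf(
    "<cc_network> %d protein nodes, %d second-messenger nodes, %d edges\n",
    np, nm, nrow(x$edges)))
  prov <- table(x$edges$species_provenance)
  if (length(prov) > 0) {
    cat("  edge provenance:",
        paste(names(prov), as.integer(prov), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Convert a `cc_network` to an igraph object
#' @param network A `cc_network`.
#' @return An undirected igraph graph with node ids as vertex names.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "cc_network"))
  igraph::graph_from_data_frame(
    d = network$edges[, c("from", "to")],
    directed = FALSE,
    vertices = network$nodes["id"]
  )
}

#' Posterior confidence of a transferred (interolog) interaction
#'
#' Naive-Bayes combination of per-feature likelihood ratios (sequence
#' similarity, sequence length, expression level, shared pathways, GO and
#' domain similarity, source quality, coevolution, interaction centrality --
#' supplied pre-computed) with a prior probability of true interaction:
#' posterior = L p / (L p + (1 - p)) with L the product of the ratios.
#' Uninformative evidence (all ratios 1) returns the prior; a single
#' impossible feature (ratio 0) annihilates the posterior.
#'
#' @param likelihood_ratios Numeric vector of nonnegative per-feature
#'   likelihood ratios, or a data frame / matrix with one row per candidate
#'   interaction and one column per feature.
#' @param prior Prior probability, strictly in (0, 1).
#' @return Posterior probability (vector if a rowwise input was given).
#' @export
interolog_posterior <- function(likelihood_ratios, prior = 0.5) {
  if (!is.numeric(prior) || prior <= 0 || prior >= 1) {
    abort("prior must be strictly between 0 and 1",
          class = "plateletcc_config_error")
  }
  if (is.data.frame(likelihood_ratios)) {
    likelihood_ratios <- as.matrix(likelihood_ratios)
  }
  if (is.matrix(likelihood_ratios)) {
    if (any(likelihood_ratios < 0)) {
      abort("likelihood ratios must be nonnegative",
            class = "plateletcc_value_error")
    }
    L <- apply(likelihood_ratios, 1, prod)
  } else {
    if (any(likelihood_ratios < 0)) {
      abort("likelihood ratios must be nonnegative",
            class = "plateletcc_value_error")
    }
    L <- prod(likelihood_ratios)
  }
  (L * prior) / (L * prior + (1 - prior))
}

#' Retain high-confidence interactions
#'
#' Keeps edges whose posterior confidence is strictly greater than the
#' threshold (near-certain interactions at the default 0.99).
#'
#' @param edges Interaction tibble with a `confidence` column.
#' @param threshold Strict lower cut; default 0.99.
#' @return The filtered tibble.
#' @export
high_confidence_filter <- function(edges, threshold = 0.99) {
  filter(as_tibble(edges), .data$confidence > threshold)
}

# Map species-level symbols to combined-network identifiers: ortholog pairs
# collapse onto the human symbol; species-specific mouse genes are prefixed to
# avoid collisions; second messengers keep their shared identifiers.
map_to_combined <- function(symbols, orthologs, species,
                            messengers = second_messenger_nodes()$id) {
  symbols <- clean_symbols(symbols)
  if (species == "human") return(symbols)
  lk <- ortholog_lookup(orthologs, symbols, from = "mouse")
  ifelse(symbols %in% messengers, symbols,
         ifelse(lk$status == "ortholog", lk$ortholog,
                paste0("MOUSE:", symbols)))
}

#' Build the combined human-mouse network
#'
#' Homologous proteins are identified through the ortholog map and collapse to
#' a single combined node (named by the human symbol); species-specific
#' proteins enter as distinct nodes flagged `human_specific` /
#' `mouse_specific` (mouse-specific ids are prefixed `MOUSE:`). An interaction
#' supported between the same combined endpoints in both species' inputs gets
#' provenance `both`. Central-cascade edges are flagged; CC edges absent from
#' the interaction inputs are added (the cascade model itself is curated
#' knowledge, not database PPI).
#'
#' @param human_edges,mouse_edges Interaction tibbles (`a`, `b`, `confidence`).
#' @param orthologs An `ortholog_map`.
#' @param second_messengers Tibble of non-protein nodes (default the eight
#'   platelet second messengers).
#' @param cc_nodes Character vector of central-cascade member ids (combined
#'   namespace), or NULL.
#' @param cc_edges Tibble with columns `a`, `b` of CC edges (combined
#'   namespace), or NULL.
#' @return A `cc_network`.
#' @export
build_combined_network <- function(human_edges, mouse_edges, orthologs,
                                   second_messengers = second_messenger_nodes(),
                                   cc_nodes = NULL, cc_edges = NULL) {
  msg_ids <- clean_symbols(second_messengers$id)
  prep <- function(edges, species) {
    edges <- as_tibble(edges)
    if (nrow(edges) == 0) {
      return(tibble(from = character(), to = character(),
                    confidence = numeric(), .key = character()))
    }
    tibble(
      from = map_to_combined(edges$a, orthologs, species, msg_ids),
      to = map_to_combined(edges$b, orthologs, species, msg_ids),
      confidence = if ("confidence" %in% names(edges)) edges$confidence else 1
    ) |>
      filter(.data$from != .data$to) |>
      mutate(.key = edge_key(.data$from, .data$to)) |>
      group_by(.data$.key) |>
      slice_max(.data$confidence, n = 1, with_ties = FALSE) |>
      ungroup()
  }
  h <- prep(human_edges, "human")
  m <- prep(mouse_edges, "mouse")
  all_keys <- union(h$.key, m$.key)
  edges <- tibble(.key = all_keys) |>
    left_join(h |> select(".key", hfrom = "from", hto = "to", hconf = "confidence"),
              by = ".key") |>
    left_join(m |> select(".key", mfrom = "from", mto = "to", mconf = "confidence"),
              by = ".key") |>
    mutate(
      from = coalesce(.data$hfrom, .data$mfrom),
      to = coalesce(.data$hto, .data$mto),
      species_provenance = case_when(
        !is.na(.data$hfrom) & !is.na(.data$mfrom) ~ "both",
        !is.na(.data$hfrom) ~ "human",
        TRUE ~ "mouse"
      ),
      confidence = pmax(.data$hconf %na% 0, .data$mconf %na% 0),
      is_cc_edge = FALSE
    ) |>
    select("from", "to", "species_provenance", "confidence", "is_cc_edge")

  h_ids <- unique(c(h$from, h$to))
  m_ids <- unique(c(m$from, m$to))
  ids <- union(union(h_ids, m_ids), msg_ids)
  if (!is.null(cc_nodes)) ids <- union(ids, clean_symbols(cc_nodes))
  orth_humans <- unique(orthologs$human_symbol)
  nodes <- tibble(id = sort(ids)) |>
    mutate(
      node_kind = ifelse(.data$id %in% msg_ids, "second_messenger", "protein"),
      species_presence = case_when(
        .data$node_kind == "second_messenger" ~ "both",
        .data$id %in% h_ids & .data$id %in% m_ids ~ "both",
        .data$id %in% h_ids ~ "human_only",
        .data$id %in% m_ids ~ "mouse_only",
        TRUE ~ "both"
      ),
      ortholog_status = case_when(
        .data$node_kind == "second_messenger" ~ NA_character_,
        startsWith(.data$id, "MOUSE:") ~ "mouse_specific",
        .data$id %in% orth_humans ~ "ortholog_pair",
        TRUE ~ "human_specific"
      ),
      is_cc = FALSE
    )
  if (!is.null(cc_nodes)) {
    nodes$is_cc <- nodes$id %in% clean_symbols(cc_nodes)
  }
  net <- cc_network(nodes, edges)
  if (!is.null(cc_edges) && nrow(as_tibble(cc_edges)) > 0) {
    cc_edges <- as_tibble(cc_edges) |>
      mutate(a = clean_symbols(.data$a), b = clean_symbols(.data$b))
    unknown <- setdiff(unique(c(cc_edges$a, cc_edges$b)), net$nodes$id)
    if (length(unknown) > 0) {
      abort(paste0("central-cascade edge references unknown node(s): ",
                   paste(head(unknown, 5), collapse = ", ")),
            class = "plateletcc_consistency_error")
    }
    cc_keys <- edge_key(cc_edges$a, cc_edges$b)
    net_keys <- edge_key(net$edges$from, net$edges$to)
    net$edges$is_cc_edge <- net_keys %in% cc_keys
    new <- cc_edges[!cc_keys %in% net_keys, , drop = FALSE]
    if (nrow(new) > 0) {
      net$edges <- bind_rows(net$edges, tibble(
        from = pmin(new$a, new$b), to = pmax(new$a, new$b),
        species_provenance = "both", confidence = 1, is_cc_edge = TRUE
      ))
    }
  }
  net
}

#' Derive one species' network from the combined network
#'
#' Keeps nodes present in that species (presence `species_only` or `both`) and
#' edges with provenance in that species or both. The union of the two derived
#' edge sets recovers the combined edge set.
#'
#' @param combined A combined `cc_network`.
#' @param species `"human"` or `"mouse"`.
#' @return A `cc_network`.
#' @export
derive_species_network <- function(combined, species = c("human", "mouse")) {
  species <- match.arg(species)
  only <- paste0(species, "_only")
  nodes <- filter(combined$nodes,
                  .data$species_presence %in% c(only, "both"))
  edges <- filter(combined$edges,
                  .data$species_provenance %in% c(species, "both"),
                  .data$from %in% nodes$id, .data$to %in% nodes$id)
  structure(list(nodes = nodes, edges = edges, species = species),
            class = "cc_network")
}

#' Basic network statistics
#'
#' Computed over the protein-induced subgraph: node and edge counts, mean
#' degree (2E/N), and nearest-rank degree percentiles. Second-messenger nodes
#' are counted separately. Empty networks report zeros.
#'
#' @param network A `cc_network`.
#' @param percentiles Percentile points to report (default 10/25/50/75/90).
#' @return A one-row tibble; degree percentiles appear as `degree_p<q>`
#'   columns.
#' @export
network_stats <- function(network, percentiles = c(10, 25, 50, 75, 90)) {
  deg <- protein_degrees(network)
  n_prot <- length(deg$degree)
  n_edges <- deg$n_edges
  out <- tibble(
    n_nodes = n_prot,
    n_messengers = sum(network$nodes$node_kind == "second_messenger"),
    n_edges = n_edges,
    mean_degree = if (n_prot > 0) 2 * n_edges / n_prot else 0
  )
  for (p in percentiles) {
    out[[paste0("degree_p", p)]] <-
      if (n_prot > 0) nearest_rank_percentile(deg$degree, p) else 0
  }
  out
}

# Degrees of protein nodes within the protein-induced subgraph.
protein_degrees <- function(network) {
  prot <- network$nodes$id[network$nodes$node_kind == "protein"]
  e <- filter(network$edges, .data$from %in% prot, .data$to %in% prot)
  deg <- setNames(rep(0L, length(prot)), prot)
  if (nrow(e) > 0) {
    tab <- table(c(e$from, e$to))
    deg[names(tab)] <- as.integer(tab)
  }
  list(degree = deg, n_edges = nrow(e))
}

#' Exclude high-binder hub proteins
#'
#' Removes protein nodes whose degree strictly exceeds the nearest-rank
#' percentile (default 90th) of the protein-degree distribution, then drops
#' their incident edges; orphaned nodes remain. Second-messenger nodes and
#' central-cascade members are never removed.
#'
#' @param network A `cc_network`.
#' @param percentile Percentile cut in (0, 100); default 90.
#' @return The pruned `cc_network`.
#' @export
exclude_high_binders <- function(network, percentile = 90) {
  stopifnot(percentile > 0, percentile < 100)
  deg <- protein_degrees(network)
  if (length(deg$degree) == 0) return(network)
  cut <- nearest_rank_percentile(deg$degree, percentile)
  hubs <- names(deg$degree)[deg$degree > cut]
  exempt <- network$nodes$id[network$nodes$is_cc |
                               network$nodes$node_kind == "second_messenger"]
  hubs <- setdiff(hubs, exempt)
  nodes <- filter(network$nodes, !.data$id %in% hubs)
  edges <- filter(network$edges,
                  !.data$from %in% hubs, !.data$to %in% hubs)
  structure(list(nodes = nodes, edges = edges), class = "cc_network")
}
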