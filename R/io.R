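#' Coerce a data frame into a validated expression dataset
#'
#' Applies the package's ingest conventions to a `symbol`/`rpkm` table: symbols
#' are whitespace-stripped and uppercased (mouse symbols share combined
#' identifiers with their human orthologs this way), blank symbols are
#' rejected, negative abundances are an error, and duplicate symbols collapse
#' to their maximum value -- consistent with the species-maximum rule applied
#' to proteome evidence downstream.
#'
#' @param data A data frame with at least the symbol and value columns.
#' @param species `"human"` or `"mouse"`.
#' @param symbol_col,value_col Column names; defaults `"symbol"` and `"rpkm"`.
#' @param dataset_id Optional identifier recorded as an attribute.
#' @param quiet Suppress the ingest log message.
#'
#' @return A tibble with columns `symbol`, `rpkm`, classed
#'   `expression_dataset`, carrying `species` and `counts` attributes. The
#'   `counts` attribute satisfies
#'   `records_read == records_kept + records_rejected + records_collapsed`.
#' @export
as_expression_dataset <- function(data, species = c("human", "mouse"),
                                  symbol_col = "symbol", value_col = "rpkm",
                                  dataset_id = NULL, quiet = TRUE) {
  species <- match.arg(species)
  tbl <- ingest_symbol_value(data, symbol_col, value_col, out_value = "rpkm")
  out <- structure(
    tbl$data,
    species = species,
    dataset_id = dataset_id %||% paste0("rna_", species),
    counts = tbl$counts,
    class = c("expression_dataset", class(tbl$data))
  )
  if (!quiet) {
    inform(sprintf(
      "expression [%s]: read %d, kept %d, rejected %d, collapsed %d",
      species, tbl$counts$records_read, tbl$counts$records_kept,
      tbl$counts$records_rejected, tbl$counts$records_collapsed
    ))
  }
  out
}

#' Coerce a data frame into a validated proteome dataset
#'
#' Same ingest rules as [as_expression_dataset()]. The measurement kind is one
#' of the four semi-quantitative measures used across published platelet
#' proteome studies: peptide spectrum counts, protein copy numbers, ion
#' abundance or ion intensity.
#'
#' @inheritParams as_expression_dataset
#' @param measure One of `"PSM"`, `"copy_number"`, `"ion_abundance"`,
#'   `"ion_intensity"`.
#' @return A tibble with columns `symbol`, `abundance`, classed
#'   `proteome_dataset`, with `species`, `dataset_id`, `measure` and `counts`
#'   attributes.
#' @export
as_proteome_dataset <- function(data, species = c("human", "mouse"),
                                dataset_id, measure = "PSM",
                                symbol_col = "symbol",
                                value_col = "abundance", quiet = TRUE) {
  species <- match.arg(species)
  measure <- match.arg(measure, proteome_measures())
  tbl <- ingest_symbol_value(data, symbol_col, value_col, out_value = "abundance")
  structure(
    tbl$data,
    species = species,
    dataset_id = dataset_id,
    measure = measure,
    counts = tbl$counts,
    class = c("proteome_dataset", class(tbl$data))
  )
}

#' The four semi-quantitative proteome measurement kinds
#' @return Character vector of length 4.
#' @export
proteome_measures <- function() {
  c("PSM", "copy_number", "ion_abundance", "ion_intensity")
}

# Shared ingest: validate, uppercase, reject blanks, collapse duplicates by max.
ingest_symbol_value <- function(data, symbol_col, value_col, out_value) {
  data <- as_tibble(data)
  for (col in c(symbol_col, value_col)) {
    if (!col %in% names(data)) {
      abort(sprintf("required column '%s' is missing", col),
            class = "plateletcc_format_error")
    }
  }
  sym <- clean_symbols(data[[symbol_col]])
  val <- as.numeric(data[[value_col]])
  bad <- which(!is.na(val) & val < 0)
  if (length(bad) > 0) {
    abort(sprintf("negative %s at row%s %s", out_value,
                  if (length(bad) > 1) "s" else "",
                  paste(bad, collapse = ", ")),
          class = "plateletcc_value_error")
  }
  keep <- !is.na(sym) & sym != "" & !is.na(val)
  n_read <- nrow(data)
  n_rejected <- sum(!keep)
  tbl <- tibble(symbol = sym[keep], value = val[keep]) |>
    group_by(.data$symbol) |>
    summarise(value = max(.data$value), .groups = "drop") |>
    arrange(.data$symbol)
  names(tbl)[2] <- out_value
  n_kept <- nrow(tbl)
  list(
    data = tbl,
    counts = list(
      records_read = n_read,
      records_kept = n_kept,
      records_rejected = n_rejected,
      records_collapsed = n_read - n_rejected - n_kept
    )
  )
}

#' Read a tab-separated gene expression table
#'
#' @param path Path to a TSV file with a header naming a symbol column and an
#'   RPKM column.
#' @inheritParams as_expression_dataset
#' @return An `expression_dataset` tibble; see [as_expression_dataset()].
#' @export
read_expression_table <- function(path, species = c("human", "mouse"),
                                  symbol_col = "symbol", value_col = "rpkm",
                                  quiet = FALSE) {
  data <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  as_expression_dataset(data, species, symbol_col, value_col,
                        dataset_id = basename(path), quiet = quiet)
}

#' Read a tab-separated proteome abundance table
#'
#' @inheritParams read_expression_table
#' @inheritParams as_proteome_dataset
#' @export
read_proteome_table <- function(path, species = c("human", "mouse"),
                                dataset_id = basename(path), measure = "PSM",
                                symbol_col = "symbol",
                                value_col = "abundance", quiet = FALSE) {
  data <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (missing(measure) && "measure" %in% names(data)) {
    measure <- unique(data$measure)[1]
  }
  as_proteome_dataset(data, species, dataset_id, measure,
                      symbol_col, value_col, quiet = quiet)
}

#' Build an ortholog map from a data frame
#'
#' An Inparanoid-style table of human/mouse gene symbol pairs with a group id
#' and an inparalog score in \[0, 1\]. Symbols are uppercased so that an
#' ortholog pair shares one combined identifier.
#'
#' @param data Data frame with columns `human_symbol`, `mouse_symbol`,
#'   `group_id`, `inparalog_score` (a `score` column is accepted too).
#' @return A tibble classed `ortholog_map`.
#' @export
as_ortholog_map <- function(data) {
  data <- as_tibble(data)
  if ("score" %in% names(data) && !"inparalog_score" %in% names(data)) {
    data <- rename(data, inparalog_score = "score")
  }
  need <- c("human_symbol", "mouse_symbol", "group_id", "inparalog_score")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(sprintf("required column '%s' is missing", miss[1]),
          class = "plateletcc_format_error")
  }
  out <- data |>
    mutate(
      human_symbol = clean_symbols(.data$human_symbol),
      mouse_symbol = clean_symbols(.data$mouse_symbol),
      group_id = as.integer(.data$group_id),
      inparalog_score = as.numeric(.data$inparalog_score)
    ) |>
    select(all_of(need)) |>
    distinct()
  key <- paste(out$human_symbol, out$mouse_symbol)
  if (anyDuplicated(key)) {
    abort("duplicate conflicting ortholog pair(s) in table",
          class = "plateletcc_format_error")
  }
  structure(out, class = c("ortholog_map", class(out)))
}

#' Read an Inparanoid-style ortholog pair table
#' @param path TSV path with columns `human_symbol`, `mouse_symbol`,
#'   `group_id`, `score`.
#' @return An `ortholog_map` tibble.
#' @export
read_ortholog_table <- function(path) {
  as_ortholog_map(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
}

#' Look up orthologs of a set of gene symbols
#'
#' Genes absent from the map are reported with status `"non_ortholog"` --
#' species-specific genes such as human BDNF. Where a symbol participates in
#' several pairs (inparalogs), the partner with the highest inparalog score is
#' returned.
#'
#' @param orthologs An `ortholog_map`.
#' @param symbols Character vector of gene symbols (any case).
#' @param from `"human"` or `"mouse"`: the species the query symbols belong to.
#' @return A tibble with columns `symbol`, `ortholog` (NA if none), `group_id`,
#'   `status` (`"ortholog"` / `"non_ortholog"`).
#' @export
ortholog_lookup <- function(orthologs, symbols, from = c("human", "mouse")) {
  from <- match.arg(from)
  symbols <- clean_symbols(symbols)
  own <- if (from == "human") "human_symbol" else "mouse_symbol"
  other <- if (from == "human") "mouse_symbol" else "human_symbol"
  best <- as_tibble(orthologs) |>
    group_by(.data[[own]]) |>
    slice_max(.data$inparalog_score, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select(symbol = all_of(own), ortholog = all_of(other), "group_id")
  tibble(symbol = symbols) |>
    left_join(best, by = "symbol") |>
    mutate(status = ifelse(is.na(.data$ortholog), "non_ortholog", "ortholog"))
}

#' Read a protein-protein interaction table
#'
#' Simple TSV dialect: columns `a`, `b`, optional `species`, `confidence`,
#' `source_quality`. Self-loops are rejected (counted, not fatal); duplicate
#' unordered pairs within a species collapse to their maximum confidence.
#'
#' @param path TSV path.
#' @param species Default species tag when the file has no `species` column.
#' @return A tibble of interaction records with a `counts` attribute.
#' @export
read_interaction_table <- function(path, species = "human") {
  data <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  as_interaction_table(data, species)
}

#' @rdname read_interaction_table
#' @param data A data frame with at least columns `a` and `b`.
#' @export
as_interaction_table <- function(data, species = "human") {
  data <- as_tibble(data)
  for (col in c("a", "b")) {
    if (!col %in% names(data)) {
      abort(sprintf("required column '%s' is missing", col),
            class = "plateletcc_format_error")
    }
  }
  out <- data |>
    mutate(
      a = clean_symbols(.data$a),
      b = clean_symbols(.data$b),
      species = if ("species" %in% names(data)) as.character(.data$species) else species,
      confidence = if ("confidence" %in% names(data)) as.numeric(.data$confidence) else 1,
      source_quality = if ("source_quality" %in% names(data)) as.numeric(.data$source_quality) else 1
    )
  n_read <- nrow(out)
  out <- filter(out, .data$a != .data$b)
  n_self <- n_read - nrow(out)
  out <- out |>
    mutate(.key = edge_key(.data$a, .data$b)) |>
    group_by(.data$species, .data$.key) |>
    slice_max(.data$confidence, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select(-".key") |>
    mutate(a0 = pmin(.data$a, .data$b), b0 = pmax(.data$a, .data$b),
           a = .data$a0, b = .data$b0) |>
    select(-"a0", -"b0") |>
    arrange(.data$a, .data$b)
  structure(out, counts = list(
    records_read = n_read,
    records_kept = nrow(out),
    records_rejected = n_self,
    records_collapsed = n_read - n_self - nrow(out)
  ))
}

#' Read a central-cascade seed list
#'
#' One node identifier per line (or a single `node` column). May contain
#' non-protein second-messenger identifiers such as ADP and ATP.
#'
#' @param path Path to the list.
#' @return Uppercased character vector of node identifiers.
#' @export
read_seed_list <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- stringr::str_trim(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (length(lines) > 0 && identical(tolower(lines[1]), "node")) {
    lines <- lines[-1]
  }
  unique(clean_symbols(lines))
}

#' Export a network with node and edge attributes to GraphML
#'
#' Node attributes carry the Cytoscape-style visual encoding (fill category,
#' border category, size value, shape); edge attributes carry species
#' provenance, central-cascade membership and confidence. Re-reading the file
#' with [read_network_graphml()] reproduces the attributed graph.
#'
#' @param network A `cc_network` (see [cc_network()]).
#' @param path Output file path.
#' @param attributes Optional node-attribute tibble (from
#'   [assign_attributes()]); every row must reference a network node.
#' @return The path, invisibly.
#' @export
write_network_graphml <- function(network, path, attributes = NULL) {
  stopifnot(inherits(network, "cc_network"))
  nodes <- network$nodes
  if (!is.null(attributes)) {
    unknown <- setdiff(attributes$id, nodes$id)
    if (length(unknown) > 0) {
      abort(paste0("attribute rows reference unknown node(s): ",
                   paste(head(unknown, 5), collapse = ", ")),
            class = "plateletcc_consistency_error")
    }
    nodes <- left_join(nodes, attributes, by = "id")
  }
  g <- as_igraph(network)
  for (col in setdiff(names(nodes), "id")) {
    v <- nodes[[col]][match(igraph::V(g)$name, nodes$id)]
    if (is.logical(v)) v <- as.integer(v)
    if (is.factor(v)) v <- as.character(v)
    g <- igraph::set_vertex_attr(g, col, value = v)
  }
  # graph_from_data_frame preserves the edge order of the edge tibble
  for (col in setdiff(names(network$edges), c("from", "to"))) {
    v <- network$edges[[col]]
    if (is.logical(v)) v <- as.integer(v)
    g <- igraph::set_edge_attr(g, col, value = v)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML network written by [write_network_graphml()]
#' @param path GraphML file path.
#' @return A `cc_network` with any extra node attributes as node columns.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  va <- igraph::vertex_attr(g)
  ids <- va$name %||% character(0)
  nodes <- tibble(id = as.character(ids))
  for (col in setdiff(names(va), c("name", "id"))) {
    nodes[[col]] <- va[[col]]
  }
  for (col in c("is_cc")) {
    if (col %in% names(nodes)) nodes[[col]] <- as.logical(nodes[[col]])
  }
  el <- igraph::as_edgelist(g)
  ea <- igraph::edge_attr(g)
  edges <- tibble(
    from = pmin(el[, 1], el[, 2]),
    to = pmax(el[, 1], el[, 2])
  )
  for (col in names(ea)) edges[[col]] <- ea[[col]]
  if ("is_cc_edge" %in% names(edges)) {
    edges$is_cc_edge <- as.logical(edges$is_cc_edge)
  }
  cc_network(nodes, edges, validate = FALSE)
}

#' Export a network in SIF format
#'
#' Lines of `a<TAB>type<TAB>b`, with the interaction type taken from the edge's
#' species provenance (`cc` for central-cascade edges).
#'
#' @inheritParams write_network_graphml
#' @export
write_network_sif <- function(network, path) {
  stopifnot(inherits(network, "cc_network"))
  e <- network$edges
  type <- ifelse(isTRUE_vec(e$is_cc_edge), "cc", e$species_provenance)
  readr::write_lines(paste(e$from, type, e$to, sep = "\t"), path)
  # isolated nodes: single-column lines keep them in the file
  iso <- setdiff(network$nodes$id, c(e$from, e$to))
  if (length(iso) > 0) readr::write_lines(iso, path, append = TRUE)
  invisible(path)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Write and read node-attribute tables as TSV
#' @param attributes A node-attribute tibble.
#' @param path TSV path.
#' @export
write_node_attributes <- function(attributes, path) {
  readr::write_tsv(attributes, path)
  invisible(path)
}

#' @rdname write_node_attributes
#' @export
read_node_attributes <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Retrieve the ingest bookkeeping of a reader result
#' @param x An object returned by one of the readers/constructors.
#' @return A list with `records_read`, `records_kept`, `records_rejected`,
#'   `records_collapsed`.
#' @export
record_counts <- function(x) attr(x, "counts")
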