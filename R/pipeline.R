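#' Configuration for an end-to-end pipeline run
#'
#' Collects all stage parameters: either a [simulation_config()] (synthetic
#' inputs) or an `input_dir` holding the TSV bundle written by
#' [write_bundle()], the detection and difference-filter thresholds, the
#' concordance delta scale and RNA-difference screen, the interolog
#' confidence threshold, the high-binder percentile and the neighbour-degree
#' cut.
#'
#' @param out_dir Output directory for all artifacts.
#' @param simulation A [simulation_config()] used when `input_dir` is NULL.
#' @param input_dir Optional directory of on-disk inputs.
#' @param detection A [detection_thresholds()] object.
#' @param filters A [filter_thresholds()] object.
#' @param concordance_scale Delta-similarity scale (log2 units); default 2.
#' @param rna_diff_min RNA log2-difference screen; default 1.
#' @param confidence_threshold Strict interolog posterior cut; default 0.99.
#' @param high_binder_percentile Degree percentile above which hubs are
#'   excluded; default 90.
#' @param max_degree Neighbour-degree cut around the central cascade;
#'   default 3.
#' @param seed Overrides the simulation seed when not NULL.
#' @return A list classed `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            simulation = simulation_config(),
                            input_dir = NULL,
                            detection = detection_thresholds(),
                            filters = filter_thresholds(),
                            concordance_scale = 2,
                            rna_diff_min = 1,
                            confidence_threshold = 0.99,
                            high_binder_percentile = 90,
                            max_degree = 3,
                            seed = NULL) {
  if (!is.null(seed)) simulation$seed <- as.integer(seed)
  structure(
    list(out_dir = out_dir, simulation = simulation, input_dir = input_dir,
         detection = detection, filters = filters,
         concordance_scale = concordance_scale, rna_diff_min = rna_diff_min,
         confidence_threshold = confidence_threshold,
         high_binder_percentile = high_binder_percentile,
         max_degree = max_degree),
    class = "pipeline_config"
  )
}

#' Read a bundle of pipeline inputs from disk
#'
#' Expects the file layout written by [write_bundle()]; any missing required
#' file is a startup error naming the path.
#'
#' @param dir Input directory.
#' @return A `cc_bundle` (without ground truth unless `truth_genes.tsv` is
#'   present).
#' @export
read_bundle <- function(dir) {
  need <- c("expression_human.tsv", "expression_mouse.tsv", "orthologs.tsv",
            "interactions_human.tsv", "interactions_mouse.tsv", "cc_seeds.txt",
            "cc_edges.tsv")
  paths <- file.path(dir, need)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0("missing input file(s): ", paste(missing, collapse = ", ")),
          class = "plateletcc_config_error")
  }
  prot_files <- list.files(dir, pattern = "^proteome_.*\\.tsv$",
                           full.names = TRUE)
  proteomes <- lapply(prot_files, function(p) {
    sp <- if (grepl("mouse", basename(p))) "mouse" else "human"
    read_proteome_table(p, species = sp, quiet = TRUE)
  })
  names(proteomes) <- vapply(proteomes, attr, character(1), "dataset_id")
  truth <- NULL
  if (file.exists(file.path(dir, "truth_genes.tsv"))) {
    truth <- list(genes = readr::read_tsv(file.path(dir, "truth_genes.tsv"),
                                          show_col_types = FALSE))
  }
  structure(
    list(
      expression = list(
        human = readr::read_tsv(paths[1], show_col_types = FALSE),
        mouse = readr::read_tsv(paths[2], show_col_types = FALSE)
      ),
      proteomes = proteomes,
      orthologs = read_ortholog_table(paths[3]),
      interactions = list(human = read_interaction_table(paths[4], "human"),
                          mouse = read_interaction_table(paths[5], "mouse")),
      second_messengers = second_messenger_nodes(),
      cc_seeds = read_seed_list(paths[6]),
      cc_edges = readr::read_tsv(paths[7], show_col_types = FALSE),
      truth = truth, config = NULL
    ),
    class = "cc_bundle"
  )
}

run_stage <- function(name, expr, quiet) {
  if (!quiet) inform(paste0("[", name, "] ..."))
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
          class = "plateletcc_stage_error")
  })
}

#' Run the full cross-species comparison pipeline
#'
#' Sequences the stages: simulate (or load) inputs, median-log2 normalise RNA
#' and proteome tables, filter interactions at the confidence threshold and
#' build the combined ortholog-aware network, annotate neighbour degrees
#' around the central cascade, assemble gene evidence and score concordance
#' over the mRNA differences, extract the degree-limited subnetwork, exclude
#' high binders, apply the clear-difference filter and export attributed
#' networks. Every output is reproducible from the configuration and seed; a
#' manifest records the package version, configuration hash and seed.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage log messages.
#' @return Invisibly, a list with the in-memory results (`bundle`,
#'   `evidence`, `records`, `summary`, `combined`, `annotations`,
#'   `filtered`, `attributes`, `files`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  bundle <- run_stage("inputs", {
    if (is.null(config$input_dir)) generate_bundle(config$simulation)
    else read_bundle(config$input_dir)
  }, quiet)

  norm <- run_stage("normalize", {
    rna_h <- median_log2_normalize(
      as_expression_dataset(bundle$expression$human, "human"))
    rna_m <- median_log2_normalize(
      as_expression_dataset(bundle$expression$mouse, "mouse"))
    prot <- lapply(bundle$proteomes, median_log2_normalize)
    sp <- vapply(bundle$proteomes, attr, character(1), "species")
    list(rna_h = rna_h, rna_m = rna_m,
         prot_h = prot[sp == "human"], prot_m = prot[sp == "mouse"])
  }, quiet)

  combined <- run_stage("build-network", {
    hi_h <- high_confidence_filter(bundle$interactions$human,
                                   config$confidence_threshold)
    hi_m <- high_confidence_filter(bundle$interactions$mouse,
                                   config$confidence_threshold)
    build_combined_network(hi_h, hi_m, bundle$orthologs,
                           bundle$second_messengers,
                           cc_nodes = bundle$cc_seeds,
                           cc_edges = bundle$cc_edges)
  }, quiet)

  annotations <- run_stage("annotate", {
    annotate_cc_degrees(combined, bundle$cc_seeds, config$max_degree)
  }, quiet)

  evidence <- run_stage("evidence", {
    build_gene_evidence(norm$rna_h, norm$rna_m, norm$prot_h, norm$prot_m,
                        bundle$orthologs)
  }, quiet)

  records <- run_stage("score", {
    score_concordance(select_rna_differences(evidence, config$rna_diff_min),
                      config$concordance_scale)
  }, quiet)
  summary <- summarize_concordance(records)

  expr_combined <- run_stage("expression-map", {
    h <- as_expression_dataset(bundle$expression$human, "human")
    m <- as_expression_dataset(bundle$expression$mouse, "mouse")
    full_join(
      tibble(id = h$symbol, human_rpkm = h$rpkm),
      tibble(id = map_to_combined(m$symbol, bundle$orthologs, "mouse"),
             mouse_rpkm = m$rpkm) |>
        group_by(.data$id) |>
        summarise(mouse_rpkm = max(.data$mouse_rpkm), .groups = "drop"),
      by = "id"
    )
  }, quiet)

  filtered <- run_stage("filter", {
    sub <- extract_cc_subnetwork(combined, annotations, config$max_degree)
    sub <- exclude_high_binders(sub, config$high_binder_percentile)
    filter_difference_network(sub, expr_combined, config$filters)
  }, quiet)

  attributes <- run_stage("attributes", {
    assign_attributes(filtered$network, expr_combined, records,
                      config$filters)
  }, quiet)

  files <- run_stage("export", {
    f <- list(
      rna_human = file.path(out_dir, "normalized_rna_human.tsv"),
      rna_mouse = file.path(out_dir, "normalized_rna_mouse.tsv"),
      concordance = file.path(out_dir, "concordance.tsv"),
      summary = file.path(out_dir, "concordance_summary.json"),
      combined_graphml = file.path(out_dir, "combined_network.graphml"),
      filtered_graphml = file.path(out_dir, "filtered_network.graphml"),
      filtered_sif = file.path(out_dir, "filtered_network.sif"),
      attributes = file.path(out_dir, "node_attributes.tsv"),
      annotations = file.path(out_dir, "cc_degree_annotations.tsv"),
      manifest = file.path(out_dir, "manifest.json")
    )
    write_normalized_table(norm$rna_h, f$rna_human)
    write_normalized_table(norm$rna_m, f$rna_mouse)
    write_concordance_table(records, f$concordance)
    jsonlite::write_json(as.list(as_tibble(summary)), f$summary,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_network_graphml(combined, f$combined_graphml)
    write_network_graphml(filtered$network, f$filtered_graphml,
                          attributes = attributes$nodes)
    write_network_sif(filtered$network, f$filtered_sif)
    write_node_attributes(attributes$nodes, f$attributes)
    readr::write_tsv(annotations, f$annotations)
    jsonlite::write_json(list(
      package_version = as.character(utils::packageVersion("plateletcc")),
      config_hash = rlang::hash(config[setdiff(names(config),
                                               c("out_dir", "input_dir"))]),
      seed = bundle$config$seed %||% NA,
      n_genes_scored = nrow(records),
      n_combined_nodes = nrow(combined$nodes),
      n_combined_edges = nrow(combined$edges),
      n_filtered_nodes = nrow(filtered$network$nodes),
      n_filtered_edges = nrow(filtered$network$edges)
    ), f$manifest, auto_unbox = TRUE, pretty = TRUE)
    f
  }, quiet)

  if (!quiet) {
    inform(sprintf(
      "[done] scored %d genes (matched %.1f%%, compatible %.1f%%, opposite %.1f%%, unclear %.1f%%)",
      summary$n, summary$pct_matched, summary$pct_compatible,
      summary$pct_opposite, summary$pct_unclear))
  }
  invisible(list(bundle = bundle, norm = norm, combined = combined,
                 annotations = annotations, evidence = evidence,
                 records = records, summary = summary,
                 expression = expr_combined, filtered = filtered,
                 attributes = attributes, files = files))
}

#' Read or write a pipeline configuration as YAML
#' @param path YAML file path.
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  to_plain <- function(x) {
    if (is.list(x)) lapply(unclass(x), to_plain)
    else if (length(x) > 1) as.list(x) else x
  }
  yaml::write_yaml(to_plain(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- y$simulation
  pipeline_config(
    out_dir = y$out_dir,
    simulation = simulation_config(
      n_genes = sim$n_genes,
      ortholog_fraction = sim$ortholog_fraction,
      n_proteome_datasets = unlist(sim$n_proteome_datasets),
      planted_class_proportions = unlist(sim$planted_class_proportions),
      rpkm_log_mean = sim$rpkm_log_mean, rpkm_log_sd = sim$rpkm_log_sd,
      effect_size_log2 = sim$effect_size_log2,
      proteome_noise_sd = sim$proteome_noise_sd,
      proteome_dropout_rate = sim$proteome_dropout_rate,
      edges_per_node = sim$edges_per_node,
      conserved_edge_fraction = sim$conserved_edge_fraction,
      cc_size = sim$cc_size, seed = sim$seed
    ),
    input_dir = y$input_dir,
    detection = do.call(detection_thresholds, unclass(y$detection)),
    filters = do.call(filter_thresholds, unclass(y$filters)),
    concordance_scale = y$concordance_scale,
    rna_diff_min = y$rna_diff_min,
    confidence_threshold = y$confidence_threshold,
    high_binder_percentile = y$high_binder_percentile,
    max_degree = y$max_degree
  )
}
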