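#' The eight non-protein second-messenger nodes
#'
#' Cytosolic calcium, ATP, ADP, cyclic AMP, diacylglycerol, inositol
#' trisphosphate, arachidonic acid and thromboxane A2: included in network
#' topology as input nodes of the cascade, but never scored for expression.
#'
#' @return A tibble with columns `id`, `full_name`, `node_kind`
#'   (`"second_messenger"` throughout), 8 rows.
#' @export
second_messenger_nodes <- function() {
  tibble(
    id = c("CAC", "ATP", "ADP", "CAMP", "DAG", "IP3", "ARAC", "TXA2"),
    full_name = c("cytosolic calcium", "adenosine triphosphate",
                  "adenosine diphosphate", "cyclic AMP", "diacylglycerol",
                  "inositol trisphosphate", "arachidonic acid",
                  "thromboxane A2"),
    node_kind = "second_messenger"
  )
}

#' The planted cross-species difference classes
#'
#' Labels the generator can assign to an ortholog gene: no difference,
#' matched shifts (concordant RNA and protein, higher in one species),
#' opposite (discordant RNA vs protein), unique expression in one species,
#' compatible (same direction, much weaker protein effect) and unclear
#' (RNA difference without protein evidence).
#'
#' @return Character vector of the eight class labels.
#' @export
planted_classes <- function() {
  c("no_difference", "matched_higher_human", "matched_higher_mouse",
    "opposite", "unique_human", "unique_mouse", "compatible", "unclear")
}

#' Configuration for the two-species synthetic bundle generator
#'
#' Defaults emulate the study conditions of the platelet comparison:
#' ~1800 genes in the combined analysis universe, 62% orthologous, the
#' non-ortholog remainder split 621:58 human:mouse, seven human and four
#' mouse proteome studies with scales differing by orders of magnitude,
#' lognormal RPKM (median about 4.5), roughly five interactors per protein
#' and 40% of interactions conserved across species.
#'
#' @param n_genes Total number of genes.
#' @param ortholog_fraction Fraction of genes with a human-mouse ortholog
#'   pair.
#' @param n_proteome_datasets Integer vector `(human, mouse)` (a scalar is
#'   recycled); default `c(7, 4)`.
#' @param planted_class_proportions Named proportions over the planted
#'   difference classes (see [planted_classes()]); must sum to 1.
#' @param rpkm_log_mean,rpkm_log_sd Lognormal RPKM parameters (natural-log
#'   scale).
#' @param effect_size_log2 Planted cross-species effect, log2 units.
#' @param proteome_noise_sd Per-dataset lognormal noise sd, log2 units.
#' @param proteome_dropout_rate Mean abundance-dependent dropout rate in
#'   \[0, 1) (low-abundance proteins drop out more, mimicking detection
#'   limits).
#' @param edges_per_node Target mean degree of the interactomes.
#' @param conserved_edge_fraction Fraction of orthologous-core edges copied
#'   across species.
#' @param cc_size Number of protein members of the central cascade seed set.
#' @param seed RNG seed; the whole bundle is reproducible from it.
#' @return A list classed `simulation_config`.
#' @export
simulation_config <- function(n_genes = 1800,
                              ortholog_fraction = 0.62,
                              n_proteome_datasets = c(human = 7, mouse = 4),
                              planted_class_proportions = c(
                                no_difference = 0.40,
                                matched_higher_human = 0.12,
                                matched_higher_mouse = 0.12,
                                opposite = 0.10,
                                unique_human = 0.08,
                                unique_mouse = 0.04,
                                compatible = 0.09,
                                unclear = 0.05
                              ),
                              rpkm_log_mean = 1.5,
                              rpkm_log_sd = 2,
                              effect_size_log2 = 3,
                              proteome_noise_sd = 0.5,
                              proteome_dropout_rate = 0.3,
                              edges_per_node = 5,
                              conserved_edge_fraction = 0.4,
                              cc_size = 20,
                              seed = 1L) {
  stopifnot(n_genes >= 1, ortholog_fraction >= 0, ortholog_fraction <= 1,
            rpkm_log_sd > 0, effect_size_log2 > 0, proteome_noise_sd >= 0,
            proteome_dropout_rate >= 0, proteome_dropout_rate < 1,
            edges_per_node >= 1, conserved_edge_fraction >= 0,
            conserved_edge_fraction <= 1, cc_size >= 1)
  if (length(n_proteome_datasets) == 1) {
    n_proteome_datasets <- rep(n_proteome_datasets, 2)
  }
  names(n_proteome_datasets) <- c("human", "mouse")
  bad <- setdiff(names(planted_class_proportions), planted_classes())
  if (length(bad) > 0) {
    abort(paste0("unknown planted class(es): ", paste(bad, collapse = ", ")),
          class = "plateletcc_config_error")
  }
  if (abs(sum(planted_class_proportions) - 1) > 1e-9) {
    abort("planted_class_proportions must sum to 1",
          class = "plateletcc_config_error")
  }
  props <- setNames(rep(0, length(planted_classes())), planted_classes())
  props[names(planted_class_proportions)] <- planted_class_proportions
  structure(
    list(n_genes = as.integer(n_genes),
         ortholog_fraction = ortholog_fraction,
         n_proteome_datasets = setNames(as.integer(n_proteome_datasets),
                                        c("human", "mouse")),
         planted_class_proportions = props,
         rpkm_log_mean = rpkm_log_mean, rpkm_log_sd = rpkm_log_sd,
         effect_size_log2 = effect_size_log2,
         proteome_noise_sd = proteome_noise_sd,
         proteome_dropout_rate = proteome_dropout_rate,
         edges_per_node = edges_per_node,
         conserved_edge_fraction = conserved_edge_fraction,
         cc_size = as.integer(cc_size),
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# Largest-remainder apportionment of n items over proportions.
apportion <- function(n, props) {
  raw <- n * props
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    idx <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[idx] <- counts[idx] + 1
  }
  as.integer(counts)
}

#' Generate a complete two-species input bundle with known ground truth
#'
#' Draws per-gene baseline RPKM lognormally shared across orthologs, plants
#' cross-species difference classes (concordant shifts for matched classes,
#' discordant for opposite, detection-zeroing for unique classes, RNA-only
#' shifts with suppressed protein evidence for unclear), simulates proteome
#' datasets as RNA-correlated signal times a dataset-specific scale with
#' lognormal noise and abundance-dependent dropout, builds preferential-
#' attachment interactomes with a conserved orthologous core plus
#' species-specific edges and low-confidence decoys, and samples the
#' central-cascade seed set from high-degree conserved nodes plus the eight
#' second messengers. Fully reproducible from the config seed.
#'
#' @param config A [simulation_config()].
#' @return A list classed `cc_bundle` with elements `expression` (human and
#'   mouse RPKM tibbles), `proteomes` (named list of proteome tibbles),
#'   `orthologs`, `interactions` (per-species edge tibbles),
#'   `second_messengers`, `cc_seeds`, `cc_edges`, `truth` (`genes` with
#'   planted class and true effects; `edges` with conserved flags) and
#'   `config`.
#' @export
generate_bundle <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, generate_bundle_impl(config))
}

generate_bundle_impl <- function(config) {
  n <- config$n_genes
  eff <- config$effect_size_log2
  n_orth <- round(n * config$ortholog_fraction)
  n_spec <- n - n_orth
  n_hspec <- round(n_spec * 621 / (621 + 58))
  n_mspec <- n_spec - n_hspec

  orth_h <- sprintf("ORTH%05d", seq_len(n_orth))
  orth_m_native <- sprintf("Orth%05d", seq_len(n_orth))
  hspec <- sprintf("HSONLY%04d", seq_len(n_hspec))
  mspec_native <- sprintf("Msonly%04d", seq_len(n_mspec))
  mspec_combined <- paste0("MOUSE:", toupper(mspec_native))

  orthologs <- as_ortholog_map(tibble(
    human_symbol = orth_h, mouse_symbol = orth_m_native,
    group_id = seq_len(n_orth), inparalog_score = 1.0
  ))

  # planted classes over ortholog genes
  counts <- apportion(n_orth, config$planted_class_proportions)
  class_vec <- sample(rep(planted_classes(), counts))

  base_log2 <- log2(exp(rnorm(n_orth, config$rpkm_log_mean, config$rpkm_log_sd)))
  comp_dir <- sample(c(1, -1), n_orth, replace = TRUE)
  uncl_dir <- sample(c(1, -1), n_orth, replace = TRUE)
  comp_prot_eff <- max(0.2, eff - 2.5)

  shift <- tibble(
    symbol = orth_h, class = class_vec,
    rna_h = 0, rna_m = 0, prot_h = 0, prot_m = 0,
    absent_h = FALSE, absent_m = FALSE, prot_suppressed = FALSE
  )
  cl <- shift$class
  shift$rna_h[cl == "matched_higher_human"] <- eff
  shift$prot_h[cl == "matched_higher_human"] <- eff
  shift$rna_m[cl == "matched_higher_mouse"] <- eff
  shift$prot_m[cl == "matched_higher_mouse"] <- eff
  shift$rna_h[cl == "opposite"] <- eff
  shift$prot_m[cl == "opposite"] <- eff
  comp <- cl == "compatible"
  shift$rna_h[comp & comp_dir == 1] <- eff
  shift$rna_m[comp & comp_dir == -1] <- eff
  shift$prot_h[comp & comp_dir == 1] <- comp_prot_eff
  shift$prot_m[comp & comp_dir == -1] <- comp_prot_eff
  uncl <- cl == "unclear"
  shift$rna_h[uncl & uncl_dir == 1] <- eff
  shift$rna_m[uncl & uncl_dir == -1] <- eff
  shift$prot_suppressed[uncl] <- TRUE
  shift$absent_m[cl == "unique_human"] <- TRUE
  shift$rna_h[cl == "unique_human"] <- eff
  shift$absent_h[cl == "unique_mouse"] <- TRUE
  shift$rna_m[cl == "unique_mouse"] <- eff

  rpkm_of <- function(base, shf, absent, floor_solid) {
    out <- 2^(base + shf)
    # unique-class genes must clear the solid-expression cut in their species
    out[floor_solid] <- pmax(out[floor_solid], 12)
    out[absent] <- 0
    out
  }
  rpkm_h_orth <- rpkm_of(base_log2, shift$rna_h, shift$absent_h,
                         cl == "unique_human")
  rpkm_m_orth <- rpkm_of(base_log2, shift$rna_m, shift$absent_m,
                         cl == "unique_mouse")
  base_hspec <- log2(exp(rnorm(n_hspec, config$rpkm_log_mean, config$rpkm_log_sd)))
  base_mspec <- log2(exp(rnorm(n_mspec, config$rpkm_log_mean, config$rpkm_log_sd)))

  expression <- list(
    human = tibble(symbol = c(orth_h, hspec),
                   rpkm = c(rpkm_h_orth, 2^base_hspec)),
    mouse = tibble(symbol = c(orth_m_native, mspec_native),
                   rpkm = c(rpkm_m_orth, 2^base_mspec))
  )

  # proteome datasets: RNA-correlated log2 signal x study scale + noise
  make_proteome <- function(species, d) {
    if (species == "human") {
      sym <- c(orth_h, hspec)
      sig <- c(base_log2 + shift$prot_h, base_hspec)
      absent <- c(shift$absent_h | shift$prot_suppressed, rep(FALSE, n_hspec))
    } else {
      sym <- c(orth_m_native, mspec_native)
      sig <- c(base_log2 + shift$prot_m, base_mspec)
      absent <- c(shift$absent_m | shift$prot_suppressed, rep(FALSE, n_mspec))
    }
    scale <- 10^runif(1, 0, 4)
    value <- scale * 2^(sig + rnorm(length(sig), 0, config$proteome_noise_sd))
    keep <- !absent
    if (config$proteome_dropout_rate > 0) {
      r <- rank(value, ties.method = "first")
      p_drop <- pmin(1, config$proteome_dropout_rate *
                       2 * (1 - (r - 0.5) / length(r)))
      keep <- keep & (runif(length(sig)) > p_drop)
    }
    id <- sprintf("%s_proteome_%02d", species, d)
    as_proteome_dataset(
      tibble(symbol = sym[keep], abundance = value[keep]),
      species = species, dataset_id = id,
      measure = proteome_measures()[(d - 1) %% 4 + 1]
    )
  }
  proteomes <- c(
    lapply(seq_len(config$n_proteome_datasets[["human"]]),
           function(d) make_proteome("human", d)),
    lapply(seq_len(config$n_proteome_datasets[["mouse"]]),
           function(d) make_proteome("mouse", d))
  )
  names(proteomes) <- vapply(proteomes, attr, character(1), "dataset_id")

  # interactomes: preferential attachment; conserved orthologous core
  m_pa <- max(1L, round(config$edges_per_node / 2))
  human_syms <- sample(c(orth_h, hspec))
  g_h <- igraph::sample_pa(length(human_syms), m = m_pa, directed = FALSE)
  el_h <- igraph::as_edgelist(g_h)
  h_edges <- tibble(a = human_syms[as.integer(el_h[, 1])],
                    b = human_syms[as.integer(el_h[, 2])])
  core <- filter(h_edges, .data$a %in% orth_h, .data$b %in% orth_h)
  core <- core[runif(nrow(core)) < config$conserved_edge_fraction, ]
  m_map <- setNames(orth_m_native, orth_h)
  core_m <- tibble(a = unname(m_map[core$a]), b = unname(m_map[core$b]))
  mouse_syms <- sample(c(orth_m_native, mspec_native))
  g_m <- igraph::sample_pa(length(mouse_syms),
                           m = max(1L, round(m_pa * (1 - config$conserved_edge_fraction))),
                           directed = FALSE)
  el_m <- igraph::as_edgelist(g_m)
  m_edges <- bind_rows(
    tibble(a = mouse_syms[as.integer(el_m[, 1])],
           b = mouse_syms[as.integer(el_m[, 2])]),
    core_m
  ) |>
    filter(.data$a != .data$b) |>
    distinct(key = edge_key(.data$a, .data$b), .keep_all = TRUE) |>
    select(-"key")

  finish_edges <- function(edges, species) {
    n_e <- nrow(edges)
    real <- mutate(edges, species = species,
                   confidence = runif(n_e, 0.992, 0.9999),
                   source_quality = runif(n_e, 0.5, 1))
    # low-confidence decoys the p > 0.99 cut must remove
    syms <- unique(c(edges$a, edges$b))
    n_dec <- max(1L, round(0.15 * n_e))
    decoy <- tibble(a = sample(syms, n_dec, replace = TRUE),
                    b = sample(syms, n_dec, replace = TRUE)) |>
      filter(.data$a != .data$b) |>
      mutate(species = species,
             confidence = runif(n(), 0.3, 0.98),
             source_quality = runif(n(), 0.2, 0.9))
    bind_rows(real, decoy)
  }
  interactions <- list(human = finish_edges(h_edges, "human"),
                       mouse = finish_edges(m_edges, "mouse"))

  # CC seeds: highest-degree conserved (orthologous) proteins + messengers
  conserved_keys <- intersect(
    edge_key(clean_symbols(core$a), clean_symbols(core$b)),
    edge_key(clean_symbols(core_m$a) |> sub_m2h(orthologs),
             clean_symbols(core_m$b) |> sub_m2h(orthologs))
  )
  deg_h <- table(c(core$a, core$b))
  cand <- names(sort(deg_h, decreasing = TRUE))
  cc_prot <- head(cand, config$cc_size)
  if (length(cc_prot) < config$cc_size) {
    cc_prot <- head(unique(c(cc_prot, orth_h)), config$cc_size)
  }
  messengers <- second_messenger_nodes()
  cc_seeds <- c(cc_prot, messengers$id)
  ring <- tibble(a = cc_prot, b = cc_prot[c(seq_along(cc_prot)[-1], 1)])
  msg_links <- bind_rows(lapply(messengers$id, function(msg) {
    tibble(a = msg, b = sample(cc_prot, min(2, length(cc_prot))))
  }))
  cc_edges <- bind_rows(ring, msg_links) |> filter(.data$a != .data$b)
  # messenger links are experimentally established in both species
  msg_both <- mutate(msg_links, confidence = 0.999, source_quality = 1)
  interactions$human <- bind_rows(interactions$human,
                                  mutate(msg_both, species = "human"))
  interactions$mouse <- bind_rows(
    interactions$mouse,
    mutate(msg_both, b = unname(m_map[msg_both$b]), species = "mouse")
  )

  truth_genes <- bind_rows(
    tibble(symbol = orth_h, class = class_vec,
           true_rna_log2_effect = shift$rna_h - shift$rna_m,
           true_prot_log2_effect = shift$prot_h - shift$prot_m),
    tibble(symbol = hspec, class = "species_specific_human",
           true_rna_log2_effect = NA_real_, true_prot_log2_effect = NA_real_),
    tibble(symbol = mspec_combined, class = "species_specific_mouse",
           true_rna_log2_effect = NA_real_, true_prot_log2_effect = NA_real_)
  )
  hk <- edge_key(clean_symbols(h_edges$a), clean_symbols(h_edges$b))
  truth_edges <- tibble(
    a = clean_symbols(h_edges$a), b = clean_symbols(h_edges$b),
    conserved = hk %in% edge_key(
      sub_m2h(clean_symbols(m_edges$a), orthologs),
      sub_m2h(clean_symbols(m_edges$b), orthologs)
    )
  )

  structure(
    list(expression = expression, proteomes = proteomes,
         orthologs = orthologs, interactions = interactions,
         second_messengers = messengers,
         cc_seeds = cc_seeds, cc_edges = cc_edges,
         truth = list(genes = truth_genes, edges = truth_edges),
         config = config),
    class = "cc_bundle"
  )
}

sub_m2h <- function(symbols, orthologs) {
  lk <- ortholog_lookup(orthologs, symbols, from = "mouse")
  ifelse(lk$status == "ortholog", lk$ortholog, symbols)
}

#' @export
print.cc_bundle <- function(x, ...) {
  cat(sprintf(
    paste0("<cc_bundle> %d genes (%d ortholog pairs), %d proteome datasets,\n",
           "  %d human / %d mouse interactions, %d CC seeds, seed %d\n"),
    nrow(x$truth$genes), nrow(x$orthologs), length(x$proteomes),
    nrow(x$interactions$human), nrow(x$interactions$mouse),
    length(x$cc_seeds), x$config$seed))
  invisible(x)
}

#' Write a synthetic bundle to disk in the package's TSV dialects
#'
#' Emits the expression, proteome, ortholog, interaction, seed-list and
#' CC-edge files plus a YAML manifest recording the generating configuration
#' and seed.
#'
#' @param bundle A `cc_bundle`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(bundle$expression$human, file.path(dir, "expression_human.tsv"))
  readr::write_tsv(bundle$expression$mouse, file.path(dir, "expression_mouse.tsv"))
  for (nm in names(bundle$proteomes)) {
    d <- bundle$proteomes[[nm]]
    out <- mutate(as_tibble(d), measure = attr(d, "measure"))
    readr::write_tsv(out, file.path(dir, paste0("proteome_", nm, ".tsv")))
  }
  readr::write_tsv(as_tibble(bundle$orthologs), file.path(dir, "orthologs.tsv"))
  readr::write_tsv(bundle$interactions$human, file.path(dir, "interactions_human.tsv"))
  readr::write_tsv(bundle$interactions$mouse, file.path(dir, "interactions_mouse.tsv"))
  readr::write_lines(bundle$cc_seeds, file.path(dir, "cc_seeds.txt"))
  readr::write_tsv(bundle$cc_edges, file.path(dir, "cc_edges.tsv"))
  readr::write_tsv(bundle$truth$genes, file.path(dir, "truth_genes.tsv"))
  cfg <- unclass(bundle$config)
  cfg$planted_class_proportions <- as.list(cfg$planted_class_proportions)
  cfg$n_proteome_datasets <- as.list(cfg$n_proteome_datasets)
  yaml::write_yaml(list(simulation = cfg), file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Compare recovered concordance labels with the planted ground truth
#'
#' Maps each scored gene back into the planted-class space (matched plus RNA
#' exclusivity implies a unique class; matched with a mutual RNA difference
#' implies matched_higher_human/mouse by the sign of the RNA delta) and
#' reports per-class recall plus overall accuracy on the key classes
#' (matched, opposite and unique), counting planted genes missing from the
#' scored set as errors.
#'
#' @param records A `concordance_tbl`.
#' @param evidence The evidence tibble the records were scored from.
#' @param truth The bundle's `truth$genes` tibble.
#' @return A list: `per_class` tibble (class, n_planted, n_recovered,
#'   recall), `accuracy_key` (key-class accuracy in \[0, 1\]), and
#'   `predicted` (per-gene predicted planted class).
#' @export
evaluate_recovery <- function(records, evidence, truth) {
  pred <- records |>
    left_join(select(evidence, "symbol", "rna_human_detected",
                     "rna_mouse_detected"), by = "symbol") |>
    mutate(predicted = case_when(
      .data$label == "matched" & .data$applicable == "presence" &
        .data$rna_human_detected ~ "unique_human",
      .data$label == "matched" & .data$applicable == "presence" ~ "unique_mouse",
      .data$label == "matched" & (.data$delta_rna %na% 0) > 0 ~ "matched_higher_human",
      .data$label == "matched" ~ "matched_higher_mouse",
      TRUE ~ as.character(.data$label)
    )) |>
    select("symbol", "predicted")
  key <- c("matched_higher_human", "matched_higher_mouse", "opposite",
           "unique_human", "unique_mouse")
  joined <- truth |>
    filter(.data$class %in% planted_classes(), .data$class != "no_difference") |>
    left_join(pred, by = "symbol") |>
    mutate(hit = !is.na(.data$predicted) & .data$predicted == .data$class)
  per_class <- joined |>
    group_by(class = .data$class) |>
    summarise(n_planted = n(), n_recovered = sum(.data$hit),
              recall = mean(.data$hit), .groups = "drop")
  key_rows <- filter(joined, .data$class %in% key)
  list(
    per_class = per_class,
    accuracy_key = if (nrow(key_rows) > 0) mean(key_rows$hit) else NA_real_,
    predicted = pred
  )
}
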