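#' Assemble per-gene cross-species evidence
#'
#' Joins normalised RNA evidence for both species with species-maximum and
#' per-dataset normalised proteome evidence on combined gene identifiers
#' (ortholog pairs share the human symbol; species-specific mouse genes are
#' `MOUSE:`-prefixed). All deltas downstream are human minus mouse.
#'
#' @param rna_human,rna_mouse Normalised RNA tibbles from
#'   [median_log2_normalize()] (mouse symbols in the mouse namespace).
#' @param protein_human,protein_mouse Lists of normalised proteome tibbles,
#'   one per study.
#' @param orthologs An `ortholog_map`.
#' @return A tibble with one row per gene: RNA and species-max protein
#'   `log2_rel_median` and detection flags per species, `delta_rna`,
#'   `delta_prot` (NA unless both species detected), and list-columns
#'   `prot_human_values` / `prot_mouse_values` holding the per-dataset
#'   normalised values (NA where undetected).
#' @export
build_gene_evidence <- function(rna_human, rna_mouse,
                                protein_human, protein_mouse, orthologs) {
  to_combined <- function(tbl, species) {
    tbl <- as_tibble(tbl)
    tbl$symbol <- map_to_combined(tbl$symbol, orthologs, species)
    # several source symbols can map to one combined id; keep the max evidence
    tbl |>
      group_by(.data$symbol) |>
      summarise(
        log2_rel_median = if (any(.data$detected))
          max(.data$log2_rel_median[.data$detected]) else NA_real_,
        detected = any(.data$detected), .groups = "drop"
      )
  }
  dataset_matrix <- function(datasets, species) {
    if (inherits(datasets, "data.frame")) datasets <- list(datasets)
    ids <- imap_chr_default(datasets)
    named <- purrr::map2(datasets, ids, function(d, id) {
      to_combined(d, species) |> mutate(dataset_id = id)
    })
    bind_rows(named)
  }
  rh <- to_combined(rna_human, "human") |>
    rename(rna_human = "log2_rel_median", rna_human_detected = "detected")
  rm_ <- to_combined(rna_mouse, "mouse") |>
    rename(rna_mouse = "log2_rel_median", rna_mouse_detected = "detected")
  ph_long <- dataset_matrix(protein_human, "human")
  pm_long <- dataset_matrix(protein_mouse, "mouse")
  ph_max <- species_max_from_long(ph_long) |>
    rename(prot_human = "log2_rel_median", prot_human_detected = "detected")
  pm_max <- species_max_from_long(pm_long) |>
    rename(prot_mouse = "log2_rel_median", prot_mouse_detected = "detected")
  ph_vals <- values_list(ph_long, "prot_human_values")
  pm_vals <- values_list(pm_long, "prot_mouse_values")

  evidence <- tibble(symbol = sort(unique(c(
    rh$symbol, rm_$symbol, ph_max$symbol, pm_max$symbol
  )))) |>
    left_join(rh, by = "symbol") |>
    left_join(rm_, by = "symbol") |>
    left_join(ph_max, by = "symbol") |>
    left_join(pm_max, by = "symbol") |>
    left_join(ph_vals, by = "symbol") |>
    left_join(pm_vals, by = "symbol") |>
    mutate(
      across(ends_with("_detected"), ~ .x %na% FALSE),
      prot_human_values = purrr::map(.data$prot_human_values,
                                     ~ .x %||% numeric(0)),
      prot_mouse_values = purrr::map(.data$prot_mouse_values,
                                     ~ .x %||% numeric(0)),
      delta_rna = ifelse(.data$rna_human_detected & .data$rna_mouse_detected,
                         .data$rna_human - .data$rna_mouse, NA_real_),
      delta_prot = ifelse(.data$prot_human_detected & .data$prot_mouse_detected,
                          .data$prot_human - .data$prot_mouse, NA_real_)
    )
  evidence
}

imap_chr_default <- function(datasets) {
  ids <- names(datasets) %||% rep("", length(datasets))
  vapply(seq_along(datasets), function(i) {
    if (!is.null(ids[i]) && nzchar(ids[i])) ids[i]
    else attr(datasets[[i]], "dataset_id") %||% paste0("dataset_", i)
  }, character(1))
}

species_max_from_long <- function(long) {
  long |>
    group_by(.data$symbol) |>
    summarise(
      log2_rel_median = if (any(.data$detected))
        max(.data$log2_rel_median[.data$detected]) else NA_real_,
      detected = any(.data$detected), .groups = "drop"
    )
}

values_list <- function(long, name) {
  out <- long |>
    group_by(.data$symbol) |>
    summarise(vals = list(setNames(
      ifelse(.data$detected, .data$log2_rel_median, NA_real_),
      .data$dataset_id
    )), .groups = "drop")
  names(out)[2] <- name
  out
}

#' Select genes exhibiting a cross-species mRNA difference
#'
#' The concordance scheme scores mRNA differences against proteome evidence;
#' genes without an RNA difference do not enter. A gene qualifies if RNA is
#' detected in exactly one species (a presence/absence difference), or
#' detected in both with `|delta_rna|` strictly above `min_abs_log2`.
#'
#' @param evidence Output of [build_gene_evidence()].
#' @param min_abs_log2 Minimal absolute RNA log2 difference for mutual genes;
#'   default 1 (two-fold).
#' @return The qualifying subset of `evidence`.
#' @export
select_rna_differences <- function(evidence, min_abs_log2 = 1) {
  filter(evidence,
         xor(.data$rna_human_detected, .data$rna_mouse_detected) |
           (.data$rna_human_detected & .data$rna_mouse_detected &
              abs(.data$delta_rna) > min_abs_log2))
}

#' Presence/absence concordance sub-score
#'
#' Applicable only when RNA detects the gene in exactly one species: +1 if
#' protein detection is exclusive to the same species, -1 if exclusive to the
#' other, 0 when no clear statement can be placed (protein absent everywhere
#' or present in both species).
#'
#' @param evidence Evidence tibble (see [build_gene_evidence()]).
#' @return Numeric vector in \{-1, 0, +1\}, NA where not applicable.
#' @export
score_presence <- function(evidence) {
  applicable <- xor(evidence$rna_human_detected, evidence$rna_mouse_detected)
  rna_side <- ifelse(evidence$rna_human_detected, 1, -1)
  prot_excl <- xor(evidence$prot_human_detected, evidence$prot_mouse_detected)
  prot_side <- ifelse(evidence$prot_human_detected, 1, -1)
  score <- ifelse(prot_excl, rna_side * prot_side, 0)
  ifelse(applicable, score, NA_real_)
}

#' Tendency concordance sub-score for mutually occurring genes
#'
#' Applicable when RNA detects the gene in both species: +1 if the protein
#' difference points the same way as the RNA difference (both proteins
#' detected, nonzero deltas), -1 if it points the opposite way, 0 when the
#' tendency is neither confirmed nor opposed (protein missing in a species,
#' or a zero delta at either level).
#'
#' @inheritParams score_presence
#' @return Numeric vector in \{-1, 0, +1\}, NA where not applicable.
#' @export
score_tendency <- function(evidence) {
  applicable <- evidence$rna_human_detected & evidence$rna_mouse_detected
  resolvable <- applicable &
    !is.na(evidence$delta_prot) &
    (evidence$delta_rna != 0) & (evidence$delta_prot != 0)
  score <- ifelse(resolvable,
                  ifelse(sign(evidence$delta_prot) == sign(evidence$delta_rna),
                         1, -1),
                  0)
  ifelse(applicable, score, NA_real_)
}

#' Delta-similarity concordance sub-score
#'
#' Compares the magnitude of the cross-species log2 fold changes:
#' `clamp(1 - |delta_rna - delta_prot| / scale, -1, +1)`, continuous from +1
#' (identical deltas) down to -1, and 0 whenever either delta is undefined
#' (a species undetected at either level).
#'
#' @inheritParams score_presence
#' @param scale Discrepancy (log2 units) at which the score crosses 0 towards
#'   -1; must be positive. Default 2.
#' @return Numeric vector in \[-1, +1\].
#' @export
score_delta <- function(evidence, scale = 2) {
  if (!is.numeric(scale) || scale <= 0) {
    abort("delta scale must be positive", class = "plateletcc_config_error")
  }
  ifelse(!is.na(evidence$delta_rna) & !is.na(evidence$delta_prot),
         pmin(1, pmax(-1, 1 - abs(evidence$delta_rna - evidence$delta_prot) / scale)),
         0)
}

#' Overall concordance score
#'
#' Exactly one categorical sub-score (presence or tendency) applies per gene;
#' the overall score is that sub-score plus the delta-similarity score and is
#' bounded in \[-2, +2\].
#'
#' @param presence,tendency Sub-score vectors (NA where not applicable).
#' @param delta Delta-similarity vector.
#' @return Numeric vector in \[-2, +2\].
#' @export
overall_score <- function(presence, tendency, delta) {
  if (any(!is.na(presence) & !is.na(tendency))) {
    abort("both categorical scores applicable for some gene; internal logic error")
  }
  categorical <- coalesce(presence, tendency, 0)
  categorical + delta
}

# Number of individual cross-study comparisons (human dataset x mouse dataset,
# both detecting the gene) whose direction matches the RNA direction.
count_supporting_pairs <- function(evidence) {
  target <- ifelse(
    xor(evidence$rna_human_detected, evidence$rna_mouse_detected),
    ifelse(evidence$rna_human_detected, 1, -1),
    sign(evidence$delta_rna %na% 0)
  )
  purrr::pmap_int(
    list(evidence$prot_human_values, evidence$prot_mouse_values, target),
    function(h, m, t) {
      h <- h[!is.na(h)]; m <- m[!is.na(m)]
      if (t == 0 || length(h) == 0 || length(m) == 0) return(0L)
      diffs <- outer(h, m, `-`)
      sum(sign(diffs) == t)
    }
  )
}

#' Score and classify transcriptome-proteome concordance
#'
#' Applies the full per-gene scoring scheme and the four-class classification:
#' overall score at least +1 is `matched` (proteome confirms the mRNA
#' difference), at most -1 is `opposite` (clear contradiction); scores
#' strictly between are `compatible` if at least one individual proteome
#' comparison supports the mRNA direction, otherwise `unclear`. Compatible
#' genes get a sub-label: `compatible_with_tendency` when the species-max
#' tendency itself confirms the direction, else `compatible_weak`.
#'
#' @param evidence Evidence tibble, normally pre-screened with
#'   [select_rna_differences()].
#' @param scale Delta-similarity scale; see [score_delta()].
#' @return A tibble classed `concordance_tbl`: per gene the sub-scores,
#'   `overall`, `label`, `sublabel`, `n_supporting_pairs`, deltas.
#' @export
score_concordance <- function(evidence, scale = 2) {
  presence <- score_presence(evidence)
  tendency <- score_tendency(evidence)
  delta <- score_delta(evidence, scale)
  overall <- overall_score(presence, tendency, delta)
  n_sup <- count_supporting_pairs(evidence)
  label <- case_when(
    overall >= 1 ~ "matched",
    overall <= -1 ~ "opposite",
    n_sup >= 1 ~ "compatible",
    TRUE ~ "unclear"
  )
  sublabel <- case_when(
    label != "compatible" ~ NA_character_,
    !is.na(tendency) & tendency == 1 ~ "compatible_with_tendency",
    TRUE ~ "compatible_weak"
  )
  out <- tibble(
    symbol = evidence$symbol,
    applicable = case_when(
      !is.na(presence) ~ "presence",
      !is.na(tendency) ~ "tendency",
      TRUE ~ "none"
    ),
    score_presence = presence,
    score_tendency = tendency,
    score_delta = delta,
    overall = overall,
    label = factor(label, levels = concordance_classes()),
    sublabel = sublabel,
    n_supporting_pairs = n_sup,
    delta_rna = evidence$delta_rna,
    delta_prot = evidence$delta_prot
  )
  structure(out, class = c("concordance_tbl", class(out)))
}

#' The four concordance classes
#' @return Character vector `matched`, `compatible`, `opposite`, `unclear`.
#' @export
concordance_classes <- function() {
  c("matched", "compatible", "opposite", "unclear")
}

#' Summarise a concordance table
#'
#' Reports the summed overall score, per-class counts and percentages (one
#' decimal, denominators over all scored genes) and the same-direction
#' percentage (matched plus compatible).
#'
#' @param records A `concordance_tbl` (or any tibble with `overall` and
#'   `label`).
#' @return A one-row tibble classed `concordance_summary`.
#' @export
summarize_concordance <- function(records) {
  if (nrow(records) == 0) {
    abort("no concordance records to summarise",
          class = "plateletcc_value_error")
  }
  n <- nrow(records)
  counts <- table(factor(records$label, levels = concordance_classes()))
  pct <- round(100 * as.numeric(counts) / n, 1)
  names(pct) <- paste0("pct_", names(counts))
  out <- tibble(
    n = n,
    summed_overall = sum(records$overall),
    n_matched = as.integer(counts[["matched"]]),
    n_compatible = as.integer(counts[["compatible"]]),
    n_opposite = as.integer(counts[["opposite"]]),
    n_unclear = as.integer(counts[["unclear"]]),
    pct_matched = pct[["pct_matched"]],
    pct_compatible = pct[["pct_compatible"]],
    pct_opposite = pct[["pct_opposite"]],
    pct_unclear = pct[["pct_unclear"]],
    pct_same_direction = round(100 * (as.integer(counts[["matched"]]) +
                                        as.integer(counts[["compatible"]])) / n, 1)
  )
  structure(out, class = c("concordance_summary", class(out)))
}

#' Write a concordance table as TSV
#' @param records A `concordance_tbl`.
#' @param path Output path.
#' @export
write_concordance_table <- function(records, path) {
  out <- as_tibble(records) |>
    select(-any_of(c("prot_human_values", "prot_mouse_values")))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @export
glance.concordance_tbl <- function(x, ...) {
  as_tibble(summarize_concordance(x))
}
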