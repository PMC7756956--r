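#' Detection thresholds for RPKM-level calls
#'
#' `detection_limit_rpkm` quantifies "not expressed in the other species"
#' (configurable; 1 RPKM by default), `exclusive_min_rpkm` is the
#' solidly-expressed cut (strictly above 10 RPKM), and `abundance_min_rpkm`
#' flags abundant genes (strictly above 3 RPKM, the cut set from the central
#' cascade's median expression).
#'
#' @param detection_limit_rpkm Nonnegative; default 1.
#' @param exclusive_min_rpkm Nonnegative; default 10.
#' @param abundance_min_rpkm Nonnegative; default 3.
#' @return A list classed `detection_thresholds`.
#' @export
detection_thresholds <- function(detection_limit_rpkm = 1.0,
                                 exclusive_min_rpkm = 10.0,
                                 abundance_min_rpkm = 3.0) {
  stopifnot(detection_limit_rpkm >= 0, exclusive_min_rpkm >= 0,
            abundance_min_rpkm >= 0)
  if (detection_limit_rpkm > exclusive_min_rpkm) {
    abort("detection_limit_rpkm must not exceed exclusive_min_rpkm",
          class = "plateletcc_config_error")
  }
  structure(
    list(detection_limit_rpkm = detection_limit_rpkm,
         exclusive_min_rpkm = exclusive_min_rpkm,
         abundance_min_rpkm = abundance_min_rpkm),
    class = "detection_thresholds"
  )
}

#' Median-relative log2 normalisation of one dataset
#'
#' Each detected (abundance > 0) record is expressed as the log2 ratio of its
#' abundance to the median abundance of detected records in the same dataset,
#' putting RNA-seq RPKM and heterogeneous semi-quantitative proteome measures
#' on one comparable scale. Zero abundances are treated as undetected and
#' excluded from the median. For an even number of detected records the median
#' is the geometric midpoint of the central pair (the arithmetic midpoint on
#' the log2 scale), which keeps the normalised values symmetric around zero.
#'
#' @param dataset An `expression_dataset` or `proteome_dataset` (any tibble
#'   with `symbol` and a `rpkm`/`abundance` value column works).
#' @return A tibble with columns `symbol`, `log2_rel_median`, `detected`,
#'   carrying the source's `species` and `dataset_id` attributes.
#' @export
median_log2_normalize <- function(dataset) {
  value_col <- intersect(c("rpkm", "abundance", "value"), names(dataset))[1]
  if (is.na(value_col)) {
    abort("dataset has no abundance column (rpkm/abundance/value)",
          class = "plateletcc_format_error")
  }
  val <- dataset[[value_col]]
  if (any(val < 0, na.rm = TRUE)) {
    abort("negative abundances", class = "plateletcc_value_error")
  }
  detected <- !is.na(val) & val > 0
  if (!any(detected)) {
    abort("dataset has no detected (positive) abundances; cannot normalize",
          class = "plateletcc_normalization_error")
  }
  log2_med <- median(log2(val[detected]))
  out <- tibble(
    symbol = dataset$symbol,
    log2_rel_median = ifelse(detected, log2(val) - log2_med, NA_real_),
    detected = detected
  )
  structure(out,
            species = attr(dataset, "species"),
            dataset_id = attr(dataset, "dataset_id"),
            measure = attr(dataset, "measure"),
            class = c("normalized_dataset", class(out)))
}

#' Per-gene species maximum over several normalised proteome datasets
#'
#' Proteome studies differ widely in coverage and depth; per gene and species
#' only the maximum normalised abundance across datasets is carried forward.
#' A gene is undetected at species level only if undetected in every dataset.
#'
#' @param normalized_datasets A list of `normalized_dataset` tibbles for one
#'   species (at least one).
#' @return A tibble with columns `symbol`, `log2_rel_median`, `detected`.
#' @export
species_max_protein <- function(normalized_datasets) {
  if (inherits(normalized_datasets, "data.frame")) {
    normalized_datasets <- list(normalized_datasets)
  }
  stopifnot(length(normalized_datasets) >= 1)
  bind_rows(lapply(normalized_datasets, as_tibble)) |>
    group_by(.data$symbol) |>
    summarise(
      log2_rel_median = if (any(.data$detected))
        max(.data$log2_rel_median[.data$detected]) else NA_real_,
      detected = any(.data$detected),
      .groups = "drop"
    ) |>
    arrange(.data$symbol)
}

#' Classify RPKM values against the detection thresholds
#'
#' Strict inequalities throughout: a gene is `absent` at or below the
#' detection limit, `detected` above it, and `solidly_expressed` if
#' additionally above the exclusive-expression minimum. The abundance flag
#' (strictly above `abundance_min_rpkm`) is reported independently.
#'
#' @param rpkm Nonnegative numeric vector.
#' @param thresholds A [detection_thresholds()] object.
#' @return A tibble with columns `rpkm`, `call` (factor: absent / detected /
#'   solidly_expressed) and `abundant` (logical).
#' @export
detection_call <- function(rpkm, thresholds = detection_thresholds()) {
  if (any(rpkm < 0, na.rm = TRUE)) {
    abort("negative RPKM", class = "plateletcc_value_error")
  }
  call <- dplyr::case_when(
    rpkm <= thresholds$detection_limit_rpkm ~ "absent",
    rpkm > thresholds$exclusive_min_rpkm ~ "solidly_expressed",
    TRUE ~ "detected"
  )
  tibble(
    rpkm = rpkm,
    call = factor(call, levels = c("absent", "detected", "solidly_expressed")),
    abundant = rpkm > thresholds$abundance_min_rpkm
  )
}

#' Write normalised values as TSV
#' @param normalized A `normalized_dataset`.
#' @param path Output path.
#' @export
write_normalized_table <- function(normalized, path) {
  out <- as_tibble(normalized)
  out$dataset_id <- attr(normalized, "dataset_id") %||% NA_character_
  readr::write_tsv(out, path)
  invisible(path)
}
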