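# Small in-code fixtures and independent oracles shared across tests.

write_tsv_fixture <- function(df, file = tempfile(fileext = ".tsv")) {
  readr::write_tsv(df, file)
  file
}

# Brute-force all-pairs shortest paths (Floyd-Warshall) on an unweighted
# undirected edge list; independent of igraph's BFS.
fw_distances <- function(ids, edges) {
  n <- length(ids)
  d <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(d) <- 0
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    d[a, b] <- 1; d[b, a] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# Random undirected simple graph as a cc_network (protein nodes only).
random_network <- function(n, p = 0.08, cc = character(0)) {
  ids <- sprintf("N%03d", seq_len(n))
  pairs <- t(combn(ids, 2))
  keep <- runif(nrow(pairs)) < p
  nodes <- tibble::tibble(id = ids, is_cc = ids %in% cc)
  cc_network(nodes, tibble::tibble(from = pairs[keep, 1], to = pairs[keep, 2]))
}

# One evidence row in the layout produced by build_gene_evidence(): supply
# normalised RNA values (NA = undetected) and per-dataset protein log2 values
# (vectors may contain NA for undetected entries).
evidence_row <- function(symbol = "G1", rna_h = NA, rna_m = NA,
                         ph = numeric(0), pm = numeric(0)) {
  smax <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) list(val = NA_real_, det = FALSE)
    else list(val = max(v), det = TRUE)
  }
  mh <- smax(ph); mm <- smax(pm)
  rhd <- !is.na(rna_h); rmd <- !is.na(rna_m)
  tibble::tibble(
    symbol = symbol,
    rna_human = ifelse(rhd, rna_h, NA_real_), rna_human_detected = rhd,
    rna_mouse = ifelse(rmd, rna_m, NA_real_), rna_mouse_detected = rmd,
    prot_human = mh$val, prot_human_detected = mh$det,
    prot_mouse = mm$val, prot_mouse_detected = mm$det,
    prot_human_values = list(stats::setNames(ph, sprintf("h%d", seq_along(ph)))),
    prot_mouse_values = list(stats::setNames(pm, sprintf("m%d", seq_along(pm)))),
    delta_rna = ifelse(rhd & rmd, rna_h - rna_m, NA_real_),
    delta_prot = ifelse(mh$det & mm$det, mh$val - mm$val, NA_real_)
  )
}

# Swap the species of every column of an evidence tibble (for the
# antisymmetry property).
swap_species_evidence <- function(ev) {
  out <- ev
  out$rna_human <- ev$rna_mouse; out$rna_mouse <- ev$rna_human
  out$rna_human_detected <- ev$rna_mouse_detected
  out$rna_mouse_detected <- ev$rna_human_detected
  out$prot_human <- ev$prot_mouse; out$prot_mouse <- ev$prot_human
  out$prot_human_detected <- ev$prot_mouse_detected
  out$prot_mouse_detected <- ev$prot_human_detected
  out$prot_human_values <- ev$prot_mouse_values
  out$prot_mouse_values <- ev$prot_human_values
  out$delta_rna <- -ev$delta_rna
  out$delta_prot <- -ev$delta_prot
  out
}

# Random evidence rows for fuzzing the score bound.
random_evidence <- function(n) {
  rows <- lapply(seq_len(n), function(i) {
    rna_h <- if (runif(1) < 0.8) rnorm(1, 0, 2) else NA
    rna_m <- if (runif(1) < 0.8) rnorm(1, 0, 2) else NA
    nh <- sample(0:3, 1); nm <- sample(0:3, 1)
    ph <- rnorm(nh, 0, 2); pm <- rnorm(nm, 0, 2)
    if (nh > 0) ph[runif(nh) < 0.3] <- NA
    if (nm > 0) pm[runif(nm) < 0.3] <- NA
    evidence_row(sprintf("G%04d", i), rna_h, rna_m, ph, pm)
  })
  dplyr::bind_rows(rows)
}
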