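test_that("presence sub-score follows the exclusivity rules", {
  # RNA human-only, protein human-only: confirmed
  expect_equal(score_presence(evidence_row(rna_h = 1, ph = 0.5)), 1)
  # RNA human-only, protein mouse-only: opposed
  expect_equal(score_presence(evidence_row(rna_h = 1, pm = 0.5)), -1)
  # RNA human-only, no protein anywhere: no clear statement
  expect_equal(score_presence(evidence_row(rna_h = 1)), 0)
  # protein in both species: no clear statement either
  expect_equal(score_presence(evidence_row(rna_h = 1, ph = 1, pm = 1)), 0)
  # mutual RNA: not applicable
  expect_true(is.na(score_presence(evidence_row(rna_h = 1, rna_m = 0.5))))
})

test_that("tendency sub-score follows the direction rules", {
  expect_equal(score_tendency(
    evidence_row(rna_h = 1.5, rna_m = 0, ph = 0.4, pm = 0)), 1)
  expect_equal(score_tendency(
    evidence_row(rna_h = 1.5, rna_m = 0, ph = -0.8, pm = 0)), -1)
  # protein undetected in one species: tendency unresolvable
  expect_equal(score_tendency(
    evidence_row(rna_h = 1.5, rna_m = 0, ph = 0.4)), 0)
  # RNA exclusive: not applicable
  expect_true(is.na(score_tendency(evidence_row(rna_h = 1, ph = 1))))
})

test_that("delta sub-score is the clamped linear similarity of the fold changes", {
  expect_equal(score_delta(
    evidence_row(rna_h = 1.5, rna_m = 0, ph = 1.5, pm = 0)), 1)
  # |delta difference| of 4 at scale 2 clamps at the floor
  expect_equal(score_delta(
    evidence_row(rna_h = 2, rna_m = 0, ph = -2, pm = 0)), -1)
  # |delta difference| of 1 at scale 2 gives +0.5
  expect_equal(score_delta(
    evidence_row(rna_h = 1, rna_m = 0, ph = 2, pm = 0)), 0.5)
  # undefined deltas contribute 0
  expect_equal(score_delta(evidence_row(rna_h = 1, ph = 1)), 0)
  expect_error(score_delta(evidence_row(rna_h = 1), scale = 0),
               class = "plateletcc_config_error")
})

test_that("delta sub-score is non-increasing in the delta discrepancy", {
  withr::with_seed(3, {
    dr <- rnorm(1)
    gaps <- sort(abs(rnorm(20, 0, 3)))
    scores <- vapply(gaps, function(g) {
      score_delta(evidence_row(rna_h = dr, rna_m = 0, ph = dr - g, pm = 0))
    }, numeric(1))
    expect_true(all(diff(scores) <= 1e-12))
  })
})

test_that("overall score adds the one applicable categorical to the delta", {
  ev <- dplyr::bind_rows(
    evidence_row("MAX", rna_h = 1.5, ph = 0.5),              # presence +1
    evidence_row("MIN", rna_h = 1, rna_m = 2, ph = 1, pm = 0) # tendency -1
  )
  rec <- score_concordance(ev)
  expect_equal(rec$overall[rec$symbol == "MAX"], 1) # +1 presence + 0 delta
  # tendency -1 with delta 1 - |(-1) - 1|/2 = 0: overall -1
  expect_equal(rec$overall[rec$symbol == "MIN"], -1)
  expect_error(overall_score(c(1, NA), c(0, NA), c(0, 0)))
})

test_that("classification boundaries and the compatible/unclear split are honoured", {
  # overall >= 1: matched (tendency +1, delta +0.75)
  m <- score_concordance(
    evidence_row(rna_h = 1.5, rna_m = 0, ph = 1, pm = 0))
  expect_equal(as.character(m$label), "matched")
  # overall exactly -1 is opposite (boundary inclusive)
  o <- score_concordance(
    evidence_row(rna_h = 1, rna_m = 2, ph = 1, pm = 0))
  expect_equal(o$overall, -1)
  expect_equal(as.character(o$label), "opposite")
  # mid score with one of three datasets direction-confirming: compatible
  c1 <- score_concordance(
    evidence_row(rna_h = 3, rna_m = 0, ph = c(0.3, NA, NA), pm = c(0.1, NA)))
  expect_true(c1$overall > -1 && c1$overall < 1)
  expect_gte(c1$n_supporting_pairs, 1)
  expect_equal(as.character(c1$label), "compatible")
  # mid score with no supporting comparison: unclear
  u <- score_concordance(evidence_row(rna_h = 3, rna_m = 0.5))
  expect_equal(as.character(u$label), "unclear")
})

test_that("summaries report counts, percentages and the summed score", {
  ev <- dplyr::bind_rows(lapply(sprintf("P%02d", 1:99), function(s) {
    evidence_row(s, rna_h = 2, rna_m = 0, ph = 2, pm = 0)
  }))
  rec <- score_concordance(ev)
  expect_true(all(rec$overall == 2))
  s <- summarize_concordance(rec)
  expect_equal(s$summed_overall, 198)
  expect_equal(s$pct_matched, 100)
  rec2 <- tibble::tibble(
    label = c("matched", "matched", "opposite", "unclear"),
    overall = c(2, 1.5, -1.5, 0)
  )
  s2 <- summarize_concordance(rec2)
  expect_equal(s2$pct_matched, 50.0)
  expect_equal(s2$pct_opposite, 25.0)
  expect_equal(s2$pct_unclear, 25.0)
  expect_equal(s2$pct_same_direction, 50.0)
  expect_equal(s2$summed_overall, 2)
  expect_error(summarize_concordance(rec2[0, ]),
               class = "plateletcc_value_error")
})

test_that("every gene gets exactly one label and percentages sum to 100", {
  withr::with_seed(53, {
    ev <- random_evidence(150)
    ev <- dplyr::filter(ev, rna_human_detected | rna_mouse_detected)
    rec <- score_concordance(ev)
    expect_false(any(is.na(rec$label)))
    expect_equal(nrow(rec), nrow(ev))
    s <- summarize_concordance(rec)
    expect_equal(s$pct_matched + s$pct_compatible + s$pct_opposite +
                   s$pct_unclear, 100, tolerance = 0.21)
  })
})

test_that("overall scores stay within [-2, 2] under fuzzing", {
  withr::with_seed(67, {
    ev <- random_evidence(300)
    rec <- score_concordance(ev)
    expect_true(all(rec$overall >= -2 & rec$overall <= 2))
    expect_true(all(rec$score_delta >= -1 & rec$score_delta <= 1))
  })
})

test_that("swapping the species flips deltas but preserves scores and labels", {
  withr::with_seed(71, {
    ev <- random_evidence(120)
    rec <- score_concordance(ev)
    swapped <- score_concordance(swap_species_evidence(ev))
    expect_equal(abs(swapped$overall), abs(rec$overall))
    expect_equal(swapped$delta_rna, -rec$delta_rna)
    expect_equal(swapped$delta_prot, -rec$delta_prot)
    expect_equal(table(swapped$label)[["matched"]],
                 table(rec$label)[["matched"]])
    expect_equal(table(swapped$label)[["opposite"]],
                 table(rec$label)[["opposite"]])
  })
})

test_that("the RNA-difference screen admits exclusivity and strong mutual differences", {
  ev <- dplyr::bind_rows(
    evidence_row("EXCL", rna_h = 0.2),
    evidence_row("BIG", rna_h = 2, rna_m = 0),
    evidence_row("SMALL", rna_h = 0.5, rna_m = 0),
    evidence_row("NONE", rna_h = 1, rna_m = 1)
  )
  sel <- select_rna_differences(ev, min_abs_log2 = 1)
  expect_setequal(sel$symbol, c("EXCL", "BIG"))
})
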