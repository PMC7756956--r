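test_that("delta RPKM is human minus mouse", {
  expect_equal(delta_rpkm(150, 20), 130)
  expect_equal(delta_rpkm(0, 0), 0)
  expect_equal(delta_rpkm(20, 150), -130)
  expect_error(delta_rpkm(-1, 0))
})

ev_tbl <- function(h, m, orth = TRUE) {
  tibble::tibble(id = sprintf("G%02d", seq_along(h)),
                 human_rpkm = h, mouse_rpkm = m, has_ortholog = orth)
}

test_that("difference filter categories follow the three clear-difference rules", {
  out <- passes_difference_filter(ev_tbl(
    h = c(150, 12, 50, 101, 0.5),
    m = c(20, 0.2, 40, 0.5, 12),
    orth = c(TRUE, TRUE, TRUE, TRUE, TRUE)
  ))
  expect_equal(as.character(out$filter_category),
               c("kept_delta",      # |delta| 130 > 100
                 "kept_exclusive",  # 12 > 10 vs 0.2 <= 1
                 "dropped",         # 50 vs 40
                 "kept_exclusive",  # exclusivity precedes the delta rule
                 "kept_exclusive")) # mouse side exclusive
  # non-ortholog genes are kept with the highest reporting precedence
  no <- passes_difference_filter(ev_tbl(150, 20, orth = FALSE))
  expect_equal(as.character(no$filter_category), "kept_non_ortholog")
})

test_that("boundary cases use strict inequalities", {
  out <- passes_difference_filter(ev_tbl(
    h = c(100.0, 10.0, 110),
    m = c(0, 0, 10)
  ))
  # delta exactly 100 fails the > 100 rule but 100 > 10 vs 0 is exclusive
  expect_equal(as.character(out$filter_category)[1], "kept_exclusive")
  # 10 RPKM is not strictly above the exclusivity threshold
  expect_equal(as.character(out$filter_category)[2], "dropped")
  # delta exactly 100 is not strictly above it, and 10 RPKM in mouse is
  # detected, so neither rule fires
  expect_equal(as.character(out$filter_category)[3], "dropped")
})

test_that("filter thresholds are monotone (property)", {
  withr::with_seed(83, {
    ev <- ev_tbl(h = runif(200, 0, 300), m = runif(200, 0, 300))
    base <- passes_difference_filter(ev, filter_thresholds(delta_rpkm_min = 100))
    tighter <- passes_difference_filter(ev, filter_thresholds(delta_rpkm_min = 150))
    # raising delta_rpkm_min never adds a kept_delta node
    expect_true(all(which(tighter$filter_category == "kept_delta") %in%
                      which(base$filter_category == "kept_delta")))
    lo <- passes_difference_filter(
      ev, filter_thresholds(detection_limit_rpkm = 0.5))
    # lowering the detection limit never removes a kept_exclusive node
    expect_true(all(which(lo$filter_category == "kept_exclusive") %in%
                      which(base$filter_category %in%
                              c("kept_exclusive", "kept_non_ortholog"))))
  })
  expect_error(filter_thresholds(delta_rpkm_min = 5),
               class = "plateletcc_config_error")
})

test_that("connectors require at least two retained neighbours in a single pass", {
  # path A - x - B: x bridges two retained nodes
  net1 <- cc_network(tibble::tibble(id = c("A", "X", "B", "Y")),
                     tibble::tibble(from = c("A", "X", "A"),
                                    to = c("X", "B", "Y")))
  expect_equal(add_connectors(net1, c("A", "B")), "X")
  # pendant Y touches only one retained node
  expect_false("Y" %in% add_connectors(net1, c("A", "B")))
  # chain A - x - y - B: single pass adds neither
  net2 <- cc_network(tibble::tibble(id = c("A", "X", "Y", "B")),
                     tibble::tibble(from = c("A", "X", "Y"),
                                    to = c("X", "Y", "B")))
  expect_equal(length(add_connectors(net2, c("A", "B"))), 0)
})

test_that("every added connector has at least two retained neighbours (soundness)", {
  withr::with_seed(97, {
    for (i in 1:5) {
      net <- random_network(40, p = 0.08)
      retained <- sample(net$nodes$id, 12)
      conn <- add_connectors(net, retained)
      for (cn in conn) {
        nb <- unique(c(net$edges$to[net$edges$from == cn],
                       net$edges$from[net$edges$to == cn]))
        expect_gte(length(intersect(nb, retained)), 2)
      }
    }
  })
})

test_that("attribute assignment encodes fill, border, size and shape", {
  net <- cc_network(
    tibble::tibble(
      id = c("BDNF", "TLN1", "MOUSE:GNG12", "ADP", "DEAD"),
      node_kind = c("protein", "protein", "protein", "second_messenger",
                    "protein"),
      species_presence = c("human_only", "both", "mouse_only", "both", "both"),
      ortholog_status = c("human_specific", "ortholog_pair", "mouse_specific",
                          NA, "ortholog_pair"),
      is_cc = FALSE
    ),
    tibble::tibble(from = c("BDNF", "ADP"), to = c("TLN1", "TLN1"),
                   species_provenance = c("human", "both"),
                   confidence = 1, is_cc_edge = c(FALSE, TRUE))
  )
  expr <- tibble::tibble(
    id = c("BDNF", "TLN1", "MOUSE:GNG12", "DEAD"),
    human_rpkm = c(15, 20, 0, 0.5),
    mouse_rpkm = c(0, 150, 40, 0.2)
  )
  at <- assign_attributes(net, expr)
  nd <- function(id) at$nodes[at$nodes$id == id, ]
  # non-ortholog human gene: genome-only fill, rectangle shape
  expect_equal(nd("BDNF")$fill_category, "human_genome_only")
  expect_equal(nd("BDNF")$shape, "rectangle")
  # ortholog with delta -130: border higher_mouse, size 130
  expect_equal(nd("TLN1")$border_category, "higher_mouse")
  expect_equal(nd("TLN1")$size_value, 130)
  expect_equal(nd("TLN1")$shape, "ellipse")
  # second messengers and genes unexpressed in both species are grey
  expect_equal(nd("ADP")$fill_category, "not_expressed_or_messenger")
  expect_equal(nd("DEAD")$fill_category, "not_expressed_or_messenger")
  # edge categories: provenance, with CC edges set apart
  expect_setequal(at$edges$edge_category, c("human", "cc"))
  # totality: one fill and one border per node
  expect_false(any(is.na(at$nodes$fill_category)))
  expect_false(any(is.na(at$nodes$border_category)))
})

test_that("difference-network filtering retains kept nodes, connectors, CC and messengers", {
  withr::with_seed(13, {
    b <- generate_bundle(simulation_config(n_genes = 120, seed = 2))
    net <- build_combined_network(
      high_confidence_filter(b$interactions$human),
      high_confidence_filter(b$interactions$mouse),
      b$orthologs, b$second_messengers,
      cc_nodes = b$cc_seeds, cc_edges = b$cc_edges
    )
    expr <- dplyr::full_join(
      tibble::tibble(id = b$expression$human$symbol,
                     human_rpkm = b$expression$human$rpkm),
      tibble::tibble(
        id = plateletcc:::map_to_combined(b$expression$mouse$symbol,
                                          b$orthologs, "mouse"),
        mouse_rpkm = b$expression$mouse$rpkm),
      by = "id")
    fl <- filter_difference_network(net, expr)
    ids <- fl$network$nodes$id
    kept <- fl$categories$id[fl$categories$filter_category != "dropped"]
    expect_true(all(kept %in% ids))
    expect_true(all(fl$connectors %in% ids))
    expect_true(all(net$nodes$id[net$nodes$is_cc] %in% ids))
    expect_true(all(b$second_messengers$id %in% ids))
    # dropped, non-connector, non-CC nodes are gone
    gone <- setdiff(net$nodes$id, ids)
    expect_true(all(fl$categories$filter_category[
      fl$categories$id %in% gone] == "dropped"))
  })
})
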