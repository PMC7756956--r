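test_that("interolog posterior reproduces the closed-form Bayes expression", {
  # uninformative evidence returns the prior
  expect_equal(interolog_posterior(rep(1, 10), prior = 0.5), 0.5)
  # combined likelihood ratio 199 at prior 0.5: 199/200
  expect_equal(interolog_posterior(c(199), prior = 0.5), 0.995)
  # an impossible feature annihilates the posterior
  expect_equal(interolog_posterior(c(3, 0, 7), prior = 0.9), 0)
  expect_error(interolog_posterior(1, prior = 1),
               class = "plateletcc_config_error")
  expect_error(interolog_posterior(-1), class = "plateletcc_value_error")
})

test_that("posterior matches an explicit product oracle and is monotone (property)", {
  withr::with_seed(7, {
    for (i in 1:50) {
      k <- sample(1:10, 1)
      ratios <- rlnorm(k, 0, 1)
      p <- runif(1, 0.05, 0.95)
      L <- 1
      for (r in ratios) L <- L * r # explicit product oracle
      expect_equal(interolog_posterior(ratios, p), L * p / (L * p + 1 - p),
                   tolerance = 1e-12)
      # raising any one ratio never lowers the posterior
      j <- sample(k, 1)
      up <- ratios; up[j] <- up[j] * runif(1, 1, 5)
      expect_gte(interolog_posterior(up, p), interolog_posterior(ratios, p))
    }
    # rowwise input agrees with elementwise calls
    m <- matrix(rlnorm(30), nrow = 10)
    expect_equal(interolog_posterior(m, 0.3),
                 apply(m, 1, interolog_posterior, prior = 0.3))
  })
})

test_that("high-confidence filter is strict at the threshold", {
  edges <- tibble::tibble(a = c("A", "B", "C"), b = c("X", "Y", "Z"),
                          confidence = c(0.995, 0.99, 0.5))
  expect_equal(nrow(high_confidence_filter(edges, 0.99)), 1)
  expect_equal(nrow(high_confidence_filter(edges, 0)), 3)
  expect_equal(nrow(high_confidence_filter(edges[0, ], 0.99)), 0)
})

simple_orthologs <- function() {
  as_ortholog_map(tibble::tibble(
    human_symbol = c("TLN1", "SRC"), mouse_symbol = c("Tln1", "Src"),
    group_id = 1:2, score = 1
  ))
}

test_that("ortholog pairs collapse to one combined edge with provenance both", {
  net <- build_combined_network(
    human_edges = tibble::tibble(a = "TLN1", b = "SRC", confidence = 1),
    mouse_edges = tibble::tibble(a = "Tln1", b = "Src", confidence = 1),
    orthologs = simple_orthologs()
  )
  prot <- net$nodes[net$nodes$node_kind == "protein", ]
  expect_setequal(prot$id, c("TLN1", "SRC"))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$species_provenance, "both")
  expect_true(all(prot$ortholog_status == "ortholog_pair"))
  expect_true(all(prot$species_presence == "both"))
})

test_that("species-specific proteins are flagged and keep single-species provenance", {
  net <- build_combined_network(
    human_edges = tibble::tibble(a = c("BDNF", "TLN1"), b = c("SRC", "SRC"),
                                 confidence = 1),
    mouse_edges = tibble::tibble(a = "Gng12", b = "Src", confidence = 1),
    orthologs = simple_orthologs()
  )
  bdnf <- net$nodes[net$nodes$id == "BDNF", ]
  expect_equal(bdnf$ortholog_status, "human_specific")
  expect_equal(bdnf$species_presence, "human_only")
  e <- net$edges[net$edges$from == "BDNF" | net$edges$to == "BDNF", ]
  expect_equal(e$species_provenance, "human")
  # non-ortholog mouse gene gets a species-prefixed combined id
  expect_true("MOUSE:GNG12" %in% net$nodes$id)
  g <- net$nodes[net$nodes$id == "MOUSE:GNG12", ]
  expect_equal(g$ortholog_status, "mouse_specific")
})

test_that("disjoint inputs with an empty ortholog map keep all nodes distinct", {
  empty <- as_ortholog_map(tibble::tibble(
    human_symbol = character(), mouse_symbol = character(),
    group_id = integer(), score = numeric()))
  net <- build_combined_network(
    human_edges = tibble::tibble(a = c("HA", "HB"), b = c("HB", "HC")),
    mouse_edges = tibble::tibble(a = "Ma", b = "Mb"),
    orthologs = empty
  )
  prot <- net$nodes[net$nodes$node_kind == "protein", ]
  expect_equal(nrow(prot), 3 + 2)
})

test_that("central-cascade edges are flagged and unknown CC nodes rejected", {
  net <- build_combined_network(
    human_edges = tibble::tibble(a = "TLN1", b = "SRC"),
    mouse_edges = tibble::tibble(a = "Tln1", b = "Src"),
    orthologs = simple_orthologs(),
    cc_nodes = c("TLN1", "SRC"),
    cc_edges = tibble::tibble(a = "TLN1", b = "SRC")
  )
  expect_true(all(net$edges$is_cc_edge[net$edges$from == "SRC"]))
  expect_error(build_combined_network(
    human_edges = tibble::tibble(a = "TLN1", b = "SRC"),
    mouse_edges = tibble::tibble(a = "Tln1", b = "Src"),
    orthologs = simple_orthologs(),
    cc_edges = tibble::tibble(a = "TLN1", b = "GHOST")
  ), class = "plateletcc_consistency_error")
})

test_that("derived species networks partition the combined edges", {
  net <- build_combined_network(
    human_edges = tibble::tibble(a = c("TLN1", "BDNF"), b = c("SRC", "SRC")),
    mouse_edges = tibble::tibble(a = c("Tln1", "Gng12"), b = c("Src", "Src")),
    orthologs = simple_orthologs()
  )
  h <- derive_species_network(net, "human")
  m <- derive_species_network(net, "mouse")
  expect_true("TLN1" %in% h$nodes$id && "SRC" %in% h$nodes$id)
  key <- function(e) paste(e$from, e$to)
  expect_setequal(union(key(h$edges), key(m$edges)), key(net$edges))
  both <- net$edges[net$edges$species_provenance == "both", ]
  expect_true(all(key(both) %in% key(h$edges)))
  expect_true(all(key(both) %in% key(m$edges)))
  # combined with only mouse-specific proteins derives an empty human network
  empty_h <- derive_species_network(build_combined_network(
    human_edges = tibble::tibble(a = character(), b = character()),
    mouse_edges = tibble::tibble(a = "Xa", b = "Xb"),
    orthologs = simple_orthologs()
  ), "human")
  expect_equal(sum(empty_h$nodes$node_kind == "protein"), 0)
  expect_equal(nrow(empty_h$edges), 0)
})

test_that("derived/combined partition holds on random synthetic networks", {
  withr::with_seed(23, {
    for (i in 1:5) {
      b <- generate_bundle(simulation_config(n_genes = 80, seed = i))
      net <- build_combined_network(b$interactions$human,
                                    b$interactions$mouse, b$orthologs)
      h <- derive_species_network(net, "human")
      m <- derive_species_network(net, "mouse")
      key <- function(e) paste(e$from, e$to)
      expect_setequal(union(key(h$edges), key(m$edges)), key(net$edges))
    }
  })
})

test_that("network statistics match hand-computed values", {
  tri <- cc_network(tibble::tibble(id = c("A", "B", "C")),
                    tibble::tibble(from = c("A", "A", "B"),
                                   to = c("B", "C", "C")))
  expect_equal(network_stats(tri)$mean_degree, 2)
  duo <- cc_network(tibble::tibble(id = c("A", "B")),
                    tibble::tibble(from = "A", to = "B"))
  expect_equal(network_stats(duo)$mean_degree, 1)
  # star with 10 leaves: nearest-rank 90th percentile over 11 degrees is 1
  star <- cc_network(
    tibble::tibble(id = c("HUB", sprintf("L%02d", 1:10))),
    tibble::tibble(from = "HUB", to = sprintf("L%02d", 1:10))
  )
  expect_equal(network_stats(star)$degree_p90, 1)
  empty <- cc_network(tibble::tibble(id = character()),
                      tibble::tibble(from = character(), to = character()))
  st <- network_stats(empty)
  expect_equal(st$n_nodes, 0)
  expect_equal(st$mean_degree, 0)
})

test_that("high-binder exclusion removes hubs but keeps leaves, CC and messengers", {
  star <- cc_network(
    tibble::tibble(id = c("HUB", sprintf("L%02d", 1:10))),
    tibble::tibble(from = "HUB", to = sprintf("L%02d", 1:10))
  )
  out <- exclude_high_binders(star, 90)
  expect_false("HUB" %in% out$nodes$id)
  expect_equal(nrow(out$nodes), 10) # leaves survive as isolates
  expect_equal(nrow(out$edges), 0)
  # regular graph: no degree exceeds its own percentile
  ring <- cc_network(
    tibble::tibble(id = sprintf("R%d", 1:6)),
    tibble::tibble(from = sprintf("R%d", 1:6),
                   to = sprintf("R%d", c(2:6, 1)))
  )
  expect_equal(nrow(exclude_high_binders(ring, 90)$nodes), 6)
  # CC-member hubs are exempt
  star_cc <- star
  star_cc$nodes$is_cc <- star_cc$nodes$id == "HUB"
  expect_true("HUB" %in% exclude_high_binders(star_cc, 90)$nodes$id)
  empty <- cc_network(tibble::tibble(id = character()),
                      tibble::tibble(from = character(), to = character()))
  expect_equal(nrow(exclude_high_binders(empty, 90)$nodes), 0)
})

test_that("high-binder exclusion never raises degrees and is idempotent (property)", {
  withr::with_seed(31, {
    for (i in 1:8) {
      net <- random_network(30, p = 0.1)
      deg0 <- igraph::degree(as_igraph(net))
      out <- exclude_high_binders(net, 90)
      deg1 <- igraph::degree(as_igraph(out))
      expect_true(all(deg1[names(deg1)] <= deg0[names(deg1)]))
      # idempotence at the same threshold degree: after removal no surviving
      # protein exceeds the original cut, so a second pass at that cut is a
      # no-op
      cut <- plateletcc:::nearest_rank_percentile(deg0, 90)
      expect_true(all(deg1 <= cut))
    }
  })
})
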