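test_that("network construction enforces bipartite structure and set semantics", {
  net <- ct_network_fixture()
  expect_equal(length(net$left_nodes), 41)
  expect_equal(length(net$right_nodes), 94)
  expect_equal(nrow(net$edges), 367)

  # empty edge list, no declared nodes
  e0 <- build_network(NULL, "compound", "target")
  expect_equal(nrow(e0$edges), 0)
  expect_equal(length(e0$left_nodes), 0)

  # duplicated edge collapses with a counted warning
  dup <- data.frame(left = c("a", "a"), right = c("x", "x"))
  expect_warning(netd <- build_network(dup, "compound", "target"), "duplicate")
  expect_equal(nrow(netd$edges), 1)
  expect_equal(netd$n_duplicates, 1)

  # same-kind endpoints are impossible in a bipartite layer
  expect_error(build_network(dup, "target", "target"), "different kinds")
})

test_that("degree report reproduces published hubs under both rules", {
  net <- ct_network_fixture()
  strict <- degree_report(net, hub_threshold = 10, strict = TRUE)
  expect_equal(length(strict$right$hubs), 8)
  expect_equal(strict$right$max_node, "P03372") # ESR1
  expect_equal(strict$right$max_degree, 34)
  expect_equal(strict$hub_rule, "degree > 10")

  # the 8 compound hubs need the inclusive rule (two have degree exactly 10)
  incl <- degree_report(net, hub_threshold = 10, strict = FALSE)
  expect_equal(length(incl$left$hubs), 8)
  expect_equal(length(strict$left$hubs), 6)
  expect_equal(incl$left$max_node, "mol01") # quercetin
  expect_equal(incl$left$max_degree, 73)
  expect_equal(sum(incl$left$hubs == 10), 2)

  # star graph K(1,5)
  star <- build_network(data.frame(left = "hub", right = paste0("l", 1:5)),
                        "compound", "target")
  sr <- degree_report(star, 3, strict = TRUE)
  expect_equal(sr$left$max_degree, 5)
  expect_true(all(bipartite_degree(star, "right") == 1))

  # hub query on an empty side yields an empty list, not an error
  er <- degree_report(build_network(NULL, "compound", "target"), 10, TRUE)
  expect_length(er$left$hubs, 0)
})

test_that("degree matches a brute-force incidence count on random graphs", {
  set.seed(17)
  for (trial in 1:60) {
    nl <- sample(1:25, 1); nr <- sample(1:25, 1)
    ln <- sprintf("L%02d", 1:nl); rn <- sprintf("R%02d", 1:nr)
    ne <- sample(0:(nl * nr), 1)
    all_pairs <- expand.grid(left = ln, right = rn, stringsAsFactors = FALSE)
    edges <- all_pairs[sample(nrow(all_pairs), ne), , drop = FALSE]
    net <- build_network(edges, "compound", "target",
                         left_nodes = ln, right_nodes = rn)
    deg <- bipartite_degree(net, "left")
    brute <- vapply(ln, function(v) sum(edges$left == v), integer(1))
    expect_equal(unname(deg), unname(brute))
    # handshake identity
    expect_equal(sum(deg), nrow(net$edges))
    expect_equal(sum(bipartite_degree(net, "right")), nrow(net$edges))
    # independent cross-check against igraph's degree on the same graph
    if (nrow(net$edges) > 0) {
      ig <- as_igraph(net)
      igd <- igraph::degree(ig)[ln]
      expect_equal(unname(igd), unname(brute))
    }
  }
})

test_that("module merge is additive and skips unknown targets with a warning", {
  ct <- build_network(data.frame(left = c("c1", "c1", "c2"),
                                 right = c("P1", "P2", "P2")),
                      "compound", "target")
  ann <- data.frame(subject_id = c("P1", "P2", "P2"),
                    term_id = c("immune regulation", "immune regulation",
                                "metabolic regulation"),
                    stringsAsFactors = FALSE)
  mod <- merge_module_network(ct, ann)
  expect_s3_class(mod, "module_network")
  expect_equal(nrow(mod$nodes), 2 + 2 + 2)   # compounds + targets + modules
  expect_equal(nrow(mod$edges), 3 + 3)       # ct edges + annotation edges
  # one target in two modules contributes two module edges
  expect_equal(sum(mod$edges$kind == "tm" & mod$edges$from == "P2"), 2)

  # empty annotation returns the C-T network unchanged
  expect_identical(merge_module_network(ct, ann[0, ]), ct)

  # unknown target is skipped and counted
  ann2 <- rbind(ann, data.frame(subject_id = "P99", term_id = "other function"))
  expect_warning(mod2 <- merge_module_network(ct, ann2), "unknown")
  expect_equal(mod2$n_skipped, 1)
  expect_equal(nrow(mod2$edges), nrow(mod$edges))
})

test_that("graph export writes sif/tsv line counts and graphml round-trips", {
  net <- ct_network_fixture()
  sif <- withr::local_tempfile(fileext = ".sif")
  export_graph(net, sif, "sif")
  expect_length(readLines(sif), 367)
  expect_true(all(grepl("\tct\t", readLines(sif), fixed = TRUE)))

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_graph(net, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 41 + 94)
  expect_equal(igraph::ecount(g), 367)
  expect_setequal(unique(igraph::V(g)$type), c("compound", "target"))
  # degree report identical after the round trip
  expect_equal(sort(unname(igraph::degree(g)[net$left_nodes])),
               sort(unname(bipartite_degree(net, "left"))))

  # empty network still yields a valid document
  gml0 <- withr::local_tempfile(fileext = ".graphml")
  export_graph(build_network(NULL, "compound", "target"), gml0, "graphml")
  g0 <- igraph::read_graph(gml0, format = "graphml")
  expect_equal(igraph::vcount(g0), 0)

  expect_error(export_graph(net, withr::local_tempfile(), "gexf"),
               "supported formats")
})

test_that("Gale-Ryser feasibility and greedy realization are exact", {
  expect_true(gale_ryser_feasible(c(2, 1), c(1, 1, 1)))
  expect_false(gale_ryser_feasible(c(2, 1), c(1, 1)))    # sums differ
  expect_false(gale_ryser_feasible(c(3), c(1, 1)))       # max degree too big
  e <- realize_bipartite(c(a = 2, b = 1), c(x = 1, y = 1, z = 1))
  expect_equal(nrow(e), 3)

  # realized degrees reproduce the requested sequences on random instances
  set.seed(23)
  for (trial in 1:40) {
    nl <- sample(2:12, 1); nr <- sample(2:12, 1)
    # build a random bipartite graph first, then realize its degree sequence
    m <- matrix(runif(nl * nr) < 0.4, nl, nr)
    ld <- setNames(rowSums(m), sprintf("L%d", 1:nl))
    rd <- setNames(colSums(m), sprintf("R%d", 1:nr))
    expect_true(gale_ryser_feasible(ld, rd))
    e <- realize_bipartite(ld, rd)
    got_l <- table(factor(e$left, levels = names(ld)))
    got_r <- table(factor(e$right, levels = names(rd)))
    expect_equal(unname(as.integer(got_l)), unname(as.integer(ld)))
    expect_equal(unname(as.integer(got_r)), unname(as.integer(rd)))
    # simple graph: no repeated edge
    expect_false(anyDuplicated(paste(e$left, e$right)) > 0)
  }
})

test_that("packaged edge fixture equals the in-code realization of the tables", {
  t1 <- table1_fixture(); t2 <- table2_fixture()
  regen <- realize_bipartite(setNames(as.integer(t1$degree), t1$ingredient_id),
                             setNames(as.integer(t2$degree), t2$uniprot_ac))
  shipped <- ct_edges_fixture()
  expect_equal(regen$left, shipped$compound_id)
  expect_equal(regen$right, shipped$target_uniprot)
})
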