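test_that("bipartite construction counts nodes as compounds + targets", {
  net <- build_bipartite_network(sprintf("c%03d", 1:118), sprintf("t%03d", 1:141))
  expect_equal(nrow(net$nodes), 259)
  net2 <- build_bipartite_network(sprintf("c%02d", 1:11), sprintf("t%03d", 1:141))
  expect_equal(nrow(net2$nodes), 152)
})

test_that("construction validates ids and collapses duplicate edges", {
  expect_error(
    build_bipartite_network("c1", "t1", data.frame(compound = "c1", target = "tX")),
    class = "netpharm_validation_error")
  expect_error(
    build_bipartite_network(c("c1", "c1"), "t1"),
    class = "netpharm_validation_error")
  expect_error(
    build_bipartite_network("x", c("x", "t1")),
    class = "netpharm_validation_error")
  dup <- build_bipartite_network(
    "c1", "t1", data.frame(compound = c("c1", "c1"), target = c("t1", "t1")))
  expect_equal(nrow(dup$edges), 1)
  expect_equal(dup$n_duplicate_edges, 1)
})

test_that("degree map covers every node and matches a hand count", {
  deg <- degree_map(toy_network())
  expect_equal(
    setNames(deg$degree, deg$id),
    c(c1 = 2L, c2 = 1L, t1 = 1L, t2 = 2L, t3 = 0L))
  empty <- build_bipartite_network(character(0), character(0))
  expect_equal(nrow(degree_map(empty)), 0)
})

test_that("degree map agrees with brute force and igraph on random graphs", {
  for (s in 1:100) {
    net <- random_bipartite(20, 25, 60, seed = s)
    deg <- degree_map(net)
    expect_equal(setNames(deg$degree, deg$id), brute_force_degrees(net))
    # independent cross-check against igraph's degree
    g <- igraph::graph_from_data_frame(
      net$edges, directed = FALSE,
      vertices = net$nodes$id)
    ig <- igraph::degree(g)[deg$id]
    expect_equal(unname(ig), unname(deg$degree))
  }
})

test_that("handshake identity holds on constructed networks", {
  for (s in 1:10) {
    net <- random_bipartite(30, 40, 100, seed = 100 + s)
    deg <- degree_map(net)
    expect_equal(sum(deg$degree), 2 * nrow(net$edges))
  }
})

test_that("hub extraction uses an inclusive degree boundary", {
  # t1 has degree exactly 3
  net <- build_bipartite_network(
    c("c1", "c2", "c3"), c("t1", "t2"),
    data.frame(compound = c("c1", "c2", "c3", "c1"),
               target = c("t1", "t1", "t1", "t2")))
  expect_equal(hub_nodes(net, "target", min_degree = 3), "t1")
  expect_equal(hub_nodes(net, "target", min_degree = 4), character(0))
  expect_equal(hub_nodes(net, "target", min_degree = 1), c("t1", "t2"))
  expect_error(hub_nodes(net, "disease"), class = "netpharm_validation_error")
})

test_that("hub extraction is monotone in the threshold", {
  net <- random_bipartite(40, 30, 200, seed = 5)
  prev <- hub_nodes(net, "target", 0)
  for (k in 1:15) {
    cur <- hub_nodes(net, "target", k)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("role fractions are full precision with guarded denominators", {
  net <- build_bipartite_network(sprintf("c%03d", 1:118), sprintf("t%03d", 1:141))
  expect_equal(role_fraction(net, sprintf("t%03d", 1:46)), 100 * 46 / 141)
  expect_equal(round(role_fraction(net, sprintf("t%03d", 1:46))), 33)
  expect_equal(role_fraction(net, sprintf("t%03d", 1:141)), 100)
  expect_equal(role_fraction(net, character(0)), 0)
  empty <- build_bipartite_network("c1", character(0))
  expect_error(role_fraction(empty, character(0), "target"),
               class = "netpharm_undefined_ratio_error")
})

test_that("target intersection is a sorted set operation", {
  expect_equal(intersect_targets(c("a", "b", "c"), c("c", "b", "d")), c("b", "c"))
  expect_equal(intersect_targets(c("a", "b"), c("x", "y")), character(0))
  # planted overlap of 50 ids between a 141-id candidate panel and a disease set
  candidates <- sprintf("t%03d", 1:141)
  disease <- c(sprintf("t%03d", 1:50), sprintf("d%03d", 1:80))
  expect_length(intersect_targets(candidates, disease), 50)
})

test_that("target-disease network is tri-layer with multi-group diseases", {
  sim <- simulate_target_disease(n_targets = 46, n_diseases = 139, n_groups = 24,
                                 seed = 2)
  tdn <- build_target_disease_network(sim$pairs, sim$groups)
  expect_equal(nrow(tdn$nodes), 46 + 139 + 24)
  expect_true(all(tdn$edges$type %in% c("td", "dg")))
  # one disease in two groups yields two disease-group edges
  two <- build_target_disease_network(
    data.frame(target = "ABL1", disease = "CML"),
    data.frame(disease = c("CML", "CML"), group = c("C04", "C15")))
  expect_equal(sum(two$edges$type == "dg"), 2)
  # strict mode rejects unclassified diseases; lenient mode absorbs them
  expect_error(
    build_target_disease_network(data.frame(target = "ABL1", disease = "CML"),
                                 data.frame(disease = character(0),
                                            group = character(0))),
    class = "netpharm_validation_error")
  lenient <- build_target_disease_network(
    data.frame(target = "ABL1", disease = "CML"),
    data.frame(disease = character(0), group = character(0)), strict = FALSE)
  expect_true("unclassified" %in% lenient$nodes$id)
  empty <- build_target_disease_network(data.frame(), data.frame())
  expect_equal(nrow(empty$nodes), 0)
})

test_that("compound subnetworks keep or drop isolated targets as asked", {
  sim <- simulate_bipartite_edges(n_compounds = 118, n_targets = 141,
                                  n_hubs = 5, seed = 9)
  net <- build_bipartite_network(sim$compounds, sim$targets, sim$edges)
  sub <- subnetwork_by_compounds(net, sim$compounds[1:11],
                                 keep_isolated_targets = TRUE)
  expect_equal(nrow(sub$nodes), 152)
  expect_true(all(sub$edges$compound %in% sim$compounds[1:11]))
  # identity when keeping all compounds
  full <- subnetwork_by_compounds(net, sim$compounds)
  expect_equal(dplyr::arrange(full$edges, compound, target),
               dplyr::arrange(net$edges, compound, target))
  # empty subset without isolated targets is the empty network
  none <- subnetwork_by_compounds(net, character(0),
                                  keep_isolated_targets = FALSE)
  expect_equal(nrow(none$nodes), 0)
  expect_error(subnetwork_by_compounds(net, "nope"),
               class = "netpharm_validation_error")
})

test_that("subnetwork extraction preserves bipartiteness and handshake", {
  net <- random_bipartite(30, 25, 120, seed = 77)
  sub <- subnetwork_by_compounds(net, sprintf("c%03d", 1:10))
  roles <- setNames(sub$nodes$role, sub$nodes$id)
  expect_true(all(roles[sub$edges$compound] == "compound"))
  expect_true(all(roles[sub$edges$target] == "target"))
  deg <- degree_map(sub)
  expect_equal(sum(deg$degree), 2 * nrow(sub$edges))
})
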