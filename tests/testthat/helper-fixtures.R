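table1_path <- function() {
  system.file("extdata", "admet_candidates.csv", package = "netpharm")
}

table1 <- function() read_admet_table(table1_path())

# toy 2-compound / 3-target network with a hand-countable degree map
toy_network <- function() {
  build_bipartite_network(
    compounds = c("c1", "c2"),
    targets = c("t1", "t2", "t3"),
    edges = data.frame(compound = c("c1", "c1", "c2"),
                       target = c("t1", "t2", "t2")))
}

# brute-force degree oracle: scan every edge for every node
brute_force_degrees <- function(network) {
  ends <- c(network$edges$compound, network$edges$target)
  vapply(network$nodes$id, function(id) sum(ends == id), integer(1))
}

random_bipartite <- function(n_compounds, n_targets, n_edges, seed) {
  withr::with_seed(seed, {
    compounds <- sprintf("c%03d", seq_len(n_compounds))
    targets <- sprintf("t%03d", seq_len(n_targets))
    edges <- tibble::tibble(
      compound = sample(compounds, n_edges, replace = TRUE),
      target = sample(targets, n_edges, replace = TRUE))
    build_bipartite_network(compounds, targets, edges)
  })
}
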