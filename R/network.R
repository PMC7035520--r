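#' Build a compound-target bipartite network
#'
#' Constructs the candidate-compound / candidate-target (cC-cT) network used
#' in network-pharmacology screening: compounds and targets are nodes, and a
#' compound-target interaction is an undirected edge. Within-role edges are
#' impossible by construction; duplicate edges collapse to one (the number
#' collapsed is recorded in `$n_duplicate_edges`).
#'
#' @param compounds Character vector of compound ids (unique).
#' @param targets Character vector of target ids (unique, disjoint from
#'   `compounds`).
#' @param edges A data frame whose first two columns are compound id and
#'   target id (e.g. from [read_edges()]), or `NULL` for an edgeless network.
#' @param metadata Optional data frame of per-node annotations with an `id`
#'   column (e.g. a chemical `family` column); carried through subsetting and
#'   file round trips.
#' @return A `bipartite_network`: list with `$nodes` (tibble `id`, `role`),
#'   `$edges` (tibble `compound`, `target`), `$metadata`,
#'   `$n_duplicate_edges`.
#' @examples
#' net <- build_bipartite_network(
#'   compounds = c("c1", "c2"), targets = c("t1", "t2", "t3"),
#'   edges = data.frame(compound = c("c1", "c1", "c2"),
#'                      target   = c("t1", "t2", "t2")))
#' degree_map(net)
#' @export
build_bipartite_network <- function(compounds, targets, edges = NULL,
                                    metadata = NULL) {
  compounds <- as.character(compounds)
  targets <- as.character(targets)
  if (anyDuplicated(compounds)) abort_validation("Compound ids must be unique.")
  if (anyDuplicated(targets)) abort_validation("Target ids must be unique.")
  both <- intersect(compounds, targets)
  if (length(both) > 0) {
    abort_validation(paste0("Ids appear in both roles: ",
                            paste(utils::head(both, 5), collapse = ", "), "."))
  }
  if (is.null(edges)) {
    edges <- tibble(compound = character(0), target = character(0))
  } else {
    edges <- as_tibble(edges)
    if (ncol(edges) < 2) abort_validation("`edges` needs two columns: compound, target.")
    edges <- stats::setNames(edges[, 1:2], c("compound", "target"))
    edges$compound <- as.character(edges$compound)
    edges$target <- as.character(edges$target)
    bad_c <- setdiff(edges$compound, compounds)
    bad_t <- setdiff(edges$target, targets)
    if (length(bad_c) > 0 || length(bad_t) > 0) {
      abort_validation(paste0(
        "Edge endpoints not declared as nodes: ",
        paste(utils::head(c(bad_c, bad_t), 5), collapse = ", "), "."))
    }
  }
  n_raw <- nrow(edges)
  edges <- dplyr::distinct(edges)
  if (!is.null(metadata)) {
    metadata <- as_tibble(metadata)
    if (!"id" %in% names(metadata)) abort_validation("`metadata` must have an `id` column.")
    unknown <- setdiff(metadata$id, c(compounds, targets))
    if (length(unknown) > 0) {
      abort_validation(paste0("Metadata for undeclared nodes: ",
                              paste(utils::head(unknown, 5), collapse = ", "), "."))
    }
  }
  structure(
    list(
      nodes = tibble(id = c(compounds, targets),
                     role = rep(c("compound", "target"),
                                c(length(compounds), length(targets)))),
      edges = edges,
      metadata = metadata,
      n_duplicate_edges = n_raw - nrow(edges)
    ),
    class = "bipartite_network"
  )
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("<bipartite_network> %d nodes (%d compounds + %d targets), %d edges\n",
              nrow(x$nodes), sum(x$nodes$role == "compound"),
              sum(x$nodes$role == "target"), nrow(x$edges)))
  invisible(x)
}

role_ids <- function(network, role) {
  if (!role %in% c("compound", "target")) {
    abort_validation("`role` must be \"compound\" or \"target\".")
  }
  network$nodes$id[network$nodes$role == role]
}

#' Node degrees of a network
#'
#' Degree of a node = number of edges incident to it. Every declared node has
#' an entry, so isolated nodes appear with degree 0; the degrees always
#' satisfy the handshake identity `sum(degree) == 2 * n_edges`.
#'
#' @param network A `bipartite_network` or `target_disease_network`.
#' @return A tibble with columns `id`, `role`, `degree` in node order.
#' @export
degree_map <- function(network) {
  if (!inherits(network, c("bipartite_network", "target_disease_network"))) {
    abort_validation("`network` must be a bipartite_network or target_disease_network.")
  }
  ends <- if (inherits(network, "bipartite_network")) {
    c(network$edges$compound, network$edges$target)
  } else {
    c(network$edges$from, network$edges$to)
  }
  counts <- table(factor(ends, levels = network$nodes$id))
  dplyr::mutate(network$nodes, degree = as.integer(counts[.data$id]))
}

#' Hub nodes by degree threshold
#'
#' Returns the nodes of one role whose degree is at least `min_degree`
#' (inclusive boundary, matching the convention "hub = degree >= 10").
#'
#' @param network A `bipartite_network`.
#' @param role `"target"` (default) or `"compound"`.
#' @param min_degree Non-negative integer threshold.
#' @return Sorted character vector of hub ids.
#' @export
hub_nodes <- function(network, role = "target", min_degree = 10) {
  if (!inherits(network, "bipartite_network")) {
    abort_validation("`network` must be a bipartite_network.")
  }
  ids <- role_ids(network, role)
  if (!is.numeric(min_degree) || length(min_degree) != 1 || min_degree < 0) {
    abort_validation("`min_degree` must be a single non-negative number.")
  }
  deg <- degree_map(network)
  hubs <- deg$id[deg$role == role & deg$degree >= min_degree]
  sort(hubs)
}

#' Fraction of a role occupied by a node subset
#'
#' Percentage `100 * |subset| / |nodes of role|`, kept at full precision
#' (round only at the reporting layer).
#'
#' @param network A `bipartite_network`.
#' @param subset Character vector of node ids, all of the given role.
#' @param role `"target"` or `"compound"`.
#' @return A percentage on the 0-100 scale.
#' @export
role_fraction <- function(network, subset, role = "target") {
  ids <- role_ids(network, role)
  if (length(ids) == 0) {
    abort_undefined_ratio(sprintf("Network has no %s nodes; fraction undefined.", role))
  }
  subset <- unique(as.character(subset))
  outside <- setdiff(subset, ids)
  if (length(outside) > 0) {
    abort_validation(paste0("Subset ids not of role ", role, ": ",
                            paste(utils::head(outside, 5), collapse = ", "), "."))
  }
  percent(length(subset), length(ids))
}

#' Intersect candidate targets with a disease target set
#'
#' Deterministic (sorted) set intersection, used to map the targets of a
#' screened compound library onto disease-associated target collections.
#'
#' @param candidate_targets,disease_targets Character vectors of ids.
#' @return Sorted character vector of shared ids.
#' @export
intersect_targets <- function(candidate_targets, disease_targets) {
  sort(intersect(unique(as.character(candidate_targets)),
                 unique(as.character(disease_targets))))
}

#' Extract the subnetwork induced by a compound subset
#'
#' Keeps the chosen compounds and the edges incident to them. With
#' `keep_isolated_targets = TRUE` (default) all target nodes are retained
#' even if they lose every edge, matching the presentation where a family
#' subnetwork (e.g. the stilbenes) is drawn against the full target panel.
#'
#' @param network A `bipartite_network`.
#' @param compound_subset Character vector of compound ids to keep.
#' @param keep_isolated_targets Keep targets with no remaining edge?
#' @return A `bipartite_network`.
#' @export
subnetwork_by_compounds <- function(network, compound_subset,
                                    keep_isolated_targets = TRUE) {
  if (!inherits(network, "bipartite_network")) {
    abort_validation("`network` must be a bipartite_network.")
  }
  compound_subset <- unique(as.character(compound_subset))
  unknown <- setdiff(compound_subset, role_ids(network, "compound"))
  if (length(unknown) > 0) {
    abort_validation(paste0("Unknown compound ids: ",
                            paste(utils::head(unknown, 5), collapse = ", "), "."))
  }
  edges <- dplyr::filter(network$edges, .data$compound %in% compound_subset)
  targets <- role_ids(network, "target")
  if (!keep_isolated_targets) targets <- targets[targets %in% edges$target]
  meta <- network$metadata
  if (!is.null(meta)) {
    meta <- dplyr::filter(meta, .data$id %in% c(compound_subset, targets))
  }
  build_bipartite_network(compound_subset, targets, edges, metadata = meta)
}

#' Build a target-disease-group tri-layer network
#'
#' Connects screened targets to the diseases they are annotated with, and
#' each disease to one or more disease groups (MeSH-style category codes such
#' as C04); a disease may belong to several groups.
#'
#' @param target_disease_pairs Data frame whose first two columns are target
#'   id and disease id.
#' @param disease_groups Data frame whose first two columns are disease id
#'   and group code. Every disease in `target_disease_pairs` must have at
#'   least one group in strict mode.
#' @param strict If `TRUE` (default), a disease without a group is an error;
#'   if `FALSE` it is assigned the group `"unclassified"`.
#' @return A `target_disease_network`: list with `$nodes` (tibble `id`,
#'   `role` in target/disease/disease_group) and `$edges` (tibble `from`,
#'   `to`, `type` in td/dg).
#' @export
build_target_disease_network <- function(target_disease_pairs, disease_groups,
                                         strict = TRUE) {
  td <- as_tibble(target_disease_pairs)
  if (nrow(td) > 0 && ncol(td) < 2) {
    abort_validation("`target_disease_pairs` needs two columns: target, disease.")
  }
  if (nrow(td) == 0) {
    td <- tibble(target = character(0), disease = character(0))
  } else {
    td <- stats::setNames(td[, 1:2], c("target", "disease"))
    td$target <- as.character(td$target)
    td$disease <- as.character(td$disease)
  }
  dg <- as_tibble(disease_groups)
  if (nrow(dg) == 0) {
    dg <- tibble(disease = character(0), group = character(0))
  } else {
    if (ncol(dg) < 2) abort_validation("`disease_groups` needs two columns: disease, group.")
    dg <- stats::setNames(dg[, 1:2], c("disease", "group"))
    dg$disease <- as.character(dg$disease)
    dg$group <- as.character(dg$group)
  }
  td <- dplyr::distinct(td)
  dg <- dplyr::distinct(dg)
  orphan <- setdiff(td$disease, dg$disease)
  if (length(orphan) > 0) {
    if (strict) {
      abort_validation(paste0("Diseases without a group: ",
                              paste(utils::head(orphan, 5), collapse = ", "), "."))
    }
    dg <- dplyr::bind_rows(dg, tibble(disease = orphan, group = "unclassified"))
  }
  dg <- dplyr::filter(dg, .data$disease %in% td$disease)
  targets <- sort(unique(td$target))
  diseases <- sort(unique(td$disease))
  groups <- sort(unique(dg$group))
  clash <- c(intersect(targets, diseases), intersect(diseases, groups),
             intersect(targets, groups))
  if (length(clash) > 0) {
    abort_validation(paste0("Ids appear in more than one role: ",
                            paste(utils::head(clash, 5), collapse = ", "), "."))
  }
  edges <- dplyr::bind_rows(
    tibble(from = td$target, to = td$disease, type = "td"),
    tibble(from = dg$disease, to = dg$group, type = "dg")
  )
  structure(
    list(
      nodes = tibble(
        id = c(targets, diseases, groups),
        role = rep(c("target", "disease", "disease_group"),
                   c(length(targets), length(diseases), length(groups)))),
      edges = edges
    ),
    class = "target_disease_network"
  )
}

#' @export
print.target_disease_network <- function(x, ...) {
  cat(sprintf(
    "<target_disease_network> %d targets, %d diseases, %d groups; %d td + %d dg edges\n",
    sum(x$nodes$role == "target"), sum(x$nodes$role == "disease"),
    sum(x$nodes$role == "disease_group"),
    sum(x$edges$type == "td"), sum(x$edges$type == "dg")))
  invisible(x)
}
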