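delim_for <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

read_delim_quiet <- function(path, delim) {
  if (!file.exists(path)) abort_validation(sprintf("File not found: %s", path))
  readr::read_delim(path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE, show_col_types = FALSE)
}

parse_numeric_cols <- function(tbl, cols, path) {
  for (cl in cols) {
    raw <- normalize_minus(tbl[[cl]])
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(val))
    if (length(bad) > 0) {
      abort_validation(sprintf(
        "Non-numeric value \"%s\" in column `%s`, row %d of %s.",
        raw[bad[1]], cl, bad[1], path))
    }
    tbl[[cl]] <- val
  }
  tbl
}

#' Read a signed-probability ADMET table
#'
#' Reads a CSV/TSV of signed ADMET class probabilities with header columns
#' `compound_id, herb, smiles, hia, caco2, cyp_1a2, cyp_2c9, cyp_2d6,
#' cyp_2c19, cyp_3a4` (CYP columns in report order). Unicode minus signs
#' (U+2212) are normalized to ASCII on read. A bundled fixture of 32
#' screened candidate compounds ships with the package (see the example).
#'
#' @param path File path; extension `.tsv`/`.txt` switches to tab delimiter.
#' @return A tibble with the columns above (plus any extras, e.g. a printed
#'   `score` column).
#' @examples
#' tbl <- read_admet_table(system.file("extdata", "admet_candidates.csv",
#'                                     package = "netpharm"))
#' nrow(tbl)
#' @export
read_admet_table <- function(path) {
  tbl <- read_delim_quiet(path, delim_for(path))
  missing <- setdiff(admet_required_cols(), names(tbl))
  if (length(missing) > 0) {
    abort_validation(paste0("ADMET table ", path, " is missing column(s): ",
                            paste(missing, collapse = ", "), "."))
  }
  num_cols <- intersect(c("hia", "caco2", cyp_cols(), "score"), names(tbl))
  parse_numeric_cols(tbl, num_cols, path)
}

#' Write an ADMET (or screened) compound table
#'
#' @param tbl A compound tibble (e.g. from [tidy()] on a `screen_result`).
#' @param path Output CSV/TSV path.
#' @param digits Decimal places for the score column in the written file
#'   (default 8, matching the conventional report precision); other numeric
#'   columns are written at full precision.
#' @return `path`, invisibly.
#' @export
write_admet_table <- function(tbl, path, digits = 8) {
  tbl <- as_tibble(tbl)
  if ("score" %in% names(tbl)) tbl$score <- round(tbl$score, digits)
  readr::write_delim(tbl, path, delim = delim_for(path), na = "")
  invisible(path)
}

#' Read a two-column compound-target edge list
#'
#' Expects a header line naming the two roles (e.g. `compound,target`);
#' the first column is taken as the compound side, the second as the target
#' side.
#'
#' @param path CSV/TSV path.
#' @return A tibble with columns `compound`, `target`.
#' @export
read_edges <- function(path) {
  tbl <- read_delim_quiet(path, delim_for(path))
  if (ncol(tbl) < 2) {
    abort_validation(sprintf("Edge list %s needs two columns (compound, target).", path))
  }
  stats::setNames(tbl[, 1:2], c("compound", "target"))
}

#' @rdname read_edges
#' @param edges A tibble with columns `compound`, `target`.
#' @export
write_edges <- function(edges, path) {
  readr::write_delim(as_tibble(edges)[, c("compound", "target")], path,
                     delim = delim_for(path))
  invisible(path)
}

#' Read a target-disease annotation table
#'
#' Three-column table `target, disease, group`; a disease listed with
#' several groups appears on several rows.
#'
#' @param path CSV/TSV path.
#' @return A list with `pairs` (tibble `target`, `disease`) and `groups`
#'   (tibble `disease`, `group`), ready for
#'   [build_target_disease_network()].
#' @export
read_disease_annotations <- function(path) {
  tbl <- read_delim_quiet(path, delim_for(path))
  missing <- setdiff(c("target", "disease", "group"), names(tbl))
  if (length(missing) > 0) {
    abort_validation(paste0("Disease annotation ", path, " is missing column(s): ",
                            paste(missing, collapse = ", "), "."))
  }
  list(pairs = dplyr::distinct(tbl[, c("target", "disease")]),
       groups = dplyr::distinct(tbl[, c("disease", "group")]))
}

network_edge_tbl <- function(network) {
  if (inherits(network, "bipartite_network")) {
    tibble(from = network$edges$compound, type = "ct", to = network$edges$target)
  } else {
    tibble(from = network$edges$from, type = network$edges$type,
           to = network$edges$to)
  }
}

#' Write a network to SIF or GraphML
#'
#' SIF output is Cytoscape-loadable (`source <interaction> target`, with
#' interaction types `ct` for compound-target, `td` for target-disease and
#' `dg` for disease-group edges; isolated nodes appear as single-field
#' lines). Because SIF itself cannot carry node attributes, a sidecar
#' node-attribute table `<path>.noa` (TSV: id, role, plus any metadata
#' columns) is written alongside, and [read_network()] consumes it, making
#' the SIF round trip lossless. GraphML carries all attributes in one file.
#'
#' @param network A `bipartite_network` or `target_disease_network`.
#' @param path Output path.
#' @param format `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (!inherits(network, c("bipartite_network", "target_disease_network"))) {
    abort_validation("`network` must be a bipartite_network or target_disease_network.")
  }
  edges <- network_edge_tbl(network)
  nodes <- network$nodes
  meta <- if (inherits(network, "bipartite_network")) network$metadata else NULL
  noa <- nodes
  if (!is.null(meta)) noa <- dplyr::left_join(noa, meta, by = "id")
  if (format == "sif") {
    lines <- sprintf("%s\t%s\t%s", edges$from, edges$type, edges$to)
    isolated <- setdiff(nodes$id, c(edges$from, edges$to))
    writeLines(c(lines, isolated), path)
    readr::write_tsv(noa, paste0(path, ".noa"), na = "")
  } else {
    g <- igraph::graph_from_data_frame(edges[, c("from", "to", "type")],
                                       directed = FALSE, vertices = noa)
    # igraph drops NA attribute values inconsistently across formats;
    # serialize as empty string and restore on read
    for (at in igraph::vertex_attr_names(g)) {
      v <- igraph::vertex_attr(g, at)
      if (is.character(v)) igraph::vertex_attr(g, at) <- ifelse(is.na(v), "", v)
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path Path to the `.sif` or `.graphml` file.
#' @param format `"sif"` or `"graphml"`.
#' @return A `bipartite_network` or `target_disease_network`, according to
#'   the roles found in the file.
#' @export
read_network <- function(path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_validation(sprintf("File not found: %s", path))
  if (format == "sif") {
    noa_path <- paste0(path, ".noa")
    if (!file.exists(noa_path)) {
      abort_validation(sprintf("Node attribute sidecar not found: %s", noa_path))
    }
    noa <- readr::read_tsv(noa_path, show_col_types = FALSE, progress = FALSE)
    fields <- strsplit(readLines(path), "\t", fixed = TRUE)
    fields <- fields[lengths(fields) > 0]
    edge_rows <- fields[lengths(fields) >= 3]
    edges <- tibble(
      from = purrr::map_chr(edge_rows, 1),
      type = purrr::map_chr(edge_rows, 2),
      to = purrr::map_chr(edge_rows, 3))
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    va <- igraph::vertex_attr(g)
    noa <- as_tibble(va[setdiff(names(va), "id")])
    names(noa)[names(noa) == "name"] <- "id"
    noa <- dplyr::mutate(noa, dplyr::across(
      dplyr::where(is.character), ~ dplyr::na_if(.x, "")))
    el <- igraph::as_edgelist(g)
    edges <- tibble(from = el[, 1], type = igraph::edge_attr(g, "type"),
                    to = el[, 2])
  }
  rebuild_network(noa, edges)
}

rebuild_network <- function(noa, edges) {
  if (!all(c("id", "role") %in% names(noa))) {
    abort_validation("Node attributes must include `id` and `role`.")
  }
  roles <- unique(noa$role)
  if (all(roles %in% c("compound", "target"))) {
    meta_cols <- setdiff(names(noa), c("id", "role"))
    meta <- if (length(meta_cols) > 0) noa[, c("id", meta_cols)] else NULL
    if (!is.null(meta)) {
      # only nodes that actually carry an annotation
      has_ann <- rowSums(!is.na(meta[meta_cols])) > 0
      meta <- meta[has_ann, ]
      if (nrow(meta) == 0) meta <- NULL
    }
    build_bipartite_network(
      compounds = noa$id[noa$role == "compound"],
      targets = noa$id[noa$role == "target"],
      edges = tibble(compound = edges$from, target = edges$to),
      metadata = meta)
  } else if (all(roles %in% c("target", "disease", "disease_group"))) {
    td <- edges[edges$type == "td", ]
    dg <- edges[edges$type == "dg", ]
    build_target_disease_network(
      tibble(target = td$from, disease = td$to),
      tibble(disease = dg$from, group = dg$to))
  } else {
    abort_validation(paste0("Unrecognized node roles: ",
                            paste(setdiff(roles, c("compound", "target", "disease",
                                                   "disease_group")), collapse = ", "), "."))
  }
}

#' Read a long-format MTT plate table
#'
#' Columns `dose, replicate, absorbance` (optional `timepoint`).
#'
#' @param path CSV/TSV path.
#' @return A tibble.
#' @export
read_plate_table <- function(path) {
  tbl <- read_delim_quiet(path, delim_for(path))
  missing <- setdiff(c("dose", "replicate", "absorbance"), names(tbl))
  if (length(missing) > 0) {
    abort_validation(paste0("Plate table ", path, " is missing column(s): ",
                            paste(missing, collapse = ", "), "."))
  }
  parse_numeric_cols(tbl, intersect(c("dose", "replicate", "absorbance", "timepoint"),
                                    names(tbl)), path)
}

#' Read a long-format qPCR Ct table
#'
#' Columns `gene, group, replicate, ct`.
#'
#' @param path CSV/TSV path.
#' @return A tibble.
#' @export
read_ct_table <- function(path) {
  tbl <- read_delim_quiet(path, delim_for(path))
  missing <- setdiff(c("gene", "group", "replicate", "ct"), names(tbl))
  if (length(missing) > 0) {
    abort_validation(paste0("Ct table ", path, " is missing column(s): ",
                            paste(missing, collapse = ", "), "."))
  }
  parse_numeric_cols(tbl, c("replicate", "ct"), path)
}

#' Read a two-channel flow-cytometry event table
#'
#' Columns `channel1, channel2` (one row per event; an FCS-style plain-text
#' export).
#'
#' @param path CSV/TSV path.
#' @return A tibble.
#' @export
read_flow_events <- function(path) {
  tbl <- read_delim_quiet(path, delim_for(path))
  missing <- setdiff(c("channel1", "channel2"), names(tbl))
  if (length(missing) > 0) {
    abort_validation(paste0("Flow event table ", path, " is missing column(s): ",
                            paste(missing, collapse = ", "), "."))
  }
  parse_numeric_cols(tbl, c("channel1", "channel2"), path)
}
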