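abort_stage <- function(stage, msg) {
  abort(sprintf("[%s] %s", stage, msg),
        class = c("netpharm_stage_error", "netpharm_error"))
}

require_input <- function(stage, path) {
  if (is.null(path)) abort_stage(stage, "no input file configured.")
  if (!file.exists(path)) {
    abort_stage(stage, sprintf("input file not found: %s", path))
  }
  path
}

default_config <- function() {
  list(
    seed = 1,
    out_dir = "netpharm_out",
    report_digits = 8,
    screen = list(run = TRUE, input = NULL, score_floor = 0,
                  weights = unname(cyp_weights())),
    network = list(run = FALSE, edges = NULL, compounds = NULL, targets = NULL,
                   simulate = FALSE, hub_min_degree = 10),
    diseasemap = list(run = FALSE, annotations = NULL, simulate = FALSE),
    doseresponse = list(run = FALSE, plate = NULL, simulate = FALSE),
    qpcr = list(run = FALSE, ct = NULL, simulate = FALSE),
    flow = list(run = FALSE, events = NULL, simulate = FALSE,
                thresholds = c(100, 100))
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Load (and validate) a pipeline configuration
#'
#' The configuration is a single declarative YAML file; values not given
#' fall back to package defaults. See [run_pipeline()] for the stage schema.
#'
#' @param config A YAML file path, a list, or `NULL` for pure defaults.
#' @return A complete configuration list.
#' @export
load_config <- function(config = NULL) {
  user <- if (is.null(config)) {
    list()
  } else if (is.character(config)) {
    if (!file.exists(config)) abort_validation(sprintf("Config file not found: %s", config))
    yaml::read_yaml(config)
  } else if (is.list(config)) {
    config
  } else {
    abort_validation("`config` must be a YAML path, a list, or NULL.")
  }
  cfg <- merge_config(default_config(), user)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) {
    abort_validation("`seed` must be a single integer.")
  }
  cfg
}

log_line <- function(con, ..., verbose = FALSE) {
  msg <- sprintf("%s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), paste0(...))
  writeLines(msg, con)
  if (verbose) message(msg)
}

#' Run the screening-to-validation pipeline
#'
#' Executes the configured stages in order - compound screening, network
#' construction and hub extraction, disease mapping, and the bioassay
#' analyses (dose-response, qPCR, flow) - writing per-stage tables, a
#' plain-text log with ISO-8601 timestamps, and a deterministic JSON summary
#' report (`report.json`; a pure function of inputs and configuration, so
#' repeated runs are byte-identical). All stage randomness derives from the
#' single configured seed.
#'
#' Stage configuration (YAML or list): each stage has `run: true/false` and
#' either an input path (`input`, `edges`, `annotations`, `plate`, `ct`,
#' `events`) or `simulate: true` to use the package's seeded generators.
#'
#' @param config A YAML path or config list, see [load_config()].
#' @return The report, invisibly (also written to
#'   `<out_dir>/report.json`).
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- load_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "pipeline.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con), add = TRUE)
  # hash the analysis configuration, not where it is written
  cfg_hash <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  log_line(con, "run start; seed=", cfg$seed, "; config hash=", cfg_hash)
  log_line(con, "netpharm version ", as.character(utils::packageVersion("netpharm")),
           "; R ", as.character(getRversion()))
  report <- list(seed = cfg$seed, config_hash = cfg_hash)

  if (isTRUE(cfg$screen$run)) {
    path <- require_input("screen", cfg$screen$input)
    tbl <- read_admet_table(path)
    res <- screen_library(tbl, weights = cfg$screen$weights,
                          score_floor = cfg$screen$score_floor)
    ranked <- rank_compounds(res)
    write_admet_table(ranked, file.path(cfg$out_dir, "screen_retained.csv"),
                      digits = cfg$report_digits)
    discarded <- dplyr::filter(tidy(res), !.data$retained)
    readr::write_csv(discarded[, c("compound_id", "score", "discard_reason")],
                     file.path(cfg$out_dir, "screen_discarded.csv"))
    report$screen <- list(
      n_input = nrow(tbl), n_retained = nrow(ranked),
      n_discarded = nrow(discarded),
      top_compound = if (nrow(ranked) > 0) ranked$compound_id[[1]] else NA,
      scores = stats::setNames(round(ranked$score, cfg$report_digits),
                               ranked$compound_id))
    log_line(con, "screen: ", nrow(ranked), "/", nrow(tbl), " retained")
  }

  net <- NULL
  if (isTRUE(cfg$network$run)) {
    if (isTRUE(cfg$network$simulate)) {
      sim <- simulate_bipartite_edges(seed = cfg$seed)
      net <- build_bipartite_network(sim$compounds, sim$targets, sim$edges)
    } else {
      path <- require_input("network", cfg$network$edges)
      edges <- read_edges(path)
      compounds <- cfg$network$compounds %||% unique(edges$compound)
      targets <- cfg$network$targets %||% unique(edges$target)
      net <- build_bipartite_network(compounds, targets, edges)
    }
    deg <- degree_map(net)
    readr::write_csv(deg, file.path(cfg$out_dir, "network_degrees.csv"))
    write_network(net, file.path(cfg$out_dir, "network.sif"), format = "sif")
    hubs <- hub_nodes(net, "target", cfg$network$hub_min_degree)
    report$network <- list(
      n_nodes = nrow(net$nodes), n_edges = nrow(net$edges),
      n_compounds = sum(net$nodes$role == "compound"),
      n_targets = sum(net$nodes$role == "target"),
      hub_min_degree = cfg$network$hub_min_degree,
      hubs = hubs,
      hub_fraction_pct = round(role_fraction(net, hubs, "target"), 2))
    log_line(con, "network: ", nrow(net$nodes), " nodes, ", nrow(net$edges),
             " edges, ", length(hubs), " hub targets")
  }

  if (isTRUE(cfg$diseasemap$run)) {
    ann <- if (isTRUE(cfg$diseasemap$simulate)) {
      simulate_target_disease(seed = cfg$seed)
    } else {
      read_disease_annotations(require_input("diseasemap", cfg$diseasemap$annotations))
    }
    tdn <- build_target_disease_network(ann$pairs, ann$groups)
    write_network(tdn, file.path(cfg$out_dir, "target_disease.sif"), format = "sif")
    shared <- if (!is.null(net)) {
      intersect_targets(role_ids(net, "target"), unique(ann$pairs$target))
    } else {
      sort(unique(ann$pairs$target))
    }
    report$diseasemap <- list(
      n_targets = sum(tdn$nodes$role == "target"),
      n_diseases = sum(tdn$nodes$role == "disease"),
      n_groups = sum(tdn$nodes$role == "disease_group"),
      n_shared_targets = length(shared))
    log_line(con, "diseasemap: ", report$diseasemap$n_diseases, " diseases in ",
             report$diseasemap$n_groups, " groups")
  }

  if (isTRUE(cfg$doseresponse$run)) {
    plate <- if (isTRUE(cfg$doseresponse$simulate)) {
      simulate_dose_response(seed = cfg$seed)$plate
    } else {
      read_plate_table(require_input("doseresponse", cfg$doseresponse$plate))
    }
    fit <- fit_dose_response(plate)
    readr::write_csv(glance(fit), file.path(cfg$out_dir, "dose_response_fit.csv"))
    report$doseresponse <- list(
      converged = fit$converged,
      ic50 = if (fit$converged) round(fit$ic50, 4) else NA,
      hill = if (fit$converged) round(fit$hill, 4) else NA)
    log_line(con, "doseresponse: IC50 = ",
             if (fit$converged) format(fit$ic50, digits = 6) else "not converged")
  }

  if (isTRUE(cfg$qpcr$run)) {
    ct <- if (isTRUE(cfg$qpcr$simulate)) {
      simulate_ct_table(seed = cfg$seed)$ct
    } else {
      read_ct_table(require_input("qpcr", cfg$qpcr$ct))
    }
    folds <- fold_change_table(ct)
    readr::write_csv(folds, file.path(cfg$out_dir, "fold_changes.csv"))
    report$qpcr <- list(fold_changes = stats::setNames(
      round(folds$fold_change, 4), paste(folds$gene, folds$group, sep = ":")))
    log_line(con, "qpcr: ", nrow(folds), " fold changes computed")
  }

  if (isTRUE(cfg$flow$run)) {
    events <- if (isTRUE(cfg$flow$simulate)) {
      simulate_flow_events(seed = cfg$seed)$events
    } else {
      read_flow_events(require_input("flow", cfg$flow$events))
    }
    qs <- classify_quadrants(events, thresholds = cfg$flow$thresholds)
    readr::write_csv(as_tibble(qs), file.path(cfg$out_dir, "quadrants.csv"))
    report$flow <- list(
      fractions = stats::setNames(round(qs$fraction, 6), qs$quadrant),
      early_apoptotic = round(apoptotic_fraction(qs, "early"), 6),
      total_apoptotic = round(apoptotic_fraction(qs, "total"), 6))
    log_line(con, "flow: early apoptotic fraction ",
             format(report$flow$early_apoptotic))
  }

  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line(con, "run complete")
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
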