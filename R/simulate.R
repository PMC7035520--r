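#' Simulate a signed-probability ADMET compound library
#'
#' Emulates the output of upstream ADMET classifiers: signed class
#' probabilities for HIA, Caco-2 and the five CYP isoforms, with magnitudes
#' in \[0.5, 1\] mimicking classifier confidence. Exactly
#' `round(pass_fraction * n_compounds)` records are planted to pass both
#' screening rules (positive absorption and positive composite score); all
#' other records fail the absorption filter. Identical arguments give
#' bit-identical output.
#'
#' @param n_compounds Library size.
#' @param pass_fraction Fraction of records planted to pass the screen.
#' @param cyp_inhibitor_prob Probability that each CYP prediction is of the
#'   inhibitor (positive) class; length 1 or 5.
#' @param seed Integer seed.
#' @return A tibble in [read_admet_table()] layout plus a logical
#'   `planted_pass` column.
#' @export
simulate_compound_library <- function(n_compounds = 100, pass_fraction = 0.4,
                                      cyp_inhibitor_prob = 0.7, seed = 1) {
  if (!is.numeric(pass_fraction) || pass_fraction < 0 || pass_fraction > 1) {
    abort_validation("`pass_fraction` must lie in [0, 1].")
  }
  cyp_inhibitor_prob <- rep_len(cyp_inhibitor_prob, 5)
  if (any(cyp_inhibitor_prob < 0) || any(cyp_inhibitor_prob > 1)) {
    abort_validation("`cyp_inhibitor_prob` entries must lie in [0, 1].")
  }
  if (n_compounds == 0) {
    return(tibble(compound_id = character(0), herb = character(0),
                  smiles = character(0), hia = numeric(0), caco2 = numeric(0),
                  cyp_1a2 = numeric(0), cyp_2c9 = numeric(0),
                  cyp_2d6 = numeric(0), cyp_2c19 = numeric(0),
                  cyp_3a4 = numeric(0), planted_pass = logical(0)))
  }
  n_pass <- round(pass_fraction * n_compounds)
  w <- cyp_weights()
  withr::with_seed(seed, {
    ids <- sprintf("cmp%04d", seq_len(n_compounds))
    planted <- seq_len(n_compounds) %in% sample(n_compounds, n_pass)
    mag <- function(n) stats::runif(n, 0.5, 1)
    hia <- mag(n_compounds)
    caco2 <- mag(n_compounds)
    # failing records miss absorption on one or both endpoints
    fail_mode <- sample(1:3, n_compounds, replace = TRUE)
    hia[!planted & fail_mode != 2] <- -hia[!planted & fail_mode != 2]
    caco2[!planted & fail_mode != 1] <- -caco2[!planted & fail_mode != 1]
    cyp <- matrix(mag(5 * n_compounds), ncol = 5)
    sign_draw <- matrix(stats::runif(5 * n_compounds), ncol = 5)
    cyp <- cyp * ifelse(sweep(sign_draw, 2, cyp_inhibitor_prob, `<=`), 1, -1)
    # planted passers must also clear the score floor: flip negative entries
    # (largest weighted deficit first) until the composite score is positive
    for (i in which(planted)) {
      while (sum(cyp[i, ] * w) <= 0) {
        j <- which.min(cyp[i, ] * w)
        cyp[i, j] <- -cyp[i, j]
      }
    }
    tibble(
      compound_id = ids, herb = NA_character_, smiles = NA_character_,
      hia = hia, caco2 = caco2,
      cyp_1a2 = cyp[, 1], cyp_2c9 = cyp[, 2], cyp_2d6 = cyp[, 3],
      cyp_2c19 = cyp[, 4], cyp_3a4 = cyp[, 5],
      planted_pass = planted
    )
  })
}

#' Simulate a compound-target edge set with planted hubs
#'
#' Generates a bipartite interaction harvest in which a chosen number of
#' "hub" targets have degrees drawn from `hub_degree_range` (at least the
#' conventional hub threshold of 10) and all remaining targets have
#' background degrees in `background_degree_range` (default 0-3), so that
#' degree-threshold hub extraction has an exact planted answer.
#'
#' @param n_compounds,n_targets Role sizes (compound ids `cmp###`, target
#'   ids `tgt###`).
#' @param n_hubs Number of planted hub targets (must be <= `n_targets`).
#' @param hub_degree_range Inclusive integer range of hub degrees; the upper
#'   end may not exceed `n_compounds`.
#' @param background_degree_range Inclusive integer range of non-hub degrees.
#' @param seed Integer seed.
#' @return A list: `compounds`, `targets`, `edges` (tibble `compound`,
#'   `target`), and `hub_targets` (the planted hub ids, sorted).
#' @export
simulate_bipartite_edges <- function(n_compounds = 118, n_targets = 141,
                                     n_hubs = 5, hub_degree_range = c(10, 30),
                                     background_degree_range = c(0, 3),
                                     seed = 1) {
  if (n_hubs > n_targets) abort_validation("`n_hubs` may not exceed `n_targets`.")
  if (max(hub_degree_range) > n_compounds || max(background_degree_range) > n_compounds) {
    abort_validation("Requested degrees exceed the number of compounds.")
  }
  if (n_hubs > 0 && min(hub_degree_range) <= max(background_degree_range)) {
    abort_validation("Hub degree range must lie strictly above the background range.")
  }
  compounds <- sprintf("cmp%04d", seq_len(n_compounds))
  targets <- sprintf("tgt%04d", seq_len(n_targets))
  sample_range <- function(lo, hi, n) lo + sample.int(hi - lo + 1, n, replace = TRUE) - 1L
  withr::with_seed(seed, {
    hubs <- sort(sample(targets, n_hubs))
    deg <- ifelse(
      targets %in% hubs,
      sample_range(hub_degree_range[1], hub_degree_range[2], n_targets),
      sample_range(background_degree_range[1], background_degree_range[2], n_targets))
    if (n_compounds == 0) deg <- rep(0L, n_targets)
    edges <- purrr::map2_dfr(targets, deg, function(t, d) {
      if (d == 0) return(tibble(compound = character(0), target = character(0)))
      tibble(compound = sample(compounds, d), target = t)
    })
    list(compounds = compounds, targets = targets, edges = edges,
         hub_targets = hubs)
  })
}

#' Simulate a target-disease annotation set
#'
#' Emulates a harvested disease annotation: each disease is linked to one or
#' more targets and assigned 1-2 MeSH-style group codes (so some diseases
#' belong to two groups, as real annotations do).
#'
#' @param n_targets,n_diseases,n_groups Layer sizes.
#' @param seed Integer seed.
#' @return A list: `pairs` (tibble `target`, `disease`) and `groups` (tibble
#'   `disease`, `group`).
#' @export
simulate_target_disease <- function(n_targets = 46, n_diseases = 139,
                                    n_groups = 24, seed = 1) {
  if (n_groups < 1 && n_diseases > 0) {
    abort_validation("Need at least one disease group.")
  }
  targets <- sprintf("tgt%04d", seq_len(n_targets))
  diseases <- sprintf("dis%04d", seq_len(n_diseases))
  groups <- sprintf("C%02d", seq_len(n_groups))
  if (n_diseases == 0 || n_targets == 0) {
    return(list(pairs = tibble(target = character(0), disease = character(0)),
                groups = tibble(disease = character(0), group = character(0))))
  }
  withr::with_seed(seed, {
    pairs <- purrr::map_dfr(diseases, function(d) {
      tibble(target = sample(targets, sample(1:min(4, n_targets), 1)), disease = d)
    })
    # guarantee every target appears at least once
    missing <- setdiff(targets, pairs$target)
    if (length(missing) > 0) {
      pairs <- dplyr::bind_rows(pairs, tibble(
        target = missing, disease = sample(diseases, length(missing), replace = TRUE)))
    }
    grp <- purrr::map_dfr(diseases, function(d) {
      tibble(disease = d, group = sample(groups, sample(1:min(2, n_groups), 1)))
    })
    # guarantee every group is used
    unused <- setdiff(groups, grp$group)
    if (length(unused) > 0) {
      grp <- dplyr::bind_rows(grp, tibble(
        disease = sample(diseases, length(unused), replace = TRUE), group = unused))
    }
    list(pairs = dplyr::distinct(pairs), groups = dplyr::distinct(grp))
  })
}

#' Simulate an MTT dose-response plate
#'
#' Generates long-format plate absorbances from a 4-parameter log-logistic
#' inhibition curve: treated-well absorbance is
#' `a_control * (1 - y(dose)/100)` with per-well Gaussian noise of
#' `noise_sd` percentage points (expressed on the inhibition scale). With
#' `noise_sd = 0`, applying [inhibition_rate()] to the plate returns the
#' curve exactly. The default truth (IC50 13.61 ug/mL at 24 h, two-fold dose
#' series up to 128 ug/mL) mirrors a typical K562 cytotoxicity experiment.
#'
#' @param doses Dose series in ug/mL; must include 0 (control) and at least
#'   2 positive doses.
#' @param n_replicates Wells per dose.
#' @param ic50,hill,top,bottom True curve parameters (percent inhibition).
#' @param noise_sd Gaussian noise, in percentage points of inhibition.
#' @param a_control Mean control absorbance (OD at 490 nm).
#' @param timepoint Hours of exposure (annotation only).
#' @param seed Integer seed.
#' @return A list: `plate` (tibble `dose`, `replicate`, `absorbance`,
#'   `timepoint`) and `truth` (the generating parameters).
#' @export
simulate_dose_response <- function(doses = c(0, 1, 2, 4, 8, 16, 32, 64, 128),
                                   n_replicates = 3, ic50 = 13.61, hill = 1.5,
                                   top = 100, bottom = 0, noise_sd = 3,
                                   a_control = 0.8, timepoint = 24, seed = 1) {
  check_finite(doses, "doses")
  if (any(doses < 0)) abort_validation("Doses must be non-negative.")
  if (sum(unique(doses) > 0) < 2) abort_validation("Need at least 2 positive doses.")
  if (!0 %in% doses) abort_validation("Dose series must include the control (0).")
  if (noise_sd < 0) abort_validation("`noise_sd` must be non-negative.")
  if (ic50 <= 0) abort_validation("`ic50` must be positive.")
  grid <- tidyr::expand_grid(dose = doses, replicate = seq_len(n_replicates))
  y <- ifelse(grid$dose == 0, 0, fourpl(grid$dose, ic50, hill, top, bottom))
  withr::with_seed(seed, {
    noise <- stats::rnorm(nrow(grid), 0, noise_sd)
    plate <- dplyr::mutate(grid,
      absorbance = a_control * (1 - (y + ifelse(.data$dose == 0, 0, noise)) / 100),
      timepoint = timepoint)
  })
  list(plate = plate,
       truth = list(ic50 = ic50, hill = hill, top = top, bottom = bottom,
                    noise_sd = noise_sd, a_control = a_control))
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' Plants per-gene expression fold changes (relative to the control group,
#' normalized to a constant reference gene) by shifting the treated-group Ct
#' by `-log2(fold)`. The default plants the Bcl-2-family pattern seen in
#' apoptosis induction: pro-apoptotic genes (Bad, Bax) up, anti-apoptotic
#' genes (Bcl-2, Bcl-xL) down.
#'
#' @param fold_changes Named positive numeric vector: planted fold change
#'   per gene in the treated group.
#' @param treated_group,control_group Group labels.
#' @param reference_gene Reference gene held constant across groups.
#' @param n_replicates Replicates per (gene, group).
#' @param base_ct_range Range of per-gene baseline Ct values.
#' @param reference_ct Reference-gene Ct.
#' @param noise_sd Gaussian Ct noise (cycles).
#' @param seed Integer seed.
#' @return A list: `ct` (tibble `gene`, `group`, `replicate`, `ct`) and
#'   `truth` (the planted fold changes).
#' @export
simulate_ct_table <- function(fold_changes = c(Bad = 2.5, Bax = 1.8,
                                               `Bcl-2` = 0.6, `Bcl-xL` = 0.35),
                              treated_group = "treated",
                              control_group = "control",
                              reference_gene = "GAPDH", n_replicates = 3,
                              base_ct_range = c(20, 28), reference_ct = 16,
                              noise_sd = 0.1, seed = 1) {
  if (is.null(names(fold_changes)) || any(names(fold_changes) == "")) {
    abort_validation("`fold_changes` must be a named vector (gene = fold).")
  }
  check_finite(fold_changes, "fold_changes")
  if (any(fold_changes <= 0)) abort_validation("Fold changes must be positive.")
  if (noise_sd < 0) abort_validation("`noise_sd` must be non-negative.")
  genes <- names(fold_changes)
  withr::with_seed(seed, {
    base_ct <- stats::setNames(
      stats::runif(length(genes), base_ct_range[1], base_ct_range[2]), genes)
    grid <- tidyr::expand_grid(
      gene = c(genes, reference_gene),
      group = c(control_group, treated_group),
      replicate = seq_len(n_replicates))
    mu <- purrr::map2_dbl(grid$gene, grid$group, function(g, grp) {
      if (g == reference_gene) return(reference_ct)
      base_ct[[g]] - if (grp == treated_group) log2(fold_changes[[g]]) else 0
    })
    ct <- dplyr::mutate(grid, ct = mu + stats::rnorm(nrow(grid), 0, noise_sd))
  })
  list(ct = ct, truth = list(fold_changes = fold_changes,
                             treated_group = treated_group,
                             control_group = control_group))
}

# strictly gate-respecting log-normal component: a half-log-normal offset
# pushes every draw at least `margin` log-units beyond the gate
gate_sided <- function(n, gate, positive, margin = 0.05, sdlog = 0.7) {
  offset <- margin + abs(stats::rnorm(n, 0, sdlog))
  gate * exp(if (positive) offset else -offset)
}

#' Simulate Annexin V / PI flow-cytometry events
#'
#' Draws per-quadrant event counts from a multinomial with the stated
#' quadrant probabilities, then draws channel intensities from log-normal
#' components constrained to the correct side of each gate, so
#' [classify_quadrants()] recovers the planted counts exactly.
#'
#' @param n_events Number of events.
#' @param quadrant_probs Length-4 probabilities for Q1 (both+), Q2 (PI+
#'   only), Q3 (both-), Q4 (Annexin+ only); must sum to 1.
#' @param thresholds Length-2 gate values (channel1, channel2).
#' @param seed Integer seed.
#' @return A list: `events` (tibble `channel1`, `channel2`), `truth`
#'   (planted probabilities and the multinomial `counts`).
#' @export
simulate_flow_events <- function(n_events = 10000,
                                 quadrant_probs = c(Q1 = 0.05, Q2 = 0.03,
                                                    Q3 = 0.80, Q4 = 0.12),
                                 thresholds = c(100, 100), seed = 1) {
  check_finite(quadrant_probs, "quadrant_probs")
  if (length(quadrant_probs) != 4 || any(quadrant_probs < 0) ||
      abs(sum(quadrant_probs) - 1) > 1e-8) {
    abort_validation("`quadrant_probs` must be 4 non-negative values summing to 1.")
  }
  if (length(thresholds) != 2 || any(thresholds <= 0)) {
    abort_validation("`thresholds` must be two strictly positive gate values.")
  }
  side1 <- c(Q1 = TRUE, Q2 = FALSE, Q3 = FALSE, Q4 = TRUE)
  side2 <- c(Q1 = TRUE, Q2 = TRUE, Q3 = FALSE, Q4 = FALSE)
  withr::with_seed(seed, {
    counts <- as.integer(stats::rmultinom(1, n_events, quadrant_probs))
    names(counts) <- names(side1)
    ev <- purrr::map_dfr(names(side1), function(q) {
      n <- counts[[q]]
      tibble(channel1 = gate_sided(n, thresholds[[1]], side1[[q]]),
             channel2 = gate_sided(n, thresholds[[2]], side2[[q]]),
             quadrant = rep(q, n))
    })
    ev <- ev[sample(nrow(ev)), ]
  })
  list(events = dplyr::select(ev, "channel1", "channel2"),
       truth = list(quadrant_probs = quadrant_probs, counts = counts,
                    thresholds = thresholds,
                    quadrant = ev$quadrant))
}

#' Simulate JC-1 two-channel events with a planted depolarized fraction
#'
#' Draws the number of depolarized events from a binomial with the planted
#' fraction, then gives depolarized events an aggregate/monomer ratio
#' strictly below the ratio gate and polarized events a ratio strictly
#' above it (log-normal monomer intensities).
#'
#' @param n_events Number of events.
#' @param depolarized_fraction Planted probability an event is depolarized.
#' @param ratio_threshold Ratio gate used at analysis time.
#' @param seed Integer seed.
#' @return A list: `events` (tibble `channel1` monomer, `channel2`
#'   aggregate), `truth` (fraction, count).
#' @export
simulate_jc1_events <- function(n_events = 20000, depolarized_fraction = 0.3,
                                ratio_threshold = 1, seed = 1) {
  if (depolarized_fraction < 0 || depolarized_fraction > 1) {
    abort_validation("`depolarized_fraction` must lie in [0, 1].")
  }
  if (ratio_threshold <= 0) abort_validation("`ratio_threshold` must be positive.")
  withr::with_seed(seed, {
    depol <- stats::rbinom(n_events, 1, depolarized_fraction) == 1
    monomer <- stats::rlnorm(n_events, log(500), 0.5)
    ratio <- ifelse(depol,
                    ratio_threshold * exp(-(0.05 + abs(stats::rnorm(n_events, 0, 0.7)))),
                    ratio_threshold * exp(0.05 + abs(stats::rnorm(n_events, 0, 0.7))))
    events <- tibble(channel1 = monomer, channel2 = monomer * ratio)
  })
  list(events = events,
       truth = list(depolarized_fraction = depolarized_fraction,
                    n_depolarized = sum(depol)))
}
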