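#' MTT inhibition rate
#'
#' Growth-inhibition percentage from optical densities at 490 nm:
#' `100 * (A_control - A_treated) / A_control`. Negative values indicate
#' growth promotion relative to control and are returned as-is.
#'
#' @param a_control Mean control-well absorbance (must be > 0).
#' @param a_treated Treated-well absorbance(s); vectorized.
#' @return Percentage inhibition (same length as `a_treated`).
#' @examples
#' inhibition_rate(0.8, 0.6)
#' @export
inhibition_rate <- function(a_control, a_treated) {
  check_finite(a_control, "a_control")
  check_finite(a_treated, "a_treated")
  if (length(a_control) != 1 || a_control <= 0) {
    abort_undefined_ratio("`a_control` must be a single positive absorbance.")
  }
  100 * (a_control - a_treated) / a_control
}

#' Per-well inhibition rates from a plate table
#'
#' Converts a long-format MTT plate table into per-well inhibition
#' percentages against the mean control (dose 0) absorbance.
#'
#' @param plate Data frame with columns `dose`, `replicate`, `absorbance`
#'   (extra columns such as `timepoint` are carried through).
#' @return A tibble of the positive-dose wells with a `response` column
#'   (percent inhibition).
#' @export
inhibition_table <- function(plate) {
  plate <- as_tibble(plate)
  missing <- setdiff(c("dose", "absorbance"), names(plate))
  if (length(missing) > 0) {
    abort_validation(paste0("Plate table missing columns: ",
                            paste(missing, collapse = ", "), "."))
  }
  check_finite(plate$dose, "dose")
  if (any(plate$dose < 0)) abort_validation("Doses must be non-negative.")
  ctrl <- plate$absorbance[plate$dose == 0]
  if (length(ctrl) == 0) {
    abort_validation("Plate table must contain control wells (dose 0).")
  }
  a0 <- mean(ctrl)
  plate |>
    dplyr::filter(.data$dose > 0) |>
    dplyr::mutate(response = inhibition_rate(a0, .data$absorbance))
}

fourpl <- function(dose, ic50, hill, top, bottom) {
  bottom + (top - bottom) / (1 + (dose / ic50)^(-hill))
}

#' Fit a four-parameter log-logistic dose-response curve
#'
#' Least-squares fit of
#' `y = bottom + (top - bottom) / (1 + (dose / ic50)^(-hill))`
#' to percent-inhibition responses, with multi-start initialization (the IC50
#' is seeded at the geometric mean dose and the Hill slope scanned over a
#' sign-and-magnitude grid; the fit is parameterized in `log(ic50)` so the
#' IC50 stays positive). Parameters are normalized after fitting so that
#' `bottom <= top` (the Hill sign flips accordingly, an identical curve).
#'
#' @param data Either a plate table with `dose`/`absorbance` columns (run
#'   through [inhibition_table()] first) or a data frame with `dose` and
#'   `response` (percent inhibition) columns. Doses of 0 are excluded from
#'   the fit.
#' @return A `dose_response_fit` with elements `ic50`, `hill`, `top`,
#'   `bottom`, `rss`, `converged`, `n_obs`, `data`. `converged` is `FALSE`
#'   when the optimizer fails or the curve is non-identifiable (e.g. a flat
#'   response). Use [tidy()], [glance()], [ggplot2::autoplot()].
#' @examples
#' sim <- simulate_dose_response(noise_sd = 0, seed = 1)
#' fit <- fit_dose_response(sim$plate)
#' glance(fit)
#' @export
fit_dose_response <- function(data) {
  data <- as_tibble(data)
  if ("absorbance" %in% names(data) && !"response" %in% names(data)) {
    data <- inhibition_table(data)
  }
  missing <- setdiff(c("dose", "response"), names(data))
  if (length(missing) > 0) {
    abort_validation(paste0("Dose-response data missing columns: ",
                            paste(missing, collapse = ", "), "."))
  }
  pts <- dplyr::filter(data, .data$dose > 0)
  check_finite(pts$dose, "dose")
  check_finite(pts$response, "response")
  if (dplyr::n_distinct(pts$dose) < 2) {
    abort_validation("Need at least 2 distinct positive doses to fit a curve.")
  }
  out <- list(ic50 = NA_real_, hill = NA_real_, top = NA_real_,
              bottom = NA_real_, rss = NA_real_, converged = FALSE,
              n_obs = nrow(pts), data = pts)
  class(out) <- "dose_response_fit"
  # flat response: the curve is non-identifiable, report non-convergence
  if (stats::sd(pts$response) < sqrt(.Machine$double.eps)) {
    return(out)
  }
  log_e0 <- mean(log(unique(pts$dose)))
  top0 <- max(pts$response)
  bot0 <- min(pts$response)
  best <- NULL
  for (h0 in c(0.5, 1, 2, 4, -0.5, -1, -2, -4)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        response ~ bottom + (top - bottom) / (1 + exp(-hill * (log(dose) - log_ic50))),
        data = pts,
        start = list(bottom = bot0, top = top0, hill = h0, log_ic50 = log_e0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(out)
  cf <- stats::coef(best$fit)
  bottom <- unname(cf["bottom"]); top <- unname(cf["top"])
  hill <- unname(cf["hill"]); ic50 <- exp(unname(cf["log_ic50"]))
  if (bottom > top) {  # same curve with asymptotes swapped and slope negated
    tmp <- bottom; bottom <- top; top <- tmp; hill <- -hill
  }
  out$ic50 <- ic50; out$hill <- hill; out$top <- top; out$bottom <- bottom
  out$rss <- best$rss; out$converged <- TRUE
  out
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "<dose_response_fit> IC50 = %.4g, hill = %.3g, top = %.3g, bottom = %.3g (rss %.3g, n = %d)\n",
      x$ic50, x$hill, x$top, x$bottom, x$rss, x$n_obs))
  } else {
    cat("<dose_response_fit> did not converge (non-identifiable or optimizer failure)\n")
  }
  invisible(x)
}

#' @rdname fit_dose_response
#' @param x A `dose_response_fit`.
#' @param ... Unused.
#' @method tidy dose_response_fit
#' @export
tidy.dose_response_fit <- function(x, ...) {
  tibble(term = c("ic50", "hill", "top", "bottom"),
         estimate = c(x$ic50, x$hill, x$top, x$bottom))
}

#' @rdname fit_dose_response
#' @method glance dose_response_fit
#' @export
glance.dose_response_fit <- function(x, ...) {
  tibble(ic50 = x$ic50, hill = x$hill, top = x$top, bottom = x$bottom,
         rss = x$rss, converged = x$converged, n_obs = x$n_obs)
}

#' Predicted inhibition at given doses
#'
#' @param object A converged `dose_response_fit`.
#' @param newdata Optional data frame with a `dose` column (defaults to the
#'   fitted data).
#' @param ... Unused.
#' @return Numeric vector of predicted percent inhibition.
#' @export
predict.dose_response_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) abort_validation("Cannot predict from a non-converged fit.")
  dose <- if (is.null(newdata)) object$data$dose else newdata$dose
  fourpl(dose, object$ic50, object$hill, object$top, object$bottom)
}

#' Relative expression by the 2^-ddCt method
#'
#' Fold change of a gene in a treatment group versus the control group,
#' normalized to a reference gene:
#' `ddCt = (Ct_gene,grp - Ct_ref,grp) - (Ct_gene,ctrl - Ct_ref,ctrl)`,
#' fold = `2^-ddCt`, using replicate-mean Ct values.
#'
#' @param ct Data frame with columns `gene`, `group`, `replicate`, `ct`.
#' @param gene Gene to quantify.
#' @param group Treatment group.
#' @param reference_gene Endogenous control gene (default `"GAPDH"`).
#' @param control_group Control group id (default `"control"`).
#' @return Fold change (dimensionless, positive).
#' @examples
#' ct <- simulate_ct_table(fold_changes = c(Bad = 2), noise_sd = 0, seed = 1)
#' fold_change_ddct(ct$ct, "Bad", "treated")
#' @export
fold_change_ddct <- function(ct, gene, group, reference_gene = "GAPDH",
                             control_group = "control") {
  ct <- as_tibble(ct)
  missing <- setdiff(c("gene", "group", "ct"), names(ct))
  if (length(missing) > 0) {
    abort_validation(paste0("Ct table missing columns: ",
                            paste(missing, collapse = ", "), "."))
  }
  check_finite(ct$ct, "ct")
  if (any(ct$ct <= 0)) abort_validation("Ct values must be positive.")
  mean_ct <- function(g, grp) {
    v <- ct$ct[ct$gene == g & ct$group == grp]
    if (length(v) == 0) {
      abort_validation(sprintf("No Ct measurements for gene \"%s\" in group \"%s\".", g, grp))
    }
    mean(v)
  }
  dct_grp <- mean_ct(gene, group) - mean_ct(reference_gene, group)
  dct_ctl <- mean_ct(gene, control_group) - mean_ct(reference_gene, control_group)
  2^(-(dct_grp - dct_ctl))
}

#' All-genes, all-groups 2^-ddCt table
#'
#' Tidy companion to [fold_change_ddct()]: one row per (gene, group) for
#' every non-reference gene and non-control group.
#'
#' @inheritParams fold_change_ddct
#' @return A tibble with columns `gene`, `group`, `fold_change`.
#' @export
fold_change_table <- function(ct, reference_gene = "GAPDH",
                              control_group = "control") {
  ct <- as_tibble(ct)
  genes <- setdiff(unique(ct$gene), reference_gene)
  groups <- setdiff(unique(ct$group), control_group)
  tidyr::expand_grid(gene = genes, group = groups) |>
    dplyr::mutate(fold_change = purrr::map2_dbl(
      .data$gene, .data$group,
      ~ fold_change_ddct(ct, .x, .y, reference_gene, control_group)))
}

#' Quadrant gating of two-channel flow-cytometry events
#'
#' Classifies each event by whether it exceeds the channel-1 and channel-2
#' gate thresholds (Annexin V-FITC and PI for apoptosis panels). An intensity
#' exactly equal to its threshold counts as negative. Quadrants follow the
#' apoptosis convention: Q1 = both positive (late apoptosis), Q2 = channel-1
#' negative / channel-2 positive (necrosis), Q3 = both negative (viable),
#' Q4 = channel-1 positive / channel-2 negative (early apoptosis).
#'
#' @param events Data frame with numeric columns `channel1`, `channel2`
#'   (non-negative intensities).
#' @param thresholds Length-2 numeric (strictly positive) gate values, in
#'   channel order.
#' @return A `quadrant_summary` tibble with columns `quadrant`, `count`,
#'   `fraction`; fractions sum to 1.
#' @examples
#' ev <- data.frame(channel1 = c(10, 200, 10, 200),
#'                  channel2 = c(10, 10, 200, 200))
#' classify_quadrants(ev, thresholds = c(100, 100))
#' @export
classify_quadrants <- function(events, thresholds = c(100, 100)) {
  events <- as_tibble(events)
  missing <- setdiff(c("channel1", "channel2"), names(events))
  if (length(missing) > 0) {
    abort_validation(paste0("Event table missing columns: ",
                            paste(missing, collapse = ", "), "."))
  }
  if (nrow(events) == 0) abort_undefined_ratio("No events: quadrant fractions undefined.")
  check_finite(events$channel1, "channel1")
  check_finite(events$channel2, "channel2")
  if (any(events$channel1 < 0) || any(events$channel2 < 0)) {
    abort_validation("Intensities must be non-negative.")
  }
  check_finite(thresholds, "thresholds")
  if (length(thresholds) != 2 || any(thresholds <= 0)) {
    abort_validation("`thresholds` must be two strictly positive gate values.")
  }
  p1 <- events$channel1 > thresholds[[1]]
  p2 <- events$channel2 > thresholds[[2]]
  q <- dplyr::case_when(p1 & p2 ~ "Q1", !p1 & p2 ~ "Q2",
                        !p1 & !p2 ~ "Q3", TRUE ~ "Q4")
  counts <- table(factor(q, levels = c("Q1", "Q2", "Q3", "Q4")))
  out <- tibble(quadrant = names(counts),
                count = as.integer(counts),
                fraction = as.integer(counts) / nrow(events))
  class(out) <- c("quadrant_summary", class(out))
  out
}

#' Apoptotic fraction from a quadrant summary
#'
#' `mode = "early"` returns the Q4 fraction (Annexin V+/PI-);
#' `mode = "total"` returns Q1 + Q4 (early plus late apoptosis).
#'
#' @param summary A `quadrant_summary` from [classify_quadrants()].
#' @param mode `"early"` or `"total"`.
#' @return A proportion in \[0, 1\].
#' @export
apoptotic_fraction <- function(summary, mode = c("early", "total")) {
  if (!inherits(summary, "quadrant_summary")) {
    abort_validation("`summary` must come from classify_quadrants().")
  }
  mode <- match.arg(mode)
  f <- stats::setNames(summary$fraction, summary$quadrant)
  if (mode == "early") unname(f["Q4"]) else unname(f["Q1"] + f["Q4"])
}

#' Depolarized fraction from JC-1 two-channel events
#'
#' In JC-1 staining, mitochondrial depolarization shifts fluorescence from
#' the aggregate channel to the monomer channel. An event is depolarized when
#' its aggregate/monomer intensity ratio falls below `ratio_threshold`.
#' Events with zero monomer signal are excluded (the ratio is undefined);
#' their count is attached as the `n_excluded` attribute.
#'
#' @param events Data frame with columns `channel1` (monomer) and `channel2`
#'   (aggregate).
#' @param ratio_threshold Positive ratio gate (default 1).
#' @return A proportion in \[0, 1\] with attributes `n_used`, `n_excluded`.
#' @export
jc1_depolarized_fraction <- function(events, ratio_threshold = 1) {
  events <- as_tibble(events)
  missing <- setdiff(c("channel1", "channel2"), names(events))
  if (length(missing) > 0) {
    abort_validation(paste0("Event table missing columns: ",
                            paste(missing, collapse = ", "), "."))
  }
  check_finite(ratio_threshold, "ratio_threshold")
  if (ratio_threshold <= 0) abort_validation("`ratio_threshold` must be positive.")
  usable <- events$channel1 > 0
  n_excluded <- sum(!usable)
  if (n_excluded > 0) {
    inform(sprintf("Excluding %d events with zero monomer signal.", n_excluded))
  }
  ev <- events[usable, ]
  if (nrow(ev) == 0) abort_undefined_ratio("No usable events: depolarized fraction undefined.")
  frac <- mean(ev$channel2 / ev$channel1 < ratio_threshold)
  structure(frac, n_used = nrow(ev), n_excluded = n_excluded)
}

#' Permutation test for a monotone dose trend
#'
#' Spearman rank correlation between dose and response, with a two-sided
#' permutation p-value obtained by shuffling responses across wells
#' (`p = (1 + #{|rho*| >= |rho|}) / (n_perm + 1)`). A constant response has
#' statistic 0 by convention.
#'
#' @param data Data frame with columns `dose` and `response`; at least 3 dose
#'   levels with at least 2 replicates each.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Seed for the permutation draw.
#' @return A one-row tibble: `statistic` (Spearman rho), `p_value`,
#'   `n_perm`, `n_obs`.
#' @export
dose_trend_test <- function(data, n_perm = 10000, seed = 1) {
  data <- as_tibble(data)
  missing <- setdiff(c("dose", "response"), names(data))
  if (length(missing) > 0) {
    abort_validation(paste0("Trend data missing columns: ",
                            paste(missing, collapse = ", "), "."))
  }
  check_finite(data$dose, "dose")
  check_finite(data$response, "response")
  reps <- table(data$dose)
  if (length(reps) < 3) abort_validation("Need at least 3 dose levels.")
  if (any(reps < 2)) abort_validation("Need at least 2 replicates per dose level.")
  rd <- rank(data$dose)
  rr <- rank(data$response)
  rho <- if (stats::sd(data$response) == 0) 0 else stats::cor(rd, rr)
  perm <- withr::with_seed(seed, replicate(n_perm, {
    rs <- rank(sample(data$response))
    if (stats::sd(rs) == 0) 0 else stats::cor(rd, rs)
  }))
  p <- (1 + sum(abs(perm) >= abs(rho) - 1e-12)) / (n_perm + 1)
  tibble(statistic = rho, p_value = p, n_perm = n_perm, n_obs = nrow(data))
}

#' Group comparisons for assay endpoints
#'
#' Thin reporting utility: one-way ANOVA across groups plus pairwise Welch
#' t-tests against a control group, with no multiplicity correction.
#'
#' @param data Data frame with a numeric `value` column and a `group` column.
#' @param control_group Group to compare the others against.
#' @return A list with `anova` (one-row tibble: `f_statistic`, `p_value`) and
#'   `pairwise` (tibble: `group`, `estimate`, `t_statistic`, `p_value`).
#' @export
compare_groups <- function(data, control_group = "control") {
  data <- as_tibble(data)
  missing <- setdiff(c("value", "group"), names(data))
  if (length(missing) > 0) {
    abort_validation(paste0("Data missing columns: ", paste(missing, collapse = ", "), "."))
  }
  if (!control_group %in% data$group) {
    abort_validation(sprintf("Control group \"%s\" not present.", control_group))
  }
  data$group <- factor(data$group)
  av <- summary(stats::aov(value ~ group, data = data))[[1]]
  anova_tbl <- tibble(f_statistic = av$`F value`[[1]], p_value = av$`Pr(>F)`[[1]])
  ctrl <- data$value[data$group == control_group]
  others <- setdiff(levels(data$group), control_group)
  pairwise <- purrr::map_dfr(others, function(g) {
    tt <- stats::t.test(data$value[data$group == g], ctrl, var.equal = FALSE)
    tibble(group = g, estimate = unname(diff(rev(tt$estimate))),
           t_statistic = unname(tt$statistic), p_value = tt$p.value)
  })
  list(anova = anova_tbl, pairwise = pairwise)
}
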