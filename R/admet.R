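#' Per-isoform predictive-accuracy weights for the composite CYP score
#'
#' The composite metabolism score weights each of the five major CYP450
#' inhibition predictions (signed class probabilities) by the overall
#' predictive accuracy of the corresponding upstream classifier. The default
#' accuracies are, applied positionally to the standard report column order
#' 1A2, 2C9, 2D6, 2C19, 3A4: 0.8147, 0.8018, 0.8551, 0.8054, 0.6450.
#'
#' @param q Numeric vector of five accuracies in (0, 1], in report column
#'   order (1A2, 2C9, 2D6, 2C19, 3A4).
#' @return A named numeric vector of length 5.
#' @examples
#' cyp_weights()
#' @export
cyp_weights <- function(q = c(0.8147, 0.8018, 0.8551, 0.8054, 0.6450)) {
  if (length(q) != 5) abort_arity("CYP weights must have exactly 5 entries.")
  check_finite(q, "q")
  if (any(q <= 0) || any(q > 1)) {
    abort_validation("CYP weights must lie in (0, 1].")
  }
  stats::setNames(as.numeric(q), cyp_cols())
}

cyp_cols <- function() c("cyp_1a2", "cyp_2c9", "cyp_2d6", "cyp_2c19", "cyp_3a4")

admet_required_cols <- function() {
  c("compound_id", "hia", "caco2", cyp_cols())
}

#' Composite CYP-inhibition score
#'
#' Weighted sum of the five signed CYP450 inhibition probabilities:
#' `score = sum_k cyp_k * q_k`. The sign of each entry encodes the predicted
#' class (inhibitor vs non-inhibitor) and its magnitude the classifier's
#' confidence, so negative predictions subtract from the score.
#'
#' @param cyp Either a numeric vector of 5 signed probabilities (in column
#'   order 1A2, 2C9, 2D6, 2C19, 3A4), or a data frame / matrix with the five
#'   `cyp_*` columns, in which case one score per row is returned.
#' @param weights Accuracy weights as produced by [cyp_weights()].
#' @return A numeric score (or vector of per-row scores).
#' @examples
#' cyp_composite_score(c(0.9774, 0.8257, 0.8931, 0.9296, 0.7959))
#' @export
cyp_composite_score <- function(cyp, weights = cyp_weights()) {
  weights <- cyp_weights(weights)
  if (is.data.frame(cyp)) {
    missing <- setdiff(cyp_cols(), names(cyp))
    if (length(missing) > 0) {
      abort_validation(paste0("Missing CYP columns: ", paste(missing, collapse = ", "), "."))
    }
    cyp <- as.matrix(cyp[, cyp_cols()])
  }
  if (is.matrix(cyp)) {
    if (ncol(cyp) != 5) abort_arity("CYP matrix must have exactly 5 columns.")
    check_finite(as.numeric(cyp), "cyp")
    if (any(abs(cyp) > 1)) abort_validation("Signed CYP probabilities must have |value| <= 1.")
    return(as.numeric(cyp %*% weights))
  }
  if (length(cyp) != 5) abort_arity("`cyp` must have exactly 5 entries.")
  check_finite(cyp, "cyp")
  if (any(abs(cyp) > 1)) abort_validation("Signed CYP probabilities must have |value| <= 1.")
  sum(cyp * weights)
}

#' Absorption filter on signed HIA and Caco-2 probabilities
#'
#' A compound is considered orally absorbable when both the human intestinal
#' absorption (HIA) and Caco-2 permeability predictions are strictly
#' positive; a value of exactly 0 fails.
#'
#' @param hia,caco2 Signed probabilities in \[-1, 1\] (vectorized).
#' @return Logical vector, `TRUE` where both endpoints are positive.
#' @examples
#' passes_absorption(0.9933, 0.6835)
#' passes_absorption(c(-0.62, 0.5), c(0.90, 0.5))
#' @export
passes_absorption <- function(hia, caco2) {
  if (anyNA(hia) || anyNA(caco2)) {
    abort_validation("`hia` and `caco2` must be present (non-missing) for every record.")
  }
  check_finite(hia, "hia")
  check_finite(caco2, "caco2")
  if (any(abs(hia) > 1) || any(abs(caco2) > 1)) {
    abort_validation("Signed probabilities must have |value| <= 1.")
  }
  hia > 0 & caco2 > 0
}

#' Screen a compound library on absorption and composite CYP score
#'
#' Applies the two-stage filter used to reduce a raw herbal chemical library
#' to candidate compounds: (1) discard compounds whose HIA or Caco-2 signed
#' probability is not positive; (2) discard compounds whose composite
#' CYP-inhibition score ([cyp_composite_score()]) does not exceed
#' `score_floor`. Every record is scored; discarded records carry a reason
#' code (`"absorption"` or `"score"`).
#'
#' @param records A data frame with columns `compound_id`, `hia`, `caco2` and
#'   the five `cyp_*` columns (see [read_admet_table()]); extra columns are
#'   carried through.
#' @param weights Accuracy weights, see [cyp_weights()].
#' @param score_floor Minimum composite score (exclusive); default 0.
#' @return A `screen_result` object: a list with `$compounds` (input tibble
#'   plus `score`, `retained`, `discard_reason`), `$weights`, `$score_floor`.
#'   Use [tidy()] / [glance()] / [rank_compounds()] on it.
#' @examples
#' tbl <- read_admet_table(system.file("extdata", "admet_candidates.csv",
#'                                     package = "netpharm"))
#' res <- screen_library(tbl)
#' glance(res)
#' @export
screen_library <- function(records, weights = cyp_weights(), score_floor = 0) {
  weights <- cyp_weights(weights)
  check_finite(score_floor, "score_floor")
  records <- as_tibble(records)
  missing <- setdiff(admet_required_cols(), names(records))
  if (length(missing) > 0) {
    abort_validation(paste0("Missing required columns: ", paste(missing, collapse = ", "), "."))
  }
  if (nrow(records) == 0) {
    compounds <- dplyr::mutate(records,
      score = numeric(0), retained = logical(0), discard_reason = character(0))
  } else {
    score <- cyp_composite_score(records, weights)
    absorbed <- passes_absorption(records$hia, records$caco2)
    retained <- absorbed & score > score_floor
    reason <- dplyr::case_when(
      retained ~ NA_character_,
      !absorbed ~ "absorption",
      TRUE ~ "score"
    )
    compounds <- records
    compounds$score <- score
    compounds$retained <- retained
    compounds$discard_reason <- reason
  }
  structure(
    list(compounds = compounds, weights = weights, score_floor = score_floor),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<screen_result> %d compounds: %d retained, %d discarded (%d absorption, %d score)\n",
    g$n_input, g$n_retained, g$n_discarded, g$n_discard_absorption, g$n_discard_score))
  cat(sprintf("score floor > %g; weights: %s\n", x$score_floor,
              paste(sprintf("%s=%.4f", names(x$weights), x$weights), collapse = ", ")))
  invisible(x)
}

#' @rdname screen_library
#' @param x A `screen_result`.
#' @param ... Unused.
#' @method tidy screen_result
#' @export
tidy.screen_result <- function(x, ...) as_tibble(x$compounds)

#' @rdname screen_library
#' @method glance screen_result
#' @export
glance.screen_result <- function(x, ...) {
  cm <- x$compounds
  tibble(
    n_input = nrow(cm),
    n_retained = sum(cm$retained),
    n_discarded = sum(!cm$retained),
    n_discard_absorption = sum(cm$discard_reason == "absorption", na.rm = TRUE),
    n_discard_score = sum(cm$discard_reason == "score", na.rm = TRUE),
    score_floor = x$score_floor
  )
}

#' Retained compounds in presentation order
#'
#' Orders the retained compounds of a [screen_library()] result the way
#' screening tables are presented: descending by composite score with ties
#' broken lexicographically by compound id, or alphabetically by id.
#'
#' @param result A `screen_result`.
#' @param key `"score"` (default, descending) or `"compound_id"` (ascending).
#' @return A tibble of the retained, scored records in order.
#' @export
rank_compounds <- function(result, key = c("score", "compound_id")) {
  if (!inherits(result, "screen_result")) {
    abort_validation("`result` must be a screen_result from screen_library().")
  }
  if (!is.character(key) || !key[[1]] %in% c("score", "compound_id")) {
    abort_validation("`key` must be one of \"score\", \"compound_id\".")
  }
  key <- key[[1]]
  kept <- dplyr::filter(result$compounds, .data$retained)
  if (key == "score") {
    dplyr::arrange(kept, dplyr::desc(.data$score), .data$compound_id)
  } else {
    dplyr::arrange(kept, .data$compound_id)
  }
}
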