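# Hypothesis scoring: survival, survival-inactive, selectivity.
#
# Survival is the fraction of actives a hypothesis matches;
# survival-inactive subtracts a lambda-penalized inactive match fraction;
# selectivity is an empirical rarity estimate, -log10 of the add-one
# smoothed fraction of an (activity-agnostic) reference set that matches.

#' Survival score: fraction of actives matched
#'
#' @param hyp A hypothesis (one row of a hypothesis table or a list).
#' @param actives Library tibble of active molecules with features.
#' @param match_fn Molecule-level matcher, `function(features, hyp)`
#'   returning a list with `matched` (default [match_molecule()]).
#' @return Fraction in \[0, 1\].
#' @export
survival_score <- function(hyp, actives, match_fn = match_molecule) {
  assert_library(actives)
  if (nrow(actives) == 0) abort("actives must be non-empty")
  hyp <- as_hypothesis(hyp)
  mean(map_lgl(actives$features, function(ft) match_fn(ft, hyp)$matched))
}

#' Survival-inactive score: survival minus penalized inactive matching
#'
#' `survival - penalty_lambda * (fraction of inactives matched)`; may be
#' negative. With an empty inactive set the plain survival score is
#' returned with a warning.
#'
#' @inheritParams survival_score
#' @param inactives Library tibble of inactive molecules.
#' @param penalty_lambda Non-negative penalty weight (default 1).
#' @return Unitless score `<=` survival.
#' @export
survival_inactive_score <- function(hyp, actives, inactives,
                                    penalty_lambda = 1,
                                    match_fn = match_molecule) {
  if (penalty_lambda < 0) abort("penalty_lambda must be >= 0")
  s <- survival_score(hyp, actives, match_fn)
  if (is.null(inactives) || nrow(inactives) == 0) {
    warn("no inactives supplied; survival-inactive equals survival")
    return(s)
  }
  hyp <- as_hypothesis(hyp)
  f_inact <- mean(map_lgl(inactives$features,
                          function(ft) match_fn(ft, hyp)$matched))
  s - penalty_lambda * f_inact
}

#' Selectivity score: empirical rarity of a hypothesis
#'
#' `-log10((n_matched + 1) / (N + 1))` over a reference set of N molecules
#' regardless of activity; higher means rarer, 0 means ubiquitous.
#'
#' @inheritParams survival_score
#' @param reference_set Library tibble used as the background population.
#' @return Non-negative score.
#' @export
selectivity_score <- function(hyp, reference_set,
                              match_fn = match_molecule) {
  assert_library(reference_set)
  if (nrow(reference_set) == 0) abort("reference_set must be non-empty")
  hyp <- as_hypothesis(hyp)
  n <- sum(map_lgl(reference_set$features,
                   function(ft) match_fn(ft, hyp)$matched))
  -log10((n + 1) / (nrow(reference_set) + 1))
}

#' Score a table of hypotheses against a labeled library
#'
#' Computes the match matrix once and derives all three scores plus match
#' counts for every hypothesis. The selectivity reference defaults to the
#' full library (actives + inactives) unless `reference` is supplied.
#'
#' @param hypotheses Hypothesis table.
#' @param library Labeled library tibble (labels `active`/`inactive`).
#' @param penalty_lambda Penalty weight for survival-inactive (default 1).
#' @param reference Optional external reference library for selectivity.
#' @param match_matrix Optional precomputed [build_match_matrix()] result
#'   for `library` x `hypotheses`.
#' @return Tibble: `hyp_id`, `survival`, `survival_inactive`,
#'   `selectivity`, `n_active_matched`, `n_inactive_matched`.
#' @export
score_hypotheses <- function(hypotheses, library, penalty_lambda = 1,
                             reference = NULL, match_matrix = NULL) {
  assert_library(library)
  if (!any(library$label == "active")) abort("library contains no actives")
  mm <- match_matrix %||% build_match_matrix(library, hypotheses)
  act <- library$label == "active"
  inact <- library$label == "inactive"
  if (!any(inact)) warn("library contains no inactives; survival-inactive equals survival")

  ref_counts <- NULL
  if (!is.null(reference)) {
    ref_mm <- build_match_matrix(reference, hypotheses)
    ref_counts <- map_dbl(hypotheses$hyp_id, function(h) sum(ref_mm[[h]]))
    ref_n <- nrow(reference)
  }

  rows <- map(hypotheses$hyp_id, function(h) {
    col <- mm[[h]]
    n_a <- sum(col[act]); n_i <- sum(col[inact])
    surv <- n_a / sum(act)
    si <- if (any(inact)) surv - penalty_lambda * n_i / sum(inact) else surv
    if (is.null(ref_counts)) {
      sel <- -log10((n_a + n_i + 1) / (sum(act) + sum(inact) + 1))
    } else {
      sel <- -log10((ref_counts[match(h, hypotheses$hyp_id)] + 1) / (ref_n + 1))
    }
    tibble(hyp_id = h, survival = surv, survival_inactive = si,
           selectivity = sel, n_active_matched = n_a, n_inactive_matched = n_i)
  })
  list_rbind(rows)
}

#' Filter scored hypotheses (two-stage)
#'
#' Stage 1 keeps hypotheses passing both score thresholds; stage 2 keeps
#' the `inactive_match_top_k` with the fewest inactive matches (ties broken
#' by higher survival-inactive, then `hyp_id`). This mirrors the
#' many-to-few-to-pool shape of a common-pharmacophore filtering pipeline.
#'
#' @param scores Score table from [score_hypotheses()].
#' @param hypotheses Hypothesis table the scores refer to.
#' @param survival_inactive_min,selectivity_min Stage-1 thresholds.
#' @param inactive_match_top_k Stage-2 pool size (>= 1).
#' @return The retained rows of `hypotheses`, sorted by `hyp_id`.
#' @export
filter_hypotheses <- function(scores, hypotheses,
                              survival_inactive_min = 0,
                              selectivity_min = 0.5,
                              inactive_match_top_k = 27) {
  if (inactive_match_top_k < 1) abort("inactive_match_top_k must be >= 1")
  stage1 <- scores |>
    filter(.data$survival_inactive >= survival_inactive_min,
           .data$selectivity >= selectivity_min)
  stage2 <- stage1 |>
    arrange(.data$n_inactive_matched, desc(.data$survival_inactive),
            .data$hyp_id) |>
    head(inactive_match_top_k)
  hypotheses |>
    filter(.data$hyp_id %in% stage2$hyp_id) |>
    arrange(.data$hyp_id)
}

#' Write hypothesis scores to CSV
#'
#' @param scores Score table from [score_hypotheses()].
#' @param path CSV path.
#' @return Invisibly, the score table.
#' @export
write_scores_csv <- function(scores, path) {
  readr::write_csv(scores, path)
  invisible(scores)
}
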