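# End-to-end combinatorial pharmacophore pipeline.

#' Run the full CP modeling pipeline on a labeled library
#'
#' Chains hypothesis generation, scoring, two-stage filtering,
#' combinatorial model enumeration and highest-BACC selection on a library
#' with perceived features.
#'
#' @details The support quota for hypothesis generation starts at
#'   `min_actives` (default `ceiling(0.5 * n_actives)`). If the filtered
#'   hypothesis pool is smaller than the smallest requested model size, no
#'   combination can be formed, so the quota is relaxed stepwise (halved,
#'   floor 2) until the pool is large enough; the quota actually used is
#'   returned. This keeps the strict combination sizes of the protocol
#'   while remaining usable on small or very clean libraries, where few
#'   distinct common geometries exist.
#'
#' @param library Labeled library tibble (labels `active`/`inactive`) with
#'   features.
#' @param k_values Hypothesis sizes to generate; subset of `c(3, 4)`.
#' @param sizes CP model sizes to enumerate; subset of `c(3, 4)`.
#' @param bin_width Distance binning width in Angstrom (default 1.0).
#' @param tol Matching tolerance in Angstrom (default 1.0).
#' @param penalty_lambda Survival-inactive penalty weight (default 1).
#' @param survival_inactive_min,selectivity_min,inactive_match_top_k
#'   Filtering knobs (see [filter_hypotheses()]).
#' @param min_actives Starting support quota (default half the actives).
#' @param max_hypotheses Cap on hypotheses carried into scoring (highest
#'   support first; combinatorial guard, default 100).
#' @return A `cp_model` with extra elements: `hypotheses` (the filtered
#'   pool), `scores`, `match_matrix`, `min_actives_used`.
#' @export
cp_pipeline <- function(library, k_values = c(3, 4), sizes = c(3, 4),
                        bin_width = 1.0, tol = 1.0, penalty_lambda = 1,
                        survival_inactive_min = 0, selectivity_min = 0.5,
                        inactive_match_top_k = 27, min_actives = NULL,
                        max_hypotheses = 100) {
  assert_library(library)
  actives <- library[library$label == "active", ]
  if (nrow(actives) == 0) abort("library contains no actives")
  q0 <- min_actives %||% ceiling(0.5 * nrow(actives))
  quotas <- q0
  while (quotas[length(quotas)] > 2) {
    quotas <- c(quotas, max(2, floor(quotas[length(quotas)] / 2)))
  }

  pool <- NULL
  scores <- NULL
  mm <- NULL
  used_quota <- NA_integer_
  for (q in quotas) {
    hyps <- enumerate_candidate_hypotheses(
      actives, k_values = k_values, min_actives = q,
      bin_width = bin_width, tol = tol
    )
    if (nrow(hyps) == 0) next
    if (nrow(hyps) > max_hypotheses) {
      hyps <- hyps |>
        arrange(desc(.data$n_support), .data$hyp_id) |>
        head(max_hypotheses) |>
        arrange(.data$hyp_id)
    }
    mm_all <- build_match_matrix(library, hyps, tol = tol)
    sc <- score_hypotheses(hyps, library, penalty_lambda = penalty_lambda,
                           match_matrix = mm_all)
    flt <- filter_hypotheses(sc, hyps,
                             survival_inactive_min = survival_inactive_min,
                             selectivity_min = selectivity_min,
                             inactive_match_top_k = inactive_match_top_k)
    if (nrow(flt) >= min(sizes)) {
      pool <- flt
      scores <- sc[sc$hyp_id %in% flt$hyp_id, ]
      mm <- mm_all[, c("mol_id", flt$hyp_id)]
      attr(mm, "tol") <- attr(mm_all, "tol")
      used_quota <- q
      break
    }
  }
  if (is.null(pool)) {
    abort("no hypothesis pool large enough to form any requested model size")
  }

  candidates <- enumerate_cp_models(pool$hyp_id, sizes = sizes)
  truth <- tibble(mol_id = library$mol_id, label = library$label)
  model <- select_best(candidates, mm, truth)
  model$hypotheses <- pool
  model$scores <- scores
  model$match_matrix <- mm
  model$min_actives_used <- used_quota
  model
}
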