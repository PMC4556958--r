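# Post-hoc component analyses: molecular-weight distributions per matched
# hypothesis, and per-class matching percentages for selective vs dual
# inhibitor sets.

#' Molecular-weight summary per matched hypothesis
#'
#' For each hypothesis, summarises the molecular weights of the molecules
#' matching it. Molecules matching several hypotheses contribute to each
#' (the columns overlap, as in per-hypothesis MW tables). Hypotheses
#' matched by nobody are omitted with a warning.
#'
#' @param library Library tibble with a `mol_weight` column.
#' @param match_matrix Match matrix from [build_match_matrix()].
#' @return Tibble: `hyp_id`, `n`, `mean`, `sd`, `median`, `min`, `max`
#'   (daltons).
#' @export
mw_by_hypothesis <- function(library, match_matrix) {
  assert_library(library)
  if (!"mol_weight" %in% names(library)) {
    abort("library has no mol_weight column")
  }
  hyps <- setdiff(names(match_matrix), "mol_id")
  mw <- library$mol_weight[match(match_matrix$mol_id, library$mol_id)]
  rows <- map(hyps, function(h) {
    v <- mw[match_matrix[[h]]]
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NULL)
    tibble(hyp_id = h, n = length(v), mean = mean(v), sd = sd(v),
           median = median(v), min = min(v), max = max(v))
  })
  empty <- hyps[map_lgl(rows, is.null)]
  if (length(empty) > 0) {
    warn(paste0("hypotheses matched by no molecule omitted: ",
                paste(empty, collapse = ", ")))
  }
  list_rbind(rows)
}

#' Matching percentages of selective and dual inhibitor classes
#'
#' Given three disjoint inhibitor libraries (selective for target A,
#' selective for target B, dual) and the hypothesis sets of both targets'
#' CP models, reports the percentage of each class matching each
#' hypothesis. Rows are independent percentages (they need not sum to
#' 100). Empty classes report `NA` with a warning.
#'
#' @param lib_a_selective,lib_b_selective,lib_dual Disjoint library
#'   tibbles with perceived features.
#' @param hyps_a,hyps_b Hypothesis tables of the two CP models.
#' @param tol Optional tolerance override for matching.
#' @return Tibble: `hyp_id`, `origin` (`"A"`/`"B"`), `class`, `n_class`,
#'   `pct` in \[0, 100\].
#' @export
selectivity_comparison <- function(lib_a_selective, lib_b_selective,
                                   lib_dual, hyps_a, hyps_b, tol = NULL) {
  libs <- list(A_selective = lib_a_selective,
               B_selective = lib_b_selective,
               dual = lib_dual)
  ids <- unlist(map(libs, function(l) l$mol_id))
  if (anyDuplicated(ids)) {
    abort("the three inhibitor classes must be disjoint by mol_id")
  }
  hyps <- bind_rows(
    mutate(hyps_a, origin = "A"),
    mutate(hyps_b, origin = "B")
  )
  rows <- list()
  for (cls in names(libs)) {
    lib <- libs[[cls]]
    if (is.null(lib) || nrow(lib) == 0) {
      warn(paste0("class ", cls, " is empty; percentages undefined"))
      rows[[cls]] <- tibble(hyp_id = hyps$hyp_id, origin = hyps$origin,
                            class = cls, n_class = 0L, pct = NA_real_)
      next
    }
    mm <- build_match_matrix(lib, hyps, tol = tol)
    rows[[cls]] <- tibble(
      hyp_id = hyps$hyp_id,
      origin = hyps$origin,
      class = cls,
      n_class = nrow(lib),
      pct = map_dbl(hyps$hyp_id, function(h) 100 * mean(mm[[h]]))
    )
  }
  list_rbind(unname(rows))
}

#' Box plot of molecular weights per matched hypothesis
#'
#' @inheritParams mw_by_hypothesis
#' @return A ggplot object.
#' @export
plot_mw_distribution <- function(library, match_matrix) {
  assert_library(library)
  mw <- library$mol_weight[match(match_matrix$mol_id, library$mol_id)]
  hyps <- setdiff(names(match_matrix), "mol_id")
  long <- list_rbind(map(hyps, function(h) {
    tibble(hyp_id = h, mol_weight = mw[match_matrix[[h]]])
  }))
  ggplot(long, aes(x = .data$hyp_id, y = .data$mol_weight)) +
    geom_boxplot() +
    labs(x = "pharmacophore hypothesis", y = "molecular weight (Da)") +
    theme_minimal()
}

#' Grouped bar chart of class matching percentages
#'
#' @param comparison Output of [selectivity_comparison()].
#' @return A ggplot object.
#' @export
plot_class_matching <- function(comparison) {
  ggplot(comparison,
         aes(x = .data$hyp_id, y = .data$pct, fill = .data$class)) +
    geom_col(position = position_dodge()) +
    labs(x = "pharmacophore hypothesis", y = "% of class matching",
         fill = "inhibitor class") +
    theme_minimal()
}

#' Bar chart of a CP model's metrics vs its members
#'
#' @param object A `cp_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cp_model
#' @export
autoplot.cp_model <- function(object, ...) {
  long <- bind_rows(
    mutate(tidy(object), model = .data$hyp_id),
    mutate(glance(object), model = "CP model")
  ) |>
    select("model", "se", "sp", "acc", "bacc") |>
    tidyr::pivot_longer(c("se", "sp", "acc", "bacc"),
                        names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$model, y = .data$value, fill = .data$metric)) +
    geom_col(position = position_dodge()) +
    labs(x = NULL, y = "metric value") +
    theme_minimal()
}
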