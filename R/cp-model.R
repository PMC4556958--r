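# Combinatorial pharmacophore (CP) model enumeration and selection.
#
# A CP model is an unordered set of 3 or 4 hypotheses classifying by the
# union rule: a molecule is predicted active when it matches any member.
# Every 3- and 4-member combination of the hypothesis pool is scored by
# confusion metrics on the calibration set and the model with the highest
# balanced accuracy is selected.

#' Union-rule classification
#'
#' A molecule is predicted `"active"` when it matches any one or more of a
#' model's member hypotheses.
#'
#' @param record_matches Logical vector: does the molecule match each
#'   member hypothesis?
#' @return `"active"` or `"inactive"`.
#' @examples
#' classify_union(c(TRUE, FALSE, FALSE))
#' @export
classify_union <- function(record_matches) {
  if (length(record_matches) == 0) abort("record_matches must be non-empty")
  if (any(is.na(record_matches))) abort("record_matches must not contain NA")
  if (any(record_matches)) "active" else "inactive"
}

#' Confusion metrics: SE, SP, ACC, BACC
#'
#' Counts true/false positives/negatives of predicted vs true activity
#' labels and derives sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`,
#' accuracy `(tp+tn)/n` and balanced accuracy `(se+sp)/2`. Values are kept
#' at full precision; round at report time (2 decimals is the table
#' convention).
#'
#' @param predictions,truth Character vectors of `"active"`/`"inactive"`,
#'   equal length; `truth` must contain both classes.
#' @return One-row tibble: `tp`, `tn`, `fp`, `fn`, `se`, `sp`, `acc`,
#'   `bacc`.
#' @examples
#' confusion_metrics(rep(c("active", "inactive"), c(4, 6)),
#'                   rep(c("active", "inactive"), c(5, 5)))
#' @export
confusion_metrics <- function(predictions, truth) {
  if (length(predictions) != length(truth)) {
    abort("predictions and truth must have equal length")
  }
  check_labels(predictions, allow_unknown = FALSE)
  check_labels(truth, allow_unknown = FALSE)
  for (cls in c("active", "inactive")) {
    if (!cls %in% truth) {
      abort(paste0("truth contains no '", cls, "' molecules; ",
                   "metrics are undefined"))
    }
  }
  tp <- sum(predictions == "active" & truth == "active")
  tn <- sum(predictions == "inactive" & truth == "inactive")
  fp <- sum(predictions == "active" & truth == "inactive")
  fn <- sum(predictions == "inactive" & truth == "active")
  se <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  tibble(tp = tp, tn = tn, fp = fp, fn = fn,
         se = se, sp = sp,
         acc = (tp + tn) / (tp + tn + fp + fn),
         bacc = (se + sp) / 2)
}

# Metrics straight from counts (back-solved printed tables, tests).
metrics_from_counts <- function(tp, tn, fp, fn) {
  se <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  tibble(tp = tp, tn = tn, fp = fp, fn = fn, se = se, sp = sp,
         acc = (tp + tn) / (tp + tn + fp + fn), bacc = (se + sp) / 2)
}

#' Enumerate all candidate CP models
#'
#' Returns every unordered subset of the hypothesis pool of each requested
#' size, exactly once, in lexicographic order of the sorted member ids.
#' With a pool of 27 hypotheses and sizes `{3, 4}` this is
#' `choose(27,3) + choose(27,4) = 20475` candidates.
#'
#' @param hyp_pool Character vector of hypothesis ids.
#' @param sizes Model sizes; subset of `c(3, 4)`.
#' @return Tibble: `model_id` (members joined by `+`), `size`, `members`
#'   (list of character vectors).
#' @examples
#' nrow(enumerate_cp_models(paste0("h", 1:4), sizes = c(3, 4)))  # 5
#' @export
enumerate_cp_models <- function(hyp_pool, sizes = c(3, 4)) {
  if (!all(sizes %in% c(3, 4))) abort("sizes must be a subset of {3, 4}")
  if (anyDuplicated(hyp_pool)) abort("hyp_pool must not contain duplicates")
  pool <- sort(unique(as.character(hyp_pool)))
  sizes <- sort(unique(sizes))
  feasible <- sizes[sizes <= length(pool)]
  if (length(feasible) == 0) {
    warn("hypothesis pool smaller than every requested model size")
    return(tibble(model_id = character(), size = integer(), members = list()))
  }
  res <- map(feasible, function(s) {
    cmb <- utils::combn(pool, s, simplify = FALSE)
    tibble(
      model_id = map_chr(cmb, paste, collapse = "+"),
      size = s,
      members = cmb
    )
  })
  list_rbind(res)
}

# Predicted labels of one member set from a logical match matrix.
union_predict <- function(M, members) {
  sub <- M[, members, drop = FALSE]
  ifelse(rowSums(sub) > 0, "active", "inactive")
}

# Align a labels input (tibble mol_id/label or named vector) to mol ids.
align_truth <- function(truth, mol_ids) {
  if (is.data.frame(truth)) {
    if (!all(c("mol_id", "label") %in% names(truth))) {
      abort("truth must have columns mol_id, label")
    }
    missing <- setdiff(mol_ids, truth$mol_id)
    if (length(missing) > 0) {
      abort(paste0("molecules missing from truth: ",
                   paste(missing, collapse = ", ")))
    }
    truth$label[match(mol_ids, truth$mol_id)]
  } else if (!is.null(names(truth))) {
    missing <- setdiff(mol_ids, names(truth))
    if (length(missing) > 0) {
      abort(paste0("molecules missing from truth: ",
                   paste(missing, collapse = ", ")))
    }
    unname(truth[mol_ids])
  } else {
    if (length(truth) != length(mol_ids)) {
      abort("unnamed truth vector must align with the match matrix rows")
    }
    as.character(truth)
  }
}

match_matrix_logical <- function(match_matrix, members = NULL) {
  cols <- setdiff(names(match_matrix), "mol_id")
  if (!is.null(members)) {
    miss <- setdiff(members, cols)
    if (length(miss) > 0) {
      abort(paste0("hypotheses missing from match matrix: ",
                   paste(miss, collapse = ", ")))
    }
    cols <- members
  }
  M <- as.matrix(as.data.frame(match_matrix)[, cols, drop = FALSE])
  storage.mode(M) <- "logical"
  rownames(M) <- match_matrix$mol_id
  M
}

#' Select the highest-BACC CP model
#'
#' Scores every candidate on the calibration set via the union rule and
#' returns the candidate with the highest balanced accuracy. Ties are
#' broken by higher sensitivity, then fewer members, then lexicographic
#' member ids, so the result is deterministic and independent of the
#' candidate order.
#'
#' @param candidates Candidate table from [enumerate_cp_models()].
#' @param match_matrix Match matrix from [build_match_matrix()] covering
#'   all member hypotheses.
#' @param truth Calibration labels: tibble `mol_id,label` or named vector.
#' @return A fitted `cp_model`: list with `members`, `size`,
#'   `metrics_calibration`, per-member single-hypothesis metrics, and the
#'   full ranked candidate table. Methods: [tidy()], [glance()],
#'   [autoplot()], `print()`.
#' @export
select_best <- function(candidates, match_matrix, truth) {
  if (nrow(candidates) == 0) abort("no candidate models to select from")
  all_members <- sort(unique(unlist(candidates$members)))
  M <- match_matrix_logical(match_matrix, all_members)
  y <- align_truth(truth, match_matrix$mol_id)
  check_labels(y, allow_unknown = FALSE)
  pos <- y == "active"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) abort("truth must contain both classes")

  stats <- map(candidates$members, function(mem) {
    hit <- rowSums(M[, mem, drop = FALSE]) > 0
    tp <- sum(hit & pos); fp <- sum(hit & !pos)
    c(tp = tp, fp = fp)
  })
  tp <- map_dbl(stats, "tp"); fp <- map_dbl(stats, "fp")
  fn <- n_pos - tp; tn <- n_neg - fp
  se <- tp / n_pos; sp <- tn / n_neg
  ranked <- candidates |>
    mutate(tp = tp, tn = tn, fp = fp, fn = fn, se = se, sp = sp,
           acc = (tp + tn) / (n_pos + n_neg), bacc = (se + sp) / 2) |>
    arrange(desc(.data$bacc), desc(.data$se), .data$size, .data$model_id)

  best <- ranked[1, ]
  members <- best$members[[1]]
  member_metrics <- list_rbind(map(members, function(h) {
    pred <- union_predict(M, h)
    bind_cols(tibble(hyp_id = h), confusion_metrics(pred, y))
  }))
  structure(
    list(
      members = members,
      size = length(members),
      metrics_calibration = select(best, "tp", "tn", "fp", "fn",
                                   "se", "sp", "acc", "bacc"),
      member_metrics = member_metrics,
      ranked = ranked,
      n_candidates = nrow(candidates)
    ),
    class = "cp_model"
  )
}

#' Evaluate a CP model (or any member set) on a labeled set
#'
#' Applies the union rule and computes confusion metrics. Single
#' hypotheses can be evaluated as degenerate 1-member models, which is how
#' per-hypothesis performance tables are produced.
#'
#' @param model A `cp_model`, or a character vector of member hyp_ids.
#' @param match_matrix Match matrix covering the members and molecules.
#' @param truth Labels: tibble `mol_id,label` or named vector.
#' @return One-row metrics tibble (see [confusion_metrics()]).
#' @export
evaluate_on_set <- function(model, match_matrix, truth) {
  members <- if (inherits(model, "cp_model")) model$members else
    as.character(model)
  M <- match_matrix_logical(match_matrix, members)
  y <- align_truth(truth, match_matrix$mol_id)
  confusion_metrics(union_predict(M, members), y)
}

#' Seeded stratified calibration/test split
#'
#' Splits a labeled library per class (default 50/50), mirroring the usual
#' calibration/test protocol for this kind of screen.
#'
#' @param library Labeled library tibble.
#' @param calibration_fraction Per-class calibration fraction (default 0.5).
#' @param seed Integer seed.
#' @return Named list of two library tibbles: `calibration`, `test`.
#' @export
split_calibration_test <- function(library, calibration_fraction = 0.5,
                                   seed = 1) {
  assert_library(library)
  withr::with_seed(seed, {
    idx <- unlist(map(unique(library$label), function(lb) {
      w <- which(library$label == lb)
      sample(w, size = round(calibration_fraction * length(w)))
    }))
  })
  list(calibration = library[sort(idx), ],
       test = library[setdiff(seq_len(nrow(library)), idx), ])
}

#' @export
print.cp_model <- function(x, ...) {
  cat("Combinatorial pharmacophore model (", x$size, " members)\n", sep = "")
  cat("  members:", paste(x$members, collapse = ", "), "\n")
  m <- x$metrics_calibration
  cat(sprintf("  calibration: SE %.2f  SP %.2f  ACC %.2f  BACC %.2f\n",
              m$se, m$sp, m$acc, m$bacc))
  cat("  selected from", x$n_candidates, "candidate models\n")
  invisible(x)
}

#' Tidy a fitted CP model: one row per member hypothesis
#'
#' @param x A `cp_model`.
#' @param ... Unused.
#' @return Tibble of per-member single-hypothesis calibration metrics.
#' @method tidy cp_model
#' @export
tidy.cp_model <- function(x, ...) {
  x$member_metrics
}

#' Glance at a fitted CP model: one-row model summary
#'
#' @param x A `cp_model`.
#' @param ... Unused.
#' @return One-row tibble with the calibration metrics, member count and
#'   candidate count.
#' @method glance cp_model
#' @export
glance.cp_model <- function(x, ...) {
  bind_cols(
    tibble(n_members = x$size, n_candidates = x$n_candidates),
    x$metrics_calibration
  )
}

#' Write / read a CP model as JSON
#'
#' Format: `{members: [...], metrics: {...}}`.
#'
#' @param model A `cp_model`.
#' @param path JSON path.
#' @return `write_cp_model()`: invisibly, the model; `read_cp_model()`: a
#'   list with `members` and `metrics`.
#' @export
write_cp_model <- function(model, path) {
  jsonlite::write_json(
    list(members = model$members,
         metrics = as.list(model$metrics_calibration)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(model)
}

#' @rdname write_cp_model
#' @export
read_cp_model <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(members = as.character(obj$members),
       metrics = as_tibble(obj$metrics))
}
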