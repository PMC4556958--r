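# Distance-based pharmacophore matching.
#
# A hypothesis with k typed sites and a k x k inter-site distance matrix is
# matched by a conformer when some injective assignment of feature points to
# sites agrees site-by-site in type and pairwise distance (|d_features -
# d_hypothesis| <= tol for every pair). Matching uses inter-feature
# distances only -- no superposition -- so it is rigid-motion invariant by
# construction and exact for k <= 4. Among valid assignments the one with
# the smallest root-mean-square pairwise-distance deviation is reported,
# ties broken by the lexicographically smallest assignment.

# Normalize a hypothesis passed either as a one-row cp_hypotheses tibble or
# as a plain list(hyp_id, sites, dist, tol).
as_hypothesis <- function(hyp) {
  if (is.data.frame(hyp)) {
    if (nrow(hyp) != 1) abort("expected a single hypothesis (one row)")
    hyp <- list(hyp_id = hyp$hyp_id[[1]], sites = hyp$sites[[1]],
                dist = hyp$dist[[1]], tol = hyp$tol[[1]])
  }
  validate_hypothesis(hyp)
  hyp
}

validate_hypothesis <- function(hyp) {
  k <- length(hyp$sites)
  if (!k %in% c(1:4)) abort("hypothesis must have 1-4 sites")
  if (!all(hyp$sites %in% ftype_vocab())) {
    abort("hypothesis sites must use the A/D/H/N/P/R vocabulary")
  }
  d <- hyp$dist
  if (!is.matrix(d) || nrow(d) != k || ncol(d) != k) {
    abort("hypothesis distance matrix must be k x k")
  }
  if (max(abs(d - t(d))) > 1e-8 || any(diag(d) != 0)) {
    abort("hypothesis distance matrix must be symmetric with zero diagonal")
  }
  if (k > 1 && any(d[upper.tri(d)] <= 0)) {
    abort("hypothesis inter-site distances must be positive")
  }
  if (k >= 3) {
    for (tri in utils::combn(k, 3, simplify = FALSE)) {
      a <- d[tri[1], tri[2]]; b <- d[tri[1], tri[3]]; cc <- d[tri[2], tri[3]]
      if (a > b + cc + 1e-8 || b > a + cc + 1e-8 || cc > a + b + 1e-8) {
        abort("hypothesis distances violate the triangle inequality")
      }
    }
  }
  invisible(hyp)
}

no_match <- function() {
  list(matched = FALSE, conf_id = NA_integer_, assignment = integer(),
       max_deviation = NA_real_, rmsd_dist = NA_real_)
}

#' Match one conformer's features against a hypothesis
#'
#' Exact search over all type-consistent injective assignments of feature
#' points to hypothesis sites; a conformer matches when every pairwise
#' feature distance deviates from the hypothesis distance by at most `tol`.
#'
#' @param features Tibble of feature points (`ftype`, `x`, `y`, `z`) for a
#'   single conformer.
#' @param hyp A hypothesis: one row of a hypothesis table or a list with
#'   `sites` (character vector), `dist` (k x k matrix, Angstrom) and `tol`.
#' @param tol Optional tolerance override (Angstrom).
#' @return A list: `matched`, `conf_id` (NA here), `assignment` (site index
#'   -> feature row), `max_deviation`, `rmsd_dist`.
#' @examples
#' feats <- tibble::tibble(ftype = c("H", "H", "R"),
#'                         x = c(0, 3, 0), y = c(0, 0, 4), z = 0)
#' hyp <- list(hyp_id = "HHR", sites = c("H", "H", "R"),
#'             dist = matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3), tol = 0.5)
#' match_conformer(feats, hyp)$matched
#' @export
match_conformer <- function(features, hyp, tol = NULL) {
  hyp <- as_hypothesis(hyp)
  tol <- tol %||% hyp$tol %||% 1.0
  k <- length(hyp$sites)
  if (is.null(features) || nrow(features) < k) return(no_match())
  cand <- map(hyp$sites, function(s) which(features$ftype == s))
  if (any(lengths(cand) == 0)) return(no_match())

  asg <- as.matrix(expand.grid(cand, KEEP.OUT.ATTRS = FALSE))
  if (k > 1) {
    distinct_rows <- rep(TRUE, nrow(asg))
    for (pp in utils::combn(k, 2, simplify = FALSE)) {
      distinct_rows <- distinct_rows & (asg[, pp[1]] != asg[, pp[2]])
    }
    asg <- asg[distinct_rows, , drop = FALSE]
  }
  if (nrow(asg) == 0) return(no_match())
  if (k == 1) {
    a <- sort(asg[, 1])[1]
    return(list(matched = TRUE, conf_id = NA_integer_,
                assignment = as.integer(a),
                max_deviation = 0, rmsd_dist = 0))
  }

  dfeat <- pairwise_dist(as.matrix(features[, c("x", "y", "z")]))
  pairs <- pair_index(k)
  dev <- matrix(NA_real_, nrow(asg), nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    dev[, p] <- abs(dfeat[cbind(asg[, i], asg[, j])] - hyp$dist[i, j])
  }
  ok <- rowSums(dev > tol) == 0
  if (!any(ok)) return(no_match())
  asg <- asg[ok, , drop = FALSE]
  dev <- dev[ok, , drop = FALSE]
  rmsd <- sqrt(rowMeans(dev^2))
  ord <- do.call(order, c(list(rmsd), as.data.frame(asg)))
  best <- ord[1]
  list(matched = TRUE, conf_id = NA_integer_,
       assignment = as.integer(asg[best, ]),
       max_deviation = max(dev[best, ]),
       rmsd_dist = rmsd[best])
}

#' Match a molecule (any conformer) against a hypothesis
#'
#' OR semantics over the conformer ensemble: the molecule matches when any
#' conformer matches; the best (lowest `rmsd_dist`) conformer is reported,
#' ties broken by the smaller `conf_id`.
#'
#' @param features Tibble of feature points with a `conf_id` column (a
#'   library's per-molecule feature table).
#' @inheritParams match_conformer
#' @return As [match_conformer()], with `conf_id` set to the best conformer.
#' @export
match_molecule <- function(features, hyp, tol = NULL) {
  if (is.null(features) || nrow(features) == 0) {
    warn("molecule has no features; reporting no match")
    return(no_match())
  }
  if (!"conf_id" %in% names(features)) {
    features <- mutate(features, conf_id = 1L)
  }
  best <- no_match()
  for (cid in sort(unique(features$conf_id))) {
    res <- match_conformer(features[features$conf_id == cid, ], hyp, tol)
    if (res$matched &&
        (!best$matched || res$rmsd_dist < best$rmsd_dist - 1e-12)) {
      res$conf_id <- as.integer(cid)
      best <- res
    }
  }
  best
}

#' Build the molecule-by-hypothesis match matrix
#'
#' Evaluates [match_molecule()] for every (molecule, hypothesis) pair and
#' caches the boolean results in a tibble: one row per molecule, one
#' logical column per `hyp_id`. This is the workhorse behind hypothesis
#' scoring and the combinatorial model scan.
#'
#' @param library Molecule library tibble with perceived features.
#' @param hypotheses Hypothesis table (e.g. from
#'   [enumerate_candidate_hypotheses()]).
#' @param tol Optional tolerance override applied to every hypothesis.
#' @return A tibble (class `cp_match_matrix`) with columns `mol_id` and one
#'   logical column per hypothesis; the tolerance is kept in the `"tol"`
#'   attribute.
#' @export
build_match_matrix <- function(library, hypotheses, tol = NULL) {
  assert_library(library)
  out <- tibble(mol_id = library$mol_id)
  for (h in seq_len(nrow(hypotheses))) {
    hyp <- as_hypothesis(hypotheses[h, ])
    out[[hyp$hyp_id]] <- map_lgl(library$features, function(ft) {
      if (is.null(ft) || nrow(ft) == 0) return(FALSE)
      match_molecule(ft, hyp, tol)$matched
    })
  }
  class(out) <- c("cp_match_matrix", class(out))
  attr(out, "tol") <- tol %||%
    (if (nrow(hypotheses) > 0) hypotheses$tol[[1]] else NA_real_)
  out
}

#' Write / read a match matrix as CSV
#'
#' Values are stored as 0/1 with a `#`-prefixed metadata header recording
#' the matching tolerance, feature-definition version and conformer seed.
#'
#' @param mm Match matrix from [build_match_matrix()].
#' @param path CSV path.
#' @param defs_version,conformer_seed Metadata recorded in the header.
#' @return `write_match_matrix()`: invisibly, `mm`; `read_match_matrix()`:
#'   the match matrix tibble.
#' @export
write_match_matrix <- function(mm, path, defs_version = NA,
                               conformer_seed = NA) {
  meta <- paste0("# tol=", attr(mm, "tol") %||% NA,
                 " defs_version=", defs_version,
                 " conformer_seed=", conformer_seed)
  num <- mm
  for (nm in setdiff(names(num), "mol_id")) num[[nm]] <- as.integer(num[[nm]])
  writeLines(meta, path)
  suppressWarnings(
    readr::write_csv(as_tibble(num), path, append = TRUE, col_names = TRUE)
  )
  invisible(mm)
}

#' @rdname write_match_matrix
#' @export
read_match_matrix <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  mm <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  meta <- readLines(path, n = 1)
  for (nm in setdiff(names(mm), "mol_id")) mm[[nm]] <- mm[[nm]] > 0
  class(mm) <- c("cp_match_matrix", class(mm))
  tol <- suppressWarnings(as.numeric(sub(".*tol=([^ ]+).*", "\\1", meta)))
  attr(mm, "tol") <- tol
  mm
}
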