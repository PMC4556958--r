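# Common-pharmacophore hypothesis generation.
#
# Every k-subset (k in {3,4}) of feature points on every conformer of every
# active is reduced to a canonical (type multiset, sorted distance vector)
# form. Tuples are partitioned by discretizing the canonical distance
# vector into bins of width `bin_width`; a cell supported by at least
# `min_actives` distinct actives becomes a hypothesis whose geometry is the
# medoid tuple of the cell. Cells of the same type multiset whose medoids
# agree within `bin_width` on every pair are merged. The procedure is
# deterministic and invariant to the order of the input actives.

# All permutations of 1..k (k <= 4), in lexicographic order.
perms_k <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  rec <- function(prefix, rest) {
    if (length(rest) == 0) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (i in seq_along(rest)) rec(c(prefix, rest[i]), rest[-i])
  }
  rec(integer(), seq_len(k))
  out
}

# Canonical form of a feature tuple: order sites so types are sorted and,
# among type-preserving orders, the upper-triangle distance vector is
# lexicographically smallest. Returns list(types, dvec).
canonical_tuple <- function(ftypes, dmat) {
  k <- length(ftypes)
  pairs <- pair_index(k)
  best <- NULL
  for (p in perms_k(k)) {
    tt <- ftypes[p]
    if (is.unsorted(tt)) next
    dd <- dmat[p, p, drop = FALSE]
    dv <- dd[cbind(pairs[, 1], pairs[, 2])]
    if (is.null(best) || lex_less(c(match(tt, LETTERS), dv),
                                  c(match(best$types, LETTERS), best$dvec))) {
      best <- list(types = tt, dvec = dv)
    }
  }
  best
}

# Strict lexicographic comparison of two equal-length numeric vectors.
lex_less <- function(a, b) {
  d <- a - b
  nz <- which(abs(d) > 1e-12)
  length(nz) > 0 && d[nz[1]] < 0
}

# Rebuild a k x k distance matrix from a canonical pair-ordered vector.
dvec_to_matrix <- function(dvec, k) {
  m <- matrix(0, k, k)
  m[upper.tri(m)] <- dvec
  m + t(m)
}

new_hypotheses <- function(hyp_id, sites, dist, tol, n_support,
                           support_ids = NULL) {
  tibble(
    hyp_id = hyp_id,
    k = lengths(sites),
    sites = sites,
    dist = dist,
    tol = tol,
    n_support = n_support,
    support_ids = support_ids %||% rep(list(character()), length(hyp_id))
  )
}

#' Enumerate candidate common-pharmacophore hypotheses from actives
#'
#' Searches all 3- and/or 4-point feature tuples across the conformers of
#' the active molecules for recurring typed geometries (see the file-level
#' notes for the binning scheme). Hypothesis ids are the sorted feature
#' letters plus a disambiguating index when several geometries share a type
#' multiset (e.g. `HHR1`, `HHR2`).
#'
#' @param actives Library tibble of active molecules with perceived
#'   features (inactives, if present, are ignored with a message).
#' @param k_values Hypothesis sizes to search; subset of `c(3, 4)`.
#' @param min_actives Minimum number of distinct actives that must carry a
#'   tuple for it to become a hypothesis. Default `ceiling(0.5 * n_actives)`.
#' @param bin_width Distance-discretization width in Angstrom (default 1.0).
#' @param tol Matching tolerance stored on each hypothesis (default 1.0 A).
#' @param max_features_per_conformer Conformers with more feature points
#'   than this are skipped with a warning (combinatorial guard, default 20).
#' @return A hypothesis table: `hyp_id`, `k`, `sites` (list), `dist` (list
#'   of k x k matrices), `tol`, `n_support`, `support_ids`, sorted by
#'   `hyp_id`.
#' @export
enumerate_candidate_hypotheses <- function(actives, k_values = c(3, 4),
                                           min_actives = NULL,
                                           bin_width = 1.0, tol = 1.0,
                                           max_features_per_conformer = 20) {
  assert_library(actives)
  if (!all(k_values %in% c(3, 4))) {
    abort("k_values must be a subset of {3, 4}")
  }
  if ("label" %in% names(actives) && any(actives$label != "active")) {
    inform("dropping non-active molecules from hypothesis generation")
    actives <- actives[actives$label == "active", ]
  }
  no_feat <- map_lgl(actives$features, function(f) is.null(f) || nrow(f) == 0)
  if (any(no_feat)) {
    warn(paste0("excluding active(s) without features: ",
                paste(actives$mol_id[no_feat], collapse = ", ")))
    actives <- actives[!no_feat, ]
  }
  n_act <- nrow(actives)
  if (n_act == 0) abort("no actives with features")
  min_actives <- min_actives %||% ceiling(0.5 * n_act)

  # canonical order regardless of input order
  actives <- arrange(actives, .data$mol_id)

  tuples <- list()
  for (i in seq_len(n_act)) {
    ft <- actives$features[[i]]
    if (!"conf_id" %in% names(ft)) ft$conf_id <- 1L
    for (cid in sort(unique(ft$conf_id))) {
      fc <- ft[ft$conf_id == cid, ]
      m <- nrow(fc)
      if (m > max_features_per_conformer) {
        warn(paste0("skipping conformer with ", m, " features (cap ",
                    max_features_per_conformer, ") in ", actives$mol_id[i]))
        next
      }
      if (m < min(k_values)) next
      xyz <- as.matrix(fc[, c("x", "y", "z")])
      dmat <- pairwise_dist(xyz)
      for (k in k_values) {
        if (m < k) next
        for (sub in utils::combn(m, k, simplify = FALSE)) {
          can <- canonical_tuple(fc$ftype[sub], dmat[sub, sub, drop = FALSE])
          tuples[[length(tuples) + 1]] <- list(
            types = paste(can$types, collapse = ""),
            dvec = can$dvec,
            mol_id = actives$mol_id[i]
          )
        }
      }
    }
  }
  if (length(tuples) == 0) {
    return(new_hypotheses(character(), list(), list(), numeric(), integer()))
  }

  keys <- map_chr(tuples, function(t) {
    paste(t$types, paste(floor(t$dvec / bin_width), collapse = ","), sep = "|")
  })
  cells <- split(tuples, keys)

  cell_summ <- map(cells, function(cell) {
    dvs <- do.call(rbind, map(cell, "dvec"))
    med <- medoid_row(dvs, map_chr(cell, "mol_id"))
    list(types = cell[[1]]$types, dvec = dvs[med, ],
         records = cell, support = unique(sort(map_chr(cell, "mol_id"))))
  })
  # deterministic order: type string, then medoid distance vector
  ord <- order(map_chr(cell_summ, "types"),
               map_chr(cell_summ, function(s) {
                 paste(sprintf("%012.6f", s$dvec), collapse = ",")
               }))
  cell_summ <- cell_summ[ord]

  # merge adjacent-bin duplicates (same type multiset, medoids within
  # bin_width on every pair)
  merged <- list()
  for (cs in cell_summ) {
    hit <- 0L
    for (j in seq_along(merged)) {
      if (merged[[j]]$types == cs$types &&
          max(abs(merged[[j]]$dvec - cs$dvec)) <= bin_width) {
        hit <- j
        break
      }
    }
    if (hit > 0L) {
      comb <- c(merged[[hit]]$records, cs$records)
      dvs <- do.call(rbind, map(comb, "dvec"))
      med <- medoid_row(dvs, map_chr(comb, "mol_id"))
      merged[[hit]] <- list(types = cs$types, dvec = dvs[med, ],
                            records = comb,
                            support = unique(sort(map_chr(comb, "mol_id"))))
    } else {
      merged[[length(merged) + 1]] <- cs
    }
  }

  # support quota applies to the merged geometries (exact inter-site
  # distances can straddle bin edges, so support is counted after merging)
  merged <- keep(merged, function(s) length(s$support) >= min_actives)
  if (length(merged) == 0) {
    return(new_hypotheses(character(), list(), list(), numeric(), integer()))
  }

  types <- map_chr(merged, "types")
  ids <- character(length(merged))
  for (tt in unique(types)) {
    idx <- which(types == tt)
    idx <- idx[order(map_chr(merged[idx], function(s) {
      paste(sprintf("%012.6f", s$dvec), collapse = ",")
    }))]
    ids[idx] <- if (length(idx) == 1) tt else paste0(tt, seq_along(idx))
  }

  k_of <- nchar(types)
  res <- new_hypotheses(
    hyp_id = ids,
    sites = map(merged, function(s) strsplit(s$types, "")[[1]]),
    dist = map(seq_along(merged), function(i) {
      dvec_to_matrix(merged[[i]]$dvec, k_of[i])
    }),
    tol = rep(tol, length(merged)),
    n_support = map_int(merged, function(s) length(s$support)),
    support_ids = map(merged, "support")
  )
  arrange(res, .data$hyp_id)
}

# Index of the medoid row of a matrix of distance vectors (min summed
# Euclidean distance to the others; ties by lexicographic vector then id).
medoid_row <- function(dvs, ids) {
  n <- nrow(dvs)
  if (n == 1) return(1L)
  dd <- as.matrix(dist(dvs))
  cost <- rowSums(dd)
  cand <- which(abs(cost - min(cost)) < 1e-9)
  if (length(cand) == 1) return(cand)
  key <- map_chr(cand, function(i) {
    paste(paste(sprintf("%012.6f", dvs[i, ]), collapse = ","), ids[i])
  })
  cand[order(key)][1]
}

#' Write / read hypotheses as JSON
#'
#' The interchange format is a JSON array of objects
#' `{hyp_id, sites, distances, tol, provenance}`; distances are the full
#' k x k matrix. Round-trips exactly.
#'
#' @param hypotheses Hypothesis table.
#' @param path JSON path.
#' @return `write_hypotheses()`: invisibly, the table;
#'   `read_hypotheses()`: a hypothesis table.
#' @export
write_hypotheses <- function(hypotheses, path) {
  objs <- map(seq_len(nrow(hypotheses)), function(i) {
    list(
      hyp_id = hypotheses$hyp_id[[i]],
      sites = as.list(hypotheses$sites[[i]]),
      distances = hypotheses$dist[[i]],
      tol = hypotheses$tol[[i]],
      provenance = if ("provenance" %in% names(hypotheses)) {
        hypotheses$provenance[[i]]
      } else NULL
    )
  })
  jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(hypotheses)
}

#' @rdname write_hypotheses
#' @export
read_hypotheses <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  objs <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- map(objs, function(o) {
    if (is.null(o$hyp_id) || is.null(o$sites) || is.null(o$distances)) {
      abort("hypothesis JSON objects need hyp_id, sites, distances")
    }
    sites <- unlist(o$sites)
    k <- length(sites)
    d <- matrix(unlist(o$distances), k, k, byrow = TRUE)
    hyp <- list(hyp_id = o$hyp_id, sites = sites, dist = d,
                tol = o$tol %||% 1.0)
    validate_hypothesis(hyp)
    hyp
  })
  new_hypotheses(
    hyp_id = map_chr(rows, "hyp_id"),
    sites = map(rows, "sites"),
    dist = map(rows, "dist"),
    tol = map_dbl(rows, "tol"),
    n_support = rep(NA_integer_, length(rows))
  )
}
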