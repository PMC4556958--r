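# Deterministic synthetic benchmark libraries.
#
# Feature-cloud libraries bypass chemistry entirely: each molecule is a
# small cloud of typed feature points. Actives carry one planted hypothesis
# geometry (jittered by isotropic Gaussian noise) plus random decoy
# features; inactives carry decoys only and are rejection-sampled so that
# none matches any planted hypothesis at the library tolerance. A manifest
# records the ground truth, making the generator usable as an oracle for
# every downstream module.

#' Default planted hypotheses
#'
#' Two 3-site hypotheses used as the standard planted ground truth: a
#' two-hydrophobe + ring triangle (`HHR`, sides 3/4/5 A) and a
#' donor + two-ring triangle (`DRR`, sides 4/5/6 A).
#'
#' @param tol Matching tolerance stored on the hypotheses (default 1 A).
#' @return A hypothesis table with two rows.
#' @export
default_planted_hypotheses <- function(tol = 1.0) {
  new_hypotheses(
    hyp_id = c("HHR", "DRR"),
    sites = list(c("H", "H", "R"), c("D", "R", "R")),
    dist = list(dvec_to_matrix(c(3, 4, 5), 3),
                dvec_to_matrix(c(4, 5, 6), 3)),
    tol = c(tol, tol),
    n_support = c(NA_integer_, NA_integer_)
  )
}

# Embed a k x k distance matrix as k points in 3D (exact for Euclidean
# matrices; k <= 4 by construction).
embed_distances <- function(dmat) {
  k <- nrow(dmat)
  if (k == 1) return(matrix(0, 1, 3))
  if (k == 2) return(rbind(c(0, 0, 0), c(dmat[1, 2], 0, 0)))
  pts <- cmdscale(stats::as.dist(dmat), k = min(3, k - 1))
  pts <- cbind(pts, matrix(0, k, 3 - ncol(pts)))
  err <- max(abs(pairwise_dist(pts) - dmat))
  if (err > 1e-6) {
    abort(paste0("distance matrix is not 3D-embeddable (error ",
                 signif(err, 3), " A)"))
  }
  pts
}

#' Generate a feature-cloud library with planted pharmacophores
#'
#' Each active contains one planted hypothesis geometry, rigidly rotated
#' and translated at random and jittered by isotropic Gaussian noise of
#' scale `noise_sigma`, plus `decoy_features_per_mol` random decoy
#' features. Plants cycle over `planted_hyps` so each hypothesis is carried
#' by an equal share of the actives. Inactives contain only decoys and are
#' rejection-sampled so that none matches any planted hypothesis at `tol`.
#' The result is byte-identical for a fixed seed.
#'
#' @param n_active,n_inactive Library composition (defaults 20 / 200).
#' @param planted_hyps Hypothesis table of planted geometries (default
#'   [default_planted_hypotheses()]).
#' @param noise_sigma Per-coordinate jitter SD in Angstrom (default 0.2).
#' @param decoy_features_per_mol Decoy features per molecule (default 5).
#' @param seed Integer seed.
#' @param box Edge length (A) of the cube containing decoy features and
#'   plant centers (default 8).
#' @param tol Library matching tolerance in Angstrom (default 1.0).
#' @param max_tries Rejection-sampling cap per inactive (default 100).
#' @return A list: `library` (feature-cloud library tibble) and `manifest`
#'   (planted hypotheses, per-molecule ground truth, seed, tol).
#' @examples
#' fix <- make_planted_library(n_active = 4, n_inactive = 10, seed = 7)
#' fix$manifest$molecules
#' @export
make_planted_library <- function(n_active = 20, n_inactive = 200,
                                 planted_hyps = default_planted_hypotheses(),
                                 noise_sigma = 0.2,
                                 decoy_features_per_mol = 5,
                                 seed = 1, box = 8, tol = 1.0,
                                 max_tries = 100) {
  if (n_active < 1) abort("n_active must be >= 1")
  if (noise_sigma < 0) abort("noise_sigma must be >= 0")
  for (i in seq_len(nrow(planted_hyps))) as_hypothesis(planted_hyps[i, ])

  vocab <- ftype_vocab()
  n_hyp <- nrow(planted_hyps)
  geoms <- map(planted_hyps$dist, embed_distances)
  k_mean <- round(mean(planted_hyps$k))

  withr::with_seed(seed, {
    wid <- max(nchar(n_active), nchar(n_inactive), 3)
    act_ids <- sprintf(paste0("ACT%0", wid, "d"), seq_len(n_active))
    inact_ids <- sprintf(paste0("INA%0", wid, "d"), seq_len(n_inactive))
    plant_of <- planted_hyps$hyp_id[((seq_len(n_active) - 1) %% n_hyp) + 1]

    act_feats <- map(seq_len(n_active), function(i) {
      hidx <- match(plant_of[i], planted_hyps$hyp_id)
      pts <- geoms[[hidx]] %*% t(random_rotation())
      ctr <- runif(3, 0.25 * box, 0.75 * box)
      pts <- sweep(pts, 2, colMeans(pts)) + matrix(ctr, nrow(pts), 3,
                                                   byrow = TRUE)
      pts <- pts + matrix(rnorm(length(pts), sd = noise_sigma), nrow(pts), 3)
      nd <- decoy_features_per_mol
      tibble(
        conf_id = 1L,
        ftype = c(planted_hyps$sites[[hidx]], sample(vocab, nd, replace = TRUE)),
        x = c(pts[, 1], runif(nd, 0, box)),
        y = c(pts[, 2], runif(nd, 0, box)),
        z = c(pts[, 3], runif(nd, 0, box))
      )
    })

    nd_inact <- decoy_features_per_mol + k_mean
    inact_feats <- map(seq_len(n_inactive), function(i) {
      for (try in seq_len(max_tries)) {
        ft <- tibble(
          conf_id = 1L,
          ftype = sample(vocab, nd_inact, replace = TRUE),
          x = runif(nd_inact, 0, box),
          y = runif(nd_inact, 0, box),
          z = runif(nd_inact, 0, box)
        )
        hit <- any(map_lgl(seq_len(n_hyp), function(h) {
          match_conformer(ft, planted_hyps[h, ], tol = tol)$matched
        }))
        if (!hit) return(ft)
      }
      abort(paste0("rejection sampling failed for ", inact_ids[i],
                   " after ", max_tries, " tries; reduce ",
                   "decoy_features_per_mol or the tolerance margin"))
    })

    mw <- runif(n_active + n_inactive, 150, 800)
  })

  library <- tibble(
    mol_id = c(act_ids, inact_ids),
    label = rep(c("active", "inactive"), c(n_active, n_inactive)),
    mol_weight = mw,
    features = c(act_feats, inact_feats)
  )
  manifest <- structure(
    list(
      planted_hyps = planted_hyps,
      molecules = tibble(
        mol_id = library$mol_id,
        label = library$label,
        planted = c(plant_of, rep(NA_character_, n_inactive)),
        noise_sigma = noise_sigma,
        seed = seed
      ),
      seed = seed, tol = tol, box = box,
      decoy_features_per_mol = decoy_features_per_mol
    ),
    class = "cp_manifest"
  )
  list(library = library, manifest = manifest)
}

#' Write / read a plant manifest as JSON
#'
#' @param manifest A manifest from [make_planted_library()].
#' @param path JSON path.
#' @return `write_manifest()`: invisibly, the manifest;
#'   `read_manifest()`: a manifest list.
#' @export
write_manifest <- function(manifest, path) {
  obj <- list(
    planted_hyps = map(seq_len(nrow(manifest$planted_hyps)), function(i) {
      list(hyp_id = manifest$planted_hyps$hyp_id[[i]],
           sites = as.list(manifest$planted_hyps$sites[[i]]),
           distances = manifest$planted_hyps$dist[[i]],
           tol = manifest$planted_hyps$tol[[i]])
    }),
    molecules = manifest$molecules,
    seed = manifest$seed, tol = manifest$tol, box = manifest$box,
    decoy_features_per_mol = manifest$decoy_features_per_mol
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(manifest)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  hyps <- obj$planted_hyps
  ph <- new_hypotheses(
    hyp_id = map_chr(hyps, "hyp_id"),
    sites = map(hyps, function(h) unlist(h$sites)),
    dist = map(hyps, function(h) {
      k <- length(unlist(h$sites))
      matrix(unlist(h$distances), k, k, byrow = TRUE)
    }),
    tol = map_dbl(hyps, "tol"),
    n_support = rep(NA_integer_, length(hyps))
  )
  cols <- obj$molecules
  molecules <- tibble(
    mol_id = map_chr(cols$mol_id, identity),
    label = map_chr(cols$label, identity),
    planted = map_chr(cols$planted, function(v) v %||% NA_character_),
    noise_sigma = map_dbl(cols$noise_sigma, identity),
    seed = map_dbl(cols$seed, identity)
  )
  structure(
    list(planted_hyps = ph,
         molecules = molecules,
         seed = obj$seed, tol = obj$tol, box = obj$box,
         decoy_features_per_mol = obj$decoy_features_per_mol),
    class = "cp_manifest"
  )
}

#' Load the shipped real-SMILES fixture library
#'
#' A ~20-molecule labeled SMILES library covering all six feature types
#' (aromatics, acids, amines, amidines, alcohols, hydrocarbons, and a few
#' drug-like multi-feature scaffolds). Labels are synthetic: the library
#' exercises structure handling end-to-end and claims no measured
#' activities.
#'
#' @return A parsed molecule library tibble (no conformers yet).
#' @export
make_smiles_fixture <- function() {
  smi <- system.file("extdata", "fixture_library.smi",
                     package = "combipharm", mustWork = TRUE)
  lab <- system.file("extdata", "fixture_labels.csv",
                     package = "combipharm", mustWork = TRUE)
  read_labeled_library(smi, lab)
}
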