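# Conformer ensemble generation.
#
# Conformers are produced by driving acyclic single-bond torsions away from
# the idealized base geometry: for few rotatable bonds the torsion grid is
# enumerated systematically, otherwise torsion settings are sampled with a
# fixed seed. Candidates with steric clashes are rejected and near-duplicate
# geometries are pruned by the RMSD of their sorted interatomic-distance
# vectors. The procedure is exactly reproducible for a fixed seed.

# Rotatable bonds: acyclic single bonds between non-terminal heavy atoms.
rotatable_bonds <- function(graph) {
  if (nrow(graph$bonds) == 0) return(tibble(a1 = integer(), a2 = integer()))
  deg <- rep(0L, nrow(graph$atoms))
  tb <- table(c(graph$bonds$a1, graph$bonds$a2))
  deg[as.integer(names(tb))] <- as.integer(tb)
  ring_atoms <- unique(unlist(graph$arom_rings))
  g <- graph$bonds |>
    filter(.data$order == 1L,
           deg[.data$a1] >= 2L, deg[.data$a2] >= 2L)
  # drop bonds inside any ring (cycle check by reachability without the bond)
  if (nrow(g) > 0) {
    adj <- molgraph_adjacency(graph)
    keep <- map_lgl(seq_len(nrow(g)), function(i) {
      a1 <- g$a1[i]; a2 <- g$a2[i]
      seen <- rep(FALSE, nrow(graph$atoms))
      seen[a1] <- TRUE
      stack <- a1
      while (length(stack) > 0) {
        v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
        for (w in adj[[v]]) {
          if (v == a1 && w == a2) next
          if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
        }
      }
      !seen[a2]                          # acyclic bond: a2 unreachable
    })
    g <- g[keep, ]
  }
  g |> select("a1", "a2")
}

# Clash test: any heavy-atom pair more than three bonds apart closer
# than `min_sep` Angstrom.
has_clash <- function(coords, topo_dist, min_sep = 1.5) {
  far <- topo_dist >= 4
  if (!any(far)) return(FALSE)
  d <- pairwise_dist(coords)
  any(d[far] < min_sep)
}

# Topological (bond-count) distance matrix via BFS.
topo_distances <- function(graph) {
  n <- nrow(graph$atoms)
  adj <- molgraph_adjacency(graph)
  td <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    td[s, s] <- 0
    queue <- s
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (td[s, w] > td[s, v] + 1) {
          td[s, w] <- td[s, v] + 1
          queue <- c(queue, w)
        }
      }
    }
  }
  td
}

# Sorted-distance signature used for duplicate pruning.
dist_signature <- function(coords) sort(as.vector(dist(coords)))

#' Generate conformer ensembles for a molecule library
#'
#' Builds an idealized 3D geometry for each parsed structure and expands it
#' into a conformer ensemble by torsion driving (see Details). Feature-cloud
#' records (no structure) are passed through unchanged.
#'
#' @details Rotatable bonds are acyclic single bonds between non-terminal
#'   heavy atoms. With \eqn{b} rotatable bonds and \eqn{6^b} no larger than
#'   `grid_cap`, the 60-degree torsion grid is enumerated exhaustively in a
#'   fixed order; otherwise torsion settings are drawn with the supplied
#'   seed. Candidates with nonbonded heavy-atom contacts under 1.5 A are
#'   rejected and geometries whose sorted interatomic-distance vectors agree
#'   within `prune_rmsd` (RMSD) are merged. At most `max_confs` conformers
#'   are kept per molecule; rigid molecules yield exactly one.
#'
#' @param library A molecule library tibble from [read_labeled_library()].
#' @param max_confs Maximum conformers per molecule (default 1000, the
#'   conventional ensemble cap for this protocol).
#' @param seed Integer seed; the ensemble is identical across runs for a
#'   fixed seed.
#' @param prune_rmsd Duplicate-pruning threshold in Angstrom (default 0.5).
#' @param grid_cap Largest torsion grid enumerated exhaustively (default 1296).
#' @return The library with the `conformers` list-column filled: one tibble
#'   per molecule with columns `conf_id`, `atom`, `x`, `y`, `z`.
#' @examples
#' \donttest{
#' lib <- make_smiles_fixture()
#' lib <- generate_conformers(lib, max_confs = 5, seed = 1)
#' }
#' @export
generate_conformers <- function(library, max_confs = 1000, seed = 1,
                                prune_rmsd = 0.5, grid_cap = 1296) {
  assert_library(library)
  if (max_confs < 1) abort("max_confs must be >= 1")
  if (!"structure" %in% names(library)) {
    abort("library has no 'structure' column; feature-cloud libraries need no conformers")
  }
  library$conformers <- imap(library$structure, function(graph, i) {
    if (is.null(graph)) return(library$conformers[[i]])
    withr::with_seed(sub_seed(seed, i), {
      conformer_ensemble(graph, max_confs = max_confs,
                         prune_rmsd = prune_rmsd, grid_cap = grid_cap)
    })
  })
  library
}

# Ensemble for one molgraph; RNG state is the caller's responsibility.
conformer_ensemble <- function(graph, max_confs, prune_rmsd = 0.5,
                               grid_cap = 1296) {
  base <- build_coords(graph)
  n <- nrow(base)
  if (n == 0) {
    return(tibble(conf_id = integer(), atom = integer(),
                  x = numeric(), y = numeric(), z = numeric()))
  }
  rb <- rotatable_bonds(graph)
  coords_list <- list(base)
  if (nrow(rb) > 0 && max_confs > 1) {
    td <- topo_distances(graph)
    sigs <- list(dist_signature(base))
    steps <- c(0, 60, 120, 180, 240, 300)
    nrot <- nrow(rb)
    settings <- if (6^nrot <= grid_cap) {
      gr <- as.matrix(expand.grid(rep(list(steps), nrot)))
      gr[rowSums(gr != 0) > 0, , drop = FALSE]      # base already kept
    } else {
      matrix(sample(steps, size = nrot * 5 * max_confs, replace = TRUE),
             ncol = nrot)
    }
    for (s in seq_len(nrow(settings))) {
      if (length(coords_list) >= max_confs) break
      cand <- base
      for (b in seq_len(nrot)) {
        if (settings[s, b] != 0) {
          cand <- rotate_torsion(cand, graph, rb$a1[b], rb$a2[b],
                                 settings[s, b])
        }
      }
      if (has_clash(cand, td)) next
      sig <- dist_signature(cand)
      dup <- any(map_lgl(sigs, function(s0) {
        sqrt(mean((s0 - sig)^2)) <= prune_rmsd
      }))
      if (dup) next
      coords_list[[length(coords_list) + 1]] <- cand
      sigs[[length(sigs) + 1]] <- sig
    }
  }
  list_rbind(imap(coords_list, function(cc, ci) {
    tibble(conf_id = as.integer(ci), atom = seq_len(n),
           x = cc[, 1], y = cc[, 2], z = cc[, 3])
  }))
}
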