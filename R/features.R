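# Pharmacophore feature perception.
#
# Maps the molecular graph + one conformer's coordinates to typed feature
# points using the shipped rule table (see feature_definitions()). The six
# types are A (acceptor), D (donor), H (hydrophobe), N (negative), P
# (positive), R (aromatic ring). Perception follows the pH-7.4 convention:
# acid groups are treated as ionized (N), aliphatic amines and
# amidine/guanidine groups as protonated (P). Atoms claimed by a charged
# group are excluded from A/D, aromatic atoms from H, so one functional
# group yields a single typed point.

#' Perceive pharmacophore features on one conformer
#'
#' Low-level perception: applies the rule table to a parsed structure and a
#' single set of 3D coordinates. Most users call [perceive_features()] on a
#' whole library instead.
#'
#' @param graph A parsed structure (an element of a library's `structure`
#'   column).
#' @param coords Numeric matrix (atoms x 3) of coordinates in Angstrom.
#' @param defs Rule table from [feature_definitions()].
#' @return Tibble with columns `ftype`, `x`, `y`, `z`, `atoms` (list of
#'   source atom indices), sorted by `ftype` then first atom index. Feature
#'   positions are arithmetic centroids of their source atoms.
#' @export
perceive_conformer_features <- function(graph, coords,
                                        defs = feature_definitions()) {
  n <- nrow(graph$atoms)
  empty <- tibble(ftype = character(), x = numeric(), y = numeric(),
                  z = numeric(), atoms = list())
  if (n == 0) return(empty)
  if (!is.matrix(coords) || nrow(coords) != n || ncol(coords) != 3) {
    abort("coords must be an (atom x 3) matrix matching the structure")
  }
  fd <- defs$features
  el <- graph$atoms$element
  ch <- graph$atoms$charge
  arom <- graph$atoms$arom
  nH <- graph$atoms$nH
  adj <- molgraph_adjacency(graph)
  om <- molgraph_order_matrix(graph)
  deg <- lengths(adj)
  claimed <- rep(FALSE, n)
  out <- list()
  add_feat <- function(ftype, atoms) {
    ctr <- colMeans(coords[atoms, , drop = FALSE])
    out[[length(out) + 1]] <<- tibble(
      ftype = ftype, x = ctr[1], y = ctr[2], z = ctr[3],
      atoms = list(sort(as.integer(atoms)))
    )
  }
  # carbonyl-like carbon: C double-bonded to O or S
  is_carbonyl_c <- map_lgl(seq_len(n), function(i) {
    el[i] == "C" && any(om[i, ] == 2 & el %in% c("O", "S"))
  })

  ## R: aromatic ring centroids -------------------------------------------
  if (isTRUE(fd$R$enabled)) {
    for (rg in graph$arom_rings) add_feat("R", rg)
  }

  ## N: ionized acid groups (pH 7.4) --------------------------------------
  if (isTRUE(fd$N$enabled)) {
    grp <- fd$N$groups %||% character()
    for (i in seq_len(n)) {
      if (claimed[i]) next
      if (el[i] == "C" && "carboxylate" %in% grp) {
        oxy <- adj[[i]][el[adj[[i]]] == "O" & deg[adj[[i]]] == 1]
        if (length(oxy) >= 2 &&
            (any(om[i, oxy] == 2) || any(ch[oxy] < 0))) {
          add_feat("N", c(i, oxy)); claimed[c(i, oxy)] <- TRUE
        }
      } else if (el[i] == "S" && "sulfonate" %in% grp) {
        oxy <- adj[[i]][el[adj[[i]]] == "O" & deg[adj[[i]]] == 1]
        if (length(oxy) >= 2) {
          add_feat("N", c(i, oxy)); claimed[c(i, oxy)] <- TRUE
        }
      } else if (el[i] == "P" && "phosphonate" %in% grp) {
        oxy <- adj[[i]][el[adj[[i]]] == "O" & deg[adj[[i]]] == 1]
        if (length(oxy) >= 2) {
          add_feat("N", c(i, oxy)); claimed[c(i, oxy)] <- TRUE
        }
      }
    }
    if ("explicit_anion" %in% grp) {
      for (i in which(ch < 0 & !claimed)) {
        add_feat("N", i); claimed[i] <- TRUE
      }
    }
  }

  ## P: basic / cationic groups (pH 7.4) ----------------------------------
  if (isTRUE(fd$P$enabled)) {
    grp <- fd$P$groups %||% character()
    if ("amidinium" %in% grp) {
      for (i in seq_len(n)) {
        if (claimed[i] || el[i] != "C" || arom[i]) next
        nn <- adj[[i]][el[adj[[i]]] == "N" & !arom[adj[[i]]] & !claimed[adj[[i]]]]
        if (length(nn) >= 2 && any(om[i, nn] == 2) &&
            !any(el[adj[[i]]] %in% c("O", "S"))) {
          add_feat("P", c(i, nn)); claimed[c(i, nn)] <- TRUE
        }
      }
    }
    if ("aliphatic_amine" %in% grp) {
      for (i in seq_len(n)) {
        if (claimed[i] || el[i] != "N" || arom[i] || ch[i] < 0) next
        nb <- adj[[i]]
        if (length(nb) == 0) next
        if (any(om[i, nb] > 1)) next                   # imine/nitrile: not basic
        if (!all(el[nb] == "C")) next                  # N-N / N-O: not basic
        if (isTRUE(fd$P$exclude_aniline) && any(arom[nb])) next
        if (isTRUE(fd$P$exclude_amide) && any(is_carbonyl_c[nb])) next
        add_feat("P", i); claimed[i] <- TRUE
      }
    }
    if (any(c("quaternary_n", "explicit_cation") %in% grp)) {
      for (i in which(ch > 0 & !claimed)) {
        add_feat("P", i); claimed[i] <- TRUE
      }
    }
  }

  ## A: hydrogen-bond acceptors -------------------------------------------
  if (isTRUE(fd$A$enabled)) {
    for (i in seq_len(n)) {
      if (claimed[i] || ch[i] != 0) next
      if (el[i] == "O" && isTRUE(fd$A$oxygen) && !arom[i]) {
        add_feat("A", i)
      } else if (el[i] == "N" && isTRUE(fd$A$nitrogen) && nH[i] == 0 &&
                 !any(is_carbonyl_c[adj[[i]]])) {
        add_feat("A", i)
      }
    }
  }

  ## D: hydrogen-bond donors ----------------------------------------------
  if (isTRUE(fd$D$enabled)) {
    delems <- fd$D$elements %||% c("N", "O", "S")
    for (i in seq_len(n)) {
      if (claimed[i] || ch[i] != 0 || nH[i] < 1) next
      if (el[i] %in% delems) add_feat("D", i)
    }
  }

  ## H: hydrophobic groups -------------------------------------------------
  if (isTRUE(fd$H$enabled)) {
    halos <- fd$H$halogens %||% c("F", "Cl", "Br", "I")
    qual <- map_lgl(seq_len(n), function(i) {
      if (claimed[i]) return(FALSE)
      if (el[i] %in% halos) return(TRUE)
      if (el[i] != "C" || arom[i] || ch[i] != 0) return(FALSE)
      nb <- adj[[i]]
      all(el[nb] %in% c("C", halos)) && !any(claimed[nb])
    })
    if (any(qual)) {
      comp <- rep(NA_integer_, n)
      cid <- 0L
      for (s in which(qual)) {
        if (!is.na(comp[s])) next
        cid <- cid + 1L
        stack <- s
        comp[s] <- cid
        while (length(stack) > 0) {
          v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
          for (w in adj[[v]]) {
            if (qual[w] && is.na(comp[w])) {
              comp[w] <- cid
              stack <- c(stack, w)
            }
          }
        }
      }
      for (g in seq_len(cid)) add_feat("H", which(comp == g))
    }
  }

  if (length(out) == 0) return(empty)
  res <- list_rbind(out)
  res |>
    mutate(.first = map_int(.data$atoms, 1)) |>
    arrange(.data$ftype, .data$.first) |>
    select(-".first")
}

#' Perceive features for every conformer of every molecule
#'
#' Fills the `features` list-column of a library: for each molecule with a
#' parsed structure and a conformer ensemble, features are perceived on
#' every conformer. Feature-cloud records (no structure) keep their
#' existing feature tables.
#'
#' @param library Molecule library tibble.
#' @param defs Rule table from [feature_definitions()].
#' @return The library with `features` filled: one tibble per molecule with
#'   columns `conf_id`, `ftype`, `x`, `y`, `z`, `atoms`.
#' @export
perceive_features <- function(library, defs = feature_definitions()) {
  assert_library(library)
  if (!"structure" %in% names(library)) return(library)
  library$features <- imap(library$structure, function(graph, i) {
    if (is.null(graph)) return(library$features[[i]])
    confs <- library$conformers[[i]]
    if (is.null(confs) || nrow(confs) == 0) {
      warn(paste0("molecule ", library$mol_id[i],
                  " has no conformers; run generate_conformers() first"))
      return(tibble(conf_id = integer(), ftype = character(),
                    x = numeric(), y = numeric(), z = numeric(),
                    atoms = list()))
    }
    split(confs, confs$conf_id) |>
      imap(function(cc, cid) {
        xyz <- as.matrix(cc[order(cc$atom), c("x", "y", "z")])
        perceive_conformer_features(graph, xyz, defs) |>
          mutate(conf_id = as.integer(cid), .before = 1)
      }) |>
      list_rbind()
  })
  library
}
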