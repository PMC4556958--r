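# Internal molecular-graph representation.
#
# Structures are parsed with ChemmineR (SDF/SMILES via OpenBabel) and
# reduced to a heavy-atom graph: explicit hydrogens are folded into per-atom
# hydrogen counts, formal charges are decoded from the V2000 charge codes,
# and aromaticity comes from ChemmineR ring perception. All downstream
# feature perception operates on this graph.

.valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3, B = 3, Si = 4,
              F = 1, Cl = 1, Br = 1, I = 1)

# Decode the V2000 atom-block charge code column (0 none, 1 -> +3 ... 7 -> -3).
decode_charge <- function(code) {
  ifelse(code == 0, 0L, 4L - as.integer(code))
}

# Parse one ChemmineR SDF object into a heavy-atom molecular graph.
#
# Returns a list with:
#   atoms: tibble(idx, element, charge, arom, nH)
#   bonds: tibble(a1, a2, order)         (heavy-atom indices)
#   arom_rings: list of integer vectors  (heavy-atom indices)
parse_molgraph <- function(sdf_item) {
  ab <- ChemmineR::atomblock(sdf_item)
  if (is.null(ab) || nrow(ab) == 0) {
    return(list(
      atoms = tibble(idx = integer(), element = character(),
                     charge = integer(), arom = logical(), nH = integer()),
      bonds = tibble(a1 = integer(), a2 = integer(), order = integer()),
      arom_rings = list(),
      all_rings = list()
    ))
  }
  element <- sub("_.*$", "", rownames(ab))
  n <- nrow(ab)
  charge <- rep(0L, n)
  if ("C6" %in% colnames(ab)) charge <- decode_charge(ab[, "C6"])

  bb <- ChemmineR::bondblock(sdf_item)
  bonds <- if (is.null(bb) || nrow(bb) == 0) {
    tibble(a1 = integer(), a2 = integer(), order = integer())
  } else {
    tibble(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
           order = as.integer(bb[, 3]))
  }

  # Ring perception via ChemmineR: all small rings (3-8) for geometry,
  # aromatic 5-7 rings for R features and aromaticity flags.
  arom_rings <- list()
  all_rings <- list()
  if (nrow(bonds) > 0 && n >= 3) {
    rr <- tryCatch(
      suppressWarnings(ChemmineR::rings(sdf_item, type = "all", arom = TRUE)),
      error = function(e) NULL
    )
    if (!is.null(rr) && length(rr$RINGS) > 0) {
      idx_rings <- map(rr$RINGS, function(rg) {
        as.integer(sub("^.*_", "", rg))
      })
      sizes <- lengths(idx_rings)
      all_rings <- idx_rings[sizes >= 3 & sizes <= 8]
      keep <- sizes >= 5 & sizes <= 7 & as.logical(rr$AROMATIC)
      arom_rings <- idx_rings[keep]
    }
  }
  arom <- rep(FALSE, n)
  for (rg in arom_rings) arom[rg] <- TRUE

  # Fold explicit hydrogens into heavy-atom H counts.
  is_h <- element == "H"
  explicit_h <- rep(0L, n)
  if (any(is_h)) {
    for (b in seq_len(nrow(bonds))) {
      a1 <- bonds$a1[b]; a2 <- bonds$a2[b]
      if (is_h[a1] && !is_h[a2]) explicit_h[a2] <- explicit_h[a2] + 1L
      if (is_h[a2] && !is_h[a1]) explicit_h[a1] <- explicit_h[a1] + 1L
    }
  }
  heavy <- which(!is_h)
  remap <- match(seq_len(n), heavy)          # old -> new index (NA for H)
  bonds <- bonds |>
    filter(!is_h[.data$a1], !is_h[.data$a2]) |>
    mutate(a1 = remap[.data$a1], a2 = remap[.data$a2])
  arom_rings <- map(arom_rings, function(v) remap[v])
  all_rings <- map(all_rings, function(v) remap[v])

  element <- element[heavy]; charge <- charge[heavy]
  arom <- arom[heavy]; explicit_h <- explicit_h[heavy]
  m <- length(heavy)

  # Implicit hydrogens from standard valences (charge-adjusted).
  order_sum <- rep(0L, m)
  if (nrow(bonds) > 0) {
    tab1 <- tapply(bonds$order, bonds$a1, sum)
    tab2 <- tapply(bonds$order, bonds$a2, sum)
    order_sum[as.integer(names(tab1))] <- order_sum[as.integer(names(tab1))] + tab1
    order_sum[as.integer(names(tab2))] <- order_sum[as.integer(names(tab2))] + tab2
  }
  val <- unname(.valence[element])
  val[is.na(val)] <- 0
  adj <- ifelse(element %in% c("N", "P", "O", "S"), charge,
                ifelse(element == "C", -abs(charge), 0L))
  implicit_h <- pmax(0L, as.integer(val + adj - order_sum))
  implicit_h[val == 0] <- 0L

  list(
    atoms = tibble(idx = seq_len(m), element = element,
                   charge = as.integer(charge), arom = arom,
                   nH = explicit_h + implicit_h),
    bonds = bonds,
    arom_rings = arom_rings,
    all_rings = all_rings
  )
}

# Adjacency list (neighbour indices) of a molgraph.
molgraph_adjacency <- function(graph) {
  n <- nrow(graph$atoms)
  adj <- vector("list", n)
  for (b in seq_len(nrow(graph$bonds))) {
    a1 <- graph$bonds$a1[b]; a2 <- graph$bonds$a2[b]
    adj[[a1]] <- c(adj[[a1]], a2)
    adj[[a2]] <- c(adj[[a2]], a1)
  }
  adj
}

# Bond order lookup matrix (0 = not bonded).
molgraph_order_matrix <- function(graph) {
  n <- nrow(graph$atoms)
  om <- matrix(0L, n, n)
  if (nrow(graph$bonds) > 0) {
    om[cbind(graph$bonds$a1, graph$bonds$a2)] <- graph$bonds$order
    om[cbind(graph$bonds$a2, graph$bonds$a1)] <- graph$bonds$order
  }
  om
}
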