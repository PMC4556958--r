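# Deterministic idealized 3D geometry from the molecular graph.
#
# Coordinates are built by depth-first placement with standard bond lengths
# (covalent-radius sums, scaled by bond order), ideal angles from a simple
# hybridization guess (sp 180, sp2/aromatic 120, sp3 109.47 degrees), planar
# in-ring torsions and staggered substituents. The builder is exactly
# reproducible: no random numbers, no force field. Ring closure for
# saturated or fused rings is approximate; positions feed feature centroids
# and inter-feature distances, not energetics.

.cov_radius <- c(C = 0.77, N = 0.75, O = 0.73, S = 1.02, P = 1.06,
                 F = 0.71, Cl = 0.99, Br = 1.14, I = 1.33, B = 0.82,
                 Si = 1.11)

bond_length <- function(e1, e2, order) {
  r <- (.cov_radius[e1] %||% 0.9) + (.cov_radius[e2] %||% 0.9)
  r <- ifelse(is.na(r), 1.5, r)
  scale <- c(`1` = 1, `2` = 0.87, `3` = 0.78)
  unname(r * (scale[as.character(order)] %||% 1))
}

# sp hybridization guess per heavy atom: 1 = sp, 2 = sp2, 3 = sp3.
hybridization <- function(graph) {
  n <- nrow(graph$atoms)
  hyb <- rep(3L, n)
  if (nrow(graph$bonds) > 0) {
    for (b in seq_len(nrow(graph$bonds))) {
      o <- graph$bonds$order[b]
      a <- c(graph$bonds$a1[b], graph$bonds$a2[b])
      if (o == 2) hyb[a] <- pmin(hyb[a], 2L)
      if (o == 3) hyb[a] <- 1L
    }
  }
  hyb[graph$atoms$arom] <- 2L
  # cumulated double bonds (e.g. allene centres) -> sp
  dbl <- rep(0L, n)
  for (b in seq_len(nrow(graph$bonds))) {
    if (graph$bonds$order[b] == 2) {
      dbl[graph$bonds$a1[b]] <- dbl[graph$bonds$a1[b]] + 1L
      dbl[graph$bonds$a2[b]] <- dbl[graph$bonds$a2[b]] + 1L
    }
  }
  hyb[dbl >= 2] <- 1L
  # 4-coordinate centres (sulfonate S, phosphate P, quaternary N) are
  # tetrahedral whatever their bond orders
  deg <- rep(0L, n)
  tb <- table(c(graph$bonds$a1, graph$bonds$a2))
  deg[as.integer(names(tb))] <- as.integer(tb)
  hyb[deg >= 4] <- 3L
  hyb
}

# Place point D given reference atoms A-B-C, bond length r (C-D), angle
# theta (B-C-D, degrees) and dihedral tau (A-B-C-D, degrees). NeRF-style.
place_atom <- function(a, b, c_, r, theta, tau) {
  theta <- theta * pi / 180
  tau <- tau * pi / 180
  bc <- c_ - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  nv <- c(ab[2] * bc[3] - ab[3] * bc[2],
          ab[3] * bc[1] - ab[1] * bc[3],
          ab[1] * bc[2] - ab[2] * bc[1])
  nn <- sqrt(sum(nv^2))
  if (nn < 1e-8) {                      # collinear reference: pick any normal
    nv <- if (abs(bc[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    nv <- nv - sum(nv * bc) * bc
    nn <- sqrt(sum(nv^2))
  }
  nv <- nv / nn
  mv <- c(nv[2] * bc[3] - nv[3] * bc[2],
          nv[3] * bc[1] - nv[1] * bc[3],
          nv[1] * bc[2] - nv[2] * bc[1])
  d2 <- c(-r * cos(theta), r * sin(theta) * cos(tau), r * sin(theta) * sin(tau))
  c_ + d2[1] * bc + d2[2] * mv + d2[3] * nv
}

# Build idealized coordinates for every heavy atom; returns an n x 3 matrix.
build_coords <- function(graph) {
  n <- nrow(graph$atoms)
  if (n == 0) return(matrix(numeric(0), 0, 3))
  coords <- matrix(NA_real_, n, 3)
  adj <- molgraph_adjacency(graph)
  om <- molgraph_order_matrix(graph)
  hyb <- hybridization(graph)
  el <- graph$atoms$element
  angle_of <- c(`1` = 180, `2` = 120, `3` = 109.47)
  rings <- graph$all_rings %||% graph$arom_rings
  in_ring <- matrix(FALSE, n, n)        # ring-edge adjacency
  ring_mask <- matrix(FALSE, n, max(1, length(rings)))  # ring membership
  for (ri in seq_along(rings)) {
    rg <- rings[[ri]]
    ring_mask[rg, ri] <- TRUE
    k <- length(rg)
    for (i in seq_len(k)) {
      j <- if (i == k) 1L else i + 1L
      in_ring[rg[i], rg[j]] <- TRUE
      in_ring[rg[j], rg[i]] <- TRUE
    }
  }
  share_ring <- function(a, b) any(ring_mask[a, ] & ring_mask[b, ])
  tau_sign <- rep(1, n)                 # alternating chair torsions

  placed <- rep(FALSE, n)
  parent <- rep(NA_integer_, n)

  place_child <- function(p, ch, n_prev_sib) {
    r <- bond_length(el[p], el[ch], om[p, ch])
    g <- parent[p]
    if (is.na(g)) {
      sibs <- which(placed & !is.na(parent) & parent == p &
                      seq_len(n) != ch)
      if (length(sibs) == 0) {
        return(coords[p, ] + c(r, 0, 0))
      }
      th <- angle_of[as.character(hyb[p])]
      ref <- sibs[1]
      tau <- if (length(sibs) == 1) 0 else 120 * (length(sibs) - 1)
      return(place_atom(coords[ref, ] + c(0, 0, 1),
                        coords[ref, ], coords[p, ], r, th, tau))
    }
    th <- angle_of[as.character(hyb[p])]
    gg <- parent[g]
    aref <- if (!is.na(gg)) coords[gg, ] else coords[g, ] + c(0, 0, 1)
    ring_edge <- in_ring[p, ch]
    if (ring_edge) {
      # interior angle of the (smallest) shared ring for planar traces
      shared <- which(ring_mask[p, ] & ring_mask[ch, ])
      if (length(shared) > 0 && hyb[p] != 3L) {
        s <- min(lengths(rings[shared]))
        th <- 180 * (s - 2) / s
      }
    }
    tau <- if (ring_edge && hyb[p] != 3L) {
      # planar ring trace: continue the arc (0) when the torsion reference
      # lies in the same ring as the new atom, otherwise extend trans so
      # the ring curls away from substituents and fused neighbours
      if (!is.na(gg) && share_ring(gg, ch)) 0 else 180
    } else if (ring_edge) {
      if (!share_ring(g, ch)) {
        # ring entry from an exocyclic parent: set the ring perpendicular
        tau_sign[ch] <<- 1
        90
      } else {
        # inside a saturated ring: alternating near-chair torsions
        tau_sign[ch] <<- -tau_sign[p]
        55 * tau_sign[ch]
      }
    } else if (hyb[p] == 2L) {
      c(180, 0)[n_prev_sib + 1]
    } else {
      c(180, 60, -60, 120)[n_prev_sib + 1]
    }
    if (is.na(tau)) tau <- 90
    closure_partner <- setdiff(adj[[ch]][placed[adj[[ch]]]], p)
    finish <- function(tt) {
      pos <- place_atom(aref, coords[g, ], coords[p, ], r, th, tt)
      # ring closure: honour the bond to a second already-placed neighbour
      # by projecting onto the locus satisfying both bond lengths
      if (length(closure_partner) > 0) {
        q <- closure_partner[1]
        pos <- close_ring_position(pos, coords[p, ], coords[q, ], r,
                                   bond_length(el[q], el[ch], om[q, ch]))
      }
      pos
    }
    score_of <- function(pos) {
      far <- which(placed & seq_len(n) != ch & om[, ch] == 0)
      sc <- if (length(far) == 0) Inf else
        min(sqrt(rowSums(sweep(coords[far, , drop = FALSE], 2, pos)^2)))
      if (length(closure_partner) > 0) {
        q <- closure_partner[1]
        err <- abs(sqrt(sum((pos - coords[q, ])^2)) -
                     bond_length(el[q], el[ch], om[q, ch]))
        sc <- sc - 10 * max(0, err - 0.3)     # closure must stay honoured
      }
      sc
    }
    pos <- finish(tau)
    if (score_of(pos) < 1.2) {
      # steric fallback: rotate the torsion in fixed steps and keep the
      # best-scoring placement (deterministic)
      cands <- map(c(120, -120, 180, 60, -60, 90, -90), function(dt) {
        finish(tau + dt)
      })
      scores <- map_dbl(cands, score_of)
      if (max(scores) > score_of(pos)) pos <- cands[[which.max(scores)]]
    }
    pos
  }

  offset_x <- 0
  for (root in seq_len(n)) {
    if (placed[root]) next
    # new connected component: offset along x from what is already placed
    coords[root, ] <- c(offset_x, 0, 0)
    placed[root] <- TRUE
    stack <- root
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      nbrs <- sort(adj[[p]])
      nbrs <- nbrs[!placed[nbrs]]
      if (length(nbrs) == 0) next
      # trace each ring in a single direction: keep only the first unplaced
      # ring neighbour, preferring the one that continues the ring we
      # entered through (fused systems finish one ring before the next);
      # the others are reached around the ring arc
      ring_nbrs <- nbrs[in_ring[p, nbrs]]
      if (length(ring_nbrs) > 1 && !is.na(parent[p])) {
        cont <- vapply(ring_nbrs, function(ch) share_ring(parent[p], ch),
                       logical(1))
        ring_nbrs <- c(ring_nbrs[cont], ring_nbrs[!cont])
      }
      children <- c(ring_nbrs[seq_len(min(1, length(ring_nbrs)))],
                    nbrs[!in_ring[p, nbrs]])
      n_sib <- 0L
      for (ch in children) {
        if (placed[ch]) next
        coords[ch, ] <- place_child(p, ch, n_sib)
        placed[ch] <- TRUE
        parent[ch] <- p
        n_sib <- n_sib + 1L
        stack <- c(stack, ch)
      }
    }
    # fallback: deferred ring atoms not reached by any arc
    repeat {
      todo <- which(!placed &
                      vapply(seq_len(n), function(a) any(placed[adj[[a]]]),
                             logical(1)))
      if (length(todo) == 0) break
      for (ch in todo) {
        p <- adj[[ch]][placed[adj[[ch]]]][1]
        coords[ch, ] <- place_child(p, ch, 0L)
        placed[ch] <- TRUE
        parent[ch] <- p
      }
    }
    offset_x <- max(coords[placed, 1]) + 3
  }

  # refinement: re-seat atoms whose bonds are badly violated (ring arcs
  # that curled the wrong way) on the locus satisfying their two first
  # bonds, picking the least-crowded point on that circle
  for (pass in 1:2) {
    moved <- FALSE
    for (a in seq_len(n)) {
      nbrs <- adj[[a]]
      if (length(nbrs) < 2) next
      r_ideal <- vapply(nbrs, function(b) bond_length(el[a], el[b], om[a, b]),
                        numeric(1))
      d_cur <- sqrt(rowSums(sweep(coords[nbrs, , drop = FALSE], 2,
                                  coords[a, ])^2))
      if (max(abs(d_cur - r_ideal)) < 0.3) next
      q1 <- nbrs[1]; q2 <- nbrs[2]
      u <- coords[q2, ] - coords[q1, ]
      L <- sqrt(sum(u^2))
      if (L < 1e-8 || L > r_ideal[1] + r_ideal[2]) next
      u <- u / L
      aa <- (r_ideal[1]^2 - r_ideal[2]^2 + L^2) / (2 * L)
      centre <- coords[q1, ] + aa * u
      rho2 <- r_ideal[1]^2 - aa^2
      if (rho2 <= 1e-10) next
      v0 <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      v1 <- v0 - sum(v0 * u) * u; v1 <- v1 / sqrt(sum(v1^2))
      v2 <- c(u[2] * v1[3] - u[3] * v1[2], u[3] * v1[1] - u[1] * v1[3],
              u[1] * v1[2] - u[2] * v1[1])
      others <- setdiff(which(om[, a] == 0), a)
      best <- NULL; best_sc <- -Inf
      for (ang in seq(0, 350, by = 10) * pi / 180) {
        cand <- centre + sqrt(rho2) * (cos(ang) * v1 + sin(ang) * v2)
        sc <- if (length(others) == 0) 1 else
          min(sqrt(rowSums(sweep(coords[others, , drop = FALSE], 2, cand)^2)))
        extra <- setdiff(nbrs, c(q1, q2))
        if (length(extra) > 0) {
          errs <- abs(sqrt(rowSums(sweep(coords[extra, , drop = FALSE], 2,
                                         cand)^2)) -
                        r_ideal[match(extra, nbrs)])
          sc <- sc - 5 * sum(pmax(0, errs - 0.3))
        }
        if (sc > best_sc) { best_sc <- sc; best <- cand }
      }
      if (!is.null(best)) { coords[a, ] <- best; moved <- TRUE }
    }
    if (!moved) break
  }
  coords
}

# Closest point to `pos` lying at distance r1 from p1 and r2 from p2
# (the circle of intersection of two spheres). Falls back to `pos` when the
# spheres do not intersect cleanly.
close_ring_position <- function(pos, p1, p2, r1, r2) {
  u <- p2 - p1
  L <- sqrt(sum(u^2))
  if (L < 1e-8 || L > r1 + r2 || L < abs(r1 - r2)) return(pos)
  u <- u / L
  a <- (r1^2 - r2^2 + L^2) / (2 * L)
  centre <- p1 + a * u
  rho2 <- r1^2 - a^2
  if (rho2 <= 1e-10) return(centre)
  v <- pos - centre
  v <- v - sum(v * u) * u
  nv <- sqrt(sum(v^2))
  if (nv < 1e-8) return(pos)
  centre + sqrt(rho2) * v / nv
}

# Rotate the a2-side subtree around the a1->a2 axis by `angle` degrees.
rotate_torsion <- function(coords, graph, a1, a2, angle) {
  n <- nrow(coords)
  adj <- molgraph_adjacency(graph)
  # atoms reachable from a2 without crossing the a1-a2 bond
  side <- rep(FALSE, n)
  side[a2] <- TRUE
  stack <- a2
  while (length(stack) > 0) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    for (w in adj[[v]]) {
      if (!side[w] && !(v == a2 && w == a1)) {
        side[w] <- TRUE
        stack <- c(stack, w)
      }
    }
  }
  side[a2] <- FALSE                      # axis atoms stay put
  axis <- coords[a2, ] - coords[a1, ]
  axis <- axis / sqrt(sum(axis^2))
  ang <- angle * pi / 180
  ca <- cos(ang); sa <- sin(ang)
  ux <- axis[1]; uy <- axis[2]; uz <- axis[3]
  rot <- matrix(c(
    ca + ux^2 * (1 - ca), ux * uy * (1 - ca) - uz * sa, ux * uz * (1 - ca) + uy * sa,
    uy * ux * (1 - ca) + uz * sa, ca + uy^2 * (1 - ca), uy * uz * (1 - ca) - ux * sa,
    uz * ux * (1 - ca) - uy * sa, uz * uy * (1 - ca) + ux * sa, ca + uz^2 * (1 - ca)
  ), 3, 3, byrow = TRUE)
  idx <- which(side)
  if (length(idx) > 0) {
    shifted <- sweep(coords[idx, , drop = FALSE], 2, coords[a2, ])
    coords[idx, ] <- sweep(shifted %*% t(rot), 2, coords[a2, ], FUN = "+")
  }
  coords
}
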