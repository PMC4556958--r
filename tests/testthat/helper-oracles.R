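# Independent oracles and random-instance generators for property tests.

# Brute-force matcher: recursive enumeration of every injective,
# type-consistent assignment of feature rows to hypothesis sites.
# Deliberately structured differently from the package matcher.
bf_match <- function(features, hyp, tol = NULL) {
  tol <- tol %||% hyp$tol %||% 1.0
  sites <- hyp$sites
  k <- length(sites)
  m <- nrow(features)
  if (m < k) return(list(matched = FALSE, rmsd_dist = NA_real_))
  xyz <- as.matrix(features[, c("x", "y", "z")])
  best_rmsd <- Inf
  found <- FALSE
  assign_next <- function(chosen) {
    s <- length(chosen) + 1
    if (s > k) {
      devs <- c()
      for (i in 1:(k - 1)) for (j in (i + 1):k) {
        d_f <- sqrt(sum((xyz[chosen[i], ] - xyz[chosen[j], ])^2))
        devs <- c(devs, abs(d_f - hyp$dist[i, j]))
      }
      if (all(devs <= tol)) {
        found <<- TRUE
        best_rmsd <<- min(best_rmsd, sqrt(mean(devs^2)))
      }
      return(invisible())
    }
    for (f in seq_len(m)) {
      if (features$ftype[f] == sites[s] && !(f %in% chosen)) {
        assign_next(c(chosen, f))
      }
    }
  }
  assign_next(integer())
  list(matched = found,
       rmsd_dist = if (found) best_rmsd else NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random feature cloud of n points in a box.
random_cloud <- function(n, box = 8) {
  tibble::tibble(
    ftype = sample(c("A", "D", "H", "N", "P", "R"), n, replace = TRUE),
    x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box)
  )
}

# Random valid k-site hypothesis: distances taken from a random point set
# so the triangle inequality holds by construction.
random_hypothesis <- function(k, box = 8, tol = 1.0) {
  pts <- matrix(runif(3 * k, 0, box), k, 3)
  d <- as.matrix(dist(pts))
  list(hyp_id = paste0("RND", k),
       sites = sort(sample(c("A", "D", "H", "N", "P", "R"), k, replace = TRUE)),
       dist = d, tol = tol)
}

# Random rigid motion applied to feature coordinates.
apply_rigid_motion <- function(features, rot, shift) {
  xyz <- as.matrix(features[, c("x", "y", "z")]) %*% t(rot)
  xyz <- sweep(xyz, 2, shift, FUN = "+")
  features$x <- xyz[, 1]; features$y <- xyz[, 2]; features$z <- xyz[, 3]
  features
}

rigid_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# n distinct valid 3-site hypotheses with deterministic ids h01..hNN.
new_test_hypotheses <- function(n, tol = 1.0) {
  rows <- lapply(seq_len(n), function(i) {
    d <- c(3, 4, 5) + 0.1 * i
    m <- matrix(0, 3, 3)
    m[upper.tri(m)] <- d
    m <- m + t(m)
    tibble::tibble(hyp_id = sprintf("h%02d", i), k = 3L,
                   sites = list(c("H", "H", "R")), dist = list(m),
                   tol = tol, n_support = NA_integer_)
  })
  dplyr::bind_rows(rows)
}

# Confusion metrics computed independently (plain arithmetic on a table).
bf_metrics <- function(pred, truth) {
  tp <- sum(pred == "active" & truth == "active")
  tn <- sum(pred == "inactive" & truth == "inactive")
  fp <- sum(pred == "active" & truth == "inactive")
  fn <- sum(pred == "inactive" & truth == "active")
  c(tp = tp, tn = tn, fp = fp, fn = fn,
    se = tp / (tp + fn), sp = tn / (tn + fp),
    acc = (tp + tn) / length(pred),
    bacc = (tp / (tp + fn) + tn / (tn + fp)) / 2)
}
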