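# Shared internal helpers.

# Canonical activity labels used throughout the package.
.labels <- c("active", "inactive", "unknown")

check_labels <- function(x, allow_unknown = TRUE) {
  ok <- .labels
  if (!allow_unknown) ok <- setdiff(ok, "unknown")
  bad <- setdiff(unique(x), ok)
  if (length(bad) > 0) {
    abort(paste0("invalid activity label(s): ", paste(bad, collapse = ", ")))
  }
  invisible(x)
}

# Pairwise Euclidean distances between rows of an n x 3 matrix,
# returned as a full symmetric matrix.
pairwise_dist <- function(xyz) {
  as.matrix(dist(xyz))
}

# Upper-triangle (i < j) pair indices of a k x k matrix, column-ordered
# the same way throughout the package: (1,2), (1,3), (2,3), (1,4), ...
pair_index <- function(k) {
  which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
}

# Vector of upper-triangle distances in canonical pair order.
upper_dist <- function(dmat) {
  dmat[upper.tri(dmat)]
}

# Random rotation matrix (Haar-ish via QR with sign fix), deterministic
# under the caller's RNG state.
random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Is `x` a molecule library tibble?
assert_library <- function(x) {
  need <- c("mol_id", "label", "features")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    abort("expected a molecule library tibble with columns mol_id, label, features")
  }
  if (anyDuplicated(x$mol_id)) {
    dup <- unique(x$mol_id[duplicated(x$mol_id)])
    abort(paste0("duplicate mol_id in library: ", paste(dup, collapse = ", ")))
  }
  invisible(x)
}

# Seed helper: derive a distinct 32-bit sub-seed from a base seed.
sub_seed <- function(seed, offset) {
  (as.integer(seed) + 10007L * as.integer(offset)) %% 2147483629L
}
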