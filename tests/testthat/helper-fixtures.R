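# Fixtures and independent oracles shared across the test files.
# Everything is built in code; no binary fixtures.

# straight root between two points with n evenly spaced nodes
straight_root <- function(id, from, to, n = 2L, order = 0L,
                          parent = NULL, attachment = NULL, diameter = 0.1) {
  t <- seq(0, 1, length.out = n)
  nodes <- outer(1 - t, from) + outer(t, to)
  root(id, nodes, diameters = diameter, order = order,
       parent_root_id = parent, parent_attachment = attachment)
}

# taproot (10 cm, vertical) with two 4 cm horizontal laterals at 2 and 5 cm
simple_gt <- function() {
  root_system(list(
    straight_root("tap", c(0, 0, 0), c(0, 0, 10), n = 11L),
    straight_root("lat1", c(0, 0, 2), c(4, 0, 2), n = 5L, order = 1L,
                  parent = "tap", attachment = 2),
    straight_root("lat2", c(0, 0, 5), c(0, 4, 5), n = 5L, order = 1L,
                  parent = "tap", attachment = 5)))
}

# drop roots by id from a system
drop_roots <- function(rsa, ids) {
  keep <- Filter(function(r) !r$root_id %in% ids, rsa$roots)
  root_system(keep, label = rsa$label, validate = FALSE)
}

# rigid transform: rotation matrix R (3x3) and translation t
apply_rigid <- function(rsa, R, t) {
  roots <- lapply(rsa$roots, function(r) {
    r$nodes <- r$nodes %*% t(R) + matrix(t, nrow(r$nodes), 3L, byrow = TRUE)
    r$parent_attachment <- NULL  # arc positions are invariant anyway
    r
  })
  root_system(roots, label = rsa$label)
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

# independent brute-force oracle: min distance between two segments by
# dense grid search over both parameters
grid_segment_distance <- function(p0, p1, q0, q1, step = 1e-3) {
  x <- seq(0, 1, by = step)
  A <- outer(1 - x, p0) + outer(x, p1)
  B <- outer(1 - x, q0) + outer(x, q1)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(max(min(d2), 0))
}

# independent exhaustive oracle for the minimum-total-distance one-to-one
# assignment of size min(nrow, ncol)
enumerate_min_assignment <- function(C) {
  n <- nrow(C); m <- ncol(C); k <- min(n, m)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- Inf
  row_sets <- utils::combn(seq_len(n), k, simplify = FALSE)
  for (rs in row_sets)
    for (cp in perms(seq_len(m))) {
      tot <- sum(C[cbind(rs, cp[seq_len(k)])])
      if (tot < best) best <- tot
    }
  best
}

# plain-loop re-statement of the two-phase segment matching rule
bruteforce_match_segments <- function(D, threshold) {
  n <- nrow(D); m <- ncol(D)
  owner <- integer(m)
  for (j in seq_len(m)) {
    i <- which.min(D[, j])
    if (D[i, j] <= threshold) owner[j] <- i
  }
  singles <- which(tabulate(owner, nbins = n) == 1L)
  for (j in which(owner == 0L)) {
    if (!length(singles)) break
    i <- singles[which.min(D[singles, j])]
    if (D[i, j] <= threshold) owner[j] <- i
  }
  owner
}

# random small root system for property tests (valid, 1 taproot + laterals)
random_small_rsa <- function(n_laterals = 3L) {
  p <- generator_params(taproot_length = 8, n_laterals = n_laterals,
                        inter_lateral_distance = 1.5,
                        first_lateral_offset = 1,
                        lateral_length_mean = 3, lateral_length_sd = 0.5,
                        node_spacing = 0.5, tortuosity = 0.05)
  generate_root_system(p)
}
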