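# Minimal Euclidean distance between straight segments, and the full
# ground-truth x traced segment distance matrix that drives matching.

# Vectorized closed-form closest approach between segment pairs
# [P0_k, P1_k] and [Q0_k, Q1_k] (rows of n x 3 matrices), parameters
# clamped to [0, 1] (Ericson-style robust formulation).
segment_pair_distance <- function(P0, P1, Q0, Q1) {
  d1 <- P1 - P0
  d2 <- Q1 - Q0
  r <- P0 - Q0
  a <- rowSums(d1 * d1)
  e <- rowSums(d2 * d2)
  b <- rowSums(d1 * d2)
  c_ <- rowSums(d1 * r)
  f <- rowSums(d2 * r)
  denom <- a * e - b * b
  s <- ifelse(denom > .Machine$double.eps * a * e,
              clamp01((b * f - c_ * e) / denom), 0)
  t <- (b * s + f) / e
  lo <- t < 0
  hi <- t > 1
  t <- clamp01(t)
  s[lo] <- clamp01(-c_[lo] / a[lo])
  s[hi] <- clamp01((b[hi] - c_[hi]) / a[hi])
  cp <- P0 + d1 * s
  cq <- Q0 + d2 * t
  sqrt(rowSums((cp - cq)^2))
}

#' Minimal distance between two straight segments
#'
#' Returns the minimum over both segment parameters in \[0, 1\] of the
#' Euclidean distance between a point on segment `a` and a point on segment
#' `b` — the entries of the segment distance matrix used for matching.
#' Computed in closed form (clamped quadratic), not by numerical search.
#'
#' @param a,b Segments, each either a single row of a [to_segments()] data
#'   frame or a list/vector with endpoints `p0`, `p1` (3-vectors, cm).
#' @return Distance in cm.
#' @export
segment_distance <- function(a, b) {
  ends <- function(s) {
    if (is.data.frame(s)) {
      list(p0 = c(s$x0[1L], s$y0[1L], s$z0[1L]),
           p1 = c(s$x1[1L], s$y1[1L], s$z1[1L]))
    } else if (is.list(s)) {
      list(p0 = as.numeric(s$p0), p1 = as.numeric(s$p1))
    } else stop_parameter("segment must be a data frame row or list(p0, p1)")
  }
  ea <- ends(a); eb <- ends(b)
  if (vnorm(ea$p1 - ea$p0) == 0 || vnorm(eb$p1 - eb$p0) == 0)
    stop_degenerate("zero-length segment passed to segment_distance")
  segment_pair_distance(matrix(ea$p0, 1L), matrix(ea$p1, 1L),
                        matrix(eb$p0, 1L), matrix(eb$p1, 1L))
}

#' Pairwise segment distance matrix between two architectures
#'
#' Computes the full matrix `D` with `D[i, j]` the minimal Euclidean distance
#' between ground-truth segment i and traced segment j. This matrix is the
#' base metric for segment and root matching.
#'
#' @param gt_segments,traced_segments Segment tables from [to_segments()];
#'   both non-empty with strictly positive lengths.
#' @return A numeric matrix (cm) with `dimnames` giving `root_id:index`
#'   identifiers for rows (ground truth) and columns (tracing).
#' @export
distance_matrix <- function(gt_segments, traced_segments) {
  if (!nrow(gt_segments) || !nrow(traced_segments))
    stop_parameter("distance_matrix requires non-empty segment tables")
  if (any(gt_segments$length <= 0) || any(traced_segments$length <= 0))
    stop_degenerate("zero-length segment in distance_matrix input")
  n <- nrow(gt_segments); m <- nrow(traced_segments)
  gi <- rep(seq_len(n), times = m)
  tj <- rep(seq_len(m), each = n)
  P0 <- cbind(gt_segments$x0, gt_segments$y0, gt_segments$z0)[gi, , drop = FALSE]
  P1 <- cbind(gt_segments$x1, gt_segments$y1, gt_segments$z1)[gi, , drop = FALSE]
  Q0 <- cbind(traced_segments$x0, traced_segments$y0, traced_segments$z0)[tj, , drop = FALSE]
  Q1 <- cbind(traced_segments$x1, traced_segments$y1, traced_segments$z1)[tj, , drop = FALSE]
  D <- matrix(segment_pair_distance(P0, P1, Q0, Q1), nrow = n, ncol = m)
  dimnames(D) <- list(paste(gt_segments$root_id, gt_segments$index, sep = ":"),
                      paste(traced_segments$root_id, traced_segments$index, sep = ":"))
  D
}
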