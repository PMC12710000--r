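# Segment correspondence and root-level matching between a ground-truth RSA
# and a traced RSA under a distance threshold.

#' Convert a voxel-unit matching threshold to cm
#'
#' The matching threshold is conventionally quoted in voxel units of the
#' virtual MRI grid (default 15 voxels); all matching APIs take cm.
#'
#' @param threshold_vox Threshold in voxel units (> 0).
#' @param voxel_size Isotropic voxel size in cm (> 0).
#' @return Threshold in cm.
#' @examples
#' voxel_threshold_to_cm(15, 0.05)  # 0.75 cm
#' @export
voxel_threshold_to_cm <- function(threshold_vox, voxel_size) {
  if (!is_scalar(threshold_vox) || threshold_vox <= 0)
    stop_parameter("threshold_vox must be a positive scalar")
  if (!is_scalar(voxel_size) || voxel_size <= 0)
    stop_parameter("voxel_size must be a positive scalar")
  threshold_vox * voxel_size
}

#' Two-phase segment correspondence under a distance threshold
#'
#' Phase 1 assigns every traced segment to its nearest ground-truth segment
#' when that distance is within the threshold, yielding 1-to-n correspondence
#' sets per ground-truth segment. Phase 2 revisits traced segments that are
#' still unmatched and attaches them to the nearest ground-truth segment
#' among those currently holding exactly one correspondence, when within
#' `threshold * phase2_relax`. Ties are broken towards the lowest row index.
#' Deterministic given `D`.
#'
#' @param D Segment distance matrix from [distance_matrix()] (rows = ground
#'   truth, columns = tracing).
#' @param threshold Distance threshold in cm (> 0).
#' @param phase2_relax Multiplier on the threshold for the second phase
#'   (default 1, i.e. no relaxation).
#' @return An object of class `segment_correspondence`: list with
#'   `assigned` (list, per ground-truth segment, of traced column indices),
#'   `distance` (list of the corresponding distances),
#'   `unmatched_traced` (column indices) and `threshold`.
#' @export
match_segments <- function(D, threshold, phase2_relax = 1) {
  if (!is.matrix(D) || !length(D))
    stop_parameter("D must be a non-empty matrix")
  if (!is_scalar(threshold) || threshold <= 0)
    stop_parameter("threshold must be a positive scalar")
  n <- nrow(D); m <- ncol(D)
  assigned <- rep(list(integer(0)), n)
  dists <- rep(list(numeric(0)), n)
  owner <- integer(m)   # 0 = unmatched

  nearest <- apply(D, 2L, which.min)            # ties -> lowest row index
  dmin <- D[cbind(nearest, seq_len(m))]
  hit <- dmin <= threshold
  for (j in which(hit)) {
    i <- nearest[j]
    assigned[[i]] <- c(assigned[[i]], j)
    dists[[i]] <- c(dists[[i]], dmin[j])
    owner[j] <- i
  }

  singles <- which(lengths(assigned) == 1L)
  if (length(singles) && any(owner == 0L)) {
    for (j in which(owner == 0L)) {
      sub <- D[singles, j]
      k <- which.min(sub)
      if (sub[k] <= threshold * phase2_relax) {
        i <- singles[k]
        assigned[[i]] <- c(assigned[[i]], j)
        dists[[i]] <- c(dists[[i]], sub[k])
        owner[j] <- i
      }
    }
  }

  structure(list(assigned = assigned, distance = dists,
                 unmatched_traced = which(owner == 0L),
                 owner = owner, threshold = threshold),
            class = "segment_correspondence")
}

#' Cumulative distance between a ground-truth root and a traced root
#'
#' For every ground-truth segment of the root, takes the minimal distance to
#' any segment of the traced root, and aggregates. The default aggregation is
#' the length-weighted mean over the ground-truth segments, which keeps the
#' result on the scale of segment distances and therefore directly comparable
#' to the matching threshold regardless of root length.
#'
#' @param D Segment distance matrix ([distance_matrix()]).
#' @param gt_rows Row indices of the ground-truth root's segments in `D`.
#' @param traced_cols Column indices of the traced root's segments in `D`.
#' @param weights Ground-truth segment lengths (cm) for the weighted mean;
#'   required for `mode = "length-weighted"`.
#' @param mode Aggregation: `"length-weighted"` (default), `"mean"` or
#'   `"sum"`.
#' @return Cumulative distance in cm.
#' @export
cumulative_root_distance <- function(D, gt_rows, traced_cols, weights = NULL,
                                     mode = c("length-weighted", "mean", "sum")) {
  mode <- match.arg(mode)
  if (!length(gt_rows) || !length(traced_cols))
    stop_degenerate("cumulative_root_distance: root with no segments")
  sub <- D[gt_rows, traced_cols, drop = FALSE]
  per_gt_min <- apply(sub, 1L, min)
  switch(mode,
         "length-weighted" = {
           if (is.null(weights))
             stop_parameter("weights required for length-weighted mode")
           sum(per_gt_min * weights) / sum(weights)
         },
         "mean" = mean(per_gt_min),
         "sum" = sum(per_gt_min))
}

# Minimum-cost complete assignment on a (possibly rectangular) cost matrix.
# Infinite costs mark forbidden pairs. Returns a 2-column matrix (row, col).
# Solved as maximum-weight bipartite matching with weights C_big - cost,
# C_big > sum of all finite costs, so maximum weight implies maximum
# cardinality first and minimum total cost second.
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  idx <- which(is.finite(cost), arr.ind = TRUE)
  if (!nrow(idx)) return(cbind(row = integer(0), col = integer(0)))
  w <- cost[idx]
  big <- sum(w) + 1
  g <- igraph::make_bipartite_graph(c(rep(FALSE, n), rep(TRUE, m)),
                                    edges = as.vector(t(cbind(idx[, 1L],
                                                              n + idx[, 2L]))))
  mm <- igraph::max_bipartite_match(
    g, types = c(rep(FALSE, n), rep(TRUE, m)),
    weights = big - w)
  mate <- mm$matching[seq_len(n)]
  keep <- !is.na(mate)
  cbind(row = which(keep), col = as.integer(mate[keep]) - n)
}

greedy_assignment <- function(cost, threshold) {
  out <- NULL
  cost <- as.matrix(cost)
  repeat {
    k <- which.min(cost)
    if (!length(k) || !is.finite(cost[k]) || cost[k] > threshold) break
    rc <- arrayInd(k, dim(cost))
    out <- rbind(out, c(rc[1L], rc[2L]))
    cost[rc[1L], ] <- Inf
    cost[, rc[2L]] <- Inf
  }
  if (is.null(out)) cbind(row = integer(0), col = integer(0))
  else {colnames(out) <- c("row", "col"); out}
}

# Cumulative distance matrix between all roots of two systems.
root_distance_matrix <- function(gt, traced, mode = "length-weighted") {
  segs_gt <- to_segments(gt)
  segs_tr <- to_segments(traced)
  D <- distance_matrix(segs_gt, segs_tr)
  gids <- root_ids(gt); tids <- root_ids(traced)
  C <- matrix(NA_real_, length(gids), length(tids),
              dimnames = list(gids, tids))
  rows_by_root <- split(seq_len(nrow(segs_gt)), factor(segs_gt$root_id, levels = gids))
  cols_by_root <- split(seq_len(nrow(segs_tr)), factor(segs_tr$root_id, levels = tids))
  for (mj in seq_along(tids)) {
    cols <- cols_by_root[[mj]]
    per_gt_min <- if (length(cols) == 1L) D[, cols] else
      do.call(pmin, lapply(cols, function(j) D[, j]))
    for (ni in seq_along(gids)) {
      rows <- rows_by_root[[ni]]
      w <- segs_gt$length[rows]
      C[ni, mj] <- switch(mode,
        "length-weighted" = sum(per_gt_min[rows] * w) / sum(w),
        "mean" = mean(per_gt_min[rows]),
        "sum" = sum(per_gt_min[rows]))
    }
  }
  list(C = C, D = D, segs_gt = segs_gt, segs_tr = segs_tr)
}

#' Match traced roots to ground-truth roots
#'
#' Stage 1 solves the globally optimal one-to-one assignment between
#' ground-truth and traced roots minimizing the total cumulative distance
#' (see [cumulative_root_distance()]), then keeps only pairs whose
#' cumulative distance is within the threshold. Stage 2 attaches each
#' remaining traced root to the Stage-1-matched ground-truth root with the
#' least cumulative distance, when within the threshold — this absorbs roots
#' traced as several fragments into a single 1-to-n pair. Ground-truth roots
#' left unmatched are false negatives; traced roots left unmatched are false
#' positives.
#'
#' @param gt Ground-truth [root_system()] (non-empty).
#' @param traced Traced [root_system()]; may be empty, in which case every
#'   ground-truth root is a false negative.
#' @param threshold Matching threshold in cm (> 0); see
#'   [voxel_threshold_to_cm()] for the voxel-unit convention (default
#'   15 voxels at 0.05 cm = 0.75 cm).
#' @param mode Cumulative-distance aggregation passed to
#'   [cumulative_root_distance()].
#' @param assignment `"optimal"` (linear assignment, default) or `"greedy"`
#'   (ascending-distance).
#' @param restrict Restrict candidate root pairs to those sharing at least
#'   one segment correspondence from [match_segments()] (default `FALSE`).
#' @return An object of class `root_match`: list with `pairs` (data frame
#'   `gt_root`, `traced_root`, `distance`, `stage`), `I_GC`, `I_TC`,
#'   `false_negative_roots`, `false_positive_roots`, `threshold`, and the
#'   root-level cumulative distance matrix `C`.
#' @export
match_roots <- function(gt, traced, threshold,
                        mode = c("length-weighted", "mean", "sum"),
                        assignment = c("optimal", "greedy"),
                        restrict = FALSE) {
  mode <- match.arg(mode)
  assignment <- match.arg(assignment)
  if (!is_scalar(threshold) || threshold <= 0)
    stop_parameter("threshold must be a positive scalar")
  validate_root_system(gt)
  validate_root_system(traced)
  if (!length(gt$roots)) stop_parameter("ground-truth system is empty")
  gids <- root_ids(gt)

  empty_match <- function() {
    structure(list(
      pairs = data.frame(gt_root = character(0), traced_root = character(0),
                         distance = numeric(0), stage = integer(0),
                         stringsAsFactors = FALSE),
      I_GC = character(0), I_TC = character(0),
      false_negative_roots = gids, false_positive_roots = character(0),
      threshold = threshold, C = NULL), class = "root_match")
  }
  if (!length(traced$roots)) return(empty_match())

  tids <- root_ids(traced)
  rd <- root_distance_matrix(gt, traced, mode = mode)
  C <- rd$C

  if (restrict) {
    corr <- match_segments(rd$D, threshold)
    allowed <- matrix(FALSE, length(gids), length(tids))
    for (i in seq_along(corr$assigned)) {
      js <- corr$assigned[[i]]
      if (length(js))
        allowed[match(rd$segs_gt$root_id[i], gids),
                match(rd$segs_tr$root_id[js], tids)] <- TRUE
    }
    C_eff <- ifelse(allowed, C, Inf)
  } else C_eff <- C

  sel <- if (assignment == "optimal") solve_assignment(C_eff)
         else greedy_assignment(C_eff, threshold)
  if (nrow(sel)) {
    d <- C[sel]
    keep <- d <= threshold
    sel <- sel[keep, , drop = FALSE]
    d <- d[keep]
  } else d <- numeric(0)

  pairs <- data.frame(gt_root = gids[sel[, "row"]],
                      traced_root = tids[sel[, "col"]],
                      distance = d,
                      stage = rep(1L, nrow(sel)),
                      stringsAsFactors = FALSE)

  # Stage 2: fragment absorption onto Stage-1 ground-truth roots
  matched_gt_idx <- sel[, "row"]
  remaining <- setdiff(seq_along(tids), sel[, "col"])
  if (length(matched_gt_idx) && length(remaining)) {
    for (j in remaining) {
      sub <- C[matched_gt_idx, j]
      k <- which.min(sub)
      if (sub[k] <= threshold)
        pairs <- rbind(pairs, data.frame(
          gt_root = gids[matched_gt_idx[k]], traced_root = tids[j],
          distance = sub[k], stage = 2L, stringsAsFactors = FALSE))
    }
  }

  I_GC <- unique(pairs$gt_root)
  I_TC <- unique(pairs$traced_root)
  structure(list(pairs = pairs, I_GC = I_GC, I_TC = I_TC,
                 false_negative_roots = setdiff(gids, I_GC),
                 false_positive_roots = setdiff(tids, I_TC),
                 threshold = threshold, C = C),
            class = "root_match")
}

#' @export
print.root_match <- function(x, ...) {
  cat(sprintf("<root_match> threshold %.3f cm\n", x$threshold))
  cat(sprintf("  matched: %d GT root(s) <- %d traced root(s)\n",
              length(x$I_GC), length(x$I_TC)))
  cat(sprintf("  false negatives: %d, false positives: %d\n",
              length(x$false_negative_roots), length(x$false_positive_roots)))
  invisible(x)
}

#' Serialize a root match to a JSON-ready list
#'
#' @param match A `root_match`.
#' @return A list (pairs with distances, false negative/positive root ids)
#'   that `jsonlite::toJSON()` renders directly.
#' @export
match_report <- function(match) {
  list(threshold_cm = match$threshold,
       pairs = match$pairs,
       false_negative_roots = as.list(match$false_negative_roots),
       false_positive_roots = as.list(match$false_positive_roots))
}
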