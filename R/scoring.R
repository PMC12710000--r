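# Matched-length decomposition and the penalized recall / precision / F1
# used to quantify tracing accuracy. All lengths are whole-root totals over
# the matched / unmatched root index sets, not per-segment sums.

#' Whole-root length decomposition of a root match
#'
#' Sums whole-root lengths over the root index sets of a [match_roots()]
#' result: `L_GT` (all ground truth), `L_GC` (matched ground-truth roots),
#' `L_TC` (matched traced roots), `L_FN` (unmatched ground-truth roots) and
#' `L_FP` (unmatched traced roots). Note `L_GC` and `L_TC` generally differ:
#' the former sums ground-truth roots, the latter the traced roots matched
#' to them. `L_GC + L_FN = L_GT` always holds.
#'
#' @param match A `root_match` produced from `gt` and `traced`.
#' @param gt,traced The two [root_system()]s the match was computed from.
#' @return An object of class `length_decomposition` with fields `L_GT`,
#'   `L_GC`, `L_TC`, `L_FN`, `L_FP` (cm).
#' @export
length_decomposition <- function(match, gt, traced) {
  gids <- root_ids(gt)
  tids <- root_ids(traced)
  if (!all(c(match$I_GC, match$false_negative_roots) %in% gids) ||
      !all(c(match$I_TC, match$false_positive_roots) %in% tids))
    stop_validation("match does not correspond to the supplied root systems")
  glen <- vapply(gt$roots, root_length, numeric(1))
  tlen <- if (length(traced$roots))
    vapply(traced$roots, root_length, numeric(1)) else numeric(0)
  names(glen) <- gids
  if (length(tlen)) names(tlen) <- tids
  ld <- list(L_GT = sum(glen),
             L_GC = sum(glen[match$I_GC]),
             L_TC = sum(tlen[match$I_TC]),
             L_FN = sum(glen[match$false_negative_roots]),
             L_FP = sum(tlen[match$false_positive_roots]))
  structure(ld, class = "length_decomposition")
}

new_length_decomposition <- function(L_GC, L_FN, L_TC, L_FP = 0,
                                     L_GT = L_GC + L_FN) {
  structure(list(L_GT = L_GT, L_GC = L_GC, L_TC = L_TC,
                 L_FN = L_FN, L_FP = L_FP),
            class = "length_decomposition")
}

check_ld <- function(ld) {
  v <- unlist(ld[c("L_GC", "L_TC", "L_FN", "L_FP")])
  if (any(!is.finite(v)) || any(v < 0))
    stop_validation("length decomposition has negative or non-finite lengths")
  invisible(TRUE)
}

penalty <- function(x, penalty_mode) {
  switch(penalty_mode, "max" = max(0, x), "literal-min" = min(0, x),
         stop_parameter("unknown penalty_mode '%s'", penalty_mode))
}

#' Penalized matched-length recall
#'
#' `R = L_GC / (L_GC + L_FN + pen)` measures how much of the ground-truth
#' root system (in length) was traced. The penalty term activates when the
#' matched traced length falls short of the matched ground-truth length
#' (under-tracing): with the default `penalty_mode = "max"`,
#' `pen = max(0, L_GC - L_TC)`. The literal published form `min(0, ·)` is
#' retained behind `penalty_mode = "literal-min"` for forensic comparison;
#' it evaluates to zero exactly when the text says the penalty should bind
#' and can push the score above 1 otherwise. Zero denominator yields 0.
#'
#' @param ld A [length_decomposition()].
#' @param penalty_mode `"max"` (default) or `"literal-min"`.
#' @return Recall; in \[0, 1\] under `"max"`.
#' @export
recall <- function(ld, penalty_mode = c("max", "literal-min")) {
  penalty_mode <- match.arg(penalty_mode)
  check_ld(ld)
  den <- ld$L_GC + ld$L_FN + penalty(ld$L_GC - ld$L_TC, penalty_mode)
  if (den <= 0) 0 else ld$L_GC / den
}

#' Penalized matched-length precision
#'
#' `P = L_GC / (L_GC + L_FP + pen)` measures whether the tracing contains
#' only as much length as the ground truth. The penalty activates when
#' matched traced roots are too long compared to the ground truth
#' (over-tracing): with `penalty_mode = "max"`, `pen = max(0, L_TC - L_GC)`.
#' See [recall()] for the `"literal-min"` mode. Zero denominator yields 0.
#'
#' @inheritParams recall
#' @return Precision; in \[0, 1\] under `"max"`.
#' @export
precision <- function(ld, penalty_mode = c("max", "literal-min")) {
  penalty_mode <- match.arg(penalty_mode)
  check_ld(ld)
  den <- ld$L_GC + ld$L_FP + penalty(ld$L_TC - ld$L_GC, penalty_mode)
  if (den <= 0) 0 else ld$L_GC / den
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2PR / (P + R)`; 0 when `P + R = 0`.
#'
#' @param P,R Precision and recall in \[0, 1\].
#' @return F1 score in \[0, 1\].
#' @export
f1_score <- function(P, R) {
  if (!is_scalar(P) || !is_scalar(R) || P < 0 || P > 1 || R < 0 || R > 1)
    stop_validation("P and R must be scalars in [0, 1]")
  if (P + R == 0) 0 else 2 * P * R / (P + R)
}

#' Score a traced root system against ground truth
#'
#' Composes [match_roots()], [length_decomposition()] and the penalized
#' [recall()], [precision()] and [f1_score()]. Matching first guarantees the
#' scores carry topological (root-level) information rather than raw overlap.
#' An empty tracing scores R = P = F1 = 0.
#'
#' @param gt Ground-truth [root_system()] (non-empty).
#' @param traced Traced [root_system()].
#' @param threshold Matching threshold in cm; default 0.75 cm, i.e. the
#'   15-voxel convention at 0.05 cm voxels ([voxel_threshold_to_cm()]).
#' @param penalty_mode See [recall()].
#' @param ... Passed on to [match_roots()] (`mode`, `assignment`,
#'   `restrict`).
#' @return An object of class `score_report` with fields `recall`,
#'   `precision`, `f1`, `penalty_mode`, `threshold`, the embedded
#'   `length_decomposition` and `match`.
#' @export
score <- function(gt, traced, threshold = 0.75,
                  penalty_mode = c("max", "literal-min"), ...) {
  penalty_mode <- match.arg(penalty_mode)
  m <- match_roots(gt, traced, threshold, ...)
  ld <- length_decomposition(m, gt, traced)
  R <- recall(ld, penalty_mode)
  P <- precision(ld, penalty_mode)
  structure(list(recall = R, precision = P, f1 = f1_score(clamp01(P), clamp01(R)),
                 penalty_mode = penalty_mode, threshold = threshold,
                 lengths = ld, match = m),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("<score_report> threshold %.3f cm, penalty_mode = %s\n",
              x$threshold, x$penalty_mode))
  cat(sprintf("  recall    R  = %.4f\n", x$recall))
  cat(sprintf("  precision P  = %.4f\n", x$precision))
  cat(sprintf("  F1           = %.4f\n", x$f1))
  ld <- x$lengths
  cat(sprintf("  lengths (cm): L_GT %.2f | L_GC %.2f | L_TC %.2f | L_FN %.2f | L_FP %.2f\n",
              ld$L_GT, ld$L_GC, ld$L_TC, ld$L_FN, ld$L_FP))
  invisible(x)
}

#' Serialize a score report to a JSON-ready list
#'
#' @param report A `score_report`.
#' @return A named list that `jsonlite::toJSON()` renders directly.
#' @export
score_report_json <- function(report) {
  list(recall = report$recall, precision = report$precision, f1 = report$f1,
       penalty_mode = report$penalty_mode, threshold_cm = report$threshold,
       lengths = unclass(report$lengths),
       match = match_report(report$match))
}
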