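#' Construct a single root organ
#'
#' A root is an ordered 3D polyline with a per-node diameter, an order label
#' (0 = taproot/primary, 1 = first-order lateral, ...) and, for laterals, a
#' reference to the parent root and optionally the arc-length position on the
#' parent where it is attached.
#'
#' @param root_id Unique identifier (character scalar).
#' @param nodes Numeric matrix with one row per node and columns x, y, z in cm.
#'   At least two rows; consecutive rows must be distinct so that every
#'   segment has positive length.
#' @param diameters Per-node diameters in cm; recycled if a single value.
#' @param order Non-negative integer branching order.
#' @param parent_root_id Identifier of the parent root, or `NULL` for a
#'   taproot.
#' @param parent_attachment Optional arc-length position (cm) along the parent
#'   where this root is attached.
#' @return An object of class `rsa_root`.
#' @export
root <- function(root_id, nodes, diameters = 0.1, order = 0L,
                 parent_root_id = NULL, parent_attachment = NULL) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  if (ncol(nodes) != 3L)
    stop_validation("root '%s': nodes must have 3 columns (x, y, z)", root_id)
  diameters <- rep_len(as.numeric(diameters), nrow(nodes))
  structure(list(root_id = as.character(root_id),
                 nodes = unname(nodes),
                 diameters = diameters,
                 order = as.integer(order),
                 parent_root_id = if (is.null(parent_root_id)) NULL
                                  else as.character(parent_root_id),
                 parent_attachment = parent_attachment),
            class = "rsa_root")
}

#' Construct a root system architecture (RSA)
#'
#' A root system is a forest of [root()] organs linked through
#' `parent_root_id`. All geometry is held in cm.
#'
#' @param roots List of [root()] objects.
#' @param label Free-text label for the plant / scan.
#' @param unit Length unit tag; the in-memory representation is always cm.
#' @param validate Run [validate_root_system()] on the result (default).
#' @return An object of class `root_system`.
#' @export
root_system <- function(roots = list(), label = "", unit = "cm",
                        validate = TRUE) {
  rsa <- structure(list(roots = roots, label = label, unit = unit),
                   class = "root_system")
  if (validate) validate_root_system(rsa)
  rsa
}

#' Validate a root system
#'
#' Checks structural invariants: unique root ids, at least two nodes per root,
#' strictly positive segment lengths, finite coordinates, non-negative
#' diameters, resolvable and acyclic parent references, and order consistency
#' (a child's order is its parent's order + 1).
#'
#' @param rsa A [root_system()].
#' @param as_report Return a list of issues instead of raising an error.
#' @return `TRUE` invisibly, or (with `as_report = TRUE`) a list with elements
#'   `valid` and `issues` suitable for JSON serialization.
#' @export
validate_root_system <- function(rsa, as_report = FALSE) {
  issues <- character(0)
  note <- function(msg, ...) issues <<- c(issues, sprintf(msg, ...))
  if (!inherits(rsa, "root_system")) {
    note("not a root_system object")
  } else {
    ids <- vapply(rsa$roots, function(r) r$root_id, character(1))
    if (anyDuplicated(ids))
      note("duplicate root ids: %s",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    for (r in rsa$roots) {
      if (nrow(r$nodes) < 2L)
        note("root '%s': fewer than 2 nodes", r$root_id)
      if (!all(is.finite(r$nodes)))
        note("root '%s': non-finite coordinates", r$root_id)
      if (any(r$diameters < 0))
        note("root '%s': negative diameter", r$root_id)
      if (nrow(r$nodes) >= 2L) {
        seglen <- sqrt(rowSums((r$nodes[-1L, , drop = FALSE] -
                                r$nodes[-nrow(r$nodes), , drop = FALSE])^2))
        if (any(seglen <= 0))
          note("root '%s': zero-length segment (consecutive duplicate nodes)",
               r$root_id)
      }
      if (r$order < 0L) note("root '%s': negative order", r$root_id)
      if (is.null(r$parent_root_id)) {
        if (r$order != 0L)
          note("root '%s': order %d but no parent", r$root_id, r$order)
      } else {
        p <- match(r$parent_root_id, ids)
        if (is.na(p)) {
          note("root '%s': unresolvable parent '%s'", r$root_id,
               r$parent_root_id)
        } else if (rsa$roots[[p]]$order + 1L != r$order) {
          note("root '%s': order %d but parent order %d", r$root_id,
               r$order, rsa$roots[[p]]$order)
        }
      }
    }
    # acyclicity of the parent forest
    if (length(rsa$roots) && !anyDuplicated(ids)) {
      parent <- vapply(rsa$roots,
                       function(r) r$parent_root_id %||% NA_character_,
                       character(1))
      for (i in seq_along(ids)) {
        seen <- integer(0); j <- i
        while (!is.na(parent[j])) {
          j <- match(parent[j], ids)
          if (is.na(j)) break
          if (j %in% seen || j == i) { note("cycle through root '%s'", ids[i]); break }
          seen <- c(seen, j)
        }
      }
    }
  }
  if (as_report)
    return(list(valid = length(issues) == 0L, issues = as.list(issues)))
  if (length(issues))
    stop_validation("invalid root system: %s", paste(issues, collapse = "; "))
  invisible(TRUE)
}

#' Root identifiers of a system, in listed order
#'
#' @param rsa A [root_system()].
#' @return Character vector of root ids.
#' @export
root_ids <- function(rsa) vapply(rsa$roots, function(r) r$root_id, character(1))

get_root <- function(rsa, id) {
  i <- match(id, root_ids(rsa))
  if (is.na(i)) stop_validation("no root with id '%s'", id)
  rsa$roots[[i]]
}

#' Arc length of a single root
#'
#' @param r An `rsa_root`.
#' @return Total polyline length in cm.
#' @export
root_length <- function(r) {
  n <- nrow(r$nodes)
  sum(sqrt(rowSums((r$nodes[-1L, , drop = FALSE] -
                    r$nodes[-n, , drop = FALSE])^2)))
}

#' Decompose a root system into straight segments
#'
#' Emits one segment per consecutive node pair per root, in a stable
#' (root order as listed, node order) sequence. The sum of segment lengths
#' equals [total_length()] of the system.
#'
#' @param rsa A [root_system()].
#' @return A data frame with columns `root_id`, `index` (segment index within
#'   its root), endpoint coordinates `x0,y0,z0,x1,y1,z1` (cm), `length` (cm)
#'   and `radius` (cm, mean of the two node radii).
#' @export
to_segments <- function(rsa) {
  validate_root_system(rsa)
  out <- lapply(rsa$roots, function(r) {
    n <- nrow(r$nodes)
    a <- r$nodes[-n, , drop = FALSE]
    b <- r$nodes[-1L, , drop = FALSE]
    data.frame(root_id = r$root_id,
               index = seq_len(n - 1L),
               x0 = a[, 1L], y0 = a[, 2L], z0 = a[, 3L],
               x1 = b[, 1L], y1 = b[, 2L], z1 = b[, 3L],
               length = sqrt(rowSums((b - a)^2)),
               radius = (r$diameters[-n] + r$diameters[-1L]) / 4,
               radius0 = r$diameters[-n] / 2,
               radius1 = r$diameters[-1L] / 2,
               stringsAsFactors = FALSE)
  })
  if (!length(out))
    return(data.frame(root_id = character(0), index = integer(0),
                      x0 = numeric(0), y0 = numeric(0), z0 = numeric(0),
                      x1 = numeric(0), y1 = numeric(0), z1 = numeric(0),
                      length = numeric(0), radius = numeric(0),
                      radius0 = numeric(0), radius1 = numeric(0)))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' @export
print.root_system <- function(x, ...) {
  cat(sprintf("<root_system> %s\n", if (nzchar(x$label)) x$label else "(unlabelled)"))
  cat(sprintf("  roots: %d (%d taproot(s), %d lateral(s))\n",
              length(x$roots),
              sum(vapply(x$roots, function(r) r$order == 0L, logical(1))),
              sum(vapply(x$roots, function(r) r$order > 0L, logical(1)))))
  if (length(x$roots))
    cat(sprintf("  total length: %.3f cm\n", total_length(x)))
  invisible(x)
}

#' @export
summary.root_system <- function(object, ...) {
  lens <- vapply(object$roots, root_length, numeric(1))
  orders <- vapply(object$roots, function(r) r$order, integer(1))
  out <- list(n_roots = length(object$roots),
              n_by_order = if (length(orders)) table(orders) else table(integer(0)),
              total_length = sum(lens),
              mean_root_length = if (length(lens)) mean(lens) else NA_real_)
  class(out) <- "summary.root_system"
  out
}

#' @export
print.summary.root_system <- function(x, ...) {
  cat(sprintf("root system: %d roots, total length %.3f cm, mean root length %.3f cm\n",
              x$n_roots, x$total_length, x$mean_root_length))
  if (x$n_roots) print(x$n_by_order)
  invisible(x)
}
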