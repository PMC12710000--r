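# Parametric generator of faba-bean-like ground-truth root systems (one
# taproot carrying first-order laterals) and a tracing-error perturbation
# model emulating the artifact classes seen in human tracings: suboptimal
# pathing (node jitter), missed roots, over-/under-traced tips, spurious
# short branches, and free-floating false positives (e.g. clicks into the
# water-noise column).

#' Parameters of the synthetic root-system generator
#'
#' Defaults describe a small faba-bean-like plant: a 15 cm taproot with 25
#' first-order laterals spaced 0.5 cm apart, lateral lengths 4 +/- 1 cm,
#' branching angles 65 +/- 10 degrees from the taproot axis.
#'
#' @param taproot_length Taproot arc length in cm.
#' @param n_laterals Number of first-order laterals (>= 0).
#' @param inter_lateral_distance Arc-length spacing between consecutive
#'   lateral attachment points on the taproot, cm.
#' @param first_lateral_offset Arc position of the first lateral, cm.
#' @param lateral_length_mean,lateral_length_sd Normal length distribution
#'   of laterals (cm), truncated below at 0.5 cm; `sd = 0` makes every
#'   lateral exactly `lateral_length_mean` long.
#' @param branching_angle_mean,branching_angle_sd Branching angle from the
#'   local taproot tangent, degrees.
#' @param node_spacing Polyline node spacing, cm.
#' @param tortuosity Magnitude of the per-step random direction
#'   perturbation; 0 gives perfectly straight organs.
#' @param arc_jitter_sd Jitter (cm) on the lateral attachment arc positions.
#' @param taproot_diameter,lateral_diameter Base diameters in cm; organs
#'   taper linearly to `taper_fraction` of the base at the tip.
#'   `lateral_diameter` may be a vector of length `n_laterals` to override
#'   individual laterals (e.g. one very thin, hard-to-see root).
#' @param taper_fraction Tip diameter as a fraction of the base diameter.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(taproot_length = 15, n_laterals = 25L,
                             inter_lateral_distance = 0.5,
                             first_lateral_offset = 1,
                             lateral_length_mean = 4, lateral_length_sd = 1,
                             branching_angle_mean = 65,
                             branching_angle_sd = 10,
                             node_spacing = 0.25, tortuosity = 0.1,
                             arc_jitter_sd = 0,
                             taproot_diameter = 0.2, lateral_diameter = 0.1,
                             taper_fraction = 0.4, seed = NULL) {
  p <- list(taproot_length = taproot_length, n_laterals = as.integer(n_laterals),
            inter_lateral_distance = inter_lateral_distance,
            first_lateral_offset = first_lateral_offset,
            lateral_length_mean = lateral_length_mean,
            lateral_length_sd = lateral_length_sd,
            branching_angle_mean = branching_angle_mean,
            branching_angle_sd = branching_angle_sd,
            node_spacing = node_spacing, tortuosity = tortuosity,
            arc_jitter_sd = arc_jitter_sd,
            taproot_diameter = taproot_diameter,
            lateral_diameter = lateral_diameter,
            taper_fraction = taper_fraction, seed = seed)
  for (f in c("taproot_length", "inter_lateral_distance", "node_spacing",
              "lateral_length_mean", "taproot_diameter"))
    if (!is_scalar(p[[f]]) || p[[f]] <= 0)
      stop_parameter("%s must be a positive scalar", f)
  if (p$n_laterals < 0L) stop_parameter("n_laterals must be >= 0")
  if (p$n_laterals > 0L &&
      p$first_lateral_offset + (p$n_laterals - 1L) * p$inter_lateral_distance >
        p$taproot_length)
    stop_parameter(
      "laterals do not fit on the taproot: offset + (n-1) * spacing = %.2f > %.2f cm",
      p$first_lateral_offset + (p$n_laterals - 1L) * p$inter_lateral_distance,
      p$taproot_length)
  structure(p, class = "generator_params")
}

# Random-walk polyline: from `start` along `dir0`, total arc length `length`,
# per-step direction perturbation `tortuosity`, gravitropic pull `gravi`
# towards +z (down). Returns an n x 3 matrix.
grow_polyline <- function(start, dir0, length, spacing, tortuosity,
                          gravi = 0.05) {
  n_steps <- max(1L, ceiling(length / spacing))
  steps <- rep(spacing, n_steps)
  steps[n_steps] <- length - spacing * (n_steps - 1L)
  if (steps[n_steps] <= 1e-9) { n_steps <- n_steps - 1L; steps <- steps[-length(steps)] }
  pts <- matrix(0, n_steps + 1L, 3L)
  pts[1L, ] <- start
  dir <- normalize(dir0)
  for (i in seq_len(n_steps)) {
    if (tortuosity > 0)
      dir <- normalize(dir + tortuosity * stats::rnorm(3L) + gravi * c(0, 0, 1))
    pts[i + 1L, ] <- pts[i, ] + dir * steps[i]
  }
  pts
}

# Interpolate position and tangent at arc position s along a polyline.
polyline_at <- function(nodes, s) {
  n <- nrow(nodes)
  seg <- nodes[-1L, , drop = FALSE] - nodes[-n, , drop = FALSE]
  lens <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(lens))
  s <- min(max(s, 0), cum[length(cum)])
  i <- max(1L, min(n - 1L, findInterval(s, cum, rightmost.closed = TRUE)))
  t <- (s - cum[i]) / lens[i]
  list(position = nodes[i, ] + t * seg[i, ], tangent = normalize(seg[i, ]))
}

linear_taper <- function(base, tip_fraction, n) {
  if (n == 1L) return(base)
  base * seq(1, tip_fraction, length.out = n)
}

#' Generate a synthetic faba-bean-like root system
#'
#' One taproot grows downward from the origin as a tortuosity-controlled
#' random walk; laterals are attached at regularly spaced arc positions
#' (optionally jittered), leave the taproot at the sampled branching angle
#' and a uniform random azimuth, and grow their own random walks with
#' sampled lengths. Fully reproducible from `params$seed`; the result
#' passes [validate_root_system()].
#'
#' @param params A [generator_params()].
#' @return A [root_system()] with `n_laterals + 1` roots.
#' @export
generate_root_system <- function(params = generator_params()) {
  if (!inherits(params, "generator_params"))
    stop_parameter("params must be generator_params()")
  p <- params
  with_seed(p$seed, {
    tap_nodes <- grow_polyline(c(0, 0, 0), c(0, 0, 1), p$taproot_length,
                               p$node_spacing, p$tortuosity)
    tap <- root("taproot", tap_nodes,
                diameters = linear_taper(p$taproot_diameter, p$taper_fraction,
                                         nrow(tap_nodes)),
                order = 0L)
    roots <- list(tap)
    if (p$n_laterals > 0L) {
      lat_dia <- rep_len(p$lateral_diameter, p$n_laterals)
      arcs <- p$first_lateral_offset +
        (seq_len(p$n_laterals) - 1L) * p$inter_lateral_distance
      if (p$arc_jitter_sd > 0)
        arcs <- pmin(pmax(arcs + stats::rnorm(p$n_laterals, 0, p$arc_jitter_sd),
                          0), p$taproot_length)
      for (i in seq_len(p$n_laterals)) {
        at <- polyline_at(tap_nodes, arcs[i])
        len <- if (p$lateral_length_sd > 0)
          max(0.5, stats::rnorm(1L, p$lateral_length_mean, p$lateral_length_sd))
        else p$lateral_length_mean
        theta <- if (p$branching_angle_sd > 0)
          stats::rnorm(1L, p$branching_angle_mean, p$branching_angle_sd)
        else p$branching_angle_mean
        theta <- theta * pi / 180
        phi <- stats::runif(1L, 0, 2 * pi)
        B <- orthobasis(at$tangent)
        dir <- cos(theta) * B[, 1L] +
          sin(theta) * (cos(phi) * B[, 2L] + sin(phi) * B[, 3L])
        nodes <- rbind(at$position,
                       grow_polyline(at$position, dir, len, p$node_spacing,
                                     p$tortuosity)[-1L, , drop = FALSE])
        roots[[length(roots) + 1L]] <- root(
          sprintf("lateral_%02d", i), nodes,
          diameters = linear_taper(lat_dia[i], p$taper_fraction, nrow(nodes)),
          order = 1L, parent_root_id = "taproot", parent_attachment = arcs[i])
      }
    }
    root_system(roots, label = "synthetic faba-bean-like RSA")
  })
}

#' Parameters of the tracing-error perturbation model
#'
#' Each field switches on one artifact class; all-zero parameters make
#' [perturb_tracing()] the identity.
#'
#' @param node_jitter_sd Gaussian jitter (cm, per coordinate) on every node:
#'   suboptimal pathing.
#' @param drop_root_prob Probability of dropping each lateral: missed roots.
#' @param false_positive_count Number of free-floating spurious roots added.
#' @param false_positive_length_mean,false_positive_length_sd Length
#'   distribution (cm) of false-positive roots.
#' @param false_positive_center,false_positive_diameter Horizontal placement
#'   region of false positives (cm); defaults mirror the water-noise
#'   cylinder, emulating clicks into the water column.
#' @param overtrace_fraction Signed fraction of each root's length: positive
#'   extends the tip along its last direction, negative truncates it.
#' @param spurious_branch_rate Expected number (Poisson) of short spurious
#'   branches added per root.
#' @param spurious_branch_length Length (cm) of spurious branches.
#' @param seed Integer seed.
#' @return An object of class `perturbation_params`.
#' @export
perturbation_params <- function(node_jitter_sd = 0, drop_root_prob = 0,
                                false_positive_count = 0L,
                                false_positive_length_mean = 1.5,
                                false_positive_length_sd = 0.5,
                                false_positive_center = c(0, 0),
                                false_positive_diameter = 1.5,
                                overtrace_fraction = 0,
                                spurious_branch_rate = 0,
                                spurious_branch_length = 0.8,
                                seed = NULL) {
  if (drop_root_prob < 0 || drop_root_prob > 1)
    stop_parameter("drop_root_prob must be in [0, 1]")
  if (node_jitter_sd < 0) stop_parameter("node_jitter_sd must be >= 0")
  if (!is_count(false_positive_count))
    stop_parameter("false_positive_count must be a non-negative integer")
  if (overtrace_fraction < -1)
    stop_parameter("overtrace_fraction cannot truncate more than the root")
  structure(list(node_jitter_sd = node_jitter_sd,
                 drop_root_prob = drop_root_prob,
                 false_positive_count = as.integer(false_positive_count),
                 false_positive_length_mean = false_positive_length_mean,
                 false_positive_length_sd = false_positive_length_sd,
                 false_positive_center = as.numeric(false_positive_center),
                 false_positive_diameter = false_positive_diameter,
                 overtrace_fraction = overtrace_fraction,
                 spurious_branch_rate = spurious_branch_rate,
                 spurious_branch_length = spurious_branch_length,
                 seed = seed),
            class = "perturbation_params")
}

# truncate the tip so that `keep` cm of arc length remain (>= first segment)
truncate_polyline <- function(nodes, keep) {
  n <- nrow(nodes)
  seg <- nodes[-1L, , drop = FALSE] - nodes[-n, , drop = FALSE]
  lens <- sqrt(rowSums(seg^2))
  cum <- cumsum(lens)
  keep <- max(keep, lens[1L] * 0.5)   # never collapse below a usable stub
  i <- findInterval(keep, c(0, cum), rightmost.closed = TRUE)
  i <- min(i, n - 1L)
  t <- (keep - c(0, cum)[i]) / lens[i]
  tip <- nodes[i, ] + max(t, 1e-6) * seg[i, ]
  rbind(nodes[seq_len(i), , drop = FALSE], tip)
}

#' Apply a tracing-error perturbation model to a root system
#'
#' Artifacts are applied in a fixed, documented order so seeds reproduce:
#' (1) lateral dropping, (2) node jitter, (3) tip over-/under-tracing,
#' (4) spurious short branches, (5) free-floating false-positive roots.
#' All-zero parameters return the input unchanged (bit-exact). The output
#' is always a valid [root_system()]; an empty tracing is a legal result.
#'
#' @param rsa Ground-truth [root_system()].
#' @param params A [perturbation_params()].
#' @return A perturbed [root_system()] emulating a human tracing.
#' @export
perturb_tracing <- function(rsa, params = perturbation_params()) {
  validate_root_system(rsa)
  if (!inherits(params, "perturbation_params"))
    stop_parameter("params must be perturbation_params()")
  p <- params
  active <- p$node_jitter_sd > 0 || p$drop_root_prob > 0 ||
    p$false_positive_count > 0 || p$overtrace_fraction != 0 ||
    p$spurious_branch_rate > 0
  if (!active) return(rsa)

  with_seed(p$seed, {
    roots <- rsa$roots
    # (1) drop laterals
    if (p$drop_root_prob > 0) {
      keep <- vapply(roots, function(r)
        r$order == 0L || stats::runif(1L) >= p$drop_root_prob, logical(1))
      kept_ids <- vapply(roots[keep], function(r) r$root_id, character(1))
      roots <- lapply(roots[keep], function(r) {
        if (!is.null(r$parent_root_id) && !r$parent_root_id %in% kept_ids) {
          r$parent_root_id <- NULL; r$parent_attachment <- NULL; r$order <- 0L
        }
        r
      })
    }
    # (2) node jitter; the recorded attachment arc position is dropped, as a
    # human tracer attaches laterals visually (traits fall back to projection)
    if (p$node_jitter_sd > 0)
      roots <- lapply(roots, function(r) {
        r$nodes <- r$nodes + matrix(stats::rnorm(length(r$nodes), 0,
                                                 p$node_jitter_sd),
                                    nrow(r$nodes), 3L)
        r$parent_attachment <- NULL
        r
      })
    # (3) over-/under-trace the tip
    if (p$overtrace_fraction != 0)
      roots <- lapply(roots, function(r) {
        L <- root_length(r)
        if (p$overtrace_fraction > 0) {
          n <- nrow(r$nodes)
          dir <- normalize(r$nodes[n, ] - r$nodes[n - 1L, ])
          ext <- p$overtrace_fraction * L
          n_new <- max(1L, ceiling(ext / 0.25))
          step <- ext / n_new
          add <- r$nodes[n, ] + outer(seq_len(n_new) * step, dir)
          r$nodes <- rbind(r$nodes, add)
          r$diameters <- c(r$diameters, rep(r$diameters[n], n_new))
        } else {
          r$nodes <- truncate_polyline(r$nodes, (1 + p$overtrace_fraction) * L)
          r$diameters <- rep_len(r$diameters, nrow(r$nodes))
        }
        r
      })
    # (4) spurious short branches on existing roots
    if (p$spurious_branch_rate > 0) {
      extra <- list()
      for (r in roots) {
        k <- stats::rpois(1L, p$spurious_branch_rate)
        if (k > 0) for (b in seq_len(k)) {
          s <- stats::runif(1L, 0, root_length(r))
          at <- polyline_at(r$nodes, s)
          dir <- normalize(at$tangent + stats::rnorm(3L))
          nodes <- rbind(at$position,
                         grow_polyline(at$position, dir,
                                       p$spurious_branch_length, 0.25,
                                       0.2)[-1L, , drop = FALSE])
          extra[[length(extra) + 1L]] <- root(
            sprintf("spur_%s_%d", r$root_id, b), nodes,
            diameters = 0.05, order = r$order + 1L,
            parent_root_id = r$root_id, parent_attachment = s)
        }
      }
      roots <- c(roots, extra)
    }
    # (5) free-floating false positives inside the placement region
    if (p$false_positive_count > 0) {
      zmax <- max(vapply(rsa$roots, function(r) max(r$nodes[, 3L]), numeric(1)))
      for (i in seq_len(p$false_positive_count)) {
        ang <- stats::runif(1L, 0, 2 * pi)
        rad <- p$false_positive_diameter / 2 * sqrt(stats::runif(1L))
        start <- c(p$false_positive_center[1L] + rad * cos(ang),
                   p$false_positive_center[2L] + rad * sin(ang),
                   stats::runif(1L, 0, max(zmax, 1)))
        len <- max(0.3, stats::rnorm(1L, p$false_positive_length_mean,
                                     p$false_positive_length_sd))
        dir <- normalize(stats::rnorm(3L) + c(0, 0, 0.5))
        fp <- grow_polyline(start, dir, len, 0.25, 0.2)
        roots[[length(roots) + 1L]] <- root(sprintf("fp_%02d", i), fp,
                                            diameters = 0.08, order = 0L)
      }
    }
    root_system(roots, label = paste0(rsa$label, " (perturbed)"))
  })
}
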