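# Steady laminar flow through a channel network (Hagen-Poiseuille nodal
# analysis with an imposed dorsal-medial split), dimensionless screening
# numbers, and the secondary-flow-strength statistic.

# Poiseuille resistance of one segment row, Pa s / m^3
segment_resistance <- function(seg, mu) {
  if (seg$shape == "circular") {
    8 * mu * seg$length / (pi * seg$radius_or_halfgap^4)
  } else if (seg$shape == "slot") {
    gap <- 2 * seg$radius_or_halfgap
    12 * mu * seg$length / (seg$width * gap^3)
  } else {
    warn(sprintf(
      "Segment %s: shape '%s' approximated by its hydraulic diameter.",
      seg$id, seg$shape
    ))
    d_h <- 4 * seg$cross_area / seg$perimeter
    8 * mu * seg$length / (pi * (d_h / 2)^4)
  }
}

# map segment endpoints to junction nodes (union-find over edge contacts)
junction_nodes <- function(network) {
  ids <- network$segments$id
  n <- length(ids)
  # nodes 1..n tails, n+1..2n heads
  parent <- seq_len(2L * n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  idx <- setNames(seq_len(n), ids)
  for (k in seq_len(nrow(network$edges))) {
    a <- idx[[network$edges$from[k]]]
    b <- idx[[network$edges$to[k]]]
    union(n + a, b)  # head of `from` == tail of `to`
  }
  tail_node <- vapply(seq_len(n), function(i) find(i), integer(1))
  head_node <- vapply(seq_len(n), function(i) find(n + i), integer(1))
  relabel <- setNames(seq_along(unique(c(tail_node, head_node))),
                      unique(c(tail_node, head_node)))
  list(
    tail = relabel[as.character(tail_node)],
    head = relabel[as.character(head_node)],
    n_nodes = length(relabel)
  )
}

#' Solve steady laminar flow through a channel network
#'
#' Each segment is a Hagen-Poiseuille resistor (circular or parallel-plate
#' formula); junction pressures are solved by nodal analysis with the total
#' inspiratory flow injected at the inlet. If the network contains a segment
#' with role `"dm_feed"` and `dm_flow_fraction` is not `NULL`, that segment is
#' treated as a flow source carrying exactly `dm_flow_fraction * Q_total`
#' (the dorsal-medial split is imposed, not resistance-derived); splitting
#' among the parallel olfactory columns downstream remains
#' resistance-proportional.
#'
#' @param network A `channel_network` with single inlet and outlet.
#' @param Q_total Total volumetric flow rate, m^3/s.
#' @param dm_flow_fraction Imposed dorsal-medial flow fraction in (0, 1),
#'   `NULL` for a purely resistive solve, or `"auto"` (default) to use the
#'   network's own metadata value when a `dm_feed` segment exists.
#' @param air An [air_properties()] list.
#' @return A `network_flow` object: per-segment tibble (`id`, `flow`,
#'   `velocity`, `resistance`, `pressure_drop`) with attributes `Q_total` and
#'   `dp_total`.
#' @export
#' @examples
#' nose <- build_nose(nose_spec("mouse"))
#' flow <- solve_flow(nose, Q_total = 25 / 60 * 1e-6)  # 25 mL/min
#' glance(flow)
solve_flow <- function(network, Q_total, dm_flow_fraction = "auto",
                       air = air_properties()) {
  check_positive(Q_total = Q_total)
  if (length(network$inlet_ids) != 1L || length(network$outlet_ids) != 1L) {
    abort("solve_flow requires a single inlet and a single outlet.",
          class = "olfnet_topology_error")
  }
  segs <- network$segments
  n <- nrow(segs)
  mu <- air$dynamic_viscosity
  R <- vapply(seq_len(n), function(i) segment_resistance(segs[i, ], mu),
              numeric(1))
  g <- 1 / R
  nodes <- junction_nodes(network)
  inlet_node <- nodes$tail[match(network$inlet_ids, segs$id)]
  outlet_node <- nodes$head[match(network$outlet_ids, segs$id)]

  if (identical(dm_flow_fraction, "auto")) {
    dm_flow_fraction <-
      if ("dm_feed" %in% segs$role) network$meta$dm_flow_fraction %||% 0.1
      else NULL
  }
  dm_idx <- integer(0)
  q_dm <- 0
  if (!is.null(dm_flow_fraction)) {
    if (dm_flow_fraction <= 0 || dm_flow_fraction >= 1) {
      abort("dm_flow_fraction must lie strictly between 0 and 1.",
            class = "olfnet_domain_error")
    }
    dm_idx <- which(segs$role == "dm_feed")
    if (length(dm_idx) > 1L) {
      abort("More than one dm_feed segment.", class = "olfnet_topology_error")
    }
    if (length(dm_idx) == 1L) q_dm <- dm_flow_fraction * Q_total
  }

  nn <- nodes$n_nodes
  L <- matrix(0, nn, nn)
  b <- numeric(nn)
  for (i in seq_len(n)) {
    if (i %in% dm_idx) next  # flow source, no conductance stamp
    t <- nodes$tail[i]; h <- nodes$head[i]
    L[t, t] <- L[t, t] + g[i]
    L[h, h] <- L[h, h] + g[i]
    L[t, h] <- L[t, h] - g[i]
    L[h, t] <- L[h, t] - g[i]
  }
  b[inlet_node] <- b[inlet_node] + Q_total
  if (length(dm_idx) == 1L) {
    t <- nodes$tail[dm_idx]; h <- nodes$head[dm_idx]
    b[t] <- b[t] - q_dm
    b[h] <- b[h] + q_dm
  }
  keep <- setdiff(seq_len(nn), outlet_node)
  P <- numeric(nn)
  sol <- tryCatch(solve(L[keep, keep, drop = FALSE], b[keep]),
                  error = function(e) e)
  if (inherits(sol, "error")) {
    abort("Network is disconnected (singular conductance system).",
          class = "olfnet_topology_error")
  }
  P[keep] <- sol

  q <- g * (P[nodes$tail] - P[nodes$head])
  if (length(dm_idx) == 1L) q[dm_idx] <- q_dm
  dp <- q * R
  out <- tibble(
    id = segs$id, flow = q, velocity = q / segs$cross_area,
    resistance = R, pressure_drop = dp
  )
  structure(
    list(table = out, Q_total = Q_total,
         dp_total = P[inlet_node] - P[outlet_node],
         dm_flow_fraction = if (length(dm_idx) == 1L) dm_flow_fraction else NA_real_,
         air = air),
    class = "network_flow"
  )
}

#' @export
print.network_flow <- function(x, ...) {
  cat(sprintf(
    "<network_flow> Q = %.4g mL/min over %d segments, dp = %.4g Pa\n",
    x$Q_total * 6e7, nrow(x$table), x$dp_total
  ))
  invisible(x)
}

#' @rdname tidiers
#' @method tidy network_flow
#' @export
tidy.network_flow <- function(x, ...) x$table

#' @rdname tidiers
#' @method glance network_flow
#' @export
glance.network_flow <- function(x, ...) {
  tibble(Q_total = x$Q_total, dp_total = x$dp_total,
         n_segments = nrow(x$table),
         dm_flow_fraction = x$dm_flow_fraction)
}

# per-segment flow lookup
segment_flow <- function(flow, id) {
  i <- match(id, flow$table$id)
  if (is.na(i)) abort(sprintf("No flow entry for segment '%s'.", id))
  flow$table[i, ]
}

#' Dimensionless screening numbers for one segment
#'
#' Reynolds `Re = U d_h / nu`, Womersley `W0 = (d_h/2) sqrt(2 pi f / nu)` and
#' Strouhal `S = f L_stroke / U`, with the quasi-steady assumption flagged
#' valid when `W0 < 4` and `S < 1` (strict), and the laminar assumption when
#' `Re < 2300` (strict).
#'
#' @param network A `channel_network`.
#' @param flow A `network_flow` for that network.
#' @param segment_id Segment to evaluate (default: the inlet).
#' @param breathing_frequency Breathing frequency, Hz (>= 0).
#' @param stroke_length Characteristic stroke length, m; defaults to the
#'   segment length.
#' @param air An [air_properties()] list.
#' @return One-row tibble: `segment`, `Re`, `W0`, `S`, `quasi_steady`,
#'   `laminar`, `S_defined`.
#' @export
dimensionless_numbers <- function(network, flow, segment_id = NULL,
                                  breathing_frequency = 0,
                                  stroke_length = NULL,
                                  air = air_properties()) {
  if (breathing_frequency < 0) abort_domain("breathing_frequency")
  segment_id <- segment_id %||% network$inlet_ids[1]
  seg <- network$segments[network$segments$id == segment_id, ]
  if (nrow(seg) != 1L) abort(sprintf("Unknown segment '%s'.", segment_id))
  U <- abs(segment_flow(flow, segment_id)$velocity)
  nu <- air$kinematic_viscosity
  d_h <- 4 * seg$cross_area / seg$perimeter
  Re <- U * d_h / nu
  W0 <- (d_h / 2) * sqrt(2 * pi * breathing_frequency / nu)
  Ls <- stroke_length %||% seg$length
  S_defined <- !(U == 0 && breathing_frequency > 0)
  S <- if (breathing_frequency == 0) 0
       else if (U > 0) breathing_frequency * Ls / U
       else NA_real_
  tibble(
    segment = segment_id, Re = Re, W0 = W0, S = S,
    quasi_steady = isTRUE(W0 < 4 && !is.na(S) && S < 1),
    laminar = Re < 2300,
    S_defined = S_defined
  )
}

# Gridded velocity fields and secondary-flow strength ------------------------

#' Construct a gridded velocity field
#'
#' `u` is the axial component (z, nostrils to nasopharynx); `v` and `w` are
#' the in-plane components (x and y). All three arrays share dimensions.
#'
#' @param u,v,w Numeric 3-d arrays, m/s.
#' @param spacing Grid spacing, length-3, m.
#' @param origin Grid origin, length-3, m.
#' @return An object of class `grid_velocity_field`.
#' @export
grid_velocity_field <- function(u, v, w, spacing, origin = c(0, 0, 0)) {
  stopifnot(identical(dim(u), dim(v)), identical(dim(u), dim(w)),
            length(dim(u)) == 3L)
  spacing <- rep_len(as.numeric(spacing), 3L)
  check_positive(spacing = spacing)
  structure(list(u = u, v = v, w = w, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "grid_velocity_field")
}

#' Secondary-flow strength of a velocity field
#'
#' Pointwise `SS = sqrt(v^2 + w^2) / sqrt(u^2 + v^2 + w^2)`, the ratio of
#' in-plane (secondary) speed to total speed, in `[0, 1]`. Zero-velocity
#' points are excluded from the regional mean and counted.
#'
#' @param field A [grid_velocity_field()].
#' @param region_mask Optional logical array matching the grid.
#' @return List with the `ss` array, the regional `mean`, `n_zero_excluded`
#'   and `n_total`; class `secondary_strength`.
#' @export
#' @examples
#' f <- synthetic_swirl_field(c(17, 17, 3), axial_speed = 1, swirl_ratio = 0.5)
#' secondary_strength(f)$mean
secondary_strength <- function(field, region_mask = NULL) {
  stopifnot(inherits(field, "grid_velocity_field"))
  tot2 <- field$u^2 + field$v^2 + field$w^2
  sec2 <- field$v^2 + field$w^2
  ss <- array(NA_real_, dim = dim(tot2))
  nz <- tot2 > 0
  ss[nz] <- sqrt(sec2[nz] / tot2[nz])
  mask <- region_mask %||% array(TRUE, dim = dim(tot2))
  stopifnot(identical(dim(mask), dim(tot2)))
  in_region <- which(mask)
  usable <- in_region[nz[in_region]]
  n_zero <- length(in_region) - length(usable)
  m <- if (length(usable) == 0) {
    warn("All points in the region have zero velocity; SS mean is undefined.")
    NA_real_
  } else {
    mean(ss[usable])
  }
  structure(
    list(ss = ss, mean = m, n_zero_excluded = n_zero,
         n_total = length(in_region)),
    class = "secondary_strength"
  )
}

#' Synthetic swirl field for exercising the secondary-flow statistic
#'
#' Uniform axial flow with a superposed solid-body in-plane rotation. The
#' rotation rate is set so that at `reference_radius` the in-plane speed is
#' `swirl_ratio * axial_speed`; there the secondary-flow strength equals
#' `swirl_ratio / sqrt(1 + swirl_ratio^2)`.
#'
#' @param n Grid dimensions `c(nx, ny, nz)`.
#' @param radius Half-extent of the grid in x and y, m.
#' @param axial_length Extent in z, m.
#' @param axial_speed Axial speed, m/s.
#' @param swirl_ratio In-plane to axial speed ratio at the reference radius
#'   (>= 0).
#' @param reference_radius Radius where the ratio is imposed; defaults to
#'   `radius`.
#' @return A [grid_velocity_field()].
#' @export
synthetic_swirl_field <- function(n = c(33, 33, 5), radius = 1e-3,
                                  axial_length = 1e-3, axial_speed = 1,
                                  swirl_ratio = 0.5,
                                  reference_radius = radius) {
  if (swirl_ratio < 0) abort_domain("swirl_ratio")
  check_positive(radius = radius, axial_length = axial_length,
                 reference_radius = reference_radius)
  n <- rep_len(as.integer(n), 3L)
  x <- seq(-radius, radius, length.out = n[1])
  y <- seq(-radius, radius, length.out = n[2])
  omega <- swirl_ratio * axial_speed / reference_radius
  u <- array(axial_speed, dim = n)
  v <- array(rep(-omega * y, each = n[1]), dim = n)     # v = -omega * y
  w <- array(rep(omega * x, times = n[2] * n[3]), dim = n)  # w = +omega * x
  spacing <- c(
    if (n[1] > 1) diff(x)[1] else radius,
    if (n[2] > 1) diff(y)[1] else radius,
    if (n[3] > 1) axial_length / (n[3] - 1) else axial_length
  )
  grid_velocity_field(u, v, w, spacing = spacing,
                      origin = c(-radius, -radius, 0))
}
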