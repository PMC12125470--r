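# Advection-diffusion odorant uptake in channels with the air-mucus Robin wall
# condition D_a dC/dn = -k_w C, k_w = D_m / (beta d), and its propagation over
# a channel network.

#' Well-mixed uptake limit
#'
#' Closed-form absorbed fraction `1 - exp(-k_w P L / Q)` valid when transverse
#' diffusion is much faster than wall uptake (small wall Damkohler number
#' `k_w r / D_a`).
#'
#' @param k_w Wall mass-transfer coefficient `D_m / (beta d)`, m/s.
#' @param perimeter Absorbing perimeter, m.
#' @param length Channel length, m.
#' @param Q Volumetric flow through the channel, m^3/s.
#' @return Absorbed fraction in `[0, 1]`.
#' @export
#' @examples
#' wellmixed_absorbed_fraction(1e-2, 1e-3, 5e-3, 4.17e-8)  # ~0.70
wellmixed_absorbed_fraction <- function(k_w, perimeter, length, Q) {
  check_positive(perimeter = perimeter, length = length, Q = Q)
  if (k_w < 0) abort_domain("k_w")
  1 - exp(-k_w * perimeter * length / Q)
}

# finite-difference operator + marching matrices for one channel
uptake_march_setup <- function(shape, half_extent, U, D, k_w, n_transverse) {
  M <- n_transverse
  h <- half_extent / M
  x <- seq(0, half_extent, length.out = M + 1L)  # r (circular) or y (slot)
  u <- if (shape == "circular") 2 * U * (1 - (x / half_extent)^2)
       else 1.5 * U * (1 - (x / half_extent)^2)
  lap <- matrix(0, M + 1L, M + 1L)
  if (shape == "circular") {
    lap[1, 1] <- -4 / h^2
    lap[1, 2] <- 4 / h^2
  } else {
    lap[1, 1] <- -2 / h^2
    lap[1, 2] <- 2 / h^2
  }
  for (j in 2:M) {
    r <- x[j]
    lap[j, j - 1] <- 1 / h^2 - if (shape == "circular") 1 / (2 * r * h) else 0
    lap[j, j] <- -2 / h^2
    lap[j, j + 1] <- 1 / h^2 + if (shape == "circular") 1 / (2 * r * h) else 0
  }
  # mixed-mean quadrature weights (flux-weighted trapezoid)
  wt <- rep(h, M + 1L)
  wt[c(1, M + 1L)] <- h / 2
  if (shape == "circular") wt <- wt * x
  wt <- wt * u
  list(x = x, u = u, lap = lap, wt = wt, h = h, M = M)
}

#' Solve odorant uptake in one channel segment
#'
#' Steady 2-d advection-diffusion (Graetz problem) with a fully developed
#' laminar profile, axial diffusion neglected, marched axially with an
#' implicit scheme. The wall carries the dimensional form of the air-mucus
#' interface condition, `D_a dC/dn = -k_w C` with `k_w = D_m / (beta d)`;
#' circular segments are solved axisymmetrically, slots in planar symmetry.
#' Concentrations are normalized to a uniform inlet value of 1.
#'
#' @param segment One segment row (from a `channel_network` or
#'   [channel_segment()]).
#' @param mean_velocity Mean axial velocity in the segment, m/s.
#' @param odorant An [odorant()].
#' @param mucosa A [mucosa_spec()].
#' @param n_axial,n_transverse Grid resolution (>= 4 each).
#' @return An `uptake_solution`: absorbed fraction, outlet mixed-mean
#'   concentration, per-station wall flux profile (`z`, `flux_per_area`
#'   normalized by the entering flux, `c_mixed`), and the reported
#'   dimensionless K of the wall condition (using the segment hydraulic
#'   diameter).
#' @export
#' @examples
#' seg <- channel_segment("c", 5e-3, "circular", 1.5e-4,
#'                        epithelium = "olfactory")
#' od <- odorant("demo", 130, 140, D_a = 6e-6, D_m = 1e-9, beta = 1e-3)
#' solve_channel_uptake(seg[1, ], 0.1, od, mucosa_spec())$absorbed_fraction
solve_channel_uptake <- function(segment, mean_velocity, odorant, mucosa,
                                 n_axial = 200, n_transverse = 64) {
  if (n_axial < 4 || n_transverse < 4) {
    abort("Resolution must be at least 4 points per dimension.",
          class = "olfnet_domain_error")
  }
  seg <- segment[1, ]
  check_positive(mean_velocity = mean_velocity)
  D <- odorant$D_a
  k_w <- wall_permeability(odorant, mucosa)
  L <- seg$length
  a <- seg$radius_or_halfgap
  dz <- L / n_axial
  z <- seq(dz, L, length.out = n_axial)

  if (k_w == 0) {
    prof <- tibble(z = z, flux_per_area = 0, c_mixed = 1)
    return(structure(
      list(segment_id = seg$id, absorbed_fraction = 0, c_out = 1,
           wall_flux = prof, k_w = 0, K = 0,
           n_axial = n_axial, n_transverse = n_transverse),
      class = "uptake_solution"
    ))
  }

  st <- uptake_march_setup(seg$shape, a, mean_velocity, D, k_w, n_transverse)
  M <- st$M
  A <- diag(st$u) - dz * D * st$lap
  # second-order one-sided Robin row at the wall: D dc/dn = -k_w c
  A[M + 1L, ] <- 0
  A[M + 1L, M - 1L] <- D / (2 * st$h)
  A[M + 1L, M] <- -4 * D / (2 * st$h)
  A[M + 1L, M + 1L] <- 3 * D / (2 * st$h) + k_w
  Ainv <- tryCatch(solve(A), error = function(e) {
    abort(sprintf(
      "Uptake marching matrix is singular (segment %s, k_w = %.3g).",
      seg$id, k_w
    ), class = "olfnet_numerical_error")
  })

  c_prof <- rep(1, M + 1L)
  wt_sum <- sum(st$wt)
  c_mixed <- numeric(n_axial)
  cm_prev <- 1
  rhs <- st$u  # u * c with c = 1; wall entry u = 0 handles the Robin rhs
  for (k in seq_len(n_axial)) {
    c_prof <- Ainv %*% rhs
    rhs <- st$u * c_prof[, 1]
    c_mixed[k] <- sum(st$wt * c_prof[, 1]) / wt_sum
  }
  if (any(!is.finite(c_mixed)) || any(c_mixed < -1e-9) ||
      any(diff(c(1, c_mixed)) > 1e-9)) {
    abort(sprintf(
      paste0("Uptake march failed on segment %s: non-finite or increasing ",
             "mixed-mean concentration (k_w = %.3g, n = %d x %d)."),
      seg$id, k_w, n_axial, n_transverse
    ), class = "olfnet_numerical_error")
  }
  Q <- mean_velocity * seg$cross_area
  d_step <- -diff(c(1, c_mixed))          # absorbed fraction per station
  flux_per_area <- Q * d_step / (seg$perimeter * dz)
  absorbed <- 1 - c_mixed[n_axial]
  d_h <- 4 * seg$cross_area / seg$perimeter
  structure(
    list(segment_id = seg$id, absorbed_fraction = absorbed,
         c_out = c_mixed[n_axial],
         wall_flux = tibble(z = z, flux_per_area = flux_per_area,
                            c_mixed = c_mixed),
         k_w = k_w, K = wall_uptake_parameter(d_h, odorant, mucosa),
         n_axial = n_axial, n_transverse = n_transverse),
    class = "uptake_solution"
  )
}

#' @export
print.uptake_solution <- function(x, ...) {
  cat(sprintf(
    "<uptake_solution> segment %s: absorbed %.4g, outlet c' %.4g (K = %.3g)\n",
    x$segment_id, x$absorbed_fraction, x$c_out, x$K
  ))
  invisible(x)
}

#' Propagate odorant uptake over a whole network
#'
#' Segments are processed in topological order; junctions mix mixed-mean
#' concentrations flux-weighted (perfect mixing) and splits inherit the mixed
#' concentration. The result partitions the entering odorant flux into
#' per-epithelium-class absorbed fractions and an escaped fraction.
#'
#' @param network A `channel_network`.
#' @param flow The corresponding `network_flow`.
#' @param odorant An [odorant()].
#' @param mucosa A [mucosa_spec()].
#' @param n_axial,n_transverse Channel-solver resolution.
#' @param keep_solutions Keep per-segment `uptake_solution`s (needed by
#'   [absorption_map()]).
#' @return A `deposition_summary`: per-segment tibble, per-class absorbed
#'   fractions, total and escaped fractions.
#' @export
#' @examples
#' nose <- build_nose(nose_spec("mouse"))
#' flow <- solve_flow(nose, 25 / 60 * 1e-6)
#' od <- odorant("isoamyl acetate", 130.19, 148.9, beta = 1e-3)
#' glance(propagate_network_uptake(nose, flow, od, mucosa_spec()))
propagate_network_uptake <- function(network, flow, odorant, mucosa,
                                     n_axial = 200, n_transverse = 64,
                                     keep_solutions = FALSE) {
  segs <- network$segments
  order <- topological_order(segs, network$edges)
  nodes <- junction_nodes(network)
  idx <- setNames(seq_len(nrow(segs)), segs$id)
  inlet_node <- nodes$tail[idx[network$inlet_ids]]

  flux_sum <- numeric(nodes$n_nodes)
  q_sum <- numeric(nodes$n_nodes)
  Q_total <- flow$Q_total
  flux_sum[inlet_node] <- Q_total   # unit inlet concentration
  q_sum[inlet_node] <- Q_total

  rows <- vector("list", length(order))
  sols <- list()
  for (k in seq_along(order)) {
    i <- idx[[order[k]]]
    seg <- segs[i, ]
    q <- segment_flow(flow, seg$id)$flow
    t_node <- nodes$tail[i]; h_node <- nodes$head[i]
    c_in <- if (q_sum[t_node] > 0) flux_sum[t_node] / q_sum[t_node] else 0
    if (q > 0 && seg$epithelium != "nonabsorbing" && c_in > 0) {
      sol <- solve_channel_uptake(seg, q / seg$cross_area, odorant, mucosa,
                                  n_axial, n_transverse)
      a_seg <- sol$absorbed_fraction
    } else {
      sol <- NULL
      a_seg <- 0
    }
    if (keep_solutions && !is.null(sol)) sols[[seg$id]] <- sol
    c_out <- c_in * (1 - a_seg)
    flux_sum[h_node] <- flux_sum[h_node] + q * c_out
    q_sum[h_node] <- q_sum[h_node] + q
    rows[[k]] <- tibble(
      id = seg$id, epithelium = seg$epithelium, flow = q,
      c_in = c_in, c_out = c_out, absorbed_fraction_local = a_seg,
      absorbed_flux = q * c_in * a_seg / Q_total
    )
  }
  per_segment <- list_rbind(rows)
  outlet_node <- nodes$head[idx[network$outlet_ids]]
  escaped <- sum(flux_sum[outlet_node]) / Q_total
  by_class <- c(respiratory = 0, olfactory = 0, nonabsorbing = 0)
  agg <- tapply(per_segment$absorbed_flux, per_segment$epithelium, sum)
  by_class[names(agg)] <- agg
  structure(
    list(per_segment = per_segment,
         respiratory = unname(by_class["respiratory"]),
         olfactory = unname(by_class["olfactory"]),
         nonabsorbing = unname(by_class["nonabsorbing"]),
         total_absorbed = sum(per_segment$absorbed_flux),
         escaped = escaped,
         odorant = odorant$name, beta = odorant$beta,
         solutions = if (keep_solutions) sols else NULL),
    class = "deposition_summary"
  )
}

#' @export
print.deposition_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<deposition_summary> %s (beta = %.3g): total %.4g ",
           "(respiratory %.4g, olfactory %.4g), escaped %.4g\n"),
    x$odorant, x$beta, x$total_absorbed, x$respiratory, x$olfactory,
    x$escaped
  ))
  invisible(x)
}

#' @rdname tidiers
#' @method tidy deposition_summary
#' @export
tidy.deposition_summary <- function(x, ...) x$per_segment

#' @rdname tidiers
#' @method glance deposition_summary
#' @export
glance.deposition_summary <- function(x, ...) {
  tibble(odorant = x$odorant, beta = x$beta,
         respiratory = x$respiratory, olfactory = x$olfactory,
         total_absorbed = x$total_absorbed, escaped = x$escaped)
}

#' Sweep deposition over odorant solubility
#'
#' Runs [propagate_network_uptake()] over a grid of air-mucus partition
#' coefficients, holding the diffusivities of a template odorant fixed.
#' Anterior scrubbing of highly soluble odorants combined with the
#' per-channel monotone uptake produces a single-peaked ("Gaussian-like")
#' olfactory deposition curve in log(beta).
#'
#' @param network A `channel_network`.
#' @param flow The corresponding `network_flow`.
#' @param mucosa A [mucosa_spec()].
#' @param beta_grid Sorted positive vector of partition coefficients.
#' @param odorant_template Odorant supplying diffusivities; the default is an
#'   isoamyl-acetate-like compound.
#' @param n_axial,n_transverse Channel-solver resolution.
#' @return Tibble (`beta`, `total_fraction`, `olfactory_fraction`,
#'   `respiratory_fraction`), class `solubility_sweep`.
#' @export
solubility_sweep <- function(network, flow, mucosa,
                             beta_grid = 10^seq(-10, 0, length.out = 21),
                             odorant_template = NULL,
                             n_axial = 200, n_transverse = 64) {
  if (any(beta_grid <= 0) || is.unsorted(beta_grid)) {
    abort("beta_grid must be sorted and strictly positive.",
          class = "olfnet_domain_error")
  }
  template <- odorant_template %||%
    odorant("sweep template", 130.19, 148.9, beta = 1e-3, mucosa = mucosa)
  rows <- map(beta_grid, function(b) {
    od <- odorant(template$name, template$molar_mass, template$molar_volume,
                  D_a = template$D_a, D_m = template$D_m, beta = b)
    s <- propagate_network_uptake(network, flow, od, mucosa,
                                  n_axial, n_transverse)
    tibble(beta = b, total_fraction = s$total_absorbed,
           olfactory_fraction = s$olfactory,
           respiratory_fraction = s$respiratory)
  })
  out <- list_rbind(rows)
  class(out) <- c("solubility_sweep", class(out))
  out
}

#' Wall absorption map along the airway
#'
#' Bins the absorbed wall flux (normalized by the flux entering the nose) per
#' unit wall area by distance from the naris tip. The area-weighted integral
#' of the map equals the total absorbed fraction.
#'
#' @inheritParams propagate_network_uptake
#' @param n_bins Number of distance bins.
#' @return Tibble (`bin`, `z_mid`, `absorbed`, `wall_area`, `flux_per_area`),
#'   class `absorption_map`, with the deposition summary attached as attribute
#'   `"summary"`.
#' @export
absorption_map <- function(network, flow, odorant, mucosa, n_bins = 30,
                           n_axial = 200, n_transverse = 64) {
  summary <- propagate_network_uptake(network, flow, odorant, mucosa,
                                      n_axial, n_transverse,
                                      keep_solutions = TRUE)
  segs <- network$segments
  z_max <- max(segs$axial_start + segs$length)
  breaks <- seq(0, z_max, length.out = n_bins + 1L)
  absorbed <- numeric(n_bins)
  area <- numeric(n_bins)
  Q_total <- flow$Q_total
  for (i in seq_len(nrow(segs))) {
    seg <- segs[i, ]
    z0 <- seg$axial_start; z1 <- z0 + seg$length
    # wall area spread uniformly
    lo <- pmin(pmax(breaks[-length(breaks)], z0), z1)
    hi <- pmin(pmax(breaks[-1], z0), z1)
    area <- area + seg$perimeter * seg$length * (hi - lo) / (z1 - z0)
    sol <- summary$solutions[[seg$id]]
    if (is.null(sol)) next
    c_in <- summary$per_segment$c_in[summary$per_segment$id == seg$id]
    q <- summary$per_segment$flow[summary$per_segment$id == seg$id]
    dz <- seg$length / sol$n_axial
    d_step <- c_in * (-diff(c(1, sol$wall_flux$c_mixed))) * q / Q_total
    z_station <- z0 + sol$wall_flux$z - dz / 2
    bin_idx <- pmin(pmax(findInterval(z_station, breaks,
                                      rightmost.closed = TRUE), 1L), n_bins)
    acc <- tapply(d_step, bin_idx, sum)
    absorbed[as.integer(names(acc))] <-
      absorbed[as.integer(names(acc))] + acc
  }
  out <- tibble(
    bin = seq_len(n_bins),
    z_mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
    absorbed = absorbed, wall_area = area,
    flux_per_area = ifelse(area > 0, absorbed / area, 0)
  )
  attr(out, "summary") <- summary
  class(out) <- c("absorption_map", class(out))
  out
}
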