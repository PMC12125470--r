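# Golay plate-height analysis of olfactory architectures: each parallel
# olfactory channel is treated as an open-tubular gas-chromatograph column
# whose stationary phase is the mucus film.

#' Specify a GC column
#'
#' @param Lc Column length: the average distance an odorant travels from the
#'   olfactory inlet to the olfactory outlet, m.
#' @param r Channel radius (circular) or half-gap, m.
#' @param d_f Stationary-film (mucus) thickness, m; must be `< r`.
#' @param D_gas Mobile-phase (air) diffusivity, m^2/s.
#' @param D_stationary Stationary-phase (mucus) diffusivity, m^2/s.
#' @param k_ret Retention factor, dimensionless.
#' @return An object of class `gc_column_spec`.
#' @export
#' @examples
#' gc_column_spec(7e-3, 1.5e-4, 1e-5, 6e-6, 1e-9, k_ret = 20)
gc_column_spec <- function(Lc, r, d_f, D_gas, D_stationary, k_ret) {
  check_positive(Lc = Lc, r = r, d_f = d_f, D_gas = D_gas,
                 D_stationary = D_stationary)
  if (!is.numeric(k_ret) || length(k_ret) != 1L || !is.finite(k_ret) ||
      k_ret < 0) {
    abort_domain("k_ret", "`k_ret` must be a finite non-negative number.")
  }
  if (d_f >= r) {
    abort("Film thickness d_f must be smaller than the channel radius.",
          class = "olfnet_geometry_error")
  }
  structure(list(Lc = Lc, r = r, d_f = d_f, D_gas = D_gas,
                 D_stationary = D_stationary, k_ret = k_ret),
            class = "gc_column_spec")
}

#' Retention factor from partitioning and thin-film geometry
#'
#' `k = (V_stationary / V_mobile) / beta`; for a thin annular film in a
#' circular channel `k = 2 d_f / (beta r)`, for a slot `k = d_f / (beta a)`.
#' Small `beta` (soluble odorant) means strong retention.
#'
#' @param odorant An [odorant()] (only `beta` is used) or a single numeric
#'   partition coefficient.
#' @param r Channel radius or half-gap, m.
#' @param d_f Film thickness, m (`d_f < r`).
#' @param shape `"circular"` or `"slot"`.
#' @return Retention factor (dimensionless).
#' @export
#' @examples
#' retention_factor(0.01, r = 1e-4, d_f = 1e-5)  # 20
retention_factor <- function(odorant, r, d_f, shape = c("circular", "slot")) {
  shape <- match.arg(shape)
  beta <- if (inherits(odorant, "odorant")) odorant$beta else odorant
  check_positive(beta = beta, r = r, d_f = d_f)
  if (d_f >= r) {
    abort("Film thickness d_f must be smaller than the channel radius.",
          class = "olfnet_geometry_error")
  }
  ratio <- if (shape == "circular") 2 * d_f / r else d_f / r
  ratio / beta
}

# Golay B and C coefficients; H(u) = B/u + C u
golay_coefficients <- function(column, include_film = TRUE) {
  k <- column$k_ret
  f_g <- (1 + 6 * k + 11 * k^2) / (24 * (1 + k)^2)
  f_s <- 2 * k / (3 * (1 + k)^2)
  B <- 2 * column$D_gas
  C <- f_g * column$r^2 / column$D_gas +
    if (include_film) f_s * column$d_f^2 / column$D_stationary else 0
  list(B = B, C = C, f_g = f_g, f_s = f_s)
}

#' Golay plate height
#'
#' Open-tubular plate height `H(u) = 2 D_g / u + f_g(k) r^2 u / D_g +
#' f_s(k) d_f^2 u / D_s` with `f_g(k) = (1 + 6k + 11k^2) / (24 (1+k)^2)` and
#' `f_s(k) = 2k / (3 (1+k)^2)` (mobile- plus stationary-phase mass-transfer
#' terms).
#'
#' @param u Carrier (air) velocity, m/s; vectorized, strictly positive.
#' @param column A [gc_column_spec()].
#' @param include_film Include the stationary-film term?
#' @return Plate height H, m.
#' @export
#' @examples
#' col <- gc_column_spec(5e-3, 1.5e-4, 1e-9, 6e-6, 1e-9, k_ret = 1e-9)
#' golay_plate_height(0.277, col)  # near H_min = r / sqrt(3)
golay_plate_height <- function(u, column, include_film = TRUE) {
  if (any(u <= 0)) abort_domain("u")
  co <- golay_coefficients(column, include_film)
  co$B / u + co$C * u
}

#' Theoretical-plate-number curve
#'
#' `N(u) = Lc / H(u)`. The optimum is located in closed form:
#' `u_opt = sqrt(B / C)`, `H_min = 2 sqrt(B C)`, `N_peak = Lc / H_min`.
#'
#' @param column A [gc_column_spec()].
#' @param u_grid Sorted positive velocity grid, m/s.
#' @param include_film Include the stationary-film term?
#' @return Tibble (`u`, `H`, `N`) of class `plate_curve` with attributes
#'   `u_opt`, `H_min`, `N_peak`, `B`, `C` and `column`.
#' @export
plate_number_curve <- function(column,
                               u_grid = 10^seq(-3, 1, length.out = 121),
                               include_film = TRUE) {
  if (any(u_grid <= 0) || is.unsorted(u_grid)) {
    abort("u_grid must be sorted and strictly positive.",
          class = "olfnet_domain_error")
  }
  co <- golay_coefficients(column, include_film)
  H <- co$B / u_grid + co$C * u_grid
  out <- tibble(u = u_grid, H = H, N = column$Lc / H)
  attr(out, "u_opt") <- sqrt(co$B / co$C)
  attr(out, "H_min") <- 2 * sqrt(co$B * co$C)
  attr(out, "N_peak") <- column$Lc / (2 * sqrt(co$B * co$C))
  attr(out, "B") <- co$B
  attr(out, "C") <- co$C
  attr(out, "column") <- column
  class(out) <- c("plate_curve", class(out))
  out
}

#' @rdname tidiers
#' @method glance plate_curve
#' @export
glance.plate_curve <- function(x, ...) {
  tibble(u_opt = attr(x, "u_opt"), H_min = attr(x, "H_min"),
         N_peak = attr(x, "N_peak"), B = attr(x, "B"), C = attr(x, "C"))
}

#' Velocity band sustaining a fraction of the peak plate number
#'
#' Solves `N(u) >= fraction * N_peak`, i.e. `C u^2 - (H_min / fraction) u + B
#' <= 0`, in closed form. The endpoints satisfy `u_lo * u_hi = B / C =
#' u_opt^2`. The log-width `log(u_hi / u_lo)` measures robustness of the
#' column to velocity variation.
#'
#' @param curve A `plate_curve` (or [gc_column_spec()]).
#' @param fraction Fraction of the peak, in (0, 1).
#' @param include_film Used when `curve` is a column spec.
#' @return One-row tibble: `fraction`, `u_lo`, `u_hi`, `log_width`,
#'   `abs_width`, `u_opt`, `empty`.
#' @export
velocity_robustness <- function(curve, fraction = 0.8, include_film = TRUE) {
  co <- if (inherits(curve, "plate_curve")) {
    list(B = attr(curve, "B"), C = attr(curve, "C"))
  } else {
    golay_coefficients(curve, include_film)
  }
  if (fraction <= 0) abort_domain("fraction")
  if (fraction >= 1) {
    if (fraction > 1) {
      warn("fraction > 1: no velocity sustains more than the peak.")
      return(tibble(fraction = fraction, u_lo = NA_real_, u_hi = NA_real_,
                    log_width = NA_real_, abs_width = NA_real_,
                    u_opt = sqrt(co$B / co$C), empty = TRUE))
    }
    u_opt <- sqrt(co$B / co$C)
    return(tibble(fraction = 1, u_lo = u_opt, u_hi = u_opt, log_width = 0,
                  abs_width = 0, u_opt = u_opt, empty = FALSE))
  }
  H_max <- 2 * sqrt(co$B * co$C) / fraction
  disc <- sqrt(H_max^2 - 4 * co$B * co$C)
  u_lo <- (H_max - disc) / (2 * co$C)
  u_hi <- (H_max + disc) / (2 * co$C)
  tibble(fraction = fraction, u_lo = u_lo, u_hi = u_hi,
         log_width = log(u_hi / u_lo), abs_width = u_hi - u_lo,
         u_opt = sqrt(co$B / co$C), empty = FALSE)
}

# Derive an equivalent GC column and operating velocity from the olfactory
# region of a network + flow solution.
olfactory_column_spec <- function(network, flow, odorant, mucosa) {
  col_ids <- unlist(network$column_groups, use.names = FALSE)
  if (length(col_ids) == 0) {
    abort("Network has no olfactory column groups.",
          class = "olfnet_topology_error")
  }
  segs <- network$segments[match(col_ids, network$segments$id), ]
  if (any(segs$shape != "circular")) {
    warn("Non-circular olfactory segments mapped to equivalent radius via hydraulic diameter.")
  }
  r_eq <- ifelse(segs$shape == "circular", segs$radius_or_halfgap,
                 2 * segs$cross_area / segs$perimeter)
  ft <- flow$table[match(col_ids, flow$table$id), ]
  w <- ft$flow / sum(ft$flow)
  chain_lengths <- map_dbl(network$column_groups, function(ids) {
    sum(segs$length[segs$id %in% ids])
  })
  Lc <- mean(chain_lengths)
  r <- sum(w * r_eq)
  u_op <- sum(w * ft$velocity)
  column <- gc_column_spec(
    Lc = Lc, r = r, d_f = mucosa$thickness, D_gas = odorant$D_a,
    D_stationary = mucus_diffusivity(odorant, mucosa),
    k_ret = retention_factor(odorant, r, mucosa$thickness)
  )
  list(column = column, u_operating = u_op,
       n_columns = length(network$column_groups))
}

#' Compare parallel-coil and elongated-tube olfactory architectures
#'
#' For two networks sharing the dorsal-medial feed flow and the olfactory
#' airspace volume, derives the equivalent GC column of each olfactory region,
#' evaluates the Golay optimum and the plate number at the actual operating
#' velocity, and reports the parallel / tube ratios.
#'
#' @param parallel,tube `channel_network`s (typically a built nose and its
#'   [elongated_tube_variant()]).
#' @param parallel_flow,tube_flow Matching `network_flow`s.
#' @param odorant An [odorant()].
#' @param mucosa A [mucosa_spec()].
#' @param fraction Bandwidth fraction passed to [velocity_robustness()].
#' @param include_film Include the stationary-film Golay term?
#' @return A `gc_comparison`: per-architecture tibble plus ratio summary.
#' @export
compare_architectures <- function(parallel, parallel_flow, tube, tube_flow,
                                  odorant, mucosa, fraction = 0.8,
                                  include_film = TRUE) {
  v_par <- olfactory_volume(parallel)
  v_tube <- olfactory_volume(tube)
  if (abs(v_par - v_tube) > 0.01 * v_par) {
    abort(sprintf(
      "Olfactory airspace volumes differ by %.2f%% (> 1%%): not comparable.",
      100 * abs(v_par - v_tube) / v_par
    ), class = "olfnet_comparability_error")
  }
  arch <- list(parallel = list(net = parallel, flow = parallel_flow),
               tube = list(net = tube, flow = tube_flow))
  rows <- imap(arch, function(a, nm) {
    spec <- olfactory_column_spec(a$net, a$flow, odorant, mucosa)
    co <- golay_coefficients(spec$column, include_film)
    u_opt <- sqrt(co$B / co$C)
    H_op <- co$B / spec$u_operating + co$C * spec$u_operating
    band <- velocity_robustness(spec$column, fraction, include_film)
    tibble(
      architecture = nm, n_columns = spec$n_columns,
      Lc = spec$column$Lc, r = spec$column$r, k_ret = spec$column$k_ret,
      u_operating = spec$u_operating, u_opt = u_opt,
      H_min = 2 * sqrt(co$B * co$C), N_peak = spec$column$Lc / (2 * sqrt(co$B * co$C)),
      N_operating = spec$column$Lc / H_op,
      band_u_lo = band$u_lo, band_u_hi = band$u_hi,
      band_log_width = band$log_width
    )
  })
  table <- list_rbind(rows)
  p <- table[table$architecture == "parallel", ]
  t <- table[table$architecture == "tube", ]
  structure(
    list(table = table,
         N_peak_ratio = p$N_peak / t$N_peak,
         N_operating_ratio = p$N_operating / t$N_operating,
         odorant = odorant$name, beta = odorant$beta),
    class = "gc_comparison"
  )
}

# total olfactory airspace volume of a network, m^3
olfactory_volume <- function(network) {
  segs <- network$segments
  olf <- segs[segs$epithelium == "olfactory", ]
  sum(olf$cross_area * olf$length)
}

#' @export
print.gc_comparison <- function(x, ...) {
  cat(sprintf(
    paste0("<gc_comparison> %s (beta = %.3g)\n  N_peak parallel/tube = %.3g, ",
           "N_operating parallel/tube = %.3g\n"),
    x$odorant, x$beta, x$N_peak_ratio, x$N_operating_ratio
  ))
  print(as.data.frame(x$table[, c("architecture", "u_operating", "u_opt",
                                  "N_peak", "N_operating")]))
  invisible(x)
}

#' @rdname tidiers
#' @method tidy gc_comparison
#' @export
tidy.gc_comparison <- function(x, ...) x$table

#' @rdname tidiers
#' @method glance gc_comparison
#' @export
glance.gc_comparison <- function(x, ...) {
  tibble(N_peak_ratio = x$N_peak_ratio,
         N_operating_ratio = x$N_operating_ratio,
         odorant = x$odorant, beta = x$beta)
}
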