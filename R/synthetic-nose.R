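# Synthetic channel-network noses: a serial respiratory section feeding a bank
# of parallel olfactory columns via a dorsal-medial (DM) stream, calibrated to
# target wall area and airspace volume.

#' Describe one channel segment
#'
#' Builds a one-row tibble describing a channel segment. Circular segments are
#' parameterized by radius; slot (parallel-plate) segments by half-gap and
#' width. Perimeter and cross-sectional area are derived from the shape.
#'
#' @param id Segment identifier (unique within a network).
#' @param length Segment length, m.
#' @param shape `"circular"` or `"slot"`.
#' @param radius_or_halfgap Radius (circular) or half-gap (slot), m.
#' @param width Slot width, m (ignored for circular segments).
#' @param epithelium `"respiratory"`, `"olfactory"` or `"nonabsorbing"`.
#' @param axial_start Distance of the segment inlet from the naris tip, m.
#' @param axis Unit 3-vector giving the segment direction (normalized here).
#' @param role Free-text structural role tag.
#' @return One-row tibble.
#' @export
#' @examples
#' channel_segment("c1", 5e-3, "circular", 1.5e-4, epithelium = "olfactory")
channel_segment <- function(id, length, shape = c("circular", "slot"),
                            radius_or_halfgap, width = NA_real_,
                            epithelium = c("respiratory", "olfactory",
                                           "nonabsorbing"),
                            axial_start = 0, axis = c(1, 0, 0),
                            role = NA_character_) {
  shape <- match.arg(shape)
  epithelium <- match.arg(epithelium)
  check_positive(length = length, radius_or_halfgap = radius_or_halfgap)
  if (shape == "slot") {
    check_positive(width = width)
    perimeter <- 2 * (width + 2 * radius_or_halfgap)
    cross_area <- width * 2 * radius_or_halfgap
  } else {
    width <- NA_real_
    perimeter <- 2 * pi * radius_or_halfgap
    cross_area <- pi * radius_or_halfgap^2
  }
  axis <- as.numeric(axis)
  stopifnot(length(axis) == 3, sum(axis^2) > 0)
  axis <- axis / sqrt(sum(axis^2))
  tibble(
    id = as.character(id), length = length, shape = shape,
    radius_or_halfgap = radius_or_halfgap, width = width,
    perimeter = perimeter, cross_area = cross_area,
    epithelium = epithelium, axial_start = axial_start,
    axis_x = axis[1], axis_y = axis[2], axis_z = axis[3],
    role = role
  )
}

# topological order of segment ids; aborts on cycles (Kahn's algorithm)
topological_order <- function(segments, edges) {
  ids <- segments$id
  indeg <- setNames(integer(length(ids)), ids)
  if (nrow(edges) > 0) {
    tab <- table(edges$to)
    indeg[names(tab)] <- as.integer(tab)
  }
  queue <- ids[indeg == 0L]
  order <- character(0)
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    down <- edges$to[edges$from == v]
    for (w in down) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(order) != length(ids)) {
    abort("Channel network contains a cycle; segments must form a DAG.",
          class = "olfnet_topology_error")
  }
  order
}

reachable_from <- function(start, edges, reverse = FALSE) {
  seen <- character(0)
  frontier <- start
  while (length(frontier) > 0) {
    seen <- union(seen, frontier)
    nxt <- if (reverse) edges$from[edges$to %in% frontier]
           else edges$to[edges$from %in% frontier]
    frontier <- setdiff(unique(nxt), seen)
  }
  seen
}

#' Assemble and validate a channel network
#'
#' A channel network is a directed acyclic graph of channel segments with
#' designated inlets and outlets. `column_groups` names the parallel olfactory
#' columns; together the groups must partition the olfactory segments.
#'
#' @param segments Tibble of rows from [channel_segment()].
#' @param edges Tibble with columns `from`, `to` (segment ids).
#' @param inlet_ids,outlet_ids Segment ids acting as network inlet/outlet.
#' @param column_groups Named list; each element is a character vector of
#'   olfactory segment ids forming one column chain.
#' @param meta Optional list of provenance fields (seed, spec, ...).
#' @return An object of class `channel_network`.
#' @export
channel_network <- function(segments, edges, inlet_ids, outlet_ids,
                            column_groups = list(), meta = list()) {
  segments <- as_tibble(segments)
  edges <- as_tibble(edges)
  stopifnot(all(c("from", "to") %in% names(edges)))
  if (anyDuplicated(segments$id)) {
    abort("Segment ids must be unique.", class = "olfnet_topology_error")
  }
  unknown <- setdiff(unique(c(edges$from, edges$to, inlet_ids, outlet_ids,
                              unlist(column_groups))), segments$id)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown segment id(s): %s", paste(unknown, collapse = ", ")),
          class = "olfnet_topology_error")
  }
  topological_order(segments, edges)  # DAG check
  fwd <- reachable_from(inlet_ids, edges)
  bwd <- reachable_from(outlet_ids, edges, reverse = TRUE)
  stranded <- setdiff(segments$id, intersect(fwd, bwd))
  if (length(stranded) > 0) {
    abort(sprintf(
      "Segment(s) not on an inlet-outlet path: %s",
      paste(stranded, collapse = ", ")
    ), class = "olfnet_topology_error")
  }
  olf <- segments$id[segments$epithelium == "olfactory"]
  grouped <- unlist(column_groups, use.names = FALSE)
  if (length(olf) > 0 || length(grouped) > 0) {
    if (!setequal(olf, grouped) || anyDuplicated(grouped)) {
      abort("column_groups must partition the olfactory segments.",
            class = "olfnet_topology_error")
    }
  }
  if (any(segments$length <= 0) || any(segments$perimeter <= 0) ||
      any(segments$cross_area <= 0)) {
    abort("Segment lengths, perimeters and cross areas must be positive.",
          class = "olfnet_construction_error")
  }
  structure(
    list(segments = segments, edges = edges,
         inlet_ids = inlet_ids, outlet_ids = outlet_ids,
         column_groups = column_groups, meta = meta),
    class = "channel_network"
  )
}

#' @export
print.channel_network <- function(x, ...) {
  cat(sprintf(
    "<channel_network> %d segments, %d edges, %d olfactory column group(s)\n",
    nrow(x$segments), nrow(x$edges), length(x$column_groups)
  ))
  cat(sprintf("  wall area %.4g cm^2, airspace volume %.4g mL\n",
              network_surface_area(x) * 1e4, network_volume(x) * 1e6))
  invisible(x)
}

#' Total wall (mucosal) surface area of a network, m^2
#' @param network A `channel_network`.
#' @return Area in m^2.
#' @export
network_surface_area <- function(network) {
  sum(network$segments$perimeter * network$segments$length)
}

#' Total airspace volume of a network, m^3
#' @param network A `channel_network`.
#' @return Volume in m^3.
#' @export
network_volume <- function(network) {
  sum(network$segments$cross_area * network$segments$length)
}

# Species presets ------------------------------------------------------------

#' Specify a synthetic nose
#'
#' Species presets fix the channel-network parameters; `"custom"` requires the
#' geometric arguments explicitly. Preset geometry is a reduced-order stand-in
#' (not measured anatomy): its wall area and airspace volume are calibrated to
#' morphometric targets, and column dimensions were chosen once so that the
#' solved olfactory velocities sit in the reported physiological bands.
#'
#' @param species `"mouse"`, `"rat"` or `"custom"`.
#' @param n_parallel_columns Number of parallel olfactory columns.
#' @param dm_flow_fraction Fraction of inspired flow entering the olfactory
#'   (dorsal-medial) feed, in (0, 1).
#' @param target_surface_area_cm2,target_volume_ml Morphometric calibration
#'   targets.
#' @param column_radius,column_length Olfactory column dimensions, m.
#' @param respiratory Named list of respiratory-path dimensions (see Details).
#' @param column_jitter Relative (log-normal) jitter applied to column lengths.
#' @param random_seed Integer seed controlling the jitter.
#' @details `respiratory` accepts `naris_radius`, `naris_length`,
#'   `vestibule_radius`, `vestibule_length`, `dm_radius`, `dm_length`,
#'   `slot_halfgap`, `slot_width`, `slot_length`, `collector_radius`,
#'   `collector_length`, `nasopharynx_radius`, `nasopharynx_length` (all m).
#' @return An object of class `nose_spec`.
#' @export
#' @examples
#' nose_spec("mouse")
nose_spec <- function(species = c("mouse", "rat", "custom"),
                      n_parallel_columns = NULL, dm_flow_fraction = NULL,
                      target_surface_area_cm2 = NULL, target_volume_ml = NULL,
                      column_radius = NULL, column_length = NULL,
                      respiratory = list(), column_jitter = 0.02,
                      random_seed = 1L) {
  species <- match.arg(species)
  preset <- switch(species,
    mouse = list(
      n_parallel_columns = 6L, dm_flow_fraction = 0.1,
      target_surface_area_cm2 = 2.90, target_volume_ml = 0.0291,
      column_radius = 1.36e-4, column_length = 7e-3,
      respiratory = list(
        naris_radius = 5.0e-4, naris_length = 1.0e-3,
        vestibule_radius = 4.5e-4, vestibule_length = 1.5e-3,
        dm_radius = 2.0e-4, dm_length = 2.0e-3,
        slot_halfgap = 0.98e-4, slot_width = 5.91e-3, slot_length = 1.0e-2,
        collector_radius = 2.5e-4, collector_length = 1.0e-3,
        nasopharynx_radius = 4.0e-4, nasopharynx_length = 2.5e-3
      )
    ),
    rat = list(
      n_parallel_columns = 24L, dm_flow_fraction = 0.1,
      # stand-in morphometric targets (the calibrated micro-CT values cover
      # the mouse only); plausible for an adult Sprague-Dawley rat
      target_surface_area_cm2 = 11.5, target_volume_ml = 0.26,
      column_radius = 2.6e-4, column_length = 1.5e-2,
      respiratory = list(
        naris_radius = 1.0e-3, naris_length = 2.0e-3,
        vestibule_radius = 9.0e-4, vestibule_length = 3.0e-3,
        dm_radius = 5.5e-4, dm_length = 4.0e-3,
        slot_halfgap = 3.1e-4, slot_width = 5.8e-3, slot_length = 2.0e-2,
        collector_radius = 7.0e-4, collector_length = 2.0e-3,
        nasopharynx_radius = 1.0e-3, nasopharynx_length = 5.0e-3
      )
    ),
    custom = list(
      n_parallel_columns = NULL, dm_flow_fraction = 0.1,
      target_surface_area_cm2 = NULL, target_volume_ml = NULL,
      column_radius = NULL, column_length = NULL, respiratory = list()
    )
  )
  spec <- list(
    species = species,
    n_parallel_columns = n_parallel_columns %||% preset$n_parallel_columns,
    dm_flow_fraction = dm_flow_fraction %||% preset$dm_flow_fraction,
    target_surface_area_cm2 =
      target_surface_area_cm2 %||% preset$target_surface_area_cm2,
    target_volume_ml = target_volume_ml %||% preset$target_volume_ml,
    column_radius = column_radius %||% preset$column_radius,
    column_length = column_length %||% preset$column_length,
    respiratory = modifyList(preset$respiratory, respiratory),
    column_jitter = column_jitter,
    random_seed = as.integer(random_seed)
  )
  required <- c("n_parallel_columns", "column_radius", "column_length")
  missing <- required[vapply(spec[required], is.null, logical(1))]
  if (length(missing) > 0) {
    abort(sprintf("nose_spec is missing: %s", paste(missing, collapse = ", ")),
          class = "olfnet_construction_error")
  }
  if (spec$n_parallel_columns < 1) {
    abort("n_parallel_columns must be >= 1.",
          class = "olfnet_construction_error")
  }
  if (spec$dm_flow_fraction <= 0 || spec$dm_flow_fraction >= 1) {
    abort("dm_flow_fraction must lie strictly between 0 and 1.",
          class = "olfnet_construction_error")
  }
  if (!is.null(spec$target_surface_area_cm2)) {
    check_positive(target_surface_area_cm2 = spec$target_surface_area_cm2,
                   target_volume_ml = spec$target_volume_ml)
  }
  structure(spec, class = "nose_spec")
}

#' Build a synthetic nose from a specification
#'
#' Topology: naris -> vestibule -> bifurcation into (a) two ventral
#' respiratory slot channels and (b) a dorsal-medial feed fanning out into
#' `n_parallel_columns` parallel olfactory columns that reconverge into a
#' collector; both routes merge into the nasopharynx outlet. Column lengths
#' receive a small seeded log-normal jitter so parallel paths are not exactly
#' identical; the build is reproducible for a fixed `random_seed`.
#'
#' @param spec A [nose_spec()].
#' @param calibrate Calibrate to the spec's morphometric targets (if any)?
#' @return A `channel_network`.
#' @export
#' @examples
#' nose <- build_nose(nose_spec("mouse"))
#' network_surface_area(nose) * 1e4  # cm^2
build_nose <- function(spec, calibrate = TRUE) {
  stopifnot(inherits(spec, "nose_spec"))
  rp <- spec$respiratory
  need <- c("naris_radius", "naris_length", "vestibule_radius",
            "vestibule_length", "dm_radius", "dm_length", "slot_halfgap",
            "slot_width", "slot_length", "collector_radius",
            "collector_length", "nasopharynx_radius", "nasopharynx_length")
  miss <- setdiff(need, names(rp))
  if (length(miss) > 0) {
    abort(sprintf("respiratory dimensions missing: %s",
                  paste(miss, collapse = ", ")),
          class = "olfnet_construction_error")
  }
  np <- spec$n_parallel_columns
  col_len <- withr::with_seed(spec$random_seed, {
    spec$column_length * exp(stats::rnorm(np, 0, spec$column_jitter))
  })

  z_naris <- 0
  z_vest <- rp$naris_length
  z_bif <- z_vest + rp$vestibule_length
  z_cols <- z_bif + rp$dm_length
  z_coll <- z_cols + spec$column_length
  z_naso <- z_bif + rp$slot_length

  segs <- list(
    channel_segment("naris", rp$naris_length, "circular", rp$naris_radius,
                    epithelium = "nonabsorbing", axial_start = z_naris,
                    axis = c(0.8, 0.6, 0), role = "naris"),
    channel_segment("vestibule", rp$vestibule_length, "circular",
                    rp$vestibule_radius, epithelium = "respiratory",
                    axial_start = z_vest, axis = c(1, 0, 0),
                    role = "vestibule"),
    channel_segment("dm_feed", rp$dm_length, "circular", rp$dm_radius,
                    epithelium = "respiratory", axial_start = z_bif,
                    axis = c(0.6, 0.8, 0), role = "dm_feed"),
    channel_segment("slot_L", rp$slot_length, "slot", rp$slot_halfgap,
                    width = rp$slot_width, epithelium = "respiratory",
                    axial_start = z_bif, axis = c(0.98, -0.2, 0.05),
                    role = "respiratory_slot"),
    channel_segment("slot_R", rp$slot_length, "slot", rp$slot_halfgap,
                    width = rp$slot_width, epithelium = "respiratory",
                    axial_start = z_bif, axis = c(0.98, -0.2, -0.05),
                    role = "respiratory_slot"),
    channel_segment("collector", rp$collector_length, "circular",
                    rp$collector_radius, epithelium = "respiratory",
                    axial_start = z_coll, axis = c(0.7, -0.7, 0),
                    role = "collector"),
    channel_segment("nasopharynx", rp$nasopharynx_length, "circular",
                    rp$nasopharynx_radius, epithelium = "nonabsorbing",
                    axial_start = z_naso, axis = c(1, 0, 0),
                    role = "nasopharynx")
  )
  col_ids <- sprintf("olf_col_%02d", seq_len(np))
  zspread <- if (np > 1) seq(-0.25, 0.25, length.out = np) else 0
  for (i in seq_len(np)) {
    segs[[length(segs) + 1L]] <- channel_segment(
      col_ids[i], col_len[i], "circular", spec$column_radius,
      epithelium = "olfactory", axial_start = z_cols,
      axis = c(0.9, -0.35, zspread[i]), role = "olfactory_column"
    )
  }
  segments <- list_rbind(segs)

  edges <- bind_rows(
    tibble(from = "naris", to = "vestibule"),
    tibble(from = "vestibule", to = c("dm_feed", "slot_L", "slot_R")),
    tibble(from = "dm_feed", to = col_ids),
    tibble(from = col_ids, to = "collector"),
    tibble(from = c("collector", "slot_L", "slot_R"), to = "nasopharynx")
  )
  network <- channel_network(
    segments, edges, inlet_ids = "naris", outlet_ids = "nasopharynx",
    column_groups = setNames(as.list(col_ids),
                             sprintf("column_%02d", seq_len(np))),
    meta = list(spec = spec, random_seed = spec$random_seed,
                dm_flow_fraction = spec$dm_flow_fraction)
  )
  if (calibrate && !is.null(spec$target_surface_area_cm2)) {
    network <- calibrate_to_morphometry(
      network, spec$target_surface_area_cm2, spec$target_volume_ml
    )
  }
  network
}

#' Calibrate a network to morphometric targets
#'
#' Rescales the network within a two-parameter similarity family — a
#' transverse scale applied to all cross-sections and an axial scale applied
#' to all lengths — so that total wall area and airspace volume match the
#' targets. With area `A ~ s_t s_a` and volume `V ~ s_t^2 s_a` the solution is
#' `s_t = (V_t/V) / (A_t/A)` and `s_a = (A_t/A)^2 / (V_t/V)`. Topology is
#' unchanged; the scales are attached as attribute `"calibration"`.
#'
#' @param network A `channel_network`.
#' @param target_area_cm2 Target wall area, cm^2.
#' @param target_volume_ml Target airspace volume, mL.
#' @return The rescaled `channel_network`.
#' @export
calibrate_to_morphometry <- function(network, target_area_cm2,
                                     target_volume_ml) {
  check_positive(target_area_cm2 = target_area_cm2,
                 target_volume_ml = target_volume_ml)
  a_ratio <- (target_area_cm2 * 1e-4) / network_surface_area(network)
  v_ratio <- (target_volume_ml * 1e-6) / network_volume(network)
  s_t <- v_ratio / a_ratio
  s_a <- a_ratio^2 / v_ratio
  if (!is.finite(s_t) || !is.finite(s_a) || s_t <= 0 || s_a <= 0) {
    abort(sprintf(
      paste0("Targets unreachable by transverse/axial scaling; closest ",
             "achievable area %.4g cm^2, volume %.4g mL."),
      network_surface_area(network) * 1e4, network_volume(network) * 1e6
    ), class = "olfnet_calibration_error")
  }
  segs <- network$segments
  segs$radius_or_halfgap <- segs$radius_or_halfgap * s_t
  segs$width <- segs$width * s_t
  segs$perimeter <- segs$perimeter * s_t
  segs$cross_area <- segs$cross_area * s_t^2
  segs$length <- segs$length * s_a
  segs$axial_start <- segs$axial_start * s_a
  out <- network
  out$segments <- segs
  attr(out, "calibration") <- list(
    transverse_scale = s_t, axial_scale = s_a,
    area_scale = a_ratio, volume_scale = v_ratio
  )
  out
}

#' Wall-area distribution along the airway
#'
#' Bins the wall area of each epithelium class by distance from the naris tip,
#' spreading each segment's area uniformly along its axial extent. The
#' cumulative column is non-decreasing and ends at the total wall area.
#'
#' @param network A `channel_network`.
#' @param n_bins Number of equal-width distance bins (>= 1).
#' @return Tibble with per-bin areas (m^2) per class, totals and cumulative
#'   total; class `epithelium_profile`.
#' @export
epithelium_profile <- function(network, n_bins) {
  if (!is.numeric(n_bins) || n_bins < 1) {
    abort("n_bins must be >= 1.", class = "olfnet_domain_error")
  }
  n_bins <- as.integer(n_bins)
  segs <- network$segments
  z_max <- max(segs$axial_start + segs$length)
  breaks <- seq(0, z_max, length.out = n_bins + 1L)
  classes <- c("respiratory", "olfactory", "nonabsorbing")
  acc <- matrix(0, nrow = n_bins, ncol = 3,
                dimnames = list(NULL, classes))
  for (i in seq_len(nrow(segs))) {
    z0 <- segs$axial_start[i]
    z1 <- z0 + segs$length[i]
    area <- segs$perimeter[i] * segs$length[i]
    lo <- pmin(pmax(breaks[-length(breaks)], z0), z1)
    hi <- pmin(pmax(breaks[-1], z0), z1)
    frac <- (hi - lo) / (z1 - z0)
    acc[, segs$epithelium[i]] <- acc[, segs$epithelium[i]] + area * frac
  }
  out <- tibble(
    bin = seq_len(n_bins),
    z_lo = breaks[-length(breaks)], z_hi = breaks[-1],
    z_mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
    respiratory = acc[, "respiratory"],
    olfactory = acc[, "olfactory"],
    nonabsorbing = acc[, "nonabsorbing"]
  )
  out$total <- out$respiratory + out$olfactory + out$nonabsorbing
  out$cumulative <- cumsum(out$total)
  class(out) <- c("epithelium_profile", class(out))
  out
}

#' Replace the olfactory columns by one volume-preserving elongated tube
#'
#' The parallel olfactory column bank is replaced by a single circular tube of
#' equal airspace volume, fed by the same dorsal-medial feed. By the default
#' packing rule the tube length equals the mean column chain length `Lc`, so
#' the tube radius is `sqrt(V_olf / (pi * Lc))`.
#'
#' @param network A `channel_network` with at least one olfactory column group.
#' @param tube_length Optional tube length, m, overriding the packing rule.
#' @return A `channel_network` with a single `olf_tube` olfactory segment.
#' @export
elongated_tube_variant <- function(network, tube_length = NULL) {
  if (length(network$column_groups) == 0) {
    abort("Network has no olfactory column groups to replace.",
          class = "olfnet_topology_error")
  }
  segs <- network$segments
  col_ids <- unlist(network$column_groups, use.names = FALSE)
  cols <- segs[segs$id %in% col_ids, ]
  v_olf <- sum(cols$cross_area * cols$length)
  chain_lengths <- map_dbl(network$column_groups, function(ids) {
    sum(segs$length[segs$id %in% ids])
  })
  l_c <- mean(chain_lengths)
  l_tube <- tube_length %||% l_c
  check_positive(tube_length = l_tube)
  r_tube <- sqrt(v_olf / (pi * l_tube))
  axis <- c(mean(cols$axis_x), mean(cols$axis_y), mean(cols$axis_z))
  if (sum(axis^2) == 0) axis <- c(1, 0, 0)
  tube <- channel_segment(
    "olf_tube", l_tube, "circular", r_tube, epithelium = "olfactory",
    axial_start = min(cols$axial_start), axis = axis, role = "olfactory_tube"
  )
  keep <- segs[!segs$id %in% col_ids, ]
  edges <- network$edges
  ups <- unique(edges$from[edges$to %in% col_ids & !edges$from %in% col_ids])
  downs <- unique(edges$to[edges$from %in% col_ids & !edges$to %in% col_ids])
  edges <- edges[!(edges$from %in% col_ids | edges$to %in% col_ids), ]
  edges <- bind_rows(edges,
                     tibble(from = ups, to = "olf_tube"),
                     tibble(from = "olf_tube", to = downs))
  channel_network(
    bind_rows(keep, tube), edges,
    inlet_ids = network$inlet_ids, outlet_ids = network$outlet_ids,
    column_groups = list(tube = "olf_tube"),
    meta = c(network$meta, list(elongated_tube = TRUE))
  )
}

#' @rdname tidiers
#' @method tidy channel_network
#' @export
tidy.channel_network <- function(x, ...) x$segments
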