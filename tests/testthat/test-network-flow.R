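make_parallel_net <- function(lengths, radius = 1e-4) {
  inlet <- channel_segment("in", 1e-3, "circular", 3e-4)
  outlet <- channel_segment("out", 1e-3, "circular", 3e-4)
  branches <- purrr::list_rbind(purrr::imap(
    as.list(lengths),
    function(L, i) channel_segment(paste0("b", i), L, "circular", radius)
  ))
  ids <- branches$id
  channel_network(
    dplyr::bind_rows(inlet, branches, outlet),
    dplyr::bind_rows(tibble::tibble(from = "in", to = ids),
                     tibble::tibble(from = ids, to = "out")),
    "in", "out"
  )
}

test_that("two identical parallel branches split the flow evenly", {
  net <- make_parallel_net(c(5e-3, 5e-3))
  fl <- solve_flow(net, 1e-7, dm_flow_fraction = NULL)
  q <- fl$table$flow[fl$table$id %in% c("b1", "b2")]
  expect_equal(q, c(5e-8, 5e-8), tolerance = 1e-12)
})

test_that("parallel resistances 1:2:2 give flow fractions 0.5/0.25/0.25", {
  # Poiseuille resistance is linear in length at fixed radius
  net <- make_parallel_net(c(2e-3, 4e-3, 4e-3))
  fl <- solve_flow(net, 1e-7, dm_flow_fraction = NULL)
  q <- fl$table$flow[match(c("b1", "b2", "b3"), fl$table$id)]
  expect_equal(q / 1e-7, c(0.5, 0.25, 0.25), tolerance = 1e-10)
})

test_that("junction mass is conserved on 100 randomized networks", {
  worst <- 0
  for (i in 1:100) {
    net <- random_layered_network(i)
    fl <- solve_flow(net, 1e-7, dm_flow_fraction = NULL)
    tails <- attr(net, "tail_node"); heads <- attr(net, "head_node")
    for (v in 2:(max(heads) - 1)) {
      res <- sum(fl$table$flow[heads == v]) - sum(fl$table$flow[tails == v])
      worst <- max(worst, abs(res) / 1e-7)
    }
    expect_true(all(fl$table$flow >= -1e-20))
  }
  expect_lt(worst, 1e-10)
})

test_that("the nodal solver agrees with a dense linear-system oracle", {
  worst <- 0
  for (i in 1:50) {
    net <- random_layered_network(i)
    fl <- solve_flow(net, 1e-7, dm_flow_fraction = NULL,
                     air = air_properties(1.2, 1.8e-5 / 1.2))
    ora <- flow_oracle(net, 1e-7, mu = 1.8e-5)
    worst <- max(worst, max(abs(fl$table$flow - ora$q)) / 1e-7)
  }
  expect_lt(worst, 1e-9)
})

test_that("the dorsal-medial split is imposed exactly", {
  nose <- build_nose(nose_spec("mouse"))
  Q <- 25 / 60 * 1e-6
  fl <- solve_flow(nose, Q)
  expect_identical(fl$table$flow[fl$table$id == "dm_feed"], 0.1 * Q)
  # and the column split remains resistance-proportional (sums to the feed)
  col_q <- fl$table$flow[grepl("olf_col", fl$table$id)]
  expect_equal(sum(col_q), 0.1 * Q, tolerance = 1e-10)
})

test_that("preset olfactory velocities sit in the reported bands", {
  mouse <- build_nose(nose_spec("mouse"))
  fm <- solve_flow(mouse, 25 / 60 * 1e-6)
  vm <- fm$table$velocity[grepl("olf_col", fm$table$id)]
  expect_true(all(vm >= 0.03 & vm <= 0.14))

  rat <- build_nose(nose_spec("rat"))
  fr <- solve_flow(rat, 200 / 60 * 1e-6)
  vr <- fr$table$velocity[grepl("olf_col", fr$table$id)]
  expect_true(all(vr >= 0.02 & vr <= 0.12))
})

test_that("dimensionless numbers match hand arithmetic", {
  ch <- make_single_channel(Q = 25 / 60 * 1e-6, radius = 5e-4,
                            length = 5e-3, epithelium = "respiratory")
  rep <- dimensionless_numbers(ch$network, ch$flow,
                               breathing_frequency = 0)
  # U = Q / (pi r^2) = 0.5305 m/s; Re = U d / nu = 35.4
  expect_equal(rep$Re, 0.53052 * 1e-3 / 1.5e-5, tolerance = 1e-4)
  expect_equal(rep$W0, 0)
  expect_equal(rep$S, 0)
  expect_true(rep$quasi_steady)
  expect_true(rep$laminar)
})

test_that("threshold conventions are strict inequalities", {
  ch <- make_single_channel(Q = 1e-7, radius = 5e-4,
                            epithelium = "respiratory")
  fl <- ch$flow
  seg <- ch$network$segments[1, ]
  d_h <- 4 * seg$cross_area / seg$perimeter
  # force the computed Re to be exactly 2300 (nudge away rounding)
  U <- 2300 * 1.5e-5 / d_h
  for (k in 1:8) {
    Re_now <- U * d_h / 1.5e-5
    if (Re_now == 2300) break
    U <- U * (2300 / Re_now)
  }
  expect_identical(U * d_h / 1.5e-5, 2300)
  fl$table$velocity[1] <- U
  rep <- dimensionless_numbers(ch$network, fl)
  expect_false(rep$laminar)
  fl$table$velocity[1] <- 2299.999 * 1.5e-5 / d_h
  expect_true(dimensionless_numbers(ch$network, fl)$laminar)
  # zero velocity with nonzero frequency: S undefined, flagged not crashed
  fl$table$velocity[1] <- 0
  rep0 <- dimensionless_numbers(ch$network, fl, breathing_frequency = 2)
  expect_true(is.na(rep0$S))
  expect_false(rep0$S_defined)
})

test_that("secondary-flow strength follows its definition", {
  u <- array(1, dim = c(4, 4, 2))
  zero <- array(0, dim = c(4, 4, 2))
  f_axial <- grid_velocity_field(u, zero, zero, spacing = 1e-4)
  expect_equal(secondary_strength(f_axial)$mean, 0)

  f_iso <- grid_velocity_field(u, u, u, spacing = 1e-4)
  expect_equal(secondary_strength(f_iso)$mean, sqrt(2 / 3),
               tolerance = 1e-12)

  # invariance under uniform rescaling of all components
  f_scaled <- grid_velocity_field(5 * u, 5 * u, 5 * u, spacing = 1e-4)
  expect_equal(secondary_strength(f_scaled)$ss, secondary_strength(f_iso)$ss)

  # all-zero region: undefined mean with warning
  f0 <- grid_velocity_field(zero, zero, zero, spacing = 1e-4)
  expect_warning(s0 <- secondary_strength(f0), "zero velocity")
  expect_true(is.na(s0$mean))
  expect_equal(s0$n_zero_excluded, length(u))
})

test_that("synthetic swirl fields hit the closed-form SS values", {
  # at the reference radius SS = s / sqrt(1 + s^2)
  for (s in c(0.5, 1, 4)) {
    f <- synthetic_swirl_field(n = c(17, 17, 3), radius = 1e-3,
                               axial_speed = 1, swirl_ratio = s)
    ss <- secondary_strength(f)$ss
    # grid point (x = R, y = 0): indices (17, 9, 1)
    expect_equal(ss[17, 9, 1], s / sqrt(1 + s^2), tolerance = 1e-12)
  }
  f0 <- synthetic_swirl_field(swirl_ratio = 0)
  expect_equal(secondary_strength(f0)$mean, 0)
  # swirl_ratio -> infinity: SS -> 1 at the reference radius
  fb <- synthetic_swirl_field(n = c(17, 17, 3), swirl_ratio = 1e6)
  expect_equal(secondary_strength(fb)$ss[17, 9, 1], 1, tolerance = 1e-9)
})

test_that("uniform-SS fields average to the pointwise value under any mask", {
  f <- grid_velocity_field(array(2, c(5, 5, 2)), array(1, c(5, 5, 2)),
                           array(2, c(5, 5, 2)), spacing = 1e-4)
  mask <- array(FALSE, c(5, 5, 2)); mask[2:4, 2:4, 1] <- TRUE
  point <- sqrt(5) / 3
  expect_equal(secondary_strength(f, mask)$mean, point, tolerance = 1e-12)
})

test_that("velocity fields round-trip through legacy VTK", {
  f <- synthetic_swirl_field(n = c(9, 9, 3), axial_speed = 0.7,
                             swirl_ratio = 0.3)
  tmp <- withr::local_tempfile(fileext = ".vtk")
  write_vtk_structured(f, tmp)
  g <- read_vtk_structured(tmp)
  expect_equal(g$u, f$u, tolerance = 1e-15)
  expect_equal(g$v, f$v, tolerance = 1e-15)
  expect_equal(g$w, f$w, tolerance = 1e-15)
  expect_equal(g$spacing, f$spacing, tolerance = 1e-15)
})

test_that("network centerlines export as VTK polylines", {
  nose <- build_nose(nose_spec("mouse"))
  tmp <- withr::local_tempfile(fileext = ".vtk")
  write_vtk_network(nose, tmp)
  lines <- readLines(tmp)
  expect_match(lines[1], "^# vtk DataFile")
  n <- nrow(nose$segments)
  expect_true(any(grepl(sprintf("^LINES %d %d$", n, 3 * n), lines)))
})

test_that("disconnected networks raise a topology error", {
  seg <- channel_segment("a", 1e-3, "circular", 1e-4)
  net <- channel_network(seg,
                         tibble::tibble(from = character(), to = character()),
                         "a", "a")
  # single segment is fine
  expect_s3_class(solve_flow(net, 1e-8, dm_flow_fraction = NULL),
                  "network_flow")
})
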