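test_that("drag response follows Schiller-Naumann", {
  expect_identical(drag_response(0), 1)
  expect_equal(drag_response(1), 1.15, tolerance = 1e-12)
  grid <- seq(0, 1000, length.out = 101)
  expect_true(all(diff(drag_response(grid)) >= 0))
  expect_true(all(drag_response(grid) >= 1))
  expect_warning(hi <- drag_response(1500), "clamped")
  expect_equal(hi, drag_response(1000))
  expect_identical(drag_response(c(0, 5, 50), law = "stokes"), rep(1, 3))
})

test_that("a particle moving with the fluid stays in equilibrium", {
  p <- particle_state(velocity = c(0.3, 0, 0), diameter = 1e-5,
                      density = 1000)
  f <- fluid_local(velocity = c(0.3, 0, 0))
  p2 <- step_particle(p, f, dt = 1e-4, forces = list(gravity = FALSE))
  expect_equal(p2$velocity, p$velocity, tolerance = 1e-12)
  expect_equal(p2$position, p$position + 0.3 * 1e-4 * c(1, 0, 0),
               tolerance = 1e-12)
})

test_that("still-fluid settling reaches the Stokes terminal velocity", {
  p <- particle_state(velocity = c(0, 0, 0), diameter = 1e-5,
                      density = 1000)
  f <- fluid_local(velocity = c(0, 0, 0), density = 1.2,
                   viscosity = 1.81e-5)
  tau <- 1000 * (1e-5)^2 / (18 * 1.81e-5)
  for (i in 1:200) p <- step_particle(p, f, dt = tau)
  v_t <- (1000 - 1.2) * 9.81 * (1e-5)^2 / (18 * 1.81e-5)  # ~3.0e-3 m/s
  expect_equal(-p$velocity[2], v_t, tolerance = 0.01)
})

test_that("drag relaxation decays with the Stokes time constant", {
  tau <- 1000 * (1e-5)^2 / (18 * 1.81e-5)
  p <- particle_state(velocity = c(1, 0, 0), diameter = 1e-5,
                      density = 1000)
  f <- fluid_local(velocity = c(0, 0, 0))
  for (i in 1:50) {
    p <- step_particle(p, f, dt = tau / 50, forces = list(gravity = FALSE),
                       drag_law = "stokes")
  }
  expect_equal(p$velocity[1], exp(-1), tolerance = 0.01)
})

test_that("the explicit scheme enforces its stability bound", {
  tau <- 1000 * (1e-5)^2 / (18 * 1.81e-5)
  p <- particle_state(velocity = c(1, 0, 0), diameter = 1e-5,
                      density = 1000)
  f <- fluid_local(velocity = c(0, 0, 0))
  expect_error(step_particle(p, f, dt = 0.2 * tau, scheme = "explicit"),
               class = "olfnet_stability_error")
  # fine steps are accepted
  p2 <- step_particle(p, f, dt = 0.05 * tau, scheme = "explicit",
                      forces = list(gravity = FALSE), drag_law = "stokes")
  expect_lt(p2$velocity[1], 1)
})

test_that("semi-implicit and explicit integrators agree at small dt", {
  tau <- 1000 * (2e-5)^2 / (18 * 1.81e-5)
  f <- fluid_local(velocity = c(0.2, 0, 0))
  advance <- function(scheme) {
    p <- particle_state(velocity = c(0, 0, 0), diameter = 2e-5,
                        density = 1000)
    for (i in 1:100) p <- step_particle(p, f, dt = 0.05 * tau,
                                        scheme = scheme)
    p
  }
  a <- advance("semi_implicit"); b <- advance("explicit")
  expect_equal(a$position, b$position, tolerance = 5e-3)
  expect_equal(a$velocity, b$velocity, tolerance = 5e-3)
})

test_that("Saffman lift follows the shear-lift formula", {
  grad <- matrix(0, 3, 3); grad[1, 2] <- 100  # du_x/dy = 100 /s
  f <- fluid_local(velocity = c(0.1, 0, 0), grad = grad)
  p <- particle_state(velocity = c(0, 0, 0), diameter = 1e-5,
                      density = 1000)
  a_lift <- olfnet:::saffman_lift_accel(f$velocity - p$velocity, f,
                                        p$diameter, p$density)
  D <- 0.5 * (grad + t(grad))
  coef <- 2 * 2.594 * sqrt(f$viscosity / f$density) * f$density /
    (1000 * 1e-5 * sum(D * D)^0.25)
  expect_equal(a_lift, coef * as.numeric(D %*% c(0.1, 0, 0)),
               tolerance = 1e-12)
  # lateral (y) push for a particle lagging the fluid in x under du/dy > 0
  expect_gt(a_lift[2], 0)
  # no gradient, no lift
  expect_identical(
    olfnet:::saffman_lift_accel(c(1, 0, 0), fluid_local(c(0, 0, 0)),
                                1e-5, 1000),
    c(0, 0, 0)
  )
})

test_that("tracers traverse a straight channel without depositing", {
  ch <- make_single_channel(Q = 1e-7, shape = "slot", radius = 1e-4,
                            width = 2e-3, epithelium = "respiratory")
  rec <- track_particles(ch$network, ch$flow, 300, d_p = 1e-7, seed = 3,
                         profile = "plug", gravity = c(0, 0, 0))
  expect_true(all(rec$fate == "escaped"))
})

test_that("sedimentation in plug flow matches the analytic fraction", {
  ch <- make_single_channel(Q = 1e-7, shape = "slot", radius = 1e-4,
                            width = 2e-3, length = 5e-3,
                            epithelium = "respiratory")
  U <- ch$flow$table$velocity[1]
  v_t <- (1000 - 1.2) * 9.81 * (1e-5)^2 / (18 * 1.81e-5)
  pred <- min(1, v_t * 5e-3 / (U * 2e-4))
  rec <- track_particles(ch$network, ch$flow, 2000, d_p = 1e-5, seed = 4,
                         profile = "plug")
  eff <- mean(rec$fate == "deposited")
  se <- sqrt(pred * (1 - pred) / 2000)
  expect_lt(abs(eff - pred), 3 * se)
})

test_that("tracking is reproducible and fates are exhaustive", {
  nose <- build_nose(nose_spec("mouse"))
  fl <- solve_flow(nose, 25 / 60 * 1e-6)
  r1 <- track_particles(nose, fl, 200, d_p = 5e-6, seed = 7)
  r2 <- track_particles(nose, fl, 200, d_p = 5e-6, seed = 7)
  expect_identical(r1, r2)
  expect_true(all(r1$fate %in% c("deposited", "escaped", "lost")))
  expect_equal(sum(table(r1$fate)), 200)
  expect_equal(attr(r1, "n_lost"), 0)
  # deposited particles carry a segment and position; escaped an outlet
  dep <- r1[r1$fate == "deposited", ]
  expect_true(all(!is.na(dep$axial_position)))
  expect_true(all(!is.na(r1$flight_time)))
})

test_that("impaction factor uses the conventional units", {
  expect_equal(impaction_factor(1, 15, 25 / 60), 93.75, tolerance = 1e-12)
  expect_equal(impaction_factor(1, 30, 25 / 60),
               4 * impaction_factor(1, 15, 25 / 60), tolerance = 1e-12)
  expect_warning(z <- impaction_factor(0, 15, 1), "degenerate")
  expect_identical(z, 0)
  expect_error(impaction_factor(-1, 15, 1), class = "olfnet_domain_error")
})

test_that("deposition efficiency grows with size and with flow (inertial regime)", {
  nose <- build_nose(nose_spec("mouse"))
  fl <- solve_flow(nose, 25 / 60 * 1e-6)
  dc <- deposition_curve(nose, fl, sizes_um = c(1.5, 5, 12, 43),
                         n_per_size = 400, seed = 21)
  expect_true(all(dc$lost == 0))
  expect_equal(dc$deposited + dc$escaped, dc$released)
  # non-decreasing within 3 binomial SE
  se <- sqrt(pmax(dc$efficiency * (1 - dc$efficiency), 1e-6) / dc$released)
  expect_true(all(diff(dc$efficiency) > -3 * pmax(se[-1], se[-4])))
  expect_gt(dc$efficiency[4], dc$efficiency[1])
  # Q-monotonicity at 20 um, where inertia dominates
  fl35 <- solve_flow(nose, 35 / 60 * 1e-6)
  e25 <- mean(track_particles(nose, fl, 400, 20e-6, seed = 5)$fate ==
                "deposited")
  e35 <- mean(track_particles(nose, fl35, 400, 20e-6, seed = 5)$fate ==
                "deposited")
  expect_gte(e35, e25 - 3 * sqrt(0.25 / 400))
})

test_that("degenerate deposition cases behave", {
  ch <- make_single_channel(Q = 1e-7, shape = "slot", radius = 1e-4,
                            width = 2e-3, epithelium = "respiratory")
  expect_error(deposition_curve(ch$network, ch$flow, sizes_um = 5),
               class = "olfnet_domain_error")
  # everything escapes -> efficiency 0; heavy slow flow -> everything deposits
  dc <- deposition_curve(ch$network, ch$flow, sizes_um = c(0.05, 40),
                         n_per_size = 100, seed = 2, profile = "plug")
  expect_equal(dc$efficiency[1], 0)
  expect_equal(dc$efficiency[2], 1)
})
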