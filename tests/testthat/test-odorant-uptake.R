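mk_od <- function(beta, D_a = 6e-6, D_m = 1e-9) {
  odorant("test", 130, 149, D_a = D_a, D_m = D_m, beta = beta)
}
MUC <- mucosa_spec()  # 10 um film, so k_w = 1e-4 / beta with D_m = 1e-9

test_that("impermeable and perfectly absorbing limits are recovered", {
  seg <- channel_segment("c", 5e-3, "circular", 1.5e-4,
                         epithelium = "olfactory")
  # beta -> infinity: insoluble odorant, nothing absorbed
  sol <- solve_channel_uptake(seg, 0.5, mk_od(1e10), MUC)
  expect_lt(sol$absorbed_fraction, 1e-6)
  expect_equal(sol$c_out, 1, tolerance = 1e-6)
  # near-perfectly absorbing wall, long channel: everything absorbed
  seg_long <- channel_segment("c", 5e-2, "circular", 1.5e-4,
                              epithelium = "olfactory")
  sol2 <- solve_channel_uptake(seg_long, 0.1, mk_od(1e-8), MUC)
  expect_gt(sol2$absorbed_fraction, 0.999)
})

test_that("solver matches the well-mixed closed form in its regime", {
  seg <- channel_segment("c", 5e-3, "circular", 1.59e-4,
                         epithelium = "olfactory")
  Q <- 4.17e-8
  U <- Q / seg$cross_area
  for (beta in c(1, 0.3, 0.1)) {  # Damkohler 0.003 - 0.03
    k_w <- 1e-9 / (beta * 1e-5)
    sol <- solve_channel_uptake(seg, U, mk_od(beta), MUC)
    wm <- wellmixed_absorbed_fraction(k_w, seg$perimeter, seg$length, Q)
    expect_equal(sol$absorbed_fraction, wm, tolerance = 0.02)
  }
})

test_that("the closed-form well-mixed fraction matches hand arithmetic", {
  # k_w P L / Q = 1.2 -> 1 - exp(-1.2)
  expect_equal(wellmixed_absorbed_fraction(1e-2, 1e-3, 5e-3, 4.17e-8),
               1 - exp(-1.199041e0), tolerance = 1e-4)
})

test_that("constant-wall-concentration Graetz asymptote is recovered", {
  # K -> infinity: local Sherwood number tends to 3.657
  seg <- channel_segment("c", 5e-3, "circular", 1.59e-4,
                         epithelium = "olfactory")
  U <- 4.17e-8 / seg$cross_area
  sol <- solve_channel_uptake(seg, U, mk_od(1e-10), MUC,
                              n_axial = 400, n_transverse = 96)
  wf <- sol$wall_flux
  n <- nrow(wf)
  Sh <- wf$flux_per_area[n] * 2 * seg$radius_or_halfgap /
    (6e-6 * wf$c_mixed[n])
  expect_equal(Sh, 3.657, tolerance = 0.02)
})

test_that("absorbed fraction is monotone in length and wall permeability", {
  base <- channel_segment("c", 5e-3, "circular", 1.5e-4,
                          epithelium = "olfactory")
  lengths <- c(2e-3, 5e-3, 1e-2, 2e-2)
  a_len <- vapply(lengths, function(L) {
    seg <- channel_segment("c", L, "circular", 1.5e-4,
                           epithelium = "olfactory")
    solve_channel_uptake(seg, 0.3, mk_od(0.05), MUC)$absorbed_fraction
  }, numeric(1))
  expect_true(all(diff(a_len) > 0))
  a_kw <- vapply(c(1, 0.1, 0.01, 0.001), function(beta) {
    solve_channel_uptake(base, 0.3, mk_od(beta), MUC)$absorbed_fraction
  }, numeric(1))
  expect_true(all(diff(a_kw) > 0))
})

test_that("defaults are grid-converged to 1%", {
  seg <- channel_segment("c", 7e-3, "circular", 1.4e-4,
                         epithelium = "olfactory")
  for (beta in c(1e-3, 0.1)) {
    s1 <- solve_channel_uptake(seg, 0.11, mk_od(beta), MUC, 200, 64)
    s2 <- solve_channel_uptake(seg, 0.11, mk_od(beta), MUC, 400, 128)
    expect_equal(s1$absorbed_fraction, s2$absorbed_fraction,
                 tolerance = 0.01)
  }
})

test_that("channel solver agrees with the finite-volume oracle", {
  sets <- list(
    list(shape = "circular", a = 1.5e-4, L = 5e-3, U = 0.5, beta = 0.05),
    list(shape = "circular", a = 1.0e-4, L = 7e-3, U = 0.12, beta = 0.02),
    list(shape = "circular", a = 3.0e-4, L = 1e-2, U = 0.06, beta = 0.3),
    list(shape = "slot", a = 1.0e-4, L = 8e-3, U = 0.15, beta = 0.08),
    list(shape = "slot", a = 2.0e-4, L = 1e-2, U = 0.30, beta = 0.3)
  )
  for (s in sets) {
    seg <- channel_segment("c", s$L, s$shape, s$a, width = 2e-3,
                           epithelium = "olfactory")
    sol <- solve_channel_uptake(seg, s$U, mk_od(s$beta), MUC)
    k_w <- 1e-9 / (s$beta * 1e-5)
    ora <- fv_uptake_oracle(s$shape, s$a, s$L, s$U, 6e-6, k_w)
    expect_equal(sol$absorbed_fraction, ora, tolerance = 0.01)
  }
})

test_that("resolution below the minimum is rejected", {
  seg <- channel_segment("c", 5e-3, "circular", 1.5e-4)
  expect_error(solve_channel_uptake(seg, 0.1, mk_od(1), MUC, n_axial = 2),
               class = "olfnet_domain_error")
})

test_that("nonabsorbing networks pass everything through", {
  seg <- channel_segment("only", 5e-3, "circular", 1.5e-4,
                         epithelium = "nonabsorbing")
  net <- channel_network(seg, tibble::tibble(from = character(),
                                             to = character()),
                         "only", "only")
  fl <- solve_flow(net, 1e-7, dm_flow_fraction = NULL)
  dep <- propagate_network_uptake(net, fl, mk_od(1e-3), MUC)
  expect_equal(dep$total_absorbed, 0)
  expect_equal(dep$escaped, 1, tolerance = 1e-12)
})

test_that("serial segments compose as 1 - (1-a1)(1-a2)", {
  s1 <- channel_segment("s1", 4e-3, "circular", 1.5e-4,
                        epithelium = "respiratory")
  s2 <- channel_segment("s2", 6e-3, "circular", 1.2e-4,
                        epithelium = "olfactory", axial_start = 4e-3)
  net <- channel_network(dplyr::bind_rows(s1, s2),
                         tibble::tibble(from = "s1", to = "s2"),
                         "s1", "s2", column_groups = list(c1 = "s2"))
  fl <- solve_flow(net, 5e-8, dm_flow_fraction = NULL)
  od <- mk_od(0.05)
  dep <- propagate_network_uptake(net, fl, od, MUC)
  a1 <- solve_channel_uptake(s1, fl$table$velocity[1], od,
                             MUC)$absorbed_fraction
  a2 <- solve_channel_uptake(s2, fl$table$velocity[2], od,
                             MUC)$absorbed_fraction
  expect_equal(dep$total_absorbed, 1 - (1 - a1) * (1 - a2),
               tolerance = 1e-8)
  expect_equal(dep$total_absorbed + dep$escaped, 1, tolerance = 1e-10)
})

test_that("highly soluble odorants deplete anteriorly on the mouse preset", {
  nose <- build_nose(nose_spec("mouse"))
  fl <- solve_flow(nose, 25 / 60 * 1e-6)
  dep <- propagate_network_uptake(nose, fl, mk_od(1e-7), MUC,
                                  n_axial = 100, n_transverse = 32)
  expect_lt(dep$olfactory, dep$respiratory)
  expect_gt(dep$respiratory, 0.9)
})

test_that("flux closes to 1e-8 on randomized networks across solubilities", {
  for (i in 1:50) {
    net <- random_layered_network(i)
    fl <- solve_flow(net, 1e-7, dm_flow_fraction = NULL)
    for (beta in 10^seq(-6, 0, length.out = 5)) {
      dep <- propagate_network_uptake(net, fl, mk_od(beta), MUC,
                                      n_axial = 40, n_transverse = 16)
      expect_equal(dep$total_absorbed + dep$escaped, 1, tolerance = 1e-8)
      expect_equal(dep$respiratory + dep$olfactory + dep$nonabsorbing,
                   dep$total_absorbed, tolerance = 1e-8)
      expect_true(all(dep$per_segment$absorbed_fraction_local >= 0 &
                        dep$per_segment$absorbed_fraction_local <= 1))
    }
  }
})

test_that("solubility sweep is unimodal with an interior olfactory peak", {
  nose <- build_nose(nose_spec("mouse"))
  fl <- solve_flow(nose, 25 / 60 * 1e-6)
  sw <- solubility_sweep(nose, fl, MUC,
                         beta_grid = 10^seq(-10, 0, length.out = 13),
                         n_axial = 100, n_transverse = 32)
  i <- which.max(sw$olfactory_fraction)
  expect_gt(i, 1)
  expect_lt(i, nrow(sw))
  # single interior maximum: non-decreasing then non-increasing
  olf <- sw$olfactory_fraction
  expect_true(all(diff(olf[seq_len(i)]) >= -1e-12))
  expect_true(all(diff(olf[i:length(olf)]) <= 1e-12))
  # total deposition monotone non-increasing in beta
  expect_true(all(diff(sw$total_fraction) <= 1e-9))
})

test_that("a single all-olfactory channel has no interior peak", {
  ch <- make_single_channel(Q = 4e-8, radius = 1.4e-4, length = 7e-3,
                            epithelium = "olfactory")
  sw <- solubility_sweep(ch$network, ch$flow, MUC,
                         beta_grid = 10^seq(-8, 0, length.out = 9),
                         n_axial = 80, n_transverse = 24)
  expect_true(all(diff(sw$olfactory_fraction) <= 1e-12))
})

test_that("the insoluble limit deposits essentially nothing", {
  ch <- make_single_channel(Q = 4e-8, radius = 1.4e-4, length = 7e-3,
                            epithelium = "olfactory")
  od <- mk_od(1e6)
  dep <- propagate_network_uptake(ch$network, ch$flow, od, MUC,
                                  n_axial = 60, n_transverse = 16)
  expect_lt(dep$total_absorbed, 1e-6)
})

test_that("absorption maps close and localize correctly", {
  nose <- build_nose(nose_spec("mouse"))
  fl <- solve_flow(nose, 25 / 60 * 1e-6)
  m <- absorption_map(nose, fl, mk_od(1e-6), MUC, n_bins = 24,
                      n_axial = 100, n_transverse = 32)
  s <- attr(m, "summary")
  expect_equal(sum(m$absorbed), s$total_absorbed, tolerance = 0.01)
  # highly soluble: flux maximum in the anteriormost absorbing bins
  absorbing <- which(m$absorbed > 0)
  expect_lte(which.max(m$flux_per_area), absorbing[2])

  # two-segment decomposition: per-bin totals match per-segment solves
  s1 <- channel_segment("s1", 4e-3, "circular", 1.5e-4,
                        epithelium = "respiratory")
  s2 <- channel_segment("s2", 4e-3, "circular", 1.5e-4,
                        epithelium = "olfactory", axial_start = 4e-3)
  net <- channel_network(dplyr::bind_rows(s1, s2),
                         tibble::tibble(from = "s1", to = "s2"),
                         "s1", "s2", column_groups = list(c1 = "s2"))
  fl2 <- solve_flow(net, 5e-8, dm_flow_fraction = NULL)
  od <- mk_od(0.05)
  m2 <- absorption_map(net, fl2, od, MUC, n_bins = 2,
                       n_axial = 100, n_transverse = 32)
  a1 <- solve_channel_uptake(s1, fl2$table$velocity[1], od, MUC,
                             100, 32)$absorbed_fraction
  a2 <- solve_channel_uptake(s2, fl2$table$velocity[2], od, MUC,
                             100, 32)$absorbed_fraction
  expect_equal(m2$absorbed, c(a1, (1 - a1) * a2), tolerance = 1e-8)
})
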