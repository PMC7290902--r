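# Representative post-calibration thresholds for the default composition
# (close to what calibrate() returns on the reference configuration).
sweep_th <- thresholds(4.75, 1.75)

test_that("a single-point sweep reproduces run_ensemble on the base configuration", {
  pp <- fs_pop(30)
  sw <- sweep_rho_ne_s(pp, fs_game(), sweep_th, grid = pp$rho_NE_S,
                       eta = 5, seed = 11)
  expect_identical(nrow(sw), 1L)
  expect_true(sw$feasible)
  s <- withr::with_seed(11, frustgame:::draw_subseeds(1))
  ens <- run_ensemble(pp, fs_game(), sweep_th, eta = 5, seed = s)
  expect_equal(sw$x_bar, ens$x_bar)
  expect_equal(sw$replicates[[1]], ens$replicates)
})

test_that("infeasible grid points are flagged and skipped, never dropped", {
  pp <- fs_pop(30)
  sw <- sweep_rho_ne_s(pp, fs_game(), sweep_th, grid = c(0.05, 0.20),
                       eta = 2, seed = 1)
  expect_identical(sw$feasible, c(TRUE, FALSE))
  expect_true(is.na(sw$x_bar[2]))
  sw2 <- sweep_rho_ne(pp, fs_game(), sweep_th, grid = c(0.25, 0.30),
                      eta = 2, seed = 1)
  expect_identical(sw2$feasible, c(TRUE, FALSE)) # 0.75 > 1 - 0.30
  sw3 <- sweep_rho_e_s(pp, fs_game(), sweep_th, grid = c(0.5, 0.9),
                       rho_ne_s_variants = 0.05, eta = 2, seed = 1)
  expect_identical(sw3$feasible, c(TRUE, FALSE)) # 0.9 > 1 - 0.188
})

test_that("prevalence falls as unschooled success replaces unschooled failure", {
  pp <- fs_pop(50)
  sw <- sweep_rho_ne_s(pp, fs_game(), sweep_th, grid = c(0, 0.09, 0.188),
                      eta = 20, seed = 13)
  # weakly decreasing, within one combined standard error per increment
  for (i in seq_len(nrow(sw) - 1)) {
    se_comb <- sqrt(sw$x_sd[i]^2 + sw$x_sd[i + 1]^2) / sqrt(sw$eta[i])
    expect_lte(sw$x_bar[i + 1] - sw$x_bar[i], se_comb)
  }
  # the exact oracle shows the same monotone trend, smoothly
  or <- vapply(sw$rho_NE_S, function(r) {
    ppr <- population_params(n = 50, male_fraction = pp$male_fraction,
                             rho_NE = pp$rho_NE, rho_NE_S = r,
                             rho_E_S = pp$rho_E_S)
    exact_prevalence(ppr, fs_game(), sweep_th)$x
  }, numeric(1))
  expect_true(all(diff(or) < 0))
})

test_that("prevalence is non-monotone in student success, with an interior peak", {
  pp <- fs_pop(50)
  grid <- seq(0, 0.812, by = 0.1015)
  # smooth reference curve from the exact oracle: rises then falls
  or <- vapply(grid, function(r) {
    ppr <- population_params(n = 50, male_fraction = pp$male_fraction,
                             rho_NE = pp$rho_NE, rho_NE_S = 0.05, rho_E_S = r)
    exact_prevalence(ppr, fs_game(), sweep_th)$x
  }, numeric(1))
  k <- which.max(or)
  expect_gt(k, 1)
  expect_lt(k, length(grid))
  expect_true(all(diff(or[1:k]) > 0))
  expect_true(all(diff(or[k:length(grid)]) < 0))
  # the stochastic sweep tracks the oracle within Monte-Carlo error
  sw <- sweep_rho_e_s(pp, fs_game(), sweep_th, grid = grid,
                      rho_ne_s_variants = 0.05, eta = 20, seed = 17)
  for (i in seq_along(grid)) {
    se <- sw$x_sd[i] / sqrt(sw$eta[i])
    expect_lt(abs(sw$x_bar[i] - or[i]), 3 * se + 1e-3)
  }
  # both variants place the peak in the same critical region
  am <- sweep_argmax(sweep_rho_e_s(pp, fs_game(), sweep_th, grid = grid,
                                   rho_ne_s_variants = c(0, 0.05),
                                   eta = 20, seed = 19),
                     by = "rho_NE_S")
  expect_identical(nrow(am), 2L)
  expect_lte(abs(am$rho_E_S[1] - am$rho_E_S[2]), 0.1015 + 1e-9)
})

test_that("the factorial grid flags the infeasible region and nests the 1-D sweeps", {
  pp <- fs_pop(30)
  sw <- sweep_grid_3d(pp, fs_game(), sweep_th,
                      grid_ne_s = c(0, 0.05),
                      grid_ne = c(0.1, 0.188),
                      grid_e_s = c(0.2, 0.5, 0.85),
                      eta = 3, seed = 23)
  expect_identical(nrow(sw), 12L)
  expect_identical(sw$feasible,
                   !(sw$rho_E_S > 1 - sw$rho_NE + 1e-9 |
                       sw$rho_NE_S > sw$rho_NE + 1e-9))
  # every feasible point carries a complete ensemble summary
  expect_true(all(!is.na(sw$x_bar[sw$feasible])))
  expect_true(all(is.na(sw$x_bar[!sw$feasible])))
  # all-zero corner: population all holds s, prevalence 0
  pp0 <- population_params(n = 30, rho_NE = 0, rho_NE_S = 0, rho_E_S = 0)
  expect_equal(run_ensemble(pp0, fs_game(), sweep_th, eta = 2, seed = 1)$x_bar, 0)
  # per-slice argmax is reported for each (rho_NE_S, rho_NE) slice
  am <- sweep_argmax(sw, by = c("rho_NE_S", "rho_NE"))
  expect_identical(nrow(am), 4L)
})
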