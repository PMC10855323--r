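# Ground-truth generators: determinism, elastic limit, round-trip recovery.

test_that("elastic noise-free curves match the Hertz closed form", {
  sp <- quick_spec(params = plr_params(2500, 0, 0), noise_nN = 0, seed = 1)
  cv <- simulate_curve(sp)
  tr <- attr(cv, "truth")
  app <- tr$i_contact:cv$i_turn
  pred <- hertz_force(tr$delta_nm[app], 2500)
  expect_lt(max(abs(pred - tr$force_clean_nN[app])), 2e-3)
})

test_that("generated curves embed full provenance", {
  sp <- quick_spec(params = plr_params(4000, 0.15, 0), seed = 77)
  cv <- simulate_curve(sp)
  tr <- attr(cv, "truth")
  expect_equal(tr$spec$seed, 77)
  expect_equal(tr$z0_nm, sp$contact_z_nm)
  expect_equal(length(tr$delta_nm), length(cv$t_s))
  expect_gt(max(tr$delta_nm), 0)
})

test_that("simulate then fit round-trips the PLR parameters", {
  sp <- quick_spec(params = plr_params(5000, 0.2, 0), noise_nN = 0, seed = 8)
  fit <- fit_ting(simulate_curve(sp))
  expect_lt(abs(fit$params$E1 / 5000 - 1), 0.01)
  expect_lt(abs(fit$params$alpha - 0.2), 0.01)
})

test_that("cell map geometry drives thickness and mask", {
  map <- simulate_cell_map(grid = 10, fov_um = 25, apex_um = 2.5,
                           base_radius_um = 8,
                           mechanics = list(ym_kpa = 3, alpha = 0.1),
                           noise_nN = 0, seed = 5, rate_hz = 10000)
  th <- map$truth$thickness_um
  # pixel centres straddle the apex, so the sampled maximum sits slightly
  # below the nominal apex height
  expect_lte(max(th), 2.5)
  expect_gt(max(th), 2.5 - 0.15)
  expect_true(all(th >= 0))
  # cap is radially decreasing from the centre
  centre <- which(th == max(th), arr.ind = TRUE)[1, ]
  expect_true(th[centre[1], 1] < max(th))
  expect_equal(sum(map$truth$mask), sum(th > 0))
  # determinism
  m2 <- simulate_cell_map(grid = 10, fov_um = 25, apex_um = 2.5,
                          base_radius_um = 8,
                          mechanics = list(ym_kpa = 3, alpha = 0.1),
                          noise_nN = 0, seed = 5, rate_hz = 10000)
  expect_identical(map$curves[[45]]$force_nN, m2$curves[[45]]$force_nN)
})

test_that("cap must fit the field of view", {
  expect_error(simulate_cell_map(grid = 8, fov_um = 10, apex_um = 3,
                                 base_radius_um = 12),
               class = "domainError")
})

test_that("cohort generator draws admissible parameters with provenance", {
  pa <- cohort_preset("a", 2.8, 1.09, cells = 3, grid = 8, fov_um = 20,
                      base_radius_um = 6)
  pb <- cohort_preset("b", 6.92, 2.87, alpha_mean = 0.15, apex_um = 2.6,
                      cells = 3, grid = 8, fov_um = 20, base_radius_um = 6)
  coh <- simulate_cohort(pa, pb, seed = 2, rate_hz = 10000)
  expect_length(coh, 6)
  dr <- attr(coh, "draws")
  expect_equal(dr$label, rep(c("a", "b"), each = 3))
  expect_true(all(dr$ym_kpa > 0))
  expect_true(all(dr$alpha >= 0.02 & dr$alpha <= 0.8))
  # determinism of the whole cohort
  coh2 <- simulate_cohort(pa, pb, seed = 2, rate_hz = 10000)
  expect_identical(attr(coh2, "draws")$ym_kpa, dr$ym_kpa)
  pc <- pa
  pc$cells <- 1
  expect_error(simulate_cohort(pc, pb), class = "domainError")
})

test_that("packaged presets load and carry the published moduli", {
  pres <- load_cohort_presets()
  expect_true(all(c("m1_control", "m1_pma", "m2_control", "m2_pma") %in%
                    names(pres)))
  expect_equal(pres$m1_control$ym_mean_kpa, 2.8)
  expect_equal(pres$m1_control$ym_sd_kpa, 1.09)
  expect_equal(pres$m1_pma$ym_mean_kpa, 6.92)
  expect_equal(pres$m1_pma$ym_sd_kpa, 2.87)
  # activated apex heights encode the printed 1.53x / 1.69x flattening
  expect_equal(pres$m1_control$apex_um / pres$m1_pma$apex_um, 1.53,
               tolerance = 0.001)
  expect_equal(pres$m2_control$apex_um / pres$m2_pma$apex_um, 1.69,
               tolerance = 0.001)
  expect_error(load_cohort_presets("no/such/file.yaml"),
               class = "configError")
})

test_that("kinetics generator is deterministic with analytic truth", {
  a <- simulate_kinetics_trace(noise_sd = 5, seed = 3)
  b <- simulate_kinetics_trace(noise_sd = 5, seed = 3)
  expect_identical(a$signal, b$signal)
  expect_error(simulate_kinetics_trace(amplitude = -1), class = "domainError")
  expect_error(simulate_kinetics_trace(t_act_s = 4000),
               class = "domainError")
})
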