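# Topography, tilt correction, central-part filtering and aggregation.

test_that("central_part_filter retains exactly the top half", {
  # 1024 distinct heights -> 512 retained, all retained >= all discarded
  set.seed(4)
  h <- sample(seq_len(1024))
  keep <- central_part_filter(h)
  expect_equal(sum(keep), 512)
  expect_gte(min(h[keep]), max(h[!keep]))

  # tie rule: equal heights, lower index wins
  keep2 <- central_part_filter(c(5, 5))
  expect_identical(keep2, c(TRUE, FALSE))

  # ceiling(n/2) for every n (property over random sizes)
  set.seed(7)
  for (n in sample(2:400, 25)) {
    k <- central_part_filter(rnorm(n))
    expect_equal(sum(k), ceiling(n / 2))
  }
  expect_error(central_part_filter(3), class = "emptyCellError")
})

test_that("central_part_filter is permutation-consistent on matrices", {
  set.seed(12)
  h <- matrix(runif(64), 8, 8)
  mask <- matrix(FALSE, 8, 8)
  mask[3:6, 3:6] <- TRUE
  keep <- central_part_filter(h, mask)
  expect_equal(sum(keep), ceiling(sum(mask) / 2))
  expect_true(all(!keep[!mask]))
  expect_gte(min(h[keep]), max(h[mask & !keep]))
  expect_error(central_part_filter(h, matrix(FALSE, 8, 8)),
               class = "emptyCellError")
})

test_that("correct_tilt removes an added plane to machine precision", {
  set.seed(2)
  flat <- matrix(0.02, 16, 16) + 1e-4 * matrix(rnorm(256), 16)
  rr <- matrix(seq_len(16), 16, 16)
  cc <- t(rr)
  tilted <- flat + 0.01 * rr + 0.02 * cc
  all_sub <- matrix(TRUE, 16, 16)
  fixed <- correct_tilt(tilted, substrate = all_sub)
  ref <- correct_tilt(flat, substrate = all_sub)
  expect_equal(unclass(fixed), unclass(ref), tolerance = 1e-9)
  # idempotence on an already-flat map
  again <- correct_tilt(fixed, substrate = all_sub)
  expect_equal(unclass(again), unclass(fixed), tolerance = 1e-9)
  # too few substrate pixels: skipped with warning, map unchanged
  few <- matrix(FALSE, 16, 16)
  few[1, 1:2] <- TRUE
  expect_warning(out <- correct_tilt(tilted, substrate = few))
  expect_equal(out, tilted)
})

test_that("topography reconstruction recovers a spherical-cap phantom", {
  map <- simulate_cell_map(grid = 12, fov_um = 30, apex_um = 3,
                           base_radius_um = 9,
                           mechanics = list(ym_kpa = 3, alpha = 0),
                           noise_nN = 0, seed = 21, rate_hz = 10000)
  h <- correct_tilt(reconstruct_topography(map))
  truth <- map$truth$height_um
  # apex within 2 z-grid steps (z step = speed / rate = 18.3 nm)
  zstep_um <- 183000 / 10000 / 1000
  expect_lt(abs(max(h, na.rm = TRUE) - max(truth)), 2 * zstep_um)
  # substrate flat near 0
  expect_lt(median(abs(h[map$truth$thickness_um == 0]), na.rm = TRUE),
            2 * zstep_um)
})

test_that("tilted phantom recovers the untilted apex after correction", {
  m0 <- simulate_cell_map(grid = 12, fov_um = 30, apex_um = 3,
                          base_radius_um = 9,
                          mechanics = list(ym_kpa = 3, alpha = 0),
                          noise_nN = 0, seed = 22, rate_hz = 10000)
  m1 <- simulate_cell_map(grid = 12, fov_um = 30, apex_um = 3,
                          base_radius_um = 9,
                          mechanics = list(ym_kpa = 3, alpha = 0),
                          tilt_nm_per_um = c(12, -8),
                          noise_nN = 0, seed = 22, rate_hz = 10000)
  sub <- m0$truth$thickness_um == 0
  h0 <- correct_tilt(reconstruct_topography(m0), substrate = sub)
  h1 <- correct_tilt(reconstruct_topography(m1), substrate = sub)
  expect_equal(max(h1, na.rm = TRUE), max(h0, na.rm = TRUE),
               tolerance = 0.01)
})

test_that("substrate-only map reconstructs to zero and yields no cell", {
  map <- simulate_cell_map(grid = 8, fov_um = 20, apex_um = 0,
                           noise_nN = 0, seed = 3, rate_hz = 10000)
  h <- reconstruct_topography(map)
  expect_lt(max(abs(h), na.rm = TRUE), 0.05)
  expect_false(any(derive_cell_mask(h)))
})

test_that("aggregate_cell means retained pixels and reports the apex", {
  map <- simulate_cell_map(grid = 12, fov_um = 30, apex_um = 3,
                           base_radius_um = 9,
                           mechanics = list(ym_kpa = 3, alpha = 0),
                           noise_nN = 0.02, seed = 31, rate_hz = 10000)
  map <- fit_map(map, model = "hertz")
  rec <- aggregate_cell(map, cell_id = 7, condition = "test")
  expect_equal(rec$cell_id, 7)
  expect_equal(rec$condition, "test")
  expect_equal(rec$height_um, 3, tolerance = 0.05)
  expect_equal(rec$ym_kpa, 3, tolerance = 0.15)
  expect_gte(rec$n_pixels, 2)
  # restriction consistency: the record mean equals the mean over the
  # retained ok pixels recomputed by hand
  keep <- central_part_filter(map$height_um, map$mask)
  sel <- keep[cbind(map$fits$row, map$fits$col)] & map$fits$status == "ok"
  expect_equal(rec$ym_kpa, mean(map$fits$ym_pa[sel]) / 1000)
})

test_that("grid smaller than 8x8 is rejected", {
  expect_error(simulate_cell_map(grid = 6), class = "domainError")
})

test_that("cohort_summary computes group stats and oriented folds", {
  rec <- data.frame(
    cell_id = 1:8,
    condition = rep(c("ctrl", "act"), each = 4),
    ym_kpa = c(2, 2, 2, 2, 4, 4, 4, 4),
    height_um = c(4, 4, 4, 4, 2, 2, 2, 2),
    alpha = c(0.3, 0.3, 0.3, 0.3, 0.15, 0.15, 0.15, 0.15))
  s <- cohort_summary(rec, control = "ctrl", activated = "act",
                      variables = c("ym_kpa", "height_um", "alpha"))
  f <- setNames(s$folds$fold, s$folds$variable)
  expect_equal(f[["ym_kpa"]], 2)      # activated / control
  expect_equal(f[["height_um"]], 2)   # control / activated (fold decrease)
  expect_equal(f[["alpha"]], 2)
  # identical groups -> fold 1; swapping labels inverts the modulus fold
  rec2 <- rec
  rec2$ym_kpa <- 3
  s2 <- cohort_summary(rec2, "ctrl", "act", variables = "ym_kpa")
  expect_equal(s2$folds$fold, 1)
  s3 <- cohort_summary(rec, control = "act", activated = "ctrl",
                       variables = "ym_kpa")
  expect_equal(s3$folds$fold, 1 / f[["ym_kpa"]])
  # unit-scale invariance
  rec4 <- rec
  rec4$ym_kpa <- rec4$ym_kpa * 1000
  s4 <- cohort_summary(rec4, "ctrl", "act", variables = "ym_kpa")
  expect_equal(s4$folds$fold, f[["ym_kpa"]])
  # small group dropped with warning
  rec5 <- rbind(rec, data.frame(cell_id = 9, condition = "x", ym_kpa = 1,
                                height_um = 1, alpha = 0.2))
  expect_warning(cohort_summary(rec5, "ctrl", "act"))
})
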