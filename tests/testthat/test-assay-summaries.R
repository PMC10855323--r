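# Kinetics AUC, DNA normalization, z-standardization, phagocytic metrics.

test_that("kinetics_auc integrates baseline-subtracted signal", {
  tt <- seq(0, 1000, by = 5)
  zero <- data.frame(time_s = tt, signal = rep(0, length(tt)))
  expect_equal(kinetics_auc(zero, t_end = 900, t_act = 100), 0)

  # constant signal c over window T gives c * T (rectangle), baseline 0
  const <- data.frame(time_s = tt, signal = rep(3, length(tt)))
  expect_equal(suppressWarnings(kinetics_auc(const, 700, t_act = 200)),
               0, tolerance = 1e-9) # baseline = 3 is subtracted
  # with a genuine pre-activation baseline of 0 and step to c at t_act
  step <- data.frame(time_s = tt, signal = ifelse(tt >= 200, 3, 0))
  expect_equal(suppressWarnings(kinetics_auc(step, 700, t_act = 200)),
               3 * 500, tolerance = 0.02)

  # invariant to constant shifts (baseline-subtracted contract)
  tr <- simulate_kinetics_trace(noise_sd = 0, seed = 1)
  a1 <- kinetics_auc(tr, 3000)
  tr2 <- tr
  tr2$signal <- tr2$signal + 123
  attr(tr2, "t_act_s") <- attr(tr, "t_act_s")
  expect_equal(kinetics_auc(tr2, 3000), a1, tolerance = 1e-8)

  # window monotonicity and domain errors
  mid <- kinetics_auc(tr, 1500)
  expect_gt(a1, mid)
  expect_error(kinetics_auc(tr, 200), class = "domainError")
  expect_error(kinetics_auc(tr, 1e6), class = "domainError")
})

test_that("kinetics_auc matches the closed-form burst integral", {
  for (amp in c(400, 1100)) {
    tr <- simulate_kinetics_trace(duration_s = 3600, dt_s = 2, t_act_s = 300,
                                  peak_time_s = 700, amplitude = amp,
                                  width = 0.5, baseline = 80, noise_sd = 0,
                                  seed = 3)
    truth <- attr(tr, "truth")
    expect_equal(kinetics_auc(tr, 3600), truth$auc(3600),
                 tolerance = 5e-3)
  }
  # linearity of the analytic ground truth in amplitude
  t1 <- attr(simulate_kinetics_trace(amplitude = 100), "truth")
  t2 <- attr(simulate_kinetics_trace(amplitude = 200), "truth")
  expect_equal(2 * t1$auc(3000), t2$auc(3000))
  expect_equal(attr(simulate_kinetics_trace(amplitude = 0), "truth")$auc(3000), 0)
})

test_that("dna_normalize scales inversely with DNA", {
  expect_equal(dna_normalize(c(10, 20), c(5, 5)), c(2, 4))
  expect_equal(dna_normalize(c(6, 6), c(2, 1)), c(3, 6))
  expect_warning(out <- dna_normalize(c(1, 2), c(4, 0)))
  expect_true(is.na(out[2]) && out[1] == 0.25)
})

test_that("zscore_standardize gives exact per-row mean 0 / sd 1", {
  expect_equal(as.numeric(zscore_standardize(matrix(c(1, 2, 3), 1))),
               c(-1, 0, 1))
  set.seed(11)
  m <- matrix(rnorm(16, 50, 9), 4)
  zz <- zscore_standardize(m)
  # brute-force independent computation
  ref <- t(apply(m, 1, function(r) (r - mean(r)) / sd(r)))
  expect_equal(zz, ref, ignore_attr = TRUE)
  expect_equal(unname(rowMeans(zz)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(zz, 1, sd)), rep(1, 4), tolerance = 1e-12)
  # idempotent and location/scale invariant per row
  expect_equal(zscore_standardize(zz), zz, ignore_attr = TRUE)
  expect_equal(zscore_standardize(3 * m + 7), zz, ignore_attr = TRUE)
  # constant row -> NA with warning
  expect_warning(z2 <- zscore_standardize(rbind(c(1, 1, 1), c(1, 2, 3))))
  expect_true(all(is.na(z2[1, ])) && !anyNA(z2[2, ]))
})

test_that("phagocytic_metrics gates against the control distribution", {
  # half the events at value v above the gate -> affinity 50, capacity v
  x <- c(rep(10, 200), rep(500, 200))
  ctrl <- rep(10, 1000) + seq(0, 1, length.out = 1000)
  pm <- phagocytic_metrics(x, ctrl)
  expect_equal(pm$affinity_pct, 50)
  expect_equal(pm$capacity_mfi, 500)

  # all below threshold
  pm0 <- phagocytic_metrics(rep(5, 300), ctrl)
  expect_equal(pm0$affinity_pct, 0)
  expect_true(is.na(pm0$capacity_mfi))

  # simulated mixture: affinity within the 99% binomial interval
  n <- 10000
  s <- simulate_cytometry_sample(n, 100, 3000, positive_fraction = 0.7,
                                 seed = 5)
  ctrl2 <- simulate_cytometry_sample(5000, 100, 3000, positive_fraction = 0,
                                     seed = 6)
  pm2 <- phagocytic_metrics(s, ctrl2)
  ci <- qbinom(c(0.005, 0.995), n, 0.7) / n * 100
  expect_gte(pm2$affinity_pct, ci[1])
  expect_lte(pm2$affinity_pct, ci[2])
  # capacity tracks the positive mode median
  expect_equal(pm2$capacity_mfi, 3000, tolerance = 0.05)

  # affinity invariant under monotone transforms fixing the gate quantile
  pm3 <- phagocytic_metrics(sqrt(as.numeric(s)), threshold = sqrt(pm2$threshold))
  expect_equal(pm3$affinity_pct, pm2$affinity_pct)

  expect_error(phagocytic_metrics(rep(1, 50), ctrl), class = "domainError")
  expect_error(phagocytic_metrics(x), class = "configError")
})

test_that("cytometry generator is seeded and flags overlapping modes", {
  a <- simulate_cytometry_sample(500, seed = 9)
  b <- simulate_cytometry_sample(500, seed = 9)
  expect_identical(as.numeric(a), as.numeric(b))
  expect_warning(simulate_cytometry_sample(500, 100, 110, 0.5, seed = 1))
  tr <- attr(simulate_cytometry_sample(500, positive_fraction = 0, seed = 2),
             "truth")
  expect_equal(tr$positive_fraction, 0)
})
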