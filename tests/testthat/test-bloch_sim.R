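test_that("water-only simulation reproduces the no-saturation and on-resonance limits", {
  w <- cest_pool("water", 1, 0, 0, R1s = 0.5, R2s = 25)
  acq0 <- cest_acquisition(b1_uT = 0)
  z0 <- simulate_zspectrum(pool_set(w), acq0)
  # with the RF off, magnetization stays at equilibrium everywhere
  expect_equal(z0$values, rep(1, length(acq0$offsets)), tolerance = 1e-10)
  z1 <- simulate_zspectrum(pool_set(w), default_acq)
  expect_lt(z1$values[default_acq$offsets == 0], 0.05)
})

test_that("two-pool steady spectrum matches the closed-form inverse sum", {
  acq <- default_acq
  ps <- two_pool_set()
  z <- simulate_zspectrum(ps, acq)
  tis <- cest_tissue(R1obs = ps$water$R1s, R1w = ps$water$R1s,
                     R2w = ps$water$R2s, fm = 0, r_MT = 0)
  analytic <- tis$R1obs *
    cestsynth:::sat_angle_terms(acq$omega1, acq$offsets)$cos2 /
    (reff(tis, acq$omega1, acq$offsets) +
       rex_slow(ps$solutes$amide, acq$omega1, acq$offsets))
  sel <- abs(acq$offsets) >= 2
  expect_lt(max(abs(z$values[sel] - analytic[sel]) / analytic[sel]), 0.01)
})

test_that("a pool set mirrored about water yields a symmetric Z-spectrum", {
  w <- cest_pool("water", 1, 0, 0, R1s = 0.5, R2s = 25)
  ps <- pool_set(w,
                 cest_pool("up", 2e-3, 40, 3.0, R2s = 50),
                 cest_pool("down", 2e-3, 40, -3.0, R2s = 50))
  grid <- seq(-6, 6, by = 0.25)
  acq <- cest_acquisition(offsets = grid)
  z <- simulate_zspectrum(ps, acq)
  expect_equal(z$values, rev(z$values), tolerance = 1e-8)
})

test_that("transient mode converges to the steady state", {
  ps <- two_pool_set()
  zs <- simulate_zspectrum(ps, default_acq, "steady")
  zt <- simulate_zspectrum(ps, cest_acquisition(t_sat = 50), "transient")
  expect_lt(max(abs(zt$values - zs$values)), 1e-6)
  # a short saturation leaves the slow CEST effect under-developed, so the
  # amide-resonance signal is still above its steady-state value
  zshort <- simulate_zspectrum(ps, cest_acquisition(t_sat = 0.2),
                               "transient")
  i0 <- which(default_acq$offsets == 3.5)
  expect_gt(zshort$values[i0], zs$values[i0])
})

test_that("ground-truth APT spectrum behaves with amide pool size", {
  acq <- default_acq
  base <- function(fs) {
    w <- cest_pool("water", 1, 0, 0, R1s = 0.5, R2s = 25)
    if (fs > 0)
      pool_set(w, cest_pool("amide", fs, 60, 3.5, R2s = 50),
               cest_pool("noe35", 8e-3, 30, -3.5, R2s = 1500))
    else
      pool_set(w, cest_pool("amide", 0, 60, 3.5, R2s = 50),
               cest_pool("noe35", 8e-3, 30, -3.5, R2s = 1500))
  }
  g0 <- ground_truth_apt(base(0), acq)
  expect_equal(g0$spectrum, rep(0, length(acq$offsets)), tolerance = 1e-10)
  expect_equal(g0$A_true, 0)
  fs <- c(0.5e-3, 1e-3, 2e-3)
  As <- vapply(fs, function(f) ground_truth_apt(base(f), acq)$A_true,
               numeric(1))
  expect_true(all(diff(As) > 0))   # A_true strictly increasing in fs
  # peak of the ground-truth spectrum lies within one grid step of 3.5 ppm
  g <- ground_truth_apt(base(1e-3), acq)
  expect_lte(abs(acq$offsets[which.max(g$spectrum)] - 3.5), 0.125)
  expect_gt(g$W_true, 0)
  expect_error(ground_truth_apt(pool_set(cest_pool("water", 1, 0, 0,
                                                   R1s = 0.5, R2s = 25)),
                                acq),
               "no 'amide' pool")
})

test_that("tissue-mimicking sampling is seeded and respects its ranges", {
  r <- default_pool_ranges()
  # degenerate ranges give a deterministic record
  rd <- rapply(r, function(x) if (length(x) == 2) mean(x) else x,
               how = "replace")
  a <- sample_tissue_mimicking(rd, n = 1, seed = 5)
  b <- sample_tissue_mimicking(rd, n = 1, seed = 99)
  expect_identical(a[[1]]$z$values, b[[1]]$z$values)
  # same seed -> bit-identical; different seed -> different draws
  s1 <- sample_tissue_mimicking(r, n = 2, seed = 7)
  s2 <- sample_tissue_mimicking(r, n = 2, seed = 7)
  s3 <- sample_tissue_mimicking(r, n = 2, seed = 8)
  expect_identical(s1[[2]]$z$values, s2[[2]]$z$values)
  expect_false(identical(s1[[1]]$z$values, s3[[1]]$z$values))
  expect_error(draw_parameters(list(), 3), "empty")
})

test_that("all drawn parameters fall inside their configured ranges", {
  r <- default_pool_ranges()
  draws <- draw_parameters(r, 1000, seed = 21)
  flat <- function(x) unlist(x)
  lo <- rapply(r, function(x) x[1], how = "unlist")
  hi <- rapply(r, function(x) x[length(x)], how = "unlist")
  vals <- sapply(draws, flat)
  expect_true(all(vals >= lo & vals <= hi))
  # coverage: the empirical span of each varied parameter fills >= 95%
  varied <- hi > lo
  span <- (apply(vals, 1, max) - apply(vals, 1, min))[varied]
  expect_true(all(span / (hi - lo)[varied] >= 0.95))
})
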