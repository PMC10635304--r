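test_that("partial synthetic records are self-consistent and well targeted", {
  mc <- measured_from_simulation()$mc
  ts <- build_partial_synthetic(mc, n = 40, seed = 3)
  off <- attr(ts, "offsets")
  for (r in ts[1:10]) {
    # CESTR recomputed from the stored label/reference pair is the truth
    expect_equal(cestr(r$z_ref, r$features), r$truth_full,
                 tolerance = 1e-14)
    # amplitude target is the spectrum maximum within one grid step of 3.5
    i_max <- which.max(r$truth_full)
    expect_lte(abs(off[i_max] - 3.5), 0.125)
    expect_equal(r$target_A, r$truth_full[off == 3.5])
    expect_gt(r$target_W, 0)
    # stored truth window covers 2-5 ppm
    expect_equal(range(r$truth_offsets), c(2, 5))
  }
})

test_that("a zero-amide range produces zero truth spectra", {
  mc <- measured_from_simulation()$mc
  rg <- default_synth_ranges()
  rg$amide$fs <- c(0, 0)
  ts <- build_partial_synthetic(mc, rg, n = 5, seed = 4)
  for (r in ts) {
    expect_equal(r$truth_full, rep(0, length(r$truth_full)),
                 tolerance = 1e-14)
    expect_equal(r$target_A, 0)
  }
})

test_that("increasing the MT scaling lowers the composed signal at -10 ppm", {
  mc <- measured_from_simulation()$mc
  rg <- default_synth_ranges()
  rg <- rapply(rg, function(x) if (length(x) == 2) mean(x) else x,
               how = "replace")
  s_at_m10 <- sapply(c(0.5, 1, 2, 3), function(rmt) {
    rg$r_MT <- rmt
    ts <- build_partial_synthetic(mc, rg, n = 1, seed = 5)
    ts[[1]]$features[attr(ts, "offsets") == -10]
  })
  expect_true(all(diff(s_at_m10) < 0))
})

test_that("fully synthetic variants follow their size and tying rules", {
  rg <- default_full_synth_ranges()
  rg$r_amines <- c(1, 1)           # pin the scaling to check the tying rule
  t1 <- build_fully_synthetic(rg, n = 3, seed = 6, variant = "type1")
  expect_length(t1, 3)
  for (r in t1)
    expect_equal(r$gen_params$amine$fs, 0.003 * r$gen_params$r_amines)
  t2 <- build_fully_synthetic(rg, n = 3, seed = 6, variant = "type2")
  expect_length(t2, 9)             # three times the type-1 size
  # the extra type-2 draws differ only in guanidinium pool size
  expect_equal(t2[[4]]$gen_params$amide, t2[[1]]$gen_params$amide)
  expect_false(t2[[4]]$gen_params$guanidinium$fs ==
                 t2[[1]]$gen_params$guanidinium$fs)
  # amide fs = 0 draw gives a zero target
  rg0 <- rg
  rg0$amide$fs <- c(0, 0)
  t0 <- build_fully_synthetic(rg0, n = 1, seed = 6)
  expect_lt(abs(t0[[1]]$target_A), 1e-10)
})

test_that("noise injection is seeded, sized and target-preserving", {
  mc <- measured_from_simulation()$mc
  ts <- build_partial_synthetic(mc, n = 120, seed = 8)
  expect_identical(add_noise(ts, 0), ts)                  # sd = 0 no-op
  n1 <- add_noise(ts, 0.01, seed = 9)
  n2 <- add_noise(ts, 0.01, seed = 9)
  expect_identical(n1[[5]]$features, n2[[5]]$features)    # same seed
  # injected noise has the right empirical sd over >= 1e4 points
  resid <- unlist(lapply(seq_along(ts), function(i)
    n1[[i]]$features - ts[[i]]$features))
  expect_gte(length(resid), 1e4)
  expect_true(sd(resid) > 0.009 && sd(resid) < 0.011)
  # targets untouched
  expect_equal(n1[[7]]$target_A, ts[[7]]$target_A)
})

test_that("pair averaging produces k(k-1)/2 means alongside the originals", {
  a <- zspectrum(1:5 / 10, rep(0.5, 5))
  b <- zspectrum(1:5 / 10, rep(0.7, 5))
  out <- augment_pair_average(list(a, b))
  expect_length(out$averages, 1)
  expect_equal(out$averages[[1]], rep(0.6, 5))
  # averaging a spectrum with itself returns it unchanged
  self <- augment_pair_average(list(a, a))
  expect_equal(self$averages[[1]], a$values)
  out4 <- augment_pair_average(list(a$values, b$values, a$values + 0.1,
                                    b$values - 0.1))
  expect_length(out4$averages, pair_average_count(4))
  expect_error(augment_pair_average(list(a)), "at least 2")
  expect_error(augment_pair_average(list(a, zspectrum(1:4 / 10,
                                                      rep(0.5, 4)))),
               "grid")
})

test_that("coverage of varied parameters spans the configured ranges", {
  rg <- default_synth_ranges()
  draws <- draw_parameters(rg, 1000, seed = 10)
  lo <- rapply(rg, function(x) x[1], how = "unlist")
  hi <- rapply(rg, function(x) x[length(x)], how = "unlist")
  vals <- sapply(draws, unlist)
  varied <- hi > lo
  span <- (apply(vals, 1, max) - apply(vals, 1, min))[varied]
  expect_true(all(span / (hi - lo)[varied] >= 0.95))
})
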