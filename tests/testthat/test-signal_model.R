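test_that("lorentzian line has its nominal amplitude, half-maximum and limits", {
  off <- c(3.5, 4.5, 0)
  l <- lorentzian_line(0.05, 2, 3.5, off)
  expect_equal(l[1], 0.05)          # peak value at the center
  expect_equal(l[2], 0.025)         # half maximum at center + W/2
  expect_equal(lorentzian_line(0, 2, 3.5, off), rep(0, 3))
  expect_error(lorentzian_line(0.05, 0, 3.5, off), "W must be")
})

test_that("rex_slow evaluates the slow-exchange closed form", {
  off <- default_acq$offsets
  w1 <- default_acq$omega1
  p <- test_amide(fs = 1e-3, ksw = 50, R2s = 30)
  r <- rex_slow(p, w1, off)
  # zero pool size gives a zero spectrum
  p0 <- test_amide(fs = 0)
  expect_equal(rex_slow(p0, w1, off), rep(0, length(off)))
  # peak sits exactly at the pool offset on a grid containing it
  expect_equal(off[which.max(r)], 3.5)
  # on-resonance value reduces to fs ksw w1^2 / (w1^2 + (R2s+ksw) ksw)
  on_res <- 1e-3 * 50 * w1^2 / (w1^2 + (30 + 50) * 50)
  expect_equal(r[off == 3.5], on_res, tolerance = 1e-12)
  expect_error(rex_slow(p, -1, off), "omega1")
})

test_that("rex_slow peak agrees with a two-pool Bloch-McConnell AREX oracle", {
  # numerical oracle: AREX from simulated label/reference pair
  acq <- default_acq
  ps <- two_pool_set(fs = 1e-3, ksw = 50, R2s = 30)
  z_lab <- simulate_zspectrum(ps, acq)
  z_ref <- simulate_zspectrum(pool_set(ps$water), acq)
  R1obs <- ps$water$R1s
  ax <- arex(z_ref$values, z_lab$values, R1obs, fm = 0)
  i <- which(acq$offsets == 3.5)
  rex <- rex_slow(ps$solutes$amide, acq$omega1, acq$offsets)
  expect_lt(abs(ax[i] - rex[i]) / rex[i], 0.05)
})

test_that("reff recovers its limiting values", {
  tis <- test_tissue()
  w1 <- default_acq$omega1
  # far from water the effective rate tends to R1obs
  expect_equal(reff(tis, w1, 250), tis$R1obs, tolerance = 1e-5)
  # on resonance it is R2w
  expect_equal(reff(tis, w1, 0), tis$R2w)
  # at dw = omega1 (rad/s) it is the mean of the two rates
  off45 <- w1 / (2 * pi * 400)
  expect_equal(reff(tis, w1, off45), (tis$R1obs + tis$R2w) / 2)
})

test_that("r1obs_from_components is a pool-size weighted mean", {
  expect_equal(r1obs_from_components(0.55, 1, 0, 1), 0.55)
  expect_equal(r1obs_from_components(0.55, 1, 0.1, 0), 0.55)
  expect_equal(r1obs_from_components(0.7, 0.7, 0.12, 2.3), 0.7)
  expect_equal(r1obs_from_components(0.5, 1, 0.1, 1), (0.5 + 0.1) / 1.1)
})

test_that("composition reduces to pure direct saturation with empty pools", {
  off <- default_acq$offsets
  w1 <- default_acq$omega1
  tis <- cest_tissue(R1w = 0.55, R2w = 25, fm = 0.09,
                     r_amines = 0, r_MT = 0)
  comps <- list(Reff = reff(tis, w1, off))
  z <- compose_zspectrum(comps, tis, w1, off)
  th <- cestsynth:::sat_angle_terms(w1, off)
  expect_equal(z$values, tis$R1obs * th$cos2 / comps$Reff, tolerance = 1e-12)
  # at a far control offset the composed signal approaches 1
  zc <- compose_zspectrum(list(Reff = reff(tis, w1, 250)), tis, w1, 250)
  expect_equal(zc$values, 1, tolerance = 1e-4)
  # unphysical (zero) denominator is an error, not a clipped value
  expect_error(compose_zspectrum(list(Reff = rep(0, length(off))), tis, w1,
                                 off),
               "denominator")
})

test_that("composition is monotone in added exchange components", {
  off <- default_acq$offsets
  w1 <- default_acq$omega1
  tis <- test_tissue()
  base <- list(Reff = reff(tis, w1, off))
  rex <- rex_slow(test_amide(), w1, off)
  z0 <- compose_zspectrum(base, tis, w1, off)
  z1 <- compose_zspectrum(c(base, list(Rex_apt = rex)), tis, w1, off)
  # the composed signal vanishes exactly on resonance (cos^2 theta = 0)
  pos <- rex > 1e-12 & off != 0
  expect_true(all(z1$values[pos] < z0$values[pos]))
  expect_true(all(z0$values >= 0 & z0$values <= 1))
  expect_equal(z0$values[off == 0], 0)
})

test_that("label/reference AREX of a composed pair returns the APT input exactly", {
  # algebraic identity: AREX = Rex_apt (1+fm) / ((1+r_MT fm) cos^2 theta)
  off <- default_acq$offsets
  w1 <- default_acq$omega1
  tis <- test_tissue(r_amines = 1.3, r_MT = 0.8)
  rex_apt <- rex_slow(test_amide(), w1, off)
  comps <- list(Reff = reff(tis, w1, off),
                Rex_noe = rex_slow(cest_pool("noe", 5e-3, 30, -3.5,
                                             R2s = 1000), w1, off),
                Rex_apt = rex_apt)
  z_lab <- compose_zspectrum(comps, tis, w1, off)
  comps$Rex_apt <- NULL
  z_ref <- compose_zspectrum(comps, tis, w1, off)
  keep <- off != 0                 # signal is exactly 0 on resonance
  ax <- arex(z_ref$values[keep], z_lab$values[keep], tis$R1obs, tis$fm)
  th <- cestsynth:::sat_angle_terms(w1, off[keep])
  expected <- rex_apt[keep] * (1 + tis$fm) /
    ((1 + tis$r_MT * tis$fm) * th$cos2)
  expect_equal(ax, expected, tolerance = 1e-12)
  # AREX refuses the on-resonance zero rather than dividing by it
  expect_error(arex(z_ref$values, z_lab$values, tis$R1obs, tis$fm), "zero")
})

test_that("cestr and arex implement their defining arithmetic", {
  expect_equal(cestr(0.60, 0.55), 0.05)
  expect_equal(cestr(c(0.6, 0.7), c(0.6, 0.7)), c(0, 0))
  expect_error(cestr(c(0.6, 0.7), 0.6), "grid")
  expect_equal(arex(0.55, 0.5, 0.6, 0.1), 0.6 * 1.1 * (2 - 1 / 0.55))
  expect_equal(arex(0.5, 0.5, 0.6, 0.1), 0)
  expect_error(arex(0.5, 0, 0.6, 0.1), "zero")
})

test_that("transient signal interpolates between no saturation and steady state", {
  off <- default_acq$offsets
  w1 <- default_acq$omega1
  tis <- test_tissue()
  comps <- list(Reff = reff(tis, w1, off),
                Rex_apt = rex_slow(test_amide(), w1, off))
  z <- compose_zspectrum(comps, tis, w1, off)
  expect_equal(transient_signal(z, t_p = 0)$values, rep(1, length(off)))
  expect_equal(transient_signal(z, t_p = 1e6)$values, z$values)
  # monotone non-increasing in t_p at every offset
  tp <- c(0.1, 0.5, 1, 2, 5)
  vals <- sapply(tp, function(t) transient_signal(z, t_p = t)$values)
  expect_true(all(diff(t(vals)) <= 1e-14))
  # after 5 s with R1rho >= 2/s the transient correction is negligible,
  # which justifies treating a 5 s saturation as steady state
  r1rho <- pmax(z$meta$R1rho, 2)
  z5 <- transient_signal(z, R1rho = r1rho, t_p = 5)
  expect_lt(max(abs(z5$values - z$values)), 1e-4)
})
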