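geom <- optical_geometry()

make_traces <- function(o2, hh, n = 50, fs = 10) {
  list(
    o2hb = time_series(rep(o2, n), fs, 0, "uM", "O2Hb"),
    hhb = time_series(rep(hh, n), fs, 0, "uM", "HHb")
  )
}

slope_term <- function(rec, geom, w) {
  rho <- geom$distances / 10
  wts <- (rho - mean(rho)) / sum((rho - mean(rho))^2)
  slope <- as.vector(rec$attenuation[, w, ] %*% wts)
  log(10) * slope - 2 / mean(rho)
}

test_that("forward slope follows the diffusion relation", {
  tr <- make_traces(30, 20)
  rec <- forward_attenuation(tr$o2hb, tr$hhb, geom)
  # doubling absorption at fixed scattering scales the slope term by sqrt(2)
  tr2 <- make_traces(60, 40)
  rec2 <- forward_attenuation(tr2$o2hb, tr2$hhb, geom)
  for (w in 1:2) {
    expect_equal(slope_term(rec2, geom, w), sqrt(2) * slope_term(rec, geom, w),
                 tolerance = 1e-10)
  }
  # zero chromophores leave a zero slope term
  tr0 <- make_traces(0, 0)
  rec0 <- forward_attenuation(tr0$o2hb, tr0$hhb, geom)
  expect_equal(slope_term(rec0, geom, 1), rep(0, 50), tolerance = 1e-12)
  # constant chromophores give attenuation constant in time at every channel
  expect_true(all(apply(rec$attenuation, c(2, 3), function(x) diff(range(x))) == 0))
})

test_that("SRS inversion recovers programmed saturation within 1% over 40-90%", {
  for (sat in seq(40, 90, by = 5)) {
    thb <- 60
    tr <- make_traces(sat / 100 * thb, (1 - sat / 100) * thb)
    tsi <- srs_tsi(forward_attenuation(tr$o2hb, tr$hhb, geom), geom)
    expect_lt(max(abs(tsi$values - sat)), 1)  # 1% absolute
  }
})

test_that("TSI is 50% for equal chromophores and invariant to scale and intensity", {
  tr <- make_traces(25, 25)
  rec <- forward_attenuation(tr$o2hb, tr$hhb, geom)
  expect_equal(mean(srs_tsi(rec, geom)$values), 50, tolerance = 1e-6)
  # common scaling of both chromophores cancels in the ratio
  tr3 <- make_traces(25 * 3, 25 * 3)
  rec3 <- forward_attenuation(tr3$o2hb, tr3$hhb, geom)
  expect_equal(srs_tsi(rec3, geom)$values, srs_tsi(rec, geom)$values,
               tolerance = 1e-6)
  # a distance-independent attenuation offset (source intensity) is
  # annihilated by the spatial slope
  tr4 <- make_traces(40, 20)
  reca <- forward_attenuation(tr4$o2hb, tr4$hhb, geom, a0 = c(1, 1))
  recb <- forward_attenuation(tr4$o2hb, tr4$hhb, geom, a0 = c(2.5, 0.3))
  expect_equal(srs_tsi(reca, geom)$values, srs_tsi(recb, geom)$values,
               tolerance = 1e-10)
})

test_that("negative-radicand samples are masked, not clipped", {
  tr <- make_traces(30, 20)
  rec <- forward_attenuation(tr$o2hb, tr$hhb, geom)
  # force a negative slope at one time point by corrupting the far channel
  rec$attenuation[7, , 3] <- rec$attenuation[7, , 1] - 1
  tsi <- srs_tsi(rec, geom)
  expect_true(is.na(tsi$values[7]))
  expect_false(anyNA(tsi$values[-7]))
  expect_equal(attr(tsi, "valid_fraction"), 49 / 50)
})

test_that("MBLL delta recovers programmed concentration changes exactly", {
  n <- 40
  d_o2 <- c(rep(0, 20), rep(1, 20))   # +1 uM step
  d_hh <- c(rep(0, 20), rep(-1, 20))  # -1 uM step
  base <- make_traces(30, 20, n = n)
  o2 <- time_series(base$o2hb$values + d_o2, 10, 0, "uM", "O2Hb")
  hh <- time_series(base$hhb$values + d_hh, 10, 0, "uM", "HHb")
  # build attenuation directly from the MBLL term at one distance
  rho_cm <- geom$distances[1] / 10
  att <- array(0, dim = c(n, 2, 3))
  for (w in 1:2) {
    dA <- (geom$extinction[w, "o2hb"] * o2$values +
             geom$extinction[w, "hhb"] * hh$values) / 1000 *
      rho_cm * geom$dpf[w]
    att[, w, ] <- dA
  }
  rec <- optical_recording(att, 10, 0)
  cs <- mbll_delta(rec, geom, distance = 30, reference = c(0, 2))
  expect_equal(cs$o2hb$values, d_o2, tolerance = 1e-9)
  expect_equal(cs$hhb$values, d_hh, tolerance = 1e-9)
  # chromophore identities hold exactly at every sample
  expect_identical(cs$thb$values, cs$o2hb$values + cs$hhb$values)
  expect_identical(cs$hbdiff$values, cs$o2hb$values - cs$hhb$values)
  expect_equal(cs$thb$values + cs$hbdiff$values, 2 * cs$o2hb$values)
})

test_that("constant recordings give identically zero deltas", {
  tr <- make_traces(30, 20)
  rec <- forward_attenuation(tr$o2hb, tr$hhb, geom)
  cs <- mbll_delta(rec, geom, reference = c(0, 5))
  expect_equal(max(abs(cs$o2hb$values)), 0, tolerance = 1e-12)
  expect_equal(max(abs(cs$hhb$values)), 0, tolerance = 1e-12)
})

test_that("geometry and recording contracts are enforced", {
  expect_error(optical_geometry(distances = c(40, 30)), "increasing")
  expect_error(optical_geometry(extinction = matrix(1, 2, 2)), "nonsingular")
  expect_error(optical_geometry(wavelengths = 800), "2 wavelengths")
  tr <- make_traces(30, 20)
  rec <- forward_attenuation(tr$o2hb, tr$hhb, geom)
  expect_error(mbll_delta(rec, geom, distance = 99, reference = c(0, 5)),
               "not present")
  expect_error(mbll_delta(rec, geom, reference = c(100, 200)),
               "outside recording")
  short <- time_series(1:10, 10)
  expect_error(forward_attenuation(short, make_traces(1, 1)$hhb, geom),
               "share length")
})
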