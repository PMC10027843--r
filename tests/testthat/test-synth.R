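test_that("identical seed and config give bit-identical traces", {
  cfg <- animal_config(seed = 11)
  a1 <- simulate_abp(cfg)
  a2 <- simulate_abp(cfg)
  expect_identical(a1$values, a2$values)
  o1 <- simulate_optics(cfg)
  o2 <- simulate_optics(cfg)
  expect_identical(o1$attenuation, o2$attenuation)
  p1 <- simulate_po2(cfg)
  p2 <- simulate_po2(cfg)
  expect_identical(p1$values, p2$values)
  # different seeds differ
  expect_false(identical(simulate_abp(animal_config(seed = 12))$values,
                         a1$values))
})

test_that("noiseless pre-arrest beats span diastolic to systolic", {
  cfg <- quiet_config(hr_baseline = 2, sys_baseline = 120, dia_baseline = 80)
  abp <- simulate_abp(cfg, fs = 100)
  seg <- ts_window(abp, 100, 130)   # 60 full beats, far from the marker
  expect_equal(max(seg$values), 120, tolerance = 1e-3)
  expect_equal(min(seg$values), 80, tolerance = 1e-3)
  # per-cycle extrema: every 0.5-s beat reaches both bounds
  m <- matrix(seg$values[1:3000], nrow = 50)
  expect_true(all(abs(apply(m, 2, max) - 120) < 0.1))
  expect_true(all(abs(apply(m, 2, min) - 80) < 0.1))
})

test_that("default tau_map puts the sub-5-mmHg MAP crossing near 52.6 s", {
  cfg <- quiet_config()
  abp <- simulate_abp(cfg, fs = 100)
  m <- map_trace(abp)
  t <- ts_time(m)
  crossing <- t[which(t >= cfg$arrest_time & m$values < 5)[1]] - cfg$arrest_time
  expect_lt(abs(crossing - 52.6) / 52.6, 0.10)
})

test_that("PO2 channel is flat without decay and matches its baseline", {
  cfg <- quiet_config(po2_lag = 0, tau_po2 = Inf)
  po2 <- simulate_po2(cfg)
  expect_equal(diff(range(po2$values)), 0, tolerance = 1e-9)
  cfg2 <- animal_config(seed = 3)
  po2n <- simulate_po2(cfg2)
  bl <- ts_window_mean(po2n, cfg2$arrest_time - 60, cfg2$arrest_time)
  expect_lt(abs(bl - cfg2$po2_baseline), 3 * cfg2$noise_sd$po2)
})

test_that("optics round trip recovers baseline saturation and programmed drop", {
  cfg <- animal_config(seed = 5)
  tsi <- srs_tsi(simulate_optics(cfg), optical_geometry())
  pre <- ts_window_mean(tsi, cfg$arrest_time - 60, cfg$arrest_time)
  expect_lt(abs(pre - cfg$tsi_baseline), 1)
  post <- ts_window_mean(tsi, cfg$arrest_time + 290, cfg$arrest_time + 300)
  expect_lt(abs((pre - post) - cfg$tsi_drop), 1)
})

test_that("saturation trajectories leaving (0, 100) are rejected", {
  cfg <- quiet_config()
  cfg$tsi_baseline <- 14
  cfg$tsi_drop <- 16     # drop exceeding the baseline crosses zero in-window
  expect_error(simulate_optics(cfg), "leaves \\(0, 100\\)")
})

test_that("pre-arrest channels are stationary across disjoint windows", {
  cfg <- animal_config(seed = 21)
  sim <- simulate_animal(cfg)
  chans <- list(MAP = map_trace(sim$abp), TSI = srs_tsi(sim$optics),
                PO2 = sim$po2)
  sds <- c(MAP = nirsarrest:::.effective_sd(cfg, "MAP"),
           TSI = nirsarrest:::.effective_sd(cfg, "TSI"),
           PO2 = nirsarrest:::.effective_sd(cfg, "PO2"))
  for (nm in names(chans)) {
    m1 <- ts_window_mean(chans[[nm]], 200, 260)
    m2 <- ts_window_mean(chans[[nm]], 450, 510)
    expect_lt(abs(m1 - m2), 3 * sds[[nm]])
  }
})

test_that("noiseless post-arrest decay trajectories are non-increasing", {
  cfg <- quiet_config()
  t <- seq(cfg$arrest_time, cfg$arrest_time + 300, by = 0.1)
  expect_true(all(diff(nirsarrest:::.map_target(cfg, t)) <= 0))
  expect_true(all(diff(nirsarrest:::.tsi_target(cfg, t)) <= 0))
  expect_true(all(diff(nirsarrest:::.po2_target(cfg, t)) <= 0))
})

test_that("recorded ground truth equals a brute-force scan of noiseless traces", {
  cfg <- animal_config(seed = 9)
  sim <- simulate_animal(cfg)
  tr <- sim$truth$crossings
  # independent scan: rebuild the noiseless trajectories and scan per sample
  scan <- function(values, fs, baseline, sd) {
    t <- (seq_along(values) - 1) / fs
    idx <- which(t >= cfg$arrest_time)
    hit <- which(values[idx] < baseline - 2 * sd)[1]
    t[idx[hit]] - cfg$arrest_time
  }
  t10 <- seq(0, cfg$arrest_time + 300, by = 0.1)
  map0 <- cfg$sys_baseline / 3 + 2 * cfg$dia_baseline / 3
  expect_equal(tr$crossing_s[tr$channel == "MAP"],
               scan(nirsarrest:::.truth_trace(cfg, "MAP", t10), 10, map0,
                    nirsarrest:::.effective_sd(cfg, "MAP")))
  expect_equal(tr$crossing_s[tr$channel == "TSI"],
               scan(nirsarrest:::.truth_trace(cfg, "TSI", t10), 10, cfg$tsi_baseline,
                    nirsarrest:::.effective_sd(cfg, "TSI")))
  t1 <- seq(0, cfg$arrest_time + 300, by = 1)
  expect_equal(tr$crossing_s[tr$channel == "PO2"],
               scan(nirsarrest:::.truth_trace(cfg, "PO2", t1), 1, cfg$po2_baseline,
                    nirsarrest:::.effective_sd(cfg, "PO2")))
  # decay-channel crossings never precede the marker
  expect_true(all(tr$crossing_s >= 0))
})

test_that("reference preset reproduces the printed per-animal baselines", {
  coh <- simulate_cohort(8, preset = "reference", abp_fs = 10)
  expect_length(coh$animals, 8)
  tsi_b <- vapply(coh$configs, function(c) c$tsi_baseline, numeric(1))
  expect_equal(tsi_b, reference_cohort()$tsi_baseline)
  hr <- vapply(coh$configs, function(c) c$hr_baseline, numeric(1))
  expect_equal(hr, c(1.44, 1.51, 1.56, 2.67, 1.33, 1.08, 1.64, 2.25))
})

test_that("cohorts are reproducible and samplers are honoured", {
  c1 <- simulate_cohort(2, seed = 42, abp_fs = 10)
  c2 <- simulate_cohort(2, seed = 42, abp_fs = 10)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$animals[[1]]$abp$values, c2$animals[[1]]$abp$values)
  # zero-variance sampler: all animals share the same physiology
  fixed <- function(i) animal_config(animal_id = sprintf("a%d", i), seed = 7L)
  c3 <- simulate_cohort(3, config_sampler = fixed, seed = 1, abp_fs = 10)
  sds <- vapply(c3$animals, function(a) a$truth$crossings$crossing_s[1],
                numeric(1))
  expect_equal(length(unique(sds)), 1)
})

test_that("configuration invariants are enforced with named messages", {
  expect_error(animal_config(hr_baseline = 5), "hr_baseline")
  expect_error(animal_config(sys_baseline = 60, dia_baseline = 80),
               "dia_baseline")
  expect_error(animal_config(tsi_baseline = 130), "tsi_baseline")
  expect_error(animal_config(tau_tsi = -1), "tau_tsi")
  expect_error(animal_config(po2_lag = -2), "po2_lag")
  expect_error(simulate_abp(animal_config(), fs = 37), "fs")
  expect_error(simulate_abp(animal_config(), post_duration = -1),
               "post_duration")
})
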