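test_that("ECG trigger times span the protocol duration", {
  tt <- ecg_triggered_times(36, 26.9 / 35, 0)
  expect_equal(tt[1], 0)
  expect_equal(tt[36], 26.9, tolerance = 0.02)
  expect_equal(diff(tt), rep(26.9 / 35, 35))   # no jitter -> uniform grid
})

test_that("jittered trigger times are reproducible, increasing and bounded", {
  a <- ecg_triggered_times(36, 0.769, 0.05, seed = 42)
  b <- ecg_triggered_times(36, 0.769, 0.05, seed = 42)
  expect_identical(a, b)
  expect_true(all(diff(a) > 0))
  expect_true(all(diff(a) >= 0.769 / 2))   # truncated-normal lower bound
  c2 <- ecg_triggered_times(36, 0.769, 0.05, seed = 43)
  expect_false(identical(a, c2))
})

test_that("label map forms three contiguous bands plus a disjoint blood pool", {
  cfg <- phantom_config(dims = c(1, 30, 20), seed = 1)
  lab <- build_phantom_labels(cfg)
  counts <- table(factor(lab, levels = region_levels()))
  # every voxel carries exactly one label
  expect_equal(sum(counts), prod(dim(lab)))
  expect_true(all(counts[c("highly", "unaffected", "moderate")] > 0))
  expect_true(counts["blood_pool"] > 0)
  # equal band fractions -> equal voxel counts up to one row of the insert
  myo_nx <- round(cfg$myo_frac_x * 20)
  expect_lte(diff(range(counts[c("highly", "unaffected", "moderate")])),
             myo_nx)
  # contiguity and top-to-bottom ordering within the insert
  col <- lab[1, , 1]
  runs <- rle(col)
  expect_equal(runs$values, c("highly", "unaffected", "moderate"))
  # blood pool never touches the myocardium columns
  expect_true(all(which(lab[1, , ] == "blood_pool", arr.ind = TRUE)[, 2] >
                    myo_nx))
})

test_that("bands thinner than one voxel are rejected", {
  expect_error(build_phantom_labels(phantom_config(dims = c(1, 2, 10))),
               "thinner")
})

test_that("iodine/HU conversion is the exact affine map", {
  expect_equal(iodine_to_hu(8, 31.25, 0), 250)
  expect_equal(iodine_to_hu(0, 17, -3), -3)
  x <- seq(-1, 10, by = 0.37)
  expect_equal(hu_to_iodine(iodine_to_hu(x, 31.25, 12), 31.25, 12), x)
  expect_error(iodine_to_hu(1, slope = 0), "slope")
})

test_that("noiseless voxel TACs equal the one-compartment forward model", {
  cfg <- small_config(seed = 5)
  sim <- simulate_series(cfg, "spectral", noise = FALSE)
  times <- sim$series$timestamps
  mat <- matrix(sim$series$data, nrow = length(times))
  for (r in c("highly", "moderate", "unaffected")) {
    idx <- which(unclass(sim$labels) == r)[1]
    tac <- mat[, idx]
    mtt <- cfg$mtt[[r]]
    expected <- forward_model(sim$aif, A = cfg$vfrac[[r]] / mtt,
                              lam = 1 / mtt, times = times)
    expect_equal(tac, expected, tolerance = 1e-12)
  }
  # blood-pool voxels carry the AIF itself
  bp <- which(unclass(sim$labels) == "blood_pool")[1]
  expect_equal(mat[, bp], sim$aif$values)
  expect_equal(sim$sigma, 0)
})

test_that("ground-truth MTT map is piecewise constant and matches the labels", {
  cfg <- small_config(seed = 5)
  sim <- simulate_series(cfg, "spectral")
  for (r in c("highly", "moderate", "unaffected")) {
    vals <- sim$truth$mtt[unclass(sim$labels) == r]
    expect_equal(unique(vals), unname(cfg$mtt[[r]]), tolerance = 1e-12)
  }
  expect_true(all(is.na(sim$truth$mtt[unclass(sim$labels) %in%
                                        c("background", "blood_pool")])))
})

test_that("measured blood-pool ROI SNR approaches the configured targets", {
  cfg <- phantom_config(seed = 9)   # default grid: >= 500 blood-pool voxels
  for (mod in c("spectral", "conventional")) {
    sim <- simulate_series(cfg, mod, seed = 9)
    aif <- measure_aif(sim$series, sim$labels)
    peak_frame <- which.max(aif$values)
    snr <- roi_snr(sim$series$data[peak_frame, , , ],
                   unclass(sim$labels) == "blood_pool")
    target <- cfg$snr[[if (mod == "spectral") "spectral" else "conventional"]]
    expect_equal(as.numeric(snr), target, tolerance = 0.10)
    expect_gte(sum(unclass(sim$labels) == "blood_pool"), 500)
  }
})

test_that("simulation is deterministic in the seed and modality-consistent", {
  cfg <- small_config(seed = 21)
  a <- simulate_series(cfg, "spectral", seed = 21)
  b <- simulate_series(cfg, "spectral", seed = 21)
  expect_identical(a$series$data, b$series$data)
  expect_identical(a$series$timestamps, b$series$timestamps)
  d <- simulate_series(cfg, "spectral", seed = 22)
  expect_false(identical(a$series$data, d$series$data))
  conv <- simulate_series(cfg, "conventional", seed = 21)
  expect_identical(conv$series$units, "HU")
  expect_identical(a$series$units, "mg/mL")
  # noiseless conventional series is the affine image of the iodine series
  an <- simulate_series(cfg, "spectral", noise = FALSE)
  cn <- simulate_series(cfg, "conventional", noise = FALSE)
  expect_equal(cn$series$data,
               iodine_to_hu(an$series$data, cfg$hu_slope, cfg$hu_baseline))
  expect_error(simulate_series(cfg, "dual_source"))
})
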