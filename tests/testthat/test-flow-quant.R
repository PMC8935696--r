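mk_series <- function(phase, mag = NULL, venc = 12, vox = c(0.6, 0.6)) {
  nb <- dim(phase)[3]
  if (is.null(mag)) mag <- array(1, dim(phase))
  phase_contrast_series(mag, phase, venc, vox,
                        bin_times_s = (seq_len(nb) - 0.5) / nb)
}

test_that("aqueduct mask area follows voxel arithmetic", {
  nb <- 4L
  mag <- array(0, c(15, 15, nb))
  ctr <- as.matrix(expand.grid(7:9, 7:9))          # 9-voxel bright square
  for (b in seq_len(nb)) mag[cbind(ctr, b)] <- 100
  s <- mk_series(array(0, c(15, 15, nb)), mag)
  m <- segment_aqueduct(s)
  expect_equal(m$area_cm2, 9 * 0.0036)
  expect_equal(sum(m$mask), 9)
})

test_that("an all-zero magnitude raises an aqueduct-not-found error", {
  s <- mk_series(array(0, c(10, 10, 3)), array(0, c(10, 10, 3)))
  expect_error(segment_aqueduct(s), "not found")
})

test_that("mask recovery stays accurate under 10% contrast noise", {
  dices <- vapply(1:25, function(s) {
    wp <- waveform_params(seed = s)
    pc <- generate_phase_contrast(wp)   # magnitude noise SD 2 on contrast 95
    dice_coefficient(segment_aqueduct(pc$series)$mask, pc$truth$mask)
  }, numeric(1))
  expect_true(all(dices >= 0.9))
})

test_that("phase converts to velocity linearly and oddly", {
  ph <- array(c(0, pi, -pi / 2, pi / 4), c(2, 2, 2))
  s <- mk_series(array(ph, c(2, 2, 2)))
  v <- phase_to_velocity(s)
  expect_equal(v[1, 1, 1], 0)
  expect_equal(v[2, 1, 1], 12)
  expect_equal(v[1, 2, 1], -6)
  # out-of-contract phase
  s$phase[1] <- 4
  expect_error(phase_to_velocity(s), "outside")
})

test_that("aliasing correction restores wrapped systolic velocities and is idempotent", {
  v <- c(2, -11, 3, -4)
  out <- correct_aliasing(v, 12, systolic_bins = 2L, margin_cm_s = 2)
  expect_equal(out[2], 13)                       # -11 + 2 * 12
  expect_equal(out[c(1, 3, 4)], v[c(1, 3, 4)])   # pass-through
  expect_equal(correct_aliasing(out, 12, 2L), out)  # idempotent
  # +5 anywhere is untouched
  expect_equal(correct_aliasing(rep(5, 4), 12, 1:4), rep(5, 4))
  # a value still implausible after one unwrap is flagged
  expect_warning(out2 <- correct_aliasing(c(-35, 1), 12, 1L), "double wrap")
  expect_identical(attr(out2, "suspect_double_wrap"), 1L)
})

test_that("flow profile is mean velocity times area with unit bookkeeping", {
  nb <- 3L
  ph <- array(pi * 1 / 12, c(10, 10, nb))        # uniform 1 cm/s
  mag <- array(0, c(10, 10, nb))
  mag[4:8, 4:8, ] <- 50
  s <- mk_series(ph, mag, vox = c(1, 2))         # 25 voxels x 0.02 cm2
  m <- segment_aqueduct(s)
  expect_equal(m$area_cm2, 0.5)
  prof <- compute_flow_profile(s, m, correct = FALSE)
  expect_equal(prof$flow_mL_s, rep(0.5, nb))     # 1 cm/s * 0.5 cm2
  # all-zero phase gives zero flow
  s0 <- mk_series(array(0, c(10, 10, nb)), mag)
  expect_equal(compute_flow_profile(s0, m)$flow_mL_s, rep(0, nb))
  # empty mask
  m$mask[] <- FALSE
  expect_error(compute_flow_profile(s, m), "empty")
})

test_that("flow metrics match hand integration", {
  # constant +0.1 mL/s over a 1 s cycle
  p1 <- flow_profile(rep(0.1, 4), c(0.125, 0.375, 0.625, 0.875))
  m1 <- compute_flow_metrics(p1)
  expect_equal(m1$net_flow_mL, 0.1)
  expect_equal(m1$absolute_flow_mL, 0.1)
  expect_equal(m1$regurgitant_fraction, 0)
  # zero-mean sinusoid: net 0, RF 1
  tt <- (seq_len(12) - 0.5) / 12
  p2 <- flow_profile(sin(2 * pi * tt), tt)
  m2 <- compute_flow_metrics(p2)
  expect_equal(m2$net_flow_mL, 0, tolerance = 1e-12)
  expect_equal(m2$regurgitant_fraction, 1, tolerance = 1e-12)
  # two-bin hand case: Q = (+0.2, -0.1), dt = 0.5 s
  p3 <- flow_profile(c(0.2, -0.1), c(0.25, 0.75))
  m3 <- compute_flow_metrics(p3)
  expect_equal(m3$anterograde_volume_mL, 0.10)
  expect_equal(m3$retrograde_volume_mL, 0.05)
  expect_equal(m3$net_flow_mL, 0.05)
  expect_equal(m3$absolute_flow_mL, 0.15)
  expect_equal(m3$regurgitant_fraction, 0.5)
  # all-retrograde profile: RF undefined with a reason
  m4 <- compute_flow_metrics(flow_profile(c(-0.1, -0.2), c(0.25, 0.75)))
  expect_true(is.na(m4$regurgitant_fraction))
  expect_match(attr(m4, "rf_reason"), "anterograde")
})

test_that("negating the phase negates the profile and swaps flow roles", {
  for (s in 1:5) {
    wp <- waveform_params(seed = s)
    pc <- generate_phase_contrast(wp)
    msk <- segment_aqueduct(pc$series)
    a <- compute_flow_profile(pc$series, msk, correct = FALSE)
    neg <- pc$series
    neg$phase <- -neg$phase
    b <- compute_flow_profile(neg, msk, correct = FALSE)
    expect_equal(b$flow_mL_s, -a$flow_mL_s)
    ma <- compute_flow_metrics(a); mb <- compute_flow_metrics(b)
    expect_equal(mb$max_anterograde_mL_s, -ma$max_retrograde_mL_s)
    expect_equal(mb$max_retrograde_mL_s, -ma$max_anterograde_mL_s)
    expect_equal(mb$absolute_flow_mL, ma$absolute_flow_mL)
    expect_equal(mb$net_flow_mL, -ma$net_flow_mL)
  }
})

test_that("a noise-free acquisition round-trips through the encoder exactly", {
  wp <- waveform_params(noise_sd_cm_s = 0, seed = 6)
  pc <- generate_phase_contrast(wp)
  prof <- compute_flow_profile(pc$series, segment_aqueduct(pc$series),
                               correct = FALSE)
  expect_equal(prof$flow_mL_s, pc$truth$profile_realized$flow_mL_s,
               tolerance = 1e-12)
})
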