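test_that("phantom ICV is recovered within 3% of the analytic ellipsoid", {
  for (s in c(11, 12)) {
    ph <- generate_head_phantom(head_phantom_params(seed = s))
    est <- estimate_icv(ph$t1)
    an <- attr(ph$truth, "analytic_cm3")$icv
    expect_lt(abs(est$icv_cm3 / an - 1), 0.03)
  }
})

test_that("label volume is exactly count times voxel volume", {
  # 1,371,000 voxels at 1 mm isotropic -> 1371 cm^3
  n <- c(120, 120, 100)
  lab <- array(0L, n)
  lab[seq_len(1371000)] <- 1L
  expect_equal(label_volume_cm3(lab, 1L, voxel_size_mm = c(1, 1, 1)), 1371)
  # 1000 voxels at 0.78 mm isotropic -> 0.474552 cm^3
  lab2 <- array(0L, c(10, 10, 10)); lab2[] <- 1L
  expect_equal(label_volume_cm3(lab2, 1L, voxel_size_mm = rep(0.78, 3)),
               0.78^3 * 1000 / 1000)
})

test_that("degenerate volumetry inputs raise errors", {
  expect_error(estimate_icv(volume_image(array(0, c(8, 8, 8)))), "empty")
  expect_error(segment_tissues(noise_free_phantom()$t1,
                               array(FALSE, c(64, 64, 64))), "empty")
})

test_that("3-class EM tissue volumes match phantom truth within 5%", {
  ph <- generate_head_phantom(head_phantom_params(seed = 11))
  tmask <- ph$truth$data %in% 1:3
  tis <- segment_tissues(ph$t1, tmask)
  truth <- vapply(1:3, function(k) label_volume_cm3(ph$truth, k), numeric(1))
  est <- c(tis$volumes$csf_cm3, tis$volumes$gm_cm3, tis$volumes$wm_cm3)
  expect_true(all(abs(est / truth - 1) < 0.05))
  # class volumes sum exactly to the mask volume
  expect_equal(sum(est), tis$volumes$icv_cm3, tolerance = 1e-12)
})

test_that("a noise-free phantom is classified voxel-perfectly in-mask", {
  ph <- noise_free_phantom()
  tmask <- ph$truth$data %in% 1:3
  tis <- segment_tissues(ph$t1, tmask)
  expect_identical(tis$labels$data[tmask], ph$truth$data[tmask])
})

test_that("a two-class image passed as three classes is flagged or collapses", {
  x <- array(0, c(20, 20, 20))
  x[] <- withr::with_seed(4, sample(c(30, 100), 8000, replace = TRUE)) +
    withr::with_seed(5, rnorm(8000, 0, 1))
  v <- volume_image(x, modality = "T1")
  res <- tryCatch(
    withCallingHandlers(
      segment_tissues(v, array(TRUE, c(20, 20, 20))),
      warning = function(w) {
        expect_match(conditionMessage(w), "empty class")
        invokeRestart("muffleWarning")
      }),
    error = function(e) {
      expect_match(conditionMessage(e), "collaps|degenerate")
      NULL
    })
  succeed()
})

test_that("classification is independent of voxel ordering", {
  ph <- generate_head_phantom(head_phantom_params(seed = 14))
  tmask <- array(ph$truth$data %in% 1:3, dim(ph$truth$data))
  t1 <- segment_tissues(ph$t1, tmask)
  # flip the volume left-right: same voxels, different order
  flip <- ph$t1
  flip$data <- flip$data[dim(flip$data)[1]:1, , ]
  tmask_f <- tmask[dim(tmask)[1]:1, , ]
  t2 <- segment_tissues(flip, tmask_f)
  expect_equal(unlist(t2$volumes), unlist(t1$volumes), tolerance = 1e-8)
})

test_that("non-isotropic spacing enters the volume arithmetic per axis", {
  lab <- array(1L, c(10, 10, 10))
  expect_equal(label_volume_cm3(lab, 1L, voxel_size_mm = c(0.5, 1, 2)), 1)
})
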