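test_that("noise-free phantom renders exact class means and tiles the grid", {
  ph <- noise_free_phantom()
  p <- head_phantom_params(class_sds = rep(0, 6), bias_amplitude = 0, seed = 3)
  lab <- ph$truth$data
  # every voxel carries exactly its class mean in both modalities
  expect_equal(ph$t1$data, array(p$class_means[, "T1"][lab + 1L], dim(lab)))
  expect_equal(ph$t2$data, array(p$class_means[, "T2"][lab + 1L], dim(lab)))
  # compartments are mutually exclusive and jointly tile the grid
  expect_true(all(lab %in% 0:5))
  # PSD hyperintense, sinus hypointense on T2
  expect_gt(mean(ph$t2$data[lab == 5L]), mean(ph$t2$data[lab == 1L]))
  expect_lt(mean(ph$t2$data[lab == 4L]), mean(ph$t2$data[lab == 3L]))
})

test_that("identical seeds give bit-identical phantoms", {
  p <- head_phantom_params(seed = 17L)
  a <- generate_head_phantom(p)
  b <- generate_head_phantom(p)
  expect_identical(a$t1$data, b$t1$data)
  expect_identical(a$t2$data, b$t2$data)
  expect_identical(a$truth$data, b$truth$data)
  c <- generate_head_phantom(head_phantom_params(seed = 18L))
  expect_false(identical(a$t2$data, c$t2$data))
})

test_that("truth label volumes match analytic solid volumes within a voxel shell", {
  p <- head_phantom_params(seed = 4L)
  ph <- generate_head_phantom(p)
  an <- attr(ph$truth, "analytic_cm3")
  vox <- voxel_volume_mm3(ph$t1)
  h <- max(p$voxel_size_mm)
  # PSD annular shell: tolerance = surface area x voxel size
  r <- p$sinus_radius_mm; t <- p$psd_thickness_mm; L <- p$sinus_length_mm
  surf_psd <- 2 * pi * (r + t) * L + 2 * pi * r * L +
    2 * pi * ((r + t)^2 - r^2)
  expect_lt(abs(label_volume_cm3(ph$truth, 5L) - an$psd),
            surf_psd * h / 1000)
  surf_sin <- 2 * pi * r * L + 2 * pi * r^2
  expect_lt(abs(label_volume_cm3(ph$truth, 4L) - an$sinus),
            surf_sin * h / 1000)
  ax <- p$icv_semi_axes_mm
  surf_icv <- 4 * pi * max(ax)^2
  expect_lt(abs(label_volume_cm3(ph$truth, 1:5) - an$icv),
            surf_icv * h / 1000)
})

test_that("degenerate phantom geometry is rejected with a parameter error", {
  expect_error(head_phantom_params(icv_semi_axes_mm = c(40, 40, 40)),
               "exceeds the grid")
  expect_error(head_phantom_params(sinus_length_mm = 60), "outside")
  expect_error(head_phantom_params(psd_thickness_mm = -1), "positive")
  expect_error(head_phantom_params(ventricle_radius_mm = 15), "ventricle")
  # PSD must stay hyperintense to the sinus on T2
  cm <- cbind(T1 = c(0, 30, 70, 100, 45, 55), T2 = c(0, 85, 55, 40, 120, 10))
  rownames(cm) <- c("background", "csf", "gm", "wm", "sinus", "psd")
  expect_error(head_phantom_params(class_means = cm), "hyperintense")
})
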