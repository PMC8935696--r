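test_that("two point masses are fit exactly", {
  fit <- fit_gmm(c(rep(10, 50), rep(100, 50)), k = 2)
  expect_equal(fit$means, c(10, 100), tolerance = 1e-6)
  expect_equal(fit$weights, c(0.5, 0.5), tolerance = 1e-6)
})

test_that("parameters of a known mixture are recovered within 5%", {
  x <- withr::with_seed(5, c(rnorm(1500, 40, 10), rnorm(3500, 120, 10)))
  fit <- fit_gmm(x, k = 2)
  expect_equal(fit$means, c(40, 120), tolerance = 0.05)
  expect_equal(fit$weights, c(0.3, 0.7), tolerance = 0.05)
  expect_equal(sqrt(fit$variances), c(10, 10), tolerance = 0.05)
  # independent EM implementation agrees
  library(mclust)
  mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(unname(mc$parameters$mean)), fit$means, tolerance = 0.01)
  # log-likelihood is non-decreasing across iterations
  expect_true(all(diff(fit$ll_history) >= -1e-8))
})

test_that("degenerate inputs raise explicit errors", {
  expect_error(fit_gmm(rep(5, 100), k = 2), "variance is zero")
  expect_error(fit_gmm(rnorm(10), k = 2), "at least")
  small_mask <- array(FALSE, c(3, 3, 3)); small_mask[1:12] <- TRUE
  expect_error(fit_gmm_map(volume_image(array(rnorm(27), c(3, 3, 3))),
                           small_mask), "20 in-mask")
})

test_that("MAP labeling equals brute-force posterior argmax", {
  p <- head_phantom_params(seed = 31)
  ph <- generate_head_phantom(p)
  env <- parasagittal_envelope(ph$truth)
  fit <- fit_gmm_map(ph$t2, env)
  lab <- label_psd_venous(fit, ph$t2, env)
  # independent oracle: densities evaluated from scratch per voxel
  x <- ph$t2$data[env]
  d1 <- fit$weights[1] * exp(-(x - fit$means[1])^2 / (2 * fit$variances[1])) /
    sqrt(2 * pi * fit$variances[1])
  d2 <- fit$weights[2] * exp(-(x - fit$means[2])^2 / (2 * fit$variances[2])) /
    sqrt(2 * pi * fit$variances[2])
  oracle <- ifelse(d2 > d1, 1L, 2L)
  expect_identical(lab$data[env], oracle)
})

test_that("label orientation and tie conventions are enforced", {
  fit <- fit_gmm(c(rep(10, 50), rep(100, 50)), k = 2)
  vol <- volume_image(array(c(55, 200, 10), c(3, 1, 1)))
  msk <- array(TRUE, c(3, 1, 1))
  lab <- label_psd_venous(fit, vol, msk)
  expect_identical(lab$data[1], 2L)   # exact midpoint tie goes to venous
  expect_identical(lab$data[2], 1L)   # far above both means: PSD dominance
  expect_identical(lab$data[3], 2L)
  # equal means cannot be oriented
  fake <- fit
  fake$means <- c(50, 50)
  expect_error(label_psd_venous(fake, vol, msk), "equal means")
})

test_that("in-mask MAP labels are >= 99% accurate at 4-SD class separation", {
  accs <- vapply(c(31, 32, 33), function(s) {
    ph <- generate_head_phantom(head_phantom_params(seed = s))
    env <- parasagittal_envelope(ph$truth)
    lab <- label_psd_venous(fit_gmm_map(ph$t2, env), ph$t2, env)
    truth <- ifelse(ph$truth$data == 5L, 1L, 2L)
    mean(lab$data[env] == truth[env])
  }, numeric(1))
  expect_true(all(accs >= 0.99))
})

test_that("native-space volumes follow voxel arithmetic", {
  lab <- array(0L, c(20, 20, 20))
  lab[1:10, 1:10, 1:10] <- 1L
  lm_ <- label_map(lab, c(0.78, 0.78, 0.78),
                   c(background = 0L, psd = 1L, venous = 2L))
  out <- to_native_and_measure(lm_)
  expect_equal(out$psd_volume_cm3, 1000 * 0.78^3 / 1000)
  expect_identical(out$space, "template")
})

test_that("voxel size above 0.8 mm triggers the resolution guard", {
  v <- volume_image(array(0, c(4, 4, 4)), c(1, 1, 1))
  expect_warning(check_psd_resolution(v), "0.8 mm")
  v2 <- volume_image(array(0, c(4, 4, 4)), c(0.78, 0.78, 0.78))
  expect_silent(check_psd_resolution(v2))
})
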