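test_that("analytic gradients match numerical differentiation", {
  withr::with_seed(1, {
    cfg <- seg_model_config(patch_size = 8L, channels = 2L)
    params <- psdflow:::unet_init(cfg)
    x <- array(rnorm(8^3), c(8, 8, 8, 1))
    y <- array(rbinom(8^3, 1, 0.3), c(8, 8, 8, 1))
    for (loss in c("bce", "dice")) {
      f <- function(pl) {
        p <- psdflow:::unet_forward(x, pl)
        psdflow:::unet_loss_grad(p, y, loss)$loss
      }
      cache <- psdflow:::unet_forward(x, params, keep = TRUE)
      lg <- psdflow:::unet_loss_grad(cache$p, y, loss)
      g <- psdflow:::unet_backward(cache, params, lg$dlogit)
      for (k in c("w1", "w2", "w3", "w4", "w5", "w6", "b1", "b5")) {
        i <- sample(length(params[[k]]), 1)
        eps <- 1e-5
        pp <- params; pp[[k]][i] <- pp[[k]][i] + eps
        pm <- params; pm[[k]][i] <- pm[[k]][i] - eps
        num <- (f(pp) - f(pm)) / (2 * eps)
        expect_equal(g[[k]][i], num, tolerance = 1e-5)
      }
    }
  })
})

test_that("training is deterministic given the seed and reduces the loss", {
  m1 <- quick_seg_model()
  m2 <- train_parasagittal_model(
    make_training_pairs(4, seed = 101),
    seg_model_config(epochs = 6L, patches_per_volume = 28L, seed = 11))
  expect_identical(m1$params, m2$params)
  expect_lt(m1$loss_history[length(m1$loss_history)], m1$loss_history[1])
  # identical predictions on a fixed probe
  probe <- generate_head_phantom(head_phantom_params(seed = 202))$t2
  roi <- psdflow:::dorsal_roi(dim(probe$data))
  p1 <- predict_parasagittal_mask(m1, probe, roi_mask = roi)
  p2 <- predict_parasagittal_mask(m2, probe, roi_mask = roi)
  expect_identical(as.logical(p1), as.logical(p2))
})

test_that("training input contracts are enforced", {
  pairs <- make_training_pairs(2, seed = 5)
  expect_error(train_parasagittal_model(pairs[1],
                                        seg_model_config(epochs = 1L)),
               "at least 2")
  pairs[[2]]$mask[] <- FALSE
  expect_error(train_parasagittal_model(pairs, seg_model_config(epochs = 1L)),
               "empty truth mask")
})

test_that("an extreme threshold yields a flagged empty mask, not an error", {
  m <- quick_seg_model()
  probe <- generate_head_phantom(head_phantom_params(seed = 203))$t2
  roi <- psdflow:::dorsal_roi(dim(probe$data))
  out <- predict_parasagittal_mask(m, probe, roi_mask = roi,
                                   prob_threshold = 1 - 1e-12)
  expect_false(any(out))
  expect_true(isTRUE(attr(out, "empty_mask")))
})

test_that("well-separated probabilities threshold to the truth mask", {
  # direct check of the threshold + largest-component post-filter
  truth <- array(FALSE, c(12, 12, 12)); truth[4:8, 4:8, 4:8] <- TRUE
  prob <- ifelse(truth, 0.9, 0.1)
  mask <- prob > 0.5
  lab <- psdflow:::.label_components(mask, dim(mask))
  expect_identical(lab == 1L, truth)
})

test_that("config contracts hold", {
  expect_error(seg_model_config(stride = 20L), "stride")
  expect_error(seg_model_config(prob_threshold = 1), "prob_threshold")
  expect_error(seg_model_config(patch_size = 15L), "even")
})
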