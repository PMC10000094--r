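test_that("micro accuracy equals the mismatch-rate complement and the confusion trace", {
  expect_equal(acc_cls(c(1, 1, 2, 2), c(1, 2, 2, 2)), 0.75)
  expect_equal(acc_cls(1:5, 1:5), 1)
  expect_error(acc_cls(integer(0), integer(0)), "empty")
  expect_error(acc_cls(1:3, 1:4), "length mismatch")
  withr::with_seed(33, {
    for (i in 1:20) {
      C <- sample(2:6, 1)
      n <- sample(50:300, 1)
      pred <- sample.int(C, n, replace = TRUE)
      lab <- sample.int(C, n, replace = TRUE)
      a <- acc_cls(pred, lab)
      expect_equal(a, 1 - mean(pred != lab))
      cm <- confusion(pred, lab, C)
      expect_equal(a, sum(diag(cm)) / sum(cm))
      expect_identical(sum(cm), as.integer(n))
    }
  })
  cm1 <- confusion(2, 1, 3)
  expect_identical(cm1[1, 2], 1L)
  expect_identical(sum(cm1), 1L)
  expect_true(all(rowSums(confusion_rates(cm1)) %in% c(0, 1)))
  expect_error(confusion(5, 1, 3), "out of range")
})

test_that("heat ratios match a brute-force pixel double loop and scale invariance", {
  froh_oracle <- function(v, b) {
    num <- 0; den <- 0
    for (y in seq_len(nrow(v))) for (x in seq_len(ncol(v))) {
      den <- den + v[y, x]
      if (x - 1 >= b[1] && x - 1 < b[3] && y - 1 >= b[2] && y - 1 < b[4])
        num <- num + v[y, x]
    }
    num / den
  }
  # uniform map over a quarter of the area
  u <- matrix(1, 16, 16)
  expect_equal(froh(u, c(0, 0, 8, 8)), 0.25)
  # all heat strictly inside the box
  v <- matrix(0, 16, 16); v[5:8, 5:8] <- 3
  expect_equal(froh(v, c(2, 2, 10, 10)), 1)
  withr::with_seed(41, {
    for (i in 1:100) {
      h <- matrix(stats::rexp(12 * 12), 12, 12)
      x0 <- sample(0:10, 1); x1 <- sample((x0 + 1):12, 1)
      y0 <- sample(0:10, 1); y1 <- sample((y0 + 1):12, 1)
      b <- c(x0, y0, x1, y1)
      expect_equal(froh(h, b), froh_oracle(h, b))
      expect_equal(froh(h * 7.3, b), froh(h, b))
    }
  })
  z <- froh(matrix(0, 8, 8), c(0, 0, 4, 4))
  expect_identical(as.numeric(z), 0)
  expect_true(attr(z, "zero_heat"))
  expect_error(froh(u, c(0, 0, 99, 2)), "invalid bounding box")
})

# A model with zeroed convolutions and BN beta = 1 has constant positive
# last-stage activations, so its attention map is spatially uniform.
constant_model <- function(classes = 3, side = 32) {
  m <- build_classifier(micro_spec(classes = classes, side = side), seed = 1)
  for (i in seq_along(m$layers)) {
    ly <- m$layers[[i]]
    if (ly$type == "conv") m$layers[[i]]$W[] <- 0
    if (ly$type == "bn") {
      m$layers[[i]]$gamma[] <- 0
      m$layers[[i]]$beta[] <- 1
      m$layers[[i]]$run_mean[] <- 0
      m$layers[[i]]$run_var[] <- 1
    }
    if (ly$type == "fc") m$layers[[i]]$W[] <- 1
  }
  m
}

test_that("Grad-CAM is the ReLU of gradient-weighted activations, upsampled", {
  m <- build_classifier(micro_spec(), seed = 7)
  rec <- toy_records(1, 32)[[1]]
  hm <- grad_cam(m, rec, 1)
  expect_s3_class(hm, "heat_map")
  expect_identical(dim(hm$values), c(32L, 32L))
  expect_true(all(hm$values >= 0))
  # hand evaluation: alpha_k = mean gradient, map = relu(sum alpha_k A_k)
  ag <- activations_and_gradients(m, rec, 1)
  alpha <- apply(ag$gradients, 3, mean)
  d <- dim(ag$activations)
  manual <- matrix(pmax(matrix(ag$activations, d[1] * d[2], d[3]) %*%
                          alpha, 0), d[1], d[2])
  up <- trapslim:::upsample_bilinear(manual, 32, 32)
  expect_equal(hm$values, pmax(up, 0))
  # zero gradient (zeroed class head) gives an identically zero map
  nl <- length(m$layers)
  m$layers[[nl]]$W[, 2] <- 0
  expect_true(all(grad_cam(m, rec, 2)$values == 0))
})

test_that("dataset-level attention reduces to box-area fractions for a uniform model", {
  cfg <- micro_scene(seed = 25, instances_per_class = c(4, 3))
  ds <- generate_dataset(cfg)
  m <- constant_model(classes = 3, side = 32)
  res <- dataset_froh(m, ds$test)
  area_frac <- vapply(ds$test$records, function(r) {
    b <- r$bbox
    (b[3] - b[1]) * (b[4] - b[2]) / (32 * 32)
  }, numeric(1))
  expect_equal(res$mean_froh, mean(area_frac), tolerance = 1e-10)
  expect_true(res$mean_froh >= 0 && res$mean_froh <= 1)
  one <- dataset_froh(m, ds$test$records[1])
  expect_equal(one$mean_froh, one$per_image$froh[1])
})

test_that("model evaluation bundles accuracy and confusion consistently", {
  cfg <- micro_scene(seed = 26)
  ds <- generate_dataset(cfg)
  m <- build_classifier(micro_spec(), seed = 3)
  ev <- evaluate_model(m, ds$test)
  expect_equal(ev$acc, sum(diag(ev$confusion)) / sum(ev$confusion))
})
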