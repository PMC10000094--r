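test_that("instantiated models carry exactly the parameters their descriptors predict", {
  withr::with_seed(10, {
    for (i in 1:8) {
      ns <- sample(1:3, 1)
      spec <- classifier_spec(
        stage_widths = sample(2:12, ns, replace = TRUE),
        blocks_per_stage = sample(1:2, ns, replace = TRUE),
        num_classes = sample(2:5, 1), input_side = 2^ns * sample(2:4, 1),
        with_residual = sample(c(TRUE, FALSE), 1))
      m <- build_classifier(spec, seed = i)
      expect_identical(trapslim:::count_net_params(m),
                       count_params(m$arch)$params_total)
      # the spec <-> descriptor mapping round-trips losslessly
      expect_identical(as_classifier_spec(m$arch), spec)
    }
  })
})

test_that("initialization and forward passes are deterministic with stated shapes", {
  spec <- micro_spec()
  m1 <- build_classifier(spec, seed = 42)
  m2 <- build_classifier(spec, seed = 42)
  expect_identical(m1$layers, m2$layers)
  expect_false(identical(m1$layers,
                         build_classifier(spec, seed = 43)$layers))
  X <- trapslim:::records_to_tensor(toy_records(2, 32), 32)
  out <- trapslim:::net_forward(m1, X)
  expect_identical(dim(out$logits), c(4L, 3L))
})

test_that("analytic gradients agree with finite differences on a residual net", {
  spec <- classifier_spec(c(4, 6), c(1, 2), num_classes = 3,
                          input_side = 8, with_residual = TRUE)
  net <- build_classifier(spec, seed = 3)
  withr::with_seed(42, {
    X <- array(rnorm(8 * 8 * 3 * 5), c(64, 3, 5))
    y <- c(1L, 2L, 3L, 1L, 2L)
    loss_of <- function(n)
      trapslim:::ce_grad(trapslim:::net_forward(n, X, training = TRUE,
                                                keep_cache = TRUE)$logits,
                         y)$loss
    fwd <- trapslim:::net_forward(net, X, training = TRUE, keep_cache = TRUE)
    grads <- trapslim:::net_backward(
      net, fwd, trapslim:::ce_grad(fwd$logits, y)$dlogits)
    eps <- 1e-6
    for (tp in trapslim:::trainable_names(net)) {
      i <- as.integer(tp[1]); p <- tp[2]
      g <- trapslim:::grad_field(grads[[i]], p)
      for (j in sample(length(g), min(3, length(g)))) {
        up <- net; up$layers[[i]][[p]][j] <- up$layers[[i]][[p]][j] + eps
        dn <- net; dn$layers[[i]][[p]][j] <- dn$layers[[i]][[p]][j] - eps
        num <- (loss_of(up) - loss_of(dn)) / (2 * eps)
        expect_lt(abs(num - g[j]), 1e-4 * max(1, abs(g[j])))
      }
    }
  })
})

test_that("training separates a trivially separable problem and keeps history", {
  recs <- toy_records(15, side = 16)
  val <- toy_records(5, side = 16, seed = 2)
  m <- build_classifier(classifier_spec(c(6, 8), 1, 2, 16), seed = 1)
  cfg <- fast_train(max_epochs = 20, batch_size = 10)
  m <- train_classifier(m, recs, val, cfg)
  expect_identical(max(m$history$train_acc), 1)
  expect_lte(nrow(m$history), 20)
  expect_true(all(c("epoch", "lr", "train_loss", "train_acc", "val_acc")
                  %in% names(m$history)))
  expect_error(train_classifier(m, list(), val, cfg), "non-empty")
})

test_that("early stopping halts after the configured patience when nothing improves", {
  recs <- toy_records(8, side = 16)
  val <- toy_records(4, side = 16, seed = 2)
  m <- build_classifier(classifier_spec(c(4), 1, 2, 16), seed = 1)
  # zero learning rate freezes the model, so validation accuracy is flat
  cfg <- train_config(initial_lr = 1e-12, batch_size = 8,
                      early_stop_patience = 3, max_epochs = 50, seed = 1)
  m <- train_classifier(m, recs, val, cfg)
  expect_identical(nrow(m$history), 1L + 3L)
})

test_that("prediction returns calibrated simplex rows with a fixed tie-break", {
  spec <- micro_spec()
  m <- build_classifier(spec, seed = 2)
  recs <- toy_records(3, 32, colours = list(c(10, 10, 10), c(240, 240, 240)))
  pr <- predict(m, recs)
  expect_equal(rowSums(pr$probabilities), rep(1, 6), tolerance = 1e-6)
  # force exactly equal logits: zero head weights and bias
  nl <- length(m$layers)
  m$layers[[nl]]$W[] <- 0
  m$layers[[nl]]$b[] <- 0
  pr0 <- predict(m, recs)
  expect_equal(unname(pr0$probabilities[1, ]), rep(1 / 3, 3),
               tolerance = 1e-12)
  expect_true(all(pr0$labels == 1L))    # ties resolve to the lowest index
})

test_that("class-logit gradients at the last stage behave like Grad-CAM inputs", {
  m <- build_classifier(micro_spec(), seed = 4)
  rec <- toy_records(1, 32)[[1]]
  ag <- activations_and_gradients(m, rec, 2)
  expect_identical(dim(ag$activations), dim(ag$gradients))
  ag2 <- activations_and_gradients(m, rec, 2)
  expect_identical(ag, ag2)
  # a zeroed class head has an identically zero gradient
  nl <- length(m$layers)
  m$layers[[nl]]$W[, 1] <- 0
  expect_true(all(activations_and_gradients(m, rec, 1)$gradients == 0))
  expect_error(activations_and_gradients(m, rec, 9), "out of range")
})
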