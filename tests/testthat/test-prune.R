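# Small shared fixture: a briefly trained teacher on the micro benchmark.
prune_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    scene <- micro_scene(seed = 6, instances_per_class = c(12, 8))
    ds <- generate_dataset(scene)
    teacher <- build_classifier(micro_spec(c(6, 8, 10), 3, 32), seed = 2)
    teacher <- train_classifier(teacher, ds$train, ds$test,
                                fast_train(max_epochs = 5))
    cache <<- list(ds = ds, teacher = teacher)
    cache
  }
})

test_that("adaptive-BN statistics implement the batch mean and unbiased variance", {
  x <- array(c(1, 2, 3), c(3, 1, 1))     # three samples of one channel
  st <- trapslim:::bn_batch_stats(x)
  expect_equal(st$mean, 2)
  expect_equal(st$var, 1)                # ((-1)^2 + 0 + 1^2) / (3 - 1)
  expect_identical(st$n, 3L)
  # sanity against stats::var on random draws
  withr::with_seed(2, {
    z <- rnorm(64)
    st2 <- trapslim:::bn_batch_stats(array(z, c(16, 1, 4)))
    expect_equal(st2$mean, mean(z))
    expect_equal(st2$var, var(z))
  })
})

test_that("recalibration replaces only BN statistics, matching a full-pass oracle", {
  fx <- prune_fixture()
  recs <- fx$ds$train$records[1:16]
  g <- c(s1 = 0.5, s2 = 0.5, s3 = 1)
  student <- materialize_student(fx$teacher, g)
  # one batch covering the calibration set exactly equals a direct pass
  recal <- recalibrate_bn(student, recs, recal_batches = 1,
                          batch_size = 16, seed = 3)
  X <- trapslim:::records_to_tensor(recs, 32)
  fwd <- trapslim:::net_forward(student, X, training = TRUE,
                                collect_bn = TRUE)
  for (i in seq_along(recal$layers)) {
    ly <- recal$layers[[i]]
    if (ly$type == "bn") {
      st <- fwd$bn_stats[[ly$name]]
      expect_equal(ly$run_mean, st$mean)
      expect_equal(ly$run_var, pmax(st$var, 1e-5))
    } else if (ly$type %in% c("conv", "fc")) {
      expect_identical(ly$W, student$layers[[i]]$W)
    }
  }
  # constant input: a padding-free 1x1-image net has exactly constant
  # pre-BN activations, so the mean is that constant and the variance
  # degenerates to the configured floor
  tiny <- build_classifier(classifier_spec(c(3), 1, 2, 2), seed = 1)
  const <- lapply(1:4, function(i)
    list(image = array(100, c(2, 2, 3)), label = 1L))
  rc <- recalibrate_bn(tiny, const, recal_batches = 2, batch_size = 4,
                       seed = 1)
  bn <- Find(function(l) l$type == "bn", rc$layers)
  Xc <- trapslim:::records_to_tensor(const, 2)
  pre <- trapslim:::conv_forward(Xc, 2, 2, Find(function(l)
    l$type == "conv", rc$layers), 4)$out
  expect_equal(bn$run_mean, colMeans(apply(pre, 2, rbind)))
  expect_true(all(bn$run_var >= 1e-5))
  expect_error(recalibrate_bn(student, recs, recal_batches = 0), ">= 1")
})

test_that("fitness follows both readings of the accuracy/size formula", {
  expect_equal(fitness_value(0.9, 100, 100, "literal_product"), 0.9)
  expect_equal(fitness_value(0.9, 100, 100, "accuracy_per_size"), 0.9)
  expect_equal(fitness_value(0.8, 50, 100, "literal_product"), 0.40)
  expect_equal(fitness_value(0.8, 50, 100, "accuracy_per_size"), 1.60)
})

test_that("genome sampling honours the MAC band, with exact enumeration on one group", {
  arch <- toy_arch(8, 12, classes = 3, side = 32)
  cfg <- desk_search_config(compression_target = 0.5,
                            band_halfwidth = 0.05, seed = 1)
  base <- count_macs(arch)$macs_total
  withr::with_seed(8, {
    for (i in 1:200) {
      g <- sample_genome(arch, cfg)
      r <- count_macs(apply_genome(arch, g))$macs_total / base
      expect_true(r >= 0.45 && r <= 0.55)
    }
  })
  # the identity band admits the all-ones genome (ratio exactly 1)
  cfg1 <- desk_search_config(compression_target = 1,
                             band_halfwidth = 0.05, seed = 1)
  g1 <- withr::with_seed(2, sample_genome(arch, cfg1))
  r1 <- count_macs(apply_genome(arch, g1))$macs_total / base
  expect_true(r1 >= 0.95 && r1 <= 1)
  expect_true(count_macs(apply_genome(arch, c(s1 = 1, s2 = 1)))$macs_total
              == base)
  # single-group net: brute-force the feasible grid and check containment
  one <- as_arch_descriptor(classifier_spec(c(10), 1, 2, 16))
  base1 <- count_macs(one)$macs_total
  feasible <- Filter(function(r) {
    ratio <- count_macs(apply_genome(one, c(s1 = r)))$macs_total / base1
    ratio >= 0.35 && ratio <= 0.65
  }, seq(0.1, 1, 0.1))
  cfg2 <- desk_search_config(compression_target = 0.5,
                             band_halfwidth = 0.15, seed = 1)
  withr::with_seed(5, {
    for (i in 1:50)
      expect_true(sample_genome(one, cfg2)[["s1"]] %in% feasible)
  })
  # infeasible band is rejected with a diagnostic
  cfg3 <- desk_search_config(compression_target = 0.02,
                             band_halfwidth = 0.001, retry_budget = 50)
  expect_error(withr::with_seed(1, sample_genome(one, cfg3)),
               "closest achieved ratio")
})

test_that("student materialization keeps the largest-L1 channels and exact costs", {
  fx <- prune_fixture()
  teacher <- fx$teacher
  # identity genome: bitwise-equal forward pass
  g1 <- c(s1 = 1, s2 = 1, s3 = 1)
  s_id <- materialize_student(teacher, g1)
  X <- trapslim:::records_to_tensor(fx$ds$test$records[1:6], 32)
  expect_identical(trapslim:::net_forward(teacher, X)$logits,
                   trapslim:::net_forward(s_id, X)$logits)
  # half pruning: kept indices are exactly the top-|.|_1 filters
  g <- c(s1 = 0.5, s2 = 0.5, s3 = 0.5)
  keeps <- trapslim:::kept_channels(teacher, g)
  conv1 <- Find(function(l) l$type == "conv", teacher$layers)
  l1 <- colSums(abs(conv1$W))
  expect_identical(keeps$s1, sort(order(-l1)[1:3]))
  student <- materialize_student(teacher, g)
  expect_identical(trapslim:::count_net_params(student),
                   count_params(apply_genome(teacher$arch, g))$params_total)
})

test_that("crossover and mutation respect parentage and the band", {
  arch <- toy_arch(8, 12, classes = 3, side = 32)
  cfg <- desk_search_config(compression_target = 0.5, band_halfwidth = 0.1,
                            population_size = 20, mutation_rate = 0,
                            seed = 1)
  p1 <- withr::with_seed(1, sample_genome(arch, cfg))
  p2 <- withr::with_seed(7, sample_genome(arch, cfg))
  base <- count_macs(arch)$macs_total
  off <- withr::with_seed(3, evolve_generation(list(p1, p2), arch, cfg))
  expect_length(off, 20)
  for (o in off) {
    # without mutation every gene comes from a parent at the same locus
    for (g in names(o)) expect_true(o[[g]] %in% c(p1[[g]], p2[[g]]))
    r <- count_macs(apply_genome(arch, o))$macs_total / base
    expect_true(r >= 0.4 && r <= 0.6)
  }
  same <- withr::with_seed(4, evolve_generation(list(p1, p1), arch, cfg))
  for (o in same) expect_identical(unname(o), unname(p1))
  expect_error(evolve_generation(list(p1), arch, cfg), "two parents")
})

test_that("the genetic search matches brute-force enumeration on a one-group net", {
  scene <- micro_scene(seed = 13, n_species = 2, n_sites = 2,
                       image_side = 16, instances_per_class = c(10, 8))
  ds <- generate_dataset(scene)
  teacher <- build_classifier(classifier_spec(c(10), 1, 2, 16), seed = 1)
  teacher <- train_classifier(teacher, ds$train, ds$test,
                              fast_train(max_epochs = 4))
  cfg <- desk_search_config(compression_target = 0.5,
                            band_halfwidth = 0.25, population_size = 6,
                            parents_kept = 2, max_generations = 4,
                            recal_batches = 2, seed = 9,
                            p0 = count_params(teacher$arch)$params_total)
  base <- count_macs(teacher$arch)$macs_total
  # brute force every feasible single ratio with the identical evaluator
  feasible <- Filter(function(r) {
    ratio <- count_macs(apply_genome(teacher$arch,
                                     c(s1 = r)))$macs_total / base
    ratio >= 0.25 && ratio <= 0.75
  }, seq(0.1, 1, 0.1))
  ev <- trapslim:::make_evaluator(teacher, ds$train, ds$test, cfg)
  best_brute <- max(vapply(feasible,
                           function(r) ev$eval(c(s1 = r))$f, numeric(1)))
  res <- ga_search(teacher, ds$train, ds$test, cfg)
  expect_equal(res$best$f, best_brute)
  # elitism: best fitness never decreases; bounded generations
  expect_true(all(diff(res$history$best_f) >= 0))
  expect_lte(nrow(res$history), cfg$max_generations + 1)
})

test_that("random-sampling search uses the same evaluation pipeline", {
  fx <- prune_fixture()
  cfg <- desk_search_config(population_size = 6, parents_kept = 2,
                            max_generations = 2, recal_batches = 2,
                            band_halfwidth = 0.1, seed = 4)
  rs <- random_search(fx$teacher, fx$ds$train, fx$ds$test, cfg,
                      n_evals = 8)
  expect_s3_class(rs, "random_search")
  base <- count_macs(fx$teacher$arch)$macs_total
  expect_true(rs$best$macs / base >= 0.4 && rs$best$macs / base <= 0.6)
  expect_true(all(diff(rs$history$best_f) >= 0))
})
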