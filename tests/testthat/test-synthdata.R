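test_that("background rasters are deterministic, well-shaped and site-separable", {
  cfg <- micro_scene(seed = 9)
  b1 <- generate_background(2, cfg, draw = 5)
  b2 <- generate_background(2, cfg, draw = 5)
  expect_identical(b1, b2)
  expect_false(identical(b1, generate_background(2, cfg, draw = 6)))
  expect_identical(dim(b1), c(32L, 32L, 3L))
  expect_true(all(b1 >= 0 & b1 <= 255))
  # distinct site signatures: channel means differ clearly with noise off
  quiet <- micro_scene(seed = 9, bg_noise_sd = 0)
  m1 <- apply(generate_background(1, quiet), 3, mean)
  m2 <- apply(generate_background(2, quiet), 3, mean)
  expect_gt(max(abs(m1 - m2)), 20)
  expect_error(generate_background(99, cfg), "site out of range")
})

test_that("instance cutouts have exact masks, species-specific shapes, contrast scaling", {
  cfg <- micro_scene(seed = 3)
  c1 <- generate_instance(1, cfg, draw = 2)
  expect_identical(c1, generate_instance(1, cfg, draw = 2))
  expect_identical(dim(c1$patch)[1:2], dim(c1$mask))
  expect_gt(mean(c1$mask), 0)
  expect_lt(mean(c1$mask), 1)
  # invisible animal at zero contrast
  c0 <- generate_instance(1, micro_scene(seed = 3, foreground_contrast = 0))
  expect_true(all(c0$patch == 128))
  # different species on the same draw give different silhouettes
  c2 <- generate_instance(2, cfg, draw = 2)
  expect_false(identical(c1$mask, c2$mask))
  # shape families differ in compactness (perimeter-like proxy): a lobed
  # blob has more boundary pixels per unit area than an ellipse
  boundary_frac <- function(m) {
    inner <- m[-1, ] & m[-nrow(m), ]
    mean(m) / max(mean(m & !rbind(inner, FALSE)), 1e-9)
  }
  expect_false(isTRUE(all.equal(boundary_frac(c1$mask),
                                boundary_frac(c2$mask))))
})

test_that("scene composition is an exact masked copy with a tight box", {
  cfg <- micro_scene(seed = 5)
  bg <- generate_background(1, cfg)
  cut <- rect_cutout(6, 9)
  rec <- compose_scene(bg, cut, c(0, 0))
  expect_identical(unname(rec$bbox), c(0L, 0L, 9L, 6L))
  # pixels outside the mask are untouched byte for byte
  out <- !rec$mask
  for (ch in 1:3)
    expect_identical(rec$image[, , ch][out], bg[, , ch][out])
  # pixels inside the mask equal the patch
  expect_true(all(rec$image[1:6, 1:9, ] == 77))
  expect_error(compose_scene(bg, cut, c(30, 30)), "does not fit")
})

test_that("generated datasets respect the confound design and bookkeeping", {
  cfg <- micro_scene(seed = 11, n_sites = 3, n_species = 3,
                     confound_strength = 1)
  ds <- generate_dataset(cfg)
  expect_identical(length(ds$train), 3L * 8L)
  expect_identical(length(ds$test), 3L * 6L)
  expect_identical(as.vector(table(records_labels(ds$train$records))),
                   rep(8L, 3))
  # reproducibility at manifest level
  ds2 <- generate_dataset(cfg)
  expect_identical(ds$train$records, ds2$train$records)
  expect_identical(ds$test$records, ds2$test$records)
  # perfect confound: the site determines the species in training data
  df <- as.data.frame(ds$train)
  expect_true(all(df$site == ((df$label - 1) %% 3) + 1))
  # decorrelated test pairing: every species seen at more than one site
  dft <- as.data.frame(ds$test)
  expect_true(all(tapply(dft$site, dft$label,
                         function(s) length(unique(s))) > 1))
  # every record satisfies the bbox/mask invariants
  for (r in c(ds$train$records, ds$test$records))
    expect_true(validate_record(r, cfg$image_side))
  expect_error(scene_config(n_sites = 2, n_species = 4,
                            confound_strength = 1), "home site")
})

test_that("a background probe predicts species on confounded train data but not at test", {
  cfg <- scene_config(n_sites = 4, n_species = 4, image_side = 48,
                      instances_per_class = c(20, 15),
                      foreground_contrast = 0.2, confound_strength = 1,
                      seed = 21)
  ds <- generate_dataset(cfg)
  feats <- function(recs) t(vapply(recs, function(r) apply(r$image, 3, mean),
                                   numeric(3)))
  ytr <- records_labels(ds$train$records)
  Xtr <- feats(ds$train$records)
  centroids <- apply(Xtr, 2, tapply, ytr, mean)
  nearest <- function(X) {
    apply(X, 1, function(x)
      which.min(colSums((t(centroids) - x)^2)))
  }
  train_acc <- mean(nearest(Xtr) == ytr)
  test_acc <- mean(nearest(feats(ds$test$records)) ==
                     records_labels(ds$test$records))
  expect_gt(train_acc, 0.9)     # backgrounds give the label away in train
  expect_lt(test_acc, 0.5)      # and carry no label signal at test
})
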