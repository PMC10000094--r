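test_that("the identity paste transform reproduces plain composition exactly", {
  cfg <- micro_scene(seed = 2)
  bg <- generate_background(1, cfg)
  cut <- rect_cutout(7, 5, value = 91)
  pp <- paste_params(rotation_range = c(0, 0), scale_range = c(1, 1))
  withr::with_seed(1, {
    pasted <- random_paste(cut, bg, pp, position = c(0, 0))
  })
  ref <- compose_scene(bg, cut, c(0, 0), provenance = "synthesized")
  expect_identical(pasted$image, ref$image)
  expect_identical(pasted$bbox, ref$bbox)
  expect_identical(pasted$provenance, "synthesized")
})

test_that("a quarter-turn swaps the bounding-box sides (within rasterization)", {
  cut <- rect_cutout(6, 12)
  tc <- trapslim:::transform_cutout(cut, 90, 1)
  expect_lte(abs(ncol(tc$mask) - 6), 1)
  expect_lte(abs(nrow(tc$mask) - 12), 1)
  # axis-aligned quarter turns preserve the mask pixel count closely
  expect_lte(abs(sum(tc$mask) - sum(cut$mask)), 0.05 * sum(cut$mask))
})

test_that("random placement covers the image and stays in bounds", {
  cfg <- micro_scene(seed = 7, image_side = 48)
  bg <- generate_background(2, cfg)
  cut <- generate_instance(1, cfg)
  quadrant <- integer(0)
  withr::with_seed(31, {
    for (i in 1:200) {
      r <- random_paste(cut, bg)
      expect_true(validate_record(r, 48))
      cx <- (r$bbox[1] + r$bbox[3]) / 2
      cy <- (r$bbox[2] + r$bbox[4]) / 2
      quadrant <- c(quadrant, (cx >= 24) + 2 * (cy >= 24) + 1)
    }
  })
  expect_setequal(unique(quadrant), 1:4)
  # oversized cutout has no placement
  big <- rect_cutout(60, 60)
  expect_error(withr::with_seed(1, random_paste(
    big, bg, paste_params(c(0, 0), c(1, 1)))), "no valid placement")
})

test_that("suppression rectangles are always disjoint from the foreground box", {
  bbox <- c(0, 0, 16, 32)               # left half of a 32x32 image
  withr::with_seed(12, {
    for (i in 1:1000) {
      m <- sample_rbs_mask(c(32, 32), bbox, area_range = c(0.02, 0.08))
      expect_false(is.null(m))
      r <- m$rect
      expect_true(r[3] <= bbox[1] || r[1] >= bbox[3] ||
                    r[4] <= bbox[2] || r[2] >= bbox[4])
      expect_true(r[1] >= 0 && r[2] >= 0 && r[3] <= 32 && r[4] <= 32)
    }
  })
  # no disjoint rectangle exists when the box covers everything
  expect_null(withr::with_seed(1, sample_rbs_mask(c(32, 32),
                                                  c(0, 0, 32, 32))))
  # degenerate area/aspect: the side is round(side * sqrt(f))
  m <- withr::with_seed(3, sample_rbs_mask(c(40, 40), c(0, 0, 4, 4),
                                           area_range = c(0.09, 0.09),
                                           aspect_range = c(1, 1)))
  expect_identical(unname(m$rect[3] - m$rect[1]), round(40 * sqrt(0.09)))
  expect_identical(unname(m$rect[4] - m$rect[2]), round(40 * sqrt(0.09)))
})

test_that("background suppression never touches the animal and fills exactly", {
  cfg <- micro_scene(seed = 8)
  ds <- generate_dataset(cfg)
  rec <- ds$train$records[[1]]
  b <- rec$bbox
  rows <- (b[2] + 1):b[4]; cols <- (b[1] + 1):b[3]
  withr::with_seed(5, {
    for (i in 1:50) {
      out <- apply_rbs(rec)
      expect_identical(out$image[rows, cols, ], rec$image[rows, cols, ])
      expect_identical(out$bbox, rec$bbox)
      expect_identical(out$label, rec$label)
      changed <- which(out$image != rec$image, arr.ind = TRUE)
      if (nrow(changed) > 0) expect_true(all(out$image[changed] == 0))
    }
  })
  expect_identical(apply_rbs(rec, n_masks = 0), rec)
  # impossible suppression leaves the record unmodified with a warning
  full <- rec; full$bbox <- c(0, 0, 32, 32)
  expect_warning(out <- apply_rbs(full, max_tries = 5), "unchanged")
  expect_identical(out$image, full$image)
})

test_that("cutout occlusion may strike the foreground while suppression cannot", {
  cfg <- micro_scene(seed = 14)
  ds <- generate_dataset(cfg)
  rec <- ds$train$records[[1]]
  b <- rec$bbox
  hit_fg <- FALSE
  withr::with_seed(6, {
    for (i in 1:60) {
      out <- apply_cutout(rec, area_range = c(0.2, 0.4))
      changed <- which(out$image[, , 1] != rec$image[, , 1], arr.ind = TRUE)
      if (nrow(changed) > 0) {
        x <- changed[, 2] - 1; y <- changed[, 1] - 1
        if (any(x >= b[1] & x < b[3] & y >= b[2] & y < b[4]))
          hit_fg <- TRUE
      }
    }
  })
  expect_true(hit_fg)
})

test_that("the augmented-set builder adds the requested records deterministically", {
  cfg <- micro_scene(seed = 4)
  ds <- generate_dataset(cfg)
  N <- length(ds$train)
  same <- build_augmented_set(ds$train, ds$cutouts, ds$backgrounds,
                              mix = list(is_fraction = 0, rbs_fraction = 0))
  expect_identical(same$records, ds$train$records)
  aug <- build_augmented_set(ds$train, ds$cutouts, ds$backgrounds,
                             mix = list(is_fraction = 0.5,
                                        rbs_fraction = 0.5), seed = 17)
  expect_identical(length(aug), as.integer(N + 2 * round(0.5 * N)))
  prov <- vapply(aug$records, function(r) r$provenance, character(1))
  expect_identical(sum(prov == "synthesized"), as.integer(round(0.5 * N)))
  expect_identical(sum(prov == "suppressed"), as.integer(round(0.5 * N)))
  # labels are never changed and invariants hold on every addition
  for (r in aug$records[(N + 1):length(aug)]) {
    expect_true(r$label %in% 1:3)
    expect_true(validate_record(r, cfg$image_side))
  }
  aug2 <- build_augmented_set(ds$train, ds$cutouts, ds$backgrounds,
                              mix = list(is_fraction = 0.5,
                                         rbs_fraction = 0.5), seed = 17)
  expect_identical(aug$records, aug2$records)
  expect_error(build_augmented_set(ds$train, ds$cutouts, list(),
                                   mix = list(is_fraction = 1,
                                              rbs_fraction = 0)),
               "background pool is empty")
})
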