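# Shared fixtures: everything is generated in code at test time.

# A micro scene that generates in well under a second.
micro_scene <- function(seed = 1, ...) {
  args <- list(n_sites = 3, n_species = 3, image_side = 32,
               instances_per_class = c(8, 6), fg_size_frac = 0.5,
               foreground_contrast = 0.6, confound_strength = 0.5,
               cutouts_per_class = 4, backgrounds_per_site = 3, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(scene_config, args)
}

micro_spec <- function(widths = c(6, 8), classes = 3, side = 32, ...) {
  classifier_spec(widths, 1, num_classes = classes, input_side = side, ...)
}

fast_train <- function(...) {
  args <- list(initial_lr = 0.05, batch_size = 16, early_stop_patience = 5,
               max_epochs = 6, seed = 1)
  args[names(list(...))] <- list(...)
  do.call(train_config, args)
}

# Solid-colour, trivially separable records (with mild noise).
toy_records <- function(n_per_class, side = 16, seed = 1,
                        colours = list(c(200, 40, 40), c(40, 40, 200))) {
  recs <- list()
  withr::with_seed(seed, {
    for (cl in seq_along(colours)) {
      for (i in seq_len(n_per_class)) {
        img <- array(rep(colours[[cl]], each = side * side),
                     c(side, side, 3)) +
          array(round(runif(side * side * 3, -8, 8)), c(side, side, 3))
        recs[[length(recs) + 1]] <-
          list(image = pmin(pmax(img, 0), 255), label = as.integer(cl),
               bbox = c(0, 0, side, side), mask = NULL, site = 1L,
               provenance = "real_composite")
      }
    }
  })
  recs
}

# A cutout whose mask is a full rectangle (tight by construction).
rect_cutout <- function(h = 6, w = 9, label = 1L, value = 77) {
  structure(list(patch = array(value, c(h, w, 3)),
                 mask = matrix(TRUE, h, w), label = label),
            class = "instance_cutout")
}

# Simple two-conv toy descriptor: conv 3->c1 -> conv c1->c2 -> gap -> fc.
toy_arch <- function(c1 = 8, c2 = 8, classes = 2, side = 16) {
  as_arch_descriptor(classifier_spec(c(c1, c2), 1, num_classes = classes,
                                     input_side = side))
}
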