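#' Synthetic camera-trap scenes with a controllable background confound
#'
#' Camera traps are fixed installations, so every image from one site
#' shares a near-constant background signature; when a species is mostly
#' photographed at "its" sites, background alone predicts the label in
#' training data. The generator reproduces exactly that statistical
#' structure: each site has a distinct background signature (base hue plus
#' a site-specific texture), each species a distinct parametric silhouette,
#' and \code{confound_strength} sets the probability that a training image
#' of a species comes from its home site. Test images pair species and
#' sites uniformly, so a background shortcut learned in training collapses
#' at test time -- the premise of shortcut learning, present by
#' construction and with exact masks and boxes available.
#'
#' @name synthdata
NULL

#' Scene configuration
#'
#' @param n_sites number of camera sites.
#' @param n_species number of species.
#' @param image_side image side length in pixels.
#' @param confound_strength probability in [0, 1] that a training image of
#'   species s is taken at s's home site; test images are always uniform.
#' @param instances_per_class c(train, test) image counts per species.
#' @param foreground_contrast visual salience of the animal against the
#'   background, in [0, 1]; 0 renders the animal as pure neutral gray.
#' @param bg_noise_sd per-pixel Gaussian noise of background rasters.
#' @param fg_size_frac silhouette patch side as a fraction of image side.
#' @param cutouts_per_class size of the standalone instance-cutout library.
#' @param backgrounds_per_site size of the standalone background library.
#' @param seed master seed; every raster is a pure function of (seed,
#'   stream indices).
#' @return A \code{scene_config} list.
#' @export
scene_config <- function(n_sites = 4, n_species = 4, image_side = 96,
                         confound_strength = 1.0,
                         instances_per_class = c(70, 30),
                         foreground_contrast = 0.3,
                         bg_noise_sd = 8, fg_size_frac = 0.38,
                         cutouts_per_class = 12, backgrounds_per_site = 10,
                         seed = 1) {
  stop_if(confound_strength < 0 || confound_strength > 1,
          "confound_strength must lie in [0, 1]")
  stop_if(confound_strength == 1 && n_sites < n_species,
          "a perfect confound needs at least one home site per species")
  stop_if(n_species < 2, "need at least two species")
  structure(list(n_sites = as.integer(n_sites),
                 n_species = as.integer(n_species),
                 image_side = as.integer(image_side),
                 confound_strength = confound_strength,
                 instances_per_class = as.integer(instances_per_class),
                 foreground_contrast = foreground_contrast,
                 bg_noise_sd = bg_noise_sd,
                 fg_size_frac = fg_size_frac,
                 cutouts_per_class = as.integer(cutouts_per_class),
                 backgrounds_per_site = as.integer(backgrounds_per_site),
                 seed = as.integer(seed)),
            class = "scene_config")
}

# pixels are 8-bit rasters: round, then clamp to 0..255
clamp255 <- function(x) pmin(pmax(round(x), 0), 255)

site_base_rgb <- function(site, n_sites) {
  hue <- (site - 1) / n_sites
  as.numeric(grDevices::col2rgb(grDevices::hsv(hue, 0.45, 0.55)))
}

species_tint <- function(label, n_species) {
  hue <- ((label - 1) + 0.5) / n_species
  as.numeric(grDevices::col2rgb(grDevices::hsv(hue, 0.9, 1))) - 128
}

#' Generate one background raster for a site
#'
#' Deterministic per (cfg$seed, site, draw): the same triple always yields
#' the same raster. Each site has a distinct base hue and a site-specific
#' texture (frequency and orientation of a sinusoidal grating), with
#' per-draw pixel noise, so even a linear probe can identify the site from
#' raw pixels.
#'
#' @param site site id in 1..n_sites.
#' @param cfg a \code{\link{scene_config}}.
#' @param draw draw index separating different images of the same site.
#' @return numeric array (side, side, 3) of pixel values in 0--255.
#' @export
generate_background <- function(site, cfg, draw = 1) {
  stop_if(site < 1 || site > cfg$n_sites, "site out of range")
  s <- cfg$image_side
  base <- site_base_rgb(site, cfg$n_sites)
  freq <- 2 + (site %% 4)                       # cycles per image
  theta <- pi * (site - 1) / cfg$n_sites
  yy <- matrix(seq_len(s), s, s)
  xx <- matrix(seq_len(s), s, s, byrow = TRUE)
  tex <- 18 * sin(2 * pi * freq * (xx * cos(theta) + yy * sin(theta)) / s)
  with_seed(derive_seed(cfg$seed, 11, site, draw), {
    img <- array(0, c(s, s, 3))
    for (ch in 1:3) {
      noise <- if (cfg$bg_noise_sd > 0)
        matrix(stats::rnorm(s * s, 0, cfg$bg_noise_sd), s, s) else 0
      img[, , ch] <- clamp255(base[ch] + tex + noise)
    }
    img
  })
}

# Polar silhouette radius for a species' shape family. phi in radians.
species_radius <- function(phi, label, aspect, wobble_phase) {
  family <- (label - 1) %% 3
  if (family == 0) {                            # ellipse
    a <- 1; b <- 1 / aspect
    a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
  } else if (family == 1) {                     # lobed blob
    lobes <- 3 + ((label - 1) %/% 3)
    1 / (1 + 0.38) * (1 + 0.38 * sin(lobes * phi + wobble_phase))
  } else {                                      # regular polygon
    m <- 3 + ((label - 1) %/% 3)
    phi_m <- (phi + wobble_phase) %% (2 * pi / m)
    cos(pi / m) / cos(phi_m - pi / m)
  }
}

#' Generate one instance cutout for a species
#'
#' Each species has a distinct parametric silhouette family (ellipse,
#' lobed blob, or polygon, with jittered pose per draw), filled with a
#' species tint and low-contrast texture scaled by
#' \code{foreground_contrast}. The binary mask covers exactly the
#' silhouette. At contrast 0 the patch is uniform neutral gray (128).
#'
#' @param label species id in 1..n_species.
#' @param cfg a \code{\link{scene_config}}.
#' @param draw draw index.
#' @return list(patch, mask, label): class \code{instance_cutout}.
#' @export
generate_instance <- function(label, cfg, draw = 1) {
  stop_if(label < 1 || label > cfg$n_species, "label out of range")
  p <- max(8L, as.integer(round(cfg$fg_size_frac * cfg$image_side)))
  with_seed(derive_seed(cfg$seed, 23, label, draw), {
    rot <- stats::runif(1, 0, 2 * pi)
    aspect <- stats::runif(1, 1.3, 1.9)
    wobble <- stats::runif(1, 0, 2 * pi)
    cy <- (p + 1) / 2; cx <- (p + 1) / 2
    R0 <- 0.42 * p
    yy <- matrix(seq_len(p), p, p) - cy
    xx <- matrix(seq_len(p), p, p, byrow = TRUE) - cx
    phi <- atan2(yy, xx) - rot
    r <- sqrt(yy^2 + xx^2)
    mask <- r <= R0 * species_radius(phi, label, aspect, wobble)
    tint <- species_tint(label, cfg$n_species)
    stripes <- 25 * sin(2 * pi * 3 * (xx * cos(rot) + yy * sin(rot)) / p)
    patch <- array(128, c(p, p, 3))
    k <- cfg$foreground_contrast
    if (k > 0) {
      for (ch in 1:3) {
        noise <- matrix(stats::rnorm(p * p, 0, 5), p, p)
        patch[, , ch] <- clamp255(128 + k * (0.7 * tint[ch] + stripes + noise))
      }
    }
    structure(list(patch = patch, mask = mask, label = as.integer(label)),
              class = "instance_cutout")
  })
}

mask_tight_bbox <- function(mask) {
  ys <- which(rowSums(mask) > 0)
  xs <- which(colSums(mask) > 0)
  stop_if(length(ys) == 0, "mask has no on-pixels")
  # 0-based, half-open (x0, y0, x1, y1)
  c(x0 = xs[1] - 1L, y0 = ys[1] - 1L, x1 = xs[length(xs)],
    y1 = ys[length(ys)])
}

#' Paste a cutout onto a background at a fixed position
#'
#' Mask-on pixels of the cutout replace the background; everything else is
#' untouched byte for byte. The bounding box is the tight box of the
#' placed mask. Coordinates are 0-based and half-open throughout.
#'
#' @param background raster (side, side, 3).
#' @param cutout an \code{instance_cutout}.
#' @param position c(x, y): 0-based top-left corner of the patch.
#' @param site optional site id recorded on the output.
#' @param provenance provenance tag for the record.
#' @return An annotated-image record: list(image, label, bbox, mask, site,
#'   provenance).
#' @export
compose_scene <- function(background, cutout, position, site = NA_integer_,
                          provenance = "real_composite") {
  d <- dim(background)
  ph <- nrow(cutout$mask); pw <- ncol(cutout$mask)
  x <- position[1]; y <- position[2]
  stop_if(x < 0 || y < 0 || y + ph > d[1] || x + pw > d[2],
          "cutout does not fit inside the background at this position")
  img <- background
  mask_full <- matrix(FALSE, d[1], d[2])
  rows <- (y + 1):(y + ph); cols <- (x + 1):(x + pw)
  mask_full[rows, cols] <- cutout$mask
  for (ch in 1:3) {
    sub <- img[rows, cols, ch]
    sub[cutout$mask] <- cutout$patch[, , ch][cutout$mask]
    img[rows, cols, ch] <- sub
  }
  bbox <- mask_tight_bbox(mask_full)
  list(image = img, label = cutout$label, bbox = bbox, mask = mask_full,
       site = as.integer(site), provenance = provenance)
}

new_trap_dataset <- function(records, cfg) {
  structure(list(records = records, n_species = cfg$n_species,
                 n_sites = cfg$n_sites, image_side = cfg$image_side),
            class = "trap_dataset")
}

#' @export
print.trap_dataset <- function(x, ...) {
  cat(sprintf("trap_dataset: %d records, %d species, %d sites, %dpx\n",
              length(x$records), x$n_species, x$n_sites, x$image_side))
  print(table(label = records_labels(x$records)))
  invisible(x)
}

#' @export
`[.trap_dataset` <- function(x, i) {
  x$records <- x$records[i]
  x
}

#' @export
length.trap_dataset <- function(x) length(x$records)

#' Metadata table of a dataset
#'
#' @param x a \code{trap_dataset}.
#' @param ... unused.
#' @return data.frame with one row per record: label, site, bbox
#'   coordinates, provenance.
#' @export
as.data.frame.trap_dataset <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$records), function(i) {
    r <- x$records[[i]]
    data.frame(id = i, label = r$label, site = r$site,
               x0 = r$bbox[1], y0 = r$bbox[2], x1 = r$bbox[3],
               y1 = r$bbox[4], provenance = r$provenance)
  }))
}

home_site <- function(label, n_sites) ((label - 1L) %% n_sites) + 1L

#' Generate a full synthetic camera-trap dataset
#'
#' Training images pair species s with its home site with probability
#' \code{confound_strength} (uniform over the other sites otherwise); test
#' images pair species and sites uniformly, so the background cue is
#' decorrelated from the label at test time. Also emits standalone cutout
#' and background libraries for the augmentation stage. Fully reproducible
#' from \code{cfg$seed}.
#'
#' @param cfg a \code{\link{scene_config}}.
#' @return list(train, test, cutouts, backgrounds): two
#'   \code{trap_dataset}s, a list of \code{instance_cutout}s, and a list of
#'   background records (list(image, site)).
#' @export
generate_dataset <- function(cfg) {
  gen_split <- function(split_id, n_per_class, confounded) {
    records <- list()
    for (s in seq_len(cfg$n_species)) {
      for (i in seq_len(n_per_class)) {
        rec_seed <- derive_seed(cfg$seed, 31, split_id, s, i)
        rec <- with_seed(rec_seed, {
          site <- if (confounded &&
                      stats::runif(1) < cfg$confound_strength)
            home_site(s, cfg$n_sites)
          else sample.int(cfg$n_sites, 1)
          bg <- generate_background(site, cfg, draw = split_id * 10000 + i)
          cut <- generate_instance(s, cfg, draw = split_id * 10000 + i)
          ph <- nrow(cut$mask); pw <- ncol(cut$mask)
          x <- sample.int(cfg$image_side - pw + 1, 1) - 1L
          y <- sample.int(cfg$image_side - ph + 1, 1) - 1L
          compose_scene(bg, cut, c(x, y), site = site)
        })
        records[[length(records) + 1]] <- rec
      }
    }
    new_trap_dataset(records, cfg)
  }
  train <- gen_split(1L, cfg$instances_per_class[1], confounded = TRUE)
  test <- gen_split(2L, cfg$instances_per_class[2], confounded = FALSE)
  cutouts <- list()
  for (s in seq_len(cfg$n_species))
    for (i in seq_len(cfg$cutouts_per_class))
      cutouts[[length(cutouts) + 1]] <-
        generate_instance(s, cfg, draw = 90000 + i)
  backgrounds <- list()
  for (site in seq_len(cfg$n_sites))
    for (i in seq_len(cfg$backgrounds_per_site))
      backgrounds[[length(backgrounds) + 1]] <-
        list(image = generate_background(site, cfg, draw = 90000 + i),
             site = site)
  list(train = train, test = test, cutouts = cutouts,
       backgrounds = backgrounds)
}

#' Validate annotated-image invariants
#'
#' Checks the bounding box lies inside the image, is non-degenerate, and
#' (when a mask is present) that every mask-on pixel lies inside the box.
#'
#' @param rec an annotated-image record.
#' @param image_side expected image side.
#' @return TRUE invisibly; errors on violation.
#' @export
validate_record <- function(rec, image_side = nrow(rec$image)) {
  b <- rec$bbox
  stop_if(!(b[1] >= 0 && b[1] < b[3] && b[3] <= image_side &&
            b[2] >= 0 && b[2] < b[4] && b[4] <= image_side),
          "bounding box violates 0-based half-open bounds")
  if (!is.null(rec$mask)) {
    on <- which(rec$mask, arr.ind = TRUE)
    x <- on[, 2] - 1L; y <- on[, 1] - 1L
    stop_if(!(all(x >= b[1]) && all(x < b[3]) &&
              all(y >= b[2]) && all(y < b[4])),
            "mask pixels outside bounding box")
  }
  invisible(TRUE)
}
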