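#' Mixed data augmentation: image synthesis and background suppression
#'
#' Two complementary augmentations break the coupling between an animal
#' and its home background. Image synthesis (IS) pastes a segmented animal
#' instance, randomly rotated and resized, onto a different background
#' frame, actively diversifying the scene behind each species. Regional
#' background suppression (RBS) zeroes a random rectangle that is strictly
#' disjoint from the animal's bounding box, suppressing background
#' evidence while guaranteeing the foreground is untouched. The mixed
#' strategy adds both kinds of records to the training set.
#'
#' @name augment
NULL

#' Random-paste parameters
#'
#' @param rotation_range degrees, interval within [0, 360).
#' @param scale_range relative-size interval (positive).
#' @param n_instances cutouts pasted per synthesized image.
#' @return A \code{paste_params} list.
#' @export
paste_params <- function(rotation_range = c(0, 360),
                         scale_range = c(0.6, 1.4), n_instances = 1) {
  stop_if(any(scale_range <= 0), "scale bounds must be positive")
  stop_if(rotation_range[1] < 0 || rotation_range[2] > 360 ||
          rotation_range[1] > rotation_range[2],
          "rotation_range must be an interval within [0, 360]")
  stop_if(n_instances < 1, "n_instances must be >= 1")
  list(rotation_range = rotation_range, scale_range = scale_range,
       n_instances = as.integer(n_instances))
}

# Rotate (about the patch center) then scale a cutout. The mask is
# re-rasterized with nearest-neighbour sampling, the patch with bilinear
# interpolation; the identity transform reproduces the input exactly.
transform_cutout <- function(cutout, angle_deg, scale) {
  h <- nrow(cutout$mask); w <- ncol(cutout$mask)
  th <- angle_deg * pi / 180
  nw <- max(1L, ceiling(scale * (w * abs(cos(th)) + h * abs(sin(th)))))
  nh <- max(1L, ceiling(scale * (h * abs(cos(th)) + w * abs(sin(th)))))
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ncy <- (nh + 1) / 2; ncx <- (nw + 1) / 2
  yy <- matrix(seq_len(nh), nh, nw) - ncy
  xx <- matrix(seq_len(nw), nh, nw, byrow = TRUE) - ncx
  # inverse map: unscale, then rotate by -angle
  sx <- (cos(th) * xx + sin(th) * yy) / scale + cx
  sy <- (-sin(th) * xx + cos(th) * yy) / scale + cy
  # nearest neighbour for the mask
  ry <- round(sy); rx <- round(sx)
  inb <- ry >= 1 & ry <= h & rx >= 1 & rx <= w
  nmask <- matrix(FALSE, nh, nw)
  nmask[inb] <- cutout$mask[cbind(ry[inb], rx[inb])]
  if (!any(nmask)) return(NULL)
  # bilinear for the patch
  y0 <- pmin(pmax(floor(sy), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(sx), 1), w); x1 <- pmin(x0 + 1, w)
  fy <- pmin(pmax(sy - y0, 0), 1); fx <- pmin(pmax(sx - x0, 0), 1)
  npatch <- array(128, c(nh, nw, 3))
  at <- function(pc, yy2, xx2)
    matrix(pc[cbind(as.vector(yy2), as.vector(xx2))], nh, nw)
  for (ch in 1:3) {
    pc <- cutout$patch[, , ch]
    v <- (1 - fy) * (1 - fx) * at(pc, y0, x0) +
         (1 - fy) * fx * at(pc, y0, x1) +
         fy * (1 - fx) * at(pc, y1, x0) +
         fy * fx * at(pc, y1, x1)
    m <- npatch[, , ch]; m[inb] <- round(v[inb]); npatch[, , ch] <- m
  }
  # crop to the tight box of the transformed mask
  bb <- mask_tight_bbox(nmask)
  rows <- (bb[2] + 1):bb[4]; cols <- (bb[1] + 1):bb[3]
  structure(list(patch = npatch[rows, cols, , drop = FALSE],
                 mask = nmask[rows, cols, drop = FALSE],
                 label = cutout$label),
            class = "instance_cutout")
}

#' Synthesize a training image by random pasting
#'
#' Draws a rotation uniformly from \code{rotation_range} and a scale from
#' \code{scale_range}, re-rasterizes the cutout, and pastes it at a
#' uniformly random position that keeps the transformed mask fully inside
#' the background. The bounding box is the tight box of the placed mask;
#' the label is preserved and provenance set to \code{"synthesized"}.
#'
#' @param cutout an \code{instance_cutout}.
#' @param background raster (side, side, 3).
#' @param params a \code{\link{paste_params}} (only one instance is pasted
#'   here; see \code{\link{build_augmented_set}} for \code{n_instances}).
#' @param position optional fixed c(x, y) placement (0-based top-left),
#'   bypassing the random draw.
#' @param site site id recorded on the output (NA for library
#'   backgrounds).
#' @return An annotated-image record.
#' @export
random_paste <- function(cutout, background, params = paste_params(),
                         position = NULL, site = NA_integer_) {
  stop_if(!any(cutout$mask), "cutout mask is empty")
  ang <- stats::runif(1, params$rotation_range[1], params$rotation_range[2])
  sc <- stats::runif(1, params$scale_range[1], params$scale_range[2])
  tc <- transform_cutout(cutout, ang, sc)
  stop_if(is.null(tc), "transformed mask is empty; scale too small")
  bh <- nrow(background); bw <- ncol(background)
  ph <- nrow(tc$mask); pw <- ncol(tc$mask)
  stop_if(ph > bh || pw > bw,
          "no valid placement: scaled cutout larger than background")
  if (is.null(position)) {
    position <- c(sample.int(bw - pw + 1, 1) - 1L,
                  sample.int(bh - ph + 1, 1) - 1L)
  }
  compose_scene(background, tc, position, site = site,
                provenance = "synthesized")
}

#' Sample a background-suppression rectangle disjoint from a bounding box
#'
#' Rejection-samples rectangles (area fraction uniform over
#' \code{area_range}, height/width ratio log-uniform over
#' \code{aspect_range}, top-left uniform) until one is disjoint from
#' \code{bbox}; returns \code{NULL} once \code{max_tries} draws fail.
#'
#' @param image_size c(height, width).
#' @param bbox foreground box (x0, y0, x1, y1), 0-based half-open.
#' @param area_range rectangle area as a fraction of the image area.
#' @param aspect_range height/width ratio interval.
#' @param max_tries rejection budget.
#' @param fill_value pixel value written into the rectangle.
#' @return list(rect, fill_value) of class \code{rbs_mask}, or NULL.
#' @export
sample_rbs_mask <- function(image_size, bbox, area_range = c(0.05, 0.25),
                            aspect_range = c(1 / 3, 3), max_tries = 100,
                            fill_value = 0) {
  h <- image_size[1]; w <- image_size[2]
  for (i in seq_len(max_tries)) {
    a <- stats::runif(1, area_range[1], area_range[2]) * h * w
    asp <- exp(stats::runif(1, log(aspect_range[1]), log(aspect_range[2])))
    rh <- min(h, max(1L, as.integer(round(sqrt(a * asp)))))
    rw <- min(w, max(1L, as.integer(round(sqrt(a / asp)))))
    x0 <- sample.int(w - rw + 1, 1) - 1L
    y0 <- sample.int(h - rh + 1, 1) - 1L
    rect <- c(x0 = x0, y0 = y0, x1 = x0 + rw, y1 = y0 + rh)
    disjoint <- rect[3] <= bbox[1] || rect[1] >= bbox[3] ||
                rect[4] <= bbox[2] || rect[2] >= bbox[4]
    if (disjoint)
      return(structure(list(rect = rect, fill_value = fill_value),
                       class = "rbs_mask"))
  }
  NULL
}

fill_rect <- function(img, rect, value) {
  rows <- (rect[2] + 1):rect[4]; cols <- (rect[1] + 1):rect[3]
  img[rows, cols, ] <- value
  img
}

#' Regional background suppression
#'
#' Samples \code{n_masks} suppression rectangles disjoint from the
#' record's bounding box and fills them with \code{fill_value} (raw pixel
#' value, applied before any normalization). Pixels inside the bounding
#' box are untouched byte for byte; label and box are unchanged. If no
#' disjoint rectangle can be sampled the record is returned unmodified
#' with a warning.
#'
#' @param record an annotated-image record with a bbox.
#' @param n_masks rectangles per image.
#' @param area_range,aspect_range,max_tries,fill_value see
#'   \code{\link{sample_rbs_mask}}.
#' @return The suppressed record (provenance \code{"suppressed"}).
#' @export
apply_rbs <- function(record, n_masks = 1, area_range = c(0.05, 0.25),
                      aspect_range = c(1 / 3, 3), max_tries = 100,
                      fill_value = 0) {
  stop_if(is.null(record$bbox), "record has no bounding box")
  if (n_masks == 0) return(record)
  img <- record$image
  placed <- 0
  for (i in seq_len(n_masks)) {
    m <- sample_rbs_mask(dim(img)[1:2], record$bbox, area_range,
                         aspect_range, max_tries, fill_value)
    if (is.null(m)) {
      warning("no disjoint suppression rectangle found; image unchanged")
      next
    }
    img <- fill_rect(img, m$rect, m$fill_value)
    placed <- placed + 1
  }
  if (placed == 0) return(record)
  record$image <- img
  record$provenance <- "suppressed"
  record
}

#' Cutout occlusion (foreground not protected)
#'
#' The classic random-erasing baseline: a rectangle is placed anywhere in
#' the image, including over the animal. This is the contrast to
#' \code{\link{apply_rbs}}, which never touches the foreground.
#'
#' @inheritParams apply_rbs
#' @return The occluded record (provenance \code{"cutout"}).
#' @export
apply_cutout <- function(record, n_masks = 1, area_range = c(0.05, 0.25),
                         aspect_range = c(1 / 3, 3), fill_value = 0) {
  img <- record$image
  h <- dim(img)[1]; w <- dim(img)[2]
  for (i in seq_len(n_masks)) {
    a <- stats::runif(1, area_range[1], area_range[2]) * h * w
    asp <- exp(stats::runif(1, log(aspect_range[1]), log(aspect_range[2])))
    rh <- min(h, max(1L, as.integer(round(sqrt(a * asp)))))
    rw <- min(w, max(1L, as.integer(round(sqrt(a / asp)))))
    x0 <- sample.int(w - rw + 1, 1) - 1L
    y0 <- sample.int(h - rh + 1, 1) - 1L
    img <- fill_rect(img, c(x0, y0, x0 + rw, y0 + rh), fill_value)
  }
  record$image <- img
  record$provenance <- "cutout"
  record
}

#' Build a mixed-augmentation training set
#'
#' Emits the original records plus \code{is_fraction * N} synthesized
#' records (random cutout of a class drawn from the original label
#' distribution, pasted on a random library background) and
#' \code{rbs_fraction * N} suppressed copies of randomly chosen originals.
#' Deterministic under \code{seed}; labels are never changed.
#'
#' @param train a \code{trap_dataset} or list of records.
#' @param cutouts instance-cutout library (list).
#' @param backgrounds background library (list of list(image, site)).
#' @param mix list(is_fraction, rbs_fraction) of additions relative to N.
#' @param pp a \code{\link{paste_params}}.
#' @param rbs_args list of arguments forwarded to \code{\link{apply_rbs}}.
#' @param seed RNG seed.
#' @return A \code{trap_dataset} (when \code{train} was one) or record
#'   list, originals first.
#' @export
build_augmented_set <- function(train, cutouts, backgrounds,
                                mix = list(is_fraction = 1,
                                           rbs_fraction = 1),
                                pp = paste_params(), rbs_args = list(),
                                seed = 1) {
  records <- as_record_list(train)
  N <- length(records)
  n_is <- round((mix$is_fraction %||% 0) * N)
  n_rbs <- round((mix$rbs_fraction %||% 0) * N)
  stop_if(n_is > 0 && length(backgrounds) == 0,
          "image synthesis requested but the background pool is empty")
  stop_if(n_is > 0 && length(cutouts) == 0,
          "image synthesis requested but the cutout library is empty")
  labels <- records_labels(records)
  cut_labels <- vapply(cutouts, function(c) c$label, integer(1))
  out <- records
  with_seed(derive_seed(seed, 41), {
    if (n_is > 0) {
      cls <- labels[sample.int(N, n_is, replace = TRUE)]
      for (k in seq_len(n_is)) {
        pool <- which(cut_labels == cls[k])
        stop_if(length(pool) == 0,
                sprintf("no cutouts available for class %d", cls[k]))
        cut <- cutouts[[if (length(pool) == 1) pool else sample(pool, 1)]]
        bg <- backgrounds[[sample.int(length(backgrounds), 1)]]
        rec <- NULL
        for (i in seq_len(pp$n_instances)) {
          base <- if (is.null(rec)) bg$image else rec$image
          one <- random_paste(cut, base, pp, site = bg$site)
          if (is.null(rec)) rec <- one
          else {                         # union of masks, joint tight box
            rec$image <- one$image
            rec$mask <- rec$mask | one$mask
            rec$bbox <- mask_tight_bbox(rec$mask)
          }
        }
        out[[length(out) + 1]] <- rec
      }
    }
    if (n_rbs > 0) {
      pick <- sample.int(N, n_rbs, replace = n_rbs > N)
      for (k in pick)
        out[[length(out) + 1]] <-
          do.call(apply_rbs, c(list(record = records[[k]]), rbs_args))
    }
  })
  if (inherits(train, "trap_dataset")) {
    train$records <- out
    train
  } else out
}
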