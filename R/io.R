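#' Dataset and artifact input/output
#'
#' Datasets are written as PNG images plus a COCO-style JSON manifest
#' (images, annotations with \code{bbox = [x, y, w, h]} converted at this
#' boundary from the package's 0-based half-open corners, and categories).
#' Masks, when present, are stored as single-channel PNGs alongside.
#'
#' @name io
NULL

bbox_to_coco <- function(b) c(b[1], b[2], b[3] - b[1], b[4] - b[2])
bbox_from_coco <- function(b) c(x0 = b[1], y0 = b[2], x1 = b[1] + b[3],
                                y1 = b[2] + b[4])

#' Write a dataset to disk (PNGs + COCO-style manifest)
#'
#' @param ds a \code{trap_dataset}.
#' @param dir output directory (created if missing).
#' @param name manifest file name.
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(ds, dir, name = "manifest.json") {
  dir.create(file.path(dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  has_mask <- any(vapply(ds$records, function(r) !is.null(r$mask),
                         logical(1)))
  if (has_mask)
    dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  images <- list(); annotations <- list()
  for (i in seq_along(ds$records)) {
    r <- ds$records[[i]]
    fn <- sprintf("img_%05d.png", i)
    png::writePNG(r$image / 255, file.path(dir, "images", fn))
    mask_fn <- NULL
    if (!is.null(r$mask)) {
      mask_fn <- sprintf("mask_%05d.png", i)
      png::writePNG(r$mask * 1, file.path(dir, "masks", mask_fn))
    }
    images[[i]] <- list(id = i, file_name = fn,
                        width = ncol(r$image), height = nrow(r$image),
                        site = r$site, provenance = r$provenance,
                        mask_file = mask_fn)
    annotations[[i]] <- list(id = i, image_id = i, category_id = r$label,
                             bbox = bbox_to_coco(unname(r$bbox)))
  }
  manifest <- list(
    images = images, annotations = annotations,
    categories = lapply(seq_len(ds$n_species), function(s)
      list(id = s, name = sprintf("species_%d", s))),
    info = list(n_sites = ds$n_sites, image_side = ds$image_side))
  path <- file.path(dir, name)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a dataset written by \code{\link{write_dataset}}
#'
#' @param dir dataset directory.
#' @param name manifest file name.
#' @return A \code{trap_dataset}.
#' @export
read_dataset <- function(dir, name = "manifest.json") {
  m <- jsonlite::read_json(file.path(dir, name))
  records <- vector("list", length(m$images))
  for (i in seq_along(m$images)) {
    im <- m$images[[i]]; an <- m$annotations[[i]]
    img <- png::readPNG(file.path(dir, "images", im$file_name))
    if (length(dim(img)) == 2) img <- array(img, c(dim(img), 3))
    mask <- NULL
    if (!is.null(im$mask_file)) {
      mk <- png::readPNG(file.path(dir, "masks", im$mask_file))
      if (length(dim(mk)) == 3) mk <- mk[, , 1]
      mask <- mk > 0.5
    }
    records[[i]] <- list(image = round(img[, , 1:3] * 255),
                         label = as.integer(an$category_id),
                         bbox = bbox_from_coco(unlist(an$bbox)),
                         mask = mask,
                         site = im$site %||% NA_integer_,
                         provenance = im$provenance %||% "real_composite")
  }
  cfg <- scene_config(n_sites = m$info$n_sites %||% 1,
                      n_species = length(m$categories),
                      image_side = m$info$image_side %||%
                        nrow(records[[1]]$image))
  new_trap_dataset(records, cfg)
}

#' Save / load a model
#'
#' Checkpoints are the model object in R's native serialized form.
#'
#' @param model a \code{trap_cnn}.
#' @param path file path.
#' @return \code{path} invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

# md5 provenance manifest over every file below `dir`.
write_hash_manifest <- function(dir) {
  files <- list.files(dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("hashes.txt$", files)]
  h <- tools::md5sum(files)
  writeLines(sprintf("%s  %s", h, substring(names(h), nchar(dir) + 2)),
             file.path(dir, "hashes.txt"))
  invisible(file.path(dir, "hashes.txt"))
}
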