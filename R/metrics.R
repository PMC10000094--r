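#' Evaluation metrics: accuracy, Grad-CAM attention, FRoH
#'
#' Classification quality is micro-averaged accuracy; attention quality is
#' the foreground ratio of heat (FRoH), the fraction of total Grad-CAM
#' heat falling inside the labeled bounding box. A model that recognizes
#' the animal rather than the background concentrates its heat in the box,
#' so a higher FRoH indicates mitigated shortcut learning.
#'
#' @name metrics
NULL

#' Micro-averaged classification accuracy
#'
#' Sum of per-class true positives over all predictions, which reduces to
#' the overall fraction of correct predictions.
#'
#' @param predictions predicted class ids.
#' @param labels true class ids, same length.
#' @return fraction in [0, 1].
#' @export
acc_cls <- function(predictions, labels) {
  stop_if(length(predictions) != length(labels), "length mismatch")
  stop_if(length(labels) == 0, "empty input")
  mean(predictions == labels)
}

#' Confusion matrix
#'
#' @param predictions predicted class ids (1..C).
#' @param labels true class ids (1..C).
#' @param C number of classes.
#' @return C x C integer matrix of class \code{confusion_matrix}; entry
#'   (i, j) counts true-class-i images predicted as class j.
#' @export
confusion <- function(predictions, labels, C) {
  stop_if(any(labels < 1 | labels > C | predictions < 1 | predictions > C),
          "class id out of range")
  m <- matrix(0L, C, C, dimnames = list(true = 1:C, pred = 1:C))
  for (k in seq_along(labels))
    m[labels[k], predictions[k]] <- m[labels[k], predictions[k]] + 1L
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Row-normalized (class-wise accuracy) view of a confusion matrix
#'
#' @param m a \code{confusion_matrix}.
#' @return matrix of row proportions (rows with no observations are 0).
#' @export
confusion_rates <- function(m) {
  rs <- rowSums(m)
  sweep(unclass(m), 1, pmax(rs, 1), "/")
}

# Bilinear upsampling of a small map to (H, W), pixel-center aligned.
upsample_bilinear <- function(map, H, W) {
  h <- nrow(map); w <- ncol(map)
  if (h == H && w == W) return(map)
  sy <- (seq_len(H) - 0.5) * h / H + 0.5
  sx <- (seq_len(W) - 0.5) * w / W + 0.5
  y0 <- pmin(pmax(floor(sy), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(sx), 1), w); x1 <- pmin(x0 + 1, w)
  fy <- pmin(pmax(sy - y0, 0), 1); fx <- pmin(pmax(sx - x0, 0), 1)
  (1 - fy) %o% (1 - fx) * map[y0, x0, drop = FALSE] +
    (1 - fy) %o% fx * map[y0, x1, drop = FALSE] +
    fy %o% (1 - fx) * map[y1, x0, drop = FALSE] +
    fy %o% fx * map[y1, x1, drop = FALSE]
}

#' Grad-CAM heatmap
#'
#' Channel weights are the spatial means of the class-logit gradient at
#' the last convolutional stage; the map is the ReLU of the
#' gradient-weighted sum of activations, bilinearly upsampled to input
#' resolution. All values are non-negative. The map is deliberately not
#' max-normalized: FRoH is a ratio of sums and therefore invariant to
#' positive rescaling.
#'
#' @param model a \code{trap_cnn}.
#' @param image one record or image array.
#' @param class_index class whose evidence is mapped (1-based).
#' @return list(values, source) of class \code{heat_map}; \code{values} is
#'   an (input_side, input_side) non-negative matrix.
#' @export
grad_cam <- function(model, image, class_index) {
  ag <- activations_and_gradients(model, image, class_index)
  alpha <- apply(ag$gradients, 3, mean)
  d <- dim(ag$activations)
  flat <- matrix(ag$activations, d[1] * d[2], d[3])
  map <- matrix(pmax(flat %*% alpha, 0), d[1], d[2])
  up <- upsample_bilinear(map, model$input_side, model$input_side)
  structure(list(values = pmax(up, 0),
                 source = list(class_index = class_index)),
            class = "heat_map")
}

#' Foreground ratio of heat
#'
#' Fraction of the heatmap's total mass lying inside the (0-based,
#' half-open) bounding box. Returns 0 with \code{attr(,"zero_heat")} set
#' when the map is identically zero.
#'
#' @param heatmap a \code{heat_map} or non-negative matrix.
#' @param bbox c(x0, y0, x1, y1).
#' @return fraction in [0, 1].
#' @export
froh <- function(heatmap, bbox) {
  v <- if (inherits(heatmap, "heat_map")) heatmap$values else heatmap
  h <- nrow(v); w <- ncol(v)
  stop_if(!(bbox[1] >= 0 && bbox[1] < bbox[3] && bbox[3] <= w &&
            bbox[2] >= 0 && bbox[2] < bbox[4] && bbox[4] <= h),
          "invalid bounding box for this heatmap")
  total <- sum(v)
  if (total == 0) {
    out <- 0
    attr(out, "zero_heat") <- TRUE
    return(out)
  }
  inside <- sum(v[(bbox[2] + 1):bbox[4], (bbox[1] + 1):bbox[3]])
  inside / total
}

#' Mean FRoH of a model over a dataset
#'
#' Computes a Grad-CAM heatmap per record (for its true class by default,
#' mirroring how labeled examples are inspected; set
#' \code{use_predicted}) and averages the foreground ratios.
#'
#' @param model a \code{trap_cnn}.
#' @param data a \code{trap_dataset} or record list with bboxes.
#' @param use_predicted use the predicted instead of the true class.
#' @return list(mean_froh, per_image, n_zero_heat).
#' @export
dataset_froh <- function(model, data, use_predicted = FALSE) {
  records <- as_record_list(data)
  stop_if(length(records) == 0, "empty dataset")
  cls <- if (use_predicted)
    predict(model, records)$labels
  else records_labels(records)
  vals <- numeric(length(records))
  zero <- 0
  for (i in seq_along(records)) {
    hm <- grad_cam(model, records[[i]], cls[i])
    f <- froh(hm, records[[i]]$bbox)
    if (isTRUE(attr(f, "zero_heat"))) zero <- zero + 1
    vals[i] <- as.numeric(f)
  }
  list(mean_froh = mean(vals),
       per_image = data.frame(id = seq_along(records), class = cls,
                              froh = vals),
       n_zero_heat = zero)
}

#' Evaluate a model on a dataset
#'
#' @param model a \code{trap_cnn}.
#' @param data a \code{trap_dataset} or record list.
#' @param with_froh also compute mean FRoH (slower).
#' @return list(acc, confusion, froh).
#' @export
evaluate_model <- function(model, data, with_froh = FALSE) {
  records <- as_record_list(data)
  pr <- predict(model, records)
  y <- records_labels(records)
  out <- list(acc = acc_cls(pr$labels, y),
              confusion = confusion(pr$labels, y, model$num_classes))
  if (with_froh) out$froh <- dataset_froh(model, records)$mean_froh
  out
}
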