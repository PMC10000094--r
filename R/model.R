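#' Configurable small convolutional classifier
#'
#' The trainable model family is a plain stage CNN: each stage opens with a
#' stride-2 3x3 convolution, followed by batch normalization and ReLU;
#' further blocks in a stage are stride-1 3x3 conv--BN--ReLU (with an
#' identity skip connection when \code{with_residual}); a global average
#' pool and a fully connected head close the network. All channel widths in
#' one stage are tied, which makes every stage one prunable channel group.
#'
#' @param stage_widths integer vector of per-stage channel counts.
#' @param blocks_per_stage integer vector (recycled) of blocks per stage.
#' @param num_classes number of output classes.
#' @param input_side input image side in pixels (must survive one halving
#'   per stage).
#' @param with_residual add identity skips inside stages.
#' @return An object of class \code{classifier_spec}.
#' @export
classifier_spec <- function(stage_widths = c(16, 32, 64),
                            blocks_per_stage = 1,
                            num_classes = 4,
                            input_side = 96,
                            with_residual = FALSE) {
  blocks_per_stage <- rep(blocks_per_stage, length.out = length(stage_widths))
  stop_if(length(stage_widths) < 1 || any(stage_widths < 1),
          "stage_widths must be positive")
  stop_if(any(blocks_per_stage < 1), "blocks_per_stage must be positive")
  stop_if(num_classes < 2, "num_classes must be at least 2")
  side <- input_side
  for (i in seq_along(stage_widths)) {
    stop_if(side %% 2 != 0, "input_side must halve once per stage")
    side <- side / 2
  }
  structure(list(stage_widths = as.integer(stage_widths),
                 blocks_per_stage = as.integer(blocks_per_stage),
                 num_classes = as.integer(num_classes),
                 input_side = as.integer(input_side),
                 with_residual = isTRUE(with_residual)),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat(sprintf("Classifier spec: stages [%s] x blocks [%s], %d classes, %dpx%s\n",
              paste(x$stage_widths, collapse = ","),
              paste(x$blocks_per_stage, collapse = ","),
              x$num_classes, x$input_side,
              if (x$with_residual) ", residual" else ""))
  invisible(x)
}

#' Architecture descriptor of a classifier spec
#'
#' The descriptor carries one prune group per stage (\code{"s1"},
#' \code{"s2"}, ...). The inverse mapping \code{\link{as_classifier_spec}}
#' recovers the spec, so the two representations round-trip losslessly.
#'
#' @param spec a \code{classifier_spec}.
#' @return An \code{arch_descriptor}.
#' @export
as_arch_descriptor <- function(spec) {
  rows <- list()
  add <- function(kind, cin, cout, K, stride, side, bias = FALSE,
                  group = NA_character_, input = NULL) {
    rows[[length(rows) + 1]] <<- data.frame(
      kind = kind, cin = cin, cout = cout, K = K, stride = stride,
      H = side, W = side, has_bias = bias, prune_group = group,
      input_id = if (is.null(input)) length(rows) else input)
    length(rows)
  }
  side <- spec$input_side
  cin <- 3L
  prev <- NA
  for (st in seq_along(spec$stage_widths)) {
    w <- spec$stage_widths[st]
    g <- sprintf("s%d", st)
    side <- side / 2
    add("conv", cin, w, 3, 2, side, group = g, input = prev)
    add("bn", w, w, 1, 1, side)
    prev <- add("act", w, w, 1, 1, side)
    if (spec$blocks_per_stage[st] > 1) {
      for (b in 2:spec$blocks_per_stage[st]) {
        add("conv", w, w, 3, 1, side, group = g, input = prev)
        bn_id <- add("bn", w, w, 1, 1, side)
        prev <- add("act", w, w, 1, 1, side, input = bn_id)
      }
    }
    cin <- w
  }
  add("pool_global", cin, cin, 1, 1, 1, input = prev)
  add("fc", cin, spec$num_classes, 1, 1, 1, bias = TRUE)
  a <- arch_descriptor(do.call(rbind, rows), c(spec$input_side,
                                               spec$input_side, 3),
                       spec$num_classes)
  a$meta <- list(blocks_per_stage = spec$blocks_per_stage,
                 with_residual = spec$with_residual)
  a
}

#' Recover a classifier spec from its descriptor
#'
#' @param arch a descriptor produced by \code{\link{as_arch_descriptor}}
#'   (possibly after \code{\link{apply_genome}}).
#' @return The corresponding \code{classifier_spec}.
#' @export
as_classifier_spec <- function(arch) {
  L <- arch$layers
  entry <- L$kind == "conv" & L$stride == 2
  widths <- L$cout[entry]
  classifier_spec(stage_widths = widths,
                  blocks_per_stage = arch$meta$blocks_per_stage %||% 1,
                  num_classes = arch$num_classes,
                  input_side = arch$input_size[1],
                  with_residual = arch$meta$with_residual %||% FALSE)
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

#' Build a trainable classifier
#'
#' Weight initialization is He-scaled Gaussian and fully determined by
#' \code{seed}; the instantiated model's trainable tensor count equals the
#' analytic \code{\link{count_params}} of its descriptor.
#'
#' @param spec a \code{classifier_spec}.
#' @param seed integer seed controlling initialization.
#' @return An object of class \code{trap_cnn}.
#' @export
build_classifier <- function(spec, seed = 1) {
  arch <- as_arch_descriptor(spec)
  layers <- list()
  bn_i <- 0
  add <- function(l) layers[[length(layers) + 1]] <<- l
  new_bn <- function(w) {
    bn_i <<- bn_i + 1
    list(type = "bn", name = sprintf("bn%d", bn_i),
         gamma = rep(1, w), beta = rep(0, w),
         run_mean = rep(0, w), run_var = rep(1, w))
  }
  with_seed(seed, {
    cin <- 3
    for (st in seq_along(spec$stage_widths)) {
      w <- spec$stage_widths[st]
      add(list(type = "conv", K = 3, stride = 2, pad = 1,
               W = he_init(9 * cin, w, 9 * cin), b = NULL))
      add(new_bn(w))
      add(list(type = "relu"))
      nb <- spec$blocks_per_stage[st]
      if (nb > 1) {
        for (b in 2:nb) {
          tag <- sprintf("s%db%d", st, b)
          if (spec$with_residual) add(list(type = "save", tag = tag))
          add(list(type = "conv", K = 3, stride = 1, pad = 1,
                   W = he_init(9 * w, w, 9 * w), b = NULL))
          add(new_bn(w))
          if (spec$with_residual) add(list(type = "add", from = tag))
          add(list(type = "relu"))
        }
      }
      cin <- w
    }
    layers[[length(layers)]]$cam_target <- TRUE   # last stage ReLU output
    add(list(type = "gap"))
    add(list(type = "fc", W = he_init(cin, spec$num_classes, cin),
             b = rep(0, spec$num_classes)))
  })
  net <- structure(list(spec = spec, layers = layers,
                        input_side = spec$input_side,
                        num_classes = spec$num_classes,
                        arch = arch, seed = seed),
                   class = "trap_cnn")
  net
}

#' @export
print.trap_cnn <- function(x, ...) {
  cat(sprintf("trap_cnn: %s classes=%d input=%dpx params=%s%s\n",
              paste(x$spec$stage_widths, collapse = "-"), x$num_classes,
              x$input_side, format(count_net_params(x), big.mark = ","),
              if (!is.null(x$history)) " (trained)" else ""))
  invisible(x)
}

#' Training configuration
#'
#' Defaults follow the published training recipe (SGD with momentum 0.9,
#' initial learning rate 1e-4, cosine decay, batch size 64, early stopping
#' with patience 50); desk-scale experiments override the learning rate,
#' batch size and patience through the same interface.
#'
#' @param optimizer only \code{"sgd"}.
#' @param momentum SGD momentum.
#' @param initial_lr initial learning rate.
#' @param lr_schedule only \code{"cosine"} decay to zero at
#'   \code{max_epochs}.
#' @param batch_size mini-batch size.
#' @param early_stop_patience epochs without validation-accuracy
#'   improvement before stopping.
#' @param max_epochs hard epoch cap.
#' @param seed RNG seed for shuffling and any augmentation-free noise.
#' @return A \code{train_config} list.
#' @export
train_config <- function(optimizer = "sgd", momentum = 0.9,
                         initial_lr = 1e-4, lr_schedule = "cosine",
                         batch_size = 64, early_stop_patience = 50,
                         max_epochs = 100, seed = 1) {
  stop_if(!identical(optimizer, "sgd"), "only SGD is supported")
  stop_if(!identical(lr_schedule, "cosine"), "only cosine decay is supported")
  stop_if(initial_lr <= 0 || momentum < 0 || batch_size < 1,
          "rates and batch size must be positive")
  stop_if(early_stop_patience < 1, "patience must be >= 1")
  structure(list(optimizer = optimizer, momentum = momentum,
                 initial_lr = initial_lr, lr_schedule = lr_schedule,
                 batch_size = as.integer(batch_size),
                 early_stop_patience = as.integer(early_stop_patience),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed)),
            class = "train_config")
}

# Convert dataset records to an input tensor (S, 3, N); pixels are mapped
# from [0, 255] to [-0.5, 0.5].
records_to_tensor <- function(records, input_side) {
  N <- length(records)
  S <- input_side * input_side
  X <- array(0, c(S, 3, N))
  for (n in seq_len(N)) {
    img <- records[[n]]$image
    stop_if(!all(dim(img)[1:2] == input_side),
            "image size does not match the model's input side")
    dim(img) <- c(S, 3)
    X[, , n] <- img / 255 - 0.5
  }
  X
}

records_labels <- function(records) {
  vapply(records, function(r) r$label, integer(1))
}

as_record_list <- function(data) {
  if (inherits(data, "trap_dataset")) data$records else data
}

# Shared SGD loop. `grad_fn(logits, idx)` returns list(loss, components,
# dlogits) for the current batch (rows of `idx` index into `records`).
sgd_train <- function(net, train_records, valid_records, cfg, grad_fn,
                      progress = FALSE) {
  Xtr <- records_to_tensor(train_records, net$input_side)
  ytr <- records_labels(train_records)
  Xva <- records_to_tensor(valid_records, net$input_side)
  yva <- records_labels(valid_records)
  n <- length(train_records)
  vel <- list()
  best <- list(acc = -Inf, layers = net$layers, epoch = 0)
  wait <- 0
  hist <- list()
  with_seed(derive_seed(cfg$seed, 7001), {
    for (epoch in seq_len(cfg$max_epochs)) {
      lr <- cfg$initial_lr * 0.5 * (1 + cos(pi * (epoch - 1) / cfg$max_epochs))
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0; comp_sums <- NULL
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, n)]
        fwd <- net_forward(net, Xtr[, , idx, drop = FALSE], training = TRUE,
                           keep_cache = TRUE, collect_bn = TRUE)
        gl <- grad_fn(fwd$logits, idx)
        grads <- net_backward(net, fwd, gl$dlogits)
        st <- sgd_step(net, grads, vel, lr, cfg$momentum)
        net <- st$net; vel <- st$vel
        net <- update_running_bn(net, fwd)
        ep_loss <- ep_loss + gl$loss * length(idx)
        pred <- max.col(fwd$logits, ties.method = "first")
        ep_correct <- ep_correct + sum(pred == ytr[idx])
        if (!is.null(gl$components)) {
          comp_sums <- (comp_sums %||% 0) + unlist(gl$components) * length(idx)
        }
      }
      va <- net_forward(net, Xva, training = FALSE)
      va_pred <- max.col(va$logits, ties.method = "first")
      va_acc <- mean(va_pred == yva)
      row <- data.frame(epoch = epoch, lr = lr, train_loss = ep_loss / n,
                        train_acc = ep_correct / n, val_acc = va_acc)
      if (!is.null(comp_sums)) {
        comps <- as.data.frame(as.list(comp_sums / n))
        row <- cbind(row, comps)
      }
      hist[[epoch]] <- row
      if (progress)
        message(sprintf("epoch %3d  loss %.4f  train %.3f  val %.3f",
                        epoch, ep_loss / n, ep_correct / n, va_acc))
      if (va_acc > best$acc) {
        best <- list(acc = va_acc, layers = net$layers, epoch = epoch)
        wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= cfg$early_stop_patience) break
      }
    }
  })
  net$layers <- best$layers
  net$history <- do.call(rbind, hist)
  net$best_epoch <- best$epoch
  net
}

#' Train a classifier with cross-entropy
#'
#' Stochastic gradient descent with momentum and cosine learning-rate
#' decay; early-stops on validation accuracy and restores the best
#' weights. Reproducible under \code{cfg$seed}.
#'
#' @param model a \code{trap_cnn} from \code{\link{build_classifier}}.
#' @param train training data: a \code{trap_dataset} or list of records.
#' @param valid validation data in the same form.
#' @param cfg a \code{\link{train_config}}.
#' @param progress print per-epoch progress.
#' @return The trained \code{trap_cnn}, with a per-epoch \code{history}
#'   data frame attached.
#' @export
train_classifier <- function(model, train, valid, cfg = train_config(),
                             progress = FALSE) {
  train_records <- as_record_list(train)
  valid_records <- as_record_list(valid)
  stop_if(length(train_records) == 0 || length(valid_records) == 0,
          "training and validation sets must be non-empty")
  y <- records_labels(train_records)
  stop_if(any(y < 1 | y > model$num_classes),
          "labels outside the model's class range")
  grad_fn <- function(logits, idx) {
    ce_grad(logits, records_labels(train_records)[idx])
  }
  sgd_train(model, train_records, valid_records, cfg, grad_fn, progress)
}

# Cross-entropy loss and gradient w.r.t. logits (mean over the batch).
ce_grad <- function(logits, labels) {
  P <- softmax(logits)
  N <- nrow(P)
  pl <- pmax(P[cbind(seq_len(N), labels)], 1e-12)
  loss <- -mean(log(pl))
  dZ <- P
  dZ[cbind(seq_len(N), labels)] <- dZ[cbind(seq_len(N), labels)] - 1
  list(loss = loss, components = list(ce_loss = loss), dlogits = dZ / N)
}

#' Predict classes, probabilities and logits
#'
#' @param object a \code{trap_cnn}.
#' @param newdata a \code{trap_dataset}, list of records, or input tensor.
#' @param ... unused.
#' @return list with \code{labels} (argmax, ties to the lowest index),
#'   \code{probabilities} (softmax rows summing to one) and \code{logits}.
#' @export
predict.trap_cnn <- function(object, newdata, ...) {
  X <- if (is.array(newdata) && length(dim(newdata)) == 3) newdata
       else records_to_tensor(as_record_list(newdata), object$input_side)
  fwd <- net_forward(object, X, training = FALSE)
  pr <- softmax(fwd$logits)
  list(labels = max.col(fwd$logits, ties.method = "first"),
       probabilities = pr, logits = fwd$logits)
}

#' Last-stage activations and class-logit gradients
#'
#' Returns the last convolutional stage's post-ReLU feature maps for one
#' image and the gradient of the chosen class logit with respect to them
#' (the two ingredients of Grad-CAM). With a global-average-pool head the
#' gradient is the class's head weights spread uniformly over spatial
#' positions.
#'
#' @param model a \code{trap_cnn}.
#' @param image one record, or an image array (side x side x 3, 0--255).
#' @param class_index class whose logit is differentiated (1-based).
#' @return list(activations, gradients): arrays of dim (H, W, C).
#' @export
activations_and_gradients <- function(model, image, class_index) {
  stop_if(class_index < 1 || class_index > model$num_classes,
          "class_index out of range")
  img <- if (is.list(image)) image$image else image
  rec <- list(list(image = img, label = 1L))
  X <- records_to_tensor(rec, model$input_side)
  fwd <- net_forward(model, X, training = FALSE)
  cam <- fwd$cam
  stop_if(is.null(cam), "model has no Grad-CAM target layer")
  A <- cam$act[, , 1, drop = FALSE]            # (S, C, 1)
  S <- cam$H * cam$W
  C <- dim(A)[2]
  fc <- model$layers[[length(model$layers)]]
  g <- matrix(rep(fc$W[, class_index], each = S) / S, S, C)
  acts <- array(A, c(cam$H, cam$W, C))
  grads <- array(g, c(cam$H, cam$W, C))
  list(activations = acts, gradients = grads)
}
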