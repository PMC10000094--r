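#' Architecture descriptors and exact cost accounting
#'
#' An architecture descriptor is an ordered layer table from which trainable
#' parameter counts and multiply--accumulate (MAC) counts are computed
#' analytically, without instantiating any weights. It is also the carrier
#' for channel-pruning arithmetic: layers that must keep equal channel
#' counts (e.g. convolutions feeding one residual sum) share a
#' \code{prune_group} identifier, and a prune genome of per-group keep
#' ratios is applied directly to the table.
#'
#' @name archspec
NULL

LAYER_KINDS <- c("conv", "fc", "bn", "act", "pool_spatial", "pool_global")
CHANNEL_PRESERVING <- c("bn", "act", "pool_spatial", "pool_global")

#' Build an architecture descriptor from a layer table
#'
#' @param layers data.frame with columns \code{kind}, \code{cin},
#'   \code{cout}, \code{K}, \code{stride}, \code{H}, \code{W} (output
#'   spatial size), \code{has_bias}, \code{prune_group} (NA for unpruned
#'   layers) and \code{input_id} (row index of the feeding layer, NA for
#'   the network input; residual joins point at their main branch).
#' @param input_size integer c(height, width, channels) of the input image.
#' @param num_classes number of output classes; the last layer must be an
#'   \code{fc} with \code{cout == num_classes}.
#' @return An object of class \code{arch_descriptor}.
#' @export
arch_descriptor <- function(layers, input_size, num_classes) {
  need <- c("kind", "cin", "cout", "K", "stride", "H", "W", "has_bias",
            "input_id")
  stop_if(!all(need %in% names(layers)), "layer table is missing columns")
  if (is.null(layers$prune_group)) layers$prune_group <- NA_character_
  layers$id <- seq_len(nrow(layers))
  x <- structure(list(layers = layers,
                      input_size = as.integer(input_size),
                      num_classes = as.integer(num_classes)),
                 class = "arch_descriptor")
  validate_arch(x)
  x
}

#' Validate an architecture descriptor
#'
#' Checks positivity of all dimensions, channel connectivity (each layer's
#' \code{cin} equals the \code{cout} of the layer feeding it), and that the
#' final layer is a classification head of width \code{num_classes}.
#'
#' @param arch an \code{arch_descriptor}.
#' @return \code{arch}, invisibly; errors on violation.
#' @export
validate_arch <- function(arch) {
  L <- arch$layers
  stop_if(!all(L$kind %in% LAYER_KINDS), "unknown layer kind")
  num <- c("cin", "cout", "K", "stride", "H", "W")
  for (cn in num)
    stop_if(any(L[[cn]] <= 0 | L[[cn]] != floor(L[[cn]])),
            sprintf("layer field '%s' must be a positive integer", cn))
  last <- L[nrow(L), ]
  stop_if(last$kind != "fc" || last$cout != arch$num_classes,
          "descriptor must end in an fc layer of width num_classes")
  for (i in seq_len(nrow(L))) {
    j <- L$input_id[i]
    feed_cout <- if (is.na(j)) arch$input_size[3] else L$cout[j]
    stop_if(L$cin[i] != feed_cout,
            sprintf("layer %d: cin (%d) != cout of feeding layer (%d)",
                    i, L$cin[i], feed_cout))
    if (L$kind[i] %in% CHANNEL_PRESERVING)
      stop_if(L$cin[i] != L$cout[i],
              sprintf("layer %d (%s) must preserve channel count",
                      i, L$kind[i]))
  }
  invisible(arch)
}

#' @export
print.arch_descriptor <- function(x, ...) {
  cat(sprintf("Architecture descriptor: %d layers, input %dx%dx%d, %d classes\n",
              nrow(x$layers), x$input_size[1], x$input_size[2],
              x$input_size[3], x$num_classes))
  p <- count_params(x); m <- count_macs(x)
  cat(sprintf("  params: %s (%.2f M)   macs: %s (%.2f G)\n",
              format(p$params_total, big.mark = ","), p$params_total / 1e6,
              format(m$macs_total, big.mark = ","), m$macs_total / 1e9))
  ng <- length(prune_groups(x))
  cat(sprintf("  prune groups: %d\n", ng))
  invisible(x)
}

#' Prunable channel groups of a descriptor
#'
#' @param arch an \code{arch_descriptor}.
#' @return character vector of distinct \code{prune_group} identifiers.
#' @export
prune_groups <- function(arch) {
  g <- arch$layers$prune_group
  unique(g[!is.na(g)])
}

per_layer_params <- function(L) {
  ifelse(L$kind == "conv", L$cout * L$K^2 * L$cin + ifelse(L$has_bias, L$cout, 0),
  ifelse(L$kind == "fc",   L$cin * L$cout + L$cout,
  ifelse(L$kind == "bn",   2 * L$cout, 0)))
}

#' Count trainable parameters of a descriptor
#'
#' Convolution layers contribute \code{cout * K^2 * cin} weights (plus
#' \code{cout} biases when present), fully connected layers
#' \code{cin * cout + cout}, batch-normalization layers a scale and shift
#' per channel; activations and pooling contribute nothing. All integer
#' exact.
#'
#' @param arch an \code{arch_descriptor}.
#' @return A \code{cost_report}: per-layer table plus exact totals.
#' @export
count_params <- function(arch) {
  validate_arch(arch)
  L <- arch$layers
  p <- per_layer_params(L)
  cost_report(L, params = p)
}

#' Count multiply--accumulate operations of a descriptor
#'
#' Uses the MAC convention under which every output position of a
#' convolution costs \code{K^2 * cin + 1} multiply--adds (the \code{+ 1} is
#' the bias slot of the per-layer operation-count formula, charged whether
#' or not the instantiated layer carries a bias), a fully connected layer
#' costs \code{cin * cout + cout}, and batch normalization, activations and
#' pooling cost one operation per element touched. A doubled
#' \code{flops_total = 2 * macs_total} is also reported for the
#' floating-point-operation reading that counts multiplies and adds
#' separately.
#'
#' @param arch an \code{arch_descriptor} with spatial sizes filled in.
#' @return A \code{cost_report} with \code{macs_total}, \code{flops_total}
#'   and a per-layer table.
#' @export
count_macs <- function(arch) {
  validate_arch(arch)
  L <- arch$layers
  m <- numeric(nrow(L))
  for (i in seq_len(nrow(L))) {
    l <- L[i, ]
    m[i] <- switch(l$kind,
      conv = l$H * l$W * l$cout * (l$K^2 * l$cin + 1),
      fc   = l$cin * l$cout + l$cout,
      bn   = l$H * l$W * l$cout,
      act  = l$H * l$W * l$cout,
      pool_spatial = l$H * l$W * l$cout * l$K^2,
      pool_global  = {
        j <- l$input_id
        stop_if(is.na(j), "global pool cannot be the first layer")
        L$H[j] * L$W[j] * l$cout
      })
  }
  cost_report(L, macs = m)
}

cost_report <- function(L, params = NULL, macs = NULL) {
  per <- data.frame(id = L$id, kind = L$kind)
  out <- list(per_layer = per)
  if (!is.null(params)) {
    out$per_layer$params <- params
    out$params_total <- sum(params)
  }
  if (!is.null(macs)) {
    out$per_layer$macs <- macs
    out$macs_total <- sum(macs)
    out$flops_total <- 2 * sum(macs)
  }
  structure(out, class = "cost_report")
}

#' @export
print.cost_report <- function(x, ...) {
  if (!is.null(x$params_total))
    cat(sprintf("Total parameters: %s (%.2f M)\n",
                format(x$params_total, big.mark = ","), x$params_total / 1e6))
  if (!is.null(x$macs_total))
    cat(sprintf("Total MACs: %s (%.2f G); doubled FLOPs: %.2f G\n",
                format(x$macs_total, big.mark = ","), x$macs_total / 1e9,
                x$flops_total / 1e9))
  invisible(x)
}

#' Apply a prune genome to a descriptor
#'
#' Every layer in prune group \code{g} has its output width replaced by
#' \code{max(1, round_half_up(ratio_g * cout))}; input widths and
#' channel-preserving layers are re-propagated along the connectivity so
#' the descriptor stays valid. The class-head width never changes.
#'
#' @param arch an \code{arch_descriptor}.
#' @param genome named numeric vector or list of keep ratios in (0, 1],
#'   one per prune group of \code{arch}.
#' @return The pruned \code{arch_descriptor}.
#' @export
apply_genome <- function(arch, genome) {
  genome <- unlist(genome)
  groups <- prune_groups(arch)
  stop_if(!all(groups %in% names(genome)),
          "genome must cover every prune group of the architecture")
  r <- genome[groups]
  stop_if(any(r <= 0 | r > 1), "keep ratios must lie in (0, 1]")
  L <- arch$layers
  for (i in seq_len(nrow(L))) {
    j <- L$input_id[i]
    L$cin[i] <- if (is.na(j)) arch$input_size[3] else L$cout[j]
    if (L$kind[i] %in% CHANNEL_PRESERVING) {
      L$cout[i] <- L$cin[i]
    } else if (!is.na(L$prune_group[i])) {
      L$cout[i] <- max(1, round_half_up(genome[[L$prune_group[i]]] * L$cout[i]))
    }
  }
  L$cin <- as.integer(L$cin)
  L$cout <- as.integer(L$cout)
  arch$layers <- L
  validate_arch(arch)
  arch
}

#' Descriptor of the standard 50-layer bottleneck residual network
#'
#' Reproduces the classic four-stage bottleneck residual classifier
#' (7x7/64 stem, stages of 3/4/6/3 bottlenecks with output widths
#' 256/512/1024/2048, batch normalization after every convolution, global
#' average pooling, and a fully connected head). Used for exact analytic
#' parameter/MAC accounting of the full-size teacher; at 6 classes and
#' 448x448 input it totals 23,520,326 parameters.
#'
#' Prune groups: each bottleneck's two internal convolutions share one
#' group; all convolutions whose outputs meet in a stage's residual sums
#' (the expansion 1x1s and the downsample projection) share one group per
#' stage; the stem has its own.
#'
#' @param num_classes number of classes (>= 2).
#' @param input_side input image side length in pixels, divisible by 32.
#' @return An \code{arch_descriptor}.
#' @export
resnet50_descriptor <- function(num_classes = 6, input_side = 448) {
  stop_if(num_classes < 2, "num_classes must be at least 2")
  stop_if(input_side %% 32 != 0,
          sprintf("input_side (%d) must be divisible by 32", input_side))
  rows <- list()
  add <- function(kind, cin, cout, K, stride, side, bias = FALSE,
                  group = NA_character_, input = NULL) {
    rows[[length(rows) + 1]] <<- data.frame(
      kind = kind, cin = cin, cout = cout, K = K, stride = stride,
      H = side, W = side, has_bias = bias, prune_group = group,
      input_id = if (is.null(input)) length(rows) else input)
    length(rows)
  }
  s <- input_side / 2
  add("conv", 3, 64, 7, 2, s, group = "stem", input = NA)
  add("bn", 64, 64, 1, 1, s)
  add("act", 64, 64, 1, 1, s)
  s <- s / 2
  add("pool_spatial", 64, 64, 3, 2, s)
  widths <- c(64, 128, 256, 512)
  blocks <- c(3, 4, 6, 3)
  cin <- 64
  prev <- length(rows)               # layer feeding the next block
  for (st in 1:4) {
    w <- widths[st]
    g_out <- sprintf("s%d.out", st)
    for (b in seq_len(blocks[st])) {
      stride <- if (st > 1 && b == 1) 2 else 1
      s_in <- s
      if (stride == 2) s <- s / 2
      g_mid <- sprintf("s%d.b%d.mid", st, b)
      block_in <- prev
      add("conv", cin, w, 1, 1, s_in, group = g_mid, input = block_in)
      add("bn", w, w, 1, 1, s_in)
      add("act", w, w, 1, 1, s_in)
      add("conv", w, w, 3, stride, s, group = g_mid)
      add("bn", w, w, 1, 1, s)
      add("act", w, w, 1, 1, s)
      add("conv", w, 4 * w, 1, 1, s, group = g_out)
      main_bn <- add("bn", 4 * w, 4 * w, 1, 1, s)
      if (b == 1) {                  # projection shortcut
        add("conv", cin, 4 * w, 1, stride, s, group = g_out, input = block_in)
        add("bn", 4 * w, 4 * w, 1, 1, s)
      }
      prev <- add("act", 4 * w, 4 * w, 1, 1, s, input = main_bn)
      cin <- 4 * w
    }
  }
  add("pool_global", 2048, 2048, 1, 1, 1, input = prev)
  add("fc", 2048, num_classes, 1, 1, 1, bias = TRUE)
  arch_descriptor(do.call(rbind, rows), c(input_side, input_side, 3),
                  num_classes)
}
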