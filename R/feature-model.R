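# Layered feature extractor: convolution (cross-correlation), ReLU, max
# pooling, and local response normalization across channels, with
# receptive-field arithmetic and center-neighborhood population extraction.

#' Layer constructors for an architecture specification
#'
#' `layer_conv()` declares a bank of square filters applied as
#' cross-correlation with zero padding; `layer_relu()` a pointwise
#' rectifier; `layer_maxpool()` window maxima at a stride;
#' `layer_lrn()` local response normalization across the channel
#' dimension: `b_i = a_i / (k + alpha * sum_j a_j^2)^beta`, the sum over
#' the `m` depth-adjacent channels centered on `i`, clamped at the channel
#' edges. LRN defaults `k = 2, m = 5, alpha = 1e-4, beta = 0.75` follow the
#' standard AlexNet setting.
#'
#' @param n_filters number of filters
#' @param kernel_side square kernel side
#' @param stride spatial stride (>= 1)
#' @param pad zero-padding on each border
#' @param window pooling window side
#' @param k,alpha,beta,m LRN hyperparameters (`m` odd)
#' @return a `layer_spec` list
#' @name layers
NULL

#' @rdname layers
#' @export
layer_conv <- function(n_filters, kernel_side, stride = 1L, pad = 0L) {
  stopifnot_scalar(n_filters, "n_filters", integerish = TRUE, positive = TRUE)
  stopifnot_scalar(kernel_side, "kernel_side", integerish = TRUE, positive = TRUE)
  stopifnot_scalar(stride, "stride", integerish = TRUE, positive = TRUE)
  stopifnot_scalar(pad, "pad", integerish = TRUE, nonneg = TRUE)
  structure(list(kind = "conv", n_filters = as.integer(n_filters),
                 kernel_side = as.integer(kernel_side),
                 stride = as.integer(stride), pad = as.integer(pad)),
            class = "layer_spec")
}

#' @rdname layers
#' @export
layer_relu <- function() structure(list(kind = "relu"), class = "layer_spec")

#' @rdname layers
#' @export
layer_maxpool <- function(window, stride) {
  stopifnot_scalar(window, "window", integerish = TRUE, positive = TRUE)
  stopifnot_scalar(stride, "stride", integerish = TRUE, positive = TRUE)
  structure(list(kind = "maxpool", window = as.integer(window),
                 stride = as.integer(stride)), class = "layer_spec")
}

#' @rdname layers
#' @export
layer_lrn <- function(k = 2, alpha = 1e-4, beta = 0.75, m = 5L) {
  stopifnot_scalar(m, "m", integerish = TRUE, positive = TRUE)
  if (m %% 2 == 0) stop("LRN neighborhood `m` must be odd", call. = FALSE)
  structure(list(kind = "lrn", k = k, alpha = alpha, beta = beta,
                 m = as.integer(m)), class = "layer_spec")
}

#' Ordered architecture specification
#'
#' Assembles layers into a named sequence. Tap-point names are generated
#' per block: `conv1, relu1, pool1, norm1, conv2, ...`, where the block
#' index increments at each convolution. Explicit names can be supplied.
#'
#' @param layers list of `layer_spec` objects
#' @param input_channels channel count of the stimulus fed to the first
#'   convolution (grayscale inputs are replicated when this is > 1)
#' @param names optional character vector of tap-point names
#' @return object of class `architecture_spec`
#' @export
architecture_spec <- function(layers, input_channels = 1L, names = NULL) {
  stopifnot(is.list(layers), length(layers) > 0,
            all(vapply(layers, inherits, logical(1), "layer_spec")))
  stopifnot_scalar(input_channels, "input_channels", integerish = TRUE,
                   positive = TRUE)
  if (is.null(names)) {
    block <- 0L
    names <- character(length(layers))
    for (i in seq_along(layers)) {
      kind <- layers[[i]]$kind
      if (kind == "conv") block <- block + 1L
      names[i] <- paste0(switch(kind, conv = "conv", relu = "relu",
                                maxpool = "pool", lrn = "norm"), block)
    }
  }
  if (length(names) != length(layers) || anyDuplicated(names)) {
    stop("`names` must be unique and match the number of layers",
         call. = FALSE)
  }
  structure(list(layers = stats::setNames(layers, names),
                 input_channels = as.integer(input_channels)),
            class = "architecture_spec")
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf("architecture_spec (%d layers, %d input channel(s))\n",
              length(x$layers), x$input_channels))
  for (nm in names(x$layers)) {
    l <- x$layers[[nm]]
    desc <- switch(l$kind,
      conv = sprintf("conv %dx%d x%d stride %d pad %d", l$kernel_side,
                     l$kernel_side, l$n_filters, l$stride, l$pad),
      relu = "relu",
      maxpool = sprintf("maxpool %dx%d stride %d", l$window, l$window,
                        l$stride),
      lrn = sprintf("lrn k=%g alpha=%g beta=%g m=%d", l$k, l$alpha, l$beta,
                    l$m))
    cat(sprintf("  %-7s %s\n", nm, desc))
  }
  invisible(x)
}

#' Bundled two-stage AlexNet-style geometry
#'
#' The CaffeNet front end (normalization after pooling) restricted to its
#' first two blocks: conv 11x11, ReLU, 3x3 stride-2 max pool, LRN; conv
#' 5x5 pad 2, ReLU, 3x3 stride-2 max pool, LRN. `conv1_stride = 2` (the
#' default) is the receptive-field-reduced variant whose L1/L2 RF sides are
#' 15 and 39 pixels; `conv1_stride = 4` is the standard front end (L2 RF 67).
#'
#' @param conv1_stride stride of the first convolution (2 or 4)
#' @param n_filters_l1,n_filters_l2 filter counts (defaults 96, 256)
#' @param input_channels stimulus channels (default 1, grayscale)
#' @return an [architecture_spec()]
#' @export
alexnet_spec <- function(conv1_stride = 2L, n_filters_l1 = 96L,
                         n_filters_l2 = 256L, input_channels = 1L) {
  architecture_spec(list(
    layer_conv(n_filters_l1, 11L, stride = conv1_stride, pad = 0L),
    layer_relu(),
    layer_maxpool(3L, 2L),
    layer_lrn(),
    layer_conv(n_filters_l2, 5L, stride = 1L, pad = 2L),
    layer_relu(),
    layer_maxpool(3L, 2L),
    layer_lrn()
  ), input_channels = input_channels)
}

#' Bundled VGG16 geometry (blocks 1-3, geometry only)
#'
#' Stacks of 3x3 stride-1 pad-1 convolutions with ReLU, each block closed
#' by a 2x2 stride-2 max pool; no normalization layers. Blocks hold 2, 2
#' and 3 convolutions. Receptive-field sides at pool1/pool2/pool3 are
#' 6, 16 and 44 pixels.
#'
#' @param n_blocks number of blocks to include (1-3)
#' @param input_channels stimulus channels
#' @return an [architecture_spec()]
#' @export
vgg_spec <- function(n_blocks = 3L, input_channels = 1L) {
  stopifnot(n_blocks >= 1, n_blocks <= 3)
  widths <- c(64L, 128L, 256L)
  convs <- c(2L, 2L, 3L)
  layers <- list()
  for (b in seq_len(n_blocks)) {
    for (i in seq_len(convs[b])) {
      layers <- c(layers, list(layer_conv(widths[b], 3L, stride = 1L,
                                          pad = 1L), layer_relu()))
    }
    layers <- c(layers, list(layer_maxpool(2L, 2L)))
  }
  # name relu/pool by block: conv uses running index within the whole net
  nms <- character(length(layers))
  ci <- 0L; block <- 0L; within <- 0L
  for (i in seq_along(layers)) {
    kind <- layers[[i]]$kind
    if (kind == "conv") {
      if (within == 0L) { block <- block + 1L }
      within <- within + 1L
      nms[i] <- sprintf("conv%d_%d", block, within)
    } else if (kind == "relu") {
      nms[i] <- sprintf("relu%d_%d", block, within)
    } else {
      nms[i] <- sprintf("pool%d", block)
      within <- 0L
    }
  }
  architecture_spec(layers, input_channels = input_channels, names = nms)
}

#' Local response normalization across channels
#'
#' `b[x,y,i] = a[x,y,i] / (k + alpha * sum_{j in N_m(i)} a[x,y,j]^2)^beta`
#' where `N_m(i)` spans the `m` channels centered on `i`, clamped at the
#' channel edges. Inputs must be nonnegative (the operation is applied after
#' rectification). Output is bounded by `a / k^beta` elementwise.
#'
#' @param maps 3-D array `[row, col, channel]` (a matrix is treated as one
#'   channel)
#' @param k,alpha,beta,m scalars; see [layer_lrn()] for defaults
#' @return array of the same shape
#' @export
local_response_norm <- function(maps, k = 2, alpha = 1e-4, beta = 0.75,
                                m = 5L) {
  if (is.matrix(maps)) maps <- array(maps, dim = c(dim(maps), 1))
  stopifnot(is.array(maps), length(dim(maps)) == 3)
  if (any(maps < 0)) {
    stop("local_response_norm expects nonnegative (rectified) inputs",
         call. = FALSE)
  }
  if (m %% 2 == 0) stop("`m` must be odd", call. = FALSE)
  n_ch <- dim(maps)[3]
  half <- m %/% 2
  sq <- maps^2
  denom <- array(0, dim = dim(maps))
  for (i in seq_len(n_ch)) {
    lo <- max(1L, i - half); hi <- min(n_ch, i + half)
    s <- sq[, , lo, drop = FALSE]
    if (hi > lo) for (j in (lo + 1L):hi) s <- s + sq[, , j, drop = FALSE]
    denom[, , i] <- (k + alpha * s)^beta
  }
  maps / denom
}

#' Receptive-field side and stride product at a tap point
#'
#' Runs the standard recursion `rf <- rf + (window - 1) * jump;
#' jump <- jump * stride` over the convolution and pooling layers up to
#' (and including) the named tap point. ReLU and LRN leave both unchanged;
#' padding does not affect the RF side.
#'
#' @param spec an [architecture_spec()]
#' @param tap_point layer name, e.g. `"pool2"`
#' @return list with `rf_side` (input pixels seen by one unit) and `jump`
#'   (input-pixel shift per unit shift at the tap point)
#' @examples
#' receptive_field_size(alexnet_spec(conv1_stride = 2), "pool2")$rf_side  # 39
#' @export
receptive_field_size <- function(spec, tap_point) {
  stopifnot(inherits(spec, "architecture_spec"))
  if (!tap_point %in% names(spec$layers)) {
    stop(sprintf("unknown tap point '%s'", tap_point), call. = FALSE)
  }
  rf <- 1; jump <- 1
  for (nm in names(spec$layers)) {
    l <- spec$layers[[nm]]
    if (l$kind == "conv") {
      rf <- rf + (l$kernel_side - 1) * jump
      jump <- jump * l$stride
    } else if (l$kind == "maxpool") {
      rf <- rf + (l$window - 1) * jump
      jump <- jump * l$stride
    }
    if (nm == tap_point) return(list(rf_side = rf, jump = jump))
  }
}

conv_shapes <- function(spec) {
  # per conv layer: input channel count, inferred sequentially
  chans <- spec$input_channels
  out <- list()
  for (nm in names(spec$layers)) {
    l <- spec$layers[[nm]]
    if (l$kind == "conv") {
      out[[nm]] <- c(l$n_filters, chans, l$kernel_side, l$kernel_side)
      chans <- l$n_filters
    }
  }
  out
}

#' Initialize, randomize or shuffle convolution weights
#'
#' `mode = "random"` draws every weight i.i.d. uniform on `[-1, 1]`;
#' `"shuffled"` permutes the spatial positions of each (filter, channel)
#' slice of `base` independently, preserving its multiset of values and
#' destroying spatial correlations; `"provided"` passes `base` through
#' after a shape check.
#'
#' @param spec an [architecture_spec()]
#' @param mode one of `"random"`, `"shuffled"`, `"provided"`
#' @param seed integer seed for random draws / permutations
#' @param base a `weight_set` (required for `"shuffled"` and `"provided"`)
#' @return a `weight_set`: named list (one 4-D array
#'   `[filter, channel, row, col]` per conv layer) with `mode` and `seed`
#'   attributes
#' @export
init_weights <- function(spec, mode = c("random", "shuffled", "provided"),
                         seed = 1L, base = NULL) {
  mode <- match.arg(mode)
  shapes <- conv_shapes(spec)
  if (mode != "random") {
    if (is.null(base)) stop(sprintf("mode '%s' requires `base`", mode),
                            call. = FALSE)
    for (nm in names(shapes)) {
      if (is.null(base[[nm]]) || !all(dim(base[[nm]]) == shapes[[nm]])) {
        stop(sprintf("weight shape mismatch at layer '%s'", nm),
             call. = FALSE)
      }
    }
  }
  w <- switch(mode,
    random = {
      ws <- list()
      for (nm in names(shapes)) {
        sh <- shapes[[nm]]
        ws[[nm]] <- with_seed(substream_seed(seed, match(nm, names(shapes))),
                              array(stats::runif(prod(sh), -1, 1), dim = sh))
      }
      ws
    },
    shuffled = {
      ws <- list()
      for (nm in names(shapes)) {
        sh <- shapes[[nm]]
        arr <- base[[nm]]
        ws[[nm]] <- with_seed(
          substream_seed(seed, match(nm, names(shapes))), {
            out <- arr
            npos <- sh[3] * sh[4]
            for (f in seq_len(sh[1])) for (ch in seq_len(sh[2])) {
              vals <- as.vector(arr[f, ch, , ])
              out[f, ch, , ] <- vals[sample.int(npos)]
            }
            out
          })
      }
      ws
    },
    provided = base[names(shapes)]
  )
  structure(w, class = "weight_set", mode = mode, seed = as.integer(seed))
}

# Cross-correlation of a [H, W, C] input with a [F, C, k, k] filter bank at
# the given stride and zero padding, via patch-matrix (im2col) and one BLAS
# matrix product. Returns [H', W', F].
conv_forward <- function(input, filters, stride, pad) {
  H <- dim(input)[1]; W <- dim(input)[2]; C <- dim(input)[3]
  nf <- dim(filters)[1]; k <- dim(filters)[3]
  if (dim(filters)[2] != C) stop("filter/input channel mismatch", call. = FALSE)
  if (pad > 0) {
    padded <- array(0, dim = c(H + 2 * pad, W + 2 * pad, C))
    padded[pad + seq_len(H), pad + seq_len(W), ] <- input
    input <- padded
    H <- H + 2 * pad; W <- W + 2 * pad
  }
  Ho <- (H - k) %/% stride + 1L
  Wo <- (W - k) %/% stride + 1L
  if (Ho < 1 || Wo < 1) {
    stop("feature map shrinks below 1x1 at a convolution", call. = FALSE)
  }
  rows <- seq.int(1L, by = stride, length.out = Ho)
  cols <- seq.int(1L, by = stride, length.out = Wo)
  patches <- matrix(0, nrow = k * k * C, ncol = Ho * Wo)
  idx <- 0L
  for (ch in seq_len(C)) for (dj in seq_len(k)) for (di in seq_len(k)) {
    idx <- idx + 1L
    patches[idx, ] <- input[rows + (di - 1L), cols + (dj - 1L), ch]
  }
  # filter matrix in matching (row-within-kernel, col, channel) order
  Wm <- matrix(0, nrow = nf, ncol = k * k * C)
  idx <- 0L
  for (ch in seq_len(C)) for (dj in seq_len(k)) for (di in seq_len(k)) {
    idx <- idx + 1L
    Wm[, idx] <- filters[, ch, di, dj]
  }
  out <- Wm %*% patches          # nf x (Ho*Wo)
  array(t(out), dim = c(Ho, Wo, nf))
}

maxpool_forward <- function(input, window, stride, layer_name = "maxpool") {
  H <- dim(input)[1]; W <- dim(input)[2]; C <- dim(input)[3]
  Ho <- (H - window) %/% stride + 1L
  Wo <- (W - window) %/% stride + 1L
  if (Ho < 1 || Wo < 1) {
    stop(sprintf("feature map shrinks below 1x1 at layer '%s'", layer_name),
         call. = FALSE)
  }
  rows <- seq.int(1L, by = stride, length.out = Ho)
  cols <- seq.int(1L, by = stride, length.out = Wo)
  out <- array(-Inf, dim = c(Ho, Wo, C))
  for (dj in seq_len(window)) for (di in seq_len(window)) {
    out <- pmax(out, input[rows + (di - 1L), cols + (dj - 1L), , drop = FALSE])
  }
  out
}

#' Run the feature model on a single image
#'
#' Applies the layers of `spec` in order up to and including `tap_point`.
#' Grayscale matrices are replicated across channels when the spec declares
#' more than one input channel.
#'
#' @param image numeric matrix (grayscale) or `[H, W, C]` array
#' @param spec an [architecture_spec()]
#' @param weights a `weight_set` from [init_weights()]
#' @param tap_point layer name at which to return the maps
#' @return 3-D array `[row, col, filter]`
#' @export
forward_image <- function(image, spec, weights, tap_point) {
  stopifnot(inherits(spec, "architecture_spec"))
  if (!tap_point %in% names(spec$layers)) {
    stop(sprintf("unknown tap point '%s'", tap_point), call. = FALSE)
  }
  x <- if (is.matrix(image)) array(image, dim = c(dim(image), 1)) else image
  if (dim(x)[3] == 1 && spec$input_channels > 1) {
    x <- array(rep(x, spec$input_channels),
               dim = c(dim(x)[1:2], spec$input_channels))
  }
  for (nm in names(spec$layers)) {
    l <- spec$layers[[nm]]
    x <- switch(l$kind,
      conv = {
        if (is.null(weights[[nm]])) {
          stop(sprintf("no weights for conv layer '%s'", nm), call. = FALSE)
        }
        conv_forward(x, weights[[nm]], l$stride, l$pad)
      },
      relu = pmax(x, 0),
      maxpool = maxpool_forward(x, l$window, l$stride, nm),
      lrn = local_response_norm(x, l$k, l$alpha, l$beta, l$m))
    if (nm == tap_point) return(x)
  }
}

#' Run the feature model over a stimulus ensemble
#'
#' @param ensemble a `texture_ensemble`
#' @param spec,weights,tap_point as in [forward_image()]
#' @return nested list mirroring the ensemble: per family, per sample, a
#'   `list(tex =, noise =)` pair of `[row, col, filter]` arrays
#' @export
run_network <- function(ensemble, spec, weights, tap_point) {
  stopifnot(inherits(ensemble, "texture_ensemble"))
  lapply(ensemble$families, function(fam) {
    lapply(fam$samples, function(s) {
      list(tex = forward_image(s$tex, spec, weights, tap_point),
           noise = forward_image(s$noise, spec, weights, tap_point))
    })
  })
}

#' Population selector
#'
#' Model neurons are (filter, spatial position) pairs taken from a centered
#' square neighborhood of the tap-point maps. The default 2x2 neighborhood
#' with all filters mirrors populations whose receptive fields cover the
#' stimulus center with slight spatial jitter.
#'
#' @param filter_indices integer vector of filter indices (NULL = all)
#' @param spatial_neighborhood neighborhood side length (>= 1)
#' @param tap_point layer name the selector applies to
#' @return object of class `population_selector`
#' @export
population_selector <- function(filter_indices = NULL,
                                spatial_neighborhood = 2L,
                                tap_point = "norm2") {
  stopifnot_scalar(spatial_neighborhood, "spatial_neighborhood",
                   integerish = TRUE, positive = TRUE)
  structure(list(filter_indices = filter_indices,
                 spatial_neighborhood = as.integer(spatial_neighborhood),
                 tap_point = tap_point),
            class = "population_selector")
}

#' Extract a neuron-by-image response matrix from feature maps
#'
#' Neurons are the selected filters crossed with a centered
#' `s x s` spatial neighborhood: for a map of side `S` the neighborhood
#' spans offsets `floor((S - s)/2) .. floor((S - s)/2) + s - 1` on both
#' axes. Ordering is filter-major, then row, then column, and is stable
#' across calls.
#'
#' @param maps list of `[row, col, filter]` arrays (one per image)
#' @param selector a [population_selector()]
#' @return list with `responses` (matrix neuron x image) and `meta`
#'   (data frame: filter, row, col)
#' @export
extract_population <- function(maps, selector) {
  stopifnot(inherits(selector, "population_selector"))
  if (is.array(maps)) maps <- list(maps)
  d <- dim(maps[[1]])
  S <- d[1]; nfilt <- d[3]
  s <- selector$spatial_neighborhood
  if (s > S || s > d[2]) {
    stop("spatial neighborhood larger than the feature map", call. = FALSE)
  }
  fidx <- selector$filter_indices
  if (is.null(fidx)) fidx <- seq_len(nfilt)
  if (any(fidx < 1 | fidx > nfilt)) {
    stop("filter indices out of range", call. = FALSE)
  }
  off_r <- (S - s) %/% 2L
  off_c <- (d[2] - s) %/% 2L
  rows <- off_r + seq_len(s)
  cols <- off_c + seq_len(s)
  meta <- data.frame(
    filter = rep(fidx, each = s * s),
    row = rep(rep(rows, each = s), times = length(fidx)),
    col = rep(rep(cols, times = s), times = length(fidx)))
  resp <- vapply(maps, function(mp) {
    v <- numeric(nrow(meta))
    i <- 0L
    for (f in fidx) for (r in rows) for (cl in cols) {
      i <- i + 1L
      v[i] <- mp[r, cl, f]
    }
    v
  }, numeric(nrow(meta)))
  list(responses = matrix(resp, nrow = nrow(meta)), meta = meta)
}

#' Compute a response tensor for an ensemble at a tap point
#'
#' Convenience wrapper: [run_network()] then [extract_population()],
#' assembled into a `[neuron, family, sample, type]` tensor.
#'
#' @inheritParams run_network
#' @param selector a [population_selector()]
#' @return a [response_tensor()]
#' @export
compute_response_tensor <- function(ensemble, spec, weights, selector) {
  feats <- run_network(ensemble, spec, weights, selector$tap_point)
  nf <- length(feats); ns <- length(feats[[1]])
  first <- extract_population(feats[[1]][[1]]$tex, selector)
  nn <- nrow(first$meta)
  arr <- array(0, dim = c(nn, nf, ns, 2))
  for (f in seq_len(nf)) for (s in seq_len(ns)) {
    arr[, f, s, 1] <- extract_population(feats[[f]][[s]]$tex,
                                         selector)$responses[, 1]
    arr[, f, s, 2] <- extract_population(feats[[f]][[s]]$noise,
                                         selector)$responses[, 1]
  }
  meta <- first$meta
  meta$tap_point <- selector$tap_point
  response_tensor(arr, meta = meta)
}
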