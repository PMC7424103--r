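# Stimulus preparation: spectrally matched noise via Fourier phase
# randomization, resolution matching by block-average downsampling, and
# affine contrast normalization.

#' Spectrally matched noise by Fourier phase randomization
#'
#' Replaces the phases of an image's 2-D discrete Fourier transform with
#' i.i.d. uniform draws on `[0, 2*pi)` while keeping the amplitude spectrum
#' bin-for-bin identical. Hermitian symmetry is enforced so the output is
#' real-valued; self-conjugate bins (DC and, for even sides, the Nyquist
#' rows/columns' self-paired bins) keep their original real values, which
#' preserves the image mean exactly.
#'
#' The result has the same second-order (spectral) statistics as the input
#' but none of its higher-order phase structure -- the "noise" half of a
#' naturalistic-texture / noise stimulus pair.
#'
#' @param image Real-valued numeric matrix, both sides >= 2.
#' @param seed Integer seed; the draw is a pure function of `(image, seed)`.
#' @return Numeric matrix of the same dimensions.
#' @examples
#' img <- matrix(rnorm(64 * 64), 64, 64)
#' noise <- phase_randomize(img, seed = 1)
#' max(abs(Mod(fft2(img)) - Mod(fft2(noise))))  # amplitude spectrum preserved
#' @export
phase_randomize <- function(image, seed = 1L) {
  check_image(image)
  n <- nrow(image); m <- ncol(image)
  if (n < 2 || m < 2) stop("both image sides must be >= 2", call. = FALSE)

  F <- stats::fft(image)
  amp <- Mod(F)

  # Index bookkeeping on the 0-based frequency grid: bin (i, j) pairs with
  # (-i mod n, -j mod m); self-paired bins must stay real.
  i0 <- rep(0:(n - 1), times = m)
  j0 <- rep(0:(m - 1), each = n)
  pi0 <- (n - i0) %% n
  pj0 <- (m - j0) %% m
  self <- (i0 == pi0) & (j0 == pj0)
  # Canonical member of each conjugate pair: lexicographically smaller index.
  lin <- i0 + n * j0
  plin <- pi0 + n * pj0
  canonical <- !self & (lin < plin)

  theta <- with_seed(seed, stats::runif(n * m, min = 0, max = 2 * pi))
  phase <- numeric(n * m)
  phase[canonical] <- theta[canonical]
  # partner bins get the negated phase of their canonical partner
  partner_of <- match(plin, lin)
  mirror <- !self & !canonical
  phase[mirror] <- -phase[partner_of[mirror]]

  Fnew <- amp * exp(1i * phase)
  Fnew[self] <- F[self]
  dim(Fnew) <- c(n, m)
  out <- Re(stats::fft(Fnew, inverse = TRUE)) / (n * m)
  out
}

#' 2-D discrete Fourier transform of a matrix
#'
#' Thin wrapper around [stats::fft()] kept for readable call sites.
#' @param image numeric matrix
#' @return complex matrix of the same dimensions
#' @export
fft2 <- function(image) stats::fft(image)

#' Downsample an image by block averaging
#'
#' Reduces each side by `factor` (a power of two), replacing every
#' `factor x factor` block by its mean. Applied as repeated 2x2 block
#' averages, which is mean-preserving and anti-aliasing. Strided subsampling
#' (top-left pixel of each block) is available via `method = "subsample"`.
#'
#' @param image numeric matrix whose sides are divisible by `factor`
#' @param factor integer power of 2 (1 = no change)
#' @param method `"mean"` (default) or `"subsample"`
#' @return matrix of dimensions `dim(image) / factor`
#' @examples
#' downsample(matrix(0:15, 4, 4, byrow = TRUE), 2)
#' @export
downsample <- function(image, factor = 4L, method = c("mean", "subsample")) {
  check_image(image)
  method <- match.arg(method)
  stopifnot_scalar(factor, "factor", integerish = TRUE, positive = TRUE)
  factor <- as.integer(factor)
  if (factor == 1L) return(image)
  if (bitwAnd(factor, factor - 1L) != 0L) {
    stop("`factor` must be a power of 2", call. = FALSE)
  }
  if (nrow(image) %% factor != 0 || ncol(image) %% factor != 0) {
    stop("image sides must be divisible by `factor`", call. = FALSE)
  }
  if (method == "subsample") {
    return(image[seq(1, nrow(image), by = factor),
                 seq(1, ncol(image), by = factor), drop = FALSE])
  }
  out <- image
  while (factor > 1L) {
    n <- nrow(out); m <- ncol(out)
    out <- (out[seq(1, n, 2), seq(1, m, 2), drop = FALSE] +
            out[seq(2, n, 2), seq(1, m, 2), drop = FALSE] +
            out[seq(1, n, 2), seq(2, m, 2), drop = FALSE] +
            out[seq(2, n, 2), seq(2, m, 2), drop = FALSE]) / 4
    factor <- factor %/% 2L
  }
  out
}

#' Contrast-normalization parameters
#'
#' `alpha` is the desired contrast (the output's population standard
#' deviation) and `beta` the desired luminance (the output mean). The
#' defaults, contrast 0.22 on a gray mean of 0.5, place pixel values in a
#' range suitable for feature models trained on [0, 1] images.
#'
#' @param alpha target standard deviation, > 0
#' @param beta target mean, in (0, 1)
#' @return an object of class `contrast_norm_params`
#' @export
contrast_norm_params <- function(alpha = 0.22, beta = 0.5) {
  stopifnot_scalar(alpha, "alpha", positive = TRUE)
  stopifnot_scalar(beta, "beta")
  if (beta <= 0 || beta >= 1) stop("`beta` must lie in (0, 1)", call. = FALSE)
  structure(list(alpha = alpha, beta = beta), class = "contrast_norm_params")
}

#' Contrast-normalize an image
#'
#' Affine map `alpha * (I - mean(I)) / sd(I) + beta` where `sd` is the
#' population (divide-by-N) standard deviation, so the output has mean
#' exactly `beta` and standard deviation exactly `alpha`. The map is
#' idempotent at its fixed point: an already-normalized image is returned
#' unchanged up to floating point. Values are not clipped to [0, 1].
#'
#' @param image non-constant numeric matrix
#' @param params a [contrast_norm_params()] object
#' @return normalized matrix
#' @export
contrast_normalize <- function(image, params = contrast_norm_params()) {
  check_image(image)
  stopifnot(inherits(params, "contrast_norm_params"))
  l <- mean(image)
  cc <- sd_pop(image)
  if (cc == 0) {
    stop("constant image: contrast is zero, normalization undefined",
         call. = FALSE)
  }
  params$alpha * (image - l) / cc + params$beta
}

#' Build a paired naturalistic/noise stimulus ensemble
#'
#' For every naturalistic input image: generate its spectrally matched noise
#' partner by [phase_randomize()] at the native resolution, then
#' [downsample()] and [contrast_normalize()] both members of the pair.
#' Phase randomization uses one seed substream per (family, sample) so
#' adding families or samples never changes existing noise images.
#'
#' @param texture_images list of families; each family a list of numeric
#'   matrices (the naturalistic samples), all of one size, equal counts
#'   across families. An optional `family_id` attribute on each family list
#'   is honoured; otherwise families are numbered `1..F`.
#' @param factor downsampling factor (power of 2; the default 4 maps
#'   256x256 inputs to 64x64)
#' @param params contrast-normalization parameters
#' @param seed integer seed for the noise draws
#' @return a `texture_ensemble`: list with `families` (each with
#'   `family_id` and `samples`, a list of `list(tex=, noise=)` pairs),
#'   `image_side`, and `provenance` (factor, alpha, beta, seed)
#' @export
build_ensemble <- function(texture_images, factor = 4L,
                           params = contrast_norm_params(), seed = 1L) {
  if (!is.list(texture_images) || length(texture_images) == 0) {
    stop("`texture_images` must be a nonempty list of families", call. = FALSE)
  }
  counts <- vapply(texture_images, length, integer(1))
  if (length(unique(counts)) != 1L || counts[1] == 0) {
    stop("all families must have the same, nonzero sample count",
         call. = FALSE)
  }
  fam_out <- vector("list", length(texture_images))
  side <- NULL
  for (f in seq_along(texture_images)) {
    fam <- texture_images[[f]]
    fid <- attr(fam, "family_id")
    if (is.null(fid)) fid <- f
    samples <- vector("list", length(fam))
    for (s in seq_along(fam)) {
      img <- fam[[s]]
      res <- tryCatch({
        check_image(img, "texture image")
        noise <- phase_randomize(img, seed = substream_seed(seed, f, s))
        tex_d <- contrast_normalize(downsample(img, factor), params)
        noi_d <- contrast_normalize(downsample(noise, factor), params)
        list(tex = tex_d, noise = noi_d)
      }, error = function(e) {
        stop(sprintf("family %s, sample %d: %s", fid, s, conditionMessage(e)),
             call. = FALSE)
      })
      if (is.null(side)) side <- nrow(res$tex)
      if (nrow(res$tex) != side || ncol(res$tex) != side) {
        stop(sprintf("family %s, sample %d: inconsistent image size", fid, s),
             call. = FALSE)
      }
      samples[[s]] <- res
    }
    fam_out[[f]] <- list(family_id = fid, samples = samples)
  }
  structure(
    list(families = fam_out, image_side = side,
         provenance = list(factor = as.integer(factor),
                           alpha = params$alpha, beta = params$beta,
                           seed = as.integer(seed))),
    class = "texture_ensemble"
  )
}

#' @export
print.texture_ensemble <- function(x, ...) {
  nf <- length(x$families)
  ns <- length(x$families[[1]]$samples)
  cat(sprintf(
    "texture_ensemble: %d families x %d samples (%d images, %dx%d px)\n",
    nf, ns, 2 * nf * ns, x$image_side, x$image_side))
  cat(sprintf("  preprocessing: downsample factor %d, contrast %.3g, mean %.3g\n",
              x$provenance$factor, x$provenance$alpha, x$provenance$beta))
  invisible(x)
}

#' Number of families / samples in an ensemble
#' @param ensemble a `texture_ensemble`
#' @return integer
#' @export
n_families <- function(ensemble) length(ensemble$families)

#' @rdname n_families
#' @export
n_samples <- function(ensemble) length(ensemble$families[[1]]$samples)
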