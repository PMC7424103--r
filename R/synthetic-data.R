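# Synthetic stimuli and planted model-neuron responses.
#
# The texture generator produces families whose samples carry family-specific
# higher-order (phase) structure while the amplitude spectrum is pinned to a
# family reference spectrum: pointwise nonlinearities (soft thresholding) are
# applied to oriented band-pass filtered noise and the result is
# spectrum-flattened back to the reference. Phase randomization of such an
# image therefore destroys exactly the planted structure and nothing else,
# which is the logic of naturalistic-texture / spectrally-matched-noise
# stimulus pairs.

#' Parameters for the synthetic texture generator
#'
#' Defaults mirror the stimulus ensembles used in cortical texture
#' experiments: 15 families, 15 samples per family, 320x320 pixels.
#' `structure_strength` in [0, 1] interpolates between pure Gaussian noise
#' with the family spectrum (0) and fully thresholded, phase-aligned
#' structure (1).
#'
#' @param n_families number of texture families (>= 1)
#' @param n_samples samples per family (>= 1)
#' @param image_side image side in pixels (even, >= 8)
#' @param structure_strength amount of planted higher-order structure, in [0,1]
#' @param seed integer master seed
#' @return an object of class `synthetic_texture_params`
#' @export
synthetic_texture_params <- function(n_families = 15L, n_samples = 15L,
                                     image_side = 320L,
                                     structure_strength = 1, seed = 1L) {
  stopifnot_scalar(n_families, "n_families", integerish = TRUE, positive = TRUE)
  stopifnot_scalar(n_samples, "n_samples", integerish = TRUE, positive = TRUE)
  stopifnot_scalar(image_side, "image_side", integerish = TRUE, positive = TRUE)
  if (image_side < 8 || image_side %% 2 != 0) {
    stop("`image_side` must be even and >= 8", call. = FALSE)
  }
  stopifnot_scalar(structure_strength, "structure_strength", nonneg = TRUE)
  if (structure_strength > 1) {
    stop("`structure_strength` must lie in [0, 1]", call. = FALSE)
  }
  stopifnot_scalar(seed, "seed", integerish = TRUE)
  structure(list(n_families = as.integer(n_families),
                 n_samples = as.integer(n_samples),
                 image_side = as.integer(image_side),
                 structure_strength = structure_strength,
                 seed = as.integer(seed)),
            class = "synthetic_texture_params")
}

# Family reference amplitude spectrum: an isotropic 1/f bed plus one or two
# oriented band-pass Gaussian bumps whose angles and bandwidths are a
# deterministic function of family_id. The bed and bump components are
# returned separately: higher-order structure is planted inside the oriented
# band only, so it is visible to orientation-matched filters and diluted in
# unselective mixtures. DC amplitude is zero (zero-mean images).
family_spectrum <- function(params, family_id) {
  n <- params$image_side
  fx <- c(0:(n / 2), -(n / 2 - 1):-1) / n   # DFT frequencies, cycles/pixel
  u <- matrix(fx, n, n)                      # row frequency
  v <- matrix(fx, n, n, byrow = TRUE)        # column frequency
  r <- sqrt(u^2 + v^2)
  ang <- atan2(v, u)

  g <- with_seed(substream_seed(params$seed, family_id, 0), {
    list(theta = stats::runif(2, 0, pi),
         sigma_ang = stats::runif(2, 0.2, 0.4),
         r0 = stats::runif(2, 0.08, 0.2),
         sigma_r = stats::runif(2, 0.03, 0.08),
         mix = stats::runif(2, 0.6, 1))
  })
  bump <- 0
  for (b in 1:2) {
    # angular distance on the orientation circle (period pi)
    d <- abs(((ang - g$theta[b] + pi / 2) %% pi) - pi / 2)
    bump <- bump + g$mix[b] *
      exp(-d^2 / (2 * g$sigma_ang[b]^2)) *
      exp(-(r - g$r0[b])^2 / (2 * g$sigma_r[b]^2))
  }
  bed <- 0.05 / (r + 0.02)
  bump <- 2 * bump / (r + 0.02)
  bed[1, 1] <- 0
  bump[1, 1] <- 0
  list(bed = bed, bump = bump, total = bed + bump, theta = g$theta)
}

shape_noise <- function(A, w) {
  n <- nrow(w)
  X <- stats::fft(w)
  Re(stats::fft(A * X / pmax(Mod(X), 1e-12), inverse = TRUE)) / (n * n)
}

# One sample: the oriented band component is soft-thresholded (sparsified,
# creating phase-aligned high-kurtosis structure inside the band), the
# isotropic bed stays Gaussian, and the total reference spectrum is
# re-imposed on the composite so texture/noise pairs differ only in phase
# structure.
synth_texture_image <- function(params, family_id, sample) {
  n <- params$image_side
  sp <- family_spectrum(params, family_id)
  w <- with_seed(substream_seed(params$seed, family_id, sample),
                 matrix(stats::rnorm(2 * n * n), 2 * n, n))
  band <- shape_noise(sp$bump, w[seq_len(n), ])
  bed <- shape_noise(sp$bed, w[n + seq_len(n), ])
  gamma <- params$structure_strength
  if (gamma > 0) {
    z <- band / max(sd_pop(band), 1e-12)
    # soft threshold at two band standard deviations: keeps ~5% of band
    # pixels as sparse, elongated, phase-aligned events
    band <- (1 - gamma) * z + gamma * sign(z) * pmax(abs(z) - 2, 0)
    # restore the band's spectral weight after thresholding
    band <- shape_noise(sp$bump, band)
  }
  x <- band + bed
  X <- stats::fft(x)
  x <- Re(stats::fft(sp$total * X / pmax(Mod(X), 1e-12),
                     inverse = TRUE)) / (n * n)
  x / max(sd_pop(x), 1e-12)
}

#' Generate one synthetic texture family
#'
#' Returns `n_samples` grayscale images (matrices) sharing the family's
#' reference amplitude spectrum and higher-order structure. Deterministic in
#' `(seed, family_id, sample index)`: regenerating with more samples leaves
#' earlier samples bit-identical.
#'
#' @param params a [synthetic_texture_params()] object
#' @param family_id family index in `1..n_families`
#' @return list of `n_samples` numeric matrices with a `family_id` attribute
#' @export
generate_texture_family <- function(params, family_id) {
  stopifnot(inherits(params, "synthetic_texture_params"))
  stopifnot_scalar(family_id, "family_id", integerish = TRUE, positive = TRUE)
  if (family_id > params$n_families) {
    stop("`family_id` exceeds n_families", call. = FALSE)
  }
  out <- lapply(seq_len(params$n_samples), function(s)
    synth_texture_image(params, family_id, s))
  attr(out, "family_id") <- as.integer(family_id)
  out
}

#' Generate all families of a synthetic texture set
#'
#' Convenience wrapper over [generate_texture_family()].
#' @param params a [synthetic_texture_params()] object
#' @return list of families, each as returned by [generate_texture_family()]
#' @export
generate_texture_set <- function(params) {
  lapply(seq_len(params$n_families), function(f)
    generate_texture_family(params, f))
}

#' Parameters for planted model-neuron response tensors
#'
#' @param planted_modulation numeric matrix (n_neurons x n_families) of
#'   per-neuron per-family modulation indices, all strictly inside (-1, 1)
#' @param n_samples samples per family
#' @param response_scale positive scale of the family-mean responses
#' @param noise_sd standard deviation of per-sample response jitter
#'   (truncated at zero); 0 gives exactly the planted indices
#' @param seed integer seed
#' @return an object of class `planted_response_params`
#' @export
planted_response_params <- function(planted_modulation, n_samples = 15L,
                                    response_scale = 1, noise_sd = 0,
                                    seed = 1L) {
  if (!is.matrix(planted_modulation) || !is.numeric(planted_modulation)) {
    stop("`planted_modulation` must be a numeric matrix", call. = FALSE)
  }
  if (any(abs(planted_modulation) >= 1)) {
    stop("planted modulation values must lie strictly inside (-1, 1)",
         call. = FALSE)
  }
  stopifnot_scalar(n_samples, "n_samples", integerish = TRUE, positive = TRUE)
  stopifnot_scalar(response_scale, "response_scale", positive = TRUE)
  stopifnot_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  stopifnot_scalar(seed, "seed", integerish = TRUE)
  structure(list(planted_modulation = planted_modulation,
                 n_neurons = nrow(planted_modulation),
                 n_families = ncol(planted_modulation),
                 n_samples = as.integer(n_samples),
                 response_scale = response_scale,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "planted_response_params")
}

#' Generate a response tensor with planted modulation structure
#'
#' Family-mean responses are `scale * (1 + m)` to naturalistic textures and
#' `scale * (1 - m)` to noise, so the modulation index `(r_na - r_no) /
#' (r_na + r_no)` equals the planted value `m` exactly when `noise_sd = 0`.
#' Per-sample responses add Gaussian jitter truncated at zero (responses are
#' post-rectification, hence nonnegative).
#'
#' @param params a [planted_response_params()] object
#' @return a `response_tensor`: 4-D array
#'   `[neuron, family, sample, type]` with `type` in
#'   `c("naturalistic", "noise")`
#' @export
generate_response_tensor <- function(params) {
  stopifnot(inherits(params, "planted_response_params"))
  m <- params$planted_modulation
  nn <- params$n_neurons; nf <- params$n_families; ns <- params$n_samples
  r_na <- params$response_scale * (1 + m)
  r_no <- params$response_scale * (1 - m)
  arr <- array(0, dim = c(nn, nf, ns, 2),
               dimnames = list(NULL, NULL, NULL, c("naturalistic", "noise")))
  for (s in seq_len(ns)) {
    if (params$noise_sd > 0) {
      eps <- with_seed(substream_seed(params$seed, s),
                       matrix(stats::rnorm(nn * nf * 2, sd = params$noise_sd),
                              nn, nf * 2))
      arr[, , s, 1] <- pmax(r_na + eps[, seq_len(nf)], 0)
      arr[, , s, 2] <- pmax(r_no + eps[, nf + seq_len(nf)], 0)
    } else {
      arr[, , s, 1] <- r_na
      arr[, , s, 2] <- r_no
    }
  }
  response_tensor(arr)
}

#' Construct a response tensor
#'
#' @param responses nonnegative 4-D array `[neuron, family, sample, type]`
#'   with the fourth extent 2 (`naturalistic`, `noise`)
#' @param meta optional data frame of per-neuron metadata (filter, row,
#'   col, tap point)
#' @return object of class `response_tensor`
#' @export
response_tensor <- function(responses, meta = NULL) {
  if (!is.array(responses) || length(dim(responses)) != 4 ||
      dim(responses)[4] != 2) {
    stop("`responses` must be a [neuron, family, sample, 2] array",
         call. = FALSE)
  }
  if (any(!is.finite(responses))) {
    stop("response tensor contains missing or non-finite entries",
         call. = FALSE)
  }
  dimnames(responses) <- list(NULL, NULL, NULL, c("naturalistic", "noise"))
  structure(responses, class = "response_tensor", meta = meta)
}

#' @export
print.response_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("response_tensor: %d neurons x %d families x %d samples x 2 types\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Target vector planted from a neuron subset
#'
#' The equally weighted mean of the selected rows of a modulation profile:
#' by construction that subset attains Euclidean error zero against the
#' returned target, enabling parameter-recovery tests of the fitting
#' procedures.
#'
#' @param profile a [modulation_profile()] (or plain matrix)
#' @param subset nonempty integer vector of neuron indices
#' @return numeric vector, one mean modulation index per family
#' @export
generate_planted_target <- function(profile, subset) {
  M <- if (inherits(profile, "modulation_profile")) profile$M else profile
  if (length(subset) == 0) stop("`subset` must be nonempty", call. = FALSE)
  if (any(subset < 1 | subset > nrow(M))) {
    stop("`subset` contains out-of-range indices", call. = FALSE)
  }
  colMeans(M[subset, , drop = FALSE])
}
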