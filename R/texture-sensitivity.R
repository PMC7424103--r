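# Per-neuron, per-family modulation indices and population summaries.
#
# The modulation index (r_na - r_no) / (r_na + r_no) measures the
# differential response to naturalistic textures versus spectrally matched
# noise: positive values mean sensitivity to the higher-order statistics
# that phase randomization destroys.

#' Modulation index of a single response pair
#'
#' @param r_na nonnegative response(s) to naturalistic textures
#' @param r_no nonnegative response(s) to spectrally matched noise
#' @return `(r_na - r_no) / (r_na + r_no)`, in `[-1, 1]`; vectorized
#' @export
modulation_index <- function(r_na, r_no) {
  if (any(r_na < 0) || any(r_no < 0)) {
    stop("responses must be nonnegative", call. = FALSE)
  }
  tot <- r_na + r_no
  if (any(tot == 0)) {
    stop("modulation index undefined: r_na + r_no = 0", call. = FALSE)
  }
  (r_na - r_no) / tot
}

#' Modulation profile of a response tensor
#'
#' For each (neuron, family), responses are averaged over samples
#' separately for the naturalistic and noise conditions and the modulation
#' index is applied to the two family means (`order = "mean_first"`, the
#' default, which stabilizes the ratio). `order = "index_first"` instead
#' averages per-sample indices. Neurons whose summed family-mean response
#' is zero for any family have an undefined index there and are flagged
#' invalid rather than erroring.
#'
#' @param tensor a [response_tensor()]
#' @param order `"mean_first"` (default) or `"index_first"`
#' @return object of class `modulation_profile`: list with `M` (matrix
#'   neuron x family, `NA` where undefined) and `valid` (logical per
#'   neuron: defined for every family)
#' @export
modulation_matrix <- function(tensor, order = c("mean_first", "index_first")) {
  stopifnot(inherits(tensor, "response_tensor"))
  order <- match.arg(order)
  d <- dim(tensor)
  r_na <- apply(tensor[, , , 1, drop = FALSE], c(1, 2), mean)
  r_no <- apply(tensor[, , , 2, drop = FALSE], c(1, 2), mean)
  if (order == "mean_first") {
    tot <- r_na + r_no
    M <- ifelse(tot > 0, (r_na - r_no) / tot, NA_real_)
  } else {
    tot_s <- tensor[, , , 1, drop = FALSE] + tensor[, , , 2, drop = FALSE]
    idx <- ifelse(tot_s > 0,
                  (tensor[, , , 1, drop = FALSE] -
                     tensor[, , , 2, drop = FALSE]) / tot_s, NA_real_)
    M <- apply(idx, c(1, 2), mean)   # NA propagates if any sample undefined
  }
  # pre-rectification taps can carry negative responses, for which the
  # ratio escapes [-1, 1]; such indices are undefined, not errors
  M[!is.na(M) & abs(M) > 1] <- NA_real_
  dim(M) <- d[1:2]
  modulation_profile(M)
}

#' Construct a modulation profile
#'
#' @param M numeric matrix (neuron x family) of modulation indices, `NA`
#'   where undefined; defined entries must lie in `[-1, 1]`
#' @return object of class `modulation_profile`
#' @export
modulation_profile <- function(M) {
  stopifnot(is.matrix(M), is.numeric(M))
  if (any(abs(M) > 1 + 1e-12, na.rm = TRUE)) {
    stop("modulation indices must lie in [-1, 1]", call. = FALSE)
  }
  structure(list(M = M, valid = !apply(is.na(M), 1, any)),
            class = "modulation_profile")
}

#' @export
print.modulation_profile <- function(x, ...) {
  cat(sprintf("modulation_profile: %d neurons x %d families (%d valid)\n",
              nrow(x$M), ncol(x$M), sum(x$valid)))
  invisible(x)
}

#' Indices of neurons with a defined modulation index for every family
#'
#' Mirrors the exclusion of model neurons with zero response to any
#' family, the exact condition under which the index is undefined.
#'
#' @param profile a [modulation_profile()]
#' @return integer vector of valid neuron indices
#' @export
filter_valid_neurons <- function(profile) {
  stopifnot(inherits(profile, "modulation_profile"))
  which(profile$valid)
}

#' Mean modulation per family over a neuron subset
#'
#' @param profile a [modulation_profile()]
#' @param indices nonempty integer vector of neuron indices
#' @return numeric vector, one equally weighted mean per family
#' @export
population_mean_modulation <- function(profile, indices) {
  stopifnot(inherits(profile, "modulation_profile"))
  if (length(indices) == 0) stop("`indices` must be nonempty", call. = FALSE)
  if (any(indices < 1 | indices > nrow(profile$M))) {
    stop("`indices` out of range", call. = FALSE)
  }
  colMeans(profile$M[indices, , drop = FALSE])
}

#' Modulation summaries over random neuron populations
#'
#' Repeatedly draws `size` valid neurons without replacement and records
#' the population's per-family mean modulation and the fraction of drawn
#' neurons whose across-family mean index is positive.
#'
#' @param profile a [modulation_profile()]
#' @param size population size per draw (e.g. 103)
#' @param n_repeats number of repeats (e.g. 10000)
#' @param seed integer seed
#' @return list with `mean_modulation` (per-family mean over repeats),
#'   `per_repeat` (matrix repeats x families), `positive_fraction`
#'   (mean over repeats), `positive_fraction_per_repeat`
#' @export
sample_random_populations <- function(profile, size = 103L,
                                      n_repeats = 10000L, seed = 1L) {
  stopifnot(inherits(profile, "modulation_profile"))
  valid <- filter_valid_neurons(profile)
  if (size > length(valid)) {
    stop("`size` exceeds the number of valid neurons", call. = FALSE)
  }
  M <- profile$M
  with_seed(seed, {
    per_repeat <- matrix(0, n_repeats, ncol(M))
    pos <- numeric(n_repeats)
    neuron_mean <- rowMeans(M)
    for (r in seq_len(n_repeats)) {
      draw <- valid[sample.int(length(valid), size)]
      per_repeat[r, ] <- colMeans(M[draw, , drop = FALSE])
      pos[r] <- mean(neuron_mean[draw] > 0)
    }
    list(mean_modulation = colMeans(per_repeat),
         per_repeat = per_repeat,
         positive_fraction = mean(pos),
         positive_fraction_per_repeat = pos)
  })
}

#' Null band for the population mean modulation
#'
#' Permutation null: within each (neuron, family) cell the
#' naturalistic/noise labels of the `2 * n_samples` responses are shuffled,
#' the modulation profile recomputed, and the population mean modulation
#' recorded per family. Returns the 2.5th and 97.5th empirical percentiles
#' (the chance band) per family.
#'
#' @param tensor a [response_tensor()] with >= 2 samples per family
#' @param n_perm number of permutations (>= 40 recommended; fewer warns)
#' @param seed integer seed
#' @return list with `lower`, `upper` (per-family percentiles), `mean`
#'   (per-family null mean) and `draws` (matrix n_perm x families)
#' @export
null_modulation_distribution <- function(tensor, n_perm = 200L, seed = 1L) {
  stopifnot(inherits(tensor, "response_tensor"))
  d <- dim(tensor)
  if (d[3] < 2) stop("need >= 2 samples per family", call. = FALSE)
  if (n_perm < 40) {
    warning("n_perm < 40: percentile band will be unstable")
  }
  nn <- d[1]; nf <- d[2]; ns <- d[3]
  with_seed(seed, {
    draws <- matrix(NA_real_, n_perm, nf)
    for (p in seq_len(n_perm)) {
      perm <- array(0, dim = d[1:4])
      for (f in seq_len(nf)) {
        pooled <- cbind(matrix(tensor[, f, , 1], nn, ns),
                        matrix(tensor[, f, , 2], nn, ns))
        for (i in seq_len(nn)) {
          sh <- pooled[i, sample.int(2 * ns)]
          perm[i, f, , 1] <- sh[seq_len(ns)]
          perm[i, f, , 2] <- sh[ns + seq_len(ns)]
        }
      }
      prof <- modulation_matrix(response_tensor(perm))
      valid <- filter_valid_neurons(prof)
      if (length(valid) > 0) {
        draws[p, ] <- population_mean_modulation(prof, valid)
      }
    }
    ok <- stats::complete.cases(draws)
    list(lower = apply(draws[ok, , drop = FALSE], 2,
                       stats::quantile, probs = 0.025, names = FALSE),
         upper = apply(draws[ok, , drop = FALSE], 2,
                       stats::quantile, probs = 0.975, names = FALSE),
         mean = colMeans(draws[ok, , drop = FALSE]),
         draws = draws)
  })
}
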