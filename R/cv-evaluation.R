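# Cross-validation schemes and pipeline orchestration.
#
# A "data point" is one group of samples from one family (nominally 15
# images). Leave-one-group-out CV re-estimates the modulation profile from
# the training samples only, refits the population, and predicts the mean
# modulation of the held-out group; leave-family-out instead drops an
# entire family's column from the fit.

#' Build a leave-one-group-out cross-validation plan
#'
#' Randomly partitions each family's samples into groups of `group_size`;
#' each group is one data point and is held out in exactly one fold. With
#' 15 families, 225 samples per family and groups of 15 this yields the
#' 225-point / 225-fold design.
#'
#' @param n_families number of families
#' @param samples_per_family samples per family (divisible by `group_size`)
#' @param group_size samples per data point (default 15)
#' @param seed integer seed for the random partition
#' @return object of class `cv_plan`: list with `points` (each
#'   `list(family, samples)`) and `group_size`
#' @export
make_cv_plan <- function(n_families, samples_per_family, group_size = 15L,
                         seed = 1L) {
  stopifnot_scalar(n_families, "n_families", integerish = TRUE, positive = TRUE)
  stopifnot_scalar(samples_per_family, "samples_per_family",
                   integerish = TRUE, positive = TRUE)
  stopifnot_scalar(group_size, "group_size", integerish = TRUE, positive = TRUE)
  if (samples_per_family %% group_size != 0) {
    stop("`samples_per_family` must be divisible by `group_size`",
         call. = FALSE)
  }
  n_groups <- samples_per_family %/% group_size
  points <- list()
  for (f in seq_len(n_families)) {
    perm <- with_seed(substream_seed(seed, f),
                      sample.int(samples_per_family))
    for (g in seq_len(n_groups)) {
      points[[length(points) + 1L]] <- list(
        family = f,
        samples = sort(perm[(g - 1L) * group_size + seq_len(group_size)]))
    }
  }
  structure(list(points = points, group_size = as.integer(group_size),
                 n_families = as.integer(n_families),
                 samples_per_family = as.integer(samples_per_family)),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("cv_plan: %d points (%d families x %d groups of %d), %d folds\n",
              length(x$points), x$n_families,
              x$samples_per_family %/% x$group_size, x$group_size,
              length(x$points)))
  invisible(x)
}

# Modulation profile restricted to a subset of samples; `keep` is a list of
# per-family sample-index vectors (NULL entry = all samples).
modulation_matrix_subset <- function(tensor, keep) {
  d <- dim(tensor)
  M <- matrix(NA_real_, d[1], d[2])
  for (f in seq_len(d[2])) {
    sel <- keep[[f]]
    if (is.null(sel)) sel <- seq_len(d[3])
    r_na <- rowMeans(matrix(tensor[, f, sel, 1], d[1], length(sel)))
    r_no <- rowMeans(matrix(tensor[, f, sel, 2], d[1], length(sel)))
    tot <- r_na + r_no
    M[, f] <- ifelse(tot > 0, (r_na - r_no) / tot, NA_real_)
  }
  modulation_profile(M)
}

fit_dispatch <- function(profile, target, method, k, lam) {
  switch(method,
         greedy = greedy_subset(profile, target, k = k),
         full_population = full_population_weights(profile, target),
         regularized = regularized_subset(profile, target, lam = lam, k = k),
         stop(sprintf("unknown fit method '%s'", method), call. = FALSE))
}

# Prediction of one family's mean modulation from a fitted population,
# using a profile computed on the evaluation samples. Returns NA when any
# needed neuron is undefined on those samples.
predict_family <- function(fit, eval_profile, family) {
  col <- eval_profile$M[, family]
  if (length(fit$selected_indices) > 0) {
    vals <- col[fit$selected_indices]
    if (any(is.na(vals))) return(NA_real_)
    mean(vals)
  } else {
    idx <- as.integer(names(fit$weights))
    vals <- col[idx]
    use <- fit$weights > 0
    if (any(is.na(vals[use]))) return(NA_real_)
    sum(fit$weights[use] * vals[use])
  }
}

#' Leave-one-group-out cross-validation of a population fit
#'
#' Per fold: the modulation profile is recomputed from the training samples
#' only (the held-out group's samples are removed from its family), the
#' population is refit to the target, and the fitted population's mean
#' modulation on the held-out samples is compared with the target entry for
#' that family. Folds whose prediction is undefined (a selected neuron with
#' zero summed response on the held-out samples) are skipped with a warning
#' and reported in `n_skipped`.
#'
#' @param tensor a [response_tensor()]
#' @param target numeric target vector (one entry per family)
#' @param plan a [make_cv_plan()] consistent with the tensor
#' @param method `"greedy"`, `"full_population"` or `"regularized"`
#' @param k subset size for the subset methods
#' @param lam ridge parameter for `"regularized"`
#' @return list with per-fold train/test errors, their means, per-family
#'   mean predictions, overall `euclidean`, `spearman`, `r_squared`, and
#'   `n_skipped`
#' @export
cross_validate <- function(tensor, target, plan,
                           method = c("greedy", "full_population",
                                      "regularized"),
                           k = 103L, lam = 0.8) {
  stopifnot(inherits(tensor, "response_tensor"), inherits(plan, "cv_plan"))
  method <- match.arg(method)
  d <- dim(tensor)
  if (plan$n_families != d[2] || plan$samples_per_family != d[3]) {
    stop("cv plan is inconsistent with the response tensor", call. = FALSE)
  }
  nf <- d[2]
  n_points <- length(plan$points)
  train_err <- test_err <- rep(NA_real_, n_points)
  pred <- rep(NA_real_, n_points)
  fam_of <- vapply(plan$points, `[[`, integer(1), "family")
  skipped <- 0L
  for (i in seq_len(n_points)) {
    pt <- plan$points[[i]]
    keep <- vector("list", nf)
    keep[[pt$family]] <- setdiff(seq_len(d[3]), pt$samples)
    res <- tryCatch({
      train_prof <- modulation_matrix_subset(tensor, keep)
      fit <- fit_dispatch(train_prof, target, method, k, lam)
      hold <- vector("list", nf)
      hold[[pt$family]] <- pt$samples
      eval_prof <- modulation_matrix_subset(tensor, hold)
      p <- predict_family(fit, eval_prof, pt$family)
      list(train = fit$train_error, pred = p)
    }, error = function(e) NULL)
    if (is.null(res) || is.na(res$pred)) {
      skipped <- skipped + 1L
      next
    }
    train_err[i] <- res$train
    pred[i] <- res$pred
    test_err[i] <- abs(res$pred - target[pt$family])
  }
  if (skipped > 0) {
    warning(sprintf("%d of %d folds skipped (undefined modulation indices)",
                    skipped, n_points))
  }
  ok <- !is.na(pred)
  fam_pred <- vapply(seq_len(nf), function(f) {
    v <- pred[ok & fam_of == f]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  comp <- !is.na(fam_pred)
  list(method = method,
       fold_train_error = train_err,
       fold_test_error = test_err,
       mean_train_error = mean(train_err[ok]),
       mean_test_error = mean(test_err[ok]),
       family_prediction = fam_pred,
       euclidean = euclidean_error(fam_pred[comp], target[comp]),
       spearman = tryCatch(spearman_correlation(fam_pred[comp], target[comp]),
                           error = function(e) NA_real_),
       r_squared = tryCatch(explained_variance(fam_pred[comp], target[comp]),
                            error = function(e) NA_real_),
       n_skipped = skipped)
}

#' Leave-family-out evaluation of a population fit
#'
#' For each family `f` the population is fit to the target restricted to
#' the other families (a 14-dimensional fit in the nominal design) and the
#' held-out family's mean modulation is predicted as the selected
#' population's profile entry for `f` computed from all samples.
#'
#' @inheritParams cross_validate
#' @return list with per-family predictions and absolute errors, overall
#'   `euclidean` and `spearman`
#' @export
leave_family_out <- function(tensor, target,
                             method = c("greedy", "full_population",
                                        "regularized"),
                             k = 103L, lam = 0.8) {
  stopifnot(inherits(tensor, "response_tensor"))
  method <- match.arg(method)
  nf <- dim(tensor)[2]
  if (nf < 2) stop("need >= 2 families", call. = FALSE)
  profile <- modulation_matrix(tensor)
  pred <- rep(NA_real_, nf)
  for (f in seq_len(nf)) {
    train_prof <- modulation_profile(profile$M[, -f, drop = FALSE])
    fit <- fit_dispatch(train_prof, target[-f], method, k, lam)
    pred[f] <- predict_family(fit, profile, f)
  }
  ok <- !is.na(pred)
  list(method = method,
       family_prediction = pred,
       abs_error = abs(pred - target),
       euclidean = euclidean_error(pred[ok], target[ok]),
       spearman = tryCatch(spearman_correlation(pred[ok], target[ok]),
                           error = function(e) NA_real_))
}

#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs. `target` may be a numeric
#' vector (one mean modulation index per family, e.g. recorded V2 data);
#' when `NULL` the full valid population's mean modulation under the first
#' weight mode and tap point serves as the reference target.
#'
#' @param texture_params a [synthetic_texture_params()]
#' @param spec an [architecture_spec()]
#' @param weight_modes character vector drawn from
#'   `c("structured", "random")`; `"structured"` uses oriented band-pass
#'   first-stage filters with nonnegative pooling-style second-stage
#'   filters (see [structured_weights()]), `"random"` uniform `[-1, 1]`
#' @param tap_points character vector of layer names to analyse
#' @param selector a [population_selector()] (its `tap_point` is replaced
#'   per analysed tap)
#' @param factor downsampling factor for stimulus preparation
#' @param methods fit methods to run
#' @param k,lam fit parameters
#' @param target optional target vector
#' @param cv_group_size group size for leave-one-group-out CV (NULL = skip CV)
#' @param out_dir output directory (NULL = no files written)
#' @param plots write ggplot2 figures (requires `out_dir`)
#' @param seed global seed
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(texture_params = synthetic_texture_params(),
                            spec = alexnet_spec(),
                            weight_modes = c("structured", "random"),
                            tap_points = "norm2",
                            selector = population_selector(),
                            factor = 4L,
                            methods = c("greedy", "full_population",
                                        "regularized"),
                            k = 103L, lam = 0.8,
                            target = NULL,
                            cv_group_size = NULL,
                            out_dir = NULL, plots = FALSE, seed = 1L) {
  structure(list(texture_params = texture_params, spec = spec,
                 weight_modes = weight_modes, tap_points = tap_points,
                 selector = selector, factor = as.integer(factor),
                 methods = methods, k = as.integer(k), lam = lam,
                 target = target, cv_group_size = cv_group_size,
                 out_dir = out_dir, plots = isTRUE(plots),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Structured weights for a two-stage feature model
#'
#' A stand-in for trained weights, built to be sensitive to the structure
#' the synthetic textures plant. First-stage filters are oriented
#' odd-symmetric Gabor kernels spanning equally spaced orientations.
#' Second-stage filters are collinear coincidence detectors: on every input
#' channel, an elongated positive ridge perpendicular to that channel's
#' wavevector (i.e., along the response ridge of an oriented wave packet)
#' minus an isotropic local average, so each channel slice has zero net
#' weight. The zero baseline makes the unit event-driven rather than
#' mean-driven, and the aligned integration responds coherently to the
#' elongated, phase-aligned events of naturalistic textures while spatially
#' scattered (phase-randomized) activation cancels. Per-(filter, channel)
#' gains vary deterministically with `seed` to diversify the population.
#'
#' @param spec an [architecture_spec()] with one or more convolution layers
#' @param seed integer seed for the gain variation
#' @return a `weight_set`
#' @export
structured_weights <- function(spec, seed = 1L) {
  shapes <- conv_shapes(spec)
  if (length(shapes) < 1) stop("spec has no convolution layers", call. = FALSE)
  ws <- list()
  nm1 <- names(shapes)[1]
  sh1 <- shapes[[nm1]]
  k1 <- sh1[3]
  n_orient <- sh1[1]
  grid <- seq(-(k1 - 1) / 2, (k1 - 1) / 2, length.out = k1)
  gx <- matrix(grid, k1, k1)
  gy <- t(gx)
  arr1 <- array(0, dim = sh1)
  for (f in seq_len(n_orient)) {
    th <- pi * (f - 1) / n_orient
    u <- cos(th) * gx + sin(th) * gy
    g <- exp(-(gx^2 + gy^2) / (2 * (k1 / 4)^2)) * sin(2 * pi * u / (k1 / 2))
    g <- g - mean(g)
    g <- g / sqrt(sum(g^2))
    for (ch in seq_len(sh1[2])) arr1[f, ch, , ] <- g
  }
  ws[[nm1]] <- arr1
  if (length(shapes) >= 2) {
    for (li in 2:length(shapes)) {
      nm2 <- names(shapes)[li]
      sh2 <- shapes[[nm2]]
      k2 <- sh2[3]
      g2 <- seq(-1, 1, length.out = k2)
      g2x <- matrix(g2, k2, k2)
      g2y <- t(g2x)
      blob <- exp(-(g2x^2 + g2y^2) / 1.2)
      blob <- blob / sum(blob)
      gains <- with_seed(substream_seed(seed, li),
                         matrix(stats::runif(sh2[1] * sh2[2], 0.5, 1.5),
                                sh2[1], sh2[2]))
      arr2 <- array(0, dim = sh2)
      for (f in seq_len(sh2[1])) for (ch in seq_len(sh2[2])) {
        th <- pi * ((ch - 1) %% n_orient) / n_orient
        u <- cos(th) * g2x + sin(th) * g2y
        v <- -sin(th) * g2x + cos(th) * g2y
        ridge <- exp(-u^2 / 0.1 - v^2 / 3)
        if (k2 == 1) {
          arr2[f, ch, , ] <- gains[f, ch]
        } else {
          arr2[f, ch, , ] <- gains[f, ch] * (ridge / sum(ridge) - blob)
        }
      }
      ws[[nm2]] <- arr2
    }
  }
  structure(ws, class = "weight_set", mode = "provided",
            seed = as.integer(seed))
}

#' Screen out weakly responsive neurons
#'
#' Returns the indices of neurons whose summed family-mean response
#' (`r_na + r_no`) reaches at least `min_fraction` of the median summed
#' response for every family. Near-silent units carry modulation indices
#' with vanishing denominators whose values are dominated by numerical
#' noise; screening them mirrors the exclusion of unresponsive neurons in
#' neurophysiological population analyses. `min_fraction = 0` reduces to
#' the exact zero-response criterion of [filter_valid_neurons()].
#'
#' @param tensor a [response_tensor()]
#' @param min_fraction response floor as a fraction of the median summed
#'   family-mean response (default 0.25)
#' @return integer vector of neuron indices
#' @export
filter_responsive_neurons <- function(tensor, min_fraction = 0.25) {
  stopifnot(inherits(tensor, "response_tensor"))
  stopifnot_scalar(min_fraction, "min_fraction", nonneg = TRUE)
  r_na <- apply(tensor[, , , 1, drop = FALSE], c(1, 2), mean)
  r_no <- apply(tensor[, , , 2, drop = FALSE], c(1, 2), mean)
  tot <- r_na + r_no
  dim(tot) <- dim(tensor)[1:2]
  thr <- min_fraction * stats::median(tot)
  which(apply(tot >= thr & tot > 0, 1, all))
}

#' Bundled two-stage geometry for synthetic-texture experiments
#'
#' A compact AlexNet-like two-block hierarchy sized for the synthetic
#' texture families: 8 oriented 11x11 stride-2 filters, ReLU, 3x3 stride-2
#' max pool, LRN; then 16 3x3 filters, ReLU, 7x7 stride-4 max pool, LRN.
#' The wide second pooling stage converts the sparse, high-amplitude
#' events that distinguish naturalistic textures from spectrally matched
#' noise into family-mean response differences.
#'
#' @param n_orient number of first-stage orientations (default 8)
#' @param n_filters_l2 second-stage filter count (default 16)
#' @return an [architecture_spec()]
#' @export
synthetic_texture_spec <- function(n_orient = 8L, n_filters_l2 = 16L) {
  architecture_spec(list(
    layer_conv(n_orient, 11L, stride = 2L, pad = 0L),
    layer_relu(),
    layer_maxpool(3L, 2L),
    layer_lrn(),
    layer_conv(n_filters_l2, 3L, stride = 1L, pad = 1L),
    layer_relu(),
    layer_maxpool(7L, 4L),
    layer_lrn()
  ), input_channels = 1L)
}

#' Compare structured against random second-stage weights
#'
#' One replicate of the trained-versus-random control analysis on
#' synthetic textures: both models share the oriented first stage; the
#' structured model uses [structured_weights()] for the second stage while
#' the control replaces them with uniform `[-1, 1]` draws. Reported are
#' (a) each population's mean modulation index over responsive neurons
#' and (b) each population's greedy-subset fit error against a target
#' planted as the mean of a random 30% subset of the structured
#' population's profile -- the stand-in for recorded cortical data. A
#' structure-sensitive second stage is expected to raise the mean
#' modulation and to lower the fit error relative to the random control,
#' whose representation cannot express the structured profile.
#'
#' @param seed integer replicate seed
#' @param n_families,n_samples,image_side synthetic ensemble size
#' @param spec two-stage [architecture_spec()]
#' @param k greedy subset size
#' @return named numeric vector: `mod_structured`, `mod_random`,
#'   `err_structured`, `err_random`
#' @export
compare_structured_random <- function(seed, n_families = 5L, n_samples = 8L,
                                      image_side = 64L,
                                      spec = synthetic_texture_spec(),
                                      k = 10L) {
  sel <- population_selector(spatial_neighborhood = 2L, tap_point = "norm2")
  tp <- synthetic_texture_params(n_families = n_families,
                                 n_samples = n_samples,
                                 image_side = image_side,
                                 structure_strength = 1, seed = seed)
  ens <- build_ensemble(generate_texture_set(tp), factor = 1L,
                        seed = substream_seed(seed, 31))
  wS <- structured_weights(spec, seed = 1L)
  wR <- wS
  conv_names <- names(conv_shapes(spec))
  nm2 <- conv_names[length(conv_names)]
  wR[[nm2]] <- init_weights(spec, "random",
                            seed = substream_seed(seed, 32))[[nm2]]
  tS <- compute_response_tensor(ens, spec, wS, sel)
  tR <- compute_response_tensor(ens, spec, wR, sel)
  pS <- modulation_matrix(tS)
  pR <- modulation_matrix(tR)
  vS <- intersect(filter_valid_neurons(pS), filter_responsive_neurons(tS))
  vR <- intersect(filter_valid_neurons(pR), filter_responsive_neurons(tR))
  mS <- mean(population_mean_modulation(pS, vS))
  mR <- mean(population_mean_modulation(pR, vR))
  sub <- with_seed(substream_seed(seed, 33),
                   sample(vS, max(2L, round(length(vS) * 0.3))))
  target <- generate_planted_target(pS, sub)
  pS2 <- modulation_profile(pS$M[vS, , drop = FALSE])
  pR2 <- modulation_profile(pR$M[vR, , drop = FALSE])
  kk <- min(k, length(vS), length(vR))
  c(mod_structured = mS, mod_random = mR,
    err_structured = greedy_subset(pS2, target, kk)$train_error,
    err_random = greedy_subset(pR2, target, kk)$train_error)
}

#' Run the full analysis pipeline
#'
#' Generates (or accepts) stimuli, extracts features at the requested tap
#' points under each weight mode, computes modulation profiles and
#' population summaries, runs the requested fits (and optionally
#' leave-one-group-out CV), and writes CSV/JSON (and optionally PNG
#' figures) when an output directory is configured. Fully reproducible
#' from `(config, seed)`.
#'
#' @param config a [pipeline_config()]
#' @param ensemble optional pre-built `texture_ensemble` (skips synthesis)
#' @return list with `target`, and per weight mode / tap point:
#'   `mean_modulation`, `n_valid`, and a fit result (plus CV summary) per
#'   method
#' @export
run_pipeline <- function(config, ensemble = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  tp <- config$texture_params
  if (is.null(ensemble)) {
    images <- generate_texture_set(tp)
    ensemble <- build_ensemble(images, factor = config$factor,
                               seed = substream_seed(config$seed, 1))
  }
  results <- list()
  target <- config$target
  rows <- list()
  for (mode in config$weight_modes) {
    weights <- switch(mode,
      structured = structured_weights(config$spec,
                                      seed = substream_seed(config$seed, 2)),
      random = init_weights(config$spec, "random",
                            seed = substream_seed(config$seed, 3)),
      stop(sprintf("unknown weight mode '%s'", mode), call. = FALSE))
    for (tap in config$tap_points) {
      sel <- config$selector
      sel$tap_point <- tap
      tensor <- compute_response_tensor(ensemble, config$spec, weights, sel)
      profile <- modulation_matrix(tensor)
      valid <- filter_valid_neurons(profile)
      mean_mod <- if (length(valid)) {
        population_mean_modulation(profile, valid)
      } else rep(NA_real_, dim(tensor)[2])
      if (is.null(target) && length(valid) > 0) target <- mean_mod
      entry <- list(mean_modulation = mean_mod, n_valid = length(valid),
                    fits = list())
      for (method in config$methods) {
        if (length(valid) == 0) {
          rows[[length(rows) + 1L]] <- data.frame(
            mode = mode, tap_point = tap, method = method, n_valid = 0L,
            train_error = NA_real_, test_error = NA_real_,
            spearman = NA_real_, r_squared = NA_real_)
          next
        }
        k_use <- min(config$k, length(valid))
        fit <- fit_dispatch(profile, target, method, k_use, config$lam)
        if (!is.null(config$cv_group_size)) {
          plan <- make_cv_plan(dim(tensor)[2], dim(tensor)[3],
                               config$cv_group_size,
                               seed = substream_seed(config$seed, 4))
          fit$cv <- cross_validate(tensor, target, plan, method,
                                   k = k_use, lam = config$lam)
          fit$test_error <- fit$cv$mean_test_error
        }
        entry$fits[[method]] <- fit
        rows[[length(rows) + 1L]] <- data.frame(
          mode = mode, tap_point = tap, method = method,
          n_valid = length(valid),
          train_error = fit$train_error,
          test_error = if (is.null(fit$test_error)) NA_real_ else fit$test_error,
          spearman = fit$spearman, r_squared = fit$r_squared)
      }
      results[[mode]][[tap]] <- entry
    }
  }
  fit_table <- do.call(rbind, rows)
  out <- list(target = target, results = results, fit_table = fit_table,
              config = config)
  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(out, config)
  }
  invisible(out)
}

write_pipeline_outputs <- function(out, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out$fit_table,
                   file.path(config$out_dir, "fit_results.csv"),
                   row.names = FALSE)
  mod_rows <- list()
  for (mode in names(out$results)) {
    for (tap in names(out$results[[mode]])) {
      mm <- out$results[[mode]][[tap]]$mean_modulation
      mod_rows[[length(mod_rows) + 1L]] <- data.frame(
        mode = mode, tap_point = tap, family = seq_along(mm),
        mean_modulation = mm)
    }
  }
  mod_table <- do.call(rbind, mod_rows)
  utils::write.csv(mod_table,
                   file.path(config$out_dir, "mean_modulation.csv"),
                   row.names = FALSE)
  summary <- list(
    seed = config$seed,
    target = out$target,
    k = config$k, lambda = config$lam,
    weight_modes = config$weight_modes,
    tap_points = config$tap_points,
    n_families = config$texture_params$n_families,
    n_samples = config$texture_params$n_samples,
    image_side = config$texture_params$image_side,
    downsample_factor = config$factor)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  if (config$plots) {
    plot_modulation_by_family(mod_table,
      file.path(config$out_dir, "modulation_by_family.png"))
    plot_error_by_tap(out$fit_table,
      file.path(config$out_dir, "error_by_tap.png"))
  }
  invisible(NULL)
}

plot_modulation_by_family <- function(mod_table, path) {
  p <- ggplot2::ggplot(mod_table,
         ggplot2::aes(x = factor(.data$family), y = .data$mean_modulation,
                      fill = .data$tap_point)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~mode) +
    ggplot2::labs(x = "texture family", y = "mean modulation index",
                  fill = "tap point") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = 8, height = 4, dpi = 120)
}

plot_error_by_tap <- function(fit_table, path) {
  p <- ggplot2::ggplot(fit_table,
         ggplot2::aes(x = .data$tap_point, y = .data$train_error,
                      fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~mode) +
    ggplot2::labs(x = "tap point", y = "Euclidean train error",
                  fill = "method") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = 8, height = 4, dpi = 120)
}
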