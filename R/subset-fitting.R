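# Population fitting: greedy forward subset selection, simplex-constrained
# least squares over the full population, and a ridge-regularized subset
# variant, plus the fit metrics (Euclidean error, Spearman rank correlation,
# explained variance).

#' Euclidean distance between two vectors
#'
#' @param x,y numeric vectors of equal length
#' @return `sqrt(sum((x - y)^2))`
#' @export
euclidean_error <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  sqrt(sum((x - y)^2))
}

#' Spearman rank-order correlation
#'
#' Pearson correlation of ranks with average ranks for ties. Errors on
#' constant input, where the correlation is undefined.
#'
#' @param x,y numeric vectors of equal length >= 3
#' @return correlation in `[-1, 1]`
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("`x` and `y` must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Spearman correlation undefined for a constant vector",
         call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}

#' Explained variance of a fit
#'
#' `1 - SSE/SST` with the total sum of squares about the target's mean.
#'
#' @param fitted numeric vector of fitted values
#' @param target numeric vector with nonzero variance
#' @return explained variance (can be negative for fits worse than the mean)
#' @export
explained_variance <- function(fitted, target) {
  if (length(fitted) != length(target)) {
    stop("`fitted` and `target` must have equal length", call. = FALSE)
  }
  sst <- sum((target - mean(target))^2)
  if (sst == 0) {
    stop("explained variance undefined: target has zero variance",
         call. = FALSE)
  }
  1 - sum((target - fitted)^2) / sst
}

# ---------------------------------------------------------------------------
# Simplex-constrained quadratic solver (active set).
#
# minimize  ||M w - t||^2 + lambda ||w||^2
# subject   sum(w) = 1,  w >= 0
#
# Primal active-set method on the bound constraints. Each subproblem is the
# equality-constrained quadratic over the free coordinates, solved from its
# KKT system; when lambda = 0 the Hessian can be rank deficient, in which
# case the least-norm KKT solution (pseudoinverse) is used -- the objective
# is constant along null directions so any KKT solution is a subproblem
# minimizer. For lambda = 0 the iteration starts from the single closest
# row (the solution support is small by Caratheodory); for lambda > 0 it
# starts from the uniform weights (the regularizer keeps the support wide).
# ---------------------------------------------------------------------------
simplex_lsq <- function(M, t, lambda = 0, tol = 1e-9, max_iter = NULL) {
  n <- nrow(M)
  if (n == 1L) return(list(w = 1, kkt = 0, iterations = 0L))
  Q <- tcrossprod(M)                  # rows of M are neurons: f = ||M'w - t||^2
  if (lambda > 0) Q <- Q + diag(lambda, n)
  b <- drop(M %*% t)
  if (is.null(max_iter)) max_iter <- 100L * n

  if (lambda > 0) {
    free <- rep(TRUE, n)
    w <- rep(1 / n, n)
  } else {
    j0 <- which.min(colSums((t(M) - t)^2))
    free <- rep(FALSE, n); free[j0] <- TRUE
    w <- numeric(n); w[j0] <- 1
  }

  solve_sub <- function(free) {
    idx <- which(free)
    k <- length(idx)
    A <- rbind(cbind(2 * Q[idx, idx, drop = FALSE], 1), c(rep(1, k), 0))
    rhs <- c(2 * b[idx], 1)
    sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(sol) || any(!is.finite(sol))) {
      sol <- drop(MASS::ginv(A) %*% rhs)
    }
    x <- numeric(n)
    x[idx] <- sol[seq_len(k)]
    list(x = x, nu = sol[k + 1])
  }

  for (iter in seq_len(max_iter)) {
    sub <- solve_sub(free)
    x <- sub$x
    if (all(x[free] >= -tol)) {
      w <- pmax(x, 0)
      w <- w / sum(w)
      # multipliers for the active bounds: mu_i = g_i - nu must be >= 0
      g <- 2 * (drop(Q %*% w) - b)
      nu <- mean(g[free])
      mu <- g - nu
      active <- which(!free)
      if (length(active) == 0 || all(mu[active] >= -tol)) {
        return(list(w = w, kkt = max(0, -suppressWarnings(min(mu[active], Inf))),
                    iterations = iter))
      }
      free[active[which.min(mu[active])]] <- TRUE
    } else {
      d <- x - w
      blocking <- which(free & x < -tol & d < 0)
      alpha <- pmin(1, w[blocking] / (w[blocking] - x[blocking]))
      j <- blocking[which.min(alpha)]
      a <- max(0, min(alpha))
      w <- w + a * d
      w[j] <- 0
      free[j] <- FALSE
      w <- pmax(w, 0); w <- w / sum(w)
    }
  }
  warning("simplex_lsq reached the iteration cap; returning current iterate")
  list(w = w, kkt = NA_real_, iterations = max_iter)
}

# Shared bookkeeping: valid rows, metrics, result container.
profile_rows <- function(profile, target) {
  M <- if (inherits(profile, "modulation_profile")) profile$M else profile
  if (!is.matrix(M)) stop("`profile` must be a modulation profile or matrix",
                          call. = FALSE)
  valid <- if (inherits(profile, "modulation_profile")) {
    filter_valid_neurons(profile)
  } else {
    which(!apply(is.na(M), 1, any))
  }
  if (length(valid) == 0) {
    stop("no valid neurons to fit (insufficient population)", call. = FALSE)
  }
  if (ncol(M) != length(target)) {
    stop("target length must equal the number of families", call. = FALSE)
  }
  list(M = M[valid, , drop = FALSE], valid = valid)
}

fit_result <- function(method, fitted, target, selected = integer(0),
                       weights = numeric(0), lambda = NULL, k = NULL,
                       extra = list()) {
  sp <- tryCatch(spearman_correlation(fitted, target),
                 error = function(e) NA_real_)
  r2 <- tryCatch(explained_variance(fitted, target),
                 error = function(e) NA_real_)
  structure(c(list(method = method,
                   selected_indices = selected,
                   weights = weights,
                   fitted = fitted,
                   train_error = euclidean_error(fitted, target),
                   test_error = NULL,
                   spearman = sp, r_squared = r2,
                   lambda = lambda, k = k), extra),
            class = "texture_fit")
}

#' @export
print.texture_fit <- function(x, ...) {
  cat(sprintf("texture_fit [%s]: train error %.4g", x$method, x$train_error))
  if (!is.null(x$test_error)) cat(sprintf(", test error %.4g", x$test_error))
  cat(sprintf(", spearman %.3f, R^2 %.3f\n", x$spearman, x$r_squared))
  if (length(x$selected_indices)) {
    cat(sprintf("  %d selected neurons\n", length(x$selected_indices)))
  }
  invisible(x)
}

#' Greedy forward subset selection
#'
#' Starting from the empty set, each step adds the unselected valid neuron
#' that minimizes the squared Euclidean distance between the target and the
#' equally weighted mean of the selected rows, until `k` neurons are
#' chosen. Ties break toward the lowest neuron index. The result is an
#' actual equally weighted population, directly comparable to how the
#' recorded data's mean modulation index is computed.
#'
#' @param profile a [modulation_profile()] (or plain matrix)
#' @param target numeric target vector, one mean modulation per family
#' @param k subset size (default 103, matching the recorded V2 population;
#'   use 102 for V1-sized populations)
#' @return a `texture_fit`
#' @export
greedy_subset <- function(profile, target, k = 103L) {
  pr <- profile_rows(profile, target)
  M <- pr$M
  n <- nrow(M)
  stopifnot_scalar(k, "k", integerish = TRUE, positive = TRUE)
  if (k > n) stop("`k` exceeds the number of valid neurons", call. = FALSE)
  selected <- integer(0)
  run_sum <- numeric(ncol(M))
  remaining <- rep(TRUE, n)
  for (j in seq_len(k)) {
    cand <- which(remaining)
    # mean if candidate i joined: (run_sum + M[i,]) / j
    cand_means <- sweep(M[cand, , drop = FALSE], 2, run_sum, "+") / j
    errs <- rowSums(sweep(cand_means, 2, target)^2)
    pick <- cand[which.min(errs)]      # which.min takes the first = lowest index
    selected <- c(selected, pick)
    run_sum <- run_sum + M[pick, ]
    remaining[pick] <- FALSE
  }
  fitted <- run_sum / k
  fit_result("greedy", fitted, target,
             selected = pr$valid[selected],
             weights = rep(1 / k, k), k = as.integer(k))
}

#' Optimal weighted average over the full population
#'
#' Solves the simplex-constrained least-squares problem
#' `min ||M w - t||^2` subject to `w >= 0, sum(w) = 1`. The resulting
#' error is the infimum over all convex combinations of neurons, hence a
#' lower bound for every subset method on the same inputs.
#'
#' @inheritParams greedy_subset
#' @param tol KKT tolerance of the active-set solver
#' @return a `texture_fit` with `weights` over the valid neurons (named by
#'   original neuron index via `selected_indices` ordering of all valid
#'   neurons)
#' @export
full_population_weights <- function(profile, target, tol = 1e-9) {
  pr <- profile_rows(profile, target)
  sol <- simplex_lsq(pr$M, target, lambda = 0, tol = tol)
  fitted <- drop(crossprod(pr$M, sol$w))
  fit_result("full_population", fitted, target,
             selected = integer(0),
             weights = stats::setNames(sol$w, pr$valid),
             extra = list(kkt = sol$kkt))
}

#' Regularized subset selection
#'
#' Solves `min ||M w - t||^2 + lambda ||w||^2` on the simplex. The ridge
#' term pushes weights toward the center of the simplex, spreading mass
#' over more neurons; the reported `weight_fraction` is the fraction of
#' weights at or above `report_threshold`. The final subset is the `k`
#' neurons with the largest weights (ties toward the lowest index),
#' re-scored as an equally weighted average -- matching how the data's
#' modulation index is computed -- and the train error refers to that
#' equally weighted subset.
#'
#' @inheritParams greedy_subset
#' @param lam ridge trade-off parameter (default 0.8)
#' @param report_threshold weight threshold for the reported fraction
#'   (default 2e-3)
#' @param tol KKT tolerance of the active-set solver
#' @return a `texture_fit`; `weights` holds the solved simplex weights,
#'   `weight_fraction` the fraction above threshold
#' @export
regularized_subset <- function(profile, target, lam = 0.8, k = 103L,
                               report_threshold = 2e-3, tol = 1e-9) {
  stopifnot_scalar(lam, "lam", nonneg = TRUE)
  pr <- profile_rows(profile, target)
  n <- nrow(pr$M)
  stopifnot_scalar(k, "k", integerish = TRUE, positive = TRUE)
  if (k > n) stop("`k` exceeds the number of valid neurons", call. = FALSE)
  sol <- simplex_lsq(pr$M, target, lambda = lam, tol = tol)
  w <- sol$w
  ord <- order(-w, seq_along(w))          # largest weight first, ties by index
  sel_local <- sort(ord[seq_len(k)])
  fitted <- colMeans(pr$M[sel_local, , drop = FALSE])
  fit_result("regularized", fitted, target,
             selected = pr$valid[sel_local],
             weights = stats::setNames(w, pr$valid),
             lambda = lam, k = as.integer(k),
             extra = list(
               weight_fraction = mean(w >= report_threshold),
               solver_fitted = drop(crossprod(pr$M, w)),
               kkt = sol$kkt))
}
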