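# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Saves and restores `.Random.seed` so seeded draws inside the package never
#' disturb the caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Deterministic substream seed for a named draw. Mixing is a fixed integer
# hash so adding samples or families never perturbs existing ones; the result
# stays inside the 32-bit range set.seed() accepts.
substream_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  h <- 0
  for (v in ids) {
    h <- (h * 1000003 + (as.numeric(v) + 1)) %% 2147483647
  }
  as.integer(h)
}

stopifnot_scalar <- function(x, name, integerish = FALSE, positive = FALSE,
                             nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (integerish && x != round(x)) {
    stop(sprintf("`%s` must be a whole number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  }
  invisible(x)
}

check_image <- function(image, name = "image") {
  if (!is.matrix(image) || !is.numeric(image) || is.complex(image)) {
    stop(sprintf("`%s` must be a real-valued 2-D matrix", name), call. = FALSE)
  }
  invisible(image)
}

# Population (divide-by-N) standard deviation.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
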