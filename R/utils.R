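#' Evaluate code with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so generators are reproducible
#' without disturbing the session. `seed = NULL` leaves the RNG stream alone.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number or NULL.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

check_scalar <- function(x, nm, min = -Inf, max = Inf, allow_min = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(paste0("`", nm, "` must be a single finite number."))
  }
  lo_ok <- if (allow_min) x >= min else x > min
  if (!lo_ok || x > max) {
    abort(paste0("`", nm, "` = ", format(x), " is outside its valid range."))
  }
  invisible(x)
}

#' Add a 2-D Gaussian spot to an image in place
#'
#' @param img Y x X matrix.
#' @param x0,y0 Spot centre in 0-based pixel-centre coordinates.
#' @param amplitude Peak height above background.
#' @param sigma Standard deviation in pixels.
#' @return The image with the spot added (local window of radius `5*sigma`).
#' @keywords internal
add_gaussian_spot <- function(img, x0, y0, amplitude, sigma) {
  r <- ceiling(5 * sigma)
  ny <- nrow(img)
  nx <- ncol(img)
  ys <- max(1L, floor(y0 + 1 - r)):min(ny, ceiling(y0 + 1 + r))
  xs <- max(1L, floor(x0 + 1 - r)):min(nx, ceiling(x0 + 1 + r))
  if (!length(ys) || !length(xs)) return(img)
  gy <- exp(-((ys - 1 - y0)^2) / (2 * sigma^2))
  gx <- exp(-((xs - 1 - x0)^2) / (2 * sigma^2))
  img[ys, xs] <- img[ys, xs] + amplitude * (gy %o% gx)
  img
}

# lognormal(meanlog, sdlog) with given arithmetic mean and CV; cv = 0 is the
# degenerate point mass at `mean`
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

apply_noise <- function(img, noise_model, noise_scale) {
  img <- switch(noise_model,
    none = img,
    gaussian = img + rnorm(length(img), sd = noise_scale),
    poisson = {
      x <- rpois(length(img), lambda = pmax(as.numeric(img), 0))
      matrix(x, nrow = nrow(img))
    },
    abort("`noise_model` must be one of 'none', 'gaussian', 'poisson'.")
  )
  pmax(img, 0)
}
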