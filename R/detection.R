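#' Gaussian noise filter with reflective boundaries
#'
#' Smooths a single-channel image by separable convolution with a normalized
#' discrete Gaussian kernel, the standard pre-filtering step before punctum
#' detection. Boundary pixels are handled by reflection about the image edge
#' (the edge row/column is repeated), so a constant image is returned
#' unchanged and the kernel mass is preserved everywhere.
#'
#' The kernel is truncated at `4 * sigma` pixels and renormalized to sum to
#' one, so the filter preserves the total intensity of an interior impulse to
#' within numerical precision.
#'
#' @param img Numeric matrix of non-negative intensities.
#' @param sigma Gaussian standard deviation in pixels; `sigma = 0` returns
#'   the input unchanged. The default (1) is the conventional choice for
#'   diffraction-limited puncta.
#' @return A numeric matrix of the same dimensions.
#' @examples
#' img <- matrix(0, 21, 21); img[11, 11] <- 1
#' sm <- gaussian_filter(img, 1)
#' sum(sm)  # ~1: kernel mass preserved
#' @export
gaussian_filter <- function(img, sigma = 1) {
  .check_image(img)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("sigma must be a single non-negative number", call. = FALSE)
  if (sigma == 0) return(img)
  r <- max(1L, ceiling(4 * sigma))
  w <- dnorm(seq(-r, r), sd = sigma)
  w <- w / sum(w)
  out <- .conv_dim1(img, w, r)
  t(.conv_dim1(t(out), w, r))
}

# reflective index: ... 2 1 | 1 2 ... n | n n-1 ...
.reflect_idx <- function(i, n) {
  j <- ((i - 1) %% (2 * n) + 2 * n) %% (2 * n)  # 0 .. 2n-1
  ifelse(j < n, j + 1, 2 * n - j)
}

# convolve each column of m with kernel w (half-width r), reflective pad
.conv_dim1 <- function(m, w, r) {
  n <- nrow(m)
  pad <- m[.reflect_idx((1 - r):(n + r), n), , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (k in seq_along(w))
    out <- out + w[k] * pad[k:(k + n - 1L), , drop = FALSE]
  out
}

#' Extract noise-tolerance (prominence) maxima from an image
#'
#' Implements maximal-point extraction with a user-defined tolerance, the
#' punctum-calling step of the quantification workflow. A regional maximum
#' `m` with value `v` is accepted as a focus if and only if no path starting
#' at `m` along pixels with values `> v - tolerance` reaches a pixel with
#' value `> v`; equivalently, its prominence (height above the highest
#' saddle connecting it to higher ground) is at least `tolerance`. A maximum
#' with no higher ground anywhere (in particular the global maximum) takes
#' the image minimum as its reference level, so a constant image and an
#' image whose total relief is below `tolerance` yield no foci.
#'
#' Plateaus (connected sets of equal-valued pixels forming a regional
#' maximum) produce one focus at their centroid, rounded half-up. Equal-height
#' maxima never suppress one another.
#'
#' @param img Numeric matrix, usually already smoothed (see
#'   [gaussian_filter()]; [detect_foci()] composes the two steps).
#' @param tolerance Positive prominence threshold, in intensity units of
#'   `img`. Per-channel values are user-set and sample-dependent.
#' @param exclude_border Drop foci whose centroid lies within this many
#'   pixels of the image edge (default 0, keep all).
#' @param channel Optional channel name attached to the result.
#' @return A `focus_set`: a data frame with columns `row`, `col` (1-based
#'   pixel coordinates) and `value` (peak intensity), ordered by row then
#'   column, with attribute `channel`.
#' @seealso [detect_foci()] for the filter + extraction composition.
#' @export
find_maxima <- function(img, tolerance, exclude_border = 0L, channel = NA_character_) {
  .check_image(img)
  if (!is.numeric(tolerance) || length(tolerance) != 1L || !is.finite(tolerance) ||
      tolerance <= 0)
    stop("tolerance must be a single positive number", call. = FALSE)
  if (exclude_border < 0)
    stop("exclude_border must be non-negative", call. = FALSE)
  df <- .find_maxima_cpp(img, tolerance, as.integer(exclude_border))
  .focus_set(df, channel)
}

.focus_set <- function(df, channel) {
  stopifnot(is.data.frame(df))
  rownames(df) <- NULL
  attr(df, "channel") <- channel
  class(df) <- c("focus_set", class(df))
  df
}

#' @export
print.focus_set <- function(x, ...) {
  ch <- attr(x, "channel")
  cat(sprintf("Focus set: %d foci%s\n", nrow(x),
              if (!is.na(ch)) paste0(" [channel ", ch, "]") else ""))
  if (nrow(x) > 0) print.data.frame(utils::head(x, 10), ...)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Detect RNAscope foci in one probe channel
#'
#' The full per-channel punctum detector: Gaussian noise filtering followed
#' by tolerance-maxima extraction. Equivalent to
#' `find_maxima(gaussian_filter(img, sigma), tolerance, ...)`.
#'
#' Note that `tolerance` applies to the *filtered* image: smoothing reduces
#' peak amplitudes (for a Gaussian spot of width `s` filtered at width
#' `sigma`, by the factor `s^2 / (s^2 + sigma^2)`), so tolerances are
#' naturally calibrated per sample on filtered intensities.
#'
#' @inheritParams find_maxima
#' @param sigma Pre-filter width in pixels (default 1).
#' @return A `focus_set`; see [find_maxima()].
#' @examples
#' img <- matrix(5, 41, 41)
#' img[15, 20] <- img[30, 11] <- 90   # two bright puncta
#' detect_foci(img, tolerance = 20, sigma = 1)
#' @export
detect_foci <- function(img, tolerance, sigma = 1, exclude_border = 0L,
                        channel = NA_character_) {
  find_maxima(gaussian_filter(img, sigma), tolerance,
              exclude_border = exclude_border, channel = channel)
}
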