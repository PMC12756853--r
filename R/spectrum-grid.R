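#' Spectral axis metadata
#'
#' An `axis_header` describes one dimension of a processed frequency-domain
#' NMR spectrum: the number of grid points, the spectral width, the observe
#' (transmitter) frequency and the chemical shift of the minimum-ppm edge.
#' The physical span of the axis in ppm is `sw / obs` (Hz divided by MHz),
#' independent of `n`.
#'
#' @param n Integer point count along the axis (>= 2).
#' @param sw Spectral width in Hz (> 0).
#' @param obs Observe/transmitter frequency in MHz (> 0).
#' @param origin_ppm Chemical shift (ppm) of the minimum-ppm edge of the
#'   axis. Grid index increases toward higher ppm; with the center-referenced
#'   convention used throughout, the 1-based pixel `i` sits at
#'   `origin_ppm + i * ss` where `ss = spectral_sampling(axis)`.
#'
#' @return An object of class `axis_header`.
#' @seealso [spectral_sampling()], [axis_center_ppm()], [spectrum_grid()]
#' @export
#' @examples
#' ax <- axis_header(n = 1000, sw = 100000, obs = 100, origin_ppm = 0)
#' spectral_sampling(ax)  # 0.001 ppm per pixel
axis_header <- function(n, sw, obs, origin_ppm = 0) {
  if (length(n) != 1L || !is.finite(n) || n < 2 || n != round(n))
    stop("axis_header: 'n' must be a single integer >= 2", call. = FALSE)
  if (length(sw) != 1L || !is.finite(sw) || sw <= 0)
    stop("axis_header: 'sw' must be a single positive number (Hz)", call. = FALSE)
  if (length(obs) != 1L || !is.finite(obs) || obs <= 0)
    stop("axis_header: 'obs' must be a single positive number (MHz)", call. = FALSE)
  if (length(origin_ppm) != 1L || !is.finite(origin_ppm))
    stop("axis_header: 'origin_ppm' must be a single finite number", call. = FALSE)
  structure(
    list(n = as.integer(n), sw = as.numeric(sw), obs = as.numeric(obs),
         origin_ppm = as.numeric(origin_ppm)),
    class = "axis_header"
  )
}

#' @export
print.axis_header <- function(x, ...) {
  cat(sprintf(
    "<axis_header> n=%d  sw=%.6g Hz  obs=%.6g MHz  origin=%.6g ppm  (%.6g ppm span, %.6g ppm/px)\n",
    x$n, x$sw, x$obs, x$origin_ppm, x$sw / x$obs, spectral_sampling(x)))
  invisible(x)
}

#' N-dimensional NMR spectrum raster
#'
#' A `spectrum_grid` bundles a real-valued intensity array with one
#' [axis_header()] per array dimension. By convention the *last* axis is the
#' direct (acquisition) dimension, and along every axis the array index
#' increases toward higher ppm.
#'
#' @param data Numeric array (2D or 3D; a matrix for 2D). All values must be
#'   finite.
#' @param axes List of [axis_header()] objects, one per dimension of `data`,
#'   in the same order as `dim(data)`.
#'
#' @return An object of class `spectrum_grid` with elements `data` and
#'   `axes`.
#' @export
#' @examples
#' g <- spectrum_grid(matrix(rnorm(12), 3, 4),
#'                    list(axis_header(3, 300, 100), axis_header(4, 400, 100)))
#' dim(g$data)
spectrum_grid <- function(data, axes) {
  if (!is.array(data) && !is.matrix(data))
    stop("spectrum_grid: 'data' must be a matrix or array", call. = FALSE)
  if (!all(is.finite(data)))
    stop("spectrum_grid: all intensities must be finite", call. = FALSE)
  if (!is.list(axes) || !all(vapply(axes, inherits, logical(1), "axis_header")))
    stop("spectrum_grid: 'axes' must be a list of axis_header objects", call. = FALSE)
  d <- dim(data)
  if (length(d) != length(axes))
    stop("spectrum_grid: data dimensionality (", length(d),
         ") does not match number of axes (", length(axes), ")", call. = FALSE)
  nn <- vapply(axes, function(a) a$n, integer(1))
  if (!all(d == nn))
    stop("spectrum_grid: data extents (", paste(d, collapse = "x"),
         ") do not match axis point counts (", paste(nn, collapse = "x"), ")",
         call. = FALSE)
  structure(list(data = data, axes = axes), class = "spectrum_grid")
}

#' @export
print.spectrum_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spectrum_grid> %s (%dD)\n", paste(d, collapse = " x "),
              length(d)))
  for (k in seq_along(x$axes)) {
    a <- x$axes[[k]]
    cat(sprintf("  axis %d%s: n=%d  sw=%.6g Hz  obs=%.6g MHz  origin=%.6g ppm\n",
                k, if (k == length(x$axes)) " (direct)" else "",
                a$n, a$sw, a$obs, a$origin_ppm))
  }
  cat(sprintf("  intensity range: [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.spectrum_grid <- function(x) dim(x$data)

#' Per-axis ppm coordinates of the grid points
#'
#' @param grid A [spectrum_grid()].
#' @return A list with one numeric vector of ppm values per axis, ascending.
#' @export
grid_ppm_coords <- function(grid) {
  lapply(grid$axes, function(a) {
    a$origin_ppm + seq_len(a$n) * spectral_sampling(a)
  })
}

n_axes <- function(grid) length(grid$axes)

axis_n <- function(grid) vapply(grid$axes, function(a) a$n, integer(1))
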