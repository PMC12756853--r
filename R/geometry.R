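#' Spectral sampling (ppm per pixel)
#'
#' The spectral sampling of an axis is its physical span in ppm divided by
#' its point count: `ss = (sw / obs) / n`, with `sw` in Hz and `obs` in MHz
#' so that `sw / obs` is ppm.
#'
#' @param axis An [axis_header()].
#' @return Sampling in ppm per pixel.
#' @export
#' @examples
#' spectral_sampling(axis_header(n = 1000, sw = 100000, obs = 100))  # 0.001
spectral_sampling <- function(axis) {
  stopifnot(inherits(axis, "axis_header"))
  (axis$sw / axis$obs) / axis$n
}

#' Chemical shift at the center of an axis
#'
#' With the center-referenced origin convention, the center of an axis of
#' `n` points sits at `origin_ppm + ((n + 1) / 2) * ss`. Relative offsets
#' between spectra are computed between these center values, which (unlike
#' the minimum-ppm origin itself) survive resampling and resizing.
#'
#' @param axis An [axis_header()].
#' @return Center chemical shift in ppm.
#' @export
axis_center_ppm <- function(axis) {
  axis$origin_ppm + ((axis$n + 1) / 2) * spectral_sampling(axis)
}

#' Center-referenced origin offset between two axes
#'
#' Computes the ppm offset between the centers of two axes that have
#' already been brought to a shared sampling and point count:
#' `(O1 + ((n+1)/2) * ss) - (O2 + ((n+1)/2) * ss)`, which reduces to
#' `O1 - O2` when `n` and `ss` are shared. Calling this on axes that do not
#' share `n` and `ss` (to within the rounding residual of
#' [resample_target_size()]) is an error: resample and resize first.
#'
#' @param a1,a2 [axis_header()] objects on a common grid.
#' @param shared_ss The common sampling in ppm/pixel (defaults to `a1`'s).
#' @return Origin offset in ppm (positive when axis 1's center is at higher
#'   ppm).
#' @export
origin_offset_center <- function(a1, a2, shared_ss = spectral_sampling(a1)) {
  stopifnot(inherits(a1, "axis_header"), inherits(a2, "axis_header"))
  if (a1$n != a2$n)
    stop("origin_offset_center: axes do not share a point count (",
         a1$n, " vs ", a2$n, "); resample/resize first", call. = FALSE)
  ss1 <- spectral_sampling(a1)
  ss2 <- spectral_sampling(a2)
  # allow the <= half-pixel-per-axis residual left by integer rounding in
  # resample_target_size, but nothing coarser
  tol <- shared_ss * (0.5 / a1$n + 1e-9)
  if (abs(ss1 - shared_ss) > tol || abs(ss2 - shared_ss) > tol)
    stop("origin_offset_center: axes do not share the spectral sampling (",
         format(ss1), " vs ", format(ss2), " ppm/px); resample first",
         call. = FALSE)
  (a1$origin_ppm + ((a1$n + 1) / 2) * shared_ss) -
    (a2$origin_ppm + ((a2$n + 1) / 2) * shared_ss)
}

#' Target point count for resampling to a reference sampling
#'
#' Number of pixels spectrum 2's axis must have, after Fourier
#' interpolation, for its sampling to match spectrum 1's:
#' `n_new = n_s2 / (ss_s1 / ss_s2)`, rounded half-up to the nearest
#' integer. The physical span `n_new * ss_s1` then matches the original
#' span `n_s2 * ss_s2` to within half a pixel.
#'
#' @param n_s2 Point count of the axis to be resampled.
#' @param ss_s1 Target (reference) sampling, ppm/pixel.
#' @param ss_s2 Current sampling of the axis, ppm/pixel.
#' @return Integer point count (>= 2).
#' @export
resample_target_size <- function(n_s2, ss_s1, ss_s2) {
  stopifnot(n_s2 > 0, ss_s1 > 0, ss_s2 > 0)
  n_new <- floor(n_s2 * ss_s2 / ss_s1 + 0.5)  # round half up
  if (n_new < 2)
    stop("resample_target_size: resampling would leave fewer than 2 pixels",
         call. = FALSE)
  as.integer(n_new)
}

#' Resample a spectrum onto a new grid by Fourier interpolation
#'
#' Transforms the raster to the frequency domain, symmetrically crops
#' (band-limits) or zero-pads each axis to the requested size, and
#' transforms back. The physical span of each axis is unchanged — only the
#' sampling changes — so headers keep their `sw` and `obs` and get the new
#' `n`, with the origin recomputed so the center chemical shift is exactly
#' preserved. Intensities are rescaled so the grid mean is preserved.
#'
#' For even sizes the Nyquist bin is handled symmetrically (merged on crop,
#' split on pad), which keeps the output real and makes
#' upsample-then-downsample the identity for band-limited input.
#'
#' @param grid A [spectrum_grid()].
#' @param new_dims Integer vector of target extents, one per axis, all >= 2.
#' @return A [spectrum_grid()] with `dim(data) == new_dims`.
#' @export
fourier_resize <- function(grid, new_dims) {
  stopifnot(inherits(grid, "spectrum_grid"))
  d <- dim(grid$data)
  new_dims <- as.integer(new_dims)
  if (length(new_dims) != length(d) || any(new_dims < 2))
    stop("fourier_resize: 'new_dims' must give an extent >= 2 per axis",
         call. = FALSE)
  if (all(new_dims == d)) return(grid)
  X <- stats::fft(grid$data)
  for (k in seq_along(d)) {
    if (new_dims[k] != d[k])
      X <- axis_apply(X, k, function(m) freq_remap_rows(m, new_dims[k]))
  }
  # 1/prod(old dims) (rather than new) preserves the mean / DC level
  out <- Re(stats::fft(X, inverse = TRUE)) / prod(d)
  axes <- mapply(function(a, n_new) {
    ss_new <- (a$sw / a$obs) / n_new
    center <- axis_center_ppm(a)
    axis_header(n_new, a$sw, a$obs, origin_ppm = center - ((n_new + 1) / 2) * ss_new)
  }, grid$axes, new_dims, SIMPLIFY = FALSE)
  spectrum_grid(out, axes)
}

# Symmetric real-space crop/pad to an explicit per-axis pixel count,
# preserving the center chemical shift to within half a pixel. Pads are
# filled with `fill` (0 by default). Used by resize_to_match() and by
# align(), which needs exact pixel-count agreement with the reference.
crop_pad_to_n <- function(grid, n_target, fill = 0) {
  d <- dim(grid$data)
  n_target <- as.integer(n_target)
  stopifnot(length(n_target) == length(d))
  if (any(n_target < 2))
    stop("resize: target extent smaller than 2 pixels", call. = FALSE)
  if (all(n_target == d)) return(grid)
  data <- grid$data
  axes <- grid$axes
  for (k in seq_along(d)) {
    nk <- dim(data)[k]
    nt <- n_target[k]
    if (nt == nk) next
    a <- axes[[k]]
    ss <- spectral_sampling(a)
    if (nt < nk) {                       # symmetric crop
      left <- (nk - nt) %/% 2L           # pixels removed below the origin side
      idx <- lapply(dim(data), seq_len)
      idx[[k]] <- (left + 1L):(left + nt)
      data <- do.call(`[`, c(list(data), idx, list(drop = FALSE)))
      origin_new <- a$origin_ppm + left * ss
    } else {                             # symmetric zero-pad
      left <- (nt - nk) %/% 2L
      dims_new <- dim(data)
      dims_new[k] <- nt
      padded <- array(fill, dims_new)
      idx <- lapply(dims_new, seq_len)
      idx[[k]] <- (left + 1L):(left + nk)
      padded <- do.call(`[<-`, c(list(padded), idx, list(value = data)))
      data <- padded
      origin_new <- a$origin_ppm - left * ss
    }
    # keep ss fixed: sw scales with n
    axes[[k]] <- axis_header(nt, ss * a$obs * nt, a$obs, origin_ppm = origin_new)
  }
  spectrum_grid(data, axes)
}

#' Crop or pad a spectrum to a target physical span
#'
#' Real-space symmetric crop or zero-pad so that each axis covers the
#' requested span in ppm at its current sampling, keeping the center
#' chemical shift fixed to within half a pixel. Padding extends the axis
#' with zero-intensity baseline; `sw` is updated so `ss` is unchanged.
#'
#' @param grid A [spectrum_grid()].
#' @param target_span_ppm Numeric vector, desired span per axis in ppm.
#' @return A resized [spectrum_grid()].
#' @export
resize_to_match <- function(grid, target_span_ppm) {
  stopifnot(inherits(grid, "spectrum_grid"))
  d <- dim(grid$data)
  stopifnot(length(target_span_ppm) == length(d), all(target_span_ppm > 0))
  n_target <- mapply(function(a, span) {
    ss <- spectral_sampling(a)
    floor(span / ss + 0.5)
  }, grid$axes, target_span_ppm)
  if (any(n_target < 2))
    stop("resize_to_match: target span smaller than 2 pixels", call. = FALSE)
  crop_pad_to_n(grid, n_target)
}
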