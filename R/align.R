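#' Alignment configuration
#'
#' @param max_shift_frac Largest allowed shift as a fraction of each axis
#'   extent, in `(0, 0.5]`. Restricting the cross-correlation peak search
#'   keeps circular wrap-around from producing spurious maxima; realistic
#'   referencing errors are a small fraction of the spectral width. Default
#'   0.25.
#' @param subpixel Logical; refine the integer peak with per-axis parabola
#'   fits (default `TRUE`).
#' @param score_surface `"conditioned"` (default) to compute correlation
#'   scores on the filtered/standardized spectra the CCF itself uses, or
#'   `"raw"` to score on the unfiltered rasters.
#' @param filter A [filter_spec()] controlling the conditioning high-pass.
#' @return An object of class `alignment_config`.
#' @export
alignment_config <- function(max_shift_frac = 0.25, subpixel = TRUE,
                             score_surface = c("conditioned", "raw"),
                             filter = filter_spec()) {
  if (length(max_shift_frac) != 1L || !is.finite(max_shift_frac) ||
      max_shift_frac <= 0 || max_shift_frac > 0.5)
    stop("alignment_config: 'max_shift_frac' must be in (0, 0.5]", call. = FALSE)
  score_surface <- match.arg(score_surface)
  stopifnot(inherits(filter, "filter_spec"))
  structure(list(max_shift_frac = as.numeric(max_shift_frac),
                 subpixel = isTRUE(subpixel),
                 score_surface = score_surface,
                 filter = filter),
            class = "alignment_config")
}

#' Circular cross-correlation of two conditioned spectra
#'
#' Computes `Re(IFFT(FFT(I1) * Conj(FFT(I2))))`, i.e. the circular
#' cross-correlation map whose value at displacement `d` is
#' `sum_x I1(x) * I2(x - d)`. The map is returned FFT-shifted so that zero
#' displacement sits at the center index `floor(n/2) + 1` along each axis.
#'
#' @param i1,i2 [spectrum_grid()] objects of identical shape, already
#'   conditioned (see [preprocess_spectrum()]).
#' @return An object of class `ccf_map`: list with `map` (the shifted CCF
#'   array), `zero` (1-based index of zero displacement per axis) and `n`
#'   (grid extents).
#' @export
cross_correlation <- function(i1, i2) {
  stopifnot(inherits(i1, "spectrum_grid"), inherits(i2, "spectrum_grid"))
  d <- dim(i1$data)
  if (!identical(d, dim(i2$data)))
    stop("cross_correlation: shape mismatch (", paste(d, collapse = "x"),
         " vs ", paste(dim(i2$data), collapse = "x"), ")", call. = FALSE)
  ccf <- Re(stats::fft(stats::fft(i1$data) * Conj(stats::fft(i2$data)),
                       inverse = TRUE)) / prod(d)
  structure(list(map = fft_shift_array(ccf),
                 zero = vapply(d, fft_center_index, integer(1)),
                 n = d),
            class = "ccf_map")
}

#' Locate the cross-correlation peak within the search window
#'
#' Returns the integer displacement (in pixels, per axis) that maximizes
#' the CCF, restricted to `|d| <= max_shift_frac * n` per axis. Exact ties
#' are broken in favor of the smallest Euclidean displacement, then
#' lexicographic order. If the global maximum lies outside the window, the
#' in-window maximum is returned and a warning recorded in the result's
#' `"warnings"` attribute.
#'
#' @param ccf A `ccf_map` from [cross_correlation()].
#' @param cfg An [alignment_config()].
#' @return Integer displacement vector with attributes `value` (CCF at the
#'   peak) and `warnings` (character vector).
#' @export
find_peak <- function(ccf, cfg = alignment_config()) {
  stopifnot(inherits(ccf, "ccf_map"))
  d <- ccf$n
  warn <- character(0)
  # displacement of each index along each axis
  disp <- lapply(seq_along(d), function(k) seq_len(d[k]) - ccf$zero[k])
  inside <- lapply(seq_along(d), function(k)
    abs(disp[[k]]) <= cfg$max_shift_frac * d[k])
  mask <- array(TRUE, d)
  for (k in seq_along(d)) mask <- mask & inside[[k]][slice.index(mask, k)]
  if (!any(mask))
    stop("find_peak: empty search window", call. = FALSE)
  m_in <- max(ccf$map[mask])
  if (max(ccf$map) > m_in)
    warn <- c(warn, sprintf(
      "CCF global maximum (%.6g) lies outside the +/-%g-fraction search window; using in-window maximum (%.6g)",
      max(ccf$map), cfg$max_shift_frac, m_in))
  hits <- which((ccf$map == m_in) & mask, arr.ind = TRUE)
  if (is.null(dim(hits))) hits <- matrix(hits, nrow = 1)
  dd <- sweep(hits, 2, ccf$zero)           # displacements of tied maxima
  ord <- do.call(order, c(list(rowSums(dd^2)), lapply(seq_len(ncol(dd)),
                                                      function(j) dd[, j])))
  peak <- as.integer(dd[ord[1], ])
  attr(peak, "value") <- m_in
  attr(peak, "warnings") <- warn
  peak
}

#' Sub-pixel refinement of a CCF peak by parabola interpolation
#'
#' For each axis independently, fits a parabola through the CCF values at
#' the peak and its two neighbors along that axis (circular wrap at map
#' edges) and moves the estimate to the parabola vertex:
#' `delta = (c_minus - c_plus) / (2 * (c_minus - 2 c_0 + c_plus))`, clamped
#' to `[-0.5, 0.5]`. Zero curvature yields `delta = 0` with a warning
#' recorded on the result.
#'
#' @param ccf A `ccf_map` from [cross_correlation()].
#' @param peak Integer displacement per axis (from [find_peak()]).
#' @return Numeric displacement per axis with attribute `warnings`.
#' @export
subpixel_refine <- function(ccf, peak) {
  stopifnot(inherits(ccf, "ccf_map"))
  d <- ccf$n
  stopifnot(length(peak) == length(d))
  idx0 <- ccf$zero + as.integer(peak)      # map index of the peak
  warn <- character(0)
  delta <- numeric(length(d))
  at <- function(ix) do.call(`[`, c(list(ccf$map), as.list(ix)))
  c0 <- at(idx0)
  for (k in seq_along(d)) {
    im <- idx0; ip <- idx0
    im[k] <- ((idx0[k] - 2) %% d[k]) + 1L  # circular neighbors
    ip[k] <- (idx0[k] %% d[k]) + 1L
    cm <- at(im); cp <- at(ip)
    denom <- cm - 2 * c0 + cp
    if (denom == 0) {
      warn <- c(warn, sprintf("axis %d: zero curvature at CCF peak; no sub-pixel refinement", k))
      delta[k] <- 0
    } else {
      delta[k] <- max(-0.5, min(0.5, (cm - cp) / (2 * denom)))
    }
  }
  out <- peak + delta
  attr(out, "warnings") <- warn
  out
}

#' Convert a pixel shift to ppm
#'
#' `shift_ppm = shift_px * ss + o_offset` per axis, where `ss` is the
#' shared sampling of the common grid and `o_offset` the center-referenced
#' origin offset ([origin_offset_center()]). Positive values mean the
#' moving spectrum's features sit at lower ppm than the reference's and
#' must move toward higher ppm to match.
#'
#' @param shift_px Numeric pixel displacement per axis.
#' @param ss Sampling in ppm/pixel per axis.
#' @param o_offset Origin offset in ppm per axis (default 0).
#' @return Numeric ppm shift per axis.
#' @export
pixels_to_ppm <- function(shift_px, ss, o_offset = 0) {
  if (length(ss) != length(shift_px) && length(ss) != 1L)
    stop("pixels_to_ppm: inconsistent axis count", call. = FALSE)
  if (length(o_offset) != length(shift_px) && length(o_offset) != 1L)
    stop("pixels_to_ppm: inconsistent axis count", call. = FALSE)
  as.numeric(shift_px) * as.numeric(ss) + as.numeric(o_offset)
}

#' Normalized correlation between two spectra at a given pixel shift
#'
#' Applies `shift` to the second raster by circular Fourier phase ramp
#' (exact for integer, band-limited interpolation for fractional shifts),
#' re-standardizes both rasters to zero mean and unit variance, and returns
#' their mean product — a Pearson-type correlation in `[-1, 1]`.
#'
#' @param i1,i2 [spectrum_grid()] objects of identical shape.
#' @param shift Numeric pixel displacement per axis applied to `i2`
#'   (positive moves content toward higher index / higher ppm).
#' @return Correlation in `[-1, 1]`.
#' @export
correlation_score <- function(i1, i2, shift = rep(0, length(dim(i1$data)))) {
  stopifnot(inherits(i1, "spectrum_grid"), inherits(i2, "spectrum_grid"))
  d <- dim(i1$data)
  if (!identical(d, dim(i2$data)))
    stop("correlation_score: shape mismatch", call. = FALSE)
  x2 <- if (all(shift == 0)) i2$data else fourier_shift(i2$data, shift)
  std <- function(x) {
    v <- mean((x - mean(x))^2)
    if (v <= 0) stop("correlation_score: degenerate variance", call. = FALSE)
    (x - mean(x)) / sqrt(v)
  }
  s <- mean(std(i1$data) * std(x2))
  max(-1, min(1, s))
}

#' Align a moving spectrum to a reference spectrum
#'
#' The full registration chain: spectral sampling from the headers, Fourier
#' resampling of the moving spectrum onto the reference sampling, symmetric
#' crop/pad to the reference extents (cropping before, zero-padding after
#' conditioning so pads sit at the zero-floated baseline), Gaussian
#' high-pass + standardization of both spectra, circular FFT
#' cross-correlation, windowed peak search, parabola sub-pixel refinement,
#' and conversion to ppm including the center-referenced origin offset.
#'
#' The result is the rigid offset of the moving spectrum (`s2`) relative to
#' the reference (`s1`): positive components mean `s2`'s features are at
#' lower ppm than `s1`'s and must move up. `apply_shift(s2, est$shift_ppm)`
#' produces the re-referenced spectrum.
#'
#' @param s1 Reference [spectrum_grid()] (2D).
#' @param s2 Moving [spectrum_grid()] (2D, same nuclei/ppm ranges up to
#'   resampling).
#' @param cfg An [alignment_config()].
#' @return An object of class `shift_estimate`: list with `shift_px`,
#'   `shift_ppm`, `ccf_peak_px`, `o_offset_ppm`, `ss_ppm_per_px`,
#'   `score_before`, `score_after`, `warnings`, `config`.
#' @export
align <- function(s1, s2, cfg = alignment_config()) {
  stopifnot(inherits(s1, "spectrum_grid"), inherits(s2, "spectrum_grid"))
  if (length(dim(s1$data)) != length(dim(s2$data)))
    stop("align: spectra have different dimensionality", call. = FALSE)
  if (length(dim(s1$data)) != 2L)
    stop("align: expects 2D spectra; project 3D volumes first (see project())",
         call. = FALSE)
  warn <- character(0)

  ss1 <- vapply(s1$axes, spectral_sampling, numeric(1))
  ss2 <- vapply(s2$axes, spectral_sampling, numeric(1))

  # Fourier-interpolate s2 onto s1's sampling where they differ
  if (any(abs(ss1 - ss2) > 1e-12 * ss1)) {
    n_new <- mapply(resample_target_size,
                    vapply(s2$axes, function(a) a$n, integer(1)), ss1, ss2)
    s2 <- fourier_resize(s2, n_new)
    ss2r <- vapply(s2$axes, spectral_sampling, numeric(1))
    resid <- abs(ss2r - ss1) / ss1
    if (any(resid > 0))
      warn <- c(warn, sprintf(
        "resampling residual: moving-spectrum sampling differs from reference by %s (relative) after integer rounding",
        paste(format(resid, digits = 3), collapse = ", ")))
  }

  n1 <- axis_n(s1)
  n2 <- axis_n(s2)
  # crop (raw surface) down to the reference extents where s2 is larger
  if (any(n2 > n1)) s2 <- crop_pad_to_n(s2, pmin(n1, axis_n(s2)))

  f1 <- preprocess_spectrum(s1, cfg$filter)
  f2 <- preprocess_spectrum(s2, cfg$filter)

  # zero-pad (conditioned surface, pad value 0 = zero-floated baseline)
  if (any(axis_n(f2) < n1)) f2 <- crop_pad_to_n(f2, n1)

  o_offset <- mapply(function(a1, a2, ss)
    origin_offset_center(a1, a2, shared_ss = ss),
    s1$axes, f2$axes, ss1)

  ccf <- cross_correlation(f1, f2)
  peak <- find_peak(ccf, cfg)
  warn <- c(warn, attr(peak, "warnings"))
  shift_px <- as.numeric(peak)
  if (cfg$subpixel) {
    refined <- subpixel_refine(ccf, peak)
    warn <- c(warn, attr(refined, "warnings"))
    shift_px <- as.numeric(refined)
  }
  # keep the estimate inside the declared search window
  wmax <- cfg$max_shift_frac * n1
  shift_px <- pmax(-wmax, pmin(wmax, shift_px))

  if (cfg$score_surface == "raw") {
    sc1 <- s1
    sc2 <- crop_pad_to_n(s2, n1)
  } else {
    sc1 <- f1
    sc2 <- f2
  }
  score_before <- correlation_score(sc1, sc2, rep(0, 2))
  score_after <- correlation_score(sc1, sc2, shift_px)
  if (score_after < score_before && !identical(as.numeric(peak), shift_px)) {
    # pathological: the interpolated shift scores below zero shift; fall
    # back to the integer CCF peak, whose score cannot be worse than 0's
    score_int <- correlation_score(sc1, sc2, as.numeric(peak))
    if (score_int > score_after) {
      shift_px <- as.numeric(peak)
      score_after <- score_int
      warn <- c(warn, "sub-pixel refinement discarded: scored below zero shift")
    }
  }

  structure(list(
    shift_px = shift_px,
    shift_ppm = pixels_to_ppm(shift_px, ss1, o_offset),
    ccf_peak_px = as.integer(peak),
    o_offset_ppm = as.numeric(o_offset),
    ss_ppm_per_px = ss1,
    score_before = score_before,
    score_after = score_after,
    warnings = warn,
    config = cfg
  ), class = "shift_estimate")
}

#' @export
print.shift_estimate <- function(x, ...) {
  cat("<shift_estimate>\n")
  cat(sprintf("  shift: %s px = %s ppm (origin offset %s ppm)\n",
              paste(sprintf("%+.3f", x$shift_px), collapse = ", "),
              paste(sprintf("%+.4f", x$shift_ppm), collapse = ", "),
              paste(sprintf("%+.4f", x$o_offset_ppm), collapse = ", ")))
  cat(sprintf("  correlation score: %.4f -> %.4f\n",
              x$score_before, x$score_after))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Apply a ppm shift to a spectrum
#'
#' Re-references a spectrum by `shift_ppm` per axis: the integer-pixel part
#' is absorbed into the header origin (lossless), and the sub-pixel
#' remainder is applied to the raster by circular Fourier phase ramp.
#' Aligning, applying the estimated `shift_ppm` to the moving spectrum and
#' re-aligning yields a residual of ~0.
#'
#' @param grid A [spectrum_grid()].
#' @param shift_ppm Numeric ppm shift per axis (positive moves features
#'   toward higher ppm).
#' @return Shifted [spectrum_grid()].
#' @export
apply_shift <- function(grid, shift_ppm) {
  stopifnot(inherits(grid, "spectrum_grid"))
  d <- dim(grid$data)
  stopifnot(length(shift_ppm) == length(d), all(is.finite(shift_ppm)))
  ss <- vapply(grid$axes, spectral_sampling, numeric(1))
  span <- vapply(grid$axes, function(a) a$sw / a$obs, numeric(1))
  if (any(abs(shift_ppm) > span))
    stop("apply_shift: shift exceeds the spectral span", call. = FALSE)
  shift_px <- shift_ppm / ss
  k <- round(shift_px)
  resid <- shift_px - k
  axes <- mapply(function(a, ki, ssk)
    axis_header(a$n, a$sw, a$obs, origin_ppm = a$origin_ppm + ki * ssk),
    grid$axes, k, ss, SIMPLIFY = FALSE)
  data <- if (any(resid != 0)) fourier_shift(grid$data, resid) else grid$data
  spectrum_grid(data, axes)
}
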