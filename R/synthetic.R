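# Deterministic synthetic correlation spectra with analytic ground truth.
# Peaks are rendered from closed-form line shapes evaluated at the grid's
# ppm coordinates, so any offset applied to peak positions is exact by
# construction (never produced by raster interpolation).

# Run code under a temporary RNG state; restores .Random.seed afterwards.
with_local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Synthetic spectrum specification
#'
#' Defines a sparse-peak synthetic correlation spectrum: a peak list
#' (positions in ppm, amplitudes, linewidths, line shape), the grid
#' geometry, the noise level and the RNG seed. Rendering is fully
#' deterministic for a fixed spec.
#'
#' @param peaks A data frame with columns `amp` (> 0), `shape`
#'   (`"gaussian"` or `"lorentzian"`), and per axis `k` the columns
#'   `pos<k>` (position, ppm) and `fw<k>` (full width at half maximum,
#'   ppm, > 0). Positions must lie within the ppm range of the axes.
#' @param axes List of [axis_header()] defining the grid.
#' @param noise_sigma Standard deviation of additive white Gaussian noise,
#'   relative to the largest peak amplitude (>= 0).
#' @param seed Integer seed controlling the noise realization.
#' @return An object of class `synthetic_spec`.
#' @seealso [render_spectrum()], [make_offset_pair()],
#'   [random_synthetic_spec()]
#' @export
synthetic_spec <- function(peaks, axes, noise_sigma = 0, seed = 1L) {
  stopifnot(is.data.frame(peaks),
            all(vapply(axes, inherits, logical(1), "axis_header")),
            length(noise_sigma) == 1L, noise_sigma >= 0,
            length(seed) == 1L, is.finite(seed))
  K <- length(axes)
  need <- c("amp", "shape", paste0("pos", seq_len(K)), paste0("fw", seq_len(K)))
  miss <- setdiff(need, names(peaks))
  if (length(miss))
    stop("synthetic_spec: peak table missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(peaks)) {
    if (any(peaks$amp <= 0)) stop("synthetic_spec: amplitudes must be > 0", call. = FALSE)
    if (!all(peaks$shape %in% c("gaussian", "lorentzian")))
      stop("synthetic_spec: shape must be 'gaussian' or 'lorentzian'", call. = FALSE)
    for (k in seq_len(K)) {
      ss <- spectral_sampling(axes[[k]])
      lo <- axes[[k]]$origin_ppm + ss
      hi <- axes[[k]]$origin_ppm + axes[[k]]$n * ss
      p <- peaks[[paste0("pos", k)]]
      if (any(p < lo | p > hi))
        stop("synthetic_spec: peak positions outside axis ", k,
             " ppm range [", format(lo), ", ", format(hi), "]", call. = FALSE)
      if (any(peaks[[paste0("fw", k)]] <= 0))
        stop("synthetic_spec: linewidths must be > 0", call. = FALSE)
    }
  }
  structure(list(peaks = peaks, axes = axes,
                 noise_sigma = as.numeric(noise_sigma),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# 1D line-shape profile centred at `pos` with FWHM `fw`, evaluated at ppm x.
line_profile <- function(x, pos, fw, shape) {
  u <- (x - pos) / fw
  switch(shape,
         gaussian = exp(-4 * log(2) * u^2),
         lorentzian = 1 / (1 + 4 * u^2),
         stop("unknown line shape: ", shape))
}

#' Render a synthetic spectrum to a grid
#'
#' Evaluates the sum of analytic line shapes at every grid point's ppm
#' coordinates (line shapes are separable products of 1D Gaussian or
#' Lorentzian profiles per axis) and adds seeded white Gaussian noise with
#' standard deviation `noise_sigma * max(amplitude)`.
#'
#' @param spec A [synthetic_spec()].
#' @param noise_shift_px Optional integer pixel shift per axis applied
#'   circularly to the noise raster (used by [make_offset_pair()]'s
#'   shared-noise mode so the noise travels with the data); default none.
#' @param noise_seed Override for the noise seed (default `spec$seed`).
#' @return A [spectrum_grid()].
#' @export
render_spectrum <- function(spec, noise_shift_px = NULL, noise_seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  coords <- lapply(spec$axes, function(a)
    a$origin_ppm + seq_len(a$n) * spectral_sampling(a))
  d <- vapply(spec$axes, function(a) a$n, integer(1))
  K <- length(d)
  grid <- array(0, d)
  for (i in seq_len(nrow(spec$peaks))) {
    pk <- spec$peaks[i, ]
    profs <- lapply(seq_len(K), function(k)
      line_profile(coords[[k]], pk[[paste0("pos", k)]],
                   pk[[paste0("fw", k)]], pk$shape))
    grid <- grid + pk$amp * Reduce(`%o%`, profs)
  }
  if (spec$noise_sigma > 0) {
    sd_abs <- spec$noise_sigma *
      (if (nrow(spec$peaks)) max(spec$peaks$amp) else 1)
    noise <- with_local_seed(noise_seed, array(stats::rnorm(prod(d), sd = sd_abs), d))
    if (!is.null(noise_shift_px) && any(noise_shift_px != 0)) {
      idx <- lapply(seq_len(K), function(k) {
        s <- as.integer(noise_shift_px[k]) %% d[k]
        ((seq_len(d[k]) - 1L - s) %% d[k]) + 1L
      })
      noise <- do.call(`[`, c(list(noise), idx, list(drop = FALSE)))
    }
    grid <- grid + noise
  }
  spectrum_grid(grid, spec$axes)
}

#' Random synthetic correlation spectrum
#'
#' Convenience generator emulating a modern solid-state 13C-13C-type
#' correlation plane: by default a 256 x 256 grid with 0.05 ppm/pixel
#' sampling (12.8 ppm span, obs 150 MHz), 30 Gaussian peaks with linewidths
#' drawn uniformly from 0.1-0.4 ppm and amplitudes from 0.5-1. The default
#' noise level of 0.05 (rms, relative to the strongest peak) corresponds to
#' a signal-to-noise ratio of 10 under the NMR convention
#' `S/N = peak amplitude / (2 x rms noise)`, with every peak at S/N >= 5.
#' Peak positions are drawn uniformly over the central 80% of each axis,
#' keeping controlled-offset experiments free of edge-truncation effects.
#'
#' @param n_peaks Number of peaks.
#' @param axes List of [axis_header()]; default as above.
#' @param noise_sigma Noise SD relative to the strongest peak
#'   (`= 1 / (2 * SNR)` under the NMR S/N convention).
#' @param seed Integer seed for peak placement and noise.
#' @param fw_range Linewidth range (ppm, FWHM).
#' @param amp_range Amplitude range.
#' @param shape Line shape for all peaks.
#' @param margin_frac Fraction of each axis span kept peak-free at either
#'   edge (default 0.1).
#' @return A [synthetic_spec()].
#' @export
random_synthetic_spec <- function(n_peaks = 30, axes = NULL,
                                  noise_sigma = 0.05, seed = 1L,
                                  fw_range = c(0.1, 0.4),
                                  amp_range = c(0.5, 1),
                                  shape = "gaussian",
                                  margin_frac = 0.1) {
  if (is.null(axes)) {
    ax <- axis_header(n = 256, sw = 1920, obs = 150, origin_ppm = 40)
    axes <- list(ax, ax)
  }
  K <- length(axes)
  peaks <- with_local_seed(seed, {
    cols <- list(amp = stats::runif(n_peaks, amp_range[1], amp_range[2]),
                 shape = rep(shape, n_peaks))
    for (k in seq_len(K)) {
      a <- axes[[k]]
      ss <- spectral_sampling(a)
      span <- a$sw / a$obs
      lo <- a$origin_ppm + ss + margin_frac * span
      hi <- a$origin_ppm + a$n * ss - margin_frac * span
      cols[[paste0("pos", k)]] <- stats::runif(n_peaks, lo, hi)
      cols[[paste0("fw", k)]] <- stats::runif(n_peaks, fw_range[1], fw_range[2])
    }
    as.data.frame(cols, stringsAsFactors = FALSE)
  })
  synthetic_spec(peaks, axes, noise_sigma = noise_sigma, seed = seed)
}

#' Build a spectrum pair with an exact known referencing offset
#'
#' Renders spectrum 1 from `spec`, then builds spectrum 2 from a subset of
#' the same peak list (fraction `overlap_frac`, seeded choice) plus
#' `extra_peaks` new random peaks, with every peak position translated so
#' that spectrum 2 appears `offset_ppm` *lower* in ppm than spectrum 1 —
#' i.e. `offset_ppm` is the referencing correction [align()] should
#' report. The translation is applied to the analytic peak positions
#' before rendering, so the ground truth is exact even for sub-pixel
#' offsets.
#'
#' With `noise_independent = FALSE` (default) the two spectra share the
#' same noise realization, circularly shifted by the nearest-integer pixel
#' offset so the noise travels with the data — emulating a pure
#' re-referencing of one recorded data set (for integer-pixel offsets the
#' rasters are then identical up to translation). With
#' `noise_independent = TRUE` spectrum 2 gets a fresh noise draw, emulating
#' independently recorded spectra.
#'
#' @param spec A [synthetic_spec()] defining spectrum 1.
#' @param offset_ppm Numeric per-axis referencing offset (ppm).
#' @param overlap_frac Fraction of `spec`'s peaks shared by spectrum 2.
#' @param extra_peaks Number of additional peaks unique to spectrum 2.
#' @param noise_independent Logical; see above.
#' @return List with elements `s1`, `s2` ([spectrum_grid()]s) and
#'   `offset_ppm` (the exact ground truth).
#' @export
make_offset_pair <- function(spec, offset_ppm, overlap_frac = 1,
                             extra_peaks = 0, noise_independent = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"),
            overlap_frac >= 0, overlap_frac <= 1, extra_peaks >= 0)
  K <- length(spec$axes)
  stopifnot(length(offset_ppm) == K)
  s1 <- render_spectrum(spec)

  np <- nrow(spec$peaks)
  n_keep <- round(overlap_frac * np)
  keep <- if (n_keep >= np) seq_len(np) else
    with_local_seed(spec$seed + 7L, sort(sample.int(np, n_keep)))
  peaks2 <- spec$peaks[keep, , drop = FALSE]

  if (extra_peaks > 0) {
    extra <- with_local_seed(spec$seed + 13L, {
      cols <- list(amp = stats::runif(extra_peaks,
                                      min(spec$peaks$amp), max(spec$peaks$amp)),
                   shape = rep(spec$peaks$shape[1], extra_peaks))
      for (k in seq_len(K)) {
        a <- spec$axes[[k]]
        ss <- spectral_sampling(a)
        span <- a$sw / a$obs
        lo <- a$origin_ppm + ss + 0.1 * span
        hi <- a$origin_ppm + a$n * ss - 0.1 * span
        cols[[paste0("pos", k)]] <- stats::runif(extra_peaks, lo, hi)
        cols[[paste0("fw", k)]] <- stats::runif(
          extra_peaks, min(spec$peaks[[paste0("fw", k)]]),
          max(spec$peaks[[paste0("fw", k)]]))
      }
      as.data.frame(cols, stringsAsFactors = FALSE)
    })
    peaks2 <- rbind(peaks2, extra)
  }

  # spectrum 2 appears offset_ppm too low: translate analytic positions down
  for (k in seq_len(K))
    peaks2[[paste0("pos", k)]] <- peaks2[[paste0("pos", k)]] - offset_ppm[k]

  spec2 <- spec
  spec2$peaks <- peaks2
  # skip the in-range validation: translated peaks may legitimately sit
  # close to (or run off) the edge; rendering just truncates their tails
  class(spec2) <- "synthetic_spec"

  ss <- vapply(spec$axes, spectral_sampling, numeric(1))
  if (noise_independent) {
    s2 <- render_spectrum(spec2, noise_seed = spec$seed + 1099L)
  } else {
    s2 <- render_spectrum(spec2, noise_shift_px = round(-offset_ppm / ss))
  }
  list(s1 = s1, s2 = s2, offset_ppm = as.numeric(offset_ppm))
}
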