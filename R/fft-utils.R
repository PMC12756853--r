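# Internal FFT helpers shared by the geometry, preprocessing and
# alignment code. All work on plain numeric/complex arrays.

# DFT sample frequencies in cycles/pixel, standard order (DC first,
# positive frequencies, then negative). Nyquist = 0.5 for even n.
fft_freqs <- function(n) {
  k <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2):1))
  k / n
}

# |f|^2 over an N-d grid: sum of squared per-axis normalized frequencies.
freq_sq_array <- function(dims) {
  out <- array(0, dims)
  for (k in seq_along(dims)) {
    fk2 <- fft_freqs(dims[k])^2
    out <- out + fk2[slice.index(out, k)]
  }
  out
}

# Apply a function to a matrix whose rows run along `axis` of array x.
# `f` may change the number of rows.
axis_apply <- function(x, axis, f) {
  d <- dim(x)
  K <- length(d)
  if (K == 1L || axis < 1L || axis > K) stop("axis_apply: bad axis")
  perm <- c(axis, seq_len(K)[-axis])
  y <- aperm(x, perm)
  m <- matrix(y, nrow = d[axis])
  m2 <- f(m)
  d2 <- d[perm]
  d2[1] <- nrow(m2)
  aperm(array(m2, dim = d2), order(perm))
}

# Remap DFT bins of length n_old (rows of m) onto length n_new, with the
# symmetric Nyquist split/merge that keeps Hermitian symmetry (and hence a
# real inverse transform) intact:
#   - cropping to even n_new: the new Nyquist bin takes the sum of the two
#     symmetric source bins at +/- n_new/2;
#   - padding from even n_old: the old Nyquist bin's value is split evenly
#     between frequencies +/- n_old/2.
freq_remap_rows <- function(m, n_new) {
  n_old <- nrow(m)
  if (n_new == n_old) return(m)
  row_of <- function(f, n) (f %% n) + 1L  # 0-based frequency -> 1-based row
  out <- matrix(0 + 0i, n_new, ncol(m))
  if (n_new < n_old) {                    # band-limit (crop)
    if (n_new %% 2L == 0L) {
      h <- n_new %/% 2L
      keep <- (-(h - 1L)):(h - 1L)
      out[row_of(keep, n_new), ] <- m[row_of(keep, n_old), ]
      out[row_of(h, n_new), ] <- m[row_of(h, n_old), ] + m[row_of(-h, n_old), ]
    } else {
      h <- (n_new - 1L) %/% 2L
      keep <- (-h):h
      out[row_of(keep, n_new), ] <- m[row_of(keep, n_old), ]
    }
  } else {                                # zero-pad
    if (n_old %% 2L == 0L) {
      h <- n_old %/% 2L
      keep <- (-(h - 1L)):(h - 1L)
      out[row_of(keep, n_new), ] <- m[row_of(keep, n_old), ]
      nyq <- m[row_of(h, n_old), ] / 2
      out[row_of(h, n_new), ] <- nyq
      out[row_of(-h, n_new), ] <- nyq
    } else {
      h <- (n_old - 1L) %/% 2L
      keep <- (-h):h
      out[row_of(keep, n_new), ] <- m[row_of(keep, n_old), ]
    }
  }
  out
}

# Circularly shift array content by (possibly fractional) `shift` pixels
# toward higher index along each axis, via Fourier phase ramps. Exact for
# integer shifts; band-limited interpolation otherwise. For even lengths
# the self-conjugate Nyquist bin gets the symmetric (real) ramp cos(pi*s),
# the average of the +/-Nyquist phases, keeping the output exactly real.
fourier_shift <- function(x, shift) {
  d <- dim(x)
  stopifnot(length(shift) == length(d))
  X <- stats::fft(x)
  for (k in seq_along(d)) {
    ramp <- exp(-2i * pi * fft_freqs(d[k]) * shift[k])
    if (d[k] %% 2L == 0L)
      ramp[d[k] %/% 2L + 1L] <- cos(pi * shift[k])
    X <- X * ramp[slice.index(X, k)]
  }
  Re(stats::fft(X, inverse = TRUE)) / prod(d)
}

# fftshift: move the zero-frequency / zero-displacement bin to the center
# index floor(n/2)+1 along every axis.
fft_shift_array <- function(x) {
  d <- dim(x)
  idx <- lapply(d, function(n) {
    h <- floor(n / 2)
    c((n - h + 1):n, 1:(n - h))
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# Center index of the fftshifted array along an axis of length n.
fft_center_index <- function(n) as.integer(floor(n / 2)) + 1L
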