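# Shared fixtures and independent brute-force oracles.

# quick grid builders with simple headers (ss = sw/obs/n)
mk_axis <- function(n, ss = 0.05, obs = 150, origin = 40)
  axis_header(n = n, sw = ss * obs * n, obs = obs, origin_ppm = origin)

mk_grid <- function(data, ss = 0.05, origin = 40) {
  d <- dim(data)
  spectrum_grid(data, lapply(d, mk_axis, ss = ss, origin = origin))
}

rand_grid <- function(dims, seed = 1, ss = 0.05) {
  set.seed(seed)
  mk_grid(array(rnorm(prod(dims)), dims), ss = ss)
}

# integer circular shift: content moves by +s along each axis
circshift_int <- function(x, s) {
  d <- dim(x)
  idx <- lapply(seq_along(d), function(k) {
    sk <- ((s[k] %% d[k]) + d[k]) %% d[k]
    ((seq_len(d[k]) - 1L - sk) %% d[k]) + 1L
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# brute-force circular cross-correlation: c(d) = sum_x i1(x) * i2(x - d),
# evaluated by explicitly shifting i2 for every displacement
brute_force_ccf <- function(a1, a2) {
  d <- dim(a1)
  out <- array(NA_real_, d)
  centers <- vapply(d, function(n) as.integer(floor(n / 2)) + 1L, integer(1))
  disp <- lapply(seq_along(d), function(k) seq_len(d[k]) - centers[k])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    dd <- c(disp[[1]][i], disp[[2]][j])
    out[i, j] <- sum(a1 * circshift_int(a2, dd))
  }
  list(map = out, zero = centers)
}

# brute-force 3D -> 2D projection by explicit triple loop
brute_force_project <- function(vol, axis, mode) {
  d <- dim(vol)
  keep <- setdiff(1:3, axis)
  out <- array(if (mode == "max") -Inf else 0, d[keep])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    ij <- c(i, j, k)[keep]
    v <- vol[i, j, k]
    out[ij[1], ij[2]] <- if (mode == "max") max(out[ij[1], ij[2]], v)
                         else out[ij[1], ij[2]] + v
  }
  out
}

# round a double vector to float32 representability
float32_round <- function(x)
  readBin(writeBin(as.numeric(x), raw(), size = 4L), "numeric",
          n = length(x), size = 4L)
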