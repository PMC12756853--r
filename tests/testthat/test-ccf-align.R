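test_that("FFT cross-correlation matches the brute-force circular oracle", {
  for (seed in 1:3) {
    a1 <- preprocess_spectrum(rand_grid(c(16, 16), seed = seed))
    a2 <- preprocess_spectrum(rand_grid(c(16, 16), seed = seed + 50))
    ccf <- cross_correlation(a1, a2)
    oracle <- brute_force_ccf(a1$data, a2$data)
    expect_equal(ccf$zero, oracle$zero)
    expect_equal(ccf$map, oracle$map, tolerance = 1e-9)
  }
})

test_that("autocorrelation of a standardized grid peaks at zero with value N", {
  g <- zero_float_normalize(rand_grid(c(16, 16), seed = 7))
  ccf <- cross_correlation(g, g)
  expect_equal(which(ccf$map == max(ccf$map), arr.ind = TRUE)[1, ],
               ccf$zero, ignore_attr = TRUE)
  expect_equal(max(ccf$map), prod(dim(g$data)))  # normalized score 1
})

test_that("a circularly shifted copy is located at its shift", {
  g <- zero_float_normalize(rand_grid(c(24, 20), seed = 8))
  # content of g2 sits 3 px lower / 2 px higher than g along axes 1/2,
  # so g must be displaced by (+3, -2) to overlap it: c(d) = sum g(x) g2(x-d)
  g2 <- spectrum_grid(circshift_int(g$data, c(-3, 2)), g$axes)
  ccf <- cross_correlation(g, g2)
  pk <- find_peak(ccf)
  expect_identical(as.integer(pk), c(3L, -2L))
})

test_that("peak search respects the window and breaks ties deterministically", {
  n <- c(32L, 32L)
  zero <- c(17L, 17L)
  mk_map <- function(vals) {
    m <- array(0, n)
    for (v in vals) m[zero[1] + v[[1]], zero[2] + v[[2]]] <- v[[3]]
    structure(list(map = m, zero = zero, n = n), class = "ccf_map")
  }
  # unique maximum inside the window
  pk <- find_peak(mk_map(list(c(4, -5, 10))))
  expect_identical(as.integer(pk), c(4L, -5L))
  # two equal maxima: smallest Euclidean displacement wins
  pk2 <- find_peak(mk_map(list(c(2, 0, 10), c(5, 0, 10))))
  expect_identical(as.integer(pk2), c(2L, 0L))
  # exact mirror tie: lexicographic order breaks it
  pk3 <- find_peak(mk_map(list(c(-3, 0, 10), c(3, 0, 10))))
  expect_identical(as.integer(pk3), c(-3L, 0L))
  # global max outside the window is ignored, with a warning recorded
  pk4 <- find_peak(mk_map(list(c(2, 1, 5), c(12, 0, 50))),
                   alignment_config(max_shift_frac = 0.1))
  expect_identical(as.integer(pk4), c(2L, 1L))
  expect_match(attr(pk4, "warnings"), "outside")
})

test_that("parabola refinement recovers exact vertices and symmetric peaks", {
  n <- c(16L, 16L)
  zero <- c(9L, 9L)
  para_map <- function(delta1, delta2) {
    m <- array(0, n)
    for (i in -1:1) for (j in -1:1)
      m[zero[1] + 2 + i, zero[2] - 1 + j] <-
        10 - (i - delta1)^2 - (j - delta2)^2
    structure(list(map = m, zero = zero, n = n), class = "ccf_map")
  }
  # symmetric neighbors -> delta 0
  r0 <- subpixel_refine(para_map(0, 0), c(2L, -1L))
  expect_equal(as.numeric(r0), c(2, -1), tolerance = 1e-12)
  # exact parabola with vertex at +0.3 is reproduced to machine precision
  r <- subpixel_refine(para_map(0.3, -0.2), c(2L, -1L))
  expect_equal(as.numeric(r), c(2.3, -1.2), tolerance = 1e-12)
  # zero curvature -> delta 0 with warning
  flat <- structure(list(map = array(1, n), zero = zero, n = n),
                    class = "ccf_map")
  rf <- subpixel_refine(flat, c(0L, 0L))
  expect_equal(as.numeric(rf), c(0, 0))
  expect_match(attr(rf, "warnings"), "curvature", all = FALSE)
})

test_that("a known 0.37-pixel sub-pixel offset is recovered to 0.05 px", {
  spec <- random_synthetic_spec(n_peaks = 20, noise_sigma = 0, seed = 55)
  ss <- spectral_sampling(spec$axes[[1]])
  pair <- make_offset_pair(spec, c(0.37, 0.37) * ss)  # exact analytic offset
  f1 <- preprocess_spectrum(pair$s1); f2 <- preprocess_spectrum(pair$s2)
  ccf <- cross_correlation(f1, f2)
  refined <- subpixel_refine(ccf, find_peak(ccf))
  expect_equal(as.numeric(refined), c(0.37, 0.37), tolerance = 0.05 / 0.37)
  expect_lte(max(abs(as.numeric(refined) - 0.37)), 0.05)
})

test_that("pixel-to-ppm conversion combines sampling and origin offset", {
  expect_equal(pixels_to_ppm(c(0, 0), c(0.01, 0.01)), c(0, 0))
  expect_equal(pixels_to_ppm(10, 0.01), 0.1)
  expect_equal(pixels_to_ppm(c(3, -2), c(0.05, 0.02), c(0.1, -0.3)),
               c(0.25, -0.34))
  expect_error(pixels_to_ppm(c(1, 2), c(0.1, 0.1, 0.1)), "axis count")
})

test_that("a pure header (origin) offset is reported with zero pixel shift", {
  g <- rand_grid(c(32, 32), seed = 66, ss = 0.05)
  g2 <- spectrum_grid(g$data, lapply(g$axes, function(a)
    axis_header(a$n, a$sw, a$obs, a$origin_ppm - 0.5)))
  est <- align(g, g2)
  expect_equal(est$shift_px, c(0, 0))
  expect_equal(est$shift_ppm, c(0.5, 0.5))   # oracle: header arithmetic
  expect_equal(est$score_after, 1, tolerance = 1e-9)
})

test_that("correlation score hits its bounds on self, shifted and negated input", {
  g <- preprocess_spectrum(rand_grid(c(20, 20), seed = 77))
  expect_equal(correlation_score(g, g, c(0, 0)), 1, tolerance = 1e-12)
  g2 <- spectrum_grid(circshift_int(g$data, c(-4, 1)), g$axes)
  expect_equal(correlation_score(g, g2, c(4, -1)), 1, tolerance = 1e-6)
  neg <- spectrum_grid(-g$data, g$axes)
  expect_equal(correlation_score(g, neg, c(0, 0)), -1, tolerance = 1e-12)
  expect_error(correlation_score(g, preprocess_spectrum(rand_grid(c(10, 10)))),
               "shape")
})

test_that("aligning a spectrum with itself gives zero shift and score 1", {
  s <- render_spectrum(random_synthetic_spec(seed = 3))
  est <- align(s, s)
  expect_equal(est$shift_ppm, c(0, 0))
  expect_equal(est$score_before, 1, tolerance = 1e-9)
  expect_equal(est$score_after, 1, tolerance = 1e-9)
})

test_that("a 0.1 ppm induced offset is recovered within 0.01 ppm at score ~1", {
  spec <- random_synthetic_spec(seed = 42)
  pair <- make_offset_pair(spec, c(0.1, 0.1))
  est <- align(pair$s1, pair$s2)
  expect_equal(est$shift_ppm, c(0.1, 0.1), tolerance = 0.01 / 0.1)
  expect_lte(max(abs(est$shift_ppm - 0.1)), 0.01)
  expect_gte(est$score_after, 0.999)
})

test_that("mixed peak sets with independent noise still align to 0.02 ppm", {
  spec <- random_synthetic_spec(seed = 19)
  pair <- make_offset_pair(spec, c(0.58, 0.61), overlap_frac = 0.6,
                           extra_peaks = 12, noise_independent = TRUE)
  est <- align(pair$s1, pair$s2)
  expect_lte(max(abs(est$shift_ppm - c(0.58, 0.61))), 0.02)
  expect_gt(est$score_after, est$score_before)
  expect_lt(est$score_after, 1)
})

test_that("alignment is invariant to affine intensity changes of either input", {
  spec <- random_synthetic_spec(seed = 23)
  pair <- make_offset_pair(spec, c(-0.31, 0.44), noise_independent = TRUE)
  est <- align(pair$s1, pair$s2)
  s2a <- spectrum_grid(5.5 * pair$s2$data + 3, pair$s2$axes)
  esta <- align(pair$s1, s2a)
  expect_equal(esta$shift_ppm, est$shift_ppm, tolerance = 1e-9)
  expect_equal(esta$score_after, est$score_after, tolerance = 1e-9)
})

test_that("alignment is antisymmetric under argument swap", {
  for (seed in c(5, 29)) {
    spec <- random_synthetic_spec(seed = seed)
    pair <- make_offset_pair(spec, c(0.27, -0.53), noise_independent = TRUE)
    fwd <- align(pair$s1, pair$s2)
    bwd <- align(pair$s2, pair$s1)
    ss <- fwd$ss_ppm_per_px
    expect_lte(max(abs(fwd$shift_ppm + bwd$shift_ppm) / ss), 1)  # 1 px
  }
})

test_that("apply_shift inverts and closes the align/apply/realign loop", {
  spec <- random_synthetic_spec(seed = 31)
  s <- render_spectrum(spec)
  expect_equal(apply_shift(s, c(0, 0))$data, s$data)

  # shift-then-unshift is the identity for band-limited content
  s_bl <- render_spectrum(random_synthetic_spec(seed = 31, noise_sigma = 0,
                                                fw_range = c(0.3, 0.4)))
  back_bl <- apply_shift(apply_shift(s_bl, c(0.123, -0.077)),
                         -c(0.123, -0.077))
  expect_lte(max(abs(back_bl$data - s_bl$data)), 1e-6 * max(abs(s_bl$data)))
  back <- apply_shift(apply_shift(s, c(0.123, -0.077)), -c(0.123, -0.077))
  expect_equal(vapply(back$axes, function(a) a$origin_ppm, numeric(1)),
               vapply(s$axes, function(a) a$origin_ppm, numeric(1)))

  pair <- make_offset_pair(spec, c(0.58, -0.33), noise_independent = TRUE)
  est <- align(pair$s1, pair$s2)
  realigned <- align(pair$s1, apply_shift(pair$s2, est$shift_ppm))
  expect_lte(max(abs(realigned$shift_ppm)), 0.01)
  expect_error(apply_shift(s, c(100, 0)), "span")
})

test_that("alignment works across differing sampling, size and origin", {
  ax1 <- axis_header(256, 1920, 150, 40)
  ax2a <- axis_header(300, 2000, 150, 39.5)
  ax2b <- axis_header(200, 1800, 150, 40.5)
  spec1 <- random_synthetic_spec(seed = 7, axes = list(ax1, ax1))
  peaks2 <- spec1$peaks
  peaks2$pos1 <- peaks2$pos1 - 0.23
  peaks2$pos2 <- peaks2$pos2 + 0.17
  spec2 <- synthetic_spec(peaks2, list(ax2a, ax2b), noise_sigma = 0.05, seed = 8)
  est <- align(render_spectrum(spec1), render_spectrum(spec2))
  expect_lte(max(abs(est$shift_ppm - c(0.23, -0.17))), 0.02)
  expect_gt(est$score_after, est$score_before)
})

test_that("score never worsens across the fixture battery", {
  cases <- list(
    make_offset_pair(random_synthetic_spec(seed = 1), c(0.1, 0.1)),
    make_offset_pair(random_synthetic_spec(seed = 2), c(-0.4, 0.85),
                     noise_independent = TRUE),
    make_offset_pair(random_synthetic_spec(seed = 4), c(0.58, 0.61),
                     overlap_frac = 0.6, extra_peaks = 12,
                     noise_independent = TRUE))
  for (pair in cases) {
    est <- align(pair$s1, pair$s2)
    expect_gte(est$score_after, est$score_before)
    expect_true(all(abs(est$shift_px) <=
                      0.25 * vapply(pair$s1$axes, function(a) a$n, integer(1))))
  }
})
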