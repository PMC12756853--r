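# Single-file NMRPipe I/O (512-float32-word FDATA header + float32 raster)
# and a plain text+header dialect used for download-free fixtures.
#
# Internal conventions: the last axis is the direct dimension and every
# axis index increases toward higher ppm. NMRPipe rasters store descending
# ppm (first point = highest ppm), so both reader and writer flip each
# axis; the text dialect stores the internal ascending-ppm orientation.

# 1-based positions of the FDATA header words we use (index = FDATA + 1)
.FD <- list(
  MAGIC = 1L, FLTFORMAT = 2L, FLTORDER = 3L, DIMCOUNT = 10L,
  PIPEFLAG = 58L, QUADFLAG = 107L, TRANSPOSED = 222L, FILECOUNT = 443L,
  SIZE = 100L, SPECNUM = 220L,
  F2 = list(SW = 101L, ORIG = 102L, OBS = 120L, FTFLAG = 221L, QUAD = 57L),
  F1 = list(SW = 230L, ORIG = 250L, OBS = 219L, FTFLAG = 223L, QUAD = 56L),
  F3 = list(SW = 12L, ORIG = 13L, OBS = 11L, FTFLAG = 14L, QUAD = 52L,
            SIZE = 16L)
)

# reverse every axis of an array (ascending <-> descending ppm)
flip_all_axes <- function(x) {
  idx <- lapply(dim(x), function(n) n:1)
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# reorder array so traversal order becomes "last axis fastest"
to_file_order <- function(x) as.vector(aperm(x, rev(seq_along(dim(x)))))
from_file_order <- function(v, d) aperm(array(v, rev(d)), rev(seq_along(d)))

#' Write a spectrum as a single-file NMRPipe spectrum
#'
#' Writes the 512-word float32 FDATA header followed by the float32
#' intensity raster (direct dimension fastest, descending ppm along each
#' axis, little-endian). Supports 2D and 3D real frequency-domain grids;
#' per-axis `sw` (Hz), `obs` (MHz) and the origin (stored natively in Hz as
#' `origin_ppm * obs`) round-trip at float32 precision.
#'
#' @param grid A 2D or 3D [spectrum_grid()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @seealso [read_nmrpipe()]
#' @export
write_nmrpipe <- function(grid, path) {
  stopifnot(inherits(grid, "spectrum_grid"))
  K <- length(grid$axes)
  if (!K %in% 2:3)
    stop("write_nmrpipe: only 2D and 3D spectra are supported", call. = FALSE)
  if (!all(is.finite(grid$data)))
    stop("write_nmrpipe: grid contains non-finite values", call. = FALSE)

  h <- numeric(512)
  h[.FD$MAGIC] <- 0
  h[.FD$FLTORDER] <- 2.345
  h[.FD$DIMCOUNT] <- K
  h[.FD$QUADFLAG] <- 1        # real data
  h[.FD$TRANSPOSED] <- 0
  h[.FD$FILECOUNT] <- 1
  h[.FD$PIPEFLAG] <- if (K == 3L) 1 else 0

  put_axis <- function(h, fd, ax) {
    h[fd$SW] <- ax$sw
    h[fd$OBS] <- ax$obs
    h[fd$ORIG] <- ax$origin_ppm * ax$obs   # native origin in Hz
    h[fd$FTFLAG] <- 1                      # frequency domain
    h[fd$QUAD] <- 1                        # real
    h
  }
  # internal axis order: (F3,) F1, F2 with F2 = direct = last
  h <- put_axis(h, .FD$F2, grid$axes[[K]])
  h <- put_axis(h, .FD$F1, grid$axes[[K - 1L]])
  if (K == 3L) {
    h <- put_axis(h, .FD$F3, grid$axes[[1L]])
    h[.FD$F3$SIZE] <- grid$axes[[1L]]$n
  }
  h[.FD$SIZE] <- grid$axes[[K]]$n
  h[.FD$SPECNUM] <- grid$axes[[K - 1L]]$n

  hdr <- writeBin(h, raw(), size = 4L, endian = "little")
  hdr[5:8] <- as.raw(rep(0xee, 4))         # FDFLTFORMAT sentinel

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(to_file_order(flip_all_axes(grid$data)), con,
           size = 4L, endian = "little")
  invisible(path)
}

#' Read a single-file NMRPipe spectrum
#'
#' Reads a 2D or 3D single-file NMRPipe frequency-domain spectrum. Axis
#' metadata is normalized into [axis_header()]s: `sw` in Hz, `obs` in MHz,
#' and the origin converted from the native Hz value to ppm
#' (`origin_ppm = orig_hz / obs_mhz`). Axes are ordered with the direct
#' dimension last and rasters flipped so the index increases toward higher
#' ppm. Both byte orders are detected via the FDFLTORDER sentinel.
#' Time-domain (FTFLAG = 0) and complex (QUADFLAG != 1) data are rejected
#' with an unsupported-format error.
#'
#' @param path Path to the `.ft2` / `.ft3` file.
#' @return A [spectrum_grid()].
#' @export
read_nmrpipe <- function(path) {
  if (!file.exists(path))
    stop("read_nmrpipe: file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 512L * 4L)
  if (length(hdr_raw) < 512L * 4L)
    stop("read_nmrpipe: file too short for an NMRPipe header", call. = FALSE)
  parse_hdr <- function(endian)
    readBin(hdr_raw, "numeric", n = 512L, size = 4L, endian = endian)
  h <- parse_hdr("little")
  endian <- "little"
  if (abs(h[.FD$FLTORDER] - 2.345) > 1e-4) {
    h <- parse_hdr("big")
    endian <- "big"
    if (abs(h[.FD$FLTORDER] - 2.345) > 1e-4)
      stop("read_nmrpipe: header magic mismatch (not an NMRPipe file?)",
           call. = FALSE)
  }
  if (h[.FD$MAGIC] != 0)
    stop("read_nmrpipe: header magic mismatch", call. = FALSE)
  K <- as.integer(round(h[.FD$DIMCOUNT]))
  if (!K %in% 2:3)
    stop("read_nmrpipe: unsupported dimension count: ", K, call. = FALSE)
  get_axis <- function(fd, n) {
    if (h[fd$FTFLAG] == 0)
      stop("read_nmrpipe: time-domain (unprocessed) data are not supported",
           call. = FALSE)
    if (h[fd$QUAD] != 1 || h[.FD$QUADFLAG] != 1)
      stop("read_nmrpipe: complex data layout is not supported", call. = FALSE)
    obs <- h[fd$OBS]
    axis_header(n = n, sw = h[fd$SW], obs = obs,
                origin_ppm = h[fd$ORIG] / obs)
  }
  n_direct <- as.integer(round(h[.FD$SIZE]))
  n_ind1 <- as.integer(round(h[.FD$SPECNUM]))
  axes <- list()
  d <- integer(0)
  if (K == 3L) {
    n3 <- as.integer(round(h[.FD$F3$SIZE]))
    axes <- c(axes, list(get_axis(.FD$F3, n3)))
    d <- c(d, n3)
  }
  axes <- c(axes, list(get_axis(.FD$F1, n_ind1), get_axis(.FD$F2, n_direct)))
  d <- c(d, n_ind1, n_direct)

  vals <- readBin(con, "numeric", n = prod(d), size = 4L, endian = endian)
  if (length(vals) != prod(d))
    stop("read_nmrpipe: raster truncated (expected ", prod(d), " values, got ",
         length(vals), ")", call. = FALSE)
  data <- flip_all_axes(from_file_order(vals, d))
  spectrum_grid(data, axes)
}

#' Write a spectrum in the text dialect
#'
#' The text dialect is a fully specified plain-text spectrum format: a
#' UTF-8 `key=value` header file with keys `ndim` and, per axis `i`,
#' `n_i`, `sw_hz_i`, `obs_mhz_i`, `origin_ppm_i`; and a data file of
#' whitespace-separated decimal intensities in row-major order with the
#' direct (last) dimension varying fastest, in the internal ascending-ppm
#' orientation. Values are written with full double precision.
#'
#' @param grid A [spectrum_grid()].
#' @param header_path,data_path Output paths.
#' @return Invisibly, `c(header_path, data_path)`.
#' @export
write_text_dialect <- function(grid, header_path, data_path) {
  stopifnot(inherits(grid, "spectrum_grid"))
  if (!all(is.finite(grid$data)))
    stop("write_text_dialect: grid contains non-finite values", call. = FALSE)
  K <- length(grid$axes)
  lines <- c(sprintf("ndim=%d", K),
             unlist(lapply(seq_len(K), function(k) {
               a <- grid$axes[[k]]
               c(sprintf("n_%d=%d", k, a$n),
                 sprintf("sw_hz_%d=%.17g", k, a$sw),
                 sprintf("obs_mhz_%d=%.17g", k, a$obs),
                 sprintf("origin_ppm_%d=%.17g", k, a$origin_ppm))
             })))
  writeLines(lines, header_path)
  vals <- to_file_order(grid$data)
  writeLines(paste(sprintf("%.17g", vals), collapse = " "), data_path)
  invisible(c(header_path, data_path))
}

#' Read a spectrum in the text dialect
#'
#' @param header_path,data_path Paths written by [write_text_dialect()] (or
#'   assembled by hand; see that function for the format).
#' @return A [spectrum_grid()].
#' @export
read_text_dialect <- function(header_path, data_path) {
  for (p in c(header_path, data_path))
    if (!file.exists(p)) stop("read_text_dialect: file not found: ", p,
                              call. = FALSE)
  lines <- readLines(header_path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L))
    stop("read_text_dialect: malformed header line(s)", call. = FALSE)
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- trimws(vapply(kv, `[`, character(1), 2L))
  if (anyDuplicated(keys))
    stop("read_text_dialect: duplicate header key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "), call. = FALSE)
  getv <- function(key) {
    i <- match(key, keys)
    if (is.na(i)) stop("read_text_dialect: missing header key '", key, "'",
                       call. = FALSE)
    v <- suppressWarnings(as.numeric(vals[i]))
    if (!is.finite(v)) stop("read_text_dialect: non-finite value for '", key,
                            "'", call. = FALSE)
    v
  }
  K <- as.integer(getv("ndim"))
  if (!K %in% 2:3)
    stop("read_text_dialect: ndim must be 2 or 3", call. = FALSE)
  axes <- lapply(seq_len(K), function(k)
    axis_header(n = getv(sprintf("n_%d", k)),
                sw = getv(sprintf("sw_hz_%d", k)),
                obs = getv(sprintf("obs_mhz_%d", k)),
                origin_ppm = getv(sprintf("origin_ppm_%d", k))))
  d <- vapply(axes, function(a) a$n, integer(1))
  vv <- scan(data_path, what = double(), quiet = TRUE)
  if (length(vv) != prod(d))
    stop("read_text_dialect: data count mismatch: header implies ", prod(d),
         " values, data file has ", length(vv), call. = FALSE)
  if (!all(is.finite(vv)))
    stop("read_text_dialect: non-finite intensity value(s)", call. = FALSE)
  spectrum_grid(from_file_order(vv, d), axes)
}

#' Read a spectrum, inferring the format from the file
#'
#' Dispatches to [read_nmrpipe()] for binary NMRPipe files and to
#' [read_text_dialect()] for the text dialect (a `path` ending in `.hdr`
#' with a sibling `.dat`, or vice versa).
#'
#' @param path Spectrum path (`.ft2`/`.ft3` binary, or `.hdr`/`.dat` text
#'   pair member).
#' @return A [spectrum_grid()].
#' @export
read_spectrum <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("hdr", "dat")) {
    base <- tools::file_path_sans_ext(path)
    read_text_dialect(paste0(base, ".hdr"), paste0(base, ".dat"))
  } else {
    read_nmrpipe(path)
  }
}

#' Write a spectrum, inferring the format from the file extension
#'
#' @param grid A [spectrum_grid()].
#' @param path Output path; `.hdr` (or `.dat`) selects the text dialect
#'   (both pair members are written), anything else NMRPipe binary.
#' @return Invisibly, the path(s) written.
#' @export
write_spectrum <- function(grid, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("hdr", "dat")) {
    base <- tools::file_path_sans_ext(path)
    write_text_dialect(grid, paste0(base, ".hdr"), paste0(base, ".dat"))
  } else {
    write_nmrpipe(grid, path)
  }
}
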