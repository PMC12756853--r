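#' Project a 3D spectrum onto a 2D plane
#'
#' Collapses one dimension of a 3D spectrum by taking, at every position of
#' the two surviving dimensions, the maximum (default) or sum of the
#' intensities along the collapsed axis. Maximum-value projection preserves
#' peak visibility (SNR) better than summation and is the default; sum
#' projection adds coherently and can be preferable when peaks are dense.
#' The two surviving axis headers are carried over unchanged, so the result
#' can be treated exactly like a native 2D spectrum.
#'
#' @param volume A 3D [spectrum_grid()].
#' @param axis Which dimension (1, 2 or 3) to collapse.
#' @param mode `"max"` (default) or `"sum"`.
#' @return A 2D [spectrum_grid()].
#' @export
#' @examples
#' v <- spectrum_grid(array(1, c(2, 2, 2)),
#'                    list(axis_header(2, 200, 100), axis_header(2, 200, 100),
#'                         axis_header(2, 200, 100)))
#' project(v, axis = 3, mode = "sum")$data  # 2x2 grid of 2
project <- function(volume, axis = 3, mode = c("max", "sum")) {
  stopifnot(inherits(volume, "spectrum_grid"))
  mode <- match.arg(mode)
  d <- dim(volume$data)
  if (length(d) != 3L)
    stop("project: input must be a 3D spectrum", call. = FALSE)
  if (length(axis) != 1L || !(axis %in% 1:3))
    stop("project: 'axis' must be 1, 2 or 3", call. = FALSE)
  keep <- setdiff(1:3, axis)
  fun <- if (mode == "max") max else sum
  plane <- apply(volume$data, keep, fun)
  spectrum_grid(plane, volume$axes[keep])
}

#' Align a 3D spectrum to a 2D plane via projection
#'
#' Projects the 3D volume through the chosen axis ([project()]) and runs
#' the pairwise 2D alignment ([align()]) of the projection against the
#' reference plane. The returned shifts apply to the two surviving
#' (projected) dimensions; the collapsed dimension's referencing is not
#' touched.
#'
#' @param volume 3D [spectrum_grid()] (moving spectrum).
#' @param plane 2D reference [spectrum_grid()] sharing the two surviving
#'   dimensions (same nuclei/ppm ranges up to resampling).
#' @param axis Dimension of `volume` to collapse.
#' @param mode Projection mode, `"max"` or `"sum"`.
#' @param cfg An [alignment_config()].
#' @return A `shift_estimate` (see [align()]).
#' @export
align_3d_to_2d <- function(volume, plane, axis = 3, mode = c("max", "sum"),
                           cfg = alignment_config()) {
  stopifnot(inherits(plane, "spectrum_grid"))
  if (length(dim(plane$data)) != 2L)
    stop("align_3d_to_2d: 'plane' must be a 2D spectrum", call. = FALSE)
  align(plane, project(volume, axis = axis, mode = mode), cfg = cfg)
}
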