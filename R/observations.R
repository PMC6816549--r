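#' Construct an observation set
#'
#' An observation set holds the detected spot localisations that the tracker
#' consumes: one record per detection with a 0-based frame index `t` and a
#' continuous pixel position `(x, y)`. The field of view is the half-open box
#' `[0, W) x [0, H)` with origin at `(0, 0)`. Birth and clutter rates are
#' expressed per frame and per normalised area `A` (100 px x 100 px), so the
#' area unit is carried along with the data.
#'
#' @param t integer vector of 0-based frame indices.
#' @param x,y numeric vectors of positions in pixels.
#' @param n_frames number of frames `T`; defaults to `max(t) + 1`.
#' @param fov numeric length-2 `(width, height)` in pixels; defaults to the
#'   data extent rounded up to whole pixels.
#' @param area_unit normalisation area for the event rates, in px^2.
#'   Default 1e4 (100 px x 100 px).
#' @return An object of class `spt_observations`: a data frame with columns
#'   `id`, `t`, `x`, `y` and attributes `n_frames`, `fov`, `area_unit`.
#'   Ids are assigned by row order, starting at 1.
#' @export
observation_set <- function(t, x, y, n_frames = NULL, fov = NULL,
                            area_unit = 1e4) {
  t <- as.integer(t)
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(t)
  stopifnot(length(x) == n, length(y) == n)
  if (n > 0L && any(t < 0L)) stop("frame indices must be >= 0")
  if (is.null(n_frames)) n_frames <- if (n == 0L) 0L else max(t) + 1L
  n_frames <- as.integer(n_frames)
  if (n > 0L && any(t >= n_frames)) stop("frame index beyond n_frames - 1")
  if (is.null(fov)) {
    fov <- if (n == 0L) c(1, 1) else c(ceiling(max(x) + 1e-9),
                                       ceiling(max(y) + 1e-9))
  }
  fov <- as.numeric(fov)
  stopifnot(length(fov) == 2L, all(fov > 0))
  if (n > 0L && (any(x < 0 | x >= fov[1]) || any(y < 0 | y >= fov[2])))
    stop("positions must lie inside the field of view [0,W) x [0,H)")
  out <- data.frame(id = seq_len(n), t = t, x = x, y = y)
  attr(out, "n_frames") <- n_frames
  attr(out, "fov") <- fov
  attr(out, "area_unit") <- as.numeric(area_unit)
  class(out) <- c("spt_observations", "data.frame")
  out
}

#' @export
print.spt_observations <- function(x, ...) {
  cat(sprintf("<spt_observations> N = %d, T = %d, fov = %g x %g px\n",
              nrow(x), n_frames(x), fov(x)[1], fov(x)[2]))
  invisible(x)
}

#' Number of frames of an observation set
#' @param obs an `spt_observations` object.
#' @export
n_frames <- function(obs) attr(obs, "n_frames")

#' Field of view (width, height) in pixels
#' @param obs an `spt_observations` object.
#' @export
fov <- function(obs) attr(obs, "fov")

#' Rate normalisation area in px^2
#' @param obs an `spt_observations` object.
#' @export
area_unit <- function(obs) attr(obs, "area_unit")

#' Ratio of the field-of-view area to the normalisation area
#'
#' Event rates (births, clutter) are specified per frame and normalised area;
#' their per-frame Poisson means are the rate times this ratio.
#' @param obs an `spt_observations` object.
#' @export
area_ratio <- function(obs) prod(fov(obs)) / area_unit(obs)
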