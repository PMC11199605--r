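#' Preprocess an image for orientation analysis
#'
#' Grayscale conversion (averaging the spectral channels), Gaussian
#' smoothing, and background removal by the rolling-ball method: the
#' grayscale opening of the image by a ball-shaped structuring element
#' (the smooth background a ball of the given radius can roll under) is
#' subtracted, which flattens illumination and topography trends much wider
#' than the stripes while preserving stripe contrast.
#'
#' @param img a [veg_field()], a numeric matrix, or a 3-dimensional array
#'   (x, y, channel or row/col/channel as returned by PNG readers after
#'   conversion).
#' @param blur_sigma Gaussian smoothing width in pixels.
#' @param ball_radius rolling-ball radius in pixels; should comfortably
#'   exceed the stripe wavelength.
#' @param ball_height ball height in intensity units; small values give an
#'   almost flat structuring element, appropriate for unit-range images.
#' @return a [veg_field()] intensity raster with nonnegative values.
#' @export
preprocess_image <- function(img, blur_sigma = 1, ball_radius = 20,
                             ball_height = 0.1) {
  v <- if (is_veg_field(img)) img$values else img
  if (is.array(v) && length(dim(v)) == 3) {
    if (dim(v)[3] %in% c(3, 4)) v <- (v[, , 1] + v[, , 2] + v[, , 3]) / 3
    else stop("3-dimensional input must have 3 (RGB) or 4 (RGBA) channels")
  }
  if (!is.matrix(v)) stop("input must be a 2-dimensional image or RGB array")
  if (nrow(v) < 64 || ncol(v) < 64)
    stop("image must be at least 64 x 64 pixels")
  if (blur_sigma > 0) v <- sep_gauss_cpp(v, blur_sigma)
  bg <- ball_opening_cpp(v, as.integer(ball_radius), ball_height)
  out <- pmax(v - bg, 0)
  dx <- if (is_veg_field(img)) img$dx else 1
  dy <- if (is_veg_field(img)) img$dy else 1
  veg_field(out, dx = dx, dy = dy, bc_x = "none", bc_y = "none")
}

#' Structure-tensor orientation field
#'
#' Image gradients (central differences) are combined into the structure
#' tensor, whose components are averaged with a Gaussian window of width
#' `sigma_w`.  The band orientation at each pixel is the direction along the
#' stripes — perpendicular to the dominant gradient direction:
#' \deqn{\gamma = \tfrac12 \mathrm{atan2}(2\langle I_xI_y\rangle,
#'   \langle I_x^2\rangle - \langle I_y^2\rangle) + 90^\circ \ (\mathrm{mod}\ 180),}
#' and the coherence is the normalized eigenvalue contrast
#' \eqn{(\lambda_1-\lambda_2)/(\lambda_1+\lambda_2) \in [0, 1]}: 1 for
#' perfect stripes, 0 for isotropic texture or flat regions (where the angle
#' is undefined and reported as `NA`).
#'
#' @param img a [veg_field()] or matrix, typically from
#'   [preprocess_image()].
#' @param sigma_w tensor averaging window (pixels).
#' @return a `veg_orientation` object: list with matrices `angle` (degrees
#'   CCW from east in `[0, 180)`, `NA` where undefined), `coherence`, and
#'   `sigma_w`.
#' @export
orientation_field <- function(img, sigma_w = 4) {
  v <- if (is_veg_field(img)) img$values else as.matrix(img)
  nx <- nrow(v); ny <- ncol(v)
  ix <- matrix(0, nx, ny); iy <- matrix(0, nx, ny)
  ix[2:(nx - 1), ] <- (v[3:nx, ] - v[1:(nx - 2), ]) / 2
  iy[, 2:(ny - 1)] <- (v[, 3:ny] - v[, 1:(ny - 2)]) / 2
  jxx <- sep_gauss_cpp(ix * ix, sigma_w)
  jxy <- sep_gauss_cpp(ix * iy, sigma_w)
  jyy <- sep_gauss_cpp(iy * iy, sigma_w)
  tr <- jxx + jyy
  disc <- sqrt(pmax((jxx - jyy)^2 + 4 * jxy^2, 0))
  eps <- 1e-12 * max(tr, 1e-300)
  coh <- ifelse(tr > eps, disc / tr, 0)
  ang <- fold180(rad2deg(0.5 * atan2(2 * jxy, jxx - jyy)) + 90)
  ang[tr <= eps] <- NA_real_
  structure(list(angle = ang, coherence = coh, sigma_w = sigma_w),
            class = "veg_orientation")
}

#' @export
print.veg_orientation <- function(x, ...) {
  cat(sprintf(
    "<veg_orientation> %d x %d; median coherence %.3f; circular mean angle %.1f deg\n",
    nrow(x$angle), ncol(x$angle), stats::median(x$coherence),
    axial_mean(x$angle[x$coherence > 0.3])))
  invisible(x)
}

# mean of axial (mod-180) data via the doubled-angle circular mean
axial_mean <- function(a) {
  a <- a[is.finite(a)]
  if (length(a) == 0) return(NA_real_)
  fold180(rad2deg(atan2(mean(sin(2 * deg2rad(a))),
                        mean(cos(2 * deg2rad(a)))) / 2))
}

#' Slope-direction field of a height raster
#'
#' Central-difference gradient of the (optionally pre-smoothed) height
#' field; the angle is the uphill direction in degrees CCW from east
#' (`[0, 360)`), undefined (`NA`) where the surface is locally flat.
#'
#' @param height a [veg_field()] or matrix of elevations.
#' @param pre_sigma Gaussian pre-smoothing width (0 = none).
#' @return a `veg_slope` object: list with matrices `angle` and `magnitude`.
#' @export
slope_field <- function(height, pre_sigma = 0) {
  v <- if (is_veg_field(height)) height$values else as.matrix(height)
  if (pre_sigma > 0) v <- sep_gauss_cpp(v, pre_sigma)
  nx <- nrow(v); ny <- ncol(v)
  hx <- matrix(NA_real_, nx, ny); hy <- matrix(NA_real_, nx, ny)
  hx[2:(nx - 1), ] <- (v[3:nx, ] - v[1:(nx - 2), ]) / 2
  hy[, 2:(ny - 1)] <- (v[, 3:ny] - v[, 1:(ny - 2)]) / 2
  mag <- sqrt(hx^2 + hy^2)
  ang <- rad2deg(atan2(hy, hx)) %% 360
  flat <- is.finite(mag) & mag < 1e-12 * max(abs(v), 1e-300)
  ang[flat] <- NA_real_
  structure(list(angle = ang, magnitude = mag), class = "veg_slope")
}

#' Histogram of angular differences with mode detection
#'
#' Per-pixel differences between the band orientation and a reference angle
#' (a scalar, e.g. the wind direction, or a per-pixel field such as a slope
#' direction), folded to `[0, 180)`.  Pixels below the coherence threshold
#' are excluded.  Modes are local maxima of the (lightly smoothed, circular)
#' histogram above a prominence fraction of the tallest bin, refined by
#' parabolic interpolation; with a wind reference, the mode nearest 90
#' degrees is the horizontal family `H` and modes above/below it the oblique
#' families `O_l` / `O_r`.
#'
#' @param orient a `veg_orientation` from [orientation_field()].
#' @param reference scalar angle (degrees CCW from east) or a matrix/
#'   `veg_slope` of per-pixel reference angles.
#' @param binwidth histogram bin width in degrees.
#' @param coherence_min coherence threshold for inclusion.
#' @param prominence fraction of the tallest bin a local maximum must reach
#'   to count as a mode.
#' @return a `veg_angle_hist` tibble (`bin_mid`, `count`) with attribute
#'   `modes`: a tibble `location`, `height`, `label`.
#' @export
angle_difference_hist <- function(orient, reference, binwidth = 1,
                                  coherence_min = 0.3, prominence = 0.2) {
  stopifnot(inherits(orient, "veg_orientation"))
  ref <- if (inherits(reference, "veg_slope")) reference$angle
  else if (is.matrix(reference)) reference
  else matrix(reference, nrow(orient$angle), ncol(orient$angle))
  ok <- orient$coherence >= coherence_min & is.finite(orient$angle) &
    is.finite(ref)
  if (!any(ok)) stop("no coherent pattern: all pixels below the coherence threshold")
  delta <- fold180(orient$angle[ok] - ref[ok])
  edges <- seq(0, 180, by = binwidth)
  counts <- graphics::hist(delta, breaks = edges, plot = FALSE)$counts
  mids <- edges[-1] - binwidth / 2
  nb <- length(counts)
  # light circular smoothing stabilizes peak detection under pixel noise
  sm <- (counts + c(counts[-1], counts[1]) + c(counts[nb], counts[-nb])) / 3
  is_peak <- sm > c(sm[nb], sm[-nb]) & sm >= c(sm[-1], sm[1]) &
    sm >= prominence * max(sm)
  locs <- heights <- numeric(0)
  for (i in which(is_peak)) {
    im <- if (i == 1) nb else i - 1
    ip <- if (i == nb) 1 else i + 1
    denom <- sm[im] - 2 * sm[i] + sm[ip]
    off <- if (denom < 0) 0.5 * (sm[im] - sm[ip]) / denom else 0
    locs <- c(locs, fold180(mids[i] + off * binwidth))
    heights <- c(heights, sm[i])
  }
  label <- rep(NA_character_, length(locs))
  if (length(locs) > 0) {
    ih <- which.min(abs(locs - 90))
    label[ih] <- "H"
    label[locs > locs[ih] & seq_along(locs) != ih] <- "O_l"
    label[locs < locs[ih] & seq_along(locs) != ih] <- "O_r"
  }
  out <- tibble::tibble(bin_mid = mids, count = counts)
  attr(out, "modes") <- tibble::tibble(location = locs, height = heights,
                                       label = label)
  attr(out, "n_pixels") <- sum(ok)
  class(out) <- c("veg_angle_hist", class(out))
  out
}

#' @describeIn angle_difference_hist detected modes of a histogram.
#' @param x a `veg_angle_hist`.
#' @param ... unused.
#' @method tidy veg_angle_hist
#' @export
tidy.veg_angle_hist <- function(x, ...) attr(x, "modes")

#' Alignment correlation between band propagation and a reference direction
#'
#' The propagation direction of a banded pattern is perpendicular to the
#' band orientation; the correlation is the spatial average
#' \eqn{\langle \cos(\gamma_\perp - \gamma_{ref}) \rangle} over coherent
#' pixels, with \eqn{\gamma_\perp = \gamma_{pattern} - 90^\circ} and the
#' deviation folded to `[-90, 90)` (orientations are axial).  It equals 1
#' when bands are exactly perpendicular to the reference everywhere and
#' about 0 when they are parallel to it.
#'
#' @inheritParams angle_difference_hist
#' @return a single correlation value in `[-1, 1]`.
#' @export
alignment_correlation <- function(orient, reference, coherence_min = 0.3) {
  stopifnot(inherits(orient, "veg_orientation"))
  ref <- if (inherits(reference, "veg_slope")) reference$angle
  else if (is.matrix(reference)) reference
  else matrix(reference, nrow(orient$angle), ncol(orient$angle))
  ok <- orient$coherence >= coherence_min & is.finite(orient$angle) &
    is.finite(ref)
  if (!any(ok)) stop("no coherent pattern: all pixels below the coherence threshold")
  dev <- fold_dev90((orient$angle[ok] - 90) - ref[ok])
  mean(cos(deg2rad(dev)))
}
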