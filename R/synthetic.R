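#' Specification of a synthetic striped scene
#'
#' Describes a grayscale scene made of one or more rectangular orientation
#' domains, each filled with a sinusoidal stripe field of prescribed band
#' angle, on top of a mean level, an optional planar background gradient,
#' Gaussian pixel noise and optional dislocation defects (phase jumps of
#' pi along a cut).  Stripes are sinusoidal rather than binary so that the
#' structure tensor has clean, closed-form ground truth.
#'
#' @param width,height image size in pixels.
#' @param wavelength stripe wavelength in pixels (>= 4).
#' @param domains list of domains, each a list with elements `xmin`, `xmax`,
#'   `ymin`, `ymax` (pixel coordinates, 0-based, half-open on the upper side)
#'   and `angle` (band orientation, degrees CCW from east, folded mod 180).
#'   Domains must not overlap.  Default: one full-frame domain at 120
#'   degrees, the dominant band angle of fog-driven Tillandsia patches.
#' @param contrast stripe amplitude in intensity units.
#' @param mean_level background intensity.
#' @param gradient length-2 background gradient (intensity per pixel in x, y).
#' @param noise_sd Gaussian pixel noise standard deviation (>= 0).
#' @param n_defects number of dislocation defects, placed at seeded random
#'   positions inside domains.
#' @param seed RNG seed; identical seeds give bit-identical scenes.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(width = 256, height = 256, wavelength = 16,
                       domains = NULL, contrast = 0.25, mean_level = 0.5,
                       gradient = c(0, 0), noise_sd = 0, n_defects = 0,
                       seed = 1) {
  if (width < 1 || height < 1) stop("scene size must be positive")
  if (wavelength < 4) stop("stripe wavelength must be >= 4 pixels")
  if (noise_sd < 0) stop("noise standard deviation must be >= 0")
  if (is.null(domains))
    domains <- list(list(xmin = 0, xmax = width, ymin = 0, ymax = height,
                         angle = 120))
  domains <- lapply(domains, function(d) {
    stopifnot(all(c("xmin", "xmax", "ymin", "ymax", "angle") %in% names(d)))
    d$angle <- fold180(d$angle)
    d
  })
  structure(
    list(width = width, height = height, wavelength = wavelength,
         domains = domains, contrast = contrast, mean_level = mean_level,
         gradient = gradient, noise_sd = noise_sd, n_defects = n_defects,
         seed = seed),
    class = "scene_spec")
}

#' Specification of a synthetic digital elevation model
#'
#' A planar ramp with prescribed uphill (slope-gradient) direction and
#' magnitude, plus optional sinusoidal ridge/valley modulation transverse to
#' the ramp, which makes the local slope direction vary in space.
#'
#' @param nx,ny grid shape in pixels.
#' @param direction slope-gradient (uphill) direction, degrees CCW from east.
#' @param magnitude slope magnitude, height units per pixel.
#' @param ridge_amplitude amplitude of the transverse sinusoidal modulation
#'   (height units); 0 gives a pure plane.
#' @param ridge_wavelength wavelength of the modulation in pixels.
#' @return an object of class `dem_spec`.
#' @export
dem_spec <- function(nx = 128, ny = 128, direction = 0, magnitude = 1,
                     ridge_amplitude = 0, ridge_wavelength = 32) {
  if (nx < 2 || ny < 2) stop("DEM grid shape must be at least 2 x 2")
  if (magnitude < 0) stop("slope magnitude must be >= 0")
  if (ridge_wavelength <= 0) stop("ridge wavelength must be positive")
  structure(
    list(nx = nx, ny = ny, direction = direction %% 360,
         magnitude = magnitude, ridge_amplitude = ridge_amplitude,
         ridge_wavelength = ridge_wavelength),
    class = "dem_spec")
}

#' Noisy initial condition for the simulators
#'
#' Uniform noise in `[-amplitude, +amplitude]` around a mean biomass level,
#' clipped at zero (biomass cannot be negative).  When the x boundary is
#' Dirichlet the first and last grid columns are set to zero so the initial
#' condition conforms to the boundary conditions.
#'
#' @param nx,ny grid shape.
#' @param dx,dy grid spacings.
#' @param mean mean biomass level (>= 0).
#' @param amplitude half-width of the uniform noise (>= 0).
#' @param seed RNG seed; the generator is a pure function of its arguments.
#' @param bc_x x boundary condition.
#' @return a [veg_field()].
#' @export
#' @examples
#' ic <- make_noise_ic(32, 32, dx = 0.5, mean = 0.5, amplitude = 0.1, seed = 1)
make_noise_ic <- function(nx, ny, dx = 0.5, dy = dx, mean = 0.5,
                          amplitude = 0.1, seed = NULL,
                          bc_x = c("dirichlet", "periodic")) {
  bc_x <- match.arg(bc_x)
  if (nx < 1 || ny < 1) stop("grid shape must be positive")
  if (amplitude < 0) stop("noise amplitude must be >= 0")
  if (mean < 0) stop("mean level must be >= 0")
  vals <- with_seed_(seed,
    matrix(mean + stats::runif(nx * ny, -amplitude, amplitude), nx, ny))
  vals <- pmax(vals, 0)
  if (bc_x == "dirichlet") vals[c(1, nx), ] <- 0
  veg_field(vals, dx = dx, dy = dy, bc_x = bc_x)
}

# rasterize one domain of a scene_spec into a logical mask on the pixel grid
domain_mask <- function(d, px, py) {
  px >= d$xmin & px < d$xmax & py >= d$ymin & py < d$ymax
}

#' Generate a synthetic banded scene
#'
#' Each domain is filled with `contrast * cos(k . r + phase)` where the
#' wavevector `k` is perpendicular to the domain's band angle.  Dislocation
#' defects add a phase jump of pi across a cut through a seeded point,
#' oriented along the local band direction.
#'
#' @param spec a [scene_spec()].
#' @return a [veg_field()] intensity raster (dx = dy = 1 pixel, no boundary
#'   conditions).
#' @export
#' @examples
#' sc <- make_banded_scene(scene_spec(width = 64, height = 64, seed = 2))
make_banded_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  w <- spec$width; h <- spec$height
  xs <- seq_len(w) - 1
  ys <- seq_len(h) - 1
  X <- matrix(xs, w, h)
  Y <- matrix(ys, w, h, byrow = TRUE)
  masks <- lapply(spec$domains, domain_mask, px = X, py = Y)
  cover <- Reduce(`+`, lapply(masks, as.numeric))
  if (any(cover > 1))
    stop("overlapping domains: ground-truth orientation would be ambiguous")

  img <- with_seed_(spec$seed, {
    img <- spec$mean_level + spec$gradient[1] * X + spec$gradient[2] * Y
    # assign defects to domains uniformly at random
    dom_of_defect <- if (spec$n_defects > 0)
      sample.int(length(spec$domains), spec$n_defects, replace = TRUE)
    else integer(0)
    for (i in seq_along(spec$domains)) {
      d <- spec$domains[[i]]
      normal <- deg2rad(d$angle + 90)
      k <- 2 * pi / spec$wavelength
      phase <- k * (cos(normal) * X + sin(normal) * Y)
      for (j in which(dom_of_defect == i)) {
        x0 <- stats::runif(1, d$xmin, d$xmax)
        y0 <- stats::runif(1, d$ymin, d$ymax)
        tx <- cos(deg2rad(d$angle)); ty <- sin(deg2rad(d$angle))
        jump <- ((X - x0) * tx + (Y - y0) * ty) > 0
        phase <- phase + pi * jump
      }
      img <- img + masks[[i]] * spec$contrast * cos(phase)
    }
    if (spec$noise_sd > 0)
      img <- img + matrix(stats::rnorm(w * h, 0, spec$noise_sd), w, h)
    img
  })
  veg_field(img, dx = 1, dy = 1, bc_x = "none", bc_y = "none")
}

#' Generate a synthetic digital elevation model
#'
#' @param spec a [dem_spec()].
#' @return a [veg_field()] height raster.
#' @export
#' @examples
#' dem <- make_dem(dem_spec(64, 64, direction = 37))
make_dem <- function(spec) {
  stopifnot(inherits(spec, "dem_spec"))
  xs <- seq_len(spec$nx) - 1
  ys <- seq_len(spec$ny) - 1
  X <- matrix(xs, spec$nx, spec$ny)
  Y <- matrix(ys, spec$nx, spec$ny, byrow = TRUE)
  th <- deg2rad(spec$direction)
  h <- spec$magnitude * (cos(th) * X + sin(th) * Y)
  if (spec$ridge_amplitude != 0) {
    # transverse coordinate: modulation perpendicular to the ramp makes the
    # local gradient direction wander around the nominal one
    tperp <- -sin(th) * X + cos(th) * Y
    h <- h + spec$ridge_amplitude * sin(2 * pi * tperp / spec$ridge_wavelength)
  }
  veg_field(h, dx = 1, dy = 1, bc_x = "none", bc_y = "none")
}
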