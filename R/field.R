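#' Rectangular scalar field on a grid
#'
#' The basic container for biomass densities, image intensities and height
#' rasters.  Values are stored as a matrix with the first index running along
#' x (east) and the second along y (north), together with grid spacings and
#' boundary-condition tags.  The y direction of simulated fields is always
#' periodic; the x direction is either `"dirichlet"` (field pinned to zero on
#' the first and last grid columns, bare ground beyond the box) or
#' `"periodic"`.  Plain rasters (images, elevation models) use `"none"`.
#'
#' @param values numeric matrix, `values[ix, iy]`.
#' @param dx,dy grid spacings.
#' @param bc_x,bc_y boundary-condition tags.
#' @return an object of class `veg_field`.
#' @export
#' @examples
#' f <- veg_field(matrix(0, 8, 8), dx = 0.5)
#' field_Lx(f)
veg_field <- function(values, dx = 1, dy = dx,
                      bc_x = c("dirichlet", "periodic", "none"),
                      bc_y = c("periodic", "none")) {
  bc_x <- match.arg(bc_x)
  bc_y <- match.arg(bc_y)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("field values must be numeric")
  if (nrow(values) < 1 || ncol(values) < 1) stop("grid shape must be positive")
  if (!is.numeric(dx) || dx <= 0 || !is.numeric(dy) || dy <= 0)
    stop("grid spacings must be positive")
  structure(
    list(values = values, dx = dx, dy = dy, bc_x = bc_x, bc_y = bc_y),
    class = "veg_field")
}

#' @rdname veg_field
#' @param field a `veg_field`.
#' @export
field_Lx <- function(field) {
  n <- nrow(field$values)
  if (field$bc_x == "periodic") n * field$dx else (n - 1) * field$dx
}

#' @rdname veg_field
#' @export
field_Ly <- function(field) {
  n <- ncol(field$values)
  if (field$bc_y == "periodic") n * field$dy else (n - 1) * field$dy
}

# x and y node coordinates (origin at 0)
field_x <- function(field) (seq_len(nrow(field$values)) - 1) * field$dx
field_y <- function(field) (seq_len(ncol(field$values)) - 1) * field$dy

is_veg_field <- function(x) inherits(x, "veg_field")

#' @export
print.veg_field <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<veg_field> %d x %d grid, dx = %g, dy = %g, bc = (%s, %s)\n",
    nrow(v), ncol(v), x$dx, x$dy, x$bc_x, x$bc_y))
  cat(sprintf("  values in [%.4g, %.4g], mean %.4g\n",
              min(v), max(v), mean(v)))
  invisible(x)
}

#' Tidy a field into long (x, y, value) form
#'
#' @param x a `veg_field`.
#' @param ... unused.
#' @return a tibble with columns `x`, `y`, `value`.
#' @method as_tibble veg_field
#' @export
as_tibble.veg_field <- function(x, ...) {
  xs <- rep(field_x(x), times = ncol(x$values))
  ys <- rep(field_y(x), each = nrow(x$values))
  vals <- as.vector(x$values)
  tibble::tibble(x = xs, y = ys, value = vals)
}

#' @export
#' @rdname as_tibble.veg_field
#' @param object a `veg_field`.
#' @method autoplot veg_field
autoplot.veg_field <- function(object, ...) {
  df <- as_tibble.veg_field(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x", y = "y", fill = "b")
}

#' @export
plot.veg_field <- function(x, ...) print(autoplot(x, ...))
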