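#' Plot a discrete mode set
#'
#' Reproduces the standard picture of pattern selection in a finite box:
#' the admitted (m, n) wavevectors as dots in the (k_x, k_y) plane, with
#' unstable modes highlighted and the neutral curve of the continuous
#' dispersion relation overlaid.
#'
#' @param object a `veg_modeset` from [enumerate_modes()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot veg_modeset
#' @export
autoplot.veg_modeset <- function(object, ...) {
  params <- attr(object, "params")
  b_s <- attr(object, "b_s")
  disp <- dispersion(params, b_s)
  kx <- seq(1e-3, max(object$kx) * 1.1, length.out = 200)
  ky <- seq(min(object$ky) * 1.1 - 1e-3, max(object$ky) * 1.1 + 1e-3,
            length.out = 200)
  surf <- expand.grid(kx = kx, ky = ky)
  surf$re <- disp$re_fun(surf$kx, surf$ky)
  ggplot2::ggplot() +
    ggplot2::geom_contour(
      data = surf,
      ggplot2::aes(.data$kx, .data$ky, z = .data$re),
      breaks = 0, colour = "black") +
    ggplot2::geom_point(
      data = object,
      ggplot2::aes(.data$kx, .data$ky, colour = .data$unstable,
                   shape = .data$label)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "k_x", y = "k_y")
}

#' Plot an amplitude bifurcation diagram
#'
#' Branch moduli against the bifurcation parameter, solid for stable and
#' dashed for unstable segments: trivial state, supercritical horizontal
#' branch, oblique branch (initially unstable, stabilized through the mixed
#' branch) and the mixed branch itself.
#'
#' @param object a `veg_branches` from [equilibrium_branches()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot veg_branches
#' @export
autoplot.veg_branches <- function(object, ...) {
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    modulus = dplyr::case_when(
      .data$branch == "H" ~ .data$mod_H,
      .data$branch %in% c("O_single", "O_pair") ~ .data$mod_Ol,
      .data$branch == "mixed" ~ pmax(.data$mod_H, .data$mod_Ol),
      TRUE ~ 0))
  ggplot2::ggplot(df, ggplot2::aes(.data$mu_hat, .data$modulus,
                                   colour = .data$branch,
                                   linetype = .data$stable)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid",
                                              `FALSE` = "dashed")) +
    ggplot2::labs(x = "mu_hat", y = "|amplitude|")
}

#' Plot an angular-difference histogram
#'
#' @param object a `veg_angle_hist` from [angle_difference_hist()].
#' @param ... unused.
#' @return a ggplot object with detected modes marked.
#' @method autoplot veg_angle_hist
#' @export
autoplot.veg_angle_hist <- function(object, ...) {
  modes <- attr(object, "modes")
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(.data$bin_mid, .data$count)) +
    ggplot2::geom_col(width = diff(object$bin_mid[1:2]), fill = "seagreen") +
    ggplot2::labs(x = "angular difference (deg)", y = "pixels")
  if (nrow(modes) > 0)
    p <- p + ggplot2::geom_vline(xintercept = modes$location,
                                 linetype = "dotted")
  p
}

#' Plot an orientation field
#'
#' @param object a `veg_orientation` from [orientation_field()].
#' @param what `"angle"` or `"coherence"`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot veg_orientation
#' @export
autoplot.veg_orientation <- function(object, what = c("angle", "coherence"),
                                     ...) {
  what <- match.arg(what)
  m <- object[[what]]
  df <- tibble::tibble(
    x = rep(seq_len(nrow(m)) - 1, times = ncol(m)),
    y = rep(seq_len(ncol(m)) - 1, each = nrow(m)),
    value = as.vector(m))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = what)
  if (what == "angle")
    p + ggplot2::scale_fill_gradientn(
      colours = c("#440154", "#31688e", "#35b779", "#fde725", "#440154"),
      limits = c(0, 180), na.value = "grey80")
  else p + ggplot2::scale_fill_viridis_c(limits = c(0, 1))
}

#' @export
plot.veg_modeset <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.veg_branches <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.veg_angle_hist <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.veg_orientation <- function(x, ...) print(autoplot(x, ...))
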