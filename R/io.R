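#' Read and write fields as CSV grids with JSON sidecars
#'
#' CSV holds the value matrix (rows = x index, full `%.17g` precision, so a
#' write/read round trip is lossless and byte-stable); the sidecar
#' `<path>.json` records grid spacings, boundary tags and shape, which is
#' checked on read.
#'
#' @param field a [veg_field()].
#' @param path CSV file path.
#' @return `write_field` returns `path` invisibly; `read_field` returns a
#'   [veg_field()].
#' @export
write_field <- function(field, path) {
  stopifnot(is_veg_field(field))
  v <- field$values
  lines <- apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(lines, path)
  meta <- list(nx = nrow(v), ny = ncol(v), dx = field$dx, dy = field$dy,
               bc_x = field$bc_x, bc_y = field$bc_y)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' @rdname write_field
#' @export
read_field <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop(sprintf("missing sidecar metadata file '%s'", sc))
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  rows <- readLines(path)
  v <- do.call(rbind, lapply(strsplit(rows, ","), as.numeric))
  if (nrow(v) != meta$nx || ncol(v) != meta$ny)
    stop(sprintf("shape mismatch: CSV is %d x %d but sidecar says %d x %d",
                 nrow(v), ncol(v), meta$nx, meta$ny))
  veg_field(v, dx = meta$dx, dy = meta$dy, bc_x = meta$bc_x, bc_y = meta$bc_y)
}

#' Write and read a field as a grayscale raster image
#'
#' Values are affinely mapped to the raster bit depth (8 bits for PNG,
#' 16 bits for TIFF); the mapping (range) is stored in the JSON sidecar so
#' reading inverts it up to quantization (documented bound: one intensity
#' step).
#'
#' @param field a [veg_field()].
#' @param path image file path.
#' @return the write functions return `path` invisibly; the read functions
#'   a [veg_field()].
#' @export
write_field_png <- function(field, path) {
  stopifnot(is_veg_field(field))
  v <- field$values
  rng <- range(v)
  span <- if (diff(rng) > 0) diff(rng) else 1
  scaled <- (v - rng[1]) / span
  # PNG rasters are [row = y from top, col = x]
  img <- t(scaled)[ncol(scaled):1, , drop = FALSE]
  png::writePNG(img, target = path, dpi = NULL)
  meta <- list(nx = nrow(v), ny = ncol(v), dx = field$dx, dy = field$dy,
               bc_x = field$bc_x, bc_y = field$bc_y,
               vmin = rng[1], vmax = rng[1] + span, bits = 8)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_field_png
#' @export
write_field_tiff <- function(field, path) {
  stopifnot(is_veg_field(field))
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF output")
  v <- field$values
  rng <- range(v)
  span <- if (diff(rng) > 0) diff(rng) else 1
  scaled <- (v - rng[1]) / span
  img <- t(scaled)[ncol(scaled):1, , drop = FALSE]
  tiff::writeTIFF(img, path, bits.per.sample = 16)
  meta <- list(nx = nrow(v), ny = ncol(v), dx = field$dx, dy = field$dy,
               bc_x = field$bc_x, bc_y = field$bc_y,
               vmin = rng[1], vmax = rng[1] + span, bits = 16)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_field_png
#' @export
read_field_tiff <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop(sprintf("missing sidecar metadata file '%s'", sc))
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF input")
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  v <- t(img[nrow(img):1, , drop = FALSE])
  if (nrow(v) != meta$nx || ncol(v) != meta$ny)
    stop(sprintf("shape mismatch: TIFF is %d x %d but sidecar says %d x %d",
                 nrow(v), ncol(v), meta$nx, meta$ny))
  veg_field(v * (meta$vmax - meta$vmin) + meta$vmin,
            dx = meta$dx, dy = meta$dy, bc_x = meta$bc_x, bc_y = meta$bc_y)
}

#' @rdname write_field_png
#' @export
read_field_png <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop(sprintf("missing sidecar metadata file '%s'", sc))
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  v <- t(img[nrow(img):1, , drop = FALSE])
  if (nrow(v) != meta$nx || ncol(v) != meta$ny)
    stop(sprintf("shape mismatch: PNG is %d x %d but sidecar says %d x %d",
                 nrow(v), ncol(v), meta$nx, meta$ny))
  veg_field(v * (meta$vmax - meta$vmin) + meta$vmin,
            dx = meta$dx, dy = meta$dy, bc_x = meta$bc_x, bc_y = meta$bc_y)
}

#' Run configuration
#'
#' A serializable description of one pipeline run: the stage to execute, its
#' parameter block, the grid/time block, a seed and an output directory.
#' Serializes to and from JSON losslessly; every [run_pipeline()] call
#' writes its resolved configuration next to its outputs.
#'
#' @param subcommand one of `"synth"`, `"simulate-nonlocal"`,
#'   `"simulate-reduced"`, `"stability"`, `"amplitude-bifurcation"`,
#'   `"orient-analyze"`, `"bifurcation-scan"`.
#' @param params named list of model/analysis parameters for the stage.
#' @param grid named list with grid and time-stepping settings.
#' @param seed integer RNG seed.
#' @param out_dir output directory (created if absent).
#' @param snapshot_stride snapshot stride for the simulators.
#' @return an object of class `run_config`.
#' @export
run_config <- function(subcommand, params = list(), grid = list(),
                       seed = 1, out_dir = tempfile("fogbands_run_"),
                       snapshot_stride = 0) {
  subcommand <- match.arg(subcommand,
    c("synth", "simulate-nonlocal", "simulate-reduced", "stability",
      "amplitude-bifurcation", "orient-analyze", "bifurcation-scan"))
  structure(list(subcommand = subcommand, params = params, grid = grid,
                 seed = as.integer(seed), out_dir = out_dir,
                 snapshot_stride = snapshot_stride),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(x$subcommand, params = as.list(x$params),
             grid = as.list(x$grid), seed = x$seed, out_dir = x$out_dir,
             snapshot_stride = x$snapshot_stride)
}

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Execute a configured run
#'
#' Dispatches to the module functions, writes the resolved configuration and
#' all stage outputs (CSV tables, CSV field grids) into the output
#' directory, and returns a manifest of written files.  Identical
#' configurations (including the seed) produce byte-identical CSV outputs.
#'
#' @param config a [run_config()].
#' @return a tibble manifest with columns `file` and `what`, invisibly the
#'   same; the resolved config is always written as `config.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$out_dir, name)
  manifest <- tibble::tibble(file = character(0), what = character(0))
  note <- function(file, what)
    manifest <<- dplyr::bind_rows(manifest,
                                  tibble::tibble(file = file, what = what))
  write_config(config, out("config.json"))
  note(out("config.json"), "resolved configuration")
  p <- config$params
  g <- config$grid
  num <- function(x, default) if (is.null(x)) default else as.numeric(x)

  if (config$subcommand == "synth") {
    p$seed <- NULL
    spec <- do.call(scene_spec, c(p, list(seed = config$seed)))
    sc <- make_banded_scene(spec)
    write_field(sc, out("scene.csv")); note(out("scene.csv"), "scene raster")
    write_field_png(sc, out("scene.png")); note(out("scene.png"), "scene PNG")
  } else if (config$subcommand == "simulate-reduced") {
    rp <- reduced_params(eta = p$eta, kappa = p$kappa, d = p$d,
                         alpha = num(p$alpha, 0), gamma = p$gamma)
    nx <- round(num(g$Lx, 85) / num(g$dx, 0.5)) + 1
    ny <- round(num(g$Ly, 100) / num(g$dy, 0.5))
    us <- uniform_states_reduced(rp$eta, rp$kappa)
    b0 <- make_noise_ic(nx, ny, dx = num(g$dx, 0.5), dy = num(g$dy, 0.5),
                        mean = max(us$b[2], 0.1, na.rm = TRUE),
                        amplitude = num(g$noise, 0.1), seed = config$seed)
    tr <- simulate_reduced(rp, b0, dt = num(g$dt, 5e-4),
                           n_steps = round(num(g$t_end, 100) / num(g$dt, 5e-4)),
                           snap_stride = config$snapshot_stride,
                           rec_stride = max(1, round(0.5 / num(g$dt, 5e-4))))
    write_field(final_state(tr), out("final.csv"))
    note(out("final.csv"), "final biomass field")
    utils::write.csv(
      data.frame(t = tr$rec_times, t(tr$mid_col)),
      out("midcol_spacetime.csv"), row.names = FALSE)
    note(out("midcol_spacetime.csv"), "space-time record b(x_mid, y, t)")
    write_csv_plain(classify_pattern(final_state(tr)), out("classification.csv"))
    note(out("classification.csv"), "pattern classification")
  } else if (config$subcommand == "simulate-nonlocal") {
    np <- nonlocal_params(mu = p$mu, chi_f = p$chi_f, chi_c = p$chi_c,
                          D = p$D, x0f = num(p$x0f, 0), x0c = num(p$x0c, 0),
                          y0f = num(p$y0f, 0), y0c = num(p$y0c, 0),
                          lfx = p$lfx, lfy = num(p$lfy, p$lfx),
                          lcx = p$lcx, lcy = num(p$lcy, p$lcx))
    dx <- num(g$dx, 0.3)
    nx <- round(num(g$Lx, 40) / dx) + 1
    ny <- round(num(g$Ly, 40) / dx)
    us <- uniform_states_nonlocal(np)
    b0 <- make_noise_ic(nx, ny, dx = dx, dy = dx,
                        mean = max(us$b), amplitude = num(g$noise, 0.05),
                        seed = config$seed)
    dt <- num(g$dt, 0.04)
    tr <- simulate_nonlocal(np, b0, dt = dt,
                            n_steps = round(num(g$t_end, 100) / dt),
                            snap_stride = config$snapshot_stride)
    write_field(final_state(tr), out("final.csv"))
    note(out("final.csv"), "final biomass field")
    write_csv_plain(classify_pattern(final_state(tr)), out("classification.csv"))
    note(out("classification.csv"), "pattern classification")
  } else if (config$subcommand == "stability") {
    rp <- reduced_params(eta = p$eta, kappa = p$kappa, d = p$d,
                         alpha = num(p$alpha, 0), gamma = p$gamma)
    us <- uniform_states_reduced(rp$eta, rp$kappa)
    disp <- dispersion(rp, us$b[2])
    write_csv_plain(tidy(disp, kx = seq(0, 2, by = 0.02),
                         ky = seq(-1, 1, by = 0.05)),
                    out("dispersion.csv"))
    note(out("dispersion.csv"), "dispersion surface")
    ms <- enumerate_modes(rp, us$b[2], Lx = num(g$Lx, 85), Ly = num(g$Ly, 100))
    write_csv_plain(as.data.frame(ms), out("modes.csv"))
    note(out("modes.csv"), "discrete mode table")
    cp <- critical_point(rp$kappa, rp$d, rp$gamma)
    jsonlite::write_json(as.list(cp), out("critical.json"),
                         auto_unbox = TRUE, digits = NA)
    note(out("critical.json"), "critical point")
  } else if (config$subcommand == "amplitude-bifurcation") {
    ap <- amplitude_params(mu_hat = 0, beta = num(p$beta, 0),
                           delta_k = p$delta_k)
    br <- equilibrium_branches(ap, seq(num(p$mu_min, -0.05),
                                       num(p$mu_max, 0.4),
                                       length.out = num(p$n_mu, 46)))
    write_csv_plain(as.data.frame(br), out("branches.csv"))
    note(out("branches.csv"), "equilibrium branches")
  } else if (config$subcommand == "orient-analyze") {
    img <- read_field(p$image)
    pre <- preprocess_image(img, blur_sigma = num(p$blur_sigma, 1),
                            ball_radius = num(p$ball_radius, 20))
    orient <- orientation_field(pre, sigma_w = num(p$sigma_w, 4))
    wind <- num(p$wind_deg, 30)
    hh <- angle_difference_hist(orient, wind,
                                binwidth = num(p$bins, 1),
                                coherence_min = num(p$coherence_min, 0.3))
    write_csv_plain(as.data.frame(hh), out("dphi_hist.csv"))
    note(out("dphi_hist.csv"), "wind angle-difference histogram")
    write_csv_plain(as.data.frame(tidy(hh)), out("dphi_modes.csv"))
    note(out("dphi_modes.csv"), "histogram modes")
    report <- list(wind_deg = wind,
                   alignment_correlation_wind =
                     alignment_correlation(orient, wind,
                       coherence_min = num(p$coherence_min, 0.3)))
    if (!is.null(p$dem)) {
      sl <- slope_field(read_field(p$dem), pre_sigma = num(p$dem_sigma, 0))
      ht <- angle_difference_hist(orient, sl,
                                  binwidth = num(p$bins, 1),
                                  coherence_min = num(p$coherence_min, 0.3))
      write_csv_plain(as.data.frame(ht), out("dtheta_hist.csv"))
      note(out("dtheta_hist.csv"), "slope angle-difference histogram")
      report$alignment_correlation_slope <-
        alignment_correlation(orient, sl,
                              coherence_min = num(p$coherence_min, 0.3))
    }
    jsonlite::write_json(report, out("correlation.json"), auto_unbox = TRUE,
                         digits = NA)
    note(out("correlation.json"), "alignment correlation report")
  } else if (config$subcommand == "bifurcation-scan") {
    rp <- reduced_params(eta = 0, kappa = p$kappa, d = p$d,
                         alpha = num(p$alpha, 0), gamma = p$gamma)
    tab <- bifurcation_scan(rp, eta_values = as.numeric(p$eta_values),
                            Lx = num(g$Lx, 42.5), Ly = num(g$Ly, 20),
                            dx = num(g$dx, 0.5), dt = num(g$dt, 1e-3),
                            t_max = num(g$t_max, 500), seed = config$seed)
    write_csv_plain(as.data.frame(tab), out("bifurcation.csv"))
    note(out("bifurcation.csv"), "bifurcation scan table")
  }
  invisible(manifest)
}
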