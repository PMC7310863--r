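#' Generative 3D model of a D2R1 repair focus
#'
#' Parameter container for the three-cluster generative model of a D2R1
#' focus: a globular "close" DMC1 nanofocus, a globular "far" DMC1 nanofocus
#' placed at a fixed 3D distance in a uniformly random direction, and a RAD51
#' ellipsoid attached to the close DMC1 nanofocus, its major axis tilted at a
#' random angle (uniform in `[0, alpha_max]`) away from the DMC1-DMC1 axis.
#' Uniform background localisations are added within a cube around the close
#' nanofocus.
#'
#' Localisation counts default to the mean numbers of localisations measured
#' per nanofocus class in spermatocyte dSTORM data: 267 (RAD51), 564 (close
#' DMC1) and 51 (far DMC1), plus 50 background events, with the far DMC1 at
#' 400 nm from the close DMC1.
#'
#' @param sigma_R_major RAD51 ellipsoid major-axis SD (nm). The default
#'   corresponds to a FWHM of 112 nm (mid best-fit range).
#' @param sigma_R_minor RAD51 minor-axis SD (nm); defaults to `sigma_D_far`.
#' @param alpha_max maximum angle (degrees, in `[0, 180]`) between the
#'   DMC1-DMC1 axis and the close-DMC1-to-RAD51 axis.
#' @param sigma_D_close,sigma_D_far isotropic SDs (nm) of the two DMC1
#'   clusters.
#' @param n_R,n_D_close,n_D_far,n_bg localisation counts per cluster and
#'   background.
#' @param d_far 3D distance (nm) between the DMC1 cluster centres.
#' @param bg_extent side (nm) of the cube, centred on the close DMC1 centre,
#'   in which background localisations are uniform. The default 1200 nm
#'   covers the full spatial extent of the model (far DMC1 at 400 nm plus
#'   cluster spreads), so background is uniform over the analysed field
#'   rather than concentrated near the close cluster.
#' @param attach_factor offset of the RAD51 centre from the close DMC1
#'   centre, in units of `sigma_R_major`, along the RAD51 major axis (the
#'   two clusters are physically connected; 1 places the filament emanating
#'   from the close cluster).
#' @return an object of class `d2r1_model`.
#' @seealso [gen_d2r1_focus()]
#' @export
d2r1_model <- function(sigma_R_major = 112 / (2 * sqrt(2 * log(2))),
                       sigma_R_minor = sigma_D_far,
                       alpha_max = 120,
                       sigma_D_close = 30,
                       sigma_D_far = 15,
                       n_R = 267, n_D_close = 564, n_D_far = 51, n_bg = 50,
                       d_far = 400, bg_extent = 1200, attach_factor = 1) {
  for (nm in c("sigma_R_major", "sigma_R_minor", "sigma_D_close",
               "sigma_D_far", "d_far", "bg_extent"))
    stopifnot_scalar_pos(get(nm), nm)
  if (!is.numeric(alpha_max) || alpha_max < 0 || alpha_max > 180)
    stop("'alpha_max' must be in [0, 180] degrees", call. = FALSE)
  counts <- c(n_R = n_R, n_D_close = n_D_close, n_D_far = n_D_far,
              n_bg = n_bg)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("localisation counts must be non-negative integers", call. = FALSE)
  structure(list(sigma_R_major = sigma_R_major,
                 sigma_R_minor = sigma_R_minor,
                 alpha_max = alpha_max,
                 sigma_D_close = sigma_D_close, sigma_D_far = sigma_D_far,
                 n_R = as.integer(n_R), n_D_close = as.integer(n_D_close),
                 n_D_far = as.integer(n_D_far), n_bg = as.integer(n_bg),
                 d_far = d_far, bg_extent = bg_extent,
                 attach_factor = attach_factor),
            class = "d2r1_model")
}

#' @export
print.d2r1_model <- function(x, ...) {
  cat(sprintf(
    "D2R1 generative model: sigma_R = %.1f nm (FWHM %.0f), alpha_max = %.0f deg\n",
    x$sigma_R_major, fwhm_from_sigma(x$sigma_R_major), x$alpha_max))
  cat(sprintf("  counts R/Dclose/Dfar/bg = %d/%d/%d/%d, d_far = %.0f nm\n",
              x$n_R, x$n_D_close, x$n_D_far, x$n_bg, x$d_far))
  invisible(x)
}

# orthonormal basis perpendicular to unit vector u
#' @noRd
perp_basis <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  cbind(e1, e2)
}

#' Simulate one 3D D2R1 focus
#'
#' Draws localisation coordinates from a [d2r1_model()]: the close DMC1
#' cluster is centred at the origin; the far DMC1 centre is placed at 3D
#' distance `d_far` in a uniformly random direction; the RAD51 ellipsoid is
#' attached to the close DMC1 centre with its major axis at an angle drawn
#' uniformly in `[0, alpha_max]` from the DMC1-DMC1 axis, with uniformly
#' random azimuth around that axis.
#'
#' @param model a [d2r1_model()].
#' @param seed optional integer seed; with a fixed seed the output is
#'   bit-identical across calls.
#' @param in_plane if `TRUE` the far-DMC1 displacement and the RAD51 tilt are
#'   confined to the xy plane (no projection loss variant).
#' @return a data.frame with columns `x`, `y`, `z` (nm), `channel`
#'   (`"DMC1"`, `"RAD51"`, or `"background"`) and `cluster`
#'   (`"dmc1_close"`, `"dmc1_far"`, `"rad51"`, `"background"`), with the true
#'   cluster centres and axis geometry in attribute `"truth"`.
#' @export
gen_d2r1_focus <- function(model = d2r1_model(), seed = NULL,
                           in_plane = FALSE) {
  stopifnot(inherits(model, "d2r1_model"))
  with_seed(seed, {
    # direction of the DMC1-DMC1 axis
    u <- if (in_plane) {
      phi <- runif(1, 0, 2 * pi)
      c(cos(phi), sin(phi), 0)
    } else {
      repeat {
        g <- rnorm(3)
        if (sum(g^2) > 1e-12) break
      }
      g / sqrt(sum(g^2))
    }
    far_centre <- model$d_far * u
    # RAD51 major-axis direction at angle theta from u
    theta <- runif(1, 0, model$alpha_max * pi / 180)
    if (in_plane) {
      sgn <- sample(c(-1, 1), 1)
      rot <- sgn * theta
      dir <- c(cos(rot) * u[1] - sin(rot) * u[2],
               sin(rot) * u[1] + cos(rot) * u[2], 0)
    } else {
      E <- perp_basis(u)
      phi <- runif(1, 0, 2 * pi)
      dir <- cos(theta) * u + sin(theta) * (cos(phi) * E[, 1] + sin(phi) * E[, 2])
    }
    r_centre <- model$attach_factor * model$sigma_R_major * dir
    W <- perp_basis(dir)

    close_pts <- matrix(rnorm(3 * model$n_D_close, 0, model$sigma_D_close),
                        ncol = 3)
    far_pts <- sweep(matrix(rnorm(3 * model$n_D_far, 0, model$sigma_D_far),
                            ncol = 3), 2, far_centre, "+")
    z1 <- rnorm(model$n_R, 0, model$sigma_R_major)
    z2 <- rnorm(model$n_R, 0, model$sigma_R_minor)
    z3 <- rnorm(model$n_R, 0, model$sigma_R_minor)
    r_pts <- sweep(outer(z1, dir) + outer(z2, W[, 1]) + outer(z3, W[, 2]),
                   2, r_centre, "+")
    bg_pts <- matrix(runif(3 * model$n_bg, -model$bg_extent / 2,
                           model$bg_extent / 2), ncol = 3)

    out <- data.frame(
      x = c(close_pts[, 1], far_pts[, 1], r_pts[, 1], bg_pts[, 1]),
      y = c(close_pts[, 2], far_pts[, 2], r_pts[, 2], bg_pts[, 2]),
      z = c(close_pts[, 3], far_pts[, 3], r_pts[, 3], bg_pts[, 3]),
      channel = rep(c("DMC1", "DMC1", "RAD51", "background"),
                    times = c(model$n_D_close, model$n_D_far, model$n_R,
                              model$n_bg)),
      cluster = rep(c("dmc1_close", "dmc1_far", "rad51", "background"),
                    times = c(model$n_D_close, model$n_D_far, model$n_R,
                              model$n_bg)),
      stringsAsFactors = FALSE)
    attr(out, "truth") <- list(close_centre = c(0, 0, 0),
                               far_centre = far_centre,
                               rad51_centre = r_centre,
                               axis_dir = u, rad51_dir = dir, theta = theta)
    out
  })
}

#' Synthetic nucleus layout
#'
#' Describes a synthetic spread nucleus: chromosome-axis polylines and repair
#' foci positioned along them. This is artifact plumbing for pipeline testing
#' (real nuclei are inputs, not simulated).
#'
#' @param axis_polylines list of numeric matrices (columns x, y in nm), each
#'   with at least two vertices, all inside the field.
#' @param focus_specs data.frame with one row per focus: `polyline` (index),
#'   `position` (arc length along the polyline, nm), `n_dmc1`, `n_rad51`
#'   (localisation counts) and `sigma_dmc1`, `sigma_rad51` (cluster SDs, nm).
#' @param field_size numeric length-2, field extent (nm) in x and y.
#' @return object of class `nucleus_layout`.
#' @export
nucleus_layout <- function(axis_polylines, focus_specs,
                           field_size = c(10000, 10000)) {
  stopifnot(is.list(axis_polylines), length(axis_polylines) >= 1)
  for (p in axis_polylines) {
    p <- as.matrix(p)
    if (nrow(p) < 2 || ncol(p) != 2 || !all(is.finite(p)))
      stop("each axis polyline needs >= 2 finite (x, y) vertices",
           call. = FALSE)
    if (any(p[, 1] < 0 | p[, 1] > field_size[1] |
            p[, 2] < 0 | p[, 2] > field_size[2]))
      stop("axis polylines must lie within the field", call. = FALSE)
  }
  fs <- as.data.frame(focus_specs)
  need <- c("polyline", "position", "n_dmc1", "n_rad51",
            "sigma_dmc1", "sigma_rad51")
  if (nrow(fs) > 0 && !all(need %in% names(fs)))
    stop("focus_specs must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  structure(list(axis_polylines = lapply(axis_polylines, as.matrix),
                 focus_specs = fs, field_size = field_size),
            class = "nucleus_layout")
}

# point at arc length s along polyline (clamped to its ends)
#' @noRd
point_on_polyline <- function(poly, s) {
  seg <- sqrt(rowSums(diff(poly)^2))
  cum <- c(0, cumsum(seg))
  s <- min(max(s, 0), cum[length(cum)])
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- min(i, length(seg))
  f <- if (seg[i] > 0) (s - cum[i]) / seg[i] else 0
  poly[i, ] + f * (poly[i + 1, ] - poly[i, ])
}

#' Generate localisations for a synthetic nucleus
#'
#' Realises each focus of a [nucleus_layout()] as isotropic 2D Gaussian
#' localisation clusters (one per channel) centred at its position on the
#' axis polyline.
#'
#' @param layout a [nucleus_layout()].
#' @param seed optional integer seed (per-focus substreams are derived from
#'   it, so output is reproducible).
#' @return data.frame with columns `x`, `y` (nm), `channel`, `focus_id`;
#'   ground-truth focus centres in attribute `"truth"` (data.frame with
#'   `focus_id`, `x`, `y`). An empty layout yields an empty table.
#' @export
gen_nucleus_localizations <- function(layout, seed = NULL) {
  stopifnot(inherits(layout, "nucleus_layout"))
  fs <- layout$focus_specs
  if (nrow(fs) == 0) {
    out <- data.frame(x = numeric(0), y = numeric(0),
                      channel = character(0), focus_id = integer(0))
    attr(out, "truth") <- data.frame(focus_id = integer(0),
                                     x = numeric(0), y = numeric(0))
    return(out)
  }
  seeds <- derive_seeds(seed, nrow(fs))
  rows <- vector("list", nrow(fs))
  centres <- matrix(NA_real_, nrow(fs), 2)
  for (i in seq_len(nrow(fs))) {
    ctr <- point_on_polyline(layout$axis_polylines[[fs$polyline[i]]],
                             fs$position[i])
    centres[i, ] <- ctr
    rows[[i]] <- with_seed(if (is.null(seed)) NULL else seeds[i], {
      nd <- fs$n_dmc1[i]; nr <- fs$n_rad51[i]
      data.frame(
        x = ctr[1] + c(rnorm(nd, 0, fs$sigma_dmc1[i]),
                       rnorm(nr, 0, fs$sigma_rad51[i])),
        y = ctr[2] + c(rnorm(nd, 0, fs$sigma_dmc1[i]),
                       rnorm(nr, 0, fs$sigma_rad51[i])),
        channel = rep(c("DMC1", "RAD51"), times = c(nd, nr)),
        focus_id = i, stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- data.frame(focus_id = seq_len(nrow(fs)),
                                   x = centres[, 1], y = centres[, 2])
  out
}

#' Confocal rendering parameters
#'
#' @param pixel_size pixel edge (nm); default 99 nm (1024x1024 field of a
#'   63x confocal).
#' @param blur_sigma SD of the Gaussian blur approximating the confocal PSF,
#'   in nm (default 110 nm, i.e. 0.11 um).
#' @param blur_sigma_um alternative way to give `blur_sigma`, in micrometres;
#'   converted to nm internally when supplied.
#' @param base_offset constant intensity offset added to the whole image
#'   before shot noise.
#' @param focus_amplitude pre-blur single-pixel impulse value for one focus.
#'   The post-blur peak is approximately
#'   `focus_amplitude * pixel_size^2 / (2*pi*blur_sigma^2)`; the default 1200
#'   gives a peak of about 155, comfortably above the 90/100 detection noise
#'   tolerances.
#' @return object of class `confocal_render_params`.
#' @export
confocal_render_params <- function(pixel_size = 99, blur_sigma = 110,
                                   blur_sigma_um = NULL, base_offset = 5,
                                   focus_amplitude = 1200) {
  if (!is.null(blur_sigma_um)) blur_sigma <- 1000 * blur_sigma_um
  stopifnot_scalar_pos(pixel_size, "pixel_size")
  stopifnot_scalar_pos(blur_sigma, "blur_sigma")
  structure(list(pixel_size = pixel_size, blur_sigma = blur_sigma,
                 base_offset = base_offset,
                 focus_amplitude = focus_amplitude),
            class = "confocal_render_params")
}

#' Render a confocal-like image from point foci
#'
#' Places a single-pixel impulse of height `focus_amplitude` at each focus
#' position, blurs with a Gaussian filter (SD `blur_sigma`), adds the
#' constant offset, and (optionally) adds per-pixel uniform shot noise in
#' plus/minus the square root of each pixel's intensity.
#'
#' @param points data.frame or matrix with columns `x`, `y` (nm), within the
#'   field.
#' @param params a [confocal_render_params()].
#' @param field_px integer length-2: image size in pixels (x, y).
#' @param noise add shot noise? (`TRUE` for the analysis chain; `FALSE`
#'   exposes the deterministic blurred image.)
#' @param seed optional integer seed for the noise.
#' @return numeric matrix of size `field_px[1] x field_px[2]`; entry `[i, j]`
#'   is the pixel with x-index `i` and y-index `j`.
#' @export
render_confocal <- function(points, params = confocal_render_params(),
                            field_px = c(256, 256), noise = TRUE,
                            seed = NULL) {
  stopifnot(inherits(params, "confocal_render_params"))
  pts <- as.data.frame(points)
  if (nrow(pts) > 0) {
    px <- floor(pts$x / params$pixel_size) + 1L
    py <- floor(pts$y / params$pixel_size) + 1L
    if (any(px < 1 | px > field_px[1] | py < 1 | py > field_px[2]))
      stop("points outside the field", call. = FALSE)
  }
  img <- matrix(0, field_px[1], field_px[2])
  if (nrow(pts) > 0)
    for (k in seq_along(px))
      img[px[k], py[k]] <- img[px[k], py[k]] + params$focus_amplitude
  sig_px <- params$blur_sigma / params$pixel_size
  half <- ceiling(4 * sig_px)
  g <- stats::dnorm(seq(-half, half), sd = sig_px)
  kern <- outer(g, g)
  kern <- kern / sum(kern)
  img <- EBImage::filter2(img, kern)  # circular boundary: mass-conserving
  img <- img + params$base_offset
  with_seed(seed, {
    if (noise) img <- img + runif(length(img), -1, 1) * sqrt(pmax(img, 0))
    img
  })
}
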