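#' Analyse one simulated 3D focus exactly like experimental data
#'
#' Discards the z coordinate, assigns each unlabeled background localisation
#' to one of the two channels uniformly at random (each real channel carries
#' its own background), segments both channels on a common grid and returns
#' the resulting [focus_configuration()]. The analysed 2D events are stored
#' in attribute `"events"`.
#'
#' @param focus a data.frame from [gen_d2r1_focus()] (columns `x`, `y`, `z`,
#'   `channel`).
#' @param bandwidth,pixel,threshold,min_area segmentation parameters, see
#'   [kde_map()] and [segment_nanofoci()].
#' @param seed optional integer seed for the background channel assignment.
#' @return a [focus_configuration()].
#' @export
analyze_d2r1_focus <- function(focus, bandwidth = 20, pixel = 5,
                               threshold = density_from_per_pixel(5, 100),
                               min_area = 50, seed = NULL) {
  ev <- as.data.frame(focus)[, c("x", "y", "channel")]
  bg <- ev$channel == "background"
  if (any(bg))
    ev$channel[bg] <- with_seed(seed,
      sample(CHANNELS, sum(bg), replace = TRUE))
  nf <- segment_roi_channels(ev, bandwidth = bandwidth, pixel = pixel,
                             threshold = threshold, min_area = min_area)
  cfg <- focus_configuration(nf)
  attr(cfg, "events") <- ev
  cfg
}

#' Summary features of an aligned simulated (or experimental) dataset
#'
#' @param sigma_R fitted RAD51 Gaussian SD (nm) along the alignment axis.
#' @param pct_D_tophalf percentage of DMC1 localisations above the centre in
#'   the RAD51-to-top rotation.
#' @param pct_R_topquad percentage of RAD51 localisations in the top
#'   quadrant in the far-DMC1-to-top rotation.
#' @return object of class `d2r1_features`.
#' @export
d2r1_features <- function(sigma_R, pct_D_tophalf, pct_R_topquad) {
  for (p in c(pct_D_tophalf, pct_R_topquad))
    if (!is.na(p) && (p < 0 || p > 100))
      stop("percentages must lie in [0, 100]", call. = FALSE)
  structure(list(sigma_R = sigma_R, pct_D_tophalf = pct_D_tophalf,
                 pct_R_topquad = pct_R_topquad), class = "d2r1_features")
}

#' Simulate and analyse one grid cell of D2R1 configurations
#'
#' Generates `n_configs` foci from the model at the given RAD51 major-axis
#' SD and maximum angle, analyses each in 2D ([analyze_d2r1_focus()]),
#' tallies the DxRy classification frequencies, and — over the foci that
#' remain D2R1 after projection — pools rotation-aligned localisations to
#' measure the three summary features ([d2r1_features()]).
#'
#' @param sigma_R_major RAD51 major-axis SD (nm).
#' @param alpha_max maximum tilt angle (degrees).
#' @param model template [d2r1_model()]; its `sigma_R_major`/`alpha_max` are
#'   replaced by the cell's values.
#' @param n_configs configurations per cell.
#' @param seed integer seed (per-focus substreams).
#' @param keep_stacks keep the pooled aligned localisation tables.
#' @param ... segmentation parameters passed to [analyze_d2r1_focus()].
#' @return object of class `d2r1_cell`: `sigma_R_major`, `alpha_max`,
#'   `n_configs`, `class_freq` (named fractions summing to 1), `features`,
#'   `n_d2r1`, and optionally `stacks`.
#' @export
simulate_d2r1_cell <- function(sigma_R_major, alpha_max,
                               model = d2r1_model(), n_configs = 200,
                               seed = NULL, keep_stacks = FALSE, ...) {
  if (n_configs < 1) stop("'n_configs' must be >= 1", call. = FALSE)
  model$sigma_R_major <- sigma_R_major
  model$alpha_max <- alpha_max
  stopifnot(inherits(model, "d2r1_model"))
  seeds <- derive_seeds(seed, 2L * n_configs)
  labels <- character(n_configs)
  rot_rad51 <- list(); rot_far <- list()
  for (k in seq_len(n_configs)) {
    fo <- gen_d2r1_focus(model, seed = if (is.null(seed)) NULL else seeds[2 * k - 1])
    cfg <- analyze_d2r1_focus(fo, seed = if (is.null(seed)) NULL else seeds[2 * k],
                              ...)
    labels[k] <- cfg$label
    if (cfg$label != "D2R1") next
    ev <- attr(cfg, "events")
    com <- lapply(cfg$nanofoci, function(f) f$com)
    close_c <- com[[which(cfg$roles == "close")]]
    far_c <- com[[which(cfg$roles == "far")]]
    r_c <- com[[which(cfg$roles == "single")]]
    rot_rad51[[length(rot_rad51) + 1]] <- rotate_align(ev, close_c, r_c)
    rot_far[[length(rot_far) + 1]] <- rotate_align(ev, close_c, far_c)
  }
  freq <- table(labels) / n_configs
  feats <- d2r1_features(NA_real_, NA_real_, NA_real_)
  if (length(rot_rad51) > 0) {
    pooled_r <- do.call(rbind, rot_rad51)
    pooled_f <- do.call(rbind, rot_far)
    sig <- tryCatch(fit_sigma(pooled_r, "RAD51")$sigma,
                    error = function(e) NA_real_)
    dm <- pooled_r[pooled_r$channel == "DMC1", , drop = FALSE]
    feats <- d2r1_features(
      sigma_R = sig,
      pct_D_tophalf = 100 * mean(dm$y > 0),
      pct_R_topquad = 100 * unname(
        quadrant_fractions(pooled_f, "RAD51")["top"]))
  }
  structure(list(sigma_R_major = sigma_R_major, alpha_max = alpha_max,
                 n_configs = n_configs,
                 class_freq = setNames(as.numeric(freq), names(freq)),
                 features = feats, n_d2r1 = length(rot_rad51),
                 stacks = if (keep_stacks)
                   list(rad51_rot = do.call(rbind, rot_rad51),
                        far_rot = do.call(rbind, rot_far)) else NULL),
            class = "d2r1_cell")
}

#' @export
print.d2r1_cell <- function(x, ...) {
  cat(sprintf(
    "d2r1_cell sigma %.1f nm (FWHM %.0f), alpha %.0f: %d/%d remain D2R1\n",
    x$sigma_R_major, fwhm_from_sigma(x$sigma_R_major), x$alpha_max,
    x$n_d2r1, x$n_configs))
  if (!is.na(x$features$sigma_R))
    cat(sprintf("  sigma_R %.1f nm, D top-half %.1f%%, R top-quad %.1f%%\n",
                x$features$sigma_R, x$features$pct_D_tophalf,
                x$features$pct_R_topquad))
  invisible(x)
}

#' DxRy classification fractions of a simulated cell
#'
#' Fraction of the cell's simulated 3D D2R1 foci per DxRy label after z is
#' discarded and the full 2D segmentation is re-run (projection and noise
#' can merge, lose or add nanofoci).
#'
#' @param cell a [simulate_d2r1_cell()] result.
#' @return named numeric vector of fractions summing to 1.
#' @export
projection_class_table <- function(cell) {
  stopifnot(inherits(cell, "d2r1_cell"))
  cell$class_freq
}

#' Default parameter grid for the D2R1 simulation
#'
#' Major-axis SDs corresponding to FWHM 80-160 nm and maximum angles
#' 90-180 degrees, bracketing the reported best-fit range (FWHM 80-144 nm,
#' angles 105-132 degrees).
#'
#' @return list with `sigma` (nm) and `alpha` (degrees).
#' @export
d2r1_default_grid <- function() {
  list(sigma = c(80, 96, 112, 128, 144, 160) / (2 * sqrt(2 * log(2))),
       alpha = c(90, 105, 120, 132, 150, 180))
}

#' Simulate a grid of D2R1 model cells
#'
#' Runs [simulate_d2r1_cell()] for every combination of RAD51 major-axis SD
#' and maximum angle.
#'
#' @param sigma_list,alpha_list parameter values (nm, degrees).
#' @param model template [d2r1_model()].
#' @param n_per_cell configurations per cell.
#' @param seed integer seed (per-cell substreams).
#' @param ... segmentation parameters passed down.
#' @return object of class `d2r1_grid`: list of `d2r1_cell`s plus the
#'   parameter vectors.
#' @export
simulate_d2r1_grid <- function(sigma_list = d2r1_default_grid()$sigma,
                               alpha_list = d2r1_default_grid()$alpha,
                               model = d2r1_model(), n_per_cell = 200,
                               seed = NULL, ...) {
  if (length(sigma_list) == 0 || length(alpha_list) == 0)
    stop("parameter lists must be nonempty", call. = FALSE)
  combos <- expand.grid(sigma = sigma_list, alpha = alpha_list,
                        KEEP.OUT.ATTRS = FALSE)
  seeds <- derive_seeds(seed, nrow(combos))
  cells <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cells[[i]] <- simulate_d2r1_cell(
      combos$sigma[i], combos$alpha[i], model = model,
      n_configs = n_per_cell,
      seed = if (is.null(seed)) NULL else seeds[i], ...)
  }
  structure(list(cells = cells, sigma = sigma_list, alpha = alpha_list),
            class = "d2r1_grid")
}

#' Grid cell features as a table
#'
#' @param grid a [simulate_d2r1_grid()] result.
#' @return data.frame with one row per cell: parameters, FWHM, the three
#'   features, the D2R1 retention count and the D1R1 fraction.
#' @export
grid_feature_table <- function(grid) {
  stopifnot(inherits(grid, "d2r1_grid"))
  do.call(rbind, lapply(grid$cells, function(cl) data.frame(
    sigma_R_major = cl$sigma_R_major,
    fwhm = fwhm_from_sigma(cl$sigma_R_major),
    alpha_max = cl$alpha_max,
    sigma_R = cl$features$sigma_R,
    pct_D_tophalf = cl$features$pct_D_tophalf,
    pct_R_topquad = cl$features$pct_R_topquad,
    n_d2r1 = cl$n_d2r1,
    frac_D1R1 = if ("D1R1" %in% names(cl$class_freq))
      cl$class_freq[["D1R1"]] else 0)))
}

#' Least-mean-squares fit of experimental features to the simulation grid
#'
#' Finds the grid cell whose three summary features best match the
#' experimental ones by mean squared difference. Because the features are
#' incommensurate (one length in nm, two percentages), each feature is
#' standardised by its range over the grid before squaring
#' (`standardize = FALSE` uses raw units). Ties break towards smaller sigma,
#' then smaller alpha.
#'
#' @param experimental a [d2r1_features()] (or list with `sigma_R`,
#'   `pct_D_tophalf`, `pct_R_topquad`).
#' @param grid a [simulate_d2r1_grid()] result.
#' @param standardize scale features by their grid range.
#' @return list with `sigma_R_major`, `alpha_max`, `fwhm`, `error` (mean
#'   squared standardised difference), `cell` (the winning `d2r1_cell`) and
#'   `table` (per-cell errors).
#' @export
lms_fit <- function(experimental, grid, standardize = TRUE) {
  stopifnot(inherits(grid, "d2r1_grid"))
  feat_names <- c("sigma_R", "pct_D_tophalf", "pct_R_topquad")
  fm <- t(vapply(grid$cells, function(cl)
    unlist(cl$features[feat_names]), numeric(3)))
  ex <- unlist(experimental[feat_names])
  usable <- stats::complete.cases(fm)
  if (!any(usable))
    stop("no grid cell produced usable features", call. = FALSE)
  scale <- if (standardize) {
    rg <- apply(fm[usable, , drop = FALSE], 2, function(v) diff(range(v)))
    ifelse(rg > 0, rg, 1)
  } else rep(1, 3)
  err <- rep(NA_real_, length(grid$cells))
  for (i in which(usable))
    err[i] <- mean(((fm[i, ] - ex) / scale)^2)
  sig <- vapply(grid$cells, `[[`, numeric(1), "sigma_R_major")
  alp <- vapply(grid$cells, `[[`, numeric(1), "alpha_max")
  ord <- order(err, sig, alp, na.last = TRUE)
  best <- ord[1]
  list(sigma_R_major = sig[best], alpha_max = alp[best],
       fwhm = fwhm_from_sigma(sig[best]), error = err[best],
       cell = grid$cells[[best]],
       table = data.frame(sigma_R_major = sig, alpha_max = alp,
                          error = err))
}
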