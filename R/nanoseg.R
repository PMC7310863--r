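#' Extract circular regions of interest from a localisation table
#'
#' Selects, for each ROI centre, all localisation events within `radius` nm
#' (closed disc: an event at exactly `radius` is included).
#'
#' @param table localisation table: data.frame with columns `x`, `y` (nm) and
#'   `channel`.
#' @param centres data.frame or matrix with ROI centre columns `x`, `y`
#'   (nm); optional columns `id`, `nucleus`, `stage`, `synapsis` are carried
#'   through as metadata.
#' @param radius ROI radius in nm (600 nm-diameter circles by default).
#' @return list of `roi_record` objects: `id`, `centre`, `radius`, metadata,
#'   and `events` (the member localisations, with their source row index in
#'   column `.event`).
#' @export
extract_rois <- function(table, centres, radius = 300) {
  tab <- as.data.frame(table)
  stopifnot(all(c("x", "y", "channel") %in% names(tab)))
  ctr <- as.data.frame(centres)
  out <- vector("list", nrow(ctr))
  ev_x <- tab$x; ev_y <- tab$y
  for (i in seq_len(nrow(ctr))) {
    keep <- (ev_x - ctr$x[i])^2 + (ev_y - ctr$y[i])^2 <= radius^2
    ev <- tab[keep, , drop = FALSE]
    ev$.event <- which(keep)
    out[[i]] <- structure(list(
      id = if ("id" %in% names(ctr)) ctr$id[i] else i,
      centre = c(ctr$x[i], ctr$y[i]),
      radius = radius,
      nucleus = if ("nucleus" %in% names(ctr)) ctr$nucleus[i] else NA,
      stage = if ("stage" %in% names(ctr)) as.character(ctr$stage[i]) else NA_character_,
      synapsis = if ("synapsis" %in% names(ctr)) ctr$synapsis[i] else NA,
      events = ev), class = "roi_record")
  }
  out
}

#' @export
print.roi_record <- function(x, ...) {
  cat(sprintf("ROI %s: centre (%.0f, %.0f) nm, radius %.0f nm, %d events\n",
              x$id, x$centre[1], x$centre[2], x$radius, nrow(x$events)))
  invisible(x)
}

#' Quality control of ROIs
#'
#' Applies the two exclusion rules used before segmentation: (i) ROI pairs
#' sharing more than `max_overlap` of their localisations (fraction relative
#' to the smaller ROI's event count) are both removed; (ii) ROIs with fewer
#' than `min_locs` localisations are removed (an ROI with exactly `min_locs`
#' is kept). By default the localisation floor applies to the ROI total over
#' both channels; `per_channel = TRUE` requires it per channel.
#'
#' @param rois list of `roi_record`s from one nucleus.
#' @param max_overlap overlap fraction above which both ROIs of a pair are
#'   excluded.
#' @param min_locs minimum localisation count.
#' @param per_channel apply `min_locs` per channel rather than to the total.
#' @return list with `kept` (the surviving `roi_record`s) and `log`
#'   (data.frame of exclusions: `roi_id`, `rule`, `detail`).
#' @export
roi_qc <- function(rois, max_overlap = 0.25, min_locs = 50,
                   per_channel = FALSE) {
  n <- length(rois)
  drop <- logical(n)
  log <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      shared <- length(intersect(rois[[i]]$events$.event,
                                 rois[[j]]$events$.event))
      denom <- min(nrow(rois[[i]]$events), nrow(rois[[j]]$events))
      if (denom > 0 && shared / denom > max_overlap) {
        drop[c(i, j)] <- TRUE
        frac <- shared / denom
        log[[length(log) + 1]] <- data.frame(
          roi_id = c(rois[[i]]$id, rois[[j]]$id), rule = "overlap",
          detail = sprintf("%.1f%% shared with ROI %s", 100 * frac,
                           c(rois[[j]]$id, rois[[i]]$id)))
      }
    }
  }
  for (i in seq_len(n)) {
    ev <- rois[[i]]$events
    low <- if (per_channel) {
      any(vapply(CHANNELS, function(ch) sum(ev$channel == ch), integer(1)) <
            min_locs)
    } else nrow(ev) < min_locs
    if (low) {
      drop[i] <- TRUE
      log[[length(log) + 1]] <- data.frame(
        roi_id = rois[[i]]$id, rule = "min_localisations",
        detail = sprintf("%d events < %d", nrow(ev), min_locs))
    }
  }
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(roi_id = character(0), rule = character(0),
               detail = character(0))
  list(kept = rois[!drop], log = log)
}

#' Absolute localisation density map by 2D kernel density estimation
#'
#' Evaluates the isotropic Gaussian KDE of one channel's localisations
#' exactly on a regular pixel grid (per-event kernels summed in compiled
#' code, truncated at four bandwidths; the truncated tail mass is below
#' 1e-4). The result is absolute density in events/nm^2 — the normalised
#' density scaled by the localisation count. For an ROI the grid covers the
#' ROI disc plus a margin of three bandwidths; for a plain event table the
#' grid covers the bounding box plus the same margin (or an explicit
#' `range`).
#'
#' @param roi a `roi_record`, or a data.frame of events with columns `x`,
#'   `y`, `channel`.
#' @param channel `"DMC1"` or `"RAD51"`.
#' @param bandwidth kernel SD in nm; the default 20 nm matches a typical
#'   average localisation precision.
#' @param pixel grid pixel edge in nm.
#' @param range optional list of `xlim`, `ylim` (nm) overriding the
#'   automatic grid (used to put several channels on one grid).
#' @return object of class `density_map`: grid centre vectors `x`, `y`,
#'   density matrix `mat` (`mat[i, j]` at `(x[i], y[j])`), `pixel`,
#'   `bandwidth`, event count `N` and `channel`. `sum(mat) * pixel^2` equals
#'   `N` up to kernel mass lost beyond the margin (under 1 percent for
#'   in-bounds data).
#' @export
kde_map <- function(roi, channel, bandwidth = 20, pixel = 5, range = NULL) {
  ev <- if (inherits(roi, "roi_record")) roi$events else as.data.frame(roi)
  ev <- ev[ev$channel == channel, , drop = FALSE]
  if (nrow(ev) == 0)
    stop(sprintf("no '%s' events to estimate a density from", channel),
         call. = FALSE)
  margin <- 3 * bandwidth
  if (is.null(range)) {
    if (inherits(roi, "roi_record")) {
      half <- roi$radius + margin
      range <- list(xlim = roi$centre[1] + c(-half, half),
                    ylim = roi$centre[2] + c(-half, half))
    } else {
      range <- list(xlim = c(min(ev$x) - margin, max(ev$x) + margin),
                    ylim = c(min(ev$y) - margin, max(ev$y) + margin))
    }
  }
  gx <- seq_grid(range$xlim, pixel)
  gy <- seq_grid(range$ylim, pixel)
  mat <- cpp_kde2d(ev$x, ev$y, gx, gy, bandwidth,
                   as.integer(ceiling(4 * bandwidth / pixel)))
  structure(list(x = gx, y = gy, mat = mat, pixel = pixel,
                 bandwidth = bandwidth, N = nrow(ev), channel = channel),
            class = "density_map")
}

# regular grid of pixel centres covering lim, spacing exactly `pixel`
#' @noRd
seq_grid <- function(lim, pixel) {
  n <- max(2L, ceiling(diff(lim) / pixel) + 1L)
  seq(lim[1], by = pixel, length.out = n)
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("density_map: %d x %d px (%.0f nm), %s, N = %d, peak %.3g /nm^2\n",
              length(x$x), length(x$y), x$pixel, x$channel, x$N, max(x$mat)))
  invisible(x)
}

#' Segment a density map into nanofoci
#'
#' Thresholds the density map and keeps connected components (8-connected by
#' default) covering at least `min_area` pixels; smaller components are
#' considered background. Each retained component becomes a nanofocus with
#' its binary pixel mask, area, density-weighted centre of mass, member
#' localisation count, and shape moments.
#'
#' The default threshold corresponds to 5 localisations per (100 nm)^2
#' camera-pixel area, i.e. 5e-4 events/nm^2; see the methods vignette for
#' the calibration of this value against per-nanofocus localisation counts
#' (with a 20 nm bandwidth a cluster of N localisations cannot exceed
#' `N/(2*pi*400)` per nm^2, so meaningful absolute thresholds are well below
#' that bound for 50-600-event nanofoci). The threshold is an explicit
#' argument everywhere; [density_from_per_pixel()] converts per-pixel counts.
#'
#' @param density a [kde_map()] result.
#' @param threshold absolute density threshold, events/nm^2.
#' @param min_area minimum component area in pixels.
#' @param events optional data.frame of the ROI's events (columns `x`, `y`,
#'   `channel`) used to count member localisations per nanofocus.
#' @param connectivity 8 (diagonal touching merges) or 4.
#' @return list of `nanofocus` objects (possibly empty), with the grid
#'   stored in attribute `"grid"`. Each nanofocus has `channel`, `mask`
#'   (logical matrix on the map grid), `area_px`, `area_nm2`, `com` (nm),
#'   `n_localisations` (`NA` when `events` is absent), `sigma_major` (nm)
#'   and `eccentricity`.
#' @export
segment_nanofoci <- function(density, threshold = density_from_per_pixel(5, 100),
                             min_area = 50, events = NULL,
                             connectivity = 8) {
  stopifnot(inherits(density, "density_map"))
  bin <- density$mat >= threshold
  lab <- cpp_label_components(bin, as.integer(connectivity))
  ids <- setdiff(sort(unique(as.integer(lab))), 0L)
  out <- list()
  if (!is.null(events)) {
    ev <- as.data.frame(events)
    ev <- ev[ev$channel == density$channel, , drop = FALSE]
    ei <- pmin(pmax(round((ev$x - density$x[1]) / density$pixel) + 1L, 1L),
               length(density$x))
    ej <- pmin(pmax(round((ev$y - density$y[1]) / density$pixel) + 1L, 1L),
               length(density$y))
  }
  for (id in ids) {
    mask <- lab == id
    npx <- sum(mask)
    if (npx < min_area) next
    w <- density$mat[mask]
    idx <- which(mask, arr.ind = TRUE)
    px <- density$x[idx[, 1]]; py <- density$y[idx[, 2]]
    com <- c(sum(px * w), sum(py * w)) / sum(w)
    # density-weighted second moments
    cxx <- sum(w * (px - com[1])^2) / sum(w)
    cyy <- sum(w * (py - com[2])^2) / sum(w)
    cxy <- sum(w * (px - com[1]) * (py - com[2])) / sum(w)
    eig <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2), symmetric = TRUE)$values
    eig <- pmax(eig, 0)
    n_loc <- if (is.null(events)) NA_integer_ else
      sum(mask[cbind(ei, ej)])
    out[[length(out) + 1]] <- structure(list(
      channel = density$channel, mask = mask, area_px = npx,
      area_nm2 = npx * density$pixel^2, com = com,
      n_localisations = n_loc,
      sigma_major = sqrt(eig[1]),
      eccentricity = if (eig[1] > 0) sqrt(1 - eig[2] / eig[1]) else 0),
      class = "nanofocus")
  }
  attr(out, "grid") <- list(x = density$x, y = density$y,
                            pixel = density$pixel)
  out
}

#' @export
print.nanofocus <- function(x, ...) {
  cat(sprintf(
    "nanofocus [%s]: %d px (%.0f nm^2), com (%.0f, %.0f) nm, %s locs\n",
    x$channel, x$area_px, x$area_nm2, x$com[1], x$com[2],
    ifelse(is.na(x$n_localisations), "?", x$n_localisations)))
  invisible(x)
}

#' Segment both channels of one ROI (or event table) on a common grid
#'
#' Convenience wrapper running [kde_map()] and [segment_nanofoci()] for DMC1
#' and RAD51 on the same pixel grid, so that masks are directly comparable
#' for overlap-based morphology. A channel with no events contributes no
#' nanofoci.
#'
#' @inheritParams kde_map
#' @inheritParams segment_nanofoci
#' @return list of `nanofocus` objects over both channels, with attribute
#'   `"grid"`.
#' @export
segment_roi_channels <- function(roi, bandwidth = 20, pixel = 5,
                                 threshold = density_from_per_pixel(5, 100),
                                 min_area = 50, connectivity = 8,
                                 range = NULL) {
  ev <- if (inherits(roi, "roi_record")) roi$events else as.data.frame(roi)
  if (is.null(range)) {
    if (inherits(roi, "roi_record")) {
      half <- roi$radius + 3 * bandwidth
      range <- list(xlim = roi$centre[1] + c(-half, half),
                    ylim = roi$centre[2] + c(-half, half))
    } else {
      m <- 3 * bandwidth
      range <- list(xlim = c(min(ev$x) - m, max(ev$x) + m),
                    ylim = c(min(ev$y) - m, max(ev$y) + m))
    }
  }
  out <- list()
  grid <- NULL
  for (ch in CHANNELS) {
    if (!any(ev$channel == ch)) next
    dm <- kde_map(ev, ch, bandwidth = bandwidth, pixel = pixel,
                  range = range)
    nf <- segment_nanofoci(dm, threshold = threshold, min_area = min_area,
                           events = ev, connectivity = connectivity)
    grid <- attr(nf, "grid")
    out <- c(out, nf)
  }
  attr(out, "grid") <- grid
  out
}
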