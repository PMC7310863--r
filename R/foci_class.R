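#' Per-focus configuration of segmented nanofoci
#'
#' Bundles the nanofoci segmented inside one ROI with the derived analytics:
#' the DxRy label, minimum and maximum inter-nanofocus distances, close/far
#' roles (for D2R1 and D1R2) and the rule-based morphology class.
#'
#' @param nanofoci list of `nanofocus` objects on one common grid (e.g. from
#'   [segment_roi_channels()]).
#' @param roi optional `roi_record` supplying `id`, `stage`, `synapsis`,
#'   `nucleus` metadata.
#' @return object of class `focus_configuration` with fields `nanofoci`,
#'   `n_D`, `n_R`, `label`, `min_dist`, `max_dist`, `pairs`, `roles`,
#'   `morphology` plus ROI metadata. Distances are `NA` when a channel is
#'   absent; roles are `NA` except for D2R1/D1R2.
#' @export
focus_configuration <- function(nanofoci, roi = NULL) {
  grid <- attr(nanofoci, "grid")
  ch <- vapply(nanofoci, function(f) f$channel, character(1))
  cfg <- structure(list(
    nanofoci = nanofoci,
    n_D = sum(ch == "DMC1"), n_R = sum(ch == "RAD51"),
    roi_id = if (!is.null(roi)) roi$id else NA,
    stage = if (!is.null(roi)) roi$stage else NA_character_,
    synapsis = if (!is.null(roi)) roi$synapsis else NA,
    nucleus = if (!is.null(roi)) roi$nucleus else NA),
    class = "focus_configuration")
  cfg$label <- classify_dxry(cfg)
  if (cfg$n_D >= 1 && cfg$n_R >= 1) {
    dd <- inter_channel_distances(cfg)
    cfg$min_dist <- dd$min_dist
    cfg$max_dist <- dd$max_dist
    cfg$pairs <- dd$pairs
  } else {
    cfg$min_dist <- NA_real_
    cfg$max_dist <- NA_real_
    cfg$pairs <- NULL
  }
  cfg$roles <- if (cfg$label %in% c("D2R1", "D1R2"))
    assign_close_far(cfg) else rep(NA_character_, length(nanofoci))
  cfg$morphology <- if (length(nanofoci) >= 1)
    classify_morphology(cfg) else "unclassified"
  cfg
}

#' @export
print.focus_configuration <- function(x, ...) {
  cat(sprintf("focus configuration %s (%s): min %.0f nm, max %.0f nm\n",
              x$label, x$morphology, x$min_dist, x$max_dist))
  invisible(x)
}

#' DxRy configuration label
#'
#' Counts nanofoci per channel and labels the focus `"D<n_D>R<n_R>"` (e.g.
#' two DMC1 and one RAD51 nanofocus give `"D2R1"`). Reporting collapses
#' labels outside D1R1 / D2R1 / D1R2 / D2R2 into a rest class, but the label
#' itself always carries the exact counts.
#'
#' @param config a [focus_configuration()], or a plain list of `nanofocus`
#'   objects.
#' @return character label.
#' @export
classify_dxry <- function(config) {
  if (inherits(config, "focus_configuration"))
    return(sprintf("D%dR%d", config$n_D, config$n_R))
  ch <- vapply(config, function(f) f$channel, character(1))
  sprintf("D%dR%d", sum(ch == "DMC1"), sum(ch == "RAD51"))
}

#' Collapse a DxRy label for summaries
#'
#' @param label DxRy label(s).
#' @return the label itself for D1R1/D2R1/D1R2/D2R2, `"rest"` otherwise.
#' @export
dxry_summary_label <- function(label) {
  ifelse(label %in% c("D1R1", "D2R1", "D1R2", "D2R2"), label, "rest")
}

#' Minimum and maximum inter-nanofocus distances
#'
#' The minimum is taken over DMC1-RAD51 (inter-channel) centre-of-mass
#' pairs; the maximum is taken over all nanofocus pairs in the ROI,
#' including same-channel pairs. For a D1R1 focus the two coincide.
#'
#' @param config a [focus_configuration()] (or list of `nanofocus`) with at
#'   least one nanofocus in each channel.
#' @return list with `min_dist`, `max_dist` (nm) and `pairs`, a data.frame
#'   of all pairwise centre distances (`i`, `j`, `channel_i`, `channel_j`,
#'   `dist`).
#' @export
inter_channel_distances <- function(config) {
  foci <- if (inherits(config, "focus_configuration")) config$nanofoci
          else config
  ch <- vapply(foci, function(f) f$channel, character(1))
  if (!any(ch == "DMC1") || !any(ch == "RAD51"))
    stop("inter-channel minimum undefined: a channel has no nanofocus",
         call. = FALSE)
  n <- length(foci)
  cx <- vapply(foci, function(f) f$com[1], numeric(1))
  cy <- vapply(foci, function(f) f$com[2], numeric(1))
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- sqrt((cx[pr[, 1]] - cx[pr[, 2]])^2 + (cy[pr[, 1]] - cy[pr[, 2]])^2)
  pairs <- data.frame(i = pr[, 1], j = pr[, 2],
                      channel_i = ch[pr[, 1]], channel_j = ch[pr[, 2]],
                      dist = d)
  inter <- pairs$channel_i != pairs$channel_j
  list(min_dist = min(pairs$dist[inter]),
       max_dist = max(pairs$dist),
       pairs = pairs)
}

#' Close/far roles in D2R1 and D1R2 configurations
#'
#' In a focus with a duplicated channel, the duplicated-channel nanofocus
#' realising the inter-channel minimum distance is "close", the other "far";
#' the singleton channel's nanofocus is "single". Ties (equidistant) go to
#' the larger-area nanofocus, then to the lower index.
#'
#' @param config a [focus_configuration()] labelled D2R1 or D1R2.
#' @return character vector of roles aligned with `config$nanofoci`.
#' @export
assign_close_far <- function(config) {
  stopifnot(inherits(config, "focus_configuration"))
  if (!config$label %in% c("D2R1", "D1R2"))
    stop("close/far roles are defined for D2R1 and D1R2 only (got ",
         config$label, ")", call. = FALSE)
  foci <- config$nanofoci
  ch <- vapply(foci, function(f) f$channel, character(1))
  dup_ch <- if (config$label == "D2R1") "DMC1" else "RAD51"
  single_i <- which(ch != dup_ch)
  dup_i <- which(ch == dup_ch)
  sc <- foci[[single_i]]$com
  d <- vapply(dup_i, function(i)
    sqrt(sum((foci[[i]]$com - sc)^2)), numeric(1))
  area <- vapply(dup_i, function(i) foci[[i]]$area_px, numeric(1))
  ord <- order(d, -area, dup_i)
  roles <- rep(NA_character_, length(foci))
  roles[single_i] <- "single"
  roles[dup_i[ord[1]]] <- "close"
  roles[dup_i[ord[2]]] <- "far"
  roles
}

# >=1 shared pixel between two nanofocus masks on the same grid
#' @noRd
masks_overlap <- function(a, b) {
  if (!identical(dim(a$mask), dim(b$mask)))
    stop("nanofocus masks are on different grids", call. = FALSE)
  any(a$mask & b$mask)
}

#' Rule-based morphology classification
#'
#' Deterministic surrogate for manual morphology calls, computed from the
#' inter-channel overlap graph (nanofoci are nodes; sharing at least one
#' mask pixel makes an edge) and shape criteria:
#' \describe{
#'   \item{bridge_D2R1}{one RAD51 nanofocus overlaps two or more DMC1
#'     nanofoci (DMC1-RAD51-DMC1 connection).}
#'   \item{bridge_D1R2}{one DMC1 nanofocus overlaps two or more RAD51
#'     nanofoci.}
#'   \item{separate}{no inter-channel overlaps at all.}
#'   \item{paired}{two or more disjoint DMC1-RAD51 overlapping twin pairs.}
#'   \item{simple}{exactly one overlapping pair, both partners "major"
#'     (area at least `major_frac` of the largest same-channel nanofocus)
#'     and both round (eccentricity at most `round_ecc`).}
#'   \item{complex}{as simple, but at least one partner fails roundness.}
#'   \item{unclassified}{anything else (e.g. a single satellite-involving
#'     overlap).}
#' }
#'
#' @param config a [focus_configuration()] (or list of `nanofocus`).
#' @param major_frac area fraction of the largest same-channel nanofocus at
#'   or above which a nanofocus counts as "major".
#' @param round_ecc eccentricity at or below which a mask counts as round.
#' @return one morphology class string.
#' @export
classify_morphology <- function(config, major_frac = 0.5, round_ecc = 0.85) {
  foci <- if (inherits(config, "focus_configuration")) config$nanofoci
          else config
  ch <- vapply(foci, function(f) f$channel, character(1))
  di <- which(ch == "DMC1"); ri <- which(ch == "RAD51")
  if (length(foci) == 0) return("unclassified")
  if (length(di) == 0 || length(ri) == 0) return("separate")
  ov <- matrix(FALSE, length(di), length(ri))
  for (a in seq_along(di)) for (b in seq_along(ri))
    ov[a, b] <- masks_overlap(foci[[di[a]]], foci[[ri[b]]])
  if (any(colSums(ov) >= 2)) return("bridge_D2R1")
  if (any(rowSums(ov) >= 2)) return("bridge_D1R2")
  if (!any(ov)) return("separate")
  npairs <- sum(ov)  # degrees are all <= 1 here, so edges form a matching
  if (npairs >= 2) return("paired")
  pair <- which(ov, arr.ind = TRUE)
  d <- foci[[di[pair[1, 1]]]]; r <- foci[[ri[pair[1, 2]]]]
  areas_d <- vapply(foci[di], function(f) f$area_px, numeric(1))
  areas_r <- vapply(foci[ri], function(f) f$area_px, numeric(1))
  major <- d$area_px >= major_frac * max(areas_d) &&
    r$area_px >= major_frac * max(areas_r)
  if (!major) return("unclassified")
  if (d$eccentricity <= round_ecc && r$eccentricity <= round_ecc)
    "simple" else "complex"
}

#' Shortest distance from a nanofocus to the chromosome axes
#'
#' Minimum point-to-segment distance from a nanofocus centre of mass (or a
#' plain point) to a set of axis polylines. Nanofoci farther than `cutoff`
#' (1 um) are flagged as not near an axis.
#'
#' @param x a `nanofocus` or a numeric `c(x, y)` in nm.
#' @param polylines list of numeric matrices (columns x, y in nm, at least
#'   two vertices each).
#' @param cutoff distance (nm) above which the focus is not near an axis.
#' @return list with `distance` (nm) and `near_axis` (logical).
#' @export
axis_min_distance <- function(x, polylines, cutoff = 1000) {
  p <- if (inherits(x, "nanofocus")) x$com else as.numeric(x)
  if (length(polylines) == 0)
    stop("no axis polylines supplied", call. = FALSE)
  best <- Inf
  for (poly in polylines) {
    poly <- as.matrix(poly)
    for (s in seq_len(nrow(poly) - 1)) {
      a <- poly[s, ]; b <- poly[s + 1, ]
      ab <- b - a
      len2 <- sum(ab^2)
      t <- if (len2 > 0) max(0, min(1, sum((p - a) * ab) / len2)) else 0
      proj <- a + t * ab
      best <- min(best, sqrt(sum((p - proj)^2)))
    }
  }
  list(distance = best, near_axis = best <= cutoff)
}

#' Flatten focus configurations into a summary table
#'
#' @param configs list of [focus_configuration()]s.
#' @return data.frame with one row per configuration: ROI metadata, label,
#'   collapsed summary label, morphology, distances and channel counts.
#' @export
configuration_table <- function(configs) {
  do.call(rbind, lapply(configs, function(cf) data.frame(
    roi_id = cf$roi_id, nucleus = cf$nucleus, stage = cf$stage,
    synapsis = cf$synapsis, n_D = cf$n_D, n_R = cf$n_R,
    label = cf$label, summary_label = dxry_summary_label(cf$label),
    morphology = cf$morphology,
    min_dist = cf$min_dist, max_dist = cf$max_dist,
    stringsAsFactors = FALSE)))
}
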