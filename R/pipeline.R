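#' Pipeline configuration
#'
#' All tunables of the dSTORM analysis chain in one place, with their
#' defaults: KDE bandwidth 20 nm on a 5 nm grid, segmentation threshold
#' 5e-4 events/nm^2 (5 localisations per 100 nm camera-pixel area; see the
#' methods vignette for the calibration), 50-pixel minimum area, 300 nm ROI
#' radius, 25 percent ROI-overlap cutoff, 50-localisation ROI floor,
#' confocal detection tolerances 90 (DMC1) and 100 (RAD51), 110 nm PSF
#' blur, 100 nm distance bins with a 3.4 um rest class, 1 um axis cutoff,
#' 50 random placements per CSR test and 200 configurations per simulation
#' grid cell.
#'
#' @param ... named overrides of any default.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    kde_bandwidth = 20, pixel = 5,
    threshold = density_from_per_pixel(5, 100),
    min_area = 50, roi_radius = 300,
    max_overlap = 0.25, min_locs = 50,
    noise_tolerance_dmc1 = 90, noise_tolerance_rad51 = 100,
    blur_sigma = 110, confocal_pixel = 99,
    bin_width = 100, rest_from = 3400, axis_cutoff = 1000,
    n_sims = 50, n_per_cell = 200, seed = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  num <- cfg[setdiff(names(cfg), "seed")]
  if (any(!vapply(num, function(v) is.numeric(v) && v > 0, logical(1))))
    stop("all config values must be positive numbers", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Run the dSTORM analysis pipeline end to end
#'
#' Reads (or accepts) a localisation table and ROI centres, extracts
#' 300 nm-radius ROIs, applies quality control, segments nanofoci, builds
#' per-ROI configurations, optionally measures axis distances, and writes a
#' results directory: the echoed configuration (`config.json`), the per-ROI
#' configuration table (`configurations.tsv`), the per-nanofocus feature
#' table (`nanofoci.tsv`), the QC exclusion log (`exclusions.tsv`) and a
#' machine-readable summary of per-stage DxRy fractions (`summary.json`).
#' Outputs written before a failure are removed.
#'
#' @param localizations localisation table (data.frame) or path to one.
#' @param roi_centres ROI centre table (data.frame) or path.
#' @param out_dir output directory (created if needed).
#' @param config a [pipeline_config()].
#' @param polylines optional axis polylines (list of matrices) or JSON path.
#' @return (invisibly) a list with `configurations` (list of
#'   [focus_configuration()]s), `table`, `summary` and `out_dir`.
#' @export
run_pipeline <- function(localizations, roi_centres, out_dir,
                         config = pipeline_config(), polylines = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  locs <- if (is.character(localizations)) read_localizations(localizations)
          else as.data.frame(localizations)
  ctrs <- if (is.character(roi_centres)) read_roi_centres(roi_centres)
          else as.data.frame(roi_centres)
  axes <- if (is.character(polylines)) read_polylines(polylines)
          else polylines
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_fail <- function(e) {
    file.remove(written[file.exists(written)])
    stop(e)
  }
  tryCatch({
    rois <- extract_rois(locs, ctrs, radius = config$roi_radius)
    qc <- roi_qc(rois, max_overlap = config$max_overlap,
                 min_locs = config$min_locs)
    configs <- lapply(qc$kept, function(roi) {
      nf <- segment_roi_channels(
        roi, bandwidth = config$kde_bandwidth, pixel = config$pixel,
        threshold = config$threshold, min_area = config$min_area)
      focus_configuration(nf, roi)
    })
    tab <- if (length(configs)) configuration_table(configs) else
      data.frame()
    if (!is.null(axes) && length(configs)) {
      ax <- t(vapply(configs, function(cf) {
        if (length(cf$nanofoci) == 0) return(c(NA_real_, NA))
        d <- vapply(cf$nanofoci, function(f)
          axis_min_distance(f, axes, cutoff = config$axis_cutoff)$distance,
          numeric(1))
        c(min(d), min(d) <= config$axis_cutoff)
      }, numeric(2)))
      tab$axis_dist <- ax[, 1]
      tab$near_axis <- as.logical(ax[, 2])
    }
    nf_rows <- do.call(rbind, lapply(configs, function(cf) {
      if (length(cf$nanofoci) == 0) return(NULL)
      do.call(rbind, lapply(seq_along(cf$nanofoci), function(i) {
        f <- cf$nanofoci[[i]]
        data.frame(roi_id = cf$roi_id, channel = f$channel,
                   role = cf$roles[i], area_nm2 = f$area_nm2,
                   com_x = f$com[1], com_y = f$com[2],
                   n_localisations = f$n_localisations,
                   sigma_major = f$sigma_major,
                   eccentricity = f$eccentricity)
      }))
    }))
    smry <- list(n_rois = length(rois), n_kept = length(qc$kept),
                 dxry_fractions = dxry_stage_fractions(tab),
                 seed = config$seed)

    p <- file.path(out_dir, "config.json")
    jsonlite::write_json(unclass(config), p, auto_unbox = TRUE,
                         digits = NA, null = "null")
    written <- c(written, p)
    p <- file.path(out_dir, "configurations.tsv")
    write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, p)
    p <- file.path(out_dir, "nanofoci.tsv")
    write.table(if (is.null(nf_rows)) data.frame() else nf_rows, p,
                sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, p)
    p <- file.path(out_dir, "exclusions.tsv")
    write.table(qc$log, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, p)
    p <- file.path(out_dir, "summary.json")
    jsonlite::write_json(smry, p, auto_unbox = TRUE, digits = NA,
                         null = "null")
    written <- c(written, p)
    invisible(list(configurations = configs, table = tab, summary = smry,
                   out_dir = out_dir))
  }, error = on_fail)
}

# per-stage fractions of the collapsed DxRy labels
#' @noRd
dxry_stage_fractions <- function(tab) {
  if (nrow(tab) == 0) return(list())
  stages <- unique(ifelse(is.na(tab$stage), "all", tab$stage))
  out <- list()
  for (st in stages) {
    sub <- tab[ifelse(is.na(tab$stage), "all", tab$stage) == st, ]
    f <- table(sub$summary_label) / nrow(sub)
    out[[st]] <- as.list(setNames(as.numeric(f), names(f)))
  }
  out
}

#' Group comparisons over per-nucleus (or per-focus) values
#'
#' Thin wrapper over Student's t-test, the paired t-test and the
#' Mann-Whitney U test for comparing feature values between groups (e.g.
#' meiotic stages, or synapsed versus unsynapsed axes within nuclei). All
#' pairwise group comparisons are reported; groups with fewer than two
#' values are skipped with a note. No multiple-testing correction is
#' applied. For a paired design with constant non-zero differences (zero
#' variance) the t statistic diverges and the p-value is reported as 0.
#'
#' @param values numeric vector of observations.
#' @param groups group label per observation.
#' @param test `"t"` or `"wilcox"` (Mann-Whitney U).
#' @param paired paired design (observations matched by position within
#'   each group).
#' @return data.frame with `group1`, `group2`, `test`, `statistic`,
#'   `p.value`, `note`.
#' @export
compare_groups <- function(values, groups, test = c("t", "wilcox"),
                           paired = FALSE) {
  test <- match.arg(test)
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) < 2) stop("need at least two groups", call. = FALSE)
  rows <- list()
  for (i in seq_len(length(lv) - 1)) for (j in (i + 1):length(lv)) {
    a <- values[groups == lv[i]]
    b <- values[groups == lv[j]]
    nm <- if (test == "wilcox") "Mann-Whitney U" else
      if (paired) "paired t" else "two-sample t"
    if (length(a) < 2 || length(b) < 2 ||
        (paired && length(a) != length(b))) {
      rows[[length(rows) + 1]] <- data.frame(
        group1 = lv[i], group2 = lv[j], test = nm,
        statistic = NA_real_, p.value = NA_real_,
        note = "skipped: group size < 2 or unpaired lengths")
      next
    }
    res <- if (test == "wilcox") {
      w <- suppressWarnings(wilcox.test(a, b, paired = paired))
      data.frame(statistic = unname(w$statistic), p.value = w$p.value,
                 note = "")
    } else {
      tryCatch({
        tt <- t.test(a, b, paired = paired)
        data.frame(statistic = unname(tt$statistic), p.value = tt$p.value,
                   note = "")
      }, error = function(e) {
        if (paired && sd(a - b) < .Machine$double.eps^0.5 &&
            mean(a - b) != 0)
          data.frame(statistic = Inf, p.value = 0,
                     note = "constant non-zero paired difference")
        else data.frame(statistic = NA_real_, p.value = NA_real_,
                        note = conditionMessage(e))
      })
    }
    rows[[length(rows) + 1]] <- cbind(
      data.frame(group1 = lv[i], group2 = lv[j], test = nm), res)
  }
  do.call(rbind, rows)
}
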