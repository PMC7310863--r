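# Readers and writers for the delimited-text / TIFF / JSON interfaces.

#' Read a localisation table
#'
#' Tab- or comma-delimited text with named columns. Coordinate columns may
#' be called `x`/`y` or `x_nm`/`y_nm` (nm); `channel` is required; optional
#' `z`/`z_nm`, `frame`, `precision`, `focus_id` are carried through.
#'
#' @param path file path.
#' @return data.frame with columns `x`, `y`, `channel` (+ optional extras).
#' @export
read_localizations <- function(path) {
  if (!file.exists(path))
    stop("cannot read localisation file: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- tryCatch(read.delim(path, sep = sep, stringsAsFactors = FALSE),
                  error = function(e)
                    stop("corrupt localisation file: ", path, call. = FALSE))
  for (nm in c("x", "y", "z"))
    if (!nm %in% names(tab) && paste0(nm, "_nm") %in% names(tab))
      names(tab)[names(tab) == paste0(nm, "_nm")] <- nm
  if (!all(c("x", "y", "channel") %in% names(tab)) ||
      !is.numeric(tab$x) || !is.numeric(tab$y) ||
      any(!is.finite(tab$x)) || any(!is.finite(tab$y)))
    stop("corrupt localisation file: ", path, call. = FALSE)
  tab
}

#' Write a localisation table
#'
#' @param table data.frame with `x`, `y`, `channel` (+ extras).
#' @param path output path; tab-delimited with `x_nm`/`y_nm` headers.
#' @export
write_localizations <- function(table, path) {
  out <- as.data.frame(table)
  names(out)[names(out) == "x"] <- "x_nm"
  names(out)[names(out) == "y"] <- "y_nm"
  if ("z" %in% names(out)) names(out)[names(out) == "z"] <- "z_nm"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read ROI centres
#'
#' Delimited text with columns `x`/`x_nm`, `y`/`y_nm` and optional `id`,
#' `nucleus`, `stage`, `synapsis`.
#'
#' @param path file path.
#' @return data.frame of centres.
#' @export
read_roi_centres <- function(path) {
  if (!file.exists(path))
    stop("cannot read ROI centre file: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- tryCatch(read.delim(path, sep = sep, stringsAsFactors = FALSE),
                  error = function(e)
                    stop("corrupt ROI centre file: ", path, call. = FALSE))
  for (nm in c("x", "y"))
    if (!nm %in% names(tab) && paste0(nm, "_nm") %in% names(tab))
      names(tab)[names(tab) == paste0(nm, "_nm")] <- nm
  if (!all(c("x", "y") %in% names(tab)))
    stop("corrupt ROI centre file: ", path, call. = FALSE)
  tab
}

#' Read axis polylines from JSON
#'
#' JSON array of polylines, each an array of `[x, y]` vertex pairs in nm.
#'
#' @param path file path.
#' @return list of two-column matrices.
#' @export
read_polylines <- function(path) {
  if (!file.exists(path))
    stop("cannot read polyline file: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(p)
    do.call(rbind, lapply(p, function(v) as.numeric(unlist(v)))))
}

#' Write axis polylines to JSON
#'
#' @param polylines list of two-column matrices (nm).
#' @param path output path.
#' @export
write_polylines <- function(polylines, path) {
  jsonlite::write_json(lapply(polylines, unname), path, digits = NA)
  invisible(path)
}

#' Read a binary mask from TIFF
#'
#' @param path TIFF path; pixel values above 0.5 (after the reader's 0-1
#'   scaling) are mask-true.
#' @return logical matrix in this package's `[x, y]` orientation.
#' @export
read_mask_tiff <- function(path) {
  if (!file.exists(path)) stop("cannot read mask: ", path, call. = FALSE)
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  t(m) > 0.5
}

#' Write an image (or mask) to TIFF
#'
#' Intensities are scaled to the 0-1 range expected by the TIFF writer
#' (masks are written as 0/1).
#'
#' @param img numeric or logical matrix in `[x, y]` orientation.
#' @param path output path.
#' @export
write_image_tiff <- function(img, path) {
  m <- t(img * 1)
  mx <- max(m)
  if (mx > 1) m <- m / mx
  tiff::writeTIFF(m, path, bits.per.sample = 32L)
  invisible(path)
}
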