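# internal helpers

#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Deterministic substream seeds (kept < 2^31) so that per-focus / per-cell
# randomness is reproducible independently of evaluation order.
#' @noRd
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

#' @noRd
stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  invisible(x)
}

#' Per-pixel count to absolute density conversion
#'
#' Converts a segmentation threshold expressed as localisations per pixel into
#' absolute density (localisations per nm^2) given the pixel edge length:
#' `count / pixel^2`. For example 5 localisations per 5 nm pixel equals
#' 0.2 localisations/nm^2, and 5 localisations per 100 nm camera pixel equals
#' 5e-4 localisations/nm^2.
#'
#' @param count localisations per pixel.
#' @param pixel_size pixel edge length in nm.
#' @return density in events/nm^2.
#' @export
#' @examples
#' density_from_per_pixel(5, 5)    # 0.2
#' density_from_per_pixel(5, 100)  # 5e-4
density_from_per_pixel <- function(count, pixel_size) {
  stopifnot_scalar_pos(pixel_size, "pixel_size")
  count / pixel_size^2
}

#' Gaussian FWHM conversion factor
#'
#' Full width at half maximum of a Gaussian profile is `2*sqrt(2*log(2))`
#' (about 2.355) times its standard deviation.
#'
#' @param sigma standard deviation (nm).
#' @return FWHM in the units of `sigma`.
#' @export
fwhm_from_sigma <- function(sigma) 2 * sqrt(2 * log(2)) * sigma
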