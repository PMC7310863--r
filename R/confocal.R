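#' Detect foci as intensity maxima with a prominence criterion
#'
#' Local maxima are accepted when they stand out from their surroundings by
#' more than `noise_tolerance`: flooding down from a candidate maximum, the
#' candidate is rejected if it connects to a higher maximum before dropping
#' `noise_tolerance` below its own level (the ImageJ "Find Maxima" dialect).
#' Each accepted focus is reported as a single pixel. On an equal-valued
#' plateau the reported pixel is the plateau pixel closest to the plateau
#' centroid, ties broken by column-major scan order.
#'
#' @param image numeric matrix; entry `[i, j]` is the pixel with x-index `i`
#'   and y-index `j`.
#' @param noise_tolerance minimum prominence (strict) for an accepted
#'   maximum.
#' @return data.frame with columns `x`, `y` (pixel indices), `value`,
#'   `prominence`, ordered by decreasing value.
#' @export
find_maxima <- function(image, noise_tolerance) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("'image' must be a 2D numeric matrix", call. = FALSE)
  res <- cpp_find_maxima(image, noise_tolerance)
  if (nrow(res) == 0)
    return(data.frame(x = integer(0), y = integer(0), value = numeric(0),
                      prominence = numeric(0)))
  # recentre plateau maxima
  nr <- nrow(image); nc <- ncol(image)
  for (k in seq_len(nrow(res))) {
    r <- res$row[k]; c <- res$col[k]; v <- res$value[k]
    nb <- expand.grid(dr = -1:1, dc = -1:1)
    nb <- nb[!(nb$dr == 0 & nb$dc == 0), ]
    has_eq <- any(vapply(seq_len(nrow(nb)), function(i) {
      rr <- r + nb$dr[i]; cc <- c + nb$dc[i]
      rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && image[rr, cc] == v
    }, logical(1)))
    if (!has_eq) next
    plat <- plateau_pixels(image, r, c)
    ctr <- colMeans(plat)
    d2 <- (plat[, 1] - ctr[1])^2 + (plat[, 2] - ctr[2])^2
    best <- plat[order(d2, (plat[, 2] - 1) * nr + plat[, 1])[1], ]
    res$row[k] <- best[1]; res$col[k] <- best[2]
  }
  out <- data.frame(x = res$row, y = res$col, value = res$value,
                    prominence = res$prominence)
  out[order(-out$value, out$x, out$y), , drop = FALSE]
}

# BFS over the connected set of pixels equal to image[r0, c0]
#' @noRd
plateau_pixels <- function(image, r0, c0) {
  v <- image[r0, c0]
  lab <- cpp_label_components(image == v, 8L)
  idx <- which(lab == lab[r0, c0], arr.ind = TRUE)
  unname(idx)
}

#' Keep only foci lying on a binary mask
#'
#' @param points data.frame with pixel columns `x`, `y`.
#' @param mask logical (or 0/1) matrix on the same pixel grid as the image
#'   the points were detected in.
#' @return the subset of `points` whose pixel is mask-true.
#' @export
mask_filter <- function(points, mask) {
  if (!is.matrix(mask)) stop("'mask' must be a matrix", call. = FALSE)
  mask <- mask > 0
  pts <- as.data.frame(points)
  if (nrow(pts) == 0) return(pts)
  if (any(pts$x < 1 | pts$x > nrow(mask) | pts$y < 1 | pts$y > ncol(mask)))
    stop("points fall outside the mask grid (grid mismatch?)", call. = FALSE)
  keep <- mask[cbind(pts$x, pts$y)]
  pts[keep, , drop = FALSE]
}

#' Nearest-neighbour distances between two point sets
#'
#' For each point of `a`, the minimum Euclidean distance to the points of
#' `b`, scaled by `pixel_size` to nm. When `exclude_self = TRUE`, `a` and
#' `b` are taken to be the same set (matched row for row) and each point's
#' own entry is excluded.
#'
#' @param a,b data.frames with columns `x`, `y` (same units).
#' @param exclude_self exclude the index-matched point (requires `a` and `b`
#'   to be the same set).
#' @param pixel_size multiplier converting coordinate units to nm (1 if the
#'   coordinates are already in nm).
#' @return numeric vector of length `nrow(a)`, distances in nm.
#' @export
nn_distances <- function(a, b = a, exclude_self = FALSE, pixel_size = 1) {
  a <- as.data.frame(a); b <- as.data.frame(b)
  if (nrow(a) == 0) stop("'a' must be nonempty", call. = FALSE)
  if (nrow(b) == 0) stop("'b' must be nonempty", call. = FALSE)
  if (exclude_self && nrow(b) < 2)
    stop("need at least 2 points for self-excluding nearest neighbours",
         call. = FALSE)
  d2 <- outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2
  if (exclude_self) {
    if (nrow(a) != nrow(b))
      stop("'exclude_self' requires a and b to be the same set",
           call. = FALSE)
    diag(d2) <- Inf
  }
  sqrt(apply(d2, 1, min)) * pixel_size
}

#' Bin nearest-neighbour distances
#'
#' Half-open 100 nm bins `[k*100, (k+1)*100)` up to `rest_from`; distances
#' of `rest_from` (3.4 um by default) and above are pooled as "rest".
#'
#' @param d distances in nm.
#' @param bin_width bin width in nm.
#' @param rest_from lower edge (nm) of the "rest" class.
#' @return list with `bin_edges` (left edges), `counts` and `rest_count`;
#'   `sum(counts) + rest_count == length(d)`.
#' @export
nn_histogram <- function(d, bin_width = 100, rest_from = 3400) {
  edges <- seq(0, rest_from, by = bin_width)
  counts <- vapply(seq_len(length(edges) - 1), function(k)
    sum(d >= edges[k] & d < edges[k + 1]), integer(1))
  list(bin_edges = edges[-length(edges)], counts = counts,
       rest_count = sum(d >= rest_from))
}

#' Uniform random foci on a mask
#'
#' Draws `n` distinct pixels uniformly from the true pixels of `mask`,
#' emulating random placement of single-pixel foci with off-mask positions
#' discarded.
#'
#' @param mask logical (or 0/1) matrix.
#' @param n number of foci.
#' @param seed optional integer seed.
#' @return data.frame with pixel columns `x`, `y`.
#' @export
random_points_on_mask <- function(mask, n, seed = NULL) {
  mask <- mask > 0
  on <- which(mask)
  if (n == 0)
    return(data.frame(x = integer(0), y = integer(0)))
  if (length(on) == 0) stop("mask has no true pixels", call. = FALSE)
  if (n > length(on))
    stop("more foci requested than mask pixels", call. = FALSE)
  idx <- with_seed(seed, sample(on, n, replace = FALSE))
  data.frame(x = (idx - 1L) %% nrow(mask) + 1L,
             y = (idx - 1L) %/% nrow(mask) + 1L)
}

#' Pooled nearest-neighbour distances from random placements
#'
#' Generates `n_sims` random placements of `n` foci on the mask and pools
#' their self nearest-neighbour distances. With `mode = "image"` (the
#' analysis default) each placement is rendered as a confocal-like image
#' (blur + offset + shot noise), foci are re-detected with [find_maxima()]
#' and mask-filtered, so the reference distances pass through the same chain
#' as observed images. `mode = "points"` uses the placed pixels directly.
#'
#' @param mask logical matrix.
#' @param n foci per placement.
#' @param n_sims number of placements.
#' @param params [confocal_render_params()] used in image mode.
#' @param noise_tolerance prominence tolerance for re-detection (image mode).
#' @param mode `"image"` or `"points"`.
#' @param seed optional integer seed (per-simulation substreams).
#' @return numeric vector of pooled distances (nm).
#' @export
csr_reference_distances <- function(mask, n, n_sims = 50,
                                    params = confocal_render_params(),
                                    noise_tolerance = 90,
                                    mode = c("image", "points"),
                                    seed = NULL) {
  if (n_sims < 1) stop("'n_sims' must be >= 1", call. = FALSE)
  mode <- match.arg(mode)
  seeds <- derive_seeds(seed, n_sims)
  pooled <- vector("list", n_sims)
  for (s in seq_len(n_sims)) {
    sseed <- if (is.null(seed)) NULL else seeds[s]
    pts <- random_points_on_mask(mask, n, seed = sseed)
    if (mode == "image") {
      nm_pts <- data.frame(x = (pts$x - 0.5) * params$pixel_size,
                           y = (pts$y - 0.5) * params$pixel_size)
      img <- render_confocal(nm_pts, params, field_px = dim(mask),
                             noise = TRUE,
                             seed = if (is.null(seed)) NULL else seeds[s] + 1)
      det <- find_maxima(img, noise_tolerance)
      det <- mask_filter(det, mask)
      if (nrow(det) >= 2)
        pooled[[s]] <- nn_distances(det, exclude_self = TRUE,
                                    pixel_size = params$pixel_size)
    } else {
      if (nrow(pts) >= 2)
        pooled[[s]] <- nn_distances(pts, exclude_self = TRUE,
                                    pixel_size = params$pixel_size)
    }
  }
  unlist(pooled)
}

#' Kolmogorov-Smirnov comparison of two nearest-neighbour samples
#'
#' Thin wrapper over the two-sample [stats::ks.test()] with asymptotic
#' p-values (tie warnings from pixel-quantised distances are suppressed).
#'
#' @param observed,reference distance vectors (nm).
#' @return list with `statistic` (D) and `p.value`.
#' @export
compare_nn_distributions <- function(observed, reference) {
  kt <- suppressWarnings(stats::ks.test(observed, reference,
                                        exact = FALSE))
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}

#' Test observed nearest-neighbour distances against mask-constrained CSR
#'
#' Compares the observed distances to distances pooled from `n_sims` random
#' placements of `n` foci on the mask (complete spatial randomness restricted
#' to the masked axes), using the two-sample Kolmogorov-Smirnov test.
#'
#' @inheritParams csr_reference_distances
#' @param observed observed nearest-neighbour distances (nm), nonempty.
#' @return list with `statistic`, `p.value`, `observed_hist`,
#'   `simulated_hist` (both [nn_histogram()]s) and `n_sims`.
#' @export
csr_test <- function(observed, mask, n, n_sims = 50,
                     params = confocal_render_params(),
                     noise_tolerance = 90, mode = c("image", "points"),
                     seed = NULL) {
  if (length(observed) == 0) stop("'observed' must be nonempty",
                                  call. = FALSE)
  ref <- csr_reference_distances(mask, n, n_sims, params, noise_tolerance,
                                 mode, seed)
  ks <- compare_nn_distributions(observed, ref)
  list(statistic = ks$statistic, p.value = ks$p.value,
       observed_hist = nn_histogram(observed),
       simulated_hist = nn_histogram(ref),
       n_sims = n_sims)
}
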