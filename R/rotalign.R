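#' Rigid alignment of a focus by rotation
#'
#' Translates the events so the anchor nanofocus centre sits at the origin,
#' then rotates (no reflection, no scaling) so the goal nanofocus centre
#' lies on the positive y axis at its original distance. Typical use centres
#' the close DMC1 nanofocus and rotates either the far DMC1 or the RAD51
#' centre to the top.
#'
#' @param events data.frame with columns `x`, `y` (nm); other columns are
#'   carried through.
#' @param anchor_centre,goal_centre numeric `c(x, y)` centres (nm); must not
#'   coincide.
#' @return `events` with `x`, `y` replaced by the aligned coordinates.
#' @export
rotate_align <- function(events, anchor_centre, goal_centre) {
  v <- goal_centre - anchor_centre
  d <- sqrt(sum(v^2))
  if (d < .Machine$double.eps^0.5)
    stop("anchor and goal centres coincide", call. = FALSE)
  ct <- v[2] / d; st <- v[1] / d  # rotation sending v to (0, d), det = +1
  ev <- as.data.frame(events)
  x0 <- ev$x - anchor_centre[1]
  y0 <- ev$y - anchor_centre[2]
  ev$x <- ct * x0 - st * y0
  ev$y <- st * x0 + ct * y0
  ev
}

#' Pooled consensus image of aligned foci
#'
#' Pools the aligned localisations of many foci and renders a per-channel
#' count image on a common grid centred on the anchor (origin). Total
#' rendered mass equals the number of pooled events; pooling order does not
#' matter.
#'
#' @param aligned list of aligned event data.frames (from [rotate_align()]),
#'   or one pooled data.frame.
#' @param pixel grid pixel edge (nm).
#' @param half_extent half-size (nm) of the square rendering window around
#'   the origin; events outside are dropped from the image (not from the
#'   pooled table).
#' @return list with per-channel count matrices (`images`), the grid centre
#'   vectors `x`, `y`, and the pooled events (`pooled`).
#' @export
pool_and_render <- function(aligned, pixel = 5, half_extent = 600) {
  if (is.data.frame(aligned)) aligned <- list(aligned)
  if (length(aligned) == 0) stop("empty pool", call. = FALSE)
  pooled <- do.call(rbind, aligned)
  gx <- seq(-half_extent, half_extent, by = pixel)
  images <- list()
  for (ch in intersect(CHANNELS, unique(pooled$channel))) {
    ev <- pooled[pooled$channel == ch, , drop = FALSE]
    i <- round((ev$x + half_extent) / pixel) + 1L
    j <- round((ev$y + half_extent) / pixel) + 1L
    ok <- i >= 1 & i <= length(gx) & j >= 1 & j <= length(gx)
    img <- matrix(0L, length(gx), length(gx))
    if (any(ok)) {
      tab <- table(factor(i[ok], levels = seq_along(gx)),
                   factor(j[ok], levels = seq_along(gx)))
      img <- matrix(as.integer(tab), length(gx), length(gx))
    }
    images[[ch]] <- img
  }
  list(images = images, x = gx, y = gx, pooled = pooled)
}

#' Quadrant fractions of an aligned localisation cloud
#'
#' Partitions the plane into four 90-degree wedges around the origin, the
#' "top" wedge bisected by the positive y axis (boundaries on the diagonals
#' `y = x` and `y = -x`), and returns the fraction of the channel's events
#' in each. Boundary events (`|x| == |y|`) count towards the vertical
#' (top/bottom) wedges; an event at the origin counts as top. Fractions sum
#' to 1.
#'
#' @param events aligned events (data.frame with `x`, `y`, `channel`).
#' @param channel channel to quantify.
#' @return named numeric vector `c(top, bottom, left, right)`.
#' @export
quadrant_fractions <- function(events, channel) {
  ev <- as.data.frame(events)
  ev <- ev[ev$channel == channel, , drop = FALSE]
  if (nrow(ev) == 0) stop("no events in channel ", channel, call. = FALSE)
  top <- ev$y >= abs(ev$x)
  bottom <- !top & (-ev$y >= abs(ev$x))
  left <- !top & !bottom & ev$x < 0
  right <- !top & !bottom & ev$x > 0
  c(top = mean(top), bottom = mean(bottom),
    left = mean(left), right = mean(right))
}

#' Fit a 1D Gaussian to the alignment-axis marginal
#'
#' Least-squares fit of a single Gaussian with constant offset to the
#' histogram of the channel's y coordinates (the alignment axis) in 5 nm
#' bins, via [minpack.lm::nlsLM()]. Reports the fitted SD and the full width
#' at half maximum (`2.355 * sigma`).
#'
#' @param events aligned (pooled) events.
#' @param channel channel to fit.
#' @param bin histogram bin width (nm).
#' @param min_events minimum number of events for a fit.
#' @return list with `sigma` (nm), `fwhm` (nm), `mu` (nm) and `n`.
#'   Degenerate input (all events coincident) returns `sigma = 0` with a
#'   warning.
#' @export
fit_sigma <- function(events, channel, bin = 5, min_events = 50) {
  ev <- as.data.frame(events)
  yv <- ev$y[ev$channel == channel]
  n <- length(yv)
  if (n < min_events)
    stop(sprintf("need at least %d events to fit (got %d)", min_events, n),
         call. = FALSE)
  if (sd(yv) < .Machine$double.eps^0.5) {
    warning("degenerate (coincident) events: sigma = 0")
    return(list(sigma = 0, fwhm = 0, mu = yv[1], n = n))
  }
  br <- seq(floor(min(yv) / bin) * bin, ceiling(max(yv) / bin) * bin + bin,
            by = bin)
  h <- hist(yv, breaks = br, plot = FALSE)
  df <- data.frame(y = h$mids, cnt = h$counts)
  start <- list(A = max(df$cnt), mu = sum(df$y * df$cnt) / sum(df$cnt),
                s = max(sd(yv) / 2, bin), c0 = 0)
  fit <- minpack.lm::nlsLM(
    cnt ~ A * exp(-(y - mu)^2 / (2 * s^2)) + c0, data = df, start = start,
    lower = c(A = 0, mu = -Inf, s = 1e-3, c0 = -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  list(sigma = unname(abs(cf["s"])), fwhm = fwhm_from_sigma(unname(abs(cf["s"]))),
       mu = unname(cf["mu"]), n = n)
}

#' Per-stage means of named nanofocus-pair distances
#'
#' For each stage, the mean and standard error of the close-DMC1 to RAD51,
#' far-DMC1 to RAD51 and DMC1-DMC1 centre distances over D2R1
#' configurations (or the channel-swapped analogues over D1R2). A stage with
#' a single configuration reports `SEM = 0` (documented convention).
#'
#' @param configs list of [focus_configuration()]s (mixed labels allowed;
#'   only those matching `label` contribute).
#' @param label `"D2R1"` or `"D1R2"`.
#' @return data.frame with columns `stage`, `pair`, `mean`, `sem`, `n`.
#' @export
stack_distances <- function(configs, label = "D2R1") {
  configs <- Filter(function(cf) cf$label == label, configs)
  rows <- lapply(configs, function(cf) {
    r <- cf$roles
    com <- lapply(cf$nanofoci, function(f) f$com)
    close_i <- which(r == "close"); far_i <- which(r == "far")
    single_i <- which(r == "single")
    data.frame(
      stage = if (is.na(cf$stage)) "all" else cf$stage,
      close_single = sqrt(sum((com[[close_i]] - com[[single_i]])^2)),
      far_single = sqrt(sum((com[[far_i]] - com[[single_i]])^2)),
      close_far = sqrt(sum((com[[close_i]] - com[[far_i]])^2)))
  })
  if (length(rows) == 0)
    return(data.frame(stage = character(0), pair = character(0),
                      mean = numeric(0), sem = numeric(0), n = integer(0)))
  tab <- do.call(rbind, rows)
  out <- list()
  for (st in unique(tab$stage)) {
    sub <- tab[tab$stage == st, , drop = FALSE]
    for (p in c("close_single", "far_single", "close_far")) {
      v <- sub[[p]]
      out[[length(out) + 1]] <- data.frame(
        stage = st, pair = p, mean = mean(v),
        sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else 0,
        n = length(v))
    }
  }
  do.call(rbind, out)
}
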