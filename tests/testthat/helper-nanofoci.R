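# shared fixtures and independent oracles, all built in code

# analytic two-dimensional Gaussian peak image (no rendering code involved)
gauss_image <- function(nr, nc, peaks) {
  img <- matrix(0, nr, nc)
  xs <- matrix(rep(seq_len(nr), nc), nr, nc)
  ys <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  for (p in peaks)
    img <- img + p$A * exp(-((xs - p$x)^2 + (ys - p$y)^2) / (2 * p$s^2))
  img
}

# brute-force prominence of every local maximum by descending-level floods
oracle_maxima <- function(img, tol) {
  nr <- nrow(img); nc <- ncol(img)
  nbrs <- function(r, c) {
    out <- list()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc)
        out[[length(out) + 1]] <- c(rr, cc)
    }
    out
  }
  is_locmax <- function(r, c)
    all(vapply(nbrs(r, c), function(q) img[q[1], q[2]] <= img[r, c],
               logical(1)))
  flood <- function(r0, c0, level) {
    seen <- matrix(FALSE, nr, nc)
    seen[r0, c0] <- TRUE
    queue <- list(c(r0, c0))
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (q in nbrs(p[1], p[2])) {
        if (!seen[q[1], q[2]] && img[q[1], q[2]] >= level) {
          seen[q[1], q[2]] <- TRUE
          queue[[length(queue) + 1]] <- q
        }
      }
    }
    seen
  }
  res <- NULL
  vals <- sort(unique(as.numeric(img)), decreasing = TRUE)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!is_locmax(r, c)) next
    v <- img[r, c]
    prom <- v - min(img)
    for (L in vals[vals < v]) {
      comp <- flood(r, c, L)
      if (max(img[comp]) > v) { prom <- v - L; break }
    }
    if (prom > tol) res <- rbind(res, c(r, c, v, prom))
  }
  res
}

# brute-force nearest neighbour by full pairwise scan
oracle_nn <- function(a, b, exclude_self = FALSE) {
  vapply(seq_len(nrow(a)), function(i) {
    d <- sqrt((a$x[i] - b$x)^2 + (a$y[i] - b$y)^2)
    if (exclude_self) d[i] <- Inf
    min(d)
  }, numeric(1))
}

# hand-built nanofocus stub on an explicit grid for morphology/distance tests
stub_nanofocus <- function(channel, mask, ecc = 0, grid_pixel = 5) {
  idx <- which(mask, arr.ind = TRUE)
  com <- c(mean(idx[, 1]), mean(idx[, 2])) * grid_pixel
  structure(list(channel = channel, mask = mask, area_px = sum(mask),
                 area_nm2 = sum(mask) * grid_pixel^2, com = com,
                 n_localisations = NA_integer_, sigma_major = NA_real_,
                 eccentricity = ecc),
            class = "nanofocus")
}

# rectangular blob mask on an nr x nc grid
blob_mask <- function(nr, nc, r1, r2, c1, c2) {
  m <- matrix(FALSE, nr, nc)
  m[r1:r2, c1:c2] <- TRUE
  m
}

stub_config <- function(nanofoci, stage = NA_character_) {
  attr(nanofoci, "grid") <- list(pixel = 5)
  cfg <- focus_configuration(nanofoci)
  cfg$stage <- stage
  cfg
}

# events drawn as two well-separated Gaussian clusters, one per channel
two_channel_cluster_events <- function(n = 600, sigma = 25, sep = 0,
                                       centre = c(0, 0), seed = 1) {
  set.seed(seed)
  data.frame(
    x = c(rnorm(n, centre[1], sigma), rnorm(n, centre[1] + sep, sigma)),
    y = c(rnorm(n, centre[2], sigma), rnorm(n, centre[2], sigma)),
    channel = rep(c("DMC1", "RAD51"), each = n))
}
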