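test_that("ROI membership is a closed 300 nm disc", {
  tab <- data.frame(x = c(300, 301, 0, -299), y = c(0, 0, 150, 0),
                    channel = "DMC1")
  rois <- extract_rois(tab, data.frame(x = 0, y = 0))
  expect_equal(sort(rois[[1]]$events$.event), c(1, 3, 4))
})

test_that("ROI extraction agrees with a brute-force membership oracle", {
  set.seed(13)
  tab <- data.frame(x = runif(1000, -800, 800), y = runif(1000, -800, 800),
                    channel = sample(c("DMC1", "RAD51"), 1000, TRUE))
  ctrs <- data.frame(x = c(-200, 350), y = c(100, -50))
  rois <- extract_rois(tab, ctrs)
  for (i in 1:2) {
    want <- which(sqrt((tab$x - ctrs$x[i])^2 + (tab$y - ctrs$y[i])^2) <= 300)
    expect_equal(rois[[i]]$events$.event, want)
  }
})

test_that("ROI pairs sharing more than 25 percent are both excluded", {
  mk <- function(n_only, centre, n_shared) {
    data.frame(x = c(rep(centre - 100, n_only), rep(250, n_shared)),
               y = 0, channel = "DMC1")
  }
  # shared events lie within 300 of both centres (0 and 500)
  tab <- rbind(mk(74, 0, 0), mk(74, 500, 0),
               data.frame(x = rep(250, 26), y = 0, channel = "DMC1"))
  rois <- extract_rois(tab, data.frame(x = c(0, 500), y = 0))
  expect_equal(nrow(rois[[1]]$events), 100)
  expect_equal(nrow(rois[[2]]$events), 100)
  qc <- roi_qc(rois)
  expect_equal(length(qc$kept), 0)
  expect_true(all(qc$log$rule == "overlap"))
  # at exactly 25 percent both are kept
  tab2 <- rbind(mk(75, 0, 0), mk(75, 500, 0),
                data.frame(x = rep(250, 25), y = 0, channel = "DMC1"))
  rois2 <- extract_rois(tab2, data.frame(x = c(0, 500), y = 0))
  expect_equal(length(roi_qc(rois2)$kept), 2)
})

test_that("the 50-localisation floor keeps 50 and drops 49", {
  mk_tab <- function(n) data.frame(x = rnorm(n, 0, 40), y = rnorm(n, 0, 40),
                                   channel = rep(c("DMC1", "RAD51"),
                                                 length.out = n))
  set.seed(2)
  r49 <- extract_rois(mk_tab(49), data.frame(x = 0, y = 0))
  r50 <- extract_rois(mk_tab(50), data.frame(x = 0, y = 0))
  expect_equal(length(roi_qc(r49)$kept), 0)
  expect_equal(roi_qc(r49)$log$rule, "min_localisations")
  expect_equal(length(roi_qc(r50)$kept), 1)
  # per-channel variant
  uneven <- data.frame(x = rnorm(80, 0, 40), y = rnorm(80, 0, 40),
                       channel = rep(c("DMC1", "RAD51"), c(70, 10)))
  ru <- extract_rois(uneven, data.frame(x = 0, y = 0))
  expect_equal(length(roi_qc(ru)$kept), 1)
  expect_equal(length(roi_qc(ru, per_channel = TRUE)$kept), 0)
})

test_that("disjoint well-populated ROIs all pass QC", {
  set.seed(3)
  tab <- do.call(rbind, lapply(c(0, 2000, 4000), function(cx)
    data.frame(x = rnorm(100, cx, 50), y = rnorm(100, 0, 50),
               channel = "DMC1")))
  rois <- extract_rois(tab, data.frame(x = c(0, 2000, 4000), y = 0))
  qc <- roi_qc(rois)
  expect_equal(length(qc$kept), 3)
  expect_equal(nrow(qc$log), 0)
})

test_that("KDE peak density matches the closed-form Gaussian peak", {
  ev <- data.frame(x = rep(0, 100), y = rep(0, 100), channel = "DMC1")
  rois <- extract_rois(ev, data.frame(x = 0, y = 0))
  dm <- kde_map(rois[[1]], "DMC1")
  expect_equal(max(dm$mat), 100 / (2 * pi * 20^2), tolerance = 0.01)
  # peak sits at the origin grid node
  peak <- which(dm$mat == max(dm$mat), arr.ind = TRUE)
  expect_equal(c(dm$x[peak[1]], dm$y[peak[2]]), c(0, 0))
  expect_error(kde_map(rois[[1]], "RAD51"), "RAD51")
})

test_that("density integrates back to the localisation count within 1 percent", {
  set.seed(9)
  ev <- data.frame(x = rnorm(500, 0, 60), y = rnorm(500, 0, 60),
                   channel = "RAD51")
  ev <- ev[ev$x^2 + ev$y^2 <= 300^2, ]
  rois <- extract_rois(ev, data.frame(x = 0, y = 0))
  dm <- kde_map(rois[[1]], "RAD51")
  expect_equal(sum(dm$mat) * dm$pixel^2, nrow(ev), tolerance = 0.01)
})

test_that("segmentation reproduces the analytic threshold disc", {
  mk <- function(n) {
    ev <- data.frame(x = rep(0, n), y = rep(0, n), channel = "DMC1")
    kde_map(extract_rois(ev, data.frame(x = 0, y = 0))[[1]], "DMC1")
  }
  # peak of 400 coincident events is 0.159 < 0.2: nothing segments
  expect_equal(length(segment_nanofoci(mk(400), threshold = 0.2)), 0)
  # 1000 events: disc radius sqrt(800*log(1000/502.65)) ~ 23.5 nm, ~69 px
  nf <- segment_nanofoci(mk(1000), threshold = 0.2)
  expect_equal(length(nf), 1)
  expect_gt(nf[[1]]$area_px, 60)
  expect_lt(nf[[1]]$area_px, 80)
  expect_equal(nf[[1]]$com, c(0, 0), tolerance = 1e-6)
  # 800 events: ~47 px, below the 50-pixel floor -> background
  expect_equal(length(segment_nanofoci(mk(800), threshold = 0.2)), 0)
  nf2 <- segment_nanofoci(mk(800), threshold = 0.2, min_area = 40)
  expect_equal(length(nf2), 1)
  expect_gt(nf2[[1]]$area_px, 42)
  expect_lt(nf2[[1]]$area_px, 52)
})

test_that("member localisation counts are attributed to the right nanofocus", {
  ev <- two_channel_cluster_events(n = 600, sigma = 20, seed = 4)
  ev$x[ev$channel == "RAD51"] <- ev$x[ev$channel == "RAD51"] + 350
  nf <- segment_roi_channels(ev)
  expect_equal(length(nf), 2)
  for (f in nf) expect_gt(f$n_localisations, 550)
})

test_that("raising the threshold never increases above-threshold area", {
  set.seed(17)
  ev <- data.frame(x = c(rnorm(700, 0, 35), runif(100, -300, 300)),
                   y = c(rnorm(700, 0, 35), runif(100, -300, 300)),
                   channel = "DMC1")
  dm <- kde_map(ev, "DMC1")
  areas <- vapply(c(1e-4, 3e-4, 5e-4, 1e-3, 5e-3, 0.02),
                  function(t) sum(dm$mat >= t), numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("segmentation is translation-equivariant within half a pixel", {
  ev <- two_channel_cluster_events(n = 700, sigma = 30, seed = 6)
  shift <- c(123.4, -77.9)
  ev2 <- ev; ev2$x <- ev2$x + shift[1]; ev2$y <- ev2$y + shift[2]
  a <- segment_roi_channels(ev)
  b <- segment_roi_channels(ev2)
  expect_equal(length(a), length(b))
  for (k in seq_along(a))
    expect_lt(max(abs(b[[k]]$com - a[[k]]$com - shift)), 2.5)
})

test_that("two separated clusters are recovered as two nanofoci", {
  ok <- 0
  for (s in 1:25) {
    set.seed(s)
    ev <- data.frame(x = c(rnorm(600, 0, 20), rnorm(600, 300, 20)),
                     y = rnorm(1200, 0, 20), channel = "DMC1")
    nf <- segment_roi_channels(ev)
    coms <- sort(vapply(nf, function(f) f$com[1], numeric(1)))
    if (length(nf) == 2 && abs(coms[1]) < 20 && abs(coms[2] - 300) < 20)
      ok <- ok + 1
  }
  expect_gte(ok, 24)
})

test_that("connectivity choice affects diagonal merging", {
  m <- matrix(FALSE, 6, 6)
  m[1:3, 1:3] <- TRUE; m[4:6, 4:6] <- TRUE  # touch at one diagonal
  lab8 <- nanofoci:::cpp_label_components(m, 8L)
  lab4 <- nanofoci:::cpp_label_components(m, 4L)
  expect_equal(max(lab8), 1)
  expect_equal(max(lab4), 2)
})

test_that("the exact KDE agrees with an independent binned estimator", {
  skip_if_not_installed("KernSmooth")
  set.seed(23)
  ev <- data.frame(x = c(rnorm(300, 0, 40), runif(50, -250, 250)),
                   y = c(rnorm(300, 20, 40), runif(50, -250, 250)),
                   channel = "DMC1")
  roi <- extract_rois(ev, data.frame(x = 0, y = 0))[[1]]
  dm <- kde_map(roi, "DMC1")
  ref <- KernSmooth::bkde2D(
    cbind(roi$events$x, roi$events$y), bandwidth = c(20, 20),
    gridsize = c(length(dm$x), length(dm$y)),
    range.x = list(range(dm$x), range(dm$y)))
  refmat <- ref$fhat * nrow(roi$events)
  expect_equal(max(dm$mat), max(refmat), tolerance = 0.02)
  expect_equal(sum(dm$mat), sum(refmat), tolerance = 0.005)
  expect_lt(max(abs(dm$mat - refmat)) / max(dm$mat), 0.03)
})
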