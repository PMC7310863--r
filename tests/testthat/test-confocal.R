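test_that("a constant image has no maxima", {
  expect_equal(nrow(find_maxima(matrix(7, 40, 40), 10)), 0)
  expect_error(find_maxima(array(1, c(3, 3, 3)), 10), "2D")
})

test_that("two well-separated peaks above tolerance are both found", {
  img <- gauss_image(120, 120, list(list(A = 200, x = 30, y = 30, s = 4),
                                    list(A = 200, x = 90, y = 95, s = 4)))
  m <- find_maxima(img, 100)
  expect_equal(nrow(m), 2)
  expect_setequal(paste(m$x, m$y), c("30 30", "90 95"))
})

test_that("a secondary bump below tolerance is suppressed", {
  # main peak 200, saddle 100, bump 150: bump prominence 50
  profile <- c(seq(0, 200, length.out = 26)[-26],
               seq(200, 100, length.out = 26)[-26],
               seq(100, 150, length.out = 21)[-21],
               seq(150, 0, length.out = 31))
  taper <- 1 - 0.001 * (seq_len(21) - 11)^2
  img <- outer(profile, taper)
  expect_equal(nrow(find_maxima(img, 90)), 1)
  m <- find_maxima(img, 45)
  expect_equal(nrow(m), 2)
  expect_equal(sort(m$prominence)[1], 50, tolerance = 0.05)
})

test_that("prominence selection agrees with a brute-force flood oracle", {
  for (s in 1:4) {
    set.seed(s)
    raw <- matrix(runif(18 * 18), 18, 18)
    img <- 200 * (raw + as.matrix(stats::filter(raw, rep(1, 3)/3)) * 0)
    img <- gauss_image(18, 18, list(list(A = 150 * s %% 3 + 50,
                                         x = 5 + s, y = 9, s = 3))) +
      30 * matrix(runif(18 * 18), 18, 18)
    tol <- 25
    got <- find_maxima(img, tol)
    want <- oracle_maxima(img, tol)
    expect_equal(nrow(got), if (is.null(want)) 0 else nrow(want))
    if (!is.null(want)) {
      expect_setequal(paste(got$x, got$y), paste(want[, 1], want[, 2]))
      expect_equal(sort(got$prominence), sort(want[, 4]), tolerance = 1e-12)
    }
  }
})

test_that("an equal-valued plateau yields one maximum near its centroid", {
  img <- matrix(0, 30, 30)
  img[10:14, 18:22] <- 50
  m <- find_maxima(img, 20)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$x, m$y), c(12, 20))
})

test_that("mask_filter keeps exactly the on-mask points and is idempotent", {
  pts <- data.frame(x = c(1, 5, 9, 12), y = c(1, 5, 9, 12))
  all_true <- matrix(TRUE, 15, 15)
  expect_equal(mask_filter(pts, all_true), pts)
  expect_equal(nrow(mask_filter(pts, matrix(FALSE, 15, 15))), 0)
  half <- matrix(FALSE, 15, 15); half[1:7, ] <- TRUE
  kept <- mask_filter(pts, half)
  expect_equal(kept$x, c(1, 5))
  expect_equal(mask_filter(kept, half), kept)
  expect_error(mask_filter(data.frame(x = 99, y = 1), half), "grid")
})

test_that("mask filtering recovers the ground-truth on-mask fraction", {
  set.seed(7)
  pts <- data.frame(x = sample(1:50, 200, TRUE), y = sample(1:50, 200, TRUE))
  mask <- matrix(FALSE, 50, 50); mask[, 1:30] <- TRUE
  truth <- pts$y <= 30
  expect_equal(nrow(mask_filter(pts, mask)), sum(truth))
})

test_that("nearest-neighbour distances match symmetry and brute force", {
  two <- data.frame(x = c(0, 300), y = c(0, 0))
  expect_equal(nn_distances(two, exclude_self = TRUE), c(300, 300))
  set.seed(12)
  a <- data.frame(x = runif(10, 0, 100), y = runif(10, 0, 100))
  b <- data.frame(x = runif(14, 0, 100), y = runif(14, 0, 100))
  expect_equal(nn_distances(a, b), oracle_nn(a, b))
  expect_equal(nn_distances(a, exclude_self = TRUE),
               oracle_nn(a, a, exclude_self = TRUE))
  # scaling to nm via pixel size
  expect_equal(nn_distances(two, exclude_self = TRUE, pixel_size = 99),
               c(29700, 29700))
  expect_error(nn_distances(a[0, ], b), "nonempty")
  expect_error(nn_distances(a[1, , drop = FALSE], exclude_self = TRUE),
               "2 points")
})

test_that("every nearest-neighbour value bounds all pairwise distances", {
  set.seed(21)
  a <- data.frame(x = runif(30, 0, 500), y = runif(30, 0, 500))
  nn <- nn_distances(a, exclude_self = TRUE)
  for (i in seq_len(nrow(a))) {
    d <- sqrt((a$x[i] - a$x[-i])^2 + (a$y[i] - a$y[-i])^2)
    expect_true(all(nn[i] <= d + 1e-12))
  }
})

test_that("distance histogram uses half-open 100 nm bins and a rest class", {
  h <- nn_histogram(c(250, 0, 99.999, 100, 3399.9, 3400, 5000))
  expect_equal(h$counts[h$bin_edges == 200], 1)  # 250 in [200, 300)
  expect_equal(h$counts[h$bin_edges == 0], 2)    # 0 and 99.999
  expect_equal(h$counts[h$bin_edges == 100], 1)  # boundary 100 goes up
  expect_equal(h$counts[h$bin_edges == 3300], 1)
  expect_equal(h$rest_count, 2)
  expect_equal(sum(h$counts) + h$rest_count, 7)
})

test_that("random placement is uniform over the mask pixels", {
  mask <- matrix(FALSE, 120, 120)
  mask[10:109, 25:104] <- TRUE  # 100 x 80 block
  pts <- random_points_on_mask(mask, 606, seed = 3)
  expect_equal(nrow(pts), 606)
  expect_true(all(mask[cbind(pts$x, pts$y)]))
  expect_equal(nrow(random_points_on_mask(mask, 0)), 0)
  expect_error(random_points_on_mask(matrix(FALSE, 5, 5), 3), "no true")
  # chi-square uniformity over a 5 x 4 tiling with 10^4 draws
  big <- random_points_on_mask(mask, 8000, seed = 9)
  tile <- paste((big$x - 10) %/% 20, (big$y - 25) %/% 20)
  expect_gt(chisq.test(table(tile))$p.value, 0.01)
})

test_that("identical samples give D = 0, p = 1; a shift is detected", {
  set.seed(5)
  d <- runif(300, 0, 2000)
  same <- compare_nn_distributions(d, d)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  shifted <- compare_nn_distributions(d + 500, d)
  expect_lt(shifted$p.value, 0.001)
})

test_that("the CSR chain re-detects placed foci and returns histograms", {
  mask <- matrix(FALSE, 128, 128)
  mask[20:100, 30:110] <- TRUE
  obs <- csr_reference_distances(mask, 40, n_sims = 1, mode = "points",
                                 seed = 2)
  res <- csr_test(obs, mask, 40, n_sims = 5, seed = 7,
                  noise_tolerance = 90)
  expect_true(res$p.value >= 0 && res$p.value <= 1)
  expect_equal(sum(res$observed_hist$counts) + res$observed_hist$rest_count,
               length(obs))
  expect_error(csr_test(numeric(0), mask, 10), "nonempty")
  expect_error(csr_reference_distances(mask, 10, n_sims = 0), "n_sims")
})

test_that("CSR self-test p-values are roughly uniform (type-I calibration)", {
  mask <- matrix(FALSE, 90, 90)
  mask[15:75, 10:80] <- TRUE
  params <- confocal_render_params()
  n <- 60
  pvals <- vapply(1:200, function(r) {
    obs <- csr_reference_distances(mask, n, n_sims = 1, mode = "points",
                                   params = params, seed = 1000 + r)
    ref <- csr_reference_distances(mask, n, n_sims = 10, mode = "points",
                                   params = params, seed = 5000 + r)
    compare_nn_distributions(obs, ref)$p.value
  }, numeric(1))
  # NN distances within a placement are dependent, so p-values are only
  # approximately uniform: the lower tail runs a little heavy
  expect_lt(mean(pvals < 0.05), 0.16)
  expect_gt(mean(pvals < 0.05), 0.005)
  expect_gt(mean(pvals < 0.5), 0.33)
  expect_lt(mean(pvals < 0.5), 0.67)
})

test_that("full image-chain CSR self-test keeps its nominal size", {
  mask <- matrix(FALSE, 96, 96)
  mask[10:85, 12:88] <- TRUE
  params <- confocal_render_params()
  pvals <- vapply(1:40, function(r) {
    obs_d <- csr_reference_distances(mask, 45, n_sims = 1, mode = "image",
                                     params = params, noise_tolerance = 90,
                                     seed = 300 + r)
    res <- csr_test(obs_d, mask, 45, n_sims = 8, params = params,
                    noise_tolerance = 90, seed = 9000 + r)
    res$p.value
  }, numeric(1))
  expect_lt(mean(pvals < 0.05), 0.2)
  expect_gt(mean(pvals > 0.2), 0.4)
})
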