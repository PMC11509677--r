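test_that("polarity axis follows the longest cell axis and the bright pole", {
  mask <- ellipse_mask(c(256, 256), semiaxes = c(100, 40), angle = 0)
  img <- matrix(1, 256, 256)
  ax <- estimate_polarity_axis(mask, img, rear_hint = c(128, 10))
  # major axis is along columns (angle 0)
  expect_gt(abs(ax$vector[2]), 0.99)
  expect_gt(ax$axis_ratio, 2)

  # circular mask without a hint is ambiguous
  circ <- ellipse_mask(c(128, 128), semiaxes = c(40, 40))
  expect_error(estimate_polarity_axis(circ, img[1:128, 1:128]), "ambiguous")
  expect_silent(estimate_polarity_axis(circ, img[1:128, 1:128],
                                       rear_hint = c(64, 10)))

  # the planted rear pole is identified from the intensity pattern
  for (seed in 1:20) {
    angle <- stats::runif(1, 0, pi)
    pol <- simulate_polarized_cell_image(angle = angle, rear_fold = 8,
                                         noise = "poisson", seed = seed)
    ax <- estimate_polarity_axis(pol$mask, pol$image)
    d_rear <- sqrt(sum((ax$rear_pole - pol$truth$rear_pole)^2))
    d_front <- sqrt(sum((ax$front_pole - pol$truth$rear_pole)^2))
    expect_lt(d_rear, d_front)
  }
})

test_that("rear localisation index is exact on constructed images", {
  uni <- simulate_polarized_cell_image(rear_fold = 1)
  ax <- estimate_polarity_axis(uni$mask, uni$image, rear_hint = c(128, 10))
  expect_equal(rear_localization_index(uni$image, uni$mask, axis = ax), 1)

  pol <- simulate_polarized_cell_image(rear_fold = 8)
  ax <- estimate_polarity_axis(pol$mask, pol$image)
  expect_equal(rear_localization_index(pol$image, pol$mask, axis = ax), 8)

  # invariant to global intensity scaling
  expect_equal(rear_localization_index(pol$image * 3.7, pol$mask, axis = ax), 8)

  # background subtraction: adding a constant offsets are removed again
  off <- pol$image + 50
  expect_equal(rear_localization_index(off, pol$mask, axis = ax,
                                       background = 50), 8)
})

test_that("noisy eightfold gradients are recovered within ten percent", {
  idx <- vapply(1:50, function(seed) {
    pol <- simulate_polarized_cell_image(rear_fold = 8, noise = "poisson",
                                         seed = seed)
    ax <- estimate_polarity_axis(pol$mask, pol$image)
    rear_localization_index(pol$image, pol$mask, axis = ax)
  }, 1)
  expect_lt(abs(mean(idx) - 8) / 8, 0.10)
})

test_that("quadrant profile reproduces the analytic ramp means", {
  # uniform image: four equal quadrant means
  uni <- simulate_polarized_cell_image(rear_fold = 1, base_intensity = 10)
  ax <- estimate_polarity_axis(uni$mask, uni$image, rear_hint = c(128, 10))
  qp <- quadrant_profile(uni$image, uni$mask, ax)
  expect_equal(unname(qp$quadrant_means), rep(10, 4), tolerance = 1e-9)

  # linear 0 -> 1 ramp rear -> front over the line
  mask <- ellipse_mask(c(256, 256), center = c(128.5, 128.5),
                       semiaxes = c(100, 40), angle = 0)
  cc <- matrix(seq_len(256), 256, 256, byrow = TRUE)
  px <- which(mask == 1, arr.ind = TRUE)
  cmin <- min(px[, 2]); cmax <- max(px[, 2])
  ramp <- (cc - cmin) / (cmax - cmin)
  ax <- estimate_polarity_axis(mask, -ramp)  # rear = low-ramp side
  qp <- quadrant_profile(ramp, mask, ax, line_width_px = 50)
  expect_equal(unname(qp$quadrant_means), c(0.125, 0.375, 0.625, 0.875),
               tolerance = 0.02)
  # profile runs rear -> front: increasing for the ramp
  expect_gt(stats::cor(qp$profile$position, qp$profile$mean_intensity), 0.99)

  # a planted rear-high gradient makes the rear quadrant strictly largest
  for (seed in 1:20) {
    pol <- simulate_polarized_cell_image(rear_fold = 2, profile = "ramp",
                                         noise = "poisson", seed = seed)
    ax <- estimate_polarity_axis(pol$mask, pol$image)
    qp <- quadrant_profile(pol$image, pol$mask, ax)
    expect_true(which.max(qp$quadrant_means) == 1)
  }
})

test_that("PLA dot counting recovers planted dots and honours the area filter", {
  blank <- simulate_pla_image(n_dots = 0, noise_sd = 1, seed = 1)
  expect_equal(count_pla_dots(blank$image, blank$mask)$n_total, 0)

  pla <- simulate_pla_image(n_dots = 12, dot_radius = 2, min_separation = 20,
                            seed = 2)
  res <- count_pla_dots(pla$image, pla$mask)
  expect_equal(res$n_total, 12)
  expect_equal(unname(res$counts["1"]), 12L)
  # centroids land near the planted centres
  d <- as.matrix(stats::dist(rbind(pla$truth$dot_centres, res$centroids)))
  nearest <- apply(d[1:12, 13:24, drop = FALSE], 1, min)
  expect_true(all(nearest < 2))

  # monotone non-increasing in the min-area threshold
  counts <- vapply(c(1, 5, 20, 60, 200), function(a)
    count_pla_dots(pla$image, pla$mask, min_area = a)$n_total, 1L)
  expect_true(all(diff(counts) <= 0))

  # a dot outside every cell is excluded from per-cell counts
  img <- matrix(0, 128, 128)
  img[10, 10] <- 100; img[64, 64] <- 100
  mask <- ellipse_mask(c(128, 128), center = c(64, 64), semiaxes = c(20, 20))
  res2 <- count_pla_dots(img, mask, sigma = 0, threshold = 50, min_area = 1)
  expect_equal(res2$n_total, 2)
  expect_equal(unname(res2$counts["1"]), 1L)
})

test_that("rear dot fraction matches planted geometry", {
  mask <- ellipse_mask(c(256, 256), center = c(128.5, 128.5),
                       semiaxes = c(100, 40), angle = 0)
  img <- matrix(0, 256, 256); img[, 1:128] <- 1  # bright rear = low columns
  ax <- estimate_polarity_axis(mask, img)
  # all dots planted deep in the rear quadrant
  rear_dots <- cbind(row = rep(128, 5), col = seq(32, 48, by = 4))
  rf <- rear_fraction_of_dots(rear_dots, ax, mask)
  expect_equal(rf$fraction, 1)

  rf0 <- rear_fraction_of_dots(matrix(numeric(0), 0, 2), ax, mask)
  expect_true(rf0$undefined)

  # uniform dots over the mask land in the rear quadrant at about its area
  # fraction (ellipse rear quarter-extent holds ~ 0.196 of the area)
  set.seed(3)
  px <- which(mask == 1, arr.ind = TRUE)
  draws <- vapply(1:40, function(i) {
    dots <- px[sample(nrow(px), 200), ]
    rear_fraction_of_dots(dots, ax, mask)$fraction
  }, 1)
  p_area <- {
    s <- (px[, 2] - ax$centroid[2]) * ax$vector[2] +
      (px[, 1] - ax$centroid[1]) * ax$vector[1]
    mean(s < min(s) + (max(s) - min(s)) / 4)
  }
  expect_lt(abs(mean(draws) - p_area), 3 * sqrt(p_area * (1 - p_area) / (40 * 200)))
})

test_that("Pearson colocalisation hits its analytic values", {
  pol <- simulate_polarized_cell_image(rear_fold = 4, noise = "gaussian",
                                       gaussian_sd = 3, seed = 4)
  expect_equal(pearson_colocalization(pol$image, pol$image, pol$mask), 1)
  expect_equal(pearson_colocalization(pol$image, 1000 - pol$image, pol$mask), -1)
  # invariance under positive affine transforms
  r0 <- pearson_colocalization(pol$image, pol$image^1, pol$mask)
  set.seed(5)
  noise <- matrix(stats::rnorm(length(pol$image)), nrow(pol$image))
  r1 <- pearson_colocalization(pol$image, pol$image + noise, pol$mask)
  r2 <- pearson_colocalization(pol$image * 2 + 7, (pol$image + noise) * 0.5 + 1,
                               pol$mask)
  expect_equal(r1, r2, tolerance = 1e-12)

  expect_error(pearson_colocalization(pol$image, matrix(5, 256, 256), pol$mask),
               "zero-variance")

  # shared component with mixing weight w over unit noise: r = w^2/(w^2+1)
  set.seed(6)
  w <- 1.5
  common <- matrix(stats::rnorm(256^2), 256)
  a <- w * common + matrix(stats::rnorm(256^2), 256)
  b <- w * common + matrix(stats::rnorm(256^2), 256)
  r <- pearson_colocalization(a, b, pol$mask)
  expect_equal(r, w^2 / (w^2 + 1), tolerance = 0.03)
})
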