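test_that("gaussian smoothing preserves constants, mass and the identity limit", {
  const <- matrix(0.7, 20, 20)
  expect_equal(gaussian_smooth(const, 1.3), const)
  # impulse response equals the normalized sampled kernel (direct oracle)
  n <- 31L
  img <- matrix(0, n, n); img[16, 16] <- 1
  sm <- gaussian_smooth(img, 1.3)
  r <- ceiling(4 * 1.3)
  k <- exp(-(-r:r)^2 / (2 * 1.3^2)); k <- k / sum(k)
  oracle <- outer(seq_len(n), seq_len(n), function(i, j) {
    ki <- abs(i - 16); kj <- abs(j - 16)
    ifelse(ki <= r & kj <= r, k[ki + r + 1] * k[kj + r + 1], 0)
  })
  expect_equal(sm, oracle, tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-12)
  # mass preservation on an interior-supported random image
  set.seed(1)
  img2 <- matrix(0.3, 40, 40)
  img2[10:30, 10:30] <- runif(21 * 21)
  expect_equal(sum(gaussian_smooth(img2, 1.3)), sum(img2), tolerance = 1e-9)
  # tiny sigma approximates identity
  expect_lt(max(abs(gaussian_smooth(img2, 1e-6) - img2)), 1e-3)
  expect_error(gaussian_smooth(matrix(c(1, NA, 1, 1), 2, 2), 1), "finite")
  expect_error(gaussian_smooth(const, 0), "sigma")
})

test_that("gradient direction and magnitude follow the image-axis convention", {
  const <- matrix(0.4, 10, 10)
  g <- compute_gradient(const)
  expect_true(all(g$magnitude == 0))
  expect_true(all(g$direction == 0))
  # ramp along columns (x): direction 0, uniform interior magnitude
  W <- 16
  rampx <- matrix(rep((seq_len(W) - 1) / W, each = 12), 12, W)
  gx <- compute_gradient(rampx)
  inner <- gx$magnitude[2:11, 2:(W - 1)]
  expect_equal(as.vector(inner), rep(1 / W, length(inner)), tolerance = 1e-12)
  expect_equal(as.vector(gx$direction[2:11, 2:(W - 1)]),
               rep(0, length(inner)), tolerance = 1e-12)
  # ramp along rows (y): direction pi/2
  H <- 14
  rampy <- matrix(rep((seq_len(H) - 1) / H, times = 10), H, 10)
  gy <- compute_gradient(rampy)
  expect_equal(as.vector(gy$direction[2:(H - 1), 2:9]),
               rep(pi / 2, (H - 2) * 8), tolerance = 1e-12)
  expect_error(compute_gradient(matrix(0, 2, 2)), "3x3")
  # sobel agrees with central differences on a linear ramp interior
  gs <- compute_gradient(rampx, operator = "sobel")
  expect_equal(gs$magnitude[2:11, 2:(W - 1)], inner, tolerance = 1e-12)
})

test_that("pixel classification matches a brute-force oracle on line/edge images", {
  cfg <- seg_config(background_magnitude_threshold = 1e-4, sigma = 1.3)
  classify <- function(img) {
    sm <- gaussian_smooth(img, cfg$sigma)
    g <- compute_gradient(sm)
    list(cm = classify_pixels(sm, g$magnitude, g$direction, cfg), sm = sm, g = g)
  }
  # independent oracle for axis-aligned structures: compare each pixel with
  # its two integer neighbours along the dominant gradient axis
  oracle_class <- function(sm, g, r, c) {
    if (abs(cos(g$direction[r, c])) > abs(sin(g$direction[r, c]))) {
      step <- sign(cos(g$direction[r, c]))
      f <- sm[r, c + step]; b <- sm[r, c - step]
    } else {
      step <- sign(sin(g$direction[r, c]))
      f <- sm[r + step, c]; b <- sm[r - step, c]
    }
    cc <- sm[r, c]
    if (cc > f && cc > b) "Ridge"
    else if (cc < f && cc < b) "Valley"
    else if (f >= b) "Rising" else "Falling"
  }
  # dark vertical line -> Valley on the line, oracle agreement on interior
  dark <- matrix(0.8, 15, 15); dark[, 8] <- 0.2
  res <- classify(dark)
  expect_true(all(res$cm[3:13, 8] == PIXEL_CLASSES[["Valley"]]))
  # bright line -> Ridge on the crest
  bright <- matrix(0.2, 15, 15); bright[, 8] <- 0.8
  resb <- classify(bright)
  expect_true(all(resb$cm[3:13, 8] == PIXEL_CLASSES[["Ridge"]]))
  for (r in 3:13) for (cl in c(6, 8, 10)) {
    expect_equal(unname(res$cm[r, cl]),
                 unname(PIXEL_CLASSES[[oracle_class(res$sm, res$g, r, cl)]]))
    expect_equal(unname(resb$cm[r, cl]),
                 unname(PIXEL_CLASSES[[oracle_class(resb$sm, resb$g, r, cl)]]))
  }
  # step edge: a Rising band on the slope, no pixel both classes, none Falling
  stepimg <- matrix(0.2, 15, 15); stepimg[, 8:15] <- 0.8
  ress <- classify(stepimg)
  slope <- ress$cm[3:13, 6:9]
  expect_true(all(slope %in% PIXEL_CLASSES[c("Rising", "Background")]))
  expect_true(any(slope == PIXEL_CLASSES[["Rising"]]))
  expect_false(any(ress$cm == PIXEL_CLASSES[["Falling"]]))
  # constant image -> all Background, and the partition is total
  constm <- classify(matrix(0.5, 12, 12))$cm
  expect_true(all(constm == PIXEL_CLASSES[["Background"]]))
  expect_true(all(res$cm %in% PIXEL_CLASSES))
})

test_that("cleanup fills closed valley rings and drops noise and debris", {
  cfg <- seg_config(min_area = 500)
  img <- disk_image(radius = 30, rim_width = 4)
  sm <- gaussian_smooth(img, cfg$sigma)
  g <- compute_gradient(sm)
  cm <- classify_pixels(sm, g$magnitude, g$direction, cfg)
  out <- cleanup_and_fill(cm, cfg)
  expect_equal(nrow(out$components), 1)
  expect_equal(out$components$area_px2, pi * 30^2, tolerance = 0.05)
  # isolated boundary fragment surrounded by Background is removed
  cm2 <- matrix(PIXEL_CLASSES[["Background"]], 21, 21)
  cm2[10, 9:11] <- PIXEL_CLASSES[["Ridge"]]
  out2 <- cleanup_and_fill(cm2, cfg)
  expect_equal(sum(out2$mask), 0)
  # a filled blob below min_area is removed by size exclusion
  cm3 <- matrix(PIXEL_CLASSES[["Background"]], 41, 41)
  cm3[15:28, 15:28] <- PIXEL_CLASSES[["Rising"]]  # ~196 px2 after erosion
  out3 <- cleanup_and_fill(cm3, seg_config(min_area = 500))
  expect_equal(sum(out3$mask), 0)
  expect_gt(sum(cleanup_and_fill(cm3, seg_config(min_area = 10))$mask), 0)
})

test_that("segment_stack recovers synthetic wells and their ground truth", {
  w <- generate_organoid_stack(small_well_spec(noise_sigma = 0.01, seed = 42L))
  seg <- segment_stack(w$stack)
  tr <- rowSums(w$truth$per_organoid_area)
  for (f in seq_along(seg$masks)) {
    expect_gte(iou(seg$masks[[f]], w$truth$masks[[f]]), 0.8)
    expect_lt(abs(seg$total_area[f] - tr[f]) / tr[f], 0.1)
  }
  # determinism
  seg2 <- segment_stack(w$stack)
  expect_identical(seg$masks, seg2$masks)
  # debris exclusion: no ground-truth debris pixel survives in any mask
  for (f in seq_along(seg$masks))
    expect_false(any(seg$masks[[f]] & w$truth$debris_masks[[f]]))
})

test_that("blank stacks segment to zero area", {
  blank <- image_stack(replicate(3, matrix(0.5, 64, 64), simplify = FALSE),
                       times = c(0, 10, 20))
  seg <- segment_stack(blank)
  expect_equal(seg$total_area, c(0, 0, 0))
})

test_that("segmentation is robust to 90-degree rotation", {
  w <- generate_organoid_stack(small_well_spec(noise_sigma = 0.005, seed = 13L))
  frame <- w$stack$frames[[1]]
  a <- sum(cleanup_and_fill(
    local({
      sm <- gaussian_smooth(frame, 1.3); g <- compute_gradient(sm)
      classify_pixels(sm, g$magnitude, g$direction, seg_config())
    }), seg_config())$mask)
  rot <- t(frame)[ncol(frame):1, ]
  b <- sum(cleanup_and_fill(
    local({
      sm <- gaussian_smooth(rot, 1.3); g <- compute_gradient(sm)
      classify_pixels(sm, g$magnitude, g$direction, seg_config())
    }), seg_config())$mask)
  expect_lt(abs(a - b) / a, 0.02)
})

test_that("measured area is non-decreasing for noise-free growing organoids", {
  w <- generate_organoid_stack(small_well_spec(noise_sigma = 0, growth_rate = 1,
                                               n_debris = 0L, seed = 21L))
  seg <- segment_stack(w$stack)
  expect_true(all(diff(seg$total_area) >= 0))
})
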