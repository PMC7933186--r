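test_that("enhancement removes constant background and validates parameters", {
  flat <- matrix(7, 40, 40)
  expect_lt(max(abs(enhance(flat))), 1e-8)
  expect_error(enhance(flat, sigma_bg = 1, sigma_spot = 2), "sigma_bg")
  expect_error(enhance(matrix(1, 2, 2)), "3x3")
  expect_error(enhance(array(1, c(8, 8, 3))), "2-D")
  # a single bright pixel becomes a positive blob centered on that pixel
  img <- matrix(0, 41, 41); img[21, 21] <- 100
  e <- enhance(img, sigma_bg = 8, sigma_spot = 1.5)
  expect_equal(which(e == max(e), arr.ind = TRUE)[1, ], c(row = 21, col = 21))
  expect_gt(max(e), 0)
})

test_that("enhanced maxima stay within one pixel of planted Gaussian centers", {
  set.seed(3)
  centers <- cbind(c(20, 45, 60), c(30, 15, 55))
  img <- spot_image(80, centers, amplitude = 50, noise_sd = 10,
                    background = 100)
  e <- enhance(img)
  for (i in seq_len(nrow(centers))) {
    win <- e[centers[i, 1] + (-4:4), centers[i, 2] + (-4:4)]
    peak <- which(win == max(win), arr.ind = TRUE)[1, ]
    expect_lte(max(abs(peak - 5)), 1)
  }
})

test_that("detection finds planted spots, respects the ROI and excludes borders", {
  set.seed(4)
  centers <- cbind(c(15, 40, 62, 30), c(20, 50, 18, 70))
  img <- spot_image(80, centers, amplitude = 60, noise_sd = 8,
                    background = 50)
  ss <- detect_spots(img, sigma_bg = 8)
  expect_equal(nrow(ss$spots), 4)
  for (i in seq_len(nrow(centers))) {
    d <- sqrt((ss$spots$y - centers[i, 1])^2 + (ss$spots$x - centers[i, 2])^2)
    expect_lte(min(d), 2)
  }
  # blank image: no spots
  blank <- matrix(stats::rnorm(80 * 80, 50, 8), 80, 80)
  expect_equal(nrow(detect_spots(blank, sigma_bg = 8)$spots), 0)
  # mask excludes the spot centered outside the ROI
  mask <- matrix(FALSE, 80, 80); mask[, 1:40] <- TRUE
  inroi <- detect_spots(img, sigma_bg = 8, mask = mask)
  expect_equal(nrow(inroi$spots), 2)  # columns 20 and 18 only
  expect_error(detect_spots(img, mask = matrix(TRUE, 3, 3)), "mask shape")
})

test_that("plateau maxima yield one spot at the smallest coordinate", {
  # operate on a pre-enhanced image so constructed plateaus stay exactly flat
  img <- matrix(0, 30, 30)
  img[14:15, 14:15] <- 10  # flat 2x2 plateau
  ss <- detect_spots(img, threshold = 1, pre_enhanced = TRUE)
  expect_equal(nrow(ss$spots), 1)
  expect_equal(c(ss$spots$y, ss$spots$x), c(14, 14))
  # a shoulder plateau adjacent to a higher peak is not a spot
  img2 <- matrix(0, 30, 30)
  img2[10, 10:12] <- c(10, 8, 8)  # 8,8 plateau beside the 10 peak
  ss2 <- detect_spots(img2, threshold = 1, pre_enhanced = TRUE)
  expect_equal(nrow(ss2$spots), 1)
  expect_equal(c(ss2$spots$y, ss2$spots$x), c(10, 10))
})

test_that("spot count is monotone in threshold and scale-equivariant", {
  set.seed(6)
  img <- spot_image(70, cbind(c(20, 50), c(25, 45)), amplitude = 40,
                    noise_sd = 6, background = 30)
  thresholds <- c(0.5, 2, 5, 10, 30)
  counts <- vapply(thresholds, function(th)
    nrow(detect_spots(img, sigma_bg = 8, threshold = th)$spots), integer(1))
  expect_true(all(diff(counts) <= 0))
  s1 <- detect_spots(img, sigma_bg = 8, threshold = 3)$spots
  s2 <- detect_spots(img * 11, sigma_bg = 8, threshold = 33)$spots
  expect_equal(s1[c("x", "y")], s2[c("x", "y")])
  # the automatic robust threshold is scale-equivariant by construction
  a1 <- detect_spots(img, sigma_bg = 8)$spots
  a2 <- detect_spots(img * 11, sigma_bg = 8)$spots
  expect_equal(a1[c("x", "y")], a2[c("x", "y")])
})

test_that("ROI counting respects the mask", {
  set.seed(8)
  centers <- cbind(c(20, 20, 50, 50), c(15, 55, 15, 55))
  img <- spot_image(70, centers, amplitude = 60, noise_sd = 5,
                    background = 20)
  ss <- detect_spots(img, sigma_bg = 8)
  full <- matrix(TRUE, 70, 70)
  expect_equal(count_in_roi(ss, full), nrow(ss$spots))
  half <- matrix(FALSE, 70, 70); half[, 1:35] <- TRUE
  expect_equal(count_in_roi(ss, half), 2L)
  empty <- structure(list(spots = data.frame(x = integer(0), y = integer(0),
                                             intensity = numeric(0)),
                          params = list()), class = "spot_set")
  expect_equal(count_in_roi(empty, full), 0L)
})
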