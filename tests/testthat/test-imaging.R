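test_that("mean filter: constant, hand case, impulse, oracle", {
  const7 <- matrix(7, 5, 5)
  expect_equal(mean_filter(const7, 3), const7)

  img9 <- matrix(as.numeric(1:9), 3, 3, byrow = TRUE)
  expect_equal(mean_filter(img9, 3)[2, 2], 5)  # mean of 1..9

  imp <- matrix(0, 5, 5); imp[3, 3] <- 255
  expect_equal(mean_filter(imp, 3)[3, 3], floor(255 / 9 + 0.5))

  expect_error(mean_filter(const7, 4), "odd")

  set.seed(2)
  img <- random_image(12, 9)
  expect_equal(mean_filter(img, 3),
               oracle_window_filter(img, 3L, mean))
  expect_equal(mean_filter(img, 5),
               oracle_window_filter(img, 5L, mean))
})

test_that("median filter: constant, impulse removal, oracle", {
  const <- matrix(42, 6, 6)
  expect_equal(median_filter(const, 3), const)

  sp <- matrix(100, 7, 7); sp[4, 4] <- 255
  expect_true(all(median_filter(sp, 3) == 100))

  expect_error(median_filter(const, 6), "odd")

  set.seed(3)
  img <- random_image(11, 13)
  expect_equal(median_filter(img, 3),
               oracle_window_filter(img, 3L, median))
  expect_equal(median_filter(img, 5),
               oracle_window_filter(img, 5L, median))
})

test_that("skull removal zeroes exactly the supra-threshold pixels", {
  set.seed(4)
  img <- random_image(4, 4)
  expect_equal(remove_skull(img, 255), img)
  pos <- matrix(c(0, 5, 0, 9), 2, 2)
  expect_equal(remove_skull(pos, 0), matrix(0, 2, 2))

  out <- remove_skull(img, 200)
  expect_equal(sum(out == 0 & img != 0), sum(img > 200 & img != 0))
  expect_true(all(out <= img))                       # anti-extensive
  expect_equal(out[img <= 200], img[img <= 200])     # rest untouched
})

test_that("band segmentation marks the closed interval", {
  set.seed(5)
  img <- random_image(6, 6)
  expect_true(all(segment_hemorrhage(img, 0, 255) == 255))

  img[2, 2] <- 10
  m10 <- segment_hemorrhage(img, 10, 10)
  expect_equal(m10 == 255, img == 10)

  m <- segment_hemorrhage(img, 130, 200)
  expect_equal(m == 255, img >= 130 & img <= 200)  # elementwise oracle
  expect_error(segment_hemorrhage(img, 201, 200), "alpha1")

  # idempotence on its own 0/255 output when the band covers 255 not 0
  m2 <- segment_hemorrhage(img, 130, 255)
  expect_equal(segment_hemorrhage(m2, 130, 255), m2)
})

test_that("erosion and dilation match the set-definition oracles", {
  se <- structuring_element(3)

  full <- matrix(255, 3, 3)
  er <- erode(full, se)
  expect_equal(sum(er == 255), 1L)      # only the center survives
  expect_equal(er[2, 2], 255)

  empty <- matrix(0, 4, 4)
  expect_equal(erode(empty, se), empty)
  expect_equal(dilate(empty, se), empty)

  single <- matrix(0, 5, 5); single[3, 3] <- 255
  expect_equal(dilate(single, se),
               matrix(ifelse(abs(row(single) - 3) <= 1 &
                             abs(col(single) - 3) <= 1, 255, 0), 5, 5))

  set.seed(6)
  for (trial in 1:5) {
    msk <- random_mask(sample(4:10, 1), sample(4:10, 1))
    expect_equal(erode(msk, se), oracle_erode(msk, se))
    expect_equal(dilate(msk, se), oracle_dilate(msk, se))
  }

  # asymmetric structuring element still matches the literal definitions
  se_a <- matrix(c(0, 1, 0, 0, 1, 1, 0, 0, 1), 3, 3)
  msk <- random_mask(8, 8)
  expect_equal(erode(msk, se_a), oracle_erode(msk, se_a))
  expect_equal(dilate(msk, se_a), oracle_dilate(msk, se_a))
})

test_that("morphology duality and extensivity properties hold", {
  se <- structuring_element(3)
  compl <- function(m) matrix(ifelse(m == 255, 0, 255), nrow(m), ncol(m))
  set.seed(7)
  for (trial in 1:5) {
    msk <- random_mask(7, 9)
    # duality under complement for a symmetric SE: interior pixels only,
    # since the binary complement makes the zero padding foreground
    dual <- compl(erode(compl(msk), se))
    dil <- dilate(msk, se)
    inner_r <- 2:(nrow(msk) - 1); inner_c <- 2:(ncol(msk) - 1)
    expect_equal(dil[inner_r, inner_c], dual[inner_r, inner_c])
    # anti-extensive / extensive for SEs containing the origin
    expect_true(all(erode(msk, se) <= msk))
    expect_true(all(msk <= dilate(msk, se)))
  }
})

test_that("structuring elements are validated", {
  expect_error(structuring_element(4), "odd")
  bad <- matrix(1, 3, 3); bad[2, 2] <- 0
  expect_error(structuring_element(bad), "origin")
})

test_that("superimposition overwrites only the mask foreground", {
  set.seed(8)
  base <- random_image(6, 5)
  empty <- matrix(0, 6, 5)
  expect_equal(superimpose(base, empty), base)
  full <- matrix(255, 6, 5)
  expect_true(all(superimpose(base, full) == 255))
  msk <- random_mask(6, 5)
  out <- superimpose(base, msk)
  expect_equal(out, matrix(ifelse(msk == 255, 255, base), 6, 5))
  expect_error(superimpose(base, matrix(0, 5, 5)), "shape")
})

test_that("flattening is row-major and invertible", {
  img <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)
  expect_equal(flatten_image(img), c(1, 2, 3, 4))
  set.seed(9)
  for (trial in 1:3) {
    im <- random_image(sample(3:8, 1), sample(3:8, 1))
    expect_equal(unflatten_image(flatten_image(im), dim(im)), im)
  }
  expect_length(flatten_image(matrix(0, 128, 128)), 16384L)
})

test_that("threshold estimation averages per-image means", {
  expect_equal(estimate_alpha(list(matrix(50, 4, 4))), 50)
  expect_equal(estimate_alpha(list(matrix(0, 3, 3), matrix(100, 3, 3))),
               50)
  expect_error(estimate_alpha(list()), "empty")

  set.seed(10)
  imgs <- lapply(1:4, function(i) random_image(5, 6))
  manual <- mean(sapply(imgs, function(im) {
    tot <- 0
    for (v in im) tot <- tot + v
    tot / length(im)
  }))
  expect_equal(estimate_alpha(imgs), manual)

  # region-restricted calibration
  reg <- matrix(0, 5, 6); reg[1:2, ] <- 255
  expect_equal(estimate_alpha(imgs[1], list(reg)),
               mean(imgs[[1]][1:2, ]))
})

test_that("CLAHE contract: constant preserved, range bounded, contrast up", {
  const <- matrix(120, 32, 32)
  expect_equal(clahe_enhance(const, tiles = c(4, 4)), const)

  set.seed(11)
  img <- random_image(32, 32)
  out <- clahe_enhance(img, tiles = c(4, 4))
  expect_true(min(out) >= 0 && max(out) <= 255)

  # low-contrast ramp gains dynamic range
  ramp <- matrix(rep(round(seq(100, 140, length.out = 40)), each = 40),
                 40, 40)
  out2 <- clahe_enhance(ramp, tiles = c(4, 4), clip = 4)
  expect_true(diff(range(out2)) >= diff(range(ramp)))

  expect_error(clahe_enhance(img, tiles = c(64, 64)), "larger than image")
  expect_error(clahe_enhance(img, distribution = "rayleigh"), "uniform")

  # dimensions not divisible by the tile grid are padded internally
  odd <- random_image(33, 35)
  expect_equal(dim(clahe_enhance(odd, tiles = c(4, 4))), c(33L, 35L))
})

test_that("pipeline recovers a planted blob and degrades gracefully", {
  cfg <- preprocess_config(clahe = NULL, noise_filter = NULL,
                           alpha = 200, alpha1 = 130, alpha2 = 200)
  ph <- synth_phantom(size = 64, blob = list(intensity = c(150, 190)),
                      noise_sd = 0, seed = 12)
  res <- preprocess_pipeline(ph$image, cfg)
  planted <- ph$blob_mask == 255
  recovered <- res$stages$raw_mask == 255
  expect_gte(sum(planted & recovered) / sum(planted), 0.9)

  # phantom without blob, band outside brain intensities -> empty mask,
  # output equals the skull-removed image
  ph0 <- synth_phantom(size = 64, blob = NULL, noise_sd = 0, seed = 13)
  res0 <- preprocess_pipeline(ph0$image, cfg)
  expect_true(all(res0$mask == 0))
  expect_equal(res0$enhanced, res0$stages$noskull)

  # all-zero image flows through as all zeros
  z <- matrix(0, 32, 32)
  resz <- preprocess_pipeline(z, preprocess_config())
  expect_true(all(resz$enhanced == 0))
  expect_true(all(resz$mask == 0))
  expect_true(all(resz$pattern == 0))

  # skull ring above alpha is removed, brain preserved
  skull_px <- ph0$regions$skull
  expect_true(all(res0$stages$noskull[skull_px] == 0))
  brain_px <- ph0$regions$brain
  expect_true(mean(res0$stages$noskull[brain_px] > 0) > 0.99)
})

test_that("pipeline is deterministic", {
  ph <- synth_phantom(size = 48, seed = 14)
  cfg <- preprocess_config()
  expect_identical(preprocess_pipeline(ph$image, cfg),
                   preprocess_pipeline(ph$image, cfg))
})
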