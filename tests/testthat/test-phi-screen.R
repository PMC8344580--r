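grayThumb <- function(h, w, value = 255L) {
  array(value, dim = c(h, w, 3L))
}

test_that("an all-white thumbnail has zero dark regions", {
  expect_equal(nrow(detectDarkRegions(grayThumb(40, 40))), 0L)
  expect_error(detectDarkRegions(array(0L, dim = c(0, 0, 3))), "empty")
})

test_that("a planted black rectangle is measured exactly", {
  img <- grayThumb(50, 40)
  img[1:20, 1:20, ] <- 0L      # 400 / 2000 pixels = 0.20
  reg <- detectDarkRegions(img)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$area_fraction, 0.20)
  expect_equal(reg$n_pixels, 400L)
  expect_identical(c(reg$ymin, reg$ymax, reg$xmin, reg$xmax),
                   c(1L, 20L, 1L, 20L))
})

test_that("two sub-threshold blocks are found but do not flag", {
  img <- grayThumb(40, 50)     # 2000 px
  img[1:10, 1:10, ] <- 10L     # 100 px = 5%
  img[25:34, 30:39, ] <- 10L   # 100 px = 5%
  params <- darkRegionParams(minAreaFraction = 0.08)
  reg <- detectDarkRegions(img, params)
  expect_equal(nrow(reg), 2L)
  expect_true(all(reg$area_fraction == 0.05))
  dec <- screenWSI(img, params, imageId = "two-blocks")
  expect_false(dec@flagged)
})

test_that("the area-fraction boundary flags inclusively (>=)", {
  img <- grayThumb(20, 20)
  img[1:4, 1:5, ] <- 0L        # exactly 20/400 = 0.05
  dec <- screenWSI(img, darkRegionParams(minAreaFraction = 0.05))
  expect_true(dec@flagged)
})

test_that("flagging is monotone in threshold and in planted area", {
  set.seed(4)
  img <- array(sample(120:255, 64 * 64 * 3, TRUE), dim = c(64, 64, 3))
  img[1:16, 1:16, ] <- 50L
  flagged_at <- function(thr) screenWSI(
    img, darkRegionParams(luminanceThreshold = thr), imageId = "m")@flagged
  thresholds <- c(30, 51, 80, 120)
  flags <- vapply(thresholds, flagged_at, logical(1))
  ## once a threshold flags, every larger threshold must flag too
  expect_true(all(diff(as.integer(flags)) >= 0))
  ## growing the dark block never un-flags
  img2 <- img; img2[1:32, 1:32, ] <- 50L
  expect_true(screenWSI(img2, darkRegionParams(), imageId = "m2")@flagged ||
                !screenWSI(img, darkRegionParams(), imageId = "m")@flagged)
})

test_that("component labeling matches independent oracles", {
  skip_if_not_installed("EBImage")
  set.seed(21)
  for (i in 1:6) {
    mask <- matrix(runif(64 * 64) < 0.35, 64, 64)
    ## 4-connectivity against EBImage::bwlabel
    ours4 <- pathbroker:::.labelComponents(mask, 4L)
    eb <- EBImage::bwlabel(mask * 1)
    expect_identical(componentAreas(ours4), componentAreas(eb))
    ## 8-connectivity against the naive stack-based flood fill
    ours8 <- pathbroker:::.labelComponents(mask, 8L)
    expect_identical(componentAreas(ours8),
                     componentAreas(oracleLabelComponents(mask, 8L)))
  }
})

test_that("screening a container is pure and uses the planted thumbnail", {
  spec <- tinySpec(seed = 6)
  ids <- list(image_id = "SCRN-1", barcode = "S19QQQQQ", accession = "S19-0001",
              mrn = "7654321", name = "Helen Weiss", scan_date = "2019-09-09")
  clean <- tempfile(fileext = ".svs")
  generateWSI(spec, ids, clean)
  cont <- readContainer(clean)
  before <- readBin(clean, "raw", file.size(clean))
  dec <- screenWSI(cont)
  expect_false(dec@flagged)
  expect_identical(readBin(clean, "raw", file.size(clean)), before)

  dark_spec <- spec; dark_spec$darkBlockFraction <- 0.10
  dark <- tempfile(fileext = ".svs")
  gt <- generateWSI(dark_spec, ids, dark)
  dec2 <- screenWSI(readContainer(dark),
                    darkRegionParams(minAreaFraction = 0.05))
  expect_true(dec2@flagged)
  ## the leading region's area agrees with the planted fraction
  expect_equal(dec2@regions$area_fraction[1], gt$darkFraction,
               tolerance = 0.02)
})

test_that("degenerate screening parameters are rejected", {
  expect_error(darkRegionParams(luminanceThreshold = 0), "0, 255")
  expect_error(darkRegionParams(minAreaFraction = 1), "0, 1")
  expect_error(darkRegionParams(connectivity = 6), "4 or 8")
})
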