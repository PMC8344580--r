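wsiIds <- function(seed = 1) {
  list(image_id = sprintf("DEAD%04d-BEEF", seed), barcode = "S12NSKJA",
       accession = "S12-0042", mrn = "1482928", name = "JANE DOE",
       scan_date = "2019-06-02")
}

writeFixtureWSI <- function(spec = tinySpec(), ids = wsiIds(),
                            path = tempfile(fileext = ".svs")) {
  gt <- generateWSI(spec, ids, path)
  list(path = path, gt = gt, ids = ids)
}

test_that("sub-images are classified with their planted roles", {
  spec <- tinySpec()
  spec$wsi$levels <- 3L
  fx <- writeFixtureWSI(spec)
  cont <- readContainer(fx$path)
  expect_identical(subImages(cont)$role, fx$gt$roles)
  expect_equal(nrow(subImages(cont)), 6L)  # 3 levels + thumb + label + macro
})

test_that("a bare single-level TIFF reads as one pyramid level", {
  path <- tempfile(fileext = ".tif")
  pathbroker:::.tiffWrite(list(list(
    width = 64L, height = 48L,
    pixels = as.raw(rep(200L, 64 * 48 * 3)), tiled = TRUE, tile = c(64L, 64L),
    description = "bare base")), path)
  cont <- readContainer(path)
  expect_identical(subImages(cont)$role, "pyramid_level")
})

test_that("non-TIFF and truncated files error with the failing offset", {
  bad <- tempfile()
  writeBin(charToRaw("not a tiff at all"), bad)
  expect_error(readContainer(bad), "not a TIFF")
  fx <- writeFixtureWSI()
  trunc <- tempfile(fileext = ".svs")
  bytes <- readBin(fx$path, "raw", 600)
  writeBin(bytes, trunc)
  expect_error(readContainer(trunc), "offset")
})

test_that("stripping removes label/macro and every planted byte string", {
  fx <- writeFixtureWSI()
  cont <- readContainer(fx$path)
  ## the planted label text is present in the source bytes
  expect_gt(sum(pathbroker:::.scanFileForBytes(fx$path, "JANE DOE")$hits), 0)
  out <- tempfile(fileext = ".svs")
  stripped <- stripAssociatedImages(cont, out)
  expect_false(any(c("label", "macro") %in% subImages(stripped)$role))
  expect_identical(sum(pathbroker:::.scanFileForBytes(out, "JANE DOE")$hits), 0L)
  ## libtiff still opens the stripped file
  expect_length(tiff::readTIFF(out, all = TRUE),
                nrow(subImages(stripped)))
})

test_that("stripping is a no-op on an already-stripped file", {
  fx <- writeFixtureWSI()
  o1 <- tempfile(fileext = ".svs"); o2 <- tempfile(fileext = ".svs")
  s1 <- stripAssociatedImages(readContainer(fx$path), o1)
  stripAssociatedImages(s1, o2)
  expect_identical(readBin(o1, "raw", file.size(o1)),
                   readBin(o2, "raw", file.size(o2)))
})

test_that("in-place editing is refused", {
  fx <- writeFixtureWSI()
  cont <- readContainer(fx$path)
  expect_error(stripAssociatedImages(cont, fx$path), "in-place")
})

test_that("metadata scrubbing masks values in place, preserving structure", {
  fx <- writeFixtureWSI()
  out <- tempfile(fileext = ".svs")
  scr <- scrubMetadata(readContainer(fx$path), sensitiveFieldPolicy(), out)
  md <- metadataFields(scr)
  before <- metadataFields(readContainer(fx$path))
  ## same keys in the same order, identical value byte lengths
  expect_identical(md$key, before$key)
  expect_identical(nchar(md$value), nchar(before$value))
  masked <- md$key %in% c("Date", "Time", "ScanScope ID", "Barcode",
                          "Filename", "User")
  expect_true(all(grepl("^X+$", md$value[masked])))
  ## spatial resolution preserved
  expect_identical(md$value[md$key == "MPP"], "0.25")
  expect_identical(file.size(out), file.size(fx$path))  # no offset shifts
})

test_that("degenerate policies are rejected", {
  expect_error(sensitiveFieldPolicy(character(0)), "at least one")
  expect_error(sensitiveFieldPolicy(c("Date", "MPP")), "geometry")
})

test_that("verification passes on a clean pipeline and localizes failures", {
  fx <- writeFixtureWSI()
  out <- tempfile(fileext = ".svs")
  rep <- deidentifyImage(fx$path, out, identifiers = unlist(fx$ids[
    c("barcode", "name", "mrn", "image_id")]))
  expect_true(rep$pass)
  expect_identical(rep$checks$pass, rep(TRUE, 4))

  ## (a) a surviving barcode is reported with its offset: strip only,
  ##     leaving the description unscrubbed
  o2 <- tempfile(fileext = ".svs")
  stripAssociatedImages(readContainer(fx$path), o2)
  v2 <- verifyDeid(fx$path, o2, fx$ids$barcode)
  expect_false(v2$pass)
  bad <- v2$checks[v2$checks$check == "no_identifier_bytes", ]
  expect_false(bad$pass)
  expect_match(bad$detail, "offset")

  ## (c) a single mutated payload byte fails pixel conservation
  o3 <- tempfile(fileext = ".svs")
  file.copy(out, o3)
  cont <- readContainer(o3)
  rng <- cont@.parsed$payloads[[1]]
  b <- readBin(o3, "raw", file.size(o3))
  pos <- rng[1, "offset"] + 10
  b[pos] <- as.raw(bitwXor(as.integer(b[pos]), 255L))
  writeBin(b, o3)
  v3 <- verifyDeid(fx$path, o3, character(0))
  expect_false(v3$checks$pass[v3$checks$check == "pyramid_pixels_identical"])
})

test_that("pyramid pixels are conserved bitwise and match libtiff's view", {
  for (seed in c(2, 9)) {
    fx <- writeFixtureWSI(tinySpec(seed = seed), wsiIds(seed))
    out <- tempfile(fileext = ".svs")
    deidentifyImage(fx$path, out)
    orig <- readContainer(fx$path); deid <- readContainer(out)
    base_o <- which(subImages(orig)$role == "pyramid_level")[1]
    base_d <- which(subImages(deid)$role == "pyramid_level")[1]
    po <- pathbroker:::.tiffDecodePixels(orig@.parsed, orig@.parsed$ifds[[base_o]])
    pd <- pathbroker:::.tiffDecodePixels(deid@.parsed, deid@.parsed$ifds[[base_d]])
    expect_identical(po, pd)
    ## cross-check our decoder against libtiff on the de-identified file
    lt <- tiff::readTIFF(out, all = TRUE)[[base_d]]
    w <- subImages(deid)$width[base_d]; h <- subImages(deid)$height[base_d]
    ours <- aperm(array(as.integer(pd), dim = c(3L, w, h)), c(3, 2, 1)) / 255
    expect_equal(lt, ours, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("the full pipeline is idempotent", {
  fx <- writeFixtureWSI()
  o1 <- tempfile(fileext = ".svs"); o2 <- tempfile(fileext = ".svs")
  deidentifyImage(fx$path, o1)
  deidentifyImage(o1, o2)
  expect_identical(readBin(o1, "raw", file.size(o1)),
                   readBin(o2, "raw", file.size(o2)))
})
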