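test_that("date truncation keeps the year only and rejects garbage", {
  expect_identical(truncateDate("2020-03-15"), "2020")
  expect_identical(truncateDate("1999-12-31"), "1999")
  expect_identical(truncateDate("2020-02-29"), "2020")  # leap day
  expect_error(truncateDate("not-a-date"), "unparseable")
  expect_error(truncateDate("2020-13-40"), "unparseable")
})

test_that("the worked redaction example produces the expected text", {
  r <- redactReport("S20-0123 from JANE DOE on 03/15/2020",
                    patient = list(name = "Jane Doe"))
  expect_identical(r@deidText, "[ACCESSION] from [PATIENT] on [DATE-2020]")
  expect_identical(r@spans$category, c("accession", "name", "date"))
})

test_that("identifier-free text passes through unchanged with zero spans", {
  txt <- "Sections show benign parenchyma without atypia."
  r <- redactReport(txt)
  expect_identical(r@deidText, txt)
  expect_equal(nrow(r@spans), 0L)
  expect_identical(redactReport("")@deidText, "")
})

test_that("an embedded MRN is replaced by the MRN placeholder", {
  r <- redactReport("The patient, record 1482928, was seen in clinic.")
  expect_identical(r@deidText,
                   "The patient, record [MRN], was seen in clinic.")
  expect_identical(r@spans$category, "mrn")
})

test_that("all three date dialects redact and keep their year", {
  r <- redactReport("Seen 2019-07-04, then 7/4/2019, then July 4, 2019.")
  expect_identical(
    r@deidText, "Seen [DATE-2019], then [DATE-2019], then [DATE-2019].")
  r2 <- redactReport("Scanned 06/02/19 at the archive.")
  expect_identical(r2@deidText, "Scanned [DATE-2019] at the archive.")
})

test_that("both name orders and lone surnames are caught", {
  p <- list(name = "Jane Doe")
  expect_identical(redactReport("Reviewed for Doe, Jane today.", p)@deidText,
                   "Reviewed for [PATIENT] today.")
  expect_identical(redactReport("Ms. Doe returned.", p)@deidText,
                   "Ms. [PATIENT] returned.")
})

test_that("spans reconstruct the de-identified text from the original", {
  spec <- tinySpec(seed = 3, phiDensity = 5)
  set.seed(99)
  pat <- list(mrn = "8273645", name = "Victor Novak")
  rep <- generateReport(spec, pat, list(accession = "H19-0042"))
  r <- redactReport(rep$text, patient = pat)
  ## rebuild deidText by substituting each recorded span
  txt <- rep$text
  for (i in rev(seq_len(nrow(r@spans))))
    txt <- paste0(substr(txt, 1, r@spans$start[i] - 1L), r@spans$placeholder[i],
                  substr(txt, r@spans$end[i] + 1L, nchar(txt)))
  expect_identical(txt, r@deidText)
})

test_that("recall on planted PHI is 100% over many generated reports", {
  spec <- tinySpec(seed = 41, phiDensity = 4)
  set.seed(spec$seed)
  recalls <- replicate(200, {
    pat <- list(mrn = as.character(sample(1000000:9999999, 1)),
                name = paste(sample(pathbroker:::.GIVEN_NAMES, 1),
                             sample(pathbroker:::.FAMILY_NAMES, 1)))
    case <- list(accession = sprintf("S%02d-%04d", sample(18:21, 1),
                                     sample(1:9999, 1)))
    rep <- generateReport(spec, pat, case)
    redactionRecall(redactReport(rep$text, patient = pat), rep$spans)
  })
  expect_identical(unname(recalls), rep(1, 200))
})

test_that("redaction is a fixed point and preserves the year multiset", {
  spec <- tinySpec(seed = 13, phiDensity = 6)
  set.seed(7)
  pat <- list(mrn = "4455667", name = "Paula Quinn")
  rep <- generateReport(spec, pat, list(accession = "C20-0881"))
  r1 <- redactReport(rep$text, patient = pat)
  r2 <- redactReport(r1@deidText, patient = pat)
  expect_identical(r2@deidText, r1@deidText)
  expect_equal(nrow(r2@spans), 0L)
  expect_identical(dateYearMultiset(r1@deidText), dateYearMultiset(rep$text))
})

test_that("rule-set invariants are enforced", {
  expect_error(new("RedactionRuleSet", rules = data.frame(
    category = "mrn", pattern = "[0-9]{6,9}", placeholder = "[MRN-99]",
    stringsAsFactors = FALSE)), "no digits")
})

test_that("record de-identification follows the PHI field rules", {
  ks <- openKeyStore(tempfile(fileext = ".jsonl"))
  sl <- deidentifyRecord(list(barcode = "S20ABCDE", accession = "S20-0123",
                              part_id = 2L, block_id = 3L, stain = "H&E",
                              scanner_vendor = "leica",
                              scanner_model = "AT2"), "slide", ks)
  expect_true(is.na(sl$barcode))        # no slide HID family: dropped
  expect_identical(sl$part_id, 2L)      # part/block preserved verbatim
  expect_identical(sl$block_id, 3L)
  expect_match(sl$accession, "^C-")

  im <- deidentifyRecord(list(image_id = "GUID-1", barcode = "S20ABCDE",
                              file_path = "\\\\path\\to\\file.svs",
                              scan_date = "2019-06-02", quality_factor = 95L,
                              sequence_index = 4L), "image", ks)
  expect_identical(im$scan_date, "2019")
  expect_null(im$file_path)             # path dropped entirely
  expect_match(im$image_id, "^I-")

  pa <- deidentifyRecord(list(mrn = "1482928", name = "Jane Doe",
                              birth_date = "1960-05-04", npp_signed = TRUE),
                         "patient", ks)
  expect_null(pa$name)
  expect_identical(pa$birth_date, "1960")

  expect_error(deidentifyRecord(list(mrn = "1", ssn = "x"), "patient", ks),
               "failing closed")
  expect_error(deidentifyRecord(list(x = 1), "biopsy", ks), "unknown record")
})
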