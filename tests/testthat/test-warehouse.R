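test_that("ingest accepts well-formed records and reports counts", {
  wh <- ingestWarehouse(
    patients = list(list(mrn = "1482928", name = "Jane Doe",
                         birth_date = "1960-05-04", npp_signed = TRUE,
                         protocol_enrollments = "PR-001=consented")),
    cases = list(list(accession = "S20-0123", mrn = "1482928",
                      parts = "1:breast;2:lymph node")))
  expect_identical(unname(warehouseCounts(wh)[c("patients", "cases", "parts")]),
                   c(1L, 1L, 2L))
})

test_that("empty streams yield an empty warehouse with zero counts", {
  wh <- ingestWarehouse()
  expect_true(all(warehouseCounts(wh) == 0L))
})

test_that("referential integrity and grammar violations fail at load time", {
  p <- list(list(mrn = "111111", name = "A B", birth_date = "1970-01-01",
                 npp_signed = TRUE, protocol_enrollments = "PR-001=consented"))
  ca <- list(list(accession = "S20-0001", mrn = "111111", parts = "1:colon"))
  sl <- list(list(barcode = "S20ABCDE", accession = "S20-0001", part_id = 1,
                  block_id = 1, stain = "H&E", scanner_vendor = "leica",
                  scanner_model = "AT2"))
  ## image pointing at a barcode absent from the slide stream
  im <- list(list(image_id = "G-1", barcode = "S20ZZZZZ",
                  file_path = "x.svs", scan_date = "2020-01-01",
                  quality_factor = 95, sequence_index = 1))
  expect_error(ingestWarehouse(p, ca, sl, im), "dangling.*image.*G-1")
  ## duplicate patient
  expect_error(ingestWarehouse(c(p, p), ca), "duplicate")
  ## accession grammar
  bad <- list(list(accession = "X20-0001", mrn = "111111", parts = "1:colon"))
  expect_error(ingestWarehouse(p, bad), "grammar")
  ## report referencing a missing case
  expect_error(ingestWarehouse(p, ca, reports = list(
    list(accession = "S20-9999", text = "t", report_date = "2020-01-01"))),
    "dangling")
})

test_that("keyword cohort query equals a brute-force report scan", {
  tw <- tinyWarehouse(tinySpec(seed = 23, nPatients = 12))
  wh <- tw$wh; gw <- tw$gw
  res <- queryCohort(wh, cohortCriteria(reportKeywords = "carcinoma"))
  ## oracle: scan every raw report, collect matching accessions, then the
  ## images hanging off them
  acc <- unique(vapply(Filter(function(r) grepl("carcinoma", r$text,
                                                ignore.case = TRUE),
                              gw$reports), `[[`, "", "accession"))
  bc <- vapply(gw$slides, `[[`, "", "barcode")[
    vapply(gw$slides, `[[`, "", "accession") %in% acc]
  expected <- sort(vapply(gw$images, `[[`, "", "image_id")[
    vapply(gw$images, `[[`, "", "barcode") %in% bc])
  expect_setequal(res$image_id, expected)
  ## deterministic ordering by (accession, image_id)
  expect_identical(res, res[order(res$accession, res$image_id), ],
                   ignore_attr = TRUE)
})

test_that("cohort edge cases: protocol-only, empty date range, unknown protocol", {
  tw <- tinyWarehouse(tinySpec(seed = 5, nPatients = 6, consentRate = 1,
                               nppRate = 1))
  wh <- tw$wh
  all_imgs <- queryCohort(wh, cohortCriteria(protocolId = "PR-001"))
  expect_equal(nrow(all_imgs), unname(warehouseCounts(wh)["images"]))
  none <- queryCohort(wh, cohortCriteria(
    dateRange = c("1900-01-01", "1900-12-31")))
  expect_equal(nrow(none), 0L)
  expect_error(queryCohort(wh, cohortCriteria(protocolId = "NOPE")),
               "unknown protocol")
  expect_error(cohortCriteria(), "at least one criterion")
})

test_that("conjunctive criteria are anti-monotone", {
  tw <- tinyWarehouse(tinySpec(seed = 31, nPatients = 10))
  base <- queryCohort(tw$wh, cohortCriteria(protocolId = "PR-001"))
  narrowed <- queryCohort(tw$wh, cohortCriteria(protocolId = "PR-001",
                                                stains = "H&E",
                                                vendors = "leica"))
  expect_true(all(narrowed$image_id %in% base$image_id))
  expect_lte(nrow(narrowed), nrow(base))
})

test_that("consent gate matches per-patient brute force and partitions input", {
  spec <- tinySpec(seed = 17, nPatients = 50, consentRate = 0.6)
  tw <- tinyWarehouse(spec)
  imgs <- queryCohort(tw$wh, cohortCriteria(protocolId = "PR-001"))$image_id
  gate <- enforceConsent(tw$wh, imgs, "PR-001")
  expect_setequal(gate$included, oracleConsent(tw$gw, "PR-001"))
  ## exact partition
  expect_setequal(c(gate$included, gate$excluded$image_id), imgs)
  expect_length(intersect(gate$included, gate$excluded$image_id), 0L)
  ## idempotence on the included subset
  gate2 <- enforceConsent(tw$wh, gate$included, "PR-001")
  expect_identical(gate2$included, gate$included)
  expect_equal(nrow(gate2$excluded), 0L)
})

test_that("consent exclusion reasons follow NPP and protocol status", {
  p <- list(
    list(mrn = "100001", name = "A One", birth_date = "1970-01-01",
         npp_signed = TRUE, protocol_enrollments = "PR-001=consented"),
    list(mrn = "100002", name = "B Two", birth_date = "1970-01-01",
         npp_signed = FALSE, protocol_enrollments = "PR-001=consented"),
    list(mrn = "100003", name = "C Three", birth_date = "1970-01-01",
         npp_signed = TRUE, protocol_enrollments = "PR-001=unknown"),
    list(mrn = "100004", name = "D Four", birth_date = "1970-01-01",
         npp_signed = TRUE, protocol_enrollments = "PR-001=declined"))
  ca <- lapply(1:4, function(i) list(accession = sprintf("S20-%04d", i),
                                     mrn = sprintf("10000%d", i),
                                     parts = "1:skin"))
  sl <- lapply(1:4, function(i) list(
    barcode = sprintf("S20BC%03d", i), accession = sprintf("S20-%04d", i),
    part_id = 1, block_id = 1, stain = "H&E", scanner_vendor = "philips",
    scanner_model = "UFS"))
  im <- lapply(1:4, function(i) list(
    image_id = sprintf("IMG-%d", i), barcode = sprintf("S20BC%03d", i),
    file_path = "f.svs", scan_date = "2020-06-01", quality_factor = NA,
    sequence_index = i))
  wh <- ingestWarehouse(p, ca, sl, im)
  gate <- enforceConsent(wh, sprintf("IMG-%d", 1:4), "PR-001")
  expect_identical(gate$included, "IMG-1")
  expect_identical(
    gate$excluded$reason[match(c("IMG-2", "IMG-3", "IMG-4"),
                               gate$excluded$image_id)],
    c("npp_missing", "unknown_consent", "not_consented"))
})
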