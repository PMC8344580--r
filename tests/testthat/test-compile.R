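compileFixture <- function(spec, darkImageIds = character(0),
                           criteria = cohortCriteria(protocolId = "PR-001")) {
  dir <- tempfile("fx")
  fx <- generateFixtureSet(spec, dir, darkImageIds = darkImageIds)
  wh <- ingestWarehouse(fx$patients, fx$cases, fx$slides, fx$images,
                        fx$reports)
  ks <- openKeyStore(tempfile(fileext = ".jsonl"))
  out <- tempfile("export")
  man <- compileDataset(wh, criteria, ks, out, wsiDir = fx$paths$wsi_dir)
  list(fx = fx, wh = wh, ks = ks, out = out, man = man)
}

test_that("manifest counts equal the ground-truth consent expectation", {
  r <- compileFixture(tinySpec(seed = 51, nPatients = 8))
  expected <- oracleConsent(r$fx, "PR-001")
  expect_equal(nrow(r$man@included), length(expected))
  ## every included HID re-identifies to a consented image
  originals <- vapply(r$man@included$image_hid, reidentify, "", store = r$ks)
  expect_setequal(originals, expected)
  expect_identical(attr(r$man, "deid_failures"), 0L)
})

test_that("without consent nothing ships and every exclusion says so", {
  r <- compileFixture(tinySpec(seed = 52, nPatients = 5, consentRate = 0))
  expect_equal(nrow(r$man@included), 0L)
  expect_true(all(r$man@excluded$reason == "consent"))
  expect_equal(length(list.files(file.path(r$out, "images"))), 0L)
})

test_that("a planted dark block excludes its WSI via the PHI screen", {
  spec <- tinySpec(seed = 53, nPatients = 4, consentRate = 1, nppRate = 1)
  gw <- generateWarehouse(spec)
  dark_id <- gw$images[[1]]$image_id
  r <- compileFixture(spec, darkImageIds = dark_id)
  dark_hid <- assignHid(r$ks, "image", dark_id)
  expect_true(dark_hid %in%
                r$man@excluded$image_hid[r$man@excluded$reason == "phi_screen"])
  expect_false(dark_hid %in% r$man@included$image_hid)
  expect_false(file.exists(file.path(r$out, "images",
                                     paste0(dark_hid, ".svs"))))
})

test_that("no planted identifier byte survives anywhere in the export", {
  r <- compileFixture(tinySpec(seed = 54, nPatients = 6))
  expect_identical(scanDirForBytes(r$out, plantedIdentifiers(r$fx)), 0)
})

test_that("the manifest is reloadable and internally consistent", {
  r <- compileFixture(tinySpec(seed = 55, nPatients = 6))
  man <- jsonlite::fromJSON(file.path(r$out, "manifest.json"))
  expect_identical(nrow(man$included), nrow(r$man@included))
  ## every listed file exists; every HID resolves through the key store
  expect_true(all(file.exists(file.path(r$out, man$included$file))))
  expect_true(all(file.exists(file.path(r$out, man$included$report))))
  for (h in man$included$image_hid) expect_silent(reidentify(r$ks, h))
  for (h in man$included$case_hid) expect_silent(reidentify(r$ks, h))
  ## included and excluded are disjoint
  expect_length(intersect(r$man@included$image_hid,
                          r$man@excluded$image_hid), 0L)
  ## the key store must not live inside the export
  expect_false(startsWith(normalizePath(r$ks@path),
                          normalizePath(r$out)))
})

test_that("the audit log records every decision without PHI", {
  r <- compileFixture(tinySpec(seed = 56, nPatients = 5))
  audit <- readLines(file.path(r$out, "audit.jsonl"), warn = FALSE)
  expect_gte(length(audit), nrow(r$man@included))
  events <- vapply(lapply(audit, jsonlite::fromJSON), `[[`, "", "event")
  expect_true(all(events %in% c("consent_exclusion", "phi_screen",
                                "deid_failure", "release")))
})

test_that("the CLI wires fixtures, ingest and compile end to end", {
  fdir <- tempfile("clifx"); out <- tempfile("cliout")
  ksp <- tempfile(fileext = ".jsonl")
  expect_identical(cliMain(c("gen-fixtures", "--out", fdir, "--seed", "9",
                             "--patients", "4")), 0L)
  expect_identical(cliMain(c("ingest",
                             "--patients", file.path(fdir, "patients.jsonl"),
                             "--cases", file.path(fdir, "cases.jsonl"),
                             "--slides", file.path(fdir, "slides.csv"),
                             "--images", file.path(fdir, "images.csv"),
                             "--reports", file.path(fdir, "reports.jsonl"))), 0L)
  expect_identical(cliMain(c("compile", "--fixtures", fdir,
                             "--protocol", "PR-001", "--keystore", ksp,
                             "--out", out)), 0L)
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_error(cliMain(c("frobnicate")), "unknown subcommand")
})
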