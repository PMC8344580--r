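#' @include warehouse.R text-deid.R image-deid.R phi-screen.R keystore.R
NULL

#' Compile a de-identified research dataset
#'
#' The honest-broker pipeline end to end: query the cohort, gate it on
#' patient consent, de-identify every structured record (HIDs, year-only
#' dates), redact every report, strip and scrub every whole-slide image,
#' verify the result byte-for-byte, screen thumbnails for label-sticker
#' bleed-through, and write a manifest plus a JSON-lines audit log. The
#' re-identification key store lives *outside* the export directory --
#' keys never ship with the dataset -- and the export contains HIDs and
#' years only.
#'
#' @param warehouse a [PathWarehouse-class].
#' @param criteria a [CohortCriteria-class]; its `protocolId` is required
#'   (release is always consent-gated).
#' @param keystore a [HIDKeyStore-class] whose backing file must not lie
#'   inside `outDir`.
#' @param outDir export directory (created; must be writable).
#' @param wsiDir directory holding the source WSI files named by the image
#'   records' `file_path`.
#' @param screenParams a [DarkRegionParams-class].
#' @param policy a [SensitiveFieldPolicy-class].
#' @param rules a [RedactionRuleSet-class].
#' @param requestId identifier stamped into the manifest.
#' @return a [DatasetManifest-class] (also written to
#'   `outDir/manifest.json`). Attribute `deid_failures` counts
#'   verification failures (a nonzero count should map to a nonzero exit
#'   status in scripted use).
#' @export
compileDataset <- function(warehouse, criteria, keystore, outDir, wsiDir,
                           screenParams = darkRegionParams(),
                           policy = sensitiveFieldPolicy(),
                           rules = redactionRules(),
                           requestId = "request-001") {
  stopifnot(is(warehouse, "PathWarehouse"), is(criteria, "CohortCriteria"),
            is(keystore, "HIDKeyStore"))
  if (!length(criteria@protocolId))
    .stopf("compileDataset requires a protocolId in the criteria")
  ok <- dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir)) .stopf("output directory is unwritable: %s", outDir)
  ks_path <- normalizePath(keystore@path, mustWork = FALSE)
  if (startsWith(ks_path, paste0(normalizePath(outDir), .Platform$file.sep)))
    .stopf("key store must live outside the export directory")
  for (d in c("images", "reports", "records"))
    dir.create(file.path(outDir, d), showWarnings = FALSE)
  audit_path <- file.path(outDir, "audit.jsonl")
  if (file.exists(audit_path)) unlink(audit_path)
  audit <- function(event, ...) .writeJsonLines(
    list(c(list(ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), event = event),
           list(...))), audit_path, append = TRUE)

  cohort <- queryCohort(warehouse, criteria)
  gate <- enforceConsent(warehouse, cohort$image_id, criteria@protocolId)
  link <- .imageLinkage(warehouse)

  excluded <- list()
  for (i in seq_len(nrow(gate$excluded))) {
    ihid <- assignHid(keystore, "image", gate$excluded$image_id[i])
    audit("consent_exclusion", image_hid = ihid,
          reason = gate$excluded$reason[i])
    excluded[[length(excluded) + 1L]] <- data.frame(
      image_hid = ihid, reason = "consent", stringsAsFactors = FALSE)
  }

  included <- list()
  deid_failures <- 0L
  done_reports <- character(0)
  for (iid in gate$included) {
    row <- link[link$image_id == iid, ]
    ihid <- assignHid(keystore, "image", iid)
    chid <- assignHid(keystore, "case", row$accession)
    phid <- assignHid(keystore, "patient", row$mrn)
    pat <- warehouse@patients[warehouse@patients$mrn == row$mrn, ]
    src <- file.path(wsiDir,
                     warehouse@images$file_path[warehouse@images$image_id == iid])
    out_img <- file.path(outDir, "images", paste0(ihid, ".svs"))
    ids <- identifierBundle(mrn = row$mrn, accession = row$accession,
                            barcode = row$barcode, image_id = iid,
                            name = pat$name)
    rep <- tryCatch(
      deidentifyImage(src, out_img, identifiers = ids, policy = policy),
      error = function(e) e)
    if (inherits(rep, "error") || !rep$pass) {
      deid_failures <- deid_failures + 1L
      unlink(out_img)
      audit("deid_failure", image_hid = ihid,
            detail = if (inherits(rep, "error")) conditionMessage(rep)
                     else paste(rep$checks$check[!rep$checks$pass], collapse = ","))
      excluded[[length(excluded) + 1L]] <- data.frame(
        image_hid = ihid, reason = "deid_failure", stringsAsFactors = FALSE)
      next
    }
    dec <- screenWSI(attr(rep, "container"), screenParams, imageId = ihid)
    audit("phi_screen", image_hid = ihid, flagged = dec@flagged,
          n_regions = nrow(dec@regions),
          threshold = screenParams@luminanceThreshold,
          min_area = screenParams@minAreaFraction)
    if (dec@flagged) {
      unlink(out_img)
      excluded[[length(excluded) + 1L]] <- data.frame(
        image_hid = ihid, reason = "phi_screen", stringsAsFactors = FALSE)
      next
    }
    if (!chid %in% done_reports) {
      txts <- warehouse@reports$text[warehouse@reports$accession == row$accession]
      for (t in txts) {
        red <- redactReport(t, patient = list(name = pat$name), rules = rules,
                            caseHid = chid)
        cat(red@deidText, file = file.path(outDir, "reports",
                                           paste0(chid, ".txt")))
      }
      done_reports <- c(done_reports, chid)
    }
    audit("release", image_hid = ihid, case_hid = chid, patient_hid = phid)
    included[[length(included) + 1L]] <- data.frame(
      image_hid = ihid, case_hid = chid, patient_hid = phid,
      scan_year = truncateDate(row$scan_date), part_id = row$part_id,
      block_id = row$block_id, stain = row$stain,
      scanner_vendor = row$scanner_vendor,
      file = file.path("images", paste0(ihid, ".svs")),
      report = file.path("reports", paste0(chid, ".txt")),
      stringsAsFactors = FALSE)
  }

  inc <- if (length(included)) do.call(rbind, included) else
    data.frame(image_hid = character(0), case_hid = character(0),
               patient_hid = character(0), scan_year = character(0),
               part_id = integer(0), block_id = integer(0),
               stain = character(0), scanner_vendor = character(0),
               file = character(0), report = character(0),
               stringsAsFactors = FALSE)
  exc <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(image_hid = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  utils::write.csv(inc, file.path(outDir, "records", "images.csv"),
                   row.names = FALSE)

  manifest <- new("DatasetManifest", requestId = requestId, included = inc,
                  excluded = exc,
                  parameters = list(
                    protocol_id = criteria@protocolId,
                    luminance_threshold = screenParams@luminanceThreshold,
                    min_area_fraction = screenParams@minAreaFraction,
                    scrubbed_keys = policy@keys),
                  version = as.character(utils::packageVersion("pathbroker")))
  jsonlite::write_json(
    list(request_id = manifest@requestId, included = inc, excluded = exc,
         parameters = manifest@parameters, version = manifest@version),
    file.path(outDir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  attr(manifest, "deid_failures") <- deid_failures
  manifest
}
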