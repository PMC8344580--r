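#' @include AllGenerics.R utils.R
NULL

## Accession grammar: specimen-class letter (S surgical, C cytology,
## H hematopathology, R research, M molecular), 2-digit year, dash,
## running number. Barcodes reuse the letter+year prefix with an
## alphanumeric suffix.
.ACCESSION_RE <- "^[SCHRM][0-9]{2}-[0-9]+$"
.BARCODE_RE <- "^[SCHRM][0-9]{2}[A-Z0-9]{4,8}$"
.HID_FAMILIES <- c("patient", "case", "image")

setOldClass("Date")

## ---- PathWarehouse ----------------------------------------------------

#' Clinical-pathology data warehouse
#'
#' Container for the five structured record streams of a digital pathology
#' archive -- patients (with consent facts), accessioned cases and their
#' parts, slides, scanned images, and free-text pathology reports -- with
#' referential integrity enforced at construction.
#'
#' @slot patients data.frame: `mrn`, `name`, `birth_date`, `npp_signed`.
#' @slot enrollments data.frame: `mrn`, `protocol_id`,
#'   `status` (consented/declined/unknown).
#' @slot cases data.frame: `accession`, `mrn`.
#' @slot parts data.frame: `accession`, `part_id`, `description`.
#' @slot slides data.frame: `barcode`, `accession`, `part_id`, `block_id`,
#'   `stain`, `scanner_vendor`, `scanner_model`.
#' @slot images data.frame: `image_id`, `barcode`, `file_path`, `scan_date`,
#'   `quality_factor`, `sequence_index`.
#' @slot reports data.frame: `accession`, `text`, `report_date`.
#' @seealso [ingestWarehouse()], [queryCohort()], [enforceConsent()]
#' @export
setClass("PathWarehouse", representation(
  patients = "data.frame", enrollments = "data.frame", cases = "data.frame",
  parts = "data.frame", slides = "data.frame", images = "data.frame",
  reports = "data.frame"
))

setValidity("PathWarehouse", function(object) {
  p <- object@patients; ca <- object@cases; sl <- object@slides
  im <- object@images; rp <- object@reports; pa <- object@parts
  msgs <- character(0)
  bad_mrn <- p$mrn[!grepl("^[0-9]+$", p$mrn)]
  if (length(bad_mrn))
    msgs <- c(msgs, paste("MRN must be a non-empty digit string:",
                          paste(bad_mrn, collapse = ", ")))
  if (anyDuplicated(p$mrn))
    msgs <- c(msgs, paste("duplicate patient MRN:",
                          paste(unique(p$mrn[duplicated(p$mrn)]), collapse = ", ")))
  bad_acc <- ca$accession[!grepl(.ACCESSION_RE, ca$accession)]
  if (length(bad_acc))
    msgs <- c(msgs, paste("accession fails grammar [SCHRM]\\d{2}-\\d+:",
                          paste(bad_acc, collapse = ", ")))
  if (anyDuplicated(ca$accession))
    msgs <- c(msgs, "duplicate accession")
  if (nrow(pa) && anyDuplicated(pa[c("accession", "part_id")]))
    msgs <- c(msgs, "duplicate part_id within a case")
  if (anyDuplicated(sl$barcode)) msgs <- c(msgs, "duplicate slide barcode")
  if (anyDuplicated(im$image_id)) msgs <- c(msgs, "duplicate image_id")
  dangle <- function(child, keys, parent_keys, what) {
    miss <- !(keys %in% parent_keys)
    if (any(miss))
      paste0("dangling reference (", what, "): ",
             paste(unique(child[miss]), collapse = ", "))
  }
  msgs <- c(msgs,
    dangle(ca$accession, ca$mrn, p$mrn, "case->patient"),
    if (nrow(pa)) dangle(pa$accession, pa$accession, ca$accession, "part->case"),
    dangle(sl$barcode, paste(sl$accession, sl$part_id),
           paste(pa$accession, pa$part_id), "slide->part"),
    dangle(im$image_id, im$barcode, sl$barcode, "image->slide"),
    dangle(rp$accession, rp$accession, ca$accession, "report->case"),
    if (nrow(object@enrollments))
      dangle(object@enrollments$mrn, object@enrollments$mrn, p$mrn,
             "enrollment->patient"))
  msgs <- msgs[!vapply(msgs, is.null, logical(1))]
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @export
setMethod("show", "PathWarehouse", function(object) {
  cat("PathWarehouse\n")
  cat(sprintf("  %d patients, %d cases, %d parts, %d slides, %d images, %d reports\n",
              nrow(object@patients), nrow(object@cases), nrow(object@parts),
              nrow(object@slides), nrow(object@images), nrow(object@reports)))
  prot <- unique(object@enrollments$protocol_id)
  if (length(prot))
    cat("  protocols:", paste(prot, collapse = ", "), "\n")
})

## ---- HIDKeyStore ------------------------------------------------------

#' Persistent bidirectional key store for de-identified identifiers
#'
#' Maintains the honest-broker key between original identifiers and their
#' de-identified surrogates (HIDs), partitioned into three disjoint
#' families: patient HIDs for medical record numbers, case HIDs for
#' pathology accession numbers, and image HIDs for vendor image IDs.
#' Entries are appended to a JSON-lines file so the mapping survives
#' process restarts byte-identically.
#'
#' @slot path character; the backing JSON-lines file.
#' @slot .env environment holding the in-memory forward/reverse maps and
#'   per-family counters.
#' @seealso [openKeyStore()], [assignHid()], [reidentify()]
#' @export
setClass("HIDKeyStore", representation(path = "character", .env = "environment"))

#' @export
setMethod("show", "HIDKeyStore", function(object) {
  cat("HIDKeyStore <", object@path, ">\n", sep = "")
  for (fam in .HID_FAMILIES)
    cat(sprintf("  %s: %d keys\n", fam, length(object@.env$forward[[fam]])))
})

## ---- WSIContainer -----------------------------------------------------

#' Parsed whole-slide image container (SVS-style pyramidal TIFF)
#'
#' The ordered set of sub-images of a pyramidal TIFF, each classified into a
#' role: `pyramid_level` (tiled resolution levels, largest = base),
#' `thumbnail`, `label` (photo of the slide sticker -- always PHI) or
#' `macro` (overview of the whole glass slide). Byte-range bookkeeping for
#' every payload is retained so de-identification can overwrite data
#' in place without shifting file offsets.
#'
#' @slot source source file path.
#' @slot dialect dialect marker (`"svs"`).
#' @slot subImages data.frame with one row per sub-image: `index`, `role`,
#'   `width`, `height`, `tiled`, `description`.
#' @slot .parsed internal parse state (raw bytes, IFD positions).
#' @seealso [readContainer()], [stripAssociatedImages()], [scrubMetadata()]
#' @export
setClass("WSIContainer", representation(
  source = "character", dialect = "character", subImages = "data.frame",
  .parsed = "list"
))

setValidity("WSIContainer", function(object) {
  si <- object@subImages
  msgs <- character(0)
  pyr <- si[si$role == "pyramid_level", , drop = FALSE]
  if (!nrow(pyr)) msgs <- c(msgs, "no pyramid level found")
  else {
    areas <- pyr$width * pyr$height
    if (sum(areas == max(areas)) != 1L)
      msgs <- c(msgs, "base pyramid level (largest area) is not unique")
  }
  for (r in c("label", "macro"))
    if (sum(si$role == r) > 1L)
      msgs <- c(msgs, paste("more than one", r, "sub-image"))
  ## payload ranges must not overlap
  rng <- do.call(rbind, object@.parsed$payloads)
  if (!is.null(rng) && nrow(rng) > 1L) {
    o <- order(rng[, 1L])
    s <- rng[o, 1L]; e <- rng[o, 1L] + rng[o, 2L]
    if (any(s[-1L] < e[-length(e)]))
      msgs <- c(msgs, "overlapping payload byte ranges")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @export
setMethod("show", "WSIContainer", function(object) {
  cat("WSIContainer <", object@source, "> [", object@dialect, "]\n", sep = "")
  si <- object@subImages
  for (i in seq_len(nrow(si)))
    cat(sprintf("  [%d] %-13s %5d x %-5d %s\n", si$index[i], si$role[i],
                si$width[i], si$height[i], if (si$tiled[i]) "tiled" else "strip"))
})

## ---- policies and parameters ------------------------------------------

#' Sensitive metadata field policy for WSI scrubbing
#'
#' Names the ImageDescription keys whose values are masked during image
#' de-identification. Pixel-geometry keys and the spatial resolution (MPP,
#' microns per pixel) may never be listed: geometry must survive so the file
#' stays decodable, and resolution is required downstream.
#'
#' @slot keys character vector of description keys (case-insensitive match).
#' @export
setClass("SensitiveFieldPolicy", representation(keys = "character"))

.GEOMETRY_KEYS <- c("width", "height", "tilewidth", "tilelength",
                    "compression", "mpp", "appmag")

setValidity("SensitiveFieldPolicy", function(object) {
  if (!length(object@keys)) return("policy must name at least one field")
  bad <- tolower(object@keys) %in% .GEOMETRY_KEYS
  if (any(bad))
    return(paste("policy may not name pixel-geometry/resolution keys:",
                 paste(object@keys[bad], collapse = ", ")))
  TRUE
})

#' @describeIn SensitiveFieldPolicy-class Constructor. The default policy
#'   masks scan date and time, scanner ID, barcode, filename and operator.
#' @param keys character vector of description keys.
#' @export
sensitiveFieldPolicy <- function(keys = c("Date", "Time", "ScanScope ID",
                                          "Barcode", "Filename", "User")) {
  new("SensitiveFieldPolicy", keys = keys)
}

#' Parameters for dark-region detection on slide thumbnails
#'
#' @slot luminanceThreshold scalar in (0, 255); pixels with Rec.601 luminance
#'   strictly below it count as dark.
#' @slot minAreaFraction fraction of thumbnail area in (0, 1) a connected
#'   dark component must reach (>=) to flag the slide.
#' @slot connectivity 4 or 8.
#' @export
setClass("DarkRegionParams", representation(
  luminanceThreshold = "numeric", minAreaFraction = "numeric",
  connectivity = "integer"
))

setValidity("DarkRegionParams", function(object) {
  t <- object@luminanceThreshold; a <- object@minAreaFraction
  if (!.isScalarNumber(t) || t <= 0 || t >= 255)
    return("luminanceThreshold must be a scalar in (0, 255)")
  if (!.isScalarNumber(a) || a <= 0 || a >= 1)
    return("minAreaFraction must be a scalar in (0, 1)")
  if (!object@connectivity %in% c(4L, 8L))
    return("connectivity must be 4 or 8")
  TRUE
})

#' @describeIn DarkRegionParams-class Constructor with package defaults
#'   (threshold 60/255, minimum area 5% of the thumbnail, 8-connectivity).
#' @param luminanceThreshold,minAreaFraction,connectivity see slots.
#' @export
darkRegionParams <- function(luminanceThreshold = 60, minAreaFraction = 0.05,
                             connectivity = 8L) {
  new("DarkRegionParams", luminanceThreshold = luminanceThreshold,
      minAreaFraction = minAreaFraction,
      connectivity = as.integer(connectivity))
}

#' PHI-screening decision for one whole-slide image
#'
#' @slot imageId identifier of the screened image.
#' @slot flagged TRUE iff at least one dark region reaches the minimum area
#'   fraction; flagged images are excluded from compiled datasets.
#' @slot regions data.frame of detected dark regions (`xmin`, `xmax`,
#'   `ymin`, `ymax`, `n_pixels`, `area_fraction`, `mean_luminance`), area
#'   descending.
#' @slot params parameters used, for auditability.
#' @export
setClass("ScreenDecision", representation(
  imageId = "character", flagged = "logical", regions = "data.frame",
  params = "list"
))

setValidity("ScreenDecision", function(object) {
  minf <- object@params$minAreaFraction
  if (!is.null(minf)) {
    qual <- any(object@regions$area_fraction >= minf)
    if (!identical(qual, object@flagged))
      return("flagged must hold iff a region reaches minAreaFraction")
  }
  TRUE
})

#' @export
setMethod("show", "ScreenDecision", function(object) {
  cat(sprintf("ScreenDecision %s: %s (%d dark region%s)\n", object@imageId,
              if (object@flagged) "FLAGGED" else "clean",
              nrow(object@regions), if (nrow(object@regions) == 1) "" else "s"))
})

## ---- redaction --------------------------------------------------------

#' Ordered rule set for Safe-Harbor text redaction
#'
#' Each rule pairs a PHI category with a regular expression and a
#' placeholder. Placeholders contain no digits and can never themselves
#' match a rule, which makes redaction a fixed point.
#'
#' @slot rules data.frame: `category` (date/accession/mrn/name), `pattern`
#'   (PCRE, case-insensitive), `placeholder`.
#' @seealso [redactionRules()], [redactReport()]
#' @export
setClass("RedactionRuleSet", representation(rules = "data.frame"))

setValidity("RedactionRuleSet", function(object) {
  r <- object@rules
  need <- c("category", "pattern", "placeholder")
  if (!all(need %in% names(r))) return("rules need category/pattern/placeholder")
  if (any(grepl("[0-9]", r$placeholder)))
    return("placeholders must contain no digits")
  for (i in seq_len(nrow(r))) for (j in seq_len(nrow(r))) {
    if (grepl(r$pattern[j], r$placeholder[i], perl = TRUE, ignore.case = TRUE))
      return(sprintf("placeholder '%s' matches rule %d (%s)",
                     r$placeholder[i], j, r$category[j]))
  }
  TRUE
})

#' Redacted pathology report
#'
#' @slot deidText report text after redaction.
#' @slot spans data.frame of replaced spans in the *original* text:
#'   `start`, `end` (1-based, inclusive), `category`, `original_length`,
#'   `placeholder`. Non-overlapping and sorted; substituting each span's
#'   placeholder into the original text reproduces `deidText`.
#' @slot caseHid de-identified case identifier the report belongs to (may be
#'   `NA` when redaction is run stand-alone).
#' @export
setClass("RedactedReport", representation(
  deidText = "character", spans = "data.frame", caseHid = "character"
))

setValidity("RedactedReport", function(object) {
  s <- object@spans
  if (nrow(s) > 1L) {
    if (is.unsorted(s$start, strictly = TRUE)) return("spans must be sorted")
    if (any(s$start[-1L] <= s$end[-nrow(s)])) return("spans must not overlap")
  }
  TRUE
})

#' @export
setMethod("show", "RedactedReport", function(object) {
  cat(sprintf("RedactedReport (case %s): %d span%s redacted, %d chars\n",
              object@caseHid, nrow(object@spans),
              if (nrow(object@spans) == 1) "" else "s", nchar(object@deidText)))
})

## ---- identifiers, access curve, manifest -------------------------------

#' The identifier set attached to a pathology record
#'
#' The platform identifiers of one record with their PHI status: every
#' identifier except part and block number is PHI or sensitive and must not
#' survive external sharing.
#'
#' @slot fields data.frame: `field`, `value`, `phi` (logical).
#' @export
setClass("IdentifierBundle", representation(fields = "data.frame"))

#' @describeIn IdentifierBundle-class Constructor. Unnamed arguments are
#'   ignored; known fields get their standard PHI flag (part_id and block_id
#'   are the only non-PHI identifiers).
#' @param ... named identifier values (mrn, accession, part_id, block_id,
#'   barcode, image_id, file_path, name).
#' @export
identifierBundle <- function(...) {
  vals <- list(...)
  phi_map <- c(mrn = TRUE, accession = TRUE, part_id = FALSE, block_id = FALSE,
               barcode = TRUE, image_id = TRUE, file_path = TRUE, name = TRUE)
  fld <- names(vals)
  unknown <- setdiff(fld, names(phi_map))
  if (length(unknown)) .stopf("unknown identifier field: %s",
                              paste(unknown, collapse = ", "))
  new("IdentifierBundle", fields = data.frame(
    field = fld, value = vapply(vals, as.character, character(1)),
    phi = unname(phi_map[fld]), stringsAsFactors = FALSE))
}

#' @describeIn IdentifierBundle-class The PHI identifier values (the strings
#'   that must never survive de-identification).
#' @param bundle an IdentifierBundle.
#' @export
phiValues <- function(bundle) {
  stopifnot(is(bundle, "IdentifierBundle"))
  f <- bundle@fields
  f$value[f$phi & nzchar(f$value) & !is.na(f$value)]
}

#' Cumulative first-access curve of whole-slide images
#'
#' Month-binned cumulative fraction of digitally reviewed WSI by time of
#' first access after scanning. Never-accessed images are excluded from the
#' denominator (the curve describes reviewed images only).
#'
#' @slot months integer months after scanning (month 1 = first 30.44 days).
#' @slot cumFraction cumulative fraction of accessed images, non-decreasing.
#' @slot nAccessed,nNever denominator bookkeeping.
#' @seealso [buildAccessCurve()], [selectTier1Window()]
#' @export
setClass("AccessCurve", representation(
  months = "integer", cumFraction = "numeric",
  nAccessed = "integer", nNever = "integer"
))

setValidity("AccessCurve", function(object) {
  if (length(object@months) != length(object@cumFraction))
    return("months and cumFraction lengths differ")
  if (is.unsorted(object@months, strictly = TRUE))
    return("months must be strictly increasing")
  if (is.unsorted(object@cumFraction)) return("cumFraction must be non-decreasing")
  if (any(object@cumFraction > 1 + 1e-12)) return("cumFraction must be <= 1")
  TRUE
})

#' @export
setMethod("show", "AccessCurve", function(object) {
  cat(sprintf("AccessCurve over %d months (%d accessed, %d never accessed)\n",
              max(object@months), object@nAccessed, object@nNever))
  pick <- object@months %in% c(1L, 2L, 6L, 12L, max(object@months))
  cat(paste(sprintf("  month %2d: %.0f%%", object@months[pick],
                    100 * object@cumFraction[pick]), collapse = "\n"), "\n")
})

#' Manifest of a compiled, de-identified research dataset
#'
#' @slot requestId identifier of the compilation request.
#' @slot included data.frame of released records (HIDs, truncated years and
#'   relative de-identified file names only -- no PHI).
#' @slot excluded data.frame of withheld images: `image_hid`, `reason`
#'   (consent / phi_screen / deid_failure).
#' @slot parameters list of the parameters used (auditability).
#' @slot version package version string.
#' @seealso [compileDataset()]
#' @export
setClass("DatasetManifest", representation(
  requestId = "character", included = "data.frame", excluded = "data.frame",
  parameters = "list", version = "character"
))

setValidity("DatasetManifest", function(object) {
  inc <- object@included; exc <- object@excluded
  if (nrow(inc) && nrow(exc) && length(intersect(inc$image_hid, exc$image_hid)))
    return("included and excluded image sets must be disjoint")
  if (nrow(exc) && !all(exc$reason %in% c("consent", "phi_screen", "deid_failure")))
    return("unknown exclusion reason")
  TRUE
})

#' @export
setMethod("show", "DatasetManifest", function(object) {
  cat(sprintf("DatasetManifest %s: %d included, %d excluded\n",
              object@requestId, nrow(object@included), nrow(object@excluded)))
  if (nrow(object@excluded)) {
    tab <- table(object@excluded$reason)
    cat("  excluded by reason:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
})
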