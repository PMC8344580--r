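#' @include AllClasses.R
NULL

#' Cohort selection criteria
#'
#' Conjunctive criteria over the warehouse: report keywords
#' (case-insensitive substring, all must match), a closed scan-date
#' interval, stains, scanner vendors, and the research protocol whose
#' consent gates release. At least one criterion or a protocol must be
#' present.
#'
#' @slot reportKeywords,stains,vendors character (zero length = unset).
#' @slot dateRange Date vector of length 2 (or zero length = unset).
#' @slot protocolId character (zero length = unset).
#' @export
setClass("CohortCriteria", representation(
  reportKeywords = "character", dateRange = "Date", stains = "character",
  vendors = "character", protocolId = "character"
))

setValidity("CohortCriteria", function(object) {
  any_set <- length(object@reportKeywords) || length(object@dateRange) ||
    length(object@stains) || length(object@vendors) || length(object@protocolId)
  if (!any_set) return("at least one criterion or a protocol_id is required")
  if (length(object@dateRange) && length(object@dateRange) != 2L)
    return("dateRange must be two dates (closed interval)")
  if (length(object@protocolId) > 1L) return("at most one protocol_id")
  TRUE
})

#' @describeIn CohortCriteria-class Constructor.
#' @param reportKeywords,dateRange,stains,vendors,protocolId see slots;
#'   `NULL` means unset.
#' @export
cohortCriteria <- function(reportKeywords = NULL, dateRange = NULL,
                           stains = NULL, vendors = NULL, protocolId = NULL) {
  new("CohortCriteria",
      reportKeywords = as.character(reportKeywords %||% character(0)),
      dateRange = if (is.null(dateRange)) as.Date(character(0))
                  else .asDate(dateRange, "dateRange"),
      stains = as.character(stains %||% character(0)),
      vendors = as.character(vendors %||% character(0)),
      protocolId = as.character(protocolId %||% character(0)))
}

## ---- ingest -----------------------------------------------------------

.emptyFrames <- function() list(
  patients = data.frame(mrn = character(0), name = character(0),
                        birth_date = character(0), npp_signed = logical(0),
                        stringsAsFactors = FALSE),
  enrollments = data.frame(mrn = character(0), protocol_id = character(0),
                           status = character(0), stringsAsFactors = FALSE),
  cases = data.frame(accession = character(0), mrn = character(0),
                     stringsAsFactors = FALSE),
  parts = data.frame(accession = character(0), part_id = integer(0),
                     description = character(0), stringsAsFactors = FALSE),
  slides = data.frame(barcode = character(0), accession = character(0),
                      part_id = integer(0), block_id = integer(0),
                      stain = character(0), scanner_vendor = character(0),
                      scanner_model = character(0), stringsAsFactors = FALSE),
  images = data.frame(image_id = character(0), barcode = character(0),
                      file_path = character(0), scan_date = character(0),
                      quality_factor = integer(0), sequence_index = integer(0),
                      stringsAsFactors = FALSE),
  reports = data.frame(accession = character(0), text = character(0),
                       report_date = character(0), stringsAsFactors = FALSE)
)

## Accept a stream as: NULL, a list of records, a data.frame, or a path to
## a .csv / .json / .jsonl file. Returns a list of records (named lists).
.loadStream <- function(x, what) {
  if (is.null(x)) return(list())
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    ext <- tolower(tools::file_ext(x))
    x <- if (ext %in% c("json", "jsonl", "ndjson")) .readJsonLines(x)
         else if (ext == "csv")
           utils::read.csv(x, stringsAsFactors = FALSE, colClasses = "character")
         else .stopf("unsupported %s stream format: .%s", what, ext)
  }
  if (is.data.frame(x)) x <- lapply(seq_len(nrow(x)), function(i) as.list(x[i, ]))
  if (!is.list(x)) .stopf("cannot interpret %s stream", what)
  x
}

## Compact CSV encodings for the nested fields:
##   patients$protocol_enrollments: "PR-001=consented;PR-002=declined"
##   cases$parts:                   "1:Left breast;2:Lymph node"
.parseEnrollments <- function(x, mrn) {
  if (is.null(x) || (is.character(x) && (!nzchar(x) || is.na(x)))) return(NULL)
  if (is.data.frame(x))
    return(data.frame(mrn = mrn, protocol_id = x$protocol_id,
                      status = x$status, stringsAsFactors = FALSE))
  if (is.character(x)) {
    kv <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    return(data.frame(mrn = mrn,
                      protocol_id = vapply(kv, `[`, "", 1L),
                      status = vapply(kv, `[`, "", 2L), stringsAsFactors = FALSE))
  }
  .stopf("cannot parse protocol_enrollments for patient %s", mrn)
}

.parseParts <- function(x, accession) {
  if (is.null(x) || (is.character(x) && (!nzchar(x) || is.na(x)))) return(NULL)
  if (is.data.frame(x))
    return(data.frame(accession = accession, part_id = as.integer(x$part_id),
                      description = as.character(x$description),
                      stringsAsFactors = FALSE))
  if (is.character(x)) {
    kv <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    return(data.frame(accession = accession,
                      part_id = as.integer(vapply(kv, `[`, "", 1L)),
                      description = vapply(kv, `[`, "", 2L),
                      stringsAsFactors = FALSE))
  }
  .stopf("cannot parse parts for case %s", accession)
}

#' Ingest record streams into a warehouse
#'
#' Loads the five record streams (in-memory lists/data.frames or CSV /
#' JSON-lines files), resolves referential fields, and returns a validated
#' [PathWarehouse-class]. Dangling references (slide to missing case part,
#' image to missing slide, report to missing case), duplicate primary
#' identifiers, and accessions violating the `[SCHRM]\\d{2}-\\d+` grammar
#' are load-time errors naming the offending record.
#'
#' @param patients records with `mrn`, `name`, `birth_date`, `npp_signed`,
#'   `protocol_enrollments`.
#' @param cases records with `accession`, `mrn`, `parts`.
#' @param slides,images,reports flat records (see [PathWarehouse-class]).
#' @return a [PathWarehouse-class] object.
#' @export
ingestWarehouse <- function(patients = NULL, cases = NULL, slides = NULL,
                            images = NULL, reports = NULL) {
  f <- .emptyFrames()
  pats <- .loadStream(patients, "patients")
  if (length(pats)) {
    f$patients <- data.frame(
      mrn = vapply(pats, function(p) as.character(p$mrn), character(1)),
      name = vapply(pats, function(p) as.character(p$name %||% NA), character(1)),
      birth_date = vapply(pats, function(p) as.character(p$birth_date %||% NA),
                          character(1)),
      npp_signed = vapply(pats, function(p) isTRUE(as.logical(p$npp_signed)),
                          logical(1)),
      stringsAsFactors = FALSE)
    enr <- lapply(pats, function(p)
      .parseEnrollments(p$protocol_enrollments, as.character(p$mrn)))
    enr <- Filter(Negate(is.null), enr)
    if (length(enr)) f$enrollments <- do.call(rbind, enr)
    bad <- !f$enrollments$status %in% c("consented", "declined", "unknown")
    if (any(bad))
      .stopf("invalid consent status: %s",
             paste(unique(f$enrollments$status[bad]), collapse = ", "))
  }
  cas <- .loadStream(cases, "cases")
  if (length(cas)) {
    f$cases <- data.frame(
      accession = vapply(cas, function(x) as.character(x$accession), character(1)),
      mrn = vapply(cas, function(x) as.character(x$mrn), character(1)),
      stringsAsFactors = FALSE)
    pr <- Filter(Negate(is.null), lapply(cas, function(x)
      .parseParts(x$parts, as.character(x$accession))))
    if (length(pr)) f$parts <- do.call(rbind, pr)
  }
  sl <- .loadStream(slides, "slides")
  if (length(sl)) {
    f$slides <- data.frame(
      barcode = vapply(sl, function(x) as.character(x$barcode), character(1)),
      accession = vapply(sl, function(x) as.character(x$accession), character(1)),
      part_id = vapply(sl, function(x) as.integer(x$part_id), integer(1)),
      block_id = vapply(sl, function(x) as.integer(x$block_id), integer(1)),
      stain = vapply(sl, function(x) as.character(x$stain), character(1)),
      scanner_vendor = vapply(sl, function(x) as.character(x$scanner_vendor),
                              character(1)),
      scanner_model = vapply(sl, function(x) as.character(x$scanner_model %||% NA),
                             character(1)),
      stringsAsFactors = FALSE)
    bad <- !f$slides$scanner_vendor %in% c("leica", "philips", "3dhistech")
    if (any(bad))
      .stopf("unknown scanner vendor: %s",
             paste(unique(f$slides$scanner_vendor[bad]), collapse = ", "))
  }
  im <- .loadStream(images, "images")
  if (length(im)) {
    qf <- vapply(im, function(x) {
      v <- x$quality_factor
      if (is.null(v) || is.na(v) || identical(v, "")) NA_integer_ else as.integer(v)
    }, integer(1))
    f$images <- data.frame(
      image_id = vapply(im, function(x) as.character(x$image_id), character(1)),
      barcode = vapply(im, function(x) as.character(x$barcode), character(1)),
      file_path = vapply(im, function(x) as.character(x$file_path %||% NA),
                         character(1)),
      scan_date = vapply(im, function(x) as.character(x$scan_date), character(1)),
      quality_factor = qf,
      sequence_index = vapply(im, function(x) as.integer(x$sequence_index),
                              integer(1)),
      stringsAsFactors = FALSE)
    if (any(f$images$sequence_index < 1L, na.rm = TRUE))
      .stopf("sequence_index must be >= 1")
  }
  rp <- .loadStream(reports, "reports")
  if (length(rp)) {
    f$reports <- data.frame(
      accession = vapply(rp, function(x) as.character(x$accession), character(1)),
      text = vapply(rp, function(x) as.character(x$text), character(1)),
      report_date = vapply(rp, function(x) as.character(x$report_date %||% NA),
                           character(1)),
      stringsAsFactors = FALSE)
  }
  new("PathWarehouse", patients = f$patients, enrollments = f$enrollments,
      cases = f$cases, parts = f$parts, slides = f$slides, images = f$images,
      reports = f$reports)
}

#' Per-type record counts of a warehouse
#'
#' @param warehouse a [PathWarehouse-class].
#' @return named integer vector.
#' @export
warehouseCounts <- function(warehouse) {
  stopifnot(is(warehouse, "PathWarehouse"))
  c(patients = nrow(warehouse@patients), cases = nrow(warehouse@cases),
    parts = nrow(warehouse@parts), slides = nrow(warehouse@slides),
    images = nrow(warehouse@images), reports = nrow(warehouse@reports))
}

## Join images up to their case and patient.
.imageLinkage <- function(wh) {
  im <- wh@images
  sl <- wh@slides[match(im$barcode, wh@slides$barcode), , drop = FALSE]
  ca <- wh@cases[match(sl$accession, wh@cases$accession), , drop = FALSE]
  data.frame(image_id = im$image_id, barcode = im$barcode,
             scan_date = im$scan_date, stain = sl$stain,
             scanner_vendor = sl$scanner_vendor, part_id = sl$part_id,
             block_id = sl$block_id, accession = ca$accession, mrn = ca$mrn,
             stringsAsFactors = FALSE)
}

#' Query a cohort of images by clinical criteria
#'
#' Returns the images whose linked report matches *all* keywords
#' (case-insensitive substring) and whose record fields satisfy every
#' stated criterion, ordered deterministically by (accession, image_id).
#'
#' @param warehouse a [PathWarehouse-class].
#' @param criteria a [CohortCriteria-class].
#' @return data.frame with `image_id`, `barcode`, `accession`, `mrn`.
#' @export
queryCohort <- function(warehouse, criteria) {
  stopifnot(is(warehouse, "PathWarehouse"), is(criteria, "CohortCriteria"))
  validObject(criteria)
  if (length(criteria@protocolId) &&
      !criteria@protocolId %in% warehouse@enrollments$protocol_id)
    .stopf("unknown protocol_id: %s", criteria@protocolId)
  link <- .imageLinkage(warehouse)
  keep <- rep(TRUE, nrow(link))
  if (length(criteria@reportKeywords)) {
    txt_by_case <- vapply(link$accession, function(acc) paste(
      warehouse@reports$text[warehouse@reports$accession == acc],
      collapse = "\n"), character(1))
    for (kw in criteria@reportKeywords)
      keep <- keep & grepl(tolower(kw), tolower(txt_by_case), fixed = TRUE)
  }
  if (length(criteria@dateRange)) {
    d <- .asDate(link$scan_date, "scan_date")
    keep <- keep & d >= criteria@dateRange[1L] & d <= criteria@dateRange[2L]
  }
  if (length(criteria@stains)) keep <- keep & link$stain %in% criteria@stains
  if (length(criteria@vendors))
    keep <- keep & link$scanner_vendor %in% criteria@vendors
  out <- link[keep, c("image_id", "barcode", "accession", "mrn"), drop = FALSE]
  out <- out[order(out$accession, out$image_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consent-gate a set of images
#'
#' A patient's images are released iff the patient has signed the Notice of
#' Privacy Practice *and* carries an affirmative "consented" status for the
#' protocol; a missing or "unknown" status excludes (conservative reading of
#' patient-level inclusion). The filter is idempotent and partitions its
#' input exactly.
#'
#' @param warehouse a [PathWarehouse-class].
#' @param imageIds character vector of image IDs (each must resolve to a
#'   patient).
#' @param protocolId the research protocol requiring consent.
#' @return list with `included` (character vector, input order) and
#'   `excluded` (data.frame `image_id`, `reason` with reason one of
#'   `npp_missing`, `not_consented`, `unknown_consent`).
#' @export
enforceConsent <- function(warehouse, imageIds, protocolId) {
  stopifnot(is(warehouse, "PathWarehouse"))
  link <- .imageLinkage(warehouse)
  idx <- match(imageIds, link$image_id)
  if (anyNA(idx))
    .stopf("image(s) not resolvable to a patient: %s",
           paste(imageIds[is.na(idx)], collapse = ", "))
  mrn <- link$mrn[idx]
  pat <- warehouse@patients[match(mrn, warehouse@patients$mrn), , drop = FALSE]
  enr <- warehouse@enrollments
  status <- vapply(mrn, function(m) {
    s <- enr$status[enr$mrn == m & enr$protocol_id == protocolId]
    if (length(s)) s[1L] else "unknown"
  }, character(1))
  reason <- ifelse(!pat$npp_signed, "npp_missing",
            ifelse(status == "consented", NA_character_,
            ifelse(status == "declined", "not_consented", "unknown_consent")))
  list(
    included = imageIds[is.na(reason)],
    excluded = data.frame(image_id = imageIds[!is.na(reason)],
                          reason = reason[!is.na(reason)],
                          stringsAsFactors = FALSE)
  )
}
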