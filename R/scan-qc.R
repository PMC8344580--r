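#' @include AllClasses.R
NULL

.RESCAN_REASONS <- c("blurriness", "missing_tissue", "air_bubbles", "other")

#' Post-scan quality-control triage
#'
#' Deterministic re-statement of the manual QC workflow: the macro image of
#' every WSI is reviewed; Leica scans with a scanner-issued quality factor
#' strictly below 90 get a detailed focus review; every Philips scan, and
#' every 10th Leica or 3DHistech scan in a batch, is fully opened to verify
#' successful scanning. A failed macro review forces a rescan (reason
#' `missing_tissue`). Triage is stateless and order-independent per image.
#'
#' @param images data.frame with `image_id`, `scanner_vendor`,
#'   `quality_factor`, `sequence_index` (use [.imageLinkage] output or the
#'   warehouse's image table joined with the slide's vendor).
#' @param macroOk logical vector, one per image: did the macro review pass?
#' @param period full-open sampling period for Leica/3DHistech (default 10).
#' @return data.frame with one disposition per image: the triggered checks
#'   (`macro_review`, `quality_factor_review`, `full_open_check`), `outcome`
#'   (`pass`/`rescan`) and `rescan_reason`.
#' @export
triageScan <- function(images, macroOk = rep(TRUE, nrow(images)), period = 10L) {
  stopifnot(is.data.frame(images),
            all(c("image_id", "scanner_vendor", "sequence_index") %in%
                  names(images)))
  if (length(macroOk) != nrow(images))
    .stopf("macroOk must have one entry per image")
  if (any(images$sequence_index < 1L))
    .stopf("sequence_index must be >= 1")
  v <- images$scanner_vendor
  qf <- images$quality_factor %||% rep(NA_integer_, nrow(images))
  miss <- v == "leica" & is.na(qf)
  if (any(miss))
    .stopf("Leica image without a quality factor: %s",
           paste(images$image_id[miss], collapse = ", "))
  qfr <- v == "leica" & !is.na(qf) & qf < 90L
  foc <- v == "philips" |
    (v %in% c("leica", "3dhistech") & images$sequence_index %% period == 0L)
  outcome <- ifelse(macroOk, "pass", "rescan")
  data.frame(
    image_id = images$image_id,
    macro_review = TRUE,
    quality_factor_review = qfr,
    full_open_check = foc,
    outcome = outcome,
    rescan_reason = ifelse(macroOk, NA_character_, "missing_tissue"),
    stringsAsFactors = FALSE
  )
}

#' Periodic full-open sampling
#'
#' Selects every `period`-th image of a contiguous batch (sequence index
#' congruent 0 modulo the period), the rule applied to Leica and 3DHistech
#' scanners. On contiguous indices 1..n this selects exactly `floor(n /
#' period)` images.
#'
#' @param images data.frame with a `sequence_index` column (indices
#'   contiguous per vendor/batch), or an integer vector of indices.
#' @param period positive sampling period (default 10).
#' @return the selected subset (same type as the input), in order.
#' @export
samplePeriodic <- function(images, period = 10L) {
  if (!.isScalarNumber(period) || period < 1)
    .stopf("period must be a positive integer")
  period <- as.integer(period)
  idx <- if (is.data.frame(images)) images$sequence_index else as.integer(images)
  sel <- idx %% period == 0L
  if (is.data.frame(images)) images[sel, , drop = FALSE] else idx[sel]
}

#' File a pathologist-initiated rescan request
#'
#' Appends a request to a persistent JSON-lines queue. Duplicate requests
#' (same image, reporter and reason on the same day) collapse to one entry.
#'
#' @param queuePath JSON-lines queue file (created if absent).
#' @param imageId image being reported.
#' @param reason one of `blurriness`, `missing_tissue`, `air_bubbles`,
#'   `other`.
#' @param reporter who reports (user id).
#' @param date report date (defaults to today).
#' @return the queue entry (list), invisibly; attribute `appended` is FALSE
#'   when the request was collapsed into an existing entry.
#' @export
fileRescanRequest <- function(queuePath, imageId, reason, reporter,
                              date = Sys.Date()) {
  if (!reason %in% .RESCAN_REASONS)
    .stopf("unknown rescan reason '%s' (must be one of %s)", reason,
           paste(.RESCAN_REASONS, collapse = ", "))
  date <- format(.asDate(date), "%Y-%m-%d")
  entry <- list(image_id = as.character(imageId), reason = reason,
                reporter = as.character(reporter), date = date)
  if (file.exists(queuePath)) {
    existing <- .readJsonLines(queuePath)
    dup <- vapply(existing, function(e)
      identical(e$image_id, entry$image_id) && identical(e$reason, entry$reason) &&
      identical(e$reporter, entry$reporter) && identical(e$date, entry$date),
      logical(1))
    if (any(dup)) {
      attr(entry, "appended") <- FALSE
      return(invisible(entry))
    }
  } else {
    dir.create(dirname(queuePath), showWarnings = FALSE, recursive = TRUE)
  }
  .writeJsonLines(list(entry), queuePath, append = TRUE)
  attr(entry, "appended") <- TRUE
  invisible(entry)
}

#' Read the rescan queue
#' @param queuePath JSON-lines queue file.
#' @return data.frame of queued requests (zero rows if the queue is absent).
#' @export
readRescanQueue <- function(queuePath) {
  if (!file.exists(queuePath))
    return(data.frame(image_id = character(0), reason = character(0),
                      reporter = character(0), date = character(0),
                      stringsAsFactors = FALSE))
  recs <- .readJsonLines(queuePath)
  do.call(rbind, lapply(recs, function(r)
    data.frame(image_id = r$image_id, reason = r$reason, reporter = r$reporter,
               date = r$date, stringsAsFactors = FALSE)))
}
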