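#' @include AllClasses.R
NULL

## Calendar-agnostic month: 30.44 days (365.25 / 12).
.DAYS_PER_MONTH <- 30.44

#' Annual storage need of a scanning operation
#'
#' `avg_size_GB x scans_per_year`, reported in decimal petabytes per year
#' (10^6 GB = 1 PB). At 1 GB per WSI and one million scans a year this is
#' 1 PB/year.
#'
#' @param avgSizeGbPerWsi average WSI size in GB (> 0).
#' @param scansPerYear yearly scanning rate (> 0).
#' @return petabytes per year (numeric scalar).
#' @examples
#' estimateAnnualStorage(1, 1e6)   # 1 PB/year
#' @export
estimateAnnualStorage <- function(avgSizeGbPerWsi, scansPerYear) {
  if (!.isScalarNumber(avgSizeGbPerWsi) || avgSizeGbPerWsi <= 0)
    .stopf("avgSizeGbPerWsi must be positive")
  if (!.isScalarNumber(scansPerYear) || scansPerYear <= 0)
    .stopf("scansPerYear must be positive")
  avgSizeGbPerWsi * scansPerYear / 1e6
}

#' Build the cumulative first-access curve from an access log
#'
#' Bins each digitally reviewed image by whole months elapsed between
#' scanning and first access (month 1 = first 30.44 days, boundary
#' inclusive) and accumulates the fraction of accessed images per month.
#' Never-accessed images are excluded from the denominator; an access date
#' before the scan date is an error.
#'
#' @param log data.frame with `image_id`, `scan_date`, `first_access_date`
#'   (`NA` if never opened).
#' @return an [AccessCurve-class].
#' @export
buildAccessCurve <- function(log) {
  stopifnot(is.data.frame(log),
            all(c("scan_date", "first_access_date") %in% names(log)))
  if (!nrow(log)) .stopf("access log is empty")
  accessed <- !is.na(log$first_access_date) & log$first_access_date != ""
  scan <- .asDate(log$scan_date[accessed], "scan_date")
  acc <- .asDate(log$first_access_date[accessed], "first_access_date")
  days <- as.numeric(acc - scan)
  if (any(days < 0))
    .stopf("first access before scan for image(s): %s",
           paste(log$image_id[accessed][days < 0], collapse = ", "))
  if (!length(days)) .stopf("no accessed entries in the log")
  month <- pmax(1, ceiling(days / .DAYS_PER_MONTH))
  months <- seq_len(max(month))
  counts <- tabulate(month, nbins = max(month))
  new("AccessCurve", months = as.integer(months),
      cumFraction = cumsum(counts) / sum(counts),
      nAccessed = sum(accessed), nNever = sum(!accessed))
}

#' Construct an access curve from explicit month/fraction pairs
#'
#' For curves taken from a published or otherwise known cumulative access
#' histogram rather than a raw log. Months may be sparse; they are kept as
#' given.
#'
#' @param months integer months after scanning, strictly increasing.
#' @param cumFraction cumulative accessed fraction at each month.
#' @param nAccessed,nNever optional denominator bookkeeping.
#' @return an [AccessCurve-class].
#' @examples
#' accessCurve(c(1, 2, 6, 12), c(0.51, 0.61, 0.79, 0.91))
#' @export
accessCurve <- function(months, cumFraction, nAccessed = 0L, nNever = 0L) {
  new("AccessCurve", months = as.integer(months),
      cumFraction = as.numeric(cumFraction),
      nAccessed = as.integer(nAccessed), nNever = as.integer(nNever))
}

#' Smallest tier-1 retention window covering a target access fraction
#'
#' Returns the smallest month m whose cumulative first-access fraction
#' reaches the coverage target -- e.g. a curve where 79% of reviewed images
#' are opened within 6 months yields 6 for a 0.79 target. Monotone
#' non-decreasing in the target; an unreachable target errors, naming the
#' maximum attainable fraction.
#'
#' @param curve an [AccessCurve-class].
#' @param coverageTarget fraction in (0, max cumulative fraction].
#' @return integer months.
#' @export
selectTier1Window <- function(curve, coverageTarget) {
  stopifnot(is(curve, "AccessCurve"))
  validObject(curve)
  if (!.isScalarNumber(coverageTarget) || coverageTarget <= 0)
    .stopf("coverageTarget must be in (0, 1]")
  cf <- curve@cumFraction
  hit <- which(cf >= coverageTarget)
  if (!length(hit))
    .stopf("coverage target %.3f unreachable: maximum attainable fraction is %.3f",
           coverageTarget, max(cf))
  curve@months[hit[1L]]
}

#' Assign images to storage tiers by scan age
#'
#' Images scanned within the tier-1 window of the reference date stay on
#' tier-1 flash storage for fast viewer access; older images move to
#' tier-2 disk. The partition is exact: every image lands in exactly one
#' tier.
#'
#' @param images data.frame with `image_id` and `scan_date`.
#' @param windowMonths tier-1 retention window in 30.44-day months.
#' @param asOfDate reference date.
#' @return list with `tier1` and `tier2` (character vectors of image IDs).
#' @export
assignTiers <- function(images, windowMonths, asOfDate) {
  stopifnot(is.data.frame(images),
            all(c("image_id", "scan_date") %in% names(images)))
  if (!.isScalarNumber(windowMonths) || windowMonths <= 0)
    .stopf("windowMonths must be positive")
  asOfDate <- .asDate(asOfDate, "asOfDate")
  scan <- .asDate(images$scan_date, "scan_date")
  age_days <- as.numeric(asOfDate - scan)
  if (any(age_days < 0))
    .stopf("scan date after asOfDate for image(s): %s",
           paste(images$image_id[age_days < 0], collapse = ", "))
  in1 <- age_days <= windowMonths * .DAYS_PER_MONTH
  list(tier1 = images$image_id[in1], tier2 = images$image_id[!in1])
}
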