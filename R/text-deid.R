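#' @include keystore.R
NULL

.MONTHS_EN <- c("January", "February", "March", "April", "May", "June", "July",
                "August", "September", "October", "November", "December")

## Date dialects covered by the redactor (and, by contract, the only ones
## the fixture generator emits): ISO 8601, US slash with 4- or 2-digit
## year, and written month. Each alternative keeps the year recoverable.
.DATE_RE <- paste0(
  "\\b[0-9]{4}-[0-9]{2}-[0-9]{2}\\b",
  "|(?<![0-9/])[0-9]{1,2}/[0-9]{1,2}/(?:[0-9]{4}|[0-9]{2})(?![0-9/])",
  "|\\b(?:", paste(.MONTHS_EN, collapse = "|"), ")\\s+[0-9]{1,2},\\s*[0-9]{4}\\b")

## Accession numbers plus slide-barcode-shaped tokens (letter + 2-digit
## year + alphanumeric suffix) share one category: both identify a case.
.ACCESSION_TOKEN_RE <-
  "\\b[SCHRM][0-9]{2}-[0-9]+\\b|\\b[SCHRM][0-9]{2}[A-Z0-9]{4,8}\\b"

## Standalone 6-9 digit runs; deliberately broad (conservative
## over-redaction is preferred over a missed MRN).
.MRN_RE <- "(?<![0-9-])[0-9]{6,9}(?![0-9])"

#' Truncate a calendar date to its year
#'
#' Safe-Harbor date handling for structured fields: day and month are
#' removed, the 4-digit year remains. Unparseable dates raise an error --
#' a date is never passed through unredacted.
#'
#' @param date a `Date` or `"YYYY-MM-DD"` string (vectorized).
#' @return character vector of 4-digit years.
#' @examples
#' truncateDate("2020-03-15")  # "2020"
#' @export
truncateDate <- function(date) {
  format(.asDate(date), "%Y")
}

#' Default Safe-Harbor redaction rule set
#'
#' Ordered pattern rules for the four PHI categories found in pathology
#' report text: dates (three dialects), accession numbers and
#' barcode-shaped tokens, medical record numbers, and the patient's name
#' (whose concrete patterns are built per patient at redaction time).
#' The date placeholder is completed with the matched year by
#' [redactReport()], since Safe Harbor permits the year to remain.
#'
#' @return a [RedactionRuleSet-class].
#' @export
redactionRules <- function() {
  new("RedactionRuleSet", rules = data.frame(
    category = c("date", "accession", "mrn", "name"),
    pattern = c(.DATE_RE, .ACCESSION_TOKEN_RE, .MRN_RE, "(?!)"),
    placeholder = c("[DATE]", "[ACCESSION]", "[MRN]", "[PATIENT]"),
    stringsAsFactors = FALSE
  ))
}

## Extract the 4-digit year from one matched date string. Two-digit years
## use a fixed pivot: 00-49 -> 2000s, 50-99 -> 1900s.
.dateYear <- function(s) {
  if (grepl("^[0-9]{4}-", s)) return(substr(s, 1L, 4L))
  if (grepl("/", s)) {
    y <- sub(".*/", "", s)
    if (nchar(y) == 2L) {
      yi <- as.integer(y)
      return(as.character(if (yi < 50L) 2000L + yi else 1900L + yi))
    }
    return(y)
  }
  sub(".*?([0-9]{4})\\s*$", "\\1", s)
}

## Patient-name patterns: "Given Family" and "Family, Given" pair forms
## first (so a full name collapses to one placeholder), then each name
## token of >= 3 characters on its own word boundary.
.namePatterns <- function(name) {
  toks <- strsplit(trimws(name), "[[:space:]]+")[[1]]
  toks <- toks[nchar(toks) >= 3L]
  if (!length(toks)) return(character(0))
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", toks)
  pats <- character(0)
  if (length(esc) >= 2L) {
    first <- esc[1L]; last <- esc[length(esc)]
    pats <- c(sprintf("\\b%s[[:space:]]+%s\\b", first, last),
              sprintf("\\b%s,[[:space:]]*%s\\b", last, first))
  }
  c(pats, sprintf("\\b%s\\b", esc))
}

#' Redact PHI from free-text pathology report
#'
#' Single-pass rule-based redaction: every maximal match of each rule
#' (dates, accession/barcode tokens, medical record numbers, and the given
#' patient's name in both "Given Family" and "Family, Given" orders,
#' case-insensitively on word boundaries) is replaced by its category
#' placeholder. Dates become `[DATE-<year>]`, retaining the year as Safe
#' Harbor permits. Redaction is a fixed point: re-redacting the output
#' changes nothing.
#'
#' @param text report text (character scalar; empty text yields empty output).
#' @param patient optional patient record (list or one-row data.frame with a
#'   `name` field) whose name tokens are redacted.
#' @param rules a [RedactionRuleSet-class]; defaults to [redactionRules()].
#' @param caseHid optional de-identified case identifier to carry in the
#'   result.
#' @return a [RedactedReport-class].
#' @examples
#' r <- redactReport("S20-0123 from JANE DOE on 03/15/2020",
#'                   patient = list(name = "Jane Doe"))
#' r@deidText  # "[ACCESSION] from [PATIENT] on [DATE-2020]"
#' @export
redactReport <- function(text, patient = NULL, rules = redactionRules(),
                         caseHid = NA_character_) {
  stopifnot(is(rules, "RedactionRuleSet"))
  validObject(rules)
  if (length(text) != 1L || is.na(text)) .stopf("text must be a single string")
  empty_spans <- data.frame(start = integer(0), end = integer(0),
                            category = character(0),
                            original_length = integer(0),
                            placeholder = character(0), stringsAsFactors = FALSE)
  if (!nzchar(text))
    return(new("RedactedReport", deidText = "", spans = empty_spans,
               caseHid = caseHid))

  ## expand the rule table: the name category gets patient-specific patterns
  r <- rules@rules
  expanded <- list()
  for (i in seq_len(nrow(r))) {
    if (r$category[i] == "name") {
      if (is.null(patient)) next
      nm <- if (is.list(patient) || is.data.frame(patient)) patient$name else patient
      if (is.null(nm) || is.na(nm)) next
      for (p in .namePatterns(as.character(nm)))
        expanded[[length(expanded) + 1L]] <-
          list(category = "name", pattern = p, placeholder = r$placeholder[i])
    } else {
      expanded[[length(expanded) + 1L]] <-
        list(category = r$category[i], pattern = r$pattern[i],
             placeholder = r$placeholder[i])
    }
  }

  ## collect matches in rule order; earlier rules win overlaps
  taken <- logical(nchar(text))
  spans <- list()
  for (rule in expanded) {
    m <- gregexpr(rule$pattern, text, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1L] == -1L) next
    lens <- attr(m, "match.length")
    for (k in seq_along(m)) {
      idx <- m[k]:(m[k] + lens[k] - 1L)
      if (any(taken[idx])) next
      taken[idx] <- TRUE
      matched <- substr(text, m[k], m[k] + lens[k] - 1L)
      ph <- if (rule$category == "date")
        sprintf("[DATE-%s]", .dateYear(matched)) else rule$placeholder
      spans[[length(spans) + 1L]] <- data.frame(
        start = m[k], end = m[k] + lens[k] - 1L, category = rule$category,
        original_length = lens[k], placeholder = ph, stringsAsFactors = FALSE)
    }
  }

  if (!length(spans))
    return(new("RedactedReport", deidText = text, spans = empty_spans,
               caseHid = caseHid))
  sp <- do.call(rbind, spans)
  sp <- sp[order(sp$start), , drop = FALSE]
  rownames(sp) <- NULL

  pieces <- character(0)
  cursor <- 1L
  for (i in seq_len(nrow(sp))) {
    pieces <- c(pieces, substr(text, cursor, sp$start[i] - 1L), sp$placeholder[i])
    cursor <- sp$end[i] + 1L
  }
  pieces <- c(pieces, substr(text, cursor, nchar(text)))
  new("RedactedReport", deidText = paste(pieces, collapse = ""),
      spans = sp, caseHid = caseHid)
}

#' Multiset of years mentioned in a text's dates
#'
#' Counts years both in raw dates (all three dialects) and in already
#' redacted `[DATE-<year>]` placeholders, so the multiset is invariant
#' under redaction.
#'
#' @param text character scalar.
#' @return sorted character vector of years, one element per date mention.
#' @export
dateYearMultiset <- function(text) {
  years <- character(0)
  m <- gregexpr(.DATE_RE, text, perl = TRUE, ignore.case = TRUE)[[1]]
  if (m[1L] != -1L) {
    lens <- attr(m, "match.length")
    years <- vapply(seq_along(m), function(k)
      .dateYear(substr(text, m[k], m[k] + lens[k] - 1L)), character(1))
  }
  m2 <- gregexpr("\\[DATE-([0-9]{4})\\]", text, perl = TRUE)[[1]]
  if (m2[1L] != -1L) {
    lens <- attr(m2, "match.length")
    years <- c(years, vapply(seq_along(m2), function(k)
      substr(text, m2[k] + 6L, m2[k] + 9L), character(1)))
  }
  sort(years)
}

.RECORD_FIELDS <- list(
  patient = c("mrn", "name", "birth_date", "npp_signed"),
  case = c("accession", "mrn"),
  slide = c("barcode", "accession", "part_id", "block_id", "stain",
            "scanner_vendor", "scanner_model"),
  image = c("image_id", "barcode", "file_path", "scan_date",
            "quality_factor", "sequence_index"),
  report = c("accession", "text", "report_date")
)

#' De-identify one structured warehouse record
#'
#' Applies the Safe-Harbor field rules: every identifier flagged PHI (MRN,
#' accession, slide barcode, image ID, file path, patient name) is replaced
#' by a HID from the key store or dropped; part and block numbers are
#' preserved verbatim; every date field is truncated to its year. There is
#' no slide HID family, so slide barcodes are dropped (set to `NA`) and
#' de-identified slides are keyed by case HID plus part/block. Report text
#' is *not* redacted here -- pass it through [redactReport()].
#'
#' Unknown fields fail closed with an error rather than passing through.
#'
#' @param record a named list or one-row data.frame.
#' @param type one of `"patient"`, `"case"`, `"slide"`, `"image"`,
#'   `"report"`.
#' @param store a [HIDKeyStore-class].
#' @return a named list, the de-identified record.
#' @export
deidentifyRecord <- function(record, type, store) {
  if (!type %in% names(.RECORD_FIELDS)) .stopf("unknown record type: %s", type)
  rec <- as.list(record)
  unknown <- setdiff(names(rec), .RECORD_FIELDS[[type]])
  if (length(unknown))
    .stopf("unknown field(s) in %s record (failing closed): %s", type,
           paste(unknown, collapse = ", "))
  out <- rec
  switch(type,
    patient = {
      out$mrn <- assignHid(store, "patient", rec$mrn)
      out$name <- NULL
      if (!is.null(rec$birth_date)) out$birth_date <- truncateDate(rec$birth_date)
    },
    case = {
      out$accession <- assignHid(store, "case", rec$accession)
      if (!is.null(rec$mrn)) out$mrn <- assignHid(store, "patient", rec$mrn)
    },
    slide = {
      out$barcode <- NA_character_
      if (!is.null(rec$accession))
        out$accession <- assignHid(store, "case", rec$accession)
    },
    image = {
      out$image_id <- assignHid(store, "image", rec$image_id)
      out$barcode <- NULL
      out$file_path <- NULL
      if (!is.null(rec$scan_date)) out$scan_date <- truncateDate(rec$scan_date)
    },
    report = {
      out$accession <- assignHid(store, "case", rec$accession)
      if (!is.null(rec$report_date))
        out$report_date <- truncateDate(rec$report_date)
    })
  out
}
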