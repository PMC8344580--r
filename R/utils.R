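`%||%` <- function(a, b) if (is.null(a)) b else a

.isScalarString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

.isScalarNumber <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' @noRd
.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## Locate every occurrence of a byte pattern in a raw vector.
## Returns 0-based file offsets (integer vector, possibly empty).
.rawFind <- function(haystack, needle) {
  if (is.character(needle)) needle <- charToRaw(needle)
  n <- length(needle)
  if (n == 0L || length(haystack) < n) return(integer(0))
  cand <- which(haystack == needle[1L])
  cand <- cand[cand + n - 1L <= length(haystack)]
  if (n > 1L) {
    for (k in 2L:n) {
      if (!length(cand)) break
      cand <- cand[haystack[cand + k - 1L] == needle[k]]
    }
  }
  cand - 1L
}

## Scan a file's raw bytes for each of a set of ASCII identifier strings.
## Returns a data.frame(pattern, hits, first_offset) with 0-based offsets.
.scanFileForBytes <- function(path, patterns) {
  stopifnot(file.exists(path))
  bytes <- readBin(path, "raw", n = file.size(path))
  hits <- lapply(patterns, function(p) .rawFind(bytes, p))
  data.frame(
    pattern = as.character(patterns),
    hits = vapply(hits, length, integer(1)),
    first_offset = vapply(hits, function(h) if (length(h)) h[1L] else NA_integer_,
                          integer(1)),
    stringsAsFactors = FALSE
  )
}

## Parse a calendar date; accepts Date or "YYYY-MM-DD" strings. Errors on
## anything unparseable -- dates are never passed through silently.
.asDate <- function(x, what = "date") {
  if (inherits(x, "Date")) return(x)
  d <- suppressWarnings(as.Date(as.character(x), format = "%Y-%m-%d"))
  if (any(is.na(d))) .stopf("unparseable %s: %s", what,
                            paste(x[is.na(d)], collapse = ", "))
  d
}

## Read a JSON-lines file into a list of records.
.readJsonLines <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
}

.writeJsonLines <- function(records, path, append = FALSE) {
  if (!length(records)) {
    if (!append) cat("", file = path)
    return(invisible(path))
  }
  txt <- vapply(records, function(r)
    jsonlite::toJSON(r, auto_unbox = TRUE, null = "null"), character(1))
  cat(paste0(txt, "\n", collapse = ""), file = path, append = append)
  invisible(path)
}
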