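#' @include AllClasses.R
NULL

.HID_PREFIX <- c(patient = "P", case = "C", image = "I")

## Keyed affine counter -> 8-hex digits. HIDs are a permutation of a
## counter, not a hash of the original identifier, so the mapping cannot be
## inverted by dictionary attack; the key store file is the only link back.
.hidFromCounter <- function(counter, family) {
  a <- 2654435761       # odd multiplier (Knuth), bijective mod 2^32
  b <- c(patient = 97531, case = 86420, image = 75309)[[family]]
  v <- (a * counter + b) %% 4294967296
  sprintf("%s-%04x%04x", .HID_PREFIX[[family]], as.integer(v %/% 65536),
          as.integer(v %% 65536))
}

## TRUE if any k-char substring of `a` occurs in `b` (case-insensitive).
.sharesSubstring <- function(a, b, k = 4L) {
  a <- tolower(a); b <- tolower(b)
  if (nchar(a) < k) return(FALSE)
  subs <- unique(substring(a, seq_len(nchar(a) - k + 1L),
                           seq_len(nchar(a) - k + 1L) + k - 1L))
  any(vapply(subs, function(s) grepl(s, b, fixed = TRUE), logical(1)))
}

#' Open (or create) a persistent HID key store
#'
#' The store is an append-only JSON-lines file, one line per issued key:
#' `{"family": ..., "original": ..., "hid": ..., "counter": ...}`.
#' Reopening the same path reconstructs the identical mapping, so HIDs are
#' stable across process restarts.
#'
#' @param path backing file; created (with its parent directory) if absent.
#' @return a [HIDKeyStore-class] object.
#' @examples
#' ks <- openKeyStore(tempfile(fileext = ".jsonl"))
#' assignHid(ks, "patient", "1482928")
#' @export
openKeyStore <- function(path) {
  e <- new.env(parent = emptyenv())
  e$forward <- e$reverse <- sapply(.HID_FAMILIES, function(f)
    new.env(parent = emptyenv()), simplify = FALSE)
  e$counter <- stats::setNames(rep(1, length(.HID_FAMILIES)), .HID_FAMILIES)
  if (file.exists(path)) {
    for (rec in .readJsonLines(path)) {
      fam <- rec$family
      assign(rec$original, rec$hid, envir = e$forward[[fam]])
      assign(rec$hid, rec$original, envir = e$reverse[[fam]])
      e$counter[[fam]] <- max(e$counter[[fam]], rec$counter + 1)
    }
  } else {
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    ok <- file.create(path)
    if (!ok) .stopf("key store path is unwritable: %s", path)
  }
  new("HIDKeyStore", path = path, .env = e)
}

#' @rdname assignHid
setMethod("assignHid", "HIDKeyStore", function(store, family, originalId) {
  if (!family %in% .HID_FAMILIES)
    .stopf("unknown HID family '%s' (must be one of %s)", family,
           paste(.HID_FAMILIES, collapse = ", "))
  originalId <- as.character(originalId)
  if (length(originalId) != 1L || is.na(originalId) || !nzchar(originalId))
    .stopf("original identifier must be a non-empty string")
  e <- store@.env
  hit <- get0(originalId, envir = e$forward[[family]])
  if (!is.null(hit)) return(hit)
  repeat {
    cnt <- e$counter[[family]]
    e$counter[[family]] <- cnt + 1
    hid <- .hidFromCounter(cnt, family)
    ## never leak: the HID must share no 4+ character run with the original
    if (!.sharesSubstring(originalId, hid) && is.null(get0(hid, envir = e$reverse[[family]])))
      break
  }
  assign(originalId, hid, envir = e$forward[[family]])
  assign(hid, originalId, envir = e$reverse[[family]])
  line <- jsonlite::toJSON(list(family = family, original = originalId,
                                hid = hid, counter = cnt), auto_unbox = TRUE)
  ok <- tryCatch({
    cat(line, "\n", sep = "", file = store@path, append = TRUE); TRUE
  }, error = function(e) FALSE, warning = function(e) FALSE)
  if (!ok) .stopf("key store is unwritable: %s", store@path)
  hid
})

#' @rdname reidentify
setMethod("reidentify", "HIDKeyStore", function(store, hid) {
  fam <- names(.HID_PREFIX)[match(substr(hid, 1L, 1L), .HID_PREFIX)]
  if (is.na(fam)) .stopf("malformed HID: %s", hid)
  orig <- get0(hid, envir = store@.env$reverse[[fam]])
  if (is.null(orig)) .stopf("unknown HID: %s", hid)
  orig
})
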