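#' @include AllClasses.R tiff-lowlevel.R
NULL

## Role classification of one parsed IFD: a description containing the
## token "label" -> label, "macro" -> macro; among the remaining images the
## smallest non-tiled strip image is the thumbnail; everything else is a
## pyramid level.
.classifyRoles <- function(ifds) {
  desc <- vapply(ifds, function(i) .ifdTagValues(i, 270L) %||% "", character(1))
  tiled <- vapply(ifds, function(i) 322L %in% i$tags, logical(1))
  w <- vapply(ifds, function(i) .ifdTagValues(i, 256L), numeric(1))
  h <- vapply(ifds, function(i) .ifdTagValues(i, 257L), numeric(1))
  role <- rep("pyramid_level", length(ifds))
  role[grepl("label", desc, ignore.case = TRUE)] <- "label"
  role[grepl("macro", desc, ignore.case = TRUE)] <- "macro"
  cand <- which(role == "pyramid_level" & !tiled)
  if (length(cand)) {
    thumb <- cand[which.min((w * h)[cand])]
    role[thumb] <- "thumbnail"
  }
  data.frame(index = seq_along(ifds), role = role, width = w, height = h,
             tiled = tiled, description = desc, stringsAsFactors = FALSE)
}

.payloadRanges <- function(ifd) {
  if (322L %in% ifd$tags)
    cbind(offset = .ifdTagValues(ifd, 324L), nbytes = .ifdTagValues(ifd, 325L))
  else
    cbind(offset = .ifdTagValues(ifd, 273L), nbytes = .ifdTagValues(ifd, 279L))
}

#' Read an SVS-style whole-slide image container
#'
#' Parses the TIFF directory chain and classifies every sub-image into
#' pyramid level, thumbnail, label or macro. Only the Aperio-style SVS/TIFF
#' dialect is handled; a non-TIFF or a TIFF without a pyramid level is an
#' error (truncated files report the failing offset).
#'
#' @param path path to an `.svs`/`.tif` file.
#' @return a [WSIContainer-class].
#' @export
readContainer <- function(path) {
  parsed <- .tiffParse(path)
  si <- .classifyRoles(parsed$ifds)
  if (!any(si$role == "pyramid_level"))
    .stopf("TIFF with zero pyramid levels: %s", path)
  parsed$payloads <- lapply(parsed$ifds, .payloadRanges)
  new("WSIContainer", source = path, dialect = "svs", subImages = si,
      .parsed = parsed)
}

#' Sub-image summary of a container
#' @param container a [WSIContainer-class].
#' @return data.frame with one row per sub-image.
#' @export
subImages <- function(container) {
  stopifnot(is(container, "WSIContainer"))
  container@subImages
}

## Parse an Aperio-style ImageDescription into key/value fields. The first
## `|`-separated segment is free header text; later segments are
## "Key = Value". Returns field positions relative to the description
## string (1-based) so values can be overwritten in place.
.parseAperioFields <- function(desc) {
  if (!nzchar(desc)) return(NULL)
  segs <- strsplit(desc, "|", fixed = TRUE)[[1]]
  if (length(segs) < 2L) return(NULL)
  pos <- cumsum(c(1L, nchar(segs) + 1L))   # start of each segment
  out <- list()
  for (i in 2:length(segs)) {
    m <- regexec("^([^=]*?)\\s=\\s(.*)$", segs[i])[[1]]
    if (m[1L] == -1L) next
    key <- substr(segs[i], m[2L], m[2L] + attr(m, "match.length")[2L] - 1L)
    val_start <- m[3L]
    val_len <- attr(m, "match.length")[3L]
    out[[length(out) + 1L]] <- data.frame(
      key = key, value = substr(segs[i], val_start, val_start + val_len - 1L),
      value_pos = pos[i] + val_start - 1L, value_len = val_len,
      stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Metadata fields of a container
#'
#' Key/value fields parsed from every sub-image's Aperio-style
#' ImageDescription.
#'
#' @param container a [WSIContainer-class].
#' @return data.frame `sub_image`, `key`, `value` (NULL-free; may have
#'   zero rows).
#' @export
metadataFields <- function(container) {
  stopifnot(is(container, "WSIContainer"))
  res <- lapply(seq_along(container@.parsed$ifds), function(i) {
    f <- .parseAperioFields(container@subImages$description[i])
    if (is.null(f)) return(NULL)
    cbind(sub_image = i, f[, c("key", "value")])
  })
  res <- Filter(Negate(is.null), res)
  if (!length(res))
    return(data.frame(sub_image = integer(0), key = character(0),
                      value = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

.refuseInPlace <- function(container, outPath) {
  if (normalizePath(outPath, mustWork = FALSE) ==
      normalizePath(container@source, mustWork = FALSE))
    .stopf("in-place editing is refused; choose a different output path")
}

## Rewrite the IFD chain so that only `keep` (indices) remain linked, in
## their original order. Operates on a raw copy of the file.
.relinkIfds <- function(bytes, parsed, keep) {
  ifds <- parsed$ifds
  offsets <- vapply(ifds, `[[`, 0, "offset")
  poke32 <- function(pos, value) {
    bytes[(pos + 1L):(pos + 4L)] <<- .rawU32(value)
  }
  prev_ptr <- 4L   # header's first-IFD pointer
  for (i in keep) {
    poke32(prev_ptr, offsets[i])
    prev_ptr <- ifds[[i]]$next_ptr_pos
  }
  poke32(prev_ptr, 0)
  bytes
}

#' @rdname stripAssociatedImages
setMethod("stripAssociatedImages", "WSIContainer", function(container, outPath) {
  .refuseInPlace(container, outPath)
  parsed <- container@.parsed
  bytes <- parsed$bytes
  drop <- which(container@subImages$role %in% c("label", "macro"))
  if (length(drop)) {
    for (i in drop) {
      ## zero payload bytes so no byte scavenger recovers pixel content
      rng <- parsed$payloads[[i]]
      for (k in seq_len(nrow(rng)))
        bytes[(rng[k, "offset"] + 1L):(rng[k, "offset"] + rng[k, "nbytes"])] <-
          as.raw(0)
      ## zero the IFD block itself and any external value areas (the
      ## description string of a label can carry PHI too)
      ifd <- parsed$ifds[[i]]
      for (e in ifd$entries)
        if (e$value_nbytes > 4L)
          bytes[(e$value_pos + 1L):(e$value_pos + e$value_nbytes)] <- as.raw(0)
      ifd_len <- 2L + 12L * ifd$n_entries + 4L
      bytes[(ifd$offset + 1L):(ifd$offset + ifd_len)] <- as.raw(0)
    }
    bytes <- .relinkIfds(bytes, parsed, setdiff(seq_len(nrow(container@subImages)),
                                                drop))
  }
  writeBin(bytes, outPath)
  readContainer(outPath)
})

#' @rdname scrubMetadata
setMethod("scrubMetadata", signature("WSIContainer", "SensitiveFieldPolicy"),
          function(container, policy, outPath) {
  validObject(policy)
  .refuseInPlace(container, outPath)
  parsed <- container@.parsed
  bytes <- parsed$bytes
  keys <- tolower(policy@keys)
  for (i in seq_along(parsed$ifds)) {
    e <- .ifdTag(parsed$ifds[[i]], 270L)
    if (is.null(e)) next
    fields <- .parseAperioFields(e$values)
    if (is.null(fields)) next
    hit <- fields[tolower(fields$key) %in% keys & fields$value_len > 0L, ,
                  drop = FALSE]
    for (k in seq_len(nrow(hit))) {
      ## mask the value with an equal-length run of "X": no offset shifts
      p0 <- e$value_pos + hit$value_pos[k] - 1L
      bytes[(p0 + 1L):(p0 + hit$value_len[k])] <-
        rep(charToRaw("X"), hit$value_len[k])
    }
  }
  writeBin(bytes, outPath)
  readContainer(outPath)
})

#' Verify a de-identified whole-slide image against its original
#'
#' Four checks: (a) no identifier string from the bundle occurs anywhere in
#' the de-identified file's raw bytes; (b) the label and macro sub-images
#' are absent; (c) every surviving pyramid level decodes to pixels bitwise
#' identical to the original; (d) a standard TIFF reader (libtiff via the
#' tiff package) opens the file. Failures are entries in the returned
#' report, never errors.
#'
#' @param originalPath,deidPath the file pair.
#' @param identifiers an [IdentifierBundle-class] (or character vector of
#'   strings that must not survive).
#' @return list with `pass` (logical), `checks` (data.frame `check`,
#'   `pass`, `detail`).
#' @export
verifyDeid <- function(originalPath, deidPath, identifiers) {
  ids <- if (is(identifiers, "IdentifierBundle")) phiValues(identifiers)
         else as.character(identifiers)
  checks <- list()
  addc <- function(check, pass, detail = "")
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, pass = pass, detail = detail, stringsAsFactors = FALSE)

  ## (a) byte scan for surviving identifiers
  if (length(ids)) {
    scan <- .scanFileForBytes(deidPath, ids)
    bad <- scan[scan$hits > 0L, , drop = FALSE]
    addc("no_identifier_bytes", nrow(bad) == 0L,
         if (nrow(bad)) paste(sprintf("'%s' x%d at offset %d", bad$pattern,
                                      bad$hits, bad$first_offset),
                              collapse = "; ") else "")
  } else addc("no_identifier_bytes", TRUE, "no identifiers supplied")

  deid <- tryCatch(readContainer(deidPath), error = function(e) e)
  if (inherits(deid, "error")) {
    addc("label_macro_absent", FALSE, conditionMessage(deid))
    addc("pyramid_pixels_identical", FALSE, "unreadable")
    addc("standard_reader_opens", FALSE, "unreadable")
  } else {
    ## (b) associated images absent
    left <- intersect(deid@subImages$role, c("label", "macro"))
    addc("label_macro_absent", length(left) == 0L,
         if (length(left)) paste(left, collapse = ", ") else "")

    ## (c) pyramid pixel conservation, level by level (matched on geometry)
    orig <- readContainer(originalPath)
    osi <- orig@subImages; dsi <- deid@subImages
    opyr <- which(osi$role == "pyramid_level")
    ok <- TRUE; detail <- ""
    for (i in opyr) {
      j <- which(dsi$role == "pyramid_level" & dsi$width == osi$width[i] &
                 dsi$height == osi$height[i])
      if (!length(j)) { ok <- FALSE; detail <- sprintf(
        "pyramid level %dx%d missing", osi$width[i], osi$height[i]); break }
      po <- .tiffDecodePixels(orig@.parsed, orig@.parsed$ifds[[i]])
      pd <- .tiffDecodePixels(deid@.parsed, deid@.parsed$ifds[[j[1L]]])
      if (!identical(po, pd)) { ok <- FALSE; detail <- sprintf(
        "pixel mismatch at level %dx%d", osi$width[i], osi$height[i]); break }
    }
    addc("pyramid_pixels_identical", ok, detail)

    ## (d) a standard reader opens the file
    std <- tryCatch({ tiff::readTIFF(deidPath, all = TRUE); TRUE },
                    error = function(e) FALSE)
    addc("standard_reader_opens", std, if (std) "" else "libtiff failed")
  }
  checks <- do.call(rbind, checks)
  list(pass = all(checks$pass), checks = checks)
}

#' One-call image de-identification
#'
#' read, strip label/macro, scrub metadata, and verify, writing the result
#' to `outPath`.
#'
#' @param path input WSI.
#' @param outPath output file.
#' @param identifiers [IdentifierBundle-class] or character vector for
#'   verification.
#' @param policy a [SensitiveFieldPolicy-class].
#' @return the [verifyDeid()] report, with the output container attached as
#'   attribute `container`.
#' @export
deidentifyImage <- function(path, outPath, identifiers = character(0),
                            policy = sensitiveFieldPolicy()) {
  cont <- readContainer(path)
  tmp <- tempfile(fileext = ".svs")
  on.exit(unlink(tmp), add = TRUE)
  stripped <- stripAssociatedImages(cont, tmp)
  scrubbed <- scrubMetadata(stripped, policy, outPath)
  rep <- verifyDeid(path, outPath, identifiers)
  attr(rep, "container") <- scrubbed
  rep
}
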