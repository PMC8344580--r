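## Minimal TIFF 6.0 reader/writer for the Aperio-style SVS dialect.
##
## De-identification here must (a) zero label/macro payload bytes in place,
## (b) unlink their image file directories (IFDs) from the directory chain,
## and (c) mask metadata values byte-for-byte without shifting any file
## offset. That requires IFD-level surgery, so the container is manipulated
## at the byte level; pixel decoding for display is left to standard readers.
## Only uncompressed (Compression = 1) RGB payloads are emitted and parsed --
## the fixture generator and the de-identifier share this dialect.

.TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L)

.u16 <- function(bytes, off, le = TRUE) {
  ## off is a 0-based file offset
  b <- as.integer(bytes[(off + 1L):(off + 2L)])
  if (le) b[1L] + 256L * b[2L] else b[2L] + 256L * b[1L]
}

.u32 <- function(bytes, off, le = TRUE) {
  b <- as.double(as.integer(bytes[(off + 1L):(off + 4L)]))
  if (!le) b <- rev(b)
  b[1] + 256 * b[2] + 65536 * b[3] + 16777216 * b[4]
}

.rawU16 <- function(x) {
  x <- as.integer(x)
  as.raw(c(x %% 256L, x %/% 256L))
}

.rawU32 <- function(x) {
  x <- as.double(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

## ---- reader -----------------------------------------------------------

## Parse the IFD chain of a TIFF file. Returns the raw bytes plus one entry
## per IFD with decoded tags and the file positions needed for editing.
.tiffParse <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  n <- file.size(path)
  bytes <- readBin(path, "raw", n = n)
  if (n < 8L) .stopf("not a TIFF (file too short, %d bytes): %s", n, path)
  order_tag <- rawToChar(bytes[1:2])
  if (order_tag == "II") le <- TRUE
  else if (order_tag == "MM") le <- FALSE
  else .stopf("not a TIFF (bad byte-order mark at offset 0): %s", path)
  if (.u16(bytes, 2L, le) != 42L)
    .stopf("not a TIFF (magic != 42 at offset 2): %s", path)

  need <- function(off, k) {
    if (off < 0 || off + k > n)
      .stopf("truncated TIFF: need %d bytes at offset %.0f, file has %.0f",
             k, off, n)
  }

  ifds <- list()
  ptr_pos <- 4L                       # file position holding next-IFD offset
  off <- .u32(bytes, 4L, le)
  seen <- character(0)
  while (off != 0) {
    if (as.character(off) %in% seen) .stopf("cyclic IFD chain at offset %.0f", off)
    seen <- c(seen, as.character(off))
    need(off, 2L)
    n_entries <- .u16(bytes, off, le)
    need(off, 2L + 12L * n_entries + 4L)
    ent <- vector("list", n_entries)
    for (i in seq_len(n_entries)) {
      epos <- off + 2L + 12L * (i - 1L)
      tag <- .u16(bytes, epos, le)
      type <- .u16(bytes, epos + 2L, le)
      count <- .u32(bytes, epos + 4L, le)
      tsize <- .TIFF_TYPE_SIZE[as.character(type)]
      if (is.na(tsize)) { ent[[i]] <- NULL; next }
      nbytes <- tsize * count
      vpos <- if (nbytes <= 4) epos + 8L else .u32(bytes, epos + 8L, le)
      need(vpos, nbytes)
      values <- switch(as.character(type),
        `1` = as.integer(bytes[(vpos + 1L):(vpos + count)]),
        `2` = {
          s <- bytes[(vpos + 1L):(vpos + count)]
          s <- s[seq_len(max(0L, which(s == as.raw(0))[1L] - 1L))]
          rawToChar(s)
        },
        `3` = vapply(seq_len(count) - 1L,
                     function(k) .u16(bytes, vpos + 2L * k, le), numeric(1)),
        `4` = vapply(seq_len(count) - 1L,
                     function(k) .u32(bytes, vpos + 4L * k, le), numeric(1)),
        `5` = vapply(seq_len(count) - 1L, function(k)
          .u32(bytes, vpos + 8L * k, le) / .u32(bytes, vpos + 8L * k + 4L, le),
          numeric(1))
      )
      ent[[i]] <- list(tag = tag, type = type, count = count,
                       entry_pos = epos, value_pos = vpos,
                       value_nbytes = nbytes, values = values)
    }
    ent <- Filter(Negate(is.null), ent)
    tags <- vapply(ent, `[[`, 0, "tag")
    ifds[[length(ifds) + 1L]] <- list(
      offset = off, n_entries = n_entries, entries = ent, tags = tags,
      prev_ptr_pos = ptr_pos,
      next_ptr_pos = off + 2L + 12L * n_entries
    )
    ptr_pos <- off + 2L + 12L * n_entries
    off <- .u32(bytes, ptr_pos, le)
  }
  if (!length(ifds)) .stopf("TIFF with no image directories: %s", path)
  list(path = path, bytes = bytes, le = le, ifds = ifds)
}

.ifdTag <- function(ifd, tag) {
  i <- which(ifd$tags == tag)
  if (!length(i)) NULL else ifd$entries[[i[1L]]]
}

.ifdTagValues <- function(ifd, tag) {
  e <- .ifdTag(ifd, tag)
  if (is.null(e)) NULL else e$values
}

## ---- writer -----------------------------------------------------------

## Each sub-image: list(width, height, pixels (raw, RGB interleaved,
## row-major, length w*h*3), description, tiled (logical), tile = c(tw, th)).
## Writes a little-endian classic TIFF; returns the path invisibly.
.tiffWrite <- function(subimages, path) {
  le_pad <- function(x) if (length(x) %% 2L) c(x, as.raw(0)) else x

  plans <- lapply(subimages, function(im) {
    w <- im$width; h <- im$height
    stopifnot(length(im$pixels) == w * h * 3L)
    if (isTRUE(im$tiled)) {
      tw <- im$tile[1L]; th <- im$tile[2L]
      ntx <- ceiling(w / tw); nty <- ceiling(h / th)
      tiles <- vector("list", ntx * nty)
      px <- matrix(im$pixels, nrow = w * 3L)   # one column per image row
      k <- 0L
      for (ty in seq_len(nty)) for (tx in seq_len(ntx)) {
        k <- k + 1L
        tile <- raw(tw * th * 3L)
        rows <- ((ty - 1L) * th + 1L):min(ty * th, h)
        cols <- ((tx - 1L) * tw + 1L):min(tx * tw, w)
        for (ri in seq_along(rows)) {
          src <- px[((cols[1L] - 1L) * 3L + 1L):(cols[length(cols)] * 3L), rows[ri]]
          dst0 <- (ri - 1L) * tw * 3L
          tile[(dst0 + 1L):(dst0 + length(src))] <- src
        }
        tiles[[k]] <- tile
      }
      list(im = im, tiled = TRUE, tw = tw, th = th, chunks = tiles)
    } else {
      list(im = im, tiled = FALSE, chunks = list(im$pixels))
    }
  })

  cur <- 8
  for (i in seq_along(plans)) {
    p <- plans[[i]]
    offs <- numeric(length(p$chunks))
    for (k in seq_along(p$chunks)) {
      offs[k] <- cur
      cur <- cur + length(p$chunks[[k]])
      if (cur %% 2) cur <- cur + 1
    }
    p$chunk_offsets <- offs
    p$chunk_counts <- vapply(p$chunks, length, numeric(1))

    desc <- charToRaw(p$im$description %||% "")
    desc <- c(desc, as.raw(0))
    p$desc_raw <- le_pad(desc)
    p$desc_count <- length(desc)

    ## external value areas: BitsPerSample always (6 bytes), description if
    ## > 4 bytes, chunk offset/count arrays if more than one chunk
    p$bits_off <- cur; cur <- cur + 6
    if (p$desc_count > 4) { p$desc_off <- cur; cur <- cur + length(p$desc_raw) }
    if (length(p$chunks) > 1L) {
      p$offs_off <- cur; cur <- cur + 4 * length(p$chunks)
      p$cnts_off <- cur; cur <- cur + 4 * length(p$chunks)
    }
    plans[[i]] <- p
  }

  n_entries <- vapply(plans, function(p) if (p$tiled) 12L else 11L, integer(1))
  ifd_offsets <- numeric(length(plans))
  for (i in seq_along(plans)) {
    ifd_offsets[i] <- cur
    cur <- cur + 2 + 12 * n_entries[i] + 4
  }

  total <- cur
  out <- raw(total)
  poke <- function(off, r) {
    if (length(r)) out[(off + 1L):(off + length(r))] <<- r
  }
  poke(0, c(charToRaw("II"), .rawU16(42L), .rawU32(ifd_offsets[1L])))

  mkentry <- function(tag, type, count, value, inline_raw = NULL) {
    v <- if (!is.null(inline_raw)) {
      c(inline_raw, raw(4L - length(inline_raw)))
    } else .rawU32(value)
    c(.rawU16(tag), .rawU16(type), .rawU32(count), v)
  }

  for (i in seq_along(plans)) {
    p <- plans[[i]]
    for (k in seq_along(p$chunks)) poke(p$chunk_offsets[k], p$chunks[[k]])
    poke(p$bits_off, c(.rawU16(8L), .rawU16(8L), .rawU16(8L)))
    if (!is.null(p$desc_off)) poke(p$desc_off, p$desc_raw)
    nchunk <- length(p$chunks)
    if (nchunk > 1L) {
      poke(p$offs_off, do.call(c, lapply(p$chunk_offsets, .rawU32)))
      poke(p$cnts_off, do.call(c, lapply(p$chunk_counts, .rawU32)))
    }

    w <- p$im$width; h <- p$im$height
    desc_entry <- if (p$desc_count > 4) {
      mkentry(270L, 2L, p$desc_count, p$desc_off)
    } else {
      mkentry(270L, 2L, p$desc_count, NULL,
              inline_raw = p$desc_raw[seq_len(p$desc_count)])
    }
    common_head <- list(
      mkentry(256L, 4L, 1L, w),
      mkentry(257L, 4L, 1L, h),
      mkentry(258L, 3L, 3L, p$bits_off),
      mkentry(259L, 3L, 1L, NULL, inline_raw = .rawU16(1L)),
      mkentry(262L, 3L, 1L, NULL, inline_raw = .rawU16(2L)),
      desc_entry
    )
    entries <- if (p$tiled) {
      c(common_head, list(
        mkentry(277L, 3L, 1L, NULL, inline_raw = .rawU16(3L)),
        mkentry(284L, 3L, 1L, NULL, inline_raw = .rawU16(1L)),
        mkentry(322L, 4L, 1L, p$tw),
        mkentry(323L, 4L, 1L, p$th),
        if (nchunk > 1L) mkentry(324L, 4L, nchunk, p$offs_off)
        else mkentry(324L, 4L, 1L, p$chunk_offsets[1L]),
        if (nchunk > 1L) mkentry(325L, 4L, nchunk, p$cnts_off)
        else mkentry(325L, 4L, 1L, p$chunk_counts[1L])
      ))
    } else {
      c(common_head, list(
        mkentry(273L, 4L, 1L, p$chunk_offsets[1L]),
        mkentry(277L, 3L, 1L, NULL, inline_raw = .rawU16(3L)),
        mkentry(278L, 4L, 1L, h),
        mkentry(279L, 4L, 1L, p$chunk_counts[1L]),
        mkentry(284L, 3L, 1L, NULL, inline_raw = .rawU16(1L))
      ))
    }
    next_off <- if (i < length(plans)) ifd_offsets[i + 1L] else 0
    ifd <- c(.rawU16(length(entries)), do.call(c, entries), .rawU32(next_off))
    poke(ifd_offsets[i], ifd)
  }

  writeBin(out, path)
  invisible(path)
}

## Decode the pixel payload of one parsed IFD (uncompressed RGB only).
## Returns a raw vector, RGB interleaved row-major, length w*h*3.
.tiffDecodePixels <- function(parsed, ifd) {
  w <- .ifdTagValues(ifd, 256L); h <- .ifdTagValues(ifd, 257L)
  comp <- .ifdTagValues(ifd, 259L) %||% 1
  if (comp != 1) .stopf("only uncompressed payloads are decoded (compression %d)", comp)
  bytes <- parsed$bytes
  if (322L %in% ifd$tags) {
    tw <- .ifdTagValues(ifd, 322L); th <- .ifdTagValues(ifd, 323L)
    offs <- .ifdTagValues(ifd, 324L); cnts <- .ifdTagValues(ifd, 325L)
    ntx <- ceiling(w / tw)
    px <- matrix(raw(1), nrow = w * 3L, ncol = h)
    for (k in seq_along(offs)) {
      tx <- (k - 1L) %% ntx; ty <- (k - 1L) %/% ntx
      tile <- bytes[(offs[k] + 1L):(offs[k] + cnts[k])]
      rows <- (ty * th + 1L):min((ty + 1L) * th, h)
      cols <- (tx * tw + 1L):min((tx + 1L) * tw, w)
      for (ri in seq_along(rows)) {
        src0 <- (ri - 1L) * tw * 3L
        px[((cols[1L] - 1L) * 3L + 1L):(cols[length(cols)] * 3L), rows[ri]] <-
          tile[(src0 + 1L):(src0 + length(cols) * 3L)]
      }
    }
    as.raw(px)
  } else {
    offs <- .ifdTagValues(ifd, 273L); cnts <- .ifdTagValues(ifd, 279L)
    do.call(c, lapply(seq_along(offs), function(k)
      bytes[(offs[k] + 1L):(offs[k] + cnts[k])]))
  }
}
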