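#' @include AllClasses.R image-deid.R
NULL

## Raw interleaved RGB (row-major) -> integer array [h, w, 3].
.rawToRgbArray <- function(px, width, height) {
  a <- array(as.integer(px), dim = c(3L, width, height))
  aperm(a, c(3L, 2L, 1L))
}

#' Rec.601 luminance of an 8-bit RGB (or gray) pixel grid
#'
#' `round(0.299 R + 0.587 G + 0.114 B)`. Accepts an `[h, w, 3]` array or an
#' `[h, w]` matrix, with channels either 0--255 or 0--1 (rescaled).
#'
#' @param pixels array or matrix.
#' @return integer matrix `[h, w]` of luminance 0--255.
#' @export
luminance601 <- function(pixels) {
  if (is.double(pixels) && max(pixels, na.rm = TRUE) <= 1) pixels <- pixels * 255
  if (length(dim(pixels)) == 3L) {
    y <- 0.299 * pixels[, , 1L] + 0.587 * pixels[, , 2L] + 0.114 * pixels[, , 3L]
  } else y <- pixels
  matrix(as.integer(round(y)), nrow = nrow(pixels))
}

## Label connected components of a logical matrix by BFS flood fill.
## Returns an integer matrix of component ids (0 = background).
.labelComponents <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  if (connectivity == 8L) {
    dr <- c(dr, -1L, -1L, 1L, 1L); dc <- c(dc, -1L, 1L, -1L, 1L)
  }
  nid <- 0L
  queue <- integer(h * w)
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nid <- nid + 1L
    lab[start] <- nid
    queue[1L] <- start; qn <- 1L; qi <- 0L
    while (qi < qn) {
      qi <- qi + 1L
      cur <- queue[qi]
      r <- ((cur - 1L) %% h) + 1L
      cl <- ((cur - 1L) %/% h) + 1L
      for (k in seq_along(dr)) {
        rr <- r + dr[k]; cc <- cl + dc[k]
        if (rr < 1L || rr > h || cc < 1L || cc > w) next
        j <- (cc - 1L) * h + rr
        if (mask[j] && lab[j] == 0L) {
          lab[j] <- nid
          qn <- qn + 1L
          queue[qn] <- j
        }
      }
    }
  }
  lab
}

#' Detect dark regions on a slide thumbnail
#'
#' Connected components of pixels with Rec.601 luminance strictly below the
#' threshold, each reported with its exact pixel count over the total pixel
#' count, ordered by area descending. Dark areas on the thumbnail arise
#' from scanned label stickers bleeding into the main image and are a PHI
#' risk.
#'
#' @param thumbnail 8-bit pixel grid (`[h, w, 3]` array, `[h, w]` matrix, or
#'   0--1 doubles).
#' @param params a [DarkRegionParams-class].
#' @return data.frame: `xmin`, `xmax`, `ymin`, `ymax` (columns/rows),
#'   `n_pixels`, `area_fraction`, `mean_luminance`.
#' @export
detectDarkRegions <- function(thumbnail, params = darkRegionParams()) {
  stopifnot(is(params, "DarkRegionParams"))
  validObject(params)
  if (is.null(dim(thumbnail)) || any(dim(thumbnail)[1:2] == 0L) ||
      length(thumbnail) == 0L)
    .stopf("empty thumbnail")
  y <- luminance601(thumbnail)
  mask <- y < params@luminanceThreshold
  lab <- .labelComponents(mask, params@connectivity)
  total <- length(y)
  n <- max(lab)
  if (n == 0L)
    return(data.frame(xmin = integer(0), xmax = integer(0), ymin = integer(0),
                      ymax = integer(0), n_pixels = integer(0),
                      area_fraction = numeric(0), mean_luminance = numeric(0)))
  out <- do.call(rbind, lapply(seq_len(n), function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    data.frame(xmin = min(idx[, 2L]), xmax = max(idx[, 2L]),
               ymin = min(idx[, 1L]), ymax = max(idx[, 1L]),
               n_pixels = nrow(idx), area_fraction = nrow(idx) / total,
               mean_luminance = mean(y[lab == id]))
  }))
  out <- out[order(-out$n_pixels, out$ymin, out$xmin), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Box-downsample an [h, w, 3] integer array by integer factor f.
.boxDownsample <- function(arr, f) {
  if (f <= 1L) return(arr)
  h <- dim(arr)[1L] %/% f * f; w <- dim(arr)[2L] %/% f * f
  arr <- arr[seq_len(h), seq_len(w), , drop = FALSE]
  out <- array(0, dim = c(h %/% f, w %/% f, 3L))
  for (ch in 1:3) {
    m <- arr[, , ch]
    ## average f x f blocks
    m <- rowsum(m, rep(seq_len(h %/% f), each = f)) / f
    m <- t(rowsum(t(m), rep(seq_len(w %/% f), each = f)) / f)
    out[, , ch] <- m
  }
  out
}

## Thumbnail source: dedicated thumbnail sub-image if present, otherwise
## the base pyramid level box-downsampled to <= 512 px on the long side.
.containerThumbnail <- function(container) {
  si <- container@subImages
  i <- which(si$role == "thumbnail")
  if (!length(i)) {
    pyr <- which(si$role == "pyramid_level")
    i <- pyr[which.max(si$width[pyr] * si$height[pyr])]
  }
  px <- .tiffDecodePixels(container@.parsed, container@.parsed$ifds[[i]])
  arr <- .rawToRgbArray(px, si$width[i], si$height[i])
  f <- ceiling(max(dim(arr)[1:2]) / 512)
  .boxDownsample(arr, as.integer(f))
}

#' @rdname screenWSI
setMethod("screenWSI", "WSIContainer", function(x, params = darkRegionParams(),
                                                imageId = NULL) {
  regions <- detectDarkRegions(.containerThumbnail(x), params)
  .screenDecision(imageId %||% x@source, regions, params)
})

#' @rdname screenWSI
setMethod("screenWSI", "array", function(x, params = darkRegionParams(),
                                         imageId = NULL) {
  .screenDecision(imageId %||% "<array>", detectDarkRegions(x, params), params)
})

.screenDecision <- function(imageId, regions, params) {
  new("ScreenDecision", imageId = as.character(imageId),
      flagged = any(regions$area_fraction >= params@minAreaFraction),
      regions = regions,
      params = list(luminanceThreshold = params@luminanceThreshold,
                    minAreaFraction = params@minAreaFraction,
                    connectivity = params@connectivity))
}
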