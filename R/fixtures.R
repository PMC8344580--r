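#' @include text-deid.R warehouse.R image-deid.R
NULL

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.GIVEN_NAMES <- c("Jane", "Alice", "Robert", "Maria", "David", "Susan",
                  "Peter", "Linda", "Thomas", "Nancy", "Carlos", "Helen",
                  "George", "Diane", "Victor", "Paula")
.FAMILY_NAMES <- c("Doe", "Smithson", "Keller", "Novak", "Ferrara", "Okafor",
                   "Lindgren", "Vasquez", "Tanaka", "Moreau", "Petrov",
                   "Castillo", "Weiss", "Hansen", "Quinn", "Abbott")
.ORGANS <- c("breast", "prostate", "colon", "lung", "skin", "kidney",
             "thyroid", "liver")
.DIAGNOSES <- c("carcinoma", "adenoma", "hyperplasia", "chronic inflammation",
                "benign parenchyma")

#' The first-access month distribution matching the reported usage shape
#'
#' Probability mass over months 1..36 whose CDF hits 51% at month 1, 61% at
#' month 2, 79% at month 6 and 91% at month 12 -- the cumulative access
#' percentages of digitally reviewed WSI that motivate a 6-month tier-1
#' window.
#'
#' @return named numeric vector (months "1".."36"), summing to 1.
#' @export
paperAccessDistribution <- function() {
  p <- c(0.51, 0.10, rep(0.045, 4), rep(0.02, 6), rep(0.00375, 24))
  stats::setNames(p, as.character(seq_along(p)))
}

#' Specification of a synthetic fixture set
#'
#' Bundles every knob of the synthetic-data generators. The seed fixes all
#' randomness end-to-end: the same spec yields byte-identical fixtures.
#'
#' @param seed integer RNG seed.
#' @param nPatients number of patients.
#' @param consentRate probability a patient's protocol status is
#'   "consented" (the rest split evenly between "declined" and "unknown").
#' @param nppRate probability the Notice of Privacy Practice is signed.
#' @param protocolId research protocol identifier.
#' @param reportsPerCase reports generated per case.
#' @param phiDensity planted PHI spans per report.
#' @param wsi pyramidal geometry: `baseWidth`/`baseHeight` (<= 2048),
#'   `levels`, `tileSize`.
#' @param darkBlockFraction fraction of the thumbnail covered by a planted
#'   dark block (0 = clean).
#' @param accessMonthDist probability vector over first-access months.
#' @param neverAccessedFraction fraction of log entries never opened.
#' @return a validated list of class `FixtureSpec`.
#' @export
fixtureSpec <- function(seed = 1L, nPatients = 50L, consentRate = 0.6,
                        nppRate = 0.9, protocolId = "PR-001",
                        reportsPerCase = 1L, phiDensity = 4L,
                        wsi = list(baseWidth = 192L, baseHeight = 160L,
                                   levels = 2L, tileSize = 64L),
                        darkBlockFraction = 0,
                        accessMonthDist = paperAccessDistribution(),
                        neverAccessedFraction = 0.2) {
  stopifnot(.isScalarNumber(seed), .isScalarNumber(nPatients), nPatients >= 1,
            consentRate >= 0, consentRate <= 1, nppRate >= 0, nppRate <= 1,
            phiDensity >= 0, darkBlockFraction >= 0, darkBlockFraction < 1)
  if (wsi$baseWidth > 2048L || wsi$baseHeight > 2048L)
    .stopf("WSI base geometry exceeds 2048 px")
  if (abs(sum(accessMonthDist) - 1) > 1e-9)
    .stopf("accessMonthDist must sum to 1")
  structure(list(seed = as.integer(seed), nPatients = as.integer(nPatients),
                 consentRate = consentRate, nppRate = nppRate,
                 protocolId = protocolId,
                 reportsPerCase = as.integer(reportsPerCase),
                 phiDensity = as.integer(phiDensity), wsi = wsi,
                 darkBlockFraction = darkBlockFraction,
                 accessMonthDist = accessMonthDist,
                 neverAccessedFraction = neverAccessedFraction),
            class = "FixtureSpec")
}

.randDate <- function(n, from = "2019-01-01", to = "2021-03-01") {
  from <- as.Date(from); to <- as.Date(to)
  from + sample.int(as.integer(to - from) + 1L, n, replace = TRUE) - 1L
}

.randGuid <- function(n) {
  hex <- function(k) toupper(vapply(seq_len(n), function(i)
    paste(sample(c(0:9, letters[1:6]), k, replace = TRUE), collapse = ""),
    character(1)))
  paste(hex(8), hex(4), hex(4), hex(4), hex(12), sep = "-")
}

## ---- report generator -------------------------------------------------

.BENIGN <- c(
  "The specimen was received in formalin and entirely submitted.",
  "Sections show well-preserved tissue architecture.",
  "Margins appear free of tumor on microscopic examination.",
  "Immunostains were reviewed with adequate controls.",
  "No lymphovascular invasion is identified.",
  "The findings were discussed at the consensus conference.",
  "Gross examination reveals a tan-white, firm cut surface.",
  "Representative sections are submitted in two blocks."
)

.formatPlantedDate <- function(d, dialect) {
  switch(dialect,
         iso = format(d, "%Y-%m-%d"),
         slash4 = sprintf("%d/%d/%s", as.integer(format(d, "%m")),
                          as.integer(format(d, "%d")), format(d, "%Y")),
         slash2 = format(d, "%m/%d/%y"),
         written = sprintf("%s %d, %s", .MONTHS_EN[as.integer(format(d, "%m"))],
                           as.integer(format(d, "%d")), format(d, "%Y")))
}

#' Generate one synthetic pathology report with ground-truth PHI spans
#'
#' Plants exactly `spec$phiDensity` PHI instances drawn from the redactor's
#' documented grammar -- dates in the three covered dialects, the patient's
#' MRN, the case accession, and the patient's name in "Given Family" or
#' "Family, Given" order -- between benign sentences, and records the exact
#' character span and category of each.
#'
#' @param spec a [fixtureSpec()].
#' @param patient list with `mrn`, `name`.
#' @param case list with `accession`.
#' @param diagnosis optional diagnosis phrase worked into the text (drives
#'   keyword queries).
#' @return list with `text` and `spans`
#'   (data.frame `start`, `end`, `category`, `text`).
#' @export
generateReport <- function(spec, patient, case, diagnosis = NULL) {
  n_phi <- spec$phiDensity
  cats <- if (n_phi > 0)
    sample(c("date", "mrn", "accession", "name"), n_phi, replace = TRUE)
  else character(0)
  ## guarantee category variety at higher densities
  if (n_phi >= 4L) cats[1:4] <- sample(c("date", "mrn", "accession", "name"))
  diagnosis <- diagnosis %||% sample(.DIAGNOSES, 1L)

  pieces <- c(sprintf("FINAL DIAGNOSIS: %s.", diagnosis))
  is_phi <- FALSE; cat_of <- NA_character_
  for (k in seq_len(n_phi)) {
    lead_in <- switch(cats[k],
      date = sample(c("Specimen collected on", "Procedure dated",
                      "Slides reviewed on"), 1L),
      mrn = sample(c("Medical record number", "Patient record"), 1L),
      accession = sample(c("Refer to case", "Previously reported as"), 1L),
      name = sample(c("Patient identified as", "Reviewed for"), 1L))
    tok <- switch(cats[k],
      date = .formatPlantedDate(.randDate(1L, "2015-06-01", "2021-02-28"),
                                sample(c("iso", "slash4", "slash2", "written"), 1L)),
      mrn = patient$mrn,
      accession = case$accession,
      name = if (stats::runif(1) < 0.5) toupper(patient$name) else {
        t2 <- strsplit(patient$name, " ")[[1]]
        sprintf("%s, %s", t2[length(t2)], t2[1L])
      })
    pieces <- c(pieces, lead_in, tok, sample(.BENIGN, 1L))
    is_phi <- c(is_phi, FALSE, TRUE, FALSE)
    cat_of <- c(cat_of, NA, cats[k], NA)
  }
  starts <- cumsum(c(1L, nchar(pieces) + 1L))[seq_along(pieces)]
  text <- paste(pieces, collapse = " ")
  phi <- which(is_phi)
  spans <- data.frame(start = starts[phi],
                      end = starts[phi] + nchar(pieces[phi]) - 1L,
                      category = cat_of[phi], text = pieces[phi],
                      stringsAsFactors = FALSE)
  list(text = text, spans = spans)
}

#' Recall of a redaction against planted ground truth
#'
#' Fraction of planted PHI spans fully covered by a single replaced span of
#' the redaction.
#'
#' @param redacted a [RedactedReport-class].
#' @param truthSpans data.frame with `start`, `end` (as from
#'   [generateReport()]).
#' @return numeric in 0..1 (1 when nothing was planted).
#' @export
redactionRecall <- function(redacted, truthSpans) {
  stopifnot(is(redacted, "RedactedReport"))
  if (!nrow(truthSpans)) return(1)
  got <- redacted@spans
  covered <- vapply(seq_len(nrow(truthSpans)), function(i)
    any(got$start <= truthSpans$start[i] & got$end >= truthSpans$end[i]),
    logical(1))
  mean(covered)
}

## ---- warehouse generator ----------------------------------------------

#' Generate a synthetic clinical-pathology warehouse with ground truth
#'
#' Produces the five record streams (identifiers conforming to the platform
#' grammars), one redaction-annotated report per case, and a ground-truth
#' table of the expected per-patient consent decision. Fully deterministic
#' under `spec$seed`.
#'
#' @param spec a [fixtureSpec()].
#' @return list with `patients`, `cases`, `slides`, `images`, `reports`
#'   (lists of records suitable for [ingestWarehouse()]) and `groundTruth`
#'   (`consent` data.frame, `reportSpans` keyed by accession, `imageMeta`
#'   keyed by image_id with the identifier strings planted into each WSI).
#' @export
generateWarehouse <- function(spec) {
  stopifnot(inherits(spec, "FixtureSpec"))
  .withSeed(spec$seed, {
    n <- spec$nPatients
    mrns <- as.character(sample(1000000:9999999, n))
    given <- sample(.GIVEN_NAMES, n, replace = TRUE)
    family <- sample(.FAMILY_NAMES, n, replace = TRUE)
    npp <- stats::runif(n) < spec$nppRate
    status <- sample(c("consented", "declined", "unknown"), n, replace = TRUE,
                     prob = c(spec$consentRate, (1 - spec$consentRate) / 2,
                              (1 - spec$consentRate) / 2))
    patients <- lapply(seq_len(n), function(i) list(
      mrn = mrns[i], name = paste(given[i], family[i]),
      birth_date = format(.randDate(1L, "1930-01-01", "1995-12-31")),
      npp_signed = npp[i],
      protocol_enrollments = sprintf("%s=%s", spec$protocolId, status[i])))

    acc_counter <- sample(100:5000, 1L)
    cases <- list(); slides <- list(); images <- list(); reports <- list()
    report_spans <- list(); image_meta <- list()
    seq_by_vendor <- c(leica = 0L, philips = 0L, `3dhistech` = 0L)
    for (i in seq_len(n)) {
      for (ci in seq_len(sample(1:2, 1L))) {
        acc_counter <- acc_counter + sample(1:9, 1L)
        acc <- sprintf("%s%02d-%04d", sample(c("S", "S", "S", "C", "H", "M"), 1L),
                       sample(18:21, 1L), acc_counter)
        n_parts <- sample(1:2, 1L)
        parts <- sprintf("%d:%s", seq_len(n_parts),
                         sample(.ORGANS, n_parts, replace = TRUE))
        cases[[length(cases) + 1L]] <- list(
          accession = acc, mrn = mrns[i], parts = paste(parts, collapse = ";"))
        diagnosis <- sample(.DIAGNOSES, 1L)
        for (pid in seq_len(n_parts)) {
          for (bid in seq_len(sample(1:2, 1L))) {
            barcode <- sprintf("%s%s", substr(acc, 1L, 3L),
                               paste(sample(LETTERS, 5L, TRUE), collapse = ""))
            vendor <- sample(c("leica", "philips", "3dhistech"), 1L,
                             prob = c(0.6, 0.3, 0.1))
            model <- switch(vendor, leica = sample(c("AT2", "GT450"), 1L),
                            philips = "UFS", `3dhistech` = "P1000")
            slides[[length(slides) + 1L]] <- list(
              barcode = barcode, accession = acc, part_id = pid, block_id = bid,
              stain = sample(c("H&E", "IHC"), 1L, prob = c(0.7, 0.3)),
              scanner_vendor = vendor, scanner_model = model)
            iid <- .randGuid(1L)
            seq_by_vendor[vendor] <- seq_by_vendor[vendor] + 1L
            scan_d <- format(.randDate(1L))
            images[[length(images) + 1L]] <- list(
              image_id = iid, barcode = barcode,
              file_path = paste0(iid, ".svs"), scan_date = scan_d,
              quality_factor = if (vendor == "leica") sample(80:100, 1L) else NA,
              sequence_index = seq_by_vendor[[vendor]])
            image_meta[[iid]] <- list(
              image_id = iid, barcode = barcode, accession = acc,
              mrn = mrns[i], name = paste(given[i], family[i]),
              scan_date = scan_d)
          }
        }
        for (ri in seq_len(spec$reportsPerCase)) {
          rep <- generateReport(spec, patients[[i]], list(accession = acc),
                                diagnosis = diagnosis)
          reports[[length(reports) + 1L]] <- list(
            accession = acc, text = rep$text,
            report_date = format(.randDate(1L)))
          report_spans[[acc]] <- rep$spans
        }
      }
    }
    list(
      patients = patients, cases = cases, slides = slides, images = images,
      reports = reports,
      groundTruth = list(
        consent = data.frame(mrn = mrns, npp_signed = npp, status = status,
                             include = npp & status == "consented",
                             stringsAsFactors = FALSE),
        reportSpans = report_spans, imageMeta = image_meta,
        protocolId = spec$protocolId))
  })
}

## ---- WSI generator ----------------------------------------------------

.noisePixels <- function(w, h, lo = 190L, hi = 255L) {
  as.raw(sample(lo:hi, w * h * 3L, replace = TRUE))
}

## Embed an ASCII byte string at a pixel-row boundary of a payload.
.embedBytes <- function(px, text, at = 1L) {
  b <- charToRaw(text)
  px[at:(at + length(b) - 1L)] <- b
  px
}

#' Generate a synthetic SVS-style whole-slide image with ground truth
#'
#' Writes a pyramidal TIFF with tiled pyramid levels, a strip thumbnail, a
#' label sub-image whose description carries the token "label" and whose
#' payload encodes the label text (patient name) and barcode as raw bytes,
#' and a macro sub-image ("macro") embedding the barcode. The base level's
#' Aperio-style ImageDescription embeds barcode, filename, scan date/time,
#' scanner ID and operator. Optionally plants a dark block covering
#' `spec$darkBlockFraction` of the thumbnail (simulating label-sticker
#' bleed-through). Tissue texture is procedural noise kept pale so clean
#' thumbnails never trigger the dark-region screen.
#'
#' @param spec a [fixtureSpec()].
#' @param identifiers list with `image_id`, `barcode`, `name`, `scan_date`
#'   (see [generateWarehouse()]'s `imageMeta`).
#' @param path output file.
#' @return ground truth list: `roles` (in file order), `plantedStrings`
#'   (byte strings present in the file), `darkFraction` (exact planted
#'   fraction of the thumbnail).
#' @export
generateWSI <- function(spec, identifiers, path) {
  g <- spec$wsi
  if (g$baseWidth > 2048L || g$baseHeight > 2048L)
    .stopf("WSI base geometry exceeds 2048 px")
  ## per-image sub-seed so each file differs but the set stays deterministic
  .withSeed(spec$seed + sum(as.integer(charToRaw(identifiers$image_id))), {
    bw <- as.integer(g$baseWidth); bh <- as.integer(g$baseHeight)
    ts <- as.integer(g$tileSize)
    scan_us <- format(.asDate(identifiers$scan_date), "%m/%d/%y")
    base_desc <- sprintf(
      paste0("Aperio Image Library v0.1.0\r\n%dx%d [0,0 %dx%d] (%dx%d) RAW",
             "|AppMag = 20|MPP = 0.25|Date = %s|Time = %02d:%02d:%02d",
             "|ScanScope ID = SS%04d|Filename = %s|Barcode = %s|User = tech%02d"),
      bw, bh, bw, bh, ts, ts, scan_us, sample(0:23, 1), sample(0:59, 1),
      sample(0:59, 1), sample(1000:9999, 1), paste0(identifiers$barcode, ".svs"),
      identifiers$barcode, sample(1:20, 1))

    subs <- list(list(width = bw, height = bh, pixels = .noisePixels(bw, bh),
                      tiled = TRUE, tile = c(ts, ts), description = base_desc))
    w <- bw; h <- bh
    for (lv in seq_len(max(0L, g$levels - 1L))) {
      w2 <- max(ts, w %/% 2L); h2 <- max(ts, h %/% 2L)
      subs[[length(subs) + 1L]] <- list(
        width = w2, height = h2, pixels = .noisePixels(w2, h2), tiled = TRUE,
        tile = c(ts, ts),
        description = sprintf("%dx%d -> %dx%d reduced", bw, bh, w2, h2))
      w <- w2; h <- h2
    }

    tw <- max(16L, bw %/% 4L); th <- max(16L, bh %/% 4L)
    thumb_px <- .noisePixels(tw, th)
    dark_fraction <- 0
    if (spec$darkBlockFraction > 0) {
      wb <- max(1L, round(tw * sqrt(spec$darkBlockFraction)))
      hb <- max(1L, round(th * sqrt(spec$darkBlockFraction)))
      m <- array(as.integer(thumb_px), dim = c(3L, tw, th))
      m[, seq_len(wb), seq_len(hb)] <- sample(5:25, 3L * wb * hb, replace = TRUE)
      thumb_px <- as.raw(m)
      dark_fraction <- (wb * hb) / (tw * th)
    }
    subs[[length(subs) + 1L]] <- list(
      width = tw, height = th, pixels = thumb_px, tiled = FALSE,
      description = sprintf("%dx%d -> %dx%d", bw, bh, tw, th))

    lw <- 64L; lh <- 32L
    label_px <- as.raw(sample(10:60, lw * lh * 3L, replace = TRUE))
    label_px <- .embedBytes(label_px, identifiers$name, at = 1L)
    label_px <- .embedBytes(label_px, identifiers$barcode, at = lw * 3L + 1L)
    subs[[length(subs) + 1L]] <- list(
      width = lw, height = lh, pixels = label_px, tiled = FALSE,
      description = sprintf("label %dx%d", lw, lh))

    mw <- 96L; mh <- 48L
    macro_px <- .noisePixels(mw, mh)
    macro_px <- .embedBytes(macro_px, identifiers$barcode, at = 1L)
    subs[[length(subs) + 1L]] <- list(
      width = mw, height = mh, pixels = macro_px, tiled = FALSE,
      description = sprintf("macro %dx%d", mw, mh))

    .tiffWrite(subs, path)
    list(
      roles = c(rep("pyramid_level", g$levels), "thumbnail", "label", "macro"),
      plantedStrings = unique(c(identifiers$name, identifiers$barcode,
                                paste0(identifiers$barcode, ".svs"), scan_us)),
      darkFraction = dark_fraction)
  })
}

## ---- access log generator ---------------------------------------------

#' Generate a synthetic WSI access log
#'
#' Scan dates are uniform over 2017--2020; a `spec$neverAccessedFraction`
#' share of entries is never opened; the rest draw their first-access month
#' from `spec$accessMonthDist` and a uniform day within that 30.44-day
#' month bin.
#'
#' @param spec a [fixtureSpec()].
#' @param n number of log entries.
#' @return data.frame `image_id`, `scan_date`, `first_access_date` (`NA`
#'   when never accessed).
#' @export
generateAccessLog <- function(spec, n) {
  stopifnot(n >= 1)
  .withSeed(spec$seed + 7919L, {
    scan <- .randDate(n, "2017-01-01", "2020-12-31")
    accessed <- stats::runif(n) >= spec$neverAccessedFraction
    p <- spec$accessMonthDist
    month <- sample(seq_along(p), n, replace = TRUE, prob = p)
    lo <- floor((month - 1) * .DAYS_PER_MONTH) + 1
    hi <- floor(month * .DAYS_PER_MONTH)
    days <- lo + floor(stats::runif(n) * (hi - lo + 1))
    first <- scan + days
    data.frame(
      image_id = sprintf("im%06d", seq_len(n)),
      scan_date = format(scan),
      first_access_date = ifelse(accessed, format(first), NA_character_),
      stringsAsFactors = FALSE)
  })
}

## ---- full fixture set --------------------------------------------------

#' Materialize a complete fixture set on disk
#'
#' Writes the warehouse streams (JSON-lines / CSV), one SVS file per image
#' record, and the ground-truth JSON into `dir`, and returns everything
#' in memory as well.
#'
#' @param spec a [fixtureSpec()].
#' @param dir output directory (created).
#' @param darkImageIds image IDs whose thumbnails get the planted dark
#'   block (defaults to none; pass IDs to exercise the PHI screen).
#' @return list: `spec`, record streams, `groundTruth`, `paths`.
#' @export
generateFixtureSet <- function(spec, dir, darkImageIds = character(0)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wsi_dir <- file.path(dir, "wsi")
  dir.create(wsi_dir, showWarnings = FALSE)
  gw <- generateWarehouse(spec)

  paths <- list(
    patients = file.path(dir, "patients.jsonl"),
    cases = file.path(dir, "cases.jsonl"),
    slides = file.path(dir, "slides.csv"),
    images = file.path(dir, "images.csv"),
    reports = file.path(dir, "reports.jsonl"),
    wsi_dir = wsi_dir)
  .writeJsonLines(gw$patients, paths$patients)
  .writeJsonLines(gw$cases, paths$cases)
  utils::write.csv(do.call(rbind, lapply(gw$slides, as.data.frame)),
                   paths$slides, row.names = FALSE)
  utils::write.csv(do.call(rbind, lapply(gw$images, as.data.frame)),
                   paths$images, row.names = FALSE)
  .writeJsonLines(gw$reports, paths$reports)

  dark_spec <- spec
  if (dark_spec$darkBlockFraction == 0) dark_spec$darkBlockFraction <- 0.12
  for (im in gw$images) {
    meta <- gw$groundTruth$imageMeta[[im$image_id]]
    use <- if (im$image_id %in% darkImageIds) dark_spec else {
      s <- spec; s$darkBlockFraction <- 0; s
    }
    gt <- generateWSI(use, meta, file.path(wsi_dir, im$file_path))
    gw$groundTruth$imageMeta[[im$image_id]]$wsi <- gt
  }
  jsonlite::write_json(gw$groundTruth["consent"],
                       file.path(dir, "ground_truth.json"))
  c(list(spec = spec, paths = paths), gw)
}
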