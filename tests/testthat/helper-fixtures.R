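## Shared fixtures and independent brute-force oracles. The oracles are
## deliberately naive re-implementations used only for equivalence checks.

tinySpec <- function(seed = 11, nPatients = 5, ...) {
  fixtureSpec(seed = seed, nPatients = nPatients, ...)
}

tinyWarehouse <- function(spec = tinySpec()) {
  gw <- generateWarehouse(spec)
  list(wh = ingestWarehouse(gw$patients, gw$cases, gw$slides, gw$images,
                            gw$reports),
       gw = gw)
}

## Independent consent filter: decide per patient straight from the raw
## patient stream, then map images up through slides and cases.
oracleConsent <- function(gw, protocolId) {
  ok_mrn <- vapply(gw$patients, function(p) {
    enr <- strsplit(p$protocol_enrollments, ";")[[1]]
    kv <- strsplit(enr, "=", fixed = TRUE)
    st <- vapply(kv, `[`, "", 2)[vapply(kv, `[`, "", 1) == protocolId]
    isTRUE(p$npp_signed) && length(st) == 1 && st == "consented"
  }, logical(1))
  ok_mrn <- vapply(gw$patients, `[[`, "", "mrn")[ok_mrn]
  acc_ok <- vapply(gw$cases, `[[`, "", "accession")[
    vapply(gw$cases, `[[`, "", "mrn") %in% ok_mrn]
  bc_ok <- vapply(gw$slides, `[[`, "", "barcode")[
    vapply(gw$slides, `[[`, "", "accession") %in% acc_ok]
  vapply(gw$images, `[[`, "", "image_id")[
    vapply(gw$images, `[[`, "", "barcode") %in% bc_ok]
}

## Naive recursive-style flood fill (stack-based, scans in a different
## order than the package's BFS).
oracleLabelComponents <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nid <- 0L
  for (c0 in seq_len(w)) for (r0 in seq_len(h)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    nid <- nid + 1L
    stack <- list(c(r0, c0))
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      r <- p[1]; cc <- p[2]
      if (r < 1 || r > h || cc < 1 || cc > w) next
      if (!mask[r, cc] || lab[r, cc] != 0L) next
      lab[r, cc] <- nid
      stack <- c(stack, list(c(r - 1, cc), c(r + 1, cc), c(r, cc - 1),
                             c(r, cc + 1)))
      if (connectivity == 8L)
        stack <- c(stack, list(c(r - 1, cc - 1), c(r - 1, cc + 1),
                               c(r + 1, cc - 1), c(r + 1, cc + 1)))
    }
  }
  lab
}

## Component area multiset -- labeling ids may differ between algorithms,
## the partition must not.
componentAreas <- function(lab) sort(tabulate(lab[lab > 0]))

## Brute-force QC triage, re-stated predicate by predicate.
oracleTriage <- function(images, macroOk, period = 10L) {
  n <- nrow(images)
  data.frame(
    image_id = images$image_id,
    macro_review = rep(TRUE, n),
    quality_factor_review = vapply(seq_len(n), function(i)
      images$scanner_vendor[i] == "leica" &&
        !is.na(images$quality_factor[i]) && images$quality_factor[i] < 90,
      logical(1)),
    full_open_check = vapply(seq_len(n), function(i) {
      v <- images$scanner_vendor[i]
      v == "philips" ||
        (v %in% c("leica", "3dhistech") && images$sequence_index[i] %% period == 0)
    }, logical(1)),
    outcome = ifelse(macroOk, "pass", "rescan"),
    rescan_reason = ifelse(macroOk, NA_character_, "missing_tissue"),
    stringsAsFactors = FALSE)
}

## Identifier strings planted in a fixture set, for byte-survival scans.
plantedIdentifiers <- function(fx) {
  unique(unlist(lapply(fx$groundTruth$imageMeta, function(m)
    c(m$mrn, m$name, m$accession, m$barcode, m$image_id,
      m$wsi$plantedStrings))))
}

scanDirForBytes <- function(dir, patterns) {
  files <- list.files(dir, recursive = TRUE, full.names = TRUE)
  sum(vapply(files, function(f)
    sum(pathbroker:::.scanFileForBytes(f, patterns)$hits), numeric(1)))
}
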