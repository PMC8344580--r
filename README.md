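# pathbroker

Honest-broker compilation and de-identification of digital pathology
research datasets.

## The problem

Clinical digital pathology archives hold millions of whole-slide images
(WSI) with their pathology reports and patient metadata — a treasure trove
for computational pathology, but one that cannot leave the clinical
boundary as-is: images, reports and records are riddled with protected
health information (PHI), and release is gated on patient-level research
consent. An *honest broker* sits between the two worlds: it compiles
cohorts from the identified warehouse, de-identifies everything it
releases, and alone retains the key linking surrogates back to the
originals.

`pathbroker` implements that broker as a reusable R toolkit, for
informatics engineers and research coordinators who need to stand up or
audit such a pipeline:

- **Warehouse** — a validated store of patients (with Notice-of-Privacy-
  Practice and protocol consent facts), accessioned cases and parts,
  slides, scanned images and free-text reports, with referential integrity
  and identifier grammars (accessions `[SCHRM]\d{2}-\d+`) enforced at
  ingest; conjunctive cohort queries; a consent gate that releases a
  patient's images iff the NPP is signed *and* the protocol status is
  affirmatively "consented".
- **Text de-identification** (HIPAA Safe Harbor) — date truncation to the
  year; surrogate identifiers (HIDs, `P-`/`C-`/`I-` + 8 hex digits from a
  keyed counter, never a hash of the original) in three families — patient
  (MRN), case (accession), image (vendor image ID) — held in a persistent
  bidirectional key store; rule-based report redaction of dates (ISO, US
  slash, written month), accession/barcode tokens, medical record numbers
  and the patient's name in both orders, with placeholders like
  `[ACCESSION]` and `[DATE-2020]` (the year may remain under Safe Harbor).
- **Image de-identification** — PHI lives in four parts of a WSI: the
  label image, the macro image, the text metadata, and (via sticker
  bleed-through) the main image. For SVS-style pyramidal TIFFs the package
  zeroes label/macro payload bytes *and* unlinks their directories, masks
  sensitive metadata values in place (equal-length `X` runs, no offset
  shifts), and verifies byte-level PHI non-survival plus bitwise pyramid
  pixel conservation.
- **PHI screen** — connected-component detection of dark thumbnail regions
  (label-sticker bleed-through); a flagged WSI is excluded from the
  dataset outright.
- **Scan QC** — deterministic triage: macro review for every scan, detail
  review of Leica scans with quality factor < 90, full manual open of
  every Philips scan and every 10th Leica/3DHistech scan, plus a
  persistent pathologist rescan queue.
- **Storage planning** — capacity arithmetic (1 GB/WSI × 10⁶ scans/yr =
  1 PB/yr), cumulative first-access curves from access logs, and the
  smallest tier-1 retention window reaching a coverage target (79% within
  6 months in the motivating usage data).
- **Fixtures** — a deterministic synthetic generator for every input
  family (warehouse streams, redaction-annotated reports, SVS files with
  planted PHI, access logs), with exact ground truth.

## Worked example

```r
library(pathbroker)

spec <- fixtureSpec(seed = 42, nPatients = 6)
fx   <- generateFixtureSet(spec, file.path(tempdir(), "fixtures"))
wh   <- ingestWarehouse(fx$patients, fx$cases, fx$slides, fx$images,
                        fx$reports)
wh
#> PathWarehouse
#>   6 patients, 9 cases, 12 parts, 18 slides, 18 images, 9 reports
#>   protocols: PR-001

ks  <- openKeyStore(file.path(tempdir(), "keys.jsonl"))  # outside the export
man <- compileDataset(wh, cohortCriteria(protocolId = "PR-001"), ks,
                      outDir = file.path(tempdir(), "export"),
                      wsiDir = fx$paths$wsi_dir)
man
#> DatasetManifest request-001: 14 included, 4 excluded
#>   excluded by reason: consent=4

head(man@included[, c("image_hid", "case_hid", "patient_hid",
                      "scan_year", "stain")], 3)
#>    image_hid   case_hid patient_hid scan_year stain
#> 1 I-171686a2 C-9e38cb45  P-9e38f6ac      2021   IHC
#> 2 I-b54e0053 C-9e38cb45  P-9e38f6ac      2019   H&E
#> 3 I-53857a04 C-9e38cb45  P-9e38f6ac      2021   IHC
```

Fourteen of the 18 images ship; the four images of non-consented patients
are excluded with reason `consent`. The export contains only HIDs,
year-truncated dates, redacted reports and stripped/scrubbed images — the
key store alone (held outside the export) can map a HID back:

```r
reidentify(ks, man@included$image_hid[1])
#> [1] "7F462949-62CC-96D7-C7DA-C29216344A9A"

redactReport("S20-0123 from JANE DOE on 03/15/2020",
             patient = list(name = "Jane Doe"))@deidText
#> [1] "[ACCESSION] from [PATIENT] on [DATE-2020]"
```

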