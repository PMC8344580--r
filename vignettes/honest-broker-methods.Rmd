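---
title: "Methods: honest-broker de-identification of digital pathology data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: honest-broker de-identification of digital pathology data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathbroker)
```

This vignette is the package's own account of its methods: the model of
the data, the de-identification procedures and their assumptions, the
tunable parameters, the numerical and design choices made where the design
was genuinely open, and what the synthetic fixtures do and do not show
about real data.

## The data model

A digital pathology platform hangs off a small set of identifiers: the
medical record number (MRN) of a patient; the accession number of a case
(specimen-class letter S/C/H/R/M + two-digit year + dash + running
number); part and block numbers locating tissue within the case; the slide
barcode; the vendor-issued image ID (often a GUID); and the image file
path. **All of these except part and block numbers are PHI or sensitive**
and must not survive external sharing. The warehouse
(`ingestWarehouse()`) enforces these grammars and the referential chain
image → slide → part → case → patient at load time, failing on dangling
references and duplicates rather than quarantining them: a broker that
silently drops records cannot certify what it released.

Consent is modeled per patient as (a) a signed Notice of Privacy Practice
and (b) a per-protocol status `consented` / `declined` / `unknown`.
`enforceConsent()` releases a patient's images iff (a) holds and (b) is
affirmatively `consented`. *Unknown excludes.* This is the conservative
reading of patient-level inclusion: an honest broker must be able to show
affirmative consent for everything it released, so absence of evidence is
treated as refusal. Consent is evaluated at request time, not snapshotted;
recompiling after a consent change yields the updated cohort.

## Safe-Harbor text de-identification

Three operations cover the structured and free-text material:

**Date truncation.** Every discretely stored date is reduced to its
4-digit year (`truncateDate()`); Safe Harbor permits the year. An
unparseable date is an error, never a pass-through.

**HID generation.** Surrogate identifiers come in three families
mirroring the source identifiers: patient HIDs for MRNs, case HIDs for
accessions, image HIDs for vendor image IDs. A HID is
`<P|C|I>-<8 hex digits>` where the hex digits are a keyed affine
permutation of a per-family counter (multiplier 2654435761, the Knuth
multiplicative-hash constant, odd and therefore bijective mod 2^32). A
counter — not a hash of the original — was chosen deliberately: a hashed
MRN can be inverted by enumerating the small MRN space, a permuted counter
cannot. As a belt-and-braces guarantee the issuer regenerates any HID that
happens to share a 4-character run with its original. The key store is an
append-only JSON-lines file; reopening it reconstructs the identical
mapping, so HIDs are stable across runs and re-identification
(`reidentify()`) is exact. The store lives outside every export directory:
keys never ship with a dataset.

**Text redaction.** `redactReport()` applies ordered regular-expression
rules for four categories — dates, accession/barcode tokens, MRNs, and the
patient's name — replacing each maximal match with a placeholder
(`[DATE-<year>]`, `[ACCESSION]`, `[MRN]`, `[PATIENT]`). Earlier rules win
overlaps; spans are recorded against the original text so the redaction is
auditable and reconstructible. Choices worth stating:

- *Date dialects covered:* ISO (`2020-03-15`), US slash (`3/15/2020`,
  `03/15/20`, two-digit years pivoted at 50), and written month
  (`March 15, 2020`). These are the only dialects the synthetic fixtures
  emit, by contract; a real deployment feeding other dialects would need
  additional rules, and passing fixtures says nothing about dialects
  outside this grammar.
- *MRN pattern:* standalone 6–9 digit runs. This deliberately
  over-redacts (a 7-digit specimen weight would be masked too); for a
  release pipeline, over-redaction is the correct failure direction.
- *Names:* the patient's own name tokens (≥ 3 characters), matched
  case-insensitively on word boundaries, with the pair forms
  "Given Family" and "Family, Given" tried first so a full name collapses
  to a single `[PATIENT]`. Initials and nicknames are out of scope.
- *Barcodes:* whether barcodes appear inside report text is
  institution-specific; barcode-shaped tokens (letter + 2-digit year +
  alphanumeric suffix) are folded into the accession rule, so they redact
  if present.
- Placeholders contain no digits and cannot match any rule (enforced by
  the rule-set validity method), which makes redaction a fixed point:
  re-redacting output changes nothing. The year retained inside
  `[DATE-<year>]` keeps the multiset of mentioned years invariant — a
  property the tests check explicitly.
- Only this rule-based pass is implemented. Production deployments often
  chain a commercial de-identification product in front of a homegrown
  pass; that product is not reproduced here, so measured recall refers to
  the rule grammar above, not to arbitrary free text.

## Image de-identification

PHI can be found in four parts of a WSI: (1) the label image (sticker
photo with barcode and patient name), (2) the macro image (whole-glass
overview, possibly showing part of the sticker), (3) text metadata
(barcode, dates, scanner ID, filename, operator), and (4) the main image
when the sticker was scanned next to the tissue.

For parts 1–3 the package operates at the TIFF byte level on an
Aperio-style SVS dialect (classic TIFF 6.0, tiled pyramid levels, strip
thumbnail/label/macro, `|key = value|` ImageDescription):

- `stripAssociatedImages()` **overwrites** label and macro payload bytes
  with zeros, zeroes their directory entries and external values (a label
  description can itself carry PHI), and **unlinks** their IFDs from the
  directory chain. Overwrite-then-unlink means neither a naive reader nor
  a byte scavenger recovers anything. The macro is always removed, not
  conditionally: deciding whether a macro shows sticker fragments is
  exactly the judgment an automated pipeline should not attempt.
- `scrubMetadata()` masks each sensitive description value with an
  equal-length run of `X`, so no file offset shifts. The default policy
  masks `Date`, `Time`, `ScanScope ID`, `Barcode`, `Filename`, `User`; the
  exact sensitive-tag list is vendor-specific and therefore configurable,
  but geometry keys and the spatial resolution (MPP) are refused —
  stripping those would corrupt or scientifically devalue the file.
- In-place editing is refused; output is always a new file, so a crashed
  run can never leave a half-de-identified original.
- `verifyDeid()` is the acceptance gate: raw-byte scan for every supplied
  identifier, label/macro absence, bitwise pyramid pixel comparison
  against the original, and a decode through libtiff (the `tiff` package)
  as an independent standard reader. Verification failures are report
  entries, not errors, so a batch can triage them.

Only this SVS/TIFF dialect is handled; Philips iSyntax and 3DHistech MRXS
containers are proprietary and out of scope — a deployment would use the
vendors' own de-identification tools for those, and `readContainer()`
errors out on anything that is not a TIFF.

Part 4 is handled by exclusion, not repair: `screenWSI()` computes Rec.601
luminance (`round(0.299R + 0.587G + 0.114B)`) on the thumbnail (or a
box-downsampled base level capped at 512 px), labels connected components
of pixels strictly below a luminance threshold, and flags the image when
any component reaches the minimum area fraction (inclusive boundary). A
flagged WSI is excluded from the dataset, never cropped or inpainted —
the conservative behavior. Defaults (threshold 60/255, minimum area 5%,
8-connectivity) are package choices, not reported values: no quantitative
definition of "dark area" exists in the motivating workflow, so the
defaults were set once against the synthetic sticker fixtures and are
exposed as `darkRegionParams()` for per-site calibration. Screening is
pure — it never mutates the container — and the labeling is
cross-checked in the tests against independent implementations
(EBImage's `bwlabel` for 4-connectivity, a naive flood fill for 8).

## Scan QC and storage planning

The post-scan QC workflow is restated as three deterministic predicates
(`triageScan()`): macro review always; detailed focus review for Leica
scans with a scanner-issued quality factor strictly below 90 (90 passes —
the inequality is printed as `<90`); full manual open for every Philips
scan and every 10th Leica/3DHistech scan per batch. "Every 10th" is
interpreted as sequence index ≡ 0 (mod 10), so contiguous indices 1..n
select exactly ⌊n/10⌋; the phase is unspecified in the source workflow and
this choice is the natural one. Philips scans get both the macro review
and the full open. A failed macro review forces a rescan with reason
`missing_tissue` — a simplification of what is human judgment in
practice. A Leica record without a quality factor violates the vendor
contract and errors. The pathologist rescan queue (`fileRescanRequest()`)
accepts the four observed reason categories (blurriness, missing tissue,
air bubbles, other) and collapses duplicate reports per image, reporter
and day.

Storage planning uses decimal units (10^6 GB = 1 PB) so that 1 GB/WSI at
one million scans a year is exactly 1 PB/year. Access curves bin first
access by calendar-agnostic 30.44-day months (month 1 = (0, 1 month],
same-day access clamps into month 1); never-opened images are excluded
from the curve's denominator — the curve describes reviewed images — but
participate normally in tier assignment by scan age.
`selectTier1Window()` returns the smallest month reaching a coverage
target; on the preset access distribution below, the 79% target yields 6
months.

## The synthetic fixtures

The generators (`generateWarehouse()`, `generateReport()`,
`generateWSI()`, `generateAccessLog()`) emulate the archive at desk
scale, fully deterministic under `fixtureSpec(seed = ...)`:

- Default study conditions: 50 patients, consent rate 0.6 (remainder
  split evenly between declined and unknown), NPP rate 0.9, 1–2 cases per
  patient, 1–2 parts per case, 1–2 blocks per part, vendor mix 60% Leica /
  30% Philips / 10% 3DHistech, 4 planted PHI spans per report. The access
  month distribution is the preset whose CDF hits 51% / 61% / 79% / 91%
  at months 1 / 2 / 6 / 12, with 20% of entries never accessed.
- WSI geometry defaults to a 192×160 base with 64-px tiles and two
  pyramid levels — small enough that the whole suite (hundreds of
  generated files) runs in seconds while still exercising ragged edge
  tiles, multi-level pyramids and all four sub-image roles. Tissue is
  procedural pale noise (every channel ≥ 190, luminance safely above the
  dark threshold); label payloads embed the patient name and barcode as
  raw bytes so byte-survival scans have real targets; sticker
  bleed-through is a planted dark block of known exact area.
- Planted PHI is restricted to the redactor's documented grammar — the
  generator must not outrun the redactor's contract. Consequently the
  measured 100% recall certifies the implementation against its own
  grammar, not against free-text clinical prose, and the WSI fixtures
  certify the SVS dialect handling, not vendor-proprietary containers.
  Real deployments should expect lower text recall and must add vendor
  tooling; that is precisely why the commercial-scale figures of the
  motivating platform (millions of slides, institutional usage counts)
  are not reproduced here.

## Numerical and degenerate-input conventions

Dates parse strictly as `YYYY-MM-DD` in structured fields; two-digit
years inside text pivot at 50. Luminance rounds to integers before
thresholding ("dark" is `< threshold`, flagging is `>= minAreaFraction`).
Dark regions are ordered by area descending with row/column tie-breaks.
Empty record streams yield a valid empty warehouse; an empty report
redacts to an empty report; a TIFF without a pyramid level, a truncated
file (reported with the failing offset), a non-positive sampling period,
an access date before its scan date, and an unreachable coverage target
(reported with the maximum attainable fraction) are all hard errors.

The acceptance script (`scripts/acceptance.R`) recomputes everything it
reports at run time: problem sizes are 10 000 access-log entries, 1 000
redacted reports, ten fully compiled three-patient datasets, and 200
key-store round trips, all seeded from `--seed`.
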