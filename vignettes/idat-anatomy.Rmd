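---
title: "Anatomy of IDAT files and the design of beadio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anatomy of IDAT files and the design of beadio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beadio)
```

## The problem

Illumina BeadArray scanners write one IDAT file per channel per sample
section. Each bead-type (probe) is represented by many physical beads; the
file stores the per-bead-type *summary* of their intensities, not bead-level
data. Historically the only route from an IDAT to usable numbers was the
vendor's GenomeStudio export, which drops control-probe intensities,
out-of-band measurements, and all scan metadata. beadio reads (and, for
testing, writes) every IDAT dialect directly, so a pipeline can start from
the scanner output itself.

Three on-disk dialects hide behind the uniform `.idat` extension:

| Platform                | Container        | Per-probe data fields |
|-------------------------|------------------|----------------------:|
| SNP genotyping          | binary           | 4 |
| Methylation             | binary           | 4 |
| Gene expression         | DES-encrypted XML| 10 |

plus gzip-compressed copies of the binary container. Because extensions are
uninformative, `detect_idat_format()` goes by leading magic bytes only:
`"IDAT"` for the binary container, `1f 8b` for gzip, and anything else is
treated as encrypted XML — ciphertext has no recognisable prefix, so the
encrypted dialect is necessarily the fallback class. One consequence worth
knowing: a binary file whose magic has been damaged is, to the dispatcher,
indistinguishable from ciphertext, so `read_idat()` on such a file reports a
missing/wrong key; the dialect-specific `read_binary_idat()` reports
not-an-IDAT. Both surfaces are tested.

## The binary container

All integers are little-endian. The layout is:

```
"IDAT" | format_version: uint64 (= 3) | n_fields: int32 |
n_fields × (field code: uint16, byte offset: uint64) |
field payloads
```

The field directory is a table of contents: readers seek to each offset
rather than scanning. Codes used by beadio: 1000 probe count (int32), 102
bead-type IDs (int32 each), 103 intensity SD (uint16), 104 mean intensity
(uint16), 107 bead count (uint8), 200 an uninterpreted int32 block, 300 the
processing log, 400 an uninterpreted channel integer, 402/403/404 barcode,
chip type and section position, and 401/405–407/510 uninterpreted strings
that are preserved verbatim. The probe count is always read first because
array lengths are not self-describing; every array read is validated against
it, and a directory offset at or beyond end-of-file is an immediate
corrupt-file error naming the offset. Unknown codes are recorded (code +
offset) and skipped — chip revisions add fields, and refusing to read a file
over an unrecognised extra would help nobody.

Strings are framed as a base-128 varint byte-length prefix (7 data bits per
byte, high bit = continuation, least-significant group first) followed by
that many bytes of Latin-1 text. Latin-1 rather than UTF-8 because scanner
software emits single-byte encodings and Latin-1 can never fail to decode; a
continuation chain longer than 5 bytes (i.e. a length that cannot fit 32
bits) is treated as corruption.

The processing log (`run_info`) holds five strings per entry: timestamp,
block type, block parameters, software name, software version.
`scan_metadata()` takes the scan date from the first entry whose block type
contains "Scan" (case-insensitively) and deduplicates the software
name/version pairs — the pieces of an IDAT most useful for batch-effect
auditing. Timestamps are parsed with the scanner's US-locale convention
(`10/30/2012 3:24:27 PM`, ISO as fallback); anything else is preserved
verbatim and flagged unparsed rather than coerced, because real files mix
locales and a silently mangled date is worse than an unparsed one.

The writer emits fields in ascending code order with contiguous payloads, so
equal objects produce byte-identical files — which is what makes whole-file
round-trip testing meaningful.

## The encrypted expression dialect

Expression IDATs are an XML document encrypted with single DES. beadio
implements the cipher from the published FIPS 46-3 tables in C (no package
in its dependency set provides single DES) and verifies it in the test suite
against published single-block vectors, the cipher's complementation
property, and round-trip identity. The padding/framing policy is PKCS#7 over
ECB, kept in one file as the single configurable policy: the vendor's exact
mode and key handling are not publicly documented, so beadio isolates that
choice and injects the key via argument or the `beadio.des_key` option. The
fixture writer uses an arbitrary documented key (`"beadio01"`); no vendor
key is shipped or recovered. Decryption failures are diagnosed through the
padding and XML checks: invalid padding or unparseable XML is reported as
wrong-key-or-corrupt rather than returned as garbage numbers.

Inside the XML, ten data vectors are Base64 strings (RFC 4648, standard
alphabet) of little-endian 4-byte elements: int32 for IDs and bead counts,
IEEE-754 single precision for intensities. Nine tags have known semantics —
IDs, mean, SD, median, trimmed mean, background mean/SD, bead counts before
and after outlier exclusion. The tenth (conventionally `CodesBinData`) has
no documented meaning; beadio decodes it as int32 and keeps it, verbatim,
under its tag name in `extra_field` rather than guessing. A payload with any
number of data fields other than ten is a dialect error listing the tags
found.

One deterministic subtlety: raw ECB ciphertext can in principle begin with
the gzip magic (probability about `2^-16` per file) and would then be
misrouted by magic-byte dispatch. The fixture writer checks for this and,
on collision, appends an XML comment and re-encrypts; output remains a pure
function of the input object.

## Manifests

A BGX manifest is a gzip-compressed sectioned text file (`[Heading]`,
`[Probes]`, `[Controls]`; tab-separated tables with one header line) mapping
bead-type IDs to probe sequences, targets and control status. Section and
column names drift across chip generations, so both are matched
case-insensitively through explicit alias tables. Declared counts in the
heading are cross-checked; a mismatch warns and parsing proceeds, because a
usable table beats a refusal over a stale header. A missing `[Probes]`
section, by contrast, is fatal. The binary BPM manifest layout is
undocumented and deliberately out of scope; `read_bpm_csv()` accepts the
text-export dialect with the same record model instead.

`annotate_idat()` left-joins intensities onto the manifest: intensity values
and row count are never altered, unmatched IDs keep their row with `NA`
annotation, and the unmatched count travels as an attribute.

## The fixture generator

All testing runs on files the package writes itself; no third-party data is
needed. The generator's defaults are fixed study conditions, not tuning
knobs: log-normal mean intensities with location `log(1000)` and scale 0.8
(BeadArray intensities span roughly two orders of magnitude within the
16-bit scanner range), per-probe SD at 10% of the mean, 5–25 beads per
bead-type (decoded arrays average about 15), and 5% control probes.

For expression fixtures the ten vectors are not independent noise: a
per-bead intensity set is simulated for every bead-type, beads farther than
3 raw median-absolute-deviations from the probe median are excluded (any
documented deterministic rule suffices; this one is simple and
scale-free), and mean, SD, median and trimmed mean (symmetric 5% trim,
`floor(0.05·m)` observations dropped per end) are computed from the
retained beads. The simulated bead sets ride along as an attribute so tests
can recompute every statistic by brute force and demand exact agreement.
Statistics are snapped to single precision at generation time, because the
file stores float32 and the codec itself never re-rounds — this is what
makes "float fields survive the round trip bit-exactly" a meaningful
assertion.

What the generator does *not* emulate: spatial artefacts, dye bias,
between-channel correlation, realistic probe-sequence composition, or any
biological signal structure. Passing round-trip and consistency tests
therefore demonstrates codec correctness — bytes in, same bytes out, fields
meaning what they claim — not that downstream analyses of real arrays will
behave.

Every fixture records its seed inside the file's own metadata, and equal
profiles yield byte-identical files. `corrupt_file()` derives error-path
inputs deterministically; its `wrong_pad` mode overwrites the final
ciphertext block with the first one, which under ECB guarantees the last
plaintext byte is ordinary XML text and the padding check fails for any key
and fixture, with no randomness involved.

## Comparison against text exports

`compare_to_text_export()` quantifies agreement with tables exported by
other software, which typically round. Rows are matched by bead-type ID and
classified exact / within-rounding / discordant; the three counts partition
the compared rows by construction. Rounding is round-half-to-even at a
configurable number of decimals, default 1 — the vendor's precision and
rounding rule are not published, so both are explicit parameters rather
than baked-in guesses. Perturbations of ±0.04 against integer truth values
land within the one-decimal grid and ±0.06 outside it, which the tests use
as a constructed oracle in both directions.

## Problem sizes and numerical choices

The round-trip suite runs on 102 randomized fixtures per dialect with probe
counts drawn from {0, 1, 1000, 50000} — 33 each of the small sizes plus
three at 50,000, a composition that exercises the degenerate, typical and
high-density regimes while keeping the default test run fast on one CPU. A
50,000-probe file of each dialect is additionally parsed end-to-end as a
smoke test with no timing assertion: wall-clock claims are
hardware-dependent and deliberately not part of the contract.

Other numerical conventions, collected in one place: 64-bit file offsets
are held as doubles (exact up to 2^53); unsigned 16-bit arrays are written
through 2-byte truncation of int32, which is the identity on the valid
range; all multi-byte values are little-endian; empty arrays, empty
sections, empty run-info and zero-probe files are valid everywhere rather
than edge-case errors.

## Limitations

* The binary field-code assignments and the encrypted container's cipher
  framing reproduce the conventions established by open reverse-engineering
  of vendor files; vendor software could diverge in future revisions. Codes
  and tag names live in single tables precisely so corrections are local.
* Semantics of `red_green`, the uninterpreted string fields, and the tenth
  expression vector are unknown; beadio preserves them without
  interpretation, and whether `sd` is a plain standard deviation or a scaled
  one is likewise left to the consumer.
* No channel-pairing logic (red/green file pairs are the caller's concern),
  no normalisation, no detection p-values, and no binary BPM support.
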