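Package: beadio
Title: Read, Write and Validate Illumina BeadArray IDAT and Manifest Files
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-contained reader and writer for the Illumina BeadArray
    IDAT file family, with no dependency on vendor software. Supports the
    binary dialect written by genotyping and methylation scanners (field
    directory, varint-framed strings, RunInfo processing log), the same
    dialect transparently gzip-compressed, and the DES-encrypted XML
    dialect used by gene expression arrays (ten Base64-encoded per-probe
    vectors). Also parses BGX bead manifests, annotates intensities with
    probe design information, extracts scan metadata for batch-effect
    auditing, generates deterministic synthetic fixtures in every dialect,
    and performs rounding-tolerant comparison against text exports such as
    those produced by GenomeStudio. Includes a command-line interface for
    dumping, validating and comparing files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    utils,
    withr,
    xml2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
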