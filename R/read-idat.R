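# Format detection and the unified reader entry point.

#' Identify the dialect of an IDAT file
#'
#' Illumina writes three on-disk dialects under the same `.idat` extension:
#' a binary container (genotyping and methylation arrays), the same
#' container gzip-compressed, and a DES-encrypted XML document (gene
#' expression arrays). Detection is by leading magic bytes only, never by
#' file extension: `"IDAT"` marks the binary container, `0x1F 0x8B` the gzip
#' wrapper, and anything else is taken to be encrypted XML (ciphertext has
#' no magic of its own).
#'
#' @param x A file path, or a raw vector holding at least the first 4 bytes.
#' @return One of `"binary"`, `"gzipped-binary"`, `"encrypted-xml"`.
#' @examples
#' detect_idat_format(charToRaw("IDAT anything"))
#' detect_idat_format(as.raw(c(0x1F, 0x8B, 0x08, 0x00)))
#' @export
detect_idat_format <- function(x) {
  bytes <- if (is.raw(x)) {
    x
  } else {
    if (!file.exists(x)) stop_malformed(sprintf("file not found: %s", x))
    readBin(x, what = "raw", n = 4L)
  }
  if (length(bytes) < 4) {
    stop_malformed(sprintf(
      "need at least 4 bytes to identify an IDAT dialect, got %d", length(bytes)
    ))
  }
  if (identical(bytes[1:4], charToRaw("IDAT"))) {
    return("binary")
  }
  if (identical(bytes[1:2], as.raw(c(0x1F, 0x8B)))) {
    return("gzipped-binary")
  }
  "encrypted-xml"
}

#' Read an IDAT file of any dialect
#'
#' Dispatches on [detect_idat_format()]: binary containers are parsed
#' directly, gzip-compressed containers are transparently decompressed
#' first, and encrypted-XML expression files are DES-decrypted with `key`.
#' This removes the dependency on vendor software for getting per-bead-type
#' intensities out of scanner output.
#'
#' @param path Path to an IDAT file.
#' @param key 8-byte raw vector: the DES key for encrypted expression files.
#'   Ignored for binary files. If `NULL`, the option `beadio.des_key` is
#'   consulted; if that is also unset, reading an encrypted file signals a
#'   missing-key error.
#' @param wanted_fields Optional restriction of which per-probe arrays to
#'   decode from a binary container: a character subset of
#'   `c("probe_ids", "mean", "sd", "n_beads")` or the corresponding integer
#'   field codes. Metadata fields are always parsed. `NULL` (default) decodes
#'   everything.
#' @return A [binary_idat()] for binary/gzipped files, an
#'   [expression_idat()] for encrypted expression files.
#' @examples
#' prof <- fixture_profile("methylation", n_probes = 10, seed = 42)
#' fx <- generate_binary_idat(prof)
#' path <- tempfile(fileext = ".idat")
#' write_binary_idat(fx$idat, path)
#' idat <- read_idat(path)
#' idat$n_probes
#' @export
read_idat <- function(path, key = NULL, wanted_fields = NULL) {
  bytes <- read_file_raw(path)
  kind <- detect_idat_format(bytes)
  switch(kind,
    "binary" = parse_binary_idat(bytes, wanted_fields = wanted_fields),
    "gzipped-binary" = {
      inner <- tryCatch(
        memDecompress(bytes, type = "gzip"),
        error = function(e) {
          stop_corrupt(
            sprintf("gzip stream could not be decompressed: %s", conditionMessage(e)),
            offset = 0
          )
        }
      )
      parse_binary_idat(inner, wanted_fields = wanted_fields)
    },
    "encrypted-xml" = {
      key <- key %||% getOption("beadio.des_key")
      if (is.null(key)) {
        stop_missing_key(paste0(
          "'", path, "' looks like an encrypted expression IDAT but no DES key ",
          "was supplied (argument `key` or option `beadio.des_key`)"
        ))
      }
      parse_encrypted_idat(bytes, key = key)
    }
  )
}

#' Extract scan metadata from a decoded IDAT
#'
#' Pulls out the information useful for batch-effect auditing that vendor
#' text exports drop: the scan timestamp, the scanner software components
#' and versions seen in the processing log, and the chip identity. The scan
#' date is taken from the first processing-log entry whose block type
#' contains the token `"Scan"` (case-insensitive).
#'
#' Timestamps are additionally parsed with the US-locale convention the
#' scanner software uses (`m/d/Y h:M:S AM/PM`, with an ISO fallback); a
#' timestamp that fits neither is preserved verbatim with
#' `scan_date_parsed = NA`, never coerced.
#'
#' @param idat A `binary_idat` or `expression_idat`.
#' @return A `scan_metadata` object: fields `scan_date` (verbatim string),
#'   `scan_date_parsed` (`POSIXct` or `NA`), `scanner_software` (tibble of
#'   deduplicated name/version pairs), `barcode`, `chip_type`, `position`.
#' @examples
#' fx <- generate_binary_idat(fixture_profile("methylation", n_probes = 5, seed = 7))
#' scan_metadata(fx$idat)
#' @export
scan_metadata <- function(idat) {
  UseMethod("scan_metadata")
}

#' @export
scan_metadata.binary_idat <- function(idat) {
  ri <- idat$run_info
  scan_rows <- grepl("scan", ri$block_type, ignore.case = TRUE)
  scan_date <- if (any(scan_rows)) ri$run_time[which(scan_rows)[1]] else ""
  software <- dplyr::distinct(
    tibble::tibble(name = ri$block_code, version = ri$code_version)
  )
  software <- software[nzchar(software$name) | nzchar(software$version), ]
  new_scan_metadata(
    scan_date = scan_date, scanner_software = software,
    barcode = idat$barcode, chip_type = idat$chip_type, position = idat$position
  )
}

#' @export
scan_metadata.expression_idat <- function(idat) {
  md <- idat$metadata
  get <- function(keys) {
    hit <- keys[tolower(keys) %in% tolower(names(md))][1]
    idx <- match(tolower(hit), tolower(names(md)))
    if (!is.na(idx)) unname(md[idx]) else ""
  }
  new_scan_metadata(
    scan_date = get(c("ScanDate", "DateScanned")),
    scanner_software = tibble::tibble(name = character(0), version = character(0)),
    barcode = get(c("Barcode", "ChipBarcode")),
    chip_type = get(c("ChipType", "SentrixFormat")),
    position = get(c("Position", "Section"))
  )
}

new_scan_metadata <- function(scan_date, scanner_software, barcode, chip_type, position) {
  structure(
    list(
      scan_date = scan_date,
      scan_date_parsed = parse_scan_timestamp(scan_date),
      scanner_software = scanner_software,
      barcode = barcode,
      chip_type = chip_type,
      position = position
    ),
    class = "scan_metadata"
  )
}

# scanner timestamps are US-locale "10/30/2012 3:24:27 PM"; ISO accepted as
# fallback; anything else stays verbatim and unparsed (NA)
parse_scan_timestamp <- function(s) {
  if (!length(s) || !nzchar(s)) {
    return(as.POSIXct(NA))
  }
  for (fmt in c("%m/%d/%Y %I:%M:%S %p", "%m/%d/%Y %H:%M:%S", "%Y-%m-%d %H:%M:%S")) {
    parsed <- as.POSIXct(s, format = fmt, tz = "UTC")
    if (!is.na(parsed)) {
      return(parsed)
    }
  }
  as.POSIXct(NA)
}

#' @export
print.scan_metadata <- function(x, ...) {
  cat("<scan_metadata>\n")
  cat("  scan_date:", if (nzchar(x$scan_date)) x$scan_date else "<absent>")
  if (nzchar(x$scan_date) && is.na(x$scan_date_parsed)) cat("  [unparsed, kept verbatim]")
  cat("\n")
  cat("  barcode:  ", x$barcode, "\n")
  cat("  chip_type:", x$chip_type, "\n")
  cat("  position: ", x$position, "\n")
  if (nrow(x$scanner_software)) {
    cat("  software: ", paste(
      paste(x$scanner_software$name, x$scanner_software$version),
      collapse = "; "
    ), "\n")
  }
  invisible(x)
}
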