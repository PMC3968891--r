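# Decoded-object constructors and validators.  The two dialects return
# distinct classes with distinct field inventories (4 per-probe fields for
# binary platforms, 10 for expression); fields absent in a dialect are
# absent, not null-filled.

#' Construct a decoded binary IDAT object
#'
#' Represents one channel of a genotyping or methylation BeadArray scan: the
#' four per-bead-type summary arrays (ID, mean intensity, intensity standard
#' deviation, bead count) plus scan metadata. Normally produced by
#' [read_idat()]; the constructor is exported so fixtures and tests can build
#' objects directly.
#'
#' @param probe_ids Integer bead-type IDs, strictly increasing.
#' @param mean,sd Integer intensities in scanner units, each in \[0, 65535\].
#' @param n_beads Integer bead counts, each in \[0, 255\].
#' @param barcode,chip_type,position Chip-level strings (position is the
#'   section on the chip, e.g. `"R01C01"`).
#' @param red_green Channel indicator integer as stored by the scanner
#'   (semantics unspecified by the format; preserved verbatim).
#' @param mid_block Integer array preserved verbatim.
#' @param run_info Data frame of scanner log records with columns
#'   `run_time`, `block_type`, `block_pars`, `block_code`, `code_version`.
#' @param format_version Container format version (3 for all known files).
#' @param extra_strings Named character vector of unidentified string fields,
#'   names are the decimal field codes.
#' @param unknown_fields Data frame (`code`, `offset`) of directory entries
#'   the parser did not recognise.
#' @return An object of class `binary_idat`.
#' @seealso [read_idat()], [write_binary_idat()], [generate_binary_idat()]
#' @export
binary_idat <- function(probe_ids = integer(0),
                        mean = integer(0),
                        sd = integer(0),
                        n_beads = integer(0),
                        barcode = "",
                        chip_type = "",
                        position = "",
                        red_green = 0L,
                        mid_block = integer(0),
                        run_info = empty_run_info(),
                        format_version = 3L,
                        extra_strings = character(0),
                        unknown_fields = empty_unknown_fields()) {
  x <- structure(
    list(
      n_probes = length(probe_ids),
      probe_ids = as.integer(probe_ids),
      mean = as.integer(mean),
      sd = as.integer(sd),
      n_beads = as.integer(n_beads),
      barcode = barcode,
      chip_type = chip_type,
      position = position,
      red_green = as.integer(red_green),
      mid_block = as.integer(mid_block),
      run_info = run_info,
      format_version = as.integer(format_version),
      extra_strings = extra_strings,
      unknown_fields = unknown_fields
    ),
    class = c("binary_idat", "idat")
  )
  validate_binary_idat(x)
  x
}

empty_run_info <- function() {
  tibble::tibble(
    run_time = character(0), block_type = character(0),
    block_pars = character(0), block_code = character(0),
    code_version = character(0)
  )
}

empty_unknown_fields <- function() {
  tibble::tibble(code = integer(0), offset = numeric(0))
}

RUN_INFO_COLS <- c("run_time", "block_type", "block_pars", "block_code", "code_version")

#' Validate a decoded IDAT object
#'
#' Checks the structural invariants of a decoded object: equal per-probe
#' array lengths, sorted unique bead-type IDs and value ranges for the binary
#' dialect; equal lengths of the ten data vectors and
#' `n_beads_used <= n_beads_raw` for the expression dialect. Arrays that were
#' deliberately not loaded (via `wanted_fields`) are skipped.
#'
#' @param x A `binary_idat` or `expression_idat` object.
#' @return `x`, invisibly; signals a validation error otherwise.
#' @export
validate_binary_idat <- function(x) {
  n <- x$n_probes
  for (f in c("probe_ids", "mean", "sd", "n_beads")) {
    v <- x[[f]]
    if (!is.null(v) && length(v) != n) {
      stop_validation(sprintf(
        "field '%s' has length %d but n_probes is %d", f, length(v), n
      ))
    }
  }
  ids <- x$probe_ids
  if (!is.null(ids) && n > 1 && any(diff(ids) <= 0)) {
    stop_validation("probe_ids must be strictly increasing (sorted, unique)")
  }
  for (f in c("mean", "sd")) {
    v <- x[[f]]
    if (!is.null(v) && length(v) && (min(v) < 0 || max(v) > 65535)) {
      stop_validation(sprintf("field '%s' outside the unsigned 16-bit range", f))
    }
  }
  if (!is.null(x$n_beads) && length(x$n_beads) &&
    (min(x$n_beads) < 0 || max(x$n_beads) > 255)) {
    stop_validation("n_beads outside the unsigned 8-bit range")
  }
  if (!all(RUN_INFO_COLS %in% names(x$run_info))) {
    stop_validation("run_info must carry all five scanner-log columns")
  }
  invisible(x)
}

EXPR_DATA_FIELDS <- c(
  "probe_ids", "mean", "sd", "median", "trimmed_mean",
  "bg_mean", "bg_sd", "n_beads_raw", "n_beads_used"
)

#' Construct a decoded expression IDAT object
#'
#' Represents a decrypted gene-expression IDAT: ten per-bead-type data
#' vectors (nine with known semantics plus one preserved verbatim under its
#' XML tag name) and a metadata map. Normally produced by [read_idat()] on an
#' encrypted file.
#'
#' @param probe_ids,n_beads_raw,n_beads_used Integer vectors (bead-type IDs
#'   and bead counts before/after outlier exclusion).
#' @param mean,sd,median,trimmed_mean Per-probe foreground summary
#'   intensities (single-precision reals in the file).
#' @param bg_mean,bg_sd Local background mean and standard deviation.
#' @param extra_field Named list holding the data vector(s) whose tag is not
#'   among the nine with known semantics; kept uninterpreted.
#' @param metadata Named character vector of file-level metadata.
#' @return An object of class `expression_idat`.
#' @export
expression_idat <- function(probe_ids = integer(0),
                            mean = numeric(0),
                            sd = numeric(0),
                            median = numeric(0),
                            trimmed_mean = numeric(0),
                            bg_mean = numeric(0),
                            bg_sd = numeric(0),
                            n_beads_raw = integer(0),
                            n_beads_used = integer(0),
                            extra_field = list(),
                            metadata = character(0)) {
  x <- structure(
    list(
      n_probes = length(probe_ids),
      probe_ids = as.integer(probe_ids),
      mean = as.double(mean),
      sd = as.double(sd),
      median = as.double(median),
      trimmed_mean = as.double(trimmed_mean),
      bg_mean = as.double(bg_mean),
      bg_sd = as.double(bg_sd),
      n_beads_raw = as.integer(n_beads_raw),
      n_beads_used = as.integer(n_beads_used),
      extra_field = extra_field,
      metadata = metadata
    ),
    class = c("expression_idat", "idat")
  )
  validate_expression_idat(x)
  x
}

#' @rdname validate_binary_idat
#' @export
validate_expression_idat <- function(x) {
  n <- x$n_probes
  lens <- vapply(x[EXPR_DATA_FIELDS], length, integer(1))
  lens <- c(lens, vapply(x$extra_field, length, integer(1)))
  if (length(unique(c(n, lens))) > 1) {
    stop_validation(sprintf(
      "expression data vectors disagree in length: %s",
      paste(unique(lens), collapse = ", ")
    ))
  }
  if (any(x$n_beads_used > x$n_beads_raw)) {
    stop_validation("n_beads_used exceeds n_beads_raw for some probes")
  }
  if (any(c(x$n_beads_raw, x$n_beads_used) < 0)) {
    stop_validation("bead counts must be non-negative")
  }
  invisible(x)
}

#' @export
print.binary_idat <- function(x, ...) {
  cat(sprintf(
    "<binary_idat> %s probes | barcode %s | %s | section %s\n",
    format(x$n_probes, big.mark = ","),
    if (nzchar(x$barcode)) x$barcode else "?",
    if (nzchar(x$chip_type)) x$chip_type else "unknown chip",
    if (nzchar(x$position)) x$position else "?"
  ))
  loaded <- Filter(function(f) !is.null(x[[f]]), c("probe_ids", "mean", "sd", "n_beads"))
  cat("  per-probe fields:", paste(loaded, collapse = ", "), "\n")
  cat("  run_info entries:", nrow(x$run_info), "\n")
  invisible(x)
}

#' @export
print.expression_idat <- function(x, ...) {
  cat(sprintf(
    "<expression_idat> %s probes | 10 data vectors (%d canonical + %d extra)\n",
    format(x$n_probes, big.mark = ","),
    length(EXPR_DATA_FIELDS), length(x$extra_field)
  ))
  if (length(x$extra_field)) {
    cat("  extra field(s):", paste(names(x$extra_field), collapse = ", "), "\n")
  }
  if (length(x$metadata)) {
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  }
  invisible(x)
}
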