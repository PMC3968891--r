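# tidy()/glance() methods: every decoded object has a tabular view (the
# per-probe data) and a one-row summary (the file-level metadata).

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-probe data of a decoded IDAT
#'
#' @param x A `binary_idat`.
#' @param ... Unused.
#' @return A tibble with one row per bead-type: `probe_id`, `mean`, `sd`,
#'   `n_beads` (binary dialect) or the ten expression vectors (expression
#'   dialect, the uninterpreted tenth under its tag name). Arrays not loaded
#'   are omitted.
#' @export
tidy.binary_idat <- function(x, ...) {
  cols <- Filter(Negate(is.null), x[c("probe_ids", "mean", "sd", "n_beads")])
  names(cols)[names(cols) == "probe_ids"] <- "probe_id"
  tibble::as_tibble(cols)
}

#' @rdname tidy.binary_idat
#' @export
tidy.expression_idat <- function(x, ...) {
  cols <- x[EXPR_DATA_FIELDS]
  names(cols)[1] <- "probe_id"
  tibble::as_tibble(c(cols, x$extra_field))
}

#' @rdname tidy.binary_idat
#' @export
tidy.bead_manifest <- function(x, ...) {
  dplyr::bind_rows(x$probes, x$controls)
}

#' @rdname tidy.binary_idat
#' @export
tidy.idat_comparison <- function(x, ...) {
  x$by_column
}

#' One-row summary of a decoded IDAT
#'
#' @param x A decoded object.
#' @param ... Unused.
#' @return A one-row tibble of the file-level metadata (probe count, chip
#'   identity, scan date, format particulars).
#' @export
glance.binary_idat <- function(x, ...) {
  md <- scan_metadata(x)
  tibble::tibble(
    n_probes = x$n_probes,
    barcode = x$barcode,
    chip_type = x$chip_type,
    position = x$position,
    red_green = x$red_green,
    format_version = x$format_version,
    n_run_info = nrow(x$run_info),
    scan_date = md$scan_date
  )
}

#' @rdname glance.binary_idat
#' @export
glance.expression_idat <- function(x, ...) {
  md <- scan_metadata(x)
  tibble::tibble(
    n_probes = x$n_probes,
    barcode = md$barcode,
    chip_type = md$chip_type,
    scan_date = md$scan_date,
    n_data_fields = length(EXPR_DATA_FIELDS) + length(x$extra_field),
    extra_field = paste(names(x$extra_field), collapse = ";")
  )
}

#' @rdname glance.binary_idat
#' @export
glance.bead_manifest <- function(x, ...) {
  tibble::tibble(
    n_probes = nrow(x$probes),
    n_controls = nrow(x$controls),
    array_name = if ("Array Name" %in% names(x$heading)) x$heading[["Array Name"]] else NA_character_
  )
}

#' @rdname glance.binary_idat
#' @export
glance.idat_comparison <- function(x, ...) {
  tibble::tibble(
    n_rows_compared = x$n_rows_compared,
    n_exact = x$n_exact,
    n_within_rounding = x$n_within_rounding,
    n_discordant = x$n_discordant,
    max_abs_diff = x$max_abs_diff,
    decimals = x$decimals
  )
}
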