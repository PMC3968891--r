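# Rounding-tolerant comparison of decoded intensities against a text export
# (the check historically done against GenomeStudio output, where small
# rounding discrepancies are expected), plus the text/JSON dump that
# replaces the vendor export step.

#' Compare a decoded IDAT against a delimited text export
#'
#' Matches rows by bead-type ID and classifies every compared row as exact
#' (all shared columns bit-equal), within-rounding (all columns agree after
#' rounding both sides to `decimals` places, at least one not bit-equal), or
#' discordant. This quantifies agreement with exports whose values were
#' rounded by other software. Rounding is round-half-to-even (the IEC 60559
#' convention used by R's `round()`); `decimals = 1` is the default
#' precision.
#'
#' @param idat A `binary_idat` or `expression_idat`.
#' @param table A data frame, or path to a delimited text file, with an ID
#'   column and one or more value columns named like the IDAT's per-probe
#'   fields (case-insensitive).
#' @param decimals Rounding precision for the within-rounding test.
#' @param delim Field delimiter when `table` is a path (default tab).
#' @return An `idat_comparison`: counts `n_rows_compared`, `n_exact`,
#'   `n_within_rounding`, `n_discordant` (which partition the compared
#'   rows), `max_abs_diff`, `decimals`, and a per-column breakdown in
#'   `$by_column`.
#' @examples
#' fx <- generate_binary_idat(fixture_profile("methylation", n_probes = 20, seed = 5))
#' cmp <- compare_to_text_export(fx$idat, tidy(fx$idat))
#' cmp$n_discordant
#' @export
compare_to_text_export <- function(idat, table, decimals = 1, delim = "\t") {
  if (is.character(table) && length(table) == 1) {
    table <- utils::read.delim(table, sep = delim, check.names = FALSE, stringsAsFactors = FALSE)
  }
  table <- as.data.frame(table)
  lhs <- generics::tidy(idat)

  id_col <- match_alias(names(table), MANIFEST_COLUMN_ALIASES$probe_id)
  if (is.na(id_col)) id_col <- names(table)[1]
  value_cols <- setdiff(names(table), id_col)
  shared <- value_cols[tolower(value_cols) %in% tolower(names(lhs))]
  shared <- shared[!tolower(shared) %in% "probe_id"]
  if (length(shared) == 0) {
    stop_empty_overlap("no value columns shared between the IDAT and the export table")
  }

  m <- match(table[[id_col]], lhs$probe_id)
  keep <- !is.na(m)
  if (!any(keep)) {
    stop_empty_overlap("no probe IDs shared between the IDAT and the export table")
  }
  n_rows <- sum(keep)

  classify <- function(col) {
    a <- lhs[[names(lhs)[match(tolower(col), tolower(names(lhs)))]]][m[keep]]
    b <- as.numeric(table[[col]][keep])
    exact <- !is.na(b) & (a == b)
    within <- !exact & !is.na(b) & (round(a, decimals) == round(b, decimals))
    tibble::tibble(
      column = col,
      n_exact = sum(exact),
      n_within_rounding = sum(within),
      n_discordant = n_rows - sum(exact) - sum(within),
      max_abs_diff = if (all(is.na(b))) NA_real_ else max(abs(a - b), na.rm = TRUE),
      status = list(ifelse(exact, "exact", ifelse(within, "within", "discordant")))
    )
  }
  by_column <- dplyr::bind_rows(lapply(shared, classify))

  status_mat <- do.call(cbind, by_column$status)
  row_status <- apply(status_mat, 1, function(s) {
    if (any(s == "discordant")) "discordant" else if (all(s == "exact")) "exact" else "within"
  })
  by_column$status <- NULL

  structure(
    list(
      n_rows_compared = n_rows,
      n_exact = sum(row_status == "exact"),
      n_within_rounding = sum(row_status == "within"),
      n_discordant = sum(row_status == "discordant"),
      max_abs_diff = max(c(0, by_column$max_abs_diff), na.rm = TRUE),
      decimals = decimals,
      columns = shared,
      by_column = by_column
    ),
    class = "idat_comparison"
  )
}

#' @export
print.idat_comparison <- function(x, ...) {
  cat(sprintf(
    "<idat_comparison> %d rows over %d column(s) at %d decimal(s)\n",
    x$n_rows_compared, length(x$columns), x$decimals
  ))
  cat(sprintf(
    "  exact %d | within rounding %d | discordant %d | max |diff| %g\n",
    x$n_exact, x$n_within_rounding, x$n_discordant, x$max_abs_diff
  ))
  invisible(x)
}

format_full_precision <- function(col) {
  if (is.double(col)) sprintf("%.17g", col) else as.character(col)
}

#' Dump a decoded IDAT as TSV or JSON
#'
#' Writes the per-probe table (one row per bead-type, one column per
#' available data field, deterministic column order) plus, for JSON, the
#' file-level metadata. Numbers are written with enough digits to
#' round-trip (single-precision values reparse bit-exactly). This performs
#' the text-export step that previously required vendor software.
#'
#' @param x A decoded IDAT object, or a path (read via [read_idat()]).
#' @param file Output path or connection; `""` prints to stdout.
#' @param format `"tsv"` or `"json"`.
#' @param key DES key, used only when `x` is a path to an encrypted file.
#' @return Invisibly, the character vector of lines written.
#' @export
dump_idat <- function(x, file = "", format = c("tsv", "json"), key = NULL) {
  format <- match.arg(format)
  idat <- if (is.character(x)) read_idat(x, key = key) else x
  tbl <- generics::tidy(idat)
  lines <- if (format == "tsv") {
    cols <- lapply(tbl, format_full_precision)
    c(
      paste(names(tbl), collapse = "\t"),
      if (nrow(tbl)) do.call(paste, c(cols, sep = "\t"))
    )
  } else {
    jsonlite::toJSON(
      list(metadata = as.list(generics::glance(idat)), data = as.list(tbl)),
      auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
    )
  }
  writeLines(lines, if (identical(file, "")) stdout() else file)
  invisible(lines)
}
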