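# BGX bead-manifest reader and the intensity/design join.
#
# A BGX file is a gzip-compressed sectioned text file: bracketed section
# headers ([Heading], [Probes], [Controls]), key/value pairs in the heading,
# and tab-separated tables with a one-line column header elsewhere.  Section
# and column names vary across chip generations, so both are matched
# case-insensitively through the alias tables below.

MANIFEST_SECTION_ALIASES <- list(
  heading = c("heading"),
  probes = c("probes", "assay"),
  controls = c("controls")
)

MANIFEST_COLUMN_ALIASES <- list(
  probe_id = c(
    "probe_id", "probeid", "address", "address_id", "array_address_id",
    "id", "illumicodeaddress"
  ),
  probe_sequence = c("probe_sequence", "sequence", "probe_seq", "seq"),
  target_id = c("target_id", "target", "ilmn_gene", "symbol", "gene")
)

MANIFEST_COUNT_KEYS <- list(
  probes = c("number of probes", "probe count", "loci count"),
  controls = c("number of controls", "control count")
)

#' Construct a bead manifest
#'
#' The array-design table linking bead-type IDs to probe sequences, intended
#' genomic targets and control status. Normally produced by [read_bgx()] or
#' [read_bpm_csv()].
#'
#' @param heading Named character vector of heading metadata.
#' @param probes,controls Data frames with columns `probe_id` (integer),
#'   `probe_sequence`, `target_id` (character) and `is_control` (logical,
#'   `FALSE` throughout `probes` and `TRUE` throughout `controls`).
#' @return An object of class `bead_manifest`.
#' @export
bead_manifest <- function(heading = character(0),
                          probes = empty_manifest_records(FALSE),
                          controls = empty_manifest_records(TRUE)) {
  probes$is_control <- FALSE
  controls$is_control <- TRUE
  x <- structure(
    list(
      heading = heading,
      probes = tibble::as_tibble(probes),
      controls = tibble::as_tibble(controls)
    ),
    class = "bead_manifest"
  )
  validate_bead_manifest(x)
  x
}

empty_manifest_records <- function(is_control) {
  tibble::tibble(
    probe_id = integer(0), probe_sequence = character(0),
    target_id = character(0), is_control = logical(0)
  )
}

validate_bead_manifest <- function(x) {
  for (part in c("probes", "controls")) {
    tbl <- x[[part]]
    if (anyDuplicated(tbl$probe_id)) {
      stop_validation(sprintf("duplicate probe_id values in manifest %s", part))
    }
    seqs <- tbl$probe_sequence
    seqs <- seqs[!is.na(seqs)]
    if (length(seqs) && any(grepl("[^ACGTNacgtn]", seqs))) {
      stop_validation(sprintf(
        "probe_sequence in %s contains characters outside [ACGTN]", part
      ))
    }
  }
  invisible(x)
}

match_alias <- function(available, aliases) {
  hit <- match(aliases, tolower(available))
  hit <- hit[!is.na(hit)]
  if (length(hit)) available[hit[1]] else NA_character_
}

parse_manifest_table <- function(lines, section) {
  if (length(lines) == 0) {
    return(empty_manifest_records(section == "controls"))
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  cells <- strsplit(lines[-1], "\t", fixed = TRUE)
  get_col <- function(field) {
    col <- match_alias(header, MANIFEST_COLUMN_ALIASES[[field]])
    if (is.na(col)) {
      return(rep(NA_character_, length(cells)))
    }
    j <- match(col, header)
    vapply(cells, function(row) if (j <= length(row)) row[j] else "", character(1))
  }
  if (length(cells) == 0) {
    return(empty_manifest_records(section == "controls"))
  }
  ids <- get_col("probe_id")
  if (all(is.na(ids))) {
    stop_manifest(sprintf(
      "section [%s] has no recognisable probe-ID column (header: %s)",
      section, paste(header, collapse = ", ")
    ))
  }
  tibble::tibble(
    probe_id = as.integer(ids),
    probe_sequence = get_col("probe_sequence"),
    target_id = get_col("target_id"),
    is_control = section == "controls"
  )
}

#' Read a BGX bead-manifest file
#'
#' Parses the gzip-compressed sectioned-text BGX format: `[Heading]`
#' key/value metadata, and `[Probes]` / `[Controls]` tab-separated tables.
#' Section and column names are matched case-insensitively against an alias
#' table (manifests vary across chip generations); missing optional columns
#' yield `NA` fields. If the heading declares probe or control counts they
#' are cross-checked against the parsed tables — a mismatch is a warning,
#' not an error, and parsing proceeds.
#'
#' @param path Path to a BGX file (plain-text input is accepted too; the
#'   gzip layer is transparent).
#' @return A [bead_manifest()].
#' @examples
#' fx <- generate_binary_idat(fixture_profile("methylation", n_probes = 8, seed = 3))
#' p <- tempfile(fileext = ".bgx")
#' write_bgx(fx$manifest, p)
#' read_bgx(p)
#' @export
read_bgx <- function(path) {
  if (!file.exists(path)) stop_malformed(sprintf("file not found: %s", path))
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  sec_at <- grep("^\\[.*\\]\\s*$", lines)
  if (length(sec_at) == 0) {
    stop_manifest("no bracketed section headers found; not a BGX manifest")
  }
  sec_names <- tolower(gsub("^\\[|\\]\\s*$", "", lines[sec_at]))
  bounds <- c(sec_at, length(lines) + 1L)
  section_lines <- lapply(seq_along(sec_at), function(i) {
    body <- lines[seq(sec_at[i] + 1L, bounds[i + 1L] - 1L)]
    body[nzchar(trimws(body))]
  })
  names(section_lines) <- sec_names

  find_section <- function(canonical) {
    nm <- intersect(MANIFEST_SECTION_ALIASES[[canonical]], sec_names)
    if (length(nm)) section_lines[[nm[1]]] else NULL
  }

  heading <- character(0)
  h <- find_section("heading")
  if (!is.null(h)) {
    kv <- strsplit(h, "\t", fixed = TRUE)
    heading <- vapply(kv, function(x) if (length(x) > 1) x[2] else "", character(1))
    names(heading) <- vapply(kv, `[`, character(1), 1)
  }

  probes_lines <- find_section("probes")
  if (is.null(probes_lines)) {
    stop_manifest(sprintf(
      "manifest has no [Probes] section (sections found: %s)",
      paste(sec_names, collapse = ", ")
    ))
  }
  probes <- parse_manifest_table(probes_lines, "probes")
  controls_lines <- find_section("controls")
  controls <- parse_manifest_table(controls_lines %||% character(0), "controls")

  check_declared_count <- function(part, tbl) {
    key <- match_alias(names(heading), MANIFEST_COUNT_KEYS[[part]])
    if (!is.na(key)) {
      declared <- suppressWarnings(as.integer(heading[[key]]))
      if (!is.na(declared) && declared != nrow(tbl)) {
        warn_beadio(
          sprintf(
            "heading declares %d %s but %d were parsed", declared, part, nrow(tbl)
          ),
          class = "beadio_warning_manifest_count"
        )
      }
    }
  }
  check_declared_count("probes", probes)
  check_declared_count("controls", controls)

  bead_manifest(heading = heading, probes = probes, controls = controls)
}

#' Write a BGX bead-manifest file (fixture writer)
#'
#' Emits the gzip-compressed sectioned-text form that [read_bgx()] parses,
#' with canonical section and column names. Deterministic for equal inputs.
#'
#' @param manifest A [bead_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bgx <- function(manifest, path) {
  validate_bead_manifest(manifest)
  fmt_table <- function(tbl) {
    c(
      "Probe_Id\tProbe_Sequence\tTarget_Id",
      sprintf(
        "%d\t%s\t%s", tbl$probe_id,
        ifelse(is.na(tbl$probe_sequence), "", tbl$probe_sequence),
        ifelse(is.na(tbl$target_id), "", tbl$target_id)
      )
    )
  }
  heading <- manifest$heading
  heading["Number of Probes"] <- as.character(nrow(manifest$probes))
  heading["Number of Controls"] <- as.character(nrow(manifest$controls))
  lines <- c(
    "[Heading]",
    sprintf("%s\t%s", names(heading), unname(heading)),
    "[Probes]",
    fmt_table(manifest$probes),
    "[Controls]",
    fmt_table(manifest$controls)
  )
  con <- gzfile(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a BPM-CSV manifest export
#'
#' The binary BPM manifest layout is undocumented and deliberately not
#' guessed at; instead this accepts the text-export dialect: one
#' comma-separated table with the same record model as BGX plus an
#' `is_control` column.
#'
#' @param path Path to a CSV file with columns `probe_id`, `probe_sequence`,
#'   `target_id`, `is_control` (names matched case-insensitively).
#' @return A [bead_manifest()].
#' @export
read_bpm_csv <- function(path) {
  if (!file.exists(path)) stop_malformed(sprintf("file not found: %s", path))
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(tbl) <- tolower(names(tbl))
  get <- function(field, aliases) {
    col <- match_alias(names(tbl), aliases)
    if (is.na(col)) rep(NA_character_, nrow(tbl)) else as.character(tbl[[col]])
  }
  ids <- get("probe_id", MANIFEST_COLUMN_ALIASES$probe_id)
  if (all(is.na(ids))) {
    stop_manifest("BPM-CSV export has no recognisable probe-ID column")
  }
  is_control <- tolower(get("is_control", c("is_control", "control"))) %in%
    c("true", "t", "1", "yes")
  rec <- tibble::tibble(
    probe_id = as.integer(ids),
    probe_sequence = get("probe_sequence", MANIFEST_COLUMN_ALIASES$probe_sequence),
    target_id = get("target_id", MANIFEST_COLUMN_ALIASES$target_id),
    is_control = is_control
  )
  bead_manifest(
    heading = c("Source Format" = "bpm-csv"),
    probes = rec[!rec$is_control, ],
    controls = rec[rec$is_control, ]
  )
}

#' Annotate IDAT intensities with manifest design information
#'
#' Left-joins the per-probe intensity table of a decoded IDAT onto the
#' manifest records, attaching the intended target and control status each
#' bead-type ID maps to — the information needed to interpret raw
#' intensities. Intensity values and row count are never altered; bead-type
#' IDs absent from the manifest are retained with `NA` annotation and
#' counted in the `n_unmatched` attribute.
#'
#' @param idat A `binary_idat` or `expression_idat`.
#' @param manifest A [bead_manifest()].
#' @return A tibble: the IDAT's per-probe columns plus `target_id` and
#'   `is_control`, with attribute `n_unmatched`.
#' @examples
#' fx <- generate_binary_idat(fixture_profile("methylation", n_probes = 6, seed = 11))
#' ann <- annotate_idat(fx$idat, fx$manifest)
#' table(ann$is_control)
#' attr(ann, "n_unmatched")
#' @export
annotate_idat <- function(idat, manifest) {
  validate_bead_manifest(manifest)
  lhs <- generics::tidy(idat)
  rhs <- dplyr::bind_rows(manifest$probes, manifest$controls)
  rhs <- rhs[, c("probe_id", "target_id", "is_control")]
  out <- dplyr::left_join(lhs, rhs, by = "probe_id")
  attr(out, "n_unmatched") <- sum(is.na(out$is_control))
  out
}

#' @export
print.bead_manifest <- function(x, ...) {
  cat(sprintf(
    "<bead_manifest> %d probes, %d controls\n",
    nrow(x$probes), nrow(x$controls)
  ))
  for (nm in names(x$heading)) {
    cat(sprintf("  %s: %s\n", nm, x$heading[[nm]]))
  }
  invisible(x)
}
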