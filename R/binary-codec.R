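# Binary IDAT container codec.
#
# Layout (all integers little-endian):
#   magic "IDAT" | format_version uint64 (expected 3) | n_fields int32 |
#   n_fields x (code uint16, offset uint64) directory | field payloads.
#
# Field codes are centralised in the tables below so a correction is a
# one-line change.  Unknown codes are skipped and preserved (code, offset),
# never fatal: chip revisions add fields.

BIN_FIELD_CODES <- c(
  n_probes  = 1000L,
  probe_ids = 102L,
  sd        = 103L,
  mean      = 104L,
  n_beads   = 107L,
  mid_block = 200L,
  run_info  = 300L,
  red_green = 400L,
  barcode   = 402L,
  chip_type = 403L,
  position  = 404L
)

# unidentified string-valued fields, preserved verbatim in extra_strings
BIN_EXTRA_STRING_CODES <- c(401L, 405L, 406L, 407L, 510L)

BIN_ARRAY_FIELDS <- c("probe_ids", "mean", "sd", "n_beads")

normalise_wanted_fields <- function(wanted_fields) {
  if (is.null(wanted_fields)) {
    return(BIN_ARRAY_FIELDS)
  }
  if (is.numeric(wanted_fields)) {
    hits <- names(BIN_FIELD_CODES)[match(as.integer(wanted_fields), BIN_FIELD_CODES)]
    if (anyNA(hits)) {
      stop_usage(sprintf(
        "unknown field code(s): %s",
        paste(wanted_fields[is.na(hits)], collapse = ", ")
      ))
    }
    wanted_fields <- hits
  }
  bad <- setdiff(wanted_fields, BIN_ARRAY_FIELDS)
  if (length(bad)) {
    stop_usage(sprintf(
      "wanted_fields must be per-probe arrays (%s); got: %s",
      paste(BIN_ARRAY_FIELDS, collapse = ", "), paste(bad, collapse = ", ")
    ))
  }
  wanted_fields
}

#' Read the binary IDAT dialect from raw bytes or a file
#'
#' Lower-level sibling of [read_idat()]: parses the binary container only
#' (no gzip or encryption handling). Exposed for callers that already hold
#' the bytes, and for restricting the decode to a subset of the per-probe
#' arrays.
#'
#' @param x Path to a binary IDAT file, or a raw vector of its bytes.
#' @param wanted_fields See [read_idat()].
#' @return A [binary_idat()].
#' @export
read_binary_idat <- function(x, wanted_fields = NULL) {
  bytes <- if (is.raw(x)) x else read_file_raw(x)
  parse_binary_idat(bytes, wanted_fields = wanted_fields)
}

parse_binary_idat <- function(bytes, wanted_fields = NULL) {
  wanted <- normalise_wanted_fields(wanted_fields)
  if (length(bytes) < 4 || !identical(bytes[1:4], charToRaw("IDAT"))) {
    stop_not_idat("file does not begin with the 'IDAT' magic bytes", offset = 0)
  }
  cur <- new_cursor(bytes)
  cur_seek(cur, 4)
  format_version <- cur_uint64(cur, what = "format version")
  if (format_version != 3) {
    warn_beadio(
      sprintf(
        "unsupported binary IDAT format version %s (expected 3); attempting best-effort parse",
        format(format_version)
      ),
      class = "beadio_warning_version"
    )
  }
  n_fields <- cur_int32(cur, what = "field count")
  if (n_fields < 0 || 16 + 10 * n_fields > length(bytes)) {
    stop_corrupt(
      sprintf("implausible field count %d for a %d-byte file", n_fields, length(bytes)),
      offset = 12
    )
  }
  codes <- integer(n_fields)
  offsets <- numeric(n_fields)
  for (i in seq_len(n_fields)) {
    codes[i] <- cur_uint16(cur, what = "directory field code")
    offsets[i] <- cur_uint64(cur, what = "directory offset")
  }
  if (anyDuplicated(codes)) {
    stop_corrupt(
      sprintf(
        "duplicate field code(s) in directory: %s",
        paste(unique(codes[duplicated(codes)]), collapse = ", ")
      ),
      offset = 16
    )
  }
  beyond <- offsets >= length(bytes)
  if (any(beyond)) {
    stop_corrupt(
      sprintf("directory offset for field code %d points beyond end of file", codes[which(beyond)[1]]),
      offset = offsets[which(beyond)[1]]
    )
  }
  at <- function(code) {
    i <- match(code, codes)
    if (is.na(i)) NA_real_ else offsets[i]
  }

  # n_probes first, whatever the directory order: array lengths are not
  # self-describing
  off <- at(BIN_FIELD_CODES[["n_probes"]])
  if (is.na(off)) {
    stop_corrupt("no probe-count field (code 1000) in directory", offset = 16)
  }
  cur_seek(cur, off)
  n_probes <- cur_int32(cur, what = "probe count")
  if (n_probes < 0) {
    stop_corrupt(sprintf("negative probe count %d", n_probes), offset = off)
  }

  read_array <- function(field) {
    off <- at(BIN_FIELD_CODES[[field]])
    if (is.na(off) || !(field %in% wanted)) {
      return(NULL)
    }
    cur_seek(cur, off)
    switch(field,
      probe_ids = cur_int32(cur, n = n_probes, what = "probe_ids array"),
      sd = cur_uint16(cur, n = n_probes, what = "sd array"),
      mean = cur_uint16(cur, n = n_probes, what = "mean array"),
      n_beads = cur_uint8(cur, n = n_probes, what = "n_beads array")
    )
  }
  arrays <- lapply(stats::setNames(BIN_ARRAY_FIELDS, BIN_ARRAY_FIELDS), read_array)

  read_string_at <- function(code) {
    off <- at(code)
    if (is.na(off)) {
      return("")
    }
    cur_seek(cur, off)
    decode_varlen_string(cur)
  }

  mid_block <- integer(0)
  off <- at(BIN_FIELD_CODES[["mid_block"]])
  if (!is.na(off)) {
    cur_seek(cur, off)
    k <- cur_int32(cur, what = "mid_block count")
    if (k < 0) stop_corrupt("negative mid_block count", offset = off)
    mid_block <- cur_int32(cur, n = k, what = "mid_block array")
  }

  run_info <- empty_run_info()
  off <- at(BIN_FIELD_CODES[["run_info"]])
  if (!is.na(off)) {
    cur_seek(cur, off)
    k <- cur_int32(cur, what = "run_info count")
    if (k < 0) stop_corrupt("negative run_info count", offset = off)
    if (k > 0) {
      rows <- vector("list", k)
      for (i in seq_len(k)) {
        vals <- vapply(RUN_INFO_COLS, function(.) decode_varlen_string(cur), character(1))
        rows[[i]] <- vals
      }
      m <- do.call(rbind, rows)
      run_info <- tibble::as_tibble(as.data.frame(m, stringsAsFactors = FALSE))
      names(run_info) <- RUN_INFO_COLS
    }
  }

  red_green <- 0L
  off <- at(BIN_FIELD_CODES[["red_green"]])
  if (!is.na(off)) {
    cur_seek(cur, off)
    red_green <- cur_int32(cur, what = "red_green")
  }

  extra_present <- intersect(BIN_EXTRA_STRING_CODES, codes)
  extra_strings <- vapply(extra_present, read_string_at, character(1))
  names(extra_strings) <- as.character(extra_present)

  known <- c(BIN_FIELD_CODES, BIN_EXTRA_STRING_CODES)
  unknown_i <- which(!(codes %in% known))
  unknown_fields <- tibble::tibble(
    code = codes[unknown_i],
    offset = offsets[unknown_i]
  )
  if (nrow(unknown_fields) && isTRUE(getOption("beadio.verbose", FALSE))) {
    rlang::inform(sprintf(
      "skipping %d unknown field code(s): %s",
      nrow(unknown_fields), paste(unknown_fields$code, collapse = ", ")
    ))
  }

  x <- structure(
    list(
      n_probes = n_probes,
      probe_ids = arrays$probe_ids,
      mean = arrays$mean,
      sd = arrays$sd,
      n_beads = arrays$n_beads,
      barcode = read_string_at(BIN_FIELD_CODES[["barcode"]]),
      chip_type = read_string_at(BIN_FIELD_CODES[["chip_type"]]),
      position = read_string_at(BIN_FIELD_CODES[["position"]]),
      red_green = red_green,
      mid_block = mid_block,
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

serialize_run_info <- function(run_info) {
  body <- w_int32(nrow(run_info))
  if (nrow(run_info) == 0) {
    return(body)
  }
  per_row <- lapply(seq_len(nrow(run_info)), function(i) {
    do.call(c, lapply(RUN_INFO_COLS, function(col) {
      encode_varlen_string(run_info[[col]][i])
    }))
  })
  c(body, do.call(c, per_row))
}

serialize_binary_idat <- function(idat) {
  validate_binary_idat(idat)
  for (f in BIN_ARRAY_FIELDS) {
    if (is.null(idat[[f]])) {
      stop_validation(sprintf(
        "cannot write a projected object: per-probe field '%s' was not loaded", f
      ))
    }
  }
  payloads <- list()
  put <- function(code, bytes) payloads[[as.character(code)]] <<- bytes
  put(BIN_FIELD_CODES[["n_probes"]], w_int32(idat$n_probes))
  put(BIN_FIELD_CODES[["probe_ids"]], w_int32(idat$probe_ids))
  put(BIN_FIELD_CODES[["sd"]], w_uint16(idat$sd))
  put(BIN_FIELD_CODES[["mean"]], w_uint16(idat$mean))
  put(BIN_FIELD_CODES[["n_beads"]], w_uint8(idat$n_beads))
  put(BIN_FIELD_CODES[["mid_block"]], c(w_int32(length(idat$mid_block)), w_int32(idat$mid_block)))
  put(BIN_FIELD_CODES[["run_info"]], serialize_run_info(idat$run_info))
  put(BIN_FIELD_CODES[["red_green"]], w_int32(idat$red_green))
  put(BIN_FIELD_CODES[["barcode"]], encode_varlen_string(idat$barcode))
  put(BIN_FIELD_CODES[["chip_type"]], encode_varlen_string(idat$chip_type))
  put(BIN_FIELD_CODES[["position"]], encode_varlen_string(idat$position))
  for (code in names(idat$extra_strings)) {
    put(as.integer(code), encode_varlen_string(idat$extra_strings[[code]]))
  }

  # ascending code order, contiguous payloads: byte-identical output for
  # equal inputs
  codes <- sort(as.integer(names(payloads)))
  payloads <- payloads[as.character(codes)]
  n_fields <- length(codes)
  header_len <- 4 + 8 + 4 + 10 * n_fields # each directory entry: uint16 + uint64
  sizes <- vapply(payloads, length, integer(1))
  offsets <- header_len + cumsum(c(0, utils::head(sizes, -1)))
  directory <- do.call(c, lapply(seq_len(n_fields), function(i) {
    c(w_uint16(codes[i]), w_uint64(offsets[i]))
  }))
  c(
    charToRaw("IDAT"),
    w_uint64(idat$format_version),
    w_int32(n_fields),
    directory,
    do.call(c, unname(payloads))
  )
}

#' Write a binary IDAT file
#'
#' Serialises a [binary_idat()] into the binary container: field directory,
#' per-probe arrays, varint-framed strings, processing log. Output is
#' deterministic (byte-identical files for equal objects) and is decoded by
#' [read_idat()] back to an equal object. Invariants are checked before any
#' bytes are written.
#'
#' @param idat A valid `binary_idat` with all four per-probe arrays loaded.
#' @param path Output file path.
#' @param gzip Compress the container with gzip (readers treat both forms
#'   identically).
#' @return Invisibly, the number of bytes written.
#' @export
write_binary_idat <- function(idat, path, gzip = FALSE) {
  bytes <- serialize_binary_idat(idat)
  if (gzip) {
    # gzfile() writes an RFC 1952 stream (1f 8b magic); memCompress would
    # emit a bare zlib wrapper and defeat format detection
    con <- gzfile(path, "wb")
    on.exit(close(con))
    writeBin(bytes, con)
  } else {
    writeBin(bytes, path)
  }
  invisible(length(bytes))
}
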