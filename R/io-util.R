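# Low-level byte plumbing: a cursor over a raw vector, little-endian scalar
# and array readers/writers, and the base-128 varint string framing used by
# the binary IDAT container.  Everything here is internal.

read_file_raw <- function(path) {
  if (!file.exists(path)) {
    stop_malformed(sprintf("file not found: %s", path))
  }
  n <- file.size(path)
  bytes <- readBin(path, what = "raw", n = n)
  if (length(bytes) < 4) {
    stop_malformed(sprintf(
      "file '%s' has only %d bytes; need at least 4 to identify an IDAT dialect",
      path, length(bytes)
    ))
  }
  bytes
}

# cursor: mutable position over an immutable raw vector; pos = bytes consumed
new_cursor <- function(bytes) {
  cur <- new.env(parent = emptyenv())
  cur$bytes <- bytes
  cur$pos <- 0
  cur
}

cur_seek <- function(cur, offset) {
  if (offset > length(cur$bytes)) {
    stop_corrupt("seek target beyond end of file", offset = offset)
  }
  cur$pos <- offset
  invisible(cur)
}

cur_take <- function(cur, n, what = "data") {
  if (n == 0) {
    return(raw(0))
  }
  if (cur$pos + n > length(cur$bytes)) {
    stop_corrupt(
      sprintf(
        "truncated %s: needed %s bytes but only %s remain",
        what, format(n, scientific = FALSE),
        format(length(cur$bytes) - cur$pos, scientific = FALSE)
      ),
      offset = cur$pos
    )
  }
  out <- cur$bytes[(cur$pos + 1):(cur$pos + n)]
  cur$pos <- cur$pos + n
  out
}

cur_uint8 <- function(cur, n = 1, what = "uint8") {
  readBin(cur_take(cur, n, what), "integer", n = n, size = 1L, signed = FALSE)
}

cur_uint16 <- function(cur, n = 1, what = "uint16") {
  readBin(cur_take(cur, 2 * n, what), "integer",
    n = n, size = 2L,
    signed = FALSE, endian = "little"
  )
}

cur_int32 <- function(cur, n = 1, what = "int32") {
  readBin(cur_take(cur, 4 * n, what), "integer", n = n, size = 4L, endian = "little")
}

# 64-bit unsigned, returned as double (exact below 2^53 -- far beyond any
# plausible file size)
cur_uint64 <- function(cur, n = 1, what = "uint64") {
  words <- readBin(cur_take(cur, 8 * n, what), "integer",
    n = 2 * n, size = 4L,
    endian = "little"
  )
  u <- ifelse(words < 0, words + 2^32, words)
  u[seq(1, 2 * n, by = 2)] + u[seq(2, 2 * n, by = 2)] * 2^32
}

w_int32 <- function(x) {
  writeBin(as.integer(x), raw(), size = 4L, endian = "little")
}

w_uint16 <- function(x) {
  x <- as.integer(x)
  # writeBin truncates int32 to the low two bytes, which is exactly the
  # unsigned-16 representation for values in [0, 65535]
  suppressWarnings(writeBin(x, raw(), size = 2L, endian = "little"))
}

w_uint8 <- function(x) {
  as.raw(x)
}

w_uint64 <- function(x) {
  lo <- x %% 2^32
  hi <- x %/% 2^32
  as_i32 <- function(u) as.integer(ifelse(u >= 2^31, u - 2^32, u))
  out <- raw(8 * length(x))
  lo_raw <- w_int32(as_i32(lo))
  hi_raw <- w_int32(as_i32(hi))
  for (i in seq_along(x)) {
    out[(8 * i - 7):(8 * i - 4)] <- lo_raw[(4 * i - 3):(4 * i)]
    out[(8 * i - 3):(8 * i)] <- hi_raw[(4 * i - 3):(4 * i)]
  }
  out
}

w_float32 <- function(x) {
  writeBin(as.double(x), raw(), size = 4L, endian = "little")
}

# snap doubles to their nearest IEEE-754 single-precision value, so that
# statistics computed in double survive a float32 file round trip bit-exactly
as_float32 <- function(x) {
  if (length(x) == 0) {
    return(numeric(0))
  }
  readBin(w_float32(x), "numeric", n = length(x), size = 4L, endian = "little")
}

# ---- base-128 varint string framing --------------------------------------

encode_varint <- function(n) {
  if (n < 0) stop_validation("varint length must be non-negative")
  out <- integer(0)
  repeat {
    b <- n %% 128L
    n <- n %/% 128L
    if (n > 0) {
      out <- c(out, b + 128L)
    } else {
      out <- c(out, b)
      break
    }
  }
  as.raw(out)
}

cur_varint <- function(cur) {
  value <- 0
  shift <- 0
  for (i in 1:5) {
    b <- cur_uint8(cur, what = "varint length prefix")
    value <- value + (b %% 128L) * 2^shift
    if (b < 128L) {
      return(value)
    }
    shift <- shift + 7
  }
  stop_corrupt("varint continuation chain longer than 5 bytes", offset = cur$pos)
}

latin1_to_string <- function(bytes) {
  if (any(bytes == as.raw(0))) {
    stop_corrupt("embedded NUL byte inside a string field", offset = NA)
  }
  s <- rawToChar(bytes)
  Encoding(s) <- "latin1"
  enc2utf8(s)
}

string_to_latin1 <- function(s) {
  if (length(s) != 1 || is.na(s)) stop_validation("string fields must be length-1, non-NA")
  if (!nzchar(s)) {
    return(raw(0))
  }
  out <- iconv(s, from = "UTF-8", to = "latin1")
  if (is.na(out)) {
    stop_validation("string not representable in Latin-1")
  }
  charToRaw(out)
}

#' Decode / encode a length-prefixed string
#'
#' Strings inside the binary IDAT container are framed as a base-128 varint
#' byte-length prefix (7 data bits per byte, high bit set on continuation
#' bytes, least-significant group first) followed by that many bytes of
#' Latin-1 text. `decode_varlen_string()` reads one such string from a raw
#' vector (or a cursor positioned at the string field); `encode_varlen_string()`
#' is its exact inverse.
#'
#' @param x A raw vector starting at the length prefix, or an internal cursor.
#' @param s A single character string.
#' @return The decoded string, or the encoded raw vector.
#' @examples
#' encode_varlen_string("R01C1")
#' decode_varlen_string(as.raw(c(0x05, charToRaw("R01C1"))))
#' @export
decode_varlen_string <- function(x) {
  cur <- if (is.raw(x)) new_cursor(x) else x
  n <- cur_varint(cur)
  latin1_to_string(cur_take(cur, n, what = "string body"))
}

#' @rdname decode_varlen_string
#' @export
encode_varlen_string <- function(s) {
  bytes <- string_to_latin1(s)
  c(encode_varint(length(bytes)), bytes)
}
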