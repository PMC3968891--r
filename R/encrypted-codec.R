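# Encrypted-XML (gene expression) IDAT codec: DES decryption, XML parsing,
# Base64 vector decoding.  The XML tag inventory and element widths live in
# the table below, not in logic: tags are the naming convention reported by
# reverse-engineering efforts, with nine known semantics for the ten data
# fields; anything not in the table is retained uninterpreted.

EXPR_TAG_TABLE <- data.frame(
  tag = c(
    "IllumicodeBinData", "MeanBinData", "DevBinData", "MedianBinData",
    "TrimmedMeanBinData", "BackgroundBinData", "BackgroundDevBinData",
    "NumBeadsBinData", "NumGoodBeadsBinData"
  ),
  field = c(
    "probe_ids", "mean", "sd", "median", "trimmed_mean",
    "bg_mean", "bg_sd", "n_beads_raw", "n_beads_used"
  ),
  type = c(
    "int32", "float32", "float32", "float32", "float32",
    "float32", "float32", "int32", "int32"
  ),
  stringsAsFactors = FALSE
)

# the conventional tag of the tenth vector; decoded as int32 like any other
# unrecognised tag, and kept uninterpreted in extra_field
EXPR_EXTRA_TAG_DEFAULT <- "CodesBinData"

BASE64_RE <- "^([A-Za-z0-9+/]{4})*([A-Za-z0-9+/]{2}==|[A-Za-z0-9+/]{3}=)?$"

#' Decode / encode a Base64-packed numeric vector
#'
#' The data vectors inside expression IDAT XML are little-endian 4-byte
#' elements (signed integers for IDs and bead counts, IEEE-754 single
#' precision for intensities) packed into standard Base64
#' (RFC 4648 alphabet, `=` padding). `decode_base64_vector()` decodes one
#' such string; `encode_base64_vector()` is its inverse. Note that float
#' vectors must already be single-precision representable to round-trip
#' bit-exactly; see `generate_expression_idat()` for how fixture statistics
#' are snapped.
#'
#' @param text A Base64 string (whitespace tolerated).
#' @param v A numeric vector to encode.
#' @param element_type `"int32"` or `"float32"`.
#' @param field Optional field name used in error messages.
#' @return The decoded numeric vector, or the Base64 string.
#' @examples
#' decode_base64_vector("AQAAAA==", "int32")
#' encode_base64_vector(c(1L, 2L, 3L), "int32")
#' @export
decode_base64_vector <- function(text, element_type = c("int32", "float32"),
                                 field = NULL) {
  element_type <- match.arg(element_type)
  clean <- gsub("[ \t\r\n]", "", text)
  if (!grepl(BASE64_RE, clean)) {
    stop_corrupt_field(
      sprintf(
        "field %s is not valid Base64",
        if (is.null(field)) "<unnamed>" else paste0("'", field, "'")
      ),
      field = field
    )
  }
  if (!nzchar(clean)) {
    return(if (element_type == "int32") integer(0) else numeric(0))
  }
  bytes <- jsonlite::base64_dec(clean)
  if (length(bytes) %% 4 != 0) {
    stop_corrupt_field(
      sprintf(
        "field %s decodes to %d bytes, not a multiple of the 4-byte element width",
        if (is.null(field)) "<unnamed>" else paste0("'", field, "'"), length(bytes)
      ),
      field = field
    )
  }
  n <- length(bytes) %/% 4
  if (element_type == "int32") {
    readBin(bytes, "integer", n = n, size = 4L, endian = "little")
  } else {
    readBin(bytes, "numeric", n = n, size = 4L, endian = "little")
  }
}

#' @rdname decode_base64_vector
#' @export
encode_base64_vector <- function(v, element_type = c("int32", "float32")) {
  element_type <- match.arg(element_type)
  bytes <- if (element_type == "int32") w_int32(v) else w_float32(v)
  gsub("[\r\n]", "", jsonlite::base64_enc(bytes))
}

#' Read an encrypted-XML expression IDAT
#'
#' Lower-level sibling of [read_idat()] for the gene-expression dialect:
#' DES-decrypts the file, parses the XML payload, checks that exactly ten
#' Base64 data fields are present, and decodes them into an
#' [expression_idat()]. Fields whose tag is not among the nine with known
#' semantics are decoded as int32 and kept verbatim in `extra_field`.
#'
#' @param x Path to an encrypted IDAT, or a raw vector of its bytes.
#' @param key 8-byte raw DES key.
#' @return An [expression_idat()].
#' @export
read_encrypted_idat <- function(x, key) {
  bytes <- if (is.raw(x)) x else read_file_raw(x)
  parse_encrypted_idat(bytes, key)
}

parse_encrypted_idat <- function(bytes, key) {
  plain <- des_decrypt(bytes, key)
  doc <- tryCatch(
    {
      txt <- rawToChar(plain)
      xml2::read_xml(txt)
    },
    beadio_error = function(e) rlang::cnd_signal(e),
    error = function(e) {
      stop_wrong_key(sprintf(
        "decrypted bytes are not well-formed XML (%s): wrong key or corrupt file",
        conditionMessage(e)
      ))
    }
  )
  metadata <- xml2::xml_attrs(doc)
  children <- xml2::xml_children(doc)
  tags <- xml2::xml_name(children)
  if (length(tags) != 10) {
    stop_dialect(sprintf(
      "expected exactly 10 data fields in an expression payload, found %d: %s",
      length(tags), paste(tags, collapse = ", ")
    ))
  }
  values <- vector("list", length(tags))
  names(values) <- tags
  for (i in seq_along(tags)) {
    row <- match(tags[i], EXPR_TAG_TABLE$tag)
    type <- if (is.na(row)) "int32" else EXPR_TAG_TABLE$type[row]
    values[[i]] <- decode_base64_vector(
      xml2::xml_text(children[[i]]), type,
      field = tags[i]
    )
  }
  known <- tags %in% EXPR_TAG_TABLE$tag
  missing_tags <- setdiff(EXPR_TAG_TABLE$tag, tags)
  if (length(missing_tags)) {
    stop_dialect(sprintf(
      "payload is missing expected data field(s): %s (tags found: %s)",
      paste(missing_tags, collapse = ", "), paste(tags, collapse = ", ")
    ))
  }
  lens <- vapply(values, length, integer(1))
  if (length(unique(lens)) > 1) {
    stop_corrupt_field(
      sprintf(
        "the ten data vectors disagree in length: %s",
        paste(sprintf("%s=%d", tags, lens), collapse = ", ")
      ),
      field = tags[which.max(lens != lens[1])]
    )
  }
  args <- stats::setNames(
    values[match(EXPR_TAG_TABLE$tag, tags)],
    EXPR_TAG_TABLE$field
  )
  args$extra_field <- values[!known]
  args$metadata <- metadata
  do.call(expression_idat, args)
}

build_expression_xml <- function(idat, comment_pad = 0) {
  doc <- xml2::xml_new_root("ExpressionIdat")
  md <- idat$metadata
  for (nm in names(md)) {
    xml2::xml_set_attr(doc, nm, md[[nm]])
  }
  for (i in seq_len(nrow(EXPR_TAG_TABLE))) {
    node <- xml2::xml_add_child(doc, EXPR_TAG_TABLE$tag[i])
    xml2::xml_set_text(
      node,
      encode_base64_vector(idat[[EXPR_TAG_TABLE$field[i]]], EXPR_TAG_TABLE$type[i])
    )
  }
  for (nm in names(idat$extra_field)) {
    node <- xml2::xml_add_child(doc, nm)
    xml2::xml_set_text(node, encode_base64_vector(idat$extra_field[[nm]], "int32"))
  }
  txt <- as.character(doc)
  if (comment_pad > 0) {
    txt <- paste0(txt, strrep("<!--pad-->", comment_pad))
  }
  charToRaw(txt)
}

#' Write an encrypted-XML expression IDAT (fixture writer)
#'
#' Serialises an [expression_idat()] to the encrypted-XML dialect:
#' deterministic XML (canonical tag order, metadata as root attributes),
#' Base64-packed data vectors, PKCS#7 padding, single-DES ECB encryption.
#' [read_encrypted_idat()] inverts it exactly. If the raw ciphertext would
#' by coincidence begin with the `"IDAT"` or gzip magic (and so confuse
#' [detect_idat_format()]), a trailing XML comment is appended and the
#' payload re-encrypted until the collision disappears; the output is still
#' deterministic for equal inputs.
#'
#' @param idat A valid `expression_idat`. Float vectors should be
#'   single-precision representable (the fixture generator guarantees this).
#' @param path Output file path.
#' @param key 8-byte raw DES key (default [beadio_fixture_key()]).
#' @return Invisibly, the number of bytes written.
#' @export
write_encrypted_idat <- function(idat, path, key = beadio_fixture_key()) {
  validate_expression_idat(idat)
  check_des_key(key)
  if (length(idat$extra_field) + nrow(EXPR_TAG_TABLE) != 10) {
    stop_validation(sprintf(
      "an expression payload must carry exactly 10 data fields; this object has %d",
      nrow(EXPR_TAG_TABLE) + length(idat$extra_field)
    ))
  }
  pad <- 0
  repeat {
    ct <- des_encrypt(build_expression_xml(idat, comment_pad = pad), key)
    head4 <- ct[seq_len(min(4, length(ct)))]
    collides <- identical(head4, charToRaw("IDAT")) ||
      identical(head4[1:2], as.raw(c(0x1F, 0x8B)))
    if (!collides) {
      break
    }
    pad <- pad + 1
  }
  writeBin(ct, path)
  invisible(length(ct))
}
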