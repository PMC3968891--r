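# R surface over the compiled single-DES core.  ECB with PKCS#7 padding is
# the one policy the package uses; it is kept in this one file so that a
# different mode/framing for vendor containers would be a local change.

check_des_key <- function(key) {
  if (!is.raw(key) || length(key) != 8) {
    stop_validation("DES key must be a raw vector of exactly 8 bytes")
  }
  key
}

pkcs7_pad <- function(x) {
  p <- 8L - (length(x) %% 8L)
  c(x, as.raw(rep(p, p)))
}

pkcs7_unpad <- function(x) {
  if (length(x) == 0) {
    stop_wrong_key("decrypted stream is empty: wrong key or corrupt file")
  }
  p <- as.integer(x[length(x)])
  if (p < 1 || p > 8 || length(x) < p ||
    !all(x[(length(x) - p + 1):length(x)] == as.raw(p))) {
    stop_wrong_key("invalid PKCS#7 padding after decryption: wrong key or corrupt file")
  }
  x[seq_len(length(x) - p)]
}

#' DES encryption and decryption (ECB, PKCS#7)
#'
#' Single DES over 8-byte blocks in ECB mode, the cipher protecting
#' gene-expression IDAT payloads. `des_encrypt()` appends PKCS#7 padding
#' before encrypting; `des_decrypt()` validates and strips it, so
#' `des_decrypt(des_encrypt(x, k), k)` is the identity for every raw vector
#' `x` and 8-byte key `k`. With `pad = FALSE` both operate on raw blocks
#' (input length must already be a multiple of 8), which is how single-block
#' test vectors are checked.
#'
#' @param x Raw vector to encrypt or decrypt.
#' @param key 8-byte raw DES key (parity bits ignored, as per the cipher).
#' @param pad Apply/expect PKCS#7 padding (default `TRUE`).
#' @return Raw vector of ciphertext or recovered plaintext.
#' @examples
#' key <- charToRaw("beadio01")
#' ct <- des_encrypt(charToRaw("intensities"), key)
#' rawToChar(des_decrypt(ct, key))
#' @export
des_encrypt <- function(x, key, pad = TRUE) {
  check_des_key(key)
  if (!is.raw(x)) stop_validation("DES input must be a raw vector")
  if (pad) {
    x <- pkcs7_pad(x)
  } else if (length(x) %% 8 != 0) {
    stop_malformed("unpadded DES input length must be a multiple of 8 bytes")
  }
  .Call(C_des_ecb, x, key, FALSE)
}

#' @rdname des_encrypt
#' @export
des_decrypt <- function(x, key, pad = TRUE) {
  check_des_key(key)
  if (!is.raw(x)) stop_validation("DES input must be a raw vector")
  if (length(x) %% 8 != 0) {
    stop_malformed(sprintf(
      "ciphertext length %d is not a multiple of the 8-byte DES block size", length(x)
    ))
  }
  pt <- .Call(C_des_ecb, x, key, TRUE)
  if (pad) pkcs7_unpad(pt) else pt
}

#' Default DES key used by the fixture writer
#'
#' An arbitrary documented constant (`"beadio01"` in ASCII). Files written by
#' the fixture generator are encrypted with this key unless another is
#' supplied; it has no relation to any vendor key.
#'
#' @return An 8-byte raw vector.
#' @export
beadio_fixture_key <- function() {
  charToRaw("beadio01")
}
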