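# Shared helpers: write a fixture to a temp path, strip the bead-level
# simulation attribute before file-equality checks, hex decoding for cipher
# test vectors.

hex2raw <- function(s) {
  s <- gsub("[^0-9A-Fa-f]", "", s)
  as.raw(strtoi(substring(s, seq(1, nchar(s), 2), seq(2, nchar(s), 2)), 16L))
}

drop_bead_attr <- function(idat) {
  attr(idat, "simulated_beads") <- NULL
  idat
}

tmp_binary_fixture <- function(n_probes = 25, seed = 1, gzip = FALSE, platform = "methylation") {
  fx <- generate_binary_idat(fixture_profile(platform, n_probes = n_probes, seed = seed))
  path <- tempfile(fileext = ".idat")
  write_binary_idat(fx$idat, path, gzip = gzip)
  list(path = path, idat = fx$idat, manifest = fx$manifest)
}

tmp_expression_fixture <- function(n_probes = 25, seed = 1, key = beadio_fixture_key()) {
  idat <- generate_expression_idat(fixture_profile("expression", n_probes = n_probes, seed = seed))
  path <- tempfile(fileext = ".idat")
  write_encrypted_idat(idat, path, key = key)
  list(path = path, idat = drop_bead_attr(idat), beads = attr(idat, "simulated_beads"))
}
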