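# Byte-exact reader/writer for the binary dialect.

test_that("write -> read is the identity on valid objects", {
  for (seed in 1:8) {
    fx <- generate_binary_idat(
      fixture_profile(if (seed %% 2) "methylation" else "genotyping",
        n_probes = c(0, 1, 5, 200)[(seed %% 4) + 1], seed = seed
      )
    )
    p <- tempfile()
    write_binary_idat(fx$idat, p)
    expect_identical(read_idat(p), fx$idat)
  }
})

test_that("writer output is deterministic, byte for byte", {
  fx <- generate_binary_idat(fixture_profile("methylation", n_probes = 40, seed = 6))
  p1 <- tempfile()
  p2 <- tempfile()
  write_binary_idat(fx$idat, p1)
  write_binary_idat(fx$idat, p2)
  expect_identical(
    readBin(p1, "raw", file.size(p1)),
    readBin(p2, "raw", file.size(p2))
  )
})

test_that("a zero-probe array is a valid file with empty arrays", {
  fx <- tmp_binary_fixture(n_probes = 0, seed = 2)
  got <- read_idat(fx$path)
  expect_identical(got$n_probes, 0L)
  expect_identical(got$probe_ids, integer(0))
  expect_identical(got, fx$idat)
})

test_that("exactly four per-probe data fields are decoded", {
  fx <- tmp_binary_fixture(n_probes = 5, seed = 1)
  got <- read_idat(fx$path)
  per_probe <- vapply(got[c("probe_ids", "mean", "sd", "n_beads")], length, integer(1))
  expect_identical(sum(per_probe == 5L), 4L)
})

test_that("wanted_fields projects the per-probe arrays but keeps metadata", {
  fx <- tmp_binary_fixture(n_probes = 20, seed = 7)
  got <- read_idat(fx$path, wanted_fields = c("probe_ids", "mean"))
  expect_identical(got$probe_ids, fx$idat$probe_ids)
  expect_identical(got$mean, fx$idat$mean)
  expect_null(got$sd)
  expect_null(got$n_beads)
  expect_identical(got$barcode, fx$idat$barcode)
  expect_identical(got$run_info, fx$idat$run_info)
  # field codes are accepted in place of names
  got2 <- read_idat(fx$path, wanted_fields = c(102L, 104L))
  expect_identical(got2, got)
  expect_error(read_idat(fx$path, wanted_fields = "banana"), class = "beadio_error_usage")
})

test_that("truncation yields a corrupt-file error with an offset, never a short array", {
  fx <- tmp_binary_fixture(n_probes = 50, seed = 8)
  corrupt_file(fx$path, "truncate")
  err <- expect_error(read_idat(fx$path), class = "beadio_error_corrupt")
  expect_true(is.numeric(err$offset))
})

test_that("a non-IDAT magic is a not-an-idat error", {
  fx <- tmp_binary_fixture(n_probes = 5, seed = 9)
  corrupt_file(fx$path, "flip_magic")
  expect_error(read_binary_idat(fx$path), class = "beadio_error_not_idat")
})

test_that("re-reading the same file twice yields identical objects", {
  fx <- tmp_binary_fixture(n_probes = 30, seed = 10)
  expect_identical(read_idat(fx$path), read_idat(fx$path))
})

test_that("an invalid object is rejected before any bytes are written", {
  fx <- generate_binary_idat(fixture_profile("methylation", n_probes = 5, seed = 11))
  bad <- fx$idat
  bad$mean <- bad$mean[-1] # length mismatch
  p <- tempfile()
  expect_error(write_binary_idat(bad, p), class = "beadio_error_validation")
  expect_false(file.exists(p))

  bad2 <- fx$idat
  bad2$probe_ids <- rev(bad2$probe_ids) # unsorted
  expect_error(write_binary_idat(bad2, p), class = "beadio_error_validation")
  expect_false(file.exists(p))
})

# --- varint string framing -------------------------------------------------

test_that("single-byte length prefix decodes as specified", {
  expect_identical(
    decode_varlen_string(c(as.raw(0x05), charToRaw("R01C1"))),
    "R01C1"
  )
})

test_that("a 200-character string takes the two-byte prefix C8 01", {
  # independent base-128 oracle: 200 = 0b11001000 -> low 7 bits 1001000 with
  # continuation (0xC8), then 1 (0x01)
  s <- strrep("a", 200)
  enc <- encode_varlen_string(s)
  expect_identical(enc[1:2], as.raw(c(0xC8, 0x01)))
  expect_identical(decode_varlen_string(enc), s)
})

test_that("varint string encoding round-trips random strings of length 0-300", {
  withr::with_seed(42, {
    alphabet <- c(LETTERS, letters, 0:9, " ", "_", "/", ".", "é", "ü")
    for (i in 1:50) {
      n <- sample(0:300, 1)
      s <- paste(sample(alphabet, n, replace = TRUE), collapse = "")
      expect_identical(decode_varlen_string(encode_varlen_string(s)), s)
    }
  })
})

test_that("an overlong varint continuation chain is a corrupt-file error", {
  expect_error(
    decode_varlen_string(as.raw(c(0x80, 0x80, 0x80, 0x80, 0x80, 0x01))),
    class = "beadio_error_corrupt"
  )
})

# --- fuzzing ---------------------------------------------------------------

test_that("single-byte mutations either error cleanly or parse to a valid object", {
  fx <- tmp_binary_fixture(n_probes = 12, seed = 13)
  bytes <- readBin(fx$path, "raw", file.size(fx$path))
  withr::with_seed(99, {
    positions <- sample(length(bytes), 80, replace = TRUE)
    values <- sample(0:255, 80, replace = TRUE)
  })
  for (i in seq_along(positions)) {
    mutated <- bytes
    mutated[positions[i]] <- as.raw(values[i])
    res <- tryCatch(
      suppressWarnings(read_binary_idat(mutated)),
      beadio_error = function(e) "clean-error"
    )
    if (!identical(res, "clean-error")) {
      # parsed: object must still satisfy the type invariants
      expect_silent(validate_binary_idat(res))
    } else {
      succeed()
    }
  }
})
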