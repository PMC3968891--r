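# The fixture generators themselves: determinism, statistical
# self-consistency of the expression summaries, and the corrupt-file modes.

test_that("equal profiles generate identical objects and identical bytes", {
  prof <- fixture_profile("methylation", n_probes = 30, seed = 123)
  a <- generate_binary_idat(prof)
  b <- generate_binary_idat(prof)
  expect_identical(a, b)
  p1 <- tempfile()
  p2 <- tempfile()
  write_binary_idat(a$idat, p1)
  write_binary_idat(b$idat, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)), readBin(p2, "raw", file.size(p2)))

  ep <- fixture_profile("expression", n_probes = 30, seed = 123)
  expect_identical(generate_expression_idat(ep), generate_expression_idat(ep))
})

test_that("the generator seed is recorded inside the file itself", {
  fx <- tmp_binary_fixture(n_probes = 5, seed = 77)
  got <- read_idat(fx$path)
  expect_identical(unname(got$extra_strings["401"]), "fixture-seed=77")
  ex <- tmp_expression_fixture(n_probes = 5, seed = 77)
  gote <- read_idat(ex$path, key = beadio_fixture_key())
  expect_identical(unname(gote$metadata["FixtureSeed"]), "77")
})

test_that("generated binary files satisfy every type invariant after reading", {
  for (seed in c(1, 2)) {
    fx <- tmp_binary_fixture(n_probes = 100, seed = seed, platform = "genotyping")
    got <- read_idat(fx$path)
    expect_silent(validate_binary_idat(got))
    expect_true(all(diff(got$probe_ids) > 0))
    expect_true(all(got$mean >= 0 & got$mean <= 65535))
    expect_true(all(got$n_beads >= 0 & got$n_beads <= 255))
    expect_true(any(grepl("scan", got$run_info$block_type, ignore.case = TRUE)))
  }
})

test_that("expression summaries are recomputable from the simulated beads", {
  idat <- generate_expression_idat(fixture_profile("expression", n_probes = 120, seed = 9))
  sim <- attr(idat, "simulated_beads")
  kept <- Map(function(x, ok) x[ok], sim$intensities, sim$retained)
  f32 <- beadio:::as_float32
  # brute-force recomputation of each statistic over the retained beads
  expect_identical(f32(vapply(kept, mean, numeric(1))), idat$mean)
  expect_identical(f32(vapply(kept, stats::median, numeric(1))), idat$median)
  expect_identical(
    f32(vapply(kept, function(x) if (length(x) < 2) 0 else stats::sd(x), numeric(1))),
    idat$sd
  )
  # independent trimmed-mean oracle: base R mean(trim = 0.05)
  expect_identical(
    f32(vapply(kept, function(x) mean(x, trim = 0.05), numeric(1))),
    idat$trimmed_mean
  )
  expect_identical(vapply(kept, length, integer(1)), idat$n_beads_used)
  expect_identical(vapply(sim$intensities, length, integer(1)), idat$n_beads_raw)
})

test_that("per-probe medians sit inside the simulated bead range", {
  idat <- generate_expression_idat(fixture_profile("expression", n_probes = 80, seed = 10))
  sim <- attr(idat, "simulated_beads")
  lo <- vapply(sim$intensities, min, numeric(1))
  hi <- vapply(sim$intensities, max, numeric(1))
  expect_true(all(idat$median >= beadio:::as_float32(lo) - 1e-3))
  expect_true(all(idat$median <= beadio:::as_float32(hi) + 1e-3))
  expect_true(all(idat$n_beads_used <= idat$n_beads_raw))
  expect_true(all(idat$n_beads_used >= 1))
})

test_that("background intensities sit below foreground on average", {
  idat <- generate_expression_idat(fixture_profile("expression", n_probes = 300, seed = 11))
  expect_lt(mean(idat$bg_mean), mean(idat$mean))
})

test_that("invalid profiles are rejected", {
  expect_error(fixture_profile("methylation", n_probes = -1), class = "beadio_error_validation")
  expect_error(fixture_profile("methylation", control_fraction = 1.5), class = "beadio_error_validation")
  expect_error(
    generate_binary_idat(fixture_profile("expression", n_probes = 5)),
    class = "beadio_error_validation"
  )
  expect_error(
    generate_expression_idat(fixture_profile("methylation", n_probes = 5)),
    class = "beadio_error_validation"
  )
})

test_that("each corruption mode triggers its designated error class", {
  # truncate -> corrupt-file with offset
  fx <- tmp_binary_fixture(n_probes = 50, seed = 40)
  corrupt_file(fx$path, "truncate")
  err <- expect_error(read_idat(fx$path), class = "beadio_error_corrupt")
  expect_match(conditionMessage(err), "offset")

  # flip_magic -> not-an-idat from the binary reader; auto-dispatch, which
  # goes by magic alone, must classify the file as encrypted XML
  fx <- tmp_binary_fixture(n_probes = 5, seed = 41)
  corrupt_file(fx$path, "flip_magic")
  expect_error(read_binary_idat(fx$path), class = "beadio_error_not_idat")
  expect_identical(detect_idat_format(fx$path), "encrypted-xml")
  expect_error(read_idat(fx$path), class = "beadio_error_missing_key")

  # bad_offset -> corrupt-file naming the offset
  fx <- tmp_binary_fixture(n_probes = 20, seed = 42)
  corrupt_file(fx$path, "bad_offset")
  expect_error(read_idat(fx$path), class = "beadio_error_corrupt")

  # bad_base64 -> corrupt-field naming the field
  ex <- tmp_expression_fixture(n_probes = 10, seed = 43)
  corrupt_file(ex$path, "bad_base64")
  err <- expect_error(
    read_idat(ex$path, key = beadio_fixture_key()),
    class = "beadio_error_corrupt_field"
  )
  expect_match(conditionMessage(err), "MeanBinData")

  # wrong_pad -> wrong-key-or-corrupt
  ex <- tmp_expression_fixture(n_probes = 10, seed = 44)
  corrupt_file(ex$path, "wrong_pad")
  expect_error(read_idat(ex$path, key = beadio_fixture_key()), class = "beadio_error_wrong_key")

  # unknown mode -> usage error
  expect_error(corrupt_file(ex$path, "melt"), class = "beadio_error_usage")
})

test_that("write_fixture emits the dialect files plus truth table and manifest", {
  dir <- tempfile()
  out <- write_fixture(fixture_profile("methylation", n_probes = 15, seed = 50), dir, gzip = TRUE)
  expect_true(file.exists(out$idat))
  expect_true(file.exists(out$idat_gz))
  expect_true(file.exists(out$bgx))
  expect_true(file.exists(out$truth))
  truth <- utils::read.delim(out$truth)
  expect_identical(nrow(truth), 15L)

  oute <- write_fixture(fixture_profile("expression", n_probes = 8, seed = 51), dir)
  expect_identical(detect_idat_format(oute$idat), "encrypted-xml")
  truth_e <- utils::read.delim(oute$truth)
  expect_identical(ncol(truth_e), 10L)
})
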