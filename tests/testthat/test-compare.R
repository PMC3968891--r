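# Rounding-tolerant comparison against text exports, and the dump that
# replaces the vendor export step.

test_that("self-comparison is exact on every row", {
  fx <- tmp_binary_fixture(n_probes = 50, seed = 60)
  cmp <- compare_to_text_export(fx$idat, tidy(fx$idat))
  expect_identical(cmp$n_rows_compared, 50L)
  expect_identical(cmp$n_exact, 50L)
  expect_identical(cmp$n_discordant, 0L)
  # and from the on-disk truth table written by the fixture set
  out <- write_fixture(fixture_profile("methylation", n_probes = 20, seed = 61), tempfile())
  cmp2 <- compare_to_text_export(read_idat(out$idat), out$truth)
  expect_identical(cmp2$n_exact, 20L)
  expect_identical(cmp2$n_discordant, 0L)
})

test_that("perturbations below the rounding grid count as within-rounding", {
  # fixture means are integers; +0.04 rounds back to the same value at one
  # decimal, so every row agrees after rounding without being bit-equal
  fx <- tmp_binary_fixture(n_probes = 30, seed = 62)
  truth <- tidy(fx$idat)
  truth$mean <- truth$mean + 0.04
  cmp <- compare_to_text_export(fx$idat, truth, decimals = 1)
  expect_identical(cmp$n_within_rounding, 30L)
  expect_identical(cmp$n_discordant, 0L)
  expect_identical(cmp$n_exact, 0L)
  expect_true(cmp$max_abs_diff > 0.039 && cmp$max_abs_diff < 0.041)
})

test_that("perturbations beyond the rounding grid are discordant", {
  fx <- tmp_binary_fixture(n_probes = 30, seed = 63)
  truth <- tidy(fx$idat)
  truth$mean <- truth$mean + 0.06
  cmp <- compare_to_text_export(fx$idat, truth, decimals = 1)
  expect_identical(cmp$n_discordant, 30L)
  expect_identical(cmp$n_within_rounding, 0L)
})

test_that("comparison counts partition the compared rows", {
  withr::with_seed(64, {
    fx <- generate_binary_idat(fixture_profile("methylation", n_probes = 60, seed = 64))
    truth <- tidy(fx$idat)
    # mixed perturbation: a third exact, a third small, a third large
    bump <- rep(c(0, 0.04, 0.06), each = 20)
    truth$mean <- truth$mean + bump
    cmp <- compare_to_text_export(fx$idat, truth, decimals = 1)
    expect_identical(
      cmp$n_exact + cmp$n_within_rounding + cmp$n_discordant,
      cmp$n_rows_compared
    )
    expect_identical(cmp$n_exact, 20L)
    expect_identical(cmp$n_within_rounding, 20L)
    expect_identical(cmp$n_discordant, 20L)
  })
})

test_that("expression comparisons work over the ten-column truth table", {
  out <- write_fixture(fixture_profile("expression", n_probes = 25, seed = 65), tempfile())
  idat <- read_idat(out$idat, key = beadio_fixture_key())
  cmp <- compare_to_text_export(idat, out$truth)
  expect_identical(cmp$n_exact, 25L)
  expect_identical(cmp$n_discordant, 0L)
  expect_true(all(c("mean", "trimmed_mean", "bg_sd") %in% cmp$columns))
})

test_that("disjoint id sets and shared-column absence are empty-overlap errors", {
  fx <- tmp_binary_fixture(n_probes = 10, seed = 66)
  truth <- tidy(fx$idat)
  truth$probe_id <- truth$probe_id + 1L # ids no longer overlap
  expect_error(compare_to_text_export(fx$idat, truth), class = "beadio_error_empty_overlap")
  only_ids <- tidy(fx$idat)["probe_id"]
  expect_error(compare_to_text_export(fx$idat, only_ids), class = "beadio_error_empty_overlap")
})

test_that("tidy()/glance() expose the comparison as tables", {
  fx <- tmp_binary_fixture(n_probes = 10, seed = 67)
  cmp <- compare_to_text_export(fx$idat, tidy(fx$idat))
  expect_s3_class(tidy(cmp), "tbl_df")
  expect_identical(nrow(glance(cmp)), 1L)
  expect_identical(glance(cmp)$n_exact, 10L)
})

test_that("TSV dump has one row per probe and the dialect's column count", {
  fx <- tmp_binary_fixture(n_probes = 5, seed = 68)
  lines <- dump_idat(fx$idat, file = tempfile(), format = "tsv")
  expect_identical(length(lines), 6L) # header + 5 rows
  expect_identical(strsplit(lines[1], "\t")[[1]], c("probe_id", "mean", "sd", "n_beads"))

  ex <- tmp_expression_fixture(n_probes = 4, seed = 68)
  lines_e <- dump_idat(ex$idat, file = tempfile(), format = "tsv")
  expect_identical(length(strsplit(lines_e[1], "\t")[[1]]), 10L)
})

test_that("dumped numbers parse back to the original arrays", {
  ex <- tmp_expression_fixture(n_probes = 40, seed = 69)
  p <- tempfile(fileext = ".tsv")
  dump_idat(ex$idat, file = p, format = "tsv")
  back <- utils::read.delim(p)
  expect_identical(back$probe_id, ex$idat$probe_ids)
  expect_identical(back$mean, ex$idat$mean)
  expect_identical(back$trimmed_mean, ex$idat$trimmed_mean)

  pj <- tempfile(fileext = ".json")
  dump_idat(ex$idat, file = pj, format = "json")
  parsed <- jsonlite::fromJSON(pj)
  expect_equal(parsed$data$bg_sd, ex$idat$bg_sd, tolerance = 1e-12)
  expect_identical(parsed$metadata$n_probes, 40L)
})

test_that("autoplot methods return ggplot objects", {
  fx <- tmp_binary_fixture(n_probes = 30, seed = 70)
  expect_s3_class(autoplot(fx$idat), "ggplot")
  ex <- tmp_expression_fixture(n_probes = 30, seed = 70)
  expect_s3_class(autoplot(ex$idat), "ggplot")
  cmp <- compare_to_text_export(fx$idat, tidy(fx$idat))
  expect_s3_class(autoplot(cmp), "ggplot")
})
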