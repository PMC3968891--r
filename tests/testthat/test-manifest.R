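# BGX parsing, the BPM-CSV dialect, and intensity annotation.

test_that("a BGX with probes and controls round-trips through write_bgx", {
  man <- bead_manifest(
    heading = c("Array Name" = "TestChip"),
    probes = tibble::tibble(
      probe_id = c(101L, 205L, 390L),
      probe_sequence = c("ACGT", "GGGTNAC", "TTAACC"),
      target_id = c("GENE_A", "GENE_B", "GENE_C"),
      is_control = FALSE
    ),
    controls = tibble::tibble(
      probe_id = c(900L, 901L),
      probe_sequence = c("ACACAC", "GTGTGT"),
      target_id = c("negative_1", "negative_2"),
      is_control = TRUE
    )
  )
  p <- tempfile(fileext = ".bgx")
  write_bgx(man, p)
  got <- read_bgx(p)
  expect_identical(nrow(got$probes), 3L)
  expect_identical(nrow(got$controls), 2L)
  expect_identical(got$probes[c("probe_id", "probe_sequence", "target_id")],
                   man$probes[c("probe_id", "probe_sequence", "target_id")])
  expect_true(all(got$controls$is_control))
  expect_false(any(got$probes$is_control))
})

test_that("an empty [Controls] section yields an empty controls table", {
  p <- tempfile(fileext = ".bgx")
  con <- gzfile(p, "wt")
  writeLines(c(
    "[Heading]", "Array Name\tMini",
    "[Probes]", "Probe_Id\tProbe_Sequence\tTarget_Id", "7\tACGT\tG1",
    "[Controls]", "Probe_Id\tProbe_Sequence\tTarget_Id"
  ), con)
  close(con)
  got <- read_bgx(p)
  expect_identical(nrow(got$controls), 0L)
  expect_identical(got$probes$probe_id, 7L)
})

test_that("section and column names match case-insensitively with aliases", {
  p <- tempfile(fileext = ".bgx")
  con <- gzfile(p, "wt")
  writeLines(c(
    "[heading]", "Array Name\tAliased",
    "[PROBES]", "ProbeID\tSEQUENCE\tILMN_Gene", "11\tACGTN\tFOO", "12\tGGCC\tBAR"
  ), con)
  close(con)
  got <- read_bgx(p)
  expect_identical(got$probes$probe_id, c(11L, 12L))
  expect_identical(got$probes$target_id, c("FOO", "BAR"))
  expect_identical(nrow(got$controls), 0L)
})

test_that("a manifest without [Probes] is malformed; count mismatch only warns", {
  p <- tempfile(fileext = ".bgx")
  con <- gzfile(p, "wt")
  writeLines(c("[Heading]", "Array Name\tBroken"), con)
  close(con)
  expect_error(read_bgx(p), class = "beadio_error_malformed_manifest")

  p2 <- tempfile(fileext = ".bgx")
  con <- gzfile(p2, "wt")
  writeLines(c(
    "[Heading]", "Number of Probes\t99",
    "[Probes]", "Probe_Id\tProbe_Sequence\tTarget_Id", "1\tACGT\tG1"
  ), con)
  close(con)
  expect_warning(got <- read_bgx(p2), class = "beadio_warning_manifest_count")
  expect_identical(nrow(got$probes), 1L)
})

test_that("the BPM-CSV text-export dialect parses to the same record model", {
  p <- tempfile(fileext = ".csv")
  writeLines(c(
    "Probe_Id,Probe_Sequence,Target_Id,Is_Control",
    "5,ACGT,G1,false",
    "9,GGTT,G2,false",
    "44,ACAC,neg,true"
  ), p)
  got <- read_bpm_csv(p)
  expect_s3_class(got, "bead_manifest")
  expect_identical(got$probes$probe_id, c(5L, 9L))
  expect_identical(got$controls$probe_id, 44L)
})

test_that("annotation joins the manifest without touching the intensity side", {
  fx <- tmp_binary_fixture(n_probes = 40, seed = 30)
  ann <- annotate_idat(fx$idat, fx$manifest)
  expect_identical(nrow(ann), 40L)
  expect_identical(ann$mean, fx$idat$mean)
  expect_identical(ann$probe_id, fx$idat$probe_ids)
  expect_identical(attr(ann, "n_unmatched"), 0L)
  # control partition matches the manifest's control set intersected with the idat ids
  expect_identical(
    sort(ann$probe_id[ann$is_control]),
    sort(intersect(fx$manifest$controls$probe_id, fx$idat$probe_ids))
  )
})

test_that("ids missing from the manifest are flagged and retained, not dropped", {
  fx <- generate_binary_idat(fixture_profile("methylation", n_probes = 10, seed = 31))
  man <- fx$manifest
  drop_id <- fx$idat$probe_ids[4]
  man$probes <- man$probes[man$probes$probe_id != drop_id, ]
  man$controls <- man$controls[man$controls$probe_id != drop_id, ]
  ann <- annotate_idat(fx$idat, man)
  expect_identical(nrow(ann), 10L)
  expect_identical(attr(ann, "n_unmatched"), 1L)
  expect_true(is.na(ann$is_control[ann$probe_id == drop_id]))
})

test_that("manifest join partitions intensities into control and non-control", {
  fx <- tmp_binary_fixture(n_probes = 60, seed = 32)
  idat <- read_idat(fx$path)
  ann <- annotate_idat(idat, fx$manifest)
  n_ctrl <- sum(ann$is_control, na.rm = TRUE)
  expect_identical(n_ctrl, nrow(fx$manifest$controls))
  expect_identical(nrow(ann) - n_ctrl, nrow(fx$manifest$probes))
})

test_that("manifest validation catches duplicate ids and non-IUPAC sequences", {
  expect_error(
    bead_manifest(probes = tibble::tibble(
      probe_id = c(1L, 1L), probe_sequence = c("AC", "GT"),
      target_id = c("a", "b"), is_control = FALSE
    )),
    class = "beadio_error_validation"
  )
  expect_error(
    bead_manifest(probes = tibble::tibble(
      probe_id = 1L, probe_sequence = "ACXT", target_id = "a", is_control = FALSE
    )),
    class = "beadio_error_validation"
  )
})
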