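# Deterministic fixture generation.  Every test in the stack runs against
# files written by this module, so the generators are first-class, validated
# code: the profile fixes the study conditions (probe counts, the intensity
# model, control fraction) and the seed makes every byte reproducible.  The
# seed is also recorded inside the file's own metadata, making each fixture
# self-describing.

#' Describe a synthetic BeadArray fixture
#'
#' Parameters for the fixture generators. The defaults emulate a plausible
#' scanned array: log-normal bead-type mean intensities centred near 1000
#' scanner units (`meanlog = log(1000)`, `sdlog = 0.8` — intensities on
#' these arrays span roughly two orders of magnitude), per-probe standard
#' deviations at 10% of the mean, 5–25 beads per bead-type (decoded arrays
#' average roughly 15), and 5% control probes.
#'
#' @param platform `"genotyping"`, `"methylation"` (binary dialect) or
#'   `"expression"` (encrypted-XML dialect).
#' @param n_probes Number of bead-types on the array (0 is a valid
#'   degenerate array).
#' @param seed Integer seed; equal profiles generate byte-identical files.
#' @param meanlog,sdlog Log-normal location/scale of mean intensities.
#' @param sd_fraction Per-probe intensity SD as a fraction of the mean.
#' @param bead_range Integer range (min, max) of beads per bead-type.
#' @param control_fraction Proportion of probes that are controls, in
#'   \[0, 1\].
#' @return A `fixture_profile` object.
#' @export
fixture_profile <- function(platform = c("methylation", "genotyping", "expression"),
                            n_probes = 1000,
                            seed = 1L,
                            meanlog = log(1000),
                            sdlog = 0.8,
                            sd_fraction = 0.1,
                            bead_range = c(5L, 25L),
                            control_fraction = 0.05) {
  platform <- match.arg(platform)
  if (length(n_probes) != 1 || is.na(n_probes) || n_probes < 0) {
    stop_validation("n_probes must be a single non-negative number")
  }
  if (control_fraction < 0 || control_fraction > 1) {
    stop_validation("control_fraction must lie in [0, 1]")
  }
  if (length(bead_range) != 2 || bead_range[1] > bead_range[2] || bead_range[1] < 0) {
    stop_validation("bead_range must be an increasing non-negative pair")
  }
  structure(
    list(
      platform = platform,
      n_probes = as.integer(n_probes),
      seed = as.integer(seed),
      meanlog = meanlog,
      sdlog = sdlog,
      sd_fraction = sd_fraction,
      bead_range = as.integer(bead_range),
      control_fraction = control_fraction
    ),
    class = "fixture_profile"
  )
}

fixture_chip_type <- function(platform) {
  switch(platform,
    methylation = "HumanMethylation450",
    genotyping = "HumanOmni2.5-8",
    expression = "HumanHT-12 v4"
  )
}

fixture_scan_date <- function(seed) {
  base <- as.POSIXct("2012-10-30 13:24:27", tz = "UTC")
  format(base + (seed %% 10000L) * 60, "%m/%d/%Y %I:%M:%S %p")
}

fixture_probe_ids <- function(n) {
  if (n == 0) {
    return(integer(0))
  }
  sort(sample.int(9.9e6, n) + 100000L)
}

fixture_manifest <- function(profile, probe_ids) {
  n <- length(probe_ids)
  n_controls <- round(profile$control_fraction * n)
  control_ids <- if (n_controls > 0) sort(sample(probe_ids, n_controls)) else integer(0)
  is_ctrl <- probe_ids %in% control_ids
  random_seq <- function(k) {
    vapply(seq_len(k), function(.) {
      paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = "")
    }, character(1))
  }
  rec <- tibble::tibble(
    probe_id = probe_ids,
    probe_sequence = random_seq(n),
    target_id = as.character(ifelse(is_ctrl,
      sprintf("negative_control_%04d", cumsum(is_ctrl)),
      sprintf("GENE_%06d", cumsum(!is_ctrl))
    )),
    is_control = is_ctrl
  )
  bead_manifest(
    heading = c(
      "Array Name" = fixture_chip_type(profile$platform),
      "Fixture Seed" = as.character(profile$seed)
    ),
    probes = rec[!rec$is_control, ],
    controls = rec[rec$is_control, ]
  )
}

#' Generate a binary-dialect fixture with its paired manifest
#'
#' Produces a valid [binary_idat()] for a genotyping or methylation profile:
#' sorted unique bead-type IDs, log-normal mean intensities rounded and
#' clipped to the unsigned 16-bit scanner range, `sd = round(sd_fraction *
#' mean)`, uniform bead counts, a processing log containing a `"Scan"` entry
#' with a synthetic timestamp, and a manifest covering every ID with the
#' profile's control fraction. Fully reproducible from the profile seed.
#'
#' @param profile A [fixture_profile()] with a binary platform.
#' @return A list with elements `idat` ([binary_idat()]) and `manifest`
#'   ([bead_manifest()]).
#' @export
generate_binary_idat <- function(profile) {
  if (!inherits(profile, "fixture_profile")) {
    stop_validation("profile must be created by fixture_profile()")
  }
  if (!profile$platform %in% c("genotyping", "methylation")) {
    stop_validation("generate_binary_idat() needs a genotyping or methylation profile")
  }
  withr::with_seed(profile$seed, {
    n <- profile$n_probes
    probe_ids <- fixture_probe_ids(n)
    mean <- pmin(round(stats::rlnorm(n, profile$meanlog, profile$sdlog)), 65535)
    sd <- pmin(round(profile$sd_fraction * mean), 65535)
    n_beads <- if (n > 0) {
      sample(seq(profile$bead_range[1], profile$bead_range[2]), n, replace = TRUE)
    } else {
      integer(0)
    }
    scan_date <- fixture_scan_date(profile$seed)
    run_info <- tibble::tibble(
      run_time = c(scan_date, scan_date, scan_date),
      block_type = c("Decoding", "Scan", "Register"),
      block_pars = c("sherlock=0", sprintf("chip=%s", fixture_chip_type(profile$platform)), ""),
      block_code = c("AutoConvert", "iScan Control Software", "iScan Control Software"),
      code_version = c("1.3.4", "3.3.28", "3.3.28")
    )
    barcode <- paste0("57", paste(sample(0:9, 8, replace = TRUE), collapse = ""))
    position <- sprintf("R%02dC%02d", sample(1:6, 1), sample(1:2, 1))
    idat <- binary_idat(
      probe_ids = probe_ids,
      mean = mean,
      sd = sd,
      n_beads = n_beads,
      barcode = barcode,
      chip_type = fixture_chip_type(profile$platform),
      position = position,
      red_green = 0L,
      mid_block = sample.int(1000L, 5),
      run_info = run_info,
      extra_strings = c(
        "401" = sprintf("fixture-seed=%d", profile$seed),
        "510" = ""
      )
    )
    list(idat = idat, manifest = fixture_manifest(profile, probe_ids))
  })
}

# symmetric trim: drop floor(m * trim) observations from each end of the
# sorted retained beads (matches base mean(x, trim = ) for these sizes)
fixture_trimmed_mean <- function(x, trim = 0.05) {
  m <- length(x)
  if (m == 0) {
    return(NaN)
  }
  k <- floor(m * trim)
  mean(sort(x)[(k + 1):(m - k)])
}

#' Generate an expression-dialect fixture
#'
#' Simulates a per-bead intensity set for every bead-type and summarises it
#' the way the scanner does, so the ten stored vectors are internally
#' consistent rather than independent noise: beads farther than 3 raw
#' median-absolute-deviations from the probe median are excluded as
#' outliers (`n_beads_used` counts the survivors), and `mean`, `sd`,
#' `median` and `trimmed_mean` (symmetric 5% trim) are computed from the
#' retained beads. Background mean/SD are drawn lower than foreground on
#' average. All real-valued vectors are snapped to single precision so the
#' file round trip is bit-exact. The simulated bead sets are attached as
#' attribute `simulated_beads` (`intensities`, `retained`) so tests can
#' recompute every statistic independently.
#'
#' @param profile A [fixture_profile()] with `platform = "expression"`.
#' @return An [expression_idat()] with attribute `simulated_beads`.
#' @export
generate_expression_idat <- function(profile) {
  if (!inherits(profile, "fixture_profile")) {
    stop_validation("profile must be created by fixture_profile()")
  }
  if (profile$platform != "expression") {
    stop_validation("generate_expression_idat() needs an expression profile")
  }
  withr::with_seed(profile$seed, {
    n <- profile$n_probes
    probe_ids <- fixture_probe_ids(n)
    n_beads_raw <- if (n > 0) {
      sample(seq(max(profile$bead_range[1], 2L), profile$bead_range[2]), n, replace = TRUE)
    } else {
      integer(0)
    }
    beads <- lapply(n_beads_raw, function(k) stats::rlnorm(k, profile$meanlog, profile$sdlog))
    retained <- lapply(beads, function(x) {
      dev <- abs(x - stats::median(x))
      cut <- 3 * stats::mad(x, constant = 1)
      if (cut == 0) rep(TRUE, length(x)) else dev <= cut
    })
    kept <- Map(function(x, ok) x[ok], beads, retained)
    stat <- function(f) as_float32(vapply(kept, f, numeric(1)))
    mean_v <- stat(mean)
    sd_v <- stat(function(x) if (length(x) < 2) 0 else stats::sd(x))
    median_v <- stat(stats::median)
    trimmed_v <- stat(fixture_trimmed_mean)
    bg_mean <- as_float32(stats::rlnorm(n, log(80), 0.3))
    bg_sd <- as_float32(bg_mean * stats::runif(n, 0.05, 0.2))
    idat <- expression_idat(
      probe_ids = probe_ids,
      mean = mean_v,
      sd = sd_v,
      median = median_v,
      trimmed_mean = trimmed_v,
      bg_mean = bg_mean,
      bg_sd = bg_sd,
      n_beads_raw = n_beads_raw,
      n_beads_used = vapply(kept, length, integer(1)),
      extra_field = list(CodesBinData = sample(0:2, n, replace = TRUE)),
      metadata = c(
        Barcode = paste0("57", paste(sample(0:9, 8, replace = TRUE), collapse = "")),
        ChipType = fixture_chip_type("expression"),
        ScanDate = fixture_scan_date(profile$seed),
        FixtureSeed = as.character(profile$seed)
      )
    )
    attr(idat, "simulated_beads") <- list(intensities = beads, retained = retained)
    idat
  })
}

#' Write a complete fixture set to disk
#'
#' Convenience wrapper used by tests and the CLI `simulate` subcommand:
#' generates the profile's array, writes the IDAT file in its dialect
#' (optionally also the gzip variant for binary platforms), the paired BGX
#' manifest (binary platforms), and a plain-text truth table (TSV of the
#' per-probe vectors as generated) for comparison tests.
#'
#' @param profile A [fixture_profile()].
#' @param dir Output directory (created if needed).
#' @param key DES key for expression fixtures.
#' @param gzip Also write a gzip-compressed copy of a binary fixture.
#' @return Named list of the paths written, plus the generated objects.
#' @export
write_fixture <- function(profile, dir, key = beadio_fixture_key(), gzip = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, sprintf("%s_seed%d_n%d", profile$platform, profile$seed, profile$n_probes))
  out <- list()
  if (profile$platform == "expression") {
    idat <- generate_expression_idat(profile)
    out$idat <- paste0(stem, ".idat")
    write_encrypted_idat(idat, out$idat, key = key)
    out$object <- idat
  } else {
    fx <- generate_binary_idat(profile)
    out$idat <- paste0(stem, "_Grn.idat")
    write_binary_idat(fx$idat, out$idat)
    if (gzip) {
      out$idat_gz <- paste0(stem, "_Grn.idat.gz")
      write_binary_idat(fx$idat, out$idat_gz, gzip = TRUE)
    }
    out$bgx <- paste0(stem, ".bgx")
    write_bgx(fx$manifest, out$bgx)
    out$object <- fx$idat
    out$manifest <- fx$manifest
  }
  out$truth <- paste0(stem, "_truth.tsv")
  dump_idat(out$object, file = out$truth, format = "tsv")
  out
}

#' Deterministically corrupt a fixture file
#'
#' Produces files that trigger each of the reader error classes, for
#' error-path testing. Modes: `truncate` (drop the final quarter of the
#' file; triggers a corrupt-file error with a byte offset), `flip_magic`
#' (invert the first byte; the binary reader raises not-an-idat, while
#' magic-based auto-dispatch necessarily classifies the file as encrypted
#' XML), `bad_offset` (patch the first directory offset to point beyond the
#' end of a binary file), `bad_base64` (inject an illegal character into a
#' Base64 field of an encrypted fixture; requires the key), and `wrong_pad`
#' (overwrite the final ciphertext block of an encrypted fixture with its
#' first block, which guarantees invalid PKCS#7 padding).
#'
#' @param path A fixture file written by this package; modified in place.
#' @param mode One of `"truncate"`, `"flip_magic"`, `"bad_offset"`,
#'   `"bad_base64"`, `"wrong_pad"`.
#' @param key DES key (only for `bad_base64`).
#' @return `path`, invisibly.
#' @export
corrupt_file <- function(path,
                         mode = c("truncate", "flip_magic", "bad_offset", "bad_base64", "wrong_pad"),
                         key = beadio_fixture_key()) {
  mode <- tryCatch(match.arg(mode), error = function(e) {
    stop_usage(sprintf("unknown corruption mode '%s'", mode[1]))
  })
  bytes <- read_file_raw(path)
  out <- switch(mode,
    truncate = bytes[seq_len(max(4, floor(length(bytes) * 0.75)))],
    flip_magic = {
      bytes[1] <- as.raw(bitwXor(as.integer(bytes[1]), 0xFFL))
      bytes
    },
    bad_offset = {
      if (detect_idat_format(bytes) != "binary") {
        stop_usage("bad_offset applies to binary fixtures")
      }
      # first directory entry: code at bytes 17-18, offset at 19-26
      bytes[19:26] <- w_uint64(length(bytes) + 100)
      bytes
    },
    bad_base64 = {
      txt <- rawToChar(des_decrypt(bytes, key))
      patched <- sub("(<MeanBinData>)[A-Za-z0-9+/=]", "\\1*", txt)
      if (identical(patched, txt)) {
        stop_usage("bad_base64 needs an expression fixture with a MeanBinData field")
      }
      des_encrypt(charToRaw(patched), key)
    },
    wrong_pad = {
      if (length(bytes) < 16 || length(bytes) %% 8 != 0) {
        stop_usage("wrong_pad applies to encrypted fixtures of at least two blocks")
      }
      n <- length(bytes)
      bytes[(n - 7):n] <- bytes[1:8]
      bytes
    }
  )
  writeBin(out, path)
  invisible(path)
}
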