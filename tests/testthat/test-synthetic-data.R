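test_that("spectrum and error-model constructors validate their fields", {
  expect_error(edit_spectrum(indel_rate = 1.2), "indel_rate")
  expect_error(edit_spectrum(deletion_weight = -0.1), "deletion_weight")
  expect_error(edit_spectrum(size_distribution = c(`1` = 0.6, `2` = 0.3)),
               "sum to 1")
  expect_error(edit_spectrum(position_jitter = -1L), "jitter")
  expect_error(error_model(substitution_rate = 0.2), "substitution_rate")
  expect_silent(error_model(substitution_rate = 0))
})

test_that("rate zero yields edit-free reads with only substitution noise", {
  ref <- make_test_ref()
  sim <- simulate_amplicon_reads(ref, 100, edit_spectrum(indel_rate = 0),
                                 error_model(substitution_rate = 0.01),
                                 seed = 3)
  expect_false(any(sim$truth$edited))
  lens <- nchar(sim$reads)
  expect_true(all(lens == nchar(ref$sequence)))  # substitutions only
})

test_that("edited fraction converges to indel_rate with binomial error", {
  ref <- make_test_ref()
  for (rate in c(0.05, 0.2, 0.5)) {
    sim <- simulate_amplicon_reads(ref, 2000,
                                   edit_spectrum(indel_rate = rate),
                                   error_model(), seed = 400L + round(rate * 100),
                                   orientation_mix = 0.5)
    frac <- mean(sim$truth$edited)
    expect_lt(abs(frac - rate), 3 * sqrt(rate * (1 - rate) / 2000))
  }
})

test_that("identical seeds give byte-identical FASTQ; truth matches reads", {
  ref <- make_test_ref()
  spec <- edit_spectrum(indel_rate = 0.4, position_jitter = 4L)
  err <- error_model(substitution_rate = 0)
  sim1 <- simulate_amplicon_reads(ref, 80, spec, err, seed = 9)
  sim2 <- simulate_amplicon_reads(ref, 80, spec, err, seed = 9)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(sim1$reads, f1, sim1$quality_char)
  write_fastq(sim2$reads, f2, sim2$quality_char)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_false(identical(sim1$reads,
                         simulate_amplicon_reads(ref, 80, spec, err,
                                                 seed = 10)$reads))

  # truth consistency, noise off: rebuild each read from its truth record
  refseq <- ref$sequence
  n <- nchar(refseq)
  for (i in seq_along(sim1$reads)) {
    tr <- sim1$truth[i, ]
    emitted <- sim1$reads[[i]]
    if (tr$orientation == "-") emitted <- dna_revcomp(emitted)
    if (!tr$edited) {
      expect_identical(emitted, refseq)
    } else if (tr$edit_type == "deletion") {
      expected <- paste0(substr(refseq, 1, tr$edit_position),
                         substr(refseq, tr$edit_position + tr$edit_length + 1, n))
      expect_identical(emitted, expected)
    } else {
      # insertion bases are random: removing them must restore the reference
      expect_equal(nchar(emitted), n + tr$edit_length)
      stripped <- paste0(substr(emitted, 1, tr$edit_position),
                         substr(emitted, tr$edit_position + tr$edit_length + 1,
                                nchar(emitted)))
      expect_identical(stripped, refseq)
    }
  }
})

test_that("each read appears exactly once in the truth table", {
  ref <- make_test_ref()
  sim <- simulate_amplicon_reads(ref, 50, edit_spectrum(), error_model(),
                                 seed = 21)
  expect_identical(sort(sim$truth$read_id), sort(names(sim$reads)))
  expect_false(any(duplicated(sim$truth$read_id)))
})

test_that("configurations that push edits off the amplicon are rejected", {
  seqc <- strrep("ACGT", 40)  # 160 bp
  ref <- amplicon_ref("edge", seqc, 130L, 153L, "+")  # cut at 148
  expect_error(
    simulate_amplicon_reads(ref, 10, edit_spectrum(position_jitter = 10L),
                            error_model(), seed = 1),
    "outside the amplicon")
  expect_error(simulate_amplicon_reads(make_test_ref(), 10, seed = 1),
               NA)
})

test_that("simulators do not disturb the caller's RNG state", {
  set.seed(123); before <- stats::runif(1)
  set.seed(123)
  invisible(simulate_amplicon_reads(make_test_ref(), 5, seed = 2))
  invisible(simulate_assay_plate(0.2, seed = 2))
  invisible(simulate_pam_panel(pam_weights("TTTV"), n_targets = 2, seed = 2))
  expect_identical(stats::runif(1), before)
})

test_that("assay plates honor disruption, determinism and truncation", {
  p0 <- simulate_assay_plate(0, seed = 5)
  # true_disruption 0: samples and controls share one distribution
  expect_equal(mean(p0$gfp_pct), 95.72, tolerance = 0.05)
  expect_identical(simulate_assay_plate(0.3, seed = 8),
                   simulate_assay_plate(0.3, seed = 8))
  expect_true(all(p0$gfp_pct >= 0 & p0$gfp_pct <= 100))
  expect_error(simulate_assay_plate(1.5, seed = 1), "true_disruption")
})

test_that("PAM panels reproduce weight ratios in the noise-free limit", {
  w <- matrix(0, 4, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  w[, "T"] <- 1
  w[4, ] <- c(1, 2, 1, 6) / 10  # T:C:A:G = 6:2:1:1 at -1
  rec <- simulate_pam_panel(w, n_targets = 3L, noise_sd = 0, seed = 6)
  expect_equal(nrow(rec), 3L * 16L)  # 4 records per varied position

  # only-T weights at a position: all non-T variants are zero
  atpos <- rec[rec$varied_position == -3L, ]
  nonT <- substr(atpos$pam, 2, 2) != "T"
  expect_true(all(atpos$activity[nonT] == 0))
  expect_true(all(atpos$activity[!nonT] > 0))

  pp <- position_preference(rec, -1L)
  expect_equal(unname(pp$ratios[c("T", "C", "A", "G")]),
               c(0.6, 0.2, 0.1, 0.1))
  expect_identical(simulate_pam_panel(w, n_targets = 3L, seed = 6),
                   simulate_pam_panel(w, n_targets = 3L, seed = 6))
})
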