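test_that("cut-site inference follows the PAM-proximal offset convention", {
  seqc <- strrep("ACGT", 60)  # 240 bp
  plus <- amplicon_ref("p", seqc, 100L, 123L, "+")
  expect_equal(plus$cut_site, 118L)
  minus <- amplicon_ref("m", seqc, 100L, 123L, "-")
  expect_equal(minus$cut_site, 105L)
  expect_error(infer_cut_site(plus, cut_offset = 30L), "protospacer length")
})

test_that("call_edits windows calls around the cut site inclusively", {
  ref <- make_test_ref()  # cut site 122
  cut <- ref$cut_site
  refseq <- ref$sequence

  # 3 bp deletion spanning the cut site
  del_read <- paste0(substr(refseq, 1, cut - 1), substr(refseq, cut + 3, 200))
  calls <- call_edits(orient_and_align(del_read, ref), ref)
  expect_equal(nrow(calls), 1L)
  expect_identical(calls$type, "deletion")
  expect_true(calls$in_window)

  # 1 bp insertion at cut_site + 61: outside the closed +/-60 window;
  # inserted base differs from both neighbors so placement is unambiguous
  unambiguous_base <- function(p)
    setdiff(BASES, c(substr(refseq, p, p), substr(refseq, p + 1, p + 1)))[1]
  p <- cut + 61L
  ins_read <- paste0(substr(refseq, 1, p), unambiguous_base(p),
                     substr(refseq, p + 1, 200))
  calls <- call_edits(orient_and_align(ins_read, ref), ref)
  ins <- calls[calls$type == "insertion", , drop = FALSE]
  expect_equal(nrow(ins), 1L)
  expect_false(any(ins$in_window))
  # ...and at exactly cut_site + 60 it is inside
  p <- cut + 60L
  ins_read <- paste0(substr(refseq, 1, p), unambiguous_base(p),
                     substr(refseq, p + 1, 200))
  calls <- call_edits(orient_and_align(ins_read, ref), ref)
  expect_true(any(calls$in_window[calls$type == "insertion"]))

  # two mismatches near the cut, no indel
  chars <- strsplit(refseq, "", fixed = TRUE)[[1]]
  for (q in cut + c(-5L, 5L)) chars[q] <- setdiff(BASES, chars[q])[1]
  calls <- call_edits(orient_and_align(paste(chars, collapse = ""), ref), ref)
  expect_equal(sum(calls$type == "mismatch" & calls$in_window), 2L)
  expect_equal(sum(calls$type %in% c("insertion", "deletion")), 0L)
})

test_that("classify_read counts indels only, never mismatches", {
  mk <- function(type, in_window)
    data.frame(type = type, ref_start = 0L, ref_end = 1L, length = 1L,
               in_window = in_window)
  expect_identical(classify_read(mk("deletion", TRUE)), "edited_indel")
  expect_identical(classify_read(mk("insertion", FALSE)), "unedited")
  expect_identical(
    classify_read(do.call(rbind, rep(list(mk("mismatch", TRUE)), 5))),
    "unedited")
  empty <- data.frame(type = character(0), in_window = logical(0))
  expect_identical(classify_read(empty), "unedited")
})

test_that("quantify_sample counts, excludes and reports per the contract", {
  ref <- make_test_ref()
  refseq <- ref$sequence
  cut <- ref$cut_site
  with_del <- function(at) paste0(substr(refseq, 1, at), substr(refseq, at + 4, 200))
  # 3 in-window indels, 2 out-of-window indels, 5 unedited
  reads <- c(replicate(3, with_del(cut)),
             replicate(2, with_del(cut + 70L)),
             replicate(5, refseq))
  names(reads) <- sprintf("r%02d", seq_along(reads))
  res <- quantify_sample(reads, ref)
  expect_equal(res$total_reads, 10L)
  expect_equal(res$filtered_reads, 10L)
  expect_equal(res$indel_reads, 3L)
  expect_equal(res$indel_frequency, 0.30)
  expect_true(res$excluded)  # 10 < 1000
  expect_false(quantify_sample(reads, ref, min_reads = 10L)$excluded)
})

test_that("anchor-failing reads enter total_reads but are never classified", {
  ref <- make_test_ref()
  # complementing every anchor base guarantees the prefix cannot match
  bad <- paste0(chartr("ACGT", "TGCA", substr(ref$sequence, 1, 20)),
                substr(ref$sequence, 21, 200))
  reads <- c(good = ref$sequence, bad = bad)
  res <- quantify_sample(reads, ref)
  expect_equal(res$total_reads, 2L)
  expect_lte(res$filtered_reads, 2L)
  pr <- res$per_read
  expect_true(all(is.na(pr$class[!pr$anchor_pass])))
})

test_that("frequency is invariant under read order permutation", {
  ref <- make_test_ref()
  sim <- simulate_amplicon_reads(ref, 120, edit_spectrum(indel_rate = 0.3),
                                 error_model(), seed = 5)
  a <- quantify_sample(sim$reads, ref, min_reads = 1L)
  withr::with_seed(2, perm <- sample(length(sim$reads)))
  b <- quantify_sample(sim$reads[perm], ref, min_reads = 1L)
  expect_equal(a$indel_frequency, b$indel_frequency)
  expect_gte(a$indel_frequency, 0)
  expect_lte(a$indel_frequency, 1)
})

test_that("simulated indel rates are recovered within 3 binomial SE", {
  ref <- make_test_ref()
  n <- 600L  # scaled-down version of the acceptance battery (n = 2000)
  for (rate in c(0.05, 0.5)) {
    sim <- simulate_amplicon_reads(
      ref, n, edit_spectrum(indel_rate = rate, position_jitter = 10L),
      error_model(substitution_rate = 0.001), seed = 1000L + round(100 * rate))
    res <- quantify_sample(sim$reads, ref, min_reads = 1L)
    se <- sqrt(rate * (1 - rate) / n)
    expect_lt(abs(res$indel_frequency - rate), 3 * se)
  }
})

test_that("edits far outside the window leave frequency at the noise-off baseline", {
  far <- make_test_ref(len = 260L, protospacer_start = 216L)  # cut at 234
  near <- amplicon_ref("near", far$sequence, 26L, 49L, "+")   # cut at 44
  sim <- simulate_amplicon_reads(far, 150,
                                 edit_spectrum(indel_rate = 0.4, position_jitter = 3L),
                                 error_model(substitution_rate = 0),
                                 seed = 77)
  res <- quantify_sample(sim$reads, near, min_reads = 1L)
  expect_equal(res$indel_frequency, 0)
})
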