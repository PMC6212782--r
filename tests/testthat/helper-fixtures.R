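# shared fixtures and independent oracles for the test suite

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# 200 bp amplicon with a TTTA PAM and a 23-nt protospacer; cut site ~ center
# so the +/-60 bp window fits inside the sequence
make_test_ref <- function(len = 200L, protospacer_start = 104L,
                          cut_offset = 18L, seed = 1234L) {
  withr::with_seed(seed, {
    seqc <- strsplit(random_dna(len), "", fixed = TRUE)[[1]]
    seqc[101:104] <- c("T", "T", "T", "A")  # PAM at [100,104)
    seqc <- paste(seqc, collapse = "")
  })
  amplicon_ref("test_amp", seqc, protospacer_start, protospacer_start + 23L,
               "+", cut_offset = cut_offset)
}

# brute-force semi-global affine DP, written independently of the package's
# C++ core: gap runs are enumerated explicitly, so the affine cost
# open + ext * L is charged per run by construction
oracle_semiglobal_score <- function(read, ref, match = 1, mismatch = 1,
                                    open = 2, ext = 1) {
  r <- strsplit(read, "", fixed = TRUE)[[1]]
  f <- strsplit(ref, "", fixed = TRUE)[[1]]
  m <- length(r); n <- length(f)
  NEG <- -1e9
  best <- matrix(NEG, m + 1L, n + 1L)
  best[1L, ] <- 0  # free leading reference overhang
  for (i in 1:m) {
    for (j in 0:n) {
      v <- NEG
      if (j >= 1L) {
        s <- if (r[i] == f[j] && r[i] != "N") match else -mismatch
        v <- max(v, best[i, j] + s)
      }
      for (L in 1:i)                       # insertion run of length L
        v <- max(v, best[i - L + 1L, j + 1L] - open - ext * L)
      if (j >= 1L) for (L in 1:j)          # deletion run of length L
        v <- max(v, best[i + 1L, j - L + 1L] - open - ext * L)
      best[i + 1L, j + 1L] <- v
    }
  }
  max(best[m + 1L, ])  # free trailing reference overhang
}

# naive window-by-window site scanner, character arithmetic only
naive_scan_sites <- function(sequence, pattern, spacer_len = 23L) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(chars)
  psym <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  plen <- length(psym)
  hits <- list()
  match_at <- function(seq_chars, start) {
    for (k in seq_len(plen)) {
      if (!(seq_chars[start + k - 1L] %in% IUPAC_SETS[[psym[k]]])) return(FALSE)
    }
    spacer <- seq_chars[(start + plen):(start + plen + spacer_len - 1L)]
    !any(spacer == "N")
  }
  for (s in seq_len(n - plen - spacer_len + 1L)) {
    if (match_at(chars, s))
      hits[[length(hits) + 1L]] <- data.frame(
        strand = "+", pam_start = s - 1L, pam_end = s - 1L + plen,
        spacer_start = s - 1L + plen, spacer_end = s - 1L + plen + spacer_len)
  }
  rc <- rev(c(A = "T", C = "G", G = "C", T = "A", N = "N")[chars])
  names(rc) <- NULL
  for (s in seq_len(n - plen - spacer_len + 1L)) {
    if (match_at(rc, s)) {
      pam_end_f <- n - (s - 1L)
      hits[[length(hits) + 1L]] <- data.frame(
        strand = "-", pam_start = pam_end_f - plen, pam_end = pam_end_f,
        spacer_start = pam_end_f - plen - spacer_len,
        spacer_end = pam_end_f - plen)
    }
  }
  if (length(hits) == 0L)
    return(data.frame(strand = character(), pam_start = integer(),
                      pam_end = integer(), spacer_start = integer(),
                      spacer_end = integer()))
  out <- do.call(rbind, hits)
  out <- out[order(out$pam_start, out$strand != "+"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# weight matrices (rows -4..-1, cols A/C/G/T) shaped like the consensus
# patterns used in the recovery tests
pam_weights <- function(shape = c("TTTV", "TWTV", "TTYV")) {
  shape <- match.arg(shape)
  w <- matrix(0.02, 4, 4, dimnames = list(c("-4", "-3", "-2", "-1"), BASES))
  w[1:3, "T"] <- 1
  w[4, c("A", "C", "G")] <- 1 / 3; w[4, "T"] <- 0.002
  if (shape == "TWTV") { w[2, ] <- 0.02; w[2, c("A", "T")] <- 0.5 }
  if (shape == "TTYV") { w[3, ] <- 0.02; w[3, c("C", "T")] <- 0.5 }
  w
}
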