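#' IUPAC degenerate base sets
#'
#' Mapping from IUPAC nucleotide symbols to the sets of concrete bases
#' they stand for (V = A/C/G "all but T", W = A/T, Y = C/T, N = any, ...).
#'
#' @format Named list of character vectors.
#' @export
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# minimal IUPAC symbol for a set of concrete bases
iupac_symbol <- function(bases) {
  bases <- sort(unique(bases))
  for (sym in names(IUPAC_SETS)) {
    if (identical(sort(IUPAC_SETS[[sym]]), bases)) return(sym)
  }
  stop("no IUPAC symbol for base set {", paste(bases, collapse = ","), "}")
}

#' Match a PAM sequence against an IUPAC pattern
#'
#' A 4-nt PAM is written at positions -4..-1, the rightmost symbol (-1)
#' adjacent to the protospacer. The sequence matches when every base lies
#' in the IUPAC set of the corresponding pattern symbol; e.g. `"TTTA"`
#' matches `"TTTV"` but `"TTTT"` does not (V excludes T).
#'
#' @param seq PAM sequence(s), same length as the pattern, alphabet ACGT
#'   (N never matches).
#' @param pattern IUPAC pattern string, length 2-6.
#' @return Logical vector.
#' @export
match_pam <- function(seq, pattern) {
  pattern <- toupper(pattern)
  psym <- strsplit(pattern, "", fixed = TRUE)[[1]]
  if (length(psym) < 2L || length(psym) > 6L)
    stop("pattern length must be 2-6")
  if (!all(psym %in% names(IUPAC_SETS)))
    stop("invalid IUPAC symbol in pattern: ", pattern)
  vapply(toupper(seq), function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    if (length(b) != length(psym))
      stop("sequence length (", length(b), ") does not match pattern length (",
           length(psym), ")")
    all(mapply(function(base, sym) base %in% IUPAC_SETS[[sym]], b, psym))
  }, logical(1), USE.NAMES = FALSE)
}

#' Per-position base-preference ratios from a PAM activity panel
#'
#' For one varied PAM position, each target contributing a complete
#' quartet (all four base variants measured) has its four activities
#' normalized to sum to 1; the per-base ratios are then averaged over
#' targets without weighting, so highly active targets do not dominate.
#' Targets whose quartet is all zero carry no preference information and
#' are dropped (their count is reported).
#'
#' @param records data.frame with columns `target_id`, `pam`, `activity`,
#'   `varied_position` (and optionally `nuclease`).
#' @param position Varied position to profile, one of -4..-1.
#' @return List: `ratios` (named numeric, A/C/G/T, sums to 1),
#'   `n_targets`, `n_dropped`, `position`.
#' @export
position_preference <- function(records, position) {
  position <- as.integer(position)
  if (!position %in% -4:-1) stop("position must be one of -4..-1")
  rec <- records[records$varied_position == position, , drop = FALSE]
  col <- 5L + position   # pam string index 1..4 for positions -4..-1
  base <- substr(rec$pam, col, col)
  ratios_by_target <- list()
  n_dropped <- 0L
  for (tid in unique(rec$target_id)) {
    sub <- rec[rec$target_id == tid, , drop = FALSE]
    b <- base[rec$target_id == tid]
    if (!setequal(b, c("A", "C", "G", "T"))) next  # incomplete quartet
    act <- vapply(c("A", "C", "G", "T"), function(x) mean(sub$activity[b == x]),
                  numeric(1))
    tot <- sum(act)
    if (tot <= 0) { n_dropped <- n_dropped + 1L; next }
    ratios_by_target[[tid]] <- act / tot
  }
  if (length(ratios_by_target) == 0L)
    stop("no complete target quartet at position ", position)
  ratios <- Reduce(`+`, ratios_by_target) / length(ratios_by_target)
  list(ratios = ratios, n_targets = length(ratios_by_target),
       n_dropped = n_dropped, position = position)
}

#' Base-preference matrix over all four PAM positions
#'
#' Runs [position_preference()] at each of positions -4..-1 and assembles
#' a 4x4 matrix of ratios (rows: positions -4..-1; columns A/C/G/T). Each
#' row sums to 1.
#'
#' @inheritParams position_preference
#' @return List of class `"preference_matrix"`: `ratios` (4x4 matrix),
#'   `n_targets` (per position), `normalization` (`"sum"`).
#' @export
preference_matrix <- function(records) {
  pos <- -4:-1
  prefs <- lapply(pos, function(p) position_preference(records, p))
  ratios <- do.call(rbind, lapply(prefs, `[[`, "ratios"))
  rownames(ratios) <- as.character(pos)
  structure(list(ratios = ratios,
                 n_targets = vapply(prefs, `[[`, integer(1), "n_targets"),
                 normalization = "sum"),
            class = "preference_matrix")
}

#' @export
print.preference_matrix <- function(x, ...) {
  cat("PAM base-preference matrix (per-target sum-normalized ratios)\n")
  print(round(x$ratios, 3))
  cat("targets per position:", paste(x$n_targets, collapse = ", "), "\n")
  invisible(x)
}

#' Call an IUPAC consensus PAM from a preference matrix
#'
#' At each position, bases whose preference ratio is at least
#' `include_threshold` form the allowed set, which is written as its
#' minimal IUPAC symbol. The default threshold 0.15 turns a T-dominant
#' position into `T` and a position where A, C and G share the activity
#' with negligible T into `V`; it is a tunable reported with the call, not
#' a biological claim.
#'
#' @param matrix A `"preference_matrix"` or a bare positions-x-bases
#'   numeric matrix with columns A/C/G/T.
#' @param include_threshold Minimum ratio for a base to enter the
#'   consensus set (default 0.15).
#' @return List: `pattern` (IUPAC string, leftmost symbol is position -4),
#'   `threshold`, `allowed` (list of base sets per position).
#' @export
consensus_from_matrix <- function(matrix, include_threshold = 0.15) {
  m <- if (inherits(matrix, "preference_matrix")) matrix$ratios else matrix
  stopifnot(is.matrix(m), ncol(m) == 4L)
  colnames(m) <- toupper(colnames(m))
  allowed <- apply(m, 1L, function(row) {
    keep <- colnames(m)[row >= include_threshold]
    if (length(keep) == 0L)
      stop("no base reaches the inclusion threshold at one position")
    keep
  }, simplify = FALSE)
  pattern <- paste(vapply(allowed, iupac_symbol, character(1)), collapse = "")
  list(pattern = pattern, threshold = include_threshold, allowed = allowed)
}

#' Enumerate candidate Cas12a target sites in a sequence
#'
#' Scans both strands of a DNA sequence for PAM matches with a full-length
#' protospacer immediately 3' of the PAM on the same strand. Coordinates
#' are reported 0-based half-open on the forward axis with a strand flag,
#' sorted by PAM start then strand (`+` first). Windows containing `N`
#' never match.
#'
#' @param sequence DNA string (A/C/G/T/N).
#' @param pattern IUPAC PAM pattern (rightmost symbol is protospacer-
#'   proximal).
#' @param spacer_len Protospacer length in bp (default 23).
#' @return data.frame: `strand`, `pam_start`, `pam_end`, `spacer_start`,
#'   `spacer_end`.
#' @export
enumerate_target_sites <- function(sequence, pattern, spacer_len = 23L) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) stop("sequence must be over A/C/G/T/N")
  spacer_len <- as.integer(spacer_len)
  plen <- nchar(pattern)
  n <- nchar(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]

  scan_strand <- function(seq_chars) {
    # returns PAM start offsets (0-based, on the scanned strand's axis)
    nn <- length(seq_chars)
    hits <- integer(0)
    last <- nn - plen - spacer_len
    if (last < 0L) return(hits)
    psym <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
    ok <- rep(TRUE, last + 1L)
    for (k in seq_len(plen)) {
      window <- seq_chars[(k):(k + last)]
      ok <- ok & window %in% IUPAC_SETS[[psym[k]]]
    }
    # require spacer bases free of N
    for (k in (plen + 1L):(plen + spacer_len)) {
      window <- seq_chars[(k):(k + last)]
      ok <- ok & window != "N"
    }
    which(ok) - 1L
  }

  fwd <- scan_strand(chars)
  rev_chars <- rev(strsplit(chartr("ACGTN", "TGCAN", sequence), "",
                            fixed = TRUE)[[1]])
  rev <- scan_strand(rev_chars)

  out <- data.frame(strand = character(0), pam_start = integer(0),
                    pam_end = integer(0), spacer_start = integer(0),
                    spacer_end = integer(0), stringsAsFactors = FALSE)
  if (length(fwd))
    out <- rbind(out, data.frame(
      strand = "+", pam_start = fwd, pam_end = fwd + plen,
      spacer_start = fwd + plen, spacer_end = fwd + plen + spacer_len,
      stringsAsFactors = FALSE))
  if (length(rev)) {
    # map reverse-axis offset p to forward coordinates
    pam_end_f <- n - rev
    pam_start_f <- pam_end_f - plen
    out <- rbind(out, data.frame(
      strand = "-", pam_start = pam_start_f, pam_end = pam_end_f,
      spacer_start = pam_start_f - spacer_len, spacer_end = pam_start_f,
      stringsAsFactors = FALSE))
  }
  out <- out[order(out$pam_start, out$strand != "+"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write target sites as BED6
#'
#' One BED record per site spanning PAM plus protospacer, 0-based
#' half-open, with the strand column set.
#'
#' @param sites data.frame from [enumerate_target_sites()].
#' @param path Output path.
#' @param seqname Chromosome/sequence name for column 1.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path, seqname = "seq") {
  start <- pmin(sites$pam_start, sites$spacer_start)
  end <- pmax(sites$pam_end, sites$spacer_end)
  bed <- data.frame(seqname, start, end,
                    name = sprintf("site_%04d", seq_len(nrow(sites))),
                    score = 0L, strand = sites$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
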