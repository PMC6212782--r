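#' Alignment scoring parameters
#'
#' Affine-gap scoring used by [semiglobal_align()]. A run of L gapped bases
#' costs `gap_open + gap_extend * L`; matches add `match_score`, mismatches
#' subtract `mismatch_penalty`. `N` bases never match (always scored as a
#' mismatch).
#'
#' @param match_score Positive integer reward per matching base.
#' @param mismatch_penalty,gap_open_penalty,gap_extend_penalty Non-negative
#'   integer costs.
#' @return A list of class `"align_params"`.
#' @export
align_params <- function(match_score = 1L, mismatch_penalty = 1L,
                         gap_open_penalty = 2L, gap_extend_penalty = 1L) {
  p <- lapply(list(match_score = match_score,
                   mismatch_penalty = mismatch_penalty,
                   gap_open_penalty = gap_open_penalty,
                   gap_extend_penalty = gap_extend_penalty), as.integer)
  if (p$match_score <= 0L) stop("match_score must be > 0")
  if (any(unlist(p[-1]) < 0L)) stop("penalties must be >= 0")
  structure(p, class = "align_params")
}

op_levels <- c("match", "mismatch", "insertion", "deletion")

#' Semi-global pairwise alignment of a read against a reference
#'
#' Aligns the full read within a (possibly longer) reference: reference
#' overhangs on either side are free, internal gaps and gaps in the read
#' are charged under the affine scheme of [align_params()]. Traceback is
#' deterministic: at equal score a diagonal step is preferred over a
#' deletion, a deletion over an insertion, and among equal-scoring end
#' positions the leftmost reference span wins.
#'
#' @param read,ref Non-empty DNA strings over A/C/G/T/N.
#' @param params An [align_params()] object.
#' @param read_id Optional identifier stored in the result.
#' @return An object of class `"alignment_result"`: list with `read_id`,
#'   `orientation` (`NA` here; set by [orient_and_align()]), `score`, `ops`
#'   (data.frame of `op`, `length`, `ref_pos` -- 0-based; inter-base for
#'   insertions, run start for the others), and `ref_span` (0-based
#'   half-open integer vector of length 2).
#' @examples
#' aln <- semiglobal_align("ACGT", "TTACGTTT", align_params())
#' aln$score      # 4
#' aln$ref_span   # c(2, 6)
#' @export
semiglobal_align <- function(read, ref, params = align_params(),
                             read_id = NA_character_) {
  stopifnot(inherits(params, "align_params"))
  read <- toupper(read); ref <- toupper(ref)
  if (!nzchar(read) || !nzchar(ref)) stop("empty sequence")
  if (grepl("[^ACGTN]", read) || grepl("[^ACGTN]", ref))
    stop("sequences must be over A/C/G/T/N")
  res <- .semiglobal_core(read, ref,
                          params$match_score, params$mismatch_penalty,
                          params$gap_open_penalty, params$gap_extend_penalty)
  ops <- merge_op_runs(res$op, res$ref_pos)
  ref_consuming <- ops$op %in% c("match", "mismatch", "deletion")
  if (any(ref_consuming)) {
    span <- c(min(ops$ref_pos[ref_consuming]),
              max(ops$ref_pos[ref_consuming] + ops$length[ref_consuming] - 1L) + 1L)
  } else {
    span <- c(ops$ref_pos[1], ops$ref_pos[1])  # pure-insertion alignment
  }
  structure(list(read_id = read_id, orientation = NA_character_,
                 score = res$score, ops = ops,
                 ref_span = as.integer(span)),
            class = "alignment_result")
}

# collapse per-base op codes (1 match, 2 mismatch, 3 ins, 4 del) into runs;
# ref_pos of a run is its first reference position (inter-base for insertions)
merge_op_runs <- function(code, ref_pos) {
  stopifnot(length(code) == length(ref_pos))
  r <- rle(code)
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  data.frame(op = op_levels[r$values],
             length = r$lengths,
             ref_pos = ref_pos[starts],
             stringsAsFactors = FALSE)
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("Alignment%s: score %d, orientation %s, ref span [%d,%d) (0-based)\n",
              if (is.na(x$read_id)) "" else paste0(" of ", x$read_id),
              x$score, ifelse(is.na(x$orientation), "?", x$orientation),
              x$ref_span[1], x$ref_span[2]))
  print(x$ops)
  invisible(x)
}

#' Align a read in both orientations and keep the better one
#'
#' Aligns the read and its reverse complement against the amplicon and
#' returns the higher-scoring alignment with the orientation recorded. On
#' an exact score tie the forward orientation wins.
#'
#' @param read DNA string.
#' @param ref An [amplicon_ref()] object (or plain reference string).
#' @param params An [align_params()] object.
#' @param read_id Optional identifier.
#' @return An `"alignment_result"` with `orientation` set to `"+"` or `"-"`.
#'   Coordinates are always on the forward reference axis.
#' @export
orient_and_align <- function(read, ref, params = align_params(),
                             read_id = NA_character_) {
  refseq <- if (inherits(ref, "amplicon_ref")) ref$sequence else ref
  fwd <- semiglobal_align(read, refseq, params, read_id)
  rev <- semiglobal_align(dna_revcomp(read), refseq, params, read_id)
  if (rev$score > fwd$score) {
    rev$orientation <- "-"
    rev
  } else {
    fwd$orientation <- "+"
    fwd
  }
}

#' Anchor identity of an alignment over the reference start
#'
#' Fraction of the first `anchor_len` reference positions that are aligned
#' as exact matches. Reference anchor positions that are mismatched,
#' deleted, or not covered by the alignment at all count as non-matching.
#' Evaluated after orientation selection, so reverse-orientation reads are
#' handled naturally. A read passes at identity >= `threshold` (the
#' boundary is inclusive: 15/20 passes at 0.75).
#'
#' @param aln An `"alignment_result"`.
#' @param ref An [amplicon_ref()] object (used only for bounds checking);
#'   may be `NULL`.
#' @param anchor_len Anchor width in bp (default 20).
#' @param threshold Pass threshold on the identity fraction (default 0.75).
#' @return List with `identity` (fraction) and `pass` (logical).
#' @export
anchor_identity <- function(aln, ref = NULL, anchor_len = 20L,
                            threshold = 0.75) {
  stopifnot(inherits(aln, "alignment_result"))
  anchor_len <- as.integer(anchor_len)
  if (!is.null(ref)) {
    refseq <- if (inherits(ref, "amplicon_ref")) ref$sequence else ref
    if (anchor_len > nchar(refseq))
      stop("anchor_len exceeds reference length")
  }
  ops <- aln$ops
  m <- ops$op == "match"
  matched <- 0L
  if (any(m)) {
    lo <- ops$ref_pos[m]
    hi <- lo + ops$length[m]             # half-open run intervals
    ov <- pmin(hi, anchor_len) - pmax(lo, 0L)
    matched <- sum(pmax(ov, 0L))
  }
  identity <- matched / anchor_len
  list(identity = identity, pass = identity >= threshold)
}
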