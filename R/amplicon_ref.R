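#' Reference amplicon with annotated protospacer and PAM
#'
#' Bundles an amplicon sequence with the coordinates of the protospacer
#' targeted by a Cas12a crRNA, the 4-nt PAM abutting its PAM-proximal end,
#' and the derived cut-site coordinate. All coordinates are 0-based
#' half-open internally; printed reports are 1-based inclusive.
#'
#' On the `+` strand the PAM lies immediately 5' of the protospacer
#' (interval `[protospacer_start - pam_len, protospacer_start)`); on the
#' `-` strand it lies immediately 3' on the forward axis
#' (`[protospacer_end, protospacer_end + pam_len)`).
#'
#' @param name Identifier for the amplicon.
#' @param sequence DNA string (alphabet A/C/G/T/N).
#' @param protospacer_start,protospacer_end 0-based half-open protospacer
#'   interval on the forward strand.
#' @param site_strand `"+"` or `"-"`: strand carrying the PAM+protospacer.
#' @param pam_len PAM length in nucleotides (2-4, default 4).
#' @param cut_offset Protospacer position (from the PAM-proximal end) after
#'   which the cut-site coordinate is placed; see [infer_cut_site()].
#' @return An object of class `"amplicon_ref"`: a list with fields `name`,
#'   `sequence`, `protospacer_start`, `protospacer_end`, `site_strand`,
#'   `pam`, `pam_start`, `pam_end`, `cut_site`.
#' @examples
#' seqc <- paste(rep("ACGT", 60), collapse = "")
#' ref <- amplicon_ref("amp1", seqc, 100, 123, "+")
#' ref$cut_site
#' @export
amplicon_ref <- function(name, sequence, protospacer_start, protospacer_end,
                         site_strand = c("+", "-"), pam_len = 4L,
                         cut_offset = 18L) {
  site_strand <- match.arg(site_strand)
  sequence <- toupper(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0L)
  if (grepl("[^ACGTN]", sequence))
    stop("amplicon sequence contains characters outside A/C/G/T/N")
  n <- nchar(sequence)
  protospacer_start <- as.integer(protospacer_start)
  protospacer_end <- as.integer(protospacer_end)
  pam_len <- as.integer(pam_len)
  if (pam_len < 2L || pam_len > 4L) stop("pam_len must be 2-4 nt")
  if (protospacer_start < 0L || protospacer_end > n ||
      protospacer_start >= protospacer_end)
    stop("protospacer interval out of bounds")
  if (site_strand == "+") {
    pam_start <- protospacer_start - pam_len
    pam_end <- protospacer_start
  } else {
    pam_start <- protospacer_end
    pam_end <- protospacer_end + pam_len
  }
  if (pam_start < 0L || pam_end > n)
    stop("PAM interval falls outside the amplicon")
  pam_fwd <- substr(sequence, pam_start + 1L, pam_end)
  pam <- if (site_strand == "+") pam_fwd else dna_revcomp(pam_fwd)
  ref <- structure(list(
    name = name, sequence = sequence,
    protospacer_start = protospacer_start,
    protospacer_end = protospacer_end,
    site_strand = site_strand,
    pam = pam, pam_start = pam_start, pam_end = pam_end,
    cut_site = NA_integer_
  ), class = "amplicon_ref")
  ref$cut_site <- infer_cut_site(ref, cut_offset = cut_offset)
  ref
}

#' Derive the cut-site coordinate from the protospacer annotation
#'
#' Cas12a cleaves distal to its PAM, producing staggered cuts with 5'
#' overhangs (around protospacer positions 18/23 on the two strands). The
#' cut site used to center the edit-search window is placed after
#' `cut_offset` protospacer bases counted from the PAM-proximal end, on the
#' annotated strand, and returned as a 0-based inter-base coordinate on the
#' forward axis. The default 18 is the PAM-distal end of the midpoint
#' convention; the surrounding +/-60 bp search window makes downstream
#' counts insensitive to a few bp of convention.
#'
#' @param site An [amplicon_ref()] object.
#' @param cut_offset Integer number of protospacer bases between the
#'   PAM-proximal end and the cut (default 18).
#' @return Integer inter-base coordinate (0-based) on the forward strand.
#' @export
infer_cut_site <- function(site, cut_offset = 18L) {
  stopifnot(inherits(site, "amplicon_ref"))
  cut_offset <- as.integer(cut_offset)
  len <- site$protospacer_end - site$protospacer_start
  if (cut_offset < 0L || cut_offset > len)
    stop("cut_offset (", cut_offset, ") exceeds protospacer length (", len, ")")
  if (site$site_strand == "+")
    site$protospacer_start + cut_offset
  else
    site$protospacer_end - cut_offset
}

#' @export
print.amplicon_ref <- function(x, ...) {
  cat("Amplicon reference '", x$name, "' (", nchar(x$sequence), " bp)\n",
      sep = "")
  cat(sprintf("  protospacer: %d-%d (1-based inclusive), strand %s\n",
              x$protospacer_start + 1L, x$protospacer_end, x$site_strand))
  cat(sprintf("  PAM: %s at %d-%d; cut site after base %d\n",
              x$pam, x$pam_start + 1L, x$pam_end, x$cut_site))
  invisible(x)
}

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA strings (A/C/G/T/N, case-insensitive).
#' @return Character vector of reverse complements (upper case).
#' @export
dna_revcomp <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGTNacgtn", "TGCANtgcan", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Read a single-record FASTA file as an amplicon reference
#'
#' @param path FASTA file with one amplicon sequence.
#' @param protospacer_start,protospacer_end,site_strand,pam_len,cut_offset
#'   Annotation, as in [amplicon_ref()].
#' @return An [amplicon_ref()] object.
#' @export
read_amplicon_fasta <- function(path, protospacer_start, protospacer_end,
                                site_strand = "+", pam_len = 4L,
                                cut_offset = 18L) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) < 1L) stop("no sequence in FASTA file: ", path)
  amplicon_ref(names(ss)[1], as.character(ss[[1]]),
               protospacer_start, protospacer_end, site_strand,
               pam_len = pam_len, cut_offset = cut_offset)
}
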