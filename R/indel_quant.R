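#' Call edits from an alignment, flagging those inside the cut-site window
#'
#' Every insertion, deletion or mismatch run in the alignment becomes one
#' edit call. A call is in-window when its reference position (inter-base
#' coordinate for insertions) or interval intersects the closed interval
#' `[cut_site - window_halfwidth, cut_site + window_halfwidth]`.
#'
#' @param aln An `"alignment_result"` from [orient_and_align()].
#' @param ref An [amplicon_ref()] carrying the cut-site coordinate.
#' @param window_halfwidth Half-width of the search window in bp
#'   (default 60).
#' @return data.frame with columns `type` (insertion/deletion/mismatch),
#'   `ref_start`, `ref_end` (0-based half-open; equal for insertions),
#'   `length`, `in_window`.
#' @export
call_edits <- function(aln, ref, window_halfwidth = 60L) {
  stopifnot(inherits(aln, "alignment_result"), inherits(ref, "amplicon_ref"))
  cut <- ref$cut_site
  lo <- cut - as.integer(window_halfwidth)
  hi <- cut + as.integer(window_halfwidth)
  ops <- aln$ops[aln$ops$op != "match", , drop = FALSE]
  if (nrow(ops) == 0L)
    return(data.frame(type = character(), ref_start = integer(),
                      ref_end = integer(), length = integer(),
                      in_window = logical(), stringsAsFactors = FALSE))
  is_ins <- ops$op == "insertion"
  ref_start <- ops$ref_pos
  ref_end <- ifelse(is_ins, ops$ref_pos, ops$ref_pos + ops$length)
  # insertions live at an inter-base coordinate p, in-window iff lo<=p<=hi;
  # interval calls intersect [lo,hi] iff start<=hi and end-1>=lo
  in_window <- ifelse(is_ins,
                      ref_start >= lo & ref_start <= hi,
                      ref_start <= hi & (ref_end - 1L) >= lo)
  data.frame(type = ops$op, ref_start = ref_start, ref_end = ref_end,
             length = ops$length, in_window = in_window,
             stringsAsFactors = FALSE)
}

#' Classify a read from its edit calls
#'
#' A read is `"edited_indel"` when it carries at least one in-window
#' insertion or deletion. Mismatches alone -- however many -- never
#' classify a read as edited; indel frequency counts reads with an indel.
#'
#' @param calls data.frame from [call_edits()] for one read.
#' @return `"edited_indel"` or `"unedited"`.
#' @export
classify_read <- function(calls) {
  hit <- calls$in_window & calls$type %in% c("insertion", "deletion")
  if (any(hit)) "edited_indel" else "unedited"
}

#' Quantify indel frequency for one amplicon sample
#'
#' Runs the full per-sample pipeline: orient and align every read, apply
#' the anchor-identity filter (at least `anchor_threshold` identity over
#' the first `anchor_len` bp of the reference), call edits within the
#' +/- `window_halfwidth` bp window around the cut site, classify reads,
#' and report the indel frequency. The frequency denominator is the number
#' of anchor-passing reads (counting was performed among reads that passed
#' the anchor filter); the all-read total is reported alongside so the
#' other convention can be recomputed. Samples with fewer than
#' `min_reads` total reads are flagged `excluded`.
#'
#' @param reads Named character vector of read sequences, or the path to a
#'   FASTQ file.
#' @param ref An [amplicon_ref()].
#' @param params An [align_params()].
#' @param window_halfwidth,anchor_len,anchor_threshold,min_reads Pipeline
#'   thresholds; defaults 60 bp, 20 bp, 0.75, 1000 reads.
#' @return An object of class `"sample_indel_result"`: list with
#'   `total_reads`, `filtered_reads`, `indel_reads`, `indel_frequency`
#'   (NA with `frequency_reason` when no read passes the filter),
#'   `excluded`, `min_reads_threshold`, and `per_read` (data.frame of
#'   read_id, orientation, score, anchor_identity, anchor_pass, class).
#' @export
quantify_sample <- function(reads, ref, params = align_params(),
                            window_halfwidth = 60L, anchor_len = 20L,
                            anchor_threshold = 0.75, min_reads = 1000L) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fastq(reads)
  if (length(reads) == 0L) stop("empty read set")
  if (is.null(names(reads)))
    names(reads) <- sprintf("read_%06d", seq_along(reads))
  ids <- names(reads)

  n <- length(reads)
  orientation <- character(n); score <- integer(n)
  anchor_id <- numeric(n); anchor_pass <- logical(n)
  klass <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    aln <- orient_and_align(reads[[i]], ref, params, read_id = ids[i])
    orientation[i] <- aln$orientation
    score[i] <- aln$score
    a <- anchor_identity(aln, ref, anchor_len, anchor_threshold)
    anchor_id[i] <- a$identity
    anchor_pass[i] <- a$pass
    if (a$pass) {
      calls <- call_edits(aln, ref, window_halfwidth)
      klass[i] <- classify_read(calls)
    }
  }

  filtered <- sum(anchor_pass)
  indels <- sum(klass == "edited_indel", na.rm = TRUE)
  freq <- if (filtered > 0L) indels / filtered else NA_real_
  structure(list(
    total_reads = n,
    filtered_reads = filtered,
    indel_reads = indels,
    indel_frequency = freq,
    frequency_reason = if (filtered == 0L) "no reads passed the anchor filter" else NA_character_,
    excluded = n < as.integer(min_reads),
    min_reads_threshold = as.integer(min_reads),
    per_read = data.frame(read_id = ids, orientation = orientation,
                          score = score, anchor_identity = anchor_id,
                          anchor_pass = anchor_pass, class = klass,
                          stringsAsFactors = FALSE)
  ), class = "sample_indel_result")
}

#' @export
print.sample_indel_result <- function(x, ...) {
  cat(sprintf(
    "Sample indel result: %d reads (%d pass anchor filter), %d with in-window indel\n",
    x$total_reads, x$filtered_reads, x$indel_reads))
  cat(sprintf("  indel frequency (over filtered reads): %s\n",
              ifelse(is.na(x$indel_frequency), paste0("NA (", x$frequency_reason, ")"),
                     sprintf("%.4f", x$indel_frequency))))
  if (x$excluded)
    cat(sprintf("  EXCLUDED: fewer than %d total reads\n", x$min_reads_threshold))
  invisible(x)
}

#' Write a per-sample indel quantification report as TSV
#'
#' Emits one summary row; the header comments name the coordinate
#' convention and the frequency denominator so either convention can be
#' recomputed.
#'
#' @param result A `"sample_indel_result"`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_result <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# per-sample indel quantification; coordinates 1-based inclusive in reports",
    "# indel_frequency = indel_reads / filtered_reads (anchor-passing denominator)"),
    con)
  df <- data.frame(total_reads = result$total_reads,
                   filtered_reads = result$filtered_reads,
                   indel_reads = result$indel_reads,
                   indel_frequency = result$indel_frequency,
                   excluded = result$excluded,
                   min_reads_threshold = result$min_reads_threshold)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
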