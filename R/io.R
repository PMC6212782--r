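#' Read a FASTQ file into a named character vector
#'
#' Qualities are ignored downstream (the pipeline is quality-unaware), so
#' only sequences and identifiers are returned.
#'
#' @param path FASTQ file path (4-line records, Sanger encoding).
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write reads as FASTQ with a constant quality symbol
#'
#' @param reads Named character vector of read sequences.
#' @param path Output path.
#' @param quality_char Single Sanger-encoded quality character applied to
#'   every base (default `"I"`, Q40).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  if (is.null(names(reads))) stop("reads must be named")
  dss <- Biostrings::DNAStringSet(reads)
  qual <- Biostrings::BStringSet(strrep(quality_char, nchar(reads)))
  Biostrings::writeXStringSet(dss, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Write a simulation truth table as TSV
#'
#' @param truth data.frame from [simulate_amplicon_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an activity-record table from TSV
#'
#' Expects columns `target_id`, `pam`, `activity`, `varied_position`
#' (plus optional `nuclease`).
#'
#' @param path TSV file path.
#' @return data.frame of activity records.
#' @export
read_activity_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("target_id", "pam", "activity", "varied_position")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("activity table missing columns: ", paste(miss, collapse = ", "))
  tab
}
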