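#' Edit spectrum for the amplicon read simulator
#'
#' Describes the population of editing outcomes injected into simulated
#' reads: what fraction of reads carry an edit, the deletion/insertion
#' split, the indel length distribution, and how far from the cut site an
#' edit may be placed. The default length distribution is geometric-like
#' over 1-20 bp -- a placeholder typical of NHEJ outcome spectra, not a
#' claim about any particular dataset.
#'
#' @param indel_rate Fraction of reads carrying an edit, in \[0,1\].
#' @param deletion_weight Fraction of edits that are deletions, in \[0,1\].
#' @param size_distribution Named numeric vector mapping indel length (bp,
#'   >= 1) to probability; must sum to 1 (tolerance 1e-9).
#' @param position_jitter Integer half-width (bp) of the uniform placement
#'   offset around the cut site; >= 0.
#' @return List of class `"edit_spectrum"`.
#' @export
edit_spectrum <- function(indel_rate = 0.2, deletion_weight = 0.7,
                          size_distribution = NULL, position_jitter = 5L) {
  if (is.null(size_distribution)) {
    p <- 0.5 ^ (1:20)
    size_distribution <- stats::setNames(p / sum(p), 1:20)
  }
  if (indel_rate < 0 || indel_rate > 1) stop("indel_rate must be in [0,1]")
  if (deletion_weight < 0 || deletion_weight > 1)
    stop("deletion_weight must be in [0,1]")
  if (abs(sum(size_distribution) - 1) > 1e-9)
    stop("size_distribution probabilities must sum to 1")
  sizes <- as.integer(names(size_distribution))
  if (any(is.na(sizes)) || any(sizes < 1L))
    stop("size_distribution lengths must be integers >= 1")
  if (position_jitter < 0L) stop("position_jitter must be >= 0")
  structure(list(indel_rate = indel_rate, deletion_weight = deletion_weight,
                 size_distribution = size_distribution,
                 position_jitter = as.integer(position_jitter)),
            class = "edit_spectrum")
}

#' Sequencing error model for simulated reads
#'
#' @param substitution_rate Per-base substitution probability, in
#'   \[0, 0.1\].
#' @param quality_char Constant quality symbol (Sanger encoding) written
#'   for every base.
#' @return List of class `"error_model"`.
#' @export
error_model <- function(substitution_rate = 0.001, quality_char = "I") {
  if (substitution_rate < 0 || substitution_rate > 0.1)
    stop("substitution_rate must be in [0, 0.1]")
  if (nchar(quality_char) != 1L) stop("quality_char must be one character")
  structure(list(substitution_rate = substitution_rate,
                 quality_char = quality_char), class = "error_model")
}

apply_substitutions <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    alt <- setdiff(c("A", "C", "G", "T"), chars[i])
    chars[i] <- alt[sample.int(3L, 1L)]
  }
  paste(chars, collapse = "")
}

random_bases <- function(n) {
  paste(c("A", "C", "G", "T")[sample.int(4L, n, replace = TRUE)],
        collapse = "")
}

#' Simulate edited amplicon reads with known ground truth
#'
#' Emits `n_reads` full-length copies of the amplicon. A seeded fraction
#' (`spectrum$indel_rate`) carries exactly one indel whose reference
#' placement is the cut site plus a uniform offset within
#' +/- `spectrum$position_jitter` bp; deletions remove reference bases
#' starting at that coordinate, insertions add random bases at it.
#' Per-base substitution noise is applied afterwards, and a seeded
#' fraction `orientation_mix` of reads is emitted reverse-complemented.
#' The truth table records, per read, whether it was edited, the edit
#' type, length, reference position, and orientation.
#'
#' @param ref An [amplicon_ref()] with a valid cut site.
#' @param n_reads Positive integer.
#' @param spectrum An [edit_spectrum()].
#' @param errors An [error_model()].
#' @param orientation_mix Fraction of reads emitted in reverse orientation
#'   (default 0.5).
#' @param seed Integer seed; required, so no implicit RNG state leaks in.
#' @return List with `reads` (named character vector), `quality_char`,
#'   and `truth` (data.frame: read_id, edited, edit_type, edit_length,
#'   edit_position, orientation).
#' @export
simulate_amplicon_reads <- function(ref, n_reads, spectrum = edit_spectrum(),
                                    errors = error_model(),
                                    orientation_mix = 0.5, seed) {
  stopifnot(inherits(ref, "amplicon_ref"), inherits(spectrum, "edit_spectrum"),
            inherits(errors, "error_model"))
  if (missing(seed)) stop("seed must be supplied explicitly")
  n_reads <- as.integer(n_reads)
  if (n_reads <= 0L) stop("n_reads must be positive")
  refseq <- ref$sequence
  reflen <- nchar(refseq)
  cut <- ref$cut_site
  jit <- spectrum$position_jitter
  max_del <- max(as.integer(names(spectrum$size_distribution)))
  if (cut - jit < 0L || cut + jit + max_del > reflen)
    stop("position_jitter/edit sizes would place edits outside the amplicon; ",
         "reduce position_jitter or the maximum indel length")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  ids <- sprintf("read_%06d", seq_len(n_reads))
  edited <- stats::runif(n_reads) < spectrum$indel_rate
  is_del <- stats::runif(n_reads) < spectrum$deletion_weight
  sizes <- as.integer(names(spectrum$size_distribution))
  len <- sizes[sample.int(length(sizes), n_reads, replace = TRUE,
                          prob = spectrum$size_distribution)]
  offset <- if (jit > 0L) sample.int(2L * jit + 1L, n_reads, replace = TRUE) - jit - 1L
            else integer(n_reads)
  pos <- cut + offset
  reverse <- stats::runif(n_reads) < orientation_mix

  reads <- character(n_reads)
  for (i in seq_len(n_reads)) {
    s <- refseq
    if (edited[i]) {
      if (is_del[i]) {
        s <- paste0(substr(s, 1L, pos[i]), substr(s, pos[i] + len[i] + 1L, reflen))
      } else {
        s <- paste0(substr(s, 1L, pos[i]), random_bases(len[i]),
                    substr(s, pos[i] + 1L, reflen))
      }
    }
    s <- apply_substitutions(s, errors$substitution_rate)
    if (reverse[i]) s <- dna_revcomp(s)
    reads[i] <- s
  }
  names(reads) <- ids

  truth <- data.frame(
    read_id = ids,
    edited = edited,
    edit_type = ifelse(edited, ifelse(is_del, "deletion", "insertion"),
                       NA_character_),
    edit_length = ifelse(edited, len, NA_integer_),
    edit_position = ifelse(edited, pos, NA_integer_),
    orientation = ifelse(reverse, "-", "+"),
    stringsAsFactors = FALSE
  )
  list(reads = reads, quality_char = errors$quality_char, truth = truth)
}

# save/restore global RNG state so seeded simulators do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate a reporter-assay plate
#'
#' Control wells draw GFP% from Normal(`control_gfp_mean`,
#' `control_gfp_sd`) truncated to \[0,100\]; sample wells draw from the
#' same distribution scaled so their expected GFP% is
#' `control_gfp_mean * (1 - true_disruption)`. The mCherry% column is
#' filled with a typical transfection readout (Normal(30, 3), truncated).
#'
#' @param true_disruption True disruption fraction in \[0,1\].
#' @param control_gfp_mean,control_gfp_sd Control-well GFP% mean and sd
#'   (defaults 95.72 and 1.13, a typical negative-control summary for a
#'   GFP-disruption line).
#' @param n_replicates Wells per role (default 3).
#' @param seed Integer seed (required).
#' @return Assay data.frame (see [assay_calc]) with conditions
#'   `"sample"` and `"control"`.
#' @export
simulate_assay_plate <- function(true_disruption, control_gfp_mean = 95.72,
                                 control_gfp_sd = 1.13, n_replicates = 3L,
                                 seed) {
  if (missing(seed)) stop("seed must be supplied explicitly")
  if (true_disruption < 0 || true_disruption > 1)
    stop("true_disruption must be in [0,1]")
  if (control_gfp_sd <= 0) stop("control_gfp_sd must be > 0")
  n_replicates <- as.integer(n_replicates)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  trunc01 <- function(x) pmin(pmax(x, 0), 100)
  ctrl <- trunc01(stats::rnorm(n_replicates, control_gfp_mean, control_gfp_sd))
  smp <- trunc01(stats::rnorm(n_replicates,
                              control_gfp_mean * (1 - true_disruption),
                              control_gfp_sd))
  mch <- trunc01(stats::rnorm(2L * n_replicates, 30, 3))
  data.frame(
    condition = rep(c("sample", "control"), each = n_replicates),
    replicate = rep(seq_len(n_replicates), 2L),
    gfp_pct = c(smp, ctrl),
    mcherry_pct = mch,
    role = rep(c("sample", "negative_control"), each = n_replicates),
    day = 1L,
    stringsAsFactors = FALSE
  )
}

#' Simulate a PAM-variation activity panel
#'
#' Emulates panels in which one PAM position at a time is varied through
#' all four bases across a set of targets. Each target gets a
#' target-specific activity scale (log-normal with sd
#' `target_effect_sd`), modeling the strong target dependence of absolute
#' editing activity; each record's activity is
#' `scale * base_weight * exp(noise)` with multiplicative log-normal
#' noise of sd `noise_sd`.
#'
#' @param base_weights 4x4 non-negative matrix: rows are PAM positions
#'   -4..-1, columns A/C/G/T; each row needs at least one positive entry.
#' @param n_targets Number of simulated targets (default 12).
#' @param target_effect_sd Log-scale sd of the per-target activity scale.
#' @param noise_sd Log-scale sd of per-record multiplicative noise.
#' @param nuclease Label stored in the records.
#' @param seed Integer seed (required).
#' @return data.frame of activity records: `target_id`, `nuclease`,
#'   `pam`, `activity`, `varied_position`.
#' @export
simulate_pam_panel <- function(base_weights, n_targets = 12L,
                               target_effect_sd = 0.5, noise_sd = 0.1,
                               nuclease = "Cas12a", seed) {
  if (missing(seed)) stop("seed must be supplied explicitly")
  stopifnot(is.matrix(base_weights), nrow(base_weights) == 4L,
            ncol(base_weights) == 4L)
  if (any(base_weights < 0)) stop("base_weights must be non-negative")
  if (any(apply(base_weights, 1L, max) <= 0))
    stop("each PAM position needs at least one positive weight")
  colnames(base_weights) <- c("A", "C", "G", "T")
  if (target_effect_sd <= 0 || noise_sd < 0)
    stop("target_effect_sd must be > 0 and noise_sd >= 0")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  bases <- c("A", "C", "G", "T")
  # backbone PAM: the top-weight base at every position
  backbone <- bases[apply(base_weights, 1L, which.max)]
  scales <- exp(stats::rnorm(n_targets, 0, target_effect_sd))
  rows <- vector("list", n_targets * 16L)
  k <- 0L
  for (t in seq_len(n_targets)) {
    for (p in 1:4) {
      for (b in bases) {
        pam <- backbone
        pam[p] <- b
        noise <- if (noise_sd > 0) exp(stats::rnorm(1L, 0, noise_sd)) else 1
        k <- k + 1L
        rows[[k]] <- data.frame(
          target_id = sprintf("target_%02d", t),
          nuclease = nuclease,
          pam = paste(pam, collapse = ""),
          activity = scales[t] * base_weights[p, b] * noise,
          varied_position = p - 5L,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
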