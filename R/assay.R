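#' Reporter-assay arithmetic
#'
#' These functions implement the flow-cytometry reporter calculations:
#' GFxFP activity with background subtraction inside the mCherry+
#' (transfected) gate, the two GFP-disruption variants (ratio and
#' subtractive), and HDR knock-in normalization for transfection
#' efficiency. Assay tables are plain data.frames with columns
#' `condition`, `replicate`, `gfp_pct`, `mcherry_pct`, `role`
#' (`"sample"` or `"negative_control"`), and optionally `day`.
#'
#' @name assay_calc
NULL

check_assay_table <- function(table) {
  need <- c("condition", "replicate", "gfp_pct", "role")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("assay table missing columns: ", paste(miss, collapse = ", "))
  if (any(table$gfp_pct < 0 | table$gfp_pct > 100, na.rm = TRUE))
    stop("gfp_pct values must lie in [0,100]")
  invisible(table)
}

#' GFxFP activity: background-subtracted GFP% within the transfected gate
#'
#' In the GFxFP assay, nuclease cleavage between homologous GFP fragments
#' restores GFP expression; the GFP% values are already gated on mCherry+
#' (transfected) cells. The background -- estimated from crRNA-less,
#' catalytically dead negative-control wells -- is subtracted from every
#' sample well, then replicate mean and sd are reported per condition.
#' Negative activities are reported as-is unless `clamp_zero = TRUE`, so
#' replicate means stay unbiased.
#'
#' @param table Assay data.frame (see [assay_calc]).
#' @param clamp_zero Clamp negative background-subtracted values to 0?
#' @return data.frame: `condition`, `n`, `mean_activity`, `sd_activity`.
#' @examples
#' tab <- data.frame(condition = c("g1", "g1", "nc", "nc", "nc"),
#'                   replicate = c(1, 2, 1, 2, 3),
#'                   gfp_pct = c(12, 12, 1.0, 1.2, 0.8),
#'                   role = c("sample", "sample", rep("negative_control", 3)))
#' gfxfp_activity(tab)  # activity 11.0
#' @export
gfxfp_activity <- function(table, clamp_zero = FALSE) {
  check_assay_table(table)
  ctrl <- table$gfp_pct[table$role == "negative_control"]
  if (length(ctrl) == 0L) stop("no negative_control rows in assay table")
  bg <- mean(ctrl)
  smp <- table[table$role == "sample", , drop = FALSE]
  act <- smp$gfp_pct - bg
  if (clamp_zero) act <- pmax(act, 0)
  agg <- split(act, smp$condition)
  out <- data.frame(
    condition = names(agg),
    n = vapply(agg, length, integer(1)),
    mean_activity = vapply(agg, mean, numeric(1)),
    sd_activity = vapply(agg, stats::sd, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' GFP disruption, ratio variant
#'
#' `1 - sample_gfp / control_mean`: the fraction of GFP signal lost
#' relative to the negative-control average, the readout of indel
#' formation in a GFP-integrated cell line.
#'
#' @param sample_gfp Sample GFP% (vectorized).
#' @param control_mean Average GFP% of negative controls; must be > 0.
#' @return Disruption as a fraction (1 = complete loss of GFP).
#' @export
gfp_disruption_ratio <- function(sample_gfp, control_mean) {
  if (!is.numeric(control_mean) || control_mean <= 0)
    stop("control_mean must be > 0")
  1 - sample_gfp / control_mean
}

#' GFP disruption, subtractive variant
#'
#' `control_mean - sample_gfp`, in percentage points. Values beyond the
#' control mean come out negative and are reported unclamped.
#'
#' @inheritParams gfp_disruption_ratio
#' @return Disruption in percentage points.
#' @export
gfp_disruption_subtractive <- function(sample_gfp, control_mean) {
  control_mean - sample_gfp
}

#' HDR activity normalized for transfection efficiency
#'
#' Knock-in (HDR) GFP% measured at day 14 is background-corrected with the
#' matched day-14 negative control, then rescaled by day-2 transient GFP
#' fluorescence, which tracks transfection efficiency:
#' `HDR = (day14_sample - day14_control) * (day2_reference / day2_condition)`
#' with the plate-wide day-2 mean as the reference, so a condition
#' transfected at half the plate mean has its HDR doubled.
#'
#' @param day14_table Assay table of day-14 sample wells.
#' @param day2_table Assay table of day-2 wells (transfection readout);
#'   values must be > 0.
#' @param controls Assay table of day-14 negative-control wells with
#'   condition labels matching `day14_table`.
#' @return data.frame: `condition`, `hdr_pct` (normalized),
#'   `hdr_raw_pct` (background-corrected, unnormalized), `day2_factor`.
#' @export
hdr_activity <- function(day14_table, day2_table, controls) {
  check_assay_table(day14_table)
  check_assay_table(controls)
  if (!all(c("condition", "gfp_pct") %in% names(day2_table)))
    stop("day2_table needs condition and gfp_pct columns")
  smp <- day14_table[day14_table$role == "sample", , drop = FALSE]
  conds <- unique(smp$condition)
  day2_mean <- vapply(conds, function(cc) {
    v <- day2_table$gfp_pct[day2_table$condition == cc]
    if (length(v) == 0L) stop("no day-2 row for condition '", cc, "'")
    mean(v)
  }, numeric(1))
  if (any(day2_mean <= 0)) stop("day-2 GFP values must be > 0")
  reference <- mean(day2_mean)
  out <- do.call(rbind, lapply(conds, function(cc) {
    cv <- controls$gfp_pct[controls$condition == cc &
                             controls$role == "negative_control"]
    if (length(cv) == 0L) stop("no matched control for condition '", cc, "'")
    raw <- mean(smp$gfp_pct[smp$condition == cc]) - mean(cv)
    fac <- reference / day2_mean[[cc]]
    data.frame(condition = cc, hdr_pct = raw * fac, hdr_raw_pct = raw,
               day2_factor = fac, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Tukey notched-boxplot statistics
#'
#' Summary statistics matching the notched-boxplot convention used to
#' display replicate assay values: box limits at the hinges computed as
#' medians of the lower and upper halves of the sorted data (the overall
#' median is excluded from both halves when n is odd, so `1:7` gives
#' hinges 2 and 6), whiskers at the most extreme data points within 1.5
#' interquartile ranges of the hinges, and notches at
#' `median +/- 1.58 * IQR / sqrt(n)` -- an approximate 95% confidence
#' interval for the median.
#'
#' @param values Numeric vector, length >= 1.
#' @return List of class `"summary_stats"`: `n`, `mean`, `sd`, `median`,
#'   `q1`, `q3`, `whisker_lo`, `whisker_hi`, `notch_lo`, `notch_hi`.
#' @examples
#' boxplot_stats(1:7)  # median 4, hinges 2 and 6
#' @export
boxplot_stats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("empty input")
  n <- length(values)
  sorted <- sort(values)
  med <- stats::median(sorted)
  half <- n %/% 2L                      # halves exclude the median for odd n
  if (half == 0L) {
    q1 <- q3 <- med
  } else {
    q1 <- stats::median(sorted[seq_len(half)])
    q3 <- stats::median(sorted[seq.int(n - half + 1L, n)])
  }
  iqr <- q3 - q1
  lo_fence <- q1 - 1.5 * iqr
  hi_fence <- q3 + 1.5 * iqr
  inside <- values[values >= lo_fence & values <= hi_fence]
  notch <- 1.58 * iqr / sqrt(n)
  structure(list(
    n = n, mean = mean(values), sd = if (n > 1) stats::sd(values) else NA_real_,
    median = med, q1 = q1, q3 = q3,
    whisker_lo = min(inside), whisker_hi = max(inside),
    notch_lo = med - notch, notch_hi = med + notch
  ), class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("n=%d mean=%.4g sd=%.4g\n", x$n, x$mean, x$sd))
  cat(sprintf("hinges [%.4g, %.4g], median %.4g, whiskers [%.4g, %.4g], notch [%.4g, %.4g]\n",
              x$q1, x$q3, x$median, x$whisker_lo, x$whisker_hi,
              x$notch_lo, x$notch_hi))
  invisible(x)
}

#' Read an assay table from CSV
#'
#' Expects a header with at least `condition, replicate, gfp_pct, role`
#' (plus optional `mcherry_pct`, `day`).
#'
#' @param path CSV file path.
#' @return Validated assay data.frame.
#' @export
read_assay_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  check_assay_table(tab)
  tab
}
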