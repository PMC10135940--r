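# Signal conditioning and quality screening.
#
# Stage order is fixed: band-pass filtering of the PPG, fixed-window
# segmentation of PPG and ABP at identical offsets, reference extraction
# and quality screening, then per-segment normalization and derivative
# channels. ABP windows are never filtered or normalized - the labels must
# stay in mmHg.

#' Cut a record into fixed-length windows
#'
#' Slides a `window_s`-second window over the record at `stride_s`-second
#' steps (defaults: non-overlapping 3-s windows). PPG and ABP are cut at
#' identical offsets; a trailing partial window is discarded. A record
#' shorter than one window yields an empty table, not an error.
#'
#' @param record A `bp_record` (PPG should already be filtered when used in
#'   the full pipeline).
#' @param window_s,stride_s Window length and stride in seconds;
#'   `window_s * fs` must be within 0.5 of an integer.
#' @return A tibble with columns `record_id`, `start_index` (0-based sample
#'   offset), `ppg` and `abp` list-columns of `round(window_s * fs)` samples.
#' @export
segment_record <- function(record, window_s = 3, stride_s = 3) {
  fs <- record$fs
  win_real <- window_s * fs
  win <- round(win_real)
  if (abs(win_real - win) > 0.5)
    abort_field("window_s", "window_s * fs must be within 0.5 of an integer")
  if (stride_s <= 0) abort_field("stride_s", "must be > 0")
  n <- length(record$ppg)
  rid <- record$meta$record_id %||% "rec"
  starts <- integer(0)
  k <- 0
  repeat {
    s0 <- round(k * stride_s * fs)
    if (s0 + win > n) break
    starts <- c(starts, s0)
    k <- k + 1
  }
  tibble::tibble(
    record_id = rep(rid, length(starts)),
    start_index = as.integer(starts),
    ppg = lapply(starts, function(s) record$ppg[(s + 1):(s + win)]),
    abp = lapply(starts, function(s) record$abp[(s + 1):(s + win)])
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract reference SBP/DBP from an ABP window
#'
#' Detects per-beat systolic maxima and diastolic minima by peak picking
#' (minimum peak separation `60 / hr_max` seconds, amplitude-gated so the
#' dicrotic wave is not counted as a beat) and returns the means of the
#' detected extrema. When fewer than two beats are detected the global
#' max/min of the window is used. A flat window (range < 1 mmHg) returns
#' `NA` references - a quality failure, not an exception.
#'
#' @param abp_window Numeric ABP samples, mmHg (unfiltered).
#' @param fs Sampling rate, Hz.
#' @param hr_max Upper physiologic heart rate bound (bpm) setting the
#'   minimum peak distance.
#' @return Named numeric `c(sbp =, dbp =)`, `NA` for a flat window.
#' @export
extract_bp_reference <- function(abp_window, fs, hr_max = 180) {
  rng <- range(abp_window)
  if (diff(rng) < 1) return(c(sbp = NA_real_, dbp = NA_real_))
  dmin <- max(1L, floor(fs * 60 / hr_max))
  mid_hi <- rng[1] + 0.6 * diff(rng)
  mid_lo <- rng[1] + 0.4 * diff(rng)
  pk <- pracma::findpeaks(abp_window, minpeakdistance = dmin,
                          minpeakheight = mid_hi)
  tr <- pracma::findpeaks(-abp_window, minpeakdistance = dmin,
                          minpeakheight = -mid_lo)
  # beats clipped at the window edges leave local extrema well short of the
  # true per-beat values; trim detections far from the median before
  # averaging (within one window, beat-to-beat BP varies by far less)
  trim <- function(v) {
    if (length(v) >= 3) v[v >= stats::median(v) - 0.25 * diff(rng)] else v
  }
  sbp <- if (!is.null(pk) && nrow(pk) >= 2) mean(trim(pk[, 1])) else rng[2]
  dbp <- if (!is.null(tr) && nrow(tr) >= 2) mean(-trim(tr[, 1])) else rng[1]
  if (sbp <= dbp) {
    sbp <- rng[2]
    dbp <- rng[1]
  }
  c(sbp = sbp, dbp = dbp)
}

#' Skewness quality index
#'
#' Population-moment skewness of a segment,
#' `mean(((x - mean(x)) / sd_pop(x))^3)` with the divide-by-N standard
#' deviation. Positive skewness is characteristic of clean PPG pulses
#' (sharp systolic upstrokes above a flat diastolic baseline); negative
#' skewness flags inverted or corrupted segments. Degenerate (constant)
#' segments return `NA`, which auto-fails screening.
#'
#' @param x Numeric segment (length >= 3).
#' @return Dimensionless skewness, or `NA` for a constant segment.
#' @export
ppg_skewness <- function(x) {
  if (length(x) < 3) abort_field("x", "needs at least 3 samples")
  mu <- mean(x)
  s2 <- mean((x - mu)^2)
  if (s2 <= 0) return(NA_real_)
  mean(((x - mu) / sqrt(s2))^3)
}

#' Autocorrelation signal-quality index
#'
#' Maximum normalized (Pearson, mean-removed) autocorrelation of the window
#' over the physiologic heart-rate lag range
#' `[fs * 60 / hr_max, fs * 60 / hr_min]`. A quasi-periodic pulse train
#' correlates strongly with itself one beat later (values near 1); damaged
#' or noise-dominated windows fall below the screening threshold.
#'
#' @param x Numeric segment.
#' @param fs Sampling rate, Hz.
#' @param hr_range Heart-rate search range `(min, max)` in bpm.
#' @return Value in \[-1, 1\], or `NA` for a zero-variance window.
#' @export
ac_sqi <- function(x, fs, hr_range = c(30, 150)) {
  n <- length(x)
  if (stats::var(x) == 0) return(NA_real_)
  lag_min <- max(1L, floor(fs * 60 / hr_range[2]))
  lag_max <- min(ceiling(fs * 60 / hr_range[1]), n - 10L)
  if (lag_max < lag_min) abort_field("x", "window too short for the lag range")
  best <- -1
  for (l in lag_min:lag_max) {
    a <- x[1:(n - l)]
    b <- x[(l + 1):n]
    ma <- mean(a); mb <- mean(b)
    va <- sum((a - ma)^2); vb <- sum((b - mb)^2)
    if (va <= 0 || vb <= 0) next
    r <- sum((a - ma) * (b - mb)) / sqrt(va * vb)
    if (r > best) best <- r
  }
  best
}

#' Annotate segments with quality indices and screening outcomes
#'
#' Computes per-segment reference pressures (if absent), the skewness and
#' autocorrelation quality indices on the PPG window, and applies the
#' screening rules. A segment is kept iff `sbp_ref <= sbp_max` and
#' `dbp_ref >= dbp_min` and `skewness >= skew_min` and
#' `ac_sqi >= ac_threshold`; every rule outcome is recorded so exclusion
#' counts reconcile.
#'
#' @param segments Tibble from [segment_record()] (possibly row-bound over
#'   records).
#' @param fs Sampling rate, Hz.
#' @param sbp_max,dbp_min Blood-pressure plausibility range, mmHg.
#' @param skew_min Minimum skewness (default 0).
#' @param ac_threshold Minimum autocorrelation quality (default 0.6).
#' @param hr_range Heart-rate range for the autocorrelation lag search, bpm.
#' @return The input tibble with added columns `sbp_ref`, `dbp_ref`,
#'   `skewness`, `ac_sqi`, `bp_in_range`, `passed`, `fail_reasons`
#'   (list-column of rule names among `"bp_range"`, `"skewness"`,
#'   `"autocorrelation"`, `"degenerate"`).
#' @export
screen_segments <- function(segments, fs = 125, sbp_max = 180, dbp_min = 50,
                            skew_min = 0, ac_threshold = 0.6,
                            hr_range = c(30, 150)) {
  if (nrow(segments) == 0) {
    return(dplyr::mutate(segments, sbp_ref = numeric(0), dbp_ref = numeric(0),
                         skewness = numeric(0), ac_sqi = numeric(0),
                         bp_in_range = logical(0), passed = logical(0),
                         fail_reasons = list()))
  }
  if (!all(c("sbp_ref", "dbp_ref") %in% names(segments))) {
    refs <- t(vapply(segments$abp, extract_bp_reference, numeric(2), fs = fs))
    segments$sbp_ref <- refs[, 1]
    segments$dbp_ref <- refs[, 2]
  }
  segments$skewness <- vapply(segments$ppg, ppg_skewness, numeric(1))
  segments$ac_sqi <- vapply(segments$ppg, ac_sqi, numeric(1),
                            fs = fs, hr_range = hr_range)
  segments$bp_in_range <- !is.na(segments$sbp_ref) & !is.na(segments$dbp_ref) &
    segments$sbp_ref <= sbp_max & segments$dbp_ref >= dbp_min
  segments$fail_reasons <- purrr::pmap(
    list(segments$bp_in_range, segments$skewness, segments$ac_sqi),
    function(bp_ok, sk, ac) {
      reasons <- character(0)
      if (!bp_ok) reasons <- c(reasons, "bp_range")
      if (is.na(sk) || is.na(ac)) reasons <- c(reasons, "degenerate")
      if (!is.na(sk) && sk < skew_min) reasons <- c(reasons, "skewness")
      if (!is.na(ac) && ac < ac_threshold) reasons <- c(reasons, "autocorrelation")
      reasons
    })
  segments$passed <- lengths(segments$fail_reasons) == 0
  segments
}

#' Split screened segments into kept segments and quality reports
#'
#' @param segments Tibble of segments; screened with [screen_segments()]
#'   first if the quality columns are absent.
#' @param ... Passed to [screen_segments()] when screening is still needed.
#' @return A list with `kept` (passing rows) and `reports` (per-segment
#'   quality report tibble covering every input row).
#' @export
quality_filter <- function(segments, ...) {
  if (!"passed" %in% names(segments)) segments <- screen_segments(segments, ...)
  reports <- segments[, intersect(
    c("record_id", "start_index", "sbp_ref", "dbp_ref", "skewness", "ac_sqi",
      "bp_in_range", "passed", "fail_reasons"), names(segments))]
  list(kept = segments[segments$passed, , drop = FALSE], reports = reports)
}

#' Min-max normalization to \[0, 1\]
#'
#' @param x Numeric vector with `max(x) > min(x)`.
#' @return `(x - min(x)) / (max(x) - min(x))`.
#' @export
minmax_normalize <- function(x) {
  rng <- range(x)
  if (rng[2] <= rng[1])
    stop("degenerate segment: constant input cannot be min-max normalized",
         call. = FALSE)
  (x - rng[1]) / (rng[2] - rng[1])
}

# First difference padded back to the input length by repeating the final
# difference, so derivative channels keep the segment length.
pad_diff <- function(x) {
  d <- diff(x)
  c(d, d[length(d)])
}

#' Build one network input from a screened segment
#'
#' Channel 0 is the min-max normalized PPG window; the velocity (VPG) and
#' acceleration (APG) channels are the first and second padded differences,
#' each independently min-max normalized so every channel lies in \[0, 1\].
#' Labels stay in mmHg.
#'
#' @param seg A one-row tibble or list with `ppg` (or `ppg_window`),
#'   `sbp_ref`, `dbp_ref`.
#' @return A list with `channels` (3 x L matrix, rows PPG/VPG/APG) and
#'   `labels` (`c(sbp, dbp)` in mmHg).
#' @export
make_model_input <- function(seg) {
  ppg <- seg$ppg %||% seg$ppg_window
  if (is.list(ppg)) ppg <- ppg[[1]]
  ch0 <- minmax_normalize(ppg)
  vpg <- pad_diff(ch0)
  apg <- pad_diff(vpg)
  near_const <- function(x) diff(range(x)) <= 1e-10 * max(abs(x), 1e-12)
  if (near_const(vpg) || near_const(apg))
    stop("degenerate segment: constant derivative channel", call. = FALSE)
  channels <- rbind(ch0, minmax_normalize(vpg), minmax_normalize(apg))
  rownames(channels) <- c("ppg", "vpg", "apg")
  list(channels = channels,
       labels = c(sbp = as.numeric(seg$sbp_ref), dbp = as.numeric(seg$dbp_ref)))
}

#' Assemble kept segments into a training array
#'
#' @param segments Tibble of kept (passing) segments.
#' @return A list of class `bp_dataset`: `inputs` (3 x L x N array),
#'   `labels` (N x 2 matrix, columns `sbp`, `dbp` in mmHg), `meta`
#'   (tibble of `record_id`, `start_index`), `stages` (provenance trail).
#' @export
build_model_inputs <- function(segments) {
  n <- nrow(segments)
  if (n == 0) stop("no segments to assemble", call. = FALSE)
  len <- length(segments$ppg[[1]])
  inputs <- array(0, dim = c(3, len, n))
  labels <- matrix(0, n, 2, dimnames = list(NULL, c("sbp", "dbp")))
  for (i in seq_len(n)) {
    mi <- make_model_input(segments[i, ])
    inputs[, , i] <- mi$channels
    labels[i, ] <- mi$labels
  }
  structure(list(inputs = inputs, labels = labels,
                 meta = segments[, c("record_id", "start_index")],
                 stages = c(attr(segments, "stages") %||% character(0),
                            "normalized")),
            class = "bp_dataset")
}

#' Run the full conditioning pipeline over raw records
#'
#' Filters each record's PPG (ABP is left raw), segments both channels at
#' identical offsets, extracts per-window reference pressures, and screens
#' segment quality. Stage order is fixed:
#' filter, segment, screen, normalize (the last applied by
#' [build_model_inputs()]).
#'
#' @param records List of `bp_record` objects.
#' @param spec A [filter_spec()].
#' @param window_s,stride_s Segmentation geometry, seconds.
#' @param ... Screening thresholds passed to [screen_segments()].
#' @return Screened segment tibble (all rows, `passed` marking keepers) with
#'   a `"counts"` attribute (totals and exclusive per-rule failure counts)
#'   and a `"stages"` provenance attribute.
#' @export
preprocess_records <- function(records, spec = filter_spec(),
                               window_s = 3, stride_s = 3, ...) {
  if (inherits(records, "bp_record")) records <- list(records)
  fs <- records[[1]]$fs
  segs <- purrr::map_dfr(records, function(rec) {
    rec$ppg <- bandpass_filter(rec$ppg, rec$fs, spec)
    rec$meta$stages <- c(rec$meta$stages, "filtered")
    segment_record(rec, window_s = window_s, stride_s = stride_s)
  })
  segs <- screen_segments(segs, fs = fs, ...)
  fails <- unlist(segs$fail_reasons)
  counts <- list(
    n_segments = nrow(segs),
    n_kept = sum(segs$passed),
    n_excluded = sum(!segs$passed),
    rule_failures = as.list(table(factor(
      fails, levels = c("bp_range", "skewness", "autocorrelation", "degenerate")))),
    exclusive_failures = as.list(table(factor(
      unlist(lapply(segs$fail_reasons[!segs$passed], `[`, 1)),
      levels = c("bp_range", "skewness", "autocorrelation", "degenerate"))))
  )
  attr(segs, "counts") <- counts
  attr(segs, "stages") <- c("filtered", "segmented", "screened")
  segs
}

#' Write a processed dataset as text artifacts
#'
#' `inputs.csv` holds one row per segment (channels concatenated
#' PPG | VPG | APG), `labels.csv` the mmHg labels with segment identity, and
#' `screening.json` the rule-by-rule exclusion counts.
#'
#' @param dataset A `bp_dataset` from [build_model_inputs()].
#' @param dir Output directory (created if needed).
#' @param counts Optional `"counts"` attribute from [preprocess_records()].
#' @return `dir`, invisibly.
#' @export
write_dataset_csv <- function(dataset, dir, counts = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(dataset$inputs)[3]
  len <- dim(dataset$inputs)[2]
  flat <- t(vapply(seq_len(n), function(i) as.vector(t(dataset$inputs[, , i])),
                   numeric(3 * len)))
  utils::write.csv(flat, file.path(dir, "inputs.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(record_id = dataset$meta$record_id,
               start_index = dataset$meta$start_index,
               sbp = dataset$labels[, "sbp"], dbp = dataset$labels[, "dbp"]),
    file.path(dir, "labels.csv"), row.names = FALSE)
  if (!is.null(counts))
    jsonlite::write_json(counts, file.path(dir, "screening.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset_csv
#' @param dir Directory written by `write_dataset_csv()`.
#' @export
read_dataset_csv <- function(dir) {
  flat <- as.matrix(utils::read.csv(file.path(dir, "inputs.csv")))
  lab <- utils::read.csv(file.path(dir, "labels.csv"))
  n <- nrow(flat)
  len <- ncol(flat) / 3
  inputs <- array(0, dim = c(3, len, n))
  for (i in seq_len(n)) inputs[, , i] <- matrix(flat[i, ], 3, len, byrow = TRUE)
  structure(list(
    inputs = inputs,
    labels = cbind(sbp = lab$sbp, dbp = lab$dbp),
    meta = tibble::tibble(record_id = lab$record_id,
                          start_index = lab$start_index),
    stages = c("filtered", "segmented", "screened", "normalized")),
    class = "bp_dataset")
}
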