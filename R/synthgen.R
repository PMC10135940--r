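# Synthetic paired PPG/ABP generator.
#
# Each cardiac cycle is a sum of Gaussian lobes: a systolic peak plus a
# dicrotic lobe. Blood pressure is coupled into the pulse *morphology*
# (systolic width shrinks with SBP; dicrotic timing and width grow with DBP)
# rather than into absolute amplitude, because downstream min-max
# normalization destroys amplitude. The ABP channel is the same pulse train
# affinely mapped so that every beat's maximum equals the target SBP and its
# minimum the target DBP.

#' Simulator configuration
#'
#' Parameters of one synthetic subject record. Defaults describe a clean but
#' realistic recording: modest baseline drift (respiration-like, 0.1 Hz),
#' weak powerline interference at 50 Hz (above the PPG pass-band), broadband
#' sensor noise at 5% of the unit pulse amplitude, and ±3% beat-to-beat
#' period jitter so the autocorrelation quality index is exercised below 1.
#'
#' @param duration_s Record length in seconds.
#' @param fs Sampling rate in Hz.
#' @param hr_bpm Heart rate, beats per minute (30-180).
#' @param sbp,dbp Target systolic / diastolic pressure, mmHg (`sbp > dbp > 0`).
#' @param drift_amp,drift_freq Baseline-drift amplitude (a.u.) and frequency (Hz).
#' @param powerline_amp,powerline_freq Powerline interference amplitude (a.u.)
#'   and frequency (Hz).
#' @param noise_sd Standard deviation of additive white noise (a.u.).
#' @param dicrotic_strength Relative amplitude of the dicrotic lobe, in \[0, 1\].
#' @param jitter Uniform half-width of the beat-to-beat period multiplier
#'   (0.03 = ±3%).
#' @param sbp_drift,dbp_drift Optional linear change of the per-beat SBP/DBP
#'   target across the record, mmHg (first beat to last beat).
#' @param seed Integer seed; `(cfg, seed)` fully determines the output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(duration_s = 30, fs = 125, hr_bpm = 75,
                       sbp = 120, dbp = 80,
                       drift_amp = 0.2, drift_freq = 0.1,
                       powerline_amp = 0.05, powerline_freq = 50,
                       noise_sd = 0.05, dicrotic_strength = 0.5,
                       jitter = 0.03, sbp_drift = 0, dbp_drift = 0,
                       seed = 1L) {
  check_number(fs, "fs", min = 0, strict_min = TRUE)
  check_number(duration_s, "duration_s", min = 0, strict_min = TRUE)
  check_number(hr_bpm, "hr_bpm", min = 30, max = 180)
  check_number(sbp, "sbp", min = 0, strict_min = TRUE)
  check_number(dbp, "dbp", min = 0, strict_min = TRUE)
  if (sbp <= dbp) abort_field("sbp", "must satisfy sbp > dbp")
  check_number(drift_amp, "drift_amp", min = 0)
  check_number(powerline_amp, "powerline_amp", min = 0)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(dicrotic_strength, "dicrotic_strength", min = 0, max = 1)
  check_number(jitter, "jitter", min = 0, max = 0.2)
  check_number(seed, "seed")
  structure(list(
    duration_s = duration_s, fs = fs, hr_bpm = hr_bpm, sbp = sbp, dbp = dbp,
    drift_amp = drift_amp, drift_freq = drift_freq,
    powerline_amp = powerline_amp, powerline_freq = powerline_freq,
    noise_sd = noise_sd, dicrotic_strength = dicrotic_strength,
    jitter = jitter, sbp_drift = sbp_drift, dbp_drift = dbp_drift,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Morphology parameters coupled to blood pressure
#'
#' Maps an (SBP, DBP) pair to the pulse-template parameters, all in seconds:
#' systolic lobe width `s1` (strictly decreasing in SBP, i.e. sharper peaks
#' at higher systolic pressure), dicrotic delay `d` and dicrotic lobe width
#' `s2` (both strictly increasing in DBP). The couplings are deterministic
#' and monotone so that pressure is in principle recoverable from waveform
#' shape alone.
#'
#' @param sbp,dbp Pressures in mmHg.
#' @return A list with `mu1`, `s1`, `d`, `mu2`, `s2` (seconds).
#' @export
pulse_params <- function(sbp, dbp) {
  mu1 <- 0.16
  s1 <- 0.09 - 0.035 * (sbp - 90) / 90
  d <- 0.16 + 0.10 * (dbp - 50) / 40
  s2 <- 0.045 + 0.02 * (dbp - 50) / 40
  list(mu1 = mu1, s1 = s1, d = d, mu2 = mu1 + d, s2 = s2)
}

# One beat's template on local time t (seconds from beat onset), min-max
# normalized to [0, 1] within the beat. The systolic lobe is asymmetric
# (fast upstroke, slower runoff, widths 0.6/1.4 of s1), matching the
# right-skewed shape of real PPG pulses - clean synthetic beats therefore
# carry positive skewness, as the skewness quality rule presumes.
beat_template <- function(t, sbp, dbp, dicrotic_strength) {
  p <- pulse_params(sbp, dbp)
  sw <- ifelse(t < p$mu1, 0.6 * p$s1, 1.4 * p$s1)
  raw <- exp(-(t - p$mu1)^2 / (2 * sw^2)) +
    dicrotic_strength * exp(-(t - p$mu2)^2 / (2 * p$s2^2))
  (raw - min(raw)) / (max(raw) - min(raw))
}

#' Generate one synthetic paired PPG/ABP record
#'
#' Builds `round(duration_s * hr_bpm / 60)` beats whose jittered periods are
#' rescaled to tile the record exactly, evaluates the morphology-coupled
#' pulse template per beat, and assembles: `abp` as the per-beat affine map
#' onto \[DBP, SBP\] mmHg (noise-free, so per-beat extrema are exact), and
#' `ppg` as the same pulse train plus baseline drift, powerline interference
#' and white noise. Ground-truth per-beat onsets and pressures are stored in
#' `meta` for oracle use by downstream reference extraction.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `bp_record`: list with `ppg` (a.u.), `abp`
#'   (mmHg), `fs` (Hz) and `meta` (beat table, config echo, stage trail).
#' @examples
#' rec <- generate_record(sim_config(duration_s = 10, hr_bpm = 60, seed = 7))
#' length(rec$ppg) # 1250 samples
#' @export
generate_record <- function(cfg) {
  if (!inherits(cfg, "sim_config")) cfg <- do.call(sim_config, cfg)
  with_seed(cfg$seed, function() {
    total <- round(cfg$duration_s * cfg$fs)
    n_beats <- max(1L, round(cfg$duration_s * cfg$hr_bpm / 60))
    mult <- stats::runif(n_beats, 1 - cfg$jitter, 1 + cfg$jitter)
    bounds <- round(cumsum(c(0, mult / sum(mult) * total)))
    bounds[n_beats + 1] <- total
    beat_len <- diff(bounds)
    frac <- if (n_beats > 1) (seq_len(n_beats) - 1) / (n_beats - 1) else 0
    beat_sbp <- cfg$sbp + cfg$sbp_drift * frac
    beat_dbp <- cfg$dbp + cfg$dbp_drift * frac

    pulse <- numeric(total)
    abp <- numeric(total)
    for (i in seq_len(n_beats)) {
      idx <- (bounds[i] + 1):bounds[i + 1]
      t_loc <- (seq_along(idx) - 1) / cfg$fs
      x01 <- beat_template(t_loc, beat_sbp[i], beat_dbp[i],
                           cfg$dicrotic_strength)
      pulse[idx] <- x01
      abp[idx] <- beat_dbp[i] + (beat_sbp[i] - beat_dbp[i]) * x01
    }

    t <- (seq_len(total) - 1) / cfg$fs
    ph <- stats::runif(2, 0, 2 * pi)
    ppg <- pulse +
      cfg$drift_amp * sin(2 * pi * cfg$drift_freq * t + ph[1]) +
      cfg$powerline_amp * sin(2 * pi * cfg$powerline_freq * t + ph[2]) +
      cfg$noise_sd * stats::rnorm(total)

    beats <- tibble::tibble(
      onset = bounds[seq_len(n_beats)] + 1L,
      length = as.integer(beat_len),
      sbp = beat_sbp, dbp = beat_dbp
    )
    structure(list(
      ppg = ppg, abp = abp, fs = cfg$fs,
      meta = list(config = unclass(cfg), beats = beats, stages = "raw")
    ), class = "bp_record")
  })
}

#' @export
print.bp_record <- function(x, ...) {
  cat(sprintf(
    "<bp_record> %d samples @ %g Hz (%.1f s), %d beats, SBP/DBP target %.1f/%.1f mmHg\n",
    length(x$ppg), x$fs, length(x$ppg) / x$fs, nrow(x$meta$beats),
    x$meta$config$sbp, x$meta$config$dbp))
  invisible(x)
}

#' Blood-pressure samplers for dataset generation
#'
#' `bp_sampler_uniform()` draws SBP ~ U(90, 180) and DBP ~ U(50, 90);
#' `bp_sampler_skewed()` draws right-skewed pressures concentrated in the
#' normotensive range (Beta-shaped, emulating the skewed pressure histogram
#' of ICU waveform collections). Both reject draws with pulse pressure
#' < 20 mmHg.
#'
#' @return A function of no arguments returning `c(sbp, dbp)`.
#' @export
bp_sampler_uniform <- function() {
  function() c(stats::runif(1, 90, 180), stats::runif(1, 50, 90))
}

#' @rdname bp_sampler_uniform
#' @export
bp_sampler_skewed <- function() {
  function() c(90 + 90 * stats::rbeta(1, 2, 4), 50 + 40 * stats::rbeta(1, 2.5, 3.5))
}

#' Generate a dataset of synthetic records
#'
#' Draws per-record (SBP, DBP) targets from a sampler (pulse pressure
#' >= 20 mmHg enforced by rejection), varies heart rate uniformly across
#' `hr_range`, and derives an independent sub-seed per record from `seed`.
#'
#' @param n_records Number of records (>= 1).
#' @param bp_sampler `"uniform"`, `"skewed"`, or a function of no arguments
#'   returning `c(sbp, dbp)` in mmHg.
#' @param base_cfg Template [sim_config()]; its BP, heart-rate and seed
#'   fields are overridden per record.
#' @param seed Integer master seed.
#' @param hr_range Heart-rate range (bpm) sampled per record.
#' @param max_retries Rejection-sampling budget per record.
#' @return A list of [generate_record()] outputs.
#' @export
generate_dataset <- function(n_records, bp_sampler = "uniform",
                             base_cfg = sim_config(), seed = 1L,
                             hr_range = c(55, 90), max_retries = 100L) {
  check_number(n_records, "n_records", min = 1)
  sampler <- if (is.function(bp_sampler)) bp_sampler
  else switch(match.arg(bp_sampler, c("uniform", "skewed")),
              uniform = bp_sampler_uniform(), skewed = bp_sampler_skewed())
  lapply(seq_len(n_records), function(i) {
    sub <- derive_seed(seed, sprintf("record%05d", i))
    draw <- with_seed(sub, function() {
      for (r in seq_len(max_retries)) {
        bp <- sampler()
        if (bp[1] - bp[2] >= 20) {
          return(list(bp = bp, hr = stats::runif(1, hr_range[1], hr_range[2])))
        }
      }
      stop("bp_sampler failed to produce sbp - dbp >= 20 after max retries",
           call. = FALSE)
    })
    cfg <- base_cfg
    cfg$sbp <- draw$bp[1]
    cfg$dbp <- draw$bp[2]
    cfg$hr_bpm <- draw$hr
    cfg$seed <- derive_seed(sub, "waveform")
    rec <- generate_record(cfg)
    rec$meta$record_id <- sprintf("rec%05d", i)
    rec
  })
}

#' Write / read one record as plain two-column CSV
#'
#' The CSV carries `ppg` and `abp` columns with the sampling rate in a
#' `# fs=` comment header; beat-level ground truth and the config echo go to
#' a JSON sidecar (`<path>.meta.json`) so the text files remain portable.
#'
#' @param record A `bp_record`.
#' @param path Output CSV path.
#' @param sidecar Write the JSON meta sidecar?
#' @return `path`, invisibly.
#' @export
write_record_csv <- function(record, path, sidecar = TRUE) {
  con <- file(path, "w")
  writeLines(sprintf("# fs=%.10g", record$fs), con)
  utils::write.csv(
    data.frame(ppg = record$ppg, abp = record$abp),
    con, row.names = FALSE)
  close(con)
  if (sidecar) {
    meta <- record$meta
    meta$beats <- as.data.frame(meta$beats)
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_record_csv
#' @export
read_record_csv <- function(path) {
  header <- readLines(path, n = 1L)
  fs <- if (grepl("^# fs=", header)) as.numeric(sub("^# fs=", "", header))
  else stop("missing `# fs=` header in ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#")
  meta <- list(stages = "raw")
  sc <- paste0(path, ".meta.json")
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$beats)) meta$beats <- tibble::as_tibble(meta$beats)
  }
  structure(list(ppg = df$ppg, abp = df$abp, fs = fs, meta = meta),
            class = "bp_record")
}
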