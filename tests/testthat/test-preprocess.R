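test_that("segmentation geometry matches the window/stride arithmetic", {
  rec <- clean_record()                       # 30 s at 125 Hz
  segs <- segment_record(rec, 3, 3)
  expect_equal(nrow(segs), 10)
  expect_true(all(lengths(segs$ppg) == 375))
  expect_equal(segs$start_index, seq(0, 9) * 375)

  expect_equal(nrow(segment_record(rec, 3, 1.5)), 19)

  short <- generate_record(sim_config(duration_s = 2, seed = 1))
  expect_equal(nrow(segment_record(short, 3, 3)), 0)
})

test_that("ABP windows are cut at identical offsets and never modified", {
  rec <- default_record()
  segs <- segment_record(rec, 3, 3)
  for (i in c(1, 5, 10)) {
    s0 <- segs$start_index[i]
    expect_identical(segs$abp[[i]], rec$abp[(s0 + 1):(s0 + 375)])
  }
})

test_that("reference extraction recovers per-beat pressures", {
  rec <- clean_record()
  seg <- segment_record(rec, 3, 3)[4, ]
  ref <- extract_bp_reference(seg$abp[[1]], rec$fs)
  expect_lt(abs(ref["sbp"] - 120), 0.5)
  expect_lt(abs(ref["dbp"] - 80), 0.5)

  # single-beat window falls back to the global extrema
  one_beat <- rec$abp[1:110]
  ref1 <- extract_bp_reference(one_beat, rec$fs)
  expect_equal(unname(ref1["sbp"]), max(one_beat))
  expect_equal(unname(ref1["dbp"]), min(one_beat))

  # flat window flags a quality failure rather than erroring
  expect_true(all(is.na(extract_bp_reference(rep(100, 375), 125))))
})

test_that("reference extraction tracks drifting per-beat SBP", {
  rec <- generate_record(sim_config(duration_s = 30, sbp = 115, dbp = 75,
                                    sbp_drift = 10, noise_sd = 0, jitter = 0,
                                    drift_amp = 0, powerline_amp = 0,
                                    seed = 8))
  segs <- segment_record(rec, 3, 3)
  beats <- rec$meta$beats
  peak_idx <- beats$onset + round(0.16 * rec$fs)   # systolic peak location
  for (i in c(2, 6, 9)) {
    s0 <- segs$start_index[i]
    inside <- which(peak_idx > s0 & peak_idx <= s0 + 375)
    truth <- mean(beats$sbp[inside])
    ref <- extract_bp_reference(segs$abp[[i]], rec$fs)
    expect_lt(abs(ref["sbp"] - truth), 0.5)
  }
})

test_that("skewness follows the population-moment definition", {
  expect_lt(abs(ppg_skewness(1:5)), 1e-9)
  expect_lt(abs(ppg_skewness(c(0, 0, 0, 1)) - 2 / sqrt(3)), 1e-9)
  expect_true(is.na(ppg_skewness(rep(2, 10))))
  expect_error(ppg_skewness(c(1, 2)), "3 samples")

  skip_if_not_installed("e1071")
  set.seed(11)
  for (i in 1:20) {
    x <- stats::rnorm(50 + i)
    expect_lt(abs(ppg_skewness(x) - e1071::skewness(x, type = 1)), 1e-10)
    # standardized moments are invariant under positive affine maps
    a <- stats::runif(1, 0.1, 5)
    b <- stats::rnorm(1, 0, 10)
    expect_lt(abs(ppg_skewness(a * x + b) - ppg_skewness(x)), 1e-9)
  }
})

test_that("autocorrelation SQI separates periodic from damaged windows", {
  fs <- 125
  t <- (0:374) / fs
  expect_gte(ac_sqi(sin(2 * pi * 1.2 * t), fs), 0.99)

  set.seed(21)
  expect_lt(ac_sqi(stats::rnorm(375), fs), 0.3)

  rec <- generate_record(sim_config(duration_s = 6, hr_bpm = 72, sbp = 120,
                                    dbp = 80, noise_sd = 0.02, seed = 104))
  ppg <- bandpass_filter(rec$ppg, fs, filter_spec())[376:750]
  expect_gte(ac_sqi(ppg, fs), 0.9)
  damaged <- ppg
  damaged[1:188] <- 0
  expect_lt(ac_sqi(damaged, fs), 0.6)

  expect_true(is.na(ac_sqi(rep(1, 375), fs)))
})

test_that("autocorrelation SQI matches a direct cor() search over lags", {
  fs <- 125
  set.seed(31)
  for (i in 1:10) {
    x <- as.numeric(stats::filter(stats::rnorm(375), rep(1, 8), sides = 1))
    x[is.na(x)] <- 0
    lags <- max(1, floor(fs * 60 / 150)):min(ceiling(fs * 60 / 30), 365)
    oracle <- max(vapply(lags, function(l)
      stats::cor(x[1:(375 - l)], x[(l + 1):375]), numeric(1)))
    expect_lt(abs(ac_sqi(x, fs) - oracle), 1e-10)
    expect_true(ac_sqi(x, fs) >= -1 && ac_sqi(x, fs) <= 1)
  }
})

test_that("min-max normalization maps onto [0, 1] and is idempotent", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1), tolerance = 1e-12)
  expect_equal(minmax_normalize(c(-1, 0, 3)), c(0, 0.25, 1), tolerance = 1e-12)
  x <- c(0, 0.3, 0.77, 1)
  expect_equal(minmax_normalize(x), x, tolerance = 1e-12)
  expect_error(minmax_normalize(rep(3, 5)), "degenerate")
})

test_that("model inputs carry normalized PPG/VPG/APG channels", {
  rec <- clean_record()
  segs <- screen_segments(
    segment_record(list(ppg = bandpass_filter(rec$ppg, rec$fs, filter_spec()),
                        abp = rec$abp, fs = rec$fs,
                        meta = rec$meta) |> structure(class = "bp_record"),
                   3, 3), fs = rec$fs)
  mi <- make_model_input(segs[3, ])
  expect_equal(dim(mi$channels), c(3, 375))
  expect_true(all(mi$channels >= 0 & mi$channels <= 1))
  expect_equal(min(mi$channels[1, ]), 0)
  expect_equal(max(mi$channels[1, ]), 1)
  expect_equal(unname(mi$labels["sbp"]), segs$sbp_ref[3])

  # APG equals the doubly differenced normalized PPG (same padding scheme)
  ch0 <- minmax_normalize(segs$ppg[[3]])
  pd <- function(x) c(diff(x), diff(x)[length(x) - 1])
  expect_equal(unname(mi$channels[3, ]),
               minmax_normalize(pd(pd(ch0))), tolerance = 1e-12)

  # a linear ramp has a constant first derivative: degenerate channel
  ramp <- segs[3, ]
  ramp$ppg[[1]] <- seq(0, 1, length.out = 375)
  expect_error(make_model_input(ramp), "degenerate")
})

test_that("the canonical five-segment batch keeps exactly the clean one", {
  batch <- canonical_quality_batch()
  out <- quality_filter(batch, fs = 125)
  expect_equal(nrow(out$kept), 1)
  expect_equal(out$kept$record_id, "fixture05")
  expect_equal(nrow(out$reports), 5)
  # each constructed defect trips its intended rule
  expect_true("bp_range" %in% out$reports$fail_reasons[[1]])   # SBP 190
  expect_true("bp_range" %in% out$reports$fail_reasons[[2]])   # DBP 45
  expect_true("skewness" %in% out$reports$fail_reasons[[3]])   # mirrored
  expect_true("autocorrelation" %in% out$reports$fail_reasons[[4]])
  expect_equal(out$reports$passed, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # passed <=> no fail reasons
  expect_equal(lengths(out$reports$fail_reasons) == 0, out$reports$passed)
})

test_that("screening an empty segment table yields an empty result", {
  rec <- generate_record(sim_config(duration_s = 2, seed = 1))
  out <- quality_filter(segment_record(rec), fs = 125)
  expect_equal(nrow(out$kept), 0)
  expect_equal(nrow(out$reports), 0)
})

test_that("a clean mid-range batch passes screening rule by rule", {
  cfgs <- expand.grid(sbp = c(115, 130, 145, 160), dbp = c(60, 70, 80))
  recs <- lapply(seq_len(nrow(cfgs)), function(i)
    generate_record(sim_config(duration_s = 27, sbp = cfgs$sbp[i],
                               dbp = cfgs$dbp[i], hr_bpm = 60 + 3 * i,
                               seed = 500 + i)))
  segs <- preprocess_records(recs)
  segs <- segs[seq_len(100), ]
  expect_true(all(segs$passed))
  expect_true(all(segs$skewness >= 0))
  expect_true(all(segs$ac_sqi >= 0.6))
  expect_true(all(segs$bp_in_range))
})

test_that("pipeline bookkeeping reconciles and records stage order", {
  recs <- generate_dataset(6, "uniform", sim_config(duration_s = 21),
                           seed = 88)
  segs <- preprocess_records(recs)
  counts <- attr(segs, "counts")
  expect_equal(counts$n_segments, nrow(segs))
  expect_equal(counts$n_kept + counts$n_excluded, counts$n_segments)
  # exclusive (first-failure) counts partition the excluded segments
  expect_equal(sum(unlist(counts$exclusive_failures)), counts$n_excluded)
  # every rule failure is visible in the per-segment reports
  expect_equal(sum(unlist(counts$rule_failures)),
               sum(lengths(segs$fail_reasons)))
  expect_equal(attr(segs, "stages"), c("filtered", "segmented", "screened"))
  ds <- build_model_inputs(segs[segs$passed, ])
  expect_equal(ds$stages,
               c("filtered", "segmented", "screened", "normalized"))
  # labels remain in mmHg: plausible clinical range, never [0, 1]
  expect_true(all(ds$labels[, "sbp"] > 60 & ds$labels[, "sbp"] < 200))
  expect_true(all(ds$labels[, "dbp"] > 30 & ds$labels[, "dbp"] < 120))
})

test_that("processed datasets round-trip through the CSV writer", {
  ds <- tiny_dataset()
  sub <- list(inputs = ds$inputs[, , 1:4, drop = FALSE],
              labels = ds$labels[1:4, ],
              meta = ds$meta[1:4, ], stages = ds$stages)
  class(sub) <- "bp_dataset"
  dir <- withr::local_tempdir()
  write_dataset_csv(sub, dir)
  back <- read_dataset_csv(dir)
  expect_equal(back$inputs, sub$inputs, tolerance = 1e-6)
  expect_equal(back$labels[, "sbp"], unname(sub$labels[, "sbp"]),
               tolerance = 1e-6)
})
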