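# End-to-end pipeline: simulate -> preprocess -> train -> evaluate, with a
# YAML-style configuration, per-stage artifacts and a provenance manifest.
# One global seed fans out to per-stage sub-seeds via derive_seed().

default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = "ppgbp-run",
    sim = list(n_records = 220L, duration_s = 30, fs = 125, preset = "uniform",
               drift_amp = 0.2, powerline_amp = 0.05, noise_sd = 0.05,
               dicrotic_strength = 0.5, write_records = FALSE),
    preprocess = list(window_s = 3, stride_s = 3, ac_threshold = 0.6,
                      sbp_max = 180, dbp_min = 50, max_segments = 2000,
                      filter_mode = "zero-phase", write_dataset = FALSE),
    model = list(width_multiplier = 0.25, reduction = 16),
    train = list(epochs = 20L, batch_size = 128L, lr0 = 0.01, delta = 1,
                 momentum = 0.9, loss = "huber", split_unit = "segment"),
    evaluate = list(plots = FALSE)
  )
}

merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(base))
      stop(sprintf("unknown configuration key `%s%s`", path, nm), call. = FALSE)
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]],
                                 paste0(path, nm, "."))
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Pipeline configuration
#'
#' Builds the nested simulate/preprocess/model/train/evaluate configuration,
#' starting from desk-scale defaults (220 records of 30 s, screened and
#' capped at 2,000 segments; width-x0.25 network; 20 Huber epochs). Unknown
#' keys are
#' rejected. `x` may be a YAML file path or a named list of overrides.
#'
#' @param x `NULL` (defaults), a YAML path, or a named list.
#' @return A validated nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(x = NULL) {
  cfg <- default_pipeline_config()
  if (is.character(x)) x <- yaml::read_yaml(x)
  if (!is.null(x$sim$sbp) || !is.null(x$sim$dbp))
    stop("per-record BP is drawn by the preset sampler; set sim$preset",
         call. = FALSE)
  if (!is.null(x)) cfg <- merge_config(cfg, x)
  check_number(cfg$sim$n_records, "sim.n_records", min = 1)
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Simulates records, conditions and screens them, trains the network and
#' evaluates it on the held-out test partition. Each stage writes its
#' artifact under `out_dir`, and a `manifest.json` records package version,
#' seeds, stage artifacts and their MD5 hashes for provenance. Identical
#' configurations reproduce identical report metrics.
#'
#' @param config A [pipeline_config()] (or anything it accepts).
#' @param out_dir Output directory; overrides the config entry.
#' @param verbose Print stage progress.
#' @return Invisibly, a list with `records`, `segments`, `dataset`, `fit`,
#'   `report` and `manifest`.
#' @export
run_bp_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                            verbose = interactive()) {
  config <- pipeline_config(if (inherits(config, "pipeline_config"))
    unclass(config) else config)
  out_dir <- out_dir %||% config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  artifacts <- character(0)

  say("simulate: %d records", config$sim$n_records)
  sim <- config$sim
  base_cfg <- sim_config(duration_s = sim$duration_s, fs = sim$fs,
                         drift_amp = sim$drift_amp,
                         powerline_amp = sim$powerline_amp,
                         noise_sd = sim$noise_sd,
                         dicrotic_strength = sim$dicrotic_strength)
  records <- generate_dataset(sim$n_records, sim$preset, base_cfg,
                              seed = derive_seed(config$seed, "simulate"))
  idx_path <- file.path(out_dir, "records_index.csv")
  utils::write.csv(purrr::map_dfr(records, function(r) tibble::tibble(
    record_id = r$meta$record_id, n_samples = length(r$ppg), fs = r$fs,
    sbp = r$meta$config$sbp, dbp = r$meta$config$dbp,
    hr_bpm = r$meta$config$hr_bpm)), idx_path, row.names = FALSE)
  artifacts <- c(artifacts, idx_path)
  if (isTRUE(sim$write_records)) {
    rec_dir <- file.path(out_dir, "records")
    dir.create(rec_dir, showWarnings = FALSE)
    for (r in records)
      write_record_csv(r, file.path(rec_dir,
                                    paste0(r$meta$record_id, ".csv")))
  }

  pp <- config$preprocess
  segs <- preprocess_records(
    records, spec = filter_spec(mode = pp$filter_mode),
    window_s = pp$window_s, stride_s = pp$stride_s,
    sbp_max = pp$sbp_max, dbp_min = pp$dbp_min,
    ac_threshold = pp$ac_threshold)
  counts <- attr(segs, "counts")
  say("preprocess: %d/%d segments kept", counts$n_kept, counts$n_segments)
  kept <- segs[segs$passed, ]
  if (!is.null(pp$max_segments))
    kept <- kept[seq_len(min(pp$max_segments, nrow(kept))), ]
  dataset <- build_model_inputs(kept)
  screen_path <- file.path(out_dir, "screening.json")
  jsonlite::write_json(counts, screen_path, auto_unbox = TRUE, digits = NA)
  artifacts <- c(artifacts, screen_path)
  if (isTRUE(pp$write_dataset)) {
    write_dataset_csv(dataset, file.path(out_dir, "processed"), counts)
    artifacts <- c(artifacts, file.path(out_dir, "processed", "inputs.csv"))
  }

  tr <- config$train
  tcfg <- train_config(delta = tr$delta, batch_size = tr$batch_size,
                       epochs = tr$epochs, lr0 = tr$lr0,
                       momentum = tr$momentum, loss = tr$loss,
                       split_unit = tr$split_unit,
                       seed = derive_seed(config$seed, "train"))
  model <- build_msa_resnet(
    model_config(width_multiplier = config$model$width_multiplier,
                 se = se_config(config$model$reduction)),
    seed = derive_seed(config$seed, "init"))
  say("train: %s parameters, %d epochs",
      format(count_parameters(model), big.mark = ","), tcfg$epochs)
  fit <- train_bp_model(model, dataset, tcfg)
  hist_path <- file.path(out_dir, "history.csv")
  utils::write.csv(fit$history, hist_path, row.names = FALSE)
  ckpt_path <- file.path(out_dir, "checkpoint.rds")
  save_checkpoint(fit$model, ckpt_path)
  artifacts <- c(artifacts, hist_path, ckpt_path)

  report <- evaluate_bp(fit$model, dataset, indices = fit$split$test)
  rep_path <- file.path(out_dir, "report.json")
  write_eval_json(report, rep_path)
  artifacts <- c(artifacts, rep_path)
  say("evaluate: test MAE %.2f (SBP) / %.2f (DBP) mmHg",
      report$sbp$stats$mae, report$dbp$stats$mae)
  if (isTRUE(config$evaluate$plots)) {
    pred <- predict(fit$model, dataset$inputs[, , fit$split$test, drop = FALSE])
    ref <- dataset$labels[fit$split$test, , drop = FALSE]
    for (j in 1:2) {
      tg <- c("SBP", "DBP")[j]
      ggplot2::ggsave(file.path(out_dir, sprintf("bland_altman_%s.png", tg)),
                      plot_bland_altman(pred[, j], ref[, j], tg),
                      width = 5, height = 4, dpi = 120)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ppgbp")),
    global_seed = config$seed,
    stage_seeds = list(simulate = derive_seed(config$seed, "simulate"),
                       train = derive_seed(config$seed, "train"),
                       init = derive_seed(config$seed, "init")),
    config = unclass(config),
    artifacts = lapply(stats::setNames(artifacts, basename(artifacts)),
                       function(p) list(path = p,
                                        md5 = unname(tools::md5sum(p))))
  )
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)

  invisible(list(records = records, segments = segs, dataset = dataset,
                 fit = fit, report = report, manifest = manifest))
}

#' Canonical five-segment screening batch
#'
#' Builds the reference quality-screening fixture: five 3-s segments of
#' which exactly one survives screening - one with SBP above 180 mmHg, one
#' with DBP below 50 mmHg, one amplitude-mirrored (negative skewness), one
#' half-zeroed (low autocorrelation), and one clean.
#'
#' @param fs Sampling rate, Hz.
#' @return A segment tibble (with references) ready for [screen_segments()].
#' @export
canonical_quality_batch <- function(fs = 125) {
  grab <- function(sbp, dbp, seed, mangle = identity) {
    rec <- generate_record(sim_config(duration_s = 6, fs = fs, hr_bpm = 72,
                                      sbp = sbp, dbp = dbp, noise_sd = 0.02,
                                      seed = seed))
    rec$ppg <- bandpass_filter(rec$ppg, fs, filter_spec())
    seg <- segment_record(rec, 3, 3)[2, ]
    seg$ppg[[1]] <- mangle(seg$ppg[[1]])
    seg
  }
  batch <- dplyr::bind_rows(
    grab(190, 80, seed = 101),                      # SBP out of range
    grab(120, 45, seed = 102),                      # DBP out of range
    grab(120, 80, seed = 103, mangle = function(x) -x),   # negative skew
    grab(120, 80, seed = 104, mangle = function(x) {      # damaged window
      x[1:(length(x) %/% 2)] <- 0
      x
    }),
    grab(120, 80, seed = 105))                      # clean
  batch$record_id <- sprintf("fixture%02d", seq_len(nrow(batch)))
  refs <- t(vapply(batch$abp, extract_bp_reference, numeric(2), fs = fs))
  batch$sbp_ref <- refs[, 1]
  batch$dbp_ref <- refs[, 2]
  batch
}

#' Write the canonical test fixtures
#'
#' Materializes the fixtures the unit tests construct in code: the
#' five-segment screening batch, a toy squeeze-and-excitation forward
#' example with hand-set weights, the reference error vectors for the error
#' statistics, and a 30-s clean record. A manifest lists each file's MD5
#' hash. All fixtures are seeded, so regeneration is platform-independent.
#'
#' @param out_dir Writable output directory.
#' @return Invisibly, the manifest (file -> md5).
#' @export
fixture_suite <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  batch <- canonical_quality_batch()
  qdir <- file.path(out_dir, "quality_batch")
  dir.create(qdir, showWarnings = FALSE)
  for (i in seq_len(nrow(batch))) {
    utils::write.csv(
      data.frame(ppg = batch$ppg[[i]], abp = batch$abp[[i]]),
      file.path(qdir, sprintf("segment%02d.csv", i)), row.names = FALSE)
  }
  utils::write.csv(
    data.frame(record_id = batch$record_id, start_index = batch$start_index,
               sbp_ref = batch$sbp_ref, dbp_ref = batch$dbp_ref),
    file.path(qdir, "references.csv"), row.names = FALSE)

  se_toy <- list(
    z = c(1, 0),
    W1 = matrix(c(1, -1), 1, 2), b1 = 0.5,
    W2 = matrix(c(2, -2), 2, 1), b2 = c(0, 0),
    s = as.numeric(1 / (1 + exp(-c(3, -3)))))
  jsonlite::write_json(se_toy, file.path(out_dir, "se_toy.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")

  utils::write.csv(
    data.frame(pred = c(0, 0, 0, 0), ref = c(1, -1, 2, -2)),
    file.path(out_dir, "error_vectors.csv"), row.names = FALSE)

  write_record_csv(
    generate_record(sim_config(duration_s = 30, noise_sd = 0, drift_amp = 0,
                               powerline_amp = 0, seed = 42)),
    file.path(out_dir, "clean_record.csv"))

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  manifest <- lapply(stats::setNames(files, sub(paste0(out_dir, "/"), "",
                                                files)),
                     function(p) unname(tools::md5sum(p)))
  jsonlite::write_json(manifest, file.path(out_dir, "fixture_manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}
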