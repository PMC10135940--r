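# Standards-based evaluation of BP predictions: ME/SD/MAE error statistics,
# AAMI pass/fail, BHS cumulative-error grading, Bland-Altman limits of
# agreement and Pearson correlation. The error sign convention is
# reference - predicted throughout.

#' Error statistics (ME, SD, MAE)
#'
#' Errors are `ref - pred` (reference minus predicted). `me` is their mean,
#' `sd` their sample standard deviation about the mean (the standard usage
#' for device evaluation), and `mae` the mean absolute error. Setting
#' `sd_as_printed = TRUE` instead computes `sqrt(sum(e^2) / (n - 1))`, an
#' uncentered variant some reports use.
#'
#' @param pred,ref Numeric vectors, mmHg, equal length `n >= 2`.
#' @param sd_as_printed Use the uncentered root-mean-square form.
#' @return A list of class `error_stats`: `me`, `sd`, `mae`, `n` (mmHg).
#' @export
error_stats <- function(pred, ref, sd_as_printed = FALSE) {
  if (length(pred) != length(ref))
    stop("pred and ref must have equal length", call. = FALSE)
  if (length(pred) < 2) stop("need n >= 2 for SD", call. = FALSE)
  e <- ref - pred
  s <- if (sd_as_printed) sqrt(sum(e^2) / (length(e) - 1)) else stats::sd(e)
  structure(list(me = mean(e), sd = s, mae = mean(abs(e)),
                 n = length(e)), class = "error_stats")
}

#' AAMI accuracy verdict
#'
#' Pass iff `|ME| <= 5` mmHg and `SD <= 8` mmHg (bounds treated as
#' inclusive).
#'
#' @param stats An [error_stats()] result (or list with `me`, `sd`).
#' @return A list of class `aami_verdict`: `pass`, `me_ok`, `sd_ok`.
#' @export
aami_check <- function(stats) {
  me_ok <- abs(stats$me) <= 5
  sd_ok <- stats$sd <= 8
  structure(list(pass = me_ok && sd_ok, me_ok = me_ok, sd_ok = sd_ok),
            class = "aami_verdict")
}

bhs_thresholds <- rbind(A = c(60, 85, 95), B = c(50, 75, 90), C = c(40, 65, 85))

#' BHS cumulative-error grade
#'
#' Computes the cumulative percentages of absolute errors within 5, 10 and
#' 15 mmHg and assigns the best grade whose three thresholds are all met
#' (A: 60/85/95, B: 50/75/90, C: 40/65/85, else D).
#'
#' @param abs_errors Nonempty vector of absolute errors, mmHg.
#' @return A list of class `bhs_report`: `pct5`, `pct10`, `pct15`, `grade`.
#' @export
bhs_grade <- function(abs_errors) {
  if (length(abs_errors) == 0) stop("empty input", call. = FALSE)
  bhs_grade_from_percent(100 * mean(abs_errors <= 5),
                         100 * mean(abs_errors <= 10),
                         100 * mean(abs_errors <= 15))
}

#' @rdname bhs_grade
#' @param pct5,pct10,pct15 Cumulative percentages of absolute errors within
#'   5 / 10 / 15 mmHg.
#' @export
bhs_grade_from_percent <- function(pct5, pct10, pct15) {
  pct <- c(pct5, pct10, pct15)
  grade <- "D"
  for (g in c("C", "B", "A")) if (all(pct >= bhs_thresholds[g, ])) grade <- g
  structure(list(pct5 = pct5, pct10 = pct10, pct15 = pct15, grade = grade),
            class = "bhs_report")
}

#' Bland-Altman agreement
#'
#' Differences are `ref - pred`; the 95% limits of agreement are
#' `mean(diff) -/+ 1.96 * sd(diff)`. `pct_within` reports the percentage of
#' differences falling inside the limits.
#'
#' @param pred,ref Numeric vectors, mmHg, `n >= 2`.
#' @return A list of class `bland_altman`: `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `pct_within`, `n`.
#' @export
bland_altman <- function(pred, ref) {
  if (length(pred) != length(ref))
    stop("pred and ref must have equal length", call. = FALSE)
  if (length(pred) < 2) stop("need n >= 2", call. = FALSE)
  d <- ref - pred
  m <- mean(d)
  s <- stats::sd(d)
  structure(list(mean_diff = m, sd_diff = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 pct_within = 100 * mean(d >= m - 1.96 * s &
                                           d <= m + 1.96 * s),
                 n = length(d)),
            class = "bland_altman")
}

#' Pearson correlation between predictions and references
#'
#' @param pred,ref Numeric vectors, `n >= 3`, both non-constant.
#' @return Pearson product-moment correlation in \[-1, 1\].
#' @export
pearson_r <- function(pred, ref) {
  if (length(pred) != length(ref))
    stop("pred and ref must have equal length", call. = FALSE)
  if (length(pred) < 3) stop("need n >= 3", call. = FALSE)
  if (stats::sd(pred) == 0 || stats::sd(ref) == 0)
    stop("constant input has no defined correlation", call. = FALSE)
  stats::cor(pred, ref)
}

#' Full evaluation report for SBP and DBP predictions
#'
#' Computes, per target, the error statistics, AAMI verdict, BHS grade,
#' Bland-Altman agreement and Pearson correlation, all from the same
#' aligned prediction set.
#'
#' @param pred N x 2 matrix or data frame with columns `sbp`, `dbp`
#'   (predicted, mmHg), or an `msa_resnet` model (then `ref` must be a
#'   `bp_dataset` whose inputs are predicted first).
#' @param ref N x 2 matrix/data frame of reference pressures, or the
#'   `bp_dataset` when `pred` is a model.
#' @param indices Optional row subset (e.g. a held-out test partition).
#' @return An object of class `bp_eval`: per-target sub-reports plus `n`.
#' @export
evaluate_bp <- function(pred, ref, indices = NULL) {
  if (inherits(pred, "msa_resnet")) {
    data <- ref
    if (!inherits(data, "bp_dataset"))
      stop("when `pred` is a model, `ref` must be a bp_dataset", call. = FALSE)
    ref <- data$labels
    pred <- predict(pred, data)
  }
  pred <- as.matrix(as.data.frame(pred))
  ref <- as.matrix(as.data.frame(ref))
  if (nrow(pred) != nrow(ref))
    stop("predictions and references are not aligned", call. = FALSE)
  if (!is.null(indices)) {
    pred <- pred[indices, , drop = FALSE]
    ref <- ref[indices, , drop = FALSE]
  }
  per_target <- function(j) {
    p <- pred[, j]
    r <- ref[, j]
    st <- error_stats(p, r)
    list(stats = st, aami = aami_check(st), bhs = bhs_grade(abs(r - p)),
         bland_altman = bland_altman(p, r), pearson_r = pearson_r(p, r))
  }
  structure(list(sbp = per_target(1), dbp = per_target(2), n = nrow(pred)),
            class = "bp_eval")
}

#' @export
print.bp_eval <- function(x, ...) {
  cat(sprintf("<bp_eval> n = %d segments\n", x$n))
  for (tg in c("sbp", "dbp")) {
    r <- x[[tg]]
    cat(sprintf(
      "  %s: ME %+.2f, SD %.2f, MAE %.2f mmHg | AAMI %s | BHS %s (%.1f/%.1f/%.1f%%) | r = %.3f\n",
      toupper(tg), r$stats$me, r$stats$sd, r$stats$mae,
      if (r$aami$pass) "pass" else "FAIL", r$bhs$grade,
      r$bhs$pct5, r$bhs$pct10, r$bhs$pct15, r$pearson_r))
  }
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x A `bp_eval`.
#' @param ... Unused.
#' @return Long tibble with `target`, `metric`, `value`.
#' @export
tidy.bp_eval <- function(x, ...) {
  purrr::map_dfr(c("sbp", "dbp"), function(tg) {
    r <- x[[tg]]
    tibble::tibble(
      target = tg,
      metric = c("me", "sd", "mae", "aami_pass", "bhs_pct5", "bhs_pct10",
                 "bhs_pct15", "loa_low", "loa_high", "pearson_r"),
      value = c(r$stats$me, r$stats$sd, r$stats$mae, as.numeric(r$aami$pass),
                r$bhs$pct5, r$bhs$pct10, r$bhs$pct15,
                r$bland_altman$loa_low, r$bland_altman$loa_high, r$pearson_r))
  })
}

#' One-row summary of an evaluation report
#'
#' @param x A `bp_eval`.
#' @param ... Unused.
#' @return One-row tibble with the headline metrics for both targets.
#' @export
glance.bp_eval <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    sbp_me = x$sbp$stats$me, sbp_sd = x$sbp$stats$sd,
    sbp_mae = x$sbp$stats$mae, sbp_aami = x$sbp$aami$pass,
    sbp_grade = x$sbp$bhs$grade, sbp_r = x$sbp$pearson_r,
    dbp_me = x$dbp$stats$me, dbp_sd = x$dbp$stats$sd,
    dbp_mae = x$dbp$stats$mae, dbp_aami = x$dbp$aami$pass,
    dbp_grade = x$dbp$bhs$grade, dbp_r = x$dbp$pearson_r)
}

eval_to_list <- function(x) {
  lapply(x[c("sbp", "dbp")], function(r)
    list(me = r$stats$me, sd = r$stats$sd, mae = r$stats$mae,
         n = r$stats$n, aami_pass = r$aami$pass,
         bhs = list(pct5 = r$bhs$pct5, pct10 = r$bhs$pct10,
                    pct15 = r$bhs$pct15, grade = r$bhs$grade),
         bland_altman = list(mean_diff = r$bland_altman$mean_diff,
                             sd_diff = r$bland_altman$sd_diff,
                             loa_low = r$bland_altman$loa_low,
                             loa_high = r$bland_altman$loa_high,
                             pct_within = r$bland_altman$pct_within),
         pearson_r = r$pearson_r))
}

#' Write / read an evaluation report as JSON
#'
#' The written report round-trips: reading it back reproduces the in-memory
#' numbers to full serialization precision (~15 significant digits).
#'
#' @param x A `bp_eval`.
#' @param path JSON file path.
#' @return `path` / a `bp_eval`-shaped list of class `bp_eval`.
#' @export
write_eval_json <- function(x, path) {
  out <- eval_to_list(x)
  out$n <- x$n
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_eval_json
#' @export
read_eval_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  per_target <- function(r) {
    list(stats = structure(list(me = r$me, sd = r$sd, mae = r$mae, n = r$n),
                           class = "error_stats"),
         aami = structure(list(pass = r$aami_pass,
                               me_ok = abs(r$me) <= 5, sd_ok = r$sd <= 8),
                          class = "aami_verdict"),
         bhs = structure(r$bhs, class = "bhs_report"),
         bland_altman = structure(c(r$bland_altman, list(n = r$n)),
                                  class = "bland_altman"),
         pearson_r = r$pearson_r)
  }
  structure(list(sbp = per_target(raw$sbp), dbp = per_target(raw$dbp),
                 n = raw$n),
            class = "bp_eval")
}

#' Bland-Altman and regression plots for an evaluation
#'
#' `autoplot()` on a `bp_eval` needs the raw prediction pairs, so it is a
#' thin wrapper over `plot_bland_altman()` / `plot_regression()` which take
#' them directly.
#'
#' @param pred,ref Numeric vectors, mmHg.
#' @param target Label used in titles ("SBP"/"DBP").
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(pred, ref, target = "BP") {
  ba <- bland_altman(pred, ref)
  df <- tibble::tibble(avg = (pred + ref) / 2, diff = ref - pred)
  ggplot2::ggplot(df, ggplot2::aes(.data$avg, .data$diff)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$mean_diff, ba$loa_high),
                        linetype = c("dashed", "solid", "dashed"),
                        colour = c("red", "blue", "red")) +
    ggplot2::labs(title = sprintf("%s Bland-Altman (LOA %.2f to %.2f mmHg)",
                                  target, ba$loa_low, ba$loa_high),
                  x = "mean of reference and prediction (mmHg)",
                  y = "reference - prediction (mmHg)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_bland_altman
#' @export
plot_regression <- function(pred, ref, target = "BP") {
  df <- tibble::tibble(ref = ref, pred = pred)
  ggplot2::ggplot(df, ggplot2::aes(.data$ref, .data$pred)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "blue", linewidth = 0.6) +
    ggplot2::labs(title = sprintf("%s regression (r = %.3f)", target,
                                  pearson_r(pred, ref)),
                  x = "reference (mmHg)", y = "predicted (mmHg)") +
    ggplot2::theme_minimal()
}
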