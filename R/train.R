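# Training: Huber-loss SGD with momentum, cosine-annealed learning rate,
# 7:1:2 splitting, per-epoch history and best-validation checkpointing.

#' Regression losses
#'
#' `huber_loss()` is quadratic (`0.5 r^2`) for residuals within `delta` and
#' linear (`delta * |r| - 0.5 * delta^2`) beyond it - continuous and once
#' differentiable at the knee, combining the outlier robustness of the MAE
#' with the smooth gradients of the MSE. `mse_loss()` and `mae_loss()` are
#' provided for loss-ablation experiments. All three return the mean over
#' every element of `pred`.
#'
#' @param pred,ref Numeric vectors/matrices of equal shape, mmHg.
#' @param delta Huber knee in mmHg (> 0); default 1.
#' @return A single loss value.
#' @examples
#' huber_loss(0, 0.5)  # 0.125
#' huber_loss(0, 3)    # 2.5
#' @export
huber_loss <- function(pred, ref, delta = 1) {
  check_number(delta, "delta", min = 0, strict_min = TRUE)
  r <- abs(ref - pred)
  mean(ifelse(r <= delta, 0.5 * r^2, delta * r - 0.5 * delta^2))
}

#' @rdname huber_loss
#' @export
mse_loss <- function(pred, ref) {
  if (length(pred) == 0) stop("empty input", call. = FALSE)
  mean((ref - pred)^2)
}

#' @rdname huber_loss
#' @export
mae_loss <- function(pred, ref) {
  if (length(pred) == 0) stop("empty input", call. = FALSE)
  mean(abs(ref - pred))
}

# Gradient of each loss with respect to `pred` (same shape), already divided
# by the element count so the batch loss is a mean.
loss_grad <- function(pred, ref, loss, delta) {
  r <- ref - pred
  g <- switch(loss,
    huber = ifelse(abs(r) <= delta, r, delta * sign(r)),
    mse = 2 * r,
    mae = sign(r))
  -g / length(pred)
}

#' Cosine-annealed learning rate
#'
#' Single annealing cycle over the full run:
#' `eta_min + 0.5 * (lr0 - eta_min) * (1 + cos(pi * epoch / total_epochs))`.
#'
#' @param epoch 0-based epoch index, `0 <= epoch <= total_epochs`.
#' @param total_epochs Total number of epochs.
#' @param lr0 Initial learning rate.
#' @param eta_min Final learning rate.
#' @return The learning rate for `epoch`.
#' @export
cosine_lr <- function(epoch, total_epochs, lr0 = 0.001, eta_min = 0) {
  check_number(epoch, "epoch", min = 0, max = total_epochs)
  eta_min + 0.5 * (lr0 - eta_min) * (1 + cos(pi * epoch / total_epochs))
}

#' Training configuration
#'
#' Defaults mirror a full-scale protocol: Huber loss with `delta = 1` mmHg,
#' batch size 1024, 120 epochs, SGD (momentum 0.9) from `lr0 = 0.001` with
#' single-cycle cosine annealing to `eta_min = 0`, and a 7:1:2
#' train/validation/test split over segments. Desk-scale experiments
#' override `epochs`, `batch_size` and `lr0`. With labels in mmHg and
#' `delta = 1`, the Huber loss behaves MAE-like for typical residuals.
#'
#' @param delta Huber knee, mmHg.
#' @param batch_size Samples per SGD step.
#' @param epochs Training epochs.
#' @param lr0,eta_min Initial and final learning rate of the cosine cycle.
#' @param momentum SGD momentum.
#' @param split Train/validation/test fractions (sum to 1).
#' @param split_unit `"segment"` (matches the usual protocol, but leaks
#'   records across partitions) or `"record"` (subject-disjoint).
#' @param seed Seed governing splitting, initialization and batch order.
#' @param loss `"huber"`, `"mse"` or `"mae"`.
#' @param init_bias_to_mean Initialize the output bias to the training-set
#'   label mean (standard regression-head initialization; removes the large
#'   constant offset the bounded Huber gradient would otherwise have to
#'   crawl across).
#' @param verbose Print a per-epoch log line.
#' @return A list of class `train_config`.
#' @export
train_config <- function(delta = 1, batch_size = 1024, epochs = 120,
                         lr0 = 0.001, eta_min = 0, momentum = 0.9,
                         split = c(0.7, 0.1, 0.2),
                         split_unit = c("segment", "record"),
                         seed = 1L, loss = c("huber", "mse", "mae"),
                         init_bias_to_mean = TRUE, verbose = FALSE) {
  check_number(delta, "delta", min = 0, strict_min = TRUE)
  check_number(epochs, "epochs", min = 1)
  if (length(split) != 3 || abs(sum(split) - 1) > 1e-8)
    abort_field("split", "must be three fractions summing to 1")
  structure(list(delta = delta, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr0 = lr0, eta_min = eta_min,
                 momentum = momentum, split = split,
                 split_unit = match.arg(split_unit), seed = as.integer(seed),
                 loss = match.arg(loss),
                 init_bias_to_mean = isTRUE(init_bias_to_mean),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Split a dataset into train/validation/test index sets
#'
#' Disjoint, exhaustive, seeded. With `split_unit = "segment"` the sizes are
#' `floor(f1 n)` / `floor(f2 n)` / remainder over a shuffled permutation.
#' With `split_unit = "record"` whole records are assigned to partitions (no
#' record spans two partitions), targeting the same fractions in segment
#' counts.
#'
#' @param n Number of segments.
#' @param cfg A [train_config()] (uses `split`, `split_unit`, `seed`).
#' @param record_ids Length-`n` record identifiers, required for
#'   record-unit splitting.
#' @return A list of integer index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(n, cfg = train_config(), record_ids = NULL) {
  check_number(n, "n", min = 10)
  f <- cfg$split
  if (cfg$split_unit == "record") {
    if (is.null(record_ids) || length(record_ids) != n)
      abort_field("record_ids", "required for record-unit splitting")
    ids <- unique(record_ids)
    perm <- with_seed(derive_seed(cfg$seed, "split"),
                      function() sample(ids))
    counts <- cumsum(table(factor(record_ids, levels = perm))[perm])
    n_train <- sum(counts <= ceiling(f[1] * n))
    n_val <- sum(counts <= ceiling((f[1] + f[2]) * n)) - n_train
    part <- rep(3L, length(perm))
    part[seq_len(n_train)] <- 1L
    if (n_val > 0) part[n_train + seq_len(n_val)] <- 2L
    assign_part <- part[match(record_ids, perm)]
    out <- list(train = which(assign_part == 1L),
                val = which(assign_part == 2L),
                test = which(assign_part == 3L))
  } else {
    perm <- with_seed(derive_seed(cfg$seed, "split"),
                      function() sample.int(n))
    n_train <- floor(f[1] * n)
    n_val <- floor(f[2] * n)
    out <- list(train = perm[seq_len(n_train)],
                val = perm[n_train + seq_len(n_val)],
                test = perm[(n_train + n_val + 1L):n])
  }
  if (any(lengths(out) == 0))
    stop("dataset too small for non-empty train/val/test partitions",
         call. = FALSE)
  out
}

batch_tensor <- function(inputs, idx) {
  new_tensor(matrix(inputs[, , idx, drop = FALSE], nrow = dim(inputs)[1]),
             dim(inputs)[1], dim(inputs)[2], length(idx))
}

#' Train an MSA-ResNet on a processed dataset
#'
#' Minimizes the configured loss over the training partition with momentum
#' SGD and a cosine-annealed learning rate, records per-epoch training loss
#' and validation MAE (SBP and DBP), and restores the parameters of the
#' epoch with the lowest mean validation MAE. Fully reproducible: the seed
#' drives splitting, initialization already fixed in the model, and batch
#' order.
#'
#' @param model A built [build_msa_resnet()] model.
#' @param data A `bp_dataset` ([build_model_inputs()]).
#' @param cfg A [train_config()].
#' @param split Optional pre-computed split (list of `train`, `val`, `test`
#'   indices); defaults to [split_dataset()] under `cfg`.
#' @return An object of class `bp_fit`: `model` (best-validation weights),
#'   `history` (per-epoch tibble), `split`, `config`, `best_epoch`.
#' @export
train_bp_model <- function(model, data, cfg = train_config(), split = NULL) {
  inputs <- data$inputs
  labels <- t(data$labels)                     # 2 x N, rows sbp/dbp
  n <- dim(inputs)[3]
  if (n == 0) stop("empty dataset", call. = FALSE)
  if (is.null(split))
    split <- split_dataset(n, cfg, record_ids = data$meta$record_id)

  if (cfg$init_bias_to_mean) {
    head_layer <- model$net$layers[[length(model$net$layers)]]
    head_layer$b <- rowMeans(labels[, split$train, drop = FALSE])
  }

  history <- vector("list", cfg$epochs)
  best <- list(mae = Inf, epoch = NA_integer_, state = NULL)
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cosine_lr(epoch - 1, cfg$epochs, cfg$lr0, cfg$eta_min)
    order_idx <- with_seed(derive_seed(cfg$seed, paste0("epoch", epoch)),
                           function() sample(split$train))
    losses <- c()
    for (start in seq(1L, length(order_idx), by = cfg$batch_size)) {
      idx <- order_idx[start:min(length(order_idx),
                                 start + cfg$batch_size - 1L)]
      if (length(idx) < 2L) next   # batch norm needs >= 2 samples
      tn <- nn_forward(model$net, batch_tensor(inputs, idx), training = TRUE)
      ref <- labels[, idx, drop = FALSE]
      loss <- switch(cfg$loss,
                     huber = huber_loss(tn$x, ref, cfg$delta),
                     mse = mse_loss(tn$x, ref),
                     mae = mae_loss(tn$x, ref))
      if (!is.finite(loss))
        stop(sprintf("training diverged (non-finite loss at epoch %d)", epoch),
             call. = FALSE)
      losses <- c(losses, loss)
      dP <- loss_grad(tn$x, ref, cfg$loss, cfg$delta)
      nn_backward(model$net, new_tensor(dP, 2L, 1L, length(idx)))
      sgd_step(model$net, lr, cfg$momentum)
    }
    val_pred <- predict(model, inputs[, , split$val, drop = FALSE])
    val_ref <- t(labels[, split$val, drop = FALSE])
    mae_sbp <- mean(abs(val_ref[, 1] - val_pred[, "sbp"]))
    mae_dbp <- mean(abs(val_ref[, 2] - val_pred[, "dbp"]))
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = lr, train_loss = mean(losses),
      val_mae_sbp = mae_sbp, val_mae_dbp = mae_dbp)
    if (cfg$verbose)
      message(sprintf(
        "epoch %3d  lr %.5f  train loss %8.4f  val MAE %6.2f / %5.2f mmHg",
        epoch, lr, mean(losses), mae_sbp, mae_dbp))
    score <- (mae_sbp + mae_dbp) / 2
    if (score < best$mae)
      best <- list(mae = score, epoch = epoch, state = nn_state(model$net))
  }
  nn_load_state(model$net, best$state)
  nn_clear_cache(model$net)
  structure(list(model = model, history = dplyr::bind_rows(history),
                 split = split, config = cfg, best_epoch = best$epoch),
            class = "bp_fit")
}

#' Inject gross label outliers into a dataset
#'
#' Robustness-ablation hook: shifts the labels of a random fraction of
#' segments by `+/- magnitude` mmHg (SBP; two thirds of that for DBP, signs
#' alternating), emulating corrupted reference annotations. The
#' physiological ordering `sbp > dbp` is preserved by clamping. Waveforms
#' are untouched.
#'
#' @param dataset A `bp_dataset`.
#' @param fraction Fraction of segments to corrupt.
#' @param magnitude Outlier shift, mmHg.
#' @param seed Integer seed.
#' @return The dataset with corrupted labels and an `outlier_idx` element.
#' @export
corrupt_labels <- function(dataset, fraction = 0.05, magnitude = 60,
                           seed = 1L) {
  n <- nrow(dataset$labels)
  k <- round(fraction * n)
  idx <- with_seed(derive_seed(seed, "outliers"),
                   function() sample.int(n, k))
  sgn <- rep(c(1, -1), length.out = k)
  sbp <- dataset$labels[idx, "sbp"] + magnitude * sgn
  dbp <- dataset$labels[idx, "dbp"] + magnitude * (2 / 3) * sgn
  dbp <- pmax(pmin(dbp, sbp - 10), 10)
  dataset$labels[idx, "sbp"] <- sbp
  dataset$labels[idx, "dbp"] <- dbp
  dataset$outlier_idx <- idx
  dataset
}

#' @export
print.bp_fit <- function(x, ...) {
  h <- x$history[x$best_epoch, ]
  cat(sprintf(
    "<bp_fit> %d epochs (%s loss), best epoch %d: val MAE %.2f (SBP) / %.2f (DBP) mmHg\n",
    nrow(x$history), x$config$loss, x$best_epoch,
    h$val_mae_sbp, h$val_mae_dbp))
  invisible(x)
}

#' Tidy the per-epoch training history
#'
#' @param x A `bp_fit`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `lr`, `train_loss`, `val_mae_sbp`,
#'   `val_mae_dbp`.
#' @export
tidy.bp_fit <- function(x, ...) x$history

#' One-row summary of a fit
#'
#' @param x A `bp_fit`.
#' @param ... Unused.
#' @return Tibble with epoch counts, partition sizes and best-epoch
#'   validation MAEs.
#' @export
glance.bp_fit <- function(x, ...) {
  h <- x$history[x$best_epoch, ]
  tibble::tibble(epochs = nrow(x$history), best_epoch = x$best_epoch,
                 loss = x$config$loss,
                 n_train = length(x$split$train), n_val = length(x$split$val),
                 n_test = length(x$split$test),
                 val_mae_sbp = h$val_mae_sbp, val_mae_dbp = h$val_mae_dbp)
}

#' Plot training curves
#'
#' @param object A `bp_fit`.
#' @param ... Unused.
#' @return A ggplot of training loss and validation MAE against epoch.
#' @export
autoplot.bp_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history,
                              c("train_loss", "val_mae_sbp", "val_mae_dbp"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single-file archive of the weights (including
#' batch-norm running statistics), the model configuration echo and a
#' pipeline version tag, loadable by the evaluation stage.
#'
#' @param model An `msa_resnet`.
#' @param path Checkpoint file path.
#' @return `path` / the restored `msa_resnet`.
#' @export
save_checkpoint <- function(model, path) {
  nn_clear_cache(model$net)
  saveRDS(list(version = as.character(utils::packageVersion("ppgbp")),
               config = model$config, seed = model$seed,
               state = nn_state(model$net)),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_msa_resnet(ck$config, seed = ck$seed)
  nn_load_state(model$net, ck$state)
  model
}
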