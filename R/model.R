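# MSA-ResNet: a 1-D ResNet34-style regression backbone whose stem is a
# four-branch multi-scale feature-extraction (MSFE) block and whose residual
# blocks carry squeeze-and-excitation channel attention, ending in a joint
# SBP/DBP head. All convolutions, pooling and global averaging are
# one-dimensional (inputs are 3 x 375 signal windows).

#' Multi-scale stem configuration
#'
#' Four parallel branches: regular convolutions with kernels
#' `regular_kernels` (3, 5, 7 by default) plus a large-kernel branch
#' realized as a depthwise convolution (kernel `large_kernel`) followed by a
#' pointwise channel-mixing convolution - the depthwise-separable split
#' keeps the large receptive field cheap in parameters. Branch outputs
#' (equal length by same-padding) are concatenated along channels and
#' reshaped by a kernel-1 convolution to `out_channels`.
#'
#' @param regular_kernels Odd kernel sizes of the regular branches.
#' @param large_kernel Odd kernel size of the depthwise-separable branch.
#' @param branch_channels Output channels per branch.
#' @param out_channels Stem output channels; must equal
#'   `(length(regular_kernels) + 1) * branch_channels`.
#' @param stride Stem stride.
#' @return A list of class `msfe_config`.
#' @export
msfe_config <- function(regular_kernels = c(3, 5, 7), large_kernel = 13,
                        branch_channels = 16, out_channels = 64, stride = 2) {
  ks <- c(regular_kernels, large_kernel)
  if (any(ks %% 2 != 1)) abort_field("kernels", "all kernels must be odd")
  if (out_channels != (length(regular_kernels) + 1) * branch_channels)
    abort_field("out_channels",
                "must equal (n_branches) * branch_channels (concat width)")
  structure(list(regular_kernels = as.integer(regular_kernels),
                 large_kernel = as.integer(large_kernel),
                 branch_channels = as.integer(branch_channels),
                 out_channels = as.integer(out_channels),
                 stride = as.integer(stride)),
            class = "msfe_config")
}

#' Squeeze-and-excitation configuration
#'
#' @param reduction Bottleneck reduction ratio of the two-layer excitation
#'   MLP; the hidden width is `max(1, channels %/% reduction)`.
#' @return A list of class `se_config`.
#' @export
se_config <- function(reduction = 16) {
  check_number(reduction, "reduction", min = 1)
  structure(list(reduction = as.integer(reduction)), class = "se_config")
}

#' Network configuration
#'
#' Defaults describe the full-size model: ResNet34 stage layout
#' (3, 4, 6, 3 residual blocks at 64, 128, 256, 512 channels) behind the
#' multi-scale stem, SE attention in every block, and a joint two-output
#' regression head (SBP, DBP in mmHg). `width_multiplier` scales every
#' channel count, giving CPU-scale variants on the same code path.
#'
#' @param in_channels Input channels (PPG, VPG, APG).
#' @param input_length Nominal window length in samples.
#' @param msfe A [msfe_config()].
#' @param se A [se_config()].
#' @param blocks_per_stage Residual blocks per stage.
#' @param stage_channels Channel width per stage.
#' @param width_multiplier Multiplier applied to all channel counts.
#' @param out_dim Output dimension (2: SBP and DBP).
#' @return A list of class `model_config`.
#' @export
model_config <- function(in_channels = 3, input_length = 375,
                         msfe = msfe_config(), se = se_config(),
                         blocks_per_stage = c(3, 4, 6, 3),
                         stage_channels = c(64, 128, 256, 512),
                         width_multiplier = 1, out_dim = 2) {
  if (length(blocks_per_stage) != length(stage_channels))
    abort_field("stage_channels",
                "blocks_per_stage and stage_channels must have equal length")
  if (out_dim != 2) abort_field("out_dim", "must be 2 (SBP, DBP)")
  check_number(width_multiplier, "width_multiplier", min = 0, strict_min = TRUE)
  structure(list(in_channels = as.integer(in_channels),
                 input_length = as.integer(input_length),
                 msfe = msfe, se = se,
                 blocks_per_stage = as.integer(blocks_per_stage),
                 stage_channels = as.integer(stage_channels),
                 width_multiplier = width_multiplier,
                 out_dim = as.integer(out_dim)),
            class = "model_config")
}

scale_width <- function(c, wm) max(1L, as.integer(round(c * wm)))

# conv -> BN -> ReLU unit (convolutions carry no bias; BN supplies the shift)
conv_bn_relu <- function(c_in, c_out, k, stride = 1L)
  nn_seq(list(nn_conv(c_in, c_out, k, stride), nn_bn(c_out), nn_relu()))

build_msfe <- function(cfg, in_channels, wm) {
  bc <- scale_width(cfg$branch_channels, wm)
  out <- (length(cfg$regular_kernels) + 1L) * bc
  branches <- c(
    lapply(cfg$regular_kernels, function(k)
      conv_bn_relu(in_channels, bc, k, cfg$stride)),
    list(nn_seq(list(
      nn_dwconv(in_channels, cfg$large_kernel, cfg$stride),
      nn_conv(in_channels, bc, 1L),
      nn_bn(bc), nn_relu()))))
  nn_msfe(branches,
          reshape = conv_bn_relu(out, out, 1L),
          branch_channels = rep(bc, length(branches)))
}

build_block <- function(c_in, c_out, stride, reduction) {
  body <- nn_seq(list(
    nn_conv(c_in, c_out, 3L, stride), nn_bn(c_out), nn_relu(),
    nn_conv(c_out, c_out, 3L), nn_bn(c_out),
    nn_se(c_out, reduction)))
  shortcut <- if (stride != 1L || c_in != c_out)
    nn_seq(list(nn_conv(c_in, c_out, 1L, stride), nn_bn(c_out)))
  nn_residual(body, shortcut)
}

#' Build an MSA-ResNet model
#'
#' Architecture: multi-scale stem (stride 2) -> max-pool (3, stride 2) ->
#' four stages of squeeze-and-excitation residual blocks (first block of
#' stages 2-4 downsamples by stride 2 with a projection shortcut) -> global
#' average pooling -> fully connected head with two outputs (SBP, DBP in
#' mmHg).
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for weight initialization (He-normal); the
#'   caller's RNG state is preserved.
#' @return An object of class `msa_resnet` exposing `net` (the layer tree),
#'   `config`, and working with [predict()], [count_parameters()] and
#'   [model_summary()].
#' @examples
#' m <- build_msa_resnet(model_config(width_multiplier = 0.25), seed = 1)
#' count_parameters(m)
#' @export
build_msa_resnet <- function(cfg = model_config(), seed = 1L) {
  wm <- cfg$width_multiplier
  with_seed(derive_seed(seed, "init"), function() {
    stem <- build_msfe(cfg$msfe, cfg$in_channels, wm)
    stem_out <- (length(cfg$msfe$regular_kernels) + 1L) *
      scale_width(cfg$msfe$branch_channels, wm)
    ch <- vapply(cfg$stage_channels, scale_width, integer(1), wm = wm)
    if (stem_out != ch[1])
      abort_field("stage_channels",
                  "first stage width must match the stem output width")
    layers <- list(stem, nn_maxpool(3L, 2L))
    c_in <- stem_out
    for (s in seq_along(cfg$blocks_per_stage)) {
      for (b in seq_len(cfg$blocks_per_stage[s])) {
        stride <- if (b == 1L && s > 1L) 2L else 1L
        layers <- c(layers, list(
          build_block(c_in, ch[s], stride, cfg$se$reduction)))
        c_in <- ch[s]
      }
    }
    layers <- c(layers, list(nn_gap(), nn_dense(c_in, cfg$out_dim)))
    structure(list(net = nn_seq(layers), config = cfg, seed = seed),
              class = "msa_resnet")
  })
}

#' Number of trainable parameters
#'
#' @param model An `msa_resnet` (or any internal layer).
#' @return Integer parameter count (weights, biases, batch-norm affine
#'   terms; running statistics excluded).
#' @export
count_parameters <- function(model) {
  ly <- if (inherits(model, "msa_resnet")) model$net else model
  nn_count_params(ly)
}

# Coerce supported input containers to a 3 x L x N array.
as_input_array <- function(inputs) {
  if (inherits(inputs, "bp_dataset")) inputs <- inputs$inputs
  if (is.matrix(inputs)) inputs <- array(inputs, dim = c(dim(inputs), 1L))
  if (length(dim(inputs)) != 3)
    stop("inputs must be a 3 x L x N array, a 3 x L matrix, or a bp_dataset",
         call. = FALSE)
  inputs
}

#' Predict SBP/DBP for a batch of windows
#'
#' Runs the network in inference mode (batch-norm uses running statistics,
#' so predictions are deterministic and independent of batch composition).
#'
#' @param object A built (and usually trained) `msa_resnet`.
#' @param inputs 3 x L x N array, 3 x L matrix, or `bp_dataset`.
#' @param batch_size Samples per forward chunk.
#' @param ... Unused.
#' @return N x 2 matrix with columns `sbp`, `dbp` (mmHg), rows in input order.
#' @export
predict.msa_resnet <- function(object, inputs, batch_size = 256L, ...) {
  inputs <- as_input_array(inputs)
  if (dim(inputs)[1] != object$config$in_channels)
    stop("wrong number of input channels", call. = FALSE)
  L <- dim(inputs)[2]
  n <- dim(inputs)[3]
  out <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("sbp", "dbp")))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1L)
    x <- matrix(inputs[, , idx, drop = FALSE], nrow = dim(inputs)[1])
    tn <- new_tensor(x, dim(inputs)[1], L, length(idx))
    out[idx, ] <- t(nn_forward(object$net, tn, training = FALSE)$x)
  }
  out
}

#' Per-component summary of an MSA-ResNet
#'
#' Traces one dummy window through the network and reports, per top-level
#' component, the output shape (channels x length) and parameter count.
#'
#' @param model An `msa_resnet`.
#' @param input_length Window length used for the trace.
#' @return A tibble with `component`, `out_channels`, `out_length`, `params`.
#' @export
model_summary <- function(model, input_length = model$config$input_length) {
  tn <- new_tensor(matrix(0, model$config$in_channels, input_length),
                   model$config$in_channels, input_length, 1L)
  rows <- lapply(seq_along(model$net$layers), function(i) {
    ly <- model$net$layers[[i]]
    tn <<- nn_forward(ly, tn, training = FALSE)
    tibble::tibble(component = ly$kind, out_channels = tn$C,
                   out_length = tn$L, params = nn_count_params(ly))
  })
  out <- dplyr::bind_rows(rows)
  out$component <- make.unique(out$component)
  out
}

#' @export
print.msa_resnet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<msa_resnet> width x%g, stages [%s] x [%s] ch, SE 1/%d, %s parameters\n",
    cfg$width_multiplier,
    paste(cfg$blocks_per_stage, collapse = ","),
    paste(vapply(cfg$stage_channels, scale_width, integer(1),
                 wm = cfg$width_multiplier), collapse = ","),
    cfg$se$reduction,
    format(count_parameters(x), big.mark = ",")))
  invisible(x)
}
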