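nt <- ppgbp:::new_tensor
fwd <- ppgbp:::nn_forward

test_that("the multi-scale stem maps 3x375 to 64x188 with equal branches", {
  set.seed(1)
  stem <- ppgbp:::build_msfe(msfe_config(), in_channels = 3, wm = 1)
  x <- nt(matrix(stats::rnorm(3 * 375 * 2), 3, 375 * 2), 3L, 375L, 2L)
  out <- fwd(stem, x, training = FALSE)
  expect_equal(out$C, 64)
  expect_equal(out$L, 188)
  # every branch produces the same output length (same padding)
  lens <- vapply(stem$branches, function(b)
    fwd(b, x, training = FALSE)$L, integer(1))
  expect_true(all(lens == 188))
})

test_that("branch lengths stay equal for arbitrary odd kernels and lengths", {
  set.seed(2)
  for (trial in 1:5) {
    ks <- sort(sample(c(3, 5, 7, 9, 11), 3))
    L <- sample(64:400, 1)
    cfg <- msfe_config(regular_kernels = ks, large_kernel = 15,
                       branch_channels = 4, out_channels = 16)
    stem <- ppgbp:::build_msfe(cfg, in_channels = 3, wm = 1)
    x <- nt(matrix(stats::rnorm(3 * L), 3, L), 3L, as.integer(L), 1L)
    lens <- vapply(stem$branches, function(b)
      fwd(b, x, training = FALSE)$L, integer(1))
    expect_equal(length(unique(lens)), 1)
    expect_equal(lens[1], as.integer(ceiling(L / 2)))
  }
})

test_that("an all-zero input with zero shifts maps to an all-zero stem output", {
  set.seed(3)
  stem <- ppgbp:::build_msfe(msfe_config(), in_channels = 3, wm = 1)
  x <- nt(matrix(0, 3, 375), 3L, 375L, 1L)
  out <- fwd(stem, x, training = FALSE)
  expect_true(all(abs(out$x) < 1e-12))
})

test_that("depthwise separable convolutions are cheaper than full ones", {
  # worked case: 3 -> 16 channels, kernel 13
  set.seed(4)
  dw <- ppgbp:::nn_dwconv(3, 13, bias = TRUE)
  pw <- ppgbp:::nn_conv(3, 16, 1, bias = TRUE)
  full <- ppgbp:::nn_conv(3, 16, 13, bias = TRUE)
  expect_equal(ppgbp:::nn_count_params(dw), 3 * 13 + 3)          # 42
  expect_equal(ppgbp:::nn_count_params(pw), 3 * 16 + 16)         # 64
  expect_equal(ppgbp:::nn_count_params(full), 3 * 16 * 13 + 16)  # 640
  expect_lt(ppgbp:::nn_count_params(dw) + ppgbp:::nn_count_params(pw),
            ppgbp:::nn_count_params(full))
  # closed-form economy: c*k + c*m < m*c*k whenever k > 1 and m >= 2
  for (c_in in c(2, 3, 8)) {
    for (k in c(3, 13)) {
      for (m in c(2, 16)) {
        expect_lt(c_in * k + c_in * m, m * c_in * k)
      }
    }
  }
})

test_that("squeeze-and-excitation preserves shape and contracts magnitudes", {
  set.seed(5)
  se <- ppgbp:::nn_se(8, reduction = 4)
  x <- nt(matrix(stats::rnorm(8 * 40 * 3), 8, 120), 8L, 40L, 3L)
  out <- fwd(se, x, training = TRUE)
  expect_equal(dim(out$x), dim(x$x))
  s <- se$cache$s
  expect_true(all(s > 0 & s < 1))                 # sigmoid gates
  expect_true(all(abs(out$x) <= abs(x$x) + 1e-12))  # elementwise contraction

  # forcing large positive logits drives the gates to 1: identity limit
  se$b2 <- rep(50, 8)
  se$W2 <- matrix(0, 8, 2)
  out_id <- fwd(se, x, training = FALSE)
  expect_equal(out_id$x, x$x, tolerance = 1e-12)
})

test_that("a hand-set two-channel SE block matches a by-hand evaluation", {
  se <- ppgbp:::nn_se(2, reduction = 2)           # hidden width 1
  se$W1 <- matrix(c(1, -1), 1, 2)
  se$b1 <- 0.5
  se$W2 <- matrix(c(2, -2), 2, 1)
  se$b2 <- c(0, 0)
  # channel means z = (1, 0) -> a1 = 1.5 -> logits (3, -3)
  x <- nt(rbind(c(1, 1), c(0, 0)), 2L, 2L, 1L)
  out <- fwd(se, x, training = FALSE)
  s_hand <- 1 / (1 + exp(-c(3, -3)))
  expect_equal(out$x, rbind(c(1, 1) * s_hand[1], c(0, 0) * s_hand[2]),
               tolerance = 1e-12)
})

test_that("residual blocks reduce to ReLU(x) when the body is silenced", {
  set.seed(6)
  blk <- ppgbp:::build_block(16, 16, stride = 1L, reduction = 16)
  expect_null(blk$shortcut)
  # zero the body's final batch-norm affine terms: F(x) = 0 exactly
  last_bn <- blk$body$layers[[5]]
  last_bn$g <- rep(0, 16)
  last_bn$b <- rep(0, 16)
  x <- nt(matrix(stats::rnorm(16 * 30), 16, 30), 16L, 30L, 1L)
  out <- fwd(blk, x, training = TRUE)
  expect_equal(out$x, pmax(x$x, 0), tolerance = 1e-12)

  # the shortcut still carries gradient when the body contributes nothing
  dt <- ppgbp:::nn_backward(blk, nt(matrix(1, 16, 30), 16L, 30L, 1L))
  expect_gt(sum(abs(dt$x)), 0)
})

test_that("stride-2 blocks halve the length (ceiling) via projection", {
  set.seed(7)
  for (L in c(64, 93, 188)) {
    blk <- ppgbp:::build_block(8, 16, stride = 2L, reduction = 8)
    x <- nt(matrix(stats::rnorm(8 * L), 8, L), 8L, as.integer(L), 1L)
    out <- fwd(blk, x, training = FALSE)
    expect_equal(out$L, as.integer(ceiling(L / 2)))
    expect_equal(out$C, 16L)
  }
})

test_that("stage lengths follow the stride arithmetic for any input length", {
  m <- build_msa_resnet(model_config(width_multiplier = 0.25), seed = 1)
  for (L in c(64, 200, 375)) {
    sm <- model_summary(m, input_length = L)
    l1 <- ceiling(L / 2)          # stem
    l2 <- ceiling(l1 / 2)         # max-pool
    expect_equal(sm$out_length[sm$component == "msfe"], l1)
    expect_equal(sm$out_length[sm$component == "maxpool"], l2)
    l <- l2
    for (s in 2:4) l <- ceiling(l / 2)
    expect_equal(sm$out_length[sm$component == "gap"], 1)
    blocks <- sm[grepl("residual", sm$component), ]
    expect_equal(blocks$out_length[nrow(blocks)], l)
  }
})

test_that("the total parameter count matches a layer-by-layer closed form", {
  # independent oracle written from the architecture description
  msfe_params <- function(cin, bc) {
    regular <- sum(vapply(c(3, 5, 7), function(k) bc * cin * k + 2 * bc,
                          numeric(1)))
    large <- cin * 13 + bc * cin + 2 * bc
    reshape <- (4 * bc) * (4 * bc) + 2 * (4 * bc)
    regular + large + reshape
  }
  block_params <- function(cin, cout, project, reduction) {
    h <- max(1, cout %/% reduction)
    p <- cout * cin * 3 + 2 * cout +      # conv1 + bn1
      cout * cout * 3 + 2 * cout +        # conv2 + bn2
      h * cout + h + cout * h + cout      # SE bottleneck
    if (project) p <- p + cout * cin + 2 * cout
    p
  }
  oracle <- function(wm) {
    bc <- max(1, round(16 * wm))
    ch <- vapply(c(64, 128, 256, 512), function(c) max(1, round(c * wm)),
                 numeric(1))
    total <- msfe_params(3, bc)
    cin <- 4 * bc
    blocks <- c(3, 4, 6, 3)
    for (s in 1:4) {
      for (b in seq_len(blocks[s])) {
        project <- (b == 1 && s > 1)
        total <- total + block_params(cin, ch[s], project, 16)
        cin <- ch[s]
      }
    }
    total + 2 * ch[4] + 2                 # head
  }
  m_quarter <- build_msa_resnet(model_config(width_multiplier = 0.25),
                                seed = 1)
  expect_equal(count_parameters(m_quarter), oracle(0.25))
  m_full <- build_msa_resnet(model_config(), seed = 1)
  expect_equal(count_parameters(m_full), oracle(1))
  expect_lt(count_parameters(m_quarter), count_parameters(m_full))
})

test_that("prediction is deterministic, batch-independent and seed-stable", {
  m <- build_msa_resnet(model_config(width_multiplier = 0.25), seed = 11)
  set.seed(99)
  x <- array(stats::rnorm(3 * 375 * 8), c(3, 375, 8))
  p1 <- predict(m, x)
  p2 <- predict(m, x)
  expect_equal(dim(p1), c(8, 2))
  expect_true(all(is.finite(p1)))
  expect_identical(p1, p2)

  # single sample vs the same sample inside a batch
  p_single <- predict(m, x[, , 3])
  expect_equal(unname(p_single[1, ]), unname(p1[3, ]), tolerance = 1e-5)

  # identical seeds give identical initializations
  m2 <- build_msa_resnet(model_config(width_multiplier = 0.25), seed = 11)
  expect_identical(predict(m2, x), p1)
  m3 <- build_msa_resnet(model_config(width_multiplier = 0.25), seed = 12)
  expect_false(identical(predict(m3, x), p1))

  expect_error(predict(m, array(0, c(2, 375, 1))), "channels")
})

test_that("configuration invariants are enforced at build time", {
  expect_error(msfe_config(regular_kernels = c(3, 4, 7)), "odd")
  expect_error(msfe_config(branch_channels = 8), "concat")
  expect_error(model_config(blocks_per_stage = c(3, 4),
                            stage_channels = c(64, 128, 256)), "equal length")
  expect_error(model_config(out_dim = 3), "SBP, DBP")
  expect_error(build_msa_resnet(
    model_config(msfe = msfe_config(branch_channels = 8, out_channels = 32),
                 stage_channels = c(64, 128, 256, 512))), "stem")
})

test_that("checkpoints restore weights and running statistics exactly", {
  ds <- tiny_dataset()
  m <- build_msa_resnet(model_config(width_multiplier = 0.25), seed = 21)
  fit <- train_bp_model(m, ds, train_config(epochs = 1, batch_size = 32,
                                            lr0 = 0.01, seed = 3))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit$model, path)
  back <- load_checkpoint(path)
  x <- ds$inputs[, , 1:5, drop = FALSE]
  expect_identical(predict(back, x), predict(fit$model, x))
})
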