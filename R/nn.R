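# Minimal 1-D neural-network engine.
#
# Feature maps are stored as C x (L*B) matrices (channels by
# length-within-sample, samples blocked along columns), so convolutions
# reduce to im2col gathers plus one BLAS gemm per layer, and the backward
# pass to the matching scatter-adds. Layers are environments (mutable in
# place): each holds its parameters, gradients, momentum buffers and the
# activation cache of the last forward call.
#
# Supported layers: conv (regular 1-D, "same" padding, arbitrary stride),
# dwconv (depthwise), bn (batch norm over batch x length), relu, maxpool,
# gap (global average pooling), dense, se (squeeze-and-excitation), seq,
# residual (body + shortcut + ReLU), msfe (parallel multi-scale stem).

new_tensor <- function(x, C, L, B) list(x = x, C = C, L = L, B = B)

new_layer <- function(.kind, ...) {
  e <- new.env(parent = emptyenv())
  e$kind <- .kind
  e$idxcache <- list()
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e
}

# "Same"-padding gather indices for kernel k, stride s on length L, batch B.
conv_indices <- function(ly, L, B, k, stride) {
  key <- paste(L, B, sep = "x")
  hit <- ly$idxcache[[key]]
  if (!is.null(hit)) return(hit)
  Lout <- as.integer(ceiling(L / stride))
  pad <- max(0L, (Lout - 1L) * stride + k - L)
  pl <- pad %/% 2L
  Lp <- L + pad
  fidx <- as.vector(outer((pl + 1L):(pl + L), (seq_len(B) - 1L) * Lp, "+"))
  taps <- lapply(seq_len(k), function(j)
    as.vector(outer((seq_len(Lout) - 1L) * stride + j,
                    (seq_len(B) - 1L) * Lp, "+")))
  idx <- list(Lout = Lout, Lp = Lp, fidx = fidx, taps = taps)
  ly$idxcache[[key]] <- idx
  idx
}

nn_conv <- function(c_in, c_out, k, stride = 1L, bias = FALSE) {
  W <- matrix(stats::rnorm(c_out * c_in * k, sd = sqrt(2 / (c_in * k))),
              c_out, c_in * k)
  new_layer("conv", c_in = c_in, c_out = c_out, k = as.integer(k),
            stride = as.integer(stride), bias = bias, W = W,
            b = if (bias) numeric(c_out) else NULL,
            pnames = if (bias) c("W", "b") else "W")
}

nn_dwconv <- function(c, k, stride = 1L, bias = FALSE) {
  W <- matrix(stats::rnorm(c * k, sd = sqrt(2 / k)), c, k)
  new_layer("dwconv", c_in = c, c_out = c, k = as.integer(k),
            stride = as.integer(stride), bias = bias, W = W,
            b = if (bias) numeric(c) else NULL,
            pnames = if (bias) c("W", "b") else "W")
}

nn_bn <- function(c, eps = 1e-5, momentum = 0.1) {
  new_layer("bn", c = c, eps = eps, momentum = momentum,
            g = rep(1, c), b = numeric(c),
            rm = numeric(c), rv = rep(1, c), pnames = c("g", "b"))
}

nn_relu <- function() new_layer("relu", pnames = character(0))

nn_maxpool <- function(k = 3L, stride = 2L)
  new_layer("maxpool", k = as.integer(k), stride = as.integer(stride),
            pnames = character(0))

nn_gap <- function() new_layer("gap", pnames = character(0))

nn_dense <- function(d_in, d_out, bias = TRUE) {
  new_layer("dense", d_in = d_in, d_out = d_out,
            W = matrix(stats::rnorm(d_out * d_in, sd = sqrt(2 / d_in)),
                       d_out, d_in),
            b = numeric(d_out), pnames = c("W", "b"))
}

nn_se <- function(c, reduction = 16L) {
  h <- max(1L, c %/% reduction)
  new_layer("se", c = c, h = h,
            W1 = matrix(stats::rnorm(h * c, sd = sqrt(2 / c)), h, c),
            b1 = numeric(h),
            W2 = matrix(stats::rnorm(c * h, sd = sqrt(2 / h)), c, h),
            b2 = numeric(c),
            pnames = c("W1", "b1", "W2", "b2"))
}

nn_seq <- function(layers) new_layer("seq", layers = layers,
                                     pnames = character(0))

nn_residual <- function(body, shortcut = NULL)
  new_layer("residual", body = body, shortcut = shortcut,
            pnames = character(0))

nn_msfe <- function(branches, reshape, branch_channels)
  new_layer("msfe", branches = branches, reshape = reshape,
            branch_channels = branch_channels, pnames = character(0))

# ---- forward ---------------------------------------------------------------

nn_forward <- function(ly, tn, training = TRUE) {
  switch(ly$kind,
    conv = {
      idx <- conv_indices(ly, tn$L, tn$B, ly$k, ly$stride)
      Xp <- matrix(0, tn$C, idx$Lp * tn$B)
      Xp[, idx$fidx] <- tn$x
      Xcol <- matrix(0, tn$C * ly$k, idx$Lout * tn$B)
      for (j in seq_len(ly$k))
        Xcol[((j - 1L) * tn$C + 1L):(j * tn$C), ] <- Xp[, idx$taps[[j]]]
      Y <- ly$W %*% Xcol
      if (ly$bias) Y <- Y + ly$b
      if (training) ly$cache <- list(Xcol = Xcol, idx = idx, C = tn$C,
                                     L = tn$L, B = tn$B)
      new_tensor(Y, ly$c_out, idx$Lout, tn$B)
    },
    dwconv = {
      idx <- conv_indices(ly, tn$L, tn$B, ly$k, ly$stride)
      Xp <- matrix(0, tn$C, idx$Lp * tn$B)
      Xp[, idx$fidx] <- tn$x
      Y <- matrix(0, tn$C, idx$Lout * tn$B)
      for (j in seq_len(ly$k)) Y <- Y + ly$W[, j] * Xp[, idx$taps[[j]]]
      if (ly$bias) Y <- Y + ly$b
      if (training) ly$cache <- list(Xp = Xp, idx = idx, C = tn$C,
                                     L = tn$L, B = tn$B)
      new_tensor(Y, ly$c_out, idx$Lout, tn$B)
    },
    bn = {
      if (training) {
        mu <- rowMeans(tn$x)
        xc <- tn$x - mu
        v <- rowMeans(xc * xc)
        istd <- 1 / sqrt(v + ly$eps)
        xhat <- xc * istd
        ly$rm <- (1 - ly$momentum) * ly$rm + ly$momentum * mu
        ly$rv <- (1 - ly$momentum) * ly$rv + ly$momentum * v
        ly$cache <- list(xhat = xhat, istd = istd)
        new_tensor(ly$g * xhat + ly$b, tn$C, tn$L, tn$B)
      } else {
        xhat <- (tn$x - ly$rm) / sqrt(ly$rv + ly$eps)
        new_tensor(ly$g * xhat + ly$b, tn$C, tn$L, tn$B)
      }
    },
    relu = {
      mask <- tn$x > 0
      if (training) ly$cache <- list(mask = mask)
      new_tensor(tn$x * mask, tn$C, tn$L, tn$B)
    },
    maxpool = {
      idx <- conv_indices(ly, tn$L, tn$B, ly$k, ly$stride)
      Xp <- matrix(-Inf, tn$C, idx$Lp * tn$B)
      Xp[, idx$fidx] <- tn$x
      Y <- Xp[, idx$taps[[1]]]
      amax <- matrix(1L, nrow(Y), ncol(Y))
      for (j in 2:ly$k) {
        cand <- Xp[, idx$taps[[j]]]
        upd <- cand > Y
        Y[upd] <- cand[upd]
        amax[upd] <- j
      }
      if (training) ly$cache <- list(amax = amax, idx = idx, C = tn$C,
                                     L = tn$L, B = tn$B)
      new_tensor(Y, tn$C, idx$Lout, tn$B)
    },
    gap = {
      grp <- rep(seq_len(tn$B), each = tn$L)
      z <- t(rowsum(t(tn$x), grp)) / tn$L
      dimnames(z) <- NULL
      if (training) ly$cache <- list(L = tn$L, B = tn$B)
      new_tensor(z, tn$C, 1L, tn$B)
    },
    dense = {
      Y <- ly$W %*% tn$x + ly$b
      if (training) ly$cache <- list(x = tn$x)
      new_tensor(Y, ly$d_out, 1L, tn$B)
    },
    se = {
      grp <- rep(seq_len(tn$B), each = tn$L)
      z <- t(rowsum(t(tn$x), grp)) / tn$L           # squeeze: C x B
      dimnames(z) <- NULL
      a1 <- ly$W1 %*% z + ly$b1
      h1 <- a1 * (a1 > 0)
      a2 <- ly$W2 %*% h1 + ly$b2
      s <- 1 / (1 + exp(-a2))                        # excite: C x B in (0,1)
      sg <- s[, grp, drop = FALSE]
      if (training) ly$cache <- list(x = tn$x, z = z, a1 = a1, h1 = h1,
                                     s = s, grp = grp, L = tn$L, B = tn$B)
      new_tensor(tn$x * sg, tn$C, tn$L, tn$B)        # scale
    },
    seq = {
      for (sub in ly$layers) tn <- nn_forward(sub, tn, training)
      tn
    },
    residual = {
      yb <- nn_forward(ly$body, tn, training)
      ys <- if (is.null(ly$shortcut)) tn else nn_forward(ly$shortcut, tn, training)
      s <- yb$x + ys$x
      mask <- s > 0
      if (training) ly$cache <- list(mask = mask, identity = is.null(ly$shortcut))
      new_tensor(s * mask, yb$C, yb$L, yb$B)
    },
    msfe = {
      outs <- lapply(ly$branches, nn_forward, tn = tn, training = training)
      Y <- do.call(rbind, lapply(outs, `[[`, "x"))
      cat_tn <- new_tensor(Y, sum(ly$branch_channels), outs[[1]]$L, tn$B)
      nn_forward(ly$reshape, cat_tn, training)
    },
    stop("unknown layer kind: ", ly$kind)
  )
}

# ---- backward --------------------------------------------------------------

nn_backward <- function(ly, dt) {
  switch(ly$kind,
    conv = {
      ch <- ly$cache
      dY <- dt$x
      ly$dW <- dY %*% t(ch$Xcol)
      if (ly$bias) ly$db <- rowSums(dY)
      dXcol <- crossprod(ly$W, dY)
      idx <- ch$idx
      dXp <- matrix(0, ch$C, idx$Lp * ch$B)
      for (j in seq_len(ly$k)) {
        rows <- ((j - 1L) * ch$C + 1L):(j * ch$C)
        dXp[, idx$taps[[j]]] <- dXp[, idx$taps[[j]]] +
          dXcol[rows, , drop = FALSE]
      }
      new_tensor(dXp[, idx$fidx, drop = FALSE], ch$C, ch$L, ch$B)
    },
    dwconv = {
      ch <- ly$cache
      dY <- dt$x
      idx <- ch$idx
      dW <- matrix(0, ch$C, ly$k)
      dXp <- matrix(0, ch$C, idx$Lp * ch$B)
      for (j in seq_len(ly$k)) {
        tp <- idx$taps[[j]]
        dW[, j] <- rowSums(dY * ch$Xp[, tp, drop = FALSE])
        dXp[, tp] <- dXp[, tp] + dY * ly$W[, j]
      }
      ly$dW <- dW
      if (ly$bias) ly$db <- rowSums(dY)
      new_tensor(dXp[, idx$fidx, drop = FALSE], ch$C, ch$L, ch$B)
    },
    bn = {
      ch <- ly$cache
      dY <- dt$x
      ly$dg <- rowSums(dY * ch$xhat)
      ly$db <- rowSums(dY)
      dX <- (ly$g * ch$istd) *
        (dY - rowMeans(dY) - ch$xhat * rowMeans(dY * ch$xhat))
      new_tensor(dX, dt$C, dt$L, dt$B)
    },
    relu = new_tensor(dt$x * ly$cache$mask, dt$C, dt$L, dt$B),
    maxpool = {
      ch <- ly$cache
      idx <- ch$idx
      dXp <- matrix(0, ch$C, idx$Lp * ch$B)
      for (j in seq_len(ly$k)) {
        sel <- ly$cache$amax == j
        if (any(sel)) {
          tp <- idx$taps[[j]]
          dXp[, tp] <- dXp[, tp] + dt$x * sel
        }
      }
      new_tensor(dXp[, idx$fidx, drop = FALSE], ch$C, ch$L, ch$B)
    },
    gap = {
      ch <- ly$cache
      dX <- dt$x[, rep(seq_len(ch$B), each = ch$L), drop = FALSE] / ch$L
      new_tensor(dX, dt$C, ch$L, ch$B)
    },
    dense = {
      ly$dW <- dt$x %*% t(ly$cache$x)
      ly$db <- rowSums(dt$x)
      new_tensor(crossprod(ly$W, dt$x), ly$d_in, 1L, dt$B)
    },
    se = {
      ch <- ly$cache
      dY <- dt$x
      dX <- dY * ch$s[, ch$grp, drop = FALSE]
      dS <- t(rowsum(t(dY * ch$x), ch$grp))          # C x B
      dimnames(dS) <- NULL
      da2 <- dS * ch$s * (1 - ch$s)
      ly$dW2 <- da2 %*% t(ch$h1)
      ly$db2 <- rowSums(da2)
      da1 <- crossprod(ly$W2, da2) * (ch$a1 > 0)
      ly$dW1 <- da1 %*% t(ch$z)
      ly$db1 <- rowSums(da1)
      dz <- crossprod(ly$W1, da1)
      dX <- dX + dz[, ch$grp, drop = FALSE] / ch$L
      new_tensor(dX, dt$C, ch$L, ch$B)
    },
    seq = {
      for (sub in rev(ly$layers)) dt <- nn_backward(sub, dt)
      dt
    },
    residual = {
      d <- new_tensor(dt$x * ly$cache$mask, dt$C, dt$L, dt$B)
      dxb <- nn_backward(ly$body, d)
      dxs <- if (ly$cache$identity) d else nn_backward(ly$shortcut, d)
      new_tensor(dxb$x + dxs$x, dxb$C, dxb$L, dxb$B)
    },
    msfe = {
      d <- nn_backward(ly$reshape, dt)
      ends <- cumsum(ly$branch_channels)
      starts <- c(1L, utils::head(ends, -1) + 1L)
      acc <- NULL
      for (i in seq_along(ly$branches)) {
        di <- new_tensor(d$x[starts[i]:ends[i], , drop = FALSE],
                         ly$branch_channels[i], d$L, d$B)
        dx <- nn_backward(ly$branches[[i]], di)
        acc <- if (is.null(acc)) dx else new_tensor(acc$x + dx$x,
                                                    dx$C, dx$L, dx$B)
      }
      acc
    },
    stop("unknown layer kind: ", ly$kind)
  )
}

# ---- traversal, SGD, state -------------------------------------------------

nn_walk <- function(ly, f) {
  f(ly)
  switch(ly$kind,
    seq = for (sub in ly$layers) nn_walk(sub, f),
    residual = {
      nn_walk(ly$body, f)
      if (!is.null(ly$shortcut)) nn_walk(ly$shortcut, f)
    },
    msfe = {
      for (sub in ly$branches) nn_walk(sub, f)
      nn_walk(ly$reshape, f)
    })
  invisible(NULL)
}

grad_name <- function(nm) paste0("d", nm)

# Momentum SGD step over every parameter in the tree; gradients are cleared.
sgd_step <- function(root, lr, momentum = 0.9) {
  nn_walk(root, function(ly) {
    for (nm in ly$pnames) {
      g <- ly[[grad_name(nm)]]
      if (is.null(g)) next
      vn <- paste0("v", nm)
      v <- ly[[vn]]
      if (is.null(v)) v <- 0
      v <- momentum * v - lr * g
      assign(vn, v, envir = ly)
      assign(nm, ly[[nm]] + v, envir = ly)
      assign(grad_name(nm), NULL, envir = ly)
    }
  })
}

nn_count_params <- function(ly) {
  total <- 0
  nn_walk(ly, function(l) {
    for (nm in l$pnames) total <<- total + length(l[[nm]])
  })
  total
}

# Snapshot / restore all parameters and batch-norm running statistics.
nn_state <- function(ly) {
  st <- list()
  i <- 0
  nn_walk(ly, function(l) {
    i <<- i + 1
    nms <- c(l$pnames, if (l$kind == "bn") c("rm", "rv"))
    if (length(nms)) st[[as.character(i)]] <<- mget(nms, envir = l)
  })
  st
}

nn_load_state <- function(ly, st) {
  i <- 0
  nn_walk(ly, function(l) {
    i <<- i + 1
    vals <- st[[as.character(i)]]
    if (!is.null(vals)) for (nm in names(vals)) assign(nm, vals[[nm]], envir = l)
  })
  invisible(ly)
}

# Drop forward caches (keeps checkpoints and returned models lean).
nn_clear_cache <- function(ly) {
  nn_walk(ly, function(l) {
    l$cache <- NULL
    l$idxcache <- list()
  })
  invisible(ly)
}
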