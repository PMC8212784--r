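# Minimal reverse-mode automatic differentiation over dense arrays.
#
# A tape records one forward pass as an ordered list of ops; each op holds the
# ids of its inputs and a closure mapping the output gradient to per-input
# gradients. backward() replays the tape in reverse, accumulating gradients at
# shared nodes (encoder features feed the downsampling path and both decoder
# skip connections, so fan-out is the rule, not the exception).
#
# Everything here is internal; the network module is the public surface.

tp_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$vals <- list()
  tp$ops <- list()
  tp$n <- 0L
  tp
}

tp_leaf <- function(tp, value) {
  tp$n <- tp$n + 1L
  tp$vals[[tp$n]] <- value
  tp$n
}

tp_op <- function(tp, value, ins, bw) {
  id <- tp_leaf(tp, value)
  tp$ops[[length(tp$ops) + 1L]] <- list(out = id, ins = as.integer(ins), bw = bw)
  id
}

# `id` may be a nested op call that appends to the tape; force it before
# touching tp$vals or the fetched list is stale
tp_value <- function(tp, id) {
  force(id)
  tp$vals[[id]]
}

# Gradients of `loss_id` (a scalar node) with respect to every node; returns a
# list indexed by node id (NULL where the node does not influence the loss).
tp_backward <- function(tp, loss_id) {
  grads <- vector("list", tp$n)
  grads[[loss_id]] <- 1
  for (k in rev(seq_along(tp$ops))) {
    op <- tp$ops[[k]]
    g <- grads[[op$out]]
    if (is.null(g)) next
    gs <- op$bw(g)
    for (j in seq_along(op$ins)) {
      if (is.null(gs[[j]])) next
      i <- op$ins[j]
      grads[[i]] <- if (is.null(grads[[i]])) gs[[j]] else grads[[i]] + gs[[j]]
    }
  }
  grads
}

# ---- ops ------------------------------------------------------------------

# 3D convolution; x: (D,H,W,Cin) node, w: (K^3*Cin x Cout) matrix node,
# b: length-Cout node.
op_conv <- function(tp, x_id, w_id, b_id, K, stride = 1L, pad = (K - 1L) %/% 2L) {
  x <- tp_value(tp, x_id); w <- tp_value(tp, w_id); b <- tp_value(tp, b_id)
  xdim <- dim(x)
  y <- .conv3d_forward(x, xdim, w, b, K, stride, pad)
  tp_op(tp, y, c(x_id, w_id, b_id), function(dy) {
    g <- .conv3d_backward(x, xdim, w, dy, K, stride, pad)
    list(g$dx, g$dw, g$db)
  })
}

# transposed convolution, kernel 2 stride 2 (doubles each spatial dim)
op_upconv <- function(tp, x_id, w_id, b_id) {
  x <- tp_value(tp, x_id); w <- tp_value(tp, w_id); b <- tp_value(tp, b_id)
  y <- .upconv2_forward(x, dim(x), w, b)
  tp_op(tp, y, c(x_id, w_id, b_id), function(dy) {
    g <- .upconv2_backward(x, dim(x), w, dy)
    list(g$dx, g$dw, g$db)
  })
}

# Per-channel normalization over spatial voxels (batch norm in the
# single-patch regime), with learned gain/shift. `ctx` (an environment or
# NULL) carries the train/eval mode and the running statistics: in training
# mode batch statistics normalize and the running averages are updated; in
# evaluation mode the stored running statistics are used, so inference is
# independent of the patch content (background-only tiles are not
# noise-amplified).
op_batchnorm <- function(tp, x_id, gamma_id, beta_id, eps = 1e-5,
                         name = NULL, ctx = NULL) {
  x <- tp_value(tp, x_id)
  gamma <- tp_value(tp, gamma_id); beta <- tp_value(tp, beta_id)
  shp <- dim(x); C <- shp[4]; nv <- prod(shp[1:3])
  xm <- matrix(x, nrow = nv, ncol = C)
  eval_stats <- NULL
  if (!is.null(ctx) && !is.null(name) &&
      (!isTRUE(ctx$training) || isTRUE(ctx$frozen)))
    eval_stats <- ctx$stats[[name]]
  if (!is.null(eval_stats)) {
    mu <- eval_stats$mean
    va <- eval_stats$var
  } else {
    mu <- colMeans(xm)
    xc0 <- sweep(xm, 2, mu)
    va <- colMeans(xc0 * xc0)
    if (!is.null(ctx) && isTRUE(ctx$training) && !is.null(name)) {
      old <- ctx$stats[[name]]
      mom <- ctx$momentum %||% 0.9
      if (is.null(old)) old <- list(mean = numeric(C), var = rep(1, C))
      ctx$stats[[name]] <- list(mean = mom * old$mean + (1 - mom) * mu,
                                var = mom * old$var + (1 - mom) * va)
    }
  }
  xc <- sweep(xm, 2, mu)
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2, istd, `*`)
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  dim(y) <- shp
  tp_op(tp, y, c(x_id, gamma_id, beta_id), function(dy) {
    dym <- matrix(dy, nrow = nv, ncol = C)
    dgamma <- colSums(dym * xhat)
    dbeta <- colSums(dym)
    dxhat <- sweep(dym, 2, gamma, `*`)
    if (!is.null(eval_stats)) {
      dx <- sweep(dxhat, 2, istd, `*`)   # fixed statistics: plain rescale
    } else {
      dx <- sweep(dxhat, 2, colMeans(dxhat)) -
        xhat * matrix(colMeans(dxhat * xhat), nv, C, byrow = TRUE)
      dx <- sweep(dx, 2, istd, `*`)
    }
    dim(dx) <- shp
    list(dx, dgamma, dbeta)
  })
}

op_relu <- function(tp, x_id) {
  x <- tp_value(tp, x_id)
  y <- pmax(x, 0)
  dim(y) <- dim(x)
  tp_op(tp, y, x_id, function(dy) list(dy * (x > 0)))
}

op_add <- function(tp, a_id, b_id) {
  y <- tp_value(tp, a_id) + tp_value(tp, b_id)
  tp_op(tp, y, c(a_id, b_id), function(dy) list(dy, dy))
}

op_avg2 <- function(tp, a_id, b_id) {
  y <- (tp_value(tp, a_id) + tp_value(tp, b_id)) / 2
  tp_op(tp, y, c(a_id, b_id), function(dy) list(dy / 2, dy / 2))
}

# concatenate along the channel (last) axis
op_concat <- function(tp, a_id, b_id) {
  a <- tp_value(tp, a_id); b <- tp_value(tp, b_id)
  da <- dim(a); db <- dim(b)
  y <- array(c(a, b), dim = c(da[1:3], da[4] + db[4]))
  tp_op(tp, y, c(a_id, b_id), function(dy) {
    list(array(dy[, , , seq_len(da[4]), drop = FALSE], dim = da),
         array(dy[, , , da[4] + seq_len(db[4]), drop = FALSE], dim = db))
  })
}

softmax_channels <- function(x) {
  shp <- dim(x); nv <- prod(shp[1:3])
  m <- matrix(x, nrow = nv, ncol = shp[4])
  mx <- m[, 1]
  for (c in seq_len(shp[4])[-1]) mx <- pmax(mx, m[, c])
  e <- exp(m - mx)
  p <- e / rowSums(e)
  dim(p) <- shp
  p
}

# fused softmax + weighted categorical focal loss (mean over voxels);
# gradients flow to the logits only
op_focal_softmax <- function(tp, logits_id, y_true, gamma, weights,
                             eps = 1e-7) {
  z <- tp_value(tp, logits_id)
  shp <- dim(z); nv <- prod(shp[1:3]); C <- shp[4]
  P <- matrix(softmax_channels(z), nrow = nv, ncol = C)
  Y <- matrix(y_true, nrow = nv, ncol = C)
  pt <- pmin(pmax(rowSums(P * Y), eps), 1 - eps)
  wt <- as.numeric(Y %*% weights)
  loss <- mean(-wt * (1 - pt)^gamma * log(pt))
  tp_op(tp, loss, logits_id, function(dy) {
    # dL/dp_t, then through softmax: dz = a * (Y - P), a = dL/dp_t * p_t
    dLdpt <- -wt * ((1 - pt)^gamma / pt - gamma * (1 - pt)^(gamma - 1) * log(pt))
    a <- dLdpt * pt / nv
    dz <- (Y - P) * a
    dim(dz) <- shp
    list(dy * dz)
  })
}

# fused sigmoid + squared-error distance loss
op_sigmoid_mse <- function(tp, logits_id, target, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  z <- tp_value(tp, logits_id)
  s <- 1 / (1 + exp(-z))
  r <- s - target
  n <- if (reduction == "mean") length(z) else 1
  loss <- sum(r * r) / n
  tp_op(tp, loss, logits_id, function(dy) {
    dz <- 2 * r * s * (1 - s) / n
    dim(dz) <- dim(z)
    list(dy * dz)
  })
}

# lam1*a + lam2*b for scalar loss nodes
op_wsum2 <- function(tp, a_id, b_id, lam1, lam2) {
  y <- lam1 * tp_value(tp, a_id) + lam2 * tp_value(tp, b_id)
  tp_op(tp, y, c(a_id, b_id), function(dy) list(lam1 * dy, lam2 * dy))
}
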