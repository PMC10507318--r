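## Minimal reverse-mode automatic differentiation on matrices.
##
## A tape records nodes in creation order; each node holds its value, a list
## of parent nodes and a backward function mapping the node's upstream
## gradient to gradients for its parents. backward() walks the tape in
## reverse. Values are plain numeric matrices; nodes are environments so
## gradients can be accumulated in place. This engine exists because the
## package trains its own small networks; it supports exactly the operations
## those architectures need and nothing more.

tape_new <- function(training = FALSE) {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp$training <- training
  tp
}

tp_node <- function(tape, val, parents = NULL, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

tp_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

tape_backward <- function(tape, loss_node) {
  loss_node$grad <- 1
  for (k in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[k]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd$grad, nd)
    for (j in seq_along(gs)) {
      if (!is.null(gs[[j]])) tp_accum(nd$parents[[j]], gs[[j]])
    }
  }
  invisible(NULL)
}

## ---- leaves ---------------------------------------------------------------

tp_leaf <- function(tape, val) tp_node(tape, val)

## ---- arithmetic -----------------------------------------------------------

tp_matmul <- function(tape, a, b) {
  tp_node(tape, a$val %*% b$val, list(a, b), function(g, nd) {
    list(tcrossprod(g, nd$parents[[2]]$val), crossprod(nd$parents[[1]]$val, g))
  })
}

# x + bias (bias recycled along rows, one entry per column)
tp_addbias <- function(tape, x, b) {
  n <- nrow(x$val)
  tp_node(tape, x$val + rep(b$val, each = n), list(x, b), function(g, nd) {
    list(g, colSums(g))
  })
}

tp_add <- function(tape, a, b) {
  tp_node(tape, a$val + b$val, list(a, b), function(g, nd) list(g, g))
}

# add a constant (no gradient for the constant)
tp_addconst <- function(tape, x, cst) {
  tp_node(tape, x$val + cst, list(x), function(g, nd) list(g))
}

tp_mul <- function(tape, a, b) {
  tp_node(tape, a$val * b$val, list(a, b), function(g, nd) {
    list(g * nd$parents[[2]]$val, g * nd$parents[[1]]$val)
  })
}

## ---- activations ----------------------------------------------------------

tp_relu <- function(tape, x) {
  tp_node(tape, pmax(x$val, 0), list(x), function(g, nd) {
    list(g * (nd$parents[[1]]$val > 0))
  })
}

tp_sigmoid <- function(tape, x) {
  tp_node(tape, 1 / (1 + exp(-x$val)), list(x), function(g, nd) {
    y <- nd$val
    list(g * y * (1 - y))
  })
}

tp_tanh <- function(tape, x) {
  tp_node(tape, tanh(x$val), list(x), function(g, nd) {
    list(g * (1 - nd$val^2))
  })
}

## ---- regularisation -------------------------------------------------------

# inverted dropout; identity when the tape is in evaluation mode
tp_dropout <- function(tape, x, rate) {
  if (!tape$training || rate <= 0) return(x)
  mask <- (runif(length(x$val)) >= rate) / (1 - rate)
  dim(mask) <- dim(x$val)
  tp_node(tape, x$val * mask, list(x), function(g, nd) list(g * nd$mask)) -> nd
  nd$mask <- mask
  nd
}

# batch normalisation over columns (features); `state` carries running
# moments used in evaluation mode, updated with momentum 0.1 in training
tp_batchnorm <- function(tape, x, gamma, beta, state, eps = 1e-5,
                         momentum = 0.1) {
  n <- nrow(x$val)
  if (tape$training) {
    bm <- colMeans(x$val)
    xc <- x$val - rep(bm, each = n)
    bv <- colMeans(xc * xc)
    invstd <- 1 / sqrt(bv + eps)
    xhat <- xc * rep(invstd, each = n)
    state$mean <- (1 - momentum) * state$mean + momentum * bm
    unb <- if (n > 1) n / (n - 1) else 1
    state$var <- (1 - momentum) * state$var + momentum * bv * unb
    nd <- tp_node(tape, xhat * rep(gamma$val, each = n) + rep(beta$val, each = n),
                  list(x, gamma, beta), function(g, nd) {
      n <- nrow(g)
      xhat <- nd$xhat
      dgamma <- colSums(g * xhat)
      dbeta <- colSums(g)
      dxhat <- g * rep(nd$parents[[2]]$val, each = n)
      dx <- (dxhat - rep(colMeans(dxhat), each = n) -
               xhat * rep(colMeans(dxhat * xhat), each = n)) *
        rep(nd$invstd, each = n)
      list(dx, dgamma, dbeta)
    })
    nd$xhat <- xhat
    nd$invstd <- invstd
    nd
  } else {
    invstd <- 1 / sqrt(state$var + eps)
    xhat <- (x$val - rep(state$mean, each = n)) * rep(invstd, each = n)
    nd <- tp_node(tape, xhat * rep(gamma$val, each = n) + rep(beta$val, each = n),
                  list(x, gamma, beta), function(g, nd) {
      n <- nrow(g)
      list(g * rep(nd$parents[[2]]$val * nd$invstd, each = n),
           colSums(g * nd$xhat), colSums(g))
    })
    nd$xhat <- xhat
    nd$invstd <- invstd
    nd
  }
}

## ---- shape ops ------------------------------------------------------------

# pure reshape: same underlying vector order
tp_reshape <- function(tape, x, dims) {
  v <- x$val
  dim(v) <- dims
  tp_node(tape, v, list(x), function(g, nd) {
    dim(g) <- dim(nd$parents[[1]]$val)
    list(g)
  })
}

tp_cols <- function(tape, x, idx) {
  tp_node(tape, x$val[, idx, drop = FALSE], list(x), function(g, nd) {
    z <- matrix(0, nrow(nd$parents[[1]]$val), ncol(nd$parents[[1]]$val))
    z[, nd$idx] <- g
    list(z)
  }) -> nd
  nd$idx <- idx
  nd
}

# row slice with unique indices (e.g. one time step of a time-major block)
tp_rows <- function(tape, x, idx) {
  tp_node(tape, x$val[idx, , drop = FALSE], list(x), function(g, nd) {
    z <- matrix(0, nrow(nd$parents[[1]]$val), ncol(nd$parents[[1]]$val))
    z[nd$idx, ] <- g
    list(z)
  }) -> nd
  nd$idx <- idx
  nd
}

# row gather with repeated indices; backward accumulates with rowsum()
tp_gather_rows <- function(tape, x, idx) {
  tp_node(tape, x$val[idx, , drop = FALSE], list(x), function(g, nd) {
    z <- matrix(0, nrow(nd$parents[[1]]$val), ncol(nd$parents[[1]]$val))
    rs <- rowsum(g, nd$idx)
    z[as.numeric(rownames(rs)), ] <- rs
    list(z)
  }) -> nd
  nd$idx <- idx
  nd
}

# append one all-zero row (padding row for gathers that index "outside")
tp_pad_row <- function(tape, x) {
  tp_node(tape, rbind(x$val, 0), list(x), function(g, nd) {
    list(g[-nrow(g), , drop = FALSE])
  })
}

# stack a list of (B x H) nodes into a (B*length) x H time-major matrix
tp_stack_rows <- function(tape, nodes) {
  tp_node(tape, do.call(rbind, lapply(nodes, function(n) n$val)), nodes,
          function(g, nd) {
            b <- nrow(nd$parents[[1]]$val)
            lapply(seq_along(nd$parents), function(t) {
              g[((t - 1) * b + 1):(t * b), , drop = FALSE]
            })
          })
}

tp_cbind <- function(tape, a, b) {
  tp_node(tape, cbind(a$val, b$val), list(a, b), function(g, nd) {
    ka <- ncol(nd$parents[[1]]$val)
    list(g[, seq_len(ka), drop = FALSE], g[, -seq_len(ka), drop = FALSE])
  })
}

## ---- embeddings -----------------------------------------------------------

# tokens: integer vector (length B*T, time-major), values 0 (PAD) .. 4;
# W: 5 x d embedding table whose first (PAD) row is frozen at zero
tp_embed <- function(tape, tokens, W) {
  tp_node(tape, W$val[tokens + 1L, , drop = FALSE], list(W), function(g, nd) {
    dW <- matrix(0, nrow(nd$parents[[1]]$val), ncol(nd$parents[[1]]$val))
    rs <- rowsum(g, nd$tokens)
    dW[as.numeric(rownames(rs)) + 1L, ] <- rs
    dW[1L, ] <- 0 # PAD row frozen
    list(dW)
  }) -> nd
  nd$tokens <- tokens
  nd
}

## ---- attention ------------------------------------------------------------

# multi-head self-attention, one-dimensional heads; q, k, v are (B*T) x H;
# the softmax weights are only retained when gradients will be needed
tp_mhsa <- function(tape, q, k, v, B, T) {
  fw <- .mhsa_forward(q$val, k$val, v$val, B, T, tape$training)
  tp_node(tape, fw$out, list(q, k, v), function(g, nd) {
    bw <- .mhsa_backward(g, nd$attn, nd$parents[[1]]$val,
                         nd$parents[[2]]$val, nd$parents[[3]]$val,
                         nd$B, nd$T)
    list(bw$dQ, bw$dK, bw$dV)
  }) -> nd
  nd$attn <- fw$attn
  nd$B <- B
  nd$T <- T
  nd
}

## ---- loss -----------------------------------------------------------------

# mean alpha-weighted binary cross-entropy over a batch; y is (B x 1),
# scores are clamped to [eps, 1 - eps] inside the loss only
tp_wbce <- function(tape, y, labels, alpha, eps = 1e-7) {
  w <- (1 - alpha) / alpha
  yc <- pmin(pmax(y$val, eps), 1 - eps)
  l <- -(w * labels * log(yc) + (1 - labels) * log(1 - yc))
  tp_node(tape, mean(l), list(y), function(g, nd) {
    n <- length(nd$yc)
    list(matrix(g / n * (-(nd$w * nd$labels / nd$yc) +
                           (1 - nd$labels) / (1 - nd$yc)), ncol = 1))
  }) -> nd
  nd$yc <- yc
  nd$labels <- labels
  nd$w <- w
  nd
}
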