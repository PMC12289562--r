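# Minimal tape-based reverse-mode automatic differentiation on dense matrices.
#
# Every value is a node (an environment) holding a numeric matrix `val`, the
# accumulated gradient `grad`, its `parents`, and a backward closure `bw` that
# pushes the node's gradient into its parents. Scalars are 1x1 matrices.
# Sequence batches are stacked row-wise: a batch of B sequences of k tokens of
# width d is a (B*k) x d matrix, so all linear ops are single BLAS calls and
# only the attention kernel loops over the batch internally.

.ad_counter <- local({
  i <- 0L
  function() {
    i <<- i + 1L
    i
  }
})

ad_node <- function(val, parents = list(), bw = NULL, requires = FALSE,
                    name = NULL) {
  n <- new.env(parent = emptyenv())
  n$val <- if (is.matrix(val)) val else matrix(as.numeric(val), nrow = 1L)
  n$grad <- NULL
  n$parents <- parents
  n$bw <- bw
  n$requires <- requires
  n$name <- name
  n$id <- .ad_counter()
  class(n) <- "adnode"
  n
}

#' @noRd
ad_const <- function(x, name = NULL) ad_node(x, name = name)

#' @noRd
ad_param <- function(x, name = NULL) ad_node(x, requires = TRUE, name = name)

ad_value <- function(n) n$val

.ad_accum <- function(p, g) {
  if (is.null(p$grad)) {
    p$grad <- g
  } else {
    p$grad <- p$grad + g
  }
}

# Reverse pass from a scalar node. Topological order by DFS over parents.
ad_backward <- function(root) {
  stopifnot(length(root$val) == 1L)
  topo <- vector("list", 256L)
  n_topo <- 0L
  visited <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$stage == 1L) {
      if (!is.null(visited[[key]])) next
      visited[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents) {
        if (is.null(visited[[as.character(p$id)]])) {
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      n_topo <- n_topo + 1L
      if (n_topo > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[n_topo]] <- node
    }
  }
  root$grad <- matrix(1, 1L, 1L)
  for (i in seq(n_topo, 1L)) {
    node <- topo[[i]]
    if (!is.null(node$bw) && !is.null(node$grad)) node$bw(node)
  }
  invisible(root)
}

ad_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

# ---- arithmetic -------------------------------------------------------------

# a + b; b may match a, be a 1 x ncol row vector (bias broadcast), or a scalar.
ad_add <- function(a, b) {
  av <- a$val
  bv <- b$val
  if (identical(dim(av), dim(bv))) {
    v <- av + bv
    mode <- "full"
  } else if (nrow(bv) == 1L && ncol(bv) == ncol(av)) {
    v <- sweep(av, 2L, bv[1L, ], "+")
    mode <- "row"
  } else if (length(bv) == 1L) {
    v <- av + bv[1L]
    mode <- "scalar"
  } else {
    stop("ad_add: incompatible shapes")
  }
  ad_node(v, list(a, b), function(n) {
    .ad_accum(a, n$grad)
    g <- switch(mode,
      full = n$grad,
      row = matrix(colSums(n$grad), 1L),
      scalar = matrix(sum(n$grad), 1L, 1L)
    )
    .ad_accum(b, g)
  })
}

# elementwise product; one operand may be a scalar node
ad_mul <- function(a, b) {
  av <- a$val
  bv <- b$val
  if (identical(dim(av), dim(bv))) {
    ad_node(av * bv, list(a, b), function(n) {
      .ad_accum(a, n$grad * bv)
      .ad_accum(b, n$grad * av)
    })
  } else if (length(bv) == 1L) {
    ad_node(av * bv[1L], list(a, b), function(n) {
      .ad_accum(a, n$grad * bv[1L])
      .ad_accum(b, matrix(sum(n$grad * av), 1L, 1L))
    })
  } else if (length(av) == 1L) {
    ad_mul(b, a)
  } else {
    stop("ad_mul: incompatible shapes")
  }
}

# constant scalar scale (no gradient to the constant)
ad_scale <- function(a, s) {
  ad_node(a$val * s, list(a), function(n) .ad_accum(a, n$grad * s))
}

ad_sub <- function(a, b) ad_add(a, ad_scale(b, -1))

ad_matmul <- function(a, b, transpose_b = FALSE) {
  v <- if (transpose_b) tcrossprod(a$val, b$val) else a$val %*% b$val
  ad_node(v, list(a, b), function(n) {
    if (transpose_b) {
      .ad_accum(a, n$grad %*% b$val)
      .ad_accum(b, crossprod(n$grad, a$val))
    } else {
      .ad_accum(a, tcrossprod(n$grad, b$val))
      .ad_accum(b, crossprod(a$val, n$grad))
    }
  })
}

ad_transpose <- function(a) {
  ad_node(t(a$val), list(a), function(n) .ad_accum(a, t(n$grad)))
}

# ---- nonlinearities ---------------------------------------------------------

ad_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$val))
  ad_node(s, list(a), function(n) .ad_accum(a, n$grad * s * (1 - s)))
}

# exact GELU: x * Phi(x)
ad_gelu <- function(a) {
  x <- a$val
  ph <- stats::pnorm(x)
  ad_node(x * ph, list(a), function(n) {
    .ad_accum(a, n$grad * (ph + x * stats::dnorm(x)))
  })
}

ad_exp <- function(a) {
  e <- exp(a$val)
  ad_node(e, list(a), function(n) .ad_accum(a, n$grad * e))
}

row_max <- function(x) {
  x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
}

ad_softmax_rows <- function(a) {
  x <- a$val
  m <- row_max(x)
  e <- exp(x - m)
  s <- e / rowSums(e)
  ad_node(s, list(a), function(n) {
    g <- n$grad
    .ad_accum(a, s * (g - rowSums(g * s)))
  })
}

ad_logsumexp_rows <- function(a) {
  x <- a$val
  m <- row_max(x)
  e <- exp(x - m)
  se <- rowSums(e)
  ad_node(matrix(m + log(se), ncol = 1L), list(a), function(n) {
    .ad_accum(a, (e / se) * n$grad[, 1L])
  })
}

# row-wise layer normalization (no affine; compose ad_mul/ad_add for gamma/beta)
ad_layernorm_rows <- function(a, eps = 1e-5) {
  x <- a$val
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  y <- xc * inv
  ad_node(y, list(a), function(n) {
    g <- n$grad
    gm <- rowMeans(g)
    gym <- rowMeans(g * y)
    .ad_accum(a, inv * (g - gm - y * gym))
  })
}

ad_l2normalize_rows <- function(a, eps = 1e-12) {
  x <- a$val
  nr <- sqrt(rowSums(x * x) + eps)
  y <- x / nr
  ad_node(y, list(a), function(n) {
    g <- n$grad
    .ad_accum(a, (g - y * rowSums(g * y)) / nr)
  })
}

# ---- shape ops --------------------------------------------------------------

# gather rows (duplicates allowed); backward is scatter-add. Covers embedding
# lookup, row permutation/selection and tiling.
ad_gather_rows <- function(a, idx) {
  idx <- as.integer(idx)
  stopifnot(all(idx >= 1L), all(idx <= nrow(a$val)))
  ad_node(a$val[idx, , drop = FALSE], list(a), function(n) {
    gs <- rowsum(n$grad, idx)                 # C-level scatter-add
    g <- matrix(0, nrow(a$val), ncol(a$val))
    g[as.integer(rownames(gs)), ] <- gs
    .ad_accum(a, g)
  })
}

ad_rbind <- function(...) {
  nodes <- list(...)
  rows <- vapply(nodes, function(n) nrow(n$val), 1L)
  v <- do.call(rbind, lapply(nodes, ad_value))
  ends <- cumsum(rows)
  starts <- ends - rows + 1L
  ad_node(v, nodes, function(n) {
    for (i in seq_along(nodes)) {
      .ad_accum(nodes[[i]], n$grad[starts[i]:ends[i], , drop = FALSE])
    }
  })
}

ad_cbind <- function(a, b) {
  ca <- ncol(a$val)
  ad_node(cbind(a$val, b$val), list(a, b), function(n) {
    .ad_accum(a, n$grad[, seq_len(ca), drop = FALSE])
    .ad_accum(b, n$grad[, -seq_len(ca), drop = FALSE])
  })
}

# multiply every row of a by the 1 x d parameter row v (broadcast over rows)
ad_mul_rowvec <- function(a, v) {
  nr <- nrow(a$val)
  d <- ncol(a$val)
  stopifnot(nrow(v$val) == 1L, ncol(v$val) == d)
  bc <- matrix(v$val, nr, d, byrow = TRUE)
  ad_node(a$val * bc, list(a, v), function(n) {
    .ad_accum(a, n$grad * bc)
    .ad_accum(v, matrix(colSums(n$grad * a$val), 1L))
  })
}

# multiply row i by constant scalar s[i] (data-side scaling, no grad to s)
ad_scale_rows <- function(a, s) {
  s <- as.numeric(s)
  stopifnot(length(s) == nrow(a$val))
  ad_node(a$val * s, list(a), function(n) .ad_accum(a, n$grad * s))
}

# mean over each consecutive block of `block_rows` rows -> B x d
ad_block_mean <- function(a, block_rows, weights = NULL) {
  nr <- nrow(a$val)
  stopifnot(nr %% block_rows == 0L)
  B <- nr %/% block_rows
  grp <- rep(seq_len(B), each = block_rows)
  if (is.null(weights)) weights <- rep(1, nr)
  wsum <- as.numeric(tapply(weights, grp, sum))
  xw <- a$val * weights
  v <- rowsum(xw, grp) / wsum
  ad_node(v, list(a), function(n) {
    .ad_accum(a, (n$grad[grp, , drop = FALSE] / wsum[grp]) * weights)
  })
}

# repeat each row `reps` times consecutively (inverse-ish of ad_block_mean)
ad_block_expand <- function(a, reps) {
  idx <- rep(seq_len(nrow(a$val)), each = reps)
  ad_gather_rows(a, idx)
}

ad_diag <- function(a) {
  n_ <- nrow(a$val)
  stopifnot(n_ == ncol(a$val))
  ad_node(matrix(diag(a$val), ncol = 1L), list(a), function(n) {
    g <- matrix(0, n_, n_)
    diag(g) <- n$grad[, 1L]
    .ad_accum(a, g)
  })
}

ad_sum <- function(a) {
  ad_node(matrix(sum(a$val), 1L, 1L), list(a), function(n) {
    .ad_accum(a, matrix(n$grad[1L], nrow(a$val), ncol(a$val)))
  })
}

ad_sqnorm <- function(a) {
  ad_node(matrix(sum(a$val^2), 1L, 1L), list(a), function(n) {
    .ad_accum(a, 2 * n$grad[1L] * a$val)
  })
}

# ---- attention kernel -------------------------------------------------------

# Multi-head scaled-dot-product attention over a row-stacked batch.
# q: (B*kq) x d, k/v: (B*kv) x d, h heads of width d/h. `mask` is an optional
# B x kv logical matrix (TRUE = valid key). Attention matrices are kept on
# the node (`$attn`, list over blocks of kq x (h*kv)) for inspection.
# (A block-dense single-GEMM variant was benchmarked and lost to this loop at
# the text lengths used here: the off-block exp/elementwise work dominates.)
ad_batched_attention <- function(q, k, v, B, h, mask = NULL) {
  d <- ncol(q$val)
  stopifnot(d %% h == 0L, ncol(k$val) == d, ncol(v$val) == d)
  kq <- nrow(q$val) %/% B
  kv <- nrow(k$val) %/% B
  stopifnot(nrow(q$val) == B * kq, nrow(k$val) == B * kv,
            nrow(v$val) == nrow(k$val))
  dk <- d %/% h
  sc <- 1 / sqrt(dk)
  qv <- q$val
  kvv <- k$val
  vv <- v$val
  # block-diagonal validity: query row i may attend keys of its own sample
  qgrp <- rep(seq_len(B), each = kq)
  kgrp <- rep(seq_len(B), each = kv)
  out <- matrix(0, B * kq, d)
  attn <- vector("list", B)
  qrs <- lapply(seq_len(B), function(b) ((b - 1L) * kq + 1L):(b * kq))
  krs <- lapply(seq_len(B), function(b) ((b - 1L) * kv + 1L):(b * kv))
  hcols <- lapply(seq_len(h), function(hh) ((hh - 1L) * dk + 1L):(hh * dk))
  for (b in seq_len(B)) {
    qr <- qrs[[b]]
    kr <- krs[[b]]
    ab <- matrix(0, kq, h * kv)
    for (hh in seq_len(h)) {
      cols <- hcols[[hh]]
      s <- tcrossprod(qv[qr, cols, drop = FALSE],
                      kvv[kr, cols, drop = FALSE]) * sc
      if (!is.null(mask)) s[, !mask[b, ]] <- -Inf
      e <- exp(s - row_max(s))
      a <- e / rowSums(e)
      ab[, ((hh - 1L) * kv + 1L):(hh * kv)] <- a
      out[qr, cols] <- a %*% vv[kr, cols, drop = FALSE]
    }
    attn[[b]] <- ab
  }
  node <- ad_node(out, list(q, k, v), function(n) {
    gq <- matrix(0, nrow(qv), d)
    gk <- matrix(0, nrow(kvv), d)
    gv <- matrix(0, nrow(vv), d)
    for (b in seq_len(B)) {
      qr <- qrs[[b]]
      kr <- krs[[b]]
      for (hh in seq_len(h)) {
        cols <- hcols[[hh]]
        a <- attn[[b]][, ((hh - 1L) * kv + 1L):(hh * kv), drop = FALSE]
        go <- n$grad[qr, cols, drop = FALSE]
        gv[kr, cols] <- gv[kr, cols] + crossprod(a, go)
        ga <- tcrossprod(go, vv[kr, cols, drop = FALSE])
        gs <- a * (ga - rowSums(ga * a))
        gq[qr, cols] <- gq[qr, cols] +
          gs %*% kvv[kr, cols, drop = FALSE] * sc
        gk[kr, cols] <- gk[kr, cols] +
          crossprod(gs, qv[qr, cols, drop = FALSE]) * sc
      }
    }
    .ad_accum(q, gq)
    .ad_accum(k, gk)
    .ad_accum(v, gv)
  })
  node$attn <- attn
  node
}

# ---- losses -----------------------------------------------------------------

# class-weighted mean cross-entropy from logits; labels in 1..ncol(logits)
ad_crossentropy_logits <- function(logits, labels, class_weights = NULL) {
  x <- logits$val
  nclass <- ncol(x)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(x), all(labels >= 1L), all(labels <= nclass))
  if (is.null(class_weights)) class_weights <- rep(1, nclass)
  w <- class_weights[labels]
  m <- row_max(x)
  lse <- m + log(rowSums(exp(x - m)))
  picked <- x[cbind(seq_along(labels), labels)]
  loss <- sum(w * (lse - picked)) / sum(w)
  ad_node(matrix(loss, 1L, 1L), list(logits), function(n) {
    p <- exp(x - lse)
    p[cbind(seq_along(labels), labels)] <-
      p[cbind(seq_along(labels), labels)] - 1
    .ad_accum(logits, n$grad[1L] * p * (w / sum(w)))
  })
}

# ---- optimizer --------------------------------------------------------------

#' @noRd
adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr
  st$beta1 <- beta1
  st$beta2 <- beta2
  st$eps <- eps
  st$t <- 0L
  st$m <- lapply(params, function(p) p$val * 0)
  st$v <- lapply(params, function(p) p$val * 0)
  st
}

#' @noRd
adam_step <- function(st) {
  st$t <- st$t + 1L
  b1 <- st$beta1
  b2 <- st$beta2
  for (i in seq_along(st$params)) {
    p <- st$params[[i]]
    if (is.null(p$grad)) next
    st$m[[i]] <- b1 * st$m[[i]] + (1 - b1) * p$grad
    st$v[[i]] <- b2 * st$v[[i]] + (1 - b2) * p$grad^2
    mhat <- st$m[[i]] / (1 - b1^st$t)
    vhat <- st$v[[i]] / (1 - b2^st$t)
    p$val <- p$val - st$lr * mhat / (sqrt(vhat) + st$eps)
  }
  invisible(st)
}
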