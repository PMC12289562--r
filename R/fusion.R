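#' Model hyperparameter configuration
#'
#' Defaults follow the package's documented choices: fusion width `d = 64`,
#' `L = 2` fusion blocks of `h = 4` heads (per-head width `d/h`), feed-forward
#' inner width `ffn_mult * d` with GELU, learnable per-block fusion
#' coefficient lambda initialized at 1, shared two-layer projection head into
#' a `d_z = 32` contrastive space, temperature initialized at 0.07 and
#' optimized in log-space clamped to `[1e-3, 10]`, and loss weights
#' `alpha = 1`, `beta = 0.5`, `gamma = 1e-5`.
#'
#' @param d fusion width of structured and projected text tokens.
#' @param n_heads attention head count (`d` must be divisible by it).
#' @param n_blocks number of stacked fusion blocks.
#' @param d_bert text backbone hidden width.
#' @param d_z contrastive projection width.
#' @param ffn_mult feed-forward expansion factor.
#' @param l_max maximum text length in tokens (incl. classification token).
#' @param lambda_init initial fusion coefficient.
#' @param tau_init initial contrastive temperature.
#' @param alpha,beta,gamma loss weights (task, contrastive, L2).
#' @param backbone `"tiny-test"` or `"pretrained"`.
#' @param backbone_seed seed fixing the frozen tiny backbone weights.
#' @param text_stream_update if TRUE the text stream is also updated by a
#'   text-side gated cross-attention pass in each block; by default the
#'   projected text features stay fixed across blocks.
#' @param lr,batch_size,max_epochs,patience,class_weighting training defaults.
#' @param early_stop validation quantity tracked for early stopping and
#'   checkpoint selection: the task (classification) loss alone (default) or
#'   the full task + contrastive objective.
#' @return object of class `model_config`.
#' @export
model_config <- function(d = 64L, n_heads = 4L, n_blocks = 2L, d_bert = 32L,
                         d_z = 32L, ffn_mult = 4L, l_max = 64L,
                         lambda_init = 1, tau_init = 0.07,
                         alpha = 1, beta = 0.5, gamma = 1e-5,
                         backbone = "tiny-test", backbone_seed = 2024L,
                         text_stream_update = FALSE,
                         lr = 1e-3, batch_size = 32L, max_epochs = 50L,
                         patience = 5L, class_weighting = TRUE,
                         early_stop = c("task", "total")) {
  early_stop <- match.arg(early_stop)
  if (d %% n_heads != 0L) stop("d must be divisible by n_heads")
  if (tau_init <= 0) stop("tau_init must be positive")
  if (alpha <= 0 && beta <= 0) stop("at least one of alpha, beta must be > 0")
  structure(as.list(environment()), class = "model_config")
}

ln_params <- function(d, prefix) {
  list(g = ad_param(matrix(1, 1L, d), name = paste0(prefix, "_g")),
       b = ad_param(matrix(0, 1L, d), name = paste0(prefix, "_b")))
}

apply_ln <- function(x, ln) {
  ad_add(ad_mul_rowvec(ad_layernorm_rows(x), ln$g), ln$b)
}

gca_layer_params <- function(d, prefix) {
  w <- function(n, m, nm) {
    ad_param(matrix(stats::rnorm(n * m, sd = 1 / sqrt(n)), n, m),
             name = paste0(prefix, "_", nm))
  }
  list(W_q = w(d, d, "Wq"), W_k = w(d, d, "Wk"), W_v = w(d, d, "Wv"),
       W_g = w(2L * d, d, "Wg"),
       ln_x = ln_params(d, paste0(prefix, "_lnx")),
       ln_h = ln_params(d, paste0(prefix, "_lnh")))
}

sa_layer_params <- function(d, prefix) {
  w <- function(n, m, nm) {
    ad_param(matrix(stats::rnorm(n * m, sd = 1 / sqrt(n)), n, m),
             name = paste0(prefix, "_", nm))
  }
  list(W_q = w(d, d, "Wq"), W_k = w(d, d, "Wk"), W_v = w(d, d, "Wv"),
       ln = ln_params(d, paste0(prefix, "_ln")))
}

# residual self-attention over the structured token sequence; without it the
# classification token could never aggregate the other structured tokens
# (cross-attention only mixes against the text stream)
self_attention_forward <- function(X, sa, B, n_heads) {
  Xn <- apply_ln(X, sa$ln)
  att <- ad_batched_attention(ad_matmul(Xn, sa$W_q), ad_matmul(Xn, sa$W_k),
                              ad_matmul(Xn, sa$W_v), B, n_heads)
  ad_add(X, att)
}

fusion_block_params <- function(d, ffn_mult, lambda_init, prefix) {
  w <- function(n, m, nm, sd = 1 / sqrt(n)) {
    ad_param(matrix(stats::rnorm(n * m, sd = sd), n, m),
             name = paste0(prefix, "_", nm))
  }
  di <- ffn_mult * d
  list(gca = gca_layer_params(d, paste0(prefix, "_gca")),
       sa = sa_layer_params(d, paste0(prefix, "_sa")),
       W1 = w(d, di, "ffn_W1"),
       b1 = ad_param(matrix(0, 1L, di), name = paste0(prefix, "_ffn_b1")),
       W2 = w(di, d, "ffn_W2"),
       b2 = ad_param(matrix(0, 1L, d), name = paste0(prefix, "_ffn_b2")),
       ln = ln_params(d, paste0(prefix, "_ln")),
       lambda = ad_param(matrix(lambda_init, 1L, 1L),
                         name = paste0(prefix, "_lambda")))
}

#' Initialize the multimodal fusion model
#'
#' Builds every trainable parameter (embedding tables, affine numeric
#' parameters, projection, attention/gate/FFN weights, fusion coefficients,
#' classifier, contrastive head, log-temperature) from a seed, plus the frozen
#' text backbone.
#'
#' @param schema a [feature_schema()].
#' @param config a [model_config()].
#' @param seed integer seed for parameter initialization.
#' @return object of class `emr_model`.
#' @export
init_model <- function(schema, config, seed = 1L) {
  with_seed(seed, {
    d <- config$d
    card <- lengths(schema$categorical_fields)
    n_num <- length(schema$numeric_fields)
    backbone <- text_backbone(config$backbone, d_bert = config$d_bert,
                              l_max = config$l_max,
                              seed = config$backbone_seed)
    blocks <- lapply(seq_len(config$n_blocks), function(l) {
      fusion_block_params(d, config$ffn_mult, config$lambda_init,
                          sprintf("blk%d", l))
    })
    text_blocks <- if (config$text_stream_update) {
      lapply(seq_len(config$n_blocks), function(l) {
        fusion_block_params(d, config$ffn_mult, config$lambda_init,
                            sprintf("tblk%d", l))
      })
    }
    w <- function(n, m, nm, sd = 1 / sqrt(n)) {
      ad_param(matrix(stats::rnorm(n * m, sd = sd), n, m), name = nm)
    }
    model <- structure(list(
      schema = schema, config = config, seed = seed,
      cat = categorical_embedder(card, d),
      num = numerical_embedder(n_num, d),
      cls = ad_param(matrix(stats::rnorm(d, sd = 0.02), 1L, d), name = "cls"),
      backbone = backbone,
      projector = text_projector(config$d_bert, d),
      blocks = blocks, text_blocks = text_blocks,
      W_c = w(d, 2L, "clf_W"),
      b_c = ad_param(matrix(0, 1L, 2L), name = "clf_b"),
      Wz1 = w(d, d, "projhead_W1"),
      bz1 = ad_param(matrix(0, 1L, d), name = "projhead_b1"),
      Wz2 = w(d, config$d_z, "projhead_W2"),
      bz2 = ad_param(matrix(0, 1L, config$d_z), name = "projhead_b2"),
      log_tau = ad_param(matrix(log(config$tau_init), 1L, 1L),
                         name = "log_tau")
    ), class = "emr_model")
    model
  })
}

# every trainable autodiff parameter, with weight-decay eligibility flags
model_params <- function(model) {
  out <- list()
  decay <- logical()
  add <- function(p, dec) {
    out[[length(out) + 1L]] <<- p
    decay[length(decay) + 1L] <<- dec
  }
  add(model$cat$E, TRUE)
  add(model$num$W, TRUE)
  add(model$num$B, FALSE)
  add(model$cls, FALSE)
  add(model$projector$W_p, TRUE)
  add(model$projector$b_p, FALSE)
  add(model$projector$ln_g, FALSE)
  add(model$projector$ln_b, FALSE)
  for (blk in c(model$blocks, model$text_blocks)) {
    g <- blk$gca
    add(g$W_q, TRUE); add(g$W_k, TRUE); add(g$W_v, TRUE); add(g$W_g, TRUE)
    add(g$ln_x$g, FALSE); add(g$ln_x$b, FALSE)
    add(g$ln_h$g, FALSE); add(g$ln_h$b, FALSE)
    add(blk$sa$W_q, TRUE); add(blk$sa$W_k, TRUE); add(blk$sa$W_v, TRUE)
    add(blk$sa$ln$g, FALSE); add(blk$sa$ln$b, FALSE)
    add(blk$W1, TRUE); add(blk$b1, FALSE)
    add(blk$W2, TRUE); add(blk$b2, FALSE)
    add(blk$ln$g, FALSE); add(blk$ln$b, FALSE)
    add(blk$lambda, FALSE)
  }
  add(model$W_c, TRUE); add(model$b_c, FALSE)
  add(model$Wz1, TRUE); add(model$bz1, FALSE)
  add(model$Wz2, TRUE); add(model$bz2, FALSE)
  add(model$log_tau, FALSE)
  names(out) <- vapply(out, function(p) p$name, "")
  attr(out, "decay") <- decay
  out
}

#' Bidirectional gated cross-attention
#'
#' Queries come from the layer-normalized query-side tokens, keys/values from
#' the layer-normalized context-side tokens; scaled-dot-product attention rows
#' are convex weights over context positions, and the output is gated
#' elementwise by `sigmoid(W_g [X ; pool(H)])`, where the context matrix is
#' mean-pooled over its (mask-valid) rows and broadcast to every query token
#' before concatenation.
#'
#' @param X query-side autodiff node, `(B * kq) x d` row-stacked.
#' @param H context-side autodiff node, `(B * kv) x d`.
#' @param layer GCA layer parameters.
#' @param B batch size; `n_heads` head count.
#' @param n_heads head count.
#' @param mask optional `B x kv` logical matrix of valid context positions.
#' @return list with `out` (node, same shape as `X`) and `attn` (per-sample
#'   attention matrices, rows summing to 1).
#' @export
gated_cross_attention <- function(X, H, layer, B, n_heads, mask = NULL) {
  if (ncol(X$val) != ncol(H$val)) stop("modality width mismatch")
  kq <- nrow(X$val) %/% B
  kv <- nrow(H$val) %/% B
  Q <- ad_matmul(apply_ln(X, layer$ln_x), layer$W_q)
  Hn <- apply_ln(H, layer$ln_h)
  K <- ad_matmul(Hn, layer$W_k)
  V <- ad_matmul(Hn, layer$W_v)
  att <- ad_batched_attention(Q, K, V, B, n_heads, mask = mask)
  wts <- if (is.null(mask)) NULL else as.numeric(t(mask))
  pooled <- ad_block_mean(H, kv, weights = wts)
  gate_in <- ad_cbind(X, ad_block_expand(pooled, kq))
  gate <- ad_sigmoid(ad_matmul(gate_in, layer$W_g))
  list(out = ad_mul(att, gate), attn = att$attn, gate = gate)
}

#' Residual hierarchical fusion block
#'
#' `X_out = X + FFN(LN(X)) + lambda * GCA(X, H)` — the exact three-term sum,
#' with a position-wise GELU feed-forward sublayer and the block's learnable
#' scalar fusion coefficient.
#'
#' @param X,H autodiff nodes (query-side tokens, context tokens).
#' @param block fusion block parameters.
#' @param B,n_heads batch size and head count.
#' @param mask optional context validity mask.
#' @param use_gca set FALSE to sever the cross-modal term (ablation).
#' @return list with `out` and the GCA diagnostics.
#' @export
fusion_block_forward <- function(X, H, block, B, n_heads, mask = NULL,
                                 use_gca = TRUE) {
  ffn <- ad_add(
    ad_matmul(ad_gelu(ad_add(ad_matmul(apply_ln(X, block$ln), block$W1),
                             block$b1)), block$W2),
    block$b2)
  out <- ad_add(X, ffn)
  gca <- NULL
  if (use_gca) {
    gca <- gated_cross_attention(X, H, block$gca, B, n_heads, mask = mask)
    out <- ad_add(out, ad_mul(gca$out, block$lambda))
  }
  list(out = out, gca = gca)
}

# ---- batch encoding ---------------------------------------------------------

# Frozen-backbone hidden states for every record (fold-independent, so they
# are computed once per cohort and reused across folds and epochs).
text_hidden_cache <- function(data, schema, backbone) {
  lapply(seq_len(nrow(data)), function(i) {
    txt <- paste(vapply(schema$text_units, function(u) data[[u]][i], ""),
                 collapse = " ")
    backbone_forward(backbone, tokenize_text(txt, backbone$vocab_size))
  })
}

# Turn an imputed cohort slice into model-ready arrays: per-field category
# indices, standardized numerics, and precomputed frozen-backbone text states.
encode_batch <- function(data, schema, std, model, rows = seq_len(nrow(data)),
                         text_cache = NULL) {
  d <- data[rows, , drop = FALSE]
  cat_nm <- names(schema$categorical_fields)
  idx <- vapply(cat_nm, function(nm) {
    match(d[[nm]], schema$categorical_fields[[nm]])
  }, integer(nrow(d)))
  if (!is.matrix(idx)) idx <- matrix(idx, nrow = nrow(d))
  idx[is.na(idx)] <- 0L                        # unknown slot
  znum <- apply_standardizer(d, std)
  if (is.null(text_cache)) {
    text_cache <- text_hidden_cache(d, schema, model$backbone)
    hs <- text_cache
  } else {
    hs <- text_cache[rows]
  }
  l_pad <- max(vapply(hs, nrow, 1L))
  H <- matrix(0, nrow(d) * l_pad, model$backbone$d_bert)
  mask <- matrix(FALSE, nrow(d), l_pad)
  for (i in seq_len(nrow(d))) {
    li <- nrow(hs[[i]])
    H[((i - 1L) * l_pad + 1L):((i - 1L) * l_pad + li), ] <- hs[[i]]
    mask[i, seq_len(li)] <- TRUE
  }
  list(cat_idx = idx, znum = znum, H_text = H, mask = mask, l_pad = l_pad,
       labels = d[[schema$label_name]], n = nrow(d))
}

#' Full model forward pass
#'
#' Builds the structured token sequence (classification token + categorical
#' embeddings + numeric embeddings), projects the text hidden states, stacks
#' the fusion blocks, and reads out class logits from the final classification
#' token, plus the pooled per-modality vectors used by the contrastive head.
#' Each block applies a residual self-attention sublayer over the structured
#' tokens before the residual/FFN/cross-attention sum, so the classification
#' token can aggregate the structured evidence (cross-attention alone only
#' mixes against the text stream). The self-attention path stays live under
#' `remove_cross_attention`, which severs only the cross-modal term.
#'
#' @param model an [init_model()] result.
#' @param batch an encoded batch (internal `encode_batch()` result).
#' @param remove_cross_attention if TRUE the lambda-weighted GCA term is
#'   severed (ablation); logits then cannot depend on the text.
#' @return list with autodiff nodes `logits` (`B x 2`), `x_cls`, `h_cls_text`,
#'   and diagnostics (`attn`, `gates`).
#' @export
forward_pass <- function(model, batch, remove_cross_attention = FALSE) {
  if (batch$n == 0L) stop("empty batch")
  B <- batch$n
  cfg <- model$config
  k_cat <- ncol(batch$cat_idx)
  k_num <- ncol(batch$znum)
  k <- 1L + k_cat + k_num
  cat_tok <- embed_categorical(batch$cat_idx, model$cat)    # (B*k_cat) x d
  num_tok <- embed_numeric(batch$znum, model$num)           # (B*k_num) x d
  cls_tok <- ad_gather_rows(model$cls, rep(1L, B))
  stacked <- ad_rbind(cls_tok, cat_tok, num_tok)
  # interleave rows into per-sample blocks [cls; cat; num]
  perm <- integer(B * k)
  for (i in seq_len(B)) {
    dst <- ((i - 1L) * k + 1L):(i * k)
    perm[dst] <- c(i, B + ((i - 1L) * k_cat + 1L):((i - 1L) * k_cat + k_cat),
                   B + B * k_cat +
                     ((i - 1L) * k_num + 1L):((i - 1L) * k_num + k_num))
  }
  X <- ad_gather_rows(stacked, perm)
  H <- project_hidden(ad_const(batch$H_text), model$projector)
  attn <- list()
  gates <- list()
  for (l in seq_along(model$blocks)) {
    X <- self_attention_forward(X, model$blocks[[l]]$sa, B, cfg$n_heads)
    res <- fusion_block_forward(X, H, model$blocks[[l]], B, cfg$n_heads,
                                mask = batch$mask,
                                use_gca = !remove_cross_attention)
    X <- res$out
    if (!is.null(res$gca)) {
      attn[[l]] <- res$gca$attn
      gates[[l]] <- res$gca$gate
    }
    if (!is.null(model$text_blocks) && !remove_cross_attention) {
      tres <- fusion_block_forward(H, X, model$text_blocks[[l]], B,
                                   cfg$n_heads)
      H <- tres$out
    }
  }
  x_cls <- ad_gather_rows(X, seq(1L, B * k, by = k))
  h_cls_text <- ad_gather_rows(H, seq(1L, B * batch$l_pad, by = batch$l_pad))
  logits <- ad_add(ad_matmul(x_cls, model$W_c), model$b_c)
  list(logits = logits, x_cls = x_cls, h_cls_text = h_cls_text,
       attn = attn, gates = gates)
}
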