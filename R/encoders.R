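#' Category offset for collision-free embedding lookup
#'
#' Each categorical field owns a contiguous block of `c_i + 1` rows in the
#' shared embedding table: one reserved unknown/missing slot plus its `c_i`
#' categories. The offset of field `i` is the prefix sum of the preceding
#' block sizes, which makes the (field, category) -> row mapping injective and
#' avoids ID conflicts between fields that share raw category indices.
#'
#' @param i field index (1-based).
#' @param cardinalities integer vector of per-field cardinalities `c_i`.
#' @return integer offset; 0 for the first field.
#' @export
field_offset <- function(i, cardinalities) {
  if (i < 1L || i > length(cardinalities)) stop("field index out of range")
  if (i == 1L) 0L else sum(cardinalities[seq_len(i - 1L)] + 1L)
}

#' Offset categorical embedder
#'
#' Holds the shared embedding table `E` (`sum(c_i + 1)` rows, width `d`) and
#' the per-field offsets. Category index 0 addresses the field's reserved
#' unknown slot; indices `1..c_i` address its categories.
#'
#' @param cardinalities integer vector of field cardinalities.
#' @param d embedding width.
#' @param init_sd standard deviation of the normal initializer.
#' @return list with `E` (an autodiff parameter), `offsets`, `cardinalities`.
#' @export
categorical_embedder <- function(cardinalities, d, init_sd = 0.02) {
  total <- sum(cardinalities + 1L)
  offsets <- vapply(seq_along(cardinalities), field_offset, 0L,
                    cardinalities = cardinalities)
  list(E = ad_param(matrix(stats::rnorm(total * d, sd = init_sd), total, d),
                    name = "cat_E"),
       offsets = offsets, cardinalities = as.integer(cardinalities), d = d)
}

#' Embed per-field category indices
#'
#' Row `i` of the result is row `x_i + phi_i` of the table (`x_i = 0` mapping
#' to the field's unknown slot). Accepts a vector (one record) or a matrix
#' (batch x fields); batch output is row-stacked sample-major.
#'
#' @param indices integer vector or matrix of per-field category indices in
#'   `0..c_i`.
#' @param embedder a [categorical_embedder()].
#' @return autodiff node, `(B * k) x d`.
#' @export
embed_categorical <- function(indices, embedder) {
  if (!is.matrix(indices)) indices <- matrix(indices, nrow = 1L)
  k <- length(embedder$cardinalities)
  stopifnot(ncol(indices) == k)
  for (j in seq_len(k)) {
    if (any(indices[, j] < 0L | indices[, j] > embedder$cardinalities[j])) {
      stop(sprintf("field %d: category index out of vocabulary (max %d)",
                   j, embedder$cardinalities[j]))
    }
  }
  glob <- t(apply(indices, 1L, function(r) r + embedder$offsets + 1L))
  if (k == 1L) glob <- matrix(glob, ncol = 1L)
  ad_gather_rows(embedder$E, as.integer(t(glob)))   # sample-major rows
}

#' Parametric affine numerical embedder
#'
#' Field `j` maps its standardized scalar `x_j` to the length-`d` token
#' `w_j * x_j + b_j` with learnable `w_j`, `b_j`.
#'
#' @param n_fields number of numeric fields.
#' @param d embedding width.
#' @return list with parameter matrices `W` and `B` (`n_fields x d`).
#' @export
numerical_embedder <- function(n_fields, d) {
  list(W = ad_param(matrix(stats::rnorm(n_fields * d, sd = 0.2), n_fields, d),
                    name = "num_W"),
       B = ad_param(matrix(0, n_fields, d), name = "num_B"),
       n_fields = n_fields, d = d)
}

#' Embed standardized numeric values
#'
#' @param x numeric vector (one record) or matrix (batch x fields) of
#'   standardized values; must be finite.
#' @param embedder a [numerical_embedder()].
#' @return autodiff node, `(B * n_fields) x d`, sample-major.
#' @export
embed_numeric <- function(x, embedder) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (any(!is.finite(x))) stop("non-finite numeric input")
  stopifnot(ncol(x) == embedder$n_fields)
  B <- nrow(x)
  tiled <- ad_gather_rows(embedder$W, rep(seq_len(embedder$n_fields), B))
  scaled <- ad_scale_rows(tiled, as.numeric(t(x)))
  ad_add(scaled, ad_gather_rows(embedder$B,
                                rep(seq_len(embedder$n_fields), B)))
}

# ---- text backbone (contract + tiny-test implementation) --------------------

#' Whitespace/punctuation tokenizer with hashed vocabulary
#'
#' Deterministic: lowercases, splits on non-alphanumerics, maps each token to
#' `1..vocab_size` by a polynomial rolling hash. Token id 0 is reserved for
#' the classification token the backbone prepends.
#'
#' @param text a string.
#' @param vocab_size hash-bucket count.
#' @return integer vector of token ids (possibly empty).
#' @export
tokenize_text <- function(text, vocab_size = 512L) {
  toks <- strsplit(tolower(gsub("[^a-z0-9]+", " ", tolower(text))), " +")[[1]]
  toks <- toks[nzchar(toks)]
  vapply(toks, function(tk) {
    h <- 0
    for (cc in utf8ToInt(tk)) h <- (h * 31 + cc) %% 1e9
    as.integer(h %% vocab_size) + 1L
  }, integer(1), USE.NAMES = FALSE)
}

#' Construct a text backbone
#'
#' The backbone contract: a deterministic map from a token sequence of length
#' `l` to an `l x d_bert` hidden-state matrix, prepending one classification
#' token (so the first output row is the sequence summary position). The
#' packaged implementation is the seeded `"tiny-test"` backbone: a randomly
#' initialized single-block transformer (token + sinusoidal position
#' embeddings, one self-attention layer, one feed-forward layer), frozen. A
#' `"pretrained"` bidirectional-transformer backbone is part of the contract
#' but cannot ship inside this package; requesting it raises an informative
#' error explaining how to plug one in.
#'
#' @param type `"tiny-test"` or `"pretrained"`.
#' @param d_bert hidden width (default 32 for tiny-test).
#' @param l_max maximum sequence length including the classification token.
#' @param vocab_size hashed vocabulary size.
#' @param n_heads self-attention heads.
#' @param seed seed fixing the random weights.
#' @return object of class `text_backbone`.
#' @export
text_backbone <- function(type = c("tiny-test", "pretrained"), d_bert = 32L,
                          l_max = 256L, vocab_size = 512L, n_heads = 2L,
                          seed = 2024L) {
  type <- match.arg(type)
  if (type == "pretrained") {
    stop(paste("no pretrained text backbone is bundled (weights cannot ship",
               "in this package); supply your own object implementing the",
               "text_backbone contract or use type = 'tiny-test'"))
  }
  with_seed(seed, {
    w <- function(n, m, sd = 1 / sqrt(m)) matrix(stats::rnorm(n * m, sd = sd),
                                                 n, m)
    pos <- outer(seq_len(l_max), seq_len(d_bert), function(p, j) {
      ifelse(j %% 2L == 0L, sin(p / 10000^(j / d_bert)),
             cos(p / 10000^((j - 1) / d_bert)))
    })
    structure(list(
      type = type, d_bert = d_bert, l_max = l_max, vocab_size = vocab_size,
      n_heads = n_heads, seed = seed,
      tok_emb = w(vocab_size + 1L, d_bert, sd = 0.5),  # last row = CLS token
      pos_emb = pos,
      Wq = w(d_bert, d_bert), Wk = w(d_bert, d_bert), Wv = w(d_bert, d_bert),
      W1 = w(d_bert, 2L * d_bert), b1 = numeric(2L * d_bert),
      W2 = w(2L * d_bert, d_bert), b2 = numeric(d_bert)
    ), class = "text_backbone")
  })
}

rowsoftmax <- function(s) {
  e <- exp(s - apply(s, 1L, max))
  e / rowSums(e)
}

layernorm_mat <- function(x, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  xc / sqrt(rowMeans(xc^2) + eps)
}

#' Run the backbone on token ids
#'
#' Prepends the classification token, truncates to `l_max`, and returns the
#' hidden-state matrix. Pure numeric (the backbone is frozen); deterministic.
#'
#' @param backbone a [text_backbone()].
#' @param token_ids integer vector from [tokenize_text()]; an empty sequence
#'   yields the single classification token.
#' @return `l x d_bert` matrix, `l = min(length(token_ids) + 1, l_max)`.
#' @export
backbone_forward <- function(backbone, token_ids) {
  ids <- c(backbone$vocab_size + 1L, token_ids)    # CLS first
  if (length(ids) > backbone$l_max) {
    ids <- ids[seq_len(backbone$l_max)]
    if (isTRUE(getOption("emrfuse.verbose"))) {
      message(sprintf("text truncated to l_max = %d tokens", backbone$l_max))
    }
  }
  l <- length(ids)
  h <- backbone$tok_emb[ids, , drop = FALSE] +
    backbone$pos_emb[seq_len(l), , drop = FALSE]
  nh <- backbone$n_heads
  dk <- backbone$d_bert / nh
  hn <- layernorm_mat(h)
  q <- hn %*% backbone$Wq
  k <- hn %*% backbone$Wk
  v <- hn %*% backbone$Wv
  att <- matrix(0, l, backbone$d_bert)
  for (hh in seq_len(nh)) {
    cols <- ((hh - 1L) * dk + 1L):(hh * dk)
    a <- rowsoftmax(tcrossprod(q[, cols, drop = FALSE],
                               k[, cols, drop = FALSE]) / sqrt(dk))
    att[, cols] <- a %*% v[, cols, drop = FALSE]
  }
  h <- h + att
  hn <- layernorm_mat(h)
  ff <- pmax(hn %*% backbone$W1 + rep(backbone$b1, each = l), 0) %*%
    backbone$W2 + rep(backbone$b2, each = l)
  h + ff
}

#' Projection layer aligning text features with the fusion width
#'
#' `LayerNorm(GELU(W_p H + b_p))`, applied row-wise, with a learnable affine
#' on the normalized output.
#'
#' @param d_bert backbone hidden width.
#' @param d fusion width.
#' @return list of autodiff parameters `W_p`, `b_p`, `ln_g`, `ln_b`.
#' @export
text_projector <- function(d_bert, d) {
  list(W_p = ad_param(matrix(stats::rnorm(d_bert * d, sd = 1 / sqrt(d_bert)),
                             d_bert, d), name = "proj_W"),
       b_p = ad_param(matrix(0, 1L, d), name = "proj_b"),
       ln_g = ad_param(matrix(1, 1L, d), name = "proj_ln_g"),
       ln_b = ad_param(matrix(0, 1L, d), name = "proj_ln_b"),
       d_bert = d_bert, d = d)
}

project_hidden <- function(h_node, projector) {
  z <- ad_add(ad_matmul(h_node, projector$W_p), projector$b_p)
  n <- ad_layernorm_rows(ad_gelu(z))
  ad_add(ad_mul_rowvec(n, projector$ln_g), projector$ln_b)
}

#' Encode one text into the fusion feature space
#'
#' Tokenizes, runs the (frozen) backbone, and applies the trainable projection
#' layer. Returns an autodiff node so gradients reach the projector.
#'
#' @param text a string; empty text maps to the bare classification token.
#' @param backbone a [text_backbone()].
#' @param projector a [text_projector()].
#' @return autodiff node of shape `l x d`; read values with
#'   `emrfuse:::ad_value()`.
#' @export
encode_text <- function(text, backbone, projector) {
  ids <- tokenize_text(text, backbone$vocab_size)
  if (length(ids) == 0L && isTRUE(getOption("emrfuse.verbose"))) {
    message("empty text: encoding the bare classification token")
  }
  h <- backbone_forward(backbone, ids)
  project_hidden(ad_const(h), projector)
}
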