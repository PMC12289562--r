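# Shared fixtures and oracles, built in code at test time.

ad <- function(name) get(name, envir = asNamespace("emrfuse"))

# central finite-difference gradient of scalar-valued f(params) wrt params[[i]]
numeric_grad <- function(f, params, i, h = 1e-6) {
  p <- params[[i]]
  g <- p$val * 0
  for (j in seq_along(p$val)) {
    orig <- p$val[j]
    p$val[j] <- orig + h
    up <- f()
    p$val[j] <- orig - h
    dn <- f()
    p$val[j] <- orig
    g[j] <- (up - dn) / (2 * h)
  }
  g
}

# run forward fn returning loss node, backprop, compare every param's grad
expect_grads_match <- function(forward, params, tol = 1e-5) {
  ad("ad_zero_grad")(params)
  loss <- forward()
  ad("ad_backward")(loss)
  for (i in seq_along(params)) {
    ng <- numeric_grad(function() ad("ad_value")(forward())[1L], params, i)
    ag <- params[[i]]$grad
    if (is.null(ag)) ag <- ng * 0
    expect_lt(max(abs(ag - ng)), tol,
              label = sprintf("grad mismatch for param %d", i))
  }
}

rand_mat <- function(n, m, sd = 0.5) matrix(rnorm(n * m, sd = sd), n, m)

# Independent direct-summation oracle for the symmetric InfoNCE loss:
# literal per-pair cosine similarities, explicit numerator/denominator sums,
# -1/(2N) normalization. Written before and independently of the package path.
infonce_oracle <- function(zs, zt, tau) {
  n <- nrow(zs)
  cs <- function(a, b) sum(a * b) / (sqrt(sum(a * a)) * sqrt(sum(b * b)))
  tot <- 0
  for (i in seq_len(n)) {
    d1 <- sum(vapply(seq_len(n),
                     function(j) exp(cs(zs[i, ], zt[j, ]) / tau), 0))
    d2 <- sum(vapply(seq_len(n),
                     function(j) exp(cs(zt[i, ], zs[j, ]) / tau), 0))
    tot <- tot + log(exp(cs(zs[i, ], zt[i, ]) / tau) / d1) +
      log(exp(cs(zt[i, ], zs[i, ]) / tau) / d2)
  }
  -tot / (2 * n)
}

# hand-rolled single-sample gated cross-attention oracle on raw matrices
oracle_layernorm <- function(x, g = 1, b = 0, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  sweep(xc / sqrt(rowMeans(xc^2) + eps), 2, g, "*") + b
}

oracle_softmax <- function(s) {
  e <- exp(s - apply(s, 1, max))
  e / rowSums(e)
}

gca_oracle <- function(X, H, Wq, Wk, Wv, Wg, h) {
  d <- ncol(X); dk <- d / h
  Q <- oracle_layernorm(X) %*% Wq
  Hn <- oracle_layernorm(H)
  K <- Hn %*% Wk
  V <- Hn %*% Wv
  att <- matrix(0, nrow(X), d)
  for (hh in seq_len(h)) {
    cols <- ((hh - 1) * dk + 1):(hh * dk)
    A <- oracle_softmax(Q[, cols, drop = FALSE] %*%
                          t(K[, cols, drop = FALSE]) / sqrt(dk))
    att[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  pooled <- colMeans(H)
  gate <- 1 / (1 + exp(-cbind(X, matrix(pooled, nrow(X), d,
                                        byrow = TRUE)) %*% Wg))
  att * gate
}

# small cohort configs used across test files
tiny_config <- function(...) {
  cohort_config(n_patients = 60, n_female = 25, n_male = 35, seed = 11, ...)
}

# compact model config so neural tests stay fast
tiny_model_config <- function(...) {
  model_config(d = 16, n_heads = 2, n_blocks = 1, d_bert = 16, d_z = 8,
               ffn_mult = 2L, l_max = 16, ...)
}

# small preprocessed cohort + initialized model + encoded batch
make_batch <- function(n = 6, seed = 1, mcfg = tiny_model_config(),
                       ccfg_args = list(), rows = NULL) {
  ccfg <- do.call(cohort_config,
                  c(list(n_patients = n, n_female = floor(n / 2),
                         n_male = n - floor(n / 2), seed = seed), ccfg_args))
  cohort <- generate_cohort(ccfg)
  schema <- cohort$schema
  imp <- impute_cohort(cohort$data, field_statistics(cohort$data, schema),
                       schema)
  std <- fit_standardizer(imp$data, schema)
  model <- init_model(schema, mcfg, seed = seed)
  if (is.null(rows)) rows <- seq_len(n)
  batch <- ad("encode_batch")(imp$data, schema, std, model, rows = rows)
  list(model = model, batch = batch, cohort = cohort, imp = imp, std = std)
}
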