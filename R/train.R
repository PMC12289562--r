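#' Stratified K-fold plan
#'
#' Shuffles indices within each class under the seed and deals them
#' round-robin, so folds partition the cohort and per-fold class counts differ
#' from the ideal proportion by at most one.
#'
#' @param labels 0/1 label vector.
#' @param K number of folds (default 5).
#' @param seed integer seed.
#' @return object of class `fold_plan`: `folds` (list of
#'   `list(train, validation)` index vectors), `K`, `seed`.
#' @export
stratified_kfold <- function(labels, K = 5L, seed = 1L) {
  if (K < 2L) stop("K must be at least 2")
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      if (length(idx) < K) {
        stop(sprintf("class %s has %d members, fewer than K = %d",
                     cl, length(idx), K))
      }
      idx <- sample(idx)
      fold[idx] <- rep(seq_len(K), length.out = length(idx))
    }
  })
  structure(list(
    folds = lapply(seq_len(K), function(k) {
      list(train = which(fold != k), validation = which(fold == k))
    }),
    K = K, seed = seed
  ), class = "fold_plan")
}

#' Fold-local preprocessing (no leakage)
#'
#' Winsorizes out-of-range values, computes imputation statistics and the
#' z-score standardizer on the training rows only, and imputes the whole
#' table with those training statistics.
#'
#' @param cohort an [emr_cohort()].
#' @param train_idx training-row indices of this fold.
#' @return list with `data` (imputed), `status`, `stats`, `std`, `winsor_log`.
#' @export
preprocess_fold <- function(cohort, train_idx) {
  schema <- cohort$schema
  wz <- winsorize_outliers(cohort$data, schema)
  stats <- field_statistics(wz$data, schema, rows = train_idx)
  imp <- impute_cohort(wz$data, stats, schema)
  std <- fit_standardizer(imp$data, schema, rows = train_idx)
  list(data = imp$data, status = imp$status, stats = stats, std = std,
       winsor_log = wz$log)
}

clamp_log_tau <- function(model) {
  model$log_tau$val[1] <- min(max(model$log_tau$val[1], log(1e-3)), log(10))
}

predict_probs <- function(model, data, schema, std, rows, text_cache,
                          remove_cross_attention = FALSE, chunk = 64L) {
  out <- numeric(length(rows))
  for (start in seq(1L, length(rows), by = chunk)) {
    sel <- rows[start:min(start + chunk - 1L, length(rows))]
    b <- encode_batch(data, schema, std, model, rows = sel,
                      text_cache = text_cache)
    lg <- ad_value(forward_pass(model, b, remove_cross_attention)$logits)
    p <- exp(lg - apply(lg, 1L, max))
    out[start:(start + length(sel) - 1L)] <- (p / rowSums(p))[, 2L]
  }
  out
}

eval_losses <- function(model, data, schema, std, rows, text_cache, cw,
                        beta, remove_cross_attention, chunk = 64L) {
  task <- 0; cont <- 0; n <- 0
  for (start in seq(1L, length(rows), by = chunk)) {
    sel <- rows[start:min(start + chunk - 1L, length(rows))]
    b <- encode_batch(data, schema, std, model, rows = sel,
                      text_cache = text_cache)
    fp <- forward_pass(model, b, remove_cross_attention)
    t_ <- ad_value(ad_crossentropy_logits(fp$logits, b$labels + 1L, cw))[1]
    c_ <- if (beta > 0) {
      zs <- project_shared(fp$x_cls, model)
      zt <- project_shared(fp$h_cls_text, model)
      ad_value(contrastive_loss(zs, zt, model$log_tau))[1]
    } else 0
    task <- task + t_ * length(sel)
    cont <- cont + c_ * length(sel)
    n <- n + length(sel)
  }
  list(task = task / n, cont = cont / n)
}

train_fold <- function(cohort, fold, mconfig, seed, text_cache,
                       remove_cross_attention = FALSE, beta = NULL) {
  schema <- cohort$schema
  if (is.null(beta)) beta <- mconfig$beta
  pp <- preprocess_fold(cohort, fold$train)
  model <- init_model(schema, mconfig, seed = seed)
  params <- model_params(model)
  opt <- adam_new(params, lr = mconfig$lr)
  y <- pp$data[[schema$label_name]]
  cw <- if (isTRUE(mconfig$class_weighting)) {
    n1 <- sum(y[fold$train] == 1)
    n0 <- sum(y[fold$train] == 0)
    length(fold$train) / (2 * c(max(n0, 1), max(n1, 1)))
  } else c(1, 1)
  best <- Inf
  best_vals <- NULL
  bad <- 0L
  curve <- list()
  with_seed(seed + 1L, {
    for (epoch in seq_len(mconfig$max_epochs)) {
      idx <- sample(fold$train)
      ep_task <- 0; ep_cont <- 0
      for (start in seq(1L, length(idx), by = mconfig$batch_size)) {
        mb <- idx[start:min(start + mconfig$batch_size - 1L, length(idx))]
        b <- encode_batch(pp$data, schema, pp$std, model, rows = mb,
                          text_cache = text_cache)
        fp <- forward_pass(model, b, remove_cross_attention)
        task <- ad_crossentropy_logits(fp$logits, b$labels + 1L, cw)
        cont <- if (beta > 0) {
          zs <- project_shared(fp$x_cls, model)
          zt <- project_shared(fp$h_cls_text, model)
          contrastive_loss(zs, zt, model$log_tau)
        } else ad_const(0)
        loss <- total_loss(task, cont, l2_penalty(params),
                           mconfig$alpha, beta, mconfig$gamma)
        ad_zero_grad(params)
        ad_backward(loss)
        adam_step(opt)
        clamp_log_tau(model)
        ep_task <- ep_task + ad_value(task)[1] * length(mb)
        ep_cont <- ep_cont + ad_value(cont)[1] * length(mb)
      }
      vl <- eval_losses(model, pp$data, schema, pp$std, fold$validation,
                        text_cache, cw, beta, remove_cross_attention)
      # checkpoint selection tracks the classification objective; the
      # contrastive term is a training-time regularizer
      val_loss <- if (identical(mconfig$early_stop, "total")) {
        mconfig$alpha * vl$task + beta * vl$cont
      } else {
        vl$task
      }
      curve[[epoch]] <- data.frame(
        epoch = epoch,
        train_task = ep_task / length(idx),
        train_cont = ep_cont / length(idx),
        val_task = vl$task, val_cont = vl$cont, val_loss = val_loss)
      if (val_loss < best - 1e-5) {
        best <- val_loss
        best_vals <- lapply(params, function(p) p$val)
        bad <- 0L
      } else {
        bad <- bad + 1L
        # halve the learning rate once training stalls, then stop
        if (bad == max(2L, mconfig$patience %/% 2L)) opt$lr <- opt$lr / 2
        if (bad >= mconfig$patience) break
      }
    }
  })
  if (!is.null(best_vals)) {
    for (nm in names(params)) params[[nm]]$val <- best_vals[[nm]]
  }
  prob <- predict_probs(model, pp$data, schema, pp$std, fold$validation,
                        text_cache, remove_cross_attention)
  pred <- as.integer(prob > 0.5)
  list(model = model,
       metrics = compute_metrics(y[fold$validation], pred),
       prob = prob, pred = pred,
       labels = y[fold$validation],
       curve = do.call(rbind, curve))
}

metrics_row <- function(variant, fold, m) {
  data.frame(variant = variant, fold = fold,
             accuracy = m$accuracy, precision = m$precision,
             recall = m$recall, specificity = m$specificity, f1 = m$f1,
             stringsAsFactors = FALSE)
}

# mean-of-folds and recomputed-from-pooled-confusion summaries, both reported
summarize_folds <- function(variant, per_fold, pooled_labels, pooled_preds) {
  mean_row <- data.frame(
    variant = variant, fold = "mean",
    accuracy = mean(per_fold$accuracy), precision = mean(per_fold$precision),
    recall = mean(per_fold$recall), specificity = mean(per_fold$specificity),
    f1 = mean(per_fold$f1), stringsAsFactors = FALSE)
  pooled <- compute_metrics(pooled_labels, pooled_preds)
  rbind(per_fold, mean_row, metrics_row(variant, "pooled", pooled))
}

ablation_variants <- c("full", "no_contrastive", "no_cross_attention",
                       "direct_fusion_lin", "direct_fusion_fft",
                       "csv_only", "text_only")

#' Cross-validated training of the fusion model
#'
#' Trains the full model (or a neural ablation variant) per fold with
#' fold-local preprocessing, Adam, and early stopping on validation loss;
#' deterministic given the seed.
#'
#' @param cohort an [emr_cohort()].
#' @param mconfig a [model_config()].
#' @param K folds (default 5).
#' @param seed integer seed driving fold assignment, initialization and
#'   batch shuffling.
#' @param variant one of `"full"`, `"no_contrastive"`, `"no_cross_attention"`.
#' @param fold_plan optional precomputed [stratified_kfold()] plan, so
#'   several variants can share identical folds.
#' @param keep_models if TRUE the per-fold trained models are returned.
#' @return list with `report` (per-fold rows plus `mean` and `pooled`
#'   summaries), `curves`, `fold_plan`, and optionally `models`.
#' @export
cross_validate <- function(cohort, mconfig, K = 5L, seed = 1L,
                           variant = "full", fold_plan = NULL,
                           keep_models = FALSE) {
  stopifnot(variant %in% c("full", "no_contrastive", "no_cross_attention"))
  y <- cohort$data[[cohort$schema$label_name]]
  if (is.null(fold_plan)) fold_plan <- stratified_kfold(y, K, seed)
  cache <- text_hidden_cache(cohort$data, cohort$schema,
                             text_backbone(mconfig$backbone,
                                           d_bert = mconfig$d_bert,
                                           l_max = mconfig$l_max,
                                           seed = mconfig$backbone_seed))
  rows <- list()
  curves <- list()
  models <- list()
  pooled_labels <- integer()
  pooled_preds <- integer()
  for (k in seq_along(fold_plan$folds)) {
    fr <- train_fold(cohort, fold_plan$folds[[k]], mconfig,
                     seed = seed + k,
                     text_cache = cache,
                     remove_cross_attention =
                       identical(variant, "no_cross_attention"),
                     beta = if (identical(variant, "no_contrastive")) 0)
    rows[[k]] <- metrics_row(variant, as.character(k), fr$metrics)
    fr$curve$fold <- k
    curves[[k]] <- fr$curve
    pooled_labels <- c(pooled_labels, fr$labels)
    pooled_preds <- c(pooled_preds, fr$pred)
    if (keep_models) models[[k]] <- fr$model
  }
  per_fold <- do.call(rbind, rows)
  list(report = summarize_folds(variant, per_fold, pooled_labels,
                                pooled_preds),
       curves = do.call(rbind, curves),
       fold_plan = fold_plan,
       models = if (keep_models) models)
}

# ---- tabular baselines ------------------------------------------------------

pooled_text_features <- function(cache) {
  do.call(rbind, lapply(cache, colMeans))
}

fit_linear_baseline <- function(x, y) {
  glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = 0.01,
                 standardize = FALSE)
}

train_mlp <- function(x, y, seed, hidden = 32L, epochs = 40L, lr = 1e-3,
                      batch_size = 32L) {
  with_seed(seed, {
    p <- ncol(x)
    W1 <- ad_param(matrix(stats::rnorm(p * hidden, sd = 1 / sqrt(p)),
                          p, hidden))
    b1 <- ad_param(matrix(0, 1L, hidden))
    W2 <- ad_param(matrix(stats::rnorm(hidden * 2L, sd = 1 / sqrt(hidden)),
                          hidden, 2L))
    b2 <- ad_param(matrix(0, 1L, 2L))
    params <- list(W1, b1, W2, b2)
    opt <- adam_new(params, lr = lr)
    fwd <- function(xm) {
      h <- ad_gelu(ad_add(ad_matmul(ad_const(xm), W1), b1))
      ad_add(ad_matmul(h, W2), b2)
    }
    for (e in seq_len(epochs)) {
      idx <- sample(nrow(x))
      for (start in seq(1L, length(idx), by = batch_size)) {
        mb <- idx[start:min(start + batch_size - 1L, length(idx))]
        loss <- ad_crossentropy_logits(fwd(x[mb, , drop = FALSE]),
                                       y[mb] + 1L)
        ad_zero_grad(params)
        ad_backward(loss)
        adam_step(opt)
      }
    }
    function(newx) {
      lg <- ad_value(fwd(newx))
      p_ <- exp(lg - apply(lg, 1L, max))
      (p_ / rowSums(p_))[, 2L]
    }
  })
}

baseline_cv <- function(cohort, variant, mconfig, fold_plan, seed) {
  schema <- cohort$schema
  y <- cohort$data[[schema$label_name]]
  cache <- text_hidden_cache(cohort$data, schema,
                             text_backbone(mconfig$backbone,
                                           d_bert = mconfig$d_bert,
                                           l_max = mconfig$l_max,
                                           seed = mconfig$backbone_seed))
  xt <- pooled_text_features(cache)
  rows <- list()
  pooled_labels <- integer()
  pooled_preds <- integer()
  for (k in seq_along(fold_plan$folds)) {
    fold <- fold_plan$folds[[k]]
    pp <- preprocess_fold(cohort, fold$train)
    xs <- encode_binary(pp$data, schema, pp$std)
    x <- switch(variant,
      csv_only = xs,
      text_only = xt,
      direct_fusion_lin = cbind(xs, xt),
      direct_fusion_fft = cbind(xs, xt),
      stop(sprintf("unknown variant tag '%s'", variant)))
    if (variant == "direct_fusion_fft") {
      predict_fn <- train_mlp(x[fold$train, , drop = FALSE], y[fold$train],
                              seed = seed + k)
      prob <- predict_fn(x[fold$validation, , drop = FALSE])
    } else {
      fit <- fit_linear_baseline(x[fold$train, , drop = FALSE], y[fold$train])
      prob <- as.numeric(stats::predict(fit,
                                        newx = x[fold$validation, ,
                                                 drop = FALSE],
                                        type = "response"))
    }
    pred <- as.integer(prob > 0.5)
    rows[[k]] <- metrics_row(variant, as.character(k),
                             compute_metrics(y[fold$validation], pred))
    pooled_labels <- c(pooled_labels, y[fold$validation])
    pooled_preds <- c(pooled_preds, pred)
  }
  list(report = summarize_folds(variant, do.call(rbind, rows),
                                pooled_labels, pooled_preds),
       fold_plan = fold_plan)
}

#' Component ablations and baselines on a shared fold plan
#'
#' Runs the requested variants — neural ablations (`no_contrastive` sets the
#' contrastive weight to zero; `no_cross_attention` severs the gated
#' cross-attention term) and direct-fusion / single-modality tabular
#' baselines — all on the identical stratified fold plan, and emits one
#' metrics table with a row per variant and fold plus the two averaged
#' summaries.
#'
#' @param cohort an [emr_cohort()].
#' @param variants subset of
#'   `c("full", "no_contrastive", "no_cross_attention", "direct_fusion_lin",
#'   "direct_fusion_fft", "csv_only", "text_only")`.
#' @param mconfig a [model_config()].
#' @param K,seed fold plan parameters.
#' @return list with the combined `report` data.frame and the `fold_plan`.
#' @export
run_ablation <- function(cohort, variants = ablation_variants,
                         mconfig = model_config(), K = 5L, seed = 1L) {
  bad <- setdiff(variants, ablation_variants)
  if (length(bad) > 0L) {
    stop(sprintf("unknown variant tag(s): %s", paste(bad, collapse = ", ")))
  }
  y <- cohort$data[[cohort$schema$label_name]]
  fold_plan <- stratified_kfold(y, K, seed)
  reports <- lapply(variants, function(v) {
    if (v %in% c("full", "no_contrastive", "no_cross_attention")) {
      cross_validate(cohort, mconfig, K, seed, variant = v,
                     fold_plan = fold_plan)$report
    } else {
      baseline_cv(cohort, v, mconfig, fold_plan, seed)$report
    }
  })
  list(report = do.call(rbind, reports), fold_plan = fold_plan)
}

#' Single-modality baselines
#'
#' `csv_only`: ridge-logistic classifier on the binary-encoded structured
#' features. `text_only`: frozen text backbone with a linear head on the
#' mean-pooled hidden states. Both use the same stratified fold plan as the
#' fusion model would.
#'
#' @inheritParams run_ablation
#' @return list with `report` and `fold_plan`.
#' @export
single_modality_baselines <- function(cohort, mconfig = model_config(),
                                      K = 5L, seed = 1L) {
  run_ablation(cohort, c("csv_only", "text_only"), mconfig, K, seed)
}
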