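test_that("stratified folds partition the cohort with balanced classes", {
  set.seed(61)
  y <- c(rep(1L, 360), rep(0L, 440))[sample(800)]
  plan <- stratified_kfold(y, K = 5, seed = 9)
  val_sizes <- vapply(plan$folds, function(f) length(f$validation), 1L)
  expect_true(all(val_sizes == 160L))
  all_val <- sort(unlist(lapply(plan$folds, `[[`, "validation")))
  expect_identical(all_val, 1:800)                     # exhaustive
  expect_identical(anyDuplicated(all_val), 0L)         # disjoint
  for (f in plan$folds) {
    expect_length(intersect(f$train, f$validation), 0)
    # counting oracle: 360 positives over 5 folds -> 72 each (within 1)
    expect_lte(abs(sum(y[f$validation] == 1) - 72), 1)
  }
  plan2 <- stratified_kfold(y, K = 5, seed = 9)
  expect_identical(plan, plan2)                        # deterministic
  expect_error(stratified_kfold(y, K = 1), "at least 2")
  expect_error(stratified_kfold(c(1L, 1L, 0L), K = 3), "fewer than K")
})

test_that("metrics match hand arithmetic and flag degenerate ratios", {
  # TP=7 FP=1 FN=2 TN=10
  labels <- c(rep(1, 9), rep(0, 11))
  preds <- c(rep(1, 7), rep(0, 2), rep(1, 1), rep(0, 10))
  m <- compute_metrics(labels, preds)
  expect_equal(m$precision, 0.875)
  expect_equal(m$recall, 7 / 9, tolerance = 1e-12)
  expect_equal(m$specificity, 10 / 11, tolerance = 1e-12)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$f1, 2 * 0.875 * (7 / 9) / (0.875 + 7 / 9), tolerance = 1e-12)
  expect_length(m$warnings, 0)

  perfect <- compute_metrics(c(0, 1, 1, 0), c(0, 1, 1, 0))
  expect_true(all(unlist(perfect[c("accuracy", "precision", "recall",
                                   "specificity", "f1")]) == 1))

  all_neg <- compute_metrics(c(0, 0, 1), c(0, 0, 0))
  expect_identical(all_neg$precision, 0)
  expect_match(all_neg$warnings, "precision", all = FALSE)
  expect_error(compute_metrics(c(1, 0), c(1)), "length mismatch")
})

test_that("metric identities hold on random confusion tables", {
  set.seed(62)
  for (i in 1:25) {
    n <- sample(20:60, 1)
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    preds <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(labels)) < 2) next
    m <- compute_metrics(labels, preds)
    expect_equal(m$accuracy * n, m$tp + m$tn, tolerance = 1e-9)
    # specificity mirrors recall on flipped labels
    flipped <- compute_metrics(1 - labels, 1 - preds)
    expect_equal(m$specificity, flipped$recall, tolerance = 1e-12)
  }
})

test_that("f1_from_pr is the rounded harmonic mean", {
  expect_equal(f1_from_pr(0.6909, 0.4935), 0.5758)
  expect_equal(f1_from_pr(0.7556, 0.7412), 0.7483)
  for (p in c(0.1, 0.37, 0.5, 0.9)) {
    expect_equal(f1_from_pr(p, p), p)      # harmonic-mean identity
  }
  expect_warning(out <- f1_from_pr(0, 0), "both zero")
  expect_identical(out, 0)
  expect_error(f1_from_pr(1.2, 0.5))
})

test_that("fold preprocessing is blind to validation labels (no leakage)", {
  cohort <- generate_cohort(tiny_config(missing_rate = 0.2))
  plan <- stratified_kfold(cohort$data$diagnosis, K = 3, seed = 5)
  fold <- plan$folds[[1]]
  pp1 <- preprocess_fold(cohort, fold$train)
  corrupted <- cohort
  corrupted$data$diagnosis[fold$validation] <-
    1L - corrupted$data$diagnosis[fold$validation]
  pp2 <- preprocess_fold(corrupted, fold$train)
  expect_identical(pp1$stats, pp2$stats)
  expect_identical(pp1$std, pp2$std)
  expect_identical(pp1$data[emrfuse:::schema_structured_fields(cohort$schema)],
                   pp2$data[emrfuse:::schema_structured_fields(cohort$schema)])
})

test_that("identical seeds and config give identical averaged metrics", {
  cfg <- cohort_config(n_patients = 80, n_female = 36, n_male = 44, seed = 4,
                       structured_effect = 3, lab_informativeness = 2)
  cohort <- generate_cohort(cfg)
  mcfg <- tiny_model_config(max_epochs = 2, patience = 2)
  r1 <- cross_validate(cohort, mcfg, K = 2, seed = 7)
  r2 <- cross_validate(cohort, mcfg, K = 2, seed = 7)
  expect_identical(r1$report, r2$report)
  expect_identical(r1$curves, r2$curves)
})

test_that("report carries both mean-of-folds and pooled summaries", {
  cohort <- generate_cohort(tiny_config())
  res <- baseline_cv_report <- run_ablation(cohort, "csv_only",
                                            tiny_model_config(), K = 2,
                                            seed = 3)
  expect_setequal(res$report$fold, c("1", "2", "mean", "pooled"))
  # the mean-of-folds F1 is reported as-is, not recomputed from averaged P/R
  mean_row <- res$report[res$report$fold == "mean", ]
  per <- res$report[res$report$fold %in% c("1", "2"), ]
  expect_equal(mean_row$f1, mean(per$f1), tolerance = 1e-12)
})

test_that("single-modality baselines follow the planted modality", {
  mcfg <- tiny_model_config()
  struct_cfg <- cohort_config(n_patients = 400, n_female = 180, n_male = 220,
                              structured_effect = 4, text_effect = 0,
                              lab_informativeness = 3, seed = 13)
  res_s <- single_modality_baselines(generate_cohort(struct_cfg), mcfg,
                                     K = 3, seed = 13)
  ms <- res_s$report[res_s$report$fold == "mean", ]
  expect_gt(ms$accuracy[ms$variant == "csv_only"],
            ms$accuracy[ms$variant == "text_only"] + 0.05)

  text_cfg <- cohort_config(n_patients = 400, n_female = 180, n_male = 220,
                            structured_effect = 0, text_effect = 4,
                            token_p_pos = 0.95, token_p_neg = 0.02, seed = 13)
  res_t <- single_modality_baselines(generate_cohort(text_cfg), mcfg,
                                     K = 3, seed = 13)
  mt <- res_t$report[res_t$report$fold == "mean", ]
  expect_gt(mt$accuracy[mt$variant == "text_only"],
            mt$accuracy[mt$variant == "csv_only"] + 0.05)

  # all variants share one fold plan by construction
  expect_error(run_ablation(generate_cohort(struct_cfg), "bogus_tag",
                            mcfg), "unknown variant")
})

test_that("checkpoints reload to an identical model", {
  mb <- make_batch(n = 4, seed = 71)
  path <- withr::local_tempfile(fileext = ".json")
  model_save(mb$model, path)
  back <- model_load(path)
  p1 <- ad("model_params")(mb$model)
  p2 <- ad("model_params")(back)
  for (nm in names(p1)) {
    expect_equal(p2[[nm]]$val, p1[[nm]]$val, tolerance = 1e-12, label = nm)
  }
  out1 <- ad("ad_value")(forward_pass(mb$model, mb$batch)$logits)
  out2 <- ad("ad_value")(forward_pass(back, mb$batch)$logits)
  expect_equal(out1, out2, tolerance = 1e-10)
})

test_that("CLI subcommands produce their documented artifacts", {
  out <- withr::local_tempdir()
  cfg_path <- file.path(out, "config.json")
  jsonlite::write_json(list(
    generator = list(n_patients = 50, n_female = 22, n_male = 28,
                     structured_effect = 3, lab_informativeness = 2),
    model = list(d = 16, n_heads = 2, n_blocks = 1, d_bert = 16, d_z = 8,
                 ffn_mult = 2, l_max = 16, max_epochs = 1, patience = 1),
    training = list(K = 2)
  ), cfg_path, auto_unbox = TRUE)

  suppressMessages(emrfuse_cli(c("simulate", "--config", cfg_path,
                                 "--seed", "5", "--out", out)))
  expect_true(file.exists(file.path(out, "cohort.csv")))
  expect_true(file.exists(file.path(out, "config_echo.json")))
  expect_true(file.exists(file.path(out, "summary.csv")))
  expect_identical(nrow(utils::read.csv(file.path(out, "cohort.csv"))), 50L)

  suppressMessages(emrfuse_cli(c("preprocess", "--config", cfg_path,
                                 "--seed", "5", "--out", out,
                                 "--cohort", file.path(out, "cohort.csv"))))
  imp <- utils::read.csv(file.path(out, "imputed.csv"))
  expect_false(anyNA(imp$crp))
  expect_true(file.exists(file.path(out, "imputation_log.csv")))

  suppressMessages(emrfuse_cli(c("train", "--config", cfg_path,
                                 "--seed", "5", "--out", out,
                                 "--cohort", file.path(out, "cohort.csv"))))
  expect_true(file.exists(file.path(out, "metrics.csv")))
  expect_true(file.exists(file.path(out, "curves.csv")))
  expect_true(file.exists(file.path(out, "checkpoint_fold1.json")))

  suppressMessages(emrfuse_cli(c("report", "--out", out)))
  rep <- jsonlite::read_json(file.path(out, "report.json"),
                             simplifyVector = TRUE)
  expect_true(all(c("variant", "fold", "accuracy") %in% names(rep)))
  expect_error(emrfuse_cli("unknown-subcommand"), "usage")
})
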