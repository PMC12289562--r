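schema <- default_emr_schema()

clean_record <- function() {
  list(id = "P1", sex = "male", fever = "no", age = 67, crp = 12, ph = 7.36,
       pao2 = 70, paco2 = 50, hco3 = 27, wbc = 9.1, neut_pct = 71, hgb = 140,
       ct_report = "CT", history = "hx", diagnosis = 1L)
}

test_that("default schema matches the documented cohort shape", {
  expect_length(schema_structured_fields(schema), 11L)
  expect_length(schema$text_units, 2L)
  expect_true(all(lengths(schema$categorical_fields) >= 2L))
  for (nm in names(schema$numeric_fields)) {
    r <- schema$numeric_fields[[nm]]$range
    expect_true(is.finite(r[1]) && is.finite(r[2]) && r[1] < r[2])
  }
})

test_that("validate_record flags each violation type (rule-by-rule oracle)", {
  expect_identical(nrow(validate_record(clean_record(), schema)), 0L)

  bad_age <- clean_record()
  bad_age$age <- 120
  v <- validate_record(bad_age, schema)
  expect_identical(v$type, "range")
  expect_identical(v$field, "age")

  # schema with a cross-field logical constraint engaged
  sch2 <- schema
  sch2$logical_constraints <- list(
    febrile_crp = function(r) {
      if (!is.na(r$fever) && r$fever == "yes" && !is.na(r$crp) && r$crp < 1) {
        "febrile patient with near-zero CRP"
      } else TRUE
    }
  )
  bad <- clean_record()
  bad$age <- 200            # range
  bad$paco2 <- 5            # range
  bad$sex <- "unknown"      # unknown category
  bad$fever <- "yes"
  bad$crp <- 0.2            # logical
  got <- validate_record(bad, sch2)

  # oracle: test every rule independently of the implementation
  oracle <- list()
  for (nm in names(sch2$numeric_fields)) {
    r <- sch2$numeric_fields[[nm]]$range
    if (!is.na(bad[[nm]]) && (bad[[nm]] < r[1] || bad[[nm]] > r[2])) {
      oracle[[length(oracle) + 1L]] <- c(nm, "range")
    }
  }
  for (nm in names(sch2$categorical_fields)) {
    if (!bad[[nm]] %in% sch2$categorical_fields[[nm]]) {
      oracle[[length(oracle) + 1L]] <- c(nm, "unknown_category")
    }
  }
  for (nm in names(sch2$logical_constraints)) {
    if (!isTRUE(sch2$logical_constraints[[nm]](bad))) {
      oracle[[length(oracle) + 1L]] <- c(nm, "logical")
    }
  }
  oracle_df <- do.call(rbind, oracle)
  expect_setequal(paste(got$field, got$type),
                  paste(oracle_df[, 1], oracle_df[, 2]))

  expect_error(validate_record(c(clean_record(), list(bogus = 1)), schema),
               "schema mismatch")
})

test_that("imputation applies the CRP baseline, mean and mode rules", {
  stats <- list(means = c(age = 66, crp = 12, ph = 7.37, pao2 = 71, paco2 = 49,
                          hco3 = 26, wbc = 9, neut_pct = 70, hgb = 139),
                modes = c(sex = "male", fever = "no"))

  afebrile <- clean_record()
  afebrile$fever <- "no"
  afebrile$crp <- NA_real_
  out <- impute_record(afebrile, stats, schema)
  expect_identical(out$record$crp, 3.5)
  expect_identical(unname(out$status["crp"]), "imputed_baseline")

  febrile <- clean_record()
  febrile$fever <- "yes"
  febrile$crp <- NA_real_
  out <- impute_record(febrile, stats, schema)
  expect_identical(out$record$crp, 12)       # training mean, not baseline
  expect_identical(unname(out$status["crp"]), "imputed_mean")

  nosex <- clean_record()
  nosex$sex <- NA_character_
  out <- impute_record(nosex, stats, schema)
  expect_identical(out$record$sex, "male")
  expect_identical(unname(out$status["sex"]), "imputed_mode")

  measured <- impute_record(clean_record(), stats, schema)
  expect_true(all(measured$status == "measured"))
  expect_identical(measured$record$crp, clean_record()$crp)

  empty_stats <- list(means = numeric(), modes = character())
  expect_error(impute_record(febrile, empty_stats, schema), "training mean")
})

test_that("imputation is idempotent and never alters measured values", {
  cfg <- tiny_config(missing_rate = 0.3, afebrile_crp_missing_rate = 0.7)
  cohort <- generate_cohort(cfg)
  stats <- field_statistics(cohort$data, schema)
  once <- impute_cohort(cohort$data, stats, schema)
  twice <- impute_cohort(once$data, stats, schema)
  expect_identical(once$data, twice$data)
  expect_true(all(twice$status == "measured"))   # nothing left to impute
  # measured values untouched, field-wise
  for (nm in schema_structured_fields(schema)) {
    measured <- !is.na(cohort$data[[nm]])
    expect_identical(once$data[[nm]][measured], cohort$data[[nm]][measured])
  }
  # after imputation nothing is missing and filled-in statuses are non-measured
  expect_false(anyNA(once$data[schema_structured_fields(schema)]))
  for (nm in schema_structured_fields(schema)) {
    was_missing <- is.na(cohort$data[[nm]])
    expect_true(all(once$status[[nm]][was_missing] != "measured"))
  }
})

test_that("standardizer fits population moments and guards sd = 0", {
  df <- data.frame(x = c(1, 2, 3), y = c(5, 5, 5))
  sch <- feature_schema(list(g = c("a", "b")),
                        list(x = list(units = "u", range = c(-10, 10)),
                             y = list(units = "u", range = c(-10, 10))),
                        text_units = "t")
  std <- fit_standardizer(df, sch)
  expect_equal(unname(std$mean), c(2, 5))
  expect_equal(unname(std$sd), c(sqrt(2 / 3), 0), tolerance = 1e-12)

  z <- apply_standardizer(data.frame(x = 3, y = 99), std)
  expect_equal(unname(z[1, "x"]), (3 - 2) / sqrt(2 / 3), tolerance = 1e-12)
  expect_identical(unname(z[1, "y"]), 0)          # sd = 0 guard

  # own fit data -> mean 0, sd(pop) 1 where sd > 0
  zz <- apply_standardizer(df, std)
  expect_lt(abs(mean(zz[, "x"])), 1e-6)
  expect_lt(abs(sqrt(mean((zz[, "x"] - mean(zz[, "x"]))^2)) - 1), 1e-6)

  one <- fit_standardizer(data.frame(x = 4, y = 1), sch)
  expect_equal(unname(one$mean), c(4, 1))
  expect_equal(unname(one$sd), c(0, 0))

  expect_error(fit_standardizer(df, sch, rows = integer()), "empty")
})

test_that("standardize/unstandardize round-trips for sd > 0 fields", {
  cfg <- tiny_config(missing_rate = 0)
  cohort <- generate_cohort(cfg)
  imp <- impute_cohort(cohort$data,
                       field_statistics(cohort$data, schema), schema)
  std <- fit_standardizer(imp$data, schema)
  z <- apply_standardizer(imp$data, std)
  back <- emrfuse:::unapply_standardizer(z, std)
  for (nm in names(schema$numeric_fields)) {
    if (std$sd[nm] > 0) {
      expect_lt(max(abs(back[, nm] - imp$data[[nm]])), 1e-9)
    }
  }
})

test_that("encode_binary one-hot layout matches a per-field oracle", {
  cfg <- tiny_config(missing_rate = 0.2)
  cohort <- generate_cohort(cfg)
  imp <- impute_cohort(cohort$data,
                       field_statistics(cohort$data, schema), schema)
  std <- fit_standardizer(imp$data, schema)
  X <- encode_binary(imp$data, schema, std)

  card <- sum(lengths(schema$categorical_fields))
  expect_identical(ncol(X), card + length(schema$numeric_fields))

  # exactly one set bit per categorical field
  off <- 0L
  for (nm in names(schema$categorical_fields)) {
    c_i <- length(schema$categorical_fields[[nm]])
    block <- X[, (off + 1):(off + c_i), drop = FALSE]
    expect_true(all(rowSums(block) == 1))
    # oracle: indicator by direct level match
    oracle <- outer(imp$data[[nm]], schema$categorical_fields[[nm]], "==") * 1
    expect_identical(unname(block), unname(oracle))
    off <- off + c_i
  }
  expect_error(encode_binary(transform(imp$data, sex = "alien"), schema, std),
               "category outside schema")
})

test_that("cohort CSV round-trip preserves values and missingness", {
  cfg <- tiny_config(missing_rate = 0.25)
  cohort <- generate_cohort(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(cohort, path)
  back <- read_cohort_csv(path, schema)
  expect_identical(back$data[[schema$label_name]],
                   cohort$data[[schema$label_name]])
  expect_identical(is.na(back$data$crp), is.na(cohort$data$crp))
  expect_equal(back$data$pao2, cohort$data$pao2)
  expect_identical(back$data$ct_report, cohort$data$ct_report)
})

test_that("winsorization clamps to range and logs every correction", {
  df <- data.frame(age = c(30, 67, 120), crp = c(10, 400, NA))
  sch <- default_emr_schema()
  out <- winsorize_outliers(df, sch)
  expect_equal(out$data$age, c(35, 67, 91))
  expect_equal(out$data$crp, c(10, 300, NA))
  expect_identical(nrow(out$log), 3L)
  expect_setequal(out$log$field, c("age", "crp"))
})
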