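#' Declarative schema for a multimodal EMR cohort
#'
#' A `feature_schema` describes the structured fields (categorical and
#' continuous), the free-text units, and the label column of a cohort table,
#' together with the clinical constants needed by the imputation rules: which
#' field is the fever indicator, which is the C-reactive protein (CRP)
#' measurement, and the afebrile CRP baseline value.
#'
#' @param categorical_fields named list; each element is a character vector of
#'   ordered, unique category labels (cardinality >= 2).
#' @param numeric_fields named list; each element a list with `units` (string)
#'   and `range` (finite numeric c(low, high), low < high).
#' @param text_units character vector of free-text column names.
#' @param label_name name of the binary 0/1 label column.
#' @param fever_field name of the categorical fever indicator ("no"/"yes").
#' @param crp_field name of the CRP numeric field (or NA to disable the rule).
#' @param crp_baseline baseline CRP in mg/L assigned to afebrile patients with
#'   no CRP test result (default 3.5).
#' @param logical_constraints named list of functions `f(record)` returning
#'   `TRUE` when satisfied or a character message describing the violation; an
#'   extensible hook for cross-field clinical rules.
#' @return an object of class `feature_schema`.
#' @seealso [default_emr_schema()] for the packaged 11-field schema.
#' @export
feature_schema <- function(categorical_fields, numeric_fields, text_units,
                           label_name = "diagnosis",
                           fever_field = NA_character_,
                           crp_field = NA_character_,
                           crp_baseline = 3.5,
                           logical_constraints = list()) {
  stopifnot(is.list(categorical_fields), is.list(numeric_fields))
  for (nm in names(categorical_fields)) {
    lv <- categorical_fields[[nm]]
    if (length(lv) < 2L || anyDuplicated(lv)) {
      stop(sprintf("categorical field '%s': need >= 2 unique levels", nm))
    }
  }
  for (nm in names(numeric_fields)) {
    r <- numeric_fields[[nm]]$range
    if (length(r) != 2L || !all(is.finite(r)) || r[1] >= r[2]) {
      stop(sprintf("numeric field '%s': range must be finite with low < high",
                   nm))
    }
  }
  if (!is.na(fever_field) && !fever_field %in% names(categorical_fields)) {
    stop("fever_field must be a categorical field")
  }
  if (!is.na(crp_field) && !crp_field %in% names(numeric_fields)) {
    stop("crp_field must be a numeric field")
  }
  structure(
    list(
      categorical_fields = categorical_fields,
      numeric_fields = numeric_fields,
      text_units = text_units,
      label_name = label_name,
      fever_field = fever_field,
      crp_field = crp_field,
      crp_baseline = crp_baseline,
      logical_constraints = logical_constraints
    ),
    class = "feature_schema"
  )
}

#' Default 11-field EMR schema
#'
#' The study cohort this package emulates exposes 11 structured fields and 2
#' text units but does not name them; this documented stand-in uses sex, age, a
#' fever indicator, CRP, four blood-gas parameters and three hematology
#' parameters, plus a pulmonary CT report and a medical-history narrative.
#' Ranges are conventional adult clinical plausibility bounds, used for
#' validation and outlier winsorization.
#'
#' @return a [feature_schema()].
#' @export
default_emr_schema <- function() {
  feature_schema(
    categorical_fields = list(
      sex = c("female", "male"),
      fever = c("no", "yes")
    ),
    numeric_fields = list(
      age      = list(units = "years",   range = c(35, 91)),
      crp      = list(units = "mg/L",    range = c(0, 300)),
      ph       = list(units = "pH",      range = c(6.8, 7.8)),
      pao2     = list(units = "mmHg",    range = c(30, 150)),
      paco2    = list(units = "mmHg",    range = c(15, 120)),
      hco3     = list(units = "mmol/L",  range = c(5, 45)),
      wbc      = list(units = "10^9/L",  range = c(1, 60)),
      neut_pct = list(units = "%",       range = c(10, 100)),
      hgb      = list(units = "g/L",     range = c(40, 220))
    ),
    text_units = c("ct_report", "history"),
    label_name = "diagnosis",
    fever_field = "fever",
    crp_field = "crp",
    crp_baseline = 3.5
  )
}

schema_structured_fields <- function(schema) {
  c(names(schema$categorical_fields), names(schema$numeric_fields))
}

#' Validate one patient record against a schema
#'
#' Checks every structured value for range violations (numeric), unknown
#' categories (categorical) and violated cross-field logical constraints.
#' Missing values (`NA`) are legal at this stage and produce no violation.
#'
#' @param record named list (or one-row data.frame) of raw values.
#' @param schema a [feature_schema()].
#' @return data.frame with columns `field`, `type`
#'   (`range`/`unknown_category`/`logical`) and `message`; zero rows iff clean.
#' @export
validate_record <- function(record, schema) {
  record <- as.list(record)
  known <- c(schema_structured_fields(schema), schema$text_units,
             schema$label_name, "id")
  extra <- setdiff(names(record), known)
  if (length(extra) > 0L) {
    stop(sprintf("schema mismatch: unknown field(s) %s",
                 paste(extra, collapse = ", ")))
  }
  v <- list()
  add <- function(field, type, message) {
    v[[length(v) + 1L]] <<- data.frame(field = field, type = type,
                                       message = message)
  }
  for (nm in names(schema$numeric_fields)) {
    x <- record[[nm]]
    if (is.null(x) || is.na(x)) next
    r <- schema$numeric_fields[[nm]]$range
    if (x < r[1] || x > r[2]) {
      add(nm, "range", sprintf("%s = %g outside [%g, %g] %s", nm, x,
                               r[1], r[2], schema$numeric_fields[[nm]]$units))
    }
  }
  for (nm in names(schema$categorical_fields)) {
    x <- record[[nm]]
    if (is.null(x) || is.na(x)) next
    if (!x %in% schema$categorical_fields[[nm]]) {
      add(nm, "unknown_category",
          sprintf("%s = '%s' not a known category", nm, x))
    }
  }
  for (nm in names(schema$logical_constraints)) {
    res <- schema$logical_constraints[[nm]](record)
    if (!isTRUE(res)) {
      add(nm, "logical", if (is.character(res)) res else
        sprintf("constraint '%s' violated", nm))
    }
  }
  if (length(v) == 0L) {
    data.frame(field = character(), type = character(), message = character())
  } else {
    do.call(rbind, v)
  }
}

#' Winsorize out-of-range numeric values
#'
#' Outlier "correction" is implemented as clamping to the schema's valid range;
#' every action is returned in a log so corrections stay auditable.
#'
#' @param data cohort data.frame.
#' @param schema a [feature_schema()].
#' @return list with the corrected `data` and a `log` data.frame
#'   (row, field, old, new).
#' @export
winsorize_outliers <- function(data, schema) {
  log <- list()
  for (nm in names(schema$numeric_fields)) {
    r <- schema$numeric_fields[[nm]]$range
    x <- data[[nm]]
    bad <- which(!is.na(x) & (x < r[1] | x > r[2]))
    if (length(bad) > 0L) {
      newv <- pmin(pmax(x[bad], r[1]), r[2])
      log[[length(log) + 1L]] <- data.frame(row = bad, field = nm,
                                            old = x[bad], new = newv)
      data[[nm]][bad] <- newv
    }
  }
  list(data = data,
       log = if (length(log)) do.call(rbind, log) else
         data.frame(row = integer(), field = character(),
                    old = numeric(), new = numeric()))
}

#' Per-field imputation statistics from a training split
#'
#' Means for continuous fields and most-frequent values for categorical fields,
#' computed over measured (non-missing) values of the given rows only, so no
#' information leaks from a validation split.
#'
#' @param data cohort data.frame.
#' @param schema a [feature_schema()].
#' @param rows integer indices of the training split (default all rows).
#' @return list with `means` (named numeric) and `modes` (named character).
#' @export
field_statistics <- function(data, schema, rows = seq_len(nrow(data))) {
  means <- vapply(names(schema$numeric_fields), function(nm) {
    mean(data[[nm]][rows], na.rm = TRUE)
  }, numeric(1))
  modes <- vapply(names(schema$categorical_fields), function(nm) {
    x <- data[[nm]][rows]
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(NA_character_)
    tb <- table(x)
    names(tb)[which.max(tb)]
  }, character(1))
  list(means = means, modes = modes)
}

#' Impute missing structured values in one record
#'
#' Applies, in order: the clinically-aware CRP rule (afebrile patient with no
#' CRP result gets the baseline value, 3.5 mg/L by default, status
#' `imputed_baseline`), training-split mean imputation for any other missing
#' continuous value (`imputed_mean`), and training-split mode imputation for
#' missing categorical values (`imputed_mode`). Measured values are never
#' modified, and every field's original testing status is retained in the
#' returned status vector.
#'
#' @param record named list of raw values (NA = missing).
#' @param stats output of [field_statistics()] on the training split.
#' @param schema a [feature_schema()].
#' @return list with `record` (fully imputed) and `status`
#'   (named character: measured/imputed_baseline/imputed_mean/imputed_mode).
#' @export
impute_record <- function(record, stats, schema) {
  record <- as.list(record)
  fields <- schema_structured_fields(schema)
  status <- stats::setNames(rep("measured", length(fields)), fields)
  afebrile <- FALSE
  if (!is.na(schema$fever_field)) {
    fev <- record[[schema$fever_field]]
    afebrile <- !is.null(fev) && !is.na(fev) && fev == "no"
  }
  for (nm in names(schema$numeric_fields)) {
    if (!is.na(record[[nm]])) next
    if (!is.na(schema$crp_field) && nm == schema$crp_field && afebrile) {
      record[[nm]] <- schema$crp_baseline
      status[nm] <- "imputed_baseline"
    } else {
      m <- unname(stats$means[nm])
      if (length(m) == 0L || is.na(m)) {
        stop(sprintf("no training mean available for field '%s'", nm))
      }
      record[[nm]] <- m
      status[nm] <- "imputed_mean"
    }
  }
  for (nm in names(schema$categorical_fields)) {
    if (!is.na(record[[nm]])) next
    md <- unname(stats$modes[nm])
    if (length(md) == 0L || is.na(md)) {
      stop(sprintf("no training mode available for field '%s'", nm))
    }
    record[[nm]] <- md
    status[nm] <- "imputed_mode"
  }
  list(record = record, status = status)
}

#' Impute a whole cohort table
#'
#' Row-wise [impute_record()]; returns the imputed data plus the per-record,
#' per-field imputation-status table (the transparency log).
#'
#' @inheritParams field_statistics
#' @param stats output of [field_statistics()] on the training split.
#' @return list with `data` and `status` data.frames of equal shape.
#' @export
impute_cohort <- function(data, stats, schema) {
  fields <- schema_structured_fields(schema)
  status <- as.data.frame(matrix("measured", nrow(data), length(fields)),
                          stringsAsFactors = FALSE)
  names(status) <- fields
  for (i in seq_len(nrow(data))) {
    rec <- as.list(data[i, fields, drop = FALSE])
    out <- impute_record(rec, stats, schema)
    for (nm in fields) data[[nm]][i] <- out$record[[nm]]
    status[i, ] <- out$status[fields]
  }
  list(data = data, status = status)
}

#' Fit a z-score standardizer on a training split
#'
#' Per-field arithmetic mean and population standard deviation (divisor n).
#' Call only after imputation so no value is missing.
#'
#' @inheritParams field_statistics
#' @return object of class `emr_standardizer` (named `mean`, `sd` vectors).
#' @export
fit_standardizer <- function(data, schema, rows = seq_len(nrow(data))) {
  if (length(rows) == 0L) stop("cannot fit a standardizer on an empty split")
  nm <- names(schema$numeric_fields)
  mu <- vapply(nm, function(f) mean(data[[f]][rows]), numeric(1))
  sd_ <- vapply(nm, function(f) {
    x <- data[[f]][rows]
    sqrt(mean((x - mean(x))^2))
  }, numeric(1))
  if (anyNA(mu)) stop("missing values present; impute before standardizing")
  structure(list(mean = mu, sd = sd_), class = "emr_standardizer")
}

#' Apply a fitted standardizer
#'
#' `(x - mean) / sd` per field; fields with zero standard deviation map to 0 so
#' degenerate (constant) synthetic configurations still run.
#'
#' @param data cohort data.frame (or one-row list) with no missing numerics.
#' @param std an `emr_standardizer` from [fit_standardizer()].
#' @return numeric matrix, one column per numeric field.
#' @export
apply_standardizer <- function(data, std) {
  nm <- names(std$mean)
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  out <- matrix(0, nrow(data), length(nm), dimnames = list(NULL, nm))
  for (j in seq_along(nm)) {
    if (std$sd[j] > 0) {
      out[, j] <- (data[[nm[j]]] - std$mean[j]) / std$sd[j]
    }
  }
  out
}

unapply_standardizer <- function(z, std) {
  nm <- names(std$mean)
  out <- z
  for (j in seq_along(nm)) out[, j] <- z[, j] * std$sd[j] + std$mean[j]
  out
}

#' One-hot / standardized-numeric flat encoding
#'
#' Expands each categorical field into indicator bits and concatenates the
#' z-scored numeric fields. This flat representation feeds only the tabular
#' baseline classifiers; the fusion model consumes per-field category indices
#' through its embedding tables instead.
#'
#' @param data imputed cohort data.frame.
#' @param schema a [feature_schema()].
#' @param std an `emr_standardizer` fitted on the training split.
#' @return numeric matrix with `sum(cardinalities) + n_numeric` columns.
#' @export
encode_binary <- function(data, schema, std) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  blocks <- lapply(names(schema$categorical_fields), function(nm) {
    lv <- schema$categorical_fields[[nm]]
    x <- data[[nm]]
    if (anyNA(x) || !all(x %in% lv)) {
      stop(sprintf("field '%s': category outside schema", nm))
    }
    m <- matrix(0, length(x), length(lv),
                dimnames = list(NULL, paste0(nm, "=", lv)))
    m[cbind(seq_along(x), match(x, lv))] <- 1
    m
  })
  cbind(do.call(cbind, blocks), apply_standardizer(data, std))
}

# ---- cohort container and I/O ----------------------------------------------

#' Construct an EMR cohort object
#'
#' @param data data.frame with id, structured fields, text units and label.
#' @param schema a [feature_schema()].
#' @param latents optional data.frame of generator latent variables (used by
#'   synthetic cohorts and their oracle tests).
#' @param config optional generator configuration.
#' @return object of class `emr_cohort`.
#' @export
emr_cohort <- function(data, schema, latents = NULL, config = NULL) {
  need <- c("id", schema_structured_fields(schema), schema$text_units,
            schema$label_name)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L) {
    stop(sprintf("cohort is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  structure(list(data = data, schema = schema, latents = latents,
                 config = config),
            class = "emr_cohort")
}

#' @export
print.emr_cohort <- function(x, ...) {
  cat(sprintf("<emr_cohort> %d patients, %d structured fields, %d text units\n",
              nrow(x$data), length(schema_structured_fields(x$schema)),
              length(x$schema$text_units)))
  invisible(x)
}

#' Write / read a cohort as CSV
#'
#' One row per patient; missing values are written as empty cells; text units
#' are quoted string columns; the label column is 0/1.
#'
#' @param cohort an `emr_cohort`.
#' @param path file path.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort$data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @param schema schema used to type the columns on read.
#' @export
read_cohort_csv <- function(path, schema) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  for (nm in names(schema$numeric_fields)) df[[nm]] <- as.numeric(df[[nm]])
  for (nm in c(names(schema$categorical_fields))) {
    df[[nm]][df[[nm]] == ""] <- NA_character_
  }
  df[[schema$label_name]] <- as.integer(df[[schema$label_name]])
  emr_cohort(df, schema)
}
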