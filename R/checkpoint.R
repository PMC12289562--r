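# Checkpoints are a single JSON archive: a manifest (architecture
# hyperparameters, schema, seed, schema hash) plus every trainable parameter,
# so a model reloads exactly.

fnv1a_hash <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

schema_to_list <- function(schema) {
  list(categorical_fields = schema$categorical_fields,
       numeric_fields = schema$numeric_fields,
       text_units = schema$text_units,
       label_name = schema$label_name,
       fever_field = schema$fever_field,
       crp_field = schema$crp_field,
       crp_baseline = schema$crp_baseline)
}

schema_from_list <- function(x) {
  feature_schema(
    categorical_fields = lapply(x$categorical_fields, unlist),
    numeric_fields = lapply(x$numeric_fields, function(f) {
      list(units = f$units, range = unlist(f$range))
    }),
    text_units = unlist(x$text_units),
    label_name = x$label_name,
    fever_field = if (is.null(x$fever_field)) NA_character_ else x$fever_field,
    crp_field = if (is.null(x$crp_field)) NA_character_ else x$crp_field,
    crp_baseline = x$crp_baseline
  )
}

schema_hash <- function(schema) {
  fnv1a_hash(jsonlite::toJSON(schema_to_list(schema), auto_unbox = TRUE))
}

#' Save / load a model checkpoint
#'
#' @param model an [init_model()] result (possibly trained).
#' @param path JSON file path.
#' @export
model_save <- function(model, path) {
  params <- model_params(model)
  jsonlite::write_json(list(
    manifest = list(
      config = unclass(model$config),
      seed = model$seed,
      schema = schema_to_list(model$schema),
      schema_hash = schema_hash(model$schema)
    ),
    params = lapply(params, function(p) p$val)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname model_save
#' @export
model_load <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  schema <- schema_from_list(x$manifest$schema)
  if (!identical(schema_hash(schema), x$manifest$schema_hash)) {
    stop("checkpoint schema hash mismatch")
  }
  cfgl <- x$manifest$config
  cfg <- do.call(model_config,
                 cfgl[intersect(names(cfgl), names(formals(model_config)))])
  model <- init_model(schema, cfg, seed = x$manifest$seed)
  params <- model_params(model)
  for (nm in names(params)) {
    v <- x$params[[nm]]
    if (is.null(v)) stop(sprintf("checkpoint missing parameter '%s'", nm))
    params[[nm]]$val <- matrix(as.numeric(v), nrow(params[[nm]]$val),
                               ncol(params[[nm]]$val))
  }
  model
}
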