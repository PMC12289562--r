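#' Configuration for the synthetic EMR cohort generator
#'
#' The defaults reproduce the composition of the emulated study cohort: 800
#' patients (276 female, 524 male), ages drawn from a normal distribution
#' truncated to [35, 91] years. Two latent binary severity indicators drive the
#' planted label signal: `s` is expressed in the blood-gas/hematology fields
#' and `t` in the text findings; the label is Bernoulli with log-odds
#' `logit(prevalence) + structured_effect*s + text_effect*t +
#' interaction_effect*s*t` (s, t in {-1, +1}), so a nonzero interaction term is
#' visible only to models that combine both modalities.
#'
#' @param n_patients,n_female,n_male cohort composition
#'   (`n_female + n_male == n_patients`).
#' @param age_mean,age_sd,age_range truncated-normal age model (years).
#' @param prevalence label prevalence in `[0, 1]`; 0 and 1 force all-negative /
#'   all-positive cohorts.
#' @param structured_effect,text_effect,interaction_effect label log-odds
#'   coefficients of the latent severity variables (`s` standard normal,
#'   expressed in the labs; `t` in {-1, +1}, expressed in the text).
#' @param lab_informativeness multiplier on the latent-to-lab loadings; 1 is
#'   the realistic default, larger values make the labs sharper readouts of
#'   `s` (used by the strong-signal preset).
#' @param token_p_pos,token_p_neg probability of each label-informative text
#'   finding token given `t = +1` / `t = -1`.
#' @param missing_rate per-lab-field missing-completely-at-random rate.
#' @param afebrile_crp_missing_rate probability that an afebrile patient has no
#'   CRP result (clinically structured missingness).
#' @param fever_rate probability of the fever indicator being "yes".
#' @param seed integer RNG seed; identical config + seed gives a byte-identical
#'   cohort.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 800, n_female = 276, n_male = 524,
                          age_mean = 65, age_sd = 10, age_range = c(35, 91),
                          prevalence = 0.45,
                          structured_effect = 1.5, text_effect = 1.5,
                          interaction_effect = 0,
                          lab_informativeness = 1,
                          token_p_pos = 0.85, token_p_neg = 0.08,
                          missing_rate = 0.05,
                          afebrile_crp_missing_rate = 0.6,
                          fever_rate = 0.3,
                          seed = 1L) {
  if (n_female + n_male != n_patients) {
    stop("n_female + n_male must equal n_patients")
  }
  rates <- c(prevalence, missing_rate, afebrile_crp_missing_rate, fever_rate,
             token_p_pos, token_p_neg)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (age_range[1] >= age_range[2]) stop("age_range must be ordered")
  if (lab_informativeness <= 0) stop("lab_informativeness must be positive")
  structure(as.list(environment()), class = "cohort_config")
}

#' Preset worlds for learnability checks
#'
#' `strong_signal_config()`: large additive structured and text effects
#' (log-odds 8 and 6), sharp labs (`lab_informativeness = 4`) and
#' high-fidelity text tokens, chosen once from the generator's Bayes-oracle
#' analysis so the achievable accuracy comfortably exceeds 0.9.
#' `interaction_signal_config()`: the label depends only on the product
#' `s * t` (log-odds 4), so neither modality alone carries any signal and
#' only genuinely cross-modal models can learn it. `null_signal_config()`:
#' all effects zero.
#'
#' @param n_patients cohort size (split ~45% female like the default cohort).
#' @param seed RNG seed.
#' @param ... further overrides passed to [cohort_config()].
#' @return a [cohort_config()].
#' @export
strong_signal_config <- function(n_patients = 800, seed = 1L, ...) {
  nf <- round(0.45 * n_patients)
  cohort_config(n_patients = n_patients, n_female = nf,
                n_male = n_patients - nf,
                structured_effect = 8, text_effect = 6,
                interaction_effect = 0, lab_informativeness = 4,
                token_p_pos = 0.95, token_p_neg = 0.02,
                seed = seed, ...)
}

#' @rdname strong_signal_config
#' @export
interaction_signal_config <- function(n_patients = 800, seed = 1L, ...) {
  nf <- round(0.45 * n_patients)
  cohort_config(n_patients = n_patients, n_female = nf,
                n_male = n_patients - nf,
                structured_effect = 0, text_effect = 0,
                interaction_effect = 4, prevalence = 0.5,
                lab_informativeness = 4,
                token_p_pos = 0.95, token_p_neg = 0.02,
                seed = seed, ...)
}

#' @rdname strong_signal_config
#' @export
null_signal_config <- function(n_patients = 800, seed = 1L, ...) {
  nf <- round(0.45 * n_patients)
  cohort_config(n_patients = n_patients, n_female = nf,
                n_male = n_patients - nf,
                structured_effect = 0, text_effect = 0,
                interaction_effect = 0, seed = seed, ...)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0L) {                  # rejection sampling
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= lo & x <= hi
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

clamp_to_range <- function(x, range) pmin(pmax(x, range[1]), range[2])

# label-informative CT finding tokens controlled by latent t
.ct_findings <- c("emphysema", "bronchial wall thickening", "hyperinflation")

#' Render one synthetic free-text unit
#'
#' Deterministic template realization of a pulmonary CT report or a
#' medical-history narrative from a record's latent state. Label-informative
#' finding tokens appear with probability `p_pos` when the text latent is
#' positive and `p_neg` otherwise.
#'
#' @param latent list with `t` (text latent, -1/+1), `age`, `sex`,
#'   `smoking_years`.
#' @param unit `"ct_report"` or `"history"`.
#' @param seed integer seed; same (latent, unit, seed) gives the same string.
#' @param p_pos,p_neg finding-token probabilities for t = +1 / t = -1.
#' @return a single string (bounded well under typical encoder l_max).
#' @export
render_text_unit <- function(latent, unit, seed, p_pos = 0.85, p_neg = 0.08) {
  with_seed(seed, {
    p <- if (latent$t > 0) p_pos else p_neg
    present <- stats::runif(length(.ct_findings)) < p
    if (unit == "ct_report") {
      findings <- if (any(present)) {
        paste0("Findings include ", paste(.ct_findings[present],
                                          collapse = ", "), ".")
      } else {
        "No acute parenchymal abnormality identified."
      }
      extra <- sample(c("Cardiac silhouette unremarkable.",
                        "Mild pleural thickening noted.",
                        "No pleural effusion."), 1L)
      paste("Pulmonary CT report:", findings, extra)
    } else if (unit == "history") {
      p_ex <- if (latent$t > 0) 0.8 * p_pos else p_neg
      exac <- if (stats::runif(1) < p_ex) {
        "Reports frequent exacerbations over the last year."
      } else {
        "No recent exacerbation reported."
      }
      sprintf(paste("Patient aged %d, %s. Chronic cough with sputum",
                    "production. Smoking history of %d pack years. %s"),
              round(latent$age), latent$sex, round(latent$smoking_years), exac)
    } else {
      stop(sprintf("unknown text unit '%s'", unit))
    }
  })
}

#' Generate a seeded synthetic EMR cohort
#'
#' Draws latent severity indicators, realizes structured labs and template
#' text conditioned on them, draws labels from the configured logistic model,
#' then applies missingness masking (including the afebrile CRP pattern). All
#' pre-masking values are clamped into the schema's valid ranges, so the clean
#' cohort passes [validate_record()] with zero violations.
#'
#' @param config a [cohort_config()].
#' @param schema a [feature_schema()] (default [default_emr_schema()]).
#' @return an [emr_cohort()] whose `latents` slot carries the generator's
#'   latent variables and Bayes-optimal probabilities (for oracle tests only).
#' @export
generate_cohort <- function(config, schema = default_emr_schema()) {
  n <- config$n_patients
  if (n < 1L) stop("n_patients must be positive")
  with_seed(config$seed, {
    s <- stats::rnorm(n)                       # continuous severity latent
    t_ <- sample(c(-1, 1), n, replace = TRUE)  # text latent
    sex <- sample(c(rep("female", config$n_female),
                    rep("male", config$n_male)))
    age <- rtruncnorm1(n, config$age_mean, config$age_sd,
                       config$age_range[1], config$age_range[2])
    fever <- ifelse(stats::runif(n) < config$fever_rate, "yes", "no")
    smoking_years <- pmax(0, stats::rnorm(n, 30, 12))

    # labs: latent s shifts the blood-gas/hematology profile; the
    # informativeness multiplier sharpens the loadings relative to noise
    nf <- schema$numeric_fields
    li <- config$lab_informativeness
    lab <- data.frame(
      ph       = stats::rnorm(n, 7.38 - 0.02 * li * s, 0.03),
      pao2     = stats::rnorm(n, 72 - 8 * li * s, 6),
      paco2    = stats::rnorm(n, 48 + 6 * li * s, 5),
      hco3     = stats::rnorm(n, 26 + 3 * li * s, 3),
      wbc      = stats::rnorm(n, 9 + 1.5 * li * s, 1.5),
      neut_pct = stats::rnorm(n, 68 + 5 * li * s, 6),
      hgb      = stats::rnorm(n, 138, 15)
    )
    crp <- exp(stats::rnorm(n, log(8), 0.7)) * ifelse(fever == "yes", 2.5, 1)
    lab$crp <- crp
    for (nm in names(lab)) {
      if (nm %in% names(nf)) lab[[nm]] <- clamp_to_range(lab[[nm]], nf[[nm]]$range)
    }

    # labels from the planted logistic model
    if (config$prevalence == 0) {
      y <- rep(0L, n)
      eta <- rep(-Inf, n)
    } else if (config$prevalence == 1) {
      y <- rep(1L, n)
      eta <- rep(Inf, n)
    } else {
      eta <- stats::qlogis(config$prevalence) +
        config$structured_effect * s + config$text_effect * t_ +
        config$interaction_effect * s * t_
      y <- as.integer(stats::runif(n) < stats::plogis(eta))
    }

    text_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n)
    ct <- character(n)
    hist_ <- character(n)
    for (i in seq_len(n)) {
      latent <- list(t = t_[i], age = age[i], sex = sex[i],
                     smoking_years = smoking_years[i])
      ct[i] <- render_text_unit(latent, "ct_report", text_seeds[2L * i - 1L],
                                p_pos = config$token_p_pos,
                                p_neg = config$token_p_neg)
      hist_[i] <- render_text_unit(latent, "history", text_seeds[2L * i],
                                   p_pos = config$token_p_pos,
                                   p_neg = config$token_p_neg)
    }

    data <- data.frame(
      id = sprintf("P%04d", seq_len(n)),
      sex = sex, fever = fever, age = round(age, 1),
      crp = round(lab$crp, 2), ph = round(lab$ph, 3),
      pao2 = round(lab$pao2, 1), paco2 = round(lab$paco2, 1),
      hco3 = round(lab$hco3, 1), wbc = round(lab$wbc, 2),
      neut_pct = round(lab$neut_pct, 1), hgb = round(lab$hgb, 1),
      ct_report = ct, history = hist_,
      stringsAsFactors = FALSE
    )
    data[[schema$label_name]] <- y

    # missingness masking: MCAR on labs, clinically structured on CRP
    mcar_fields <- setdiff(names(schema$numeric_fields), c("age", "crp"))
    for (nm in mcar_fields) {
      miss <- stats::runif(n) < config$missing_rate
      data[[nm]][miss] <- NA_real_
    }
    crp_miss_p <- ifelse(fever == "no", config$afebrile_crp_missing_rate,
                         config$missing_rate)
    data$crp[stats::runif(n) < crp_miss_p] <- NA_real_

    latents <- data.frame(s = s, t = t_, eta = eta,
                          bayes_prob = stats::plogis(eta))
    emr_cohort(data, schema, latents = latents, config = config)
  })
}

#' Bayes-optimal reference predictions from the generator's latent state
#'
#' The oracle that sees the latent variables; used to bound what any trained
#' model can achieve on a synthetic cohort.
#'
#' @param cohort a synthetic [emr_cohort()] with latents.
#' @return list with `pred` (0/1 vector), `prob`, and `expected_accuracy`
#'   (mean of max(p, 1-p), the Bayes accuracy of the planted model).
#' @export
latent_oracle <- function(cohort) {
  if (is.null(cohort$latents)) stop("cohort carries no latent variables")
  p <- cohort$latents$bayes_prob
  list(pred = as.integer(p > 0.5), prob = p,
       expected_accuracy = mean(pmax(p, 1 - p)))
}

#' Summarize a cohort
#'
#' @param cohort an [emr_cohort()].
#' @return list with counts, label prevalence, sex split, per-field missingness
#'   rates and per-numeric-field mean/sd (over measured values).
#' @export
cohort_summary <- function(cohort) {
  d <- cohort$data
  if (nrow(d) == 0L) stop("empty cohort")
  schema <- cohort$schema
  fields <- schema_structured_fields(schema)
  missingness <- vapply(fields, function(nm) mean(is.na(d[[nm]])), numeric(1))
  nm <- names(schema$numeric_fields)
  list(
    n = nrow(d),
    n_female = sum(d$sex == "female", na.rm = TRUE),
    n_male = sum(d$sex == "male", na.rm = TRUE),
    n_structured_fields = length(fields),
    n_text_units = length(schema$text_units),
    prevalence = mean(d[[schema$label_name]]),
    age_mean = mean(d$age, na.rm = TRUE),
    age_sd = stats::sd(d$age, na.rm = TRUE),
    missingness = missingness,
    field_mean = vapply(nm, function(f) mean(d[[f]], na.rm = TRUE), numeric(1)),
    field_sd = vapply(nm, function(f) stats::sd(d[[f]], na.rm = TRUE),
                      numeric(1))
  )
}
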