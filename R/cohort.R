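# Synthetic cohort generation: lognormal biomarker panels with class-dependent
# shifts, detection limits, missingness and gender-specific markers, emulating
# the unbalanced structure of a haematuria clinic population.

SICK_CATEGORIES <- c(
  "chronic kidney disease", "infection", "other benign diagnosis",
  "bladder cancer", "history of bladder cancer", "other cancer"
)
HEALTHY_CATEGORY <- "no cause identified"

#' Describe one synthetic biomarker
#'
#' A biomarker is simulated on the log scale: raw values are
#' `exp(Normal(log_mean, log_sd))` with a class-dependent mean, which
#' guarantees positivity and the right-skewed marginals typical of urine and
#' serum panels. Values falling below the limit of detection (LOD) are stored
#' as censored flags, not numbers; substitution happens in preprocessing.
#'
#' @param name marker identifier (syntactic, e.g. `"microalbumin"`).
#' @param units free-text measurement units.
#' @param log_mean_healthy,log_mean_sick class-conditional means of the log
#'   values. A marker is informative when the two differ.
#' @param log_sd common log-scale standard deviation, must be positive.
#' @param lod limit of detection on the raw scale (non-negative; same units
#'   as the raw values).
#' @param missing_rate probability in `[0, 1)` that a measurement is missing.
#' @param gender_specific one of `"none"`, `"male_only"`, `"female_only"`.
#'   For the excluded gender the marker sits at the LOD (e.g. serum tPSA in
#'   females).
#' @return a one-row `data.frame` of class `biomarker_spec`.
#' @export
biomarker_spec <- function(name, units = "", log_mean_healthy = 0,
                           log_mean_sick = log_mean_healthy, log_sd = 0.5,
                           lod = 0, missing_rate = 0,
                           gender_specific = c("none", "male_only",
                                               "female_only")) {
  gender_specific <- match.arg(gender_specific)
  if (!is.numeric(log_sd) || log_sd <= 0)
    stopf("biomarker '%s': log_sd must be > 0", name)
  if (missing_rate < 0 || missing_rate >= 1)
    stopf("biomarker '%s': missing_rate must be in [0, 1)", name)
  if (lod < 0)
    stopf("biomarker '%s': lod must be >= 0", name)
  if (gender_specific != "none" && lod <= 0)
    stopf("biomarker '%s': gender-specific markers need lod > 0", name)
  out <- data.frame(
    name = name, units = units,
    log_mean_healthy = log_mean_healthy, log_mean_sick = log_mean_sick,
    log_sd = log_sd, lod = lod, missing_rate = missing_rate,
    gender_specific = gender_specific, stringsAsFactors = FALSE
  )
  class(out) <- c("biomarker_spec", "data.frame")
  out
}

#' Full parameterization of a synthetic cohort
#'
#' @param n_male,n_female total patients per gender.
#' @param sick_male,sick_female number of sick patients per gender (must not
#'   exceed the gender totals).
#' @param diagnosis_mix named numeric vector of proportions over the sick
#'   subcategories; normalized to sum to 1.
#' @param biomarkers a `data.frame` of stacked [biomarker_spec()] rows.
#' @param seed default seed used by [generate_cohort()].
#' @return a list of class `generator_config`.
#' @seealso [default_habio_config()] for the study-structure defaults.
#' @export
generator_config <- function(n_male, n_female, sick_male, sick_female,
                             diagnosis_mix = NULL, biomarkers, seed = 1L) {
  if (is.null(diagnosis_mix)) {
    diagnosis_mix <- stats::setNames(rep(1 / length(SICK_CATEGORIES),
                                         length(SICK_CATEGORIES)),
                                     SICK_CATEGORIES)
  }
  cfg <- structure(
    list(n_male = as.integer(n_male), n_female = as.integer(n_female),
         sick_male = as.integer(sick_male),
         sick_female = as.integer(sick_female),
         diagnosis_mix = diagnosis_mix / sum(diagnosis_mix),
         biomarkers = as.data.frame(biomarkers), seed = as.integer(seed)),
    class = "generator_config"
  )
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(config) {
  if (!inherits(config, "generator_config"))
    stopf("config must be a generator_config")
  with(config, {
    if (sick_male > n_male)
      stopf("invalid config: sick_male (%d) > n_male (%d)", sick_male, n_male)
    if (sick_female > n_female)
      stopf("invalid config: sick_female (%d) > n_female (%d)",
            sick_female, n_female)
    if (nrow(biomarkers) < 1)
      stopf("invalid config: at least one biomarker is required")
    if (abs(sum(diagnosis_mix) - 1) > 1e-8)
      stopf("invalid config: diagnosis_mix proportions must sum to 1")
    if (anyDuplicated(biomarkers$name))
      stopf("invalid config: duplicated biomarker names")
  })
  invisible(config)
}

# Default biomarker panel: 24 markers with realistic names, units and raw
# scales. Ten are informative: the class shift is 2 * log_sd * qnorm(0.7), a
# class-conditional flip-probability gap of 0.4 at the midpoint threshold.
default_biomarker_panel <- function() {
  shift <- 2 * 0.5 * stats::qnorm(0.7)  # ~0.524 on the log scale
  spec <- function(name, units, mu, informative = FALSE, sign = 1,
                   lod = exp(mu - 2.5 * 0.5), miss = 0.03, gender = "none") {
    biomarker_spec(name, units,
                   log_mean_healthy = mu,
                   log_mean_sick = mu + if (informative) sign * shift else 0,
                   log_sd = 0.5, lod = lod, missing_rate = miss,
                   gender_specific = gender)
  }
  do.call(rbind, list(
    # informative markers (class-shifted)
    spec("microalbumin",    "mg/l",   2.0, TRUE),
    spec("cystatin_C",      "ng/ml",  0.5, TRUE),
    spec("CXCL16",          "ng/ml", -3.5, TRUE),
    spec("sTNFRI",          "ng/ml", -1.2, TRUE),
    spec("MCP_1",           "pg/ml",  3.8, TRUE),
    spec("IL8",             "pg/ml",  3.0, TRUE),
    spec("pERK",            "pg/ml",  5.4, TRUE),
    spec("progranulin",     "ng/ml",  1.9, TRUE),
    spec("D_dimer",         "ng/ml",  2.8, TRUE, sign = -1),
    spec("serum_tPSA",      "ng/ml",  0.0, TRUE, gender = "male_only",
         lod = 0.05),
    # uninformative background panel
    spec("osmolarity",      "mOsm",   6.3),
    spec("urinary_protein", "mg/ml", -2.3),
    spec("creatinine",      "mmol/l", 2.1),
    spec("BTA",             "U/ml",   1.8),
    spec("NGAL",            "ng/ml",  4.6),
    spec("midkine",         "pg/ml",  4.9),
    spec("IL7",             "pg/ml",  0.9),
    spec("sTNFRII",         "ng/ml", -0.9),
    spec("clusterin",       "ng/ml",  5.1),
    spec("cystatin_B",      "ng/ml",  1.4),
    spec("serum_CRP",       "mg/ml",  0.6),
    spec("serum_CEA",       "ng/ml",  0.4),
    spec("serum_VEGF",      "pg/ml",  5.2),
    spec("serum_HAD",       "U/l",   -1.6)
  ))
}

#' Default cohort configuration mirroring the haematuria study structure
#'
#' Returns a [generator_config()] with the published cohort structure:
#' 485 males and 190 females (675 patients, roughly 2.5:1), 444 sick males
#' and 111 sick females, six sick diagnosis subcategories, and a 24-marker
#' panel of which ten are informative, including the male-only serum tPSA.
#'
#' @param seed default generation seed.
#' @return a `generator_config`.
#' @export
default_habio_config <- function(seed = 1L) {
  mix <- c("chronic kidney disease" = 0.08, "infection" = 0.22,
           "other benign diagnosis" = 0.34, "bladder cancer" = 0.17,
           "history of bladder cancer" = 0.09, "other cancer" = 0.10)
  generator_config(n_male = 485L, n_female = 190L,
                   sick_male = 444L, sick_female = 111L,
                   diagnosis_mix = mix,
                   biomarkers = default_biomarker_panel(), seed = seed)
}

#' Generate a synthetic cohort
#'
#' Draws a patient-by-biomarker table from a [generator_config()]: raw values
#' are class-conditionally lognormal, values below the marker's LOD are
#' flagged censored (no number stored), missing entries are inserted at the
#' configured rate, and gender-specific markers sit at the LOD for the
#' excluded gender. Identical `(config, seed)` pairs yield identical tables.
#'
#' @param config a valid `generator_config`.
#' @param seed integer seed; defaults to `config$seed`.
#' @return a `cohort_table`: a `data.frame` with columns `patient_id`,
#'   `gender` (`"M"`/`"F"`), `age`, `diagnosis`, `label`
#'   (`"sick"`/`"healthy"`) and one numeric column per biomarker (`NA` =
#'   missing), carrying attributes `censored` (logical matrix), `lod` and
#'   `units` (named vectors), `truth` (the config) and `scale` (`"raw"`).
#' @export
generate_cohort <- function(config, seed = config$seed) {
  validate_generator_config(config)
  with_seed(seed, {
    n <- config$n_male + config$n_female
    gender <- rep(c("M", "F"), c(config$n_male, config$n_female))
    sick <- c(rep(c(TRUE, FALSE), c(config$sick_male,
                                    config$n_male - config$sick_male)),
              rep(c(TRUE, FALSE), c(config$sick_female,
                                    config$n_female - config$sick_female)))
    label <- ifelse(sick, "sick", "healthy")
    diagnosis <- rep(HEALTHY_CATEGORY, n)
    diagnosis[sick] <- sample(names(config$diagnosis_mix), sum(sick),
                              replace = TRUE, prob = config$diagnosis_mix)
    age <- ifelse(sick, stats::rnorm(n, 65, 10), stats::rnorm(n, 58, 10))
    age <- round(pmin(pmax(age, 18), 95))

    specs <- config$biomarkers
    values <- matrix(NA_real_, n, nrow(specs),
                     dimnames = list(NULL, specs$name))
    censored <- matrix(FALSE, n, nrow(specs),
                       dimnames = list(NULL, specs$name))
    for (j in seq_len(nrow(specs))) {
      s <- specs[j, ]
      mu <- ifelse(sick, s$log_mean_sick, s$log_mean_healthy)
      x <- exp(stats::rnorm(n, mu, s$log_sd))
      excluded <- switch(s$gender_specific,
                         male_only = gender == "F",
                         female_only = gender == "M",
                         rep(FALSE, n))
      x[excluded] <- s$lod
      cens <- !excluded & x < s$lod
      x[cens] <- NA_real_
      miss <- stats::runif(n) < s$missing_rate
      x[miss] <- NA_real_
      cens[miss] <- FALSE
      values[, j] <- x
      censored[, j] <- cens
    }

    tab <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                      gender = gender, age = age, diagnosis = diagnosis,
                      label = label, stringsAsFactors = FALSE)
    tab <- cbind(tab, as.data.frame(values))
    new_cohort_table(tab,
                     censored = censored,
                     lod = stats::setNames(specs$lod, specs$name),
                     units = stats::setNames(specs$units, specs$name),
                     truth = config, scale = "raw")
  })
}

new_cohort_table <- function(df, censored, lod, units = NULL, truth = NULL,
                             scale = "raw") {
  rownames(df) <- NULL
  rownames(censored) <- NULL
  structure(df, censored = censored, lod = lod, units = units, truth = truth,
            scale = scale, class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d patients x %d biomarkers (%s scale)\n",
              nrow(x), length(marker_names(x)), attr(x, "scale")))
  tab <- table(x$gender, x$label)
  print(tab)
  cens <- attr(x, "censored")
  cat(sprintf("missing: %d cells, below-LOD: %d cells\n",
              sum(is.na(marker_values(x))) - sum(cens), sum(cens)))
  invisible(x)
}

#' Biomarker column names of a cohort
#' @param table a `cohort_table`.
#' @return character vector of marker names.
#' @export
marker_names <- function(table) {
  setdiff(names(table), c("patient_id", "gender", "age", "diagnosis", "label"))
}

#' Numeric biomarker matrix of a cohort
#' @param table a `cohort_table`.
#' @return numeric matrix patients x markers (`NA` where missing/censored).
#' @export
marker_values <- function(table) {
  as.matrix(table[, marker_names(table), drop = FALSE])
}

# Replace the marker block, preserving cohort attributes.
set_marker_values <- function(table, values) {
  table[, colnames(values)] <- as.data.frame(values)
  table
}

# Subset rows of a cohort keeping the censored mask aligned.
cohort_rows <- function(table, idx) {
  new_cohort_table(as.data.frame(table)[idx, , drop = FALSE],
                   censored = attr(table, "censored")[idx, , drop = FALSE],
                   lod = attr(table, "lod"), units = attr(table, "units"),
                   truth = attr(table, "truth"), scale = attr(table, "scale"))
}

# Drop marker columns (e.g. constant gender-specific markers in a subset).
drop_markers <- function(table, drop) {
  if (!length(drop)) return(table)
  keep <- setdiff(names(table), drop)
  cens <- attr(table, "censored")
  new_cohort_table(as.data.frame(table)[, keep, drop = FALSE],
                   censored = cens[, setdiff(colnames(cens), drop),
                                   drop = FALSE],
                   lod = attr(table, "lod")[setdiff(names(attr(table, "lod")),
                                                    drop)],
                   units = attr(table, "units"), truth = attr(table, "truth"),
                   scale = attr(table, "scale"))
}
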