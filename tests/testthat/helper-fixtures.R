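# Fixtures built in code: tiny cohorts via the public CSV dialect, and small
# generator configs for simulation-based tests.

# A hand-written cohort with known values, missing cells and one <LOD cell.
# Returns the raw-scale cohort_table read back through the public reader.
tiny_cohort <- function() {
  csv <- file.path(tempdir(), "tiny_cohort.csv")
  writeLines(c(
    'patient_id,gender,age,diagnosis,label,m1,m2',
    'P1,M,70,bladder cancer,sick,1,5.2',
    'P2,M,61,infection,sick,2.718281828459045,<LOD',
    'P3,M,55,no cause identified,healthy,1,0.5',
    'P4,F,58,no cause identified,healthy,,2'
  ), csv)
  writeLines(c(
    'biomarkers:',
    '  m1:',
    '    lod: 0.3',
    "    units: 'ng/ml'",
    '  m2:',
    '    lod: 1.0',
    "    units: 'pg/ml'"
  ), paste0(csv, ".yaml"))
  read_cohort_csv(csv)
}

# Small single-gender generator config: n sick + n healthy males, `p`
# markers with a chosen log-scale class shift; no censoring or missingness
# unless asked for.
sim_config <- function(n_sick, n_healthy, p = 5, shift = 1, log_sd = 0.5,
                       lod = 0, missing_rate = 0, seed = 1) {
  specs <- do.call(rbind, lapply(seq_len(p), function(j)
    biomarker_spec(sprintf("mk%02d", j), "au",
                   log_mean_healthy = 0, log_mean_sick = shift,
                   log_sd = log_sd, lod = lod,
                   missing_rate = missing_rate)))
  generator_config(n_male = n_sick + n_healthy, n_female = 0L,
                   sick_male = n_sick, sick_female = 0L,
                   biomarkers = specs, seed = seed)
}

# Independent oracle for the Youden scan: enumerate every candidate
# threshold with explicit counting (no shared code with youden_cutoff).
brute_force_youden <- function(values, labels) {
  u <- sort(unique(values))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best_t <- NA_real_
  best_j <- -Inf
  for (t in cand) {
    sens <- mean(values[labels == "sick"] > t)
    spec <- mean(values[labels == "healthy"] <= t)
    j <- abs(sens + spec - 1)
    if (j > best_j + 1e-12 ||
        (abs(j - best_j) <= 1e-12 && t < best_t)) {
      best_j <- j
      best_t <- t
    }
  }
  list(threshold = best_t, j = best_j)
}

# Direct-product cost oracle: per-class product of conditional probabilities
# over observed flips, no logs.
brute_force_cost <- function(flips_row, model) {
  costs <- sapply(model$classes, function(cls) {
    prod(vapply(names(flips_row)[!is.na(flips_row)], function(m)
      model$prob[[flips_row[[m]]]][m, cls], 0))
  })
  costs
}
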