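#' Configuration for the synthetic OPCAB cohort generator
#'
#' Defines the ground-truth data-generating process for a paired cardiac
#' index series emulating an OPCAB monitoring study: patient-level baseline
#' CI, within-patient AR(1) drift with additive phase effects, a
#' multiplicative-error reference device (thermodilution-like, precision
#' quoted as a coefficient of variation) and a test device with constant
#' plus proportional bias, a patient-level offset, and additive noise.
#'
#' Defaults reproduce the study conditions the generator emulates: 20
#' patients at 29 measurements each, cohort mean CI 2.4 L/min/m^2,
#' reference CV 0.10 (i.e. +/-20% precision as 1.96 x CV), a lowered true
#' CI during distal anastomoses, and test-device error scaled so the total
#' SD of paired differences is about 0.7 L/min/m^2.
#'
#' @param n_patients Number of patients (default 20).
#' @param measurements_per_patient Either a single count (default 29, split
#'   over phases in clinical order) or a named vector of per-phase counts.
#' @param patient_mean_ci Cohort mean baseline CI, L/min/m^2 (default 2.4).
#' @param patient_sd Between-patient SD of baseline CI (default 0.4).
#' @param ar_coefficient AR(1) coefficient in `[0, 1)` of the within-patient
#'   true-CI drift (default 0.8).
#' @param innovation_sd SD of AR(1) innovations, L/min/m^2 (default 0.25).
#' @param phase_effects Named numeric vector of additive shifts of the true
#'   CI per phase (default: -0.3 during `distal_anastomoses`, 0 elsewhere).
#' @param ref_cv Coefficient of variation of the reference device
#'   (default 0.10).
#' @param test_bias0 Constant test-device bias, L/min/m^2 (default 0.13).
#' @param test_bias1 Proportional bias slope, per L/min/m^2 of true CI above
#'   `patient_mean_ci` (default 0).
#' @param test_patient_sd SD of the patient-level test-device offset
#'   (default 0.3).
#' @param test_noise_sd SD of test-device measurement noise (default 0.58).
#' @param seed RNG seed; identical (seed, config) gives a bit-identical
#'   dataset.
#'
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_patients = 20,
                              measurements_per_patient = 29,
                              patient_mean_ci = 2.4,
                              patient_sd = 0.4,
                              ar_coefficient = 0.8,
                              innovation_sd = 0.25,
                              phase_effects = c(distal_anastomoses = -0.3),
                              ref_cv = 0.10,
                              test_bias0 = 0.13,
                              test_bias1 = 0,
                              test_patient_sd = 0.3,
                              test_noise_sd = 0.58,
                              seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    measurements_per_patient = measurements_per_patient,
    patient_mean_ci = patient_mean_ci,
    patient_sd = patient_sd,
    ar_coefficient = ar_coefficient,
    innovation_sd = innovation_sd,
    phase_effects = phase_effects,
    ref_cv = ref_cv,
    test_bias0 = test_bias0,
    test_bias1 = test_bias1,
    test_patient_sd = test_patient_sd,
    test_noise_sd = test_noise_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  if (cfg$n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  sds <- c(cfg$patient_sd, cfg$innovation_sd, cfg$test_patient_sd,
           cfg$test_noise_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  if (cfg$ref_cv < 0) stop("ref_cv must be >= 0", call. = FALSE)
  if (cfg$ar_coefficient < 0 || cfg$ar_coefficient >= 1) {
    stop("ar_coefficient must lie in [0, 1)", call. = FALSE)
  }
  if (length(phase_schedule(cfg)) < 1) {
    stop("measurements_per_patient must give >= 1 measurement", call. = FALSE)
  }
  if (!is.null(names(cfg$phase_effects))) {
    unknown <- setdiff(names(cfg$phase_effects), ci_phases())
    if (length(unknown) > 0) {
      stop("phase_effects names must be known phases; unknown: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  invisible(cfg)
}

# Per-patient phase label sequence in clinical order. A scalar count is
# split across phases in roughly the proportions of a 579-measurement OPCAB
# series (24/27/85/104 in the four named phases, the rest unphased).
phase_schedule <- function(cfg) {
  m <- cfg$measurements_per_patient
  if (!is.null(names(m))) {
    unknown <- setdiff(names(m), ci_phases())
    if (length(unknown) > 0) {
      stop("unknown phase(s) in measurements_per_patient: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    counts <- setNames(rep(0L, length(ci_phases())), ci_phases())
    counts[names(m)] <- as.integer(m)
  } else {
    m <- as.integer(m)
    props <- c(baseline = 24, aortic_side_clamp = 27,
               distal_anastomoses = 85, icu_pre_extubation = 104,
               other = 339) / 579
    cum <- round(cumsum(props) * m)
    counts <- setNames(as.integer(diff(c(0, cum))), names(props))
  }
  c(rep("baseline", counts[["baseline"]]),
    rep("other", ceiling(counts[["other"]] / 2)),
    rep("aortic_side_clamp", counts[["aortic_side_clamp"]]),
    rep("distal_anastomoses", counts[["distal_anastomoses"]]),
    rep("other", counts[["other"]] - ceiling(counts[["other"]] / 2)),
    rep("icu_pre_extubation", counts[["icu_pre_extubation"]]))
}

phase_effect_vector <- function(cfg, phases) {
  eff <- setNames(rep(0, length(ci_phases())), ci_phases())
  if (length(cfg$phase_effects) > 0) {
    eff[names(cfg$phase_effects)] <- cfg$phase_effects
  }
  unname(eff[phases])
}

#' Simulate a paired cardiac-index cohort with known ground truth
#'
#' For each patient i, a baseline level `T_i ~ N(patient_mean_ci,
#' patient_sd^2)` is drawn; the true CI series follows an AR(1) process
#' around `T_i` plus the phase effect, truncated below at 0.5 L/min/m^2
#' (below physiological interest; truncation keeps row counts and
#' determinism). The reference reading is `true * (1 + e)` with
#' `e ~ N(0, ref_cv^2)`; the test reading is
#' `true + bias0 + bias1 * (true - patient_mean_ci) + u_i + noise` with a
#' patient offset `u_i ~ N(0, test_patient_sd^2)`, truncated below at
#' 0.1 L/min/m^2. The returned dataset carries the generating config and
#' its implied agreement parameters as a `ground_truth` attribute.
#'
#' @param config A [simulation_config()].
#' @return A `cohort_dataset` with attribute `ground_truth` (a list with
#'   the config and the [expected_agreement()] decomposition).
#' @export
simulate_cohort <- function(config) {
  validate_simulation_config(config)
  sched <- phase_schedule(config)
  m <- length(sched)
  k <- config$n_patients
  peff <- phase_effect_vector(config, sched)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  rows <- vector("list", k)
  ar <- config$ar_coefficient
  stat_sd <- if (config$innovation_sd > 0) {
    config$innovation_sd / sqrt(1 - ar^2)
  } else 0
  for (i in seq_len(k)) {
    T_i <- rnorm(1, config$patient_mean_ci, config$patient_sd)
    x <- numeric(m)
    x[1] <- rnorm(1, 0, stat_sd)
    if (m > 1) {
      innov <- rnorm(m - 1, 0, config$innovation_sd)
      for (j in 2:m) x[j] <- ar * x[j - 1] + innov[j - 1]
    }
    true_ci <- pmax(0.5, T_i + peff + x)
    ref <- true_ci * (1 + rnorm(m, 0, config$ref_cv))
    ref <- pmax(0.1, ref)
    u_i <- rnorm(1, 0, config$test_patient_sd)
    tst <- true_ci + config$test_bias0 +
      config$test_bias1 * (true_ci - config$patient_mean_ci) +
      u_i + rnorm(m, 0, config$test_noise_sd)
    tst <- pmax(0.1, tst)
    rows[[i]] <- data.frame(
      patient_id = sprintf("P%03d", i),
      time_index = seq_len(m) - 1L,
      phase = sched,
      ci_ref = ref,
      ci_test = tst,
      true_ci = true_ci,
      stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, rows)
  out <- cohort_dataset(df[c("patient_id", "time_index", "phase",
                             "ci_ref", "ci_test")],
                        device_name = "simulated_device",
                        reference_name = "simulated_reference")
  attr(out, "ground_truth") <- list(
    config = config,
    true_ci = df$true_ci,
    expected = expected_agreement(config)
  )
  out
}

#' Analytic bias and difference-SD implied by a simulation config
#'
#' Closed-form moments of the paired difference `ci_test - ci_ref` under
#' the generating model (ignoring the low truncation floors, which are
#' essentially never hit at default settings). Writing `t` for the true CI,
#' `p_j` for the phase effect at slot j and `mu` for `patient_mean_ci`:
#'
#' \describe{
#'   \item{bias}{`bias0 + bias1 * mean(p_j)` -- the reference error is
#'     mean-zero and the patient offsets average out.}
#'   \item{between-patient variance}{`test_patient_sd^2 +
#'     bias1^2 * patient_sd^2` -- the patient offset plus the proportional
#'     bias propagating the spread of patient baselines.}
#'   \item{within-patient variance}{`test_noise_sd^2 + ref_cv^2 * E[t^2] +
#'     bias1^2 * (ar_var + var(p_j))` where `ar_var =
#'     innovation_sd^2 / (1 - ar^2)` is the stationary AR(1) variance and
#'     `E[t^2] = (mu + mean(p_j))^2 + patient_sd^2 + ar_var + var(p_j)`
#'     (population variance of the phase schedule).}
#' }
#'
#' @param config A [simulation_config()].
#' @return A list with `bias`, `var_between`, `var_within`, `sd_total`, and
#'   a `terms` breakdown.
#' @export
expected_agreement <- function(config) {
  validate_simulation_config(config)
  sched <- phase_schedule(config)
  peff <- phase_effect_vector(config, sched)
  pbar <- mean(peff)
  pvar <- mean((peff - pbar)^2)
  ar_var <- if (config$innovation_sd > 0) {
    config$innovation_sd^2 / (1 - config$ar_coefficient^2)
  } else 0
  mu_t <- config$patient_mean_ci + pbar
  e_t2 <- mu_t^2 + config$patient_sd^2 + ar_var + pvar
  bias <- config$test_bias0 + config$test_bias1 * pbar
  var_between <- config$test_patient_sd^2 +
    config$test_bias1^2 * config$patient_sd^2
  var_within <- config$test_noise_sd^2 +
    config$ref_cv^2 * e_t2 +
    config$test_bias1^2 * (ar_var + pvar)
  list(
    bias = bias,
    var_between = var_between,
    var_within = var_within,
    sd_total = sqrt(var_between + var_within),
    terms = list(
      patient_offset_var = config$test_patient_sd^2,
      prop_bias_between_var = config$test_bias1^2 * config$patient_sd^2,
      test_noise_var = config$test_noise_sd^2,
      reference_error_var = config$ref_cv^2 * e_t2,
      prop_bias_within_var = config$test_bias1^2 * (ar_var + pvar),
      mean_true_ci = mu_t,
      e_true_ci_sq = e_t2,
      ar_stationary_var = ar_var,
      phase_effect_var = pvar
    )
  )
}
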