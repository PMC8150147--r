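test_that("difference construction follows the test-minus-reference convention", {
  ds <- make_cohort(c("A", "A", "B"), c(0, 1, 0),
                    ci_ref = c(2.0, 2.0, 3.0),
                    ci_test = c(2.5, 2.0, 2.4))
  d <- differences(ds)
  expect_equal(d$diff, c(0.5, 0, -0.6))
  expect_equal(d$pair_mean, c(2.25, 2.0, 2.7))
  empty <- make_cohort(character(0), integer(0), numeric(0), numeric(0),
                       phase = character(0))
  expect_error(differences(empty), "empty")
})

test_that("variance components reproduce the hand-worked unbalanced ANOVA", {
  d <- tibble::tibble(patient_id = c("A", "A", "B", "B"),
                      diff = c(0, 2, -1, 1))
  vc <- variance_components(d)
  expect_equal(vc$grand_mean_diff, 0.5)
  expect_equal(vc$ms_between, 1)
  expect_equal(vc$ms_within, 2)
  expect_equal(vc$n0, 2)
  expect_equal(vc$sigma2_between, 0)
  expect_true(vc$truncated)
  expect_equal(vc$sd_total, sqrt(2))
})

test_that("degenerate inputs collapse to the documented special cases", {
  # one measurement per patient: ordinary sample SD
  vc1 <- variance_components(tibble::tibble(patient_id = c("a", "b", "c"),
                                            diff = c(1, 2, 3)))
  expect_equal(vc1$sd_total, 1)
  expect_equal(vc1$sigma2_within, 0)
  expect_equal(vc1$n0, 1)
  # constant differences: bias c, zero SD
  vc0 <- variance_components(tibble::tibble(
    patient_id = rep(c("a", "b"), each = 3), diff = rep(0.7, 6)))
  expect_equal(vc0$grand_mean_diff, 0.7)
  expect_equal(vc0$sd_total, 0)
  # single patient: undefined between component
  expect_error(variance_components(tibble::tibble(
    patient_id = rep("a", 5), diff = rnorm(5))), ">= 2 patients")
})

test_that("variance components match an lm/anova oracle on random datasets", {
  set.seed(202)
  for (rep in 1:200) {
    k <- sample(2:6, 1)
    m_i <- sample(1:6, k, replace = TRUE)
    if (sum(m_i) == k) m_i[1] <- m_i[1] + 1  # ensure within df unless all 1
    pid <- rep(letters[1:k], times = m_i)
    diff <- rnorm(sum(m_i), mean = rnorm(k, 0, 0.5)[match(pid, letters[1:k])],
                  sd = 0.4)
    vc <- variance_components(tibble::tibble(patient_id = pid, diff = diff))
    oracle <- brute_variance_components(pid, diff)
    expect_equal(vc$grand_mean_diff, oracle$bias, tolerance = 1e-12)
    expect_equal(vc$ms_between, oracle$ms_between, tolerance = 1e-10)
    expect_equal(vc$ms_within, oracle$ms_within, tolerance = 1e-10)
    expect_equal(vc$sd_total, oracle$sd_total, tolerance = 1e-10)
    expect_gte(vc$sigma2_between, 0)
  }
})

test_that("with one measurement per patient sd_total equals the sample SD exactly", {
  set.seed(7)
  for (rep in 1:20) {
    d <- rnorm(sample(3:40, 1), 0.1, 0.7)
    vc <- variance_components(tibble::tibble(
      patient_id = paste0("p", seq_along(d)), diff = d))
    expect_equal(vc$sd_total, sd(d), tolerance = 1e-15)
    lims <- loa(vc)
    expect_equal(lims[["lower"]], mean(d) - 1.96 * sd(d), tolerance = 1e-15)
    expect_equal(lims[["upper"]], mean(d) + 1.96 * sd(d), tolerance = 1e-15)
  }
})

test_that("limits of agreement are bias -/+ z * sd and symmetric about the bias", {
  d <- tibble::tibble(patient_id = rep(c("a", "b", "c"), each = 4),
                      diff = c(rnorm(12, 0.13, 0.7)))
  vc <- variance_components(d)
  lims <- loa(vc)
  expect_equal(lims[["upper"]] - lims[["lower"]], 2 * 1.96 * vc$sd_total)
  expect_equal((lims[["upper"]] + lims[["lower"]]) / 2, vc$grand_mean_diff)
  expect_equal(unname(loa(vc, z = 0)), rep(vc$grand_mean_diff, 2))
})

test_that("bias CI collapses correctly and is zero-width for constant differences", {
  # sigma2_between = 0, balanced: reduces to dbar +/- t * sd_w / sqrt(N)
  vc <- list(k = 4, n_total = 12, m_i = rep(3L, 4), grand_mean_diff = 0.2,
             ms_between = 0.5, ms_within = 0.5, n0 = 3,
             sigma2_between = 0, sigma2_within = 0.5,
             sd_total = sqrt(0.5), truncated = TRUE)
  class(vc) <- "variance_components"
  ci <- bias_ci(vc)
  half <- qt(0.975, 3) * sqrt(0.5 / 12)
  expect_equal(unname(ci), c(0.2 - half, 0.2 + half))

  vc0 <- variance_components(tibble::tibble(
    patient_id = rep(c("a", "b"), each = 2), diff = rep(1.1, 4)))
  expect_equal(unname(bias_ci(vc0)), c(1.1, 1.1))
})

test_that("LOA CI methods agree asymptotically and near the classical formula", {
  # large balanced cohort: delta and MOVER widths within 10%
  cfg <- simulation_config(n_patients = 200, measurements_per_patient = 30,
                           seed = 17)
  vc <- variance_components(simulate_cohort(cfg))
  mov <- loa_ci(vc, method = "mover")
  del <- loa_ci(vc, method = "delta")
  for (side in c("lower", "upper")) {
    w_m <- diff(unname(mov[[side]]))
    w_d <- diff(unname(del[[side]]))
    expect_lt(abs(w_m - w_d), 0.10 * w_d)
    # each interval contains its point limit
    lims <- loa(vc)
    expect_lt(mov[[side]][["lower"]], lims[[side]])
    expect_gt(mov[[side]][["upper"]], lims[[side]])
  }

  # single measurement per patient: classical SE(LOA) = sd * sqrt(3/N)
  set.seed(88)
  d <- rnorm(100, 0.1, 0.7)
  vc1 <- variance_components(tibble::tibble(
    patient_id = paste0("p", 1:100), diff = d))
  classical <- 2 * qnorm(0.975) * sd(d) * sqrt(3 / 100)
  for (meth in c("mover", "delta")) {
    ci <- loa_ci(vc1, method = meth)
    expect_equal(diff(unname(ci$upper)), classical, tolerance = 0.05)
    expect_equal(diff(unname(ci$lower)), classical, tolerance = 0.05)
  }
})

test_that("zero-spread differences give degenerate LOA CIs with a warning", {
  vc0 <- variance_components(tibble::tibble(
    patient_id = rep(c("a", "b"), each = 2), diff = rep(0.5, 4)))
  expect_warning(ci <- loa_ci(vc0), "degenerate")
  expect_true(ci$degenerate)
  expect_equal(unname(ci$lower), c(0.5, 0.5))
})

test_that("percentage error arithmetic, threshold case, and scale invariance", {
  # z * sd = 0.6 against reference mean 2.0 sits exactly at the 30% bar
  ds <- make_cohort(rep(c("a", "b"), each = 2), rep(0:1, 2),
                    ci_ref = rep(2, 4), ci_test = rep(2, 4))
  vc <- list(k = 2, n_total = 4, m_i = c(2L, 2L), grand_mean_diff = 0,
             ms_between = 0, ms_within = 0, n0 = 2, sigma2_between = 0,
             sigma2_within = (0.6 / 1.96)^2, sd_total = 0.6 / 1.96,
             truncated = FALSE)
  class(vc) <- "variance_components"
  expect_equal(as.numeric(percentage_error(vc, ds)), 30)

  # sd 0 data -> 0%
  vc0 <- variance_components(differences(ds))
  expect_equal(as.numeric(percentage_error(vc0, ds)), 0)

  # invariance under common rescaling of both devices
  set.seed(12)
  base <- simulate_cohort(simulation_config(n_patients = 5,
                                            measurements_per_patient = 6,
                                            seed = 12))
  pe1 <- as.numeric(percentage_error(variance_components(base), base))
  for (c_scale in c(0.25, 3.7)) {
    scaled <- make_cohort(base$patient_id, base$time_index,
                          ci_ref = base$ci_ref * c_scale,
                          ci_test = base$ci_test * c_scale,
                          phase = base$phase)
    pe2 <- as.numeric(percentage_error(variance_components(scaled), scaled))
    expect_equal(pe2, pe1, tolerance = 1e-12)
  }

  # denominator choice is recorded and changes the value accordingly
  pe_ref <- percentage_error(variance_components(base), base, "reference")
  pe_both <- percentage_error(variance_components(base), base, "both")
  expect_equal(attr(pe_ref, "denominator"), "reference")
  expect_equal(as.numeric(pe_ref) / as.numeric(pe_both),
               attr(pe_both, "denominator_mean") / attr(pe_ref, "denominator_mean"),
               tolerance = 1e-12)
})

test_that("percentage-error bootstrap interval is deterministic under a seed and sane", {
  ds <- simulate_cohort(simulation_config(n_patients = 10,
                                          measurements_per_patient = 8,
                                          seed = 44))
  ci1 <- percentage_error_ci(ds, B = 200, seed = 9)
  ci2 <- percentage_error_ci(ds, B = 200, seed = 9)
  expect_identical(ci1, ci2)
  expect_lt(ci1[["lower"]], ci1[["upper"]])

  # sd 0 data -> interval (0, 0)
  flat <- make_cohort(rep(c("a", "b"), each = 2), rep(0:1, 2),
                      ci_ref = rep(2, 4), ci_test = rep(2, 4))
  expect_equal(as.numeric(percentage_error_ci(flat, B = 50, seed = 1)),
               c(0, 0))

  # interval contains the point PE across simulated datasets
  hits <- 0L
  for (s in 1:20) {
    d <- simulate_cohort(simulation_config(n_patients = 12,
                                           measurements_per_patient = 10,
                                           seed = 400 + s))
    pe <- as.numeric(percentage_error(variance_components(d), d))
    ci <- percentage_error_ci(d, B = 200, seed = s)
    hits <- hits + (pe >= ci[["lower"]] && pe <= ci[["upper"]])
  }
  expect_gte(hits, 19L)
})

test_that("proportional-bias regression: exact fit, cluster permutation, recovery", {
  # differences exactly linear in the means -> slope recovered, zero width
  pm <- c(1.8, 2.1, 2.4, 2.9, 3.3, 3.8)
  di <- -0.4 + 0.5 * pm
  ref <- pm - di / 2
  tst <- pm + di / 2
  ds <- make_cohort(rep(c("a", "b"), each = 3), rep(0:2, 2), ref, tst)
  # lm flags the perfect fit; that is exactly the scenario under test
  pb <- suppressWarnings(proportional_bias(ds))
  expect_equal(pb$slope, 0.5, tolerance = 1e-10)
  expect_equal(unname(pb$slope_ci), c(0.5, 0.5), tolerance = 1e-6)

  # permuting patient labels leaves the OLS slope unchanged
  set.seed(5)
  sim <- simulate_cohort(simulation_config(n_patients = 8,
                                           measurements_per_patient = 6,
                                           test_bias1 = 0.3, seed = 5))
  pb1 <- proportional_bias(sim)
  perm <- make_cohort(sample(sim$patient_id), seq_len(nrow(sim)),
                      sim$ci_ref, sim$ci_test)
  expect_equal(proportional_bias(perm)$slope, pb1$slope, tolerance = 1e-12)

  expect_error(proportional_bias(make_cohort(c("a", "a", "b"), c(0, 1, 0),
                                             rep(2, 3), rep(2.5, 3))),
               "zero variance")
})

test_that("regression slope recovers the generator's proportional bias", {
  # Monte-Carlo oracle: direct simulation of the generating model (written
  # independently of simulate_cohort), OLS of difference on pairwise mean.
  set.seed(606)
  n_oracle <- 1e6
  mu <- 2.4
  t <- rnorm(n_oracle, mu, sqrt(0.4^2 + 0.25^2 / (1 - 0.8^2)))
  ref <- t * (1 + rnorm(n_oracle, 0, 0.10))
  tst <- t + 0.13 + 0.3 * (t - mu) + rnorm(n_oracle, 0, sqrt(0.3^2 + 0.58^2))
  oracle_slope <- unname(coef(lm(I(tst - ref) ~ I((tst + ref) / 2)))[2])

  cfg <- simulation_config(n_patients = 500, measurements_per_patient = 30,
                           test_bias1 = 0.3, phase_effects = numeric(0),
                           seed = 77)
  pb <- proportional_bias(simulate_cohort(cfg))
  expect_lt(abs(pb$slope - oracle_slope), 0.05)
})

test_that("analyze_agreement runs the full chain per phase with invariants intact", {
  cfg <- simulation_config(seed = 21)
  ds <- simulate_cohort(cfg)
  res <- analyze_agreement(ds, phases = setdiff(ci_phases(), "other"),
                           boot_B = 100, seed = 2)
  expect_s3_class(res, "agreement_result")
  expect_equal(nrow(res), 5)  # all + 4 phases
  expect_equal(res$phase[1], "all")
  ok <- !res$insufficient
  expect_true(all(res$loa_lower[ok] <= res$bias[ok]))
  expect_true(all(res$bias[ok] <= res$loa_upper[ok]))
  expect_equal(res$loa_upper[ok] - res$loa_lower[ok],
               2 * 1.96 * (res$loa_upper[ok] - res$bias[ok]) / 1.96,
               tolerance = 1e-12)
  # CIs contain their point estimates
  expect_true(all(res$bias_lower[ok] <= res$bias[ok] &
                    res$bias[ok] <= res$bias_upper[ok]))
  expect_true(all(res$pe_lower[ok] <= res$percentage_error[ok] + 1e-9))

  # noiseless identical devices: bias 0, LOA (0,0), PE 0
  flat_cfg <- simulation_config(ref_cv = 0, test_bias0 = 0, test_bias1 = 0,
                                test_patient_sd = 0, test_noise_sd = 0,
                                n_patients = 4, measurements_per_patient = 5,
                                seed = 3)
  flat <- simulate_cohort(flat_cfg)
  r0 <- suppressWarnings(analyze_agreement(flat, boot_B = 50, seed = 1))
  expect_equal(r0$bias[1], 0)
  expect_equal(r0$loa_lower[1], 0)
  expect_equal(r0$loa_upper[1], 0)
  expect_equal(r0$percentage_error[1], 0)

  # a phase with < 2 patients is flagged insufficient, not an error
  one_pt <- make_cohort(c("a", "a", "a", "b", "b"), c(0:2, 0:1),
                        ci_ref = c(2, 2.2, 2.1, 3, 2.9),
                        ci_test = c(2.1, 2.4, 2.0, 3.2, 2.8),
                        phase = c("baseline", "other", "other",
                                  "other", "other"))
  r1 <- analyze_agreement(one_pt, phases = "baseline", boot_B = 50, seed = 1)
  expect_true(r1$insufficient[r1$phase == "baseline"])
  expect_true(is.na(r1$bias[r1$phase == "baseline"]))
})

test_that("LOA symmetry holds across randomly generated cohorts", {
  for (s in 1:25) {
    cfg <- simulation_config(
      n_patients = sample(3:10, 1),
      measurements_per_patient = sample(3:12, 1),
      test_bias0 = runif(1, -0.5, 0.5),
      test_bias1 = runif(1, -0.3, 0.3),
      test_noise_sd = runif(1, 0.05, 0.8),
      seed = 9000 + s)
    vc <- variance_components(simulate_cohort(cfg))
    lims <- loa(vc)
    expect_equal(lims[["upper"]] - lims[["lower"]], 2 * 1.96 * vc$sd_total,
                 tolerance = 1e-12)
    expect_gte(vc$sigma2_between, 0)
  }
})
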