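# Builders and independent oracles shared across test files.

make_cohort <- function(patient_id, time_index, ci_ref, ci_test,
                        phase = "other", ...) {
  cohort_dataset(
    data.frame(patient_id = patient_id, time_index = time_index,
               phase = phase, ci_ref = ci_ref, ci_test = ci_test,
               stringsAsFactors = FALSE),
    ...
  )
}

# A contiguous cohort with a prescribed number of measurements per patient
# and fixed pseudo-random but valid CI values.
contiguous_cohort <- function(m_i, seed = 42) {
  set.seed(seed)
  pid <- rep(sprintf("P%02d", seq_along(m_i)), times = m_i)
  tix <- unlist(lapply(m_i, seq_len)) - 1L
  n <- sum(m_i)
  make_cohort(pid, tix,
              ci_ref = exp(rnorm(n, log(2.4), 0.2)),
              ci_test = exp(rnorm(n, log(2.4), 0.2)))
}

# Independent variance-components oracle: one-way ANOVA through stats::lm /
# stats::anova rather than explicit sums.
brute_variance_components <- function(pid, diff) {
  fit <- stats::lm(diff ~ factor(pid))
  an <- stats::anova(fit)
  ms_b <- an["factor(pid)", "Mean Sq"]
  ms_w <- an["Residuals", "Mean Sq"]
  m_i <- table(pid)
  n <- length(diff)
  k <- length(m_i)
  n0 <- (n^2 - sum(m_i^2)) / ((k - 1) * n)
  s2b <- max(0, (ms_b - ms_w) / n0)
  list(bias = mean(diff), ms_between = ms_b, ms_within = ms_w,
       sd_total = sqrt(s2b + ms_w))
}

# Independently written zone classifier following the verbal rule table,
# one pair at a time with explicit branches.
brute_zone <- function(pr, pt) {
  cat_of <- function(p) {
    if (abs(p) < 5) return("none")
    if (abs(p) <= 15) return("moderate")
    "large"
  }
  cr <- cat_of(pr)
  ct <- cat_of(pt)
  if (cr == "none" && ct == "none") return(1L)
  if (cr == "none" || ct == "none") return(3L)
  if ((pr > 0) != (pt > 0)) return(4L)
  if (cr == ct) return(1L)
  2L
}
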