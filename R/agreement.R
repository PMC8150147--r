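#' Paired differences and pairwise means
#'
#' The Bland-Altman construction: for every simultaneous pair, the
#' difference `ci_test - ci_ref` (so a positive value means the test device
#' overestimates) and the pairwise mean `(ci_test + ci_ref) / 2`.
#'
#' @param dataset A non-empty `cohort_dataset`.
#' @return Tibble with columns `patient_id`, `time_index`, `phase`,
#'   `diff`, `pair_mean`.
#' @export
differences <- function(dataset) {
  if (nrow(dataset) == 0) stop("dataset is empty", call. = FALSE)
  tibble::tibble(
    patient_id = dataset$patient_id,
    time_index = dataset$time_index,
    phase = dataset$phase,
    diff = dataset$ci_test - dataset$ci_ref,
    pair_mean = (dataset$ci_test + dataset$ci_ref) / 2
  )
}

as_diff_frame <- function(x) {
  if (inherits(x, "cohort_dataset")) return(differences(x))
  if (!all(c("patient_id", "diff") %in% names(x))) {
    stop("expected a cohort_dataset or a data frame with patient_id and diff",
         call. = FALSE)
  }
  x
}

#' Variance components of paired differences under repeated measurements
#'
#' One-way ANOVA of the differences with patient as the grouping factor,
#' the standard adjustment for Bland-Altman analysis when the true value
#' varies between repeated measurements within a subject. With k patients,
#' m_i differences in patient i and N in total:
#'
#' \itemize{
#'   \item `SS_between = sum_i m_i (dbar_i - dbar)^2` on k - 1 df;
#'   \item `SS_within = sum_ij (d_ij - dbar_i)^2` on N - k df;
#'   \item `n0 = (N^2 - sum m_i^2) / ((k - 1) N)`, the effective
#'     per-patient count for unbalanced designs;
#'   \item `sigma2_within = MS_within`;
#'     `sigma2_between = max(0, (MS_between - MS_within) / n0)` (negative
#'     ANOVA estimates truncate to zero and set the `truncated` flag);
#'   \item `sd_total = sqrt(sigma2_between + sigma2_within)`, the SD that
#'     enters the limits of agreement.
#' }
#'
#' With exactly one measurement per patient the within component has zero
#' df; the decomposition then degenerates to `sigma2_within = 0`, `n0 = 1`,
#' and `sd_total` equals the ordinary sample SD of the differences.
#'
#' @param x A `cohort_dataset` or the tibble from [differences()].
#' @return A `variance_components` object: list with `k`, `n_total`, `m_i`,
#'   `grand_mean_diff`, `ms_between`, `ms_within`, `n0`, `sigma2_between`,
#'   `sigma2_within`, `sd_total`, `truncated`.
#' @export
variance_components <- function(x) {
  d <- as_diff_frame(x)
  pid <- as.character(d$patient_id)
  di <- d$diff
  k <- length(unique(pid))
  n <- length(di)
  if (k < 2) {
    stop("variance components need >= 2 patients (between component ",
         "undefined with k = ", k, ")", call. = FALSE)
  }
  m_i <- tapply(di, pid, length)
  dbar_i <- tapply(di, pid, mean)
  dbar <- mean(di)
  ss_between <- sum(m_i * (dbar_i - dbar)^2)
  ms_between <- ss_between / (k - 1)
  if (all(m_i == 1)) {
    # one measurement per patient: ordinary sample SD of differences
    vc <- list(k = k, n_total = n, m_i = as.integer(m_i),
               grand_mean_diff = dbar,
               ms_between = ms_between, ms_within = NA_real_,
               n0 = 1, sigma2_between = ms_between, sigma2_within = 0,
               sd_total = sqrt(ms_between), truncated = FALSE)
  } else {
    ss_within <- sum((di - dbar_i[pid])^2)
    ms_within <- ss_within / (n - k)
    n0 <- (n^2 - sum(m_i^2)) / ((k - 1) * n)
    s2b_raw <- (ms_between - ms_within) / n0
    vc <- list(k = k, n_total = n, m_i = as.integer(m_i),
               grand_mean_diff = dbar,
               ms_between = ms_between, ms_within = ms_within,
               n0 = n0, sigma2_between = max(0, s2b_raw),
               sigma2_within = ms_within,
               sd_total = sqrt(max(0, s2b_raw) + ms_within),
               truncated = s2b_raw < 0)
  }
  names(vc$m_i) <- names(m_i)
  class(vc) <- "variance_components"
  vc
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "<variance_components> k = %d patients, N = %d differences\n", x$k,
    x$n_total))
  cat(sprintf("  bias (mean diff)  %.4f\n", x$grand_mean_diff))
  cat(sprintf("  sigma2 between    %.5f%s\n", x$sigma2_between,
              if (isTRUE(x$truncated)) "  (truncated at 0)" else ""))
  cat(sprintf("  sigma2 within     %.5f\n", x$sigma2_within))
  cat(sprintf("  sd_total          %.4f\n", x$sd_total))
  invisible(x)
}

#' Limits of agreement
#'
#' `bias -/+ z * sd_total` with the conventional fixed multiplier
#' `z = 1.96` (no small-sample t adjustment, per Bland-Altman convention).
#'
#' @param vc A [variance_components()] object.
#' @param z Coverage multiplier (default 1.96).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
loa <- function(vc, z = 1.96) {
  stopifnot(inherits(vc, "variance_components"))
  c(lower = vc$grand_mean_diff - z * vc$sd_total,
    upper = vc$grand_mean_diff + z * vc$sd_total)
}

# Var(dbar) for clustered differences:
# Var(dbar) = (sigma2_between * sum(m_i^2) + sigma2_within * N) / N^2
var_of_bias <- function(vc) {
  (vc$sigma2_between * sum(as.numeric(vc$m_i)^2) +
     vc$sigma2_within * vc$n_total) / vc$n_total^2
}

#' Confidence interval for the bias
#'
#' `dbar +/- t_{k-1} * sqrt(Var(dbar))` with
#' `Var(dbar) = (sigma2_between * sum(m_i^2) + sigma2_within * N) / N^2`,
#' the variance of the grand mean under the two-component model. The t
#' reference on k - 1 df reflects that patients, not measurements, carry
#' the independent information.
#'
#' @param vc A [variance_components()] object.
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
bias_ci <- function(vc, level = 0.95) {
  stopifnot(inherits(vc, "variance_components"))
  se <- sqrt(var_of_bias(vc))
  tq <- qt((1 + level) / 2, df = vc$k - 1)
  c(lower = vc$grand_mean_diff - tq * se,
    upper = vc$grand_mean_diff + tq * se)
}

# Coefficients and dfs of the linear combination
# sd_total^2-hat = cb * MS_between + cw * MS_within (untruncated form).
vc_combination <- function(vc) {
  if (is.na(vc$ms_within)) {
    list(coef = 1 / vc$n0, ms = vc$ms_between, df = vc$k - 1)
  } else {
    list(coef = c(1 / vc$n0, 1 - 1 / vc$n0),
         ms = c(vc$ms_between, vc$ms_within),
         df = c(vc$k - 1, vc$n_total - vc$k))
  }
}

#' Confidence intervals for the limits of agreement
#'
#' Two constructions for the sampling uncertainty of `bias +/- z * sd_total`
#' under the variance-components model:
#'
#' \describe{
#'   \item{mover}{(default) The method-of-variance-estimates-recovery
#'     construction. The total difference variance is the linear
#'     combination `v = MS_between / n0 + (1 - 1/n0) * MS_within`. Each
#'     mean square gets a chi-square interval on its own df,
#'     `[c MS df / chisq_{(1+level)/2, df}, c MS df / chisq_{(1-level)/2, df}]`,
#'     and the component intervals are combined by squaring and adding the
#'     distances from the point estimate:
#'     `L_v = v - sqrt(sum (c MS - l_comp)^2)`,
#'     `U_v = v + sqrt(sum (u_comp - c MS)^2)`.
#'     The limit interval then squares-and-adds the mean and SD margins,
#'     e.g. for the upper limit `U = dbar + z * s`:
#'     `lower = U - sqrt(q^2 Var(dbar) + z^2 (s - sqrt(L_v))^2)`,
#'     `upper = U + sqrt(q^2 Var(dbar) + z^2 (sqrt(U_v) - s)^2)`,
#'     with `q` the standard-normal `(1+level)/2` quantile; the lower limit
#'     mirrors this.}
#'   \item{delta}{First-order error propagation:
#'     `Var(limit) = Var(dbar) + z^2 Var(s)` with
#'     `Var(s) = Var(v) / (4 s^2)` and
#'     `Var(v) = sum c^2 * 2 MS^2 / df` per component; symmetric normal
#'     interval around each limit.}
#' }
#'
#' @param vc A [variance_components()] object.
#' @param level Confidence level (default 0.95).
#' @param z LOA multiplier (default 1.96).
#' @param method `"mover"` (default) or `"delta"`.
#' @return List with `lower` and `upper`, each a named `c(lower, upper)`
#'   interval, plus `method` and a `degenerate` flag (set with a warning
#'   when `sd_total` is 0 and the intervals collapse).
#' @export
loa_ci <- function(vc, level = 0.95, z = 1.96,
                   method = c("mover", "delta")) {
  stopifnot(inherits(vc, "variance_components"))
  method <- match.arg(method)
  lims <- loa(vc, z)
  if (vc$sd_total == 0) {
    warning("sd_total is 0; LOA confidence intervals are degenerate")
    zero <- c(lower = lims[["lower"]], upper = lims[["lower"]])
    return(list(lower = zero,
                upper = c(lower = lims[["upper"]], upper = lims[["upper"]]),
                method = method, degenerate = TRUE))
  }
  comb <- vc_combination(vc)
  v <- sum(comb$coef * comb$ms)
  s <- vc$sd_total
  vb <- var_of_bias(vc)
  alpha <- 1 - level
  if (method == "mover") {
    term <- comb$coef * comb$ms
    l_comp <- term * comb$df / qchisq(1 - alpha / 2, comb$df)
    u_comp <- term * comb$df / qchisq(alpha / 2, comb$df)
    L_v <- max(0, v - sqrt(sum((term - l_comp)^2)))
    U_v <- v + sqrt(sum((u_comp - term)^2))
    s_lo <- sqrt(L_v)
    s_hi <- sqrt(U_v)
    zq <- qnorm(1 - alpha / 2)
    me_mean2 <- zq^2 * vb
    lower_lim <- lims[["lower"]]
    upper_lim <- lims[["upper"]]
    lower_int <- c(
      lower = lower_lim - sqrt(me_mean2 + z^2 * (s_hi - s)^2),
      upper = lower_lim + sqrt(me_mean2 + z^2 * (s - s_lo)^2)
    )
    upper_int <- c(
      lower = upper_lim - sqrt(me_mean2 + z^2 * (s - s_lo)^2),
      upper = upper_lim + sqrt(me_mean2 + z^2 * (s_hi - s)^2)
    )
  } else {
    var_v <- sum(comb$coef^2 * 2 * comb$ms^2 / comb$df)
    var_s <- var_v / (4 * s^2)
    se_lim <- sqrt(vb + z^2 * var_s)
    zq <- qnorm(1 - alpha / 2)
    lower_int <- c(lower = lims[["lower"]] - zq * se_lim,
                   upper = lims[["lower"]] + zq * se_lim)
    upper_int <- c(lower = lims[["upper"]] - zq * se_lim,
                   upper = lims[["upper"]] + zq * se_lim)
  }
  list(lower = lower_int, upper = upper_int, method = method,
       degenerate = FALSE)
}

pe_denominator_mean <- function(dataset, denominator) {
  dm <- switch(denominator,
               reference = mean(dataset$ci_ref),
               both = mean((dataset$ci_ref + dataset$ci_test) / 2),
               stop("denominator must be 'reference' or 'both'",
                    call. = FALSE))
  if (!is.finite(dm) || dm <= 0) {
    stop("percentage-error denominator mean must be positive", call. = FALSE)
  }
  dm
}

#' Percentage error
#'
#' The Critchley precision metric: `100 * z * sd_total / mean CI`, with
#' `z = 1.96`. Values under 30% are conventionally taken to indicate
#' interchangeability with the reference method. The denominator is the
#' mean of the reference device by default (`"reference"`); `"both"` uses
#' the mean of the pairwise means instead, as some of the literature does.
#' The choice is recorded in the result.
#'
#' @param vc A [variance_components()] object.
#' @param dataset The `cohort_dataset` the components came from (supplies
#'   the denominator mean).
#' @param denominator `"reference"` (default) or `"both"`.
#' @param z Coverage multiplier (default 1.96).
#' @return Numeric percentage with attributes `denominator` and
#'   `denominator_mean`.
#' @export
percentage_error <- function(vc, dataset,
                             denominator = c("reference", "both"),
                             z = 1.96) {
  stopifnot(inherits(vc, "variance_components"))
  denominator <- match.arg(denominator)
  dm <- pe_denominator_mean(dataset, denominator)
  pe <- 100 * z * vc$sd_total / dm
  attr(pe, "denominator") <- denominator
  attr(pe, "denominator_mean") <- dm
  pe
}

#' Cluster-bootstrap confidence interval for the percentage error
#'
#' Resamples patients with replacement `B` times (each draw keeps its own
#' cluster identity, so every replicate has the original number of
#' clusters), recomputes the percentage error per replicate, and returns
#' the percentile interval. Clustered resampling respects the
#' repeated-measures structure of the data.
#'
#' @param dataset A `cohort_dataset` with >= 2 patients.
#' @param level Confidence level (default 0.95).
#' @param B Bootstrap replicates (default 2000).
#' @param seed Optional RNG seed; the same seed gives an identical interval.
#' @param denominator Passed to [percentage_error()].
#' @param z LOA multiplier (default 1.96).
#' @return Named numeric vector `c(lower, upper)` with attribute `B`.
#' @export
percentage_error_ci <- function(dataset, level = 0.95, B = 2000,
                                seed = NULL,
                                denominator = c("reference", "both"),
                                z = 1.96) {
  denominator <- match.arg(denominator)
  ids <- unique(dataset$patient_id)
  k <- length(ids)
  if (k < 2) stop("need >= 2 patients for a cluster bootstrap", call. = FALSE)
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (!is.null(old_seed)) {
        assign(".Random.seed", old_seed, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  by_patient <- split(seq_len(nrow(dataset)), dataset$patient_id)
  pes <- numeric(B)
  for (b in seq_len(B)) {
    draw <- sample(ids, k, replace = TRUE)
    idx <- unlist(by_patient[draw], use.names = FALSE)
    boot <- dataset[idx, , drop = FALSE]
    # relabel so repeated draws of one patient stay distinct clusters
    boot$patient_id <- rep(seq_len(k), times = lengths(by_patient[draw]))
    d <- tibble::tibble(patient_id = boot$patient_id,
                        diff = boot$ci_test - boot$ci_ref)
    vc_b <- variance_components(d)
    dm <- switch(denominator,
                 reference = mean(boot$ci_ref),
                 both = mean((boot$ci_ref + boot$ci_test) / 2))
    pes[b] <- 100 * z * vc_b$sd_total / dm
  }
  alpha <- 1 - level
  out <- quantile(pes, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  out <- c(lower = out[1], upper = out[2])
  attr(out, "B") <- B
  out
}

#' Proportional-bias regression
#'
#' Ordinary least squares of the paired difference on the pairwise mean;
#' a non-zero slope means the disagreement between devices depends on the
#' magnitude of the cardiac index. The slope's confidence interval uses
#' patient-clustered (sandwich) standard errors with a t reference on
#' k - 1 df, since naive OLS standard errors ignore the within-patient
#' correlation. The slope is reported unstandardized with its sign.
#'
#' @param dataset A `cohort_dataset` with >= 3 measurements over >= 2
#'   patients.
#' @param level Confidence level for the slope (default 0.95).
#' @return List with `slope`, `intercept`, `slope_se`, `slope_ci`
#'   (named `c(lower, upper)`), `k`, `n`.
#' @export
proportional_bias <- function(dataset, level = 0.95) {
  d <- differences(dataset)
  k <- length(unique(d$patient_id))
  if (nrow(d) < 3 || k < 2) {
    stop("proportional bias needs >= 3 measurements over >= 2 patients",
         call. = FALSE)
  }
  if (var(d$pair_mean) == 0) {
    stop("pairwise means have zero variance; slope undefined", call. = FALSE)
  }
  fit <- lm(diff ~ pair_mean, data = d)
  vcl <- sandwich::vcovCL(fit, cluster = d$patient_id)
  slope <- unname(coef(fit)[["pair_mean"]])
  se <- sqrt(vcl["pair_mean", "pair_mean"])
  tq <- qt((1 + level) / 2, df = k - 1)
  list(
    slope = slope,
    intercept = unname(coef(fit)[["(Intercept)"]]),
    slope_se = se,
    slope_ci = c(lower = slope - tq * se, upper = slope + tq * se),
    k = k,
    n = nrow(d)
  )
}

agreement_row_na <- function(device, phase, n, k) {
  tibble::tibble(
    device = device, phase = phase, n = n, k = k,
    bias = NA_real_, bias_lower = NA_real_, bias_upper = NA_real_,
    loa_lower = NA_real_, loa_lower_lower = NA_real_,
    loa_lower_upper = NA_real_,
    loa_upper = NA_real_, loa_upper_lower = NA_real_,
    loa_upper_upper = NA_real_,
    percentage_error = NA_real_, pe_lower = NA_real_, pe_upper = NA_real_,
    prop_bias_slope = NA_real_, prop_bias_lower = NA_real_,
    prop_bias_upper = NA_real_,
    between_truncated = NA, insufficient = TRUE
  )
}

#' Full agreement analysis, overall and per phase
#'
#' Runs the whole chain -- differences, variance components, limits of
#' agreement, bias and LOA confidence intervals, percentage error with
#' cluster-bootstrap interval, proportional-bias regression -- on the full
#' dataset and on each requested phase subset. Phases with fewer than 2
#' patients (or fewer than 3 measurements) are flagged `insufficient` and
#' reported with the point counts only.
#'
#' @param dataset A `cohort_dataset`.
#' @param phases Character vector of phase labels to stratify by, or
#'   `"all"` for the pooled analysis only. The pooled `"all"` row is always
#'   included first.
#' @param z LOA multiplier (default 1.96).
#' @param level Confidence level (default 0.95).
#' @param pe_denominator `"reference"` (default) or `"both"`.
#' @param loa_ci_method `"mover"` (default) or `"delta"`.
#' @param boot_B Bootstrap replicates for the percentage-error interval
#'   (default 2000).
#' @param seed Seed for the bootstrap (recorded; default 1).
#' @return An `agreement_result` tibble, one row per phase (plus `"all"`),
#'   with bias, LOA, percentage error and proportional-bias columns and
#'   their confidence bounds.
#' @export
analyze_agreement <- function(dataset, phases = "all", z = 1.96,
                              level = 0.95,
                              pe_denominator = c("reference", "both"),
                              loa_ci_method = c("mover", "delta"),
                              boot_B = 2000, seed = 1L) {
  pe_denominator <- match.arg(pe_denominator)
  loa_ci_method <- match.arg(loa_ci_method)
  validate_cohort(dataset)
  device <- attr(dataset, "device_name")
  want <- if (identical(phases, "all")) character(0) else phases
  subsets <- c(list(all = dataset),
               setNames(lapply(want, filter_phase, dataset = dataset), want))
  rows <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    lab <- names(subsets)[i]
    ds <- subsets[[i]]
    n <- nrow(ds)
    k <- n_patients(ds)
    if (k < 2 || n < 3) {
      rows[[i]] <- agreement_row_na(device, lab, n, k)
      next
    }
    vc <- variance_components(ds)
    lims <- loa(vc, z)
    bci <- bias_ci(vc, level)
    lci <- suppressWarnings(loa_ci(vc, level, z, loa_ci_method))
    pe <- percentage_error(vc, ds, pe_denominator, z)
    pci <- percentage_error_ci(ds, level, boot_B, seed = seed,
                               denominator = pe_denominator, z = z)
    pb <- tryCatch(proportional_bias(ds, level),
                   error = function(e) NULL)
    rows[[i]] <- tibble::tibble(
      device = device, phase = lab, n = n, k = k,
      bias = vc$grand_mean_diff,
      bias_lower = bci[["lower"]], bias_upper = bci[["upper"]],
      loa_lower = lims[["lower"]],
      loa_lower_lower = lci$lower[["lower"]],
      loa_lower_upper = lci$lower[["upper"]],
      loa_upper = lims[["upper"]],
      loa_upper_lower = lci$upper[["lower"]],
      loa_upper_upper = lci$upper[["upper"]],
      percentage_error = as.numeric(pe),
      pe_lower = pci[["lower"]], pe_upper = pci[["upper"]],
      prop_bias_slope = if (is.null(pb)) NA_real_ else pb$slope,
      prop_bias_lower = if (is.null(pb)) NA_real_ else pb$slope_ci[["lower"]],
      prop_bias_upper = if (is.null(pb)) NA_real_ else pb$slope_ci[["upper"]],
      between_truncated = vc$truncated,
      insufficient = FALSE
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "options") <- list(z = z, level = level,
                               pe_denominator = pe_denominator,
                               loa_ci_method = loa_ci_method,
                               boot_B = boot_B, seed = seed,
                               sign_convention = "test_minus_reference")
  class(out) <- c("agreement_result", class(out))
  out
}
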