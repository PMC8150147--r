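#' Equivalence-study sample size for paired differences
#'
#' Number of paired measurements needed to declare two monitors equivalent
#' by the two one-sided tests (TOST) procedure, normal approximation:
#'
#' `N = 2 * (z_{1-alpha} + z_{1-beta/2})^2 * sd_diff^2 / (margin - |true_diff|)^2`
#'
#' `z_{1-beta/2}` (not `z_{1-beta}`) is the TOST power convention: both
#' one-sided tests must reject. N is rounded to the nearest integer; the
#' raw value is also returned together with the formula constants so the
#' calculation is auditable. Repeated measurements are treated as
#' independent -- no design-effect correction for within-patient
#' clustering is applied, which overstates the effective information when
#' measurements are correlated; interpret N accordingly.
#'
#' @param sd_diff SD of the paired differences, L/min/m^2.
#' @param margin Equivalence (non-inferiority) margin, L/min/m^2; must
#'   exceed `|true_diff|`.
#' @param true_diff Assumed true mean difference, L/min/m^2 (default 0).
#' @param alpha One-sided type-I error (default 0.05).
#' @param power Target power `1 - beta` (default 0.9).
#' @return A `sample_size_result` list: `n` (rounded), `n_raw`, `z_alpha`,
#'   `z_beta_half`, and the echoed inputs.
#' @export
equivalence_n <- function(sd_diff, margin, true_diff = 0,
                          alpha = 0.05, power = 0.9) {
  if (sd_diff <= 0) stop("sd_diff must be > 0", call. = FALSE)
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must be in (0, 0.5)",
                                       call. = FALSE)
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)",
                                     call. = FALSE)
  if (margin <= abs(true_diff)) {
    stop("margin must exceed |true_diff| (otherwise N is infinite)",
         call. = FALSE)
  }
  beta <- 1 - power
  z_a <- qnorm(1 - alpha)
  z_b2 <- qnorm(1 - beta / 2)
  n_raw <- 2 * (z_a + z_b2)^2 * sd_diff^2 / (margin - abs(true_diff))^2
  out <- list(
    n = as.integer(round(n_raw)),
    n_raw = n_raw,
    z_alpha = z_a,
    z_beta_half = z_b2,
    inputs = list(sd_diff = sd_diff, margin = margin,
                  true_diff = true_diff, alpha = alpha, power = power),
    method = "tost_equivalence"
  )
  class(out) <- "sample_size_result"
  out
}

#' Sample size for a target precision of the limits of agreement
#'
#' Bland's precision-based calculation: the standard error of a 95% limit
#' of agreement is approximately `sd_diff * sqrt(3 / N)`, so achieving a
#' 95% confidence-interval half-width `h` for a limit requires
#'
#' `N = 3 * (z * sd_diff / h)^2`
#'
#' rounded to the nearest integer (with `z = 1.96` the CI half-width of a
#' limit is `1.96 * SE`, and the formula above absorbs both 1.96 factors).
#'
#' @param sd_diff SD of the paired differences, L/min/m^2.
#' @param ci_halfwidth Desired half-width of the 95% CI of one limit of
#'   agreement, L/min/m^2.
#' @param z Coverage multiplier (default 1.96).
#' @return A `sample_size_result` list: `n`, `n_raw`, echoed inputs.
#' @export
loa_precision_n <- function(sd_diff, ci_halfwidth, z = 1.96) {
  if (sd_diff <= 0) stop("sd_diff must be > 0", call. = FALSE)
  if (ci_halfwidth <= 0) stop("ci_halfwidth must be > 0", call. = FALSE)
  n_raw <- 3 * (z * sd_diff / ci_halfwidth)^2
  out <- list(
    n = as.integer(round(n_raw)),
    n_raw = n_raw,
    inputs = list(sd_diff = sd_diff, ci_halfwidth = ci_halfwidth, z = z),
    method = "loa_precision"
  )
  class(out) <- "sample_size_result"
  out
}

#' @export
print.sample_size_result <- function(x, ...) {
  cat(sprintf("<sample_size_result> %s: N = %d (raw %.2f)\n",
              x$method, x$n, x$n_raw))
  inp <- x$inputs
  cat("  inputs:", paste(sprintf("%s = %g", names(inp), unlist(inp)),
                         collapse = ", "), "\n")
  invisible(x)
}
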