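#' Consecutive-change (delta) pairs
#'
#' For every pair of consecutive measurements within a patient, the percent
#' change of each device relative to its own earlier reading,
#' `100 * (CI_t - CI_{t-1}) / CI_{t-1}`, together with the absolute changes
#' in L/min/m^2. Pairs never span two patients, so a contiguous series of
#' N measurements over k patients yields exactly N - k pairs. Each pair is
#' labelled with the phase of its endpoint, which is how per-phase trending
#' subsets are formed.
#'
#' @param dataset A `cohort_dataset`.
#' @return Tibble with columns `patient_id`, `from_time`, `to_time`,
#'   `phase` (of the endpoint), `pct_ref`, `pct_test`, `abs_ref`,
#'   `abs_test`.
#' @export
delta_pairs <- function(dataset) {
  validate_cohort(dataset)
  rows <- lapply(split(seq_len(nrow(dataset)), dataset$patient_id),
                 function(idx) {
    if (length(idx) < 2) return(NULL)
    a <- idx[-length(idx)]
    b <- idx[-1]
    tibble::tibble(
      patient_id = dataset$patient_id[b],
      from_time = dataset$time_index[a],
      to_time = dataset$time_index[b],
      phase = dataset$phase[b],
      pct_ref = 100 * (dataset$ci_ref[b] - dataset$ci_ref[a]) /
        dataset$ci_ref[a],
      pct_test = 100 * (dataset$ci_test[b] - dataset$ci_test[a]) /
        dataset$ci_test[a],
      abs_ref = dataset$ci_ref[b] - dataset$ci_ref[a],
      abs_test = dataset$ci_test[b] - dataset$ci_test[a]
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(patient_id = character(), from_time = integer(),
                          to_time = integer(), phase = character(),
                          pct_ref = numeric(), pct_test = numeric(),
                          abs_ref = numeric(), abs_test = numeric())
  }
  out
}

#' Magnitude category of a percent change
#'
#' Bins a percent change into `"none"` (|pct| < 5), `"moderate"`
#' (5 <= |pct| <= 15, boundaries inclusive) or `"large"` (|pct| > 15).
#' A sub-5% change is treated as no change for zone classification.
#'
#' @param pct Numeric vector of percent changes.
#' @return Character vector of categories.
#' @export
magnitude_category <- function(pct) {
  stopifnot(all(is.finite(pct)))
  a <- abs(pct)
  ifelse(a < 5, "none", ifelse(a <= 15, "moderate", "large"))
}

#' Error-grid zone of a delta pair
#'
#' Classifies a pair of consecutive percent changes into the four
#' clinical-concordance zones:
#' \describe{
#'   \item{Zone 1}{both devices changed in the same direction to the same
#'     extent -- both under 5%, or both in the same magnitude bin with the
#'     same sign. Treatment decisions agree.}
#'   \item{Zone 2}{same direction but different magnitude bins:
#'     insufficient or exaggerated treatment.}
#'   \item{Zone 3}{exactly one device registered a change (the other moved
#'     under 5%): unnecessary treatment started or necessary treatment
#'     withheld.}
#'   \item{Zone 4}{opposite directions, both at 5% or more: opposite
#'     treatment.}
#' }
#'
#' @param pct_ref,pct_test Percent changes of the reference and test
#'   device (vectorized).
#' @return Integer vector of zones in 1..4.
#' @export
classify_zone <- function(pct_ref, pct_test) {
  cr <- magnitude_category(pct_ref)
  ct <- magnitude_category(pct_test)
  both_none <- cr == "none" & ct == "none"
  one_none <- (cr == "none") != (ct == "none")
  same_sign <- sign(pct_ref) == sign(pct_test)
  out <- integer(length(cr))
  out[both_none] <- 1L
  out[one_none] <- 3L
  both <- !both_none & !one_none
  out[both & !same_sign] <- 4L
  out[both & same_sign & cr == ct] <- 1L
  out[both & same_sign & cr != ct] <- 2L
  out
}

#' Error-grid analysis of consecutive changes
#'
#' Classifies every delta pair with [classify_zone()] and tabulates counts
#' and percentages per zone. Results based on fewer than `min_n` pairs are
#' flagged `reported = FALSE` (percentages from a handful of changes are
#' not clinically interpretable), mirroring the usual practice of not
#' reporting error grids for sparsely measured phases.
#'
#' @param deltas Tibble from [delta_pairs()] (>= 1 row).
#' @param min_n Minimum pair count for a reportable grid (default 30).
#' @return An `error_grid_result` list: `n_deltas`, `zone_counts`,
#'   `zone_percentages` (named "1".."4"), `reported`, `reason`.
#' @export
error_grid <- function(deltas, min_n = 30) {
  if (nrow(deltas) == 0) stop("no delta pairs to classify", call. = FALSE)
  zones <- classify_zone(deltas$pct_ref, deltas$pct_test)
  counts <- vapply(1:4, function(z) sum(zones == z), integer(1))
  names(counts) <- as.character(1:4)
  out <- list(
    n_deltas = length(zones),
    zone_counts = counts,
    zone_percentages = 100 * counts / length(zones),
    reported = length(zones) >= min_n,
    reason = if (length(zones) >= min_n) NA_character_ else {
      sprintf("n below error-grid minimum (%d < %d)", length(zones), min_n)
    }
  )
  class(out) <- "error_grid_result"
  out
}

#' @export
print.error_grid_result <- function(x, ...) {
  cat(sprintf("<error_grid_result> %d delta pairs%s\n", x$n_deltas,
              if (!x$reported) paste0("  [not reported: ", x$reason, "]")
              else ""))
  for (z in 1:4) {
    cat(sprintf("  zone %s: %3d  (%.1f%%)\n", names(x$zone_counts)[z],
                x$zone_counts[z], x$zone_percentages[z]))
  }
  invisible(x)
}

#' Four-quadrant trending concordance
#'
#' Excludes pairs in which both devices' changes fall below the exclusion
#' threshold -- small changes carry no directional information -- and
#' reports the percentage of retained pairs in which the two devices moved
#' in the same direction (a zero change is concordant only with a zero
#' change). In `"percent"` mode the threshold applies to |percent change|;
#' in `"absolute"` mode to |change| in L/min/m^2.
#'
#' @param deltas Tibble from [delta_pairs()] (>= 1 row).
#' @param exclusion Exclusion-zone threshold (default 10, i.e. 10% in
#'   percent mode).
#' @param mode `"percent"` (default) or `"absolute"`.
#' @return A `four_quadrant_result` list: `n_deltas`, `n_excluded`,
#'   `n_retained`, `concordance_rate` (% or `NA` if nothing retained),
#'   `exclusion`, `mode`, `all_excluded` flag.
#' @export
four_quadrant <- function(deltas, exclusion = 10,
                          mode = c("percent", "absolute")) {
  mode <- match.arg(mode)
  if (nrow(deltas) == 0) stop("no delta pairs", call. = FALSE)
  if (mode == "percent") {
    excl <- abs(deltas$pct_ref) < exclusion & abs(deltas$pct_test) < exclusion
  } else {
    excl <- abs(deltas$abs_ref) < exclusion & abs(deltas$abs_test) < exclusion
  }
  kept <- deltas[!excl, , drop = FALSE]
  conc <- if (nrow(kept) > 0) {
    100 * mean(sign(kept$pct_ref) == sign(kept$pct_test))
  } else NA_real_
  out <- list(
    n_deltas = nrow(deltas),
    n_excluded = sum(excl),
    n_retained = nrow(kept),
    concordance_rate = conc,
    exclusion = exclusion,
    mode = mode,
    all_excluded = nrow(kept) == 0
  )
  class(out) <- "four_quadrant_result"
  out
}

#' @export
print.four_quadrant_result <- function(x, ...) {
  cat(sprintf(
    "<four_quadrant_result> %d pairs, %d excluded (%s %.3g)\n",
    x$n_deltas, x$n_excluded, x$mode, x$exclusion))
  if (is.na(x$concordance_rate)) {
    cat("  concordance: undefined (all pairs excluded)\n")
  } else {
    cat(sprintf("  concordance: %.1f%% of %d retained pairs\n",
                x$concordance_rate, x$n_retained))
  }
  invisible(x)
}
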