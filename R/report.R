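#' Per-device, per-phase study report
#'
#' Orchestrates the full method-comparison analysis in the layout standard
#' for monitor validation studies: one agreement row and one trending block
#' (error grid + four-quadrant concordance) for the pooled data and for
#' each clinical phase. Error grids for phases with too few delta pairs are
#' suppressed with an explicit reason code. A provenance block records the
#' options, seed and package version; every stochastic step consumes the
#' explicit seed.
#'
#' @param dataset A `cohort_dataset`.
#' @param phases Phase labels to stratify by (default: the four named
#'   OPCAB phases).
#' @param z LOA multiplier (default 1.96).
#' @param level Confidence level (default 0.95).
#' @param pe_denominator `"reference"` (default) or `"both"`.
#' @param loa_ci_method `"mover"` (default) or `"delta"`.
#' @param boot_B Bootstrap replicates for percentage-error CIs
#'   (default 2000).
#' @param exclusion Four-quadrant exclusion threshold (default 10).
#' @param exclusion_mode `"percent"` (default) or `"absolute"`.
#' @param grid_min_n Minimum delta count for a reportable error grid
#'   (default 30).
#' @param seed Seed for all stochastic steps (default 1).
#' @return A `study_report` list: `agreement` (tibble from
#'   [analyze_agreement()]), `trending` (per-stratum list with `n_deltas`,
#'   `error_grid`, `four_quadrant`), `provenance`.
#' @export
run_study_report <- function(dataset,
                             phases = setdiff(ci_phases(), "other"),
                             z = 1.96, level = 0.95,
                             pe_denominator = c("reference", "both"),
                             loa_ci_method = c("mover", "delta"),
                             boot_B = 2000,
                             exclusion = 10,
                             exclusion_mode = c("percent", "absolute"),
                             grid_min_n = 30,
                             seed = 1L) {
  pe_denominator <- match.arg(pe_denominator)
  loa_ci_method <- match.arg(loa_ci_method)
  exclusion_mode <- match.arg(exclusion_mode)
  validate_cohort(dataset)

  agreement <- analyze_agreement(dataset, phases = phases, z = z,
                                 level = level,
                                 pe_denominator = pe_denominator,
                                 loa_ci_method = loa_ci_method,
                                 boot_B = boot_B, seed = seed)
  all_deltas <- delta_pairs(dataset)
  strata <- c("all", phases)
  trending <- lapply(strata, function(ph) {
    dd <- if (ph == "all") all_deltas else {
      all_deltas[all_deltas$phase == ph, , drop = FALSE]
    }
    if (nrow(dd) == 0) {
      return(list(phase = ph, n_deltas = 0L, error_grid = NULL,
                  four_quadrant = NULL,
                  reason = "no delta pairs in stratum"))
    }
    list(
      phase = ph,
      n_deltas = nrow(dd),
      error_grid = error_grid(dd, min_n = grid_min_n),
      four_quadrant = four_quadrant(dd, exclusion = exclusion,
                                    mode = exclusion_mode),
      reason = NA_character_
    )
  })
  names(trending) <- strata

  out <- list(
    agreement = agreement,
    trending = trending,
    provenance = list(
      device = attr(dataset, "device_name"),
      reference = attr(dataset, "reference_name"),
      n_measurements = nrow(dataset),
      n_patients = n_patients(dataset),
      options = list(z = z, level = level,
                     pe_denominator = pe_denominator,
                     loa_ci_method = loa_ci_method, boot_B = boot_B,
                     exclusion = exclusion,
                     exclusion_mode = exclusion_mode,
                     grid_min_n = grid_min_n, seed = seed,
                     sign_convention = "test_minus_reference"),
      package_version = as.character(utils::packageVersion("cicompare"))
    )
  )
  class(out) <- "study_report"
  out
}

#' @export
print.study_report <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("<study_report> %s vs %s: %d measurements, %d patients\n",
              p$device, p$reference, p$n_measurements, p$n_patients))
  ag <- x$agreement
  for (i in seq_len(nrow(ag))) {
    r <- ag[i, ]
    if (isTRUE(r$insufficient)) {
      cat(sprintf("  %-20s n=%3d  insufficient data\n", r$phase, r$n))
    } else {
      cat(sprintf(
        "  %-20s n=%3d  bias %+.2f (%+.2f to %+.2f)  LOA %+.2f to %+.2f  PE %.1f%%\n",
        r$phase, r$n, r$bias, r$bias_lower, r$bias_upper,
        r$loa_lower, r$loa_upper, r$percentage_error))
    }
  }
  invisible(x)
}

#' Write a study report as JSON
#'
#' JSON is the canonical serialization of the report: the agreement table,
#' per-stratum trending blocks (suppressed error-grid percentages replaced
#' by a reason code), and the provenance block. Given the same data and
#' seed, output is byte-identical across runs when `timestamp = FALSE`.
#'
#' @param report A `study_report`.
#' @param path Output path.
#' @param timestamp Include a generation timestamp (default `TRUE`; set
#'   `FALSE` for byte-reproducible output).
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path, timestamp = TRUE) {
  stopifnot(inherits(report, "study_report"))
  trend <- lapply(report$trending, function(tb) {
    eg <- tb$error_grid
    list(
      phase = tb$phase,
      n_deltas = tb$n_deltas,
      error_grid = if (is.null(eg)) {
        list(reported = FALSE, reason = tb$reason)
      } else if (!eg$reported) {
        list(reported = FALSE, reason = eg$reason, n_deltas = eg$n_deltas)
      } else {
        list(reported = TRUE, n_deltas = eg$n_deltas,
             zone_counts = as.list(eg$zone_counts),
             zone_percentages = as.list(eg$zone_percentages))
      },
      four_quadrant = if (is.null(tb$four_quadrant)) NULL else {
        unclass(tb$four_quadrant)
      }
    )
  })
  obj <- list(
    agreement = report$agreement,
    trending = trend,
    provenance = report$provenance
  )
  if (timestamp) obj$provenance$generated_at <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Write the flattened report table as CSV
#'
#' A convenience view shaped like the per-phase tables of monitor
#' validation papers: one row per stratum with bias, LOA, percentage
#' error, regression coefficient (each with CI bounds), error-grid zone
#' percentages (empty where suppressed) and four-quadrant concordance.
#' Numeric values are written at full precision and survive re-reading at
#' 12+ significant digits.
#'
#' @param report A `study_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  stopifnot(inherits(report, "study_report"))
  ag <- as.data.frame(report$agreement)
  tr <- report$trending
  zones <- t(vapply(ag$phase, function(ph) {
    tb <- tr[[ph]]
    if (is.null(tb) || is.null(tb$error_grid) || !tb$error_grid$reported) {
      rep(NA_real_, 4)
    } else {
      unname(tb$error_grid$zone_percentages)
    }
  }, numeric(4)))
  colnames(zones) <- paste0("zone", 1:4, "_pct")
  conc <- vapply(ag$phase, function(ph) {
    tb <- tr[[ph]]
    if (is.null(tb) || is.null(tb$four_quadrant)) NA_real_
    else tb$four_quadrant$concordance_rate
  }, numeric(1))
  grid_note <- vapply(ag$phase, function(ph) {
    tb <- tr[[ph]]
    if (is.null(tb)) return("no delta pairs")
    if (is.null(tb$error_grid)) return(tb$reason)
    if (!tb$error_grid$reported) return(tb$error_grid$reason)
    ""
  }, character(1))
  out <- cbind(ag, zones,
               concordance_pct = conc,
               error_grid_note = grid_note)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
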