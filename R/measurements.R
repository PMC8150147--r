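#' Default clinical phase labels
#'
#' The four analysis phases of an OPCAB (off-pump coronary bypass) monitoring
#' series -- pre-induction baseline, aortic side-clamping during proximal
#' anastomoses, distal coronary anastomoses, and the ICU period before
#' extubation -- plus `"other"` for measurements outside any named phase.
#'
#' @return Character vector of known phase labels.
#' @export
ci_phases <- function() {
  c("baseline", "aortic_side_clamp", "distal_anastomoses",
    "icu_pre_extubation", "other")
}

#' Construct a paired cardiac-index cohort dataset
#'
#' A cohort dataset is a tibble of simultaneous paired cardiac index (CI)
#' measurements, one row per timepoint, with columns `patient_id`,
#' `time_index`, `phase`, `ci_ref` (reference device, L/min/m^2) and
#' `ci_test` (test device, L/min/m^2). Rows are sorted by patient and time.
#'
#' @param measurements Data frame with the five columns above.
#' @param device_name Label of the test device.
#' @param reference_name Label of the reference method.
#' @param phase_levels Character vector of permitted phase labels.
#'
#' @return A `cohort_dataset` (a tibble subclass).
#' @export
cohort_dataset <- function(measurements,
                           device_name = "test_device",
                           reference_name = "thermodilution",
                           phase_levels = ci_phases()) {
  req <- c("patient_id", "time_index", "phase", "ci_ref", "ci_test")
  missing_cols <- setdiff(req, names(measurements))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  m <- tibble::as_tibble(measurements[req])
  m$patient_id <- as.character(m$patient_id)
  m$time_index <- as.integer(m$time_index)
  m$phase <- as.character(m$phase)
  m$ci_ref <- as.numeric(m$ci_ref)
  m$ci_test <- as.numeric(m$ci_test)
  m <- m[order(m$patient_id, m$time_index), , drop = FALSE]
  out <- tibble::new_tibble(
    m,
    device_name = device_name,
    reference_name = reference_name,
    phase_levels = phase_levels,
    class = "cohort_dataset"
  )
  validate_cohort(out)
  out
}

#' Validate a cohort dataset's invariants
#'
#' Checks positivity of both CI series, uniqueness of `time_index` within
#' patient, non-negative integer time indices, and known phase labels.
#' Errors cite the offending row numbers (in patient/time sort order).
#'
#' @param x A `cohort_dataset`.
#' @return `x`, invisibly, if valid.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "cohort_dataset"))
  if (nrow(x) > 0) {
    bad_ci <- which(!is.finite(x$ci_ref) | !is.finite(x$ci_test) |
                      x$ci_ref <= 0 | x$ci_test <= 0)
    if (length(bad_ci) > 0) {
      stop("non-positive or non-finite CI value at row(s): ",
           paste(head(bad_ci, 5), collapse = ", "), call. = FALSE)
    }
    if (anyNA(x$time_index) || any(x$time_index < 0)) {
      bad <- which(is.na(x$time_index) | x$time_index < 0)
      stop("negative or missing time_index at row(s): ",
           paste(head(bad, 5), collapse = ", "), call. = FALSE)
    }
    dup <- duplicated(x[c("patient_id", "time_index")])
    if (any(dup)) {
      stop("duplicate (patient_id, time_index) at row(s): ",
           paste(head(which(dup), 5), collapse = ", "), call. = FALSE)
    }
    lv <- attr(x, "phase_levels")
    unknown <- setdiff(unique(x$phase), lv)
    if (length(unknown) > 0) {
      stop("unknown phase label(s): ", paste(unknown, collapse = ", "),
           "; known labels: ", paste(lv, collapse = ", "), call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %s vs %s: %d measurements, %d patient(s)\n",
              attr(x, "device_name"), attr(x, "reference_name"),
              nrow(x), n_patients(x)))
  NextMethod()
}

#' Number of patients in a cohort dataset
#' @param dataset A `cohort_dataset`.
#' @return Integer count of distinct patients.
#' @export
n_patients <- function(dataset) length(unique(dataset$patient_id))

#' Read a paired cardiac-index cohort from CSV
#'
#' Reads a UTF-8, comma-separated file with a header row. Column names can
#' be remapped through `schema`, a named character vector from canonical
#' name (`patient_id`, `time_index`, `phase`, `ci_ref`, `ci_test`) to the
#' column name present in the file. A missing `phase` column defaults every
#' row to `"other"`. Real-valued time stamps are accepted and converted to
#' within-patient ranks, since only ordering matters downstream.
#'
#' @param path Path to the CSV file.
#' @param schema Optional named character vector remapping columns.
#' @inheritParams cohort_dataset
#' @return A validated `cohort_dataset`.
#' @export
read_cohort <- function(path, schema = NULL,
                        device_name = "test_device",
                        reference_name = "thermodilution",
                        phase_levels = ci_phases()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8", check.names = FALSE)
  canon <- c("patient_id", "time_index", "phase", "ci_ref", "ci_test")
  colmap <- setNames(canon, canon)
  if (!is.null(schema)) {
    bad <- setdiff(names(schema), canon)
    if (length(bad) > 0) {
      stop("schema keys must be among: ", paste(canon, collapse = ", "),
           call. = FALSE)
    }
    colmap[names(schema)] <- unname(schema)
  }
  need <- setdiff(canon, "phase")
  for (k in need) {
    if (!colmap[[k]] %in% names(raw)) {
      stop("column '", colmap[[k]], "' (for ", k, ") not found in ", path,
           call. = FALSE)
    }
  }
  df <- data.frame(
    patient_id = as.character(raw[[colmap[["patient_id"]]]]),
    time_index = raw[[colmap[["time_index"]]]],
    phase = if (colmap[["phase"]] %in% names(raw)) {
      as.character(raw[[colmap[["phase"]]]])
    } else {
      rep("other", nrow(raw))
    },
    ci_ref = as.numeric(raw[[colmap[["ci_ref"]]]]),
    ci_test = as.numeric(raw[[colmap[["ci_test"]]]]),
    stringsAsFactors = FALSE
  )
  tt <- suppressWarnings(as.numeric(df$time_index))
  if (anyNA(tt)) stop("time_index column is not numeric", call. = FALSE)
  if (any(tt != round(tt))) {
    # real clock times: map to within-patient ranks
    df$time_index <- as.integer(
      stats::ave(tt, df$patient_id, FUN = function(v) rank(v, ties.method = "first") - 1)
    )
  } else {
    df$time_index <- as.integer(tt)
  }
  cohort_dataset(df, device_name = device_name,
                 reference_name = reference_name,
                 phase_levels = phase_levels)
}

#' Write a cohort dataset to CSV
#'
#' One row per measurement, header row included, full double precision
#' (values survive a round trip through [read_cohort()] exactly).
#'
#' @param dataset A `cohort_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(dataset, path) {
  validate_cohort(dataset)
  df <- as.data.frame(dataset)
  # format numerics at full precision so the round trip is exact
  df$ci_ref <- vapply(df$ci_ref, function(v) format(v, digits = 17), "")
  df$ci_test <- vapply(df$ci_test, function(v) format(v, digits = 17), "")
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Subset a cohort to one clinical phase
#'
#' Keeps only measurements labelled with `phase`; patients with no matching
#' rows are dropped and per-patient time ordering is preserved. Filtering on
#' a known phase absent from the data returns an empty dataset.
#'
#' @param dataset A `cohort_dataset`.
#' @param phase A single known phase label.
#' @return A `cohort_dataset` containing the matching measurements.
#' @export
filter_phase <- function(dataset, phase) {
  lv <- attr(dataset, "phase_levels")
  if (length(phase) != 1 || !phase %in% lv) {
    stop("unknown phase '", paste(phase, collapse = ","),
         "'; known labels: ", paste(lv, collapse = ", "), call. = FALSE)
  }
  keep <- dataset$phase == phase
  out <- dataset[keep, , drop = FALSE]
  tibble::new_tibble(
    out,
    device_name = attr(dataset, "device_name"),
    reference_name = attr(dataset, "reference_name"),
    phase_levels = lv,
    class = "cohort_dataset"
  )
}

#' Convert long-format device readings to a paired cohort
#'
#' Convenience converter for exports with one row per (patient, time,
#' device) reading. Rows for the reference and one test device are matched
#' on (patient, time); unmatched timepoints are dropped.
#'
#' @param long_df Data frame with columns `patient_id`, `time_index`,
#'   `device`, `ci`, and optionally `phase`.
#' @param device Value of the `device` column identifying the test device.
#' @param reference Value identifying the reference method.
#' @inheritParams cohort_dataset
#' @return A `cohort_dataset`.
#' @export
widen_cohort <- function(long_df, device, reference,
                         phase_levels = ci_phases()) {
  req <- c("patient_id", "time_index", "device", "ci")
  if (!all(req %in% names(long_df))) {
    stop("long format requires columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (!"phase" %in% names(long_df)) long_df$phase <- "other"
  ref <- long_df[long_df$device == reference,
                 c("patient_id", "time_index", "phase", "ci")]
  tst <- long_df[long_df$device == device, c("patient_id", "time_index", "ci")]
  names(ref)[names(ref) == "ci"] <- "ci_ref"
  names(tst)[names(tst) == "ci"] <- "ci_test"
  wide <- merge(ref, tst, by = c("patient_id", "time_index"))
  cohort_dataset(wide, device_name = as.character(device),
                 reference_name = as.character(reference),
                 phase_levels = phase_levels)
}
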