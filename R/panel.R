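# Person-visit panel data model: construction, validation, CSV I/O,
# LOCF imputation and baseline uric-acid quintile stratification.

# Visit-level columns that are not labs. Everything else in `visits`
# is treated as a time-varying lab.
VISIT_FIXED_COLS <- c("patient_id", "visit", "treatment",
                      "event_death", "event_cvd", "censored")

# Baseline demographic columns recognised on read; columns prefixed
# "baseline_" (lab values at entry) or "cm_" (comorbidity flags) are
# also routed to the baseline table.
BASELINE_DEMOG_COLS <- c("age", "sex_male", "bmi", "diabetes",
                         "hd_vintage", "baseline_treatment")

#' Construct a cohort panel
#'
#' A cohort panel is the single currency of the workflow: a baseline table
#' (one row per patient: demographics, entry treatment status, entry lab
#' values, optional comorbidity flags) plus a long person-visit table
#' (one row per patient per monthly visit: treatment indicator, time-varying
#' labs, death/CVD/censoring indicators). Follow-up rows stop at the first
#' death or censoring; a first cardiovascular event is recorded but does not
#' terminate follow-up.
#'
#' @param baseline data.frame with one row per patient; must contain
#'   `patient_id` with unique values.
#' @param visits data.frame with columns `patient_id`, `visit`, `treatment`,
#'   `event_death`, `event_cvd`, `censored` plus any number of lab columns.
#' @param n_visits maximum visit index of the study design (defaults to the
#'   largest observed visit).
#' @param validate run invariant checks (disable only for trusted callers).
#' @return an object of class `cohort_panel` with elements `baseline`,
#'   `visits` (sorted by patient and visit) and `n_visits`.
#' @export
cohort_panel <- function(baseline, visits, n_visits = NULL, validate = TRUE) {
  baseline <- as.data.frame(baseline, stringsAsFactors = FALSE)
  visits <- as.data.frame(visits, stringsAsFactors = FALSE)
  miss <- setdiff(VISIT_FIXED_COLS, names(visits))
  if (length(miss)) {
    stop("visits table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"patient_id" %in% names(baseline)) {
    stop("baseline table is missing required column: patient_id", call. = FALSE)
  }
  baseline <- baseline[order(baseline$patient_id), , drop = FALSE]
  visits <- visits[order(visits$patient_id, visits$visit), , drop = FALSE]
  rownames(baseline) <- NULL
  rownames(visits) <- NULL
  if (is.null(n_visits)) {
    n_visits <- if (nrow(visits)) max(visits$visit) else 0L
  }
  panel <- structure(
    list(baseline = baseline, visits = visits, n_visits = as.integer(n_visits)),
    class = "cohort_panel"
  )
  if (validate) validate_panel(panel)
  panel
}

#' Names of the time-varying lab columns of a panel
#' @param panel a `cohort_panel`.
#' @return character vector of lab column names.
#' @export
panel_labs <- function(panel) {
  setdiff(names(panel$visits), VISIT_FIXED_COLS)
}

#' Number of patients in a panel
#' @param panel a `cohort_panel`.
#' @export
n_patients <- function(panel) nrow(panel$baseline)

#' Validate cohort panel invariants
#'
#' Checks: unique patient ids; every visit row's patient present at baseline;
#' per-patient visit indices consecutive from 1; binary treatment and event
#' indicators; death and censoring never flagged on the same row; positive
#' age/BMI/baseline uric acid where those columns exist.
#'
#' @param panel a `cohort_panel`.
#' @return invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_panel <- function(panel) {
  b <- panel$baseline
  v <- panel$visits
  if (anyDuplicated(b$patient_id)) {
    stop("duplicate patient_id in baseline table: ",
         paste(unique(b$patient_id[duplicated(b$patient_id)])[1:3],
               collapse = ", "), call. = FALSE)
  }
  if (nrow(v)) {
    orphan <- setdiff(unique(v$patient_id), b$patient_id)
    if (length(orphan)) {
      stop("visit rows reference patients absent from baseline: ",
           paste(utils::head(orphan, 3), collapse = ", "), call. = FALSE)
    }
    # visits must be 1, 2, ... within patient (rows already sorted)
    newp <- !duplicated(v$patient_id)
    idx <- seq_len(nrow(v))
    start_idx <- idx[newp][cumsum(newp)]
    pos <- idx - start_idx + 1L
    bad <- v$visit != pos
    if (any(bad)) {
      stop("non-consecutive visit indices for patient ",
           v$patient_id[which(bad)[1]], call. = FALSE)
    }
    for (col in c("treatment", "event_death", "event_cvd", "censored")) {
      x <- v[[col]]
      if (anyNA(x) || !all(x %in% c(0, 1))) {
        stop("column '", col, "' must be binary 0/1", call. = FALSE)
      }
    }
    both <- v$event_death == 1 & v$censored == 1
    if (any(both)) {
      stop("event_death and censored both set for patient ",
           v$patient_id[which(both)[1]], call. = FALSE)
    }
  }
  for (col in c("age", "bmi", "baseline_ua")) {
    if (col %in% names(b) && any(!is.na(b[[col]]) & b[[col]] <= 0)) {
      stop("baseline column '", col, "' must be strictly positive",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.cohort_panel <- function(x, ...) {
  cat("<cohort_panel> ", nrow(x$baseline), " patients, ",
      nrow(x$visits), " person-visits (design: ", x$n_visits,
      " monthly visits)\n", sep = "")
  cat("  labs: ", paste(panel_labs(x), collapse = ", "), "\n", sep = "")
  cat("  deaths: ", sum(x$visits$event_death),
      "; first CVD events: ", sum(x$visits$event_cvd),
      "; censored: ", sum(x$visits$censored), "\n", sep = "")
  invisible(x)
}

#' Read a cohort panel from a long-format CSV
#'
#' One row per person-visit; baseline covariates repeated on every row;
#' missing lab values encoded as empty fields. Column names can be remapped
#' through `schema`, a named character vector `c(canonical = "file_column")`.
#'
#' @param path CSV file path.
#' @param schema optional named character vector renaming file columns to the
#'   canonical names used by the package.
#' @param quiet suppress the row/patient count message.
#' @return a validated `cohort_panel`.
#' @export
read_panel <- function(path, schema = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (canonical in names(schema)) {
      j <- match(schema[[canonical]], names(df))
      if (is.na(j)) {
        stop("schema maps '", canonical, "' to missing file column '",
             schema[[canonical]], "'", call. = FALSE)
      }
      names(df)[j] <- canonical
    }
  }
  miss <- setdiff(VISIT_FIXED_COLS, names(df))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bl_cols <- names(df)[names(df) %in% BASELINE_DEMOG_COLS |
                         startsWith(names(df), "baseline_") |
                         startsWith(names(df), "cm_")]
  lab_cols <- setdiff(names(df), c(VISIT_FIXED_COLS, bl_cols))
  df <- df[order(df$patient_id, df$visit), , drop = FALSE]
  baseline <- df[!duplicated(df$patient_id),
                 c("patient_id", bl_cols), drop = FALSE]
  visits <- df[, c(VISIT_FIXED_COLS, lab_cols), drop = FALSE]
  panel <- cohort_panel(baseline, visits)
  if (!quiet) {
    message("read_panel: ", nrow(visits), " person-visit rows, ",
            nrow(baseline), " patients from ", path)
  }
  panel
}

#' Write a cohort panel to a long-format CSV
#'
#' Inverse of [read_panel()]: baseline covariates are repeated on each
#' person-visit row, missing lab values become empty fields. Column and row
#' order are deterministic, so rewriting the same panel yields a byte-identical
#' file.
#'
#' @param panel a `cohort_panel`.
#' @param path output CSV path.
#' @export
write_panel <- function(panel, path) {
  b <- panel$baseline
  v <- panel$visits
  bl_cols <- setdiff(names(b), "patient_id")
  if (nrow(v)) {
    merged <- cbind(
      v[, "patient_id", drop = FALSE],
      b[match(v$patient_id, b$patient_id), bl_cols, drop = FALSE],
      v[, setdiff(names(v), "patient_id"), drop = FALSE]
    )
  } else {
    merged <- cbind(
      b[integer(0), c("patient_id", bl_cols), drop = FALSE],
      v[integer(0), setdiff(names(v), "patient_id"), drop = FALSE]
    )
  }
  rownames(merged) <- NULL
  utils::write.csv(merged, path, row.names = FALSE, na = "")
  invisible(path)
}

# Forward fill within groups; `start_idx[i]` is the row index where the
# group of row i begins. Leading NAs are left in place.
.fill_forward <- function(x, start_idx) {
  idx <- seq_along(x)
  obs <- ifelse(!is.na(x), idx, 0L)
  last <- cummax(obs)
  ok <- last >= start_idx
  out <- x
  out[!ok] <- NA
  out[ok] <- x[last[ok]]
  out
}

#' Last-observation-carried-forward imputation of time-varying labs
#'
#' Replaces every missing lab value by the most recent prior observed value
#' for that patient; leading missing values are back-filled from the first
#' observed value. Patients for whom a requested lab is never observed are
#' dropped from the panel and reported.
#'
#' Idempotent: applying it twice equals applying it once.
#'
#' @param panel a `cohort_panel`.
#' @param lab_names labs to impute (default: all lab columns).
#' @param quiet suppress the drop report.
#' @return a `cohort_panel` with no missing values in the named labs.
#' @export
locf_impute <- function(panel, lab_names = panel_labs(panel), quiet = FALSE) {
  absent <- setdiff(lab_names, panel_labs(panel))
  if (length(absent)) {
    stop("lab(s) not present in panel: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  v <- panel$visits
  if (!nrow(v)) return(panel)
  newp <- !duplicated(v$patient_id)
  grp <- cumsum(newp)
  # patients with a lab never observed are dropped before filling
  drop_ids <- character(0)
  for (lab in lab_names) {
    n_obs <- rowsum(as.integer(!is.na(v[[lab]])), grp)
    never <- which(n_obs[, 1] == 0L)
    if (length(never)) {
      drop_ids <- union(drop_ids, as.character(v$patient_id[newp][never]))
    }
  }
  if (length(drop_ids)) {
    if (!quiet) {
      message("locf_impute: dropping ", length(drop_ids),
              " patient(s) with a lab never observed: ",
              paste(utils::head(drop_ids, 5), collapse = ", "),
              if (length(drop_ids) > 5) ", ..." else "")
    }
    keep <- !(as.character(v$patient_id) %in% drop_ids)
    v <- v[keep, , drop = FALSE]
    panel$baseline <-
      panel$baseline[!(as.character(panel$baseline$patient_id) %in% drop_ids), ,
                     drop = FALSE]
    rownames(panel$baseline) <- NULL
    newp <- !duplicated(v$patient_id)
  }
  idx <- seq_len(nrow(v))
  grp <- cumsum(newp)
  starts <- idx[newp]
  ends <- c(starts[-1] - 1L, nrow(v))
  start_idx <- starts[grp]
  end_idx <- ends[grp]
  for (lab in lab_names) {
    x <- .fill_forward(v[[lab]], start_idx)
    # back-fill leading gaps: forward fill on the reversed series
    xr <- rev(.fill_forward(rev(x), rev(length(x) - end_idx + 1L)))
    v[[lab]] <- xr
  }
  rownames(v) <- NULL
  panel$visits <- v
  panel
}

#' Assign baseline uric-acid quintiles
#'
#' Patients are ranked by baseline serum uric acid and split into five groups
#' of (near-)equal size; quintile 1 holds the lowest values. Patients with
#' tied uric-acid values at a group boundary are all assigned to the lower
#' quintile, so the assignment is deterministic and invariant to any strictly
#' monotone transform of the uric-acid scale.
#'
#' @param panel a `cohort_panel` whose baseline table has `baseline_ua`.
#' @return integer vector of quintile indices (1-5) named by patient id,
#'   in baseline-table order.
#' @export
assign_ua_quintiles <- function(panel) {
  b <- panel$baseline
  if (!"baseline_ua" %in% names(b)) {
    stop("baseline table has no 'baseline_ua' column", call. = FALSE)
  }
  ua <- b$baseline_ua
  if (anyNA(ua)) stop("baseline_ua missing for some patients", call. = FALSE)
  n <- length(ua)
  if (n < 5) stop("need at least 5 patients to form quintiles", call. = FALSE)
  ord <- order(ua, seq_len(n))
  q <- integer(n)
  q[ord] <- ceiling(5 * seq_len(n) / n)
  # tied values share the lowest quintile any of them received
  q <- as.integer(stats::ave(q, ua, FUN = min))
  stats::setNames(q, as.character(b$patient_id))
}
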