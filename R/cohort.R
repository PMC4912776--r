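#' Validate a cohort data frame
#'
#' A cohort is a data frame with one row per serum sample and columns
#' `patient_id` (identifier), `time_h` (hours since trauma, `>= 0`) and
#' `s100b_ugL` (concentration in \eqn{\mu}g/L, `>= 0`). Rows are sorted by
#' patient and time; duplicate (patient, time) pairs are rejected.
#'
#' @param cohort A data frame in the cohort sample format.
#' @return The validated cohort, sorted by `patient_id` then `time_h`.
#' @export
as_cohort <- function(cohort) {
  if (!is.data.frame(cohort)) stop("`cohort` must be a data.frame")
  need <- c("patient_id", "time_h", "s100b_ugL")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "))
  }
  cohort <- as.data.frame(cohort)[need]
  cohort$patient_id <- as.character(cohort$patient_id)
  for (col in c("time_h", "s100b_ugL")) {
    v <- cohort[[col]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0)) {
      stop("column `", col, "` must be finite, numeric and non-negative")
    }
  }
  key <- paste(cohort$patient_id, cohort$time_h)
  if (anyDuplicated(key)) {
    stop("duplicate (patient_id, time_h) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  cohort <- cohort[order(cohort$patient_id, cohort$time_h), , drop = FALSE]
  rownames(cohort) <- NULL
  cohort
}

# Split a cohort into a named list of per-patient series (data frames with
# time_h, s100b_ugL), preserving first-appearance order of patients.
split_cohort <- function(cohort) {
  cohort <- as_cohort(cohort)
  ids <- unique(cohort$patient_id)
  out <- lapply(ids, function(id) {
    s <- cohort[cohort$patient_id == id, , drop = FALSE]
    rownames(s) <- NULL
    s
  })
  names(out) <- ids
  out
}

#' Read a cohort from delimited text
#'
#' Reads comma-separated sample data with header
#' `patient_id,time_h,s100b_ugL`. Lines starting with `#` are ignored
#' (run-stamp comments written by [run_pipeline()]). Rows are validated
#' (numeric, finite, non-negative; no duplicate patient-time pairs) and
#' returned sorted by patient and time; malformed rows are reported with
#' their line number in the file.
#'
#' @param path Path to the CSV file.
#' @return A validated cohort data frame (see [as_cohort()]).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) stop("file has no data: ", path)
  header <- strsplit(trimws(lines[idx[1]]), ",")[[1]]
  need <- c("patient_id", "time_h", "s100b_ugL")
  if (!all(need %in% trimws(header))) {
    stop("header must contain columns patient_id, time_h, s100b_ugL ",
         "(line ", idx[1], ")")
  }
  cols <- match(need, trimws(header))
  rows <- idx[-1]
  if (!length(rows)) stop("file has a header but no sample rows: ", path)
  parts <- strsplit(lines[rows], ",")
  pid <- character(length(rows))
  tim <- con <- numeric(length(rows))
  for (k in seq_along(rows)) {
    p <- trimws(parts[[k]])
    if (length(p) < length(header)) {
      stop("malformed row at line ", rows[k], ": expected ",
           length(header), " fields, found ", length(p))
    }
    pid[k] <- p[cols[1]]
    tv <- suppressWarnings(as.numeric(p[cols[2]]))
    cv <- suppressWarnings(as.numeric(p[cols[3]]))
    if (is.na(tv) || !is.finite(tv) || tv < 0) {
      stop("malformed row at line ", rows[k],
           ": time_h must be a non-negative number, got '", p[cols[2]], "'")
    }
    if (is.na(cv) || !is.finite(cv) || cv < 0) {
      stop("malformed row at line ", rows[k],
           ": s100b_ugL must be a non-negative number, got '", p[cols[3]], "'")
    }
    tim[k] <- tv
    con[k] <- cv
  }
  key <- paste(pid, tim)
  if (anyDuplicated(key)) {
    first_dup <- which(duplicated(key))[1]
    stop("duplicate sample for patient '", pid[first_dup], "' at time ",
         tim[first_dup], " h (line ", rows[first_dup], ")")
  }
  as_cohort(data.frame(patient_id = pid, time_h = tim, s100b_ugL = con,
                       stringsAsFactors = FALSE))
}

#' Write a cohort to delimited text
#'
#' Writes the cohort sample format read by [read_cohort()]. An optional
#' stamp (e.g. seed and configuration hash) is written as a `#` comment
#' line before the header.
#'
#' @param cohort A cohort data frame.
#' @param path Output file path.
#' @param stamp Optional character scalar written as a leading comment.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, stamp = NULL) {
  cohort <- as_cohort(cohort)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(stamp)) writeLines(paste0("# ", stamp), con)
  writeLines("patient_id,time_h,s100b_ugL", con)
  writeLines(sprintf("%s,%s,%s", cohort$patient_id,
                     format(cohort$time_h, digits = 15, trim = TRUE),
                     format(cohort$s100b_ugL, digits = 15, trim = TRUE)), con)
  invisible(path)
}
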