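# CSV interchange in the MIMIC-shaped three-table layout:
#   inputevents.csv  patient_id,itemid,starttime,endtime,rate,totalamount
#   vitals.csv       patient_id,charttime,channel,value
#   labels.csv       patient_id,hospital_expire_flag
# Cells are RFC-4180, UTF-8, header row; an empty cell is a missing value.
# Numerics are written with enough digits to round-trip exactly.

EVENT_COLS <- c("patient_id", "itemid", "starttime", "endtime", "rate",
                "totalamount")
VITAL_COLS <- c("patient_id", "charttime", "channel", "value")
LABEL_COLS <- c("patient_id", "hospital_expire_flag")

write_csv_exact <- function(df, path, quote_cols = character(0)) {
  if (nrow(df) == 0) {
    writeLines(paste(names(df), collapse = ","), path)
    return(invisible(path))
  }
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !nm %in% c("patient_id", "hospital_expire_flag")) {
      out[[nm]] <- format_num(out[[nm]])
    } else if (nm %in% quote_cols) {
      out[[nm]] <- paste0('"', gsub('"', '""', out[[nm]]), '"')
    }
    out[[nm]][is.na(df[[nm]])] <- ""
  }
  lines <- c(paste(names(out), collapse = ","),
             if (nrow(out)) do.call(paste, c(unname(out), sep = ",")))
  writeLines(lines, path)
}

#' Write a cohort to the three-table CSV layout
#'
#' @param cohort an `icu_cohort`.
#' @param directory output directory (created if absent).
#' @param imputed_flags if `TRUE` and the cohort has been through
#'   [impute_cohort()], an extra boolean `imputed` column is written for the
#'   event-level channels.
#' @return `directory`, invisibly.
#' @seealso [read_cohort_tables()], [validate_input_tables()]
#' @export
write_cohort_tables <- function(cohort, directory, imputed_flags = FALSE) {
  stopifnot(inherits(cohort, "icu_cohort"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  ev_list <- list(); vt_list <- list(); lb_list <- list()
  for (p in cohort$patients) {
    if (nrow(p$events)) {
      ev <- data.frame(patient_id = p$patient_id, p$events[, EVENT_COLS[-1]],
                       stringsAsFactors = FALSE)
      if (imputed_flags) {
        ev$rate_imputed <- p$events$rate_imputed %||% rep(FALSE, nrow(ev))
        ev$totalamount_imputed <- p$events$totalamount_imputed %||%
          rep(FALSE, nrow(ev))
      }
      ev_list[[length(ev_list) + 1L]] <- ev
    }
    for (ch in names(p$vitals)) {
      v <- p$vitals[[ch]]
      if (nrow(v)) {
        vt_list[[length(vt_list) + 1L]] <- data.frame(
          patient_id = p$patient_id, charttime = v$time, channel = ch,
          value = v$value, stringsAsFactors = FALSE)
      }
    }
    lb_list[[length(lb_list) + 1L]] <- data.frame(
      patient_id = p$patient_id, hospital_expire_flag = p$label)
  }
  empty_ev <- stats::setNames(
    data.frame(integer(0), character(0), numeric(0), numeric(0), numeric(0),
               numeric(0)), EVENT_COLS)
  empty_vt <- stats::setNames(
    data.frame(integer(0), numeric(0), character(0), numeric(0)), VITAL_COLS)
  empty_lb <- stats::setNames(data.frame(integer(0), integer(0)), LABEL_COLS)
  write_csv_exact(if (length(ev_list)) do.call(rbind, ev_list) else empty_ev,
                  file.path(directory, "inputevents.csv"),
                  quote_cols = "itemid")
  write_csv_exact(if (length(vt_list)) do.call(rbind, vt_list) else empty_vt,
                  file.path(directory, "vitals.csv"), quote_cols = "channel")
  write_csv_exact(if (length(lb_list)) do.call(rbind, lb_list) else empty_lb,
                  file.path(directory, "labels.csv"))
  invisible(directory)
}

parse_num <- function(x, file, col, report) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & is.na(out))
  for (b in bad) report(file, b + 1L, sprintf("column '%s' is not numeric: '%s'",
                                              col, x[b]))
  out[x == ""] <- NA_real_
  out
}

read_table_checked <- function(directory, file, cols, report) {
  path <- file.path(directory, file)
  if (!file.exists(path)) {
    report(file, NA_integer_, "required table absent")
    return(NULL)
  }
  df <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = FALSE),
    error = function(e) {
      report(file, NA_integer_, paste("unreadable:", conditionMessage(e)))
      NULL
    })
  if (is.null(df)) return(NULL)
  extra_ok <- c("rate_imputed", "totalamount_imputed", "imputed")
  unknown <- setdiff(names(df), c(cols, extra_ok))
  missing <- setdiff(cols, names(df))
  for (u in unknown) report(file, 1L, sprintf("unknown column '%s'", u))
  for (m in missing) report(file, 1L, sprintf("missing column '%s'", m))
  if (length(missing)) return(NULL)
  df
}

# Shared scanner behind read_cohort_tables() and validate_input_tables().
scan_tables <- function(directory) {
  violations <- data.frame(file = character(0), line = integer(0),
                           message = character(0), stringsAsFactors = FALSE)
  report <- function(file, line, message) {
    violations[nrow(violations) + 1L, ] <<- list(file, line, message)
  }
  if (!dir.exists(directory)) {
    report("(directory)", NA_integer_, sprintf("no such directory: %s", directory))
    return(list(violations = violations))
  }
  ev <- read_table_checked(directory, "inputevents.csv", EVENT_COLS, report)
  vt <- read_table_checked(directory, "vitals.csv", VITAL_COLS, report)
  lb <- read_table_checked(directory, "labels.csv", LABEL_COLS, report)
  if (!is.null(ev)) {
    for (col in c("starttime", "endtime", "rate", "totalamount")) {
      ev[[col]] <- parse_num(ev[[col]], "inputevents.csv", col, report)
    }
    bad <- which(is.finite(ev$starttime) & is.finite(ev$endtime) &
                   ev$endtime < ev$starttime)
    for (b in bad) report("inputevents.csv", b + 1L,
                          sprintf("endtime (%g) < starttime (%g)",
                                  ev$endtime[b], ev$starttime[b]))
    empty_t <- which(is.na(ev$starttime) | is.na(ev$endtime))
    for (b in empty_t) report("inputevents.csv", b + 1L,
                              "starttime/endtime must be present")
  }
  if (!is.null(vt)) {
    vt$charttime <- parse_num(vt$charttime, "vitals.csv", "charttime", report)
    vt$value <- parse_num(vt$value, "vitals.csv", "value", report)
    for (b in which(is.na(vt$charttime))) {
      report("vitals.csv", b + 1L, "charttime must be present")
    }
  }
  if (!is.null(lb)) {
    lb$hospital_expire_flag <- parse_num(lb$hospital_expire_flag, "labels.csv",
                                         "hospital_expire_flag", report)
    bad <- which(!(lb$hospital_expire_flag %in% c(0, 1)))
    for (b in bad) report("labels.csv", b + 1L,
                          "hospital_expire_flag must be 0 or 1")
    dup <- which(duplicated(lb$patient_id))
    for (b in dup) report("labels.csv", b + 1L, "duplicate patient_id")
  }
  list(violations = violations, events = ev, vitals = vt, labels = lb)
}

#' Read a cohort back from the three-table CSV layout
#'
#' Inverse of [write_cohort_tables()]: `read_cohort_tables(write_cohort_tables(x))`
#' reproduces `x`'s patients exactly, including missing-value sentinels.
#' Any schema violation (unknown/missing columns, non-numeric cells,
#' `endtime < starttime`, labels outside `{0, 1}`) aborts with the offending
#' file and line number.
#'
#' @param directory directory holding `inputevents.csv`, `vitals.csv`,
#'   `labels.csv`.
#' @return an `icu_cohort` (without ground truth).
#' @export
read_cohort_tables <- function(directory) {
  sc <- scan_tables(directory)
  if (nrow(sc$violations)) {
    v <- sc$violations[1, ]
    stopf("invalid input tables (%d problem%s), first: %s line %s: %s",
          nrow(sc$violations), if (nrow(sc$violations) > 1) "s" else "",
          v$file, ifelse(is.na(v$line), "?", v$line), v$message)
  }
  lb <- sc$labels; ev <- sc$events; vt <- sc$vitals
  ids <- lb$patient_id
  int_ids <- !anyNA(suppressWarnings(as.integer(ids))) && length(ids) > 0
  patients <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    e <- ev[ev$patient_id == id, , drop = FALSE]
    events <- data.frame(itemid = e$itemid, starttime = e$starttime,
                         endtime = e$endtime, rate = e$rate,
                         totalamount = e$totalamount, stringsAsFactors = FALSE)
    events <- events[order(events$starttime), , drop = FALSE]
    rownames(events) <- NULL
    v <- vt[vt$patient_id == id, , drop = FALSE]
    channels <- unique(v$channel)
    channels <- c(intersect(VITALS_CHANNELS, channels),
                  sort(setdiff(channels, VITALS_CHANNELS)))
    vitals <- list()
    for (ch in channels) {
      s <- v[v$channel == ch, , drop = FALSE]
      s <- s[order(s$charttime), , drop = FALSE]
      vitals[[ch]] <- data.frame(time = s$charttime, value = s$value)
      rownames(vitals[[ch]]) <- NULL
    }
    patients[[i]] <- list(
      patient_id = if (int_ids) as.integer(id) else id,
      events = events, vitals = vitals,
      label = as.integer(lb$hospital_expire_flag[i]))
  }
  ord <- order(if (int_ids) as.integer(ids) else ids)
  structure(list(patients = patients[ord], config = NULL, ground_truth = NULL),
            class = "icu_cohort")
}

#' Validate input tables against the expected schema
#'
#' Non-throwing counterpart of [read_cohort_tables()]: scans the directory and
#' returns every schema violation found (machine-readable), instead of
#' stopping at the first.
#'
#' @param directory directory to check.
#' @return data.frame with columns `file`, `line`, `message`; zero rows means
#'   the tables are clean. Attribute `clean` carries the same fact as a flag.
#' @export
validate_input_tables <- function(directory) {
  v <- scan_tables(directory)$violations
  attr(v, "clean") <- nrow(v) == 0L
  v
}
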