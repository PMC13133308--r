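# Typed data model and delimited-file I/O for the pipeline.
#
# A cohort bundle is a list of five data frames with documented schemas:
#   stays   stay_id, subject_id, icu_in, icu_out, death_time
#   events  stay_id, time, kind, value          (kind: pao2_mmHg,
#           fio2_fraction, peep_cmH2O, vent_flag)
#   reports stay_id, time, text
#   icd     stay_id, code, version              (version: 9 or 10)
#   labels  stay_id, label                      (ARDS, POSSIBLE,
#           NON_ARDS_AHRF)
# Files are UTF-8 comma-delimited with quoted free text; timestamps are
# ISO-8601 at minute resolution.

.EVENT_KINDS <- c("pao2_mmHg", "fio2_fraction", "peep_cmH2O", "vent_flag")
.LABELS3 <- c("ARDS", "POSSIBLE", "NON_ARDS_AHRF")

.SCHEMAS <- list(
  stays   = c("stay_id", "subject_id", "icu_in", "icu_out", "death_time"),
  events  = c("stay_id", "time", "kind", "value"),
  reports = c("stay_id", "time", "text"),
  icd     = c("stay_id", "code", "version"),
  labels  = c("stay_id", "label")
)

#' Normalise FiO2 to a fraction
#'
#' EHR extracts record FiO2 either as a fraction (0.21--1) or as a percent
#' (21--100). Values in (1, 100] are interpreted as percent and divided by
#' 100; values in (0, 1] pass through; values > 100 or <= 0 become `NA`
#' (rejected upstream). The transform is idempotent: a value already on the
#' fraction scale is never divided again.
#'
#' @param x numeric vector of recorded FiO2 values.
#' @return numeric vector of fractions in (0, 1], `NA` where invalid.
#' @export
#' @examples
#' normalize_fio2(c(0.5, 50, 100, 1))  # 0.5 0.5 1 1
normalize_fio2 <- function(x) {
  x <- as.numeric(x)
  out <- ifelse(!is.na(x) & x > 1 & x <= 100, x / 100, x)
  out[!is.na(out) & (out <= 0 | out > 1)] <- NA_real_
  out
}

#' Canonicalise ICD codes
#'
#' Codes are stored dot-free and uppercased (`J80`, `51882`) so that set
#' membership tests are unambiguous across coding dialects.
#'
#' @param code character vector of ICD-9/10 codes.
#' @return character vector of canonical codes.
#' @export
canonicalize_icd <- function(code) {
  gsub(".", "", toupper(trimws(as.character(code))), fixed = TRUE)
}

.check_columns <- function(df, table) {
  need <- .SCHEMAS[[table]]
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stopf("schema error in '%s': missing required column(s): %s",
          table, paste(missing, collapse = ", "))
  }
  df[need]
}

# Validate one table; returns list(data = kept rows, rejected = diagnostics).
.validate_table <- function(df, table) {
  df <- .check_columns(df, table)
  n <- nrow(df)
  reasons <- character(n)
  flag <- function(bad, why) {
    bad <- which(bad & !nzchar(reasons))
    reasons[bad] <<- why
  }
  df$stay_id <- as.character(df$stay_id)
  flag(is.na(df$stay_id) | !nzchar(df$stay_id), "empty stay_id")

  if (table == "stays") {
    df$subject_id <- as.character(df$subject_id)
    df$icu_in <- parse_timestamp(df$icu_in)
    df$icu_out <- parse_timestamp(df$icu_out)
    df$death_time <- parse_timestamp(df$death_time)
    flag(is.na(df$icu_in) | is.na(df$icu_out), "unparseable icu_in/icu_out")
    flag(!is.na(df$icu_in) & !is.na(df$icu_out) & df$icu_in >= df$icu_out,
         "icu_in not before icu_out")
    flag(!is.na(df$death_time) & !is.na(df$icu_in) & df$death_time < df$icu_in,
         "death_time before icu_in")
    flag(duplicated(df$stay_id), "duplicate stay_id")
  } else if (table == "events") {
    df$time <- parse_timestamp(df$time)
    df$value <- suppressWarnings(as.numeric(df$value))
    flag(is.na(df$time), "unparseable time")
    flag(!(df$kind %in% .EVENT_KINDS),
         paste("kind not one of", paste(.EVENT_KINDS, collapse = "/")))
    flag(is.na(df$value), "non-numeric value")
    raw_fio2 <- df$kind == "fio2_fraction"
    df$value[raw_fio2] <- normalize_fio2(df$value[raw_fio2])
    flag(raw_fio2 & is.na(df$value), "FiO2 outside (0, 100]")
    flag(df$kind == "pao2_mmHg" & !is.na(df$value) & df$value <= 0,
         "PaO2 must be positive")
    flag(df$kind == "peep_cmH2O" & !is.na(df$value) & df$value < 0,
         "PEEP must be non-negative")
    flag(df$kind == "vent_flag" & !is.na(df$value) & !(df$value %in% c(0, 1)),
         "vent_flag must be 0 or 1")
  } else if (table == "reports") {
    df$time <- parse_timestamp(df$time)
    df$text <- as.character(df$text)
    flag(is.na(df$time), "unparseable time")
    flag(is.na(df$text) | !nzchar(trimws(df$text)), "empty report text")
  } else if (table == "icd") {
    df$code <- canonicalize_icd(df$code)
    df$version <- suppressWarnings(as.integer(df$version))
    flag(is.na(df$code) | !nzchar(df$code), "empty code")
    flag(!(df$version %in% c(9L, 10L)), "version must be 9 or 10")
  } else if (table == "labels") {
    df$label <- toupper(trimws(as.character(df$label)))
    flag(!(df$label %in% .LABELS3),
         paste("label not one of", paste(.LABELS3, collapse = "/")))
    flag(duplicated(df$stay_id), "duplicate label for stay")
  }

  bad <- nzchar(reasons)
  rejected <- data.frame(table = rep(table, sum(bad)), row = which(bad),
                         reason = reasons[bad], stringsAsFactors = FALSE)
  list(data = df[!bad, , drop = FALSE], rejected = rejected)
}

.empty_table <- function(table) {
  proto <- list(
    stays = data.frame(stay_id = character(), subject_id = character(),
                       icu_in = parse_timestamp(character()),
                       icu_out = parse_timestamp(character()),
                       death_time = parse_timestamp(character()),
                       stringsAsFactors = FALSE),
    events = data.frame(stay_id = character(),
                        time = parse_timestamp(character()),
                        kind = character(), value = numeric(),
                        stringsAsFactors = FALSE),
    reports = data.frame(stay_id = character(),
                         time = parse_timestamp(character()),
                         text = character(), stringsAsFactors = FALSE),
    icd = data.frame(stay_id = character(), code = character(),
                     version = integer(), stringsAsFactors = FALSE),
    labels = data.frame(stay_id = character(), label = character(),
                        stringsAsFactors = FALSE)
  )
  proto[[table]]
}

#' Assemble and validate a cohort bundle from in-memory tables
#'
#' Runs row-level validation (units, enums, timestamp parsing, invariants)
#' and referential-integrity checks, and returns an `ards_cohort` object.
#' Rows failing validation are dropped with a warning and recorded in
#' `attr(bundle, "rejected")`; a `stay_id` in any satellite table that does
#' not resolve to `stays` is an error.
#'
#' @param stays,events,reports,icd,labels data frames per the documented
#'   schemas; satellite tables may be `NULL` (treated as empty).
#' @return an object of class `ards_cohort`: a named list of the five
#'   validated tables.
#' @seealso [read_cohort()], [write_outputs()]
#' @export
as_cohort <- function(stays, events = NULL, reports = NULL, icd = NULL,
                      labels = NULL) {
  raw <- list(stays = stays, events = events, reports = reports,
              icd = icd, labels = labels)
  out <- list()
  rejected <- list()
  for (tab in names(.SCHEMAS)) {
    if (is.null(raw[[tab]]) || nrow(raw[[tab]]) == 0) {
      out[[tab]] <- .empty_table(tab)
      next
    }
    v <- .validate_table(as.data.frame(raw[[tab]]), tab)
    out[[tab]] <- v$data
    rejected[[tab]] <- v$rejected
  }
  rejected <- do.call(rbind, rejected)
  if (!is.null(rejected) && nrow(rejected)) {
    warning(sprintf("%d row(s) rejected during validation; see attr(x, 'rejected')",
                    nrow(rejected)), call. = FALSE)
  } else {
    rejected <- data.frame(table = character(), row = integer(),
                           reason = character(), stringsAsFactors = FALSE)
  }
  known <- out$stays$stay_id
  for (tab in c("events", "reports", "icd", "labels")) {
    orphan <- setdiff(unique(out[[tab]]$stay_id), known)
    if (length(orphan)) {
      stopf("referential error: %s references unknown stay_id(s): %s",
            tab, paste(utils::head(orphan, 10), collapse = ", "))
    }
  }
  structure(out, rejected = rejected, class = "ards_cohort")
}

#' @export
print.ards_cohort <- function(x, ...) {
  cat("<ards_cohort>\n")
  cat(sprintf("  stays:   %6d (%d subjects)\n", nrow(x$stays),
              length(unique(x$stays$subject_id))))
  cat(sprintf("  events:  %6d\n", nrow(x$events)))
  cat(sprintf("  reports: %6d\n", nrow(x$reports)))
  cat(sprintf("  icd:     %6d\n", nrow(x$icd)))
  cat(sprintf("  labels:  %6d\n", nrow(x$labels)))
  invisible(x)
}

#' Read a cohort bundle from delimited files
#'
#' Reads `stays.csv`, `events.csv`, `reports.csv`, `icd.csv` and
#' `labels.csv` (satellites optional) from a directory, or from explicitly
#' named paths, validates them and resolves cross-references. FiO2 values
#' recorded as percent are normalised to fractions; ICD codes are
#' canonicalised.
#'
#' @param path directory containing the CSV files, or a named list/vector
#'   with elements `stays`, `events`, `reports`, `icd`, `labels` giving
#'   file paths.
#' @return an `ards_cohort` (see [as_cohort()]).
#' @export
read_cohort <- function(path) {
  if (is.character(path) && length(path) == 1 && is.null(names(path))) {
    if (!dir.exists(path)) stopf("directory not found: %s", path)
    paths <- file.path(path, paste0(names(.SCHEMAS), ".csv"))
    names(paths) <- names(.SCHEMAS)
  } else {
    paths <- unlist(path)
  }
  if (!("stays" %in% names(paths)) || !file.exists(paths[["stays"]])) {
    stopf("stays file is required and was not found")
  }
  read1 <- function(tab) {
    p <- paths[tab]
    if (is.na(p) || !file.exists(p)) return(NULL)
    utils::read.csv(p, stringsAsFactors = FALSE, colClasses = "character",
                    encoding = "UTF-8")
  }
  as_cohort(stays = read1("stays"), events = read1("events"),
            reports = read1("reports"), icd = read1("icd"),
            labels = read1("labels"))
}

# Serialise one in-memory table to its file representation.
.table_for_output <- function(df) {
  for (col in names(df)) {
    if (inherits(df[[col]], "POSIXct")) df[[col]] <- format_timestamp(df[[col]])
  }
  df
}

#' Write a cohort bundle and result tables to a directory
#'
#' Writes the five bundle CSVs plus, when supplied, `screen_results.csv`,
#' `enrich_flags.csv` and `metrics.json`. Re-reading the written bundle with
#' [read_cohort()] reproduces the in-memory tables (timestamps at minute
#' resolution).
#'
#' @param bundle an `ards_cohort`, or `NULL` to write results only.
#' @param path output directory (created if absent).
#' @param screen_results,enrich_flags optional result data frames.
#' @param metrics optional named list of metrics, serialised as JSON.
#' @return invisibly, the paths written.
#' @export
write_outputs <- function(bundle = NULL, path, screen_results = NULL,
                          enrich_flags = NULL, metrics = NULL) {
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(path)) stopf("cannot create output directory: %s", path)
  }
  written <- character()
  wr <- function(df, file) {
    p <- file.path(path, file)
    utils::write.csv(.table_for_output(df), p, row.names = FALSE, na = "")
    written <<- c(written, p)
  }
  if (!is.null(bundle)) {
    stopifnot(inherits(bundle, "ards_cohort"))
    for (tab in names(.SCHEMAS)) wr(bundle[[tab]], paste0(tab, ".csv"))
  }
  if (!is.null(screen_results)) wr(screen_results, "screen_results.csv")
  if (!is.null(enrich_flags)) wr(enrich_flags, "enrich_flags.csv")
  if (!is.null(metrics)) {
    p <- file.path(path, "metrics.json")
    jsonlite::write_json(metrics, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    written <- c(written, p)
  }
  invisible(written)
}
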