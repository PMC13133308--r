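# Persistence screening. A stay's qualifying episode is the FIRST unbroken
# run of consecutive qualifying 24-h windows; persistence classes:
#   H24  run of >= 1 window
#   H48  run of >= 2 windows
#   H72  run of >= 3 windows, OR a run of >= 2 windows with death on day 3
#        of the episode (death in [onset + 48 h, onset + 72 h))
#   ANYTIME_ONLY  no qualifying window, but at least one single paired
#        measurement met the criteria at some point during the stay
# Subjects dying within 48 h of onset are flagged excluded_early_death.

.PERSIST_LEVELS <- c("ANYTIME_ONLY", "H24", "H48", "H72")

#' Find the first qualifying episode for one stay
#'
#' Scans the ordered 24-h windows and returns the earliest run of
#' consecutive qualifying windows (a broken run restarts the count; later,
#' possibly longer runs are ignored — the first episode is retained).
#'
#' @param windows window table for one stay ([build_day_windows()]),
#'   ordered by `index`.
#' @param anytime_hit logical: did any single paired measurement meet the
#'   criteria (the any-time screen)? Defaults to `NA` (unknown).
#' @return list with `onset` (POSIXct), `onset_index`, `n_consecutive` and
#'   `anytime_hit`, or `NULL` when no window qualifies (the `anytime_hit`
#'   flag is then attached as an attribute of the `NULL` via the caller).
#' @export
find_first_episode <- function(windows, anytime_hit = NA) {
  if (nrow(windows) == 0 || !any(windows$qualifies)) return(NULL)
  windows <- windows[order(windows$index), , drop = FALSE]
  r <- rle(windows$qualifies)
  first <- which(r$values)[1]
  start_pos <- if (first == 1) 1L else sum(r$lengths[seq_len(first - 1)]) + 1L
  list(onset = windows$win_start[start_pos],
       onset_index = windows$index[start_pos],
       n_consecutive = as.integer(r$lengths[first]),
       anytime_hit = anytime_hit)
}

#' Classify the persistence of an episode
#'
#' Applies the persistence rules to a stay's first episode: `H72` requires
#' three consecutive qualifying windows, or two with death on day 3 of the
#' episode (death time in `[onset + 48, onset + 72)` hours, half-open so the
#' variant is disjoint from qualification by survival). Stays with death
#' before `onset + 48 h` are flagged `excluded_early_death`. The stratum for
#' the missed-case analysis is `h48_72plus` for `H72`, `h24_48` for a
#' two-window run, `h0_24` otherwise.
#'
#' @param episode result of [find_first_episode()] (may be `NULL`).
#' @param stay single-row data frame with `death_time`.
#' @param anytime_hit logical any-time screen flag for the stay.
#' @return list with `persistence_class` (`NA` when the stay never screens
#'   positive), `stratum`, `excluded_early_death`, `death_within_48_72h`.
#' @export
classify_persistence <- function(episode, stay, anytime_hit = NA) {
  if (is.null(episode)) {
    cls <- if (isTRUE(anytime_hit)) "ANYTIME_ONLY" else NA_character_
    return(list(persistence_class = cls,
                stratum = if (is.na(cls)) NA_character_ else "h0_24",
                excluded_early_death = FALSE, death_within_48_72h = FALSE))
  }
  n <- episode$n_consecutive
  drel <- if (is.na(stay$death_time[1])) NA_real_ else
    hours_between(episode$onset, stay$death_time[1])
  death_day3 <- !is.na(drel) && drel >= 48 && drel < 72
  cls <- if (n >= 3 || (n >= 2 && death_day3)) "H72"
         else if (n >= 2) "H48" else "H24"
  stratum <- switch(cls, H72 = "h48_72plus", H48 = "h24_48", H24 = "h0_24")
  list(persistence_class = cls, stratum = stratum,
       excluded_early_death = !is.na(drel) && drel < 48,
       death_within_48_72h = death_day3)
}

#' Screen a cohort bundle
#'
#' Harmonises every stay, finds first episodes, classifies persistence, and
#' returns one row per SUBJECT: for subjects with multiple screen-positive
#' stays, the stay with the earliest onset is retained. Ventilation columns
#' record whether a `vent_flag = 1` event falls inside the onset window
#' (`vent_at_onset`) or at/after onset (`vent_after_onset`).
#'
#' @param bundle an `ards_cohort`.
#' @param config an [ards_config()] or override list.
#' @param harmonized optionally, a precomputed [harmonize_cohort()] result
#'   for `bundle` (avoids recomputation).
#' @return data frame (`ards_screen` class) with one row per screen-positive
#'   subject: `subject_id`, `stay_id`, `onset`, `n_consecutive`,
#'   `persistence_class`, `stratum`, `excluded_early_death`,
#'   `death_within_48_72h`, `anytime_hit`, `vent_at_onset`,
#'   `vent_after_onset`. Cascade counts via [cascade_counts()].
#' @export
screen_cohort <- function(bundle, config = ards_config(), harmonized = NULL) {
  stopifnot(inherits(bundle, "ards_cohort"))
  cfg <- ards_config(config)
  if (is.null(harmonized)) harmonized <- harmonize_cohort(bundle, cfg)
  stays <- bundle$stays
  win_split <- split(harmonized$windows, factor(harmonized$windows$stay_id,
                                                levels = stays$stay_id))
  flags <- harmonized$stay_flags
  vent <- bundle$events[bundle$events$kind == "vent_flag" &
                          bundle$events$value == 1, c("stay_id", "time")]
  vent_t <- split(as.numeric(vent$time), factor(vent$stay_id,
                                                levels = stays$stay_id))

  rows <- vector("list", nrow(stays))
  for (i in seq_len(nrow(stays))) {
    id <- stays$stay_id[i]
    ep <- find_first_episode(win_split[[id]], flags$anytime_hit[i])
    cl <- classify_persistence(ep, stays[i, , drop = FALSE],
                               flags$anytime_hit[i])
    if (is.na(cl$persistence_class)) next
    onset <- if (is.null(ep)) as.POSIXct(NA) else ep$onset
    vt <- vent_t[[id]]
    on_s <- as.numeric(onset)
    rows[[i]] <- data.frame(
      subject_id = stays$subject_id[i], stay_id = id, onset = onset,
      n_consecutive = if (is.null(ep)) 0L else ep$n_consecutive,
      persistence_class = cl$persistence_class, stratum = cl$stratum,
      excluded_early_death = cl$excluded_early_death,
      death_within_48_72h = cl$death_within_48_72h,
      anytime_hit = isTRUE(flags$anytime_hit[i]),
      vent_at_onset = !is.na(on_s) && length(vt) > 0 &&
        any(vt >= on_s & vt < on_s + 86400),
      vent_after_onset = !is.na(on_s) && length(vt) > 0 && any(vt >= on_s),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(subject_id = character(), stay_id = character(),
                      onset = parse_timestamp(character()),
                      n_consecutive = integer(), persistence_class = character(),
                      stratum = character(), excluded_early_death = logical(),
                      death_within_48_72h = logical(), anytime_hit = logical(),
                      vent_at_onset = logical(), vent_after_onset = logical(),
                      stringsAsFactors = FALSE)
  } else {
    # first qualifying episode per subject: earliest onset; anytime-only
    # stays (no onset) sort after any dated onset, then by stay order.
    key <- ifelse(is.na(res$onset), Inf, as.numeric(res$onset))
    res <- res[order(res$subject_id, key), , drop = FALSE]
    res <- res[!duplicated(res$subject_id), , drop = FALSE]
    res <- res[order(match(res$stay_id, stays$stay_id)), , drop = FALSE]
    rownames(res) <- NULL
  }
  class(res) <- c("ards_screen", "data.frame")
  res
}

#' Cascade counts across persistence cohorts
#'
#' Nested subject counts in the style of an inclusion (consort) cascade:
#' each row counts subjects meeting at least that persistence requirement,
#' so counts are non-increasing from `ANYTIME` to `H72`.
#'
#' @param screen result of [screen_cohort()].
#' @return data frame with `cohort` and `n_subjects`.
#' @export
cascade_counts <- function(screen) {
  lev <- match(screen$persistence_class, .PERSIST_LEVELS)  # 1..4
  data.frame(
    cohort = c("ANYTIME", "H24", "H48", "H72"),
    n_subjects = c(sum(lev >= 1), sum(lev >= 2), sum(lev >= 3), sum(lev >= 4)),
    stringsAsFactors = FALSE)
}

#' Subject identifiers meeting a given persistence requirement
#'
#' @param screen result of [screen_cohort()].
#' @param window `"anytime"`, 24, 48 or 72.
#' @param drop_early_death drop subjects flagged `excluded_early_death`
#'   (the design exclusion applied to the 72-h study cohort). Default FALSE.
#' @return character vector of `subject_id`.
#' @export
cohort_members <- function(screen, window = 72, drop_early_death = FALSE) {
  min_lev <- if (identical(window, "anytime")) 1L else
    switch(as.character(window), "24" = 2L, "48" = 3L, "72" = 4L,
           stopf("window must be 'anytime', 24, 48 or 72"))
  keep <- match(screen$persistence_class, .PERSIST_LEVELS) >= min_lev
  if (drop_early_death) keep <- keep & !screen$excluded_early_death
  screen$subject_id[keep]
}
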