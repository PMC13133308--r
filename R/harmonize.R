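# Harmonisation: pair P/F ratios with contemporaneous PEEP, then aggregate
# into non-overlapping 24-h windows anchored at ICU admission. A window
# qualifies when the mean P/F over points with paired PEEP >= 5 cm H2O is
# below 300 mm Hg.

.FIO2_MATCH_MIN <- 5  # PaO2 and FiO2 must come from the same blood-gas
                      # record: identical timestamp or within 5 minutes.

# Nearest-neighbour match of each target time against a sorted reference
# grid; ties broken toward the EARLIER reference. Returns reference indices
# (NA where no reference within tol_h).
.nearest_earlier_tie <- function(t, ref_t, tol_h) {
  if (length(ref_t) == 0) return(rep(NA_integer_, length(t)))
  lo <- findInterval(t, ref_t)                  # last ref <= t (0 if none)
  hi <- pmin(lo + 1L, length(ref_t))
  lo_ok <- lo >= 1L
  d_lo <- ifelse(lo_ok, t - ref_t[pmax(lo, 1L)], Inf)
  d_hi <- ref_t[hi] - t
  d_hi[hi == lo] <- Inf                         # t beyond last ref
  pick_lo <- lo_ok & d_lo <= d_hi               # tie -> earlier
  idx <- ifelse(pick_lo, lo, hi)
  dist <- ifelse(pick_lo, d_lo, d_hi)
  idx[!is.finite(dist) | dist > tol_h] <- NA_integer_
  idx
}

# Vector core shared by the per-stay API and the cohort driver. Times are
# numeric hours on a common origin; all inputs must be sorted by time.
.pair_core <- function(t_pao2, v_pao2, t_fio2, v_fio2, t_peep, v_peep,
                       tolerance_h) {
  if (any(v_fio2 == 0, na.rm = TRUE)) {
    stopf("invalid measurement: FiO2 = 0 cannot form a P/F ratio")
  }
  fidx <- .nearest_earlier_tie(t_pao2, t_fio2, .FIO2_MATCH_MIN / 60)
  n_dropped <- sum(is.na(fidx))
  keep <- !is.na(fidx)
  t_pf <- t_pao2[keep]
  pf <- v_pao2[keep] / v_fio2[fidx[keep]]
  pidx <- .nearest_earlier_tie(t_pf, t_peep, tolerance_h)
  list(time = t_pf, pf = pf,
       peep = ifelse(is.na(pidx), NA_real_, v_peep[pidx]),
       paired = !is.na(pidx), n_dropped = n_dropped)
}

#' Pair P/F ratios with contemporaneous PEEP for one stay
#'
#' PaO2 and FiO2 are matched at identical timestamps or within 5 minutes
#' (same blood-gas record); each resulting P/F point is then paired with the
#' nearest-in-time PEEP within `tolerance_h` hours, ties broken toward the
#' earlier PEEP. Points with no PEEP inside the tolerance are returned with
#' `paired = FALSE` and are excluded from window means downstream. PaO2
#' measurements with no FiO2 within 5 minutes are dropped; the count is
#' available as `attr(x, "n_dropped")` and raises a warning.
#'
#' @param events data frame of events for a single stay (`stay_id`, `time`,
#'   `kind`, `value`), times as POSIXct.
#' @param tolerance_h PEEP pairing tolerance in hours (default 2).
#' @return data frame with columns `stay_id`, `time`, `pf`, `peep`,
#'   `paired`, ordered by time.
#' @export
pair_pf_with_peep <- function(events, tolerance_h = 2) {
  stopifnot(is.data.frame(events), tolerance_h > 0)
  if (length(unique(events$stay_id)) > 1) {
    stopf("pair_pf_with_peep() expects events for a single stay")
  }
  events <- events[order(events$time), , drop = FALSE]
  h <- as.numeric(events$time) / 3600
  sel <- function(kind) events$kind == kind
  core <- .pair_core(h[sel("pao2_mmHg")], events$value[sel("pao2_mmHg")],
                     h[sel("fio2_fraction")], events$value[sel("fio2_fraction")],
                     h[sel("peep_cmH2O")], events$value[sel("peep_cmH2O")],
                     tolerance_h)
  if (core$n_dropped > 0) {
    warning(sprintf("%d PaO2 measurement(s) without FiO2 within %d min dropped",
                    core$n_dropped, .FIO2_MATCH_MIN), call. = FALSE)
  }
  out <- data.frame(
    stay_id = rep(events$stay_id[1] %||% NA_character_, length(core$time)),
    time = as.POSIXct(core$time * 3600, origin = "1970-01-01", tz = "UTC"),
    pf = core$pf, peep = core$peep, paired = core$paired,
    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- core$n_dropped
  out
}

# Window aggregation core on numeric hours relative to ICU admission.
.windows_core <- function(rel_h, pf, peep, paired, los_h,
                          pf_threshold, peep_threshold, carry_forward) {
  n_win <- max(1L, as.integer(ceiling(los_h / 24)))
  elig <- paired & !is.na(peep) & peep >= peep_threshold &
    rel_h >= 0 & rel_h < los_h
  widx <- floor(rel_h[elig] / 24) + 1L          # 1-based for tabulation
  mean_pf <- rep(NA_real_, n_win)
  n_points <- integer(n_win)
  if (any(elig)) {
    sums <- vapply(split(pf[elig], factor(widx, levels = seq_len(n_win))),
                   sum, numeric(1))
    cnt <- tabulate(widx, nbins = n_win)
    n_points <- cnt
    mean_pf[cnt > 0] <- sums[cnt > 0] / cnt[cnt > 0]
  }
  carried <- rep(FALSE, n_win)
  if (carry_forward > 0 && n_win > 1) {
    gap <- 0L
    for (i in 2:n_win) {
      if (is.na(mean_pf[i])) {
        gap <- gap + 1L
        if (gap <= carry_forward && !is.na(mean_pf[i - 1])) {
          mean_pf[i] <- mean_pf[i - 1]
          carried[i] <- TRUE
        }
      } else gap <- 0L
    }
  }
  list(index = seq_len(n_win) - 1L, mean_pf = mean_pf, n_points = n_points,
       carried = carried, qualifies = !is.na(mean_pf) & mean_pf < pf_threshold)
}

#' Aggregate paired P/F points into 24-h windows for one stay
#'
#' Windows tile `[icu_in, icu_out)` in 24-h steps anchored at ICU admission
#' (the number of windows is `ceiling(stay_hours / 24)`; the last window may
#' be partial). Each window's `mean_pf` is the mean P/F over points whose
#' paired PEEP is at least `peep_threshold`; a window with no eligible point
#' has `mean_pf = NA` and never qualifies. `qualifies` is `mean_pf <
#' pf_threshold`.
#'
#' @param pfpoints output of [pair_pf_with_peep()] for the same stay.
#' @param stay single-row data frame with `icu_in`, `icu_out` (POSIXct).
#' @param pf_threshold mean P/F qualification threshold, mm Hg (default 300).
#' @param peep_threshold minimum paired PEEP, cm H2O (default 5).
#' @param carry_forward_windows carry a defined window mean forward across up
#'   to this many empty windows to bridge sampling gaps (default 0 = off).
#' @return data frame with `stay_id`, `index` (0-based), `win_start`,
#'   `mean_pf`, `n_points`, `carried`, `qualifies`.
#' @export
build_day_windows <- function(pfpoints, stay, pf_threshold = 300,
                              peep_threshold = 5, carry_forward_windows = 0) {
  stopifnot(nrow(stay) == 1)
  los_h <- hours_between(stay$icu_in, stay$icu_out)
  if (!is.finite(los_h) || los_h <= 0) stopf("stay must have icu_in < icu_out")
  rel_h <- hours_between(stay$icu_in, pfpoints$time)
  core <- .windows_core(rel_h, pfpoints$pf, pfpoints$peep, pfpoints$paired,
                        los_h, pf_threshold, peep_threshold,
                        carry_forward_windows)
  data.frame(stay_id = stay$stay_id, index = core$index,
             win_start = stay$icu_in + core$index * 86400,
             mean_pf = core$mean_pf, n_points = core$n_points,
             carried = core$carried, qualifies = core$qualifies,
             stringsAsFactors = FALSE)
}

#' Harmonise a whole cohort bundle
#'
#' Runs [pair_pf_with_peep()] and [build_day_windows()] over every stay and
#' additionally records, per stay, whether any single paired measurement
#' ever met the physiologic criteria (P/F below threshold with PEEP at or
#' above threshold) -- the "any-time" screen.
#'
#' @param bundle an `ards_cohort`.
#' @param config list of options; recognised elements `pf_threshold` (300),
#'   `peep_threshold` (5), `pairing_tolerance_h` (2),
#'   `carry_forward_windows` (0). See [ards_config()].
#' @return list with `windows` (stacked window table) and `stay_flags`
#'   (per-stay: `anytime_hit`, `n_pf_points`, `n_dropped`).
#' @export
harmonize_cohort <- function(bundle, config = ards_config()) {
  stopifnot(inherits(bundle, "ards_cohort"))
  cfg <- ards_config(config)
  ev <- bundle$events
  stays <- bundle$stays
  h <- as.numeric(ev$time) / 3600
  sid <- factor(ev$stay_id, levels = stays$stay_id)
  ord <- order(sid, h)
  h <- h[ord]; kind <- ev$kind[ord]; val <- ev$value[ord]; sid <- sid[ord]
  by_stay <- function(keep) {
    list(t = split(h[keep], sid[keep]), v = split(val[keep], sid[keep]))
  }
  pao2 <- by_stay(kind == "pao2_mmHg")
  fio2 <- by_stay(kind == "fio2_fraction")
  peep <- by_stay(kind == "peep_cmH2O")

  n <- nrow(stays)
  win_list <- vector("list", n)
  anytime <- logical(n)
  n_pts <- integer(n)
  n_drop <- integer(n)
  in_h <- as.numeric(stays$icu_in) / 3600
  los_h <- hours_between(stays$icu_in, stays$icu_out)
  for (i in seq_len(n)) {
    id <- stays$stay_id[i]
    core <- .pair_core(pao2$t[[id]], pao2$v[[id]], fio2$t[[id]], fio2$v[[id]],
                       peep$t[[id]], peep$v[[id]], cfg$pairing_tolerance_h)
    n_drop[i] <- core$n_dropped
    n_pts[i] <- length(core$time)
    anytime[i] <- any(core$paired & core$pf < cfg$pf_threshold &
                        core$peep >= cfg$peep_threshold, na.rm = TRUE)
    w <- .windows_core(core$time - in_h[i], core$pf, core$peep, core$paired,
                       los_h[i], cfg$pf_threshold, cfg$peep_threshold,
                       cfg$carry_forward_windows)
    win_list[[i]] <- w
  }
  n_win <- vapply(win_list, function(w) length(w$index), integer(1))
  windows <- data.frame(
    stay_id = rep(stays$stay_id, n_win),
    index = unlist(lapply(win_list, `[[`, "index")),
    mean_pf = unlist(lapply(win_list, `[[`, "mean_pf")),
    n_points = unlist(lapply(win_list, `[[`, "n_points")),
    carried = unlist(lapply(win_list, `[[`, "carried")),
    qualifies = unlist(lapply(win_list, `[[`, "qualifies")),
    stringsAsFactors = FALSE)
  windows$win_start <- rep(stays$icu_in, n_win) + windows$index * 86400
  stay_flags <- data.frame(stay_id = stays$stay_id, anytime_hit = anytime,
                           n_pf_points = n_pts, n_dropped = n_drop,
                           stringsAsFactors = FALSE)
  list(windows = windows, stay_flags = stay_flags)
}
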