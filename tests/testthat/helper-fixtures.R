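# Fixture builders shared across the test files. All fixtures are built in
# code; `ts0` is an arbitrary admission instant.

ts0 <- as.POSIXct("2021-03-01 00:00", tz = "UTC")

hrs <- function(h) ts0 + h * 3600

make_stay <- function(stay_id = "s1", subject_id = stay_id, in_h = 0,
                      out_h = 96, death_h = NA) {
  data.frame(stay_id = stay_id, subject_id = subject_id,
             icu_in = hrs(in_h), icu_out = hrs(out_h),
             death_time = if (is.na(death_h)) as.POSIXct(NA) else hrs(death_h),
             stringsAsFactors = FALSE)
}

ev <- function(stay_id, h, kind, value) {
  data.frame(stay_id = stay_id, time = hrs(h), kind = kind, value = value,
             stringsAsFactors = FALSE)
}

# Blood gas (PaO2 + FiO2 at one minute) plus a PEEP reading, giving a paired
# P/F point with the requested values at hour `h`.
pf_point_events <- function(stay_id, h, pf, peep, fio2 = 0.5) {
  rbind(ev(stay_id, h, "pao2_mmHg", pf * fio2),
        ev(stay_id, h, "fio2_fraction", fio2),
        ev(stay_id, h, "peep_cmH2O", peep))
}

# Events realising a per-24h-window qualification pattern: for each TRUE a
# qualifying P/F point (pf = 150, peep = 8) mid-window, for each FALSE a
# non-qualifying one (pf = 350).
pattern_events <- function(stay_id, pattern, peep = 8) {
  do.call(rbind, lapply(seq_along(pattern), function(i) {
    pf_point_events(stay_id, (i - 1) * 24 + 12,
                    if (pattern[i]) 150 else 350, peep)
  }))
}

pattern_bundle <- function(pattern, out_h = length(pattern) * 24,
                           death_h = NA, stay_id = "s1") {
  as_cohort(stays = make_stay(stay_id, out_h = out_h, death_h = death_h),
            events = pattern_events(stay_id, pattern))
}

# Random valid bundle, independent of the synth module, for round-trip and
# screening property tests.
random_bundle <- function(seed, n_stays = 6) {
  set.seed(seed)
  ids <- sprintf("r%02d", seq_len(n_stays))
  subj <- sprintf("u%02d", sample(ceiling(n_stays / 2), n_stays, replace = TRUE))
  stays <- do.call(rbind, lapply(seq_len(n_stays), function(i) {
    out_h <- sample(30:200, 1)
    death_h <- if (runif(1) < 0.3) runif(1, 10, out_h) else NA
    s <- make_stay(ids[i], subj[i], in_h = (i - 1) * 240,
                   out_h = (i - 1) * 240 + out_h,
                   death_h = if (is.na(death_h)) NA else (i - 1) * 240 + death_h)
    s
  }))
  events <- do.call(rbind, lapply(seq_len(n_stays), function(i) {
    base <- (i - 1) * 240
    los <- as.numeric(difftime(stays$icu_out[i], stays$icu_in[i], units = "hours"))
    n_pts <- sample(3:12, 1)
    do.call(rbind, lapply(sort(runif(n_pts, 0, los - 1)), function(h) {
      pf_point_events(ids[i], base + h, pf = runif(1, 80, 420),
                      peep = sample(3:14, 1), fio2 = round(runif(1, 0.3, 0.9), 2))
    }))
  }))
  reports <- data.frame(stay_id = ids,
                        time = stays$icu_in + 3600 * runif(n_stays, 1, 20),
                        text = sample(c("Bilateral patchy opacities.",
                                        "Lungs are clear.",
                                        "No bilateral opacities seen."),
                                      n_stays, replace = TRUE),
                        stringsAsFactors = FALSE)
  icd <- data.frame(stay_id = sample(ids, n_stays, replace = TRUE),
                    code = sample(c("J80", "I509", "51882", "4280"),
                                  n_stays, replace = TRUE),
                    version = sample(c(9L, 10L), n_stays, replace = TRUE),
                    stringsAsFactors = FALSE)
  labels <- data.frame(stay_id = ids,
                       label = sample(c("ARDS", "POSSIBLE", "NON_ARDS_AHRF"),
                                      n_stays, replace = TRUE),
                       stringsAsFactors = FALSE)
  b <- as_cohort(stays = stays, events = events, reports = reports,
                 icd = icd, labels = labels)
  # minute resolution so file round-trips are exact
  for (tab in c("stays", "events", "reports")) {
    for (col in intersect(names(b[[tab]]), c("icu_in", "icu_out",
                                             "death_time", "time"))) {
      b[[tab]][[col]] <- as.POSIXct(floor(as.numeric(b[[tab]][[col]]) / 60) * 60,
                                    origin = "1970-01-01", tz = "UTC")
    }
  }
  b
}

expect_tables_equal <- function(a, b) {
  expect_equal(names(a), names(b))
  for (tab in names(ardsscreen:::.SCHEMAS)) {
    ta <- a[[tab]]; tb <- b[[tab]]
    expect_equal(nrow(ta), nrow(tb), info = tab)
    for (col in names(ta)) {
      va <- ta[[col]]; vb <- tb[[col]]
      if (inherits(va, "POSIXct")) {
        expect_equal(as.numeric(va), as.numeric(vb), info = paste(tab, col))
      } else if (is.numeric(va)) {
        expect_equal(va, vb, tolerance = 1e-12, info = paste(tab, col))
      } else {
        expect_equal(va, vb, info = paste(tab, col))
      }
    }
  }
}
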