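windows_for <- function(pattern, stay = make_stay("s1", out_h = length(pattern) * 24)) {
  pts <- pair_pf_with_peep(pattern_events("s1", pattern))
  build_day_windows(pts, stay)
}

test_that("the FIRST run of consecutive qualifying windows is retained", {
  ep <- find_first_episode(windows_for(c(TRUE, TRUE, TRUE, FALSE)))
  expect_equal(ep$onset_index, 0)
  expect_equal(ep$n_consecutive, 3)
  # a later, longer run never displaces the first run
  ep2 <- find_first_episode(windows_for(c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE)))
  expect_equal(ep2$onset_index, 1)
  expect_equal(ep2$n_consecutive, 1)
  # oracle: enumerate runs directly for random patterns
  set.seed(7)
  for (i in 1:20) {
    pat <- runif(sample(3:8, 1)) < 0.5
    ep3 <- find_first_episode(windows_for(pat))
    if (!any(pat)) {
      expect_null(ep3)
    } else {
      first <- which(pat)[1]
      run_len <- which(!pat[first:length(pat)])[1] - 1
      if (is.na(run_len)) run_len <- length(pat) - first + 1
      expect_equal(ep3$onset_index, first - 1)
      expect_equal(ep3$n_consecutive, run_len)
    }
  }
})

test_that("a single qualifying measurement without a qualifying window still screens any-time", {
  stay <- make_stay("s1", out_h = 48)
  # one low P/F among high ones: window mean 316.7 does not qualify
  events <- rbind(pf_point_events("s1", 5, 250, 6),
                  pf_point_events("s1", 10, 350, 8),
                  pf_point_events("s1", 15, 350, 8))
  pts <- pair_pf_with_peep(events)
  w <- build_day_windows(pts, stay)
  expect_false(any(w$qualifies))
  ep <- find_first_episode(w)
  expect_null(ep)
  cl <- classify_persistence(NULL, stay, anytime_hit = TRUE)
  expect_equal(cl$persistence_class, "ANYTIME_ONLY")
})

test_that("persistence classes follow the 72-h rule and its death-on-day-3 variant", {
  stay <- make_stay("s1", out_h = 96)
  ep3 <- list(onset = hrs(0), onset_index = 0, n_consecutive = 3)
  expect_equal(classify_persistence(ep3, stay)$persistence_class, "H72")

  ep2 <- list(onset = hrs(0), onset_index = 0, n_consecutive = 2)
  expect_equal(classify_persistence(ep2, stay)$persistence_class, "H48")
  expect_equal(classify_persistence(ep2, stay)$stratum, "h24_48")

  # two windows + death at onset+60 h -> day-3 death variant promotes to H72
  died <- make_stay("s1", out_h = 60, death_h = 60)
  cl <- classify_persistence(ep2, died)
  expect_equal(cl$persistence_class, "H72")
  expect_true(cl$death_within_48_72h)

  # death inside 48 h of onset flags the design exclusion
  early <- make_stay("s1", out_h = 30, death_h = 30)
  ep1 <- list(onset = hrs(0), onset_index = 0, n_consecutive = 1)
  cl2 <- classify_persistence(ep1, early)
  expect_equal(cl2$persistence_class, "H24")
  expect_true(cl2$excluded_early_death)
  expect_equal(cl2$stratum, "h0_24")
})

test_that("the death variant never fires for subjects alive at onset+72h", {
  set.seed(17)
  for (i in 1:30) {
    n <- sample(1:4, 1)
    death_h <- if (runif(1) < 0.5) NA else runif(1, 0, 200)
    stay <- make_stay("s1", out_h = max(96, death_h + 1, na.rm = TRUE),
                      death_h = death_h)
    cl <- classify_persistence(list(onset = hrs(0), onset_index = 0,
                                    n_consecutive = n), stay)
    alive_at_72 <- is.na(death_h) || death_h >= 72
    if (alive_at_72) expect_false(cl$death_within_48_72h)
    if (cl$death_within_48_72h) expect_true(death_h >= 48 && death_h < 72)
    # the variant only ever promotes n >= 2 episodes
    if (n < 2 && cl$persistence_class == "H72") fail("H72 from a 1-window run")
  }
})

test_that("screen cohorts nest monotonically on randomized fixtures", {
  for (seed in 51:56) {
    b <- random_bundle(seed, n_stays = 8)
    s <- screen_cohort(b)
    casc <- cascade_counts(s)
    expect_true(all(diff(casc$n_subjects) <= 0))
    any_m <- cohort_members(s, "anytime")
    m24 <- cohort_members(s, 24)
    m48 <- cohort_members(s, 48)
    m72 <- cohort_members(s, 72)
    expect_true(all(m72 %in% m48))
    expect_true(all(m48 %in% m24))
    expect_true(all(m24 %in% any_m))
  }
})

test_that("screening results agree with a brute-force per-subject oracle", {
  b <- random_bundle(61, n_stays = 10)
  s <- screen_cohort(b)
  for (i in seq_len(nrow(b$stays))) {
    id <- b$stays$stay_id[i]
    # oracle: nearest-PEEP pairing and window classification by plain loops
    evs <- b$events[b$events$stay_id == id, ]
    evs <- evs[order(evs$time), ]
    gas <- evs[evs$kind == "pao2_mmHg", ]
    fio <- evs[evs$kind == "fio2_fraction", ]
    pep <- evs[evs$kind == "peep_cmH2O", ]
    los <- as.numeric(difftime(b$stays$icu_out[i], b$stays$icu_in[i],
                               units = "hours"))
    qual <- rep(FALSE, ceiling(los / 24))
    sums <- rep(0, length(qual)); cnts <- rep(0, length(qual))
    anytime <- FALSE
    for (g in seq_len(nrow(gas))) {
      df <- abs(as.numeric(fio$time) - as.numeric(gas$time[g]))
      if (!length(df) || min(df) > 300) next
      fi <- fio$value[order(df, fio$time)][1]
      pf <- gas$value[g] / fi
      dp <- as.numeric(pep$time) - as.numeric(gas$time[g])
      if (!length(dp) || min(abs(dp)) > 7200) next
      best <- order(abs(dp), dp)[1]          # tie -> earlier
      if (pep$value[best] >= 5) {
        rel <- as.numeric(difftime(gas$time[g], b$stays$icu_in[i],
                                   units = "hours"))
        if (pf < 300) anytime <- TRUE
        k <- floor(rel / 24) + 1
        if (rel >= 0 && rel < los) {
          sums[k] <- sums[k] + pf; cnts[k] <- cnts[k] + 1
        }
      }
    }
    qual <- cnts > 0 & ifelse(cnts > 0, sums / pmax(cnts, 1), Inf) < 300
    row <- s[s$stay_id == id, ]
    if (!any(qual) && !anytime) {
      expect_false(id %in% s$stay_id)
    } else if (nrow(row) == 1) {       # subject may have picked another stay
      if (any(qual)) {
        first <- which(qual)[1]
        run <- which(!qual[first:length(qual)])[1] - 1
        if (is.na(run)) run <- length(qual) - first + 1
        expect_equal(row$n_consecutive, run)
      } else {
        expect_equal(row$persistence_class, "ANYTIME_ONLY")
      }
    }
  }
})

test_that("subjects with multiple qualifying stays keep the earliest onset", {
  stays <- rbind(make_stay("a1", "subj", in_h = 0, out_h = 96),
                 make_stay("a2", "subj", in_h = 500, out_h = 596))
  events <- rbind(pattern_events("a1", c(FALSE, TRUE, TRUE, TRUE)),
                  local({
                    e <- pattern_events("a2", c(TRUE, TRUE, TRUE, TRUE))
                    e$time <- e$time + 500 * 3600
                    e
                  }))
  b <- as_cohort(stays = stays, events = events)
  s <- screen_cohort(b)
  expect_equal(nrow(s), 1)
  expect_equal(s$stay_id, "a1")
  expect_equal(s$persistence_class, "H72")
})

test_that("an empty bundle yields an empty result and a zero cascade", {
  b <- as_cohort(stays = make_stay("s1", out_h = 48))
  s <- screen_cohort(b)
  expect_equal(nrow(s), 0)
  expect_equal(cascade_counts(s)$n_subjects, c(0, 0, 0, 0))
})

test_that("screening is deterministic for identical inputs", {
  b <- random_bundle(71)
  s1 <- screen_cohort(b)
  s2 <- screen_cohort(b)
  expect_identical(s1, s2)
})

test_that("ventilation columns reflect vent events around onset", {
  stay <- make_stay("s1", out_h = 96)
  events <- rbind(pattern_events("s1", c(TRUE, TRUE, TRUE, TRUE)),
                  ev("s1", 2, "vent_flag", 1))
  b <- as_cohort(stays = stay, events = events)
  s <- screen_cohort(b)
  expect_true(s$vent_at_onset)
  expect_true(s$vent_after_onset)
  # vent only before onset: episode starts at window 1
  events2 <- rbind(pattern_events("s2", c(FALSE, TRUE, TRUE, TRUE)),
                   ev("s2", 2, "vent_flag", 1))
  b2 <- as_cohort(stays = make_stay("s2", out_h = 96), events = events2)
  s2 <- screen_cohort(b2)
  expect_false(s2$vent_at_onset)
  expect_false(s2$vent_after_onset)
})
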