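test_that("rules parse to the expected expression tree", {
  r <- compile_ruleset("bilateral AND (infiltrat OR opacit)")
  expect_equal(r$expr$op, "and")
  expect_equal(r$expr$args[[1]], list(op = "term", pattern = "bilateral"))
  expect_equal(r$expr$args[[2]]$op, "or")
  expect_equal(vapply(r$expr$args[[2]]$args, `[[`, "", "pattern"),
               c("infiltrat", "opacit"))
})

test_that("malformed rules fail with positional parse errors", {
  expect_error(compile_ruleset("NOT effusion"), "no positive")
  expect_error(compile_ruleset("a AND (b OR c"), "position.*unbalanced|unbalanced")
  expect_error(compile_ruleset(""), "empty rule")
  expect_error(compile_ruleset("a AND \"\""), "empty term")
  expect_error(compile_ruleset("a ) b"), "position 3")
})

test_that("compile(serialise(compile(s))) is the identity on random rules", {
  set.seed(91)
  terms <- c("ards", "bilateral", "opacit", "infiltrat", "ground glass",
             "oedema")
  random_expr <- function(depth) {
    if (depth <= 0 || runif(1) < 0.4) {
      t <- sample(terms, 1)
      return(if (grepl(" ", t)) sprintf("\"%s\"", t) else t)
    }
    op <- sample(c("AND", "OR"), 1)
    lhs <- random_expr(depth - 1)
    rhs <- random_expr(depth - 1)
    neg <- if (runif(1) < 0.2) "NOT " else ""
    sprintf("(%s %s %s%s)", lhs, op, neg, rhs)
  }
  for (i in 1:25) {
    s <- random_expr(3)
    r1 <- try(compile_ruleset(s), silent = TRUE)
    if (inherits(r1, "try-error")) next   # all-negative draws are invalid
    r2 <- compile_ruleset(format(r1))
    expect_equal(r2$expr, r1$expr, info = s)
  }
})

test_that("rule application honours the report window relative to onset", {
  rule <- compile_ruleset("bilateral AND (infiltrat OR opacit)")
  onset <- hrs(0)
  rep6 <- data.frame(stay_id = "s1", time = hrs(6),
                     text = "Bilateral airspace opacities.")
  expect_true(apply_ruleset(rule, rep6, onset, "H0_48"))
  rep60 <- rep6; rep60$time <- hrs(60)
  expect_false(apply_ruleset(rule, rep60, onset, "H0_48"))
  expect_true(apply_ruleset(rule, rep60, onset, "ANY"))
  expect_false(apply_ruleset(rule, rep6[0, ], onset, "ANY"))
})

test_that("negation masking suppresses cued mentions within a sentence", {
  rule <- compile_ruleset("bilateral AND (infiltrat OR opacit)")
  neg <- data.frame(stay_id = "s1", time = hrs(6),
                    text = "No bilateral opacities.")
  expect_false(apply_ruleset(rule, neg, hrs(0), "ANY"))
  # cue in a previous sentence does not mask the next sentence
  split <- data.frame(stay_id = "s1", time = hrs(6),
                      text = "No effusion. Bilateral opacities present.")
  expect_true(apply_ruleset(rule, split, hrs(0), "ANY"))
  # a term before the cue still counts
  pre <- data.frame(stay_id = "s1", time = hrs(6),
                    text = "Bilateral opacities, now without consolidation.")
  expect_true(apply_ruleset(rule, pre, hrs(0), "ANY"))
  # masking never creates positives the unmasked rule missed
  set.seed(92)
  texts <- replicate(40, paste(sample(c("no", "bilateral", "opacities",
                                        "clear", "infiltrates", "without"),
                                      sample(2:6, 1), replace = TRUE),
                               collapse = " "))
  masked <- ardsscreen:::.texts_match_rule(rule, texts)
  unmasked_rule <- compile_ruleset(format(rule), negation_cues = character(0))
  unmasked <- ardsscreen:::.texts_match_rule(unmasked_rule, texts)
  expect_true(all(!masked | unmasked))
})

test_that("widening a rule never loses keyword positives", {
  rules <- default_rulesets()
  expect_equal(names(rules), paste0("T", 1:6))
  set.seed(93)
  vocab <- c("ards", "bilateral", "infiltrates", "opacities", "consolidation",
             "diffuse", "ground glass", "clear", "effusion", "oedema", "no")
  texts <- replicate(60, paste(sample(vocab, sample(2:7, 1), replace = TRUE),
                               collapse = " "))
  hits <- vapply(rules, function(r) ardsscreen:::.texts_match_rule(r, texts),
                 logical(length(texts)))
  for (k in 1:5) expect_true(all(hits[, k] <= hits[, k + 1]),
                             info = paste("T", k))
  # adding an OR term to an arbitrary rule is monotone too
  base <- compile_ruleset("bilateral AND infiltrat")
  wide <- compile_ruleset("(bilateral AND infiltrat) OR opacit")
  hb <- ardsscreen:::.texts_match_rule(base, texts)
  hw <- ardsscreen:::.texts_match_rule(wide, texts)
  expect_true(all(hb <= hw))
})

test_that("ICD matching is canonical with prefix wildcard support", {
  expect_true(match_icd(data.frame(code = "J80"), default_codeset()))
  expect_true(match_icd("j80"))                         # lowercase input
  expect_false(match_icd(data.frame(code = "I509"), default_codeset()))
  expect_false(match_icd(data.frame(code = character(0)), default_codeset()))
  expect_true(match_icd("J96001", default_codeset()))   # via J9600* prefix
  expect_false(match_icd("J9610", default_codeset()))
  expect_true(match_icd("518.82", default_codeset()))   # dotted input
})

test_that("cohort enrichment flags respect windows and code-sets", {
  stays <- rbind(make_stay("e1", out_h = 96), make_stay("e2", out_h = 96))
  events <- rbind(pattern_events("e1", rep(TRUE, 4)),
                  pattern_events("e2", rep(TRUE, 4)))
  reports <- data.frame(
    stay_id = c("e1", "e2"),
    time = c(hrs(10), hrs(60)),
    text = c("Bilateral patchy opacities.", "Bilateral patchy opacities."),
    stringsAsFactors = FALSE)
  icd <- data.frame(stay_id = "e1", code = "J80", version = 10L)
  b <- as_cohort(stays = stays, events = events, reports = reports, icd = icd)
  s <- screen_cohort(b)
  fl <- enrich_cohort(b, s)
  fl <- fl[order(fl$stay_id), ]
  expect_equal(fl$keyword_hit_48h, c(TRUE, FALSE))
  expect_equal(fl$keyword_hit_any, c(TRUE, TRUE))
  expect_equal(fl$icd_hit, c(TRUE, FALSE))
  # invariant: a 48-h hit is always an any-time hit
  expect_true(all(!fl$keyword_hit_48h | fl$keyword_hit_any))
})
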