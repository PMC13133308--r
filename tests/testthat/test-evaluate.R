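test_that("confusion matrices reproduce hand tallies", {
  # worked example: 993 ARDS (756 flagged), 879 non-ARDS (451 flagged),
  # possible cases excluded
  labels <- data.frame(
    stay_id = sprintf("c%04d", 1:2000),
    label = rep(c("ARDS", "POSSIBLE", "NON_ARDS_AHRF"), c(993, 128, 879)))
  flag <- rep(FALSE, 2000)
  flag[1:756] <- TRUE                      # 756 of the ARDS cases coded
  flag[993 + 128 + (1:451)] <- TRUE        # 451 of the non-ARDS cases coded
  cm <- confusion(labels, data.frame(stay_id = labels$stay_id, flag = flag))
  expect_equal(cm$tp, 756)
  expect_equal(cm$fn, 237)
  expect_equal(cm$fp, 451)
  expect_equal(cm$tn, 428)

  # element-wise enumeration oracle on random small sets
  set.seed(101)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    lab <- data.frame(stay_id = sprintf("x%02d", 1:n),
                      label = sample(c("ARDS", "POSSIBLE", "NON_ARDS_AHRF"),
                                     n, replace = TRUE))
    fl <- runif(n) < 0.5
    for (pd in c("ARDS_ONLY", "ARDS_OR_POSSIBLE")) {
      for (ph in c("EXCLUDE", "AS_NEGATIVE")) {
        cm2 <- confusion(lab, data.frame(stay_id = lab$stay_id, flag = fl),
                         positive_definition = pd, possible_handling = ph)
        keep <- if (pd == "ARDS_ONLY" && ph == "EXCLUDE")
          lab$label != "POSSIBLE" else rep(TRUE, n)
        pos <- if (pd == "ARDS_ONLY") lab$label == "ARDS" else
          lab$label != "NON_ARDS_AHRF"
        expect_equal(cm2$tp, sum(keep & pos & fl))
        expect_equal(cm2$fp, sum(keep & !pos & fl))
        expect_equal(cm2$fn, sum(keep & pos & !fl))
        expect_equal(cm2$tn, sum(keep & !pos & !fl))
      }
    }
  }
  expect_error(
    confusion(labels[1:10, ], data.frame(stay_id = "zz", flag = TRUE)),
    "without an adjudication label")
})

test_that("accuracy metrics match the printed-count worked example", {
  cm <- confusion2x2(tp = 756, fp = 451, fn = 237, tn = 428)
  m <- dx_metrics(cm)
  est <- setNames(m$estimate, m$metric)
  expect_equal(unname(est["sensitivity"]), 756 / 993, tolerance = 1e-12)
  expect_equal(round_half_up(100 * est[["sensitivity"]]), 76)
  expect_equal(unname(est["specificity"]), 428 / 879, tolerance = 1e-12)
  expect_equal(round(est[["specificity"]], 4), 0.4869)
  expect_true(all(m$ci_low <= m$estimate & m$estimate <= m$ci_high))
  # undefined margins stay undefined, not zero
  none <- dx_metrics(confusion2x2(tp = 0, fp = 0, fn = 3, tn = 5))
  expect_true(is.na(none$estimate[none$metric == "ppv"]))
  expect_false(is.na(none$estimate[none$metric == "npv"]))
})

test_that("Wilson intervals match the score-test oracle and its boundaries", {
  expect_equal(wilson_ci(0, 10)[["lower"]], 0)
  expect_equal(wilson_ci(10, 10)[["upper"]], 1)
  # frozen from the independent oracle prop.test(6, 100, correct = FALSE)
  expect_equal(unname(wilson_ci(6, 100)), c(0.027786, 0.124768),
               tolerance = 5e-6)
  set.seed(111)
  for (i in 1:20) {
    n <- sample(5:500, 1)
    x <- sample(0:n, 1)
    w <- wilson_ci(x, n)
    oracle <- stats::prop.test(x, n, correct = FALSE)$conf.int
    expect_equal(unname(w), as.numeric(oracle), tolerance = 1e-9)
    expect_true(w[["lower"]] <= x / n && x / n <= w[["upper"]])
    expect_true(w[["lower"]] >= 0 && w[["upper"]] <= 1)
  }
  expect_error(wilson_ci(1, 0), "n must be positive")
})

test_that("Clopper-Pearson intervals are exact and wider than Wilson", {
  expect_equal(clopper_pearson_ci(0, 10)[["lower"]], 0)
  expect_equal(clopper_pearson_ci(10, 10)[["upper"]], 1)
  set.seed(112)
  for (i in 1:20) {
    n <- sample(5:500, 1)
    x <- sample(0:n, 1)
    cp <- clopper_pearson_ci(x, n)
    oracle <- stats::binom.test(x, n)$conf.int
    expect_equal(unname(cp), as.numeric(oracle), tolerance = 1e-9)
  }
  cp <- clopper_pearson_ci(6, 100)
  w <- wilson_ci(6, 100)
  expect_lt(cp[["lower"]], w[["lower"]])
  expect_gt(cp[["upper"]], w[["upper"]])
})

test_that("both interval methods cover a known proportion at near-nominal rate", {
  set.seed(113)
  p <- 0.3; n <- 60; sims <- 1500
  x <- rbinom(sims, n, p)
  w <- vapply(x, function(xi) wilson_ci(xi, n), numeric(2))
  cp <- vapply(x, function(xi) clopper_pearson_ci(xi, n), numeric(2))
  cover_w <- mean(w[1, ] <= p & p <= w[2, ])
  cover_cp <- mean(cp[1, ] <= p & p <= cp[2, ])
  expect_gte(cover_cp, 0.95)         # exact method is conservative
  expect_gte(cover_w, 0.93)          # score interval is near-nominal
})

test_that("Cohen's kappa identities and brute-force oracle hold", {
  expect_equal(cohen_kappa(diag(c(10, 5, 8)))$kappa, 1)
  # independent margins (outer product) give kappa ~ 0
  m <- outer(c(0.5, 0.3, 0.2), c(0.4, 0.4, 0.2)) * 1000
  expect_equal(cohen_kappa(m)$kappa, 0, tolerance = 1e-12)
  tab <- matrix(c(40, 5, 0, 5, 20, 5, 0, 5, 20), 3, byrow = TRUE)
  k <- cohen_kappa(tab)
  expect_equal(k$p_o, 0.8)
  expect_equal(k$p_e, 0.355)
  expect_equal(k$kappa, 0.6899225, tolerance = 1e-6)
  # invariant under simultaneous permutation of categories
  perm <- c(3, 1, 2)
  expect_equal(cohen_kappa(tab[perm, perm])$kappa, k$kappa)
  expect_true(is.na(cohen_kappa(matrix(c(5, 0, 0, 0), 2))$kappa))
})

test_that("finite-population margins reproduce the design calculation", {
  expect_equal(fpc_margin(0.5, 2000, 3940), 0.0153784, tolerance = 1e-6)
  expect_equal(round_half_up(100 * fpc_margin(0.5, 2000, 3940), 1), 1.5)
  expect_equal(fpc_margin(0.5, 500, 500), 0)   # census
  big <- fpc_margin(0.5, 2000, 1e9)
  srs <- stats::qnorm(0.975) * sqrt(0.25 / 2000)
  expect_equal(big, srs, tolerance = 1e-4)
  expect_error(fpc_margin(0.5, 10, 5), "n <= N")
})

test_that("PPV gradients match direct proportions with intervals", {
  counts <- data.frame(window = c("H48", "H72"),
                       n_ards = c(21, 993), n_possible = c(5, 128),
                       n_non = c(74, 879))
  g <- ppv_gradient(counts)
  expect_equal(g$n_reviewed, c(100, 2000))
  expect_equal(g$ppv, c(0.21, 0.4965))
  expect_equal(g$ppv_with_possible[1], 0.26)
  expect_true(all(g$ci_low <= g$ppv & g$ppv <= g$ci_high))
  all_ards <- ppv_gradient(data.frame(window = "X", n_ards = 50,
                                      n_possible = 0, n_non = 0))
  expect_equal(all_ards$ppv, 1)
  # random tally oracle
  set.seed(121)
  for (i in 1:10) {
    k <- sample(1:50, 3, replace = TRUE)
    g2 <- ppv_gradient(data.frame(window = "W", n_ards = k[1],
                                  n_possible = k[2], n_non = k[3]))
    expect_equal(g2$ppv, k[1] / sum(k))
    expect_equal(g2$ppv_with_possible, (k[1] + k[2]) / sum(k))
  }
})

test_that("odds ratios follow the cross-product with Wald intervals", {
  or <- odds_ratio_2x2(276, 717, 304, 575)
  expect_equal(or$or, 0.7280885, tolerance = 1e-6)
  expect_false(or$corrected)
  expect_true(or$ci_low < or$or && or$or < or$ci_high)
  expect_equal(odds_ratio_2x2(10, 20, 5, 10)$or, 1)
  # swapping rows inverts the ratio
  a <- odds_ratio_2x2(7, 13, 4, 21)
  b <- odds_ratio_2x2(4, 21, 7, 13)
  expect_equal(a$or, 1 / b$or, tolerance = 1e-12)
  zero <- odds_ratio_2x2(0, 10, 5, 5)
  expect_true(zero$corrected)
  expect_gt(zero$or, 0)
})
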