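# Diagnostic-accuracy layer: confusion matrices against the 3-class
# adjudication label, proportion metrics with Wilson / Clopper-Pearson
# intervals, Cohen's kappa for three categories, finite-population margins
# of error, PPV gradients across persistence windows, and 2x2 odds ratios.

#' Build a 2x2 confusion matrix against 3-class adjudication
#'
#' The reference label has three categories (`ARDS`, `POSSIBLE`,
#' `NON_ARDS_AHRF`). The positive reference class is either definite ARDS
#' only or ARDS-or-possible; when it is definite ARDS only, `POSSIBLE` cases
#' are either excluded from the table (default) or counted as reference
#' negatives.
#'
#' @param labels data frame with `stay_id`, `label`.
#' @param flags data frame with `stay_id` and a logical `flag` column (or a
#'   named logical vector keyed by stay_id).
#' @param positive_definition `"ARDS_ONLY"` or `"ARDS_OR_POSSIBLE"`.
#' @param possible_handling `"EXCLUDE"` or `"AS_NEGATIVE"` (ignored when the
#'   positive definition already includes possible cases).
#' @return list of class `ards_confusion` with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(labels, flags,
                      positive_definition = c("ARDS_ONLY", "ARDS_OR_POSSIBLE"),
                      possible_handling = c("EXCLUDE", "AS_NEGATIVE")) {
  positive_definition <- match.arg(positive_definition)
  possible_handling <- match.arg(toupper(possible_handling),
                                 c("EXCLUDE", "AS_NEGATIVE"))
  if (is.data.frame(flags)) {
    fl <- stats::setNames(as.logical(flags$flag), flags$stay_id)
  } else {
    fl <- as.logical(flags)
    names(fl) <- names(flags)
  }
  missing_lab <- setdiff(names(fl), labels$stay_id)
  if (length(missing_lab)) {
    stopf("flagged stay(s) without an adjudication label: %s",
          paste(utils::head(missing_lab, 10), collapse = ", "))
  }
  lab <- stats::setNames(labels$label, labels$stay_id)[names(fl)]
  if (positive_definition == "ARDS_ONLY" && possible_handling == "EXCLUDE") {
    keep <- lab != "POSSIBLE"
    lab <- lab[keep]; fl <- fl[keep]
  }
  pos <- if (positive_definition == "ARDS_ONLY") lab == "ARDS" else
    lab %in% c("ARDS", "POSSIBLE")
  structure(list(tp = sum(pos & fl), fp = sum(!pos & fl),
                 fn = sum(pos & !fl), tn = sum(!pos & !fl)),
            class = "ards_confusion")
}

#' Construct a confusion matrix from counts
#' @param tp,fp,fn,tn non-negative cell counts.
#' @return `ards_confusion` object.
#' @export
confusion2x2 <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != round(cells)))
    stopf("confusion cells must be non-negative integers")
  if (sum(cells) == 0) stopf("confusion matrix total must be positive")
  structure(as.list(cells), class = "ards_confusion")
}

#' @export
print.ards_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("flag+", "flag-"), c("ref+", "ref-")))
  print(m)
  invisible(x)
}

#' Wilson score interval for a binomial proportion
#'
#' @param x number of successes (0 <= x <= n).
#' @param n number of trials (> 0).
#' @param conf confidence level (default 0.95).
#' @return numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' wilson_ci(6, 100)
wilson_ci <- function(x, n, conf = 0.95) {
  if (n <= 0) stopf("wilson_ci: n must be positive")
  if (x < 0 || x > n) stopf("wilson_ci: x must lie in [0, n]")
  z <- stats::qnorm((1 + conf) / 2)
  centre <- (x + z^2 / 2) / (n + z^2)
  half <- z / (n + z^2) * sqrt(x * (n - x) / n + z^2 / 4)
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Clopper-Pearson (exact) interval for a binomial proportion
#'
#' @inheritParams wilson_ci
#' @return numeric vector `c(lower, upper)`.
#' @export
clopper_pearson_ci <- function(x, n, conf = 0.95) {
  if (n <= 0) stopf("clopper_pearson_ci: n must be positive")
  if (x < 0 || x > n) stopf("clopper_pearson_ci: x must lie in [0, n]")
  a <- 1 - conf
  lower <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

.prop_ci <- function(x, n, conf, method) {
  if (method == "clopper-pearson") clopper_pearson_ci(x, n, conf)
  else wilson_ci(x, n, conf)
}

#' Diagnostic accuracy metrics from a 2x2 confusion matrix
#'
#' Sensitivity, specificity, PPV, NPV and accuracy, each with a binomial
#' confidence interval. A metric whose margin is zero is reported as `NA`
#' (undefined), not 0.
#'
#' @param c an `ards_confusion`.
#' @param ci_method `"wilson"` (default) or `"clopper-pearson"`.
#' @param conf confidence level.
#' @return data frame with `metric`, `x`, `n`, `estimate`, `ci_low`,
#'   `ci_high`.
#' @export
dx_metrics <- function(c, ci_method = c("wilson", "clopper-pearson"),
                       conf = 0.95) {
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(c, "ards_confusion"))
  defs <- list(
    sensitivity = c(c$tp, c$tp + c$fn),
    specificity = c(c$tn, c$tn + c$fp),
    ppv = c(c$tp, c$tp + c$fp),
    npv = c(c$tn, c$tn + c$fn),
    accuracy = c(c$tp + c$tn, c$tp + c$fp + c$fn + c$tn))
  rows <- lapply(names(defs), function(m) {
    x <- defs[[m]][1]; n <- defs[[m]][2]
    if (n == 0) {
      data.frame(metric = m, x = NA_integer_, n = 0L, estimate = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_)
    } else {
      ci <- .prop_ci(x, n, conf, ci_method)
      data.frame(metric = m, x = x, n = n, estimate = x / n,
                 ci_low = ci[[1]], ci_high = ci[[2]])
    }
  })
  do.call(rbind, rows)
}

#' Cohen's kappa for a k x k agreement table
#'
#' Observed agreement is the diagonal proportion; expected agreement is the
#' sum of products of matching row and column margins. Designed for the
#' 3-category adjudication labels but valid for any square table.
#'
#' @param table square matrix of agreement counts (rater 1 in rows).
#' @return list with `p_o`, `p_e`, `kappa` (kappa is `NA` when `p_e = 1`).
#' @export
#' @examples
#' cohen_kappa(matrix(c(40, 5, 0, 5, 20, 5, 0, 5, 20), 3, byrow = TRUE))
cohen_kappa <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != ncol(table)) stopf("agreement table must be square")
  total <- sum(table)
  if (total <= 0) stopf("agreement table total must be positive")
  p_o <- sum(diag(table)) / total
  p_e <- sum(rowSums(table) * colSums(table)) / total^2
  kappa <- if (p_e >= 1) NA_real_ else (p_o - p_e) / (1 - p_e)
  list(p_o = p_o, p_e = p_e, kappa = kappa)
}

#' Margin of error with finite-population correction
#'
#' Half-width of the normal-approximation interval for a proportion
#' estimated from a sample of `n` drawn without replacement from a
#' population of `N`: `z * sqrt(p(1-p)/n) * sqrt((N-n)/(N-1))`.
#'
#' @param p assumed proportion.
#' @param n sample size.
#' @param N population size (`n <= N`).
#' @param conf confidence level.
#' @return numeric half-width on the proportion scale.
#' @export
#' @examples
#' fpc_margin(0.5, 2000, 3940)  # ~0.0154, i.e. +/- 1.5%
fpc_margin <- function(p, n, N, conf = 0.95) {
  if (n <= 0 || n > N) stopf("fpc_margin: need 0 < n <= N")
  if (p < 0 || p > 1) stopf("fpc_margin: p must be in [0, 1]")
  z <- stats::qnorm((1 + conf) / 2)
  fpc <- if (N == 1) 0 else sqrt((N - n) / (N - 1))
  z * sqrt(p * (1 - p) / n) * fpc
}

#' PPV gradient across persistence windows
#'
#' For each reviewed screen window, the diagnostic yield: the proportion of
#' reviewed cases adjudicated definite ARDS (`ppv`) and definite-or-possible
#' (`ppv_with_possible`), with binomial intervals.
#'
#' @param counts data frame with columns `window`, `n_ards`, `n_possible`,
#'   `n_non` (one row per screen window; `n_reviewed` is their sum).
#' @param ci_method,conf interval settings, as in [dx_metrics()].
#' @return data frame with per-window counts, `ppv`, `ci_low`, `ci_high`,
#'   `ppv_with_possible`, `ci_low_wp`, `ci_high_wp`.
#' @export
ppv_gradient <- function(counts, ci_method = c("wilson", "clopper-pearson"),
                         conf = 0.95) {
  ci_method <- match.arg(ci_method)
  need <- c("window", "n_ards", "n_possible", "n_non")
  missing <- setdiff(need, names(counts))
  if (length(missing)) stopf("ppv_gradient: missing column(s): %s",
                             paste(missing, collapse = ", "))
  n_rev <- counts$n_ards + counts$n_possible + counts$n_non
  out <- data.frame(window = counts$window, n_reviewed = n_rev,
                    n_ards = counts$n_ards, n_possible = counts$n_possible,
                    n_non = counts$n_non, stringsAsFactors = FALSE)
  ci <- t(mapply(function(x, n) .prop_ci(x, n, conf, ci_method),
                 counts$n_ards, n_rev))
  ci_wp <- t(mapply(function(x, n) .prop_ci(x, n, conf, ci_method),
                    counts$n_ards + counts$n_possible, n_rev))
  out$ppv <- counts$n_ards / n_rev
  out$ci_low <- ci[, 1]; out$ci_high <- ci[, 2]
  out$ppv_with_possible <- (counts$n_ards + counts$n_possible) / n_rev
  out$ci_low_wp <- ci_wp[, 1]; out$ci_high_wp <- ci_wp[, 2]
  out
}

#' Tally adjudication labels within nested screen cohorts
#'
#' Convenience bridge from [screen_cohort()] output plus labels to the
#' count table [ppv_gradient()] expects, over the four nested windows.
#'
#' @param screen result of [screen_cohort()].
#' @param labels data frame with `stay_id`, `label`.
#' @return data frame with one row per window (`ANYTIME`, `H24`, `H48`,
#'   `H72`) and columns `n_ards`, `n_possible`, `n_non`.
#' @export
gradient_counts <- function(screen, labels) {
  lab <- stats::setNames(labels$label, labels$stay_id)[screen$stay_id]
  lev <- match(screen$persistence_class, .PERSIST_LEVELS)
  one <- function(min_lev, name) {
    l <- lab[lev >= min_lev & !is.na(lab)]
    data.frame(window = name, n_ards = sum(l == "ARDS"),
               n_possible = sum(l == "POSSIBLE"),
               n_non = sum(l == "NON_ARDS_AHRF"), stringsAsFactors = FALSE)
  }
  rbind(one(1, "ANYTIME"), one(2, "H24"), one(3, "H48"), one(4, "H72"))
}

#' Odds ratio for a 2x2 table with Wald interval
#'
#' `OR = (a d) / (b c)` with a log-scale Wald confidence interval. When any
#' cell is zero the Haldane-Anscombe correction (add 0.5 to every cell) is
#' applied and flagged.
#'
#' @param a,b,c,d cell counts (`a`/`b` exposed outcome yes/no, `c`/`d`
#'   unexposed).
#' @param conf confidence level.
#' @return list with `or`, `ci_low`, `ci_high`, `corrected`.
#' @export
#' @examples
#' odds_ratio_2x2(276, 717, 304, 575)  # ~0.728
odds_ratio_2x2 <- function(a, b, c, d, conf = 0.95) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stopf("odds_ratio_2x2: cells must be non-negative")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm((1 + conf) / 2)
  list(or = or, ci_low = exp(log(or) - z * se), ci_high = exp(log(or) + z * se),
       corrected = corrected)
}
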