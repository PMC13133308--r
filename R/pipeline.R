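# End-to-end drivers tying harmonisation, screening, enrichment and
# evaluation together. These are the programmatic entry points the analysis
# scripts under analysis/ call; every stage logs its input/output row counts
# in inclusion-cascade style via message() (suppressible).

.log_stage <- function(fmt, ...) message(sprintf(fmt, ...))

#' Screen a bundle and summarise the persistence cascade
#'
#' @param bundle an `ards_cohort`.
#' @param config an [ards_config()] or override list.
#' @param quiet suppress stage logging.
#' @return list with `screen` (per-subject results) and `cascade` (nested
#'   subject counts).
#' @export
screen_summary <- function(bundle, config = ards_config(), quiet = FALSE) {
  cfg <- ards_config(config)
  if (!quiet) .log_stage("screen: %d stays, %d events in",
                         nrow(bundle$stays), nrow(bundle$events))
  screen <- screen_cohort(bundle, cfg)
  casc <- cascade_counts(screen)
  if (!quiet) .log_stage("screen: %d screen-positive subjects (H72: %d)",
                         nrow(screen), casc$n_subjects[casc$cohort == "H72"])
  list(screen = screen, cascade = casc)
}

#' Evaluate enrichment signals against adjudication labels
#'
#' Computes keyword (0--48 h window) and ICD confusion matrices and accuracy
#' metrics against the adjudicated label, restricted to subjects meeting
#' the configured persistence window (the paper-style design evaluates
#' enrichment within the 72-h screen-positive cohort).
#'
#' @param bundle an `ards_cohort` with a non-empty `labels` table.
#' @param screen optional precomputed [screen_cohort()] result.
#' @param ruleset keyword rule-set (default shipped `T3`).
#' @param codeset ICD code-set (default [default_codeset()]).
#' @param config an [ards_config()]; `window` selects the evaluation cohort
#'   and `possible_handling`/`ci_method` govern the 2x2 layer.
#' @param quiet suppress stage logging.
#' @return list with `flags`, `icd` and `keyword` elements, each holding
#'   the confusion matrix and a [dx_metrics()] table; plus `n_evaluated`.
#' @export
evaluate_enrichment <- function(bundle, screen = NULL,
                                ruleset = default_rulesets()$T3,
                                codeset = default_codeset(),
                                config = ards_config(), quiet = FALSE) {
  cfg <- ards_config(config)
  if (nrow(bundle$labels) == 0) {
    stopf("labels required: the bundle has no adjudication labels")
  }
  if (is.null(screen)) screen <- screen_cohort(bundle, cfg)
  members <- cohort_members(screen, cfg$window)
  sub <- screen[screen$subject_id %in% members, , drop = FALSE]
  flags <- enrich_cohort(bundle, sub, ruleset = ruleset, codeset = codeset)
  labelled <- flags$stay_id %in% bundle$labels$stay_id
  if (!quiet) {
    .log_stage("enrich: %d subjects in %s-h cohort, %d labelled",
               nrow(sub), as.character(cfg$window), sum(labelled))
  }
  flags <- flags[labelled, , drop = FALSE]
  ph <- toupper(cfg$possible_handling)
  mk <- function(col) {
    cm <- confusion(bundle$labels,
                    data.frame(stay_id = flags$stay_id, flag = flags[[col]],
                               stringsAsFactors = FALSE),
                    positive_definition = "ARDS_ONLY",
                    possible_handling = ph)
    list(confusion = cm, metrics = dx_metrics(cm, ci_method = cfg$ci_method,
                                              conf = cfg$conf_level))
  }
  list(flags = flags, icd = mk("icd_hit"), keyword = mk("keyword_hit_48h"),
       n_evaluated = nrow(flags))
}

#' Diagnostic-yield table across persistence windows
#'
#' A report-style summary: for each nested screen window, the adjudicated
#' composition and the PPV (definite ARDS) and PPV-with-possible, with
#' binomial intervals.
#'
#' @param bundle an `ards_cohort` with labels.
#' @param screen optional precomputed screen result.
#' @param config an [ards_config()].
#' @return a [ppv_gradient()] data frame.
#' @export
yield_table <- function(bundle, screen = NULL, config = ards_config()) {
  cfg <- ards_config(config)
  if (nrow(bundle$labels) == 0) {
    stopf("labels required: the bundle has no adjudication labels")
  }
  if (is.null(screen)) screen <- screen_cohort(bundle, cfg)
  ppv_gradient(gradient_counts(screen, bundle$labels),
               ci_method = cfg$ci_method, conf = cfg$conf_level)
}

#' Run the full synthetic-study pipeline
#'
#' simulate -> harmonise/screen -> enrich -> evaluate, returning everything
#' the analysis scripts and acceptance checks consume.
#'
#' @param synth a [synth_config()] (default: [default_calibration()]).
#' @param config an [ards_config()].
#' @param quiet suppress stage logging.
#' @return list with `bundle`, `screen`, `cascade`, `yield`, `enrichment`.
#' @export
run_study <- function(synth = default_calibration(), config = ards_config(),
                      quiet = FALSE) {
  cfg <- ards_config(config)
  if (!quiet) .log_stage("simulate: n_subjects = %d, seed = %d",
                         synth$n_subjects, synth$seed)
  bundle <- simulate_cohort(synth)
  sc <- screen_summary(bundle, cfg, quiet = quiet)
  enr <- evaluate_enrichment(bundle, screen = sc$screen, config = cfg,
                             quiet = quiet)
  list(bundle = bundle, screen = sc$screen, cascade = sc$cascade,
       yield = yield_table(bundle, sc$screen, cfg), enrichment = enr)
}
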