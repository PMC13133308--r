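# Radiology keyword rule-sets and ICD code-sets as case-finding signals.
#
# Rule language: case-insensitive substring patterns on word stems combined
# with AND / OR / NOT and parentheses; quoted strings allow multi-word
# patterns ("ground glass"). Precedence NOT > AND > OR. Negation masking: a
# pattern occurrence preceded by a negation cue within the same sentence
# (sentences split on . ; :) does not count.

.DEFAULT_NEGATION_CUES <- c("no ", "not ", "without ", "never ",
                            "absence of", "free of", "resolved", "clearing")

# --- tokenizer -------------------------------------------------------------

.tokenize_rule <- function(s) {
  toks <- list()
  i <- 1L
  n <- nchar(s)
  push <- function(type, value, pos) {
    toks[[length(toks) + 1L]] <<- list(type = type, value = value, pos = pos)
  }
  while (i <= n) {
    ch <- substr(s, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "(") { push("lparen", "(", i); i <- i + 1L; next }
    if (ch == ")") { push("rparen", ")", i); i <- i + 1L; next }
    if (ch == "\"") {
      j <- regexpr("\"", substr(s, i + 1L, n), fixed = TRUE)
      if (j < 0) stopf("rule parse error at position %d: unterminated quote", i)
      term <- substr(s, i + 1L, i + j - 1L)
      if (!nzchar(trimws(term)))
        stopf("rule parse error at position %d: empty term", i)
      push("term", tolower(term), i)
      i <- i + j + 1L
      next
    }
    m <- regmatches(substr(s, i, n),
                    regexpr("^[^[:space:]()\"]+", substr(s, i, n)))
    word <- m[1]
    up <- toupper(word)
    if (up %in% c("AND", "OR", "NOT", "&", "|", "!")) {
      push(switch(up, "AND" = "and", "&" = "and", "OR" = "or", "|" = "or",
                  "NOT" = "not", "!" = "not"), up, i)
    } else {
      push("term", tolower(word), i)
    }
    i <- i + nchar(word)
  }
  toks
}

# --- recursive-descent parser ---------------------------------------------

.parse_rule <- function(s) {
  toks <- .tokenize_rule(s)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  err <- function(msg, tok = peek()) {
    at <- if (is.null(tok)) nchar(s) + 1L else tok$pos
    stopf("rule parse error at position %d: %s", at, msg)
  }
  parse_or <- function() {
    args <- list(parse_and())
    while (!is.null(peek()) && peek()$type == "or") {
      take()
      args[[length(args) + 1L]] <- parse_and()
    }
    if (length(args) == 1) args[[1]] else .flatten("or", args)
  }
  parse_and <- function() {
    args <- list(parse_not())
    while (!is.null(peek()) && peek()$type == "and") {
      take()
      args[[length(args) + 1L]] <- parse_not()
    }
    if (length(args) == 1) args[[1]] else .flatten("and", args)
  }
  parse_not <- function() {
    if (!is.null(peek()) && peek()$type == "not") {
      take()
      list(op = "not", arg = parse_not())
    } else parse_primary()
  }
  parse_primary <- function() {
    tok <- peek()
    if (is.null(tok)) err("unexpected end of rule")
    if (tok$type == "lparen") {
      take()
      e <- parse_or()
      if (is.null(peek()) || peek()$type != "rparen")
        err("unbalanced parentheses: expected ')'")
      take()
      return(e)
    }
    if (tok$type == "term") { take(); return(list(op = "term", pattern = tok$value)) }
    err(sprintf("unexpected token '%s'", tok$value), tok)
  }
  if (length(toks) == 0) stopf("rule parse error at position 1: empty rule")
  e <- parse_or()
  if (!is.null(peek())) err(sprintf("unexpected token '%s' after expression",
                                    peek()$value))
  e
}

# Flatten nested AND/OR chains into a stable n-ary normal form.
.flatten <- function(op, args) {
  out <- list()
  for (a in args) {
    if (is.list(a) && identical(a$op, op)) out <- c(out, a$args)
    else out[[length(out) + 1L]] <- a
  }
  list(op = op, args = out)
}

# Does the expression contain at least one positive (non-negated) term?
.has_positive_term <- function(node, negated = FALSE) {
  switch(node$op,
    term = !negated,
    not = .has_positive_term(node$arg, !negated),
    any(vapply(node$args, .has_positive_term, logical(1), negated = negated)))
}

.serialize_expr <- function(node, parent = "or") {
  if (node$op == "term") {
    p <- node$pattern
    return(if (grepl("[[:space:]()\"]", p)) sprintf("\"%s\"", p) else p)
  }
  if (node$op == "not") {
    inner <- .serialize_expr(node$arg, parent = "not")
    arg_is_term <- identical(node$arg$op, "term")
    return(paste0("NOT ", if (arg_is_term) inner else paste0("(", inner, ")")))
  }
  sep <- if (node$op == "and") " AND " else " OR "
  s <- paste(vapply(node$args, .serialize_expr, character(1),
                    parent = node$op), collapse = sep)
  needs_paren <- (node$op == "or" && parent %in% c("and", "not")) ||
    (node$op == "and" && parent == "not")
  if (needs_paren) paste0("(", s, ")") else s
}

#' Compile a keyword rule-set
#'
#' Parses a Boolean rule over text patterns into a stable expression tree.
#' The rule must contain at least one positive (non-negated) term.
#'
#' @param spec rule string, e.g. `"bilateral AND (infiltrat OR opacit)"`.
#' @param id optional identifier (e.g. `"T3"`).
#' @param negation_cues patterns that mask a subsequent term occurrence in
#'   the same sentence; `character(0)` disables masking.
#' @return object of class `ards_ruleset` with elements `id`, `expr`,
#'   `negation_cues`.
#' @export
#' @examples
#' r <- compile_ruleset("bilateral AND (infiltrat OR opacit)", id = "demo")
#' format(r)
compile_ruleset <- function(spec, id = NULL,
                            negation_cues = .DEFAULT_NEGATION_CUES) {
  stopifnot(is.character(spec), length(spec) == 1)
  expr <- .parse_rule(spec)
  if (!.has_positive_term(expr)) {
    stopf("invalid rule: no positive (non-negated) term")
  }
  structure(list(id = id %||% NA_character_, expr = expr,
                 negation_cues = tolower(negation_cues)),
            class = "ards_ruleset")
}

#' @export
format.ards_ruleset <- function(x, ...) .serialize_expr(x$expr)

#' @export
print.ards_ruleset <- function(x, ...) {
  cat(sprintf("<ards_ruleset %s> %s\n",
              if (is.na(x$id)) "" else x$id, format(x)))
  invisible(x)
}

#' Patterns referenced by a rule-set
#' @param rule an `ards_ruleset`.
#' @return character vector of unique term patterns.
#' @export
rule_patterns <- function(rule) {
  collect <- function(node) {
    switch(node$op,
      term = node$pattern,
      not = collect(node$arg),
      unlist(lapply(node$args, collect)))
  }
  unique(collect(rule$expr))
}

# --- application -----------------------------------------------------------

# For each text, which of `patterns` has an unmasked occurrence? Returns a
# logical matrix [length(texts) x length(patterns)]. Masking: within each
# sentence, occurrences at/after the earliest negation cue do not count.
.term_hit_matrix <- function(texts, patterns, negation_cues) {
  n <- length(texts)
  hit <- matrix(FALSE, n, length(patterns),
                dimnames = list(NULL, patterns))
  if (n == 0 || length(patterns) == 0) return(hit)
  sent <- strsplit(tolower(texts), "[.;:]")
  sidx <- rep(seq_len(n), lengths(sent))
  sent <- unlist(sent)
  if (length(sent) == 0) return(hit)
  cue_min <- rep(Inf, length(sent))
  for (cue in negation_cues) {
    p <- regexpr(cue, sent, fixed = TRUE)
    ok <- p > 0
    cue_min[ok] <- pmin(cue_min[ok], p[ok])
  }
  for (j in seq_along(patterns)) {
    p <- regexpr(patterns[j], sent, fixed = TRUE)
    active <- p > 0 & p < cue_min
    if (any(active)) {
      hit[unique(sidx[active]), j] <- TRUE
    }
  }
  hit
}

.eval_expr <- function(node, present) {
  switch(node$op,
    term = isTRUE(unname(present[node$pattern])),
    not = !.eval_expr(node$arg, present),
    and = all(vapply(node$args, .eval_expr, logical(1), present = present)),
    or = any(vapply(node$args, .eval_expr, logical(1), present = present)))
}

# Logical vector: does each text satisfy the rule?
.texts_match_rule <- function(rule, texts) {
  pats <- rule_patterns(rule)
  hit <- .term_hit_matrix(texts, pats, rule$negation_cues)
  apply(hit, 1, function(row) .eval_expr(rule$expr, row))
}

#' Apply a keyword rule-set to a stay's radiology reports
#'
#' Returns `TRUE` iff any report inside the chosen time window satisfies the
#' rule after negation masking. Window `H0_48` restricts to reports with
#' time in `[onset, onset + 48 h)`; window `ANY` uses every report of the
#' stay.
#'
#' @param rule an `ards_ruleset` from [compile_ruleset()].
#' @param reports data frame with `time` (POSIXct) and `text` for one stay.
#' @param onset episode onset (POSIXct); required for `H0_48`.
#' @param window `"H0_48"` or `"ANY"`.
#' @return logical scalar.
#' @export
apply_ruleset <- function(rule, reports, onset = NULL,
                          window = c("H0_48", "ANY")) {
  window <- match.arg(window)
  stopifnot(inherits(rule, "ards_ruleset"))
  if (nrow(reports) == 0) return(FALSE)
  if (window == "H0_48") {
    if (is.null(onset) || is.na(onset)) return(FALSE)
    rel <- hours_between(onset, reports$time)
    reports <- reports[!is.na(rel) & rel >= 0 & rel < 48, , drop = FALSE]
    if (nrow(reports) == 0) return(FALSE)
  }
  any(.texts_match_rule(rule, reports$text))
}

#' Match a stay's ICD records against a code-set
#'
#' Codes are compared in canonical form (dot-free, uppercase). A code-set
#' entry ending in `*` is a prefix wildcard (`"J9600*"` matches `J96001`).
#'
#' @param records data frame with a `code` column (one stay's ICD records),
#'   or a character vector of codes.
#' @param codeset character vector of canonical codes / prefix patterns.
#' @return logical scalar: any record matches.
#' @export
match_icd <- function(records, codeset = default_codeset()) {
  codes <- if (is.data.frame(records)) records$code else records
  if (length(codes) == 0) return(FALSE)
  codes <- canonicalize_icd(codes)
  wild <- grepl("\\*$", codeset)
  exact <- canonicalize_icd(codeset[!wild])
  prefixes <- canonicalize_icd(sub("\\*$", "", codeset[wild]))
  if (any(codes %in% exact)) return(TRUE)
  for (p in prefixes) if (any(startsWith(codes, p))) return(TRUE)
  FALSE
}

#' Illustrative keyword rule-sets of strictly increasing breadth
#'
#' Six rule-sets `T1` (narrowest) to `T6` (broadest), each widening its
#' predecessor by OR-ing additional clauses, so the set of keyword-positive
#' stays is monotone non-decreasing from `T1` to `T6`. These are
#' illustrative defaults for radiographic ARDS language, not a published
#' list; supply your own rules via [compile_ruleset()] to reproduce a
#' specific instrument.
#'
#' @return named list of `ards_ruleset` objects.
#' @export
default_rulesets <- function() {
  specs <- c(
    T1 = "ards",
    T2 = "ards OR (bilateral AND infiltrat)",
    T3 = "ards OR (bilateral AND (infiltrat OR opacit))",
    T4 = "ards OR (bilateral AND (infiltrat OR opacit OR consolidat))",
    T5 = paste("ards OR (bilateral AND (infiltrat OR opacit OR consolidat))",
               "OR (diffuse AND (opacit OR \"ground glass\"))"),
    T6 = paste("ards OR (bilateral AND (infiltrat OR opacit OR consolidat))",
               "OR (diffuse AND (opacit OR \"ground glass\"))",
               "OR infiltrat OR opacit OR \"airspace disease\" OR oedema OR edema"))
  out <- lapply(names(specs), function(id) compile_ruleset(specs[[id]], id = id))
  names(out) <- names(specs)
  out
}

#' Illustrative ARDS-related ICD code-set
#'
#' Contains J80 (ARDS, ICD-10), 51882 (other pulmonary insufficiency,
#' ICD-9), 5185 (post-trauma pulmonary insufficiency, ICD-9) and the
#' J9600 prefix (acute respiratory failure, ICD-10). Illustrative default,
#' not a published list.
#'
#' @return character vector of canonical codes / prefix patterns.
#' @export
default_codeset <- function() c("J80", "51882", "5185", "J9600*")

#' Keyword and ICD enrichment flags for a screened cohort
#'
#' Applies one keyword rule-set (in both the 0--48 h-from-onset and any-time
#' windows) and an ICD code-set to every screened stay.
#'
#' @param bundle an `ards_cohort`.
#' @param screen result of [screen_cohort()] on `bundle`.
#' @param ruleset an `ards_ruleset` (default: the shipped `T3`).
#' @param codeset character vector of codes / prefix patterns.
#' @return data frame with `stay_id`, `subject_id`, `keyword_hit_48h`,
#'   `keyword_hit_any`, `icd_hit`.
#' @export
enrich_cohort <- function(bundle, screen, ruleset = default_rulesets()$T3,
                          codeset = default_codeset()) {
  stopifnot(inherits(bundle, "ards_cohort"))
  rep_df <- bundle$reports
  match_flag <- if (nrow(rep_df)) .texts_match_rule(ruleset, rep_df$text) else logical(0)
  rep_t <- as.numeric(rep_df$time)
  rep_by_stay <- split(seq_len(nrow(rep_df)), factor(rep_df$stay_id,
                                                     levels = screen$stay_id))
  icd_match <- if (nrow(bundle$icd)) {
    per_code <- vapply(bundle$icd$code, function(cc) match_icd(cc, codeset),
                       logical(1), USE.NAMES = FALSE)
    tapply(per_code, factor(bundle$icd$stay_id, levels = screen$stay_id), any)
  } else {
    stats::setNames(rep(NA, length(screen$stay_id)), screen$stay_id)
  }
  n <- nrow(screen)
  k48 <- logical(n); kany <- logical(n)
  onset_s <- as.numeric(screen$onset)
  for (i in seq_len(n)) {
    idx <- rep_by_stay[[screen$stay_id[i]]]
    if (length(idx) == 0) next
    kany[i] <- any(match_flag[idx])
    if (!is.na(onset_s[i]) && kany[i]) {
      rel <- (rep_t[idx] - onset_s[i]) / 3600
      k48[i] <- any(match_flag[idx] & rel >= 0 & rel < 48)
    }
  }
  ih <- icd_match[screen$stay_id]
  data.frame(stay_id = screen$stay_id, subject_id = screen$subject_id,
             keyword_hit_48h = k48, keyword_hit_any = kany,
             icd_hit = !is.na(ih) & ih, stringsAsFactors = FALSE)
}
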