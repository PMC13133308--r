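# Run configuration. Every threshold the screen uses is configuration with
# the Berlin-criteria defaults, so sensitivity analyses (24/48/72-h windows,
# alternative pairing tolerances) are parameter changes, not code changes.

.CONFIG_DEFAULTS <- list(
  pf_threshold = 300,          # mm Hg, qualifying mean P/F must be below
  peep_threshold = 5,          # cm H2O, paired PEEP must be at or above
  pairing_tolerance_h = 2,     # PEEP pairing tolerance (hours)
  carry_forward_windows = 0,   # bridge empty windows with the last mean
  window = 72,                 # persistence requirement: "anytime", 24, 48, 72
  ci_method = "wilson",        # wilson | clopper-pearson
  possible_handling = "exclude", # exclude | as_negative (2x2 POSSIBLE rule)
  conf_level = 0.95
)

#' Build and validate a run configuration
#'
#' Unspecified elements take the Berlin-criteria defaults (P/F < 300 mm Hg,
#' PEEP >= 5 cm H2O, 2-h pairing tolerance, 72-h persistence window).
#'
#' @param config named list of overrides, or an existing config.
#' @param ... individual overrides (take precedence over `config`).
#' @return validated named list of class `ards_config`.
#' @export
#' @examples
#' ards_config(window = 48)$window
ards_config <- function(config = list(), ...) {
  if (inherits(config, "ards_config") && !length(list(...))) return(config)
  over <- utils::modifyList(as.list(config), list(...))
  unknown <- setdiff(names(over), names(.CONFIG_DEFAULTS))
  if (length(unknown)) {
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(.CONFIG_DEFAULTS, over)
  if (!is.numeric(cfg$pf_threshold) || cfg$pf_threshold <= 0)
    stopf("config: pf_threshold must be positive")
  if (!is.numeric(cfg$peep_threshold) || cfg$peep_threshold <= 0)
    stopf("config: peep_threshold must be positive")
  if (!is.numeric(cfg$pairing_tolerance_h) || cfg$pairing_tolerance_h <= 0)
    stopf("config: pairing_tolerance_h must be positive")
  if (!(identical(cfg$window, "anytime") || cfg$window %in% c(24, 48, 72)))
    stopf("config: window must be 'anytime', 24, 48 or 72")
  if (!(cfg$ci_method %in% c("wilson", "clopper-pearson")))
    stopf("config: ci_method must be 'wilson' or 'clopper-pearson'")
  if (!(cfg$possible_handling %in% c("exclude", "as_negative")))
    stopf("config: possible_handling must be 'exclude' or 'as_negative'")
  if (!is.numeric(cfg$conf_level) || cfg$conf_level <= 0 || cfg$conf_level >= 1)
    stopf("config: conf_level must be in (0, 1)")
  structure(cfg, class = "ards_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose top-level keys are [ards_config()] fields.
#' @return validated `ards_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  ards_config(yaml::read_yaml(path))
}
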