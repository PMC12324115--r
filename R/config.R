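#' Analysis configuration: the rule thresholds of the six-state model
#'
#' Bundles every tunable threshold used by episode building and state
#' classification.  Defaults encode the rule set of the trajectory model:
#' "a month" is 30 days, "three months" is 90 days, a "week" is a 7-day
#' window, and short HD inter-session gaps are bridged up to 7 days.
#'
#' @param mixed_max_days an episode belongs to a mixed (unstable) run only
#'   if its duration is strictly below this many days; default 30.
#' @param mixed_min_run minimum number of alternating PD/HD episodes that
#'   constitute a mixed run; default 3 (i.e. at least two switches).
#' @param hybrid_min_days minimum total span, in days, of sustained weekly
#'   PD+HD co-occurrence to call the regime hybrid; default 90.
#' @param hybrid_week_len length, in days, of the tiled windows used to test
#'   weekly co-occurrence; default 7.
#' @param hd_gap_tolerance maximum gap, in days, between two HD sessions
#'   that is still bridged into one HD-covered stretch; default 7 (covers
#'   thrice- and twice-weekly schedules).
#' @param sankey_max_states number of leading states kept in the Sankey
#'   graph; default 4.
#' @param registry_min_days ascending vector of minimum-duration thresholds
#'   (days) used by registry-style transition definitions; default
#'   `c(30, 60, 90, 180)`.
#' @return an object of class `traj_config` (a validated list).
#' @seealso [classify_states()], [compare_transition_definitions()]
#' @export
analysis_config <- function(mixed_max_days = 30,
                            mixed_min_run = 3,
                            hybrid_min_days = 90,
                            hybrid_week_len = 7,
                            hd_gap_tolerance = 7,
                            sankey_max_states = 4,
                            registry_min_days = c(30, 60, 90, 180)) {
  cfg <- list(
    mixed_max_days = mixed_max_days,
    mixed_min_run = mixed_min_run,
    hybrid_min_days = hybrid_min_days,
    hybrid_week_len = hybrid_week_len,
    hd_gap_tolerance = hd_gap_tolerance,
    sankey_max_states = sankey_max_states,
    registry_min_days = registry_min_days
  )
  for (nm in c("mixed_max_days", "mixed_min_run", "hybrid_min_days",
               "hybrid_week_len", "sankey_max_states")) {
    if (!is_count(cfg[[nm]])) abort("`%s` must be a single positive integer", nm)
  }
  if (cfg$mixed_min_run < 2) abort("`mixed_min_run` must be at least 2")
  if (cfg$sankey_max_states < 2) abort("`sankey_max_states` must be at least 2")
  if (!is.numeric(cfg$hd_gap_tolerance) || length(cfg$hd_gap_tolerance) != 1L ||
      cfg$hd_gap_tolerance < 0) {
    abort("`hd_gap_tolerance` must be a single non-negative number")
  }
  if (!is.numeric(cfg$registry_min_days) || length(cfg$registry_min_days) == 0L ||
      any(cfg$registry_min_days <= 0) || is.unsorted(cfg$registry_min_days)) {
    abort("`registry_min_days` must be positive and sorted ascending")
  }
  structure(cfg, class = "traj_config")
}

#' @export
print.traj_config <- function(x, ...) {
  cat("Six-state trajectory rule configuration\n")
  cat(sprintf("  mixed:  episodes < %d days, runs of >= %d alternating PD/HD episodes\n",
              x$mixed_max_days, x$mixed_min_run))
  cat(sprintf("  hybrid: weekly (%d-day window) PD+HD co-occurrence over >= %d days\n",
              x$hybrid_week_len, x$hybrid_min_days))
  cat(sprintf("  HD gap tolerance: %s days; Sankey depth: %d states\n",
              format(x$hd_gap_tolerance), x$sankey_max_states))
  cat(sprintf("  registry transition thresholds: %s days\n",
              paste(x$registry_min_days, collapse = ", ")))
  invisible(x)
}

#' Cohort configuration for the synthetic-cohort simulator
#'
#' @param n_patients number of patients to simulate.
#' @param archetype_mix named numeric vector of archetype sampling
#'   probabilities (names must match archetypes passed to
#'   [generate_cohort()]); must sum to 1.  Default:
#'   [default_archetype_mix()].
#' @param window_days end of the observation window; patients are observed
#'   over days `[0, window_days]` and truncated (censored) at the window
#'   end.  Default 4383 days (a 12-year registry window).
#' @param hd_sessions_per_week number of HD sessions emitted per 7-day week
#'   during plain HD spells; default 3 (in-centre schedule, days 1/3/5 of
#'   each week).
#' @param entry_day day offset at which treatment starts (day 0 is the
#'   study start); default 1.
#' @param dropout_rate probability that any single PD or HD event is lost
#'   from the emitted stream (coding-error emulation); default 0
#'   (noise-free).
#' @param seed integer seed; a fixed seed makes [generate_cohort()] output
#'   byte-identical.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          archetype_mix = default_archetype_mix(),
                          window_days = 4383,
                          hd_sessions_per_week = 3,
                          entry_day = 1,
                          dropout_rate = 0,
                          seed = 1) {
  if (!is_count(n_patients)) abort("`n_patients` must be a positive integer")
  if (is.null(names(archetype_mix)) || any(!nzchar(names(archetype_mix)))) {
    abort("`archetype_mix` must be a named vector of probabilities")
  }
  if (any(archetype_mix < 0) || abs(sum(archetype_mix) - 1) > 1e-9) {
    abort("`archetype_mix` probabilities must be non-negative and sum to 1")
  }
  if (!is_count(window_days)) abort("`window_days` must be a positive integer")
  if (!is_count(hd_sessions_per_week) || hd_sessions_per_week > 7) {
    abort("`hd_sessions_per_week` must be an integer in 1..7")
  }
  if (!is_day(entry_day) || entry_day < 0) abort("`entry_day` must be a day offset >= 0")
  if (!is.numeric(dropout_rate) || dropout_rate < 0 || dropout_rate >= 1) {
    abort("`dropout_rate` must be in [0, 1)")
  }
  if (!is_count(seed + 1)) abort("`seed` must be an integer")
  structure(list(
    n_patients = as.integer(n_patients),
    archetype_mix = archetype_mix,
    window_days = as.integer(window_days),
    hd_sessions_per_week = as.integer(hd_sessions_per_week),
    entry_day = as.integer(entry_day),
    dropout_rate = dropout_rate,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients over days [0, %d], seed %d\n",
              x$n_patients, x$window_days, x$seed))
  cat(sprintf("  HD sessions/week %d, entry day %d, event dropout %.3f\n",
              x$hd_sessions_per_week, x$entry_day, x$dropout_rate))
  mix <- sort(x$archetype_mix, decreasing = TRUE)
  cat("  archetype mix:\n")
  for (nm in names(mix)) cat(sprintf("    %-12s %.3f\n", nm, mix[[nm]]))
  invisible(x)
}
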