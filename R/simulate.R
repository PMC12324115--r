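#' @noRd
draw_duration <- function(sp) {
  if (sp$dist == "fixed") {
    return(max(1L, as.integer(round(sp$median_days))))
  }
  d <- exp(stats::rnorm(1, mean = log(sp$median_days), sd = log(sp$gsd)))
  max(1L, as.integer(round(d)))
}

# Within-week day offsets of HD sessions (Mon/Wed/Fri-style pattern).
hd_week_offsets <- function(k) {
  switch(as.character(k),
         "1" = 0L, "2" = c(0L, 3L), "3" = c(0L, 2L, 4L),
         sort(unique(as.integer(seq(0, 6, length.out = k)))))
}

# Expand a MIXBLOCK of `total` days into >= 3 alternating PD/HD sub-spells,
# each strictly shorter than `mixed_max_days`.  The first sub-spell must
# differ from the preceding raw modality and the last from the following
# one, otherwise contiguous same-modality days would fuse into one long
# episode and dissolve the block.  Sub-spells are also floored at
# `gap_tol + 1` days: shorter alternations are unobservable, because HD
# session bridging would swallow the intervening PD days.
expand_mixblock <- function(total, prev_mod, next_mod, mixed_max_days, min_run,
                            gap_tol) {
  cap <- mixed_max_days - 1L
  min_part <- min(as.integer(gap_tol) + 1L, cap)
  start_mod <- if (identical(prev_mod, "HD")) "PD" else "HD"
  other <- if (start_mod == "HD") "PD" else "HD"
  k <- max(min_run, as.integer(ceiling(total / cap)))
  end_mod <- if (k %% 2L == 1L) start_mod else other
  if (!is.na(next_mod) && end_mod == next_mod) k <- k + 1L
  total <- max(total, k * min_part)
  base <- total %/% k
  parts <- rep(base, k)
  rem <- total - base * k
  if (rem > 0) parts[seq_len(rem)] <- parts[seq_len(rem)] + 1L
  data.frame(
    modality = rep(c(start_mod, other), length.out = k),
    duration = as.integer(parts),
    stringsAsFactors = FALSE
  )
}

#' Simulate one patient's day-level event stream from an archetype
#'
#' Draws spell durations, expands `MIXBLOCK`/`HYBBLOCK` spells into concrete
#' day-level regimes, truncates at the observation window and emits the
#' event stream together with the ground-truth state sequence.  Truth labels
#' are produced here, by construction, and never re-derived from the stream,
#' so downstream recovery tests are free of circularity.
#'
#' Emission rules: PD spells emit one `PD` coverage event per day; HD spells
#' emit `hd_sessions_per_week` sessions per 7-day week (days 1/3/5 pattern);
#' `KT` emits a single event at the spell start; `HYBBLOCK` emits daily `PD`
#' events plus one weekly `HD` session; a `death` terminal emits one `DEATH`
#' event the day after the last spell.  Spells bordering a `MIXBLOCK` are
#' floored at `cfg$mixed_max_days` and `HYBBLOCK` durations at
#' `cfg$hybrid_min_days`, so the emitted truth labels remain valid
#' descriptions of the realized stream.
#'
#' Uses the R session RNG: seed it (or call via [generate_cohort()]) for
#' reproducibility.
#'
#' @param archetype a [archetype_spec()] object.
#' @param window_days observation window end (day offset).
#' @param hd_sessions_per_week HD sessions per week in plain HD spells.
#' @param cfg an [analysis_config()]; supplies the mixed/hybrid thresholds
#'   the block expansions must respect.
#' @param entry_day first treatment day; default 1 (day 0 = study start).
#' @param dropout_rate per-event loss probability for PD/HD events.
#' @return list with `sessions` (data.frame `day`, `event`), `truth`
#'   (data.frame `state`, `start_day`, `end_day`, `censored`), `death_day`
#'   (`NA` if alive), `censor_day` (last observed day) and `censored`.
#' @export
generate_patient <- function(archetype, window_days,
                             hd_sessions_per_week = 3,
                             cfg = analysis_config(),
                             entry_day = 1,
                             dropout_rate = 0) {
  if (!inherits(archetype, "traj_archetype")) {
    abort("`archetype` must be built with archetype_spec()")
  }
  if (!is_count(window_days)) abort("`window_days` must be a positive integer")
  if (!is_day(entry_day) || entry_day < 0) abort("`entry_day` must be >= 0")
  window_days <- as.integer(window_days)
  entry_day <- as.integer(entry_day)
  spells <- archetype$spells
  mods <- vapply(spells, `[[`, character(1), "modality")
  n <- length(spells)

  durs <- vapply(spells, draw_duration, integer(1))
  for (i in seq_len(n)) {
    near_mix <- (i > 1 && mods[i - 1] == "MIXBLOCK") ||
      (i < n && mods[i + 1] == "MIXBLOCK")
    if (mods[i] %in% c("PD", "HD") && near_mix) {
      # HD episodes end at the last session, up to a week short of the
      # spell, so HD spells get extra head-room above the mixed threshold
      floor_i <- as.integer(cfg$mixed_max_days) + if (mods[i] == "HD") 7L else 0L
      durs[i] <- max(durs[i], floor_i)
    }
    if (mods[i] == "HYBBLOCK") {
      durs[i] <- max(durs[i], as.integer(cfg$hybrid_min_days))
    }
  }

  # concrete units: one row per homogeneous day-range regime
  units <- vector("list", n)
  for (i in seq_len(n)) {
    if (mods[i] == "MIXBLOCK") {
      prev_mod <- if (i > 1 && mods[i - 1] %in% c("PD", "HD")) mods[i - 1] else NA_character_
      next_mod <- if (i < n && mods[i + 1] %in% c("PD", "HD")) mods[i + 1] else NA_character_
      sub <- expand_mixblock(durs[i], prev_mod, next_mod,
                             as.integer(cfg$mixed_max_days),
                             as.integer(cfg$mixed_min_run),
                             cfg$hd_gap_tolerance)
      units[[i]] <- data.frame(spell_idx = i, state = "MIX",
                               regime = sub$modality, duration = sub$duration,
                               stringsAsFactors = FALSE)
    } else {
      state <- switch(mods[i], HYBBLOCK = "HYB", mods[i])
      units[[i]] <- data.frame(spell_idx = i, state = state,
                               regime = mods[i], duration = durs[i],
                               stringsAsFactors = FALSE)
    }
  }
  units <- do.call(rbind, units)
  units$start <- entry_day + cumsum(c(0L, units$duration[-nrow(units)]))
  units$end <- units$start + units$duration - 1L

  # truncate at the window
  censored_by_window <- units$end[nrow(units)] >= window_days ||
    (archetype$terminal == "death" && units$end[nrow(units)] + 1L > window_days)
  units <- units[units$start <= window_days, , drop = FALSE]
  if (nrow(units) == 0L) {
    return(list(
      sessions = data.frame(day = integer(), event = character(),
                            stringsAsFactors = FALSE),
      truth = data.frame(state = character(), start_day = integer(),
                         end_day = integer(), censored = logical(),
                         stringsAsFactors = FALSE),
      death_day = NA_integer_, censor_day = as.integer(window_days),
      censored = TRUE
    ))
  }
  units$end <- pmin(units$end, as.integer(window_days))
  units$duration <- units$end - units$start + 1L

  # a truncated mixed block that lost sub-spells below the minimum run is
  # no longer a mixed regime: its truth degrades to the raw labels
  for (i in unique(units$spell_idx[units$state == "MIX"])) {
    if (sum(units$spell_idx == i) < cfg$mixed_min_run) {
      units$state[units$spell_idx == i] <- units$regime[units$spell_idx == i]
    }
  }

  died <- archetype$terminal == "death" && !censored_by_window
  death_day <- if (died) units$end[nrow(units)] + 1L else NA_integer_
  censor_day <- if (died) death_day else
    if (censored_by_window) as.integer(window_days) else units$end[nrow(units)]

  # events
  days <- integer(0)
  events <- character(0)
  wk <- hd_week_offsets(hd_sessions_per_week)
  for (r in seq_len(nrow(units))) {
    s <- units$start[r]; e <- units$end[r]
    reg <- units$regime[r]
    if (reg == "PD") {
      d <- s:e
      days <- c(days, d); events <- c(events, rep("PD", length(d)))
    } else if (reg == "HD") {
      off <- as.vector(outer(wk, seq(0L, e - s, by = 7L), `+`))
      d <- s + off[s + off <= e]
      days <- c(days, sort(d)); events <- c(events, rep("HD", length(d)))
    } else if (reg == "KT") {
      days <- c(days, s); events <- c(events, "KT")
    } else if (reg == "HYBBLOCK") {
      d <- s:e
      days <- c(days, d); events <- c(events, rep("PD", length(d)))
      hd <- seq(s, e, by = 7L)
      days <- c(days, hd); events <- c(events, rep("HD", length(hd)))
    }
  }
  if (dropout_rate > 0 && length(days) > 0) {
    droppable <- events %in% c("PD", "HD")
    drop <- droppable & stats::runif(length(days)) < dropout_rate
    days <- days[!drop]; events <- events[!drop]
  }
  if (died) {
    days <- c(days, death_day); events <- c(events, "DEATH")
  }
  ord <- order(days, match(events, EVENT_LEVELS))
  sessions <- data.frame(day = days[ord], event = events[ord],
                         stringsAsFactors = FALSE)

  # truth: merge consecutive units with identical state labels
  grp <- cumsum(c(TRUE, units$state[-1] != units$state[-nrow(units)]))
  idx <- unname(split(seq_len(nrow(units)), factor(grp, levels = unique(grp))))
  truth <- data.frame(
    state = vapply(idx, function(j) units$state[j[1]], character(1)),
    start_day = vapply(idx, function(j) min(units$start[j]), integer(1)),
    end_day = vapply(idx, function(j) max(units$end[j]), integer(1)),
    stringsAsFactors = FALSE
  )
  if (died) {
    truth <- rbind(truth, data.frame(state = "DEATH", start_day = death_day,
                                     end_day = death_day))
  }
  truth$censored <- FALSE
  if (!died) truth$censored[nrow(truth)] <- TRUE
  rownames(truth) <- NULL

  list(sessions = sessions, truth = truth, death_day = death_day,
       censor_day = as.integer(censor_day), censored = !died)
}

#' Simulate a cohort of day-level dialysis event streams
#'
#' Draws one archetype per patient from `config$archetype_mix`, generates
#' each patient with [generate_patient()] and returns the three tables the
#' rest of the pipeline consumes.  Fixing `config$seed` makes the output
#' byte-identical across runs.
#'
#' @param config a [cohort_config()].
#' @param archetypes named list of [archetype_spec()] objects; default
#'   [default_archetypes()].  Every name in `config$archetype_mix` must be
#'   present.
#' @param cfg an [analysis_config()] supplying the thresholds the generated
#'   blocks must respect.
#' @return list with `sessions` (`patient_id`, `day`, `event`), `patients`
#'   (`patient_id`, `entry_day`, `censor_day`, `archetype`) and `truth`
#'   (`patient_id`, `state`, `start_day`, `end_day`, `censored`).
#' @examples
#' coh <- generate_cohort(cohort_config(20, seed = 7))
#' head(coh$sessions)
#' @export
generate_cohort <- function(config, archetypes = default_archetypes(),
                            cfg = analysis_config()) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be built with cohort_config()")
  }
  missing <- setdiff(names(config$archetype_mix), names(archetypes))
  if (length(missing) > 0) {
    abort("archetype(s) %s in the mix are not defined",
          paste(sQuote(missing), collapse = ", "))
  }
  set.seed(config$seed)
  n <- config$n_patients
  labels <- sample(names(config$archetype_mix), n, replace = TRUE,
                   prob = config$archetype_mix)
  ids <- sprintf("P%0*d", max(4L, nchar(n)), seq_len(n))

  sess_l <- vector("list", n)
  truth_l <- vector("list", n)
  censor <- integer(n)
  for (i in seq_len(n)) {
    p <- generate_patient(archetypes[[labels[i]]], config$window_days,
                          hd_sessions_per_week = config$hd_sessions_per_week,
                          cfg = cfg, entry_day = config$entry_day,
                          dropout_rate = config$dropout_rate)
    if (nrow(p$sessions) > 0) {
      p$sessions <- cbind(patient_id = ids[i], p$sessions,
                          stringsAsFactors = FALSE)
    }
    if (nrow(p$truth) > 0) {
      p$truth <- cbind(patient_id = ids[i], p$truth, stringsAsFactors = FALSE)
    }
    sess_l[[i]] <- p$sessions
    truth_l[[i]] <- p$truth
    censor[i] <- p$censor_day
  }
  sessions <- rbind_all(sess_l, data.frame(
    patient_id = character(), day = integer(), event = character(),
    stringsAsFactors = FALSE))
  truth <- rbind_all(truth_l, data.frame(
    patient_id = character(), state = character(), start_day = integer(),
    end_day = integer(), censored = logical(), stringsAsFactors = FALSE))
  patients <- data.frame(patient_id = ids,
                         entry_day = config$entry_day,
                         censor_day = censor,
                         archetype = labels,
                         stringsAsFactors = FALSE)
  list(sessions = sessions, patients = patients, truth = truth)
}
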