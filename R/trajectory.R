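# per-patient list of state labels, in timeline order
state_labels <- function(states) {
  lapply(split_patients(states), function(x) x$state[order(x$start_day)])
}

#' Extract all state-to-state transitions
#'
#' A transition is a sequence between states: one row per adjacent pair of
#' state intervals, in timeline order.  `DEATH` can only ever be a
#' destination.
#'
#' @param states state-sequence data.frame ([classify_states()] output).
#' @return data.frame `patient_id`, `from_state`, `to_state`, `day` (start
#'   of the destination interval), `order_index` (1 = first transition).
#' @export
extract_transitions <- function(states) {
  empty <- data.frame(patient_id = character(), from_state = character(),
                      to_state = character(), day = integer(),
                      order_index = integer(), stringsAsFactors = FALSE)
  if (!is.data.frame(states) || nrow(states) == 0L) {
    return(empty)
  }
  out <- lapply(split_patients(states), function(x) {
    x <- x[order(x$start_day), , drop = FALSE]
    n <- nrow(x)
    if (n < 2L) {
      return(NULL)
    }
    data.frame(patient_id = x$patient_id[1],
               from_state = x$state[-n], to_state = x$state[-1],
               day = as.integer(x$start_day[-1]),
               order_index = seq_len(n - 1L), stringsAsFactors = FALSE)
  })
  rbind_all(out, empty)
}

#' Group patients by their first transition
#'
#' Labels each patient by the (from, to) pair of their first transition,
#' keeping the four major first transitions as their own groups and pooling
#' the rest into `other`; patients who never leave their first state are
#' `none`.  The groups partition the cohort.
#'
#' @inheritParams extract_transitions
#' @return data.frame `patient_id`, `group` with `group` one of
#'   `"PD->HD"`, `"PD->DEATH"`, `"HD->PD"`, `"PD->KT"`, `"other"`,
#'   `"none"`.
#' @export
first_transition_group <- function(states) {
  if (!is.data.frame(states) || nrow(states) == 0L) {
    return(data.frame(patient_id = character(), group = character(),
                      stringsAsFactors = FALSE))
  }
  major <- c("PD->HD", "PD->DEATH", "HD->PD", "PD->KT")
  labs <- state_labels(states)
  grp <- vapply(labs, function(s) {
    if (length(s) < 2L) {
      return("none")
    }
    key <- paste0(s[1], "->", s[2])
    if (key %in% major) key else "other"
  }, character(1))
  data.frame(patient_id = names(labs), group = unname(grp),
             stringsAsFactors = FALSE)
}

#' Pattern-level duration table
#'
#' Groups patients by their first `depth` states and reports, per pattern,
#' the number of patients and the median duration (days) of the first and
#' second intervals.  Medians are taken over completed (non-censored)
#' intervals only — censored spells have unknown true length — but censored
#' patients still count towards pattern membership.  `DEATH` intervals
#' carry no duration.
#'
#' @inheritParams extract_transitions
#' @param depth number of leading states defining a pattern (2 or 3).
#' @return data.frame `pattern` (e.g. `"PD-HD-PD"`), `n_patients`,
#'   `median_days_1st`, `median_days_2nd`, ordered by decreasing
#'   `n_patients`.
#' @export
pattern_table <- function(states, depth = 3) {
  if (!depth %in% c(2, 3)) abort("`depth` must be 2 or 3")
  empty <- data.frame(pattern = character(), n_patients = integer(),
                      median_days_1st = numeric(), median_days_2nd = numeric(),
                      stringsAsFactors = FALSE)
  if (!is.data.frame(states) || nrow(states) == 0L) {
    return(empty)
  }
  per <- lapply(split_patients(states), function(x) {
    x <- x[order(x$start_day), , drop = FALSE]
    k <- min(depth, nrow(x))
    dur <- function(i) {
      if (i > nrow(x) || x$state[i] == "DEATH" || x$censored[i]) {
        return(NA_real_)
      }
      as.numeric(x$end_day[i] - x$start_day[i] + 1L)
    }
    data.frame(pattern = paste(x$state[seq_len(k)], collapse = "-"),
               d1 = dur(1L), d2 = dur(2L), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  pats <- unique(per$pattern)
  out <- do.call(rbind, lapply(pats, function(p) {
    sub <- per[per$pattern == p, , drop = FALSE]
    data.frame(pattern = p, n_patients = nrow(sub),
               median_days_1st = traj_median(sub$d1),
               median_days_2nd = traj_median(sub$d2),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$n_patients, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Distribution of the number of KRTs per patient
#'
#' Histogram of per-patient modality counts, pooling counts above `cap`
#' into the top bin, plus the median and interquartile range of the
#' (uncapped) counts under the package quantile convention
#' ([traj_quantile()]).
#'
#' @inheritParams extract_transitions
#' @param cap top histogram bin; counts above it are pooled (default 10).
#' @return list with `histogram` (data.frame `n_krt` 1..`cap`,
#'   `n_patients`), `median`, `q1`, `q3`.
#' @export
modality_count_distribution <- function(states, cap = 10) {
  counts <- count_krt_modalities(states)
  hist <- data.frame(n_krt = seq_len(cap),
                     n_patients = vapply(seq_len(cap), function(k) {
                       if (k < cap) sum(counts$n_krt == k)
                       else sum(counts$n_krt >= cap)
                     }, integer(1)))
  q <- traj_quantile(counts$n_krt, c(0.25, 0.5, 0.75))
  list(histogram = hist, median = q[2], q1 = q[1], q3 = q[3])
}

#' Point prevalence: alive / on dialysis / on PD at a given day
#'
#' Counts, at day `t`: patients under observation (entered on or before `t`
#' and not yet dead), those in a dialysis state (`PD`, `HD`, `MIX`, `HYB`)
#' at `t`, and those specifically on `PD`.  The counts are nested:
#' `on_pd <= on_dialysis <= alive`.
#'
#' @inheritParams extract_transitions
#' @param t day offset (>= 0).
#' @param patients optional patient table supplying `entry_day`; defaults
#'   to each patient's first interval start.
#' @return one-row data.frame `day`, `alive`, `on_dialysis`, `on_pd`.
#' @export
point_prevalence <- function(states, t, patients = NULL) {
  if (!is_day(t) || t < 0) abort("`t` must be a day offset >= 0")
  pats <- split_patients(states)
  res <- vapply(pats, function(x) {
    x <- x[order(x$start_day), , drop = FALSE]
    entry <- x$start_day[1]
    if (!is.null(patients)) {
      row <- patients[patients$patient_id == x$patient_id[1], , drop = FALSE]
      if (nrow(row) == 1L) entry <- row$entry_day
    }
    death <- x$start_day[x$state == "DEATH"]
    alive <- entry <= t && (length(death) == 0L || death > t)
    at_t <- x$state[x$start_day <= t & x$end_day >= t & x$state != "DEATH"]
    on_dial <- alive && length(at_t) == 1L && at_t %in% DIALYSIS_STATES
    on_pd <- on_dial && at_t == "PD"
    c(alive, on_dial, on_pd)
  }, logical(3))
  data.frame(day = as.integer(t),
             alive = sum(res[1, ]),
             on_dialysis = sum(res[2, ]),
             on_pd = sum(res[3, ]))
}

# registry-style suppression of one patient's sequence: repeatedly absorb
# the first non-terminal interval shorter than `d` days into its
# neighbours (merging when both match, else into the preceding state)
suppress_short_intervals <- function(x, d) {
  x <- x[order(x$start_day), , drop = FALSE]
  repeat {
    n <- nrow(x)
    if (n < 2L) {
      return(x)
    }
    dur <- x$end_day - x$start_day + 1L
    protected <- x$state == "DEATH" | seq_len(n) == n  # terminal interval kept
    short <- which(!protected & dur < d)
    if (length(short) == 0L) {
      return(x)
    }
    i <- short[1]
    if (i == 1L) {
      # no preceding state: the registry would record the next state from entry
      x$start_day[2] <- x$start_day[1]
      x <- x[-1, , drop = FALSE]
    } else {
      x$end_day[i - 1] <- x$end_day[i]
      x <- x[-i, , drop = FALSE]
    }
    # merge newly adjacent identical states
    n <- nrow(x)
    same <- which(x$state[-1] == x$state[-n] & x$state[-n] != "DEATH")
    if (length(same) > 0) {
      j <- same[1]
      x$end_day[j] <- x$end_day[j + 1]
      x$censored[j] <- x$censored[j + 1]
      x <- x[-(j + 1), , drop = FALSE]
    }
  }
}

#' Compare the exhaustive and registry-style transition definitions
#'
#' National registries typically count a transition only when the new
#' modality lasts at least a minimum number of days (commonly 30, with
#' 60/90/180-day sensitivity variants), whereas the exhaustive day-level
#' definition counts every change of state.  For each threshold `d`, every
#' non-terminal interval shorter than `d` days is absorbed into its
#' neighbours (merged when both sides match, else into the preceding
#' state) and the remaining transitions are recounted.
#'
#' @inheritParams extract_transitions
#' @param registry_min_days positive thresholds, in days.
#' @return data.frame `definition` (`"exhaustive"` or `"min_<d>d"`),
#'   `min_days` (`NA` for exhaustive), `n_transitions`.
#' @export
compare_transition_definitions <- function(states,
                                           registry_min_days = c(30, 60, 90, 180)) {
  if (any(registry_min_days <= 0)) abort("thresholds must be positive")
  pats <- split_patients(states)
  n_trans <- function(seqs) sum(vapply(seqs, function(x) nrow(x) - 1L, integer(1)))
  out <- data.frame(definition = "exhaustive", min_days = NA_real_,
                    n_transitions = n_trans(pats), stringsAsFactors = FALSE)
  for (d in registry_min_days) {
    supp <- lapply(pats, suppress_short_intervals, d = d)
    out <- rbind(out, data.frame(definition = sprintf("min_%dd", d),
                                 min_days = as.numeric(d),
                                 n_transitions = n_trans(supp),
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
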