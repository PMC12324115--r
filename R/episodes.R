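#' Validate a session table
#'
#' Checks the day-level event-stream contract: required columns, known
#' event codes, integer non-negative days, at most one `DEATH` per patient
#' and no events after it.  Duplicate `(patient_id, day, event)` rows are
#' removed with a warning (claims extracts routinely contain them).
#'
#' @param records data.frame with columns `patient_id`, `day`, `event`.
#' @param patients optional patient table (`patient_id`, `entry_day`,
#'   `censor_day`); when given, events outside a patient's observation
#'   window are rejected, naming the patient.
#' @return the validated (possibly deduplicated) session table.
#' @export
validate_sessions <- function(records, patients = NULL) {
  need <- c("patient_id", "day", "event")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    abort("session table must have columns %s", paste(need, collapse = ", "))
  }
  if (nrow(records) == 0L) {
    return(records)
  }
  bad <- !records$event %in% EVENT_LEVELS
  if (any(bad)) {
    abort("unknown event code(s) %s at row(s) %s",
          paste(sQuote(unique(records$event[bad])), collapse = ", "),
          paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  if (!is.numeric(records$day) || any(is.na(records$day)) ||
      any(records$day != round(records$day)) || any(records$day < 0)) {
    bad <- which(is.na(records$day) | records$day < 0 |
                   records$day != round(records$day))
    abort("`day` must be integer offsets >= 0; bad row(s): %s",
          paste(utils::head(bad, 5L), collapse = ", "))
  }
  records$day <- as.integer(records$day)
  dup <- duplicated(records[, need])
  if (any(dup)) {
    warning(sprintf("removed %d duplicate session row(s)", sum(dup)),
            call. = FALSE)
    records <- records[!dup, , drop = FALSE]
  }
  records <- records[order(match(records$patient_id, unique(records$patient_id)),
                           records$day, match(records$event, EVENT_LEVELS)), ,
                     drop = FALSE]
  rownames(records) <- NULL

  for (pd in split_patients(records)) {
    pid <- pd$patient_id[1]
    dth <- pd$day[pd$event == "DEATH"]
    if (length(dth) > 1L) abort("patient %s has multiple DEATH events", pid)
    if (length(dth) == 1L && any(pd$day > dth)) {
      abort("patient %s has events after the DEATH event (day %d)", pid, dth)
    }
    if (!is.null(patients)) {
      row <- patients[patients$patient_id == pid, , drop = FALSE]
      if (nrow(row) == 1L &&
          (any(pd$day < row$entry_day) || any(pd$day > row$censor_day))) {
        abort("patient %s has events outside the observation window [%d, %d]",
              pid, row$entry_day, row$censor_day)
      }
    }
  }
  records
}

# coverage for a single patient's sorted sessions; returns integer-coded
# vector over [lo, hi] with 0 none / 1 PD / 2 HD / 3 KT
coverage_one <- function(pd, hd_gap_tolerance, censor_day = NA) {
  hd <- sort(unique(pd$day[pd$event == "HD"]))
  pdd <- sort(unique(pd$day[pd$event == "PD"]))
  kt <- sort(unique(pd$day[pd$event == "KT"]))
  death <- pd$day[pd$event == "DEATH"]
  death <- if (length(death) == 1L) death else NA_integer_

  lo <- min(pd$day)
  hi <- if (!is.na(censor_day)) max(censor_day, max(pd$day)) else max(pd$day)
  if (!is.na(death)) hi <- min(hi, death - 1L)
  if (hi < lo) {
    return(list(lo = lo, code = integer(0)))
  }
  code <- integer(hi - lo + 1L)

  # HD sessions, bridging inter-session gaps up to the tolerance;
  # the trailing tolerance after the last session is NOT appended
  if (length(hd) > 0) {
    hd <- hd[hd <= hi]
  }
  if (length(hd) > 0) {
    code[hd - lo + 1L] <- 2L
    if (length(hd) > 1L) {
      a <- hd[-length(hd)]
      b <- hd[-1]
      keep <- (b - a) <= hd_gap_tolerance & (b - a) > 1L
      if (any(keep)) {
        mids <- unlist(Map(function(x, y) (x + 1L):(y - 1L), a[keep], b[keep]))
        code[mids - lo + 1L] <- 2L
      }
    }
  }

  # PD coverage days, where not already HD (day-level priority HD > PD)
  if (length(pdd) > 0) {
    pdd <- pdd[pdd <= hi]
    idx <- pdd - lo + 1L
    idx <- idx[code[idx] == 0L]
    code[idx] <- 1L
  }

  # transplant: from the KT event until the day before the next dialysis
  # event (graft-failure proxy), bounded by death/censoring
  if (length(kt) > 0) {
    dial <- sort(c(hd, pdd))
    for (k in kt) {
      if (k > hi) next
      nxt <- dial[dial > k]
      e <- if (length(nxt) > 0) min(nxt) - 1L else hi
      e <- min(e, hi)
      if (e >= k) code[(k - lo + 1L):(e - lo + 1L)] <- 3L
    }
  }
  list(lo = lo, code = code)
}

#' Assign one raw modality to every covered day
#'
#' Expands a day-level event stream into per-day raw-modality coverage.
#' An HD session covers its own day, and the days up to the next session
#' when the gap is at most `hd_gap_tolerance` (bridging the usual 2-3 day
#' inter-session gaps); trailing days after the last session are not
#' covered.  PD coverage days are PD unless the day is already HD (a day
#' carrying both an HD session and PD coverage is HD, so single-day
#' transfers stay visible).  From a `KT` event until the day before the
#' next dialysis event, coverage is `KT`.  No day after a `DEATH` event is
#' covered.
#'
#' @inheritParams validate_sessions
#' @param hd_gap_tolerance maximum bridged gap between HD sessions, days.
#' @return data.frame `patient_id`, `day`, `modality` (`PD`/`HD`/`KT`),
#'   one row per covered day, ordered by patient and day.
#' @examples
#' s <- data.frame(patient_id = "A", day = c(1, 3, 5, 8), event = "HD")
#' build_daily_coverage(s)  # days 1..8 all HD
#' @export
build_daily_coverage <- function(records, hd_gap_tolerance = 7, patients = NULL) {
  records <- validate_sessions(records, patients)
  empty <- data.frame(patient_id = character(), day = integer(),
                      modality = character(), stringsAsFactors = FALSE)
  if (nrow(records) == 0L) {
    return(empty)
  }
  out <- lapply(split_patients(records), function(pd) {
    pid <- pd$patient_id[1]
    cens <- NA_integer_
    if (!is.null(patients)) {
      row <- patients[patients$patient_id == pid, , drop = FALSE]
      if (nrow(row) == 1L) cens <- as.integer(row$censor_day)
    }
    cov <- coverage_one(pd, hd_gap_tolerance, cens)
    keep <- which(cov$code != 0L)
    if (length(keep) == 0L) {
      return(NULL)
    }
    data.frame(patient_id = pid,
               day = cov$lo + keep - 1L,
               modality = c("PD", "HD", "KT")[cov$code[keep]],
               stringsAsFactors = FALSE)
  })
  rbind_all(out, empty)
}

#' Collapse daily coverage into maximal contiguous modality episodes
#'
#' A new episode starts at every change of modality and at every break in
#' day contiguity (an uncovered day closes the preceding episode).
#' Durations count days inclusively: `end_day - start_day + 1`.
#'
#' @param coverage data.frame as returned by [build_daily_coverage()].
#' @return data.frame `patient_id`, `modality`, `start_day`, `end_day`,
#'   `duration_days`, ordered by patient and `start_day`.
#' @export
segment_episodes <- function(coverage) {
  need <- c("patient_id", "day", "modality")
  if (!is.data.frame(coverage) || !all(need %in% names(coverage))) {
    abort("coverage must have columns %s", paste(need, collapse = ", "))
  }
  empty <- data.frame(patient_id = character(), modality = character(),
                      start_day = integer(), end_day = integer(),
                      duration_days = integer(), stringsAsFactors = FALSE)
  if (nrow(coverage) == 0L) {
    return(empty)
  }
  ord <- order(match(coverage$patient_id, unique(coverage$patient_id)),
               coverage$day)
  cv <- coverage[ord, , drop = FALSE]
  n <- nrow(cv)
  newrun <- c(TRUE,
              cv$patient_id[-1] != cv$patient_id[-n] |
                cv$modality[-1] != cv$modality[-n] |
                cv$day[-1] != cv$day[-n] + 1L)
  first <- which(newrun)
  last <- c(first[-1] - 1L, n)
  out <- data.frame(patient_id = cv$patient_id[first],
                    modality = cv$modality[first],
                    start_day = as.integer(cv$day[first]),
                    end_day = as.integer(cv$day[last]),
                    stringsAsFactors = FALSE)
  out$duration_days <- out$end_day - out$start_day + 1L
  rownames(out) <- NULL
  out
}
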