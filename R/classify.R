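#' Detect hybrid-dialysis intervals (sustained weekly PD+HD co-occurrence)
#'
#' Hybrid dialysis is a stable regime combining PD on most days with one or
#' two weekly HD sessions, sustained for a minimum span.  Detection works
#' on the raw events (not on the collapsed daily coverage, which gives HD
#' priority): starting at an HD session day, consecutive
#' `cfg$hybrid_week_len`-day windows are tiled forward as long as every
#' window contains at least one HD session and at least one PD coverage
#' day; the candidate interval ends at the last event day inside the tiled
#' span, and is kept when it spans at least `cfg$hybrid_min_days` days.
#' Windows are tiled from the interval start, not from calendar weeks, so
#' the result does not depend on calendar alignment.
#'
#' @inheritParams validate_sessions
#' @param cfg an [analysis_config()].
#' @return data.frame `patient_id`, `start_day`, `end_day` of maximal
#'   hybrid intervals (possibly zero rows).
#' @examples
#' s <- rbind(data.frame(patient_id = "A", day = 0:119, event = "PD"),
#'            data.frame(patient_id = "A", day = seq(0, 119, 7), event = "HD"))
#' detect_hybrid(s)  # one 120-day hybrid interval
#' @export
detect_hybrid <- function(records, cfg = analysis_config()) {
  records <- validate_sessions(records)
  empty <- data.frame(patient_id = character(), start_day = integer(),
                      end_day = integer(), stringsAsFactors = FALSE)
  if (nrow(records) == 0L) {
    return(empty)
  }
  wl <- as.integer(cfg$hybrid_week_len)
  out <- lapply(split_patients(records), function(pd) {
    hd <- sort(unique(pd$day[pd$event == "HD"]))
    pdd <- sort(unique(pd$day[pd$event == "PD"]))
    if (length(hd) == 0L || length(pdd) == 0L) {
      return(NULL)
    }
    act <- sort(unique(c(hd, pdd)))
    has_in <- function(x, a, b) findInterval(b, x) > findInterval(a - 1L, x)
    # only HD days with a PD day in the same leading window can start a
    # hybrid interval, which prunes candidates inside pure HD spells
    cand <- hd[findInterval(hd + wl - 1L, pdd) > findInterval(hd - 1L, pdd)]
    res <- list()
    done_until <- -Inf
    for (s in cand) {
      if (s <= done_until) next
      m <- 0L
      repeat {
        w0 <- s + m * wl
        w1 <- w0 + wl - 1L
        if (!has_in(hd, w0, w1) || !has_in(pdd, w0, w1)) break
        m <- m + 1L
      }
      if (m == 0L) next
      e <- min(s + m * wl - 1L, max(act[act <= s + m * wl - 1L]))
      if (e - s + 1L >= cfg$hybrid_min_days) {
        res[[length(res) + 1L]] <- c(s, e)
        done_until <- e
      }
    }
    if (length(res) == 0L) {
      return(NULL)
    }
    iv <- do.call(rbind, res)
    data.frame(patient_id = pd$patient_id[1],
               start_day = as.integer(iv[, 1]), end_day = as.integer(iv[, 2]),
               stringsAsFactors = FALSE)
  })
  rbind_all(out, empty)
}

#' Detect mixed-dialysis intervals (short unstable PD/HD alternation)
#'
#' Mixed dialysis marks clinically unstable phases: a run of at least
#' `cfg$mixed_min_run` consecutive alternating PD/HD episodes, each lasting
#' strictly less than `cfg$mixed_max_days` days.  Runs are extended
#' greedily while the next episode qualifies; a transplant episode, or an
#' episode at or above the threshold, closes the run.  A qualifying run is
#' reported as one interval from the first episode start to the last
#' episode end.
#'
#' @param episodes data.frame as returned by [segment_episodes()].
#' @inheritParams detect_hybrid
#' @return data.frame `patient_id`, `start_day`, `end_day`.
#' @export
detect_mixed <- function(episodes, cfg = analysis_config()) {
  empty <- data.frame(patient_id = character(), start_day = integer(),
                      end_day = integer(), stringsAsFactors = FALSE)
  if (!is.data.frame(episodes) || nrow(episodes) == 0L) {
    return(empty)
  }
  out <- lapply(split_patients(episodes), function(ep) {
    ep <- ep[order(ep$start_day), , drop = FALSE]
    res <- list()
    run <- integer(0)
    close_run <- function(run) {
      if (length(run) >= cfg$mixed_min_run) {
        res[[length(res) + 1L]] <<- c(ep$start_day[run[1]],
                                      ep$end_day[run[length(run)]])
      }
    }
    for (i in seq_len(nrow(ep))) {
      qual <- ep$modality[i] %in% c("PD", "HD") &&
        ep$duration_days[i] < cfg$mixed_max_days
      alternates <- length(run) == 0L ||
        ep$modality[i] != ep$modality[run[length(run)]]
      if (qual && alternates) {
        run <- c(run, i)
      } else {
        close_run(run)
        run <- if (qual) i else integer(0)
      }
    }
    close_run(run)
    if (length(res) == 0L) {
      return(NULL)
    }
    iv <- do.call(rbind, res)
    data.frame(patient_id = ep$patient_id[1],
               start_day = as.integer(iv[, 1]), end_day = as.integer(iv[, 2]),
               stringsAsFactors = FALSE)
  })
  rbind_all(out, empty)
}

# subtract interval set `cut` (2-col matrix) from [s, e]; returns matrix of
# remaining pieces (possibly none)
interval_subtract <- function(s, e, cut) {
  pieces <- matrix(integer(0), ncol = 2)
  cur <- s
  if (nrow(cut) > 0) {
    cut <- cut[order(cut[, 1]), , drop = FALSE]
    for (r in seq_len(nrow(cut))) {
      a <- cut[r, 1]; b <- cut[r, 2]
      if (b < cur || a > e) next
      if (a > cur) pieces <- rbind(pieces, c(cur, a - 1L))
      cur <- max(cur, b + 1L)
      if (cur > e) break
    }
  }
  if (cur <= e) pieces <- rbind(pieces, c(cur, e))
  pieces
}

#' Assemble the six-state sequence of one patient
#'
#' Relabels a patient's episode timeline with the hybrid and mixed
#' intervals (precedence `HYB` > `MIX` > raw episode modality), merges
#' adjacent intervals with identical states (bridging uncovered gap days
#' inside a same-state stretch), appends a one-day `DEATH` interval when a
#' death day is given, and flags the last interval as censored when the
#' patient is alive at the end of observation.
#'
#' @param episodes episodes of one patient ([segment_episodes()] rows).
#' @param hybrid_intervals,mixed_intervals data.frames with `start_day`,
#'   `end_day` (as from [detect_hybrid()] / [detect_mixed()], already
#'   filtered to this patient).
#' @param death_day day of death, or `NA` if alive.
#' @param censor_day last observed day (ignored for patients who died).
#' @inheritParams detect_hybrid
#' @return data.frame `patient_id`, `state`, `start_day`, `end_day`,
#'   `censored`.
#' @export
build_state_sequence <- function(episodes, hybrid_intervals = NULL,
                                 mixed_intervals = NULL,
                                 death_day = NA, censor_day = NA,
                                 cfg = analysis_config()) {
  empty <- data.frame(patient_id = character(), state = character(),
                      start_day = integer(), end_day = integer(),
                      censored = logical(), stringsAsFactors = FALSE)
  pid <- if (!is.null(episodes) && nrow(episodes) > 0) episodes$patient_id[1] else NA
  if (is.null(episodes) || nrow(episodes) == 0L) {
    return(empty)
  }

  as_mat <- function(iv) {
    if (is.null(iv) || nrow(iv) == 0L) {
      return(matrix(integer(0), ncol = 2))
    }
    cbind(as.integer(iv$start_day), as.integer(iv$end_day))
  }
  hyb <- as_mat(hybrid_intervals)
  mix <- as_mat(mixed_intervals)

  st <- character(0); s0 <- integer(0); s1 <- integer(0)
  add <- function(state, a, b) {
    st <<- c(st, state); s0 <<- c(s0, as.integer(a)); s1 <<- c(s1, as.integer(b))
  }
  if (nrow(hyb) > 0) for (r in seq_len(nrow(hyb))) add("HYB", hyb[r, 1], hyb[r, 2])
  # mixed claims yield to hybrid claims on overlapping days
  if (nrow(mix) > 0) {
    for (r in seq_len(nrow(mix))) {
      pieces <- interval_subtract(mix[r, 1], mix[r, 2], hyb)
      if (nrow(pieces) > 0) for (q in seq_len(nrow(pieces))) {
        add("MIX", pieces[q, 1], pieces[q, 2])
      }
    }
  }
  overlay <- cbind(s0, s1)
  for (i in seq_len(nrow(episodes))) {
    pieces <- interval_subtract(as.integer(episodes$start_day[i]),
                                as.integer(episodes$end_day[i]), overlay)
    if (nrow(pieces) > 0) for (q in seq_len(nrow(pieces))) {
      add(episodes$modality[i], pieces[q, 1], pieces[q, 2])
    }
  }

  ord <- order(s0)
  st <- st[ord]; s0 <- s0[ord]; s1 <- s1[ord]
  # clip at the day before death
  if (!is.na(death_day)) {
    keep <- s0 < death_day
    st <- st[keep]; s0 <- s0[keep]; s1 <- pmin(s1[keep], death_day - 1L)
  }
  if (length(st) == 0L) {
    return(empty)
  }
  # merge adjacent identical states, bridging uncovered gaps between them
  grp <- cumsum(c(TRUE, st[-1] != st[-length(st)]))
  idx <- unname(split(seq_along(st), factor(grp, levels = unique(grp))))
  out <- data.frame(
    patient_id = pid,
    state = vapply(idx, function(j) st[j[1]], character(1)),
    start_day = vapply(idx, function(j) min(s0[j]), integer(1)),
    end_day = vapply(idx, function(j) max(s1[j]), integer(1)),
    stringsAsFactors = FALSE
  )
  if (!is.na(death_day)) {
    out <- rbind(out, data.frame(patient_id = pid, state = "DEATH",
                                 start_day = as.integer(death_day),
                                 end_day = as.integer(death_day),
                                 stringsAsFactors = FALSE))
  }
  out$censored <- FALSE
  if (is.na(death_day)) out$censored[nrow(out)] <- TRUE
  rownames(out) <- NULL
  out
}

#' Classify a cohort's event streams into six-state sequences
#'
#' The cohort-level entry point of the classifier: builds daily coverage,
#' segments episodes, detects hybrid and mixed intervals and assembles one
#' state sequence per patient.
#'
#' @inheritParams validate_sessions
#' @inheritParams detect_hybrid
#' @return data.frame `patient_id`, `state`, `start_day`, `end_day`,
#'   `censored`, ordered by patient and `start_day`.
#' @examples
#' coh <- generate_cohort(cohort_config(5, seed = 1))
#' classify_states(coh$sessions, coh$patients)
#' @export
classify_states <- function(records, patients = NULL, cfg = analysis_config()) {
  records <- validate_sessions(records, patients)
  empty <- data.frame(patient_id = character(), state = character(),
                      start_day = integer(), end_day = integer(),
                      censored = logical(), stringsAsFactors = FALSE)
  if (nrow(records) == 0L) {
    return(empty)
  }
  coverage <- build_daily_coverage(records, cfg$hd_gap_tolerance, patients)
  episodes <- segment_episodes(coverage)
  hybrid <- detect_hybrid(records, cfg)
  mixed <- detect_mixed(episodes, cfg)

  ep_l <- split_patients(episodes)
  rec_l <- split_patients(records)
  hyb_l <- if (nrow(hybrid) > 0) split(hybrid, hybrid$patient_id) else list()
  mix_l <- if (nrow(mixed) > 0) split(mixed, mixed$patient_id) else list()
  out <- lapply(names(ep_l), function(pid) {
    pd <- rec_l[[pid]]
    death <- pd$day[pd$event == "DEATH"]
    death <- if (length(death) == 1L) death else NA_integer_
    cens <- NA_integer_
    if (!is.null(patients)) {
      row <- patients[patients$patient_id == pid, , drop = FALSE]
      if (nrow(row) == 1L) cens <- as.integer(row$censor_day)
    }
    build_state_sequence(
      ep_l[[pid]], hyb_l[[pid]], mix_l[[pid]],
      death_day = death, censor_day = cens, cfg = cfg
    )
  })
  rbind_all(out, empty)
}

#' Count kidney replacement therapies per patient
#'
#' Counts every non-death state interval, including repeats (`PD, HD, PD`
#' is 3 KRTs) and counting a mixed or hybrid phase as one modality in its
#' own right — even one day spent in a KRT counts.
#'
#' @param states state-sequence data.frame ([classify_states()] output).
#' @return data.frame `patient_id`, `n_krt`.
#' @export
count_krt_modalities <- function(states) {
  if (!is.data.frame(states) || nrow(states) == 0L) {
    return(data.frame(patient_id = character(), n_krt = integer(),
                      stringsAsFactors = FALSE))
  }
  krt <- states[states$state != "DEATH", , drop = FALSE]
  ids <- unique(states$patient_id)
  n <- vapply(ids, function(p) sum(krt$patient_id == p), integer(1))
  data.frame(patient_id = ids, n_krt = unname(n), stringsAsFactors = FALSE)
}
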