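# Independent oracles and fixture builders.  The oracles deliberately use
# naive day-by-day loops (coverage) and base rle() (segmentation) so they
# share no code path with the package implementation.

# day-by-day scan: returns data.frame(day, modality) for one patient
oracle_coverage_one <- function(pd, tol, censor_day = NA) {
  hd <- sort(unique(pd$day[pd$event == "HD"]))
  pdd <- sort(unique(pd$day[pd$event == "PD"]))
  kt <- sort(unique(pd$day[pd$event == "KT"]))
  death <- pd$day[pd$event == "DEATH"]
  death <- if (length(death) == 1) death else NA
  lo <- min(pd$day)
  hi <- if (!is.na(censor_day)) max(censor_day, max(pd$day)) else max(pd$day)
  if (!is.na(death)) hi <- min(hi, death - 1)
  if (hi < lo) {
    return(data.frame(day = integer(), modality = character()))
  }
  mod <- rep("none", hi - lo + 1)
  for (d in lo:hi) {
    i <- d - lo + 1
    if (d %in% hd) {
      mod[i] <- "HD"
    } else {
      before <- hd[hd < d]
      after <- hd[hd > d]
      if (length(before) > 0 && length(after) > 0 &&
          min(after) - max(before) <= tol) {
        mod[i] <- "HD"
      } else if (d %in% pdd) {
        mod[i] <- "PD"
      }
    }
  }
  for (k in kt) {
    if (k > hi) next
    d <- k
    while (d <= hi) {
      if (d > k && (d %in% hd || d %in% pdd)) break
      mod[d - lo + 1] <- "KT"
      d <- d + 1
    }
  }
  keep <- mod != "none"
  data.frame(day = as.integer((lo:hi)[keep]), modality = mod[keep],
             stringsAsFactors = FALSE)
}

oracle_coverage <- function(records, tol = 7, patients = NULL) {
  out <- lapply(split(records, factor(records$patient_id,
                                      levels = unique(records$patient_id))),
                function(pd) {
    cens <- NA
    if (!is.null(patients)) {
      row <- patients[patients$patient_id == pd$patient_id[1], , drop = FALSE]
      if (nrow(row) == 1) cens <- row$censor_day
    }
    cv <- oracle_coverage_one(pd, tol, cens)
    if (nrow(cv) == 0) return(NULL)
    cbind(patient_id = pd$patient_id[1], cv, stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(patient_id = character(), day = integer(),
                      modality = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# run-length encoding over the full day-expanded vector, "none" for gaps
oracle_segment <- function(coverage) {
  out <- lapply(split(coverage, factor(coverage$patient_id,
                                       levels = unique(coverage$patient_id))),
                function(cv) {
    full <- rep("none", max(cv$day) - min(cv$day) + 1)
    full[cv$day - min(cv$day) + 1] <- cv$modality
    r <- rle(full)
    ends <- cumsum(r$lengths) + min(cv$day) - 1
    starts <- ends - r$lengths + 1
    keep <- r$values != "none"
    if (!any(keep)) return(NULL)
    data.frame(patient_id = cv$patient_id[1], modality = r$values[keep],
               start_day = as.integer(starts[keep]),
               end_day = as.integer(ends[keep]),
               duration_days = as.integer(r$lengths[keep]),
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# random small event stream over at most `max_days` days
random_stream <- function(id, max_days = 120) {
  span <- sample(5:max_days, 1)
  days <- 0:(span - 1)
  ev_day <- integer(0)
  ev <- character(0)
  if (runif(1) < 0.8) {   # some HD sessions at random days
    hd <- sort(sample(days, sample(1:min(20, span), 1)))
    ev_day <- c(ev_day, hd); ev <- c(ev, rep("HD", length(hd)))
  }
  if (runif(1) < 0.8) {   # one or two PD coverage ranges
    for (r in seq_len(sample(1:2, 1))) {
      a <- sample(days, 1); b <- min(span - 1, a + sample(0:40, 1))
      ev_day <- c(ev_day, a:b); ev <- c(ev, rep("PD", b - a + 1))
    }
  }
  if (runif(1) < 0.2) {   # occasionally a transplant
    ev_day <- c(ev_day, sample(days, 1)); ev <- c(ev, "KT")
  }
  if (length(ev_day) == 0) {
    ev_day <- sample(days, 1); ev <- "PD"
  }
  if (runif(1) < 0.3) {   # sometimes death right after the last event
    ev_day <- c(ev_day, max(ev_day) + 1); ev <- c(ev, "DEATH")
  }
  df <- unique(data.frame(patient_id = id, day = ev_day, event = ev,
                          stringsAsFactors = FALSE))
  df[order(df$day), ]
}

# event stream from explicit (modality, n_days) spells, mimicking claims
# streams: PD daily, HD thrice weekly (days 1/3/5), KT single event
stream_from_spells <- function(spells, id = "A", start = 1, death = FALSE) {
  day <- start
  ev_day <- integer(0); ev <- character(0)
  for (sp in spells) {
    n <- sp[[2]]
    if (sp[[1]] == "PD") {
      ev_day <- c(ev_day, day:(day + n - 1)); ev <- c(ev, rep("PD", n))
    } else if (sp[[1]] == "HD") {
      off <- as.vector(outer(c(0, 2, 4), seq(0, n, by = 7), `+`))
      off <- sort(off[off <= n - 1])
      ev_day <- c(ev_day, day + off); ev <- c(ev, rep("HD", length(off)))
    } else if (sp[[1]] == "KT") {
      ev_day <- c(ev_day, day); ev <- c(ev, "KT")
    }
    day <- day + n
  }
  if (death) {
    ev_day <- c(ev_day, day); ev <- c(ev, "DEATH")
  }
  data.frame(patient_id = id, day = ev_day, event = ev,
             stringsAsFactors = FALSE)
}

# hand-built state table row helper
state_rows <- function(id, states, starts, ends, censored = NULL) {
  if (is.null(censored)) {
    censored <- c(rep(FALSE, length(states) - 1),
                  states[length(states)] != "DEATH")
  }
  data.frame(patient_id = id, state = states, start_day = starts,
             end_day = ends, censored = censored, stringsAsFactors = FALSE)
}

label_seq <- function(tbl) {
  sp <- split(tbl, factor(tbl$patient_id, levels = unique(tbl$patient_id)))
  vapply(sp, function(x) paste(x$state[order(x$start_day)], collapse = ","),
         character(1))
}

recovery_rate <- function(truth, states) {
  t_l <- label_seq(truth)
  s_l <- label_seq(states)
  ids <- names(t_l)
  mean(vapply(ids, function(p) identical(t_l[[p]], s_l[[p]]), logical(1)))
}
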