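test_that("transitions are adjacent state pairs in timeline order", {
  one <- state_rows("A", "PD", 1, 100)
  expect_equal(nrow(extract_transitions(one)), 0)
  three <- state_rows("B", c("PD", "HD", "PD"), c(1, 101, 111), c(100, 110, 300))
  tr <- extract_transitions(three)
  expect_equal(tr$from_state, c("PD", "HD"))
  expect_equal(tr$to_state, c("HD", "PD"))
  expect_equal(tr$day, c(101, 111))
  expect_equal(tr$order_index, 1:2)
  expect_true(all(tr$from_state != tr$to_state))
  expect_false("DEATH" %in% tr$from_state)
})

test_that("cohort transfer counts dominate patient counts (pigeonhole)", {
  coh <- generate_cohort(cohort_config(200, seed = 41))
  st <- classify_states(coh$sessions, coh$patients)
  tr <- extract_transitions(st)
  pd_hd <- tr[tr$from_state == "PD" & tr$to_state == "HD", ]
  expect_gte(nrow(pd_hd), length(unique(pd_hd$patient_id)))
  # conservation: total transitions = sum over patients of (states - 1)
  per_patient <- table(st$patient_id)
  expect_equal(nrow(tr), sum(per_patient - 1))
})

test_that("first-transition groups partition the cohort", {
  st <- rbind(state_rows("A", c("PD", "DEATH"), c(1, 51), c(50, 51)),
              state_rows("B", c("HD", "PD", "HD"), c(1, 31, 101), c(30, 100, 200)),
              state_rows("C", "PD", 1, 400),
              state_rows("D", c("MIX", "PD"), c(1, 41), c(40, 300)))
  grp <- first_transition_group(st)
  expect_equal(grp$group[grp$patient_id == "A"], "PD->DEATH")
  expect_equal(grp$group[grp$patient_id == "B"], "HD->PD")
  expect_equal(grp$group[grp$patient_id == "C"], "none")
  expect_equal(grp$group[grp$patient_id == "D"], "other")
  coh <- generate_cohort(cohort_config(150, seed = 43))
  stc <- classify_states(coh$sessions, coh$patients)
  grpc <- first_transition_group(stc)
  expect_equal(nrow(grpc), length(unique(stc$patient_id)))
  expect_equal(sum(table(grpc$group)), 150)
})

test_that("pattern table groups leading states and uses completed durations", {
  one <- state_rows("A", c("PD", "DEATH"), c(1, 11), c(10, 11))
  tab <- pattern_table(one, depth = 3)
  expect_equal(tab$pattern, "PD-DEATH")
  expect_equal(tab$n_patients, 1)
  expect_equal(tab$median_days_1st, 10)
  expect_true(is.na(tab$median_days_2nd))  # death carries no duration
  # censored first intervals are excluded from medians but kept in counts
  two <- rbind(state_rows("B", "PD", 1, 400),
               state_rows("C", "PD", 1, 100))
  tab2 <- pattern_table(two, depth = 2)
  expect_equal(tab2$n_patients, 2)
  expect_true(is.na(tab2$median_days_1st))
})

test_that("pattern table matches a brute-force group-by on random sequences", {
  set.seed(44)
  coh <- generate_cohort(cohort_config(50, seed = 44))
  st <- classify_states(coh$sessions, coh$patients)
  tab <- pattern_table(st, depth = 3)
  sp <- split(st, st$patient_id)
  pats <- vapply(sp, function(x) {
    x <- x[order(x$start_day), ]
    paste(head(x$state, 3), collapse = "-")
  }, character(1))
  for (p in unique(pats)) {
    row <- tab[tab$pattern == p, ]
    expect_equal(row$n_patients, sum(pats == p))
    d1 <- vapply(sp[pats == p], function(x) {
      x <- x[order(x$start_day), ]
      if (x$state[1] == "DEATH" || x$censored[1]) NA_real_
      else as.numeric(x$end_day[1] - x$start_day[1] + 1)
    }, numeric(1))
    expect_equal(row$median_days_1st,
                 unname(stats::median(d1, na.rm = TRUE)),
                 info = p)
  }
  expect_equal(sum(tab$n_patients), 50)
})

test_that("modality-count histogram caps at 10 and matches quantile oracle", {
  alt <- state_rows("A", rep(c("PD", "HD"), 6),
                    seq(1, by = 10, length.out = 12),
                    seq(10, by = 10, length.out = 12))
  d <- modality_count_distribution(alt)
  expect_equal(d$histogram$n_patients[10], 1)
  expect_equal(sum(d$histogram$n_patients), 1)
  coh <- generate_cohort(cohort_config(120, seed = 45))
  st <- classify_states(coh$sessions, coh$patients)
  d2 <- modality_count_distribution(st)
  counts <- count_krt_modalities(st)$n_krt
  expect_equal(sum(d2$histogram$n_patients), 120)
  expect_equal(d2$median, unname(stats::quantile(counts, 0.5, type = 2)))
  expect_equal(d2$q1, unname(stats::quantile(counts, 0.25, type = 2)))
  expect_equal(d2$q3, unname(stats::quantile(counts, 0.75, type = 2)))
})

test_that("point prevalence matches a hand-built timeline and is nested", {
  st <- rbind(
    state_rows("A", c("PD", "DEATH"), c(1, 201), c(200, 201)),   # dies day 201
    state_rows("B", c("PD", "KT"), c(1, 301), c(300, 900)),      # transplanted
    state_rows("C", c("HD", "PD"), c(1, 101), c(100, 900))       # on PD late
  )
  p100 <- point_prevalence(st, 100)
  expect_equal(p100[, c("alive", "on_dialysis", "on_pd")],
               data.frame(alive = 3L, on_dialysis = 3L, on_pd = 2L))
  p250 <- point_prevalence(st, 250)
  expect_equal(p250$alive, 2)       # A is dead
  expect_equal(p250$on_dialysis, 2) # B still on PD, C on PD
  p400 <- point_prevalence(st, 400)
  expect_equal(p400$on_dialysis, 1) # B now transplanted
  expect_equal(p400$on_pd, 1)
  coh <- generate_cohort(cohort_config(100, seed = 47))
  stc <- classify_states(coh$sessions, coh$patients)
  for (t in c(0, 365, 1095, 3000)) {
    pv <- point_prevalence(stc, t, coh$patients)
    expect_lte(pv$on_pd, pv$on_dialysis)
    expect_lte(pv$on_dialysis, pv$alive)
  }
})

test_that("registry-style definitions suppress short spells", {
  st <- state_rows("A", c("PD", "HD", "PD"), c(1, 201, 210), c(200, 209, 382))
  cmp <- compare_transition_definitions(st, 30)
  expect_equal(cmp$n_transitions[cmp$definition == "exhaustive"], 2)
  expect_equal(cmp$n_transitions[cmp$definition == "min_30d"], 0)
  # a 60-day HD spell before death survives the 30-day rule
  st2 <- state_rows("B", c("PD", "HD", "DEATH"), c(1, 201, 261), c(200, 260, 261))
  cmp2 <- compare_transition_definitions(st2, 30)
  expect_equal(cmp2$n_transitions[cmp2$definition == "exhaustive"], 2)
  expect_equal(cmp2$n_transitions[cmp2$definition == "min_30d"], 2)
  # a 9-day HD spell before death is absorbed into the preceding PD
  st3 <- state_rows("C", c("PD", "HD", "DEATH"), c(1, 201, 210), c(200, 209, 210))
  cmp3 <- compare_transition_definitions(st3, 30)
  expect_equal(cmp3$n_transitions[cmp3$definition == "min_30d"], 1)
})

test_that("registry counts decrease monotonically with the threshold", {
  coh <- generate_cohort(cohort_config(150, seed = 49))
  st <- classify_states(coh$sessions, coh$patients)
  cmp <- compare_transition_definitions(st, c(30, 60, 90, 180))
  expect_true(all(diff(cmp$n_transitions) <= 0))
  expect_lte(cmp$n_transitions[2], cmp$n_transitions[1])
})
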