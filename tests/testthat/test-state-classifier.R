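test_that("weekly PD+HD co-occurrence over 120 days is one hybrid interval", {
  s <- rbind(data.frame(patient_id = "A", day = 0:119, event = "PD"),
             data.frame(patient_id = "A", day = seq(0, 119, 7), event = "HD"))
  hyb <- detect_hybrid(s)
  expect_equal(nrow(hyb), 1)
  expect_equal(hyb$start_day, 0)
  expect_equal(hyb$end_day, 119)
})

test_that("a single modality or a sub-threshold span is never hybrid", {
  pd_only <- data.frame(patient_id = "A", day = 0:200, event = "PD")
  expect_equal(nrow(detect_hybrid(pd_only)), 0)
  s56 <- rbind(data.frame(patient_id = "A", day = 0:55, event = "PD"),
               data.frame(patient_id = "A", day = seq(0, 55, 7), event = "HD"))
  expect_equal(nrow(detect_hybrid(s56)), 0)
})

test_that("three short alternating episodes form one mixed interval", {
  cv <- data.frame(patient_id = "A", day = 1:45,
                   modality = rep(c("PD", "HD", "PD"), c(20, 10, 15)))
  mix <- detect_mixed(segment_episodes(cv))
  expect_equal(nrow(mix), 1)
  expect_equal(mix$end_day - mix$start_day + 1, 45)
})

test_that("episodes at or above the one-month threshold block mixed runs", {
  cv <- data.frame(patient_id = "A", day = 1:460,
                   modality = rep(c("PD", "HD"), c(400, 60)))
  expect_equal(nrow(detect_mixed(segment_episodes(cv))), 0)
  # a 40-day leading episode stays out, the following three short ones are MIX
  cv2 <- data.frame(patient_id = "A", day = 1:63,
                    modality = rep(c("PD", "HD", "PD", "HD"), c(40, 10, 5, 8)))
  mix <- detect_mixed(segment_episodes(cv2))
  expect_equal(nrow(mix), 1)
  expect_equal(mix$start_day, 41)
  expect_equal(mix$end_day, 63)
})

test_that("a transplant episode interrupts a mixed run", {
  cv <- data.frame(patient_id = "A", day = 1:40,
                   modality = rep(c("PD", "KT", "HD", "PD"), c(10, 10, 10, 10)))
  expect_equal(nrow(detect_mixed(segment_episodes(cv))), 0)
})

test_that("short HD transfer inside PD reconstructs as PD-HD-PD", {
  s <- stream_from_spells(list(list("PD", 262), list("HD", 9), list("PD", 173)))
  st <- classify_states(s)
  expect_equal(st$state, c("PD", "HD", "PD"))
  expect_equal(st$censored, c(FALSE, FALSE, TRUE))
})

test_that("death closes the sequence with a one-day DEATH interval", {
  s <- stream_from_spells(list(list("PD", 100)), death = TRUE)
  st <- classify_states(s)
  expect_equal(st$state, c("PD", "DEATH"))
  expect_equal(st$start_day[2], 101)
  expect_equal(st$end_day[2], 101)
  expect_false(any(st$censored))
})

test_that("hybrid takes precedence over mixed and raw episodes on overlap", {
  ep <- data.frame(patient_id = "A",
                   modality = c("PD", "HD", "PD"),
                   start_day = c(1, 101, 121),
                   end_day = c(100, 120, 240))
  ep$duration_days <- ep$end_day - ep$start_day + 1
  hyb <- data.frame(patient_id = "A", start_day = 90, end_day = 200)
  mix <- data.frame(patient_id = "A", start_day = 101, end_day = 140)
  st <- build_state_sequence(ep, hyb, mix, death_day = NA, censor_day = 240)
  expect_equal(st$state, c("PD", "HYB", "PD"))
  expect_equal(st$start_day, c(1, 90, 201))
  expect_equal(st$end_day, c(89, 200, 240))
})

test_that("state sequences satisfy the six-state closure and merge invariants", {
  coh <- generate_cohort(cohort_config(120, seed = 31))
  st <- classify_states(coh$sessions, coh$patients)
  expect_true(all(st$state %in% c("PD", "HD", "MIX", "HYB", "KT", "DEATH")))
  for (x in split(st, st$patient_id)) {
    x <- x[order(x$start_day), ]
    expect_true(all(x$state[-1] != x$state[-nrow(x)]))        # merged
    expect_true(all(x$start_day[-1] > x$end_day[-nrow(x)]))   # disjoint, ordered
    if ("DEATH" %in% x$state) {
      expect_equal(which(x$state == "DEATH"), nrow(x))
      expect_equal(x$start_day[nrow(x)], x$end_day[nrow(x)])
    }
  }
  # classification is deterministic / idempotent
  expect_identical(st, classify_states(coh$sessions, coh$patients))
})

test_that("mixed intervals decompose into enough short episodes, hybrids are long", {
  cfg <- analysis_config()
  mix_heavy <- c(PD_MIX_PD = 0.3, MIX_PD = 0.2, PD_HYB = 0.3, PD_HD = 0.2)
  coh <- generate_cohort(cohort_config(80, archetype_mix = mix_heavy, seed = 33))
  cv <- build_daily_coverage(coh$sessions, cfg$hd_gap_tolerance, coh$patients)
  ep <- segment_episodes(cv)
  mix <- detect_mixed(ep, cfg)
  expect_gt(nrow(mix), 0)
  for (r in seq_len(nrow(mix))) {
    inside <- ep[ep$patient_id == mix$patient_id[r] &
                   ep$start_day >= mix$start_day[r] &
                   ep$end_day <= mix$end_day[r], ]
    expect_gte(nrow(inside), cfg$mixed_min_run)
    expect_true(all(inside$duration_days < cfg$mixed_max_days))
  }
  hyb <- detect_hybrid(coh$sessions, cfg)
  expect_gt(nrow(hyb), 0)
  expect_true(all(hyb$end_day - hyb$start_day + 1 >= cfg$hybrid_min_days))
})

test_that("raising the mixed threshold never loses MIX patients", {
  mix_heavy <- c(PD_MIX_PD = 0.4, MIX_PD = 0.3, HD_MIX_PD = 0.3)
  coh <- generate_cohort(cohort_config(80, archetype_mix = mix_heavy, seed = 35))
  n_mix <- vapply(c(20, 30, 45), function(th) {
    st <- classify_states(coh$sessions, coh$patients,
                          analysis_config(mixed_max_days = th))
    length(unique(st$patient_id[st$state == "MIX"]))
  }, integer(1))
  expect_true(all(diff(n_mix) >= 0))
})

test_that("KRT counts include repeats and count MIX/HYB as modalities", {
  one <- state_rows("A", "PD", 1, 50)
  expect_equal(count_krt_modalities(one)$n_krt, 1)
  four <- state_rows("B", c("PD", "HD", "PD", "KT"),
                     c(1, 51, 61, 201), c(50, 60, 200, 400))
  expect_equal(count_krt_modalities(four)$n_krt, 4)
  mixpd <- state_rows("C", c("MIX", "PD", "DEATH"),
                      c(1, 41, 301), c(40, 300, 301))
  expect_equal(count_krt_modalities(mixpd)$n_krt, 2)
})
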