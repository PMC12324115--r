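test_that("HD sessions within the gap tolerance are bridged into one stretch", {
  s <- data.frame(patient_id = "A", day = c(1, 3, 5, 8), event = "HD")
  cv <- build_daily_coverage(s, hd_gap_tolerance = 7)
  expect_equal(cv$day, 1:8)
  expect_true(all(cv$modality == "HD"))
  # trailing tolerance is not appended and wide gaps are not bridged
  s2 <- data.frame(patient_id = "A", day = c(1, 20), event = "HD")
  cv2 <- build_daily_coverage(s2, hd_gap_tolerance = 7)
  expect_equal(cv2$day, c(1, 20))
})

test_that("a single HD session splits PD coverage (day-level HD priority)", {
  s <- rbind(data.frame(patient_id = "A", day = 1:30, event = "PD"),
             data.frame(patient_id = "A", day = 15, event = "HD"))
  cv <- build_daily_coverage(s)
  expect_equal(cv$modality[cv$day == 15], "HD")
  expect_true(all(cv$modality[cv$day != 15] == "PD"))
  ep <- segment_episodes(cv)
  expect_equal(ep$modality, c("PD", "HD", "PD"))
  expect_equal(ep$duration_days, c(14, 1, 15))
})

test_that("empty input gives empty coverage and episodes", {
  empty <- data.frame(patient_id = character(), day = integer(),
                      event = character())
  expect_equal(nrow(build_daily_coverage(empty)), 0)
  expect_equal(nrow(segment_episodes(build_daily_coverage(empty))), 0)
})

test_that("a one-day episode is kept with duration 1", {
  s <- data.frame(patient_id = "A", day = 5, event = "PD")
  ep <- segment_episodes(build_daily_coverage(s))
  expect_equal(ep$duration_days, 1)
  expect_equal(ep$start_day, 5)
  expect_equal(ep$end_day, 5)
})

test_that("transplant coverage runs from the KT event to the next dialysis day", {
  s <- rbind(data.frame(patient_id = "A", day = 1:10, event = "PD"),
             data.frame(patient_id = "A", day = 11, event = "KT"),
             data.frame(patient_id = "A", day = 40:45, event = "PD"))
  cv <- build_daily_coverage(s)
  expect_true(all(cv$modality[cv$day %in% 11:39] == "KT"))
  expect_true(all(cv$modality[cv$day %in% 40:45] == "PD"))
  # and without further dialysis, KT extends to the censoring day
  s2 <- rbind(data.frame(patient_id = "A", day = 1:10, event = "PD"),
              data.frame(patient_id = "A", day = 11, event = "KT"))
  pats <- data.frame(patient_id = "A", entry_day = 1, censor_day = 60)
  cv2 <- build_daily_coverage(s2, patients = pats)
  expect_equal(max(cv2$day[cv2$modality == "KT"]), 60)
})

test_that("coverage and segmentation match the day-scan and rle oracles", {
  set.seed(42)
  streams <- lapply(1:100, function(i) random_stream(sprintf("S%03d", i)))
  records <- do.call(rbind, streams)
  cv <- build_daily_coverage(records, hd_gap_tolerance = 7)
  expect_equal(cv, oracle_coverage(records, tol = 7))
  expect_equal(segment_episodes(cv), oracle_segment(cv))
})

test_that("episodes partition the covered days and segmentation is idempotent", {
  set.seed(43)
  records <- do.call(rbind, lapply(1:40, function(i) {
    random_stream(sprintf("S%03d", i))
  }))
  cv <- build_daily_coverage(records)
  ep <- segment_episodes(cv)
  # partition: episode day-sets equal covered days, with no overlap
  ep_days <- unlist(Map(`:`, ep$start_day, ep$end_day))
  ep_ids <- rep(ep$patient_id, ep$duration_days)
  expect_equal(sort(paste(ep_ids, ep_days)),
               sort(paste(cv$patient_id, cv$day)))
  # idempotence: re-segmenting coverage rebuilt from episodes changes nothing
  rebuilt <- data.frame(patient_id = ep_ids, day = ep_days,
                        modality = rep(ep$modality, ep$duration_days),
                        stringsAsFactors = FALSE)
  expect_equal(segment_episodes(rebuilt), ep)
})

test_that("bad session tables are rejected with informative errors", {
  expect_error(build_daily_coverage(data.frame(patient_id = "A", day = 1,
                                               event = "XX")),
               "unknown event")
  expect_error(build_daily_coverage(data.frame(patient_id = "A", day = -1,
                                               event = "PD")),
               "day")
  two_deaths <- data.frame(patient_id = "A", day = c(1, 2),
                           event = c("DEATH", "DEATH"))
  expect_error(build_daily_coverage(two_deaths), "multiple DEATH")
  after_death <- data.frame(patient_id = "A", day = c(5, 6),
                            event = c("DEATH", "PD"))
  expect_error(build_daily_coverage(after_death), "after the DEATH")
  outside <- data.frame(patient_id = "A", day = 99, event = "PD")
  pats <- data.frame(patient_id = "A", entry_day = 0, censor_day = 50)
  expect_error(build_daily_coverage(outside, patients = pats),
               "outside the observation window")
  dup <- data.frame(patient_id = "A", day = c(1, 1), event = c("PD", "PD"))
  expect_warning(build_daily_coverage(dup), "duplicate")
})
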