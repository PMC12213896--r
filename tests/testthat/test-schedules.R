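test_that("RT schedules satisfy the 80 Gy closest-multiple rule", {
  s <- build_rt_schedule(2, 5)
  expect_equal(s$N_wks, 8)
  expect_equal(nrow(s$rt_windows), 40)
  expect_equal(total_rt_dose(s), 80)
  s2 <- build_rt_schedule(5, 1)
  expect_equal(s2$N_wks, 16)
  expect_equal(s2$t_end, 161280)
  # 75 Gy beats 90 Gy: oracle = exhaustive search over 1..100 weeks
  s3 <- build_rt_schedule(3, 5)
  expect_equal(s3$N_wks, 5)
  expect_equal(total_rt_dose(s3), 75)
  for (D in 1:5) for (nf in c(1, 3, 5)) {
    best <- which.min(abs(D * nf * (1:100) - 80))
    s <- build_rt_schedule(D, nf)
    expect_equal(s$N_wks, best)
    expect_lte(total_rt_dose(s), 84)
    if (80 %% (D * nf) == 0) expect_equal(total_rt_dose(s), 80)
  }
  expect_error(build_rt_schedule(6, 5), "0..5")
  expect_error(build_rt_schedule(2, 4), "N_frac")
})

test_that("HT schedules enforce the thermal cap", {
  s <- build_ht_schedule(0.001, 80)
  expect_equal(nrow(s$ht_windows), 80)
  expect_equal(s$t_end, 80 * 10080)
  expect_silent(build_ht_schedule(0.005, 8))       # total 0.04
  expect_error(build_ht_schedule(0.01, 9), "MTD")  # total 0.09
  expect_error(build_combined(2, 5, 0.011), "MTD") # 0.088 over 8 weeks
})

test_that("combined schedules interleave HT one minute after Monday RT", {
  cb <- build_combined(2, 5, 0.005)
  expect_equal(unname(cb$ht_windows[1, ]), c(11, 71))
  expect_equal(unname(cb$ht_windows[2, ]), c(10080 + 11, 10080 + 71))
  expect_equal(cb$N_wks, build_rt_schedule(2, 5)$N_wks)
  # degenerate combination reduces to RT-only windows
  cb0 <- build_combined(2, 5, 0)
  expect_equal(cb0$rt_windows, build_rt_schedule(2, 5)$rt_windows)
  expect_equal(nrow(cb0$ht_windows), 0)
  # HT alone anchors at the Monday slot itself
  ht <- build_ht_schedule(0.005, 2)
  expect_equal(unname(ht$ht_windows[, 1]), c(0, 10080))
})

test_that("fraction spacing follows the Mon-anchored day pattern", {
  et5 <- event_times(build_rt_schedule(2, 5))
  expect_equal(et5[et5 < 10080 & et5 %% 1440 == 0],
               c(0, 1440, 2880, 4320, 5760))
  s3 <- build_rt_schedule(3, 3)   # Mon/Wed/Fri
  expect_equal(unname(s3$rt_windows[1:3, 1]), c(0, 2880, 5760))
  s1 <- build_rt_schedule(5, 1)
  expect_equal(unname(s1$rt_windows[1:2, 1]), c(0, 10080))
})

test_that("event times bracket the horizon and windows never overlap", {
  expect_equal(event_times(null_schedule(8)), c(0, 80640))
  et <- event_times(build_combined(2, 5, 0.005))
  expect_equal(max(et), 80640)
  expect_true(!is.unsorted(et, strictly = TRUE))
  for (s in list(build_rt_schedule(2, 5), build_ht_schedule(0.005, 8),
                 build_combined(5, 3, 0.005))) {
    for (w in list(s$rt_windows, s$ht_windows)) {
      if (nrow(w) < 2) next
      expect_true(all(w[-1, 1] > w[-nrow(w), 2]))  # disjoint, ordered
    }
    if (nrow(s$rt_windows) > 0 && nrow(s$ht_windows) > 0) {
      # the Monday rule keeps HT clear of every RT window
      overlaps <- outer(seq_len(nrow(s$rt_windows)),
                        seq_len(nrow(s$ht_windows)),
                        Vectorize(function(i, j)
                          s$rt_windows[i, 1] <= s$ht_windows[j, 2] &&
                          s$ht_windows[j, 1] <= s$rt_windows[i, 2]))
      expect_false(any(overlaps))
    }
  }
})

test_that("schedules serialise to JSON with explicit windows", {
  f <- tempfile(fileext = ".json")
  write_schedule_json(build_combined(2, 5, 0.005), f)
  raw <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(raw$t_end, 80640)
  expect_equal(dim(raw$ht_windows), c(8, 2))
  expect_equal(raw$ht_windows[1, ], c(11, 71))
})
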