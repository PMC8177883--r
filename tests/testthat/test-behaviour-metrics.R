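test_that("segmentation partitions the block and labels the CS periods", {
  # block with no CS: a single 180 s ITI interval
  log <- manual_iti_log(5, 5)
  segs <- segment_periods(log)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$label, "iti")
  expect_equal(segs$duration_s, 180)

  # 6 s CS with a shield at onset + 3: 3 s unshielded + 3 s shielded
  log2 <- one_cs_log(shield_at = 24.5)
  segs2 <- segment_periods(log2)
  expect_equal(segs2$duration_s[segs2$label == "cs_unshielded"], 3)
  expect_equal(segs2$duration_s[segs2$label == "cs_shielded"], 3)
  # the 1.5 s pending window is its own label, in neither denominator
  expect_equal(segs2$duration_s[segs2$label == "cs_pending"], 1.5)
  # durations tile the whole timeline exactly
  expect_equal(sum(segs2$duration_s), max(log2$time_s))
  expect_equal(sum(segs2$duration_s[segs2$label == "iti"]),
               180 - 1.5 - 6)
})

test_that("the post-trading tail is carved out of the rate denominators", {
  log <- event_log("x", 1L, "punish",
                   time_s = c(10, 179, 180.5, 181, 186.5, 186.5),
                   kind = c("click", "cs_trigger", "cs_onset",
                            "reward", "attack", "cs_offset"),
                   planet = c("R1", "R1", "R1", "R1", "none", "R1"),
                   cs_type = c("none", "CS+", "CS+", "none", "CS+", "CS+"),
                   points_delta = c(0, 0, 0, 100, -20, 0))
  segs <- segment_periods(log)
  expect_true("post_trading_tail" %in% segs$label)
  expect_equal(sum(segs$duration_s[segs$label == "post_trading_tail"]), 6.5)
  # CS time past 180 s contributes nothing to the CS denominator
  expect_equal(sum(segs$duration_s[segs$label == "cs_unshielded"]), 0)
  expect_equal(sum(segs$duration_s), max(log$time_s))
})

test_that("preference ratio matches its defining arithmetic", {
  expect_equal(preference_ratio(manual_iti_log(60, 60), 1)$ratio, 0.5)
  expect_equal(preference_ratio(manual_iti_log(0, 45), 1)$ratio, 0)
  expect_equal(preference_ratio(manual_iti_log(30, 90), 1)$ratio, 0.25)
  expect_true(is.na(preference_ratio(manual_iti_log(0, 0), 1)$ratio))
  # relabelling symmetry: swapping planets reflects the ratio about 0.5
  log <- manual_iti_log(30, 90)
  swapped <- log
  swapped$planet <- c(R1 = "R2", R2 = "R1", none = "none")[log$planet]
  expect_equal(preference_ratio(swapped, 1)$ratio,
               1 - preference_ratio(log, 1)$ratio)
})

test_that("suppression ratios honour the stated anchors", {
  # equal CS and ITI rates -> 0.5 (no suppression)
  iti_T <- 180 - 7.5   # ITI time once pending + CS are removed
  n_iti <- round(iti_T / 60 * 20)  # 20 clicks/min
  cs_T <- 6
  n_cs <- 2            # 2 clicks in 6 s = 20/min
  log <- one_cs_log(iti_clicks_r1 = n_iti, cs_clicks = n_cs)
  sup <- suppression_ratios(log)
  expect_equal(sup$csplus, 0.5, tolerance = 0.01)
  expect_true(is.na(sup$csminus)) # no CS- exposure -> missing

  # complete silence during the CS -> 0
  log0 <- one_cs_log(iti_clicks_r1 = 60, cs_clicks = 0)
  expect_equal(suppression_ratios(log0)$csplus, 0)

  # CS rate 30/min vs ITI rate 90/min -> 0.25
  n_iti <- round(iti_T / 60 * 90)
  n_cs <- 3 # 3 clicks in 6 s = 30/min
  log25 <- one_cs_log(iti_clicks_r1 = n_iti, cs_clicks = n_cs)
  expect_equal(suppression_ratios(log25)$csplus, 0.25, tolerance = 0.01)
  # the literal quotient variant returns CS/ITI instead
  expect_equal(suppression_ratios(log25, formula = "literal")$csplus,
               1 / 3, tolerance = 0.04)
})

test_that("shielded CS time is excluded from the suppression denominator", {
  # clicks only in the unshielded 3 s window
  log <- one_cs_log(shield_at = 24.5, iti_clicks_r1 = 100, cs_clicks = 2)
  sup <- suppression_ratios(log)
  segs <- segment_periods(log)
  expect_equal(sum(segs$duration_s[segs$label == "cs_unshielded"]), 3)
  # 2 clicks in 3 s = 40/min against the ITI rate
  iti_rate <- sup$iti_rate
  expect_equal(sup$csplus, 40 / (40 + iti_rate), tolerance = 0.01)
})

test_that("shield use is the percentage of offered shields taken", {
  mk <- function(offered, taken, cs = "CS+") {
    times <- c(); kinds <- c(); cst <- c()
    t <- 10
    for (i in seq_len(offered)) {
      times <- c(times, t, t + 1.5, t + 4.5)
      kinds <- c(kinds, "cs_trigger", "cs_onset", "shield_offered")
      cst <- c(cst, cs, cs, cs)
      if (i <= taken) {
        times <- c(times, t + 5)
        kinds <- c(kinds, "shield_activated")
        cst <- c(cst, cs)
      }
      times <- c(times, t + 7.5)
      kinds <- c(kinds, "cs_offset")
      cst <- c(cst, cs)
      t <- t + 10
    }
    event_log("m", 1L, "punish", c(times, 180), c(kinds, "block_end"),
              cs_type = c(cst, "none"))
  }
  expect_equal(shield_use(mk(5, 0))$csplus, 0)
  expect_equal(shield_use(mk(2, 2))$csplus, 100)
  expect_equal(shield_use(mk(4, 3))$csplus, 75)
  expect_true(is.na(shield_use(mk(2, 1))$csminus)) # none offered for CS-
})

test_that("pre-punishment blocks collapse by simple means", {
  s <- tibble::tibble(
    participant_id = "p", block = c(1L, 2L, 3L), phase = c("pre", "pre",
                                                           "punish"),
    iti_rate_r1 = c(60, 80, 50), iti_rate_r2 = c(60, 80, 70),
    overall_iti_rate = c(120, 160, 120),
    preference_ratio = c(0.48, 0.52, 0.4),
    points_gained = c(900, 1100, 500),
    suppression_csplus = NA_real_, suppression_csminus = NA_real_,
    shield_use_csplus = NA_real_, shield_use_csminus = NA_real_)
  cp <- collapse_pre(s)
  pre <- cp[cp$phase == "pre", ]
  expect_equal(nrow(pre), 1)
  expect_equal(pre$preference_ratio, 0.5)
  expect_equal(pre$iti_rate_r1, 70)
  expect_equal(pre$points_gained, 1000)
  expect_equal(nrow(cp[cp$phase == "punish", ]), 1)
})

test_that("exclusion rules enforce response-time bounds and catch questions", {
  sr <- tibble::tibble(
    participant_id = rep(c("a", "b", "c", "d"), each = 2),
    rt_mean_s = c(10, 12, 45, 10, 8, 9, 10, 0.5))
  q <- tibble::tibble(
    participant_id = c("a", "b", "c", "d"),
    catch1_correct = c(TRUE, TRUE, FALSE, TRUE),
    catch2_correct = c(TRUE, TRUE, TRUE, TRUE))
  excl <- apply_exclusions(sr, q)
  expect_equal(excl$retained, "a")
  expect_equal(
    excl$excluded$reason[match(c("b", "c", "d"),
                               excl$excluded$participant_id)],
    c("response_time", "catch_question", "response_time"))
  # missing questionnaire -> incomplete
  excl2 <- apply_exclusions(sr, q[q$participant_id != "a", ])
  expect_equal(
    excl2$excluded$reason[excl2$excluded$participant_id == "a"],
    "incomplete")
})

test_that("simulated-log metrics are reproducible and ratios stay in range", {
  ps <- fixture_summary()
  expect_true(all(ps$preference_ratio >= 0 & ps$preference_ratio <= 1,
                  na.rm = TRUE))
  for (m in c("suppression_csplus", "suppression_csminus")) {
    expect_true(all(ps[[m]] >= 0 & ps[[m]] <= 1, na.rm = TRUE))
  }
  for (m in c("shield_use_csplus", "shield_use_csminus")) {
    expect_true(all(ps[[m]] >= 0 & ps[[m]] <= 100, na.rm = TRUE))
  }
  ps2 <- participant_summary(fixture_cohort()$events)
  expect_identical(ps, ps2)
})

test_that("a no-punishment cohort keeps group mean preference at indifference", {
  cfg <- task_config(cs_prob = 0)
  ratios <- vapply(1:15, function(i) {
    sim <- simulate_session(cfg, policy_agent(make_agent("sensitive")),
                            seed = 900, p_index = i)
    ps <- participant_summary(sim$log)
    mean(ps$preference_ratio[ps$phase == "punish"], na.rm = TRUE)
  }, numeric(1))
  ci <- 1.96 * sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 0.5), ci + 0.02)
})
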