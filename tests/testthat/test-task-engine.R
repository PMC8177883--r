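test_that("clicks start trades only on free planets and rewards resolve after the countdown", {
  # forced rewards: every trade must succeed and pay at the countdown end
  cfg <- forced_config(reward_prob = 1, cs_prob = 0)
  pol <- policy_scripted_clicker(interval_s = 0.5, planets = "R1",
                                 first_click_s = 10)
  sim <- simulate_session(cfg, pol, seed = 1)
  log <- sim$log[sim$log$block == 1, ]
  ts <- log[log$kind == "trade_start", ]
  rw <- log[log$kind == "reward", ]
  expect_equal(ts$time_s[1], 10)
  expect_equal(rw$time_s[1], 12) # 2 s trading signal
  expect_true(all(rw$points_delta == 100))
  # trades on one planet are at least one countdown apart
  expect_true(all(diff(ts$time_s) >= cfg$trade_countdown_s - 1e-9))
  # clicks at 0.5 s spacing outnumber trades: countdown clicks don't restart
  expect_gt(sum(log$kind == "click"), nrow(ts))
  expect_equal(sum(log$kind == "no_reward"), 0)
})

test_that("CS scheduling follows the trigger-delay-onset rule and blocked rolls are lost", {
  # forced CS: first eligible click must trigger, delay 1.5 s to onset
  cfg <- forced_config(cs_prob = 1, reward_prob = 0, shield_avail_prob = 0)
  pol <- policy_scripted_clicker(interval_s = 0.5, planets = "R1",
                                 first_click_s = 20)
  sim <- simulate_session(cfg, pol, seed = 1)
  pun <- sim$log[sim$log$phase == "punish", ]
  trig <- pun[pun$kind == "cs_trigger", ]
  ons <- pun[pun$kind == "cs_onset", ]
  expect_equal(trig$time_s[1], 20)
  expect_equal(ons$time_s[1], 21.5)
  expect_true(all(ons$cs_type == "CS+")) # R1 exclusively yields CS+
  # a second click at 20.5 fell inside the pending window: no second trigger
  # before the first episode ends at 21.5 + 6
  expect_gte(trig$time_s[2], 27.5)
  # at most one CS at a time even with cs_prob = 1
  expect_length(validate_event_log(sim$log), 0)
})

test_that("unshielded CS+ attacks remove a rounded 20% of current points at onset + 6 s", {
  # build up exactly 1000 points (10 forced rewards), then force a CS+
  cfg <- forced_config(reward_prob = 1, cs_prob = 1, shield_avail_prob = 0)
  pol <- policy_scripted_clicker(interval_s = 2.5, planets = "R1",
                                 first_click_s = 2.5)
  sim <- simulate_session(cfg, pol, seed = 1)
  atk <- sim$log[sim$log$kind == "attack", ]
  expect_gt(nrow(atk), 0)
  for (i in seq_len(nrow(atk))) {
    before <- atk$points_total[i] - atk$points_delta[i]
    expect_equal(atk$points_delta[i], -round(0.2 * max(before, 0)))
  }
  # attack lands exactly cs_duration_s after its onset
  ons <- sim$log[sim$log$kind == "cs_onset", ]
  expect_equal(atk$time_s[1], ons$time_s[1] + cfg$cs_duration_s)
})

test_that("CS- never attacks and never changes points", {
  cfg <- forced_config(cs_prob = 1, shield_avail_prob = 0)
  pol <- policy_scripted_clicker(interval_s = 0.5, planets = "R2")
  sim <- simulate_session(cfg, pol, seed = 3)
  pun <- sim$log[sim$log$phase == "punish", ]
  expect_true(all(pun$cs_type[pun$kind == "cs_onset"] == "CS-"))
  expect_equal(sum(pun$kind == "attack"), 0)
  expect_equal(sum(pun$points_delta[pun$kind %in%
                                      c("cs_onset", "cs_offset")]), 0)
})

test_that("an activated shield costs 50, prevents the attack and blocks new trades", {
  cfg <- forced_config(cs_prob = 1, shield_avail_prob = 1, reward_prob = 1)
  sim <- simulate_session(cfg, policy_one_click_shielder(), seed = 4)
  pun <- sim$log[sim$log$phase == "punish", ]
  act <- pun[pun$kind == "shield_activated", ]
  expect_equal(nrow(act), 1)
  expect_equal(act$points_delta, -50)
  expect_equal(sum(pun$kind == "attack"), 0)
  # shield offer arrives shield_charge_s after onset
  ons <- pun[pun$kind == "cs_onset", ]
  off <- pun[pun$kind == "shield_offered", ]
  expect_equal(off$time_s, ons$time_s + cfg$shield_charge_s)
})

test_that("shield activation without an offer is rejected", {
  cfg <- forced_config(cs_prob = 1, shield_avail_prob = 0, n_pre_blocks = 0L)
  expect_error(
    simulate_session(cfg, policy_blind_shielder(), seed = 5),
    "without an offered shield")
})

test_that("clicks during an active shield produce no trade_start", {
  cfg <- forced_config(cs_prob = 1, shield_avail_prob = 1, reward_prob = 1,
                       n_pre_blocks = 0L)
  shield_then_click <- list(
    init = function(mem) { mem$clicked <- 0L; mem$shielded <- FALSE },
    next_action = function(obs, mem) {
      if (mem$clicked == 0L) {
        return(list(time = 1, action = "click", planet = "R1"))
      }
      if (obs$shield_offered && !obs$shield_active) {
        return(list(time = obs$t_now + 0.2, action = "shield"))
      }
      if (obs$shield_active && mem$clicked < 4L) {
        return(list(time = obs$t_now + 0.3, action = "click", planet = "R2"))
      }
      list(time = Inf, action = "none")
    },
    observe = function(info, mem) {
      if (info$kind == "click") mem$clicked <- mem$clicked + 1L
      if (info$kind == "shield_activated") mem$shielded <- TRUE
    }
  )
  sim <- simulate_session(cfg, shield_then_click, seed = 6)
  pun <- sim$log[sim$log$phase == "punish", ]
  t_shield <- pun$time_s[pun$kind == "shield_activated"][1]
  t_off <- pun$time_s[pun$kind == "cs_offset"][1]
  clicks_during <- pun[pun$kind == "click" & pun$time_s > t_shield &
                         pun$time_s < t_off, ]
  expect_gt(nrow(clicks_during), 0) # clicks are still recorded
  trades_during <- pun[pun$kind == "trade_start" & pun$time_s > t_shield &
                         pun$time_s < t_off, ]
  expect_equal(nrow(trades_during), 0) # but start no trades
})

test_that("a null policy yields an empty session and the default block structure holds", {
  sim <- simulate_session(task_config(), policy_null(), seed = 1)
  expect_true(all(sim$log$kind == "block_end"))
  expect_equal(nrow(sim$log), 5) # 2 pre + 3 punishment blocks
  expect_equal(sim$final_points, 0)
  expect_equal(sim$log$phase, c("pre", "pre", "punish", "punish", "punish"))
  expect_true(all(sim$log$time_s == 180))
})

test_that("trading stops at the block boundary but pending outcomes resolve in the tail", {
  cfg <- forced_config(reward_prob = 1, cs_prob = 1, shield_avail_prob = 0,
                       n_pre_blocks = 0L)
  # click right up to the boundary so a trade and a CS are pending at 180 s
  pol <- policy_scripted_clicker(interval_s = 0.4, planets = "R1")
  sim <- simulate_session(cfg, pol, seed = 7)
  log <- sim$log
  expect_equal(sum(log$kind == "click" & log$time_s > 180), 0)
  expect_equal(sum(log$kind == "trade_start" & log$time_s > 180), 0)
  tail_ev <- log[log$time_s > 180 & log$kind != "block_end", ]
  expect_gt(nrow(tail_ev), 0) # outcomes presented to completion
  expect_true(all(tail_ev$kind %in%
                    c("reward", "no_reward", "cs_onset", "cs_offset",
                      "attack", "shield_offered", "shield_unavailable")))
  expect_equal(log$time_s[log$kind == "block_end"],
               max(log$time_s))
})

test_that("identical (config, policy, seed) give identical logs; seeds differ", {
  pol <- function() policy_agent(make_agent("sensitive"))
  a <- simulate_session(task_config(), pol(), seed = 11)
  b <- simulate_session(task_config(), pol(), seed = 11)
  c <- simulate_session(task_config(), pol(), seed = 12)
  expect_identical(a$log, b$log)
  expect_false(identical(a$log, c$log))
})

test_that("points are conserved: final total equals rewards minus shields minus attacks", {
  sim <- simulate_session(task_config(),
                          policy_agent(make_agent("sensitive")), seed = 21)
  log <- sim$log
  expect_equal(sim$final_points,
               sum(log$points_delta[log$kind == "reward"]) +
                 sum(log$points_delta[log$kind == "shield_activated"]) +
                 sum(log$points_delta[log$kind == "attack"]))
  expect_equal(sim$final_points, log$points_total[nrow(log)])
})

test_that("no attack ever follows a CS- or a shielded CS+", {
  for (seed in 1:5) {
    sim <- simulate_session(task_config(),
                            policy_agent(make_agent("insensitive")),
                            seed = seed)
    log <- sim$log
    expect_true(all(log$cs_type[log$kind == "attack"] == "CS+"))
    # within each CS episode, attack and shield_activated never co-occur
    for (b in unique(log$block)) {
      bl <- log[log$block == b, ]
      shielded <- FALSE
      for (i in seq_len(nrow(bl))) {
        k <- bl$kind[i]
        if (k == "shield_activated") shielded <- TRUE
        if (k == "attack") expect_false(shielded)
        if (k == "cs_offset") shielded <- FALSE
      }
    }
  }
})

test_that("with cs_prob = 0 the punishment phase matches pre-punishment reward throughput", {
  cfg <- task_config(cs_prob = 0)
  sim <- simulate_session(cfg, policy_scripted_clicker(0.5), seed = 31)
  log <- sim$log
  expect_equal(sum(log$kind %in% c("cs_trigger", "cs_onset")), 0)
  # identical scripted clicking: per-block trade counts match exactly
  trades <- function(ph) sum(log$kind == "trade_start" & log$phase == ph) /
    length(unique(log$block[log$phase == ph]))
  expect_equal(trades("pre"), trades("punish"))
  # reward proportion per trade agrees within a 99% two-sample binomial CI
  prop <- function(ph) sum(log$kind == "reward" & log$phase == ph) /
    sum(log$kind == "trade_start" & log$phase == ph)
  n1 <- sum(log$kind == "trade_start" & log$phase == "pre")
  n2 <- sum(log$kind == "trade_start" & log$phase == "punish")
  expect_lt(abs(prop("pre") - prop("punish")),
            2.576 * sqrt(0.25 * (1 / n1 + 1 / n2)))
})

test_that("schedule calibration recovers the programmed probabilities", {
  cal <- schedule_calibration(seed = 17, min_eligible = 5000,
                              min_trades = 5000, min_cs = 2000)
  ci99 <- function(p, n) 2.576 * sqrt(p * (1 - p) / n) * 100
  expect_gte(cal$n_eligible, 5000)
  expect_gte(cal$n_trades, 5000)
  expect_gte(cal$n_episodes, 2000)
  expect_lt(abs(cal$cs_pct - 20), ci99(0.2, cal$n_eligible))
  expect_lt(abs(cal$reward_pct - 50), ci99(0.5, cal$n_trades))
  expect_lt(abs(cal$shield_pct - 50), ci99(0.5, cal$n_episodes))
})

test_that("the validator flags constructed violations and passes simulator output", {
  sim <- simulate_session(task_config(), policy_scripted_clicker(0.5),
                          seed = 41)
  expect_length(validate_event_log(sim$log), 0)

  # overlapping CS episodes
  bad <- event_log("x", 1, "punish",
                   time_s = c(1, 2, 3, 4),
                   kind = c("cs_onset", "cs_onset", "cs_offset", "cs_offset"),
                   cs_type = c("CS+", "CS-", "CS-", "CS+"))
  v <- validate_event_log(bad)
  expect_true(any(grepl("one CS", v)))

  # broken running total
  bad2 <- simulate_session(forced_config(reward_prob = 1),
                           policy_scripted_clicker(1, planets = "R1"),
                           seed = 1)$log
  bad2$points_total[5] <- bad2$points_total[5] + 1
  expect_true(any(grepl("running sum", validate_event_log(bad2))))

  # unknown planet rejected by the engine
  bad_pol <- list(next_action = function(obs, mem)
    list(time = 1, action = "click", planet = "R7"))
  expect_error(simulate_session(task_config(), bad_pol, seed = 1),
               "unknown planet")

  # non-monotone action times rejected
  rew <- list(
    init = function(mem) mem$n <- 0L,
    next_action = function(obs, mem) {
      mem$n <- mem$n + 1L
      list(time = if (mem$n == 1L) 10 else 5, action = "click",
           planet = "R1")
    })
  expect_error(simulate_session(task_config(), rew, seed = 1),
               "non-monotone")
})

test_that("task_config validates its invariants and round-trips through YAML", {
  expect_error(task_config(cs_prob = 1.2), "probabilities")
  expect_error(task_config(shield_charge_s = 7), "shield_charge_s")
  expect_error(task_config(block_duration_s = 0), "durations")
  path <- tempfile(fileext = ".yaml")
  write_task_config(task_config(), path)
  expect_equal(unclass(read_task_config(path)), unclass(task_config()))
  shipped <- system.file("extdata", "paper_default.yaml",
                         package = "pirateplanets")
  expect_equal(unclass(read_task_config(shipped)), unclass(task_config()))
})
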