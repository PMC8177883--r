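# Shared fixtures, computed lazily once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

# mixed cohort at the default study conditions, small n for speed
fixture_cohort <- function() {
  cached("cohort", generate_cohort(40, sensitive_fraction = 0.3, seed = 101))
}

# zero-report-noise cohort: direct and chained inferences must coincide
fixture_noiseless <- function() {
  cached("noiseless",
         generate_cohort(12, sensitive_fraction = 0.5, seed = 202,
                         overrides = list(report_noise_sd = 0)))
}

fixture_summary <- function() {
  cached("summary", participant_summary(fixture_cohort()$events))
}

# hand-built one-participant log: one block, given ITI clicks, no CS
manual_iti_log <- function(n_r1, n_r2, block = 1L, phase = "pre",
                           duration = 180) {
  n <- n_r1 + n_r2
  times <- seq(1, duration - 1, length.out = max(n, 1))
  planets <- c(rep("R1", n_r1), rep("R2", n_r2))
  ord <- order(rep(times, length.out = n))
  event_log("manual", block = block, phase = phase,
            time_s = c(times[seq_len(n)], duration),
            kind = c(rep("click", n), "block_end"),
            planet = c(planets, "none"))
}

# scripted config forcing deterministic outcomes
forced_config <- function(...) {
  do.call(task_config, utils::modifyList(
    list(n_pre_blocks = 1L, n_punish_blocks = 1L), list(...)))
}

# a policy that clicks once then tries to shield whenever a CS is active,
# regardless of whether a shield was offered (for error-path tests)
policy_blind_shielder <- function(click_t = 1) {
  list(
    init = function(mem) mem$done <- FALSE,
    next_action = function(obs, mem) {
      if (!mem$done) return(list(time = click_t, action = "click",
                                 planet = "R1"))
      if (obs$cs_stage == 2L && !obs$shield_active) {
        return(list(time = obs$t_now + 0.1, action = "shield"))
      }
      list(time = Inf, action = "none")
    },
    observe = function(info, mem) if (info$kind == "click") mem$done <- TRUE
  )
}

# clicks R1 once per block at t=1, shields whenever offered
policy_one_click_shielder <- function() {
  list(
    init = function(mem) mem$block <- 0L,
    next_action = function(obs, mem) {
      if (mem$block < obs$block) {
        return(list(time = 1, action = "click", planet = "R1"))
      }
      if (obs$shield_offered && !obs$shield_active) {
        return(list(time = obs$t_now + 0.2, action = "shield"))
      }
      list(time = Inf, action = "none")
    },
    observe = function(info, mem) {
      if (info$kind == "click") mem$block <- mem$block + 1L
    }
  )
}

# hand-built punishment log: one CS+ episode at known times, optional shield
one_cs_log <- function(shield_at = NA, cs = "CS+",
                       iti_clicks_r1 = 0, iti_clicks_r2 = 0,
                       cs_clicks = 0) {
  t_trig <- 20; t_on <- 21.5; t_off <- 27.5
  times <- c(t_trig, t_on)
  kinds <- c("cs_trigger", "cs_onset")
  cst <- c(cs, cs)
  planets <- c("R1", "R1")
  if (!is.na(shield_at)) {
    times <- c(times, t_on + 3, shield_at)
    kinds <- c(kinds, "shield_offered", "shield_activated")
    cst <- c(cst, cs, cs)
    planets <- c(planets, "none", "none")
  }
  times <- c(times, t_off, 180)
  kinds <- c(kinds, "cs_offset", "block_end")
  cst <- c(cst, cs, "none")
  planets <- c(planets, "R1", "none")
  # clicks: ITI clicks spread over [30, 170], CS clicks inside the
  # unshielded window
  n_iti <- iti_clicks_r1 + iti_clicks_r2
  if (n_iti > 0) {
    ct <- seq(30, 170, length.out = n_iti)
    times <- c(times, ct)
    kinds <- c(kinds, rep("click", n_iti))
    cst <- c(cst, rep("none", n_iti))
    planets <- c(planets, rep(c("R1", "R2"),
                              c(iti_clicks_r1, iti_clicks_r2)))
  }
  if (cs_clicks > 0) {
    hi <- if (!is.na(shield_at)) shield_at else t_off
    ct <- seq(t_on + 0.1, hi - 0.1, length.out = cs_clicks)
    times <- c(times, ct)
    kinds <- c(kinds, rep("click", cs_clicks))
    cst <- c(cst, rep("none", cs_clicks))
    planets <- c(planets, rep("R1", cs_clicks))
  }
  ord <- order(times)
  event_log("manual", 1L, "punish", times[ord], kinds[ord],
            planet = planets[ord], cs_type = cst[ord])
}

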