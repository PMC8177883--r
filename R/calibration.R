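# Schedule calibration -----------------------------------------------------

#' Empirical calibration of the programmed contingencies
#'
#' Runs long scripted-clicker simulations and measures the realised
#' contingency probabilities: the fraction of CS-eligible punished-planet
#' responses that trigger their CS, the fraction of initiated trades ending
#' in reward, and the fraction of CS presentations on which a shield is
#' offered.  Sessions are accumulated (with independent participant
#' indices under the same master seed) until each denominator reaches its
#' requested minimum.
#'
#' @param seed integer master seed.
#' @param min_eligible minimum CS-eligible R1 responses for the CS rate.
#' @param min_trades minimum initiated trades for the reward rate.
#' @param min_cs minimum CS episodes for the shield-availability rate.
#' @param click_interval_s scripted inter-click interval.
#' @param config a [task_config()]; block structure is overridden
#'   internally (punishment-only runs for CS/shield, pre-punishment-only
#'   runs for reward).
#' @return a list with `cs_pct`, `reward_pct`, `shield_pct` (percent) and
#'   the denominators `n_eligible`, `n_trades`, `n_episodes`.
#' @export
schedule_calibration <- function(seed, min_eligible = 5000,
                                 min_trades = 5000, min_cs = 2000,
                                 click_interval_s = 0.4,
                                 config = task_config()) {
  # punishment-only runs: CS probability per eligible R1 response and
  # shield availability per CS episode
  cfg_p <- config
  cfg_p$n_pre_blocks <- 0L
  cfg_p$n_punish_blocks <- 3L
  n_eligible <- 0L; n_csplus <- 0L
  n_episodes <- 0L; n_offered <- 0L
  i <- 0L
  while (n_eligible < min_eligible || n_episodes < min_cs) {
    i <- i + 1L
    sim <- simulate_session(cfg_p, policy_scripted_clicker(click_interval_s,
                                                          planets = "R1"),
                            seed = seed, participant_id = sprintf("cal%d", i),
                            p_index = i)
    log <- sim$log
    n_eligible <- n_eligible + count_eligible_clicks(log, planet = "R1")
    n_csplus <- n_csplus + sum(log$kind == "cs_onset" & log$cs_type == "CS+")
    n_episodes <- n_episodes + sum(log$kind == "cs_onset")
    n_offered <- n_offered + sum(log$kind == "shield_offered")
  }

  # pre-punishment-only runs: reward probability per initiated trade
  cfg_r <- config
  cfg_r$n_pre_blocks <- 2L
  cfg_r$n_punish_blocks <- 0L
  n_trades <- 0L; n_rewards <- 0L
  j <- 0L
  while (n_trades < min_trades) {
    j <- j + 1L
    sim <- simulate_session(cfg_r, policy_scripted_clicker(click_interval_s),
                            seed = seed + 1L,
                            participant_id = sprintf("cal%d", j), p_index = j)
    n_trades <- n_trades + sum(sim$log$kind == "trade_start")
    n_rewards <- n_rewards + sum(sim$log$kind == "reward")
  }

  list(
    cs_pct = 100 * n_csplus / n_eligible,
    reward_pct = 100 * n_rewards / n_trades,
    shield_pct = 100 * n_offered / n_episodes,
    n_eligible = n_eligible,
    n_trades = n_trades,
    n_episodes = n_episodes
  )
}
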