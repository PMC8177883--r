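# Agent policies ---------------------------------------------------------

#' Inactive policy
#'
#' Never acts; a session under this policy contains only block boundaries
#' and ends with 0 points.
#'
#' @return a policy list for [simulate_session()].
#' @export
policy_null <- function() {
  list(next_action = function(obs, mem) list(time = Inf, action = "none"))
}

#' Deterministic scripted clicker
#'
#' Clicks at a fixed interval, on a fixed planet or alternating between the
#' two, and never shields.  Used for schedule-calibration runs where the
#' response process must be exogenous to the task contingencies.
#'
#' @param interval_s seconds between clicks.
#' @param planets `"R1"`, `"R2"` or `"alternate"`.
#' @param first_click_s time of the first click in each block.
#' @return a policy list for [simulate_session()].
#' @export
policy_scripted_clicker <- function(interval_s = 0.5, planets = "alternate",
                                    first_click_s = interval_s) {
  list(
    init = function(mem) {
      mem$next_t <- first_click_s
      mem$k <- 0L
      mem$block <- 1L
    },
    next_action = function(obs, mem) {
      if (mem$block != obs$block) { # block rollover: restart the schedule
        mem$block <- obs$block
        mem$next_t <- first_click_s
      }
      pl <- switch(planets,
                   alternate = c("R1", "R2")[mem$k %% 2L + 1L],
                   planets)
      list(time = mem$next_t, action = "click", planet = pl)
    },
    observe = function(info, mem) {
      if (info$kind == "click") {
        mem$k <- mem$k + 1L
        mem$next_t <- info$time + interval_s
      }
    }
  )
}

#' Learning agent policy
#'
#' Generative policy of a synthetic participant.  Clicking is a Poisson
#' process at `base_click_rate`, slowed by a factor
#' `1 - suppression_gain * V_CS` while a CS with Pavlovian value `V_CS` is
#' on screen (conditioned suppression).  Planet choice is a softmax over
#' action values `Q_R = w_reward * E[reward] - w_punish * loss_nominal *
#' sum_CS kappa[R, CS] * V[CS]`, where `kappa[R, CS]` is the agent's learned
#' Response->CS contingency knowledge (delta rule at rate `alpha_instr` on
#' every CS-eligible click, prior `kappa_prior` for all pairs) and `V[CS]`
#' the Pavlovian CS->Attack value (delta rule at rate `alpha_pav` at each CS
#' offset, attack or deflected-attack feedback counting as the aversive
#' outcome).  When a shield is offered it is taken with probability
#' `plogis(shield_bias + shield_slope * V[CS])` after a fixed reaction time.
#'
#' Only the difference `Q_R1 - Q_R2` matters for choice, so the reward term
#' (equal across planets under the symmetric reward schedule) cancels; it is
#' kept for completeness.
#'
#' @param params an [agent_params()] object.
#' @return a policy list for [simulate_session()].
#' @export
policy_agent <- function(params) {
  p <- params
  rate0 <- p$base_click_rate / 60 # clicks per second

  list(
    init = function(mem) {
      mem$kappa <- matrix(p$kappa_prior, 2, 2,
                          dimnames = list(c("R1", "R2"), c("CS+", "CS-")))
      mem$V <- c("CS+" = 0, "CS-" = 0)
      mem$r_hat <- c(R1 = 0.5, R2 = 0.5) # reward-probability estimates
      mem$epoch <- 0L      # bumped whenever the click rate changes
      mem$click_t <- -1
      mem$click_epoch <- -1L
      mem$click_block <- -1L
      mem$shield_t <- Inf
      mem$shield_decided_t <- -1
    },
    next_action = function(obs, mem) {
      # pending shield activation
      if (mem$shield_t < Inf) {
        if (obs$shield_offered && mem$shield_t < obs$cs_end_t) {
          return(list(time = mem$shield_t, action = "shield"))
        }
        mem$shield_t <- Inf # offer lapsed (CS ended first)
      }
      if (obs$shield_offered && mem$shield_decided_t != obs$cs_end_t) {
        mem$shield_decided_t <- obs$cs_end_t # one decision per episode
        v <- mem$V[[obs$cs_type]]
        if (stream_unif(mem$stream) <
              stats::plogis(p$shield_bias + p$shield_slope * v)) {
          mem$shield_t <- obs$t_now + p$shield_rt_s
          if (mem$shield_t < obs$cs_end_t) {
            return(list(time = mem$shield_t, action = "shield"))
          }
          mem$shield_t <- Inf
        }
      }
      # next click (cached while the rate regime is unchanged)
      if (mem$click_block != obs$block || mem$click_epoch != mem$epoch ||
          mem$click_t < obs$t_now) {
        rate <- rate0
        if (obs$cs_stage == 2L) {
          rate <- rate * max(0, 1 - p$suppression_gain * mem$V[[obs$cs_type]])
        }
        dt <- stream_exp(mem$stream, rate)
        mem$click_t <- obs$t_now + dt
        mem$click_epoch <- mem$epoch
        mem$click_block <- obs$block
        pen <- as.vector(mem$kappa %*% mem$V) # expected punishment per planet
        q <- p$w_reward * mem$r_hat * p$reward_points_belief -
          p$w_punish * p$loss_nominal * pen
        p1 <- 1 / (1 + exp(-p$softmax_beta * (q[1] - q[2])))
        mem$click_planet <- if (stream_unif(mem$stream) < p1) "R1" else "R2"
      }
      if (mem$click_t > obs$duration) return(list(time = Inf, action = "none"))
      list(time = mem$click_t, action = "click", planet = mem$click_planet)
    },
    observe = function(info, mem) {
      k <- info$kind
      if (k == "click") {
        mem$click_t <- -1 # force a fresh draw
        if (isTRUE(info$eligible) && p$alpha_instr > 0) {
          r <- info$planet
          tgt <- c("CS+", "CS-") == info$cs_triggered
          mem$kappa[r, ] <- mem$kappa[r, ] +
            p$alpha_instr * (tgt - mem$kappa[r, ])
        }
      } else if (k == "cs_outcome") {
        out <- if (info$cs_type == "CS+") 1 else 0
        mem$V[[info$cs_type]] <- mem$V[[info$cs_type]] +
          p$alpha_pav * (out - mem$V[[info$cs_type]])
        mem$epoch <- mem$epoch + 1L
        mem$shield_t <- Inf
        mem$shield_decided_t <- -1
      } else if (k == "cs_onset" || k == "shield_activated") {
        mem$epoch <- mem$epoch + 1L
      } else if (k == "reward" || k == "no_reward") {
        out <- if (k == "reward") 1 else 0
        mem$r_hat[[info$planet]] <- mem$r_hat[[info$planet]] +
          p$alpha_reward * (out - mem$r_hat[[info$planet]])
      }
    },
    snapshot = function(mem) {
      list(kappa = mem$kappa, V = mem$V, r_hat = mem$r_hat)
    }
  )
}
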