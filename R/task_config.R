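# Task configuration -----------------------------------------------------

#' Construct a task configuration
#'
#' All contingency parameters of the conditioned-punishment paradigm.  The
#' defaults reproduce the published schedule: two 3-min pre-punishment
#' blocks of free-operant clicking on two planets (R1, R2) rewarded at 50%
#' (+100 points per successful 2-s trade), followed by three 3-min
#' punishment blocks in which R1 responses additionally trigger a CS+
#' (20% chance, 1.5 s delay) that ends in an attack removing 20% of current
#' points 6 s after onset, and R2 responses trigger a consequence-free CS-
#' under the same schedule.  On a random 50% of CS presentations a shield
#' becomes available 3 s after CS onset; activating it costs 50 points,
#' prevents the attack and blocks further trading until the CS ends.
#'
#' @param block_duration_s trading window per block, seconds.
#' @param n_pre_blocks number of pre-punishment blocks.
#' @param n_punish_blocks number of punishment blocks.
#' @param reward_prob probability a trade ends in reward.
#' @param reward_points points per reward.
#' @param trade_countdown_s trade (countdown) duration, seconds.
#' @param cs_prob probability an eligible response triggers its CS.
#' @param cs_delay_s delay from response to CS onset, seconds.
#' @param cs_duration_s CS duration, seconds.
#' @param attack_fraction fraction of current total points removed by an
#'   unshielded attack.
#' @param shield_avail_prob probability a shield is offered on a CS.
#' @param shield_charge_s delay from CS onset to shield offer, seconds.
#' @param shield_cost_points cost of activating the shield.
#' @param punished_planet which planet is R1 (the CS+ source), `"R1"` by
#'   construction; kept explicit for counterbalance bookkeeping.
#' @param cs_plus_identity label of the CS+ ship (counterbalance flag).
#' @param side_assignment `"left"` or `"right"`: on-screen side of R1.
#' @return an object of class `task_config` (a validated list).
#' @examples
#' cfg <- task_config()
#' cfg$cs_prob
#' @export
task_config <- function(block_duration_s = 180,
                        n_pre_blocks = 2L,
                        n_punish_blocks = 3L,
                        reward_prob = 0.5,
                        reward_points = 100,
                        trade_countdown_s = 2.0,
                        cs_prob = 0.2,
                        cs_delay_s = 1.5,
                        cs_duration_s = 6.0,
                        attack_fraction = 0.2,
                        shield_avail_prob = 0.5,
                        shield_charge_s = 3.0,
                        shield_cost_points = 50,
                        punished_planet = "R1",
                        cs_plus_identity = "type_I",
                        side_assignment = "left") {
  cfg <- list(
    block_duration_s = block_duration_s,
    n_pre_blocks = as.integer(n_pre_blocks),
    n_punish_blocks = as.integer(n_punish_blocks),
    reward_prob = reward_prob,
    reward_points = reward_points,
    trade_countdown_s = trade_countdown_s,
    cs_prob = cs_prob,
    cs_delay_s = cs_delay_s,
    cs_duration_s = cs_duration_s,
    attack_fraction = attack_fraction,
    shield_avail_prob = shield_avail_prob,
    shield_charge_s = shield_charge_s,
    shield_cost_points = shield_cost_points,
    punished_planet = punished_planet,
    cs_plus_identity = cs_plus_identity,
    side_assignment = side_assignment
  )
  class(cfg) <- "task_config"
  validate_task_config(cfg)
  cfg
}

#' Validate a task configuration
#'
#' Checks probability ranges, positive durations and that the shield charge
#' time fits inside the CS (otherwise the shield could never be offered
#' before the attack).
#'
#' @param cfg a `task_config`.
#' @return `cfg` invisibly; errors on violation.
#' @export
validate_task_config <- function(cfg) {
  stopifnot(inherits(cfg, "task_config"))
  probs <- c(cfg$reward_prob, cfg$cs_prob, cfg$shield_avail_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  durs <- c(cfg$block_duration_s, cfg$trade_countdown_s, cfg$cs_duration_s,
            cfg$shield_charge_s)
  if (any(durs <= 0)) stop("durations must be > 0", call. = FALSE)
  if (cfg$cs_delay_s < 0) stop("cs_delay_s must be >= 0", call. = FALSE)
  if (!is.finite(cfg$cs_delay_s + cfg$cs_duration_s)) {
    stop("CS timing must be finite", call. = FALSE)
  }
  if (cfg$shield_charge_s >= cfg$cs_duration_s) {
    stop("shield_charge_s must be < cs_duration_s", call. = FALSE)
  }
  if (cfg$attack_fraction < 0 || cfg$attack_fraction > 1) {
    stop("attack_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_pre_blocks < 0 || cfg$n_punish_blocks < 0) {
    stop("block counts must be >= 0", call. = FALSE)
  }
  invisible(cfg)
}

#' Read / write a task configuration as YAML
#'
#' The packaged file `paper_default.yaml` holds the published defaults:
#' `system.file("extdata", "paper_default.yaml", package = "pirateplanets")`.
#'
#' @param path file path.
#' @return `read_task_config()` returns a `task_config`.
#' @export
read_task_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(task_config, vals)
}

#' @rdname read_task_config
#' @param cfg a `task_config` to write.
#' @export
write_task_config <- function(cfg, path) {
  validate_task_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.task_config <- function(x, ...) {
  cat("<task_config>\n")
  cat(sprintf("  blocks: %d pre + %d punishment x %gs trading\n",
              x$n_pre_blocks, x$n_punish_blocks, x$block_duration_s))
  cat(sprintf("  reward: p=%.2f, +%g pts after %gs trade\n",
              x$reward_prob, x$reward_points, x$trade_countdown_s))
  cat(sprintf("  CS: p=%.2f, delay %gs, duration %gs; attack -%g%% of points\n",
              x$cs_prob, x$cs_delay_s, x$cs_duration_s, 100 * x$attack_fraction))
  cat(sprintf("  shield: p=%.2f, charge %gs, cost %g pts\n",
              x$shield_avail_prob, x$shield_charge_s, x$shield_cost_points))
  invisible(x)
}
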