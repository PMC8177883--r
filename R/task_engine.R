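# Event-driven task engine ----------------------------------------------
#
# A session is simulated as an event loop: the agent policy proposes its
# next action (click / shield / none) given an observable snapshot, the
# engine holds the scheduled timers (trade resolutions, CS onset, shield
# offer, CS end), and whichever comes first is processed.  All stochastic
# resolutions draw from keyed per-(participant, block, channel) streams, so
# identical (config, policy, seed) give byte-identical logs.

.CH_REWARD <- 1L
.CH_CS <- 2L
.CH_SHIELD <- 3L
.CH_POLICY <- 4L
.CH_REPORT <- 5L
.CH_COHORT <- 6L

#' Simulate one session of the conditioned-punishment task
#'
#' Runs `n_pre_blocks` pre-punishment blocks followed by `n_punish_blocks`
#' punishment blocks.  Trading is suspended at `block_duration_s`, but any
#' pending trades, CSs and outcomes resolve to completion before the block
#' ends.  During punishment blocks, each click on a planet with no CS
#' pending or active rolls that planet's CS (`R1 -> CS+`, `R2 -> CS-`) with
#' probability `cs_prob`; at most one CS runs at a time and blocked rolls
#' are lost, not deferred.  An unshielded CS+ ends in an attack removing
#' `attack_fraction` of current points (rounded, never increasing points);
#' activating an offered shield costs `shield_cost_points`, prevents the
#' attack and blocks new trades until CS offset.
#'
#' @param config a [task_config()].
#' @param policy an agent policy, e.g. [policy_null()],
#'   [policy_scripted_clicker()] or [policy_agent()].  A policy is a list of
#'   functions: `next_action(obs, mem)` returning
#'   `list(time =, action = "click"|"shield"|"none", planet =)`, and
#'   optionally `init(mem)`, `observe(info, mem)` (feedback after each
#'   event) and `snapshot(mem)` (called at each block end; collected).
#' @param seed integer master seed.
#' @param participant_id identifier stored in the log.
#' @param p_index integer participant index used to key the RNG streams
#'   (distinct participants of a cohort get independent streams).
#' @return a list with elements `log` (an [event_log()] tibble),
#'   `snapshots` (per-block policy snapshots) and `final_points`.
#' @examples
#' sim <- simulate_session(task_config(), policy_null(), seed = 1)
#' table(sim$log$kind)
#' @export
simulate_session <- function(config, policy, seed, participant_id = "sim",
                             p_index = 1L) {
  validate_task_config(config)
  phases <- c(rep("pre", config$n_pre_blocks),
              rep("punish", config$n_punish_blocks))
  n_blocks <- length(phases)

  # growable event buffers
  cap <- 4096L
  ev_time <- numeric(cap); ev_kind <- character(cap)
  ev_planet <- character(cap); ev_cs <- character(cap)
  ev_delta <- numeric(cap); ev_total <- numeric(cap)
  ev_block <- integer(cap); ev_phase <- character(cap)
  n_ev <- 0L
  points <- 0
  cur_block <- 0L; cur_phase <- ""

  emit <- function(time, kind, planet = "none", cs = "none", delta = 0) {
    n_ev <<- n_ev + 1L
    if (n_ev > cap) {
      cap <<- cap * 2L
      length(ev_time) <<- cap; length(ev_kind) <<- cap
      length(ev_planet) <<- cap; length(ev_cs) <<- cap
      length(ev_delta) <<- cap; length(ev_total) <<- cap
      length(ev_block) <<- cap; length(ev_phase) <<- cap
    }
    points <<- points + delta
    ev_time[n_ev] <<- time; ev_kind[n_ev] <<- kind
    ev_planet[n_ev] <<- planet; ev_cs[n_ev] <<- cs
    ev_delta[n_ev] <<- delta; ev_total[n_ev] <<- points
    ev_block[n_ev] <<- cur_block; ev_phase[n_ev] <<- cur_phase
  }

  mem <- new.env(parent = emptyenv())
  if (!is.null(policy$init)) policy$init(mem)
  observe <- policy$observe
  snapshots <- vector("list", n_blocks)

  dur <- config$block_duration_s
  countdown <- config$trade_countdown_s
  punished <- config$punished_planet

  ob <- new.env(parent = emptyenv())
  ob$duration <- dur

  for (b in seq_len(n_blocks)) {
    cur_block <- b
    cur_phase <- phases[b]
    is_punish <- cur_phase == "punish"

    s_reward <- rng_stream(stream_seed(seed, p_index, b, .CH_REWARD))
    s_cs <- rng_stream(stream_seed(seed, p_index, b, .CH_CS))
    s_shield <- rng_stream(stream_seed(seed, p_index, b, .CH_SHIELD))
    mem$stream <- rng_stream(stream_seed(seed, p_index, b, .CH_POLICY))
    mem$block_started <- b # lets policies reset per-block caches

    t <- 0
    cd_end <- c(-Inf, -Inf)                 # R1, R2 countdown end times
    t_trade <- c(Inf, Inf)                  # pending trade resolution timers
    cs_stage <- 0L                          # 0 none, 1 pending, 2 active
    cs_type_cur <- "none"; cs_planet_cur <- "none"
    t_cs_onset <- Inf; t_shield_offer <- Inf; t_cs_end <- Inf
    shield_avail <- FALSE; offer_open <- FALSE; shield_active <- FALSE

    ob$block <- b; ob$phase <- cur_phase

    repeat {
      t_timer <- min(t_trade[1], t_trade[2], t_cs_onset, t_shield_offer,
                     t_cs_end)

      ob$t_now <- t
      ob$points <- points
      ob$cd_end <- cd_end
      ob$cs_stage <- cs_stage
      ob$cs_type <- if (cs_stage == 2L) cs_type_cur else "none"
      ob$shield_offered <- offer_open
      ob$shield_active <- shield_active
      ob$cs_end_t <- t_cs_end
      act <- policy$next_action(ob, mem)
      ta <- act$time
      if (is.null(ta) || is.na(ta)) ta <- Inf
      if (ta < Inf && act$action == "click" && ta > dur) ta <- Inf

      if (ta == Inf && t_timer == Inf) break

      if (t_timer <= ta) {
        # ---- scheduled event ----
        tt <- t_timer
        t <- tt
        if (tt == t_trade[1] || tt == t_trade[2]) {
          j <- if (t_trade[1] <= t_trade[2]) 1L else 2L
          pl <- c("R1", "R2")[j]
          if (stream_unif(s_reward) < config$reward_prob) {
            emit(tt, "reward", planet = pl, delta = config$reward_points)
            if (!is.null(observe)) {
              observe(list(kind = "reward", planet = pl, time = tt), mem)
            }
          } else {
            emit(tt, "no_reward", planet = pl)
            if (!is.null(observe)) {
              observe(list(kind = "no_reward", planet = pl, time = tt), mem)
            }
          }
          cd_end[j] <- -Inf
          t_trade[j] <- Inf
        } else if (tt == t_cs_onset) {
          cs_stage <- 2L
          emit(tt, "cs_onset", planet = cs_planet_cur, cs = cs_type_cur)
          shield_avail <- stream_unif(s_shield) < config$shield_avail_prob
          t_shield_offer <- tt + config$shield_charge_s
          t_cs_end <- tt + config$cs_duration_s
          t_cs_onset <- Inf
          if (!is.null(observe)) {
            observe(list(kind = "cs_onset", cs_type = cs_type_cur,
                         planet = cs_planet_cur, time = tt), mem)
          }
        } else if (tt == t_shield_offer) {
          if (shield_avail) {
            emit(tt, "shield_offered", cs = cs_type_cur)
            offer_open <- TRUE
          } else {
            emit(tt, "shield_unavailable", cs = cs_type_cur)
          }
          t_shield_offer <- Inf
          if (!is.null(observe)) {
            observe(list(kind = if (shield_avail) "shield_offered"
                                else "shield_unavailable",
                         cs_type = cs_type_cur, time = tt), mem)
          }
        } else { # CS end
          attacked <- cs_type_cur == "CS+" && !shield_active
          if (attacked) {
            loss <- -round(config$attack_fraction * max(points, 0))
            emit(tt, "attack", cs = cs_type_cur, delta = loss)
          }
          emit(tt, "cs_offset", planet = cs_planet_cur, cs = cs_type_cur)
          if (!is.null(observe)) {
            observe(list(kind = "cs_outcome", cs_type = cs_type_cur,
                         attacked = attacked,
                         deflected = cs_type_cur == "CS+" && shield_active,
                         time = tt), mem)
          }
          cs_stage <- 0L
          cs_type_cur <- "none"; cs_planet_cur <- "none"
          t_cs_end <- Inf; t_shield_offer <- Inf
          shield_avail <- FALSE; offer_open <- FALSE; shield_active <- FALSE
        }
      } else {
        # ---- policy action ----
        if (ta < t) stop("non-monotone policy action times", call. = FALSE)
        t <- ta
        if (act$action == "click") {
          pl <- act$planet
          j <- if (pl == "R1") 1L else if (pl == "R2") 2L else
            stop("unknown planet id: ", pl, call. = FALSE)
          emit(ta, "click", planet = pl)
          eligible <- is_punish && cs_stage == 0L
          triggered <- "none"
          if (!shield_active && cd_end[j] <= ta) {
            emit(ta, "trade_start", planet = pl)
            cd_end[j] <- ta + countdown
            t_trade[j] <- cd_end[j]
          }
          if (eligible && stream_unif(s_cs) < config$cs_prob) {
            triggered <- if (pl == punished) "CS+" else "CS-"
            emit(ta, "cs_trigger", planet = pl, cs = triggered)
            cs_stage <- 1L
            cs_planet_cur <- pl
            cs_type_cur <- triggered
            t_cs_onset <- ta + config$cs_delay_s
          }
          if (!is.null(observe)) {
            observe(list(kind = "click", planet = pl, eligible = eligible,
                         cs_triggered = triggered, time = ta), mem)
          }
        } else if (act$action == "shield") {
          if (cs_stage != 2L || !offer_open || shield_active || ta >= t_cs_end) {
            stop("shield activation without an offered shield", call. = FALSE)
          }
          emit(ta, "shield_activated", cs = cs_type_cur,
               delta = -config$shield_cost_points)
          shield_active <- TRUE
          offer_open <- FALSE
          if (!is.null(observe)) {
            observe(list(kind = "shield_activated", cs_type = cs_type_cur,
                         time = ta), mem)
          }
        }
        # "none" actions with finite time just advance the clock
      }
    }

    emit(max(dur, t), "block_end")
    if (!is.null(policy$snapshot)) snapshots[[b]] <- policy$snapshot(mem)
  }

  idx <- seq_len(n_ev)
  log <- tibble::tibble(
    participant_id = participant_id,
    block = ev_block[idx],
    phase = ev_phase[idx],
    time_s = ev_time[idx],
    kind = ev_kind[idx],
    planet = ev_planet[idx],
    cs_type = ev_cs[idx],
    points_delta = ev_delta[idx],
    points_total = ev_total[idx]
  )
  list(log = as_event_log(log), snapshots = snapshots, final_points = points)
}

#' Count CS-eligible clicks in a log
#'
#' A click is CS-eligible when it occurs in a punishment block with no CS
#' pending or active (the engine can roll a CS only for such clicks).
#' Reconstructed from the log by tracking `cs_trigger` .. `cs_offset`
#' windows; the click that itself triggers a CS counts as eligible.
#'
#' @param log an event log.
#' @param planet optionally restrict to one planet.
#' @return integer count.
#' @export
count_eligible_clicks <- function(log, planet = NULL) {
  total <- 0L
  for (pid in unique(log$participant_id)) {
    sub <- log[log$participant_id == pid & log$phase == "punish", ]
    for (b in unique(sub$block)) {
      bl <- sub[sub$block == b, ]
      open <- FALSE
      for (i in seq_len(nrow(bl))) {
        k <- bl$kind[i]
        if (k == "cs_trigger") open <- TRUE
        else if (k == "cs_offset") open <- FALSE
        else if (k == "click" && !open) {
          if (is.null(planet) || bl$planet[i] == planet) total <- total + 1L
        }
      }
    }
  }
  total
}
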