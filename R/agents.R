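# Synthetic participants --------------------------------------------------

.CH_QUEST <- 7L

#' Generative parameters of a synthetic participant
#'
#' @param base_click_rate baseline clicking rate, clicks/min.
#' @param softmax_beta inverse temperature of the planet-choice softmax,
#'   per point of action-value difference.
#' @param alpha_instr learning rate for the Response->CS contingency
#'   knowledge `kappa` (instrumental fidelity), in `[0, 1]`.
#' @param alpha_pav Pavlovian learning rate for the CS->Attack value `V`,
#'   in `[0, 1]`.
#' @param alpha_reward learning rate of the reward-probability estimate.
#' @param kappa_prior prior Response->CS contingency for every
#'   (response, CS) pair before any punishment-phase experience.
#' @param w_reward,w_punish value weights of the reward and punishment
#'   terms in the action value.
#' @param loss_nominal nominal stake (points) an attack is felt to risk;
#'   scales the punishment term of the action value.
#' @param reward_points_belief believed reward magnitude (points).
#' @param suppression_gain proportional click-rate reduction per unit of
#'   CS value `V` while the CS is on screen.
#' @param shield_bias,shield_slope intercept and slope of the logistic
#'   shield-activation policy in `V`.
#' @param shield_rt_s reaction time from shield offer to activation.
#' @param report_noise_sd sd of the truncated-normal rating noise (rating
#'   points on the 0-100 scale).
#' @param rt_mean_s,rt_sd_s mean and sd of per-check-screen response times.
#' @param catch_fail_prob probability of failing each catch question.
#' @return an object of class `agent_params`.
#' @export
agent_params <- function(base_click_rate = 60,
                         softmax_beta = 0.02,
                         alpha_instr = 0.12,
                         alpha_pav = 0.3,
                         alpha_reward = 0.1,
                         kappa_prior = 0.2,
                         w_reward = 1,
                         w_punish = 1,
                         loss_nominal = 500,
                         reward_points_belief = 100,
                         suppression_gain = 0.5,
                         shield_bias = -2,
                         shield_slope = 4,
                         shield_rt_s = 0.5,
                         report_noise_sd = 10,
                         rt_mean_s = 6,
                         rt_sd_s = 1.5,
                         catch_fail_prob = 0) {
  p <- as.list(environment())
  class(p) <- "agent_params"
  validate_agent_params(p)
  p
}

validate_agent_params <- function(p) {
  if (p$alpha_instr < 0 || p$alpha_instr > 1) {
    stop("alpha_instr must lie in [0, 1]", call. = FALSE)
  }
  if (p$alpha_pav < 0 || p$alpha_pav > 1) {
    stop("alpha_pav must lie in [0, 1]", call. = FALSE)
  }
  if (p$kappa_prior < 0 || p$kappa_prior > 1) {
    stop("kappa_prior must lie in [0, 1]", call. = FALSE)
  }
  if (p$base_click_rate < 0) stop("base_click_rate must be >= 0", call. = FALSE)
  if (p$report_noise_sd < 0) stop("report_noise_sd must be >= 0", call. = FALSE)
  if (p$catch_fail_prob < 0 || p$catch_fail_prob > 1) {
    stop("catch_fail_prob must lie in [0, 1]", call. = FALSE)
  }
  invisible(p)
}

#' Create an agent of a named archetype
#'
#' The two archetypes differ *only* in instrumental contingency learning:
#' `"sensitive"` agents learn the Response->CS mapping (`alpha_instr` at its
#' default), while `"insensitive"` agents have `alpha_instr = 0` and keep
#' the undifferentiated prior `kappa_prior` for every (response, CS) pair.
#' Pavlovian CS->Attack learning (`alpha_pav`) is intact in both, so both
#' archetypes suppress to and shield against the CS+; only the sensitive
#' archetype comes to bias ITI clicking away from the punished planet.
#'
#' @param archetype `"sensitive"` or `"insensitive"`.
#' @param overrides named list of [agent_params()] fields to override.
#' @param seed unused placeholder for API symmetry; archetype defaults are
#'   deterministic.
#' @return an `agent_params` object.
#' @export
make_agent <- function(archetype = c("sensitive", "insensitive"),
                       overrides = list(), seed = NULL) {
  archetype <- match.arg(archetype)
  defaults <- as.list(agent_params())
  if (archetype == "insensitive") defaults$alpha_instr <- 0
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad) > 0) {
    stop("unknown agent parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  defaults[names(overrides)] <- overrides
  p <- do.call(agent_params, defaults[names(formals(agent_params))])
  attr(p, "archetype") <- archetype
  p
}

#' Generate a post-block self-report
#'
#' Reports are noisy readouts of the agent's own causal model: each
#' Response->CS inference is `100 * kappa[R, CS]`, each CS->Attack inference
#' `100 * V[CS]`, and each *direct* Response->Attack inference is the capped
#' chain product of the agent's own `kappa` and `V`
#' (`min(100, 100 * sum_CS kappa[R, CS] * V[CS])`), so at zero report noise
#' direct and chained estimates coincide exactly.  Valuations map the
#' agent's learned expectancies onto the 0-100 slider around the neutral
#' midpoint 50.  All ratings are drawn from normals truncated to `[0, 100]`;
#' response times from a normal truncated to `(0, Inf)`.
#'
#' @param state a policy snapshot (`kappa`, `V`, `r_hat`), as collected by
#'   [simulate_session()].
#' @param params the agent's [agent_params()].
#' @param block_index 1-based block index.
#' @param phase `"pre"` or `"punish"`; pre-punishment check screens contain
#'   only reward/planet items.
#' @param stream RNG stream for the report noise.
#' @return a one-row tibble.
#' @export
generate_self_report <- function(state, params, block_index, phase, stream) {
  sd <- params$report_noise_sd
  rate1 <- function(mu) stream_truncnorm(stream, 1L, mu, sd, 0, 100)

  kap <- state$kappa
  v <- state$V
  pen <- as.vector(kap %*% v) # expected punishment per response
  direct <- pmin(100, 100 * pen)

  punish <- phase == "punish"
  na_if_pre <- function(x) if (punish) x else NA_real_

  tibble::tibble(
    block = as.integer(block_index),
    phase = phase,
    val_reward = rate1(90),
    val_attack = na_if_pre(rate1(10)),
    val_r1 = rate1(50 + 30 * state$r_hat[["R1"]] - 50 * pen[1]),
    val_r2 = rate1(50 + 30 * state$r_hat[["R2"]] - 50 * pen[2]),
    val_csplus = na_if_pre(rate1(50 - 40 * v[["CS+"]])),
    val_csminus = na_if_pre(rate1(50 - 40 * v[["CS-"]])),
    inf_r1_reward = rate1(100 * state$r_hat[["R1"]]),
    inf_r2_reward = rate1(100 * state$r_hat[["R2"]]),
    inf_r1_csplus = na_if_pre(rate1(100 * kap["R1", "CS+"])),
    inf_r1_csminus = na_if_pre(rate1(100 * kap["R1", "CS-"])),
    inf_r2_csplus = na_if_pre(rate1(100 * kap["R2", "CS+"])),
    inf_r2_csminus = na_if_pre(rate1(100 * kap["R2", "CS-"])),
    inf_csplus_attack = na_if_pre(rate1(100 * v[["CS+"]])),
    inf_csminus_attack = na_if_pre(rate1(100 * v[["CS-"]])),
    inf_r1_attack = na_if_pre(rate1(direct[1])),
    inf_r2_attack = na_if_pre(rate1(direct[2])),
    confidence_mean = rate1(75),
    rt_mean_s = stream_truncnorm(stream, 1L, params$rt_mean_s,
                                 params$rt_sd_s, 0, Inf)
  )
}

.jitter_params <- function(p, dispersion, stream) {
  mult <- function(x) x * exp(dispersion * stream_norm(stream))
  p$base_click_rate <- mult(p$base_click_rate)
  p$softmax_beta <- mult(p$softmax_beta)
  p$loss_nominal <- mult(p$loss_nominal)
  p$suppression_gain <- min(1, mult(p$suppression_gain))
  p$alpha_pav <- min(1, mult(p$alpha_pav))
  p$alpha_instr <- min(1, mult(p$alpha_instr)) # 0 stays exactly 0
  p$rt_mean_s <- mult(p$rt_mean_s)
  p
}

#' Generate a synthetic cohort
#'
#' Simulates `n` full sessions under a mixture of punishment-sensitive and
#' punishment-insensitive agent archetypes (see [make_agent()]), with
#' per-participant parameters jittered multiplicatively around the
#' archetype defaults.  Returns the combined event log, per-block
#' self-reports, a questionnaire stub (catch-question correctness plus
#' generic trait-subscale covariates) and a manifest recording every
#' agent's true archetype and parameters for recovery tests.
#'
#' @param n cohort size.
#' @param sensitive_fraction proportion of sensitive agents (count rounded).
#' @param param_dispersion sd of the multiplicative (log-scale) parameter
#'   jitter.
#' @param seed integer master seed; the cohort is fully reproducible given
#'   `(n, sensitive_fraction, param_dispersion, seed, config)`.
#' @param config a [task_config()].
#' @param overrides named list of [agent_params()] overrides applied to
#'   every agent before jitter (e.g. `list(report_noise_sd = 0)`).
#' @return a list with elements `events`, `self_reports`, `questionnaires`
#'   and `manifest`.
#' @examples
#' coh <- generate_cohort(3, sensitive_fraction = 1/3, seed = 7)
#' table(coh$manifest$agents$archetype)
#' @export
generate_cohort <- function(n, sensitive_fraction = 0.3,
                            param_dispersion = 0.1, seed = 1L,
                            config = task_config(), overrides = list()) {
  stopifnot(n >= 0, sensitive_fraction >= 0, sensitive_fraction <= 1)
  phases <- c(rep("pre", config$n_pre_blocks),
              rep("punish", config$n_punish_blocks))

  empty <- list(
    events = as_event_log(tibble::tibble(
      participant_id = character(), block = integer(), phase = character(),
      time_s = numeric(), kind = character(), planet = character(),
      cs_type = character(), points_delta = numeric(),
      points_total = numeric())),
    self_reports = tibble::tibble(),
    questionnaires = tibble::tibble(),
    manifest = list(seed = seed, n = n,
                    sensitive_fraction = sensitive_fraction,
                    param_dispersion = param_dispersion,
                    agents = tibble::tibble())
  )
  if (n == 0) return(empty)

  # archetype assignment: fixed count, order shuffled deterministically
  n_sens <- round(n * sensitive_fraction)
  s_assign <- rng_stream(stream_seed(seed, 0L, 0L, .CH_COHORT))
  ord <- order(stream_unif(s_assign, n))
  archetypes <- rep("insensitive", n)
  archetypes[ord[seq_len(n_sens)]] <- "sensitive"

  logs <- vector("list", n)
  reports <- vector("list", n)
  quests <- vector("list", n)
  agent_rows <- vector("list", n)
  subscales <- c("dass_depression", "dass_anxiety", "dass_stress",
                 "bis11", "bis", "bas_drive", "bas_fun", "bas_reward",
                 "ipip_extraversion", "ipip_agreeableness",
                 "ipip_conscientiousness", "ipip_neuroticism",
                 "ipip_intellect", "aor_positive", "aor_negative")

  for (i in seq_len(n)) {
    pid <- sprintf("P%03d", i)
    base <- make_agent(archetypes[i], overrides = overrides)
    s_jit <- rng_stream(stream_seed(seed, i, 0L, .CH_COHORT))
    pars <- .jitter_params(as.list(base), param_dispersion, s_jit)
    class(pars) <- "agent_params"

    sim <- simulate_session(config, policy_agent(pars), seed = seed,
                            participant_id = pid, p_index = i)
    logs[[i]] <- sim$log

    rep_i <- vector("list", length(phases))
    for (b in seq_along(phases)) {
      s_rep <- rng_stream(stream_seed(seed, i, b, .CH_REPORT))
      rep_i[[b]] <- generate_self_report(sim$snapshots[[b]], pars, b,
                                         phases[b], s_rep)
    }
    rep_i <- dplyr::bind_rows(rep_i)
    rep_i$participant_id <- pid
    reports[[i]] <- rep_i[, c("participant_id",
                              setdiff(names(rep_i), "participant_id"))]

    s_q <- rng_stream(stream_seed(seed, i, 0L, .CH_QUEST))
    q <- tibble::tibble(
      participant_id = pid,
      catch1_correct = stream_unif(s_q) >= pars$catch_fail_prob,
      catch2_correct = stream_unif(s_q) >= pars$catch_fail_prob
    )
    for (s in subscales) {
      q[[s]] <- round(stream_truncnorm(s_q, 1L, 50, 10, 0, 100), 1)
    }
    quests[[i]] <- q

    agent_rows[[i]] <- tibble::tibble(
      participant_id = pid, archetype = archetypes[i],
      !!!pars[!vapply(pars, is.character, logical(1))]
    )
  }

  list(
    events = as_event_log(dplyr::bind_rows(logs)),
    self_reports = dplyr::bind_rows(reports),
    questionnaires = dplyr::bind_rows(quests),
    manifest = list(
      seed = seed, n = n, sensitive_fraction = sensitive_fraction,
      param_dispersion = param_dispersion,
      generative_model = paste(
        "softmax planet choice over punishment-weighted action values;",
        "delta-rule kappa (instrumental) and V (Pavlovian) learning;",
        "logistic shield policy; truncated-normal report noise"),
      agents = dplyr::bind_rows(agent_rows)
    )
  )
}
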