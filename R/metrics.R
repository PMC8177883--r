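# Behavioural measures ----------------------------------------------------

#' Segment a block timeline into analysis periods
#'
#' Partitions each block of an event log into labelled intervals:
#' `iti` (no CS on screen), `cs_pending` (the delay between a CS trigger
#' and its onset, when the cue is not yet visible), `cs_unshielded` /
#' `cs_shielded` (CS on screen, before/after a shield activation) and
#' `post_trading_tail` (time past the trading window, where responding is
#' suspended).  `cs_pending` and `post_trading_tail` are excluded from all
#' rate denominators downstream; unshielded CS time runs from `cs_onset` to
#' `shield_activated` (or `cs_offset`).
#'
#' @param log a validated event log.
#' @param block_duration_s trading-window length used to place the tail
#'   boundary (the task default, 180 s).
#' @return a tibble with columns `participant_id`, `block`, `phase`,
#'   `label`, `cs_type`, `start_s`, `end_s`, `duration_s`.
#' @export
segment_periods <- function(log, block_duration_s = 180) {
  viol <- validate_event_log(log)
  if (length(viol) > 0) {
    stop("event log fails validation: ", viol[1], call. = FALSE)
  }
  out <- list()
  for (pid in unique(log$participant_id)) {
    sub <- log[log$participant_id == pid, ]
    for (b in unique(sub$block)) {
      bl <- sub[sub$block == b, ]
      dur <- block_duration_s
      end_t <- max(bl$time_s, dur)
      # change points: cs_trigger, cs_onset, shield_activated, cs_offset
      cuts <- bl[bl$kind %in% c("cs_trigger", "cs_onset", "shield_activated",
                                "cs_offset"), ]
      segs <- list()
      t0 <- 0
      state <- "iti"
      cs_now <- "none"
      push <- function(t1, lab, cs) {
        if (t1 > t0) segs[[length(segs) + 1L]] <<- list(
          start_s = t0, end_s = t1, label = lab, cs_type = cs)
        t0 <<- t1
      }
      if (nrow(cuts) > 0) {
        for (i in seq_len(nrow(cuts))) {
          k <- cuts$kind[i]
          tt <- cuts$time_s[i]
          if (k == "cs_trigger") {
            push(tt, state, cs_now)
            state <- "cs_pending"; cs_now <- cuts$cs_type[i]
          } else if (k == "cs_onset") {
            push(tt, state, cs_now)
            state <- "cs_unshielded"; cs_now <- cuts$cs_type[i]
          } else if (k == "shield_activated") {
            push(tt, state, cs_now)
            state <- "cs_shielded"
          } else { # cs_offset
            push(tt, state, cs_now)
            state <- "iti"; cs_now <- "none"
          }
        }
      }
      push(end_t, state, cs_now)
      seg <- dplyr::bind_rows(lapply(segs, tibble::as_tibble))
      # carve out the post-trading tail (overrides other labels past `dur`)
      pre_tail <- seg[seg$start_s < dur, ]
      pre_tail$end_s <- pmin(pre_tail$end_s, dur)
      tail_dur <- end_t - dur
      if (tail_dur > 0) {
        pre_tail <- dplyr::bind_rows(pre_tail, tibble::tibble(
          start_s = dur, end_s = end_t, label = "post_trading_tail",
          cs_type = "none"))
      }
      seg <- pre_tail
      seg$duration_s <- seg$end_s - seg$start_s
      seg$participant_id <- pid
      seg$block <- b
      seg$phase <- bl$phase[1]
      out[[length(out) + 1L]] <- seg
    }
  }
  res <- dplyr::bind_rows(out)
  res[, c("participant_id", "block", "phase", "label", "cs_type",
          "start_s", "end_s", "duration_s")]
}

# clicks falling inside intervals of a given label, with total time
.period_clicks <- function(log, segs, labels, planet = NULL,
                           cs_type = NULL) {
  segs <- segs[segs$label %in% labels, ]
  if (!is.null(cs_type)) segs <- segs[segs$cs_type %in% cs_type, ]
  clicks <- log[log$kind == "click", ]
  if (!is.null(planet)) clicks <- clicks[clicks$planet %in% planet, ]
  n <- 0L
  if (nrow(segs) > 0 && nrow(clicks) > 0) {
    for (i in seq_len(nrow(segs))) {
      n <- n + sum(clicks$block == segs$block[i] &
                     clicks$time_s >= segs$start_s[i] &
                     clicks$time_s < segs$end_s[i])
    }
  }
  list(n = n, time_s = sum(segs$duration_s))
}

#' Preference ratio for one block
#'
#' `R1 ITI rate / (R1 ITI rate + R2 ITI rate)` over CS-free inter-trial
#' time: 0.5 means no preference, 0 a complete preference for R2, 1 a
#' complete preference for R1.  With equal ITI time for both planets this
#' reduces to the R1 share of ITI clicks.
#'
#' @param log an event log for one participant.
#' @param block block index.
#' @param segs optional precomputed [segment_periods()] table.
#' @return a list with `ratio`, `iti_rate_r1`, `iti_rate_r2`,
#'   `overall_iti_rate` (clicks/min); `ratio` is `NA` when there are no ITI
#'   clicks.
#' @export
preference_ratio <- function(log, block, segs = NULL) {
  if (is.null(segs)) segs <- segment_periods(log)
  segs <- segs[segs$block == block, ]
  log <- log[log$block == block, ]
  r1 <- .period_clicks(log, segs, "iti", planet = "R1")
  r2 <- .period_clicks(log, segs, "iti", planet = "R2")
  t_min <- r1$time_s / 60
  rate1 <- if (t_min > 0) r1$n / t_min else NA_real_
  rate2 <- if (t_min > 0) r2$n / t_min else NA_real_
  ratio <- if (!is.na(rate1) && (rate1 + rate2) > 0) {
    rate1 / (rate1 + rate2)
  } else NA_real_
  list(ratio = ratio, iti_rate_r1 = rate1, iti_rate_r2 = rate2,
       overall_iti_rate = rate1 + rate2)
}

#' Conditioned-suppression ratios
#'
#' Aggregated across punishment blocks (CSs are scarce within a block):
#' overall planet click rate during *unshielded* portions of each CS type
#' against the ITI click rate.  The default `standard` formula is
#' `CS / (CS + ITI)`, anchored at 0.5 = no change, 0 = complete
#' suppression, above 0.5 = facilitation; `literal` returns the plain
#' quotient `CS / ITI` instead.  Participants with no unshielded exposure
#' to a CS type get `NA` for it.
#'
#' @param log an event log for one participant.
#' @param segs optional precomputed segmentation.
#' @param formula `"standard"` or `"literal"`.
#' @return a list with `csplus`, `csminus`, `iti_rate`, `cs_rates`.
#' @export
suppression_ratios <- function(log, segs = NULL,
                               formula = c("standard", "literal")) {
  formula <- match.arg(formula)
  if (is.null(segs)) segs <- segment_periods(log)
  segs <- segs[segs$phase == "punish", ]
  log <- log[log$phase == "punish", ]
  iti <- .period_clicks(log, segs, "iti")
  iti_rate <- if (iti$time_s > 0) iti$n / (iti$time_s / 60) else NA_real_
  one <- function(cs) {
    p <- .period_clicks(log, segs, "cs_unshielded", cs_type = cs)
    if (p$time_s <= 0 || is.na(iti_rate)) return(NA_real_)
    cs_rate <- p$n / (p$time_s / 60)
    if (formula == "standard") {
      if (cs_rate + iti_rate == 0) NA_real_ else {
        min(1, cs_rate / (cs_rate + iti_rate))
      }
    } else {
      if (iti_rate == 0) NA_real_ else cs_rate / iti_rate
    }
  }
  cs_rate_of <- function(cs) {
    p <- .period_clicks(log, segs, "cs_unshielded", cs_type = cs)
    if (p$time_s > 0) p$n / (p$time_s / 60) else NA_real_
  }
  list(csplus = one("CS+"), csminus = one("CS-"), iti_rate = iti_rate,
       cs_rates = c("CS+" = cs_rate_of("CS+"), "CS-" = cs_rate_of("CS-")))
}

#' Shield use percentage per CS type
#'
#' `100 * activations / shields offered`, aggregated across punishment
#' blocks; `NA` when no shield was offered for that CS type.
#'
#' @param log an event log for one participant.
#' @return a list with `csplus`, `csminus`, and offered/activated counts.
#' @export
shield_use <- function(log) {
  log <- log[log$phase == "punish", ]
  one <- function(cs) {
    offered <- sum(log$kind == "shield_offered" & log$cs_type == cs)
    taken <- sum(log$kind == "shield_activated" & log$cs_type == cs)
    list(pct = if (offered > 0) 100 * taken / offered else NA_real_,
         offered = offered, taken = taken)
  }
  p <- one("CS+"); m <- one("CS-")
  list(csplus = p$pct, csminus = m$pct,
       offered = c("CS+" = p$offered, "CS-" = m$offered),
       activated = c("CS+" = p$taken, "CS-" = m$taken))
}

#' Per-participant, per-block behavioural summary
#'
#' One row per participant and block with ITI click rates, preference
#' ratio and points gained, plus punishment-phase aggregates (suppression
#' ratios and shield use) repeated on punishment rows.
#'
#' @param log an event log (one or many participants).
#' @param suppression_formula passed to [suppression_ratios()].
#' @return a tibble.
#' @export
participant_summary <- function(log, suppression_formula = "standard") {
  rows <- list()
  for (pid in unique(log$participant_id)) {
    sub <- log[log$participant_id == pid, ]
    segs <- segment_periods(sub)
    supp <- suppression_ratios(sub, segs, formula = suppression_formula)
    sh <- shield_use(sub)
    for (b in sort(unique(sub$block))) {
      pr <- preference_ratio(sub, b, segs)
      bl <- sub[sub$block == b, ]
      punish <- bl$phase[1] == "punish"
      rows[[length(rows) + 1L]] <- tibble::tibble(
        participant_id = pid,
        block = b,
        phase = bl$phase[1],
        iti_rate_r1 = pr$iti_rate_r1,
        iti_rate_r2 = pr$iti_rate_r2,
        overall_iti_rate = pr$overall_iti_rate,
        preference_ratio = pr$ratio,
        points_gained = sum(bl$points_delta),
        suppression_csplus = if (punish) supp$csplus else NA_real_,
        suppression_csminus = if (punish) supp$csminus else NA_real_,
        shield_use_csplus = if (punish) sh$csplus else NA_real_,
        shield_use_csminus = if (punish) sh$csminus else NA_real_
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Collapse the pre-punishment blocks
#'
#' Averages the metrics of the pre-punishment blocks of a
#' [participant_summary()] into a single `Pre` entry per participant
#' (block label `0`), leaving punishment blocks unchanged.
#'
#' @param summary a [participant_summary()] tibble.
#' @return a tibble with one `Pre` row plus punishment rows per participant.
#' @export
collapse_pre <- function(summary) {
  pre <- summary[summary$phase == "pre", ]
  pun <- summary[summary$phase == "punish", ]
  num <- names(pre)[vapply(pre, is.numeric, logical(1))]
  num <- setdiff(num, "block")
  pre_c <- dplyr::summarise(
    dplyr::group_by(pre, .data$participant_id),
    dplyr::across(dplyr::all_of(num), ~ mean(.x, na.rm = TRUE)),
    .groups = "drop")
  pre_c$block <- 0L
  pre_c$phase <- "pre"
  dplyr::bind_rows(pre_c[, names(summary)], pun)
}

#' Apply participant exclusion rules
#'
#' A participant is retained iff every check screen's mean per-question
#' response time lies within `[1, 30]` seconds and both catch questions
#' were answered correctly; participants with missing fields are excluded
#' with reason `"incomplete"`.
#'
#' @param self_reports per-block self-report tibble with `rt_mean_s`.
#' @param questionnaires tibble with `catch1_correct`, `catch2_correct`.
#' @param rt_bounds inclusive response-time window, seconds.
#' @return a list with `retained` (character ids) and `excluded` (tibble of
#'   id + reason).
#' @export
apply_exclusions <- function(self_reports, questionnaires,
                             rt_bounds = c(1, 30)) {
  ids <- union(unique(self_reports$participant_id),
               unique(questionnaires$participant_id))
  excluded <- list()
  retained <- character(0)
  for (pid in ids) {
    rts <- self_reports$rt_mean_s[self_reports$participant_id == pid]
    q <- questionnaires[questionnaires$participant_id == pid, ]
    if (length(rts) == 0 || nrow(q) == 0 || anyNA(rts) ||
        anyNA(q$catch1_correct) || anyNA(q$catch2_correct)) {
      excluded[[length(excluded) + 1L]] <- tibble::tibble(
        participant_id = pid, reason = "incomplete")
    } else if (any(rts < rt_bounds[1] | rts > rt_bounds[2])) {
      excluded[[length(excluded) + 1L]] <- tibble::tibble(
        participant_id = pid, reason = "response_time")
    } else if (!q$catch1_correct[1] || !q$catch2_correct[1]) {
      excluded[[length(excluded) + 1L]] <- tibble::tibble(
        participant_id = pid, reason = "catch_question")
    } else {
      retained <- c(retained, pid)
    }
  }
  list(retained = retained,
       excluded = if (length(excluded) > 0) dplyr::bind_rows(excluded) else
         tibble::tibble(participant_id = character(), reason = character()))
}
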