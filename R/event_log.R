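# Event logs -------------------------------------------------------------

EVENT_KINDS <- c("click", "trade_start", "reward", "no_reward",
                 "cs_trigger", "cs_onset", "cs_offset",
                 "shield_offered", "shield_unavailable", "shield_activated",
                 "attack", "block_end")

#' Construct an event log tibble
#'
#' Canonical tidy representation of a session: one row per event, ordered in
#' time within block.  `points_total` is the running sum of `points_delta`.
#'
#' @param participant_id participant identifier.
#' @param block integer block index (1-based, across phases).
#' @param phase `"pre"` or `"punish"`.
#' @param time_s seconds from block start.
#' @param kind event kind (one of `click`, `trade_start`, `reward`,
#'   `no_reward`, `cs_trigger`, `cs_onset`, `cs_offset`, `shield_offered`,
#'   `shield_unavailable`, `shield_activated`, `attack`, `block_end`).
#' @param planet `"R1"`, `"R2"` or `"none"`.
#' @param cs_type `"CS+"`, `"CS-"` or `"none"`.
#' @param points_delta signed points change of the event.
#' @return a tibble of class `event_log`.
#' @export
event_log <- function(participant_id, block, phase, time_s, kind,
                      planet = "none", cs_type = "none", points_delta = 0) {
  out <- tibble::tibble(
    participant_id = as.character(participant_id),
    block = as.integer(block),
    phase = as.character(phase),
    time_s = as.numeric(time_s),
    kind = as.character(kind),
    planet = as.character(planet),
    cs_type = as.character(cs_type),
    points_delta = as.numeric(points_delta)
  )
  out$points_total <- stats::ave(out$points_delta, out$participant_id,
                                 FUN = cumsum)
  class(out) <- c("event_log", class(out))
  out
}

as_event_log <- function(df) {
  class(df) <- unique(c("event_log", class(df)))
  df
}

#' Validate an event log
#'
#' Checks the structural invariants of a session log and returns a character
#' vector of violations (empty when the log is consistent):
#' nondecreasing times within block, valid event kinds, exactly one
#' `cs_offset` per `cs_onset` with no overlapping CS episodes,
#' `points_total` equal to the running sum of `points_delta`, and
#' `shield_activated` occurring only between a `shield_offered` and the
#' matching `cs_offset`.
#'
#' @param log an event log tibble.
#' @return character vector of violation messages; `character(0)` if clean.
#' @export
validate_event_log <- function(log) {
  viol <- character(0)
  need <- c("participant_id", "block", "time_s", "kind", "planet",
            "cs_type", "points_delta", "points_total")
  missing_cols <- setdiff(need, names(log))
  if (length(missing_cols) > 0) {
    return(sprintf("missing columns: %s", paste(missing_cols, collapse = ", ")))
  }
  bad_kind <- setdiff(unique(log$kind), EVENT_KINDS)
  if (length(bad_kind) > 0) {
    viol <- c(viol, sprintf("unknown event kinds: %s",
                            paste(bad_kind, collapse = ", ")))
  }
  for (pid in unique(log$participant_id)) {
    sub <- log[log$participant_id == pid, ]
    # running point total
    if (max(abs(sub$points_total - cumsum(sub$points_delta))) > 1e-9) {
      viol <- c(viol, sprintf(
        "%s: points_total does not equal the running sum of points_delta", pid))
    }
    for (b in unique(sub$block)) {
      bl <- sub[sub$block == b, ]
      if (is.unsorted(bl$time_s)) {
        viol <- c(viol, sprintf("%s block %d: times not nondecreasing", pid, b))
      }
      # CS pairing / overlap / shield placement, by linear scan
      cs_open <- FALSE
      shield_window <- FALSE
      for (i in seq_len(nrow(bl))) {
        k <- bl$kind[i]
        if (k == "cs_onset") {
          if (cs_open) {
            viol <- c(viol, sprintf(
              "%s block %d: overlapping CS episodes (only one CS may run at a time)",
              pid, b))
          }
          cs_open <- TRUE
        } else if (k == "cs_offset") {
          if (!cs_open) {
            viol <- c(viol, sprintf("%s block %d: cs_offset without cs_onset",
                                    pid, b))
          }
          cs_open <- FALSE
          shield_window <- FALSE
        } else if (k == "shield_offered") {
          shield_window <- TRUE
        } else if (k == "shield_activated") {
          if (!shield_window) {
            viol <- c(viol, sprintf(
              "%s block %d: shield_activated outside a shield_offered..cs_offset window",
              pid, b))
          }
          shield_window <- FALSE # at most one activation per offer
        }
      }
      if (cs_open) {
        viol <- c(viol, sprintf("%s block %d: cs_onset without matching cs_offset",
                                pid, b))
      }
    }
  }
  viol
}

#' Write / read an event log as tidy CSV or JSON-Lines
#'
#' @param log an event log.
#' @param path output file; `.jsonl` extension selects JSON-Lines (one event
#'   object per line), anything else tidy CSV.
#' @export
write_event_log <- function(log, path) {
  if (grepl("\\.jsonl$", path)) {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(log))) {
      writeLines(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE), con)
    }
  } else {
    utils::write.csv(as.data.frame(log), path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  if (grepl("\\.jsonl$", path)) {
    rows <- lapply(readLines(path), function(l) {
      as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
    })
    df <- tibble::as_tibble(do.call(rbind, rows))
  } else {
    df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  }
  df$block <- as.integer(df$block)
  as_event_log(df)
}
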