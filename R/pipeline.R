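# Pipeline orchestration ---------------------------------------------------

#' Phase-averaged self-report bias ratios
#'
#' Normalised R1:R2 (and CS+:CS-) bias ratios of the punishment-phase
#' self-reports, one row per participant: e.g. the Response->Attack ratio
#' is `inf_r1_attack / (inf_r1_attack + inf_r2_attack)` after averaging
#' each inference across punishment blocks (0.5 = undifferentiated).
#'
#' @param self_reports cohort self-report tibble.
#' @return tibble with `participant_id`, `attack_ratio`, `reward_ratio`,
#'   `cs_attack_ratio` (CS+ : CS+ + CS-).
#' @export
self_report_ratios <- function(self_reports) {
  sr <- self_reports[self_reports$phase == "punish", ]
  agg <- dplyr::summarise(
    dplyr::group_by(sr, .data$participant_id),
    dplyr::across(dplyr::where(is.numeric), ~ mean(.x, na.rm = TRUE)),
    .groups = "drop")
  ratio <- function(a, b) ifelse(a + b > 0, a / (a + b), NA_real_)
  tibble::tibble(
    participant_id = agg$participant_id,
    attack_ratio = ratio(agg$inf_r1_attack, agg$inf_r2_attack),
    reward_ratio = ratio(agg$inf_r1_reward, agg$inf_r2_reward),
    cs_attack_ratio = ratio(agg$inf_csplus_attack, agg$inf_csminus_attack)
  )
}

#' Simulate a cohort and write it to disk
#'
#' Writes `events.csv`, `self_reports.csv`, `questionnaires.csv` and
#' `manifest.json` (true archetypes and parameters) into `out_dir`.
#' Fully reproducible: the same configuration and seed give identical
#' files.
#'
#' @param out_dir output directory (created if needed).
#' @param n cohort size.
#' @param sensitive_fraction,param_dispersion,seed,config,overrides passed
#'   to [generate_cohort()].
#' @return `out_dir`, invisibly.
#' @export
run_simulate <- function(out_dir, n = 135, sensitive_fraction = 0.3,
                         param_dispersion = 0.1, seed = 1L,
                         config = task_config(), overrides = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  coh <- generate_cohort(n, sensitive_fraction, param_dispersion, seed,
                         config, overrides)
  utils::write.csv(as.data.frame(coh$events),
                   file.path(out_dir, "events.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(coh$self_reports),
                   file.path(out_dir, "self_reports.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(coh$questionnaires),
                   file.path(out_dir, "questionnaires.csv"), row.names = FALSE)
  man <- coh$manifest
  man$config <- unclass(config)
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}

#' Analyse a cohort directory
#'
#' Runs the full analysis pipeline on a cohort written by
#' [run_simulate()] (or assembled in the same layout): exclusions first,
#' then per-participant behavioural metrics with the pre-punishment blocks
#' collapsed, k-means sensitivity clustering on final-block preference
#' ratios, one-sample ratio tests, orthogonal-contrast ANOVAs, chain
#' inference regressions with component omission, stepwise linear and
#' logistic regressions, and a varimax PCA of the instrumental items.
#' Each stage's output is written as tidy CSV into `out_dir`, plus a
#' `run_log.txt`.
#'
#' @param cohort_dir directory holding `events.csv`, `self_reports.csv`,
#'   `questionnaires.csv`.
#' @param out_dir output directory (created if needed).
#' @param suppression_formula `"standard"` or `"literal"` (see
#'   [suppression_ratios()]).
#' @param k_range candidate cluster counts.
#' @param p_enter,p_remove stepwise thresholds.
#' @param seed seed for the clustering restarts.
#' @return (invisibly) a list of the main result objects.
#' @export
run_analyze <- function(cohort_dir, out_dir,
                        suppression_formula = "standard", k_range = 2:4,
                        p_enter = 0.05, p_remove = 0.1, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  events <- read_event_log(file.path(cohort_dir, "events.csv"))
  sr <- tibble::as_tibble(utils::read.csv(
    file.path(cohort_dir, "self_reports.csv"), stringsAsFactors = FALSE))
  quest <- tibble::as_tibble(utils::read.csv(
    file.path(cohort_dir, "questionnaires.csv"), stringsAsFactors = FALSE))

  viol <- validate_event_log(events)
  if (length(viol) > 0) {
    stop("cohort event log invalid: ", viol[1], call. = FALSE)
  }

  excl <- apply_exclusions(sr, quest)
  say("exclusions: %d retained, %d excluded", length(excl$retained),
      nrow(excl$excluded))
  events <- events[events$participant_id %in% excl$retained, ]
  sr <- sr[sr$participant_id %in% excl$retained, ]

  summary_raw <- participant_summary(events,
                                     suppression_formula = suppression_formula)
  summary <- collapse_pre(summary_raw)
  utils::write.csv(as.data.frame(summary),
                   file.path(out_dir, "participant_summary.csv"),
                   row.names = FALSE)
  pav <- unique(summary_raw[summary_raw$phase == "punish",
                            c("participant_id", "suppression_csplus",
                              "suppression_csminus", "shield_use_csplus",
                              "shield_use_csminus")])
  utils::write.csv(as.data.frame(pav),
                   file.path(out_dir, "pavlovian_summary.csv"),
                   row.names = FALSE)

  # clustering on final punishment block preference ratio
  final_block <- max(summary$block)
  fin <- summary[summary$block == final_block, ]
  fin <- fin[!is.na(fin$preference_ratio), ]
  clus <- tryCatch(
    cluster_sensitivity(fin$preference_ratio, seed = seed,
                        k_range = k_range, ids = fin$participant_id),
    error = function(e) e)
  if (inherits(clus, "error")) {
    say("clustering degenerate: %s", conditionMessage(clus))
    clus <- NULL
  } else {
    utils::write.csv(as.data.frame(clus$assignment),
                     file.path(out_dir, "clusters.csv"), row.names = FALSE)
    say("clustering: k = %d, sizes %s, mean silhouette %.3f",
        clus$chosen_k, paste(table(clus$labels), collapse = "+"),
        clus$mean_silhouette[paste0("k", clus$chosen_k)])
  }

  # one-sample ratio tests per block
  rt_rows <- list()
  for (b in sort(unique(summary$block))) {
    vals <- summary$preference_ratio[summary$block == b]
    if (sum(!is.na(vals)) >= 2) {
      r <- one_sample_ratio_test(vals)
      r$measure <- "preference_ratio"
      r$block <- b
      rt_rows[[length(rt_rows) + 1L]] <- r
    }
  }
  for (m in c("suppression_csplus", "suppression_csminus")) {
    vals <- pav[[m]]
    if (sum(!is.na(vals)) >= 2) {
      r <- one_sample_ratio_test(vals)
      r$measure <- m
      r$block <- NA_integer_
      rt_rows[[length(rt_rows) + 1L]] <- r
    }
  }
  ratio_tests <- dplyr::bind_rows(rt_rows)
  utils::write.csv(as.data.frame(ratio_tests),
                   file.path(out_dir, "ratio_tests.csv"), row.names = FALSE)

  # contrast ANOVAs over punishment blocks (with cluster where available)
  anova_rows <- list()
  wide <- tidyr::pivot_wider(
    summary[summary$phase == "punish",
            c("participant_id", "block", "preference_ratio")],
    names_from = "block", values_from = "preference_ratio")
  cells <- as.matrix(wide[, -1])
  groups <- if (!is.null(clus)) unname(clus$labels[wide$participant_id])
  nb <- ncol(cells)
  lin <- seq_len(nb) - mean(seq_len(nb))
  a1 <- contrast_anova(cells, contrast_spec(block_linear = lin),
                       groups = groups)
  a1$measure <- "preference_ratio"
  anova_rows[[1]] <- a1
  pav_cells <- as.matrix(pav[, c("suppression_csplus", "suppression_csminus")])
  ok <- stats::complete.cases(pav_cells)
  if (sum(ok) > 3) {
    a2 <- contrast_anova(pav_cells[ok, ],
                         contrast_spec(cs_plus_vs_minus = c(1, -1)),
                         groups = if (!is.null(clus))
                           unname(clus$labels[pav$participant_id[ok]]))
    a2$measure <- "suppression_ratio"
    anova_rows[[2]] <- a2
  }
  anova_results <- dplyr::bind_rows(anova_rows)
  utils::write.csv(as.data.frame(anova_results),
                   file.path(out_dir, "anova_results.csv"), row.names = FALSE)

  # chain inferences
  chain_tab <- chain_estimates_table(sr)
  utils::write.csv(as.data.frame(chain_tab),
                   file.path(out_dir, "chain_estimates.csv"),
                   row.names = FALSE)
  groups_map <- if (!is.null(clus)) clus$labels
  chain_reg <- dplyr::bind_rows(
    regress_direct_vs_chained(chain_tab, groups_map, level = "block"),
    regress_direct_vs_chained(chain_tab, groups_map, level = "phase"))
  utils::write.csv(as.data.frame(chain_reg),
                   file.path(out_dir, "chain_regression.csv"),
                   row.names = FALSE)
  om <- omission_analysis(chain_tab)
  utils::write.csv(as.data.frame(om$single_path),
                   file.path(out_dir, "omission_analysis.csv"),
                   row.names = FALSE)

  # stepwise regressions: behaviour from inference ratios
  ratios <- self_report_ratios(sr)
  pref_phase <- dplyr::summarise(
    dplyr::group_by(summary[summary$phase == "punish", ], .data$participant_id),
    preference_ratio = mean(.data$preference_ratio, na.rm = TRUE),
    .groups = "drop")
  dat <- dplyr::inner_join(pref_phase, ratios, by = "participant_id")
  dat <- dat[stats::complete.cases(dat[, c("preference_ratio", "attack_ratio",
                                           "reward_ratio")]), ]
  sw_paths <- list()
  if (nrow(dat) > 5) {
    sw <- stepwise_linear(dat$preference_ratio,
                          dat[, c("attack_ratio", "reward_ratio")],
                          p_enter = p_enter, p_remove = p_remove)
    if (nrow(sw$steps) > 0) {
      s <- sw$steps
      s$model <- "preference_ratio~inference_ratios"
      sw_paths[[length(sw_paths) + 1L]] <- s
    }
    say("stepwise linear: entered %s",
        if (length(sw$included)) paste(sw$included, collapse = ", ") else
          "none")
  }
  if (!is.null(clus)) {
    lab <- unname(clus$labels[dat$participant_id])
    keep <- lab %in% c("sensitive", "insensitive")
    if (sum(keep) > 5 && length(unique(lab[keep])) == 2) {
      swl <- stepwise_logistic(lab[keep] == "sensitive",
                               dat[keep, c("attack_ratio", "reward_ratio")],
                               p_enter = p_enter, p_remove = p_remove)
      if (nrow(swl$steps) > 0) {
        s <- swl$steps
        s$model <- "cluster~inference_ratios"
        s$F <- NA_real_; s$df1 <- NA_integer_; s$df2 <- NA_integer_
        s$r2 <- swl$nagelkerke_r2; s$r2_increment <- NA_real_
        sw_paths[[length(sw_paths) + 1L]] <-
          s[, c("step", "action", "predictor", "F", "df1", "df2", "p",
                "r2", "r2_increment", "model")]
      }
      say("stepwise logistic: accuracy %.1f%%, Nagelkerke r2 = %.3f",
          100 * swl$accuracy, swl$nagelkerke_r2)
    }
  }
  if (length(sw_paths) > 0) {
    utils::write.csv(as.data.frame(dplyr::bind_rows(sw_paths)),
                     file.path(out_dir, "regression_paths.csv"),
                     row.names = FALSE)
  }

  # PCA of instrumental items (phase-averaged punishment metrics)
  items <- dplyr::inner_join(
    dplyr::summarise(
      dplyr::group_by(summary[summary$phase == "punish", ],
                      .data$participant_id),
      overall_iti_rate = mean(.data$overall_iti_rate, na.rm = TRUE),
      preference_ratio = mean(.data$preference_ratio, na.rm = TRUE),
      .groups = "drop"),
    ratios, by = "participant_id")
  item_mat <- items[, c("overall_iti_rate", "preference_ratio",
                        "attack_ratio", "reward_ratio")]
  if (nrow(item_mat) > 10) {
    pca <- tryCatch(pca_varimax(item_mat), error = function(e) NULL)
    if (!is.null(pca)) {
      load_df <- as.data.frame(pca$loadings)
      load_df$item <- rownames(pca$loadings)
      load_df$communality <- pca$communalities
      utils::write.csv(load_df, file.path(out_dir, "pca_loadings.csv"),
                       row.names = FALSE)
      say("pca: %d component(s) reach the communality rule",
          pca$n_components)
    }
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(summary = summary, clusters = clus,
                 ratio_tests = ratio_tests, anova = anova_results,
                 chain_regression = chain_reg, omission = om,
                 exclusions = excl))
}
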