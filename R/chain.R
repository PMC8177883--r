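# Hierarchical (Response -> CS -> Attack) chain inferences ---------------

#' Chained Response->Attack estimate from component inferences
#'
#' Combines the two mediating paths on the probability scale and
#' re-expresses the result in percent:
#' `min(100, a*b/100 + c*d/100)` for components
#' `(R->CS+, CS+->Attack, R->CS-, CS-->Attack)`, so that two certain links
#' (100% x 100%) give a 100% chained estimate and the summed paths are
#' capped at 100%.  Vectorised over participants/blocks.
#'
#' @param r_to_csplus,csplus_to_attack,r_to_csminus,csminus_to_attack
#'   percent-scale likelihood inferences in `[0, 100]`.
#' @return a tibble with `csplus_path`, `csminus_path`, `uncapped` and the
#'   capped `overall` estimate (all percent).
#' @examples
#' chain_estimate(90, 90, 80, 80)$overall # capped at 100
#' chain_estimate(50, 40, 20, 10)$overall # 22
#' @export
chain_estimate <- function(r_to_csplus, csplus_to_attack,
                           r_to_csminus, csminus_to_attack) {
  args <- list(r_to_csplus, csplus_to_attack, r_to_csminus, csminus_to_attack)
  rng_ok <- vapply(args, function(x) all(is.na(x) | (x >= 0 & x <= 100)),
                   logical(1))
  if (!all(rng_ok)) {
    stop("component inferences must lie in [0, 100]", call. = FALSE)
  }
  plus <- r_to_csplus * csplus_to_attack / 100
  minus <- r_to_csminus * csminus_to_attack / 100
  tibble::tibble(
    csplus_path = plus,
    csminus_path = minus,
    uncapped = plus + minus,
    overall = pmin(100, plus + minus)
  )
}

#' Chain estimates for a self-report table
#'
#' Adds per-response chained estimates (and their single-path components)
#' to the punishment-phase rows of a cohort self-report table.
#'
#' @param self_reports tibble as produced by [generate_cohort()].
#' @return tibble with columns `participant_id`, `block`, `response`,
#'   `direct` (self-reported R->Attack), `chained`, `csplus_path`,
#'   `csminus_path`.
#' @export
chain_estimates_table <- function(self_reports) {
  sr <- self_reports[self_reports$phase == "punish", ]
  out <- list()
  for (resp in c("R1", "R2")) {
    lo <- tolower(resp)
    ce <- chain_estimate(sr[[paste0("inf_", lo, "_csplus")]],
                         sr$inf_csplus_attack,
                         sr[[paste0("inf_", lo, "_csminus")]],
                         sr$inf_csminus_attack)
    out[[resp]] <- tibble::tibble(
      participant_id = sr$participant_id,
      block = sr$block,
      response = resp,
      direct = sr[[paste0("inf_", lo, "_attack")]],
      chained = ce$overall,
      csplus_path = ce$csplus_path,
      csminus_path = ce$csminus_path
    )
  }
  dplyr::bind_rows(out)
}

.ols_fit <- function(y, x) {
  ok <- !is.na(y) & !is.na(x)
  y <- y[ok]; x <- x[ok]
  n <- length(y)
  if (n < 3) {
    return(list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
                f = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
                p = NA_real_, n = n))
  }
  if (stats::sd(x) == 0) {
    return(list(slope = NA_real_, intercept = mean(y), r2 = NA_real_,
                f = NA_real_, df1 = 1L, df2 = n - 2L, p = NA_real_, n = n))
  }
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit)) # perfect fits are legitimate here
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = sm$r.squared,
       f = unname(sm$fstatistic[1]),
       df1 = as.integer(sm$fstatistic[2]),
       df2 = as.integer(sm$fstatistic[3]),
       p = stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                     lower.tail = FALSE),
       n = n)
}

#' Regress direct Response->Attack inferences on chained estimates
#'
#' Unweighted OLS of the direct inference on the chained estimate, per
#' group (typically cluster x response), either pooling per-block
#' observations (`level = "block"`) or first averaging each participant
#' across the punishment phase (`level = "phase"`).  An intercept is
#' included and reported.
#'
#' @param chain_table output of [chain_estimates_table()].
#' @param groups optional named character vector mapping participant ids to
#'   group labels (e.g. cluster labels); omit for a single group.
#' @param level `"block"` (pooled per-block points) or `"phase"`
#'   (per-subject phase averages).
#' @return a tibble with one row per group x response: `slope`, `intercept`,
#'   `r2`, `f`, `df1`, `df2`, `p`, `n`.
#' @export
regress_direct_vs_chained <- function(chain_table, groups = NULL,
                                      level = c("block", "phase")) {
  level <- match.arg(level)
  tab <- chain_table
  tab$group <- if (is.null(groups)) "all" else
    unname(groups[tab$participant_id])
  if (level == "phase") {
    tab <- dplyr::summarise(
      dplyr::group_by(tab, .data$participant_id, .data$group, .data$response),
      direct = mean(.data$direct, na.rm = TRUE),
      chained = mean(.data$chained, na.rm = TRUE),
      .groups = "drop")
  }
  res <- list()
  for (g in unique(tab$group)) {
    for (resp in unique(tab$response)) {
      sub <- tab[tab$group == g & tab$response == resp, ]
      fit <- .ols_fit(sub$direct, sub$chained)
      res[[length(res) + 1L]] <- tibble::tibble(
        group = g, response = resp, level = level,
        slope = fit$slope, intercept = fit$intercept, r2 = fit$r2,
        f = fit$f, df1 = fit$df1, df2 = fit$df2, p = fit$p, n = fit$n)
    }
  }
  dplyr::bind_rows(res)
}

#' Component-omission analysis of the chain model
#'
#' Asks what is lost when one mediating path is dropped: regresses direct
#' Response->Attack inferences on each single-path estimate alone
#' (CS+ only, CS- only), reports the stepwise entry of the two paths as
#' predictors (via [stepwise_linear()]), and summarises the bias of each
#' omission as the mean signed prediction error
#' `single-path estimate - direct` (negative = underprediction).
#'
#' @param chain_table output of [chain_estimates_table()].
#' @param response which response to analyse, `"R1"` or `"R2"`; `"both"`
#'   pools them.
#' @return a list with `single_path` (per-path OLS fits + mean signed
#'   error), `stepwise` (entry path of CS+ and CS- path estimates) and
#'   `full_fit` (the both-paths regression, identical to
#'   [regress_direct_vs_chained()] on the same rows).
#' @export
omission_analysis <- function(chain_table, response = "both") {
  tab <- if (response == "both") chain_table else
    chain_table[chain_table$response == response, ]
  tab <- tab[!is.na(tab$direct), ]

  single <- list()
  for (path in c("csplus_path", "csminus_path")) {
    est <- pmin(100, tab[[path]])
    fit <- .ols_fit(tab$direct, est)
    single[[length(single) + 1L]] <- tibble::tibble(
      omitted = if (path == "csplus_path") "CS- path (CS+ only)" else
        "CS+ path (CS- only)",
      kept_path = path,
      slope = fit$slope, intercept = fit$intercept, r2 = fit$r2,
      mean_signed_error = mean(est - tab$direct), n = fit$n)
  }

  sw <- stepwise_linear(tab$direct,
                        data.frame(csplus_path = tab$csplus_path,
                                   csminus_path = tab$csminus_path))
  full <- .ols_fit(tab$direct, pmin(100, tab$csplus_path + tab$csminus_path))

  list(single_path = dplyr::bind_rows(single),
       stepwise = sw,
       full_fit = tibble::tibble(
         slope = full$slope, intercept = full$intercept, r2 = full$r2,
         f = full$f, df1 = full$df1, df2 = full$df2, p = full$p, n = full$n))
}
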