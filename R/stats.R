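# Cohort statistics --------------------------------------------------------

#' One-sample t-test of a ratio against a null value
#'
#' Two-sided Student t of a vector of ratios against `null` (0.5 = no
#' preference / no suppression).
#'
#' @param values numeric vector (NAs dropped).
#' @param null null value.
#' @return tibble with `mean`, `t`, `df`, `p`, `n`; `t` is signed infinity
#'   (p = 0) when the values have zero variance but a mean different from
#'   the null.
#' @export
one_sample_ratio_test <- function(values, null = 0.5) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 2) stop("need at least 2 finite values", call. = FALSE)
  if (stats::sd(x) == 0) {
    if (mean(x) == null) {
      return(tibble::tibble(mean = mean(x), t = 0, df = n - 1L, p = 1, n = n))
    }
    return(tibble::tibble(mean = mean(x), t = sign(mean(x) - null) * Inf,
                          df = n - 1L, p = 0, n = n))
  }
  tt <- stats::t.test(x, mu = null)
  tibble::tibble(mean = mean(x), t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value, n = n)
}

#' Specify an orthogonal within-subject contrast family
#'
#' @param ... named numeric contrast vectors over the condition cells; each
#'   must sum to 0 and the family must be mutually orthogonal.
#' @return a named list of contrast vectors (class `contrast_spec`).
#' @examples
#' contrast_spec(block_linear = c(-1, 0, 1))
#' @export
contrast_spec <- function(...) {
  cs <- list(...)
  if (is.null(names(cs)) || any(names(cs) == "")) {
    stop("contrasts must be named", call. = FALSE)
  }
  len <- unique(vapply(cs, length, integer(1)))
  if (length(len) != 1) stop("contrasts must have equal length", call. = FALSE)
  for (nm in names(cs)) {
    if (abs(sum(cs[[nm]])) > 1e-10) {
      stop("contrast '", nm, "' does not sum to 0", call. = FALSE)
    }
  }
  if (length(cs) > 1) {
    for (i in seq_along(cs)) for (j in seq_len(i - 1)) {
      if (abs(sum(cs[[i]] * cs[[j]])) > 1e-10) {
        stop("contrasts '", names(cs)[j], "' and '", names(cs)[i],
             "' are not orthogonal", call. = FALSE)
      }
    }
  }
  structure(cs, class = "contrast_spec")
}

#' Orthogonal-contrast (mixed) ANOVA
#'
#' Single-df contrast tests in the style of SPSS mixed-design output.  Each
#' within-subject contrast `c` is reduced to per-subject scores
#' `L_i = sum_j c_j x_ij`; the within effect is the test of the (unweighted)
#' grand mean of `L` against 0, `F(1, n - g)`; the contrast x group
#' interaction is the one-way ANOVA of `L` across groups,
#' `F(g - 1, n - g)`; the between-groups effect is the one-way ANOVA of the
#' subject cell-means.  Subjects with incomplete cells are dropped
#' (pairwise per contrast).
#'
#' @param cells numeric matrix, participants x condition cells.
#' @param spec a [contrast_spec()].
#' @param groups optional factor/character vector of between-subject group
#'   labels (e.g. cluster); omit for a purely within-subject analysis.
#' @return tibble with columns `effect`, `F`, `df1`, `df2`, `p`.
#' @export
contrast_anova <- function(cells, spec, groups = NULL) {
  if (!inherits(spec, "contrast_spec")) {
    spec <- do.call(contrast_spec, as.list(spec))
  }
  cells <- as.matrix(cells)
  if (ncol(cells) != length(spec[[1]])) {
    stop("contrast length must equal the number of condition cells",
         call. = FALSE)
  }
  has_groups <- !is.null(groups)
  g <- if (has_groups) factor(groups) else factor(rep("all", nrow(cells)))
  ng <- nlevels(g)

  res <- list()
  for (nm in names(spec)) {
    L <- as.vector(cells %*% spec[[nm]])
    ok <- !is.na(L) & !is.na(g)
    Lk <- L[ok]; gk <- droplevels(g[ok])
    n <- length(Lk); gk_n <- nlevels(gk)
    df2 <- n - gk_n
    # pooled within-group variance of L
    ss_within <- sum(tapply(Lk, gk, function(v) sum((v - mean(v))^2)))
    mse <- ss_within / df2
    grand <- mean(tapply(Lk, gk, mean)) # unweighted mean of group means
    # se of the unweighted grand mean
    n_per <- tapply(Lk, gk, length)
    se2 <- mse * sum(1 / n_per) / gk_n^2
    f_within <- if (se2 == 0) {
      if (grand == 0) 0 else Inf # zero error variance
    } else grand^2 / se2
    res[[length(res) + 1L]] <- tibble::tibble(
      effect = nm, F = f_within, df1 = 1L, df2 = df2,
      p = stats::pf(f_within, 1, df2, lower.tail = FALSE))
    if (has_groups && gk_n > 1) {
      means <- tapply(Lk, gk, mean)
      ss_between <- sum(n_per * (means - sum(n_per * means) / n)^2)
      f_int <- if (mse == 0) {
        if (ss_between == 0) 0 else Inf
      } else (ss_between / (gk_n - 1)) / mse
      res[[length(res) + 1L]] <- tibble::tibble(
        effect = paste0(nm, ":group"), F = f_int, df1 = gk_n - 1L, df2 = df2,
        p = stats::pf(f_int, gk_n - 1, df2, lower.tail = FALSE))
    }
  }
  if (has_groups && ng > 1) {
    m_subj <- rowMeans(cells)
    ok <- !is.na(m_subj) & !is.na(g)
    a <- stats::anova(stats::lm(m_subj[ok] ~ droplevels(g[ok])))
    res[[length(res) + 1L]] <- tibble::tibble(
      effect = "group", F = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
      p = a$`Pr(>F)`[1])
  }
  dplyr::bind_rows(res)
}

#' Varimax-rotated PCA with a communality retention rule
#'
#' Correlation-matrix PCA; the number of retained components is the
#' smallest `m` such that every item's m-component communality is at least
#' `min_communality` (50% of each item's variance by default).  Loadings
#' are varimax-rotated with Kaiser normalisation and annotated at the 0.5
#' (`+`) and 0.707 (`++`) absolute-loading thresholds.
#'
#' @param items numeric matrix/data frame, participants x items.
#' @param min_communality per-item communality threshold.
#' @param max_components cap on the number of components considered.
#' @return list with `n_components`, `loadings` (rotated), `communalities`,
#'   `variance_explained` (per rotated component, proportion of total),
#'   `annotation` (character matrix of ""/"+"/"++"), `dropped` (constant
#'   items removed).
#' @export
pca_varimax <- function(items, min_communality = 0.5,
                        max_components = NULL) {
  X <- as.matrix(items)
  if (ncol(X) < 2) stop("need at least 2 items", call. = FALSE)
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  dropped <- colnames(X)[sds == 0 | is.na(sds)]
  if (length(dropped) > 0) {
    warning("dropping constant item(s): ", paste(dropped, collapse = ", "))
    X <- X[, !(colnames(X) %in% dropped), drop = FALSE]
  }
  X <- X[stats::complete.cases(X), , drop = FALSE]
  p <- ncol(X)
  if (is.null(max_components)) max_components <- p
  eig <- eigen(stats::cor(X), symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  load_full <- eig$vectors %*% diag(sqrt(lam), p)
  rownames(load_full) <- colnames(X)

  m <- NA_integer_
  for (k in seq_len(min(max_components, p))) {
    comm <- rowSums(load_full[, seq_len(k), drop = FALSE]^2)
    if (all(comm >= min_communality)) { m <- k; break }
  }
  if (is.na(m)) m <- min(max_components, p)
  L <- load_full[, seq_len(m), drop = FALSE]
  if (m > 1) {
    rot <- stats::varimax(L, normalize = TRUE)
    L <- unclass(rot$loadings)
  }
  comm <- rowSums(L^2)
  ann <- matrix("", nrow(L), ncol(L), dimnames = dimnames(L))
  ann[abs(L) > 0.5] <- "+"
  ann[abs(L) > 0.707] <- "++"
  colnames(L) <- paste0("PC", seq_len(m))
  colnames(ann) <- colnames(L)
  list(
    n_components = m,
    loadings = L,
    communalities = comm,
    variance_explained = colSums(L^2) / p,
    annotation = ann,
    dropped = dropped
  )
}

# partial-F p-value of adding `cand` to the model containing `incl`
.partial_f <- function(y, X, incl, cand) {
  n <- length(y)
  x_new <- X[, cand]
  if (length(incl) > 0) {
    base_X <- cbind(1, as.matrix(X[, incl, drop = FALSE]))
    # tolerance: residual variance of the candidate given included predictors
    r_cand <- stats::lsfit(base_X, x_new, intercept = FALSE)$residuals
    tol <- sum(r_cand^2) / sum((x_new - mean(x_new))^2)
    if (!is.finite(tol) || tol < 1e-8) return(NULL) # collinear
    fit0 <- stats::lm(y ~ ., data = X[, incl, drop = FALSE])
  } else {
    if (stats::sd(x_new) == 0) return(NULL)
    fit0 <- stats::lm(y ~ 1, data = X)
  }
  fit1 <- stats::lm(y ~ ., data = X[, c(incl, cand), drop = FALSE])
  a <- stats::anova(fit0, fit1)
  rss0 <- a$RSS[1]; rss1 <- a$RSS[2]
  df2 <- a$Res.Df[2]
  f <- (rss0 - rss1) / (rss1 / df2)
  tss <- sum((y - mean(y))^2)
  list(f = f, df2 = df2,
       p = if (rss1 <= 0) 0 else stats::pf(f, 1, df2, lower.tail = FALSE),
       r2_inc = (rss0 - rss1) / tss, r2 = 1 - rss1 / tss)
}

#' Stepwise linear regression (partial-F entry and removal)
#'
#' SPSS-style stepwise selection: at each step the candidate with the
#' smallest partial-F p-value enters if `p <= p_enter` (ties broken by the
#' larger r-squared increment, then input order); after each entry any
#' retained predictor whose partial-F p-value has risen to `>= p_remove`
#' is removed.  Collinear candidates (tolerance below `1e-8`) are skipped
#' with a warning.  Deterministic: no RNG is consumed.
#'
#' @param y response vector.
#' @param X data frame of candidate predictors.
#' @param p_enter entry threshold.
#' @param p_remove removal threshold.
#' @return list with `steps` (tibble: step, action, predictor, F, df1, df2,
#'   p, r2, r2_increment), `included` (final predictors, in entry order)
#'   and `fit` (the final `lm`, or `NULL` for the empty model).
#' @export
stepwise_linear <- function(y, X, p_enter = 0.05, p_remove = 0.1) {
  X <- as.data.frame(X)
  ok <- stats::complete.cases(X) & !is.na(y)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  if (length(y) <= ncol(X) + 2) {
    stop("need n > number of predictors + 2", call. = FALSE)
  }
  incl <- character(0)
  steps <- list()
  step_i <- 0L
  repeat {
    cands <- setdiff(names(X), incl)
    if (length(cands) == 0) break
    best <- NULL
    for (cand in cands) {
      pf <- .partial_f(y, X, incl, cand)
      if (is.null(pf)) {
        warning("skipping collinear predictor: ", cand)
        next
      }
      if (is.null(best) || pf$p < best$p - 1e-12 ||
          (abs(pf$p - best$p) <= 1e-12 && pf$r2_inc > best$r2_inc + 1e-12)) {
        best <- c(pf, list(name = cand))
      }
    }
    if (is.null(best) || best$p > p_enter) break
    incl <- c(incl, best$name)
    step_i <- step_i + 1L
    steps[[length(steps) + 1L]] <- tibble::tibble(
      step = step_i, action = "enter", predictor = best$name,
      F = best$f, df1 = 1L, df2 = best$df2, p = best$p,
      r2 = best$r2, r2_increment = best$r2_inc)
    # backward pass
    repeat {
      if (length(incl) < 2) break
      worst <- NULL
      for (v in incl) {
        pf <- .partial_f(y, X, setdiff(incl, v), v)
        if (is.null(pf)) next
        if (is.null(worst) || pf$p > worst$p) worst <- c(pf, list(name = v))
      }
      if (is.null(worst) || worst$p < p_remove) break
      incl <- setdiff(incl, worst$name)
      step_i <- step_i + 1L
      fit_now <- stats::lm(y ~ ., data = X[, incl, drop = FALSE])
      steps[[length(steps) + 1L]] <- tibble::tibble(
        step = step_i, action = "remove", predictor = worst$name,
        F = worst$f, df1 = 1L, df2 = worst$df2, p = worst$p,
        r2 = summary(fit_now)$r.squared, r2_increment = -worst$r2_inc)
    }
  }
  fit <- if (length(incl) > 0) {
    stats::lm(y ~ ., data = X[, incl, drop = FALSE])
  }
  list(
    steps = if (length(steps) > 0) dplyr::bind_rows(steps) else
      tibble::tibble(step = integer(), action = character(),
                     predictor = character(), F = numeric(), df1 = integer(),
                     df2 = integer(), p = numeric(), r2 = numeric(),
                     r2_increment = numeric()),
    included = incl,
    fit = fit
  )
}

#' Nagelkerke pseudo r-squared
#'
#' `[1 - (L0/L1)^(2/n)] / [1 - L0^(2/n)]` for a fitted binary logistic
#' model against the intercept-only model.
#'
#' @param fit a binomial `glm`.
#' @return numeric scalar.
#' @export
nagelkerke_r2 <- function(fit) {
  # for binary outcomes the saturated log-likelihood is 0, so
  # deviance = -2 logLik and the null model needs no refit
  n <- length(fit$y)
  cox_snell <- 1 - exp((fit$deviance - fit$null.deviance) / n)
  cox_snell / (1 - exp(-fit$null.deviance / n))
}

#' Stepwise logistic regression with Nagelkerke r-squared
#'
#' Likelihood-ratio stepwise entry/removal at `p_enter` / `p_remove`,
#' reporting the Nagelkerke pseudo r-squared and in-sample classification
#' accuracy at a 0.5 probability threshold.  Perfect separation is flagged
#' (`separation = TRUE`) and the model reported as non-converged.
#'
#' @param labels binary vector (logical, 0/1, or 2-level factor).
#' @param X data frame of candidate predictors.
#' @param p_enter,p_remove entry and removal thresholds (likelihood-ratio
#'   test p-values).
#' @return list with `steps`, `included`, `fit`, `nagelkerke_r2`,
#'   `accuracy`, `separation`.
#' @export
stepwise_logistic <- function(labels, X, p_enter = 0.05, p_remove = 0.1) {
  X <- as.data.frame(X)
  yb <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  ok <- stats::complete.cases(X) & !is.na(yb)
  yb <- yb[ok]; X <- X[ok, , drop = FALSE]
  if (length(unique(yb)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  lr_p <- function(incl, cand) {
    f0 <- if (length(incl) > 0) {
      stats::glm(yb ~ ., family = stats::binomial(),
                 data = X[, incl, drop = FALSE])
    } else stats::glm(yb ~ 1, family = stats::binomial())
    f1 <- stats::glm(yb ~ ., family = stats::binomial(),
                     data = X[, c(incl, cand), drop = FALSE])
    dev <- f0$deviance - f1$deviance
    list(chisq = dev, p = stats::pchisq(dev, 1, lower.tail = FALSE))
  }
  incl <- character(0)
  steps <- list()
  step_i <- 0L
  repeat {
    cands <- setdiff(names(X), incl)
    if (length(cands) == 0) break
    best <- NULL
    for (cand in cands) {
      lt <- suppressWarnings(lr_p(incl, cand))
      if (is.null(best) || lt$p < best$p) best <- c(lt, list(name = cand))
    }
    if (is.null(best) || best$p > p_enter) break
    incl <- c(incl, best$name)
    step_i <- step_i + 1L
    steps[[length(steps) + 1L]] <- tibble::tibble(
      step = step_i, action = "enter", predictor = best$name,
      chisq = best$chisq, df = 1L, p = best$p)
    repeat {
      if (length(incl) < 2) break
      worst <- NULL
      for (v in incl) {
        lt <- suppressWarnings(lr_p(setdiff(incl, v), v))
        if (is.null(worst) || lt$p > worst$p) worst <- c(lt, list(name = v))
      }
      if (is.null(worst) || worst$p < p_remove) break
      incl <- setdiff(incl, worst$name)
      step_i <- step_i + 1L
      steps[[length(steps) + 1L]] <- tibble::tibble(
        step = step_i, action = "remove", predictor = worst$name,
        chisq = worst$chisq, df = 1L, p = worst$p)
    }
  }
  fit <- suppressWarnings(if (length(incl) > 0) {
    stats::glm(yb ~ ., family = stats::binomial(),
               data = X[, incl, drop = FALSE])
  } else {
    stats::glm(yb ~ 1, family = stats::binomial())
  })
  pr <- stats::fitted(fit)
  separation <- length(incl) > 0 &&
    (!fit$converged || any(abs(stats::coef(fit)) > 15) ||
       all(pr[yb == 1] > 0.999) && all(pr[yb == 0] < 0.001))
  list(
    steps = if (length(steps) > 0) dplyr::bind_rows(steps) else
      tibble::tibble(step = integer(), action = character(),
                     predictor = character(), chisq = numeric(),
                     df = integer(), p = numeric()),
    included = incl,
    fit = fit,
    nagelkerke_r2 = if (length(incl) > 0) nagelkerke_r2(fit) else 0,
    accuracy = mean((pr > 0.5) == (yb == 1)),
    separation = separation
  )
}
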