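test_that("one-sample ratio tests match hand arithmetic and flag degenerate input", {
  r <- one_sample_ratio_test(rep(0.5, 10))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  r2 <- one_sample_ratio_test(c(0.2, 0.3, 0.4))
  expect_equal(r2$t, -3.464, tolerance = 1e-3) # mean 0.3, sd 0.1, n 3
  expect_equal(r2$df, 2)
  r3 <- one_sample_ratio_test(rep(0.3, 5))
  expect_true(is.infinite(r3$t) && r3$t < 0)
  expect_equal(r3$p, 0)
  expect_error(one_sample_ratio_test(0.4), "at least 2")
})

test_that("contrast specifications enforce zero-sum and orthogonality", {
  expect_error(contrast_spec(bad = c(1, 1, 0)), "sum to 0")
  expect_error(contrast_spec(a = c(1, -1, 0), b = c(1, 0, -1)),
               "not orthogonal")
  ok <- contrast_spec(lin = c(-1, 0, 1), quad = c(1, -2, 1))
  expect_s3_class(ok, "contrast_spec")
})

test_that("a null within-contrast gives F = 0 and the interaction equals the squared t", {
  X <- matrix(rep(c(1, 2, 3), each = 10), 10, 3)
  a <- contrast_anova(X, contrast_spec(flat = c(1, -2, 1)))
  expect_equal(a$F[a$effect == "flat"], 0)

  set.seed(5)
  X2 <- matrix(rnorm(60), 20, 3)
  gr <- rep(c("s", "i"), each = 10)
  a2 <- contrast_anova(X2, contrast_spec(lin = c(-1, 0, 1)), groups = gr)
  L <- X2 %*% c(-1, 0, 1)
  tt <- t.test(L[gr == "s"], L[gr == "i"], var.equal = TRUE)
  expect_equal(a2$F[a2$effect == "lin:group"], unname(tt$statistic)^2,
               tolerance = 1e-10)
})

test_that("contrast ANOVA matches the independent GLM oracle on random instances", {
  set.seed(21)
  for (rep_i in 1:8) {
    n <- sample(8:20, 1)
    ncell <- sample(3:6, 1)
    ngr <- sample(1:3, 1)
    X <- matrix(rnorm(n * ncell), n, ncell)
    gr <- sample(letters[seq_len(ngr)], n, replace = TRUE)
    while (length(unique(gr)) < ngr || min(table(gr)) < 2) {
      gr <- sample(letters[seq_len(ngr)], n, replace = TRUE)
    }
    contr <- c(-1, 1, rep(0, ncell - 2))
    a <- contrast_anova(X, contrast_spec(c1 = contr), groups = gr)
    o <- contrast_anova_oracle(X, contr, gr)
    expect_equal(a$F[a$effect == "c1"], o$f_within, tolerance = 1e-8)
    if (ngr > 1) {
      expect_equal(a$F[a$effect == "c1:group"], o$f_interaction,
                   tolerance = 1e-8)
      expect_equal(a$F[a$effect == "group"], o$f_between, tolerance = 1e-8)
    }
  }
})

test_that("PCA with the communality rule recovers planted structure", {
  # two perfectly correlated items: one component, communalities 1
  set.seed(31)
  z <- rnorm(80)
  p1 <- pca_varimax(cbind(a = z, b = 2 * z + 3))
  expect_equal(p1$n_components, 1)
  expect_equal(unname(p1$communalities), c(1, 1), tolerance = 1e-10)

  # two independent blocks (within-block r = 0.8): two components aligned
  make_block <- function(n, k, r) {
    f <- rnorm(n)
    sapply(seq_len(k), function(i) sqrt(r) * f + sqrt(1 - r) * rnorm(n))
  }
  A <- make_block(300, 3, 0.8)
  B <- make_block(300, 3, 0.8)
  X <- cbind(A, B)
  colnames(X) <- c("a1", "a2", "a3", "b1", "b2", "b3")
  p2 <- pca_varimax(X)
  expect_equal(p2$n_components, 2)
  hi <- abs(p2$loadings) > 0.707
  expect_true(all(colSums(hi) == 3)) # each component owns one block
  expect_true(all(rowSums(hi) == 1))

  # rotation leaves communalities unchanged (checked against unrotated)
  eig <- eigen(cor(X), symmetric = TRUE)
  unrot <- eig$vectors[, 1:2] %*% diag(sqrt(eig$values[1:2]))
  expect_equal(unname(p2$communalities), unname(rowSums(unrot^2)),
               tolerance = 1e-10)
  # constant item dropped with a warning
  expect_warning(pca_varimax(cbind(X, const = rep(1, 300))), "constant")
})

test_that("stepwise linear regression enters exact predictors and stops", {
  set.seed(41)
  x1 <- rnorm(60)
  X <- data.frame(x1 = x1, x2 = rnorm(60), x3 = rnorm(60))
  sw <- stepwise_linear(x1, X)
  expect_equal(sw$included, "x1")
  expect_equal(sw$steps$r2[1], 1)
  expect_equal(nrow(sw$steps), 1)
})

test_that("each stepwise entry matches the exhaustive best-addition oracle", {
  set.seed(43)
  for (rep_i in 1:5) {
    n <- 80
    X <- as.data.frame(matrix(rnorm(n * 5), n, 5))
    names(X) <- paste0("v", 1:5)
    y <- 0.8 * X$v1 - 0.5 * X$v3 + 0.3 * X$v5 + rnorm(n)
    sw <- stepwise_linear(y, X)
    incl <- character(0)
    for (i in seq_len(nrow(sw$steps))) {
      if (sw$steps$action[i] != "enter") next
      # brute force: the entered predictor must have the smallest partial-F
      # p-value among all remaining candidates
      ps <- vapply(setdiff(names(X), incl), function(v) {
        f1 <- lm(y ~ ., data = X[, c(incl, v), drop = FALSE])
        f0 <- if (length(incl) > 0) {
          lm(y ~ ., data = X[, incl, drop = FALSE])
        } else lm(y ~ 1)
        anova(f0, f1)$`Pr(>F)`[2]
      }, numeric(1))
      expect_equal(sw$steps$predictor[i], names(which.min(ps)))
      incl <- c(incl, sw$steps$predictor[i])
    }
  }
})

test_that("under the null the stepwise model stays empty at the nominal rate", {
  set.seed(47)
  empties <- 0L
  n_seeds <- 60
  for (s in seq_len(n_seeds)) {
    X <- as.data.frame(matrix(rnorm(200 * 3), 200, 3))
    y <- rnorm(200)
    sw <- stepwise_linear(y, X)
    if (length(sw$included) == 0) empties <- empties + 1L
  }
  # per-candidate alpha = 0.05: expected empty rate (1 - .05)^3 ~ 0.857;
  # demand a clear majority of empty models (binomial 99% lower bound)
  expect_gt(empties / n_seeds, 0.75)
})

test_that("collinear predictors are skipped with a warning", {
  set.seed(53)
  x <- rnorm(50)
  X <- data.frame(a = x, b = x) # perfectly collinear
  y <- x + rnorm(50, 0, 0.1)
  expect_warning(sw <- stepwise_linear(y, X), "collinear")
  expect_length(sw$included, 1)
})

test_that("Nagelkerke r2 is zero for null models and matches the likelihood formula", {
  set.seed(61)
  y <- rbinom(100, 1, 0.4)
  sw <- stepwise_logistic(y, data.frame(junk = rnorm(100)))
  expect_length(sw$included, 0)
  expect_equal(sw$nagelkerke_r2, 0)
  # direct formula check on a non-null fit
  x <- rnorm(200)
  yy <- rbinom(200, 1, plogis(x))
  fit <- glm(yy ~ x, family = binomial())
  n <- 200
  ll1 <- as.numeric(logLik(fit))
  ll0 <- as.numeric(logLik(glm(yy ~ 1, family = binomial())))
  expect_equal(nagelkerke_r2(fit),
               (1 - exp((2 / n) * (ll0 - ll1))) / (1 - exp((2 / n) * ll0)),
               tolerance = 1e-10)
})

test_that("perfectly separable data is flagged and classified perfectly", {
  x <- c(rnorm(30, -3), rnorm(30, 3))
  y <- rep(c(0, 1), each = 30)
  sw <- stepwise_logistic(y, data.frame(x = x))
  expect_true(sw$separation)
  expect_equal(sw$accuracy, 1)
})

test_that("logistic coefficients are recovered from simulated data", {
  set.seed(71)
  beta <- 1.2
  coefs <- vapply(1:40, function(s) {
    x <- rnorm(500)
    y <- rbinom(500, 1, plogis(beta * x))
    sw <- stepwise_logistic(y, data.frame(x = x))
    if (length(sw$included) > 0) unname(coef(sw$fit)["x"]) else NA_real_
  }, numeric(1))
  expect_lt(abs(mean(coefs, na.rm = TRUE) - beta) / beta, 0.1)
})
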