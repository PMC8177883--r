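# Independent brute-force oracles.

# exhaustive optimal 1-D k-means: best contiguous partition by total
# within-cluster SS (optimal 1-D clusters are contiguous in sorted order)
kmeans_1d_oracle <- function(x, k) {
  xs <- sort(x)
  n <- length(xs)
  wss <- function(v) if (length(v) == 0) 0 else sum((v - mean(v))^2)
  best <- list(ss = Inf, breaks = NULL)
  # enumerate all k-1 cut points
  cuts <- utils::combn(n - 1, k - 1)
  for (j in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, j], n)
    ss <- 0
    for (i in seq_len(k)) ss <- ss + wss(xs[(b[i] + 1):b[i + 1]])
    if (ss < best$ss) best <- list(ss = ss, breaks = b)
  }
  best
}

# naive silhouette widths for 1-D data
silhouette_oracle <- function(x, labels) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    same <- x[labels == labels[i]]
    a <- if (length(same) > 1) sum(abs(x[i] - same)) / (length(same) - 1) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(abs(x[i] - x[labels == l]))
    }, numeric(1)))
    if (length(same) > 1) (b - a) / max(a, b) else 0
  }, numeric(1))
}

# mixed-design single-df contrast ANOVA via an independent lm route:
# within effect and interaction from lm(L ~ group) with sum-to-zero
# contrasts (unweighted grand mean), between effect from aov on subject
# means
contrast_anova_oracle <- function(cells, contr, groups) {
  L <- as.vector(as.matrix(cells) %*% contr)
  g <- factor(groups)
  if (nlevels(g) > 1) {
    fit <- stats::lm(L ~ g, contrasts = list(g = "contr.sum"))
    sm <- summary(fit)$coefficients
    f_within <- sm[1, "t value"]^2
    a <- stats::anova(fit)
    f_int <- a$`F value`[1]
    m <- rowMeans(cells)
    ab <- stats::anova(stats::lm(m ~ g))
    list(f_within = f_within, f_interaction = f_int,
         f_between = ab$`F value`[1])
  } else {
    tt <- stats::t.test(L)
    list(f_within = unname(tt$statistic)^2, f_interaction = NA,
         f_between = NA)
  }
}
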