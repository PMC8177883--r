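# Punishment-sensitivity clustering ---------------------------------------

#' Mean silhouette values of a clustering
#'
#' Euclidean silhouettes via \pkg{cluster}.
#'
#' @param x numeric vector (1-D feature).
#' @param labels integer cluster labels.
#' @return list with `mean`, `min` and the per-point widths.
#' @export
silhouette_summary <- function(x, labels) {
  sil <- cluster::silhouette(labels, stats::dist(x))
  w <- sil[, "sil_width"]
  list(mean = mean(w), min = min(w), widths = w)
}

# exact 1-D k-means: optimal clusters of sorted data are contiguous, so a
# dynamic programme over contiguous segments finds the global WSS optimum
.kmeans_1d_exact <- function(x, k) {
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  segcost <- function(i, j) { # WSS of xs[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, k, n)     # D[m, j]: best WSS of xs[1..j] in m clusters
  B <- matrix(0L, k, n)      # argmin split points
  for (j in 1:n) D[1, j] <- segcost(1, j)
  if (k > 1) {
    for (m in 2:k) {
      for (j in m:n) {
        best <- Inf; bi <- m
        for (i in m:j) {
          v <- D[m - 1, i - 1] + segcost(i, j)
          if (v < best) { best <- v; bi <- i }
        }
        D[m, j] <- best
        B[m, j] <- bi
      }
    }
  }
  # backtrack cluster assignment (1 = lowest values)
  lab_sorted <- integer(n)
  j <- n
  for (m in k:1) {
    i <- if (m == 1) 1L else B[m, j]
    lab_sorted[i:j] <- m
    j <- i - 1L
  }
  labels <- integer(n)
  labels[ord] <- lab_sorted
  centers <- vapply(1:k, function(m) mean(x[labels == m]), numeric(1))
  withinss <- vapply(1:k, function(m) sum((x[labels == m] -
                                             centers[m])^2), numeric(1))
  list(cluster = labels, centers = matrix(centers, ncol = 1),
       withinss = withinss, tot_withinss = D[k, n])
}

#' Cluster punishment sensitivity from final-block preference ratios
#'
#' k-means on the 1-D vector of final-block preference ratios, with the
#' number of clusters chosen over `k_range` by maximal mean Euclidean
#' silhouette (ties broken toward the smaller k).  In one dimension the
#' optimal k-means clusters are contiguous in sorted order, so the global
#' within-cluster-SS optimum is computed exactly by dynamic programming
#' rather than by random restarts; the procedure is fully deterministic.
#' The cluster with the lowest mean final preference ratio is labelled
#' `sensitive`; with k = 2 the other is `insensitive`, with k > 2 the
#' remaining clusters are `other_3`, ... in increasing order of their
#' means.
#'
#' @param final_ratios numeric vector in `[0, 1]`, one per participant.
#' @param seed kept for interface stability; the exact solver consumes no
#'   randomness.
#' @param k_range candidate cluster counts.
#' @param nstart ignored (exact solver); kept for interface stability.
#' @param ids optional participant identifiers.
#' @return an object of class `cluster_result`: list with `chosen_k`,
#'   `labels` (named character vector), `assignment` (tibble), `mean_silhouette`
#'   (per k), `min_silhouette`, `cluster_means`, `withinss`.
#' @export
cluster_sensitivity <- function(final_ratios, seed = 1L, k_range = 2:4,
                                nstart = 50L, ids = NULL) {
  x <- as.numeric(final_ratios)
  if (anyNA(x) || any(!is.finite(x))) {
    stop("final_ratios must be finite and non-missing", call. = FALSE)
  }
  n <- length(x)
  if (n < 5) stop("need at least 5 participants to cluster", call. = FALSE)
  if (length(unique(x)) == 1) {
    stop("degenerate input: all preference ratios identical; silhouette undefined",
         call. = FALSE)
  }
  if (is.null(ids)) ids <- sprintf("P%03d", seq_len(n))
  k_range <- k_range[k_range < length(unique(x)) + 1 & k_range <= n - 1]

  fits <- list()
  mean_sil <- stats::setNames(rep(NA_real_, length(k_range)),
                              paste0("k", k_range))
  for (i in seq_along(k_range)) {
    km <- .kmeans_1d_exact(x, k_range[i])
    fits[[i]] <- km
    mean_sil[i] <- silhouette_summary(x, km$cluster)$mean
  }
  best <- which(mean_sil == max(mean_sil))[1] # first index = smaller k
  km <- fits[[best]]
  chosen_k <- k_range[best]
  sil <- silhouette_summary(x, km$cluster)

  # name clusters by increasing mean preference ratio
  ord <- order(km$centers[, 1])
  name_of <- character(chosen_k)
  name_of[ord[1]] <- "sensitive"
  name_of[ord[2]] <- "insensitive"
  if (chosen_k > 2) {
    for (j in 3:chosen_k) name_of[ord[j]] <- sprintf("other_%d", j)
  }
  labels <- stats::setNames(name_of[km$cluster], ids)

  out <- list(
    chosen_k = chosen_k,
    labels = labels,
    assignment = tibble::tibble(
      participant_id = ids, final_ratio = x,
      cluster_label = unname(labels),
      silhouette = unname(sil$widths)),
    mean_silhouette = mean_sil,
    min_silhouette = sil$min,
    cluster_means = stats::setNames(as.numeric(km$centers[ord, 1]),
                                    name_of[ord]),
    withinss = km$tot_withinss
  )
  class(out) <- "cluster_result"
  out
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d (mean silhouette %.3f, min %.3f)\n",
              x$chosen_k, x$mean_silhouette[paste0("k", x$chosen_k)],
              x$min_silhouette))
  tab <- table(x$labels)
  for (nm in names(x$cluster_means)) {
    cat(sprintf("  %-12s n = %3d  mean final ratio %.3f\n",
                nm, tab[[nm]], x$cluster_means[[nm]]))
  }
  invisible(x)
}

#' Join cluster labels onto a behavioural summary
#'
#' Produces the tidy long table feeding the group contrasts: one row per
#' participant x block x metric, keyed by cluster label.
#'
#' @param summary a [participant_summary()] (or [collapse_pre()]) tibble.
#' @param clusters a `cluster_result` from [cluster_sensitivity()].
#' @return a tibble with columns `participant_id`, `cluster`, `block`,
#'   `phase`, `metric`, `value`.
#' @export
compare_clusters <- function(summary, clusters) {
  if (nrow(summary) == 0) {
    return(tibble::tibble(participant_id = character(), cluster = character(),
                          block = integer(), phase = character(),
                          metric = character(), value = numeric()))
  }
  miss <- setdiff(unique(summary$participant_id), names(clusters$labels))
  if (length(miss) > 0) {
    stop("participants missing a cluster label: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  num <- setdiff(names(summary)[vapply(summary, is.numeric, logical(1))],
                 "block")
  long <- tidyr::pivot_longer(summary, dplyr::all_of(num),
                              names_to = "metric", values_to = "value")
  long$cluster <- unname(clusters$labels[long$participant_id])
  long[, c("participant_id", "cluster", "block", "phase", "metric", "value")]
}
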