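# Risk trajectories over the seven milestones and their K-means grouping.

#' Assemble 7-milestone risk trajectories
#'
#' One row per encounter over (admission, day1..day5, discharge). Milestones
#' beyond discharge are padded with the discharge prediction and flagged in
#' the padding mask.
#'
#' @param daily_risk Data.frame with `encounter_id`, `milestone` and a risk
#'   column.
#' @param value_col Name of the risk column (default `"predicted_risk"`).
#' @return Object of class `hf_trajectories`: `encounter_id`, `risks`
#'   (n x 7 matrix), `padded` (n x 7 logical matrix).
#' @export
build_trajectories <- function(daily_risk, value_col = "predicted_risk") {
  if (!value_col %in% names(daily_risk)) {
    stop_hf("no column '%s' in daily risk table", value_col)
  }
  mils <- hf_milestones()
  ids <- unique(daily_risk$encounter_id)
  risks <- matrix(NA_real_, length(ids), length(mils),
                  dimnames = list(ids, mils))
  idx <- cbind(match(daily_risk$encounter_id, ids),
               match(daily_risk$milestone, mils))
  risks[idx] <- daily_risk[[value_col]]
  no_discharge <- is.na(risks[, "discharge"])
  if (any(no_discharge)) {
    stop_hf("missing discharge prediction for encounter(s): %s",
            paste(utils::head(ids[no_discharge], 5), collapse = ", "))
  }
  padded <- is.na(risks)
  for (m in mils) {
    na <- is.na(risks[, m])
    if (any(na)) risks[na, m] <- risks[na, "discharge"]
  }
  structure(list(encounter_id = ids, risks = risks, padded = padded),
            class = "hf_trajectories")
}

# Squared Euclidean distances between rows of X and rows of C.
dist2 <- function(X, C) {
  outer(rowSums(X^2), rep(1, nrow(C))) - 2 * tcrossprod(X, C) +
    outer(rep(1, nrow(X)), rowSums(C^2))
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  if (k == 1) return(centers)
  d2 <- dist2(X, centers[1, , drop = FALSE])[, 1]
  for (j in 2:k) {
    if (all(d2 <= 0)) {
      centers[j, ] <- X[sample.int(n, 1), ]
    } else {
      centers[j, ] <- X[sample.int(n, 1, prob = pmax(d2, 0)), ]
    }
    d2 <- pmin(d2, dist2(X, centers[j, , drop = FALSE])[, 1])
  }
  centers
}

lloyd <- function(X, centers, iter_max = 100) {
  k <- nrow(centers)
  assign_old <- rep(0L, nrow(X))
  for (it in seq_len(iter_max)) {
    d2 <- dist2(X, centers)
    assign <- max.col(-d2, ties.method = "first")
    # empty cluster: reseed from the point farthest from its center
    for (j in which(tabulate(assign, k) == 0)) {
      far <- which.max(d2[cbind(seq_len(nrow(X)), assign)])
      centers[j, ] <- X[far, ]
      assign[far] <- j
      d2 <- dist2(X, centers)
    }
    if (all(assign == assign_old)) break
    assign_old <- assign
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(X[assign == j, , drop = FALSE])
    }
  }
  d2 <- dist2(X, centers)
  assign <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(nrow(X)), assign)])
  list(centers = centers, assign = assign, inertia = inertia)
}

#' K-means clustering of risk trajectories
#'
#' Lloyd's algorithm with Euclidean distance on the 7-milestone vectors,
#' k-means++ initialization, and the best of `n_restarts` starts by within-
#' cluster sum of squares. Deterministic under a fixed seed; an empty
#' cluster during iteration is re-seeded from the farthest point.
#'
#' @param trajectories An `hf_trajectories` object (or a numeric matrix).
#' @param k Number of clusters (default 4).
#' @param n_restarts Number of k-means++ restarts (default 50).
#' @param seed RNG seed.
#' @return Object of class `hf_clusters`: `k`, `centroids` (k x 7),
#'   `assignments` (named by encounter), `labels` (filled by
#'   [label_clusters()]), `inertia`, `seed`, `n_restarts`.
#' @export
kmeans_cluster <- function(trajectories, k = 4, n_restarts = 50, seed = 1L) {
  X <- if (inherits(trajectories, "hf_trajectories")) {
    trajectories$risks
  } else as.matrix(trajectories)
  if (nrow(X) < k) stop_hf("need at least k = %d trajectories", k,
                           class = "hftraj_validation_error")
  best <- NULL
  with_local_seed(seed, {
    for (r in seq_len(n_restarts)) {
      res <- lloyd(X, kmeanspp_init(X, k))
      if (is.null(best) || res$inertia < best$inertia) best <- res
    }
  })
  assignments <- best$assign
  names(assignments) <- rownames(X)
  centroids <- best$centers
  dimnames(centroids) <- list(paste0("cluster-", seq_len(k)), colnames(X))
  structure(list(k = k, centroids = centroids, assignments = assignments,
                 labels = NULL, inertia = best$inertia, seed = seed,
                 n_restarts = n_restarts),
            class = "hf_clusters")
}

#' Attach semantic labels to trajectory clusters
#'
#' For `k = 4`: the cluster whose centroid shows the largest
#' admission-to-discharge drop, provided the drop exceeds `drop_threshold`,
#' is labelled `"decreasing"`; the rest are `"high"`, `"moderate"`, `"low"`
#' by descending centroid mean. If no centroid drops enough, all clusters
#' are labelled by mean level (`"very high"`, `"high"`, `"moderate"`,
#' `"low"`) with a notice. For `k != 4` generic `"cluster-i"` labels are
#' kept.
#'
#' @param result An `hf_clusters` object.
#' @param drop_threshold Minimum admission-discharge centroid drop to call a
#'   cluster decreasing (default 0.15).
#' @return The clusters object with `labels` filled (cluster id -> label).
#' @export
label_clusters <- function(result, drop_threshold = 0.15) {
  k <- result$k
  if (k != 4) {
    result$labels <- stats::setNames(paste0("cluster-", seq_len(k)),
                                     seq_len(k))
    return(result)
  }
  cen <- result$centroids
  # first and last milestone columns: admission and discharge
  drop <- cen[, 1] - cen[, ncol(cen)]
  lvl <- rowMeans(cen)
  labels <- rep(NA_character_, 4)
  if (max(drop) > drop_threshold) {
    dec <- which.max(drop)
    labels[dec] <- "decreasing"
    rest <- setdiff(seq_len(4), dec)
    labels[rest[order(lvl[rest], decreasing = TRUE)]] <-
      c("high", "moderate", "low")
  } else {
    message("no cluster drops by more than ", drop_threshold,
            "; labelling all four by mean level")
    labels[order(lvl, decreasing = TRUE)] <-
      c("very high", "high", "moderate", "low")
  }
  result$labels <- stats::setNames(labels, seq_len(4))
  result
}
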