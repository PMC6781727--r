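test_that("short stays are padded with the discharge value and masked", {
  dr <- data.frame(
    encounter_id = c(rep("e1", 4), rep("e2", 7)),
    milestone = c("admission", "day1", "day2", "discharge",
                  hf_milestones()),
    predicted_risk = c(0.6, 0.5, 0.4, 0.35, seq(0.7, 0.1, length.out = 7)))
  tr <- build_trajectories(dr)
  i <- which(tr$encounter_id == "e1")
  expect_equal(unname(tr$padded[i, ]), c(F, F, F, T, T, T, F))
  expect_equal(unname(tr$risks[i, c("day3", "day4", "day5")]),
               rep(0.35, 3))
  j <- which(tr$encounter_id == "e2")
  expect_false(any(tr$padded[j, ]))

  # constant risk gives a constant 7-vector
  dc <- data.frame(encounter_id = "c", milestone = c("admission", "discharge"),
                   predicted_risk = c(0.4, 0.4))
  expect_equal(unname(build_trajectories(dc)$risks[1, ]), rep(0.4, 7))

  # a missing discharge prediction is an error
  bad <- dr[dr$milestone != "discharge", ]
  expect_error(build_trajectories(bad), "discharge")
})

test_that("k-means closed forms hold: k = 1 and duplicated points", {
  set.seed(10)
  X <- matrix(runif(35), 5, 7, dimnames = list(paste0("e", 1:5),
                                               hf_milestones()))
  r1 <- kmeans_cluster(X, k = 1, n_restarts = 3, seed = 1)
  expect_equal(unname(r1$centroids[1, ]), unname(colMeans(X)))
  expect_equal(r1$inertia, sum(sweep(X, 2, colMeans(X))^2))

  Xd <- rbind(X, X)
  rownames(Xd) <- paste0("e", 1:10)
  rd <- kmeans_cluster(Xd, k = 2, n_restarts = 5, seed = 2)
  expect_equal(unname(rd$assignments[1:5]), unname(rd$assignments[6:10]))
})

test_that("k-means matches stats::kmeans on well-separated data", {
  set.seed(33)
  X <- rbind(matrix(rnorm(70 * 7, 0, 0.05), 70, 7),
             matrix(rnorm(70 * 7, 1, 0.05), 70, 7),
             matrix(rnorm(70 * 7, 2, 0.05), 70, 7))
  rownames(X) <- paste0("e", 1:210)
  ours <- kmeans_cluster(X, k = 3, n_restarts = 10, seed = 4)
  ref <- stats::kmeans(X, 3, nstart = 10, iter.max = 50)
  expect_equal(ours$inertia, ref$tot.withinss, tolerance = 1e-8)
  # same partition up to label permutation
  expect_equal(length(unique(paste(ours$assignments, ref$cluster))), 3)
})

test_that("clustering is deterministic under a fixed seed and order-invariant", {
  g <- shared_cohort()
  tr <- as.matrix(g$truth[, paste0("risk_", hf_milestones())])
  rownames(tr) <- g$truth$encounter_id
  c1 <- kmeans_cluster(tr, 4, 20, seed = 11)
  c2 <- kmeans_cluster(tr, 4, 20, seed = 11)
  expect_identical(c1$assignments, c2$assignments)
  expect_identical(c1$centroids, c2$centroids)
  perm <- sample(nrow(tr))
  c3 <- kmeans_cluster(tr[perm, ], 4, 20, seed = 11)
  # same partition of the same encounters, whatever the row order
  pairs1 <- outer(c1$assignments, c1$assignments, "==")
  pairs3 <- outer(c3$assignments[names(c1$assignments)],
                  c3$assignments[names(c1$assignments)], "==")
  expect_equal(mean(pairs1 == pairs3), 1, tolerance = 0.02)
})

test_that("planted archetypes are recovered from latent trajectories", {
  skip_if_not_installed("mclust")
  g <- shared_cohort()
  tr <- as.matrix(g$truth[, paste0("risk_", hf_milestones())])
  rownames(tr) <- g$truth$encounter_id
  cl <- kmeans_cluster(tr, 4, 30, seed = 5)
  ari <- mclust::adjustedRandIndex(cl$assignments, g$truth$archetype)
  expect_gt(ari, 0.85)
})

test_that("recovery degrades as archetype separation shrinks", {
  skip_if_not_installed("mclust")
  mean_ari <- function(sep) {
    mean(vapply(1:4, function(s) {
      g <- generate_cohort(generator_config(150, seed = 3000 + s,
                                            archetype_separation = sep))
      tr <- as.matrix(g$truth[, paste0("risk_", hf_milestones())])
      rownames(tr) <- g$truth$encounter_id
      cl <- kmeans_cluster(tr, 4, 15, seed = s)
      mclust::adjustedRandIndex(cl$assignments, g$truth$archetype)
    }, 0))
  }
  a_full <- mean_ari(1)
  a_half <- mean_ari(0.5)
  a_tiny <- mean_ari(0.12)
  expect_gt(a_full, a_half)
  expect_gt(a_half, a_tiny)
})

test_that("cluster labelling follows the drop-then-level rule", {
  mk <- function(cen) {
    dimnames(cen) <- list(paste0("cluster-", seq_len(nrow(cen))),
                          hf_milestones())
    structure(list(k = nrow(cen), centroids = cen,
                   assignments = setNames(rep(1, 8), paste0("e", 1:8)),
                   labels = NULL, inertia = 0, seed = 1, n_restarts = 1),
              class = "hf_clusters")
  }
  # the four reported trajectory groups: decreasing 0.69 -> 0.30, flat
  # high 0.75, flat moderate 0.61, low 0.39 -> 0.21
  cen <- rbind(seq(0.69, 0.30, length.out = 7),
               rep(0.75, 7),
               rep(0.61, 7),
               seq(0.39, 0.21, length.out = 7))
  lab <- label_clusters(mk(cen))
  expect_equal(unname(lab$labels),
               c("decreasing", "high", "moderate", "low"))

  # no centroid drops enough: level labels plus a notice
  flat <- rbind(rep(0.2, 7), rep(0.4, 7), rep(0.6, 7), rep(0.8, 7))
  expect_message(lf <- label_clusters(mk(flat)), "no cluster drops")
  expect_equal(unname(lf$labels), c("low", "moderate", "high", "very high"))

  # two droppers: the larger drop wins "decreasing"
  two <- rbind(seq(0.8, 0.55, length.out = 7),
               seq(0.7, 0.25, length.out = 7),
               rep(0.5, 7), rep(0.3, 7))
  lt <- label_clusters(mk(two))
  expect_equal(unname(lt$labels[2]), "decreasing")

  # k != 4 keeps generic labels
  l2 <- label_clusters(mk(flat[1:2, ]))
  expect_equal(unname(l2$labels), c("cluster-1", "cluster-2"))
})
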