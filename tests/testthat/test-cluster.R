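test_that("standardization is exact on the reference and reusable for new data", {
  coh <- simulate_cohort(default_cluster_groups(n_fish = 20), seed = 1)
  std <- standardize_behavior(coh)
  x <- coords_mat <- as.matrix(std[, c("z_freezing", "z_evasion", "z_evasion_active")])
  expect_true(all(abs(colMeans(x)) < 1e-12))
  expect_true(all(abs(apply(x, 2, sd) - 1) < 1e-12))

  params <- attr(std, "params")
  # a new point at the reference mean maps to the origin
  at_mean <- tibble::as_tibble(as.list(setNames(params$mean, params$variable)))
  z0 <- standardize_behavior(at_mean, params = params)
  expect_equal(unlist(z0[, c("z_freezing", "z_evasion", "z_evasion_active")]),
               c(z_freezing = 0, z_evasion = 0, z_evasion_active = 0))
  # roundtrip: z * sd + mean recovers the input
  back <- sweep(sweep(x, 2, params$sd, "*"), 2, -params$mean, "-")
  expect_equal(unname(back[, 1]), coh$pct_freezing, tolerance = 1e-12)

  flat <- exact_summary(rep(10, 5), rep(20, 5))
  expect_error(standardize_behavior(flat), "Zero SD",
               class = "fearfish_validation_error")
})

test_that("similarity score is 1/(1+D) with its fixed points", {
  expect_equal(similarity_score(0), 1)
  expect_equal(similarity_score(1), 0.5)
  expect_equal(similarity_score(3), 0.25)
  d <- seq(0, 10, by = 0.5)
  expect_true(all(diff(similarity_score(d)) < 0))   # strictly decreasing
  expect_true(all(similarity_score(d) > 0 & similarity_score(d) <= 1))
  expect_error(similarity_score(c(1, NA)), class = "fearfish_validation_error")

  m <- similarity_matrix(matrix(rnorm(30), 10, 3))
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 1))
})

test_that("k-NN graphs link each fish to its most similar neighbors", {
  # 3 points on a line: 0, 1, 3 -> 1-NN edges (1,2) and (2,3) only
  x <- matrix(c(0, 1, 3), ncol = 1)
  g <- knn_graph(x, k = 1)
  el <- igraph::as_edgelist(g)
  expect_equal(nrow(el), 2)
  expect_true(all(apply(el, 1, paste, collapse = "-") %in% c("1-2", "2-3")))

  y <- matrix(rnorm(40), 20, 2)
  gc <- knn_graph(y, k = 19)
  expect_equal(igraph::ecount(gc), choose(20, 2))  # k = n-1 is complete
  a <- igraph::as_adjacency_matrix(knn_graph(y, 4), sparse = FALSE)
  expect_equal(a, t(a))  # union symmetrization
  expect_error(knn_graph(y, 20), class = "fearfish_validation_error")
})

test_that("Louvain recovers trivially separable structure", {
  g <- igraph::disjoint_union(igraph::make_full_graph(8), igraph::make_full_graph(8))
  p <- louvain_partition(g, seed = 1)
  expect_equal(length(unique(p$cluster)), 2)
  expect_equal(length(unique(p$cluster[1:8])), 1)
  expect_gte(attr(p, "modularity"), 0)  # beats the trivial all-one partition

  p1 <- louvain_partition(igraph::make_full_graph(10), seed = 1)
  expect_equal(length(unique(p1$cluster)), 1)
  expect_error(louvain_partition(igraph::make_empty_graph(0)),
               class = "fearfish_validation_error")
})

test_that("internal indices match brute-force formulas and perfect separation", {
  # two zero-spread clusters: silhouette is exactly 1
  x <- rbind(matrix(0, 5, 2), matrix(5, 5, 2))
  m <- internal_metrics(x, rep(1:2, each = 5))
  expect_equal(m$value[m$metric == "silhouette"], 1)

  # 6-point hand example for Calinski-Harabasz
  x6 <- matrix(c(0, 0, 1, 0, 0, 1, 10, 10, 11, 10, 10, 11), ncol = 2, byrow = TRUE)
  lab <- rep(1:2, each = 3)
  ch <- internal_metrics(x6, lab)$value[1]
  centr <- rbind(colMeans(x6[1:3, ]), colMeans(x6[4:6, ]))
  overall <- colMeans(x6)
  B <- sum(3 * rowSums(sweep(centr, 2, overall)^2))
  W <- sum((x6 - centr[lab, ])^2)
  expect_equal(ch, (B / 1) / (W / 4), tolerance = 1e-12)

  expect_warning(m1 <- internal_metrics(x, rep(1, 10)), "undefined")
  expect_true(all(is.na(m1$value)))

  # random labels on one Gaussian: silhouette near zero
  withr::with_seed(2, {
    xn <- matrix(rnorm(400), 200, 2)
    sil <- internal_metrics(xn, sample(1:2, 200, TRUE))$value[2]
  })
  expect_lt(abs(sil), 0.1)
})

test_that("k selection returns curves per k and finds planted structure", {
  coh <- simulate_cohort(default_cluster_groups(n_fish = 40), seed = 3)
  std <- standardize_behavior(coh)
  one <- select_k(std, k_range = 15, seed = 4)
  expect_equal(one$k, 15)
  sel <- select_k(std, k_range = seq(8, 28, by = 4), seed = 4)
  expect_equal(nrow(sel$curves), length(seq(8, 28, by = 4)))
  chosen <- sel$curves[sel$curves$k == sel$k, ]
  expect_equal(chosen$n_clusters, 4)
  expect_error(select_k(std, integer(0)), class = "fearfish_validation_error")
})

test_that("cluster naming follows the freezing/evasion quadrants", {
  coh <- simulate_cohort(default_cluster_groups(n_fish = 60), seed = 5)
  cm <- fit_behavior_clusters(coh, k = 30, seed = 6)
  tab <- table(cm$partition$cluster_name,
               coh$group[match(cm$partition$fish_id, coh$fish_id)])
  if (length(unique(cm$partition$cluster)) == 4) {
    # each named cluster is dominated by its namesake planted group
    expect_true(all(colnames(tab)[apply(tab, 1, which.max)] == rownames(tab)))
  }
  expect_s3_class(glance(cm), "tbl_df")
  expect_equal(nrow(tidy(cm)), 240)
})

test_that("33-NN assignment is idempotent and respects geometry", {
  coh <- simulate_cohort(default_cluster_groups(n_fish = 40), seed = 7)
  cm <- fit_behavior_clusters(coh, k = 25, seed = 8)

  # a new fish exactly at a cluster's raw centroid joins that cluster
  g <- default_cluster_groups()
  centroid <- exact_summary(g$pct_freezing[4], g$pct_evasion[4], fish_id = "probe")
  asg <- assign_clusters(centroid, cm, n_vote = 33)
  freezer_cl <- cm$partition$cluster[which.max(
    cm$partition$fish_id %in% coh$fish_id[coh$group == "freezer"])]
  expect_equal(asg$cluster, freezer_cl)

  # n_vote = 1 is the nearest-neighbor rule
  nn1 <- assign_clusters(centroid, cm, n_vote = 1)
  expect_equal(nn1$n_votes, 1L)

  # reassigning the reference fish reproduces itself deterministically
  r1 <- assign_clusters(coh, cm)
  r2 <- assign_clusters(coh, cm)
  expect_identical(r1, r2)
  agree <- mean(r1$cluster == cm$partition$cluster[match(r1$fish_id,
                                                         cm$partition$fish_id)])
  expect_gte(agree, 0.9)

  expect_error(assign_clusters(centroid, cm, n_vote = 200),
               class = "fearfish_validation_error")
})

test_that("representation permutation test detects enrichment and respects nulls", {
  # constant cluster labels: every permutation is identical, all p = 1
  d <- tibble::tibble(cluster = rep(1, 30),
                      strain = rep(c("AB", "TL"), 15), sex = "F")
  r <- representation_test(d, n_perm = 200, seed = 1, tie_smoothing = FALSE)
  expect_true(all(r$p_value == 1))

  # one strain fully concentrated in one cluster
  d2 <- tibble::tibble(
    cluster = rep(c(1, 2), each = 20),
    strain = c(rep("AB", 20), rep("TL", 20)),
    sex = "F")
  r2 <- representation_test(d2, n_perm = 2000, seed = 2)
  expect_true(all(r2$p_adj < 0.05))
  # hypergeometric oracle: P(cell AB,1 = 20) under permutation
  p_exact <- 2 * dhyper(20, 20, 20, 20)
  expect_lt(r2$p_value[1], 10 * p_exact + 0.01)
})
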