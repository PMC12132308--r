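test_that("markov scripts respect absorbing states, seeds and validation", {
  lv <- behavior_levels(5)
  ident <- diag(5); dimnames(ident) <- list(lv, lv)
  s <- markov_script(ident, 100, init = "freeze", seed = 1)
  expect_true(all(s$behavior == "freeze"))
  expect_equal(nrow(s), 100)

  s1 <- markov_script(default_transition_matrix(), 500, seed = 42)
  s2 <- markov_script(default_transition_matrix(), 500, seed = 42)
  expect_identical(s1, s2)

  bad <- default_transition_matrix()
  bad["turn", 1] <- bad["turn", 1] + 0.1
  expect_error(markov_script(bad, 10), "turn", class = "fearfish_validation_error")
})

test_that("long-run state occupancy converges to the stationary distribution", {
  unif <- matrix(0.2, 5, 5)
  s <- markov_script(unif, 100000, seed = 7)
  occ <- as.numeric(table(s$behavior)) / 100000
  expect_true(all(abs(occ - 0.2) < 0.01))
})

test_that("freeze bout lengths follow the geometric 1/(1-p) mean", {
  lv <- behavior_levels(5)
  m <- matrix(0.2, 5, 5, dimnames = list(lv, lv))
  m["freeze", ] <- c(0.0125, 0.0125, 0.95, 0.0125, 0.0125)
  s <- markov_script(m, 60000, seed = 11)
  runs <- rle(as.character(s$behavior))
  mean_bout <- mean(runs$lengths[runs$values == "freeze"])
  expect_equal(mean_bout, 1 / (1 - 0.95), tolerance = 0.1)
})

test_that("trajectories realize their behavioral script kinematics", {
  frz <- tibble::tibble(behavior = rep("freeze", 500))
  tr <- simulate_track(frz, seed = 3)
  path <- sum(sqrt(diff(tr$head_x)^2 + diff(tr$head_y)^2))
  jit <- default_kinematics()$jitter_sd[default_kinematics()$behavior == "freeze"]
  expect_lt(path, jit * 500)

  brs <- tibble::tibble(behavior = rep("burst", 500))
  tb <- simulate_track(brs, seed = 4)
  spd <- sqrt(diff(tb$head_x)^2 + diff(tb$head_y)^2) * 60
  expect_gt(mean(spd), 15 - 1)
  expect_lt(mean(spd), 30 + 1)

  mixed <- markov_script(default_transition_matrix(), 3000, seed = 5)
  tm <- simulate_track(mixed, seed = 6)
  expect_true(all(tm$head_x >= 0 & tm$head_x <= 20))
  expect_true(all(tm$head_y >= 0 & tm$head_y <= 7))
  expect_true(all(tm$tail_x >= 0 & tm$tail_x <= 20))

  expect_error(simulate_track(tibble::tibble(behavior = "hover")),
               "hover", class = "fearfish_validation_error")
})

test_that("recomputed speeds respect the per-behavior spec bounds in >= 99% of frames", {
  script <- markov_script(default_transition_matrix(), 5000, seed = 8)
  tr <- simulate_track(script, seed = 9)
  spd <- c(NA, sqrt(diff(tr$head_x)^2 + diff(tr$head_y)^2) * 60)
  specs <- default_kinematics()
  idx <- match(as.character(tr$behavior), specs$behavior)
  # skip the first frame of every bout: its step straddles two behaviors
  same <- c(FALSE, tr$behavior[-1] == tr$behavior[-nrow(tr)])
  ok <- spd >= specs$speed_min[idx] - 1 & spd <= specs$speed_max[idx] + 1
  expect_gt(mean(ok[same], na.rm = TRUE), 0.99)
})

test_that("cohort generator plants clusters with the requested geometry", {
  g <- default_cluster_groups(n_fish = 5, spread = 0)
  coh <- simulate_cohort(g, seed = 1)
  for (gr in g$group) {
    rows <- coh[coh$group == gr, ]
    expect_true(all(rows$pct_freezing == g$pct_freezing[g$group == gr]))
    expect_true(all(rows$pct_evasion == g$pct_evasion[g$group == gr]))
  }
  # spread 0, two centroids: between-group distance equals centroid distance
  two <- g[1:2, ]
  coh2 <- simulate_cohort(two, seed = 2)
  d_pts <- sqrt(sum((as.numeric(coh2[1, c("pct_freezing", "pct_evasion")]) -
                       as.numeric(coh2[10, c("pct_freezing", "pct_evasion")]))^2))
  d_cent <- sqrt(sum((as.numeric(two[1, c("pct_freezing", "pct_evasion")]) -
                        as.numeric(two[2, c("pct_freezing", "pct_evasion")]))^2))
  expect_equal(d_pts, d_cent)

  bad <- default_cluster_groups()
  bad$pct_freezing[1] <- 120
  expect_error(simulate_cohort(bad), class = "fearfish_validation_error")
})

test_that("planted clusters are recoverable: silhouette and k-means oracle", {
  coh <- simulate_cohort(default_cluster_groups(n_fish = 80), seed = 21)
  z <- scale(as.matrix(coh[, c("pct_freezing", "pct_evasion", "pct_evasion_active")]))
  sil <- mean(cluster::silhouette(as.integer(factor(coh$group)),
                                  dist(z))[, "sil_width"])
  expect_gt(sil, 0.5)
  aris <- vapply(1:3, function(s) {
    ch <- simulate_cohort(default_cluster_groups(n_fish = 80), seed = 30 + s)
    zz <- scale(as.matrix(ch[, c("pct_freezing", "pct_evasion", "pct_evasion_active")]))
    km <- withr::with_seed(s, kmeans(zz, centers = 4, nstart = 10))
    mclust::adjustedRandIndex(km$cluster, ch$group)
  }, numeric(1))
  expect_true(all(aris >= 0.9))
})

test_that("region counts carry the planted covariance, salience and batch structure", {
  coh <- simulate_cohort(default_cluster_groups(n_fish = 125, spread = 8), seed = 41)
  # independent regions, vanishing dispersion: correlations are pure noise
  c0 <- simulate_region_counts(coh, regions = default_regions(8),
                               salience = 0, noise_sd = 0, seed = 42)
  r0 <- cor(as.matrix(c0[, default_regions(8)]))
  expect_lt(max(abs(r0[upper.tri(r0)])), 3 / sqrt(nrow(coh)))

  # planted latent correlation survives count noise
  sig <- diag(4); sig[1, 2] <- sig[2, 1] <- 0.9
  coh2 <- simulate_cohort(default_cluster_groups(n_fish = 50, spread = 8), seed = 43)
  c1 <- simulate_region_counts(coh2, regions = default_regions(4),
                               latent_cor = sig, seed = 44)
  r1 <- cor(as.matrix(c1[, default_regions(4)]))
  expect_gt(r1[1, 2], 0.6)

  # cohort batch factor scales total counts multiplicatively
  coh3 <- simulate_cohort(default_cluster_groups(n_fish = 40, spread = 8),
                          seed = 45, n_cohorts = 2)
  c2 <- simulate_region_counts(coh3, regions = default_regions(6),
                               batch_factors = c(cohort_1 = 1, cohort_2 = 2),
                               seed = 46)
  tot <- rowSums(as.matrix(c2[, default_regions(6)]))
  ratio <- median(tot[c2$cohort == "cohort_2"]) / median(tot[c2$cohort == "cohort_1"])
  expect_equal(ratio, 2, tolerance = 0.1)

  notpsd <- matrix(c(1, 2, 2, 1), 2)
  expect_error(simulate_region_counts(coh, regions = default_regions(2),
                                      latent_cor = notpsd),
               "positive semidefinite", class = "fearfish_validation_error")
})
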