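sim_group_counts <- function(n, regions = 20, rho = 0, blocks = NULL, seed = 1) {
  p <- regions
  sigma <- diag(p)
  if (!is.null(blocks)) {
    for (b in blocks) sigma[b, b] <- rho
    diag(sigma) <- 1
  }
  withr::with_seed(seed, {
    L <- chol(sigma)
    m <- matrix(rnorm(n * p), n, p) %*% L
  })
  colnames(m) <- default_regions(p)
  d <- tibble::as_tibble(m)
  d$fish_id <- sprintf("f%03d", seq_len(n))
  d
}

test_that("correlation networks validate input and capture construction", {
  d <- sim_group_counts(30, regions = 5, seed = 1)
  d$dup <- d[[default_regions(1)]]
  net <- correlation_network(d, group = "g")
  expect_equal(net$r[default_regions(1), "dup"], 1)

  anti <- d
  anti$dup <- -anti$dup
  expect_lt(correlation_network(anti)$r[default_regions(1), "dup"], 0)

  # independent regions at n = 200: all |r| small
  big <- sim_group_counts(200, regions = 10, seed = 2)
  r <- correlation_network(big)$r
  expect_lt(max(abs(r[upper.tri(r)])), 0.3)

  expect_error(correlation_network(d[1:3, ]), class = "fearfish_validation_error")
  dd <- d
  dd$flat <- 1
  expect_warning(correlation_network(dd), "constant")
})

test_that("FDR thresholding matches the single-test critical r oracle", {
  # all-zero correlations: no edges
  d0 <- sim_group_counts(50, regions = 8, seed = 3)
  n0 <- threshold_fdr(correlation_network(d0), alpha = 0.001, n_effective = 16)
  expect_lte(sum(n0$adjacency), 2)  # essentially nothing survives FDR 0.001

  # single pair: BH reduces to the raw test; invert the t CDF for critical r
  crit <- uniroot(function(r) {
    2 * pt(r * sqrt(14 / (1 - r^2)), df = 14, lower.tail = FALSE) - 0.001
  }, c(0.5, 0.999))$root
  for (r_target in c(crit - 0.02, crit + 0.02)) {
    m <- exact_corr_pair(30, r_target, seed = 4)
    d <- tibble::as_tibble(m)
    d$fish_id <- sprintf("f%02d", 1:30)
    net <- threshold_fdr(correlation_network(d), alpha = 0.001, n_effective = 16)
    expect_equal(unname(net$adjacency["a", "b"]), r_target > crit)
  }

  # planted correlated block survives, null edges do not
  db <- sim_group_counts(20, regions = 20, rho = 0.9, blocks = list(1:10), seed = 5)
  nb <- threshold_fdr(correlation_network(db), alpha = 0.001, n_effective = 20)
  block <- nb$adjacency[1:10, 1:10]
  expect_gte(mean(block[upper.tri(block)]), 0.8)
  null_part <- nb$adjacency[11:20, 11:20]
  expect_lte(mean(null_part[upper.tri(null_part)]), 0.05)
})

test_that("Fisher-z intervals match direct evaluation and shrink with n", {
  d <- sim_group_counts(16, regions = 4, seed = 6)
  net <- edge_confidence_intervals(correlation_network(d))
  half <- tanh(qnorm(0.975) / sqrt(16 - 3))
  z <- atanh(net$r[1, 2])
  expect_equal(net$ci$hi[1, 2], tanh(z + qnorm(0.975) / sqrt(13)), tolerance = 1e-9)
  # at r = 0 the interval is +/- tanh(1.96/sqrt(13)) ~ +/- 0.497
  expect_equal(half, 0.497, tolerance = 0.005)
  ut <- upper.tri(net$r)
  expect_true(all(net$ci$lo[ut] <= net$r[ut] & net$r[ut] <= net$ci$hi[ut]))

  d2 <- sim_group_counts(64, regions = 4, seed = 6)
  net2 <- edge_confidence_intervals(correlation_network(d2))
  expect_lt(mean(net2$ci$hi - net2$ci$lo), mean(net$ci$hi - net$ci$lo))
})

test_that("unique edges require both significance and CI non-overlap", {
  db <- sim_group_counts(20, regions = 10, rho = 0.9, blocks = list(1:4), seed = 7)
  net <- prep_net <- threshold_fdr(correlation_network(db, "a"), n_effective = 20)
  net <- edge_confidence_intervals(net)

  # identical networks: zero unique edges
  ue_self <- unique_edges(net, list(net))
  expect_gt(nrow(ue_self), 0)
  expect_true(all(ue_self$status == "shared"))

  # strong target edge vs null other: unique
  strong <- exact_corr_pair(20, 0.95, seed = 8)
  flat <- exact_corr_pair(20, 0.0, seed = 9)
  mk <- function(m, g) {
    d <- tibble::as_tibble(m); d$fish_id <- sprintf("f%02d", 1:20)
    edge_confidence_intervals(threshold_fdr(correlation_network(d, g),
                                            n_effective = 20))
  }
  ua <- unique_edges(mk(strong, "hi"), mk(flat, "lo"))
  expect_equal(ua$status, "unique")

  mismatch <- sim_group_counts(20, regions = 6, seed = 10)
  expect_error(unique_edges(net, correlation_network(mismatch)),
               class = "fearfish_validation_error")
})

test_that("degree contrasts follow the relative-degree formula", {
  adj <- function(edges, p = 6) {
    a <- matrix(FALSE, p, p, dimnames = list(default_regions(p), default_regions(p)))
    for (e in edges) { a[e[1], e[2]] <- TRUE; a[e[2], e[1]] <- TRUE }
    a
  }
  fake_net <- function(a) {
    structure(list(r = a * 0.5, n_fish = 16, group = "x", data = NULL,
                   adjacency = a, p_adj = a * 0, ci = list(lo = a * 0, hi = a * 0),
                   alpha = 0.001, n_effective = 16),
              class = "corr_network")
  }
  a1 <- adj(list(c(1, 2), c(1, 3), c(1, 4), c(2, 3)))
  a2 <- adj(list(c(1, 2), c(3, 4)))
  rd <- relative_degree(fake_net(a1), fake_net(a2))
  expect_equal(rd$relative_degree[rd$region == default_regions(6)[1]],
               (3 - 1) / (3 + 1))
  expect_true(all(stats::na.omit(rd$relative_degree) >= -1 &
                    stats::na.omit(rd$relative_degree) <= 1))
  expect_true(is.na(rd$relative_degree[rd$degree_a == 0 & rd$degree_b == 0][1]))
  # the published example values
  expect_equal((3 - 9) / (3 + 9), -0.5)
  expect_equal((20 - 0) / (20 + 0), 1)
})

test_that("matrix similarity is 1 against itself and near 0 for independent groups", {
  d1 <- sim_group_counts(40, regions = 12, rho = 0.6, blocks = list(1:6), seed = 11)
  n1 <- correlation_network(d1, "a")
  self <- matrix_similarity(n1, n1, n_boot = 100, seed = 12)
  expect_equal(self$r, 1)

  d2 <- sim_group_counts(40, regions = 12, seed = 13)
  n2 <- correlation_network(d2, "b")
  ind <- matrix_similarity(n1, n2, n_boot = 200, seed = 14)
  expect_lt(abs(ind$r), 0.4)
  expect_true(ind$ci_lo <= ind$r & ind$r <= ind$ci_hi)
  expect_warning(matrix_similarity(n1, n2, n_boot = 50, seed = 1), "unstable")
})

test_that("modularity partitions find planted blocks", {
  p <- 12
  a <- matrix(FALSE, p, p, dimnames = list(default_regions(p), default_regions(p)))
  a[1:6, 1:6] <- TRUE; a[7:12, 7:12] <- TRUE; diag(a) <- FALSE
  part <- modularity_partition(a, seed = 1)
  expect_equal(length(unique(part$community)), 2)
  expect_equal(length(unique(part$community[1:6])), 1)

  full <- matrix(TRUE, 6, 6, dimnames = list(default_regions(6), default_regions(6)))
  diag(full) <- FALSE
  expect_equal(length(unique(modularity_partition(full, seed = 1)$community)), 1)
})

test_that("edge counts are monotone in alpha and effective n", {
  d <- sim_group_counts(30, regions = 15, rho = 0.5, blocks = list(1:8), seed = 15)
  net <- correlation_network(d)
  e_strict <- sum(threshold_fdr(net, alpha = 0.001, n_effective = 16)$adjacency)
  e_loose <- sum(threshold_fdr(net, alpha = 0.01, n_effective = 16)$adjacency)
  e_bign <- sum(threshold_fdr(net, alpha = 0.001, n_effective = 30)$adjacency)
  expect_lte(e_strict, e_loose)
  expect_lte(e_strict, e_bign)
})
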