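test_that("behavioral summaries compute the three percentages exactly", {
  s <- summarize_behavior(tibble::tibble(
    behavior = rep(c("freeze", "burst", "straight"), c(50, 25, 25))))
  expect_equal(s$pct_freezing, 50)
  expect_equal(s$pct_evasion, 25)
  expect_equal(s$pct_evasion_active, 50)  # 25 evasive / 50 active frames

  all_freeze <- summarize_behavior(tibble::tibble(behavior = rep("freeze", 10)))
  expect_equal(all_freeze$pct_evasion_active, 0)
  expect_false(all_freeze$evasion_active_defined)

  all_ev <- summarize_behavior(tibble::tibble(behavior = rep("burst", 10)))
  expect_equal(c(all_ev$pct_freezing, all_ev$pct_evasion, all_ev$pct_evasion_active),
               c(0, 100, 100))
  # freezing plus active share is exactly 100
  expect_equal(s$pct_freezing + s$pct_normal + s$pct_evasion, 100)
  expect_error(summarize_behavior(tibble::tibble(behavior = NA_character_)),
               class = "fearfish_validation_error")
})

test_that("difference scores subtract the reference stage and are antisymmetric", {
  a <- exact_summary(c(60, 20), c(10, 30))
  b <- exact_summary(c(10, 20), c(10, 10))
  d <- difference_scores(a, b)
  expect_equal(d$delta_pct_freezing, c(50, 0))
  d0 <- difference_scores(a, a)
  expect_true(all(d0$delta_pct_freezing == 0))
  expect_equal(difference_scores(b, a)$delta_pct_freezing,
               -d$delta_pct_freezing)
  b_extra <- dplyr::bind_rows(b, exact_summary(5, 5, fish_id = "zz"))
  expect_warning(difference_scores(a, b_extra), "zz")
})

test_that("time profiles average per-fish proportions with t-intervals", {
  seqs <- purrr::map_dfr(1:4, function(i) {
    tibble::tibble(fish_id = paste0("f", i), frame = 1:600,
                   behavior = rep("freeze", 600))
  })
  pr <- time_profile(seqs, bin_seconds = 5, fps = 60)
  frz <- pr[pr$behavior == "freezing", ]
  expect_true(all(frz$mean == 100))
  expect_true(all(frz$ci_hi - frz$ci_lo == 0))  # identical fish, zero-width CI

  one <- seqs[seqs$fish_id == "f1", ]
  suppressWarnings(pr1 <- time_profile(one, bin_seconds = 5, fps = 60))
  expect_true(all(is.na(pr1$ci_lo)))  # CI undefined at n = 1
  expect_error(time_profile(one, bin_seconds = 60, fps = 60),
               class = "fearfish_validation_error")

  # constructed rising freeze: monotone mean profile
  rising <- purrr::map_dfr(1:3, function(i) {
    p <- seq(0.05, 0.95, length.out = 600)
    withr::with_seed(i, tibble::tibble(
      fish_id = paste0("r", i), frame = 1:600,
      behavior = ifelse(runif(600) < p, "freeze", "straight")))
  })
  prr <- time_profile(rising, bin_seconds = 2.5, fps = 60)
  m <- prr$mean[prr$behavior == "freezing"]
  expect_gt(cor(seq_along(m), m), 0.9)
})

test_that("transition matrices count frame-to-frame transitions exactly", {
  ab <- tibble::tibble(behavior = rep(c("straight", "turn"), 20))
  suppressWarnings(tm <- transition_matrix(ab))
  p <- as_matrix(tm)
  expect_equal(p["straight", "turn"], 1)
  expect_equal(p["turn", "straight"], 1)

  cst <- tibble::tibble(behavior = rep("freeze", 10))
  expect_warning(tmc <- transition_matrix(cst), "never observed as source")
  expect_equal(as_matrix(tmc)["freeze", "freeze"], 1)

  # rows with outgoing transitions are stochastic
  s <- markov_script(default_transition_matrix(), 2000, seed = 3)
  suppressWarnings(tms <- transition_matrix(s))
  rs <- rowSums(as_matrix(tms))
  expect_true(all(abs(rs[rowSums(as_matrix(tms, "counts")) > 0] - 1) < 1e-9))
})

test_that("transitions pool within but never across fish, and reverse by transpose", {
  two <- tibble::tibble(fish_id = rep(c("a", "b"), each = 3),
                        behavior = c("straight", "turn", "freeze",
                                     "burst", "erratic", "burst"))
  suppressWarnings(tm <- transition_matrix(two))
  cnt <- as_matrix(tm, "counts")
  expect_equal(sum(cnt), 4)  # 2 per fish, no cross-boundary transition
  expect_equal(cnt["freeze", "burst"], 0)

  s <- markov_script(default_transition_matrix(), 3000, seed = 9)
  fwd <- as_matrix(transition_matrix(s), "counts")
  rev <- s; rev$behavior <- rev(rev$behavior)
  bwd <- as_matrix(transition_matrix(rev), "counts")
  expect_equal(bwd, t(fwd))
})

test_that("a generated chain's matrix is recovered from its own script", {
  tmat <- default_transition_matrix()
  s <- markov_script(tmat, 50000, seed = 13)
  suppressWarnings(rec <- as_matrix(transition_matrix(s)))
  seen <- rowSums(as_matrix(transition_matrix(s), "counts")) > 0
  expect_lt(max(abs(rec[seen, ] - tmat[seen, ])), 0.02)
})

test_that("group comparisons run Welch and one-sample t machinery", {
  d <- tibble::tibble(y = c(1, 2, 3, 1, 2, 3), g = rep(c("a", "b"), each = 3))
  r <- compare_groups(d, "y", group = "g")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  z <- tibble::tibble(y = rep(0, 8))
  r1 <- compare_groups(z, "y", test = "one_sample")
  expect_equal(r1$statistic, 0)

  flat <- tibble::tibble(y = rep(c(0, 1), each = 4), g = rep(c("a", "b"), each = 4))
  rf <- compare_groups(flat, "y", group = "g")
  expect_true(is.na(rf$p_value))  # zero variance in both groups: flagged

  # power at a 2 SD shift, n = 40/group
  hits <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      dd <- tibble::tibble(y = c(rnorm(40), rnorm(40, 2)),
                           g = rep(c("a", "b"), each = 40))
    })
    compare_groups(dd, "y", group = "g")$p_value < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
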