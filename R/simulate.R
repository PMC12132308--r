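#' Default kinematic signatures of the five swimming behaviors
#'
#' One row per behavior with the speed range (cm/s), angular-velocity range
#' (deg/s), heading-reversal rate (reversals/s, the quick C-bend signature of
#' erratic movement), positional jitter bound (cm per frame), and body-bend
#' variability (deg).  The defaults are chosen so that the five behaviors are
#' kinematically separable the way hand-scored zebrafish behaviors are:
#' freezing is near-motionless, burst swimming is much faster than straight
#' swimming, normal turns share straight-swimming speed but have high angular
#' velocity, and erratic movement combines high speed with large bends and at
#' least 3 heading reversals per second.
#'
#' @return Tibble with columns `behavior`, `speed_min`, `speed_max`,
#'   `angvel_min`, `angvel_max`, `reversal_rate`, `jitter_sd`, `bend_sd`.
#' @export
#' @examples
#' default_kinematics()
default_kinematics <- function() {
  tibble::tribble(
    ~behavior,  ~speed_min, ~speed_max, ~angvel_min, ~angvel_max, ~reversal_rate, ~jitter_sd, ~bend_sd,
    "straight",        2.0,        8.0,           0,          40,              0,      0.010,        6,
    "turn",            2.0,        8.0,         250,         600,              0,      0.010,       18,
    "freeze",          0.0,       0.03,           0,          10,              0,      0.003,        1,
    "burst",          15.0,       30.0,           0,          60,              0,      0.020,        8,
    "erratic",        10.0,       25.0,         500,        1200,              4,      0.020,       45
  )
}

validate_kinematics <- function(specs) {
  need <- c("behavior", "speed_min", "speed_max", "angvel_min", "angvel_max",
            "reversal_rate", "jitter_sd", "bend_sd")
  check_that(all(need %in% names(specs)),
             paste0("Kinematic specs must have columns: ",
                    paste(setdiff(need, names(specs)), collapse = ", ")))
  check_that(all(specs$speed_min >= 0) && all(specs$speed_max >= specs$speed_min),
             "Speed ranges must be non-negative with max >= min.")
  fr <- specs[specs$behavior == "freeze", ]
  st <- specs[specs$behavior == "straight", ]
  if (nrow(fr) == 1 && nrow(st) == 1) {
    check_that(fr$speed_max < st$speed_min,
               "Freezing speed range must lie below the straight-swimming range.")
  }
  er <- specs[specs$behavior == "erratic", ]
  if (nrow(er) == 1) {
    check_that(er$reversal_rate >= 3,
               "Erratic movement requires a heading-reversal rate of at least 3/s.")
  }
  invisible(specs)
}

#' Default behavioral-state transition matrix
#'
#' A row-stochastic 5x5 matrix over the raw ethogram with high self-transition
#' probabilities, so that behaviors occur in realistic bouts even though the
#' chain is first-order at the frame level.  Freezing is the most stable state.
#'
#' @return 5x5 row-stochastic matrix with behavior dimnames.
#' @export
default_transition_matrix <- function() {
  lv <- behavior_levels(5)
  m <- matrix(0, 5, 5, dimnames = list(lv, lv))
  m["straight", ] <- c(0.960, 0.020, 0.010, 0.005, 0.005)
  m["turn", ]     <- c(0.060, 0.920, 0.010, 0.005, 0.005)
  m["freeze", ]   <- c(0.005, 0.003, 0.990, 0.001, 0.001)
  m["burst", ]    <- c(0.020, 0.010, 0.005, 0.950, 0.015)
  m["erratic", ]  <- c(0.015, 0.010, 0.005, 0.020, 0.950)
  m
}

#' Simulate a behavioral label sequence from a first-order Markov chain
#'
#' Generates a per-frame behavior sequence by iterating a frame-level
#' first-order Markov chain, the same semantics in which downstream transition
#' matrices are computed (frame-to-frame, including self-transitions).
#'
#' @param transition Row-stochastic square matrix; dimnames give the state
#'   labels (defaults to the five-behavior ethogram when dimnames are absent
#'   and the matrix is 5x5).
#' @param n_frames Number of frames to generate (>= 1).
#' @param init Starting state label; default is a draw from the stationary
#'   distribution's leading eigenvector (uniform fallback).
#' @param seed Integer seed; the global RNG stream is left untouched.
#' @return Tibble with columns `frame` and `behavior` (factor over the states).
#' @export
#' @examples
#' markov_script(default_transition_matrix(), 100, seed = 1)
markov_script <- function(transition, n_frames, init = NULL, seed = NULL) {
  transition <- as.matrix(transition)
  check_that(nrow(transition) == ncol(transition), "Transition matrix must be square.")
  states <- rownames(transition)
  if (is.null(states)) {
    states <- if (nrow(transition) == 5) behavior_levels(5) else paste0("S", seq_len(nrow(transition)))
    dimnames(transition) <- list(states, states)
  }
  check_that(all(transition >= 0), "Transition probabilities must be non-negative.")
  rs <- rowSums(transition)
  bad <- which(abs(rs - 1) > 1e-9)
  if (length(bad) > 0) {
    abort(paste0("Transition matrix rows must sum to 1; offending row(s): ",
                 paste(states[bad], collapse = ", ")),
          class = "fearfish_validation_error")
  }
  check_that(is.numeric(n_frames) && n_frames >= 1, "`n_frames` must be >= 1.")
  n_frames <- as.integer(n_frames)
  if (!is.null(init)) {
    check_that(init %in% states, paste0("Unknown initial state: ", init))
  }

  cum <- t(apply(transition, 1, cumsum))
  seq_idx <- with_seed_(seed, {
    u <- runif(n_frames)
    out <- integer(n_frames)
    s <- if (is.null(init)) sample.int(length(states), 1) else match(init, states)
    out[1] <- s
    for (t in seq_len(n_frames - 1L)) {
      s <- findInterval(u[t], cum[s, ], left.open = TRUE) + 1L
      out[t + 1L] <- s
    }
    out
  })
  tibble::tibble(
    frame = seq_len(n_frames),
    behavior = factor(states[seq_idx], levels = states)
  )
}

#' Simulate a pose track from a behavioral script
#'
#' Emits per-frame head/trunk/tail coordinates (cm, top-down view, origin at a
#' tank corner) realizing each frame's scripted behavior with the given
#' kinematic signatures.  The fish is a three-point rigid-ish body: the trunk
#' trails the head along the heading, the tail trails the trunk at the current
#' body-bend angle.  Walls are handled by reflecting the offending step, so
#' coordinates always stay inside the arena.
#'
#' @param script Data frame with a `behavior` column (one row per frame), as
#'   produced by [markov_script()].
#' @param kinematics Kinematic spec table, one row per behavior present in the
#'   script; see [default_kinematics()].
#' @param arena Numeric length-2, tank width and depth in cm (top-down);
#'   default `c(20, 7)`.
#' @param fps Frames per second; default 60.
#' @param seed Integer seed.
#' @param fish_id,stage Metadata labels attached to the track.
#' @return Tibble of class `pose_track` with columns `frame`, `behavior`,
#'   `head_x`, `head_y`, `trunk_x`, `trunk_y`, `tail_x`, `tail_y` and
#'   attributes `fps`, `arena`.
#' @export
simulate_track <- function(script, kinematics = default_kinematics(),
                           arena = c(20, 7), fps = 60, seed = NULL,
                           fish_id = "fish_1", stage = "memory") {
  check_that(is.data.frame(script) && "behavior" %in% names(script),
             "`script` must be a data frame with a `behavior` column.")
  validate_kinematics(kinematics)
  beh <- as.character(script$behavior)
  missing_specs <- setdiff(unique(beh), kinematics$behavior)
  if (length(missing_specs) > 0) {
    abort(paste0("No kinematic spec for behavior(s): ",
                 paste(missing_specs, collapse = ", ")),
          class = "fearfish_validation_error")
  }
  n <- length(beh)
  check_that(n >= 1, "Script must have at least one frame.")
  W <- arena[1]; H <- arena[2]
  idx <- match(beh, kinematics$behavior)
  L1 <- 0.4; L2 <- 0.4  # head-trunk and trunk-tail segment lengths, cm

  res <- with_seed_(seed, {
    step <- runif(n, kinematics$speed_min[idx], kinematics$speed_max[idx]) / fps
    dtheta_mag <- runif(n, kinematics$angvel_min[idx], kinematics$angvel_max[idx]) / fps
    rev_ev <- runif(n) < kinematics$reversal_rate[idx] / fps
    jit_x <- rnorm(n, 0, kinematics$jitter_sd[idx] / 4)
    jit_y <- rnorm(n, 0, kinematics$jitter_sd[idx] / 4)
    flip <- runif(n) < 0.05  # turn-direction persistence
    # body bend: erratic movements zig-zag as alternating C-bends (~6 Hz)
    bend <- rnorm(n, 0, kinematics$bend_sd[idx])
    err <- beh == "erratic"
    if (any(err)) {
      cbend <- 50 * sign(sin(2 * pi * 6 * seq_len(n) / fps))
      bend[err] <- bend[err] * 0.3 + cbend[err]
    }

    x <- numeric(n); y <- numeric(n)
    x[1] <- runif(1, 0.1 * W, 0.9 * W)
    y[1] <- runif(1, 0.1 * H, 0.9 * H)
    theta <- runif(1, 0, 360)
    dir_sign <- sample(c(-1, 1), 1)
    thetas <- numeric(n); thetas[1] <- theta
    for (t in seq_len(n)[-1]) {
      if (flip[t]) dir_sign <- -dir_sign
      theta <- theta + dir_sign * dtheta_mag[t] + if (rev_ev[t]) 180 else 0
      rad <- theta * pi / 180
      nx <- x[t - 1] + step[t] * cos(rad) + jit_x[t]
      ny <- y[t - 1] + step[t] * sin(rad) + jit_y[t]
      # reflective boundaries: fold the step back into the tank
      for (k in 1:4) {
        if (nx < 0) { nx <- -nx; theta <- 180 - theta }
        if (nx > W) { nx <- 2 * W - nx; theta <- 180 - theta }
        if (ny < 0) { ny <- -ny; theta <- -theta }
        if (ny > H) { ny <- 2 * H - ny; theta <- -theta }
        if (nx >= 0 && nx <= W && ny >= 0 && ny <= H) break
      }
      x[t] <- nx; y[t] <- ny; thetas[t] <- theta
    }
    list(x = x, y = y, theta = thetas, bend = bend)
  })

  rad <- res$theta * pi / 180
  trunk_x <- pmin(pmax(res$x - L1 * cos(rad), 0), W)
  trunk_y <- pmin(pmax(res$y - L1 * sin(rad), 0), H)
  brad <- (res$theta - res$bend) * pi / 180
  tail_x <- pmin(pmax(trunk_x - L2 * cos(brad), 0), W)
  tail_y <- pmin(pmax(trunk_y - L2 * sin(brad), 0), H)

  out <- tibble::tibble(
    frame = seq_len(n),
    behavior = factor(beh, levels = levels(factor(script$behavior))),
    head_x = res$x, head_y = res$y,
    trunk_x = trunk_x, trunk_y = trunk_y,
    tail_x = tail_x, tail_y = tail_y
  )
  attr(out, "fps") <- fps
  attr(out, "arena") <- arena
  attr(out, "fish_id") <- fish_id
  attr(out, "stage") <- stage
  class(out) <- c("pose_track", class(out))
  out
}

#' Default planted behavioral-cluster specification
#'
#' Four groups at the qualitative positions of the four fear-memory behavioral
#' types: non-reactive (low freezing, low evasion), evaders (low freezing,
#' high evasion), evading freezers (high freezing, high evasion), and freezers
#' (high freezing, low evasion).  `spread` is the per-axis SD (percentage
#' points) of the generative axes (% freezing, % evasion); by default a
#' quarter of the minimum inter-centroid distance on those axes, the regime in
#' which cluster recovery is expected to be essentially perfect.  `spread` is
#' the RMS radius of a group's scatter (per-axis SD = spread / sqrt(2)).
#'
#' @param n_fish Fish per group.
#' @param spread Per-axis SD in percentage points; `NULL` for the default.
#' @return Tibble with columns `group`, `pct_freezing`, `pct_evasion`,
#'   `spread`, `n_fish`.
#' @export
default_cluster_groups <- function(n_fish = 80, spread = NULL) {
  g <- tibble::tribble(
    ~group,             ~pct_freezing, ~pct_evasion,
    "non_reactive",                10,           10,
    "evader",                      10,           60,
    "evading_freezer",             60,           25,
    "freezer",                     70,            5
  )
  if (is.null(spread)) {
    d <- as.matrix(stats::dist(g[, c("pct_freezing", "pct_evasion")]))
    spread <- min(d[upper.tri(d)]) / 4
  }
  g$spread <- spread
  g$n_fish <- n_fish
  g
}

#' Simulate per-fish behavioral summaries with planted clusters
#'
#' Draws, for each group, `n_fish` fish whose (% freezing, % evasion) are
#' Gaussian around the group centroid (truncated to valid percentages, with
#' evasion capped at the non-freezing share) and derives % evasion of active
#' time as `100 * evasion / (100 - freezing)`.  Strain, sex and cohort are
#' taken from the group table when present, otherwise assigned independently
#' of group (uniform strain/sex, round-robin cohort) so that strata are null
#' with respect to cluster membership by construction.
#'
#' @param groups Group table as from [default_cluster_groups()]; required
#'   columns `group`, `pct_freezing`, `pct_evasion`, `spread`, `n_fish`;
#'   optional `strain`, `sex`, `cohort`.
#' @param seed Integer seed.
#' @param strains,sexes,n_cohorts Pools used when the group table does not fix
#'   them.
#' @return Tibble with one row per fish: `fish_id`, `group` (truth label),
#'   `strain`, `sex`, `cohort`, `stage`, `treatment`, `pct_freezing`,
#'   `pct_evasion`, `pct_evasion_active`.
#' @export
#' @examples
#' simulate_cohort(default_cluster_groups(n_fish = 10), seed = 1)
simulate_cohort <- function(groups = default_cluster_groups(), seed = NULL,
                            strains = c("AB", "TL", "TU", "WIK"),
                            sexes = c("F", "M"), n_cohorts = 4) {
  need <- c("group", "pct_freezing", "pct_evasion", "spread", "n_fish")
  check_that(all(need %in% names(groups)),
             paste0("`groups` must have columns: ", paste(need, collapse = ", ")))
  check_that(all(groups$n_fish >= 1), "Each group needs n_fish >= 1.")
  check_that(all(groups$pct_freezing >= 0 & groups$pct_freezing <= 100 &
                   groups$pct_evasion >= 0 & groups$pct_evasion <= 100),
             "Group centroids must lie in [0, 100].")
  check_that(all(groups$pct_evasion <= 100 - groups$pct_freezing),
             "Centroid %evasion must not exceed 100 - %freezing.")

  with_seed_(seed, {
    rows <- purrr::pmap(groups, function(group, pct_freezing, pct_evasion,
                                         spread, n_fish, ...) {
      extra <- list(...)
      # `spread` is the RMS radius of the within-group scatter on the two
      # generative axes, so each axis gets sd = spread / sqrt(2)
      ax_sd <- spread / sqrt(2)
      fr <- pmin(pmax(rnorm(n_fish, pct_freezing, ax_sd), 0), 100)
      ev <- pmin(pmax(rnorm(n_fish, pct_evasion, ax_sd), 0), 100 - fr)
      ea <- ifelse(fr >= 100, 0, 100 * ev / (100 - fr))
      tibble::tibble(
        group = group,
        strain = if (!is.null(extra$strain)) extra$strain else sample(strains, n_fish, replace = TRUE),
        sex = if (!is.null(extra$sex)) extra$sex else sample(sexes, n_fish, replace = TRUE),
        cohort = if (!is.null(extra$cohort)) extra$cohort else NA_character_,
        pct_freezing = fr, pct_evasion = ev, pct_evasion_active = ea
      )
    })
    out <- dplyr::bind_rows(rows)
    if (all(is.na(out$cohort))) {
      out$cohort <- paste0("cohort_", rep_len(seq_len(n_cohorts), nrow(out)))
    }
    out <- dplyr::mutate(out,
      fish_id = sprintf("fish_%03d", dplyr::row_number()),
      stage = "memory", treatment = "CAS", .before = 1
    )
    dplyr::relocate(out, "fish_id", "group", "strain", "sex", "cohort",
                    "stage", "treatment")
  })
}

#' Default brain-region abbreviation set
#'
#' Atlas-style region abbreviations (AZBA vocabulary) for simulated region
#' count tables; padded with generic `R<k>` names past the built-in list.
#'
#' @param n Number of regions.
#' @return Character vector of length `n`.
#' @export
default_regions <- function(n = 30) {
  base <- c("CC", "CCe-m", "MON", "LCa", "nLOTs", "BSTs", "Vc", "Vl", "Dp",
            "Dc", "Dm", "NI", "SCO", "Vmn", "NLV", "NLL", "DTN", "Vd-vd",
            "Vv", "Vp", "Hd", "Hv", "PPa", "PPp", "SC", "IO", "PO", "PSp",
            "PPv", "SG", "P", "PGl", "PGm", "TLa", "Dl")
  if (n <= length(base)) base[seq_len(n)] else c(base, paste0("R", seq_len(n - length(base))))
}

# Factor a symmetric PSD matrix for sampling; errors if not PSD.
psd_factor <- function(sigma) {
  check_that(is.matrix(sigma) && nrow(sigma) == ncol(sigma) &&
               max(abs(sigma - t(sigma))) < 1e-8,
             "Latent covariance must be a symmetric square matrix.")
  e <- eigen(sigma, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values))) {
    abort("Latent covariance is not positive semidefinite.",
          class = "fearfish_validation_error")
  }
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(sigma))
}

#' Simulate per-fish regional cfos cell counts
#'
#' Log-normal latent + Poisson emission model for regional activity.  The
#' expected log count of fish `i` in region `r` is
#' `log(base_count) + noise_sd * (salience[r] * contrast_i + z_ir)`, where
#' `z_i ~ MVN(0, latent_cor)` plants inter-regional covariance and
#' `contrast_i` is the z-scored freezing-minus-evasion contrast of the fish's
#' behavioral summary (so `salience[r] = 1` shifts the region's log activity
#' by one latent SD per SD of behavioral contrast).  Counts are then Poisson
#' draws scaled by the fish's cohort batch factor, emulating batch-to-batch
#' brightness differences.
#'
#' @param summaries Behavioral summary table (one row per fish) with columns
#'   `fish_id`, `group`, `cohort`, `pct_freezing`, `pct_evasion`.
#' @param regions Character vector of region names.
#' @param latent_cor Region x region symmetric PSD latent covariance
#'   (default identity).
#' @param salience Per-region loading onto the behavioral contrast (recycled
#'   scalar allowed; default 0).
#' @param batch_factors Named positive multipliers per cohort (default 1).
#' @param base_count Baseline expected count per region (default 500).
#' @param noise_sd Latent log-scale SD (the dispersion knob; 0 gives pure
#'   Poisson noise).
#' @param seed Integer seed.
#' @return Tibble with `fish_id`, `group`, `cohort` plus one integer column
#'   per region.
#' @export
simulate_region_counts <- function(summaries, regions = default_regions(30),
                                   latent_cor = diag(length(regions)),
                                   salience = 0, batch_factors = NULL,
                                   base_count = 500, noise_sd = 0.3,
                                   seed = NULL) {
  need <- c("fish_id", "cohort", "pct_freezing", "pct_evasion")
  check_that(all(need %in% names(summaries)),
             paste0("`summaries` must have columns: ", paste(need, collapse = ", ")))
  n <- nrow(summaries)
  check_that(n >= 1, "Need at least one fish.")
  p <- length(regions)
  salience <- rep_len(salience, p)
  L <- psd_factor(latent_cor)
  cohorts <- as.character(summaries$cohort)
  if (is.null(batch_factors)) {
    batch_factors <- setNames(rep(1, length(unique(cohorts))), unique(cohorts))
  }
  check_that(all(unique(cohorts) %in% names(batch_factors)),
             "Every cohort needs a batch factor.")
  check_that(all(batch_factors > 0), "Batch factors must be positive.")

  raw <- summaries$pct_freezing - summaries$pct_evasion
  contrast <- if (sd(raw) > 0) as.numeric(scale(raw)) else rep(0, n)

  counts <- with_seed_(seed, {
    z <- matrix(rnorm(n * p), n, p) %*% t(L)
    logmu <- log(base_count) + noise_sd * (outer(contrast, salience) + z)
    mu <- exp(logmu) * batch_factors[cohorts]
    matrix(rpois(n * p, lambda = mu), n, p)
  })
  colnames(counts) <- regions
  dplyr::bind_cols(
    tibble::tibble(fish_id = summaries$fish_id,
                   group = if ("group" %in% names(summaries)) summaries$group else NA_character_,
                   cohort = cohorts),
    tibble::as_tibble(counts)
  )
}
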