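# Shared fixtures, all generated in code.

# A stationary three-point fish at (x, y), n frames.
still_track <- function(n = 60, x = 5, y = 3, fps = 60) {
  tr <- tibble::tibble(
    frame = seq_len(n),
    head_x = rep(x, n), head_y = rep(y, n),
    trunk_x = rep(x - 0.4, n), trunk_y = rep(y, n),
    tail_x = rep(x - 0.8, n), tail_y = rep(y, n)
  )
  attr(tr, "fps") <- fps
  tr
}

# Straight-line swim along +x at `step` cm per frame.
line_track <- function(n = 60, step = 2, fps = 60) {
  x <- seq_len(n) * step
  tr <- tibble::tibble(
    frame = seq_len(n),
    head_x = x, head_y = rep(3, n),
    trunk_x = x - 0.4, trunk_y = rep(3, n),
    tail_x = x - 0.8, tail_y = rep(3, n)
  )
  attr(tr, "fps") <- fps
  tr
}

# Gaussian class blobs standing in for windowed features: fast fixtures for
# the classifier harness (class separation `sep` in SD units).
labeled_gaussians <- function(n_per_class = 60, p = 10, sep = 4, seed = 1,
                              classes = behavior_levels(5)) {
  withr::with_seed(seed, {
    purrr::imap_dfr(setNames(seq_along(classes), classes), function(i, cls) {
      centers <- rep(0, p)
      centers[((i - 1) %% p) + 1] <- sep
      centers[(i %% p) + 1] <- -sep
      m <- matrix(rnorm(n_per_class * p), n_per_class, p)
      m <- sweep(m, 2, centers, "+")
      colnames(m) <- paste0("f", seq_len(p))
      out <- tibble::as_tibble(m)
      out$behavior <- cls
      out
    })
  })
}

# Cohort summaries with two exactly-placed points (no noise).
exact_summary <- function(freeze, evade, fish_id = NULL) {
  tibble::tibble(
    fish_id = fish_id %||% sprintf("f%02d", seq_along(freeze)),
    pct_freezing = freeze,
    pct_evasion = evade,
    pct_evasion_active = ifelse(freeze >= 100, 0, 100 * evade / (100 - freeze))
  )
}

# Data matrix with an exact sample Pearson correlation `r` between two
# columns (Gram-Schmidt construction).
exact_corr_pair <- function(n, r, seed = 1) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    y0 <- rnorm(n)
    x <- as.numeric(scale(x))
    e <- as.numeric(scale(resid(lm(y0 ~ x))))
    y <- r * x + sqrt(1 - r^2) * e
    cbind(a = x, b = y)
  })
}
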