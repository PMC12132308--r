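#' Per-frame kinematic primitives of a pose track
#'
#' Computes, for each frame, the instantaneous kinematics underlying the
#' windowed feature bank: speed of each of the three body points (cm/s),
#' trunk acceleration (cm/s^2), heading of the head-trunk axis (deg),
#' absolute heading change (deg/s), body-bend angle at the trunk (deg; 180 =
#' collinear), absolute bend-angle change (deg/s), and the head-trunk and
#' trunk-tail distances (cm).  First-frame derivatives use the forward
#' difference so every frame has a defined value.
#'
#' Frames where head and trunk coincide have an undefined heading and bend
#' angle; these are linearly interpolated from neighboring frames and a
#' warning is issued.
#'
#' @param track Data frame with columns `head_x`, `head_y`, `trunk_x`,
#'   `trunk_y`, `tail_x`, `tail_y`, e.g. from [simulate_track()] or
#'   [read_pose_csv()].
#' @param fps Frames per second; defaults to the track's `fps` attribute,
#'   else 60.
#' @return Tibble with one row per frame: `frame`, `speed_head`,
#'   `speed_trunk`, `speed_tail`, `accel`, `heading`, `heading_change`,
#'   `bend_angle`, `bend_change`, `dist_head_trunk`, `dist_trunk_tail`.
#' @export
pose_primitives <- function(track, fps = NULL) {
  need <- c("head_x", "head_y", "trunk_x", "trunk_y", "tail_x", "tail_y")
  check_that(all(need %in% names(track)),
             paste0("`track` is missing columns: ",
                    paste(setdiff(need, names(track)), collapse = ", ")))
  n <- nrow(track)
  check_that(n >= 2, "Need at least 2 frames to compute kinematics.")
  fps <- fps %||% attr(track, "fps") %||% 60

  spd <- function(x, y) {
    d <- sqrt(diff(x)^2 + diff(y)^2) * fps
    c(d[1], d)  # forward difference for the first frame
  }
  speed_head <- spd(track$head_x, track$head_y)
  speed_trunk <- spd(track$trunk_x, track$trunk_y)
  speed_tail <- spd(track$tail_x, track$tail_y)
  accel <- c(diff(speed_trunk)[1], diff(speed_trunk)) * fps

  hx <- track$head_x - track$trunk_x
  hy <- track$head_y - track$trunk_y
  deg <- atan2(hy, hx) * 180 / pi
  degenerate <- hx == 0 & hy == 0
  if (any(degenerate)) {
    warn(paste0("Coincident head/trunk in ", sum(degenerate),
                " frame(s); heading and bend angle interpolated."))
    deg[degenerate] <- NA_real_
  }

  # angular difference folded to (-180, 180]
  ang_diff <- function(a) {
    d <- diff(a)
    d <- ((d + 180) %% 360) - 180
    c(d[1], d)
  }

  tx <- track$tail_x - track$trunk_x
  ty <- track$tail_y - track$trunk_y
  # bend angle: angle at the trunk between the trunk->head and trunk->tail rays
  dotp <- hx * tx + hy * ty
  nh <- sqrt(hx^2 + hy^2); nt <- sqrt(tx^2 + ty^2)
  bend <- acos(pmin(pmax(dotp / (nh * nt), -1), 1)) * 180 / pi
  bend[degenerate | nt == 0] <- NA_real_

  interp <- function(v) {
    if (!anyNA(v)) return(v)
    ok <- which(!is.na(v))
    check_that(length(ok) >= 1, "All frames degenerate; cannot interpolate.")
    stats::approx(ok, v[ok], xout = seq_along(v), rule = 2)$y
  }
  deg <- interp(deg)
  bend <- interp(bend)

  tibble::tibble(
    frame = if ("frame" %in% names(track)) track$frame else seq_len(n),
    speed_head = speed_head,
    speed_trunk = speed_trunk,
    speed_tail = speed_tail,
    accel = accel,
    heading = deg,
    heading_change = abs(ang_diff(deg)) * fps,
    bend_angle = bend,
    bend_change = abs(ang_diff(bend)) * fps,
    dist_head_trunk = nh,
    dist_trunk_tail = nt
  )
}

#' Default windowed feature bank
#'
#' Nine translation-invariant primitives crossed with four windowed statistics
#' (mean, SD, max, min), minus the two near-constant segment-length minima,
#' for 34 features in total.  Fully configurable: pass any primitive/statistic
#' table with logical columns `mean`, `sd`, `max`, `min`.
#'
#' @return Tibble with columns `primitive`, `mean`, `sd`, `max`, `min`.
#' @export
default_feature_bank <- function() {
  prim <- c("speed_head", "speed_trunk", "speed_tail", "accel",
            "heading_change", "bend_angle", "bend_change",
            "dist_head_trunk", "dist_trunk_tail")
  bank <- tibble::tibble(primitive = prim, mean = TRUE, sd = TRUE,
                         max = TRUE, min = TRUE)
  bank$min[bank$primitive %in% c("dist_head_trunk", "dist_trunk_tail")] <- FALSE
  bank
}

# Rolling statistic over a centered (or trailing) window, truncated at the
# edges so every frame gets a value.  Matches a brute-force per-frame
# recomputation exactly.
roll_stat <- function(x, window, stat = c("mean", "sd", "max", "min"),
                      centered = TRUE) {
  stat <- match.arg(stat)
  n <- length(x)
  if (centered) {
    lo <- pmax(seq_len(n) - (window - 1L) %/% 2L, 1L)
    hi <- pmin(seq_len(n) + window %/% 2L, n)
  } else {
    lo <- pmax(seq_len(n) - window + 1L, 1L)
    hi <- seq_len(n)
  }
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  wsum <- cs[hi] - c(0, cs)[lo]
  wsum2 <- cs2[hi] - c(0, cs2)[lo]
  m <- hi - lo + 1L
  switch(stat,
    mean = wsum / m,
    sd = {
      v <- (wsum2 - wsum^2 / m) / pmax(m - 1L, 1L)
      out <- sqrt(pmax(v, 0))
      out[m < 2] <- 0
      out
    },
    max = vapply(seq_len(n), function(i) max(x[lo[i]:hi[i]]), numeric(1)),
    min = vapply(seq_len(n), function(i) min(x[lo[i]:hi[i]]), numeric(1))
  )
}

#' Extract the windowed kinematic feature matrix from a pose track
#'
#' Computes the per-frame primitives ([pose_primitives()]) and, for each, the
#' windowed statistics configured in the feature bank over a sliding window of
#' `window` frames (default 45, i.e. 750 ms at 60 fps) centered on each frame.
#' Edge frames use truncated windows so every frame is classifiable.  The
#' default bank yields 34 features.
#'
#' @param track Pose track data frame (see [pose_primitives()]).
#' @param window Window length in frames (>= 3); default 45.
#' @param bank Feature bank table; default [default_feature_bank()].
#' @param fps Frames per second (default from the track attribute, else 60).
#' @param centered Centered windows (default) or trailing when `FALSE`.
#' @return Tibble with `frame` plus one column per feature, named
#'   `<primitive>_<stat>`; attributes `feature_names`, `window`, `fps`.
#' @export
extract_features <- function(track, window = 45, bank = default_feature_bank(),
                             fps = NULL, centered = TRUE) {
  check_that(is.numeric(window) && window >= 3, "`window` must be >= 3 frames.")
  window <- as.integer(window)
  check_that(nrow(track) >= window,
             "Track must be at least as long as the window.")
  fps <- fps %||% attr(track, "fps") %||% 60
  prim <- pose_primitives(track, fps = fps)

  cols <- list()
  for (i in seq_len(nrow(bank))) {
    p <- bank$primitive[i]
    check_that(p %in% names(prim), paste0("Unknown primitive: ", p))
    for (s in c("mean", "sd", "max", "min")) {
      if (isTRUE(bank[[s]][i])) {
        cols[[paste0(p, "_", s)]] <-
          roll_stat(prim[[p]], window, s, centered = centered)
      }
    }
  }
  out <- tibble::as_tibble(c(list(frame = prim$frame), cols))
  attr(out, "feature_names") <- names(cols)
  attr(out, "window") <- window
  attr(out, "fps") <- fps
  out
}

# Names of the feature columns of a feature tibble (everything but frame and
# any label/metadata column).
feature_cols <- function(features) {
  fn <- attr(features, "feature_names")
  if (!is.null(fn)) return(intersect(fn, names(features)))
  setdiff(names(features), c("frame", "behavior", "fish_id", "stage"))
}
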