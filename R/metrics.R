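#' Summarize a behavior sequence into the three clustering behaviors
#'
#' Computes % freezing, % evasion, and % evasion as a proportion of active
#' (non-freezing) time from a per-frame behavior sequence (five-state labels
#' are collapsed first).  When every frame is freezing the active-time
#' proportion is undefined and reported as 0 with `evasion_active_defined =
#' FALSE`.  When the table has grouping columns (`fish_id`, `stage`), one row
#' is returned per group.
#'
#' @param seq_df Data frame with a `behavior` column; optional `fish_id` and
#'   `stage` columns group the output.
#' @param na_rm Drop frames with missing labels (default TRUE; an all-missing
#'   sequence is an error).
#' @return Tibble with `pct_freezing`, `pct_evasion`, `pct_evasion_active`,
#'   `pct_normal`, `n_frames`, `evasion_active_defined`, plus any grouping
#'   columns.
#' @export
#' @examples
#' s <- tibble::tibble(behavior = rep(c("freeze", "burst", "straight"),
#'                                    c(50, 25, 25)))
#' summarize_behavior(s)
summarize_behavior <- function(seq_df, na_rm = TRUE) {
  check_that(is.data.frame(seq_df) && "behavior" %in% names(seq_df),
             "`seq_df` must be a data frame with a `behavior` column.")
  check_that(nrow(seq_df) > 0, "Empty behavior sequence.")
  keys <- intersect(c("fish_id", "stage"), names(seq_df))

  one <- function(b) {
    b <- collapse_labels(b)
    if (na_rm) b <- b[!is.na(b)]
    check_that(length(b) > 0, "Behavior sequence has no usable (non-missing) frames.")
    n <- length(b)
    fr <- sum(b == "freezing"); ev <- sum(b == "evasive")
    active <- n - fr
    tibble::tibble(
      pct_freezing = 100 * fr / n,
      pct_evasion = 100 * ev / n,
      pct_evasion_active = if (active > 0) 100 * ev / active else 0,
      pct_normal = 100 * sum(b == "normal") / n,
      n_frames = n,
      evasion_active_defined = active > 0
    )
  }

  if (length(keys) == 0) return(one(seq_df$behavior))
  seq_df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::reframe(one(.data$behavior)) |>
    tibble::as_tibble()
}

#' Per-fish behavioral difference scores between stages
#'
#' Subtracts the reference-stage (typically pre-exposure) percentages from a
#' later stage's, per fish.  Fish present in only one table are reported in a
#' warning and skipped.
#'
#' @param summary_stage,summary_pre Behavioral summary tibbles with `fish_id`
#'   and the three percentage columns.
#' @return Tibble with `fish_id` and `delta_pct_freezing`,
#'   `delta_pct_evasion`, `delta_pct_evasion_active`.
#' @export
difference_scores <- function(summary_stage, summary_pre) {
  vars <- c("pct_freezing", "pct_evasion", "pct_evasion_active")
  for (d in list(summary_stage, summary_pre)) {
    check_that(all(c("fish_id", vars) %in% names(d)),
               "Summaries need fish_id and the three percentage columns.")
  }
  unmatched <- c(setdiff(summary_stage$fish_id, summary_pre$fish_id),
                 setdiff(summary_pre$fish_id, summary_stage$fish_id))
  if (length(unmatched) > 0) {
    warn(paste0("Skipping fish present in only one stage: ",
                paste(unique(unmatched), collapse = ", ")))
  }
  dplyr::inner_join(
    dplyr::select(summary_stage, "fish_id", dplyr::all_of(vars)),
    dplyr::select(summary_pre, "fish_id", dplyr::all_of(vars)),
    by = "fish_id", suffix = c("", "_pre")
  ) |>
    dplyr::transmute(
      fish_id = .data$fish_id,
      delta_pct_freezing = .data$pct_freezing - .data$pct_freezing_pre,
      delta_pct_evasion = .data$pct_evasion - .data$pct_evasion_pre,
      delta_pct_evasion_active = .data$pct_evasion_active - .data$pct_evasion_active_pre
    )
}

#' Binned time profile of behavior proportions across fish
#'
#' Bins each fish's sequence into `bin_seconds` bins, computes per-fish
#' per-bin behavior proportions, and returns the across-fish mean with a
#' t-based 95% confidence interval per bin and behavior.  With a single fish
#' the CI is undefined (`NA`).
#'
#' @param seq_df Data frame with `fish_id`, `frame`, `behavior` (any state
#'   set; collapsed to three states).
#' @param bin_seconds Bin width in seconds.
#' @param fps Frames per second (default 60).
#' @param conf Confidence level (default 0.95).
#' @return Tibble with `bin`, `time_s`, `behavior`, `mean`, `ci_lo`, `ci_hi`,
#'   `n_fish`.
#' @export
time_profile <- function(seq_df, bin_seconds, fps = 60, conf = 0.95) {
  check_that(all(c("fish_id", "frame", "behavior") %in% names(seq_df)),
             "`seq_df` needs fish_id, frame and behavior columns.")
  n_frames <- max(seq_df$frame)
  check_that(bin_seconds * fps <= n_frames,
             "Bin is longer than the trial.")
  df <- seq_df
  df$behavior <- collapse_labels(df$behavior)
  df$bin <- floor((df$frame - 1) / (bin_seconds * fps)) + 1
  per_fish <- df |>
    dplyr::filter(!is.na(.data$behavior)) |>
    dplyr::count(.data$fish_id, .data$bin, .data$behavior, .drop = FALSE) |>
    dplyr::group_by(.data$fish_id, .data$bin) |>
    dplyr::mutate(prop = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  alpha <- 1 - conf
  per_fish |>
    dplyr::group_by(.data$bin, .data$behavior) |>
    dplyr::summarise(
      n_fish = dplyr::n(),
      m = mean(.data$prop),
      se = ifelse(dplyr::n() > 1, sd(.data$prop) / sqrt(dplyr::n()), NA_real_),
      .groups = "drop"
    ) |>
    dplyr::transmute(
      bin = .data$bin,
      time_s = (.data$bin - 0.5) * bin_seconds,
      behavior = .data$behavior,
      mean = .data$m,
      ci_lo = .data$m - qt(1 - alpha / 2, .data$n_fish - 1) * .data$se,
      ci_hi = .data$m + qt(1 - alpha / 2, .data$n_fish - 1) * .data$se,
      n_fish = .data$n_fish
    )
}

#' Frame-to-frame behavioral transition matrix
#'
#' Counts transitions between consecutive frames (self-transitions included;
#' freezing's stability shows up as a heavy diagonal), pooled across fish but
#' never across trial boundaries, and row-normalizes to frequencies.  A
#' bout-level variant that first compresses consecutive runs is available via
#' `bouts = TRUE`.
#'
#' @param seq_df Data frame with `behavior` and optionally `fish_id` (one
#'   trial per fish).
#' @param states 5 (raw) or 3 (collapsed) states.
#' @param bouts Compress consecutive runs before counting (drops
#'   self-transitions); default FALSE.
#' @return Object of class `transition_matrix`: tidy tibble with `from`,
#'   `to`, `n`, `prob`; attributes `counts` and `probs` (matrices),
#'   `n_transitions`.
#' @export
transition_matrix <- function(seq_df, states = 5, bouts = FALSE) {
  check_that(is.data.frame(seq_df) && "behavior" %in% names(seq_df),
             "`seq_df` must have a `behavior` column.")
  lv <- if (states == 3) behavior_levels(3) else behavior_levels(5)
  if (bouts) {
    groups0 <- if ("fish_id" %in% names(seq_df)) {
      split(as.character(seq_df$behavior), seq_df$fish_id)
    } else list(as.character(seq_df$behavior))
    runs <- lapply(groups0, function(b) rle(b[!is.na(b)])$values)
    return(transition_matrix(
      tibble::tibble(fish_id = rep(seq_along(runs), lengths(runs)),
                     behavior = unlist(runs)),
      states = states, bouts = FALSE))
  }
  b_all <- as.character(seq_df$behavior)
  if (states == 3) b_all <- as.character(collapse_labels(b_all))
  extra <- setdiff(unique(b_all[!is.na(b_all)]), lv)
  if (length(extra) > 0) lv <- c(lv, extra)  # tolerate custom state sets
  counts <- matrix(0L, length(lv), length(lv), dimnames = list(lv, lv))
  groups <- if ("fish_id" %in% names(seq_df)) {
    split(b_all, seq_df$fish_id)
  } else list(b_all)
  for (b in groups) {
    b <- b[!is.na(b)]
    if (length(b) < 2) next
    from <- factor(b[-length(b)], levels = lv)
    to <- factor(b[-1], levels = lv)
    counts <- counts + table(from, to)
  }
  counts <- unclass(counts)
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs == 0, 1, rs)
  if (any(rs == 0)) {
    warn(paste0("State(s) never observed as source: ",
                paste(lv[rs == 0], collapse = ", ")))
  }
  out <- tibble::as_tibble(as.data.frame(as.table(counts),
                                         stringsAsFactors = FALSE))
  names(out) <- c("from", "to", "n")
  out$prob <- probs[cbind(match(out$from, lv), match(out$to, lv))]
  attr(out, "counts") <- counts
  attr(out, "probs") <- probs
  attr(out, "n_transitions") <- sum(counts)
  class(out) <- c("transition_matrix", class(out))
  out
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("Transition matrix (", attr(x, "n_transitions"), " transitions)\n", sep = "")
  print(round(attr(x, "probs"), 3))
  invisible(x)
}

#' Extract the probability or count matrix of a `transition_matrix`
#'
#' @param x A `transition_matrix`.
#' @param what `"probs"` (default) or `"counts"`.
#' @return A labeled matrix.
#' @export
as_matrix <- function(x, what = c("probs", "counts")) {
  check_that(inherits(x, "transition_matrix"), "`x` must be a transition_matrix.")
  attr(x, match.arg(what))
}

#' Compare behavioral measures between groups
#'
#' Welch two-sample t-tests between two groups (e.g. CAS vs vehicle) or
#' one-sample t-tests of difference scores against zero, per response
#' variable.
#'
#' @param data Data frame of per-fish measures.
#' @param vars Character vector of response columns.
#' @param group Grouping column name (two levels) for the two-sample test;
#'   ignored for one-sample tests.
#' @param test `"welch"` (default) or `"one_sample"`.
#' @param mu Null value for the one-sample test (default 0).
#' @return Tibble with `variable`, `estimate` (mean difference or mean),
#'   `statistic`, `df`, `p_value`, `conf_lo`, `conf_hi`.
#' @export
compare_groups <- function(data, vars, group = NULL,
                           test = c("welch", "one_sample"), mu = 0) {
  test <- match.arg(test)
  purrr::map_dfr(vars, function(v) {
    check_that(v %in% names(data), paste0("Column not found: ", v))
    x <- data[[v]]
    if (test == "welch") {
      check_that(!is.null(group) && group %in% names(data),
                 "Two-sample test needs a `group` column.")
      g <- factor(data[[group]])
      check_that(nlevels(g) == 2, "Grouping column must have exactly 2 levels.")
      if (all(tapply(x, g, sd) == 0)) {
        # zero variance in both groups: t undefined, flagged as NA
        return(tibble::tibble(variable = v,
                              estimate = unname(-diff(tapply(x, g, mean))),
                              statistic = NA_real_, df = NA_real_,
                              p_value = NA_real_,
                              conf_lo = NA_real_, conf_hi = NA_real_))
      }
      tt <- t.test(x ~ g)
      tibble::tibble(variable = v,
                     estimate = unname(diff(rev(tt$estimate))),
                     statistic = unname(tt$statistic),
                     df = unname(tt$parameter), p_value = tt$p.value,
                     conf_lo = tt$conf.int[1], conf_hi = tt$conf.int[2])
    } else {
      if (sd(x) == 0) {
        return(tibble::tibble(variable = v, estimate = mean(x) - mu,
                              statistic = if (mean(x) == mu) 0 else NA_real_,
                              df = length(x) - 1,
                              p_value = if (mean(x) == mu) 1 else NA_real_,
                              conf_lo = NA_real_, conf_hi = NA_real_))
      }
      tt <- t.test(x, mu = mu)
      tibble::tibble(variable = v, estimate = unname(tt$estimate) - mu,
                     statistic = unname(tt$statistic),
                     df = unname(tt$parameter), p_value = tt$p.value,
                     conf_lo = tt$conf.int[1], conf_hi = tt$conf.int[2])
    }
  })
}
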