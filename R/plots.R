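#' Heatmap of a behavioral transition matrix
#'
#' @param object A `transition_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot transition_matrix
#' @export
autoplot.transition_matrix <- function(object, ...) {
  df <- tibble::as_tibble(object)
  lv <- rownames(attr(object, "probs"))
  df$from <- factor(df$from, levels = rev(lv))
  df$to <- factor(df$to, levels = lv)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$prob)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$prob)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "destination", y = "source", fill = "P") +
    ggplot2::theme_minimal()
}

#' Behavior-proportion time profiles with confidence ribbons
#'
#' @param profile Output of [time_profile()].
#' @return A ggplot with per-behavior mean lines and 95% CI ribbons.
#' @export
plot_time_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$time_s, y = .data$mean,
                                        color = .data$behavior,
                                        fill = .data$behavior)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         alpha = 0.25, color = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "% of frames") +
    ggplot2::theme_minimal()
}

#' Behavioral-space scatter of a cluster model
#'
#' @param object A `cluster_model`.
#' @param ... Unused.
#' @return A ggplot of the standardized freezing and evasion axes colored by
#'   cluster.
#' @method autoplot cluster_model
#' @export
autoplot.cluster_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z_freezing, y = .data$z_evasion,
                                   color = .data$cluster_name)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "freezing (z)", y = "evasion (z)", color = "cluster") +
    ggplot2::theme_minimal()
}

#' Behavioral saliences of a PLS result
#'
#' @param object A `pls_result`.
#' @param lvs Latent variables to show (default the first two).
#' @param ... Unused.
#' @return A ggplot bar chart of behavior saliences per latent variable.
#' @method autoplot pls_result
#' @export
autoplot.pls_result <- function(object, lvs = 1:2, ...) {
  df <- tidy(object)
  df <- df[df$block == "behavior" & df$lv %in% lvs, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$salience)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::facet_wrap(~lv, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "behavioral salience") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Bootstrap-ratio profile of PLS brain saliences
#'
#' @param pls A `pls_result` with bootstrap ratios.
#' @param lv Latent variable (default 1).
#' @param threshold Reporting threshold line (default 2.5).
#' @return A ggplot of per-region bootstrap ratios.
#' @export
plot_bootstrap_ratios <- function(pls, lv = 1, threshold = 2.5) {
  check_that(!is.null(pls$bootstrap_ratios), "Run fit_behavioral_pls() first.")
  br <- pls$bootstrap_ratios[, lv]
  df <- tibble::tibble(region = names(br), ratio = as.numeric(br))
  df$region <- factor(df$region, levels = df$region[order(df$ratio)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$ratio)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = c(-threshold, threshold),
                        linetype = "dashed", color = "#b2182b") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = sprintf("bootstrap ratio (LV%d)", lv)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
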