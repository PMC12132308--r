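#' Stratified train/test split of labeled feature frames
#'
#' Splits a labeled feature table into train and test sets, stratified by
#' class so the 80/20 design holds within every behavior.
#'
#' @param features Data frame of features plus a label column.
#' @param label_col Name of the label column (default `"behavior"`).
#' @param train_fraction Fraction of each class used for training
#'   (default 0.8).
#' @param seed Integer seed; the split is reproducible.
#' @return List with tibbles `train` and `test`.
#' @export
split_train_test <- function(features, label_col = "behavior",
                             train_fraction = 0.8, seed = NULL) {
  check_that(label_col %in% names(features),
             paste0("Label column `", label_col, "` not found."))
  check_that(train_fraction > 0 && train_fraction <= 1,
             "`train_fraction` must be in (0, 1].")
  labs <- as.character(features[[label_col]])
  tab <- table(labs)
  if (any(tab < 2)) {
    abort(paste0("Class(es) with fewer than 2 instances: ",
                 paste(names(tab)[tab < 2], collapse = ", ")),
          class = "fearfish_validation_error")
  }
  idx <- with_seed_(seed, {
    unlist(lapply(split(seq_along(labs), labs), function(ii) {
      sample(ii, size = round(length(ii) * train_fraction))
    }), use.names = FALSE)
  })
  if (length(idx) == nrow(features)) {
    warn("`train_fraction` leaves an empty test set.")
  }
  list(train = tibble::as_tibble(features[sort(idx), , drop = FALSE]),
       test = tibble::as_tibble(features[setdiff(seq_len(nrow(features)), idx), ,
                                         drop = FALSE]))
}

# Internal: feature matrix + factor labels from a labeled feature tibble.
xy_from_features <- function(features, label_col = "behavior",
                             feature_names = NULL) {
  fc <- feature_names %||% setdiff(feature_cols(features), label_col)
  missing <- setdiff(fc, names(features))
  if (length(missing) > 0) {
    abort(paste0("Missing feature column(s): ", paste(missing, collapse = ", ")),
          class = "fearfish_validation_error")
  }
  x <- as.matrix(features[, fc, drop = FALSE])
  y <- if (label_col %in% names(features)) {
    factor(as.character(features[[label_col]]),
           levels = intersect(behavior_levels(5),
                              unique(as.character(features[[label_col]]))))
  } else NULL
  if (!is.null(y) && anyNA(y)) {
    y <- factor(as.character(features[[label_col]]))
  }
  list(x = x, y = y, feature_names = fc)
}

#' Fit the behavior random forest
#'
#' Trains a random forest mapping windowed kinematic features to the
#' five-behavior ethogram.  Defaults follow the tuned published harness:
#' 2,000 trees and 10 variables per tree; use [tune_forest()] to re-derive
#' them on new data via the out-of-bag (OOB) error grid.
#'
#' @param train Labeled feature tibble (label column `behavior`).
#' @param n_trees Number of trees (default 2000).
#' @param mtry Variables tried at each split (default 10).
#' @param seed Integer seed.
#' @param label_col Label column name.
#' @return Object of class `behavior_forest`: the fitted forest, feature
#'   names, class labels, and OOB error.
#' @export
fit_forest <- function(train, n_trees = 2000, mtry = 10, seed = NULL,
                       label_col = "behavior") {
  d <- xy_from_features(train, label_col)
  check_that(!is.null(d$y), "Training data needs a label column.")
  check_that(mtry <= ncol(d$x),
             paste0("`mtry` (", mtry, ") exceeds the number of features (",
                    ncol(d$x), ")."))
  fit <- with_seed_(seed, {
    randomForest::randomForest(x = d$x, y = droplevels(d$y),
                               ntree = n_trees, mtry = mtry)
  })
  structure(
    list(forest = fit, feature_names = d$feature_names,
         class_labels = levels(droplevels(d$y)),
         n_trees = n_trees, mtry = mtry,
         oob_error = unname(fit$err.rate[n_trees, "OOB"])),
    class = "behavior_forest"
  )
}

#' @export
print.behavior_forest <- function(x, ...) {
  cat("Behavior random forest:", x$n_trees, "trees,", x$mtry,
      "variables/tree\n")
  cat("Classes:", paste(x$class_labels, collapse = ", "), "\n")
  cat(sprintf("OOB error: %.2f%%\n", 100 * x$oob_error))
  invisible(x)
}

#' Tune forest size and variables per tree by OOB error
#'
#' Evaluates every (n_trees, mtry) cell of the grid, recording the out-of-bag
#' error, and returns the full grid with the argmin attached.  Ties are broken
#' toward fewer variables per tree, then fewer trees.
#'
#' @param train Labeled feature tibble.
#' @param trees_grid Integer vector of forest sizes.
#' @param mtry_grid Integer vector of variables per tree (the published
#'   harness scanned 1-15).
#' @param seed Integer seed.
#' @param label_col Label column name.
#' @return Tibble with columns `n_trees`, `mtry`, `oob_error`, `best`
#'   (logical); attribute `best` holds the winning row.
#' @export
tune_forest <- function(train, trees_grid = c(500, 1000, 2000),
                        mtry_grid = 1:15, seed = NULL,
                        label_col = "behavior") {
  check_that(length(trees_grid) >= 1 && length(mtry_grid) >= 1,
             "Tuning grids must be non-empty.")
  d <- xy_from_features(train, label_col)
  check_that(max(mtry_grid) <= ncol(d$x),
             paste0("mtry grid exceeds the feature count (", ncol(d$x), ")."))
  grid <- tidyr::expand_grid(n_trees = sort(unique(as.integer(trees_grid))),
                             mtry = sort(unique(as.integer(mtry_grid))))
  # one forest per mtry at the largest size; smaller sizes read off the
  # cumulative OOB error curve
  res <- with_seed_(seed, {
    purrr::map(sort(unique(grid$mtry)), function(m) {
      fit <- randomForest::randomForest(x = d$x, y = droplevels(d$y),
                                        ntree = max(grid$n_trees), mtry = m)
      tibble::tibble(mtry = m,
                     n_trees = sort(unique(grid$n_trees)),
                     oob_error = unname(fit$err.rate[sort(unique(grid$n_trees)),
                                                     "OOB"]))
    })
  })
  out <- dplyr::arrange(dplyr::bind_rows(res), .data$n_trees, .data$mtry)
  best_i <- order(out$oob_error, out$mtry, out$n_trees)[1]
  out$best <- seq_len(nrow(out)) == best_i
  attr(out, "best") <- out[best_i, ]
  out
}

#' Evaluate a fitted behavior forest on held-out frames
#'
#' @param model `behavior_forest` object.
#' @param test Labeled feature tibble with the same feature names.
#' @param label_col Label column name.
#' @return Object of class `behavior_confusion`: true x predicted count
#'   matrix, per-class and overall accuracy, and the most-confused label
#'   pairs.
#' @export
evaluate_classifier <- function(model, test, label_col = "behavior") {
  check_that(inherits(model, "behavior_forest"), "`model` must be a behavior_forest.")
  d <- xy_from_features(test, label_col, feature_names = model$feature_names)
  check_that(!is.null(d$y), "Test data needs a label column.")
  pred <- stats::predict(model$forest, d$x)
  lv <- model$class_labels
  cm <- table(true = factor(as.character(d$y), levels = lv),
              predicted = factor(as.character(pred), levels = lv))
  per_class <- diag(cm) / pmax(rowSums(cm), 1)
  off <- as.data.frame(cm, stringsAsFactors = FALSE)
  off <- off[off$true != off$predicted & off$Freq > 0, ]
  off <- off[order(-off$Freq), ]
  structure(
    list(confusion = cm,
         per_class_accuracy = per_class,
         overall_accuracy = sum(diag(cm)) / sum(cm),
         confused_pairs = tibble::as_tibble(off)),
    class = "behavior_confusion"
  )
}

#' @export
print.behavior_confusion <- function(x, ...) {
  cat(sprintf("Overall accuracy: %.1f%%\n", 100 * x$overall_accuracy))
  print(x$confusion)
  invisible(x)
}

#' Predict a per-frame behavior sequence
#'
#' Applies a fitted forest to a feature tibble, returning one hard label per
#' frame.  Frames with non-finite features are labeled `NA` and excluded from
#' downstream summaries.  Optional modal smoothing replaces each label by the
#' mode of a centered window (off by default, matching the published
#' analysis).
#'
#' @param model `behavior_forest` object.
#' @param features Feature tibble (no label column required).
#' @param smooth_window Odd window length for modal smoothing; `NULL`/0 for
#'   none.
#' @return Tibble with columns `frame` and `behavior`.
#' @export
predict_sequence <- function(model, features, smooth_window = NULL) {
  check_that(inherits(model, "behavior_forest"), "`model` must be a behavior_forest.")
  if (nrow(features) == 0) {
    return(tibble::tibble(frame = integer(),
                          behavior = factor(character(),
                                            levels = model$class_labels)))
  }
  d <- xy_from_features(features, label_col = "..none..",
                        feature_names = model$feature_names)
  ok <- rowSums(!is.finite(d$x)) == 0
  pred <- rep(NA_character_, nrow(d$x))
  if (any(ok)) {
    pred[ok] <- as.character(stats::predict(model$forest, d$x[ok, , drop = FALSE]))
  }
  if (!is.null(smooth_window) && smooth_window > 1) {
    half <- (as.integer(smooth_window) - 1L) %/% 2L
    sm <- vapply(seq_along(pred), function(i) {
      w <- pred[max(1, i - half):min(length(pred), i + half)]
      w <- w[!is.na(w)]
      if (length(w) == 0) NA_character_ else names(sort(table(w), decreasing = TRUE))[1]
    }, character(1))
    pred <- sm
  }
  tibble::tibble(
    frame = if ("frame" %in% names(features)) features$frame else seq_along(pred),
    behavior = factor(pred, levels = model$class_labels)
  )
}

#' @rdname tidy.behavior_confusion
#' @method glance behavior_forest
#' @export
glance.behavior_forest <- function(x, ...) {
  tibble::tibble(n_trees = x$n_trees, mtry = x$mtry, oob_error = x$oob_error,
                 n_classes = length(x$class_labels))
}

#' Tidiers for classifier results
#'
#' `tidy()` on a `behavior_confusion` returns the confusion matrix in long
#' form; `glance()` on a `behavior_forest` returns the one-row model summary.
#'
#' @param x A `behavior_confusion` or `behavior_forest` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy behavior_confusion
#' @export
tidy.behavior_confusion <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$confusion, stringsAsFactors = FALSE))
  names(out) <- c("true", "predicted", "n")
  out
}

#' @rdname tidy.behavior_confusion
#' @method glance behavior_confusion
#' @export
glance.behavior_confusion <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(overall_accuracy = x$overall_accuracy),
    tibble::as_tibble(as.list(setNames(x$per_class_accuracy,
                                       paste0("acc_", names(x$per_class_accuracy)))))
  )
}
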