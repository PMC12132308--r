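behavior_vars <- c("pct_freezing", "pct_evasion", "pct_evasion_active")

#' Standardize behavioral summaries
#'
#' Z-scores the three clustering behaviors (% freezing, % evasion, % evasion
#' of active time).  When `params` is supplied (from a previous
#' standardization, e.g. the reference clustering) its means and SDs are
#' applied unchanged, which is how new fish are projected into the reference
#' behavioral space.
#'
#' @param summaries Data frame with the three percentage columns (plus any
#'   metadata, carried through).
#' @param params Optional parameter table (`variable`, `mean`, `sd`) from a
#'   previous call (stored in its `params` attribute).
#' @return Tibble with `z_freezing`, `z_evasion`, `z_evasion_active` plus the
#'   input's metadata columns; attribute `params`.
#' @export
standardize_behavior <- function(summaries, params = NULL) {
  check_that(all(behavior_vars %in% names(summaries)),
             paste0("`summaries` must contain: ",
                    paste(behavior_vars, collapse = ", ")))
  if (is.null(params)) {
    params <- tibble::tibble(
      variable = behavior_vars,
      mean = vapply(behavior_vars, function(v) mean(summaries[[v]]), numeric(1)),
      sd = vapply(behavior_vars, function(v) sd(summaries[[v]]), numeric(1))
    )
    if (any(params$sd == 0)) {
      abort(paste0("Zero SD in: ",
                   paste(params$variable[params$sd == 0], collapse = ", ")),
            class = "fearfish_validation_error")
    }
  }
  z <- purrr::map2_dfc(behavior_vars,
                       c("z_freezing", "z_evasion", "z_evasion_active"),
                       function(v, nm) {
    p <- params[params$variable == v, ]
    tibble::tibble(!!nm := as.numeric((summaries[[v]] - p$mean) / p$sd))
  })
  meta <- summaries[, setdiff(names(summaries), behavior_vars), drop = FALSE]
  out <- dplyr::bind_cols(tibble::as_tibble(meta), z)
  attr(out, "params") <- params
  out
}

#' Similarity score between fish in behavioral space
#'
#' `similarity_score(d)` converts a Euclidean distance `D` in standardized
#' three-dimensional behavior space into the similarity `1 / (1 + D)`, which
#' lies in (0, 1] and equals 1 exactly when the fish coincide.
#' `similarity_matrix()` applies it pairwise to a coordinate table.
#'
#' @param d Non-negative distance(s).
#' @return Similarity value(s) in (0, 1].
#' @export
#' @examples
#' similarity_score(c(0, 1, 3))  # 1, 0.5, 0.25
similarity_score <- function(d) {
  check_that(all(is.finite(d)) && all(d >= 0),
             "Distances must be finite and non-negative.")
  1 / (1 + d)
}

#' @rdname similarity_score
#' @param coords Data frame or matrix of standardized coordinates (only
#'   `z_*` columns are used from data frames).
#' @export
similarity_matrix <- function(coords) {
  x <- coords_matrix(coords)
  similarity_score(as.matrix(stats::dist(x)))
}

# Coordinate matrix from a standardized tibble (z_* columns) or matrix.
coords_matrix <- function(coords) {
  if (is.matrix(coords)) {
    x <- coords
  } else {
    zc <- grep("^z_", names(coords), value = TRUE)
    check_that(length(zc) >= 1,
               "No z_* coordinate columns found; run standardize_behavior() first.")
    x <- as.matrix(coords[, zc, drop = FALSE])
    if ("fish_id" %in% names(coords)) rownames(x) <- coords$fish_id
  }
  check_that(all(is.finite(x)), "Coordinates must be finite.")
  x
}

#' Build the k-nearest-neighbor similarity network
#'
#' Links every fish to its `k` most similar neighbors (highest similarity
#' score, i.e. smallest Euclidean distance in standardized behavior space),
#' then symmetrizes the directed relation by union into an unweighted,
#' undirected graph.  Distance ties are broken deterministically by row
#' order.
#'
#' @param coords Standardized coordinate table or matrix.
#' @param k Number of neighbors (0 < k < number of fish).
#' @return Undirected `igraph` graph with vertex names.
#' @export
knn_graph <- function(coords, k) {
  x <- coords_matrix(coords)
  n <- nrow(x)
  check_that(k >= 1 && k < n, "`k` must satisfy 1 <= k < n.")
  d <- as.matrix(stats::dist(x))
  nbr <- t(vapply(seq_len(n), function(i) {
    # ties broken by index order; self excluded
    ord <- order(d[i, ], seq_len(n))
    ord <- ord[ord != i]
    ord[seq_len(k)]
  }, integer(k)))
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nbr)))
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::V(g)$name <- rownames(x) %||% as.character(seq_len(n))
  g
}

#' Louvain community detection on a similarity network
#'
#' @param graph Undirected `igraph` graph.
#' @param seed Integer seed (community detection is run under it for
#'   reproducibility).
#' @return Tibble with `node` and `cluster` (integer communities); attribute
#'   `modularity`.
#' @export
louvain_partition <- function(graph, seed = NULL) {
  check_that(inherits(graph, "igraph") && igraph::vcount(graph) > 0,
             "`graph` must be a non-empty igraph graph.")
  cl <- with_seed_(seed %||% 0L, igraph::cluster_louvain(graph))
  out <- tibble::tibble(
    node = igraph::V(graph)$name %||% as.character(seq_len(igraph::vcount(graph))),
    cluster = as.integer(igraph::membership(cl))
  )
  attr(out, "modularity") <- max(igraph::modularity(cl))
  out
}

#' Internal cluster validation indices
#'
#' Calinski-Harabasz (between/within variance ratio; higher is better),
#' mean silhouette width (higher is better), and Davies-Bouldin (mean of the
#' worst-case cluster-pair scatter-to-separation ratio; lower is better).
#' With fewer than two clusters the indices are undefined and returned as
#' `NA`.
#'
#' @param coords Standardized coordinate table or matrix.
#' @param labels Cluster labels, one per row.
#' @return Tibble with columns `metric`, `value`, `higher_better`.
#' @export
internal_metrics <- function(coords, labels) {
  x <- coords_matrix(coords)
  check_that(length(labels) == nrow(x), "One label per coordinate row required.")
  f <- factor(labels)
  k <- nlevels(f)
  n <- nrow(x)
  if (k < 2 || k >= n) {
    warn("Internal metrics undefined for fewer than 2 clusters (or k >= n).")
    return(tibble::tibble(metric = c("calinski_harabasz", "silhouette", "davies_bouldin"),
                          value = NA_real_,
                          higher_better = c(TRUE, TRUE, FALSE)))
  }
  centroids <- apply(x, 2, function(col) tapply(col, f, mean))
  overall <- colMeans(x)
  sizes <- as.integer(table(f))
  B <- sum(sizes * rowSums((centroids - matrix(overall, k, ncol(x), byrow = TRUE))^2))
  W <- sum((x - centroids[as.integer(f), , drop = FALSE])^2)
  ch <- (B / (k - 1)) / (W / (n - k))

  sil <- mean(cluster::silhouette(as.integer(f), stats::dist(x))[, "sil_width"])

  scatter <- vapply(seq_len(k), function(i) {
    mean(sqrt(rowSums((x[as.integer(f) == i, , drop = FALSE] -
                         matrix(centroids[i, ], sizes[i], ncol(x), byrow = TRUE))^2)))
  }, numeric(1))
  cd <- as.matrix(stats::dist(centroids))
  db <- mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      (scatter[i] + scatter[j]) / cd[i, j]
    }, numeric(1)))
  }, numeric(1)))

  tibble::tibble(metric = c("calinski_harabasz", "silhouette", "davies_bouldin"),
                 value = c(ch, sil, db),
                 higher_better = c(TRUE, TRUE, FALSE))
}

#' Select the neighbor count k for clustering
#'
#' Runs the k-NN + Louvain procedure across `k_range`, computes the three
#' internal validation indices for each partition, rank-aggregates them
#' (Calinski-Harabasz and silhouette descending, Davies-Bouldin ascending),
#' and picks the midpoint of the widest contiguous plateau of k values whose
#' aggregated score is within a tolerance of the optimum.  The plateau rule
#' operationalizes "best and robust to small changes in k": a k in the middle
#' of a wide near-optimal run is preferred over a lone spike.
#'
#' @param coords Standardized coordinate table or matrix.
#' @param k_range Integer vector of candidate k values (each in (1, n)).
#' @param seed Integer seed.
#' @param tolerance Fraction of the aggregated-score range treated as "as
#'   good as the best" when forming plateaus (default 0.05).
#' @return List with `k` (chosen), `curves` (tibble: k, n_clusters,
#'   modularity, calinski_harabasz, silhouette, davies_bouldin, score,
#'   in_plateau).
#' @export
select_k <- function(coords, k_range, seed = NULL, tolerance = 0.05) {
  x <- coords_matrix(coords)
  check_that(length(k_range) >= 1, "`k_range` must be non-empty.")
  k_range <- sort(unique(as.integer(k_range)))
  check_that(all(k_range > 1 & k_range < nrow(x)),
             "All k must lie strictly between 1 and n.")
  rows <- purrr::map_dfr(k_range, function(k) {
    g <- knn_graph(x, k)
    part <- louvain_partition(g, seed = seed)
    m <- internal_metrics(x, part$cluster)
    tibble::tibble(k = k,
                   n_clusters = length(unique(part$cluster)),
                   modularity = attr(part, "modularity"),
                   calinski_harabasz = m$value[1],
                   silhouette = m$value[2],
                   davies_bouldin = m$value[3])
  })
  valid <- !is.na(rows$silhouette)
  check_that(any(valid), "No k produced a valid (>= 2 cluster) partition.")
  rk <- function(v, desc) {
    r <- rank(if (desc) -v else v, na.last = "keep")
    r[is.na(r)] <- length(v)
    r
  }
  score <- (rk(rows$calinski_harabasz, TRUE) + rk(rows$silhouette, TRUE) +
              rk(rows$davies_bouldin, FALSE)) / 3
  rows$score <- score
  tol <- min(score) + tolerance * max(diff(range(score)), 1e-12)
  good <- score <= tol & valid
  # widest contiguous run of near-optimal k
  r <- rle(good)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  widths <- ends[runs] - starts[runs] + 1
  span <- rows$k[ends[runs]] - rows$k[starts[runs]]
  pick <- runs[order(-span, -widths)[1]]
  plateau_idx <- starts[pick]:ends[pick]
  rows$in_plateau <- seq_len(nrow(rows)) %in% plateau_idx
  chosen <- rows$k[plateau_idx[ceiling(length(plateau_idx) / 2)]]
  list(k = chosen, curves = rows)
}

# Name four clusters by centroid rank on the freezing and evasion axes:
# the two low-freezing clusters split into non-reactive (lower evasion) and
# evader; the two high-freezing ones into freezer and evading freezer.
# Other cluster counts get generic names.
name_clusters <- function(coords, clusters) {
  x <- coords_matrix(coords)
  ids <- sort(unique(clusters))
  if (length(ids) != 4) {
    return(setNames(paste0("cluster_", ids), ids))
  }
  cf <- as.numeric(tapply(x[, "z_freezing"], factor(clusters, levels = ids), mean))
  ce <- as.numeric(tapply(x[, "z_evasion"], factor(clusters, levels = ids), mean))
  low <- order(cf)[1:2]; high <- order(cf)[3:4]
  nm <- character(4)
  nm[low[order(ce[low])]] <- c("non_reactive", "evader")
  nm[high[order(ce[high])]] <- c("freezer", "evading_freezer")
  setNames(nm, ids)
}

#' Fit the behavioral cluster model
#'
#' The full reference clustering: standardize the three behaviors, build the
#' k-NN similarity network, partition it with Louvain, and (when four
#' clusters emerge) name them by their centroid position on the freezing and
#' evasion axes (non-reactive, evader, evading freezer, freezer).  If `k` is
#' not given it is chosen by [select_k()] over `k_range`.
#'
#' @param summaries Behavioral summary table (`fish_id` plus the three
#'   percentage columns).
#' @param k Neighbor count; `NULL` to select automatically.
#' @param k_range Candidate k values for selection (default
#'   `seq(10, floor(n/3), by = 4)`).
#' @param seed Integer seed.
#' @return Object of class `cluster_model` with elements `params`, `coords`,
#'   `k`, `graph`, `partition` (tibble `fish_id`, `cluster`,
#'   `cluster_name`), `modularity`, `curves` (when k was selected).
#' @export
fit_behavior_clusters <- function(summaries, k = NULL, k_range = NULL,
                                  seed = NULL) {
  check_that("fish_id" %in% names(summaries), "`summaries` needs a fish_id column.")
  std <- standardize_behavior(summaries)
  x <- coords_matrix(std)
  curves <- NULL
  if (is.null(k)) {
    if (is.null(k_range)) {
      k_range <- seq(10, max(12, floor(nrow(x) / 3)), by = 4)
    }
    sel <- select_k(x, k_range, seed = seed)
    k <- sel$k
    curves <- sel$curves
  }
  g <- knn_graph(x, k)
  part <- louvain_partition(g, seed = seed)
  nms <- name_clusters(x, part$cluster)
  structure(
    list(params = attr(std, "params"),
         coords = x,
         k = k,
         graph = g,
         partition = tibble::tibble(fish_id = part$node,
                                    cluster = part$cluster,
                                    cluster_name = unname(nms[as.character(part$cluster)])),
         modularity = attr(part, "modularity"),
         curves = curves),
    class = "cluster_model"
  )
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("Behavioral cluster model: k =", x$k, ",",
      length(unique(x$partition$cluster)), "clusters, modularity",
      round(x$modularity, 3), "\n")
  print(table(x$partition$cluster_name))
  invisible(x)
}

#' Assign new fish to reference clusters by nearest-neighbor vote
#'
#' Standardizes new behavioral summaries with the reference parameters and
#' gives each fish the majority cluster among its `n_vote` nearest reference
#' fish (33 by default, half the size of the smallest published cluster).
#' Ties go to the cluster of the single nearest neighbor.  A new fish whose
#' `fish_id` matches a reference fish is compared against the other reference
#' fish only (self excluded), so reassigning the reference set is a
#' leave-one-out check.
#'
#' @param new_summaries Behavioral summary table for the fish to assign.
#' @param model `cluster_model` from [fit_behavior_clusters()].
#' @param n_vote Number of reference neighbors voting (default 33).
#' @return Tibble with `fish_id`, `cluster`, `cluster_name`, `n_votes` (votes
#'   for the winning cluster).
#' @export
assign_clusters <- function(new_summaries, model, n_vote = 33) {
  check_that(inherits(model, "cluster_model"), "`model` must be a cluster_model.")
  nref <- nrow(model$coords)
  check_that(n_vote >= 1 && n_vote <= nref - 1,
             paste0("`n_vote` must be between 1 and the reference size minus 1 (",
                    nref - 1, ")."))
  std <- standardize_behavior(new_summaries, params = model$params)
  xnew <- coords_matrix(std)
  ref_ids <- rownames(model$coords)
  ref_cl <- model$partition$cluster[match(ref_ids, model$partition$fish_id)]
  nm_map <- unique(model$partition[, c("cluster", "cluster_name")])
  ids <- if ("fish_id" %in% names(new_summaries)) new_summaries$fish_id else
    paste0("new_", seq_len(nrow(xnew)))

  res <- purrr::map_dfr(seq_len(nrow(xnew)), function(i) {
    d <- sqrt(colSums((t(model$coords) - xnew[i, ])^2))
    if (ids[i] %in% ref_ids) d[ref_ids == ids[i]] <- Inf  # self excluded
    ord <- order(d, seq_along(d))
    votes <- table(ref_cl[ord[seq_len(n_vote)]])
    top <- names(votes)[votes == max(votes)]
    win <- if (length(top) == 1) top else {
      # tie: follow the single nearest neighbor
      as.character(ref_cl[ord[1]])
    }
    tibble::tibble(fish_id = ids[i], cluster = as.integer(win),
                   n_votes = as.integer(votes[win]))
  })
  res$cluster_name <- nm_map$cluster_name[match(res$cluster, nm_map$cluster)]
  res[, c("fish_id", "cluster", "cluster_name", "n_votes")]
}

#' Permutation test of strain/sex representation across clusters
#'
#' For every (stratum, cluster) cell, tests whether the stratum is over- or
#' under-represented in the cluster by permuting cluster labels across fish
#' (resampling without replacement).  The two-sided p-value is the proportion
#' of permutations whose cell count deviates from the expected count at least
#' as much as the observed one (with the +1 finite-sample correction), and
#' Benjamini-Hochberg FDR adjustment is applied across all cells.
#'
#' The cell count is a discrete statistic, so a plain "at least as extreme"
#' p-value is super-uniform (conservative) under the null.  By default ties
#' between permuted and observed deviations are broken by a seeded uniform
#' draw (a randomized p-value), which makes the null distribution of the
#' p-value exactly uniform and the test exactly calibrated; set
#' `tie_smoothing = FALSE` for the conservative step-function p-value.
#'
#' @param data Data frame with one row per fish.
#' @param cluster_col Cluster label column (default `"cluster"`).
#' @param strata_cols Columns crossed into strata (default
#'   `c("strain", "sex")`).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param tie_smoothing Randomize ties for exact calibration (default TRUE).
#' @return Tibble with `stratum`, `cluster`, `observed`, `expected`,
#'   `p_value`, `p_adj`.
#' @export
representation_test <- function(data, cluster_col = "cluster",
                                strata_cols = c("strain", "sex"),
                                n_perm = 10000, seed = NULL,
                                tie_smoothing = TRUE) {
  check_that(all(c(cluster_col, strata_cols) %in% names(data)),
             "Cluster and strata columns must be present.")
  check_that(n_perm >= 100, "`n_perm` must be at least 100.")
  strat <- interaction(data[, strata_cols, drop = FALSE], sep = ":", drop = TRUE)
  empty <- levels(strat)[table(strat) == 0]
  if (length(empty) > 0) warn(paste0("Empty strata skipped: ", paste(empty, collapse = ", ")))
  cl <- factor(data[[cluster_col]])
  n <- length(cl)
  S <- nlevels(strat); K <- nlevels(cl)
  si <- as.integer(strat); ci <- as.integer(cl)
  ncell <- S * K
  cell <- function(c_idx) tabulate((si - 1L) * K + c_idx, nbins = ncell)
  obs <- cell(ci)
  expected <- as.vector(outer(tabulate(si, S), tabulate(ci, K)) / n)
  dev_obs <- abs(obs - expected)
  greater <- integer(ncell)
  ties <- integer(ncell)
  p <- with_seed_(seed, {
    for (b in seq_len(n_perm)) {
      dev <- abs(cell(ci[sample.int(n)]) - expected)
      greater <- greater + (dev > dev_obs + 1e-12)
      ties <- ties + (abs(dev - dev_obs) <= 1e-12)
    }
    if (tie_smoothing) {
      # randomized rank among the B+1 exchangeable values: exactly uniform
      # under the null despite the discrete count statistic
      (greater + runif(ncell) * (ties + 1)) / (1 + n_perm)
    } else {
      (1 + greater + ties) / (1 + n_perm)
    }
  })
  out <- tibble::tibble(
    stratum = rep(levels(strat), each = K),
    cluster = rep(levels(cl), S),
    observed = obs,
    expected = expected,
    p_value = p
  )
  out$p_adj <- p.adjust(out$p_value, method = "BH")
  out
}

#' Tidiers for cluster models
#'
#' `tidy()` returns the per-fish partition with standardized coordinates;
#' `glance()` the one-row model summary (k, cluster count, modularity,
#' cluster sizes).
#'
#' @param x A `cluster_model`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy cluster_model
#' @export
tidy.cluster_model <- function(x, ...) {
  dplyr::bind_cols(
    x$partition,
    tibble::as_tibble(x$coords[match(x$partition$fish_id, rownames(x$coords)), ,
                               drop = FALSE])
  )
}

#' @rdname tidy.cluster_model
#' @method glance cluster_model
#' @export
glance.cluster_model <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n_fish = nrow(x$coords),
    n_clusters = length(unique(x$partition$cluster)),
    modularity = x$modularity,
    min_cluster_size = min(table(x$partition$cluster))
  )
}
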