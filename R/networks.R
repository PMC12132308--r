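#' Regional correlation network for one experimental group
#'
#' Pairwise Pearson correlations of regional cfos counts across the fish of
#' one group.  Constant regions are dropped with a warning; fewer than four
#' fish is an error.  The fish-by-region data are retained inside the object
#' so bootstrap operations ([matrix_similarity()]) can resample fish.
#'
#' @param counts Data frame with `fish_id` and region columns (one group's
#'   fish), e.g. a filtered [normalize_counts()] output.
#' @param group Group label attached to the network.
#' @param region_cols Region columns; default auto-detected.
#' @return Object of class `corr_network`: `r` (region x region matrix),
#'   `n_fish`, `group`, `data`; thresholding slots filled by
#'   [threshold_fdr()] / [edge_confidence_intervals()].
#' @export
correlation_network <- function(counts, group = "group", region_cols = NULL) {
  region_cols <- region_cols %||% region_cols_of(counts)
  m <- as.matrix(counts[, region_cols, drop = FALSE])
  check_that(nrow(m) >= 4, "Need at least 4 fish to build a correlation network.")
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    warn(paste0("Dropping constant region(s): ",
                paste(colnames(m)[sds == 0], collapse = ", ")))
    m <- m[, sds > 0, drop = FALSE]
  }
  structure(
    list(r = cor(m), n_fish = nrow(m), group = group, data = m,
         p = NULL, p_adj = NULL, adjacency = NULL, ci = NULL,
         alpha = NULL, n_effective = NULL),
    class = "corr_network"
  )
}

#' @export
print.corr_network <- function(x, ...) {
  cat("Correlation network `", x$group, "`: ", ncol(x$r), " regions, ",
      x$n_fish, " fish", sep = "")
  if (!is.null(x$adjacency)) {
    cat("; ", sum(x$adjacency[upper.tri(x$adjacency)]),
        " suprathreshold edges (FDR < ", x$alpha, ", n_eff = ",
        x$n_effective, ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

# Two-sided p-value of a Pearson r at a given n via the t transform.
r_to_p <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(t, df = n - 2, lower.tail = FALSE)
}

#' Threshold a correlation network by FDR
#'
#' Computes a two-sided p-value for each unique region pair from
#' `t = r sqrt((n_eff - 2) / (1 - r^2))`, adjusts with Benjamini-Hochberg
#' across all pairs, and keeps edges with adjusted p below `alpha`.  The
#' effective n defaults to the network's own fish count but is normally set
#' to the smallest group size across the compared networks, a conservative
#' correction that stops the edge count from simply tracking group size.
#'
#' @param network `corr_network` object.
#' @param alpha FDR threshold (default 0.001).
#' @param n_effective Effective sample size for p-values (default the
#'   network's own `n_fish`; >= 4).
#' @return The network with `p`, `p_adj`, `adjacency` (logical matrix),
#'   `alpha`, `n_effective` filled in.
#' @export
threshold_fdr <- function(network, alpha = 0.001, n_effective = NULL) {
  check_that(inherits(network, "corr_network"), "`network` must be a corr_network.")
  n_eff <- n_effective %||% network$n_fish
  check_that(n_eff >= 4, "`n_effective` must be at least 4.")
  r <- network$r
  p <- r_to_p(r, n_eff)
  diag(p) <- NA
  ut <- upper.tri(r)
  padj <- matrix(NA_real_, nrow(r), ncol(r), dimnames = dimnames(r))
  padj[ut] <- p.adjust(p[ut], method = "BH")
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  adj <- !is.na(padj) & padj < alpha
  network$p <- p
  network$p_adj <- padj
  network$adjacency <- adj
  network$alpha <- alpha
  network$n_effective <- n_eff
  network
}

#' Fisher-z confidence intervals for network edges
#'
#' 95% (by default) confidence intervals for each pairwise correlation using
#' the Fisher transform, `tanh(atanh(r) +/- z * 1/sqrt(n - 3))`, at the
#' network's own sample size.  Perfect correlations give a degenerate CI and
#' are flagged with a warning.
#'
#' @param network `corr_network` object.
#' @param conf Confidence level (default 0.95).
#' @return The network with a `ci` element: list of matrices `lo` and `hi`.
#' @export
edge_confidence_intervals <- function(network, conf = 0.95) {
  check_that(inherits(network, "corr_network"), "`network` must be a corr_network.")
  n <- network$n_fish
  check_that(n >= 4, "Need n >= 4 for Fisher-z intervals.")
  r <- network$r
  if (any(abs(r[upper.tri(r)]) >= 1)) {
    warn("Edges with |r| = 1 have degenerate confidence intervals.")
  }
  z <- atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15))
  zc <- stats::qnorm(1 - (1 - conf) / 2)
  half <- zc / sqrt(n - 3)
  network$ci <- list(lo = tanh(z - half), hi = tanh(z + half))
  network$conf <- conf
  network
}

# Ensure a network has thresholding and CIs, using defaults if absent.
prep_network <- function(net, alpha = 0.001, n_effective = NULL) {
  if (is.null(net$adjacency)) net <- threshold_fdr(net, alpha, n_effective)
  if (is.null(net$ci)) net <- edge_confidence_intervals(net)
  net
}

#' Classify a network's suprathreshold edges as unique or shared
#'
#' An edge of the target network is `unique` when it survives the FDR
#' threshold and its confidence interval overlaps the corresponding
#' interval of none of the other networks; otherwise it is `shared`.
#' Asymmetric by construction: uniqueness is a property of the target.
#'
#' @param target `corr_network` (thresholded; CIs computed on demand).
#' @param others A `corr_network` or list of them, on the same region set.
#' @param alpha,n_effective Passed to [threshold_fdr()] when the target has
#'   not been thresholded yet.
#' @return Tibble of the target's suprathreshold edges: `region_a`,
#'   `region_b`, `r`, `p_adj`, `ci_lo`, `ci_hi`, `status`
#'   (`"unique"`/`"shared"`).
#' @export
unique_edges <- function(target, others, alpha = 0.001, n_effective = NULL) {
  if (inherits(others, "corr_network")) others <- list(others)
  target <- prep_network(target, alpha, n_effective)
  others <- lapply(others, function(o) {
    mismatch <- c(setdiff(colnames(target$r), colnames(o$r)),
                  setdiff(colnames(o$r), colnames(target$r)))
    if (length(mismatch) > 0) {
      abort(paste0("Region sets differ; symmetric difference: ",
                   paste(unique(mismatch), collapse = ", ")),
            class = "fearfish_validation_error")
    }
    o <- if (is.null(o$ci)) edge_confidence_intervals(o) else o
    # align region order to the target
    ord <- match(colnames(target$r), colnames(o$r))
    o$ci$lo <- o$ci$lo[ord, ord]
    o$ci$hi <- o$ci$hi[ord, ord]
    o
  })
  ut <- which(upper.tri(target$r) & target$adjacency, arr.ind = TRUE)
  if (nrow(ut) == 0) {
    return(tibble::tibble(region_a = character(), region_b = character(),
                          r = numeric(), p_adj = numeric(), ci_lo = numeric(),
                          ci_hi = numeric(), status = character()))
  }
  lo <- target$ci$lo[ut]; hi <- target$ci$hi[ut]
  no_overlap <- rep(TRUE, nrow(ut))
  for (o in others) {
    olo <- o$ci$lo[ut]; ohi <- o$ci$hi[ut]
    no_overlap <- no_overlap & (lo > ohi | hi < olo)
  }
  tibble::tibble(
    region_a = colnames(target$r)[ut[, 1]],
    region_b = colnames(target$r)[ut[, 2]],
    r = target$r[ut],
    p_adj = target$p_adj[ut],
    ci_lo = lo, ci_hi = hi,
    status = ifelse(no_overlap, "unique", "shared")
  )
}

#' Degree and relative degree between two thresholded networks
#'
#' Per-region suprathreshold-edge counts in each network and the relative
#' degree score `(d_a - d_b) / (d_a + d_b)`, which is +1 for regions
#' connected only in network `a`, -1 for only `b`, 0 for balanced, and
#' undefined (`NA`) when the region is isolated in both.  A reporting filter
#' at the published thresholds (|score| > 0.5 and degree > 12) is available
#' via `filter_hubs = TRUE`.
#'
#' @param net_a,net_b Thresholded `corr_network` objects on the same region
#'   set (network `a` plays the role of the freezer network in the published
#'   contrast).
#' @param filter_hubs Keep only regions with |score| > `score_min` and
#'   max degree > `degree_min`.
#' @param score_min,degree_min Reporting thresholds (defaults 0.5 and 12).
#' @return Tibble with `region`, `degree_a`, `degree_b`, `relative_degree`.
#' @export
relative_degree <- function(net_a, net_b, filter_hubs = FALSE,
                            score_min = 0.5, degree_min = 12) {
  net_a <- prep_network(net_a); net_b <- prep_network(net_b)
  check_that(identical(sort(colnames(net_a$r)), sort(colnames(net_b$r))),
             "Networks must share the same region set.")
  regions <- colnames(net_a$r)
  da <- unname(rowSums(net_a$adjacency)[regions])
  db <- unname(rowSums(net_b$adjacency)[regions])
  score <- ifelse(da + db > 0, (da - db) / (da + db), NA_real_)
  out <- tibble::tibble(region = regions, degree_a = as.integer(da),
                        degree_b = as.integer(db), relative_degree = score)
  if (filter_hubs) {
    out <- dplyr::filter(out, abs(.data$relative_degree) > score_min,
                         pmax(.data$degree_a, .data$degree_b) > degree_min)
  }
  out
}

#' Similarity of two correlation matrices with a bootstrap CI
#'
#' Pearson correlation between the vectorized lower triangles of two group
#' correlation matrices, with a percentile confidence interval obtained by
#' resampling fish with replacement within each group and recomputing both
#' matrices.
#'
#' @param net_a,net_b `corr_network` objects (carrying their fish-level
#'   data).
#' @param n_boot Bootstrap replicates (default 1000; < 100 warns).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return Tibble with `r`, `ci_lo`, `ci_hi`, `n_boot`.
#' @export
matrix_similarity <- function(net_a, net_b, n_boot = 1000, conf = 0.95,
                              seed = NULL) {
  check_that(inherits(net_a, "corr_network") && inherits(net_b, "corr_network"),
             "Both inputs must be corr_network objects.")
  common <- intersect(colnames(net_a$r), colnames(net_b$r))
  check_that(length(common) >= 3, "Networks share too few regions.")
  if (n_boot < 100) warn("`n_boot` below 100 gives unstable intervals.")
  lt <- lower.tri(matrix(0, length(common), length(common)))
  vec <- function(m) m[common, common][lt]
  r_obs <- cor(vec(net_a$r), vec(net_b$r))
  boots <- with_seed_(seed, {
    vapply(seq_len(n_boot), function(b) {
      ia <- sample.int(nrow(net_a$data), replace = TRUE)
      ib <- sample.int(nrow(net_b$data), replace = TRUE)
      ra <- suppressWarnings(cor(net_a$data[ia, common, drop = FALSE]))
      rb <- suppressWarnings(cor(net_b$data[ib, common, drop = FALSE]))
      v <- cbind(ra[lt], rb[lt])
      v <- v[complete.cases(v), , drop = FALSE]
      cor(v[, 1], v[, 2])
    }, numeric(1))
  })
  qs <- quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
  tibble::tibble(r = r_obs, ci_lo = qs[1], ci_hi = qs[2], n_boot = n_boot)
}

#' Modularity-optimizing partition of a thresholded network
#'
#' Louvain community detection on the suprathreshold adjacency, returning
#' the partition that optimizes modularity.
#'
#' @param network Thresholded `corr_network`, or a logical/0-1 adjacency
#'   matrix.
#' @param seed Integer seed.
#' @return Tibble with `region` and `community`; attribute `modularity`.
#' @export
modularity_partition <- function(network, seed = NULL) {
  adj <- if (inherits(network, "corr_network")) {
    check_that(!is.null(network$adjacency), "Threshold the network first.")
    network$adjacency
  } else network
  check_that(is.matrix(adj) && nrow(adj) > 0, "Adjacency must be a non-empty matrix.")
  g <- igraph::graph_from_adjacency_matrix(adj * 1, mode = "undirected",
                                           diag = FALSE)
  part <- louvain_partition(g, seed = seed)
  out <- tibble::tibble(region = part$node, community = part$cluster)
  attr(out, "modularity") <- attr(part, "modularity")
  out
}

#' Export a thresholded network for graph tools
#'
#' Writes the suprathreshold edges (with r, adjusted p, CI bounds and the
#' unique/shared flag) as an edge-list CSV and, optionally, GraphML for
#' Cytoscape-style rendering.
#'
#' @param target Thresholded `corr_network`.
#' @param others Other networks for the unique/shared classification (may be
#'   an empty list, in which case all edges are `shared`).
#' @param path Output CSV path.
#' @param graphml_path Optional GraphML output path.
#' @return The edge tibble, invisibly.
#' @export
write_network_edges <- function(target, others = list(), path,
                                graphml_path = NULL) {
  edges <- if (length(others) > 0) unique_edges(target, others) else {
    e <- unique_edges(target, list(target))
    e$status <- "shared"
    e
  }
  readr::write_csv(edges, path)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(
      edges[, c("region_a", "region_b", "r", "p_adj", "ci_lo", "ci_hi", "status")],
      directed = FALSE,
      vertices = data.frame(name = colnames(target$r)))
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(edges)
}
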