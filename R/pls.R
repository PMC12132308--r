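#' Cohort-median normalization of regional cell counts
#'
#' Corrects batch-to-batch brightness differences by rescaling every fish's
#' counts by the ratio of the global median per-fish total count to its
#' cohort's median per-fish total count.  After normalization all cohorts
#' share the same median total, so a second application is a no-op.
#'
#' @param counts Data frame with `fish_id`, `cohort`, and one numeric column
#'   per region.
#' @param region_cols Region column names; default everything numeric except
#'   metadata.
#' @return Tibble of the same shape with scaled counts; attribute
#'   `scale_factors` (per-cohort tibble).
#' @export
normalize_counts <- function(counts, region_cols = NULL) {
  check_that(all(c("fish_id", "cohort") %in% names(counts)),
             "`counts` needs fish_id and cohort columns.")
  region_cols <- region_cols %||% region_cols_of(counts)
  totals <- rowSums(counts[, region_cols, drop = FALSE])
  coh <- as.character(counts$cohort)
  med_by <- tapply(totals, coh, median)
  check_that(all(med_by > 0), "Cohort median total count is zero.")
  global <- median(totals)
  fac <- global / med_by
  out <- counts
  out[, region_cols] <- counts[, region_cols, drop = FALSE] * fac[coh]
  out <- tibble::as_tibble(out)
  attr(out, "scale_factors") <- tibble::tibble(cohort = names(fac),
                                               factor = unname(fac))
  out
}

# Region columns: numeric columns that are not recognised metadata.
region_cols_of <- function(counts) {
  meta <- c("fish_id", "group", "cohort", "strain", "sex", "stage", "treatment",
            "cluster", "cluster_name")
  nm <- setdiff(names(counts), meta)
  nm[vapply(counts[nm], is.numeric, logical(1))]
}

#' Behavioral summary table to PLS behavior block
#'
#' Returns the four behaviors used for brain-behavior covariation: % normal
#' swimming, % freezing, % evasion, and % evasion while active.
#'
#' @param summaries Behavioral summary table.
#' @return Tibble with the four behavior columns (normal derived as
#'   `100 - freezing - evasion` when absent).
#' @export
behavior_block <- function(summaries) {
  check_that(all(behavior_vars %in% names(summaries)),
             "Summaries must contain the three percentage columns.")
  tibble::tibble(
    pct_normal = if ("pct_normal" %in% names(summaries)) summaries$pct_normal
                 else 100 - summaries$pct_freezing - summaries$pct_evasion,
    pct_freezing = summaries$pct_freezing,
    pct_evasion = summaries$pct_evasion,
    pct_evasion_active = summaries$pct_evasion_active
  )
}

# Column-standardize a numeric matrix, erroring on constant columns.
scale_block <- function(m, what) {
  m <- as.matrix(m)
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("Constant column(s) in ", what, ": ",
                 paste(colnames(m)[sds == 0], collapse = ", ")),
          class = "fearfish_validation_error")
  }
  scale(m)
}

#' Behavioral PLS: SVD of the behavior-brain correlation matrix
#'
#' Mean-centered behavioral PLS correlation for a single group: the
#' behaviors-by-regions matrix of Pearson correlations `R` is decomposed as
#' `R = U S V'`.  Columns of `U` are the behavioral saliences (one contrast
#' per latent variable), columns of `V` the brain-region saliences, and the
#' singular values order the latent variables by the cross-block covariance
#' they explain.  The sign of each latent variable is fixed by making its
#' largest-magnitude behavioral salience positive.
#'
#' @param brain Fish x regions table or matrix of normalized counts.
#' @param behavior Fish x behaviors table or matrix (same fish order), e.g.
#'   from [behavior_block()].
#' @return Object of class `pls_result` with `singular_values`,
#'   `behavior_saliences`, `brain_saliences`, `correlations` (the R matrix),
#'   and `n_fish`; inference slots are filled by [fit_behavioral_pls()].
#' @export
behavioral_pls <- function(brain, behavior) {
  Xb <- as.matrix(if (is.data.frame(brain)) brain[, region_cols_of(brain), drop = FALSE] else brain)
  Yb <- as.matrix(behavior)
  check_that(nrow(Xb) == nrow(Yb), "Brain and behavior blocks must have the same fish.")
  check_that(nrow(Xb) >= 3, "Need at least 3 fish.")
  Xs <- scale_block(Xb, "brain block")
  Ys <- scale_block(Yb, "behavior block")
  n <- nrow(Xs)
  R <- crossprod(Ys, Xs) / (n - 1)  # behaviors x regions Pearson correlations
  sv <- svd(R)
  # deterministic sign: largest |behavioral salience| positive per LV
  for (j in seq_along(sv$d)) {
    i <- which.max(abs(sv$u[, j]))
    if (sv$u[i, j] < 0) {
      sv$u[, j] <- -sv$u[, j]
      sv$v[, j] <- -sv$v[, j]
    }
  }
  dimnames(sv$u) <- list(colnames(Yb), paste0("LV", seq_along(sv$d)))
  dimnames(sv$v) <- list(colnames(Xb), paste0("LV", seq_along(sv$d)))
  structure(
    list(singular_values = sv$d,
         behavior_saliences = sv$u,
         brain_saliences = sv$v,
         correlations = R,
         n_fish = n,
         permutation_p = NULL,
         bootstrap_ratios = NULL),
    class = "pls_result"
  )
}

#' Permutation test for PLS latent variables
#'
#' Permutes whole rows of the behavior block relative to the brain block
#' (resampling without replacement), recomputes the singular values, and
#' reports for each latent variable
#' `p = (1 + #(permuted s_k >= observed s_k)) / (1 + n_perm)`.
#'
#' @param brain,behavior As in [behavioral_pls()].
#' @param n_perm Number of permutations (>= 100; default 10000).
#' @param seed Integer seed.
#' @return Numeric vector of p-values, one per latent variable.
#' @export
pls_permutation <- function(brain, behavior, n_perm = 10000, seed = NULL) {
  check_that(n_perm >= 100, "`n_perm` must be at least 100.")
  Xb <- as.matrix(if (is.data.frame(brain)) brain[, region_cols_of(brain), drop = FALSE] else brain)
  Yb <- as.matrix(behavior)
  Xs <- scale_block(Xb, "brain block")
  Ys <- scale_block(Yb, "behavior block")
  n <- nrow(Xs)
  d_obs <- svd(crossprod(Ys, Xs) / (n - 1), nu = 0, nv = 0)$d
  L <- length(d_obs)
  exceed <- integer(L)
  with_seed_(seed, {
    for (b in seq_len(n_perm)) {
      dp <- svd(crossprod(Ys[sample.int(n), , drop = FALSE], Xs) / (n - 1),
                nu = 0, nv = 0)$d
      exceed <- exceed + (dp >= d_obs - 1e-12)
    }
  })
  (1 + exceed) / (1 + n_perm)
}

#' Bootstrap ratios for PLS brain saliences
#'
#' Resamples fish with replacement, recomputes the decomposition, aligns each
#' replicate's latent variables to the original ones (matching by maximal
#' absolute inner product of the brain saliences, then flipping sign), and
#' divides each original salience by its bootstrap standard error.  The
#' resulting ratios behave like z-scores; the published reporting threshold
#' is |ratio| >= 2.5.  Replicates in which a region or behavior becomes
#' constant are redrawn (count reported in the `n_redrawn` attribute).
#'
#' @param brain,behavior As in [behavioral_pls()].
#' @param n_boot Number of bootstrap replicates (>= 100; default 10000).
#' @param seed Integer seed.
#' @return Regions x LV matrix of bootstrap ratios; attributes `se`
#'   (bootstrap SEs) and `n_redrawn`.
#' @export
pls_bootstrap <- function(brain, behavior, n_boot = 10000, seed = NULL) {
  check_that(n_boot >= 100, "`n_boot` must be at least 100.")
  fit <- behavioral_pls(brain, behavior)
  Xb <- as.matrix(if (is.data.frame(brain)) brain[, region_cols_of(brain), drop = FALSE] else brain)
  Yb <- as.matrix(behavior)
  n <- nrow(Xb)
  V0 <- fit$brain_saliences
  L <- ncol(V0)
  acc <- array(NA_real_, dim = c(nrow(V0), L, n_boot))
  n_redrawn <- 0L
  with_seed_(seed, {
    b <- 1L
    while (b <= n_boot) {
      idx <- sample.int(n, replace = TRUE)
      Xr <- Xb[idx, , drop = FALSE]
      Yr <- Yb[idx, , drop = FALSE]
      if (any(apply(Xr, 2, sd) == 0) || any(apply(Yr, 2, sd) == 0)) {
        n_redrawn <- n_redrawn + 1L
        next
      }
      svb <- svd(crossprod(scale(Yr), scale(Xr)) / (n - 1))
      # align replicate LVs to the originals: greedy max |<v_b, v_0>|
      taken <- logical(ncol(svb$v))
      for (j in seq_len(L)) {
        ip <- as.numeric(crossprod(svb$v[, !taken, drop = FALSE], V0[, j]))
        pick_rel <- which.max(abs(ip))
        pick <- which(!taken)[pick_rel]
        acc[, j, b] <- svb$v[, pick] * sign(ip[pick_rel])
        taken[pick] <- TRUE
      }
      b <- b + 1L
    }
  })
  se <- apply(acc, c(1, 2), sd)
  ratios <- ifelse(se > 0, V0 / se, ifelse(V0 == 0, 0, NA_real_))
  dimnames(ratios) <- dimnames(V0)
  attr(ratios, "se") <- se
  attr(ratios, "n_redrawn") <- n_redrawn
  ratios
}

#' Fit behavioral PLS with permutation and bootstrap inference
#'
#' Convenience wrapper running [behavioral_pls()], [pls_permutation()] and
#' [pls_bootstrap()] and returning a single `pls_result` with all inference
#' slots filled.
#'
#' @param brain,behavior As in [behavioral_pls()].
#' @param n_perm,n_boot Resampling sizes (default 10000 each).
#' @param seed Integer seed (both resampling schemes derive from it).
#' @return A `pls_result` with `permutation_p` and `bootstrap_ratios`.
#' @export
fit_behavioral_pls <- function(brain, behavior, n_perm = 10000, n_boot = 10000,
                               seed = NULL) {
  fit <- behavioral_pls(brain, behavior)
  fit$permutation_p <- pls_permutation(brain, behavior, n_perm = n_perm, seed = seed)
  fit$bootstrap_ratios <- pls_bootstrap(brain, behavior, n_boot = n_boot,
                                        seed = if (is.null(seed)) NULL else seed + 1)
  fit
}

#' @export
print.pls_result <- function(x, ...) {
  cat("Behavioral PLS:", length(x$singular_values), "latent variables,",
      x$n_fish, "fish\n")
  df <- data.frame(singular_value = round(x$singular_values, 4))
  if (!is.null(x$permutation_p)) df$p_perm <- signif(x$permutation_p, 3)
  print(df)
  invisible(x)
}

#' Tidiers for PLS results
#'
#' `tidy()` returns the saliences in long form (one row per term and latent
#' variable, with bootstrap ratios when available); `glance()` returns one
#' row per latent variable with its singular value, explained cross-block
#' covariance fraction and permutation p-value.
#'
#' @param x A `pls_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy pls_result
#' @export
tidy.pls_result <- function(x, ...) {
  long <- function(m, block) {
    tibble::tibble(
      block = block,
      term = rep(rownames(m), ncol(m)),
      lv = rep(seq_len(ncol(m)), each = nrow(m)),
      salience = as.vector(m)
    )
  }
  out <- dplyr::bind_rows(long(x$behavior_saliences, "behavior"),
                          long(x$brain_saliences, "brain"))
  if (!is.null(x$bootstrap_ratios)) {
    br <- long(x$bootstrap_ratios, "brain")
    names(br)[names(br) == "salience"] <- "bootstrap_ratio"
    out <- dplyr::left_join(out, br, by = c("block", "term", "lv"))
  }
  out
}

#' @rdname tidy.pls_result
#' @method glance pls_result
#' @export
glance.pls_result <- function(x, ...) {
  tibble::tibble(
    lv = seq_along(x$singular_values),
    singular_value = x$singular_values,
    var_explained = x$singular_values^2 / sum(x$singular_values^2),
    p_perm = if (is.null(x$permutation_p)) NA_real_ else x$permutation_p,
    n_fish = x$n_fish
  )
}
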