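#' Default pipeline configuration
#'
#' All analysis defaults are the published parameters: 45-frame (750 ms)
#' feature window, 80/20 stratified split, 2000-tree / 10-variable forest,
#' 33-neighbor cluster assignment, 10,000 permutations and bootstraps, FDR
#' 0.001 with the smallest group as the conservative effective n.  Synthetic
#' problem sizes (frames per class, fish per group, regions) are configurable
#' so demonstrations can run at any scale.
#'
#' @param ... Named overrides of any default.
#' @return A named list (class `fearfish_config`).
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    out_dir = "fearfish_run",
    stages = c("classifier", "behavior", "cluster", "pls", "network"),
    window = 45,
    fps = 60,
    train_fraction = 0.8,
    n_trees = 2000,
    mtry = 10,
    frames_per_class = 2000,
    n_demo_fish = 6,
    demo_frames = 3000,
    n_fish_per_group = 80,
    k = NULL,
    k_range = NULL,
    n_vote = 33,
    n_perm = 10000,
    n_boot = 10000,
    alpha = 0.001,
    n_regions = 30,
    planted_salience = 1,
    planted_region = 1,
    batch_factors = c(cohort_1 = 1, cohort_2 = 1.3, cohort_3 = 0.8, cohort_4 = 1.1)
  )
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "fearfish_config")
}

log_line <- function(out_dir, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", paste0(...))
  cat(msg, "\n", sep = "")
  cat(msg, "\n", sep = "", file = file.path(out_dir, "run.log"), append = TRUE)
}

#' Run the synthetic end-to-end pipeline
#'
#' Drives every stage of the analysis on synthetic data with known ground
#' truth: (1) classifier -- simulate labeled trajectories, extract windowed
#' features, train and evaluate the behavior forest; (2) behavior -- predict
#' sequences for demo fish, summarize them and compute transition matrices;
#' (3) cluster -- simulate a cohort with planted clusters, fit the
#' similarity/k-NN/Louvain model and test strain/sex representation;
#' (4) pls -- simulate region counts coupled to behavior, normalize by cohort
#' medians, run behavioral PLS with permutation and bootstrap inference;
#' (5) network -- build group correlation networks, threshold at FDR, find
#' unique edges and relative degree.  Every output is written under
#' `config$out_dir` with a provenance sidecar; identical seeds give
#' identical tables.
#'
#' @param config A [default_config()] list, a YAML file path, or a named
#'   list of overrides.
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "fearfish_config")) config <- do.call(default_config, config)
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  seed <- as.integer(cfg$seed)
  enabled <- function(s) s %in% cfg$stages

  if (enabled("classifier")) {
    log_line(cfg$out_dir, "stage classifier: frames_per_class=", cfg$frames_per_class,
             " window=", cfg$window, " n_trees=", cfg$n_trees, " mtry=", cfg$mtry)
    labeled <- purrr::imap_dfr(setNames(nm = behavior_levels(5)), function(b, i) {
      script <- tibble::tibble(frame = seq_len(cfg$frames_per_class), behavior = b)
      track <- simulate_track(script, fps = cfg$fps,
                              seed = seed + 100 + match(b, behavior_levels(5)))
      f <- extract_features(track, window = cfg$window, fps = cfg$fps)
      f$behavior <- b
      f
    })
    sp <- split_train_test(labeled, train_fraction = cfg$train_fraction,
                           seed = seed + 1)
    model <- fit_forest(sp$train, n_trees = cfg$n_trees, mtry = cfg$mtry,
                        seed = seed + 2)
    ev <- evaluate_classifier(model, sp$test)
    write_with_provenance(tidy(ev), file.path(cfg$out_dir, "confusion.csv"),
                          params = cfg[c("seed", "window", "n_trees", "mtry",
                                         "frames_per_class")])
    log_line(cfg$out_dir, sprintf("  oob=%.4f test_acc=%.4f", model$oob_error,
                                  ev$overall_accuracy))
    res$classifier <- list(model = model, evaluation = ev)
  } else log_line(cfg$out_dir, "stage classifier: skipped")

  if (enabled("behavior")) {
    check_that(!is.null(res$classifier), "behavior stage needs the classifier stage.")
    log_line(cfg$out_dir, "stage behavior: n_demo_fish=", cfg$n_demo_fish)
    seqs <- purrr::map_dfr(seq_len(cfg$n_demo_fish), function(i) {
      script <- markov_script(default_transition_matrix(), cfg$demo_frames,
                              seed = seed + 200 + i)
      track <- simulate_track(script, fps = cfg$fps, seed = seed + 300 + i)
      f <- extract_features(track, window = cfg$window, fps = cfg$fps)
      pred <- predict_sequence(res$classifier$model, f)
      pred$fish_id <- sprintf("demo_%02d", i)
      pred
    })
    summaries <- summarize_behavior(seqs)
    tm <- transition_matrix(seqs, states = 5)
    write_with_provenance(summaries, file.path(cfg$out_dir, "summaries.csv"),
                          params = cfg[c("seed", "n_demo_fish", "demo_frames")])
    write_with_provenance(tibble::as_tibble(tm),
                          file.path(cfg$out_dir, "transitions.csv"),
                          params = cfg[c("seed", "n_demo_fish")])
    res$behavior <- list(sequences = seqs, summaries = summaries, transitions = tm)
  } else log_line(cfg$out_dir, "stage behavior: skipped")

  cohort <- simulate_cohort(default_cluster_groups(n_fish = cfg$n_fish_per_group),
                            seed = seed + 400)

  if (enabled("cluster")) {
    log_line(cfg$out_dir, "stage cluster: n=", nrow(cohort), " n_vote=", cfg$n_vote)
    cm <- fit_behavior_clusters(cohort, k = cfg$k, k_range = cfg$k_range,
                                seed = seed + 401)
    rep_test <- representation_test(
      dplyr::left_join(cohort, cm$partition, by = "fish_id"),
      n_perm = min(cfg$n_perm, 2000), seed = seed + 402)
    write_cluster_model(cm, file.path(cfg$out_dir, "cluster_model.json"))
    write_with_provenance(tidy(cm), file.path(cfg$out_dir, "cluster_labels.csv"),
                          params = cfg[c("seed", "k", "n_vote")])
    write_with_provenance(rep_test, file.path(cfg$out_dir, "representation.csv"),
                          params = cfg[c("seed", "n_perm")])
    log_line(cfg$out_dir, "  k=", cm$k, " clusters=",
             length(unique(cm$partition$cluster)))
    res$cluster <- list(model = cm, representation = rep_test)
  } else log_line(cfg$out_dir, "stage cluster: skipped")

  if (enabled("pls") || enabled("network")) {
    regions <- default_regions(cfg$n_regions)
    sal <- rep(0, cfg$n_regions)
    sal[cfg$planted_region] <- cfg$planted_salience
    bf <- cfg$batch_factors[unique(cohort$cohort)]
    bf[is.na(bf)] <- 1
    names(bf) <- unique(cohort$cohort)
    counts <- simulate_region_counts(cohort, regions = regions, salience = sal,
                                     batch_factors = bf, seed = seed + 500)
    norm <- normalize_counts(counts)
  }

  if (enabled("pls")) {
    log_line(cfg$out_dir, "stage pls: n_perm=", cfg$n_perm, " n_boot=", cfg$n_boot)
    pls <- fit_behavioral_pls(norm, behavior_block(cohort),
                              n_perm = cfg$n_perm, n_boot = cfg$n_boot,
                              seed = seed + 501)
    write_with_provenance(tidy(pls), file.path(cfg$out_dir, "pls_saliences.tsv"),
                          params = cfg[c("seed", "n_perm", "n_boot")])
    jsonlite::write_json(
      list(singular_values = pls$singular_values, p_perm = pls$permutation_p),
      file.path(cfg$out_dir, "pls_summary.json"), digits = NA)
    log_line(cfg$out_dir, sprintf("  LV1 p=%.4g", pls$permutation_p[1]))
    res$pls <- pls
  } else log_line(cfg$out_dir, "stage pls: skipped")

  if (enabled("network")) {
    log_line(cfg$out_dir, "stage network: alpha=", cfg$alpha)
    by_group <- split(tibble::as_tibble(norm), cohort$group)
    n_eff <- min(vapply(by_group, nrow, integer(1)))
    nets <- purrr::imap(by_group, function(d, g) {
      prep_network(correlation_network(d, group = g), alpha = cfg$alpha,
                   n_effective = n_eff)
    })
    tg <- if (all(c("freezer", "evading_freezer") %in% names(nets))) {
      c("freezer", "evading_freezer")
    } else names(nets)[1:2]
    edges <- unique_edges(nets[[tg[1]]], nets[names(nets) != tg[1]])
    rd <- relative_degree(nets[[tg[1]]], nets[[tg[2]]])
    sim <- matrix_similarity(nets[[tg[1]]], nets[[tg[2]]],
                             n_boot = min(cfg$n_boot, 1000), seed = seed + 502)
    write_network_edges(nets[[tg[1]]], nets[names(nets) != tg[1]],
                        path = file.path(cfg$out_dir, "network_edges.csv"),
                        graphml_path = file.path(cfg$out_dir, "network.graphml"))
    write_with_provenance(rd, file.path(cfg$out_dir, "relative_degree.csv"),
                          params = cfg[c("seed", "alpha")])
    log_line(cfg$out_dir, "  edges(", tg[1], ")=", nrow(edges),
             " unique=", sum(edges$status == "unique"))
    res$network <- list(networks = nets, edges = edges, relative_degree = rd,
                        similarity = sim)
  } else log_line(cfg$out_dir, "stage network: skipped")

  invisible(res)
}
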