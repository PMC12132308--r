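#' Write and read pose tracks in DeepLabCut CSV layout
#'
#' The DeepLabCut dialect has a three-row header (scorer / bodyparts /
#' coords) above an index column and x, y, likelihood triplets per body
#' part.  `write_pose_csv()` emits that layout for the three-point
#' (head/trunk/tail) rig; `read_pose_csv()` parses it strictly, erroring on
#' malformed headers or missing body parts.
#'
#' @param track Pose track tibble with `head_x` .. `tail_y` columns (and
#'   optional `*_likelihood` columns; missing ones are written as 1).
#' @param path File path.
#' @param scorer Scorer name written into the header.
#' @return `write_pose_csv()` returns `path` invisibly.
#' @export
write_pose_csv <- function(track, path, scorer = "fearfish") {
  parts <- c("head", "trunk", "tail")
  need <- as.vector(outer(parts, c("x", "y"), function(p, c) paste0(p, "_", c)))
  check_that(all(need %in% names(track)),
             paste0("Track is missing: ", paste(setdiff(need, names(track)), collapse = ", ")))
  cols <- list()
  for (p in parts) {
    lik <- track[[paste0(p, "_likelihood")]] %||% rep(1, nrow(track))
    cols[[p]] <- data.frame(track[[paste0(p, "_x")]], track[[paste0(p, "_y")]], lik)
  }
  body <- do.call(cbind, unname(cols))
  hdr1 <- c("scorer", rep(scorer, 9))
  hdr2 <- c("bodyparts", rep(parts, each = 3))
  hdr3 <- c("coords", rep(c("x", "y", "likelihood"), 3))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(hdr1, collapse = ","), paste(hdr2, collapse = ","),
               paste(hdr3, collapse = ",")), con)
  utils::write.table(cbind(seq_len(nrow(track)) - 1L, body), con, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_pose_csv
#' @param fps Frames per second attached to the returned track (not stored in
#'   the CSV dialect itself); default 60.
#' @param min_likelihood Optional threshold: points tracked with lower
#'   likelihood are treated as missing and linearly interpolated (the usual
#'   low-confidence filter; 0.9 is a common choice).
#' @return `read_pose_csv()` returns a `pose_track` tibble.
#' @export
read_pose_csv <- function(path, fps = 60, min_likelihood = NULL) {
  hdr <- readLines(path, n = 3)
  check_that(length(hdr) == 3,
             "Expected a DeepLabCut-style three-row header (scorer/bodyparts/coords).")
  h2 <- strsplit(hdr[2], ",")[[1]]
  h3 <- strsplit(hdr[3], ",")[[1]]
  check_that(identical(tolower(h2[1]), "bodyparts") && identical(tolower(h3[1]), "coords"),
             "Malformed header: expected rows 2 and 3 to start with 'bodyparts' and 'coords'.")
  parts <- h2[-1]; coords <- h3[-1]
  need <- c("head", "trunk", "tail")
  for (p in need) {
    have <- coords[parts == p]
    check_that(all(c("x", "y") %in% have),
               paste0("Body part `", p, "` missing x/y columns in header."))
  }
  dat <- utils::read.csv(path, skip = 3, header = FALSE)
  check_that(ncol(dat) == length(parts) + 1, "Data width does not match the header.")
  out <- tibble::tibble(frame = seq_len(nrow(dat)))
  for (p in need) {
    for (cc in c("x", "y", "likelihood")) {
      j <- which(parts == p & coords == cc)
      if (length(j) == 1) {
        out[[paste0(p, "_", if (cc == "likelihood") "likelihood" else cc)]] <-
          as.numeric(dat[[j + 1]])
      }
    }
  }
  if (!is.null(min_likelihood)) {
    for (p in need) {
      lik <- out[[paste0(p, "_likelihood")]]
      if (is.null(lik)) next
      bad <- lik < min_likelihood
      if (any(bad)) {
        for (cc in c("_x", "_y")) {
          v <- out[[paste0(p, cc)]]
          v[bad] <- NA
          ok <- which(!is.na(v))
          out[[paste0(p, cc)]] <- stats::approx(ok, v[ok], xout = seq_along(v),
                                                rule = 2)$y
        }
      }
    }
  }
  attr(out, "fps") <- fps
  class(out) <- c("pose_track", class(out))
  out
}

#' Write and read regional count tables
#'
#' Tab-separated tables with one row per fish: metadata columns (`fish_id`,
#' `group`, `cohort`) followed by one column per atlas region abbreviation.
#' Reading validates that counts are non-negative numbers.
#'
#' @param counts Count tibble as from [simulate_region_counts()].
#' @param path File path.
#' @return `write_counts_tsv()` returns `path` invisibly; `read_counts_tsv()`
#'   the validated tibble.
#' @export
write_counts_tsv <- function(counts, path) {
  check_that("fish_id" %in% names(counts), "`counts` needs a fish_id column.")
  readr::write_tsv(counts, path)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @param regions Optional character vector to validate region columns
#'   against (unknown columns error).
#' @export
read_counts_tsv <- function(path, regions = NULL) {
  counts <- readr::read_tsv(path, show_col_types = FALSE)
  check_that("fish_id" %in% names(counts), "Counts table must have a fish_id column.")
  rc <- region_cols_of(counts)
  check_that(length(rc) >= 1, "No region columns found.")
  if (!is.null(regions)) {
    unknown <- setdiff(rc, regions)
    check_that(length(unknown) == 0,
               paste0("Unknown region column(s): ", paste(unknown, collapse = ", ")))
  }
  vals <- as.matrix(counts[, rc])
  check_that(all(is.finite(vals)), "Counts contain non-finite values.")
  check_that(all(vals >= 0), "Counts must be non-negative.")
  counts
}

#' Write a table with a provenance sidecar
#'
#' Writes `data` as CSV (or TSV) and a JSON sidecar `<path>.prov.json`
#' recording the generating parameters, seed, package version and timestamp,
#' so every output is reproducible from config plus seeds alone.
#'
#' @param data Data frame.
#' @param path Output path (`.tsv` extension selects tab separation).
#' @param params Named list recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_with_provenance <- function(data, path, params = list()) {
  if (grepl("\\.tsv$", path)) readr::write_tsv(data, path) else readr::write_csv(data, path)
  prov <- list(
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    package = "fearfish",
    version = as.character(utils::packageVersion("fearfish")),
    params = params
  )
  jsonlite::write_json(prov, paste0(path, ".prov.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Serialize and restore a cluster model as JSON
#'
#' Stores the standardization parameters, k, reference coordinates and
#' partition in plain JSON so the reference clustering can be reloaded and
#' used to assign new fish without refitting.
#'
#' @param model `cluster_model`.
#' @param path JSON file path.
#' @return `write_cluster_model()` returns `path` invisibly;
#'   `read_cluster_model()` a `cluster_model` (graph rebuilt from k and the
#'   coordinates).
#' @export
write_cluster_model <- function(model, path) {
  check_that(inherits(model, "cluster_model"), "`model` must be a cluster_model.")
  obj <- list(
    params = model$params,
    k = model$k,
    modularity = model$modularity,
    coords = as.data.frame(cbind(fish_id = rownames(model$coords),
                                 as.data.frame(model$coords))),
    partition = model$partition
  )
  jsonlite::write_json(obj, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cluster_model
#' @export
read_cluster_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cdf <- as.data.frame(obj$coords, stringsAsFactors = FALSE)
  coords <- as.matrix(cdf[, c("z_freezing", "z_evasion", "z_evasion_active")])
  storage.mode(coords) <- "double"
  rownames(coords) <- cdf$fish_id
  structure(
    list(params = tibble::as_tibble(obj$params),
         coords = coords,
         k = obj$k,
         graph = knn_graph(coords, obj$k),
         partition = tibble::as_tibble(obj$partition),
         modularity = obj$modularity,
         curves = NULL),
    class = "cluster_model"
  )
}
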