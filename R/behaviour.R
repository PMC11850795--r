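#' Per-track summaries of distance to a structure
#'
#' Summarises a per-step distance column (e.g. distance to the nearest
#' lymphatic-vessel point from [nearest_structure_distance()]) per track by
#' mean, standard deviation, 95% upper quantile (`qUp`) and 5% lower
#' quantile (`qLow`) — the convention used when structure proximity is fed
#' into behaviour clustering.
#'
#' @param steps a tibble with `track_id` and the distance column.
#' @param distance_col name of the distance column.
#' @return tibble: `track_id`, `dist_mean`, `dist_sd`, `dist_qUp`,
#'   `dist_qLow`.
#' @export
structure_distance_summary <- function(steps, distance_col = "structure_distance") {
  if (!distance_col %in% names(steps)) {
    rlang::abort(sprintf("column `%s` not found", distance_col),
                 class = "celltrax_schema_error")
  }
  steps |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      dist_mean = mean(.data[[distance_col]], na.rm = TRUE),
      dist_sd = ifelse(dplyr::n() > 1, stats::sd(.data[[distance_col]], na.rm = TRUE), 0),
      dist_qUp = stats::quantile(.data[[distance_col]], 0.95, na.rm = TRUE, names = FALSE),
      dist_qLow = stats::quantile(.data[[distance_col]], 0.05, na.rm = TRUE, names = FALSE),
      .groups = "drop"
    )
}

#' Assemble the tracks-by-features behaviour matrix
#'
#' Joins whole-track statistics, HMM state occupancies and observed state
#' transition frequencies (plus optional per-track extras such as
#' structure-distance summaries) into one matrix, one row per track, and
#' z-scores every column. Degenerate columns (standard deviation below
#' machine noise, e.g. with a single track) are scaled with a standard
#' deviation floor of 1, so they become zeros rather than NaNs. Remaining
#' missing values are imputed to the column mean (0 after scaling), with a
#' message. Tracks present in only one of the inputs are dropped with a
#' message.
#'
#' @param stats output of [track_stats()].
#' @param annot a `state_annotation` from [decode_states()]; optional
#'   further annotations (e.g. a shape-state annotation) can be supplied in
#'   `extra_annotations` and are joined the same way.
#' @param extras optional tibble keyed by `track_id` with additional numeric
#'   per-track columns.
#' @param extra_annotations optional list of further `state_annotation`
#'   objects; their occupancy/transition columns are prefixed `a2_`, `a3_`,
#'   ... to stay distinct.
#' @return a tibble of class `behaviour_matrix`: `track_id` plus z-scored
#'   feature columns; scaling stored in `attr(, "scaling")`.
#' @export
assemble_behaviour_matrix <- function(stats, annot, extras = NULL,
                                      extra_annotations = NULL) {
  stopifnot(inherits(annot, "state_annotation"))
  stat_cols <- intersect(
    c("duration", "total_length", "net_displacement", "straightness",
      "mean_speed", "median_speed", "sd_speed", "mean_turning_angle",
      "mean_asphericity", "mean_prolateness"),
    names(stats)
  )
  stat_cols <- stat_cols[vapply(stats[stat_cols],
                                function(v) !all(is.na(v)), logical(1))]
  tab <- stats[c("track_id", stat_cols)]
  ann_tab <- dplyr::inner_join(annot$occupancy, annot$transitions, by = "track_id")
  if (!is.null(extra_annotations)) {
    for (i in seq_along(extra_annotations)) {
      a <- extra_annotations[[i]]
      stopifnot(inherits(a, "state_annotation"))
      extra <- dplyr::inner_join(a$occupancy, a$transitions, by = "track_id")
      names(extra)[-1] <- paste0("a", i + 1, "_", names(extra)[-1])
      ann_tab <- dplyr::inner_join(ann_tab, extra, by = "track_id")
    }
  }
  joined <- dplyr::inner_join(tab, ann_tab, by = "track_id")
  dropped <- setdiff(union(tab$track_id, ann_tab$track_id), joined$track_id)
  if (length(dropped)) {
    message(sprintf("assemble_behaviour_matrix: dropped %d track(s) missing from one input",
                    length(dropped)))
  }
  if (!is.null(extras)) {
    stopifnot("track_id" %in% names(extras))
    before <- nrow(joined)
    joined <- dplyr::inner_join(joined, extras, by = "track_id")
    if (nrow(joined) < before) {
      message(sprintf("assemble_behaviour_matrix: dropped %d track(s) missing from extras",
                      before - nrow(joined)))
    }
  }
  feat_cols <- setdiff(names(joined), "track_id")
  mu <- vapply(joined[feat_cols], function(v) mean(v, na.rm = TRUE), numeric(1))
  sdv <- vapply(joined[feat_cols], function(v) stats::sd(v, na.rm = TRUE), numeric(1))
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  mu[!is.finite(mu)] <- 0
  n_imputed <- 0
  for (j in seq_along(feat_cols)) {
    v <- (joined[[feat_cols[j]]] - mu[j]) / sdv[j]
    n_imputed <- n_imputed + sum(!is.finite(v))
    v[!is.finite(v)] <- 0
    joined[[feat_cols[j]]] <- v
  }
  if (n_imputed > 0) {
    message(sprintf("assemble_behaviour_matrix: imputed %d missing value(s) to column mean",
                    n_imputed))
  }
  out <- tibble::as_tibble(joined)
  attr(out, "scaling") <- tibble::tibble(feature = feat_cols, mean = unname(mu),
                                         sd = unname(sdv))
  class(out) <- c("behaviour_matrix", class(out))
  out
}

#' Cluster tracks into behaviours
#'
#' Builds an undirected Euclidean k-nearest-neighbour graph on the scaled
#' behaviour features (union of neighbourhoods) and partitions it with
#' Leiden community detection at the given resolution. Labels are stable
#' for a fixed seed and renumbered by first appearance in track order.
#'
#' @param matrix a `behaviour_matrix` from [assemble_behaviour_matrix()]
#'   (any tibble with `track_id` plus numeric columns works).
#' @param knn_k neighbours per track in the graph (default 20).
#' @param resolution Leiden (modularity) resolution parameter. Behaviour
#'   phenotypes at the whole-track level number a handful, while modularity
#'   granularity at resolution 1 scales with graph size and splits even
#'   feature-homogeneous cohorts of ~100 tracks; the default of 0.25
#'   targets the coarse phenotype scale for cohorts of a few hundred
#'   tracks. Raise it to dig into finer substructure.
#' @param seed integer seed for the Leiden refinement.
#' @param n_iterations Leiden iterations (default 3).
#' @return tibble: `track_id`, `behaviour_cluster` (integer, 1-based).
#' @export
cluster_behaviours <- function(matrix, knn_k = 20, resolution = 0.25, seed = 1,
                               n_iterations = 3) {
  stopifnot(is.data.frame(matrix), "track_id" %in% names(matrix))
  feat <- as.matrix(matrix[setdiff(names(matrix), "track_id")])
  n <- nrow(feat)
  if (n < knn_k + 1) {
    rlang::abort(sprintf(
      "need at least knn_k + 1 = %d tracks (have %d); use a smaller `knn_k`",
      knn_k + 1, n), class = "celltrax_parameter_error")
  }
  g <- knn_graph(feat, knn_k)
  set.seed(seed)
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution,
                                 n_iterations = n_iterations)
  memb <- igraph::membership(comm)
  labels <- as.integer(factor(memb, levels = unique(memb)))
  tibble::tibble(track_id = matrix$track_id, behaviour_cluster = labels)
}

# Undirected union-of-neighbourhoods kNN graph on Euclidean distances.
#' @keywords internal
knn_graph <- function(feat, k) {
  n <- nrow(feat)
  d <- cross_dist(feat, feat)
  diag(d) <- Inf
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- order(d[i, ])[seq_len(k)]
    cbind(i, nb)
  }))
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges)
  igraph::graph_from_edgelist(edges, directed = FALSE)
}
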