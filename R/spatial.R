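#' Delaunay neighbour graph
#'
#' Computes the edges of the Delaunay triangulation (tetrahedralisation in
#' 3D) of the cell centroids: two cells are neighbours when they share a
#' simplex whose circumscribed circle/sphere contains no other cell. Exact
#' co-circular/co-spherical ties are broken deterministically by an
#' index-keyed jitter of relative magnitude ~1e-9, so the same table always
#' yields the same graph; reported edge distances use the original
#' coordinates. The implementation checks every candidate simplex against
#' the empty-circumball property, which is robust but O(n^3)-O(n^4): suited
#' to tables of a few hundred cells per image.
#'
#' @param cells a cell table.
#' @param max_edge optional pruning: drop edges longer than this (µm).
#' @return a tibble of class `neighbour_graph`: `from`, `to` (cell ids,
#'   `from < to`), `distance` (µm); attributes `method` and `parameters`.
#' @export
delaunay_neighbours <- function(cells, max_edge = NULL) {
  validate_cell_table(cells)
  xyz <- coord_matrix(cells)
  n <- nrow(xyz); d <- ncol(xyz)
  if (n < d + 1) {
    rlang::abort(sprintf("need at least %d points in %dD", d + 1, d),
                 class = "celltrax_input_error")
  }
  span <- apply(xyz, 2, function(v) diff(range(v)))
  if (any(span == 0) || degenerate_affine(xyz)) {
    rlang::abort("points are collinear/coplanar: no triangulation exists (jitter the coordinates)",
                 class = "celltrax_degeneracy_error")
  }
  scale <- max(span)
  pj <- xyz + index_jitter(n, d) * (1e-9 * scale)
  edges <- if (d == 2) delaunay_edges_2d_cpp(pj) else delaunay_edges_3d_cpp(pj)
  dist <- sqrt(rowSums((xyz[edges[, 1], , drop = FALSE] -
                          xyz[edges[, 2], , drop = FALSE])^2))
  out <- tibble::tibble(
    from = cells$cell_id[edges[, 1]],
    to = cells$cell_id[edges[, 2]],
    distance = dist
  )
  swap <- out$from > out$to
  tmp <- out$from[swap]; out$from[swap] <- out$to[swap]; out$to[swap] <- tmp
  out <- dplyr::arrange(out, .data$from, .data$to)
  if (!is.null(max_edge)) out <- out[out$distance <= max_edge, ]
  attr(out, "method") <- "delaunay"
  attr(out, "parameters") <- list(max_edge = max_edge)
  class(out) <- c("neighbour_graph", class(out))
  out
}

#' @keywords internal
degenerate_affine <- function(xyz) {
  c0 <- sweep(xyz, 2, colMeans(xyz))
  qr(c0)$rank < ncol(xyz)
}

#' Radius or k-nearest neighbour graph
#'
#' Alternative neighbour definitions to the Delaunay graph: all pairs
#' within a fixed radius, or the union of each cell's k nearest neighbours.
#'
#' @param cells a cell table.
#' @param method `"radius"` or `"knn"`.
#' @param radius neighbourhood radius in µm (radius method).
#' @param k neighbours per cell (knn method).
#' @return a `neighbour_graph` tibble as in [delaunay_neighbours()].
#' @export
neighbour_graph <- function(cells, method = c("radius", "knn"), radius = NULL, k = NULL) {
  validate_cell_table(cells)
  method <- match.arg(method)
  xyz <- coord_matrix(cells)
  n <- nrow(xyz)
  d <- cross_dist(xyz, xyz)
  diag(d) <- Inf
  if (method == "radius") {
    check_number(radius, "radius", 0, strict = TRUE)
    idx <- which(d <= radius & upper.tri(d), arr.ind = TRUE)
  } else {
    check_number(k, "k", 1)
    if (n < k + 1) {
      rlang::abort("need at least k + 1 cells", class = "celltrax_parameter_error")
    }
    idx <- do.call(rbind, lapply(seq_len(n), function(i) {
      cbind(i, order(d[i, ])[seq_len(k)])
    }))
    idx <- unique(t(apply(idx, 1, sort)))
  }
  out <- tibble::tibble(
    from = cells$cell_id[idx[, 1]],
    to = cells$cell_id[idx[, 2]],
    distance = d[idx]
  )
  swap <- out$from > out$to
  tmp <- out$from[swap]; out$from[swap] <- out$to[swap]; out$to[swap] <- tmp
  out <- dplyr::arrange(out, .data$from, .data$to)
  attr(out, "method") <- method
  attr(out, "parameters") <- list(radius = radius, k = k)
  class(out) <- c("neighbour_graph", class(out))
  out
}

#' Closest-neighbour interaction partner
#'
#' For every cell, the interaction partner is its closest adjacent cell in
#' the neighbour graph — optionally restricted to partners from a given set
#' of populations. Cells without an admissible neighbour get partner `NA`.
#'
#' @param graph a `neighbour_graph` (typically from [delaunay_neighbours()]).
#' @param cells the cell table the graph was built from.
#' @param partner_populations optional character vector restricting
#'   partners; requires `population_col`.
#' @param population_col name of the population label column.
#' @return tibble: `cell_id`, `partner_id`, `partner_population` (when a
#'   population column exists), `distance`.
#' @export
closest_interaction <- function(graph, cells, partner_populations = NULL,
                                population_col = "population") {
  stopifnot(is.data.frame(graph), all(c("from", "to", "distance") %in% names(graph)))
  validate_cell_table(cells)
  has_pop <- population_col %in% names(cells)
  if (!is.null(partner_populations) && !has_pop) {
    rlang::abort(sprintf("population column `%s` not found", population_col),
                 class = "celltrax_schema_error")
  }
  long <- dplyr::bind_rows(
    tibble::tibble(cell_id = graph$from, partner_id = graph$to, distance = graph$distance),
    tibble::tibble(cell_id = graph$to, partner_id = graph$from, distance = graph$distance)
  )
  if (has_pop) {
    pop <- stats::setNames(as.character(cells[[population_col]]), cells$cell_id)
    long$partner_population <- unname(pop[as.character(long$partner_id)])
    if (!is.null(partner_populations)) {
      long <- long[long$partner_population %in% partner_populations, , drop = FALSE]
    }
  }
  best <- long |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::arrange(.data$distance, .data$partner_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  out <- dplyr::left_join(tibble::tibble(cell_id = cells$cell_id), best, by = "cell_id")
  out
}

#' DBSCAN aggregate detection
#'
#' Standard density-based clustering of cell centroids: a cell is a core
#' point when at least `min_pts` cells (itself included) lie within `eps`
#' micrometres; clusters are the connected components of core points within
#' `eps` of each other, plus border points attached to a reachable core
#' point; everything else is noise (cluster 0). Labelling is deterministic:
#' clusters are numbered by their lowest member `cell_id`, and a border
#' point reachable from several clusters joins the one containing the
#' lowest core `cell_id` among its in-range cores.
#'
#' The headline use is aggregate (cluster) detection with `eps = 20` µm and
#' `min_pts = 4`; note `eps` is DBSCAN's neighbourhood radius — the 20 µm
#' figure is adopted for it directly even though it is quoted as a cluster
#' "diameter" in the motivating analysis.
#'
#' @param cells a cell table.
#' @param eps neighbourhood radius, µm.
#' @param min_pts minimum points (self included) for a core point.
#' @return `cells` with an integer `dbscan_cluster` column (0 = noise).
#' @export
dbscan_clusters <- function(cells, eps = 20, min_pts = 4) {
  validate_cell_table(cells)
  check_number(eps, "eps", 0, strict = TRUE)
  check_number(min_pts, "min_pts", 1)
  xyz <- coord_matrix(cells)
  n <- nrow(xyz)
  cells$dbscan_cluster <- integer(n)
  if (n == 0) return(cells)
  d <- cross_dist(xyz, xyz)
  within <- d <= eps
  n_nb <- rowSums(within)  # includes self (diagonal is 0 <= eps)
  core <- n_nb >= min_pts
  comp <- integer(n)
  if (any(core)) {
    core_idx <- which(core)
    adj <- within[core_idx, core_idx, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
    memb <- igraph::components(g)$membership
    comp[core_idx] <- memb
    # border points: non-core within eps of >= 1 core; deterministic choice
    border <- which(!core & rowSums(within[, core_idx, drop = FALSE]) > 0)
    for (i in border) {
      cand_cores <- core_idx[within[i, core_idx]]
      cand_comps <- unique(comp[cand_cores])
      best <- cand_comps[which.min(vapply(cand_comps, function(cm) {
        min(cells$cell_id[core_idx[memb == cm]])
      }, numeric(1)))]
      comp[i] <- best
    }
    # renumber clusters by lowest member cell_id
    present <- sort(unique(comp[comp > 0]))
    min_id <- vapply(present, function(cm) min(cells$cell_id[comp == cm]), numeric(1))
    remap <- integer(max(present))
    remap[present[order(min_id)]] <- seq_along(present)
    cells$dbscan_cluster <- ifelse(comp > 0, remap[pmax(comp, 1)], 0L)
  }
  cells
}

#' Cellular neighbourhood composition profiles
#'
#' For each cell, the fraction of every population among the cells within
#' `radius` micrometres, centre cell included (so the neighbourhood is
#' never empty and the composition always sums to 1). These profiles are
#' the per-cell "cellular neighbourhoods" that region/niche detection
#' clusters.
#'
#' @param cells a cell table with a categorical population column.
#' @param radius neighbourhood radius, µm (the motivating analyses use 50
#'   µm for protein panels and 100 µm for transcript panels).
#' @param by name of the population column.
#' @return tibble: `cell_id`, `n_neighbours` (within radius, incl. self),
#'   one `frac_<population>` column per population level.
#' @export
neighbourhood_profiles <- function(cells, radius = 50, by = "population") {
  validate_cell_table(cells)
  check_number(radius, "radius", 0, strict = TRUE)
  if (!by %in% names(cells)) {
    rlang::abort(sprintf("population column `%s` not found", by),
                 class = "celltrax_schema_error")
  }
  xyz <- coord_matrix(cells)
  pop <- factor(cells[[by]])
  levs <- levels(pop)
  onehot <- 1 * outer(as.character(pop), levs, `==`)
  colnames(onehot) <- levs
  within <- cross_dist(xyz, xyz) <= radius  # diagonal TRUE: centre included
  counts <- within %*% onehot
  totals <- rowSums(counts)
  frac <- counts / totals
  colnames(frac) <- paste0("frac_", levs)
  dplyr::bind_cols(
    tibble::tibble(cell_id = cells$cell_id, n_neighbours = as.integer(totals)),
    tibble::as_tibble(frac)
  )
}

#' K-means region (niche) detection
#'
#' Clusters cellular-neighbourhood composition profiles into R regions with
#' Lloyd's algorithm, taking the best of `n_init` seeded starts by
#' within-cluster sum of squares. The SSE is non-increasing across
#' iterations by construction; a cluster emptied during iteration is
#' re-seeded at the point farthest from its centroid (with a message). The
#' final assignment is exactly nearest-centroid.
#'
#' @param profiles output of [neighbourhood_profiles()] (any tibble with
#'   `cell_id` plus numeric feature columns works).
#' @param R number of regions, >= 1 and <= number of cells (R = 1 returns
#'   the global mean as the single centroid).
#' @param seed integer seed; start s uses `seed + s - 1`.
#' @param n_init number of random starts.
#' @param max_iter Lloyd iteration cap per start.
#' @return tibble of class `region_assignment`: `cell_id`, `region`
#'   (integer 1..R); centroids in `attr(, "centroids")`, total
#'   within-cluster SSE in `attr(, "sse")`.
#' @export
kmeans_regions <- function(profiles, R = 3, seed = 1, n_init = 10, max_iter = 100) {
  stopifnot(is.data.frame(profiles), "cell_id" %in% names(profiles))
  feat_cols <- setdiff(names(profiles), c("cell_id", "n_neighbours"))
  x <- as.matrix(profiles[feat_cols])
  n <- nrow(x)
  check_number(R, "R", 1)
  if (R > n) {
    rlang::abort("`R` cannot exceed the number of cells", class = "celltrax_parameter_error")
  }
  best <- NULL
  for (s in seq_len(n_init)) {
    set.seed(seed + s - 1)
    cent <- x[sample(n, R), , drop = FALSE]
    sse_prev <- Inf
    for (it in seq_len(max_iter)) {
      d2 <- cross_dist(x, cent)^2
      assign <- max.col(-d2, ties.method = "first")
      for (r in seq_len(R)) {
        if (!any(assign == r)) {
          far <- which.max(d2[cbind(seq_len(n), assign)])
          message("kmeans_regions: re-seeded an empty cluster at the farthest point")
          cent[r, ] <- x[far, ]
          assign[far] <- r
        }
      }
      cent <- rowsum(x, assign) / as.integer(table(factor(assign, levels = seq_len(R))))
      sse <- sum((x - cent[assign, , drop = FALSE])^2)
      if (sse > sse_prev + 1e-9) {
        rlang::abort("k-means SSE increased", class = "celltrax_internal_error")
      }
      if (sse_prev - sse < 1e-12) break
      sse_prev <- sse
    }
    d2 <- cross_dist(x, cent)^2
    assign <- max.col(-d2, ties.method = "first")
    sse <- sum(d2[cbind(seq_len(n), assign)])
    if (is.null(best) || sse < best$sse) best <- list(assign = assign, cent = cent, sse = sse)
  }
  out <- tibble::tibble(cell_id = profiles$cell_id, region = as.integer(best$assign))
  attr(out, "centroids") <- best$cent
  attr(out, "sse") <- best$sse
  class(out) <- c("region_assignment", class(out))
  out
}

#' Distance to the nearest structure point
#'
#' Exact 1-nearest-neighbour Euclidean distance from every cell centroid to
#' a structure point cloud (e.g. sampled lymphatic vessels or a stromal
#' network) — the k = 1 nearest-neighbour structure-proximity measure.
#'
#' @param cells a cell table.
#' @param structure a data frame of structure points with `x`, `y`
#'   (optionally `z`) matching the cells' dimensionality.
#' @return tibble: `cell_id`, `structure_distance` (µm),
#'   `structure_point` (row index of the nearest structure point).
#' @export
nearest_structure_distance <- function(cells, structure) {
  validate_cell_table(cells)
  if (is.null(structure) || nrow(structure) == 0) {
    rlang::abort("`structure` must contain at least one point",
                 class = "celltrax_input_error")
  }
  xyz <- coord_matrix(cells)
  scols <- intersect(c("x", "y", "z"), names(structure))
  if (!identical(scols, colnames(xyz))) {
    rlang::abort("structure points must share the cells' coordinate columns",
                 class = "celltrax_schema_error")
  }
  sm <- as.matrix(structure[scols])
  # chunk over cells to keep the distance block modest
  n <- nrow(xyz)
  nn_idx <- integer(n); nn_dist <- numeric(n)
  chunk <- max(1L, floor(2e6 / max(1, nrow(sm))))
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(n, start + chunk - 1L)
    d <- cross_dist(xyz[rows, , drop = FALSE], sm)
    nn_idx[rows] <- max.col(-d, ties.method = "first")
    nn_dist[rows] <- d[cbind(seq_along(rows), nn_idx[rows])]
  }
  tibble::tibble(cell_id = cells$cell_id, structure_distance = nn_dist,
                 structure_point = nn_idx)
}

#' Detect cell-cell contacts
#'
#' Two cells are in contact when their minimum separation is at most
#' `max_dist` micrometres. With per-object surface point samples the
#' separation is the minimum surface-to-surface sample distance; without
#' surfaces it falls back to centre distance minus both volume-equivalent
#' sphere radii (floored at 0), which preserves the thresholded-minimum-
#' distance contract for roughly convex cells.
#'
#' @param cells a cell table; the fallback needs a `volume` column.
#' @param max_dist contact threshold, µm (the motivating analysis uses 5).
#' @param surfaces optional data frame of surface samples: `cell_id`, `x`,
#'   `y` (optionally `z`).
#' @return tibble: `from`, `to` (cell ids, `from < to`), `gap` (µm, the
#'   minimum separation, 0 when overlapping).
#' @export
detect_contacts <- function(cells, max_dist = 5, surfaces = NULL) {
  validate_cell_table(cells)
  check_number(max_dist, "max_dist", 0, strict = TRUE)
  ids <- cells$cell_id
  n <- length(ids)
  if (n < 2) {
    return(tibble::tibble(from = integer(0), to = integer(0), gap = numeric(0)))
  }
  if (is.null(surfaces)) {
    if (!"volume" %in% names(cells)) {
      rlang::abort("centre-based contact detection needs a `volume` column",
                   class = "celltrax_schema_error")
    }
    xyz <- coord_matrix(cells)
    d <- ncol(xyz)
    r <- if (d == 3) (3 * cells$volume / (4 * pi))^(1 / 3) else sqrt(cells$volume / pi)
    cd <- cross_dist(xyz, xyz)
    gap <- pmax(cd - outer(r, r, `+`), 0)
    idx <- which(gap <= max_dist & upper.tri(gap), arr.ind = TRUE)
    out <- tibble::tibble(from = ids[idx[, 1]], to = ids[idx[, 2]],
                          gap = gap[idx])
  } else {
    scols <- intersect(c("x", "y", "z"), names(surfaces))
    pts <- split(as.data.frame(surfaces[scols]), surfaces$cell_id)
    have <- ids[as.character(ids) %in% names(pts)]
    res <- list()
    for (a in seq_along(have)) {
      pa <- as.matrix(pts[[as.character(have[a])]])
      for (b in seq_along(have)) {
        if (b <= a) next
        pb <- as.matrix(pts[[as.character(have[b])]])
        g <- min(cross_dist(pa, pb))
        if (g <= max_dist) {
          res[[length(res) + 1]] <- tibble::tibble(
            from = min(have[a], have[b]), to = max(have[a], have[b]), gap = g)
        }
      }
    }
    out <- if (length(res)) dplyr::bind_rows(res) else
      tibble::tibble(from = integer(0), to = integer(0), gap = numeric(0))
  }
  dplyr::arrange(out, .data$from, .data$to)
}

#' Region-to-region interaction matrix
#'
#' Maps the closest cells to each other across regions: every cell votes for
#' the region of its single nearest other cell, and the tallies are row-
#' normalised so row r gives the distribution of nearest-neighbour regions
#' for cells in region r. Same-region partners are included, so the
#' diagonal measures regional self-cohesion.
#'
#' @param cells a cell table with a region column.
#' @param region_col name of the region column.
#' @return an R x R matrix with rows and columns named by region; rows sum
#'   to 1 (rows for regions with no cells would be dropped — every level
#'   present in the data gets a row).
#' @export
region_interactions <- function(cells, region_col = "region") {
  validate_cell_table(cells)
  if (!region_col %in% names(cells)) {
    rlang::abort(sprintf("region column `%s` not found", region_col),
                 class = "celltrax_schema_error")
  }
  if (nrow(cells) < 2) {
    rlang::abort("need at least 2 cells", class = "celltrax_input_error")
  }
  xyz <- coord_matrix(cells)
  d <- cross_dist(xyz, xyz)
  diag(d) <- Inf
  nn <- max.col(-d, ties.method = "first")
  reg <- factor(cells[[region_col]])
  tab <- table(reg, reg[nn])
  m <- as.matrix(tab)
  rs <- rowSums(m)
  m <- sweep(m, 1, pmax(rs, 1), `/`)
  m
}
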