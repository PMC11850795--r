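test_that("Delaunay graph handles the triangle and the co-circular square", {
  tri <- tibble::tibble(cell_id = 1:3, x = c(0, 4, 1), y = c(0, 0, 3))
  g <- delaunay_neighbours(tri)
  expect_equal(nrow(g), 3)  # single triangle: all pairs adjacent

  sq <- tibble::tibble(cell_id = 1:4, x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  gs <- delaunay_neighbours(sq)
  expect_equal(nrow(gs), 5)  # 4 sides + exactly one diagonal
  gs2 <- delaunay_neighbours(sq)
  expect_identical(as.data.frame(gs), as.data.frame(gs2))  # deterministic tie break

  line <- tibble::tibble(cell_id = 1:5, x = 1:5, y = 2 * (1:5))
  expect_error(delaunay_neighbours(line), class = "celltrax_degeneracy_error")
})

test_that("every point's nearest neighbour is Delaunay-adjacent (2D and 3D)", {
  set.seed(51)
  cells <- random_cells(200)
  g <- delaunay_neighbours(cells)
  xy <- as.matrix(cells[c("x", "y")])
  d <- as.matrix(dist(xy)); diag(d) <- Inf
  nn <- cells$cell_id[apply(d, 1, which.min)]
  edge_key <- paste(g$from, g$to)
  for (i in seq_len(nrow(cells))) {
    a <- min(cells$cell_id[i], nn[i]); b <- max(cells$cell_id[i], nn[i])
    expect_true(paste(a, b) %in% edge_key)
  }
  # graph distances agree with coordinates
  dd <- sqrt(rowSums((xy[match(g$from, cells$cell_id), ] -
                        xy[match(g$to, cells$cell_id), ])^2))
  expect_equal(g$distance, dd, tolerance = 1e-12)

  cells3 <- random_cells(40, dim = 3)
  g3 <- delaunay_neighbours(cells3)
  xyz <- as.matrix(cells3[c("x", "y", "z")])
  d3 <- as.matrix(dist(xyz)); diag(d3) <- Inf
  nn3 <- cells3$cell_id[apply(d3, 1, which.min)]
  key3 <- paste(g3$from, g3$to)
  for (i in seq_len(nrow(cells3))) {
    a <- min(cells3$cell_id[i], nn3[i]); b <- max(cells3$cell_id[i], nn3[i])
    expect_true(paste(a, b) %in% key3)
  }
})

test_that("closest interaction picks the nearest admissible Delaunay partner", {
  # cell 1 sits inside the hull of 2,3,4, so it is adjacent to all of them
  cells <- tibble::tibble(cell_id = 1:4, x = c(0, 3, 0, -8), y = c(0, 1, 5, -1),
                          population = c("T", "DC", "B", "B"))
  g <- delaunay_neighbours(cells)
  ci <- closest_interaction(g, cells)
  expect_equal(ci$partner_id[ci$cell_id == 1], 2)  # sqrt(10) beats 5 and sqrt(65)
  ci_b <- closest_interaction(g, cells, partner_populations = "B")
  expect_equal(ci_b$partner_id[ci_b$cell_id == 1], 3)
  ci_none <- closest_interaction(g, cells, partner_populations = "NK")
  expect_true(all(is.na(ci_none$partner_id)))

  set.seed(52)
  rc <- random_cells(100)
  rc$population <- sample(c("T", "B", "DC"), 100, replace = TRUE)
  gg <- delaunay_neighbours(rc)
  ci2 <- closest_interaction(gg, rc)
  # oracle: min over adjacency by exhaustive scan
  adj <- rbind(as.matrix(gg[c("from", "to")]), as.matrix(gg[c("to", "from")]))
  dmap <- c(gg$distance, gg$distance)
  for (cid in sample(rc$cell_id, 20)) {
    rows <- adj[, 1] == cid
    expect_equal(ci2$distance[ci2$cell_id == cid], min(dmap[rows]))
  }
})

test_that("DBSCAN satisfies the quoted aggregate definition and edge cases", {
  # 4 mutually-close cells at the 20 um / 4 cells setting -> one cluster
  cells <- tibble::tibble(cell_id = 1:5,
                          x = c(0, 10, 0, 10, 200), y = c(0, 0, 10, 10, 200))
  res <- dbscan_clusters(cells, eps = 20, min_pts = 4)
  expect_equal(res$dbscan_cluster, c(1, 1, 1, 1, 0))  # isolated point is noise
  expect_error(dbscan_clusters(cells, eps = 0), class = "celltrax_parameter_error")
})

test_that("DBSCAN equals the reachability oracle on random instances", {
  set.seed(53)
  for (rep in 1:20) {
    n <- sample(50:300, 1)
    cells <- random_cells(n, size = 150)
    cells$cell_id <- sample(1000, n)  # scrambled ids exercise the labelling rule
    eps <- runif(1, 5, 15); min_pts <- sample(2:6, 1)
    res <- dbscan_clusters(cells, eps = eps, min_pts = min_pts)
    oracle <- dbscan_oracle(as.matrix(cells[c("x", "y")]), cells$cell_id,
                            eps, min_pts)
    expect_identical(as.integer(res$dbscan_cluster), as.integer(oracle))
  }
})

test_that("neighbourhood compositions count the centre cell and sum to one", {
  cells <- tibble::tibble(cell_id = 1:3, x = c(0, 10, 20), y = 0,
                          population = c("T", "T", "B"))
  pr <- neighbourhood_profiles(cells, radius = 12)
  expect_equal(pr$frac_T[1], 1)                       # isolated pair end: T,T
  expect_equal(unlist(pr[2, c("frac_B", "frac_T")], use.names = FALSE),
               c(1 / 3, 2 / 3))                       # self T + 1 T + 1 B
  iso <- neighbourhood_profiles(cells[3, ], radius = 5)
  expect_equal(iso$frac_B, 1)                         # own one-hot when alone

  set.seed(54)
  rc <- random_cells(200)
  rc$population <- sample(c("T", "B", "M"), 200, replace = TRUE)
  pr2 <- neighbourhood_profiles(rc, radius = 25)
  frac <- as.matrix(pr2[grep("^frac_", names(pr2))])
  expect_equal(rowSums(frac), rep(1, 200), tolerance = 1e-12)
  # brute-force distance scan oracle
  xy <- as.matrix(rc[c("x", "y")])
  for (i in sample(200, 15)) {
    nb <- which(sqrt(colSums((t(xy) - xy[i, ])^2)) <= 25)
    expect_equal(pr2$n_neighbours[i], length(nb))
    expect_equal(pr2$frac_T[i], mean(rc$population[nb] == "T"), tolerance = 1e-12)
  }
})

test_that("k-means regions recover structure and satisfy the Lloyd contract", {
  # duplicated profiles split perfectly with zero SSE
  prof <- tibble::tibble(cell_id = 1:6,
                         frac_a = c(1, 1, 1, 0, 0, 0),
                         frac_b = c(0, 0, 0, 1, 1, 1))
  r <- kmeans_regions(prof, R = 2, seed = 1, n_init = 2)
  expect_equal(attr(r, "sse"), 0)
  expect_equal(length(unique(r$region[1:3])), 1)
  expect_equal(length(unique(r$region[4:6])), 1)
  expect_false(r$region[1] == r$region[4])

  r1 <- kmeans_regions(prof, R = 1, seed = 1, n_init = 1)
  expect_equal(as.vector(attr(r1, "centroids")), c(0.5, 0.5))

  # three Dirichlet-like modes
  set.seed(55)
  mk <- function(center, n) {
    m <- matrix(rnorm(n * 3, 0, 0.03), n, 3) + matrix(center, n, 3, byrow = TRUE)
    m <- pmax(m, 0.001); m / rowSums(m)
  }
  x <- rbind(mk(c(0.8, 0.1, 0.1), 70), mk(c(0.1, 0.8, 0.1), 70),
             mk(c(0.1, 0.1, 0.8), 60))
  prof3 <- tibble::tibble(cell_id = seq_len(200), f1 = x[, 1], f2 = x[, 2],
                          f3 = x[, 3])
  r3 <- kmeans_regions(prof3, R = 3, seed = 2, n_init = 5)
  truth <- rep(1:3, c(70, 70, 60))
  expect_gte(adjusted_rand_index(r3$region, truth), 0.9)
  # assignment is nearest-centroid at convergence
  cent <- attr(r3, "centroids")
  d2 <- as.matrix(celltrax:::cross_dist(x, cent))^2
  expect_equal(r3$region, max.col(-d2, ties.method = "first"))
  # determinism and cross-check against the reference Lloyd implementation
  r3b <- kmeans_regions(prof3, R = 3, seed = 2, n_init = 5)
  expect_identical(r3$region, r3b$region)
  km <- suppressWarnings(stats::kmeans(x, centers = 3, nstart = 20,
                                       algorithm = "Lloyd", iter.max = 100))
  expect_gte(adjusted_rand_index(r3$region, km$cluster), 0.95)
  expect_equal(attr(r3, "sse"), km$tot.withinss, tolerance = 0.02 * km$tot.withinss)
})

test_that("nearest structure distances are exact", {
  cells <- tibble::tibble(cell_id = 1:2, x = c(0, 7), y = c(0, 24), z = c(0, 0))
  structure <- tibble::tibble(x = c(3, 7), y = c(4, 24), z = c(0, 0))
  ns <- nearest_structure_distance(cells, structure)
  expect_equal(ns$structure_distance, c(5, 0))  # 3-4-5 triangle; coincident point
  expect_error(nearest_structure_distance(cells, structure[0, ]),
               class = "celltrax_input_error")

  set.seed(56)
  rc <- random_cells(300)
  stru <- tibble::tibble(x = runif(400, 0, 100), y = runif(400, 0, 100))
  ns2 <- nearest_structure_distance(rc, stru)
  d <- celltrax:::cross_dist(as.matrix(rc[c("x", "y")]), as.matrix(stru))
  expect_equal(ns2$structure_distance, apply(d, 1, min), tolerance = 1e-12)
  expect_equal(ns2$structure_point, apply(d, 1, which.min))
})

test_that("contact detection thresholds the surface gap", {
  # volume-equivalent spheres of radius 5 um (3D): V = 4/3 pi 125
  v <- 4 / 3 * pi * 125
  cells <- tibble::tibble(cell_id = 1:3, x = c(0, 12, 37), y = 0, z = 0,
                          volume = v)
  ct <- detect_contacts(cells, max_dist = 5)
  expect_equal(nrow(ct), 1)
  expect_equal(c(ct$from, ct$to), c(1, 2))
  expect_equal(ct$gap, 2)  # 12 - 5 - 5

  # surface samples: two rings almost touching
  th <- seq(0, 2 * pi, length.out = 40)
  surf <- dplyr::bind_rows(
    tibble::tibble(cell_id = 1, x = 5 * cos(th), y = 5 * sin(th)),
    tibble::tibble(cell_id = 2, x = 13 + 5 * cos(th), y = 5 * sin(th)),
    tibble::tibble(cell_id = 3, x = 40 + 5 * cos(th), y = 5 * sin(th))
  )
  cells2 <- tibble::tibble(cell_id = 1:3, x = c(0, 13, 40), y = 0, volume = 1)
  ct2 <- detect_contacts(cells2, max_dist = 5, surfaces = surf)
  expect_equal(nrow(ct2), 1)
  expect_equal(c(ct2$from, ct2$to), c(1, 2))
  # oracle: brute-force all-pairs min distance
  pts <- split(surf[c("x", "y")], surf$cell_id)
  gap_oracle <- min(celltrax:::cross_dist(as.matrix(pts[[1]]), as.matrix(pts[[2]])))
  expect_equal(ct2$gap, gap_oracle, tolerance = 1e-12)
})

test_that("contact pairs equal the brute-force oracle on random surface clouds", {
  set.seed(57)
  n_obj <- 30
  centres <- cbind(runif(n_obj, 0, 120), runif(n_obj, 0, 120))
  th <- seq(0, 2 * pi, length.out = 25)
  surf <- dplyr::bind_rows(lapply(seq_len(n_obj), function(i) {
    a <- runif(1, 2, 6); b <- runif(1, 2, 6)
    tibble::tibble(cell_id = i, x = centres[i, 1] + a * cos(th),
                   y = centres[i, 2] + b * sin(th))
  }))
  cells <- tibble::tibble(cell_id = seq_len(n_obj), x = centres[, 1],
                          y = centres[, 2], volume = 1)
  ct <- detect_contacts(cells, max_dist = 5, surfaces = surf)
  pts <- split(surf[c("x", "y")], surf$cell_id)
  expected <- list()
  for (a in 1:(n_obj - 1)) for (b in (a + 1):n_obj) {
    g <- min(celltrax:::cross_dist(as.matrix(pts[[a]]), as.matrix(pts[[b]])))
    if (g <= 5) expected[[length(expected) + 1]] <- c(a, b)
  }
  expect_equal(nrow(ct), length(expected))
  if (length(expected)) {
    em <- do.call(rbind, expected)
    expect_equal(as.matrix(ct[c("from", "to")]), em, ignore_attr = TRUE)
  }
})

test_that("region interactions tally nearest cells and row-normalise", {
  cells <- tibble::tibble(cell_id = 1:2, x = c(0, 1), y = 0, region = c(1, 2))
  m <- region_interactions(cells)
  expect_equal(unname(m), matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE))

  one <- tibble::tibble(cell_id = 1:5, x = 1:5, y = 0, region = 1)
  expect_equal(unname(region_interactions(one)), matrix(1))

  set.seed(58)
  rc <- random_cells(300)
  rc$region <- sample(1:3, 300, replace = TRUE)
  m3 <- region_interactions(rc)
  expect_equal(unname(rowSums(m3)), rep(1, 3), tolerance = 1e-12)
  # brute-force nearest-cell tally
  xy <- as.matrix(rc[c("x", "y")])
  d <- as.matrix(dist(xy)); diag(d) <- Inf
  nn_reg <- rc$region[apply(d, 1, which.min)]
  tab <- table(rc$region, nn_reg)
  expect_equal(unname(m3), unname(as.matrix(tab / rowSums(tab))), tolerance = 1e-12)
})

test_that("neighbour and contact relations are symmetric and self-loop-free", {
  set.seed(59)
  rc <- random_cells(80)
  rc$volume <- runif(80, 50, 400)
  g <- delaunay_neighbours(rc)
  expect_true(all(g$from != g$to))
  expect_true(all(g$distance > 0))
  gr <- neighbour_graph(rc, "radius", radius = 20)
  expect_true(all(gr$from < gr$to))  # undirected: stored once per pair
  gk <- neighbour_graph(rc, "knn", k = 4)
  expect_true(all(gk$from != gk$to))
  ct <- detect_contacts(rc, max_dist = 3)
  expect_true(all(ct$from < ct$to))
})

test_that("two-blob tissue recovers its regions through the niche pipeline", {
  sim <- simulate_tissue(c(T_cell = 150, B_cell = 150), layout = "blobs",
                         image_size = 500, seed = 61)
  pr <- neighbourhood_profiles(sim$cells, radius = 50, by = "population")
  reg <- kmeans_regions(pr, R = 2, seed = 61)
  expect_gte(adjusted_rand_index(reg$region, sim$cells$region_truth), 0.9)
})
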