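# Independent brute-force oracles. Each re-derives a quantity by the most
# direct (usually exhaustive) route so it shares no code path with the
# implementation it checks.

# Marginal log-likelihood of a 1..K-state Gaussian HMM by explicit
# enumeration of all K^T hidden-state paths.
enum_loglik <- function(x, means, vars, A, pi) {
  x <- as.matrix(x)
  T_ <- nrow(x); K <- nrow(means)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  total <- -Inf
  for (r in seq_len(nrow(paths))) {
    st <- as.integer(paths[r, ])
    lp <- log(pi[st[1]])
    if (T_ > 1) for (t in 2:T_) lp <- lp + log(A[st[t - 1], st[t]])
    for (t in seq_len(T_)) {
      lp <- lp + sum(stats::dnorm(x[t, ], means[st[t], ], sqrt(vars[st[t], ]), log = TRUE))
    }
    total <- max(total, lp) + log1p(exp(min(total, lp) - max(total, lp)))
  }
  total
}

# Joint log-probability of one explicit state path.
path_logprob <- function(x, st, means, vars, A, pi) {
  x <- as.matrix(x)
  lp <- log(pi[st[1]])
  if (length(st) > 1) for (t in 2:length(st)) lp <- lp + log(A[st[t - 1], st[t]])
  for (t in seq_along(st)) {
    lp <- lp + sum(stats::dnorm(x[t, ], means[st[t], ], sqrt(vars[st[t], ]), log = TRUE))
  }
  lp
}

# Random valid Gaussian HMM (K states, D features).
random_hmm <- function(K, D) {
  A <- matrix(stats::runif(K * K, 0.05, 1), K, K)
  A <- A / rowSums(A)
  pi <- stats::runif(K, 0.05, 1); pi <- pi / sum(pi)
  hmm_model(means = matrix(stats::rnorm(K * D, sd = 2), K, D),
            variances = matrix(stats::runif(K * D, 0.2, 1.5), K, D),
            A = A, pi = pi)
}

# DBSCAN by literal reachability: core points, BFS over eps-neighbourhoods
# from cores, border attachment to the cluster holding the lowest core id.
dbscan_oracle <- function(xy, ids, eps, min_pts) {
  n <- nrow(xy)
  d <- as.matrix(stats::dist(xy))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  comp <- integer(n)
  cid <- 0
  for (i in which(core)) {
    if (comp[i] > 0) next
    cid <- cid + 1
    queue <- i
    comp[i] <- cid
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (j in nb[[cur]]) {
        if (core[j] && comp[j] == 0) { comp[j] <- cid; queue <- c(queue, j) }
      }
    }
  }
  for (i in which(!core)) {
    cores_near <- nb[[i]][core[nb[[i]]]]
    if (length(cores_near)) {
      comps <- unique(comp[cores_near])
      best <- comps[which.min(vapply(comps, function(cm) min(ids[core & comp == cm]),
                                     numeric(1)))]
      comp[i] <- best
    }
  }
  present <- sort(unique(comp[comp > 0]))
  if (length(present)) {
    min_id <- vapply(present, function(cm) min(ids[comp == cm]), numeric(1))
    remap <- integer(max(present))
    remap[present[order(min_id)]] <- seq_along(present)
    comp[comp > 0] <- remap[comp[comp > 0]]
  }
  comp
}

# Independent even-odd point-in-polygon: ray cast in +y instead of +x, plus
# an explicit on-segment test for the boundary-inclusive convention.
pip_oracle <- function(px, py, vx, vy) {
  n <- length(vx)
  vapply(seq_along(px), function(q) {
    x <- px[q]; y <- py[q]
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
      cross <- (x - x1) * (y2 - y1) - (y - y1) * (x2 - x1)
      if (cross == 0 && x >= min(x1, x2) && x <= max(x1, x2) &&
          y >= min(y1, y2) && y <= max(y1, y2)) return(TRUE)
      if ((x1 > x) != (x2 > x)) {
        y_cross <- (y2 - y1) * (x - x1) / (x2 - x1) + y1
        if (y < y_cross) inside <- !inside
      }
      j <- i
    }
    inside
  }, logical(1))
}

# Per-pixel window sum by direct double loop.
window_sum_oracle <- function(binned, r) {
  ny <- nrow(binned); nx <- ncol(binned)
  out <- matrix(0, ny, nx)
  for (i in seq_len(ny)) {
    for (j in seq_len(nx)) {
      out[i, j] <- sum(binned[max(1, i - r):min(ny, i + r),
                              max(1, j - r):min(nx, j + r)])
    }
  }
  out
}

# Random simple (star-shaped, hence non-self-intersecting) polygon.
random_polygon <- function(n_vert = 6) {
  ang <- sort(stats::runif(n_vert, 0, 2 * pi))
  r <- stats::runif(n_vert, 0.3, 1)
  cbind(r * cos(ang), r * sin(ang))
}

# Small random cell table.
random_cells <- function(n, dim = 2, size = 100) {
  tab <- tibble::tibble(cell_id = seq_len(n),
                        x = stats::runif(n, 0, size),
                        y = stats::runif(n, 0, size))
  if (dim == 3) tab$z <- stats::runif(n, 0, size)
  tab
}

# Relative shape anisotropy from eigenvalues via the pair-sum identity
# (independent of the package's sum-of-squares formulation).
gyration_shape_oracle <- function(lambda) {
  stopifnot(length(lambda) == 3)
  1 - 3 * (lambda[1] * lambda[2] + lambda[2] * lambda[3] + lambda[1] * lambda[3]) /
    sum(lambda)^2
}
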