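#' Specify a motility mode for track simulation
#'
#' A mode is a persistent-random-walk recipe: per-step direction is a
#' persistence-weighted blend of the previous direction with a fresh random
#' unit vector, step length comes from a clipped Gaussian speed, and the
#' aggregating mode adds drift towards a shared attractor point. Each mode
#' can carry a shape program — Gaussian targets for the shape descriptors
#' emitted alongside the positions — so that shape-state models can be
#' benchmarked against known truth.
#'
#' @param mode one of `"directed"`, `"meandering"`, `"scanning"`,
#'   `"aggregating"` (free-text names are allowed too).
#' @param speed_mean,speed_sd speed distribution, µm/min (clipped at 0).
#' @param persistence directional correlation of successive steps in
#'   \[0, 1\]: 1 = ballistic, 0 = uncorrelated headings.
#' @param attractor attractor point (numeric x, y\[, z\]) for aggregation.
#' @param attractor_strength fraction of the remaining distance to the
#'   attractor travelled per step, in \[0, 1\].
#' @param shape_mean,shape_sd optional named numeric vectors over
#'   `asphericity`, `prolateness`, `kappa_sq`, `volume`.
#' @return a `motility_mode` object.
#' @export
motility_mode <- function(mode, speed_mean, speed_sd = 0, persistence = 0.5,
                          attractor = NULL, attractor_strength = 0,
                          shape_mean = NULL, shape_sd = NULL) {
  check_number(speed_mean, "speed_mean", 0, strict = TRUE)
  check_number(speed_sd, "speed_sd", 0)
  check_number(persistence, "persistence", 0)
  if (persistence > 1) {
    rlang::abort("persistence must be in [0, 1]", class = "celltrax_parameter_error")
  }
  structure(list(mode = mode, speed_mean = speed_mean, speed_sd = speed_sd,
                 persistence = persistence, attractor = attractor,
                 attractor_strength = attractor_strength,
                 shape_mean = shape_mean, shape_sd = shape_sd),
            class = "motility_mode")
}

#' The four canonical behaviour modes
#'
#' Default simulation conditions spanning the four behaviour phenotypes the
#' live-imaging analyses distinguish: directed motion (high speed, high
#' persistence, aspherical/prolate shape), meandering (intermediate speed
#' and persistence, intermediate shape), scanning (low speed, low
#' persistence — high turning angle — low asphericity) and aggregating
#' (slow, attractor-bound clustering). Speeds are in the µm/min range of
#' lymph-node T cells.
#'
#' @param arena_size side length (µm) of the square arena; the aggregating
#'   attractor sits at its centre.
#' @return named list of four [motility_mode()] objects.
#' @export
default_motility_modes <- function(arena_size = 400) {
  ctr <- rep(arena_size / 2, 2)
  list(
    directed = motility_mode("directed", speed_mean = 12, speed_sd = 2,
                             persistence = 0.95,
                             shape_mean = c(asphericity = 6, prolateness = 0.6,
                                            kappa_sq = 0.6, volume = 220),
                             shape_sd = c(asphericity = 1, prolateness = 0.1,
                                          kappa_sq = 0.08, volume = 25)),
    meandering = motility_mode("meandering", speed_mean = 7, speed_sd = 1.5,
                               persistence = 0.6,
                               shape_mean = c(asphericity = 3, prolateness = 0.1,
                                              kappa_sq = 0.3, volume = 200),
                               shape_sd = c(asphericity = 0.8, prolateness = 0.15,
                                            kappa_sq = 0.08, volume = 25)),
    scanning = motility_mode("scanning", speed_mean = 3, speed_sd = 1,
                             persistence = 0.15,
                             shape_mean = c(asphericity = 1, prolateness = -0.2,
                                            kappa_sq = 0.1, volume = 180),
                             shape_sd = c(asphericity = 0.4, prolateness = 0.12,
                                          kappa_sq = 0.05, volume = 20)),
    aggregating = motility_mode("aggregating", speed_mean = 2.5, speed_sd = 1,
                                persistence = 0.3, attractor = ctr,
                                attractor_strength = 0.08,
                                shape_mean = c(asphericity = 1.5, prolateness = 0,
                                               kappa_sq = 0.15, volume = 190),
                                shape_sd = c(asphericity = 0.5, prolateness = 0.12,
                                             kappa_sq = 0.06, volume = 20))
  )
}

#' @keywords internal
random_unit <- function(n, d) {
  v <- matrix(stats::rnorm(n * d), n, d)
  v / sqrt(rowSums(v^2))
}

#' Simulate tracks from motility modes
#'
#' Persistent-random-walk simulator producing a cell table plus aligned
#' ground truth. Each track starts uniformly in the arena and takes
#' `n_steps` steps of `dt_seconds`; the heading blends the previous heading
#' with a fresh random unit vector at the mode's persistence, the step
#' length is `speed * dt` with speed drawn from a clipped Gaussian, and
#' aggregating modes additionally move a fixed fraction of the remaining
#' distance towards the attractor each step. All randomness flows through
#' one seeded generator, so identical seeds give bit-identical output.
#'
#' @param specs list of [motility_mode()]s (default the four canonical
#'   modes).
#' @param n_per_mode tracks per mode.
#' @param n_steps steps per track (>= 2 positions result).
#' @param dt_seconds frame interval (default 10 s, the usual two-photon
#'   acquisition interval).
#' @param arena_size side length of the square arena, µm.
#' @param dim 2 or 3.
#' @param seed integer seed.
#' @return list with `cells` (cell table: `cell_id`, `frame`, coordinates,
#'   `track_id`, shape-descriptor columns when the modes carry shape
#'   programs) and `truth` (tibble: `track_id`, `mode`).
#' @export
simulate_tracks <- function(specs = default_motility_modes(), n_per_mode = 25,
                            n_steps = 60, dt_seconds = 10, arena_size = 400,
                            dim = 2, seed = 1) {
  stopifnot(is.list(specs), length(specs) >= 1)
  if (!all(vapply(specs, inherits, logical(1), "motility_mode"))) {
    rlang::abort("`specs` must be motility_mode objects", class = "celltrax_parameter_error")
  }
  check_number(n_steps, "n_steps", 2)
  check_number(dt_seconds, "dt_seconds", 0, strict = TRUE)
  set.seed(seed)
  dt_min <- dt_seconds / 60
  rows <- list()
  truth <- list()
  track_id <- 0L
  cell_id <- 0L
  coords <- c("x", "y", "z")[seq_len(dim)]
  for (m in seq_along(specs)) {
    spec <- specs[[m]]
    has_shape <- !is.null(spec$shape_mean)
    for (tr in seq_len(n_per_mode)) {
      track_id <- track_id + 1L
      pos <- matrix(NA_real_, n_steps + 1, dim)
      pos[1, ] <- stats::runif(dim, 0, arena_size)
      dir <- random_unit(1, dim)
      for (s in seq_len(n_steps)) {
        fresh <- random_unit(1, dim)
        dir <- spec$persistence * dir + (1 - spec$persistence) * fresh
        nrm <- sqrt(sum(dir^2))
        if (nrm < 1e-12) dir <- fresh else dir <- dir / nrm
        speed <- max(0, stats::rnorm(1, spec$speed_mean, spec$speed_sd))
        step <- dir * speed * dt_min
        if (!is.null(spec$attractor) && spec$attractor_strength > 0) {
          pull <- spec$attractor_strength * (spec$attractor[seq_len(dim)] - pos[s, ])
          # cells chemotax at cell speed: cap the drift at the drawn step length
          pull_len <- sqrt(sum(pull^2))
          max_pull <- speed * dt_min
          if (pull_len > max_pull && pull_len > 0) pull <- pull * (max_pull / pull_len)
          step <- step + pull
        }
        pos[s + 1, ] <- pos[s, ] + step
      }
      tab <- tibble::as_tibble(as.data.frame(pos))
      names(tab) <- coords
      tab$frame <- 0:(n_steps)
      tab$track_id <- track_id
      tab$cell_id <- cell_id + seq_len(n_steps + 1)
      cell_id <- cell_id + n_steps + 1L
      if (has_shape) {
        for (f in names(spec$shape_mean)) {
          v <- stats::rnorm(n_steps + 1, spec$shape_mean[[f]], spec$shape_sd[[f]])
          if (f %in% c("asphericity", "volume")) v <- pmax(v, 0)
          if (f == "kappa_sq") v <- pmin(pmax(v, 0), 1)
          if (f == "prolateness") v <- pmin(pmax(v, -1), 1)
          tab[[f]] <- v
        }
      }
      rows[[track_id]] <- tab
      truth[[track_id]] <- tibble::tibble(track_id = track_id,
                                          mode = spec$mode)
    }
  }
  cells <- dplyr::bind_rows(rows)[, c("cell_id", "frame", coords, "track_id",
                                      setdiff(names(rows[[1]]),
                                              c("cell_id", "frame", coords, "track_id")))]
  list(cells = cells, truth = dplyr::bind_rows(truth))
}

#' Sample observation sequences from an HMM
#'
#' Exact ancestral sampling: states from the initial distribution and
#' transition matrix, emissions from the state's diagonal Gaussian (on the
#' model's scaled space, mapped back through the stored scaling so the
#' output is on the raw feature scale).
#'
#' @param model a `celltrax_hmm`.
#' @param n_seqs number of sequences.
#' @param length observations per sequence.
#' @param seed integer seed.
#' @return list with `sequences` (tibble: `track_id`, `frame`, one column
#'   per feature) and `states` (tibble: `track_id`, `frame`, `state`).
#' @export
simulate_hmm_sequences <- function(model, n_seqs, length, seed = 1) {
  stopifnot(inherits(model, "celltrax_hmm"))
  set.seed(seed)
  K <- model$K; D <- model$D
  seqs <- list(); sts <- list()
  for (s in seq_len(n_seqs)) {
    state <- integer(length)
    state[1] <- sample.int(K, 1, prob = model$pi)
    if (length > 1) {
      for (t in 2:length) {
        state[t] <- sample.int(K, 1, prob = model$A[state[t - 1], ])
      }
    }
    x <- matrix(stats::rnorm(length * D,
                             mean = model$means[state, , drop = FALSE],
                             sd = sqrt(model$variances[state, , drop = FALSE])),
                length, D)
    # back to raw feature scale
    x <- sweep(sweep(x, 2, model$scaling$sd, `*`), 2, model$scaling$mean, `+`)
    tab <- tibble::as_tibble(as.data.frame(x))
    names(tab) <- model$feature_names
    tab <- dplyr::bind_cols(tibble::tibble(track_id = s, frame = seq_len(length)), tab)
    seqs[[s]] <- tab
    sts[[s]] <- tibble::tibble(track_id = s, frame = seq_len(length), state = state)
  }
  list(sequences = dplyr::bind_rows(seqs), states = dplyr::bind_rows(sts))
}

#' Simulate a tissue of labelled cell populations
#'
#' Places cells of several populations with spatially varying density in a
#' square field, recording the ground-truth region of every cell. Layouts:
#' `"blobs"` gives each population its own Gaussian blob (region = blob);
#' `"stripes"` splits the field into vertical bands, each dominated (90%)
#' by one population. Optionally emits a tubular structure — points sampled
#' along a sinusoidal "vessel" spanning the field — for structure-distance
#' analyses.
#'
#' @param n_per_population named integer vector: cells per population (>= 2
#'   populations for region analyses).
#' @param layout `"blobs"` or `"stripes"`.
#' @param image_size field side length, µm.
#' @param include_structure emit the tubular structure point table?
#' @param structure_spacing distance between consecutive tube points, µm.
#' @param seed integer seed.
#' @return list with `cells` (cell table with `population` and
#'   `region_truth`), and `structure` (point tibble or `NULL`).
#' @export
simulate_tissue <- function(n_per_population, layout = c("blobs", "stripes"),
                            image_size = 500, include_structure = FALSE,
                            structure_spacing = 2, seed = 1) {
  layout <- match.arg(layout)
  stopifnot(!is.null(names(n_per_population)), all(n_per_population >= 1))
  pops <- names(n_per_population)
  set.seed(seed)
  rows <- list()
  if (layout == "blobs") {
    # blob centres on a circle around the field centre
    k <- length(pops)
    ang <- 2 * pi * (seq_len(k) - 1) / k
    r0 <- image_size * (if (k == 1) 0 else 0.28)
    ctr <- cbind(image_size / 2 + r0 * cos(ang), image_size / 2 + r0 * sin(ang))
    sdv <- image_size / 12
    for (p in seq_along(pops)) {
      n <- n_per_population[[p]]
      xy <- cbind(stats::rnorm(n, ctr[p, 1], sdv), stats::rnorm(n, ctr[p, 2], sdv))
      xy <- pmin(pmax(xy, 0), image_size)
      rows[[p]] <- tibble::tibble(x = xy[, 1], y = xy[, 2], population = pops[p],
                                  region_truth = p)
    }
  } else {
    k <- length(pops)
    band_w <- image_size / k
    for (p in seq_along(pops)) {
      n <- n_per_population[[p]]
      # 90% of this population in its own band, 10% spread uniformly
      n_in <- round(0.9 * n)
      x_in <- stats::runif(n_in, (p - 1) * band_w, p * band_w)
      x_out <- stats::runif(n - n_in, 0, image_size)
      x <- c(x_in, x_out)
      y <- stats::runif(n, 0, image_size)
      rows[[p]] <- tibble::tibble(x = x, y = y, population = pops[p],
                                  region_truth = pmin(k, floor(x / band_w) + 1))
    }
  }
  cells <- dplyr::bind_rows(rows)
  cells <- dplyr::bind_cols(tibble::tibble(cell_id = seq_len(nrow(cells))), cells)
  structure_pts <- NULL
  if (include_structure) {
    t <- seq(0, image_size, by = structure_spacing)
    structure_pts <- tibble::tibble(
      x = t,
      y = image_size / 2 + image_size / 6 * sin(2 * pi * t / image_size),
      category = "vessel"
    )
  }
  list(cells = cells, structure = structure_pts)
}

#' Rasterise a solid ellipsoid into a label image
#'
#' Voxelises an axis-aligned (optionally rotated, 2D only) solid ellipsoid
#' into a label image, for benchmarking object measurement against the
#' closed-form gyration tensor of a uniform ellipsoid (eigenvalues
#' a^2/5, b^2/5, c^2/5 for semi-axes a, b, c).
#'
#' @param semiaxes semi-axis lengths in µm: length 2 (2D) or 3 (3D), in
#'   `x, y[, z]` order.
#' @param voxel_size isotropic voxel edge, µm.
#' @param angle optional in-plane rotation in degrees (2D only).
#' @param label label value for the object.
#' @param pad background margin in voxels around the object.
#' @return a [label_image()].
#' @export
simulate_ellipsoid_label <- function(semiaxes, voxel_size = 1, angle = 0,
                                     label = 1L, pad = 2) {
  d <- length(semiaxes)
  stopifnot(d %in% c(2, 3))
  ext <- max(semiaxes) / voxel_size + pad
  n <- ceiling(2 * ext) + 1
  centre <- (n / 2) * voxel_size
  axseq <- (seq_len(n) - 0.5) * voxel_size - centre
  if (d == 2) {
    g <- expand.grid(y = axseq, x = axseq)
    xr <- g$x; yr <- g$y
    if (angle != 0) {
      th <- angle * pi / 180
      xr2 <- cos(th) * xr + sin(th) * yr
      yr <- -sin(th) * xr + cos(th) * yr
      xr <- xr2
    }
    inside <- (xr / semiaxes[1])^2 + (yr / semiaxes[2])^2 <= 1
    arr <- array(0L, c(n, n))  # (y, x)
    arr[matrix(inside, n, n)] <- as.integer(label)
  } else {
    g <- expand.grid(z = axseq, y = axseq, x = axseq)
    inside <- (g$x / semiaxes[1])^2 + (g$y / semiaxes[2])^2 + (g$z / semiaxes[3])^2 <= 1
    arr <- array(0L, c(n, n, n))  # (z, y, x)
    arr[array(inside, c(n, n, n))] <- as.integer(label)
  }
  label_image(arr, voxel_size = voxel_size)
}
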