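#' Collective-motion flow field from track steps
#'
#' Bins every step's velocity vector into the spatial grid cell of its
#' start position and averages per bin, giving a coarse field of local mean
#' cell motion. Bins with fewer than `min_count` steps are masked (kept in
#' the output but flagged) so sparse corners do not contribute noise to the
#' anisotropy score.
#'
#' @param steps output of [step_features()] (needs the start-coordinate
#'   `x0`/`y0`(/`z0`) and step `dx`/`dy`(/`dz`) columns plus `dt_min`).
#' @param bin_size grid bin edge length, µm.
#' @param min_count minimum steps per bin for the bin to count (default 3).
#' @return a tibble of class `flow_field`: one row per populated bin with
#'   bin indices, bin-centre coordinates, mean velocity components
#'   (µm/min), `n` and `masked`; `bin_size` and `min_count` as attributes.
#' @export
flow_field <- function(steps, bin_size = 50, min_count = 3) {
  check_number(bin_size, "bin_size", 0, strict = TRUE)
  check_number(min_count, "min_count", 1)
  if (nrow(steps) == 0) {
    rlang::abort("no steps to bin", class = "celltrax_input_error")
  }
  dims <- if ("z0" %in% names(steps)) c("x", "y", "z") else c("x", "y")
  for (a in dims) {
    for (col in c(paste0(a, "0"), paste0("d", a))) {
      if (!col %in% names(steps)) {
        rlang::abort(sprintf("column `%s` required", col), class = "celltrax_schema_error")
      }
    }
  }
  vel <- as.matrix(steps[paste0("d", dims)]) / steps$dt_min
  bins <- floor(as.matrix(steps[paste0(dims, "0")]) / bin_size)
  key <- apply(bins, 1, paste, collapse = ",")
  grp <- factor(key, levels = unique(key))
  n <- as.integer(table(grp))
  mean_vel <- rowsum(vel, grp) / n
  bin_idx <- rowsum(bins, grp) / n  # constant within group
  out <- tibble::as_tibble(as.data.frame(bin_idx))
  names(out) <- paste0("bin_", dims)
  centres <- (bin_idx + 0.5) * bin_size
  colnames(centres) <- dims
  out <- dplyr::bind_cols(out, tibble::as_tibble(centres))
  mv <- tibble::as_tibble(as.data.frame(mean_vel))
  names(mv) <- paste0("v", dims)
  out <- dplyr::bind_cols(out, mv)
  out$n <- n
  out$masked <- n < min_count
  attr(out, "bin_size") <- bin_size
  attr(out, "min_count") <- min_count
  class(out) <- c("flow_field", class(out))
  out
}

#' Nematic anisotropy of a flow field
#'
#' Scores how strongly the unmasked bins' mean-velocity directions share a
#' common axis. From the unit direction vectors u of the unmasked bins the
#' orientation (nematic order) tensor Q = mean(u u^T) - I/d is formed; the
#' score is its leading eigenvalue rescaled by d/(d - 1) so that 1 means
#' all directions parallel or antiparallel and 0 means isotropic. The
#' sign-blindness (nematic symmetry) makes the score invariant under
#' reversing any subset of vectors, which is the right behaviour for
#' bidirectional collective flows. This is this package's operational
#' definition of flow anisotropy — documented here, not imported from
#' elsewhere.
#'
#' @param field a [flow_field()].
#' @return a single number in [0, 1].
#' @export
anisotropy <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  dims <- sub("^v", "", grep("^v[xyz]$", names(field), value = TRUE))
  v <- as.matrix(field[!field$masked, paste0("v", dims)])
  speed <- sqrt(rowSums(v^2))
  v <- v[speed > 0, , drop = FALSE]
  if (nrow(v) == 0) {
    rlang::abort("all bins masked or zero-velocity: anisotropy undefined",
                 class = "celltrax_input_error")
  }
  u <- v / sqrt(rowSums(v^2))
  d <- ncol(u)
  Q <- crossprod(u) / nrow(u) - diag(d) / d
  lambda1 <- max(eigen(Q, symmetric = TRUE, only.values = TRUE)$values)
  min(1, max(0, lambda1 * d / (d - 1)))
}

#' Plot a 2D flow field
#'
#' Arrow plot of per-bin mean velocities; masked bins are shown faint.
#'
#' @param object a [flow_field()] (2D).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.flow_field <- function(object, ...) {
  stopifnot(!"vz" %in% names(object))
  bin <- attr(object, "bin_size")
  sc <- 0.4 * bin / max(sqrt(object$vx^2 + object$vy^2), na.rm = TRUE)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$x + .data$vx * sc, yend = .data$y + .data$vy * sc,
                   alpha = !.data$masked),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "cm"))) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.25), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = "flow field (bin mean velocity)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
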