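#' Link objects across frames into tracks
#'
#' Simple greedy nearest-neighbour linker: for each pair of (gap-bridged)
#' frames, candidate links shorter than `max_link_dist` are taken globally
#' shortest first, one-to-one. Track ends may stay unmatched for up to
#' `max_gap` frames before the track is closed. Objects that never link to
#' anything keep `track_id` 0 (the untracked sentinel); linked chains get
#' consecutive positive ids ordered by first appearance.
#'
#' This is plumbing for data without an external tracker — adequate for
#' well-separated objects, not a probabilistic tracker.
#'
#' @param cells a cell table with `frame` and coordinate columns.
#' @param max_link_dist maximum link length in micrometres, > 0.
#' @param max_gap frames an unmatched track end survives (0 = none).
#' @return `cells` with a `track_id` column added/replaced.
#' @export
link_tracks <- function(cells, max_link_dist, max_gap = 0) {
  validate_cell_table(cells)
  check_number(max_link_dist, "max_link_dist", 0, strict = TRUE)
  check_number(max_gap, "max_gap", 0)
  if (!"frame" %in% names(cells)) {
    rlang::abort("`cells` must have a `frame` column to be linked",
                 class = "celltrax_schema_error")
  }
  frames <- sort(unique(cells$frame))
  cells$track_id <- 0L
  if (length(frames) < 2) {
    rlang::warn("single-frame input: nothing to link, all track_id set to 0")
    return(cells)
  }
  xyz <- coord_matrix(cells)
  row_of <- split(seq_len(nrow(cells)), cells$frame)
  # open track ends: row index, frame last seen, chain id
  chain <- integer(nrow(cells))    # provisional chain id per row
  next_chain <- 1L
  open_rows <- integer(0)
  for (f in frames) {
    rows_f <- row_of[[as.character(f)]]
    live <- open_rows[cells$frame[open_rows] >= f - 1 - max_gap &
                        cells$frame[open_rows] < f]
    if (length(live) && length(rows_f)) {
      dmat <- cross_dist(xyz[live, , drop = FALSE], xyz[rows_f, , drop = FALSE])
      cand <- which(dmat <= max_link_dist, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(dmat[cand], cells$cell_id[live[cand[, 1]]])  # shortest first, stable
        used_from <- logical(length(live)); used_to <- logical(length(rows_f))
        for (k in ord) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (!used_from[i] && !used_to[j]) {
            used_from[i] <- TRUE; used_to[j] <- TRUE
            from_row <- live[i]; to_row <- rows_f[j]
            if (chain[from_row] == 0L) {
              chain[from_row] <- next_chain
              next_chain <- next_chain + 1L
            }
            chain[to_row] <- chain[from_row]
          }
        }
        open_rows <- setdiff(open_rows, live[used_from])
      }
    }
    open_rows <- c(open_rows, rows_f)
    open_rows <- open_rows[cells$frame[open_rows] >= f - max_gap]
  }
  # chains with >= 2 points become tracks, renumbered by first appearance
  linked <- chain > 0L
  if (any(linked)) {
    first_row <- vapply(split(seq_len(nrow(cells))[linked], chain[linked]),
                        min, integer(1))
    remap <- stats::setNames(rank(first_row, ties.method = "first"), names(first_row))
    cells$track_id[linked] <- as.integer(remap[as.character(chain[linked])])
  }
  cells
}

#' Per-step track kinematics
#'
#' Computes, for every tracked object and frame-ordered consecutive pair of
#' observations, the step displacement (micrometres), speed (micrometres per
#' minute, using the true elapsed time so frame gaps do not inflate speeds)
#' and the unsigned turning angle (degrees, 0–180) between successive
#' displacement vectors. The angle is undefined (`NA`) at track starts and
#' around zero-length steps. Steps that bridge a frame gap are flagged with
#' `gap = TRUE` so downstream model fitting can drop them.
#'
#' @param cells a cell table with positive `track_id`s and `frame`.
#' @param dt_seconds acquisition interval between consecutive frames, > 0.
#' @return a tibble with one row per step: `track_id`, `frame` (step end),
#'   step components `dx`, `dy` (`dz`), start coordinates `x0`, `y0`
#'   (`z0`), `dt_min`, `displacement`, `speed`, `turning_angle`, `gap`, plus
#'   any shape-descriptor columns (`asphericity`, `prolateness`, `kappa_sq`,
#'   `volume`) present in `cells`, taken at the step's end observation.
#'   Tracks with fewer than 2 points are excluded with a message.
#' @examples
#' cells <- tibble::tibble(cell_id = 1:3, frame = 0:2, track_id = 1,
#'                         x = c(0, 10, 10), y = c(0, 0, 10))
#' step_features(cells, dt_seconds = 10)  # 10 um per 10 s = 60 um/min
#' @export
step_features <- function(cells, dt_seconds) {
  validate_cell_table(cells)
  check_number(dt_seconds, "dt_seconds", 0, strict = TRUE)
  tracked <- cells[is_tracked(cells), , drop = FALSE]
  if (nrow(tracked) == 0) {
    rlang::abort("no tracked rows (track_id > 0) in input", class = "celltrax_input_error")
  }
  cols <- coord_cols(tracked)
  shape_cols <- intersect(c("asphericity", "prolateness", "kappa_sq", "volume"),
                          names(tracked))
  tracked <- dplyr::arrange(tracked, .data$track_id, .data$frame)
  n_pts <- table(tracked$track_id)
  short <- names(n_pts)[n_pts < 2]
  if (length(short)) {
    message(sprintf("step_features: excluded %d track(s) with < 2 points", length(short)))
    tracked <- tracked[!tracked$track_id %in% as.numeric(short), , drop = FALSE]
  }
  if (nrow(tracked) == 0) {
    rlang::abort("all tracks have < 2 points", class = "celltrax_input_error")
  }
  steps <- tracked |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_modify(function(tr, key) {
      p <- as.matrix(tr[cols])
      dp <- diff(p)
      dframe <- diff(tr$frame)
      dt_min <- dframe * dt_seconds / 60
      disp <- sqrt(rowSums(dp^2))
      ang <- turning_angles(dp)
      out <- tibble::tibble(
        frame = tr$frame[-1],
        dt_min = dt_min,
        displacement = disp,
        speed = disp / dt_min,
        turning_angle = ang,
        gap = dframe > 1
      )
      start <- p[-nrow(p), , drop = FALSE]
      colnames(start) <- paste0(cols, "0")
      dpm <- dp
      colnames(dpm) <- paste0("d", cols)
      out <- dplyr::bind_cols(out, tibble::as_tibble(start), tibble::as_tibble(dpm))
      for (sc in shape_cols) out[[sc]] <- tr[[sc]][-1]
      out
    }) |>
    dplyr::ungroup()
  steps
}

# Unsigned angle (degrees) between successive displacement vectors; NA for
# the first step and wherever either vector is zero.
#' @keywords internal
turning_angles <- function(dp) {
  n <- nrow(dp)
  ang <- rep(NA_real_, n)
  if (n < 2) return(ang)
  len <- sqrt(rowSums(dp^2))
  for (i in 2:n) {
    if (len[i - 1] > 0 && len[i] > 0) {
      cosv <- sum(dp[i - 1, ] * dp[i, ]) / (len[i - 1] * len[i])
      ang[i] <- acos(max(-1, min(1, cosv))) * 180 / pi
    }
  }
  ang
}

#' Whole-track summary statistics
#'
#' Aggregates per-step kinematics into one row per track: duration, total
#' path length, net displacement, straightness (net displacement divided by
#' total path length, in [0, 1] by construction), speed summaries, mean
#' turning angle and — when shape descriptors are present — mean asphericity
#' and prolateness. A track whose total path length is zero gets
#' straightness 0 and is flagged `stationary`.
#'
#' @param steps output of [step_features()].
#' @return a tibble with one row per track.
#' @examples
#' cells <- tibble::tibble(cell_id = 1:3, frame = 0:2, track_id = 1,
#'                         x = c(0, 1, 1), y = c(0, 0, 1))
#' track_stats(step_features(cells, dt_seconds = 60))  # straightness sqrt(2)/2
#' @export
track_stats <- function(steps) {
  stopifnot(is.data.frame(steps), all(c("track_id", "displacement", "speed") %in% names(steps)))
  dcols <- grep("^d[xyz]$", names(steps), value = TRUE)
  steps |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      n_points = dplyr::n() + 1L,
      duration = sum(.data$dt_min),
      total_length = sum(.data$displacement),
      net_displacement = sqrt(sum(dplyr::across(dplyr::all_of(dcols), sum)^2)),
      straightness = ifelse(.data$total_length > 0,
                            .data$net_displacement / .data$total_length, 0),
      stationary = .data$total_length == 0,
      mean_speed = mean(.data$speed),
      median_speed = stats::median(.data$speed),
      sd_speed = ifelse(dplyr::n() > 1, stats::sd(.data$speed), 0),
      mean_turning_angle = mean(.data$turning_angle, na.rm = TRUE),
      mean_asphericity = if ("asphericity" %in% names(steps))
        mean(.data$asphericity, na.rm = TRUE) else NA_real_,
      mean_prolateness = if ("prolateness" %in% names(steps))
        mean(.data$prolateness, na.rm = TRUE) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mean_turning_angle = ifelse(is.nan(.data$mean_turning_angle), NA_real_,
                                  .data$mean_turning_angle)
    )
}
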