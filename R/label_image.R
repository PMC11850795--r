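#' Construct a label image
#'
#' A label image wraps a non-negative integer array (0 = background, positive
#' integers = object labels) together with its voxel size in micrometres per
#' axis and optional aligned intensity channels. Axis order is `(y, x)` for
#' 2D and `(z, y, x)` for 3D, matching how image stacks are stored; cell
#' tables, in contrast, carry coordinates as `x, y[, z]` — conversion between
#' the two orders is always explicit.
#'
#' @param array a 2D or 3D array of non-negative integers.
#' @param voxel_size micrometres per axis: a single number (isotropic) or one
#'   value per array axis, in array axis order.
#' @param channels optional named list of numeric arrays with the same shape
#'   as `array` (aligned intensity channels).
#' @return an object of class `label_image`.
#' @export
label_image <- function(array, voxel_size, channels = NULL) {
  if (!(length(dim(array)) %in% c(2, 3))) {
    rlang::abort("`array` must be 2D or 3D", class = "celltrax_parameter_error")
  }
  if (anyNA(array) || any(array < 0) || any(array != round(array))) {
    rlang::abort("labels must be non-negative integers (0 = background)",
                 class = "celltrax_type_error")
  }
  d <- length(dim(array))
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, d)
  if (length(voxel_size) != d || any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    rlang::abort("`voxel_size` must be strictly positive, one value per axis",
                 class = "celltrax_parameter_error")
  }
  if (!is.null(channels)) {
    stopifnot(is.list(channels), !is.null(names(channels)))
    for (ch in channels) {
      if (!identical(dim(ch), dim(array))) {
        rlang::abort("channel images must share the label array's shape",
                     class = "celltrax_geometry_error")
      }
    }
  }
  structure(
    list(array = array, voxel_size = as.numeric(voxel_size), channels = channels),
    class = "label_image"
  )
}

#' @export
print.label_image <- function(x, ...) {
  d <- dim(x$array)
  labs <- setdiff(unique(as.vector(x$array)), 0L)
  cat(sprintf("<label_image> %s voxels (%s), %d label(s), voxel size %s um\n",
              paste(d, collapse = " x "),
              if (length(d) == 3) "z,y,x" else "y,x",
              length(labs),
              paste(signif(x$voxel_size, 4), collapse = " x ")))
  if (!is.null(x$channels)) {
    cat(sprintf("  channels: %s\n", paste(names(x$channels), collapse = ", ")))
  }
  invisible(x)
}

#' Read a label image from TIFF
#'
#' Reads a single- or multi-page TIFF of integer labels; multi-page files
#' become 3D `(z, y, x)` stacks. Label values are preserved exactly — no
#' relabelling happens on read. Voxel size comes from the file's resolution
#' metadata when present, otherwise it must be supplied.
#'
#' @param path path to a TIFF file.
#' @param voxel_size optional micrometres-per-axis override (single value or
#'   one per axis); required when the file carries no resolution metadata.
#' @param cast if `TRUE`, a float-valued image with integral values is cast
#'   to integer labels; otherwise float pixel data is an error.
#' @return a [label_image()].
#' @export
read_label_image <- function(path, voxel_size = NULL, cast = FALSE) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("file not found: %s", path), class = "celltrax_io_error")
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  arr <- if (length(pages) == 1) {
    pages[[1]]
  } else {
    aperm(simplify2array(pages), c(3, 1, 2))  # pages become the z axis
  }
  if (is.double(arr)) {
    if (!cast) {
      rlang::abort("image has float pixel type; pass `cast = TRUE` to read integral labels",
                   class = "celltrax_type_error")
    }
    if (any(arr != round(arr))) {
      rlang::abort("float image has non-integral values; cannot cast to labels",
                   class = "celltrax_type_error")
    }
    arr <- round(arr)
  }
  if (is.null(voxel_size)) {
    xres <- attr(pages[[1]], "x.resolution")
    if (is.null(xres) || !is.finite(xres) || xres <= 0) {
      rlang::abort("no voxel-size metadata in file; supply `voxel_size`",
                   class = "celltrax_metadata_error")
    }
    voxel_size <- 1 / xres
  }
  label_image(arr, voxel_size = voxel_size)
}

#' Rasterise a point table to an intensity image
#'
#' Bins weighted points onto a pixel grid and replaces each pixel by the sum
#' of point weights within a Chebyshev (square box) distance `radius`, i.e. a
#' box kernel of side `2 * radius + 1` pixels. This is the local-sum
#' expansion used to turn transcript point clouds into viewable, analysable
#' image channels.
#'
#' @param points a data frame with numeric `x`, `y` (micrometres or pixels —
#'   the caller's unit, interpreted via `pixel_size`) and optional `weight`
#'   (default 1).
#' @param shape grid shape in pixels, `c(ny, nx)`.
#' @param pixel_size size of one pixel in the units of `x`/`y`, > 0.
#' @param radius box half-width in pixels, >= 0.
#' @param origin coordinate of the grid's lower corner, default `c(0, 0)`
#'   as `(x, y)`.
#' @return a numeric `ny x nx` matrix (row = y, column = x) with attributes
#'   `pixel_size` and `origin`. Points falling off the grid are dropped with
#'   a message.
#' @examples
#' pts <- tibble::tibble(x = 5, y = 5)
#' img <- points_to_image(pts, shape = c(10, 10), pixel_size = 1, radius = 1)
#' sum(img)  # 9: a 3x3 box of ones
#' @export
points_to_image <- function(points, shape, pixel_size, radius = 0, origin = c(0, 0)) {
  check_number(pixel_size, "pixel_size", 0, strict = TRUE)
  check_number(radius, "radius", 0)
  stopifnot(length(shape) == 2, all(shape >= 1))
  if (!all(c("x", "y") %in% names(points))) {
    rlang::abort("`points` must have `x` and `y` columns", class = "celltrax_schema_error")
  }
  if (nrow(points) > 0 && any(!is.finite(points$x) | !is.finite(points$y))) {
    rlang::abort("point positions must be finite", class = "celltrax_schema_error")
  }
  w <- if ("weight" %in% names(points)) points$weight else rep(1, nrow(points))
  if (any(w < 0)) {
    rlang::abort("weights must be >= 0", class = "celltrax_parameter_error")
  }
  ny <- shape[1]; nx <- shape[2]
  col <- floor((points$x - origin[1]) / pixel_size) + 1
  row <- floor((points$y - origin[2]) / pixel_size) + 1
  keep <- col >= 1 & col <= nx & row >= 1 & row <= ny
  if (any(!keep)) {
    message(sprintf("points_to_image: dropped %d point(s) outside the grid", sum(!keep)))
  }
  binned <- matrix(0, ny, nx)
  if (any(keep)) {
    idx <- cbind(row[keep], col[keep])
    for (i in seq_len(nrow(idx))) {
      binned[idx[i, 1], idx[i, 2]] <- binned[idx[i, 1], idx[i, 2]] + w[keep][i]
    }
  }
  r <- as.integer(radius)
  out <- if (r == 0) binned else box_sum(binned, r)
  attr(out, "pixel_size") <- pixel_size
  attr(out, "origin") <- origin
  out
}

# Box-filter sum of half-width r via an integral image (edge-clipped window).
#' @keywords internal
box_sum <- function(m, r) {
  ny <- nrow(m); nx <- ncol(m)
  cum <- rbind(0, apply(m, 2, cumsum))
  cum <- cbind(0, t(apply(cum, 1, cumsum)))
  a <- pmax(1, seq_len(ny) - r); b <- pmin(ny, seq_len(ny) + r)
  cc <- pmax(1, seq_len(nx) - r); d <- pmin(nx, seq_len(nx) + r)
  rows <- cum[b + 1, , drop = FALSE] - cum[a, , drop = FALSE]
  rows[, d + 1, drop = FALSE] - rows[, cc, drop = FALSE]
}
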