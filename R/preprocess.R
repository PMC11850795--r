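#' Channel-division spill-over correction
#'
#' Divides a signal channel by a (spill-over/autofluorescence) divisor
#' channel plus a positive offset: `signal / (divisor + offset)`. Unlike
#' channel subtraction this needs no per-image scaling factor, which makes
#' it usable for batch processing; the offset guards the division and damps
#' the correction where the divisor is dark.
#'
#' @param signal,divisor numeric arrays of identical shape (aligned channels).
#' @param offset single number > 0 added to the divisor.
#' @return numeric array of the same shape; non-negative whenever the inputs
#'   are non-negative.
#' @export
channel_division_correct <- function(signal, divisor, offset = 1) {
  check_number(offset, "offset", 0, strict = TRUE)
  if (!identical(dim(signal), dim(divisor)) || length(signal) != length(divisor)) {
    rlang::abort("`signal` and `divisor` must have identical shape",
                 class = "celltrax_geometry_error")
  }
  signal / (divisor + offset)
}

#' Merge independently produced segmentations
#'
#' Combines several label images of the same scene (e.g. one segmentation
#' per marker or cell type) into one. Conflicting voxels go to the
#' highest-priority source, priority being input order (first wins). Output
#' labels are relabelled to consecutive integers `1..L`; the provenance
#' table records which source and original label each output label came
#' from, so alternative conflict policies can be layered on later.
#'
#' @param sources list of [label_image()]s sharing shape and voxel size,
#'   highest priority first. Names, if given, become provenance source names.
#' @return list with `labels` (a merged [label_image()]) and `provenance`
#'   (tibble: `label`, `source`, `source_label`, `n_voxels`).
#' @export
merge_labels <- function(sources) {
  stopifnot(is.list(sources), length(sources) >= 1)
  if (is.null(names(sources)) || any(names(sources) == "")) {
    names(sources) <- paste0("source_", seq_along(sources))
  }
  ref <- sources[[1]]
  for (s in sources[-1]) {
    if (!identical(dim(s$array), dim(ref$array)) ||
        !isTRUE(all.equal(s$voxel_size, ref$voxel_size))) {
      rlang::abort("all sources must share shape and voxel size",
                   class = "celltrax_geometry_error")
    }
  }
  merged <- array(0L, dim(ref$array))
  owner <- array(0L, dim(ref$array))  # which source claimed the voxel
  for (k in seq_along(sources)) {
    src <- sources[[k]]$array
    claim <- merged == 0L & src > 0L
    merged[claim] <- src[claim]
    owner[claim] <- k
  }
  # relabel (source, original label) pairs to consecutive ids, priority order
  key <- paste(owner[owner > 0], merged[owner > 0])
  pairs <- unique(data.frame(
    source_idx = owner[owner > 0], source_label = merged[owner > 0]
  ))
  pairs <- pairs[order(pairs$source_idx, pairs$source_label), , drop = FALSE]
  pairs$label <- seq_len(nrow(pairs))
  lookup <- stats::setNames(pairs$label, paste(pairs$source_idx, pairs$source_label))
  out <- array(0L, dim(ref$array))
  out[owner > 0] <- lookup[key]
  counts <- table(factor(out[out > 0], levels = pairs$label))
  provenance <- tibble::tibble(
    label = pairs$label,
    source = names(sources)[pairs$source_idx],
    source_label = pairs$source_label,
    n_voxels = as.integer(counts)
  )
  list(labels = label_image(out, voxel_size = ref$voxel_size), provenance = provenance)
}

# Shape descriptors from sorted (descending) gyration-tensor eigenvalues.
# asphericity in um^2; prolateness in [-1, 1] (3D; 2D uses the eccentricity-
# like (l1 - l2)/(l1 + l2)); kappa_sq (relative shape anisotropy) in [0, 1].
#' @keywords internal
gyration_shape <- function(lambda) {
  lambda <- sort(pmax(lambda, 0), decreasing = TRUE)
  tot <- sum(lambda)
  d <- length(lambda)
  if (tot <= .Machine$double.eps) {
    return(list(asphericity = 0, prolateness = 0, kappa_sq = 0))
  }
  if (d == 3) {
    asph <- lambda[1] - (lambda[2] + lambda[3]) / 2
    mu <- lambda - mean(lambda)
    denom <- (sum(mu^2) / 3)^(3 / 2)
    prol <- if (denom > 0) sqrt(2) * prod(mu) / denom else 0
    prol <- max(-1, min(1, prol))
  } else {
    asph <- lambda[1] - lambda[2]
    prol <- (lambda[1] - lambda[2]) / tot
  }
  kappa <- (d / (d - 1)) * (sum(lambda^2) / tot^2 - 1 / d)
  list(asphericity = asph, prolateness = prol,
       kappa_sq = max(0, min(1, kappa)))
}

#' Measure labelled objects
#'
#' Extracts per-object measurements from a label image: centroid
#' (micrometres, voxel-count weighted, intensity-unweighted), volume (voxel
#' count times voxel volume; an area in 2D), per-channel mean intensity,
#' voxel-face surface extent, and shape descriptors from the
#' eigen-decomposition of the voxel-position covariance (gyration) tensor —
#' sorted eigenvalues, asphericity, prolateness and relative shape
#' anisotropy kappa^2.
#'
#' @param labels a [label_image()].
#' @param channels optional named list of intensity arrays matching the
#'   label array's shape (defaults to `labels$channels`).
#' @param ids optional integer vector of labels to measure; requesting a
#'   label absent from the image is an error.
#' @return a tibble with one row per object: `cell_id`, centroid `x`, `y`
#'   (`z` in 3D), `n_voxels`, `volume`, `surface_extent`, `mean_<channel>`
#'   columns, `lambda1..lambdaD`, `asphericity`, `prolateness`, `kappa_sq`.
#' @export
measure_objects <- function(labels, channels = NULL, ids = NULL) {
  stopifnot(inherits(labels, "label_image"))
  arr <- labels$array
  d <- length(dim(arr))
  vox <- labels$voxel_size  # array axis order: (z,)y,x
  if (is.null(channels)) channels <- labels$channels
  present <- sort(setdiff(unique(as.vector(arr)), 0L))
  if (length(present) == 0) {
    rlang::abort("label image contains no foreground objects",
                 class = "celltrax_input_error")
  }
  if (!is.null(ids)) {
    missing_ids <- setdiff(ids, present)
    if (length(missing_ids)) {
      rlang::abort(sprintf("label(s) absent from image: %s",
                           paste(missing_ids, collapse = ", ")),
                   class = "celltrax_lookup_error")
    }
    present <- sort(ids)
  }
  fg <- which(arr %in% present)
  lab <- arr[fg]
  idx <- arrayInd(fg, dim(arr))  # columns in array axis order
  # voxel centres in um, converted to x,y(,z) table order (array is (z,)y,x)
  pos_um <- sweep(idx - 0.5, 2, vox, `*`)
  xyz <- pos_um[, rev(seq_len(d)), drop = FALSE]
  grp <- factor(lab, levels = present)
  n <- as.integer(table(grp))
  cent <- rowsum(xyz, grp) / n
  # population covariance per object (gyration tensor), via second moments
  m2 <- rowsum(cbind(xyz^2, if (d == 2) xyz[, 1] * xyz[, 2] else
    cbind(xyz[, 1] * xyz[, 2], xyz[, 1] * xyz[, 3], xyz[, 2] * xyz[, 3])), grp) / n
  shp <- lapply(seq_along(present), function(i) {
    if (d == 2) {
      cov <- matrix(c(m2[i, 1] - cent[i, 1]^2, m2[i, 3] - cent[i, 1] * cent[i, 2],
                      m2[i, 3] - cent[i, 1] * cent[i, 2], m2[i, 2] - cent[i, 2]^2), 2, 2)
    } else {
      cxy <- m2[i, 4] - cent[i, 1] * cent[i, 2]
      cxz <- m2[i, 5] - cent[i, 1] * cent[i, 3]
      cyz <- m2[i, 6] - cent[i, 2] * cent[i, 3]
      cov <- matrix(c(m2[i, 1] - cent[i, 1]^2, cxy, cxz,
                      cxy, m2[i, 2] - cent[i, 2]^2, cyz,
                      cxz, cyz, m2[i, 3] - cent[i, 3]^2), 3, 3)
    }
    lambda <- sort(pmax(eigen(cov, symmetric = TRUE, only.values = TRUE)$values, 0),
                   decreasing = TRUE)
    c(list(lambda = lambda), gyration_shape(lambda))
  })
  surf <- surface_extent_by_label(arr, present, vox)
  out <- tibble::tibble(cell_id = as.integer(present))
  out$x <- unname(cent[, 1]); out$y <- unname(cent[, 2])
  if (d == 3) out$z <- unname(cent[, 3])
  out$n_voxels <- n
  out$volume <- n * prod(vox)
  out$surface_extent <- surf
  if (!is.null(channels)) {
    for (ch in names(channels)) {
      out[[paste0("mean_", ch)]] <- as.numeric(rowsum(channels[[ch]][fg], grp) / n)
    }
  }
  lam <- t(vapply(shp, function(s) s$lambda, numeric(d)))
  colnames(lam) <- paste0("lambda", seq_len(d))
  out <- dplyr::bind_cols(out, tibble::as_tibble(lam))
  out$asphericity <- vapply(shp, function(s) s$asphericity, numeric(1))
  out$prolateness <- vapply(shp, function(s) s$prolateness, numeric(1))
  out$kappa_sq <- vapply(shp, function(s) s$kappa_sq, numeric(1))
  out
}

# Exposed voxel-face area per label: faces against background, other labels,
# or the image border; in 2D this is the exposed-edge perimeter length.
#' @keywords internal
surface_extent_by_label <- function(arr, labels, vox) {
  d <- length(dim(arr))
  total <- stats::setNames(numeric(length(labels)), labels)
  for (ax in seq_len(d)) {
    face_area <- prod(vox) / vox[ax]
    n_ax <- dim(arr)[ax]
    slice <- function(i) {
      ix <- rep(list(quote(expr = )), d)
      ix[[ax]] <- i
      do.call(`[`, c(list(arr), ix, list(drop = FALSE)))
    }
    for (shift in c(-1L, 1L)) {
      here <- slice(seq_len(n_ax))
      there <- array(0L, dim(arr))
      src <- if (shift == 1L) seq_len(n_ax - 1L) else seq(2L, n_ax)
      dst <- if (shift == 1L) seq(2L, n_ax) else seq_len(n_ax - 1L)
      ix <- rep(list(quote(expr = )), d)
      ix[[ax]] <- dst
      there <- do.call(`[<-`, c(list(there), ix, list(value = slice(src))))
      exposed <- here > 0L & here != there
      tab <- table(factor(here[exposed], levels = labels))
      total <- total + as.numeric(tab) * face_area
    }
  }
  as.numeric(total)
}
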