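#' @keywords internal
coord_cols <- function(cells) {
  stopifnot(is.data.frame(cells))
  cols <- intersect(c("x", "y", "z"), names(cells))
  if (!all(c("x", "y") %in% cols)) {
    rlang::abort("cell table must contain numeric `x` and `y` columns (micrometres)",
                 class = "celltrax_schema_error")
  }
  cols
}

#' @keywords internal
coord_matrix <- function(cells) {
  cols <- coord_cols(cells)
  m <- as.matrix(cells[cols])
  storage.mode(m) <- "double"
  if (anyNA(m) || any(!is.finite(m))) {
    rlang::abort("coordinates must be finite", class = "celltrax_schema_error")
  }
  m
}

# Euclidean distance from each row of `a` to each row of `b` (dense; callers
# keep n modest or chunk).
#' @keywords internal
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' @keywords internal
check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > lower else x >= lower)
  if (!ok) {
    cmp <- if (strict) ">" else ">="
    rlang::abort(sprintf("`%s` must be a single finite number %s %s", name, cmp, lower),
                 class = "celltrax_parameter_error")
  }
  invisible(x)
}

# Deterministic per-index jitter in (-1, 1), independent of the R RNG state.
# Used to break exact geometric degeneracies reproducibly.
#' @keywords internal
index_jitter <- function(n, dim) {
  i <- seq_len(n)
  sapply(seq_len(dim), function(d) {
    x <- sin(i * (d * 7919 + 104729) + d * 0.61803398875)
    x - round(x / 2) * 2
  })
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions (up to label names), about 0 for independent
#' ones. Used to score cluster/region recovery against simulation truth.
#'
#' @param a,b vectors of cluster labels, equal length.
#' @return a single number, at most 1.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
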