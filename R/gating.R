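#' Define a 2D gate
#'
#' A gate is a named 2D shape drawn over two cell-table columns, optionally
#' after a `log10(v + 1)` axis transform (which admits zero intensities).
#' Gates nest: a cell belongs to a gate only if it also belongs to the
#' gate's parent, so a tree of gates defines nested populations exactly as
#' in flow-cytometry practice.
#'
#' @param name unique gate name.
#' @param x_axis,y_axis cell-table column names the gate is drawn over.
#' @param vertices polygon vertices as a 2-column matrix/data frame (>= 3
#'   vertices, in transformed axis units), or `NULL` when `rect` is given.
#' @param rect rectangle as `c(xmin, xmax, ymin, ymax)` (converted to a
#'   4-vertex polygon).
#' @param parent parent gate name, `"root"` for top-level gates.
#' @param transform_x,transform_y `"linear"` or `"log10"` per axis.
#' @return a `gate` object.
#' @export
gate <- function(name, x_axis, y_axis, vertices = NULL, rect = NULL,
                 parent = "root", transform_x = "linear", transform_y = "linear") {
  stopifnot(is.character(name), nchar(name) > 0)
  transform_x <- match.arg(transform_x, c("linear", "log10"))
  transform_y <- match.arg(transform_y, c("linear", "log10"))
  if (is.null(vertices)) {
    stopifnot(length(rect) == 4)
    vertices <- cbind(rect[c(1, 2, 2, 1)], rect[c(3, 3, 4, 4)])
  }
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3 || ncol(vertices) != 2 || anyNA(vertices)) {
    rlang::abort("a polygon gate needs >= 3 finite 2D vertices",
                 class = "celltrax_parameter_error")
  }
  structure(list(name = name, parent = parent, x_axis = x_axis, y_axis = y_axis,
                 vertices = unname(vertices),
                 transform_x = transform_x, transform_y = transform_y),
            class = "gate")
}

#' Assemble gates into a gating tree
#'
#' @param ... `gate` objects (or a single list of them).
#' @return a `gating_tree` object; construction fails on duplicate names,
#'   unknown parents or parent cycles.
#' @export
gating_tree <- function(...) {
  gates <- list(...)
  if (length(gates) == 1 && !inherits(gates[[1]], "gate")) gates <- gates[[1]]
  stopifnot(all(vapply(gates, inherits, logical(1), "gate")))
  names(gates) <- vapply(gates, `[[`, character(1), "name")
  if (anyDuplicated(names(gates))) {
    rlang::abort("duplicate gate names", class = "celltrax_structure_error")
  }
  for (g in gates) {
    if (g$parent != "root" && !g$parent %in% names(gates)) {
      rlang::abort(sprintf("gate `%s` has unknown parent `%s`", g$name, g$parent),
                   class = "celltrax_structure_error")
    }
  }
  # cycle check by walking each gate to root
  for (g in gates) {
    seen <- character(0); cur <- g$name
    while (cur != "root") {
      if (cur %in% seen) {
        rlang::abort("cycle in gating tree", class = "celltrax_structure_error")
      }
      seen <- c(seen, cur)
      cur <- gates[[cur]]$parent
    }
  }
  structure(list(gates = gates), class = "gating_tree")
}

#' @export
print.gating_tree <- function(x, ...) {
  cat(sprintf("<gating_tree> %d gate(s)\n", length(x$gates)))
  for (g in x$gates) {
    cat(sprintf("  %s (parent: %s) on %s x %s\n", g$name, g$parent, g$x_axis, g$y_axis))
  }
  invisible(x)
}

# Boundary-inclusive even-odd point-in-polygon. Points exactly on an edge or
# vertex count as inside (gates drawn through points behave predictably).
#' @keywords internal
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # boundary test: collinear and within the segment's bounding box
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    on_seg <- cross == 0 &
      px >= pmin(x1, x2) & px <= pmax(x1, x2) &
      py >= pmin(y1, y2) & py <= pmax(y1, y2)
    on_edge <- on_edge | on_seg
    # even-odd crossing of a horizontal ray towards +x
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' @keywords internal
gate_transform <- function(v, transform) {
  if (transform == "log10") log10(v + 1) else v
}

#' Evaluate a gating tree over a cell table
#'
#' Applies every gate's polygon (boundary-inclusive even-odd point-in-
#' polygon on transformed coordinates) top-down, intersecting each gate's
#' membership with its parent's, and asserts the nesting invariant
#' (child subset of parent) after evaluation.
#'
#' @param tree a [gating_tree()].
#' @param cells a cell table containing all referenced columns (numeric).
#' @return a tibble: `cell_id` plus one logical column per gate.
#' @export
evaluate_gates <- function(tree, cells) {
  stopifnot(inherits(tree, "gating_tree"))
  validate_cell_table(cells)
  memb <- list(root = rep(TRUE, nrow(cells)))
  remaining <- tree$gates
  out <- tibble::tibble(cell_id = cells$cell_id)
  while (length(remaining)) {
    ready <- vapply(remaining, function(g) g$parent %in% names(memb), logical(1))
    for (g in remaining[ready]) {
      for (col in c(g$x_axis, g$y_axis)) {
        if (!col %in% names(cells)) {
          rlang::abort(sprintf("gate `%s` references missing column `%s`", g$name, col),
                       class = "celltrax_schema_error")
        }
        if (!is.numeric(cells[[col]])) {
          rlang::abort(sprintf("gate axis column `%s` must be numeric", col),
                       class = "celltrax_schema_error")
        }
      }
      px <- gate_transform(cells[[g$x_axis]], g$transform_x)
      py <- gate_transform(cells[[g$y_axis]], g$transform_y)
      inside <- point_in_polygon(px, py, g$vertices[, 1], g$vertices[, 2])
      memb[[g$name]] <- inside & memb[[g$parent]]
      stopifnot(all(!memb[[g$name]] | memb[[g$parent]]))  # child subset of parent
      out[[g$name]] <- memb[[g$name]]
    }
    remaining <- remaining[!ready]
  }
  out
}

#' Filtered (rule-based) populations
#'
#' Defines a population by a predicate over cell-table columns. The
#' built-in rule `"tracked"` is exactly `track_id > 0` — the membership
#' rule separating tracked from untracked objects. Any other rule is parsed
#' as an R expression over the table's columns (e.g.
#' `"behaviour_cluster == 2"`); a bare name that is neither a built-in rule
#' nor an expression yielding a logical is an error.
#'
#' @param cells a cell table.
#' @param rule `"tracked"` or a predicate expression as a string.
#' @return logical vector, one entry per row.
#' @export
filtered_population <- function(cells, rule) {
  validate_cell_table(cells)
  stopifnot(is.character(rule), length(rule) == 1)
  if (rule == "tracked") return(is_tracked(cells))
  if (grepl("^[A-Za-z._][A-Za-z0-9._]*$", rule)) {
    rlang::abort(sprintf("unknown rule name `%s`", rule),
                 class = "celltrax_lookup_error")
  }
  expr <- tryCatch(rlang::parse_expr(rule), error = function(e) {
    rlang::abort(sprintf("cannot parse rule: %s", rule),
                 class = "celltrax_lookup_error")
  })
  res <- rlang::eval_tidy(expr, data = cells)
  if (!is.logical(res) || length(res) != nrow(cells)) {
    rlang::abort("rule must evaluate to one logical per row",
                 class = "celltrax_lookup_error")
  }
  res
}

#' Read / write gate definitions as JSON
#'
#' Gates serialise to a portable JSON array of objects with fields `name`,
#' `parent`, `x_axis`, `y_axis`, `transform_x`, `transform_y`, `vertices`.
#'
#' @param path JSON file path.
#' @return `read_gates()` returns a [gating_tree()]; `write_gates()` the
#'   path, invisibly.
#' @export
read_gates <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  gates <- lapply(raw, function(g) {
    verts <- if (is.list(g$vertices)) do.call(rbind, g$vertices) else
      as.matrix(g$vertices)
    gate(name = g$name, parent = g$parent %||% "root",
         x_axis = g$x_axis, y_axis = g$y_axis,
         vertices = verts,
         transform_x = g$transform_x %||% "linear",
         transform_y = g$transform_y %||% "linear")
  })
  gating_tree(gates)
}

#' @rdname read_gates
#' @param tree a [gating_tree()].
#' @export
write_gates <- function(tree, path) {
  stopifnot(inherits(tree, "gating_tree"))
  out <- lapply(unname(tree$gates), function(g) {
    list(name = g$name, parent = g$parent, x_axis = g$x_axis, y_axis = g$y_axis,
         transform_x = g$transform_x, transform_y = g$transform_y,
         vertices = lapply(seq_len(nrow(g$vertices)),
                           function(i) as.numeric(g$vertices[i, ])))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
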