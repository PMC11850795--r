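#' Validate a cell table
#'
#' Checks the core table contract: `cell_id` present, integer-valued and
#' >= 1; `(cell_id, frame)` pairs unique (plain `cell_id` uniqueness when no
#' `frame` column exists); coordinates `x`, `y` (and optionally `z`) numeric
#' and finite; `track_id`, when present, integer-valued and >= 0 (0 is the
#' untracked sentinel). Returns the table invisibly so it can sit in a pipe.
#'
#' @param cells a data frame following the cell-table contract.
#' @return `cells`, invisibly.
#' @export
validate_cell_table <- function(cells) {
  if (!is.data.frame(cells)) {
    rlang::abort("`cells` must be a data frame", class = "celltrax_schema_error")
  }
  if (!"cell_id" %in% names(cells)) {
    rlang::abort("missing required column `cell_id`", class = "celltrax_schema_error")
  }
  coord_matrix(cells)
  id <- cells$cell_id
  if (!is.numeric(id) || (nrow(cells) > 0 && (anyNA(id) || any(id < 1) || any(id != round(id))))) {
    rlang::abort("`cell_id` must be integer-valued and >= 1", class = "celltrax_schema_error")
  }
  key <- if ("frame" %in% names(cells)) paste(id, cells$frame) else as.character(id)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    rlang::abort(sprintf("duplicate (cell_id, frame) pair: %s", dup),
                 class = "celltrax_integrity_error")
  }
  if ("frame" %in% names(cells) && nrow(cells) > 0 &&
      (anyNA(cells$frame) || any(cells$frame < 0) || any(cells$frame != round(cells$frame)))) {
    rlang::abort("`frame` must be integer-valued and >= 0", class = "celltrax_schema_error")
  }
  if ("track_id" %in% names(cells) && nrow(cells) > 0) {
    tid <- cells$track_id
    if (!is.numeric(tid) || anyNA(tid) || any(tid < 0) || any(tid != round(tid))) {
      rlang::abort("`track_id` must be integer-valued and >= 0 (0 = untracked)",
                   class = "celltrax_schema_error")
    }
  }
  invisible(cells)
}

#' Read a cell table from CSV
#'
#' Reads a comma-separated, UTF-8, headered file of per-object (optionally
#' per-timepoint) records and maps its columns onto the cell-table contract.
#' Unmapped columns are kept untouched as extra label/measurement columns.
#'
#' @param path path to a CSV file.
#' @param column_map named character vector mapping contract names to file
#'   column names, e.g. `c(cell_id = "id", x = "pos_x", y = "pos_y")`.
#'   Contract names: `cell_id`, `x`, `y`, `z`, `frame`, `track_id`. Names
#'   already matching the contract need no entry.
#' @param dim dimensionality, 2 or 3; with `dim = 3` a `z` column is required.
#' @return a validated tibble following the cell-table contract.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("id,x,y", "1,0,0", "2,5,5", "3,9,1"), tf)
#' read_cell_table(tf, column_map = c(cell_id = "id"))
#' @export
read_cell_table <- function(path, column_map = NULL, dim = 2) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("file not found: %s", path), class = "celltrax_io_error")
  }
  if (!dim %in% c(2, 3)) {
    rlang::abort("`dim` must be 2 or 3", class = "celltrax_parameter_error")
  }
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(column_map)) {
    missing_src <- setdiff(unname(column_map), names(tab))
    if (length(missing_src)) {
      rlang::abort(sprintf("mapped column(s) absent from file: %s",
                           paste(missing_src, collapse = ", ")),
                   class = "celltrax_schema_error")
    }
    for (target in names(column_map)) {
      names(tab)[names(tab) == column_map[[target]]] <- target
    }
  }
  required <- c("cell_id", "x", "y", if (dim == 3) "z")
  missing_req <- setdiff(required, names(tab))
  if (length(missing_req)) {
    rlang::abort(sprintf("missing required column(s): %s",
                         paste(missing_req, collapse = ", ")),
                 class = "celltrax_schema_error")
  }
  for (col in intersect(c("x", "y", "z"), names(tab))) {
    if (!is.numeric(tab[[col]])) {
      rlang::abort(sprintf("coordinate column `%s` must be numeric", col),
                   class = "celltrax_schema_error")
    }
  }
  validate_cell_table(tibble::as_tibble(tab))
  tibble::as_tibble(tab)
}

#' Write a cell table to CSV
#'
#' Inverse of [read_cell_table()]: plain comma-separated UTF-8 with a header
#' row; read-write-read round trips are value-identical for all columns.
#'
#' @param cells a cell table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  validate_cell_table(cells)
  readr::write_csv(cells, path, progress = FALSE)
  invisible(path)
}

#' Tracked-cell membership
#'
#' A row belongs to the tracked population exactly when its `track_id` is
#' above 0; 0 (or a missing `track_id` column) marks untracked objects.
#'
#' @param cells a cell table.
#' @return logical vector, one entry per row.
#' @export
is_tracked <- function(cells) {
  if (!"track_id" %in% names(cells)) return(rep(FALSE, nrow(cells)))
  cells$track_id > 0
}
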