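#' Hexagonal cell lattice with periodic boundaries
#'
#' Builds the topology of a grid of hexagonal cells used by the segment
#' polarity network model.  Each cell has six membrane sides, numbered 1..6
#' clockwise.  Side 5 faces the next cell along the anterior--posterior
#' (column) axis and side 2 the previous one, so that side 5 of
#' `cell(0,1)` apposes side 2 of `cell(0,2)`.  The remaining four sides are
#' diagonal and appose cells in the rows above/below; both lattice
#' directions wrap around (toroidal boundary).  In a 1-row grid the
#' diagonal neighbors wrap back into the same row, so each cell effectively
#' apposes its left and right column neighbors three times each.
#'
#' @param n_rows,n_cols positive integers, grid dimensions.
#' @return An object of class `spn_grid` with elements `n_rows`, `n_cols`,
#'   `n_cells`, `cells` (data frame of 0-based `row`, `col`), and
#'   `neighbor`, an `n_cells x 6` integer matrix giving the 0-based index
#'   of the cell apposed across each side.
#' @examples
#' g <- make_grid(1, 4)
#' apposed(g, c(0, 1), 5)   # cell (0,2), side 2
#' @export
make_grid <- function(n_rows, n_cols) {
  if (length(n_rows) != 1L || length(n_cols) != 1L ||
      !is.finite(n_rows) || !is.finite(n_cols) ||
      n_rows < 1 || n_cols < 1 ||
      n_rows != round(n_rows) || n_cols != round(n_cols)) {
    stop("'n_rows' and 'n_cols' must be positive integers", call. = FALSE)
  }
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  n_cells <- n_rows * n_cols
  cells <- data.frame(
    row = rep(seq_len(n_rows) - 1L, each = n_cols),
    col = rep(seq_len(n_cols) - 1L, times = n_rows)
  )
  nbr <- matrix(NA_integer_, nrow = n_cells, ncol = 6L)
  off <- .side_offsets()
  for (i in seq_len(n_cells)) {
    r <- cells$row[i]; cc <- cells$col[i]
    for (j in 1:6) {
      rn <- (r + off[j, 1L]) %% n_rows
      cn <- (cc + off[j, 2L]) %% n_cols
      nbr[i, j] <- rn * n_cols + cn
    }
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols, n_cells = n_cells,
         boundary = "periodic", cells = cells, neighbor = nbr),
    class = "spn_grid"
  )
}

# Row/column offsets of the cell apposed across sides 1..6.  Sides 5/2 are
# the posterior/anterior column neighbors; the four diagonal sides reach
# the rows above (1, 6) and below (3, 4), one column to the right (1, 3)
# or left (4, 6).  Opposite sides carry opposite offsets, which makes the
# apposition map an involution on any toroidal grid.
.side_offsets <- function() {
  matrix(c(-1L, +1L,   # side 1
            0L, -1L,   # side 2
           +1L, +1L,   # side 3
           +1L, -1L,   # side 4
            0L, +1L,   # side 5
           -1L, -1L),  # side 6
         ncol = 2L, byrow = TRUE)
}

#' Apposed (cell, side) pair across a membrane
#'
#' For a cell and one of its six sides, returns the neighboring cell and
#' the neighbor's side that is in physical contact.  The apposed side index
#' is always the opposite one: 1<->4, 2<->5, 3<->6.
#'
#' @param grid an `spn_grid`.
#' @param cell integer vector `c(row, col)`, 0-based.
#' @param side integer in 1..6.
#' @return list with elements `cell` (0-based `c(row, col)`) and `side`.
#' @export
apposed <- function(grid, cell, side) {
  stopifnot(inherits(grid, "spn_grid"))
  .check_side(side)
  if (length(cell) != 2L || any(cell < 0) ||
      cell[1L] >= grid$n_rows || cell[2L] >= grid$n_cols) {
    stop("'cell' must be c(row, col) within the grid (0-based)", call. = FALSE)
  }
  i <- cell[1L] * grid$n_cols + cell[2L] + 1L
  nb <- grid$neighbor[i, side]
  list(cell = c(nb %/% grid$n_cols, nb %% grid$n_cols),
       side = opposite_side(side))
}

#' @rdname apposed
#' @export
opposite_side <- function(side) {
  .check_side(side)
  as.integer(((side + 2L) %% 6L) + 1L)
}

#' Within-membrane adjacent sides
#'
#' The two sides of the same hexagonal cell that are cyclically adjacent to
#' `side`; membrane proteins diffuse between a side and these two.
#'
#' @param side integer in 1..6.
#' @return integer vector of length 2.
#' @examples
#' adjacent_sides(5)  # 6 and 4
#' @export
adjacent_sides <- function(side) {
  .check_side(side)
  as.integer(c((side %% 6L) + 1L, ((side + 4L) %% 6L) + 1L))
}

.check_side <- function(side) {
  if (length(side) != 1L || !is.finite(side) || side != round(side) ||
      side < 1 || side > 6) {
    stop("'side' must be an integer in 1..6", call. = FALSE)
  }
}

#' @export
print.spn_grid <- function(x, ...) {
  cat(sprintf("<spn_grid> %d x %d hexagonal cells, %s boundaries (%d (cell, side) pairs)\n",
              x$n_rows, x$n_cols, x$boundary, 6L * x$n_cells))
  invisible(x)
}

#' Serialize a grid topology to JSON (debugging aid)
#' @param grid an `spn_grid`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
grid_to_json <- function(grid, path = NULL) {
  stopifnot(inherits(grid, "spn_grid"))
  obj <- list(n_rows = grid$n_rows, n_cols = grid$n_cols,
              boundary = grid$boundary, neighbor = grid$neighbor)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
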