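#' Assemble the segment polarity network model on a cell grid
#'
#' Builds the full multicellular model: 33 dynamic species per cell
#' (5 mRNAs `en`, `wg`, `ptc`, `ci`, `hh`; 4 cytosolic proteins `EN`,
#' `IWG`, `CI`, `CN`; 4 membrane proteins `EWG`, `PTC`, `HH`, `PH` in six
#' per-side pools), wired by the regulatory network of the segment
#' polarity circuit, with 53 shared global parameters.  A 1x4 grid gives
#' the standard 132-species model.
#'
#' Species identifiers follow `<name><side>_<row>_<col>` (e.g.
#' `EWG5_0_1`).  The derived totals `EWG_T` (sum of the six apposed
#' neighbor EWG pools), `PTC_T` and `PH_T` (within-cell sums) are not
#' dynamic species; see [spn_totals()].
#'
#' @param n_rows,n_cols grid dimensions (positive integers).
#' @param params parameter registry, see [spn_parameters()].
#' @param guard guard configuration, see [guard_config()].
#' @return An object of class `spn_model`.
#' @examples
#' m <- build_model(1, 4)
#' m$n_species   # 132
#' @export
build_model <- function(n_rows = 1, n_cols = 4, params = spn_parameters(),
                        guard = guard_config()) {
  grid <- make_grid(n_rows, n_cols)
  .new_spn_model(grid, params, guard, single_cell = FALSE, boundary = NULL)
}

#' Single-cell model with fixed neighbor concentrations
#'
#' Builds the one-cell variant in which every species read from a
#' neighboring cell (the six `EWG`, `PTC` and `HH` pools apposed to this
#' cell) is replaced by a fixed concentration.  `boundary_values` must
#' name all 18 pools as `EWG1..EWG6`, `PTC1..PTC6`, `HH1..HH6`, indexed by
#' the *neighbor's* side.
#'
#' @param params parameter registry.
#' @param boundary_values named numeric vector of length 18.
#' @param guard guard configuration.
#' @return An `spn_model` with 33 species and `single_cell = TRUE`.
#' @export
build_single_cell <- function(params = spn_parameters(), boundary_values,
                              guard = guard_config()) {
  need <- c(paste0("EWG", 1:6), paste0("PTC", 1:6), paste0("HH", 1:6))
  if (missing(boundary_values) || is.null(names(boundary_values)) ||
      !all(need %in% names(boundary_values))) {
    miss <- if (missing(boundary_values)) need
            else setdiff(need, names(boundary_values))
    stop("incomplete boundary map; missing: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bv <- as.numeric(boundary_values[need])
  if (any(!is.finite(bv))) stop("boundary values must be finite", call. = FALSE)
  grid <- make_grid(1, 1)
  .new_spn_model(grid, params, guard, single_cell = TRUE, boundary = bv)
}

.canonical_param_names <- function() spn_parameters()$name

.new_spn_model <- function(grid, params, guard, single_cell, boundary) {
  stopifnot(inherits(guard, "spn_guard"))
  canon <- .canonical_param_names()
  if (!is.data.frame(params) || !all(c("name", "value") %in% names(params))) {
    stop("'params' must be a data frame with 'name' and 'value'",
         call. = FALSE)
  }
  idx <- match(canon, params$name)
  if (anyNA(idx)) {
    stop("missing parameter: ", canon[is.na(idx)][1L], call. = FALSE)
  }
  params <- params[idx, , drop = FALSE]
  rownames(params) <- NULL
  v <- params$value
  if (any(!is.na(v) & v < 0) || anyNA(v)) {
    stop("parameter values must be non-negative numbers", call. = FALSE)
  }
  H <- v[params$category == "half_life" & startsWith(params$name, "H_")]
  if (any(H <= 0)) stop("half-lives must be positive", call. = FALSE)

  nbr <- grid$neighbor
  if (single_cell) nbr[] <- -1L

  species <- .species_table(grid)
  structure(
    list(grid = grid, params = params, guard = guard,
         single_cell = single_cell, boundary = boundary,
         neighbor = nbr, species = species,
         n_species = nrow(species)),
    class = "spn_model"
  )
}

# Per-cell species layout; must match the compiled right-hand side.
.species_layout <- function() {
  base <- c("en", "wg", "ptc", "ci", "hh", "EN", "IWG", "CI", "CN")
  mem <- c(paste0("EWG", 1:6), paste0("PTC", 1:6),
           paste0("HH", 1:6), paste0("PH", 1:6))
  data.frame(
    name = c("en", "wg", "ptc", "ci", "hh", "EN", "IWG", "CI", "CN",
             rep(c("EWG", "PTC", "HH", "PH"), each = 6L)),
    label = c(base, mem),
    side = c(rep(NA_integer_, 9L), rep(1:6, times = 4L))
  )
}

.species_table <- function(grid) {
  lay <- .species_layout()
  n <- grid$n_cells
  out <- lay[rep(seq_len(nrow(lay)), times = n), , drop = FALSE]
  out$cell <- rep(seq_len(n) - 1L, each = nrow(lay))
  out$row <- grid$cells$row[out$cell + 1L]
  out$col <- grid$cells$col[out$cell + 1L]
  out$id <- paste0(out$label, "_", out$row, "_", out$col)
  rownames(out) <- NULL
  out[c("id", "name", "label", "side", "cell", "row", "col")]
}

#' @export
print.spn_model <- function(x, ...) {
  cat(sprintf(
    "<spn_model> segment polarity network, %d x %d cells%s\n  %d dynamic species, %d parameters (%d sampled), guard %s (epsilon = %g)\n",
    x$grid$n_rows, x$grid$n_cols,
    if (x$single_cell) " (single cell, fixed boundary)" else "",
    x$n_species, nrow(x$params), sum(x$params$sampled),
    if (x$guard$enabled) "on" else "off", x$guard$epsilon))
  invisible(x)
}

# Named parameter value lookup
.pv <- function(model, name) {
  model$params$value[match(name, model$params$name)]
}

# Install the model into the compiled evaluator (static C-side state).
.spn_activate <- function(model) {
  .Call(C_spn_set_model,
        as.numeric(model$params$value),
        as.integer(t(model$neighbor)),
        model$guard$enabled,
        model$guard$epsilon,
        if (is.null(model$boundary)) numeric(0) else model$boundary)
  invisible(model)
}

#' Compile the model into an ODE right-hand side
#'
#' Returns a pure function `f(state, t = 0)` evaluating the full
#' derivative vector through the compiled core.  The state must be in the
#' model's species order (see `model$species$id`).
#'
#' @param model an `spn_model`.
#' @return function mapping a numeric state vector to its derivative.
#' @export
compile_rhs <- function(model) {
  stopifnot(inherits(model, "spn_model"))
  force(model)
  function(state, t = 0) {
    if (length(state) != model$n_species) {
      stop(sprintf("state length %d does not match model (%d species)",
                   length(state), model$n_species), call. = FALSE)
    }
    .spn_activate(model)
    .Call(C_spn_rhs, as.numeric(state))
  }
}

#' Derived totals per cell
#'
#' `PTC_T` and `PH_T` are the within-cell sums of the six `PTC` and `PH`
#' pools; `EWG_T` is the total EWG in the membranes of the six neighboring
#' cells apposed to the cell (the pools a cell's `en` promoter actually
#' sees).
#'
#' @param model an `spn_model`.
#' @param state numeric state vector (or a matrix with one state per row).
#' @return matrix with one row per state and columns
#'   `EWG_T_<r>_<c>`, `PTC_T_<r>_<c>`, `PH_T_<r>_<c>` for each cell.
#' @export
spn_totals <- function(model, state) {
  stopifnot(inherits(model, "spn_model"))
  if (is.null(dim(state))) state <- matrix(state, nrow = 1L)
  n <- model$grid$n_cells
  sp <- model$species
  out <- matrix(0, nrow = nrow(state), ncol = 3L * n)
  cn <- character(3L * n)
  for (c0 in seq_len(n) - 1L) {
    r <- model$grid$cells$row[c0 + 1L]; cc <- model$grid$cells$col[c0 + 1L]
    ewg_idx <- integer(6)
    for (j in 1:6) {
      nb <- model$neighbor[c0 + 1L, j]
      jop <- opposite_side(j)
      ewg_idx[j] <- if (nb >= 0) nb * 33L + 9L + jop else NA_integer_
    }
    ewg_idx <- ewg_idx[!is.na(ewg_idx)]
    ptc_idx <- c0 * 33L + 15L + 1:6
    ph_idx <- c0 * 33L + 27L + 1:6
    ewg_T <- if (length(ewg_idx)) rowSums(state[, ewg_idx, drop = FALSE])
             else {
               bv <- model$boundary
               rep(sum(bv[1:6]), nrow(state))
             }
    out[, 3L * c0 + 1L] <- ewg_T
    out[, 3L * c0 + 2L] <- rowSums(state[, ptc_idx, drop = FALSE])
    out[, 3L * c0 + 3L] <- rowSums(state[, ph_idx, drop = FALSE])
    cn[3L * c0 + 1:3] <- paste0(c("EWG_T_", "PTC_T_", "PH_T_"), r, "_", cc)
  }
  colnames(out) <- cn
  out
}
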