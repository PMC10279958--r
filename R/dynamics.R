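#' Toy one-variable models for testing the dynamics machinery
#'
#' `toy_decay()` is `dx/dt = -x` (solution `exp(-t)` from `x0 = 1`);
#' `toy_bistable()` is `dx/dt = x (1 - x) (x - 0.3)` with stable fixed
#' points 0 and 1 and a separatrix at 0.3; `toy_oscillator()` is the
#' undamped harmonic oscillator, which never reaches a steady state.
#'
#' @return object of class `spn_ode` usable with [run_timecourse()] and
#'   [find_steady_state()].
#' @export
toy_decay <- function() {
  structure(list(n_species = 1L, species_ids = "x",
                 rhs_r = function(t, y) -y, label = "toy_decay"),
            class = "spn_ode")
}

#' @rdname toy_decay
#' @export
toy_bistable <- function() {
  structure(list(n_species = 1L, species_ids = "x",
                 rhs_r = function(t, y) y * (1 - y) * (y - 0.3),
                 label = "toy_bistable", attractors = c(0, 1)),
            class = "spn_ode")
}

#' @rdname toy_decay
#' @export
toy_oscillator <- function() {
  structure(list(n_species = 2L, species_ids = c("x", "v"),
                 rhs_r = function(t, y) c(y[2L], -y[1L]),
                 label = "toy_oscillator"),
            class = "spn_ode")
}

.n_state <- function(model) {
  if (inherits(model, "spn_model")) model$n_species else model$n_species
}

.state_ids <- function(model) {
  if (inherits(model, "spn_model")) model$species$id else model$species_ids
}

# Evaluate the RHS of any supported model at a state.
.rhs_at <- function(model, state, t = 0) {
  if (inherits(model, "spn_model")) {
    .spn_activate(model)
    .Call(C_spn_rhs, as.numeric(state))
  } else if (inherits(model, "spn_ode")) {
    model$rhs_r(t, as.numeric(state))
  } else if (inherits(model, "sbml_model")) {
    sbml_rhs(model)(state, t)
  } else {
    stop("unsupported model class", call. = FALSE)
  }
}

# One deSolve integration; returns the raw deSolve matrix or NULL on error.
.integrate <- function(model, x0, times, atol, rtol, maxsteps) {
  if (inherits(model, "spn_model")) {
    .spn_activate(model)
    out <- try(suppressWarnings(
      deSolve::lsoda(y = as.numeric(x0), times = times,
                     func = "spn_derivs", dllname = "spnsim",
                     initfunc = "spn_init", parms = numeric(0),
                     atol = atol, rtol = rtol, maxsteps = maxsteps)),
      silent = TRUE)
  } else {
    f <- if (inherits(model, "spn_ode")) {
      function(t, y, p) list(model$rhs_r(t, y))
    } else {
      rhs <- sbml_rhs(model)
      function(t, y, p) list(rhs(y, t))
    }
    out <- try(suppressWarnings(
      deSolve::lsoda(y = as.numeric(x0), times = times, func = f,
                     parms = NULL, atol = atol, rtol = rtol,
                     maxsteps = maxsteps)),
      silent = TRUE)
  }
  if (inherits(out, "try-error")) NULL else out
}

#' Run a time course
#'
#' Integrates the model with a stiff-capable solver (LSODA), sampling the
#' state on a regular output grid.  Defaults follow the reference
#' simulation protocol: end time 1100 time units sampled every 5, absolute
#' tolerance 1e-13, relative tolerance 1e-8.  Solver failures never raise:
#' the trajectory `status` is `"ok"`, `"invalid_state"` (non-finite values
#' were produced; possible with guards off) or `"no_convergence"`.
#'
#' @param model an `spn_model`, `spn_ode` toy model, or imported
#'   `sbml_model`.
#' @param x0 initial state vector.
#' @param t_end,dt_out end time and output interval.
#' @param atol,rtol solver tolerances.
#' @param maxsteps solver step budget per output interval.
#' @return object of class `spn_trajectory`: list with `times`, `states`
#'   (time x species matrix, columns named by species id), `status`,
#'   `solver_stats`.
#' @export
run_timecourse <- function(model, x0, t_end = 1100, dt_out = 5,
                           atol = 1e-13, rtol = 1e-8, maxsteps = 20000L) {
  n <- .n_state(model)
  if (length(x0) != n) {
    stop(sprintf("x0 has length %d; model has %d species", length(x0), n),
         call. = FALSE)
  }
  stopifnot(t_end > 0, dt_out > 0)
  times <- seq(0, t_end, by = dt_out)
  out <- .integrate(model, x0, times, atol, rtol, maxsteps)
  .as_trajectory(model, out, times, x0)
}

.as_trajectory <- function(model, out, times, x0) {
  ids <- .state_ids(model)
  if (is.null(out)) {
    status <- if (all(is.finite(.rhs_at(model, x0))))
      "no_convergence" else "invalid_state"
    # error before any step: classify by finiteness of the RHS at x0
    return(structure(list(times = numeric(0),
                          states = matrix(numeric(0), 0, length(ids),
                                          dimnames = list(NULL, ids)),
                          status = status, solver_stats = list()),
                     class = "spn_trajectory"))
  }
  states <- unname(out[, -1L, drop = FALSE])
  colnames(states) <- ids
  got <- nrow(states)
  finite <- all(is.finite(states))
  status <- if (finite && got == length(times)) {
    "ok"
  } else if (!finite) {
    "invalid_state"
  } else {
    # truncated but finite so far: non-finite derivatives at the last
    # reached state indicate an invalid state, otherwise stalled stepping
    last <- states[got, ]
    if (all(is.finite(.rhs_at(model, last)))) "no_convergence"
    else "invalid_state"
  }
  istate <- attr(out, "istate")
  structure(list(times = out[, 1L], states = states, status = status,
                 solver_stats = list(istate = if (!is.null(istate)) istate[1L],
                                     n_steps = if (!is.null(istate) &&
                                                   length(istate) >= 12)
                                       istate[12L])),
            class = "spn_trajectory")
}

#' @export
print.spn_trajectory <- function(x, ...) {
  cat(sprintf("<spn_trajectory> %d samples x %d species, status: %s\n",
              nrow(x$states), ncol(x$states), x$status))
  invisible(x)
}

#' Tidy data frame and CSV export of a trajectory
#'
#' @param x an `spn_trajectory`.
#' @param row.names,optional,... passed for S3 compatibility (unused).
#' @return long data frame with columns `time`, `species`, `value` (and
#'   `cell`, `row`, `col` if the species ids carry cell coordinates).
#' @export
as.data.frame.spn_trajectory <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  ids <- colnames(x$states)
  df <- data.frame(
    time = rep(x$times, times = length(ids)),
    species = rep(ids, each = length(x$times)),
    value = as.vector(x$states)
  )
  m <- regmatches(df$species,
                  regexec("^([A-Za-z]+[0-9]?)_([0-9]+)_([0-9]+)$", df$species))
  ok <- lengths(m) == 4L
  if (all(ok)) {
    df$row <- as.integer(vapply(m, `[`, character(1), 3L))
    df$col <- as.integer(vapply(m, `[`, character(1), 4L))
  }
  df
}

#' @rdname as.data.frame.spn_trajectory
#' @param traj an `spn_trajectory`.
#' @param path output CSV path.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Locate a steady state by integration
#'
#' Integrates over successively doubling time spans and declares
#' convergence by a dual "distance and time" criterion: the max-norm of
#' the right-hand side at the current state is below `resolution` *and*
#' the state moved less than `resolution` over the last span.  No Newton
#' refinement is used; the reported state is always re-checked by direct
#' evaluation of the right-hand side.
#'
#' @param model model object (see [run_timecourse()]).
#' @param x0 initial state.
#' @param resolution convergence threshold on normalized concentrations
#'   (default 1e-4).
#' @param t_max give up after this much integrated time (default 1e6).
#' @param span0 first integration span; spans double thereafter.
#' @param atol,rtol,maxsteps solver controls.
#' @return object of class `spn_steady_state`: list with `state`,
#'   `residual` (max-norm RHS), `t_reached`, `converged`, `status`.
#' @export
find_steady_state <- function(model, x0, resolution = 1e-4, t_max = 1e6,
                              span0 = 100, atol = 1e-12, rtol = 1e-6,
                              maxsteps = 20000L) {
  stopifnot(resolution > 0, t_max > 0, span0 > 0)
  x <- as.numeric(x0)
  if (length(x) != .n_state(model)) {
    stop("x0 length does not match model", call. = FALSE)
  }
  t_acc <- 0
  span <- span0
  status <- "max_time"
  converged <- FALSE
  while (t_acc < t_max) {
    out <- .integrate(model, x, c(0, span), atol, rtol, maxsteps)
    if (is.null(out) || nrow(out) < 2L || !all(is.finite(out[2L, ]))) {
      status <- "integration_failure"
      break
    }
    xn <- unname(out[2L, -1L])
    t_acc <- t_acc + span
    moved <- max(abs(xn - x))
    x <- xn
    resid <- max(abs(.rhs_at(model, x, t_acc)))
    if (is.finite(resid) && resid < resolution && moved < resolution) {
      converged <- TRUE
      status <- "converged"
      break
    }
    span <- span * 2
  }
  residual <- max(abs(.rhs_at(model, x, t_acc)))
  structure(list(state = stats::setNames(x, .state_ids(model)),
                 residual = residual, t_reached = t_acc,
                 converged = converged, status = status),
            class = "spn_steady_state")
}

#' @export
print.spn_steady_state <- function(x, ...) {
  cat(sprintf("<spn_steady_state> converged: %s (residual %.3g at t = %g)\n",
              x$converged, x$residual, x$t_reached))
  invisible(x)
}
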