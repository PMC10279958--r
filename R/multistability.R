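#' Steady-state multistability census
#'
#' For each of `n_params` random parameter sets (sampled exactly as in
#' the robustness screen), draws `n_ic` random initial conditions uniform
#' on `[0, 1]` per species, locates the steady state reachable from each
#' by integration only (see [find_steady_state()]), and counts how many
#' distinct steady states the parameter set supports.  Two converged
#' states are the same attractor when their max-norm difference is below
#' `dedup_tol` (default 1e-2, two orders of magnitude above the
#' steady-state resolution, separating numerical jitter from genuinely
#' distinct states).  Parameter sets where no initial condition converges
#' are counted as having no steady state (such sets typically sustain
#' oscillations).
#'
#' @param n_params number of parameter sets.
#' @param n_ic initial conditions per set (default 15).
#' @param seed integer base seed.
#' @param params parameter registry.
#' @param guard guard configuration.
#' @param grid grid dimensions `c(n_rows, n_cols)`.
#' @param resolution steady-state resolution (default 1e-4).
#' @param dedup_tol attractor deduplication tolerance.
#' @param t_max per-search integration horizon.
#' @param progress print a progress line every 25 sets.
#' @return list of class `spn_census`: `records` (one entry per set:
#'   `index`, `params`, `n_ic`, `n_converged`, `n_distinct`,
#'   `distinct_states`) and `summary` (`n_params`, `n_with_ss`,
#'   `n_multi`, and the corresponding fractions).
#' @export
run_multistab_census <- function(n_params = 5000, n_ic = 15, seed,
                                 params = spn_parameters(),
                                 guard = guard_config(),
                                 grid = c(1, 4), resolution = 1e-4,
                                 dedup_tol = 1e-2, t_max = 5e4,
                                 progress = FALSE) {
  validate_parameters(params)
  n_params <- as.integer(n_params); n_ic <- as.integer(n_ic)
  stopifnot(n_params >= 1, n_ic >= 1)
  model <- build_model(grid[1L], grid[2L], params, guard)
  pm <- sample_parameters(params, n_params, seed)
  n_sp <- model$n_species

  records <- vector("list", n_params)
  for (i in seq_len(n_params)) {
    model$params$value <- unname(pm[i, model$params$name])
    # independent IC stream per record, distinct from the parameter draw
    set.seed(.record_seed(seed + 777000L, i))
    ics <- matrix(stats::runif(n_ic * n_sp), nrow = n_ic)
    states <- list()
    n_conv <- 0L
    for (k in seq_len(n_ic)) {
      ss <- find_steady_state(model, ics[k, ], resolution = resolution,
                              t_max = t_max)
      if (ss$converged) {
        n_conv <- n_conv + 1L
        states[[length(states) + 1L]] <- unname(ss$state)
      }
    }
    dd <- dedup_states(states, dedup_tol)
    records[[i]] <- list(index = i, params = pm[i, ], n_ic = n_ic,
                         n_converged = n_conv,
                         distinct_states = dd,
                         n_distinct = length(dd))
    if (progress && i %% 25L == 0L) {
      message(sprintf("census: %d/%d sets", i, n_params))
    }
  }
  n_with <- sum(vapply(records, function(r) r$n_distinct >= 1L, logical(1)))
  n_multi <- sum(vapply(records, function(r) r$n_distinct > 1L, logical(1)))
  structure(
    list(records = records,
         summary = list(n_params = n_params, n_ic = n_ic,
                        n_with_ss = n_with, n_multi = n_multi,
                        frac_with_ss = n_with / n_params,
                        frac_multi = n_multi / n_params)),
    class = "spn_census")
}

#' @export
print.spn_census <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<spn_census> %d parameter sets x %d ICs: %d with a steady state (%.3f), %d multistable (%.3f)\n",
    s$n_params, s$n_ic, s$n_with_ss, s$frac_with_ss, s$n_multi,
    s$frac_multi))
  invisible(x)
}

#' Deduplicate converged states into distinct attractors
#'
#' Greedy clustering under the max-norm: a state joins the first
#' representative within `tol`, otherwise founds a new one.  The result
#' does not depend on the input order when, as intended, within-attractor
#' scatter and between-attractor separation differ by well over `tol`.
#'
#' @param states list of numeric state vectors.
#' @param tol max-norm tolerance.
#' @return list of representative state vectors.
#' @export
dedup_states <- function(states, tol = 1e-2) {
  reps <- list()
  for (s in states) {
    hit <- FALSE
    for (r in reps) {
      if (max(abs(s - r)) < tol) { hit <- TRUE; break }
    }
    if (!hit) reps[[length(reps) + 1L]] <- s
  }
  reps
}

#' Compare parameter distributions between mono- and multistable sets
#'
#' Splits the census records into parameter sets with exactly one steady
#' state and sets with more than one, and reports the per-parameter
#' medians of both groups and the fold change
#' `median_multi / median_mono`, sorted by its distance from 1 on the log
#' scale.  Values below 1 mean the parameter runs smaller in the
#' multistable set.
#'
#' @param census an `spn_census`, or its `records` list.
#' @param sampled_only restrict to sampled parameters (default TRUE).
#' @param table parameter registry (for the sampled flag).
#' @return data frame: `parameter`, `median_mono`, `median_multi`,
#'   `fold_change`.
#' @export
compare_parameter_distributions <- function(census,
                                            sampled_only = TRUE,
                                            table = spn_parameters()) {
  records <- if (inherits(census, "spn_census")) census$records else census
  nd <- vapply(records, function(r) r$n_distinct, integer(1))
  mono <- records[nd == 1L]
  multi <- records[nd > 1L]
  if (!length(mono) || !length(multi)) {
    stop("both a monostable and a multistable group are required",
         call. = FALSE)
  }
  pmat <- function(group) do.call(rbind, lapply(group, `[[`, "params"))
  mm <- pmat(mono); mu <- pmat(multi)
  nm <- colnames(mm)
  if (sampled_only) nm <- intersect(nm, table$name[table$sampled])
  med_mono <- apply(mm[, nm, drop = FALSE], 2L, stats::median)
  med_multi <- apply(mu[, nm, drop = FALSE], 2L, stats::median)
  out <- data.frame(parameter = nm, median_mono = unname(med_mono),
                    median_multi = unname(med_multi),
                    fold_change = unname(med_multi / med_mono))
  out[order(-abs(log(out$fold_change))), , drop = FALSE]
}

#' Export census results and scatter data
#'
#' Writes one CSV row per parameter set (parameters, `n_converged`,
#' `n_distinct`), a companion wide CSV of the distinct states, a JSON
#' summary, and -- for a chosen parameter pair -- the scatter/histogram
#' data comparing mono- and multistable sets.
#'
#' @param census an `spn_census`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @param pair optional character vector of two parameter names for the
#'   scatter export.
#' @return paths, invisibly.
#' @export
write_census_results <- function(census, dir, prefix = "census",
                                 pair = c("kappa_CNptc", "kappa_CNen")) {
  stopifnot(inherits(census, "spn_census"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- census$records
  pmat <- do.call(rbind, lapply(recs, `[[`, "params"))
  df <- data.frame(index = vapply(recs, `[[`, integer(1), "index"),
                   n_converged = vapply(recs, `[[`, integer(1),
                                        "n_converged"),
                   n_distinct = vapply(recs, `[[`, integer(1),
                                       "n_distinct"))
  df <- cbind(df, as.data.frame(pmat))
  p_rec <- file.path(dir, paste0(prefix, "_records.csv"))
  utils::write.csv(df, p_rec, row.names = FALSE)

  ss <- do.call(rbind, lapply(recs, function(r) {
    if (r$n_distinct == 0L) return(NULL)
    cbind(index = r$index,
          state_id = seq_len(r$n_distinct),
          do.call(rbind, r$distinct_states))
  }))
  p_states <- file.path(dir, paste0(prefix, "_states.csv"))
  utils::write.csv(as.data.frame(ss), p_states, row.names = FALSE)

  p_sum <- file.path(dir, paste0(prefix, "_summary.json"))
  jsonlite::write_json(census$summary, p_sum, auto_unbox = TRUE,
                       digits = NA)

  paths <- c(records = p_rec, states = p_states, summary = p_sum)
  if (!is.null(pair) && all(pair %in% colnames(pmat))) {
    nd <- df$n_distinct
    sc <- data.frame(group = ifelse(nd > 1L, "multi",
                                    ifelse(nd == 1L, "mono", "none")),
                     pmat[, pair, drop = FALSE])
    p_pair <- file.path(dir, paste0(prefix, "_scatter.csv"))
    utils::write.csv(sc, p_pair, row.names = FALSE)
    paths <- c(paths, scatter = p_pair)
  }
  invisible(paths)
}
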