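#' Target expression pattern of the four-cell parasegment repeat
#'
#' The stripe pattern the screen looks for, per scored mRNA: the set of
#' "on" cells and "off" cells (1-based, anterior to posterior) within the
#' four-cell repeat.  The default places the parasegment boundary between
#' cells 2 and 3: `wingless` on in cell 2, `engrailed` and `hedgehog` on
#' in cell 3, and `patched` on in the cells flanking the
#' `engrailed`-expressing cell (2 and 4).
#'
#' @param n_cells cells in the repeat (default 4).
#' @param wg_on,ptc_on,en_on,hh_on "on" cells per scored species; all
#'   other cells are "off".
#' @param shift cyclic shift applied to all cell labels (for symmetry
#'   checks).
#' @return named list of `list(on, off)` cell sets, class `spn_target`.
#' @export
pattern_target <- function(n_cells = 4L, wg_on = 2L, ptc_on = c(2L, 4L),
                           en_on = 3L, hh_on = 3L, shift = 0L) {
  mk <- function(on) {
    on <- sort(unique(((as.integer(on) - 1L + shift) %% n_cells) + 1L))
    off <- setdiff(seq_len(n_cells), on)
    if (!length(on) || !length(off)) {
      stop("each scored species needs non-empty 'on' and 'off' sets",
           call. = FALSE)
    }
    list(on = on, off = off)
  }
  structure(list(wg = mk(wg_on), ptc = mk(ptc_on),
                 en = mk(en_on), hh = mk(hh_on)),
            class = "spn_target")
}

#' Initial-condition presets of the hit-rate screen
#'
#' Builds the full state vector for one of the named starting patterns
#' probed by the screen.  Descriptive ranges are mapped to fixed values:
#' "low" (<20%) -> 0.15, "medium" (20--60%) -> 0.4, "high" (60--100%)
#' -> 0.9.  Species not named by a preset start at zero.
#'
#' Available presets (four-cell repeat, parasegment boundary between
#' cells 2 and 3): `"crisp"` (sharp `wg` stripe in cell 2, `en` stripe in
#' cell 3), `"degraded"` (the same stripes blurred over the neighboring
#' cells), `"crisp_ci_ptc"` (crisp plus ubiquitous low-level `ci` and
#' `ptc`), `"ci_band_wg"` (3-cell `ci` band with a `wg` stripe on its
#' posterior margin), `"ptc_band_en"` (3-cell `ptc` band with an `en`
#' stripe on its anterior margin), `"ptc_ci_bands"` (3-cell `ptc` band and
#' an out-of-phase 3-cell `ci` band), `"close_to_target"` (mRNAs and main
#' proteins already near the target pattern).
#'
#' @param name preset name.
#' @param grid an `spn_grid`; presets are defined on a 1 x 4 grid.
#' @param shift cyclic shift of the cell labels (for symmetry checks).
#' @return named numeric state vector (length 132 on the 1 x 4 grid).
#' @export
ic_preset <- function(name = c("crisp", "degraded", "crisp_ci_ptc",
                               "ci_band_wg", "ptc_band_en", "ptc_ci_bands",
                               "close_to_target"),
                      grid = make_grid(1, 4), shift = 0L) {
  name <- match.arg(name)
  if (grid$n_rows != 1L || grid$n_cols != 4L) {
    stop("initial-condition presets are defined on the 1 x 4 grid",
         call. = FALSE)
  }
  LO <- 0.15; MED <- 0.4; HI <- 0.9
  sp <- .species_table(grid)
  x <- stats::setNames(numeric(nrow(sp)), sp$id)
  set <- function(label, cells, value) {
    cells <- ((as.integer(cells) - 1L + shift) %% 4L) + 1L
    ids <- paste0(label, "_0_", cells - 1L)
    x[ids] <<- value
  }
  switch(name,
    crisp = {
      set("wg", 2, HI); set("en", 3, HI)
    },
    degraded = {
      set("wg", 2, HI); set("wg", c(1, 3), MED); set("wg", 4, LO)
      set("en", 3, HI); set("en", c(2, 4), MED); set("en", 1, LO)
    },
    crisp_ci_ptc = {
      set("wg", 2, HI); set("en", 3, HI)
      set("ci", 1:4, LO); set("ptc", 1:4, LO)
    },
    ci_band_wg = {
      set("ci", c(4, 1, 2), HI); set("wg", 2, HI)
    },
    ptc_band_en = {
      set("ptc", c(4, 1, 2), HI); set("en", 3, HI)
    },
    ptc_ci_bands = {
      set("ptc", c(4, 1, 2), HI); set("ci", c(2, 3, 4), HI)
    },
    close_to_target = {
      set("wg", 2, HI); set("en", 3, HI); set("hh", 3, HI)
      set("ptc", c(2, 4), HI); set("ci", c(1, 2, 4), HI)
      set("EN", 3, HI); set("IWG", 2, MED); set("CI", c(1, 2, 4), MED)
    })
  x
}

#' Names of the available initial-condition presets
#' @return character vector.
#' @export
ic_preset_names <- function() {
  c("crisp", "degraded", "crisp_ci_ptc", "ci_band_wg", "ptc_band_en",
    "ptc_ci_bands", "close_to_target")
}

#' Sample random parameter vectors
#'
#' Draws `n` parameter vectors from the registry: each sampled parameter
#' is drawn log-uniformly within its `[range_lo, range_hi]`; fixed
#' parameters keep their registry value.  Each vector uses its own seed
#' derived from `seed` and the record index, so batches are
#' order-independent and resumable.
#'
#' @param table parameter registry (see [spn_parameters()]).
#' @param n number of vectors.
#' @param seed integer base seed.
#' @param index_offset global index of the first record (for batching).
#' @return `n x nrow(table)` matrix, columns named by parameter.
#' @export
sample_parameters <- function(table, n, seed, index_offset = 0L) {
  validate_parameters(table, require_counts = FALSE)
  n <- as.integer(n)
  stopifnot(n >= 0)
  m <- matrix(rep(table$value, each = max(n, 1L)), nrow = max(n, 1L),
              dimnames = list(NULL, table$name))
  if (n == 0L) return(m[0L, , drop = FALSE])
  s <- which(table$sampled)
  lo <- log(table$range_lo[s]); hi <- log(table$range_hi[s])
  for (i in seq_len(n)) {
    set.seed(.record_seed(seed, index_offset + i))
    u <- stats::runif(length(s))
    m[i, s] <- exp(lo + u * (hi - lo))
  }
  m
}

# Per-record derived seed, kept within 32-bit integer range.
.record_seed <- function(seed, index) {
  v <- (abs(as.numeric(seed)) %% 1e9) * 2 + 1 + as.numeric(index)
  as.integer(v %% 2147483647)
}

#' Stripe-pattern score of a trajectory
#'
#' For each scored mRNA, concentrations are time-averaged per cell over
#' the final `window` time units; with `m_on` the minimum over "on" cells
#' and `m_off` the maximum over "off" cells, the species score is
#' `m_off / max(m_on, eps_score)` and the total score is the maximum over
#' species.  A score below 0.2 therefore demands at least a 5-fold on/off
#' separation for every scored mRNA.  This contrast-ratio score judges
#' the pattern only, not expression amplitude, and therefore identifies
#' somewhat more parameter sets than a criterion that additionally
#' requires strong absolute expression; `eps_score` merely protects the
#' division.  Failed trajectories score `Inf` and can never be hits.
#'
#' @param traj an `spn_trajectory` from an `spn_model` run.
#' @param target an [pattern_target()].
#' @param window length of the terminal averaging window (time units).
#' @param eps_score numerical floor on the denominator.
#' @return non-negative score (lower is better; 0 = perfect pattern).
#' @export
pattern_score <- function(traj, target = pattern_target(), window = 200,
                          eps_score = 1e-12) {
  stopifnot(inherits(traj, "spn_trajectory"), inherits(target, "spn_target"))
  if (traj$status != "ok") return(Inf)
  keep <- traj$times >= (max(traj$times) - window)
  avg <- colMeans(traj$states[keep, , drop = FALSE])
  score <- 0
  for (s in names(target)) {
    cells <- function(set) {
      ids <- paste0(s, "_0_", set - 1L)
      if (!all(ids %in% names(avg))) {
        stop("trajectory does not contain scored species ", s, call. = FALSE)
      }
      avg[ids]
    }
    m_on <- min(cells(target[[s]]$on))
    m_off <- max(cells(target[[s]]$off))
    score <- max(score, m_off / max(m_on, eps_score))
  }
  score
}

#' Random-parameter robustness screen
#'
#' Samples parameter sets, integrates the standard 1100-time-unit time
#' course from the chosen initial-condition preset, scores the final
#' pattern, and calls hits at score below `threshold`.  Failed
#' integrations count as tries, never as hits.
#'
#' @param preset preset name (see [ic_preset()]) or a numeric state
#'   vector.
#' @param n_tries number of sampled parameter sets.
#' @param seed integer base seed.
#' @param params parameter registry.
#' @param target an [pattern_target()].
#' @param guard guard configuration.
#' @param threshold hit threshold on the score (default 0.2).
#' @param t_end,dt_out,atol,rtol,maxsteps integration controls (screening
#'   uses wider tolerances than the reference time course by default).
#' @param window scoring window (time units).
#' @param index_offset global index of the first record (resumable
#'   batches).
#' @param progress print a progress line every 200 records.
#' @return list of class `spn_screen`: `records` (data frame: index,
#'   seed, score, hit, status, and the 48 sampled parameter values) and
#'   `summary` (hits, tries, hit_rate, reciprocal_rate, failure counts).
#' @export
run_screen <- function(preset = "crisp", n_tries, seed,
                       params = spn_parameters(),
                       target = pattern_target(), guard = guard_config(),
                       threshold = 0.2, t_end = 1100, dt_out = 5,
                       atol = 1e-12, rtol = 1e-6, maxsteps = 20000L,
                       window = 200, index_offset = 0L, progress = FALSE) {
  validate_parameters(params)
  grid4 <- make_grid(1, 4)
  x0 <- if (is.character(preset)) ic_preset(preset, grid4) else {
    stopifnot(is.numeric(preset), length(preset) == 132L)
    preset
  }
  n_tries <- as.integer(n_tries)
  pm <- sample_parameters(params, n_tries, seed, index_offset)
  model <- build_model(1, 4, params, guard)
  sampled <- params$name[params$sampled]

  idx <- integer(n_tries); sc <- numeric(n_tries)
  st <- character(n_tries); seeds <- integer(n_tries)
  for (i in seq_len(n_tries)) {
    model$params$value <- unname(pm[i, model$params$name])
    traj <- run_timecourse(model, x0, t_end = t_end, dt_out = dt_out,
                           atol = atol, rtol = rtol, maxsteps = maxsteps)
    idx[i] <- index_offset + i
    seeds[i] <- .record_seed(seed, index_offset + i)
    st[i] <- traj$status
    sc[i] <- pattern_score(traj, target, window = window)
    if (progress && i %% 200L == 0L) {
      message(sprintf("screen: %d/%d records, %d hits", i, n_tries,
                      sum(sc[seq_len(i)] < threshold)))
    }
  }
  records <- data.frame(index = idx, seed = seeds, score = sc,
                        hit = sc < threshold, status = st)
  records <- cbind(records, as.data.frame(pm[, sampled, drop = FALSE]))
  hits <- sum(records$hit)
  summary <- list(
    hits = hits, tries = n_tries,
    hit_rate = if (n_tries > 0) hits / n_tries else 0,
    reciprocal_rate = if (hits > 0) n_tries / hits else Inf,
    threshold = threshold,
    n_invalid_state = sum(st == "invalid_state"),
    n_no_convergence = sum(st == "no_convergence")
  )
  structure(list(records = records, summary = summary, preset = preset),
            class = "spn_screen")
}

#' @export
print.spn_screen <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<spn_screen> %d hits / %d tries (rate %s, score < %g; %d invalid, %d unconverged)\n",
    s$hits, s$tries,
    if (s$hits > 0) sprintf("1/%.0f", s$reciprocal_rate) else "0",
    s$threshold, s$n_invalid_state, s$n_no_convergence))
  invisible(x)
}

#' Normalized log-position profile of screen hits
#'
#' Maps each hit's sampled parameters to their normalized log-scale
#' position `(log x - log lo) / (log hi - log lo)` in `[0, 1]` and
#' reports the per-parameter mean and standard deviation -- the data
#' behind the radar representation of successful parameter sets.
#' Half-lives and cooperativity exponents can be omitted, as in that
#' display.
#'
#' @param records screen records data frame (or an `spn_screen`).
#' @param table the parameter registry used for the screen.
#' @param omit_categories categories to drop (e.g.
#'   `c("half_life", "nu")`); default keeps everything.
#' @return list with `positions` (hits x parameters matrix) and `stats`
#'   (data frame: parameter, mean, sd).
#' @export
export_hit_profile <- function(records, table = spn_parameters(),
                               omit_categories = character()) {
  if (inherits(records, "spn_screen")) records <- records$records
  hits <- records[records$hit %in% TRUE, , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(list(positions = NULL, stats = NULL, n_hits = 0L))
  }
  keep <- table$sampled & !(table$category %in% omit_categories)
  nm <- table$name[keep]
  lo <- log(table$range_lo[keep]); hi <- log(table$range_hi[keep])
  pos <- sapply(seq_along(nm), function(k) {
    (log(hits[[nm[k]]]) - lo[k]) / (hi[k] - lo[k])
  })
  pos <- matrix(pos, nrow = nrow(hits), dimnames = list(NULL, nm))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  stats <- data.frame(parameter = nm,
                      mean = colMeans(pos),
                      sd = apply(pos, 2L, pop_sd))
  rownames(stats) <- NULL
  list(positions = pos, stats = stats, n_hits = nrow(hits))
}

#' Write screen results to disk
#'
#' One CSV of per-record results plus a JSON summary.
#'
#' @param screen an `spn_screen`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return paths, invisibly.
#' @export
write_screen_results <- function(screen, dir, prefix = "screen") {
  stopifnot(inherits(screen, "spn_screen"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(prefix, "_records.csv"))
  js <- file.path(dir, paste0(prefix, "_summary.json"))
  utils::write.csv(screen$records, csv, row.names = FALSE)
  jsonlite::write_json(screen$summary, js, auto_unbox = TRUE, digits = NA)
  invisible(c(records = csv, summary = js))
}
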