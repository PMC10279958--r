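test_that("sampled parameters stay in range and reproduce from the seed", {
  tab <- spn_parameters()
  pm <- sample_parameters(tab, 50, seed = 123)
  expect_equal(dim(pm), c(50L, 53L))
  for (nm in tab$name[tab$sampled]) {
    i <- match(nm, tab$name)
    expect_true(all(pm[, nm] >= tab$range_lo[i] - 1e-12))
    expect_true(all(pm[, nm] <= tab$range_hi[i] + 1e-12))
  }
  for (nm in tab$name[!tab$sampled]) {
    expect_true(all(pm[, nm] == tab$value[match(nm, tab$name)]))
  }
  pm2 <- sample_parameters(tab, 50, seed = 123)
  expect_identical(pm, pm2)
  # order-independent batching: records 26..50 match a shifted batch
  pm3 <- sample_parameters(tab, 25, seed = 123, index_offset = 25)
  expect_identical(pm[26:50, ], pm3)
  expect_false(isTRUE(all.equal(pm[1:25, ], pm3)))
  bad <- tab; bad$range_lo[2] <- 0
  expect_error(sample_parameters(bad, 5, 1), "range")
})

test_that("log10 of sampled HH_0 is uniform on [0, 3]", {
  tab <- spn_parameters()
  pm <- sample_parameters(tab, 10000, seed = 2024)
  lg <- log10(pm[, "HH_0"])
  expect_gte(min(lg), 0); expect_lte(max(lg), 3)
  ks <- suppressWarnings(ks.test(lg, "punif", 0, 3))
  expect_gt(ks$p.value, 0.01)
})

.mock_traj <- function(values_by_species, n_cells = 4, t_end = 1100) {
  # constant-in-time trajectory with prescribed per-cell mRNA levels
  m <- build_model(1, n_cells)
  times <- seq(0, t_end, by = 50)
  states <- matrix(0, nrow = length(times), ncol = m$n_species,
                   dimnames = list(NULL, m$species$id))
  for (s in names(values_by_species)) {
    for (cell in seq_len(n_cells)) {
      states[, paste0(s, "_0_", cell - 1)] <- values_by_species[[s]][cell]
    }
  }
  structure(list(times = times, states = states, status = "ok",
                 solver_stats = list()), class = "spn_trajectory")
}

test_that("pattern score: exact target scores 0, uniform scores 1", {
  target <- pattern_target()
  exact <- .mock_traj(list(wg = c(0, 1, 0, 0), ptc = c(0, 1, 0, 1),
                           en = c(0, 0, 1, 0), hh = c(0, 0, 1, 0)))
  expect_equal(pattern_score(exact, target), 0)
  uni <- .mock_traj(list(wg = rep(0.4, 4), ptc = rep(0.4, 4),
                         en = rep(0.4, 4), hh = rep(0.4, 4)))
  expect_equal(pattern_score(uni, target), 1)
  # m_off/m_on = 0.1 for every species -> score 0.1 -> hit
  tenth <- .mock_traj(list(wg = c(0.1, 1, 0.1, 0.1),
                           ptc = c(0.1, 1, 0.1, 1),
                           en = c(0.1, 0.1, 1, 0.1),
                           hh = c(0.1, 0.1, 1, 0.1)))
  expect_equal(pattern_score(tenth, target), 0.1)
  expect_lt(pattern_score(tenth, target), 0.2)
})

test_that("the score is scale-free and monotone in off-cell levels", {
  target <- pattern_target()
  base <- list(wg = c(0.05, 0.8, 0.02, 0.01), ptc = c(0.1, 0.9, 0.2, 0.7),
               en = c(0.01, 0.03, 0.6, 0.02), hh = c(0.02, 0.1, 0.5, 0.04))
  s0 <- pattern_score(.mock_traj(base), target)
  scaled <- lapply(base, function(v) v * 7.3)
  expect_equal(pattern_score(.mock_traj(scaled), target), s0,
               tolerance = 1e-12)
  # decreasing an off-cell value never increases the score
  worse <- base
  worse$wg[1] <- worse$wg[1] / 2
  expect_lte(pattern_score(.mock_traj(worse), target), s0)
})

test_that("failed trajectories can never be hits", {
  tr <- .mock_traj(list(wg = c(0, 1, 0, 0)))
  tr$status <- "invalid_state"
  expect_equal(pattern_score(tr), Inf)
})

test_that("target sets are disjoint, non-empty, and shiftable", {
  t0 <- pattern_target()
  expect_setequal(t0$ptc$on, c(2L, 4L))
  expect_setequal(t0$ptc$off, c(1L, 3L))
  for (s in names(t0)) {
    expect_length(intersect(t0[[s]]$on, t0[[s]]$off), 0)
  }
  t1 <- pattern_target(shift = 1)
  expect_setequal(t1$wg$on, 3L)
  expect_setequal(t1$en$on, 4L)
  expect_error(pattern_target(wg_on = 1:4), "non-empty")
})

test_that("initial-condition presets map range classes to 0.15/0.4/0.9", {
  g <- make_grid(1, 4)
  crisp <- ic_preset("crisp", g)
  expect_length(crisp, 132L)
  expect_equal(unname(crisp["wg_0_1"]), 0.9)
  expect_equal(unname(crisp["en_0_2"]), 0.9)
  expect_equal(sum(crisp > 0), 2L)
  deg <- ic_preset("degraded", g)
  expect_equal(unname(deg[c("wg_0_0", "wg_0_1", "wg_0_2", "wg_0_3")]),
               c(0.4, 0.9, 0.4, 0.15))
  expect_equal(unname(deg[c("en_0_0", "en_0_1", "en_0_2", "en_0_3")]),
               c(0.15, 0.4, 0.9, 0.4))
  cip <- ic_preset("crisp_ci_ptc", g)
  expect_true(all(cip[paste0("ci_0_", 0:3)] == 0.15))
  expect_true(all(cip[paste0("ptc_0_", 0:3)] == 0.15))
  for (nm in ic_preset_names()) {
    x <- ic_preset(nm, g)
    expect_true(all(x >= 0 & x <= 0.9))
  }
  expect_error(ic_preset("crisp", make_grid(1, 8)), "1 x 4")
})

test_that("a zero-try screen returns empty records and zero summary", {
  sc <- run_screen("crisp", n_tries = 0, seed = 1)
  expect_equal(nrow(sc$records), 0L)
  expect_equal(sc$summary$hits, 0L)
  expect_equal(sc$summary$tries, 0L)
})

test_that("screen records carry scores, statuses and sampled parameters", {
  sc <- run_screen("crisp", n_tries = 6, seed = 99)
  expect_equal(nrow(sc$records), 6L)
  expect_true(all(c("index", "seed", "score", "hit", "status",
                    "kappa_CNptc", "HH_0") %in% names(sc$records)))
  expect_true(all(sc$records$status %in%
                  c("ok", "invalid_state", "no_convergence")))
  expect_equal(sc$records$hit, sc$records$score < 0.2)
  # reproducible
  sc2 <- run_screen("crisp", n_tries = 6, seed = 99)
  expect_equal(sc$records$score, sc2$records$score)
  paths <- write_screen_results(sc, withr::local_tempdir())
  expect_true(all(file.exists(paths)))
})

test_that("hit scoring is invariant under cyclic relabeling of cells", {
  n <- 12
  s0 <- run_screen("crisp", n_tries = n, seed = 7)
  s1 <- run_screen(ic_preset("crisp", make_grid(1, 4), shift = 2),
                   n_tries = n, seed = 7,
                   target = pattern_target(shift = 2))
  ok <- s0$records$status == "ok" & s1$records$status == "ok"
  expect_gt(sum(ok), 0)
  # identical up to solver step-selection noise in the permuted system
  expect_equal(s1$records$score[ok], s0$records$score[ok],
               tolerance = 1e-2)
  expect_equal(s1$records$hit[ok], s0$records$hit[ok])
})

test_that("hit profiles normalize log-positions onto [0, 1]", {
  tab <- spn_parameters()
  rec <- data.frame(index = 1:2, seed = 1:2, score = c(0.1, 0.15),
                    hit = c(TRUE, TRUE), status = "ok")
  for (nm in tab$name[tab$sampled]) {
    i <- match(nm, tab$name)
    rec[[nm]] <- c(tab$range_lo[i], tab$range_hi[i])
  }
  # midpoint check with a third record at the geometric midpoint
  rec3 <- rec[1, ]
  for (nm in tab$name[tab$sampled]) {
    i <- match(nm, tab$name)
    rec3[[nm]] <- sqrt(tab$range_lo[i] * tab$range_hi[i])
  }
  prof <- export_hit_profile(rbind(rec, rec3), tab)
  expect_equal(prof$n_hits, 3L)
  expect_true(all(abs(prof$positions[1, ] - 0) < 1e-12))
  expect_true(all(abs(prof$positions[2, ] - 1) < 1e-12))
  expect_true(all(abs(prof$positions[3, ] - 0.5) < 1e-12))
  # two hits at lo and hi: mean 0.5, population SD 0.5
  prof2 <- export_hit_profile(rec, tab)
  expect_true(all(abs(prof2$stats$mean - 0.5) < 1e-12))
  expect_true(all(abs(prof2$stats$sd - 0.5) < 1e-12))
  # omission flag drops half-lives and cooperativities
  prof3 <- export_hit_profile(rec, tab, omit_categories = c("half_life", "nu"))
  expect_false(any(grepl("^H_|^nu_", colnames(prof3$positions))))
  # zero hits signalled
  none <- rec[0, ]
  expect_equal(export_hit_profile(none, tab)$n_hits, 0L)
})
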