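test_that("model dimensions: species and parameter counts", {
  m4 <- build_model(1, 4)
  expect_equal(m4$n_species, 132L)
  expect_equal(nrow(m4$params), 53L)
  expect_equal(sum(m4$params$sampled), 48L)
  expect_equal(build_model(1, 1)$n_species, 33L)
  expect_equal(make_fixtures("tiny_grid")$model$n_species, 66L)
  # per cell: 5 mRNAs, 4 cytosolic, 4 membrane proteins x 6 sides
  sp <- m4$species[m4$species$cell == 0L, ]
  expect_equal(nrow(sp), 33L)
  expect_equal(sum(is.na(sp$side)), 9L)
  expect_equal(sum(!is.na(sp$side)), 24L)
})

test_that("parameter registry invariants and errors", {
  p <- spn_parameters()
  expect_silent(validate_parameters(p))
  expect_true(all(p$value[p$sampled] >= p$range_lo[p$sampled]))
  expect_true(all(p$value[p$sampled] <= p$range_hi[p$sampled]))
  expect_setequal(p$name[!p$sampled],
                  c("B", "V_max", "r_mem_WG", "r_mem_PTC", "r_mem_HH"))
  expect_equal(p$range_lo[p$name == "PTC_0"], 1)
  expect_equal(p$range_hi[p$name == "PTC_0"], 1000)
  expect_equal(p$range_hi[p$name == "HH_0"], 1000)
  bad <- p; bad$range_lo[1] <- 200   # lo above value
  expect_error(validate_parameters(bad), "H_en")
  expect_error(build_model(1, 4, p[-3, ]), "missing parameter")
})

test_that("compiled RHS agrees with the reaction-registry reference", {
  set.seed(5)
  for (m in list(build_model(1, 4), build_model(1, 2),
                 build_model(2, 2))) {
    f <- compile_rhs(m)
    ref <- spn_reference_rhs(m)
    for (k in 1:3) {
      x <- runif(m$n_species, 0, 1.5)
      d1 <- f(x); d2 <- ref(x)
      expect_lt(max(abs(d1 - d2) / pmax(abs(d2), 1e-8)), 1e-12)
    }
  }
})

test_that("all-zero state yields a finite derivative vector", {
  m <- build_model(1, 4)
  d <- compile_rhs(m)(numeric(132))
  expect_true(all(is.finite(d)))
  # basal ci transcription is the dominant nonzero term
  ci_idx <- which(m$species$name == "ci")
  expect_true(all(d[ci_idx] > 0))
})

test_that("RHS is finite over the overshoot box with guards on", {
  m <- build_model(1, 4)
  f <- compile_rhs(m)
  set.seed(99)
  for (k in 1:50) {
    x <- runif(132, -1e-6, 2)
    expect_true(all(is.finite(f(x))))
  }
})

test_that("homogeneous states give identical per-cell derivative blocks", {
  m <- build_model(1, 4)
  set.seed(3)
  cell_state <- runif(33)
  d <- compile_rhs(m)(rep(cell_state, 4))
  blocks <- matrix(d, ncol = 4)
  for (c in 2:4) expect_equal(blocks[, c], blocks[, 1], tolerance = 1e-14)
})

test_that("cyclic column relabeling commutes with the RHS", {
  m <- build_model(1, 4)
  f <- compile_rhs(m)
  set.seed(13)
  x <- runif(132)
  # permutation moving cell c's block to cell (c+1) mod 4
  perm <- as.vector(outer(1:33, c(3, 0, 1, 2) * 33, "+"))
  expect_equal(f(x[perm]), f(x)[perm], tolerance = 1e-13)
})

test_that("side-to-side diffusion conserves each within-cell total", {
  p <- spn_parameters()
  p <- set_parameters(p, c(
    setNames(rep(Inf, 13), p$name[p$category == "half_life"]),
    V_max = 0, B = 0, k_bind = 0, r_exo_WG = 0, r_endo_WG = 0,
    C_CI = 0, T_EN = 0, T_IWG = 0, T_PTC = 0, T_CI = 0, T_HH = 0,
    r_mem_WG = 2.5, r_mem_PTC = 0.7, r_mem_HH = 1.3))
  m <- build_model(1, 4, p)
  f <- compile_rhs(m)
  set.seed(21)
  x <- runif(132)
  d <- f(x)
  for (c0 in 0:3) {
    for (off in c(9L, 15L, 21L)) {      # EWG, PTC, HH pools
      expect_equal(sum(d[c0 * 33L + off + 1:6]), 0, tolerance = 1e-14)
    }
    expect_true(any(abs(d[c0 * 33L + 9L + 1:6]) > 1e-6)) # but flux flows
  }
})

test_that("single-cell model matches the embedded cell of the 1x4 model", {
  m4 <- build_model(1, 4)
  f4 <- compile_rhs(m4)
  set.seed(31)
  x <- runif(132)
  cell <- 1L  # 0-based
  bv <- numeric(0)
  for (j in 1:6) {
    nb <- m4$neighbor[cell + 1L, j]
    jop <- opposite_side(j)
    bv[paste0("EWG", jop)] <- x[nb * 33L + 9L + jop]
    bv[paste0("PTC", jop)] <- x[nb * 33L + 15L + jop]
    bv[paste0("HH", jop)] <- x[nb * 33L + 21L + jop]
  }
  m1 <- build_single_cell(spn_parameters(), bv)
  expect_equal(m1$n_species, 33L)
  d1 <- compile_rhs(m1)(x[cell * 33L + 1:33])
  d4 <- f4(x)[cell * 33L + 1:33]
  expect_equal(d1, d4, tolerance = 1e-13)
  # reference path agrees too
  expect_equal(spn_reference_rhs(m1)(x[cell * 33L + 1:33]), d1,
               tolerance = 1e-12)
})

test_that("incomplete boundary map is rejected", {
  bv <- setNames(rep(0, 17), c(paste0("EWG", 1:6), paste0("PTC", 1:6),
                               paste0("HH", 1:5)))
  expect_error(build_single_cell(spn_parameters(), bv), "HH6")
  expect_error(build_single_cell(spn_parameters()), "incomplete")
})

test_that("with zero boundary input, en expression decays away", {
  bv <- setNames(rep(0, 18), c(paste0("EWG", 1:6), paste0("PTC", 1:6),
                               paste0("HH", 1:6)))
  m1 <- build_single_cell(spn_parameters(), bv)
  x0 <- setNames(numeric(33), m1$species$id)
  x0["en_0_0"] <- 0.9; x0["EN_0_0"] <- 0.5
  tr <- run_timecourse(m1, x0, t_end = 1100, dt_out = 50,
                       atol = 1e-12, rtol = 1e-6)
  expect_equal(tr$status, "ok")
  expect_lt(tr$states[nrow(tr$states), "en_0_0"], 1e-3)
})

test_that("derived totals sum the correct pools", {
  m <- build_model(1, 4)
  set.seed(41)
  x <- runif(132)
  tot <- spn_totals(m, x)
  # PTC_T of cell (0,1): its own six PTC pools
  expect_equal(unname(tot[1, "PTC_T_0_1"]), sum(x[33L + 15L + 1:6]))
  expect_equal(unname(tot[1, "PH_T_0_1"]), sum(x[33L + 27L + 1:6]))
  # EWG_T of cell (0,1): apposed pools of cells (0,0) and (0,2)
  ewg <- 0
  for (j in 1:6) {
    nb <- m$neighbor[2, j]; jop <- opposite_side(j)
    ewg <- ewg + x[nb * 33L + 9L + jop]
  }
  expect_equal(unname(tot[1, "EWG_T_0_1"]), ewg)
})
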