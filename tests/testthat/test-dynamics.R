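test_that("pure decay matches the closed-form exponential", {
  fx <- make_fixtures("toy_decay")
  tr <- run_timecourse(fx$model, 1, t_end = 10, dt_out = 0.5,
                       atol = 1e-12, rtol = 1e-8)
  expect_equal(tr$status, "ok")
  expect_equal(unname(tr$states[, 1]),
               fx$expectations$solution(tr$times), tolerance = 1e-6)
})

test_that("a decay-only network decays every species exponentially", {
  # half-life ln(2) for everything = unit decay rate; no synthesis
  p <- spn_parameters()
  p <- set_parameters(p, c(
    setNames(rep(log(2), 13), p$name[p$category == "half_life"]),
    V_max = 0, B = 0, k_bind = 0, r_exo_WG = 0, r_endo_WG = 0,
    C_CI = 0, T_EN = 0, T_IWG = 0, T_PTC = 0, T_CI = 0, T_HH = 0,
    r_mem_WG = 0, r_mem_PTC = 0, r_mem_HH = 0))
  m <- build_model(1, 4, p)
  tr <- run_timecourse(m, rep(1, 132), t_end = 5, dt_out = 1,
                       atol = 1e-12, rtol = 1e-8)
  expect_equal(tr$status, "ok")
  for (k in seq_along(tr$times)) {
    expect_equal(unname(tr$states[k, ]), rep(exp(-tr$times[k]), 132),
                 tolerance = 1e-6)
  }
})

test_that("an all-zero-rate model yields a constant trajectory", {
  p <- spn_parameters()
  p <- set_parameters(p, c(
    setNames(rep(Inf, 13), p$name[p$category == "half_life"]),
    V_max = 0, B = 0, k_bind = 0, r_exo_WG = 0, r_endo_WG = 0,
    C_CI = 0, T_EN = 0, T_IWG = 0, T_PTC = 0, T_CI = 0, T_HH = 0,
    r_mem_WG = 0, r_mem_PTC = 0, r_mem_HH = 0))
  m <- build_model(1, 4, p)
  x0 <- runif(132)
  tr <- run_timecourse(m, x0, t_end = 100, dt_out = 20)
  expect_equal(tr$status, "ok")
  for (k in seq_along(tr$times)) {
    expect_equal(unname(tr$states[k, ]), x0, tolerance = 1e-10)
  }
})

test_that("steady-state search finds the bistable attractors", {
  toy <- toy_bistable()
  lo <- find_steady_state(toy, 0.1, resolution = 1e-4, t_max = 1e6)
  hi <- find_steady_state(toy, 0.9, resolution = 1e-4, t_max = 1e6)
  expect_true(lo$converged)
  expect_true(hi$converged)
  expect_equal(unname(lo$state), 0, tolerance = 1e-4)
  expect_equal(unname(hi$state), 1, tolerance = 1e-4)
  dec <- find_steady_state(toy_decay(), 1)
  expect_true(dec$converged)
  expect_equal(unname(dec$state), 0, tolerance = 1e-4)
})

test_that("a pure oscillator never converges", {
  ss <- find_steady_state(toy_oscillator(), c(1, 0), resolution = 1e-4,
                          t_max = 2000, span0 = 50)
  expect_false(ss$converged)
  expect_gte(ss$t_reached, 2000 - 1e-9)
})

test_that("reported steady states pass an independent residual check", {
  m <- build_model(1, 4)
  x0 <- ic_preset("crisp")
  ss <- find_steady_state(m, x0, resolution = 1e-4, t_max = 5e4)
  expect_true(ss$converged)
  # independent evaluation, not solver trust
  resid <- max(abs(compile_rhs(m)(unname(ss$state))))
  expect_lt(resid, 1e-4)
})

test_that("homogeneous initial conditions stay homogeneous", {
  m <- build_model(1, 4)
  set.seed(8)
  x0 <- rep(runif(33), 4)
  tr <- run_timecourse(m, x0, t_end = 200, dt_out = 50,
                       atol = 1e-12, rtol = 1e-8)
  expect_equal(tr$status, "ok")
  for (k in seq_along(tr$times)) {
    blocks <- matrix(tr$states[k, ], ncol = 4)
    for (c in 2:4) {
      expect_equal(blocks[, c], blocks[, 1], tolerance = 1e-7)
    }
  }
})

test_that("trajectory bookkeeping and tidy export", {
  m <- build_model(1, 2)
  tr <- run_timecourse(m, numeric(66), t_end = 50, dt_out = 10)
  expect_s3_class(tr, "spn_trajectory")
  expect_equal(length(tr$times), 6L)
  expect_true(all(diff(tr$times) > 0))
  expect_equal(dim(tr$states), c(6L, 66L))
  df <- as.data.frame(tr)
  expect_equal(nrow(df), 6L * 66L)
  expect_true(all(c("time", "species", "value", "col") %in% names(df)))
  p <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, p)
  back <- read.csv(p)
  expect_equal(nrow(back), nrow(df))
  expect_equal(back$value, df$value)
})

test_that("state-length mismatches are argument errors", {
  m <- build_model(1, 4)
  expect_error(run_timecourse(m, numeric(10)), "132")
  expect_error(compile_rhs(m)(numeric(5)), "132")
  expect_error(find_steady_state(m, numeric(3)), "length")
})
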