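# Shared, memoised heavy computations so several test files can reuse the
# same screen/census runs instead of re-integrating thousands of ODEs.
.acc_cache <- new.env(parent = emptyenv())

acc_memo <- function(name, compute) {
  if (!exists(name, envir = .acc_cache, inherits = FALSE)) {
    assign(name, compute(), envir = .acc_cache)
  }
  get(name, envir = .acc_cache, inherits = FALSE)
}

# Monte-Carlo problem sizes used by the acceptance-style checks; chosen so
# the whole suite completes on a single desktop core while the binomial
# confidence intervals stay informative.
ACC_N_CRISP <- 1500L
ACC_N_CLOSE <- 800L
ACC_N_CENSUS <- 40L
ACC_N_GUARD_OFF <- 250L

acc_crisp_screen <- function() {
  acc_memo("crisp", function() {
    run_screen("crisp", n_tries = ACC_N_CRISP, seed = 42)
  })
}

acc_close_screen <- function() {
  acc_memo("close", function() {
    run_screen("close_to_target", n_tries = ACC_N_CLOSE, seed = 43)
  })
}

acc_census <- function() {
  acc_memo("census", function() {
    run_multistab_census(n_params = ACC_N_CENSUS, n_ic = 15, seed = 7)
  })
}

acc_timecourse1_model <- function() {
  build_model(1, 4, set_parameters(spn_parameters(),
                                   timecourse1_parameters()))
}
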