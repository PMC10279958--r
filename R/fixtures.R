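#' Test fixtures: small models with known expectations
#'
#' `"tiny_grid"` is a 1x2 segment polarity model (66 species) for fast
#' integration tests; `"toy_bistable"` and `"toy_decay"` are
#' one-dimensional systems with closed-form attractors used as oracles
#' for the dynamics and multistability machinery.
#'
#' @param kind fixture name.
#' @param seed integer; used for reproducible random states bundled with
#'   the fixture.
#' @return list with `model` and `expectations` (reference values the
#'   fixture guarantees).
#' @export
make_fixtures <- function(kind = c("tiny_grid", "toy_bistable",
                                   "toy_decay"), seed = 1L) {
  kind <- match.arg(kind)
  switch(kind,
    tiny_grid = {
      model <- build_model(1, 2)
      set.seed(.record_seed(seed, 1L))
      random_states <- matrix(stats::runif(5L * model$n_species),
                              nrow = 5L)
      list(model = model,
           random_states = random_states,
           expectations = list(n_species = 66L, n_cells = 2L,
                               n_parameters = 53L, n_sampled = 48L))
    },
    toy_bistable = {
      list(model = toy_bistable(),
           expectations = list(attractors = c(0, 1), separatrix = 0.3))
    },
    toy_decay = {
      list(model = toy_decay(),
           expectations = list(solution = function(t, x0 = 1) x0 * exp(-t)))
    })
}
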