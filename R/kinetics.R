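#' Guard configuration for numerically protected rate laws
#'
#' The model's Hill-type rate laws raise state variables to non-integer
#' powers.  IEEE arithmetic computes `base^exponent` as
#' `exp(exponent * log(base))`, which is NaN for any negative base -- and
#' predictor-corrector integrators routinely overshoot a concentration
#' slightly below zero.  The guard replaces every exponentiation whose base
#' depends on the state by `max(epsilon, base)^exponent`, making the
#' right-hand side a total function of the state.  Constant bases
#' (half-saturation constants) are never guarded.
#'
#' @param epsilon positive guard floor (dimensionless); default `1e-80`.
#' @param enabled logical; disable to reproduce the unprotected rate laws
#'   and their NaN failure mode.
#' @return object of class `spn_guard`.
#' @export
guard_config <- function(epsilon = 1e-80, enabled = TRUE) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !(epsilon > 0)) {
    stop("'epsilon' must be a single positive number", call. = FALSE)
  }
  structure(list(epsilon = as.numeric(epsilon), enabled = isTRUE(enabled)),
            class = "spn_guard")
}

#' Guarded exponentiation
#'
#' `max(epsilon, base)^exponent` when the guard is enabled, plain
#' `base^exponent` otherwise.  With the guard on the result is finite for
#' every finite base, including small negative values produced by
#' integrator overshoot.
#'
#' @param base,exponent numeric (vectorized over `base`).
#' @param guard an [guard_config()] object.
#' @return numeric.
#' @export
pow_guarded <- function(base, exponent, guard = guard_config()) {
  stopifnot(inherits(guard, "spn_guard"))
  if (guard$enabled) base <- pmax(guard$epsilon, base)
  base^exponent
}

#' Hill activation and repression
#'
#' `hill_activation()` is the saturating activation fraction
#' `phi(x) = x^nu / (kappa^nu + x^nu)`, equal to 1/2 at `x = kappa`.
#' `hill_repression()` is `psi(x) = 1 - phi(x)`.  With the guard enabled
#' the state-dependent base is floored at `epsilon` before exponentiation,
#' and the repression factor is additionally clamped to at least `epsilon`
#' so that it can never go negative.  `kappa^nu` is a positive constant
#' and is never guarded.
#'
#' @param x concentration (vectorized).
#' @param kappa positive half-saturation constant.
#' @param nu cooperativity exponent, `>= 1`.
#' @param guard an [guard_config()] object.
#' @return fraction in `[0, 1]` (guarded repression in `[epsilon, 1]`).
#' @export
hill_activation <- function(x, kappa, nu, guard = guard_config()) {
  stopifnot(kappa > 0, nu >= 1)
  xp <- pow_guarded(x, nu, guard)
  xp / (kappa^nu + xp)
}

#' @rdname hill_activation
#' @export
hill_repression <- function(x, kappa, nu, guard = guard_config()) {
  r <- 1 - hill_activation(x, kappa, nu, guard)
  if (guard$enabled) r <- pmax(guard$epsilon, r)
  r
}

#' Transcription rate for an inducer--repressor pair
#'
#' The rate law driving `en`, `ptc` and `hh` transcription: the repressor
#' attenuates the inducer through the guarded repression factor
#' `psi(R; kappa_R, nu_R)`, and the effective inducer `I * psi` enters a
#' Hill activation with constants `kappa_I`, `nu_I`:
#' \deqn{V \frac{\max(\epsilon, I\psi)^{\nu_I}}
#'              {\kappa_I^{\nu_I} + \max(\epsilon, I\psi)^{\nu_I}}.}
#' Every exponentiation base that is a function of the state is guarded;
#' the constant terms `kappa_I^nu_I` and `kappa_R^nu_R` are not.  With the
#' guard disabled the original, NaN-prone law is evaluated.
#'
#' @param V maximal rate, `>= 0`.
#' @param I inducer concentration.
#' @param R repressor concentration.
#' @param kappa_I,nu_I half-saturation and exponent of the inducer term.
#' @param kappa_R,nu_R half-saturation and exponent of the repressor term.
#' @param guard an [guard_config()] object.
#' @return transcription rate.
#' @export
transcription_inducer_repressor <- function(V, I, R, kappa_I, nu_I,
                                            kappa_R, nu_R,
                                            guard = guard_config()) {
  stopifnot(V >= 0)
  psi <- hill_repression(R, kappa_R, nu_R, guard)
  num <- pow_guarded(I * psi, nu_I, guard)
  V * num / (kappa_I^nu_I + num)
}

#' First-order rate terms
#'
#' Mass-action first-order rates used for translation, decay, membrane
#' transfer and conversion steps: `rate_constant * x`.  Decay steps are
#' parameterized by a half-life `H`, with rate constant `log(2) / H`; use
#' [half_life_rate()] to convert.
#'
#' @param kind one of `"translation"`, `"decay"`, `"transfer"`,
#'   `"conversion"` (informational).
#' @param rate_constant non-negative first-order rate constant (per time).
#' @param x concentration.
#' @return rate.
#' @export
linear_rate <- function(kind = c("translation", "decay", "transfer",
                                 "conversion"),
                        rate_constant, x) {
  kind <- match.arg(kind)
  if (any(rate_constant < 0)) {
    stop("'rate_constant' must be non-negative", call. = FALSE)
  }
  rate_constant * x
}

#' @rdname linear_rate
#' @param H half-life (time units); `Inf` gives a rate constant of 0.
#' @export
half_life_rate <- function(H) {
  if (any(H <= 0)) stop("half-life must be positive", call. = FALSE)
  log(2) / H
}
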