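#' Default parameter registry of the segment polarity network model
#'
#' The model has 53 named global parameters shared by all cells, 48 of
#' which are sampled in the robustness screen; the remaining 5 (the basal
#' transcription input `B`, the shared maximal transcription rate `V_max`,
#' and the three within-membrane side-to-side diffusion rates) are held
#' fixed.  Sampling is log-uniform within the per-category ranges:
#' half-lives 5--100 time units, half-saturation constants `kappa`
#' 1e-3--1, cooperativity exponents `nu` 1--10, kinetic rate constants
#' 1e-3--1e3, and the concentration scale factors `PTC_0`/`HH_0` 1--1000.
#' Default values sit at the geometric midpoint of each range.
#'
#' @return A data frame (one row per parameter) with columns `name`,
#'   `value`, `range_lo`, `range_hi`, `scale` (`"log"`), `sampled`
#'   (logical) and `category`.
#' @examples
#' p <- spn_parameters()
#' nrow(p)            # 53
#' sum(p$sampled)     # 48
#' @export
spn_parameters <- function() {
  half_lives <- c("H_en", "H_EN", "H_wg", "H_IWG", "H_EWG", "H_ptc",
                  "H_PTC", "H_ci", "H_CI", "H_CN", "H_hh", "H_HH", "H_PH")
  arrows <- c("WGen", "CNen", "CIwg", "CNwg", "WGwg", "CIptc", "CNptc",
              "ENci", "PTCCI", "ENhh", "CNhh")
  kn <- as.vector(rbind(paste0("kappa_", arrows), paste0("nu_", arrows)))
  rates <- c("alpha_CIwg", "beta_WGwg", "C_CI", "k_bind",
             "r_exo_WG", "r_endo_WG",
             "T_EN", "T_IWG", "T_PTC", "T_CI", "T_HH")
  scales <- c("PTC_0", "HH_0")
  fixed <- c("B", "V_max", "r_mem_WG", "r_mem_PTC", "r_mem_HH")

  name <- c(half_lives, kn, rates, scales, fixed)
  category <- c(rep("half_life", length(half_lives)),
                rep(c("kappa", "nu"), length(arrows)),
                rep("rate", length(rates)),
                rep("scale_factor", length(scales)),
                rep("rate", length(fixed)))
  lims <- list(half_life    = c(5, 100),
               kappa        = c(1e-3, 1),
               nu           = c(1, 10),
               rate         = c(1e-3, 1e3),
               scale_factor = c(1, 1000))
  range_lo <- vapply(category, function(k) lims[[k]][1L], numeric(1))
  range_hi <- vapply(category, function(k) lims[[k]][2L], numeric(1))
  value <- sqrt(range_lo * range_hi)
  sampled <- !(name %in% fixed)
  value[name %in% c("B", "V_max", "r_mem_WG", "r_mem_PTC", "r_mem_HH")] <- 1

  data.frame(name = name, value = value, range_lo = range_lo,
             range_hi = range_hi, scale = "log", sampled = sampled,
             category = category, row.names = NULL)
}

#' Validate a parameter table
#'
#' Checks the structural invariants of a parameter registry: required
#' columns, positive ranges with `range_lo <= value <= range_hi` for
#' sampled rows, and (for the default registry shape) 53 rows of which 48
#' are sampled.
#'
#' @param params parameter data frame as returned by [spn_parameters()].
#' @param require_counts enforce the 53/48 registry shape (default TRUE).
#' @return `params`, invisibly; errors describe the offending row.
#' @export
validate_parameters <- function(params, require_counts = TRUE) {
  need <- c("name", "value", "range_lo", "range_hi", "scale", "sampled",
            "category")
  if (!is.data.frame(params) || !all(need %in% names(params))) {
    stop("parameter table must contain columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(params$name)) {
    stop("duplicated parameter name: ",
         params$name[duplicated(params$name)][1L], call. = FALSE)
  }
  s <- params$sampled
  bad <- s & (!(params$range_lo > 0) | params$range_lo >= params$range_hi)
  if (any(bad)) {
    stop("invalid sampling range for parameter ",
         params$name[bad][1L], call. = FALSE)
  }
  bad <- s & (params$value < params$range_lo | params$value > params$range_hi)
  if (any(bad)) {
    stop("value outside sampling range for parameter ",
         params$name[bad][1L], call. = FALSE)
  }
  if (require_counts && (nrow(params) != 53L || sum(s) != 48L)) {
    stop(sprintf("registry must have 53 parameters with 48 sampled (got %d/%d)",
                 nrow(params), sum(s)), call. = FALSE)
  }
  invisible(params)
}

#' Replace parameter values in a registry
#'
#' @param params parameter data frame.
#' @param values named numeric vector of replacement values.
#' @return the updated data frame.
#' @export
set_parameters <- function(params, values) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  idx <- match(names(values), params$name)
  if (anyNA(idx)) {
    stop("unknown parameter: ", names(values)[is.na(idx)][1L], call. = FALSE)
  }
  params$value[idx] <- unname(values)
  params
}

#' Read/write a parameter registry as JSON
#'
#' The JSON configuration is the normative parameter list: every row with
#' name, value, range, scale and sampled flag.
#'
#' @param params parameter data frame.
#' @param path file path.
#' @return `read_parameters()` returns the data frame.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params, require_counts = FALSE)
  jsonlite::write_json(params, path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  p <- jsonlite::fromJSON(path)
  p <- as.data.frame(p)
  validate_parameters(p, require_counts = FALSE)
  p
}
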