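# Symbolic reaction registry: every ODE term of the model as a reaction
# with reactants/products/modifiers and a rate expression over species
# identifiers and parameter names.  This is the source for the SBML
# export and for the pure-R reference right-hand side; the compiled core
# in src/ must agree with it (tested).

# -- rate-expression builders (strings; 'guard_eps' is the guard floor) --

.e_pow <- function(x, e, guarded) {
  if (guarded) sprintf("max(guard_eps, %s)^%s", x, e)
  else sprintf("(%s)^%s", x, e)
}
.e_phi <- function(x, kap, nu, guarded) {
  g <- .e_pow(x, nu, guarded)
  sprintf("(%s/(%s^%s + %s))", g, kap, nu, g)
}
.e_psi <- function(x, kap, nu, guarded) {
  inner <- .e_phi(x, kap, nu, guarded)
  if (guarded) sprintf("max(guard_eps, 1 - %s)", inner)
  else sprintf("(1 - %s)", inner)
}
.e_txn <- function(I, R, kI, nI, kR, nR, guarded) {
  num <- sprintf("(%s * %s)", I, .e_psi(R, kR, nR, guarded))
  g <- .e_pow(num, nI, guarded)
  sprintf("V_max * %s/(%s^%s + %s)", g, kI, nI, g)
}

.rxn <- function(id, reactants = NULL, products = NULL,
                 modifiers = character(), math, reversible = FALSE) {
  list(id = id, reactants = reactants, products = products,
       modifiers = modifiers, math = math, reversible = reversible)
}

#' Reaction registry of a model
#'
#' Enumerates every reaction of the assembled network (transcription,
#' translation, decay, membrane exchange and diffusion, CI cleavage,
#' PTC--HH binding) with its rate expression, plus the assignment rules
#' for the derived totals `EWG_T`, `PTC_T`, `PH_T`.
#'
#' @param model an `spn_model`.
#' @return list with elements `rules` (named character, evaluation order)
#'   and `reactions` (list; each has `id`, `reactants`, `products`,
#'   `modifiers`, `math`, `reversible`).
#' @export
spn_reactions <- function(model) {
  stopifnot(inherits(model, "spn_model"))
  gd <- model$guard$enabled
  grid <- model$grid
  rules <- list()
  rx <- list()

  nbr_ref <- function(c0, j, label) {
    nb <- model$neighbor[c0 + 1L, j]
    jop <- opposite_side(j)
    if (nb >= 0) {
      paste0(label, jop, "_", grid$cells$row[nb + 1L], "_",
             grid$cells$col[nb + 1L])
    } else {
      paste0("b_", label, jop)       # fixed boundary pool (parameter)
    }
  }
  is_species <- function(ref) !startsWith(ref, "b_")

  for (c0 in seq_len(grid$n_cells) - 1L) {
    s <- paste0(grid$cells$row[c0 + 1L], "_", grid$cells$col[c0 + 1L])
    sp <- function(label) paste0(label, "_", s)

    ewg_nb <- vapply(1:6, nbr_ref, character(1), c0 = c0, label = "EWG")
    hh_nb  <- vapply(1:6, nbr_ref, character(1), c0 = c0, label = "HH")
    ptc_nb <- vapply(1:6, nbr_ref, character(1), c0 = c0, label = "PTC")

    rules[[paste0("EWG_T_", s)]] <- paste(ewg_nb, collapse = " + ")
    rules[[paste0("PTC_T_", s)]] <- paste(sp(paste0("PTC", 1:6)),
                                          collapse = " + ")
    rules[[paste0("PH_T_", s)]] <- paste(sp(paste0("PH", 1:6)),
                                         collapse = " + ")

    add <- function(r) rx[[length(rx) + 1L]] <<- r

    ## transcription
    add(.rxn(paste0("tx_en_", s), products = stats::setNames(1, sp("en")),
             modifiers = c(ewg_nb[is_species(ewg_nb)], sp("CN")),
             math = .e_txn(paste0("EWG_T_", s), sp("CN"),
                           "kappa_WGen", "nu_WGen", "kappa_CNen", "nu_CNen",
                           gd)))
    wg_num <- sprintf(
      "(alpha_CIwg * %s * %s + beta_WGwg * %s)",
      .e_phi(sp("CI"), "kappa_CIwg", "nu_CIwg", gd),
      .e_psi(sp("CN"), "kappa_CNwg", "nu_CNwg", gd),
      .e_phi(sp("IWG"), "kappa_WGwg", "nu_WGwg", gd))
    add(.rxn(paste0("tx_wg_", s), products = stats::setNames(1, sp("wg")),
             modifiers = c(sp("CI"), sp("CN"), sp("IWG")),
             math = sprintf("V_max * %s/(1 + %s)", wg_num, wg_num)))
    add(.rxn(paste0("tx_ptc_", s), products = stats::setNames(1, sp("ptc")),
             modifiers = c(sp("CI"), sp("CN")),
             math = .e_txn(sp("CI"), sp("CN"), "kappa_CIptc", "nu_CIptc",
                           "kappa_CNptc", "nu_CNptc", gd)))
    add(.rxn(paste0("tx_ci_", s), products = stats::setNames(1, sp("ci")),
             modifiers = sp("EN"),
             math = sprintf("V_max * B * %s",
                            .e_psi(sp("EN"), "kappa_ENci", "nu_ENci", gd))))
    add(.rxn(paste0("tx_hh_", s), products = stats::setNames(1, sp("hh")),
             modifiers = c(sp("EN"), sp("CN")),
             math = .e_txn(sp("EN"), sp("CN"), "kappa_ENhh", "nu_ENhh",
                           "kappa_CNhh", "nu_CNhh", gd)))

    ## mRNA decay
    for (m in c("en", "wg", "ptc", "ci", "hh")) {
      add(.rxn(paste0("deg_", m, "_", s),
               reactants = stats::setNames(1, sp(m)),
               math = sprintf("(log(2)/H_%s) * %s", m, sp(m))))
    }

    ## translation
    add(.rxn(paste0("tl_EN_", s), products = stats::setNames(1, sp("EN")),
             modifiers = sp("en"), math = sprintf("T_EN * %s", sp("en"))))
    add(.rxn(paste0("tl_IWG_", s), products = stats::setNames(1, sp("IWG")),
             modifiers = sp("wg"), math = sprintf("T_IWG * %s", sp("wg"))))
    add(.rxn(paste0("tl_CI_", s), products = stats::setNames(1, sp("CI")),
             modifiers = sp("ci"), math = sprintf("T_CI * %s", sp("ci"))))
    for (j in 1:6) {
      add(.rxn(paste0("tl_PTC", j, "_", s),
               products = stats::setNames(1, sp(paste0("PTC", j))),
               modifiers = sp("ptc"),
               math = sprintf("(T_PTC/6) * %s", sp("ptc"))))
      add(.rxn(paste0("tl_HH", j, "_", s),
               products = stats::setNames(1, sp(paste0("HH", j))),
               modifiers = sp("hh"),
               math = sprintf("(T_HH/6) * %s", sp("hh"))))
    }

    ## cytosolic protein decay
    for (pp in c("EN", "IWG", "CI", "CN")) {
      add(.rxn(paste0("deg_", pp, "_", s),
               reactants = stats::setNames(1, sp(pp)),
               math = sprintf("(log(2)/H_%s) * %s", pp, sp(pp))))
    }

    ## CI cleavage, promoted by free PTC
    add(.rxn(paste0("cleave_CI_", s),
             reactants = stats::setNames(1, sp("CI")),
             products = stats::setNames(1, sp("CN")),
             modifiers = sp(paste0("PTC", 1:6)),
             math = sprintf("C_CI * %s * %s", sp("CI"),
                            .e_phi(paste0("PTC_T_", s),
                                   "kappa_PTCCI", "nu_PTCCI", gd))))

    ## IWG <-> EWG membrane exchange
    for (j in 1:6) {
      add(.rxn(paste0("exo_WG", j, "_", s),
               reactants = stats::setNames(1, sp("IWG")),
               products = stats::setNames(1, sp(paste0("EWG", j))),
               math = sprintf("(r_exo_WG/6) * %s", sp("IWG"))))
      add(.rxn(paste0("endo_WG", j, "_", s),
               reactants = stats::setNames(1, sp(paste0("EWG", j))),
               products = stats::setNames(1, sp("IWG")),
               math = sprintf("r_endo_WG * %s", sp(paste0("EWG", j)))))
    }

    ## side-to-side membrane diffusion (net reversible exchange per edge)
    for (pr in list(c("EWG", "r_mem_WG"), c("PTC", "r_mem_PTC"),
                    c("HH", "r_mem_HH"))) {
      for (j in 1:6) {
        jp <- (j %% 6L) + 1L
        a <- sp(paste0(pr[1L], j)); b <- sp(paste0(pr[1L], jp))
        add(.rxn(paste0("diff_", pr[1L], j, jp, "_", s),
                 reactants = stats::setNames(1, a),
                 products = stats::setNames(1, b),
                 math = sprintf("%s * (%s - %s)", pr[2L], a, b),
                 reversible = TRUE))
      }
    }

    ## membrane protein decay
    for (pp in c("EWG", "PTC", "HH", "PH")) {
      for (j in 1:6) {
        add(.rxn(paste0("deg_", pp, j, "_", s),
                 reactants = stats::setNames(1, sp(paste0(pp, j))),
                 math = sprintf("(log(2)/H_%s) * %s", pp,
                                sp(paste0(pp, j)))))
      }
    }

    ## PTC-HH binding across apposed sides (normalized-scale fluxes)
    for (j in 1:6) {
      add(.rxn(paste0("bind_PH", j, "_", s),
               reactants = stats::setNames(1, sp(paste0("PTC", j))),
               products = stats::setNames(1, sp(paste0("PH", j))),
               modifiers = hh_nb[j][is_species(hh_nb[j])],
               math = sprintf("k_bind * HH_0 * %s * %s",
                              sp(paste0("PTC", j)), hh_nb[j])))
      add(.rxn(paste0("bind_HH", j, "_", s),
               reactants = stats::setNames(1, sp(paste0("HH", j))),
               modifiers = ptc_nb[j][is_species(ptc_nb[j])],
               math = sprintf("k_bind * PTC_0 * %s * %s",
                              ptc_nb[j], sp(paste0("HH", j)))))
    }
  }

  list(rules = rules, reactions = rx)
}

#' Reference (interpreted) right-hand side
#'
#' Evaluates the ODE right-hand side by summing the rate expressions of
#' the reaction registry, independently of the compiled core.  Slow;
#' intended for verification and for comparing against imported SBML.
#'
#' @param model an `spn_model`.
#' @return function `f(state, t = 0)` returning the derivative vector.
#' @export
spn_reference_rhs <- function(model) {
  net <- spn_reactions(model)
  ids <- model$species$id
  rule_expr <- lapply(net$rules, str2lang)
  rx <- lapply(net$reactions, function(r) {
    list(math = str2lang(r$math),
         r_idx = match(names(r$reactants), ids),
         r_st = unname(r$reactants),
         p_idx = match(names(r$products), ids),
         p_st = unname(r$products))
  })
  par_list <- as.list(stats::setNames(model$params$value,
                                      model$params$name))
  par_list$guard_eps <- model$guard$epsilon
  if (model$single_cell) {
    bn <- c(paste0("b_EWG", 1:6), paste0("b_PTC", 1:6), paste0("b_HH", 1:6))
    par_list[bn] <- as.list(model$boundary)
  }
  function(state, t = 0) {
    stopifnot(length(state) == length(ids))
    env <- list2env(par_list, parent = baseenv())
    for (i in seq_along(ids)) assign(ids[i], state[i], envir = env)
    for (nm in names(rule_expr)) {
      assign(nm, eval(rule_expr[[nm]], env), envir = env)
    }
    d <- numeric(length(ids))
    for (r in rx) {
      v <- eval(r$math, env)
      if (length(r$r_idx)) d[r$r_idx] <- d[r$r_idx] - r$r_st * v
      if (length(r$p_idx)) d[r$p_idx] <- d[r$p_idx] + r$p_st * v
    }
    d
  }
}
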