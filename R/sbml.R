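# SBML Level 3 Version 1 export/import.
#
# The writer serializes the assembled reaction network: one compartment
# per cell, cell-qualified species identifiers (EWG5_0_1 ...), global
# parameters, the derived totals as assignment-ruled parameters, and full
# kinetic laws in MathML.  The guard max(epsilon, x) has no MathML
# operator in L3V1 core and is encoded as a piecewise.  The reader
# reconstructs a model whose right-hand side is evaluated directly from
# the document (species, rules, reactions), which is what the round-trip
# equivalence tests compare against the compiled core.
# Validation is structural: well-formedness, id uniqueness and
# resolution, and parseability of every math element.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

## ---- R expression -> MathML ----

.cn_xml <- function(x) {
  if (is.finite(x) && x == floor(x) && abs(x) < 2^31) {
    return(sprintf('<cn type="integer">%d</cn>', as.integer(x)))
  }
  s <- formatC(x, digits = 17, format = "g")
  if (grepl("[eE]", s)) {
    parts <- strsplit(s, "[eE]")[[1L]]
    sprintf('<cn type="e-notation">%s<sep/>%s</cn>',
            parts[1L], as.integer(parts[2L]))
  } else {
    sprintf("<cn>%s</cn>", s)
  }
}

.expr_to_mathml <- function(e) {
  if (is.numeric(e)) return(.cn_xml(e))
  if (is.name(e)) return(sprintf("<ci>%s</ci>", as.character(e)))
  if (!is.call(e)) stop("cannot encode ", deparse(e), " as MathML")
  op <- as.character(e[[1L]])
  args <- as.list(e)[-1L]
  enc <- function(x) .expr_to_mathml(x)
  nary <- function(tag) {
    paste0("<apply><", tag, "/>",
           paste(vapply(args, enc, character(1)), collapse = ""),
           "</apply>")
  }
  switch(op,
    "(" = enc(args[[1L]]),
    "+" = nary("plus"),
    "-" = nary("minus"),
    "*" = nary("times"),
    "/" = nary("divide"),
    "^" = nary("power"),
    ">" = nary("gt"),
    "<" = nary("lt"),
    ">=" = nary("geq"),
    "<=" = nary("leq"),
    "log" = {
      if (length(args) != 1L) stop("only natural log is encodable")
      paste0("<apply><ln/>", enc(args[[1L]]), "</apply>")
    },
    "exp" = paste0("<apply><exp/>", enc(args[[1L]]), "</apply>"),
    "sqrt" = paste0("<apply><root/>", enc(args[[1L]]), "</apply>"),
    "max" = {
      # max(a, b) -> piecewise(a when a > b, otherwise b)
      stopifnot(length(args) == 2L)
      a <- enc(args[[1L]]); b <- enc(args[[2L]])
      paste0("<piecewise><piece>", a, "<apply><gt/>", a, b,
             "</apply></piece><otherwise>", b, "</otherwise></piecewise>")
    },
    "sbml_piecewise" = {
      n <- length(args)
      stopifnot(n %% 2L == 1L)
      pieces <- character(0)
      k <- 1L
      while (k + 1L <= n - 1L) {
        pieces <- c(pieces, paste0("<piece>", enc(args[[k]]),
                                   enc(args[[k + 1L]]), "</piece>"))
        k <- k + 2L
      }
      paste0("<piecewise>", paste(pieces, collapse = ""),
             "<otherwise>", enc(args[[n]]), "</otherwise></piecewise>")
    },
    stop("operator not encodable as MathML: ", op)
  )
}

.math_element <- function(expr_string) {
  e <- str2lang(expr_string)
  paste0('<math xmlns="', MATHML_NS, '">', .expr_to_mathml(e), "</math>")
}

## ---- MathML -> R expression ----

.mathml_to_expr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1L) stop("math element must have one child")
    return(.mathml_to_expr(kids[[1L]]))
  }
  if (nm == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (nm == "cn") {
    type <- xml2::xml_attr(node, "type")
    if (!is.na(type) && type == "e-notation") {
      txt <- xml2::xml_find_all(node, "text()")
      vals <- as.numeric(trimws(vapply(txt, xml2::xml_text, character(1))))
      return(vals[1L] * 10^vals[2L])
    }
    if (!is.na(type) && type == "rational") {
      txt <- xml2::xml_find_all(node, "text()")
      vals <- as.numeric(trimws(vapply(txt, xml2::xml_text, character(1))))
      return(vals[1L] / vals[2L])
    }
    return(as.numeric(trimws(xml2::xml_text(node))))
  }
  if (nm == "piecewise") {
    kids <- xml2::xml_children(node)
    args <- list()
    otherwise <- NULL
    for (k in kids) {
      kn <- xml2::xml_name(k)
      sub <- xml2::xml_children(k)
      if (kn == "piece") {
        if (length(sub) != 2L) stop("piece must have value and condition")
        args <- c(args, list(.mathml_to_expr(sub[[1L]]),
                             .mathml_to_expr(sub[[2L]])))
      } else if (kn == "otherwise") {
        otherwise <- .mathml_to_expr(sub[[1L]])
      } else {
        stop("unsupported piecewise child: ", kn)
      }
    }
    if (is.null(otherwise)) stop("piecewise without otherwise")
    return(as.call(c(as.name("sbml_piecewise"), args, list(otherwise))))
  }
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1L]])
    args <- lapply(kids[-1L], .mathml_to_expr)
    fold <- function(sym) {
      Reduce(function(a, b) call(sym, a, b), args)
    }
    return(switch(op,
      plus = if (length(args) == 0L) 0 else fold("+"),
      minus = if (length(args) == 1L) call("-", args[[1L]]) else fold("-"),
      times = fold("*"),
      divide = fold("/"),
      power = fold("^"),
      gt = fold(">"), lt = fold("<"), geq = fold(">="), leq = fold("<="),
      ln = call("log", args[[1L]]),
      exp = call("exp", args[[1L]]),
      root = call("sqrt", args[[1L]]),
      stop("unsupported MathML operator: ", op)
    ))
  }
  stop("unsupported MathML element: ", nm)
}

#' Piecewise evaluation helper for imported SBML math
#'
#' Evaluates `sbml_piecewise(v1, cond1, v2, cond2, ..., otherwise)`:
#' the first value whose condition is TRUE, else the final argument.
#' MathML `piecewise` parses to calls of this function.
#'
#' @param ... alternating values and conditions, then the otherwise value.
#' @return scalar value.
#' @export
sbml_piecewise <- function(...) {
  args <- list(...)
  n <- length(args)
  k <- 1L
  while (k + 1L <= n - 1L) {
    if (isTRUE(args[[k + 1L]])) return(args[[k]])
    k <- k + 2L
  }
  args[[n]]
}

## ---- export ----

#' Export a model as SBML Level 3 Version 1
#'
#' Writes the full reaction network: one unit-size compartment per cell,
#' species with cell-qualified identifiers, the 53 global parameters, the
#' derived totals (`EWG_T`, `PTC_T`, `PH_T`) as assignment rules, and
#' every reaction with its kinetic law.  Guarded `max(epsilon, x)` terms
#' are encoded as MathML piecewise expressions (L3V1 has no max
#' operator); with the guard disabled the document contains plain power
#' terms.  A JSON sidecar with the reference time-course specification
#' (end time 1100, output interval 5, tolerances) and a provenance block
#' is written next to the model file.
#'
#' @param model an `spn_model`.
#' @param path output file path (`.xml`).
#' @param x0 optional named initial state (defaults to all-zero).
#' @param sidecar write the JSON simulation sidecar (default TRUE).
#' @return invisibly, a list with `path`, `sidecar` (the simulation setup)
#'   and `provenance`.
#' @export
export_sbml <- function(model, path, x0 = NULL, sidecar = TRUE) {
  stopifnot(inherits(model, "spn_model"))
  net <- spn_reactions(model)
  sp <- model$species
  ini <- stats::setNames(numeric(nrow(sp)), sp$id)
  if (!is.null(x0)) {
    if (is.null(names(x0))) {
      stopifnot(length(x0) == nrow(sp))
      ini[] <- as.numeric(x0)
    } else {
      ini[names(x0)] <- x0
    }
  }

  comp_id <- function(r, cc) paste0("cell_", r, "_", cc)
  comps <- unique(comp_id(sp$row, sp$col))

  buf <- character(0)
  w <- function(...) buf[[length(buf) + 1L]] <<- paste0(...)

  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="', SBML_NS, '" level="3" version="1">')
  w('<model id="segment_polarity_network" name="Segment polarity network, ',
    model$grid$n_rows, 'x', model$grid$n_cols, ' cell grid">')

  w("<listOfCompartments>")
  for (cid in comps) {
    w('<compartment id="', cid,
      '" spatialDimensions="3" size="1" constant="true"/>')
  }
  w("</listOfCompartments>")

  w("<listOfSpecies>")
  for (i in seq_len(nrow(sp))) {
    w('<species id="', sp$id[i], '" compartment="',
      comp_id(sp$row[i], sp$col[i]),
      '" initialConcentration="', formatC(ini[i], digits = 17,
                                          format = "g"),
      '" hasOnlySubstanceUnits="false" boundaryCondition="false"',
      ' constant="false"/>')
  }
  w("</listOfSpecies>")

  w("<listOfParameters>")
  for (i in seq_len(nrow(model$params))) {
    w('<parameter id="', model$params$name[i], '" value="',
      formatC(model$params$value[i], digits = 17, format = "g"),
      '" constant="true"/>')
  }
  w('<parameter id="guard_eps" value="',
    formatC(model$guard$epsilon, digits = 17, format = "g"),
    '" constant="true"/>')
  if (model$single_cell) {
    bn <- c(paste0("b_EWG", 1:6), paste0("b_PTC", 1:6), paste0("b_HH", 1:6))
    for (k in seq_along(bn)) {
      w('<parameter id="', bn[k], '" value="',
        formatC(model$boundary[k], digits = 17, format = "g"),
        '" constant="true"/>')
    }
  }
  for (nm in names(net$rules)) {
    w('<parameter id="', nm, '" value="0" constant="false"/>')
  }
  w("</listOfParameters>")

  w("<listOfRules>")
  for (nm in names(net$rules)) {
    w('<assignmentRule variable="', nm, '">',
      .math_element(net$rules[[nm]]), "</assignmentRule>")
  }
  w("</listOfRules>")

  w("<listOfReactions>")
  for (r in net$reactions) {
    w('<reaction id="', r$id, '" reversible="',
      tolower(as.character(isTRUE(r$reversible))), '" fast="false">')
    if (length(r$reactants)) {
      w("<listOfReactants>")
      for (k in seq_along(r$reactants)) {
        w('<speciesReference species="', names(r$reactants)[k],
          '" stoichiometry="', r$reactants[k], '" constant="true"/>')
      }
      w("</listOfReactants>")
    }
    if (length(r$products)) {
      w("<listOfProducts>")
      for (k in seq_along(r$products)) {
        w('<speciesReference species="', names(r$products)[k],
          '" stoichiometry="', r$products[k], '" constant="true"/>')
      }
      w("</listOfProducts>")
    }
    if (length(r$modifiers)) {
      w("<listOfModifiers>")
      for (m in r$modifiers) {
        w('<modifierSpeciesReference species="', m, '"/>')
      }
      w("</listOfModifiers>")
    }
    w("<kineticLaw>", .math_element(r$math), "</kineticLaw>")
    w("</reaction>")
  }
  w("</listOfReactions>")
  w("</model>")
  w("</sbml>")

  writeLines(paste(buf, collapse = "\n"), path)

  check <- validate_sbml(path)
  if (!check$valid) {
    stop("exported SBML failed validation: ",
         paste(check$messages, collapse = "; "), call. = FALSE)
  }

  sim <- list(t_end = 1100, dt_out = 5, atol = 1e-13, rtol = 1e-8,
              algorithm = "LSODA")
  prov <- list(package = "spnsim",
               version = as.character(utils::packageVersion("spnsim")),
               created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               n_species = model$n_species,
               guard_enabled = model$guard$enabled,
               guard_epsilon = model$guard$epsilon)
  if (sidecar) {
    jsonlite::write_json(list(simulation = sim, provenance = prov),
                         paste0(path, ".sim.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(path = path, sidecar = sim, provenance = prov))
}

#' Structural validation of an SBML file
#'
#' Checks well-formedness, the L3V1 namespace, identifier uniqueness,
#' that species/compartment/speciesReference identifiers resolve, and
#' that every math element parses.  (Full XSD schema validation is not
#' performed.)
#'
#' @param path SBML file path.
#' @return list with `valid` (logical) and `messages` (character).
#' @export
validate_sbml <- function(path) {
  msgs <- character(0)
  doc <- try(xml2::read_xml(path), silent = TRUE)
  if (inherits(doc, "try-error")) {
    return(list(valid = FALSE, messages = "file is not well-formed XML"))
  }
  if (xml2::xml_name(doc) != "sbml") {
    msgs <- c(msgs, "root element is not <sbml>")
  }
  ns <- c(s = SBML_NS, m = MATHML_NS)
  mdl <- xml2::xml_find_first(doc, "./s:model", ns)
  if (inherits(mdl, "xml_missing")) {
    return(list(valid = FALSE, messages = c(msgs, "no <model> element")))
  }
  get_ids <- function(xp) {
    xml2::xml_attr(xml2::xml_find_all(mdl, xp, ns), "id")
  }
  comp_ids <- get_ids(".//s:listOfCompartments/s:compartment")
  spc <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  sp_ids <- xml2::xml_attr(spc, "id")
  par_ids <- get_ids(".//s:listOfParameters/s:parameter")
  all_ids <- c(comp_ids, sp_ids, par_ids)
  if (anyDuplicated(all_ids)) {
    msgs <- c(msgs, paste("duplicate id:",
                          all_ids[duplicated(all_ids)][1L]))
  }
  bad_comp <- setdiff(xml2::xml_attr(spc, "compartment"), comp_ids)
  if (length(bad_comp)) {
    msgs <- c(msgs, paste("species compartment not found:", bad_comp[1L]))
  }
  refs <- xml2::xml_attr(
    xml2::xml_find_all(mdl, ".//s:speciesReference | .//s:modifierSpeciesReference",
                       ns), "species")
  bad_ref <- setdiff(refs, sp_ids)
  if (length(bad_ref)) {
    msgs <- c(msgs, paste("species reference not found:", bad_ref[1L]))
  }
  maths <- xml2::xml_find_all(mdl, ".//m:math", ns)
  for (mn in maths) {
    ok <- try(.mathml_to_expr(mn), silent = TRUE)
    if (inherits(ok, "try-error")) {
      msgs <- c(msgs, paste("unparseable math:",
                            conditionMessage(attr(ok, "condition"))))
      break
    }
  }
  list(valid = length(msgs) == 0L, messages = msgs)
}

## ---- import ----

#' Import an SBML Level 3 model
#'
#' Reads an SBML file with full kinetic laws and reconstructs a model
#' whose right-hand side is evaluated from the document: assignment rules
#' are applied in document order, every kinetic law is evaluated, and
#' stoichiometries are accumulated per species.  Constructs outside the
#' supported subset (events, rate/algebraic rules, function definitions,
#' delays) are rejected with a message listing them.
#'
#' @param path SBML file path.
#' @return object of class `sbml_model` with elements `species` (data
#'   frame `id`, `compartment`, `initial`, `boundary`), `parameters`
#'   (named numeric), `rules`, `reactions`, `species_ids`, `n_species`.
#' @seealso [sbml_rhs()]
#' @export
import_sbml <- function(path) {
  doc <- try(xml2::read_xml(path), silent = TRUE)
  if (inherits(doc, "try-error")) {
    stop("cannot read SBML file: not well-formed XML", call. = FALSE)
  }
  ns <- c(s = SBML_NS, m = MATHML_NS)
  if (xml2::xml_name(doc) != "sbml") {
    stop("not an SBML document", call. = FALSE)
  }
  mdl <- xml2::xml_find_first(doc, "./s:model", ns)
  if (inherits(mdl, "xml_missing")) {
    stop("SBML document has no <model>", call. = FALSE)
  }
  unsupported <- c(
    events = ".//s:listOfEvents/s:event",
    functionDefinitions = ".//s:listOfFunctionDefinitions/s:functionDefinition",
    rateRules = ".//s:rateRule",
    algebraicRules = ".//s:algebraicRule",
    constraints = ".//s:listOfConstraints/s:constraint",
    delays = ".//s:delay")
  found <- names(unsupported)[vapply(unsupported, function(xp) {
    length(xml2::xml_find_all(mdl, xp, ns)) > 0L
  }, logical(1))]
  if (length(found)) {
    stop("unsupported SBML constructs: ", paste(found, collapse = ", "),
         call. = FALSE)
  }

  spc <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  species <- data.frame(
    id = xml2::xml_attr(spc, "id"),
    compartment = xml2::xml_attr(spc, "compartment"),
    initial = suppressWarnings(
      as.numeric(xml2::xml_attr(spc, "initialConcentration"))),
    boundary = xml2::xml_attr(spc, "boundaryCondition") %in% "true"
  )
  species$initial[is.na(species$initial)] <- 0

  parn <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  parameters <- stats::setNames(
    suppressWarnings(as.numeric(xml2::xml_attr(parn, "value"))),
    xml2::xml_attr(parn, "id"))
  parameters[is.na(parameters)] <- 0
  cmpn <- xml2::xml_find_all(mdl, ".//s:listOfCompartments/s:compartment",
                             ns)
  comp_sizes <- stats::setNames(
    suppressWarnings(as.numeric(xml2::xml_attr(cmpn, "size"))),
    xml2::xml_attr(cmpn, "id"))

  rulen <- xml2::xml_find_all(mdl, ".//s:listOfRules/s:assignmentRule", ns)
  rules <- lapply(rulen, function(rn) {
    list(variable = xml2::xml_attr(rn, "variable"),
         expr = .mathml_to_expr(xml2::xml_find_first(rn, "./m:math", ns)))
  })

  rxnn <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  reactions <- lapply(rxnn, function(rn) {
    refs <- function(xp) {
      nodes <- xml2::xml_find_all(rn, xp, ns)
      if (!length(nodes)) return(NULL)
      st <- suppressWarnings(as.numeric(xml2::xml_attr(nodes,
                                                       "stoichiometry")))
      st[is.na(st)] <- 1
      stats::setNames(st, xml2::xml_attr(nodes, "species"))
    }
    math <- xml2::xml_find_first(rn, "./s:kineticLaw/m:math", ns)
    if (inherits(math, "xml_missing")) {
      stop("reaction ", xml2::xml_attr(rn, "id"),
           " has no kinetic law", call. = FALSE)
    }
    list(id = xml2::xml_attr(rn, "id"),
         reactants = refs("./s:listOfReactants/s:speciesReference"),
         products = refs("./s:listOfProducts/s:speciesReference"),
         math = .mathml_to_expr(math))
  })

  structure(list(id = xml2::xml_attr(mdl, "id"), species = species,
                 parameters = parameters, comp_sizes = comp_sizes,
                 rules = rules, reactions = reactions,
                 species_ids = species$id,
                 n_species = nrow(species)),
            class = "sbml_model")
}

#' @export
print.sbml_model <- function(x, ...) {
  cat(sprintf("<sbml_model> '%s': %d species, %d parameters, %d reactions, %d rules\n",
              x$id, x$n_species, length(x$parameters), length(x$reactions),
              length(x$rules)))
  invisible(x)
}

#' Right-hand side of an imported SBML model
#'
#' @param model an `sbml_model` from [import_sbml()].
#' @return function `f(state, t = 0)` evaluating the derivative vector in
#'   the order of `model$species_ids`.
#' @export
sbml_rhs <- function(model) {
  stopifnot(inherits(model, "sbml_model"))
  ids <- model$species_ids
  dynamic <- !model$species$boundary
  par_list <- as.list(model$parameters)
  rx <- lapply(model$reactions, function(r) {
    list(math = r$math,
         r_idx = match(names(r$reactants), ids),
         r_st = unname(r$reactants),
         p_idx = match(names(r$products), ids),
         p_st = unname(r$products))
  })
  function(state, t = 0) {
    stopifnot(length(state) == length(ids))
    env <- list2env(par_list, parent = asNamespace("spnsim"))
    assign("time", t, envir = env)
    for (i in seq_along(ids)) assign(ids[i], state[i], envir = env)
    for (rl in model$rules) {
      assign(rl$variable, eval(rl$expr, env), envir = env)
    }
    d <- numeric(length(ids))
    for (r in rx) {
      v <- eval(r$math, env)
      if (length(r$r_idx)) d[r$r_idx] <- d[r$r_idx] - r$r_st * v
      if (length(r$p_idx)) d[r$p_idx] <- d[r$p_idx] + r$p_st * v
    }
    d[!dynamic] <- 0
    d
  }
}
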