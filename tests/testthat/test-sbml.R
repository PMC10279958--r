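test_that("a 1x4 model exports to valid SBML with all components", {
  m <- build_model(1, 4)
  path <- withr::local_tempfile(fileext = ".xml")
  bundle <- export_sbml(m, path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".sim.json")))
  expect_equal(bundle$sidecar$t_end, 1100)
  expect_equal(bundle$sidecar$dt_out, 5)

  check <- validate_sbml(path)
  expect_true(check$valid)

  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core")
  expect_equal(xml2::xml_attr(doc, "level"), "3")
  expect_equal(xml2::xml_attr(doc, "version"), "1")
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  expect_length(sp, 132L)
  comps <- xml2::xml_find_all(doc, ".//s:listOfCompartments/s:compartment",
                              ns)
  expect_length(comps, 4L)
  rules <- xml2::xml_find_all(doc, ".//s:listOfRules/s:assignmentRule", ns)
  expect_length(rules, 12L)   # EWG_T, PTC_T, PH_T per cell
  # cell-qualified membrane-pool identifiers are present
  ids <- xml2::xml_attr(sp, "id")
  expect_true("EWG5_0_1" %in% ids)
  expect_true("en_0_0" %in% ids)
})

test_that("guarded exports use piecewise; unguarded exports do not", {
  m_on <- build_model(1, 1)
  m_off <- build_model(1, 1, guard = guard_config(enabled = FALSE))
  p_on <- withr::local_tempfile(fileext = ".xml")
  p_off <- withr::local_tempfile(fileext = ".xml")
  export_sbml(m_on, p_on, sidecar = FALSE)
  export_sbml(m_off, p_off, sidecar = FALSE)
  expect_true(any(grepl("piecewise", readLines(p_on))))
  expect_false(any(grepl("piecewise", readLines(p_off))))
})

test_that("export -> import round-trips the right-hand side to 1e-9", {
  set.seed(23)
  for (m in list(build_model(1, 4),
                 build_model(1, 2, guard = guard_config(enabled = FALSE)))) {
    path <- withr::local_tempfile(fileext = ".xml")
    export_sbml(m, path, sidecar = FALSE)
    imp <- import_sbml(path)
    expect_equal(imp$n_species, m$n_species)
    # importer must line species up with the native order
    expect_equal(imp$species_ids, m$species$id)
    f <- compile_rhs(m)
    g <- sbml_rhs(imp)
    for (k in 1:25) {
      x <- runif(m$n_species, 0, 1.5)
      d1 <- f(x); d2 <- g(x)
      expect_lt(max(abs(d1 - d2) / pmax(abs(d1), 1e-6)), 1e-9)
    }
  }
})

test_that("single-cell exports carry boundary pools as parameters", {
  bv <- setNames(runif(18), c(paste0("EWG", 1:6), paste0("PTC", 1:6),
                              paste0("HH", 1:6)))
  m <- build_single_cell(spn_parameters(), bv)
  path <- withr::local_tempfile(fileext = ".xml")
  export_sbml(m, path, sidecar = FALSE)
  imp <- import_sbml(path)
  expect_equal(unname(imp$parameters["b_EWG3"]), unname(bv["EWG3"]))
  x <- runif(33)
  expect_equal(sbml_rhs(imp)(x), compile_rhs(m)(x), tolerance = 1e-9)
})

test_that("totals import as derived quantities, not dynamic species", {
  m <- build_model(1, 2)
  path <- withr::local_tempfile(fileext = ".xml")
  export_sbml(m, path, sidecar = FALSE)
  imp <- import_sbml(path)
  expect_length(imp$rules, 6L)
  expect_false(any(grepl("_T_", imp$species_ids)))
  vars <- vapply(imp$rules, `[[`, character(1), "variable")
  expect_true("EWG_T_0_0" %in% vars)
})

test_that("malformed and unsupported documents are rejected clearly", {
  m <- build_model(1, 1)
  path <- withr::local_tempfile(fileext = ".xml")
  export_sbml(m, path, sidecar = FALSE)
  txt <- readLines(path)
  trunc <- withr::local_tempfile(fileext = ".xml")
  writeLines(txt[1:(length(txt) %/% 2)], trunc)
  expect_error(import_sbml(trunc), "well-formed")
  expect_false(validate_sbml(trunc)$valid)
  # an event-bearing document is out of the supported subset
  ev <- sub("<listOfReactions>",
            paste0("<listOfEvents><event id=\"e1\" useValuesFromTriggerTime=\"true\"/>",
                   "</listOfEvents><listOfReactions>"),
            paste(txt, collapse = "\n"))
  evp <- withr::local_tempfile(fileext = ".xml")
  writeLines(ev, evp)
  expect_error(import_sbml(evp), "unsupported.*events")
})

test_that("imported SBML models can be integrated directly", {
  m <- build_model(1, 1)
  path <- withr::local_tempfile(fileext = ".xml")
  export_sbml(m, path, sidecar = FALSE)
  imp <- import_sbml(path)
  set.seed(61)
  x0 <- runif(33)
  tr_native <- run_timecourse(m, x0, t_end = 20, dt_out = 5,
                              atol = 1e-10, rtol = 1e-7)
  tr_sbml <- run_timecourse(imp, x0, t_end = 20, dt_out = 5,
                            atol = 1e-10, rtol = 1e-7)
  expect_equal(tr_sbml$status, "ok")
  expect_equal(tr_sbml$states, tr_native$states, tolerance = 1e-5)
})

test_that("MathML encoding round-trips representative expressions", {
  exprs <- c("1 + 2 * x", "max(guard_eps, y)^2.5",
             "V_max * (log(2)/H_en) * en_0_0",
             "a/(b + c) - 4", "2e-05 * q", "1e-80^0.5")
  for (s in exprs) {
    xml <- spnsim:::.math_element(s)
    node <- xml2::read_xml(xml)
    back <- spnsim:::.mathml_to_expr(node)
    env <- list2env(list(x = 1.3, y = -0.2, guard_eps = 1e-80,
                         V_max = 2, H_en = 7, en_0_0 = 0.4, a = 3, b = 1,
                         c = 0.5, q = 10,
                         sbml_piecewise = sbml_piecewise),
                    parent = baseenv())
    expect_equal(eval(back, env), eval(str2lang(s), env),
                 tolerance = 1e-12, label = s)
  }
})
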