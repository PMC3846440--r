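test_that("derivatives follow stoichiometry, compartments and boundaries", {
  none <- empty_model("none")
  none$compartments <- list(sbml_compartment("c", size = 1))
  none$species <- list(sbml_species("S1", "c", initial_concentration = 2))
  sys0 <- build_ode_system(none)
  expect_equal(sys0$deriv(0, sys0$init), 0)

  m <- scheme_to_model("S1 -> S2", "ab", rate_constants = 1)
  sys <- build_ode_system(m)
  y <- c(S1 = 0.7, S2 = 0)
  expect_equal(sys$deriv(0, y), c(-0.7, 0.7))

  # concentration derivative divides by compartment size (law here lacks
  # the compartment factor on purpose)
  m2 <- m
  m2$compartments[[1]]$size <- 2
  m2$reactions[[1]]$kinetic_law$math <- math_op("times", math_id("k1"),
                                                math_id("S1"))
  sys2 <- build_ode_system(m2)
  expect_equal(sys2$deriv(0, y), c(-0.35, 0.35))

  # boundary species keep zero derivative but still drive the rate
  mb <- scheme_to_model("X0 -> T, T -> X1", "bnd", rate_constants = c(1, 1))
  sysb <- build_ode_system(mb)
  yb <- sysb$init
  dy <- sysb$deriv(0, yb)
  names(dy) <- sysb$state_ids
  expect_equal(dy[["X0"]], 0)
  expect_equal(dy[["X1"]], 0)
  expect_equal(sysb$rates(0, yb)[1], yb[["X0"]])
})

test_that("reactions without kinetic laws are rejected by name", {
  m <- scheme_to_model("S1 -> S2", "m")
  m$reactions[[1]]$kinetic_law <- NULL
  err <- expect_error(build_ode_system(m),
                      class = "sbmlfuse_simulation_error")
  expect_match(conditionMessage(err), "reaction1")
})

test_that("unresolved kinetic-law identifiers are rejected by name", {
  m <- scheme_to_model("S1 -> S2", "m")
  m$reactions[[1]]$kinetic_law$math <- math_op("times", math_id("kghost"),
                                               math_id("S1"))
  err <- expect_error(build_ode_system(m),
                      class = "sbmlfuse_simulation_error")
  expect_match(conditionMessage(err), "kghost")
})

test_that("A->B mass action reproduces the closed form within tolerance", {
  m <- scheme_to_model("S1 -> S2", "ab", rate_constants = 1)
  st <- simulation_settings(t_start = 0, t_end = 5, n_points = 100)
  sim <- simulate_model(m, st)
  expect_length(sim$time, 100)
  expect_equal(sim$time[1], 0)
  expect_equal(sim$time[100], 5)
  tol <- max(1e-4, 100 * st$rel_tol)
  expect_true(all(abs(sim$species[, "S1"] - exp(-sim$time)) < tol))
  expect_true(all(abs(sim$species[, "S2"] - (1 - exp(-sim$time)) - 1) < tol))
})

test_that("conserved moieties stay constant along enzyme kinetics", {
  sim <- simulate_model(enzyme_model())
  e_tot <- sim$species[, "E"] + sim$species[, "ES"]
  s_tot <- sim$species[, "S"] + sim$species[, "ES"] + sim$species[, "P"]
  expect_lt(max(abs(e_tot - e_tot[1])), 1e-6)
  expect_lt(max(abs(s_tot - s_tot[1])), 1e-6)
})

test_that("linear conservation laws hold on closed generated networks", {
  for (g in c(5, 7, 15, 22, 28)) {
    m <- scheme_to_model(scheme_groups()[g], sprintf("g%02d", g), seed = g)
    sys <- build_ode_system(m)
    sim <- simulate_model(m, simulation_settings(t_end = 5, n_points = 50))
    # left null space of N: w with t(w) %*% N = 0 => t(w) %*% y conserved
    N <- sys$stoichiometry
    sv <- svd(N, nu = nrow(N), nv = 0)
    d_full <- c(sv$d, rep(0, nrow(N) - length(sv$d)))
    basis <- sv$u[, d_full < 1e-10 * max(sv$d, 1), drop = FALSE]
    if (!ncol(basis)) next
    expect_lt(max(abs(t(basis) %*% N)), 1e-10)
    tot <- sim$species[, sys$state_ids, drop = FALSE] %*% basis
    drift <- apply(tot, 2, function(x) max(abs(x - x[1])))
    expect_lt(max(drift), 1e-6)
  }
})

test_that("parameter and initial overrides apply before integration", {
  m <- scheme_to_model("S1 -> S2", "ab", rate_constants = 1)
  flat <- simulate_model(m, simulation_settings(
    parameter_overrides = c(k1 = 0)))
  expect_true(all(flat$species[, "S1"] == 1))

  boosted <- simulate_model(m, simulation_settings(
    t_end = 1, initial_overrides = c(S1 = 3)))
  expect_equal(unname(boosted$species[1, "S1"]), 3)
  expect_error(simulate_model(m, simulation_settings(
    parameter_overrides = c(nope = 1))),
    class = "sbmlfuse_settings_error")
  expect_error(simulation_settings(initial_overrides = c(S1 = -1)),
               class = "sbmlfuse_settings_error")
  expect_error(simulation_settings(t_start = 5, t_end = 1),
               class = "sbmlfuse_settings_error")
})

test_that("flux series equal the kinetic law along the trajectory", {
  m <- scheme_to_model("S1 -> S2", "ab", rate_constants = 2)
  sim <- simulate_model(m, simulation_settings(t_end = 2, n_points = 20))
  expect_equal(unname(sim$fluxes[, "reaction1"]),
               unname(2 * sim$species[, "S1"]), tolerance = 1e-12)
})

test_that("adaptive solver tracks the independent reference integrator", {
  for (g in c(1, 12, 21, 24, 31, 38)) {
    sch <- parse_scheme(scheme_groups()[g])
    nk <- sum(vapply(sch$reactions,
                     function(r) if (r$reversible) 2L else 1L, integer(1)))
    k <- seq(0.4, 1.6, length.out = nk)
    m <- scheme_to_model(sch, sprintf("g%02d", g), rate_constants = k)
    st <- simulation_settings(t_end = 2, n_points = 40)
    sim <- simulate_model(m, st)
    ref <- reference_trajectory(sch, k, sim$time, h = 1e-4 * 2)
    err <- max(abs(sim$species[, colnames(ref)] - ref) /
                 pmax(abs(ref), 1))
    expect_lt(err, max(1e-4, 100 * st$rel_tol))
  }
})

test_that("tightening rel_tol never increases error vs the reference", {
  sch <- parse_scheme("E+S <-> ES, ES -> E+P")
  k <- c(1, 0.5, 1.5)
  m <- enzyme_model(k)
  tg <- seq(0, 5, length.out = 30)
  ref <- reference_trajectory(sch, k, tg, h = 5e-4,
                              init = c(E = 1, S = 1, ES = 0, P = 0))
  errs <- vapply(c(1e-4, 1e-5, 1e-6, 1e-7), function(rt) {
    sim <- simulate_model(m, simulation_settings(
      t_end = 5, n_points = 30, rel_tol = rt, abs_tol = 1e-12))
    max(abs(sim$species[, colnames(ref)] - ref))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("unsupported constructs are rejected with the feature named", {
  ev <- parse_sbml(event_model_xml())
  err <- expect_error(build_ode_system(ev),
                      class = "sbmlfuse_unsupported_error")
  expect_match(conditionMessage(err), "events")
})

test_that("experimental CSV parsing honors headers, order and errors", {
  es <- load_experimental_csv("t,S1\n0,1\n1,0.5")
  expect_equal(es$time, c(0, 1))
  expect_equal(es$columns$S1, c(1, 0.5))

  headerless <- load_experimental_csv("0,1,2\n1,0.5,1.5")
  expect_equal(names(headerless$columns), c("col1", "col2"))

  shuffled <- load_experimental_csv("t,S1\n2,0.2\n1,0.5\n0,1")
  expect_equal(shuffled$time, c(0, 1, 2))
  expect_equal(shuffled$columns$S1, c(1, 0.5, 0.2))

  err <- expect_error(load_experimental_csv("t,S1\n0,1\n1"),
                      class = "sbmlfuse_csv_error")
  expect_match(conditionMessage(err), "row 3")
  expect_error(load_experimental_csv("t,S1\n0,abc"),
               class = "sbmlfuse_csv_error")
  expect_error(load_experimental_csv("t,S1\n0,1\n0,2"),
               class = "sbmlfuse_csv_error")
})

test_that("overlay interpolates, reports RMS, and flags unmatched labels", {
  m <- scheme_to_model("S1 -> S2", "ab", rate_constants = 1)
  sim <- simulate_model(m, simulation_settings(t_end = 5, n_points = 100))
  texp <- sim$time[c(10, 30, 50)]   # on the simulation grid
  exp_csv <- paste(c("t,S1", sprintf("%.12f,%.12f", texp, exp(-texp))),
                   collapse = "\n")
  ov <- overlay(sim, load_experimental_csv(exp_csv))
  expect_lt(ov$rms[["S1"]], 1e-6)
  expect_true(all(texp %in% ov$table$time))

  empty <- overlay(sim, NULL)
  expect_equal(nrow(empty$table), 100)
  expect_length(empty$rms, 0)

  ov2 <- overlay(sim, load_experimental_csv("t,notaspecies\n0,1\n1,2"))
  expect_equal(ov2$unmatched, "notaspecies")
})

test_that("assignment rules are evaluated before each derivative call", {
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="ruled">',
    '<listOfCompartments><compartment id="c" size="1"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="S1" compartment="c" initialConcentration="1"/>',
    '<species id="S2" compartment="c" initialConcentration="0"/>',
    '</listOfSpecies>',
    '<listOfParameters><parameter id="kd" value="0"/></listOfParameters>',
    '<listOfRules><assignmentRule variable="kd">',
    '<math xmlns="http://www.w3.org/1998/Math/MathML"><cn>2</cn></math>',
    '</assignmentRule></listOfRules>',
    '<listOfReactions><reaction id="r1" reversible="false">',
    '<listOfReactants><speciesReference species="S1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="S2"/></listOfProducts>',
    '<kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML">',
    '<apply><times/><ci>kd</ci><ci>S1</ci></apply></math></kineticLaw>',
    '</reaction></listOfReactions></model></sbml>')
  m <- parse_sbml(xml)
  sim <- simulate_model(m, simulation_settings(t_end = 1, n_points = 20))
  expect_equal(unname(sim$species[20, "S1"]), exp(-2), tolerance = 1e-4)
})
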