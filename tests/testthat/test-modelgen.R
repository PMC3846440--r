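test_that("scheme strings parse faithfully", {
  s <- parse_scheme("S1+S2 -> S3+S4, 2S3+S4 -> S1+S2")
  expect_length(s$reactions, 2)
  r2 <- s$reactions[[2]]
  expect_equal(r2$reactants[[1]]$label, "S3")
  expect_equal(r2$reactants[[1]]$stoichiometry, 2)
  expect_false(r2$reversible)
  expect_equal(s$species, c("S1", "S2", "S3", "S4"))

  rev <- parse_scheme("S1 <-> S2")
  expect_true(rev$reactions[[1]]$reversible)

  fr <- parse_scheme("S1 -> 0.3S2, 0.7S2 -> S1")
  expect_equal(fr$reactions[[1]]$products[[1]]$stoichiometry, 0.3)
  expect_equal(fr$reactions[[2]]$reactants[[1]]$stoichiometry, 0.7)
})

test_that("malformed schemes fail with positional diagnostics", {
  err <- expect_error(parse_scheme("S1 -> S2, S3 + -> S4"),
                      class = "sbmlfuse_scheme_error")
  expect_match(conditionMessage(err), "reaction 2")
  expect_error(parse_scheme("S1 S2"), class = "sbmlfuse_scheme_error")
  expect_error(parse_scheme("S1 -> 0S2"), class = "sbmlfuse_scheme_error")
})

test_that("rendering a parsed canonical scheme is the identity", {
  for (g in seq_along(scheme_groups())) {
    canon <- scheme_groups()[g]
    expect_equal(render_scheme(parse_scheme(canon)), canon,
                 label = sprintf("group %d", g))
  }
})

test_that("generated models follow the fixture conventions", {
  m <- scheme_to_model(scheme_groups()[15], "case00015")
  expect_equal(m$id, "case00015")
  expect_equal(vapply(m$reactions, `[[`, character(1), "id"),
               c("reaction1", "reaction2"))
  expect_equal(vapply(m$parameters, `[[`, character(1), "id"),
               c("k1", "k2"))
  expect_equal(m$compartments[[1]]$id, "compartment")
  expect_equal(m$compartments[[1]]$size, 1)
  for (s in m$species) {
    expect_equal(s$initial, list(type = "concentration", value = 1))
    expect_false(s$boundary_condition)
  }

  # boundary labels get the boundary flag
  mb <- scheme_to_model(scheme_groups()[24], "b24")
  bnd <- vapply(mb$species, `[[`, logical(1), "boundary_condition")
  names(bnd) <- vapply(mb$species, `[[`, character(1), "id")
  expect_true(bnd[["X0"]]); expect_true(bnd[["X1"]]); expect_false(bnd[["T"]])

  # reversible reactions consume two rate constants
  mr <- scheme_to_model(scheme_groups()[38], "b38", seed = 1)
  expect_length(mr$parameters, 4)

  # empty scheme: compartment only
  e <- scheme_to_model("", "nothing")
  expect_length(e$species, 0)
  expect_length(e$reactions, 0)
  expect_length(e$compartments, 1)
})

test_that("generated kinetic laws have no free identifiers", {
  for (g in c(3, 9, 19, 26, 33, 37)) {
    m <- scheme_to_model(scheme_groups()[g], sprintf("g%02d", g), seed = g)
    known <- model_ids(m)
    for (r in m$reactions)
      expect_true(all(sbmlfuse:::math_identifiers(r$kinetic_law$math)
                      %in% known),
                  label = sprintf("group %d reaction %s", g, r$id))
  }
})

test_that("generation is deterministic under a fixed seed", {
  a <- write_sbml(scheme_to_model(scheme_groups()[21], "m", seed = 42))
  b <- write_sbml(scheme_to_model(scheme_groups()[21], "m", seed = 42))
  expect_identical(a, b)
  c2 <- write_sbml(scheme_to_model(scheme_groups()[21], "m", seed = 43))
  expect_false(identical(a, c2))
})

test_that("the worked-example pair states the reference facts", {
  p <- worked_example_pair()
  expect_equal(p$m1$id, "case00015")
  expect_equal(p$m2$id, "case00020")
  sp1 <- vapply(p$m1$species, `[[`, character(1), "id")
  sp2 <- vapply(p$m2$species, `[[`, character(1), "id")
  expect_setequal(union(sp1, sp2), c("S1", "S2", "S3", "S4"))
  expect_equal(intersect(sp1, sp2), "S1")
  for (m in p) {
    expect_equal(vapply(m$reactions, `[[`, character(1), "id"),
                 c("reaction1", "reaction2"))
    expect_equal(vapply(m$parameters, `[[`, character(1), "id"),
                 c("k1", "k2"))
    expect_true(model_equal(m, parse_sbml(write_sbml(m))))
  }
})

test_that("random pairs are seeded, reproducible, and from distinct groups", {
  p1 <- random_pair(7)
  p2 <- random_pair(7)
  expect_identical(write_sbml(p1$m1), write_sbml(p2$m1))
  expect_identical(write_sbml(p1$m2), write_sbml(p2$m2))
  for (seed in 1:25) {
    pr <- random_pair(seed)
    expect_length(unique(pr$groups), 2)
    expect_false(identical(pr$m1$id, pr$m2$id))
  }
})

test_that("pair generation leaves the session RNG state untouched", {
  set.seed(123); before <- .Random.seed
  invisible(random_pair(99))
  expect_identical(.Random.seed, before)
})
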