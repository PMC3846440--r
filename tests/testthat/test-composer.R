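test_that("worked-example composition reproduces the reference structure", {
  p <- worked_example_pair()
  res <- compose(p$m1, p$m2)
  expect_setequal(
    vapply(res$composed$reactions, `[[`, character(1), "id"),
    c("reaction1", "reaction2", "case00020_reaction1",
      "case00020_reaction2"))
  sp <- vapply(res$composed$species, `[[`, character(1), "id")
  expect_setequal(sp, c("S1", "S2", "S3", "S4"))
  expect_false(anyDuplicated(sp) > 0)
  pars <- vapply(res$composed$parameters, `[[`, character(1), "id")
  expect_true(all(c("case00020_k1", "case00020_k2") %in% pars))
  # renamed parameters are referenced by the renamed reactions' laws
  r3 <- res$composed$reactions[[3]]
  expect_true("case00020_k1" %in% sbmlfuse:::math_identifiers(
    r3$kinetic_law$math))
})

test_that("composing with an empty model is the identity with no warnings", {
  m <- scheme_to_model("S1+S2 -> S3, S3 -> S1+S2", "m", seed = 3)
  res <- compose(m, empty_model())
  expect_length(res$warnings, 0)
  for (cl in c("compartments", "species", "reactions", "parameters"))
    expect_length(res$composed[[cl]], length(m[[cl]]))
})

test_that("self-composition merges elements but duplicates parameters", {
  m <- scheme_to_model("S1 -> S3, S3 -> S1", "case00015")
  res <- compose(m, m)
  expect_length(res$composed$compartments, length(m$compartments))
  expect_length(res$composed$species, length(m$species))
  expect_length(res$composed$reactions, length(m$reactions))
  expect_length(res$composed$parameters, 2 * length(m$parameters))
})

test_that("compartment merging pivots on model 1 and warns on differences", {
  c1 <- sbml_compartment("c", size = 1)
  c2 <- sbml_compartment("c", size = 2)
  res <- merge_compartments(c1, c2)
  expect_equal(res$merged$size, 1)
  expect_length(res$warnings, 1)
  w <- res$warnings[[1]]
  expect_equal(w$category, "attribute-conflict")
  expect_equal(w$value1, "1"); expect_equal(w$value2, "2")
  expect_equal(w$chosen, "1")

  expect_length(merge_compartments(c1, c1)$warnings, 0)
  # absence is not a conflict
  res2 <- merge_compartments(c1, sbml_compartment("c"))
  expect_equal(res2$merged$size, 1)
  expect_length(res2$warnings, 0)
})

test_that("species merging warns on initial value and form conflicts", {
  s1 <- sbml_species("S1", "c", initial_concentration = 1)
  same <- merge_species(s1, s1)
  expect_length(same$warnings, 0)

  s2 <- sbml_species("S1", "c", initial_concentration = 0.5)
  res <- merge_species(s1, s2)
  expect_equal(res$merged$initial$value, 1)
  expect_length(res$warnings, 1)
  expect_equal(res$warnings[[1]]$attribute, "initialValue")
  expect_equal(res$warnings[[1]]$chosen, res$warnings[[1]]$value1)

  s3 <- sbml_species("S1", "c", initial_amount = 0.5)
  res3 <- merge_species(s1, s3)
  expect_equal(res3$merged$initial$type, "concentration")
  expect_match(res3$warnings[[1]]$value1, "concentration")
  expect_match(res3$warnings[[1]]$value2, "amount")
})

test_that("reaction merging keeps model 1 and warns on stoichiometry/law", {
  m <- scheme_to_model("S1+S2 -> S3", "m")
  r1 <- m$reactions[[1]]
  expect_length(merge_reactions(r1, r1)$warnings, 0)

  r2 <- r1
  r2$reactants[[1]]$stoichiometry <- 2
  res <- merge_reactions(r1, r2)
  expect_equal(res$merged$reactants[[1]]$stoichiometry, 1)
  ws <- Filter(function(w) grepl("stoichiometry", w$attribute),
               res$warnings)
  expect_length(ws, 1)
  expect_equal(ws[[1]]$chosen, "1")

  r3 <- r1
  r3$kinetic_law$math <- math_op("times", math_id("k9"), math_id("S1"))
  res3 <- merge_reactions(r1, r3)
  expect_true(any(vapply(res3$warnings, function(w)
    w$attribute == "kineticLaw", logical(1))))
  expect_identical(res3$merged$kinetic_law, r1$kinetic_law)

  r4 <- r1
  r4$modifiers <- "S3"
  expect_equal(merge_reactions(r1, r4)$merged$modifiers, "S3")
})

test_that("prefix renaming matches the reference scheme", {
  expect_equal(rename_with_prefix("reaction1", "case00020",
                                  c("reaction1", "reaction2")),
               "case00020_reaction1")
  expect_equal(rename_with_prefix("reactionX", "m2", character()),
               "m2_reactionX")
  expect_equal(rename_with_prefix("reaction1", "case00020",
                                  c("reaction1", "case00020_reaction1")),
               "case00020_reaction1_2")
})

test_that("non-colliding model-2 ids are kept unless prefix_all is set", {
  a <- scheme_to_model("S1 -> S2", "a")
  b <- scheme_to_model("A1 -> A2", "b")   # disjoint species names
  res <- compose(a, b)
  sp <- vapply(res$composed$species, `[[`, character(1), "id")
  expect_true(all(c("A1", "A2") %in% sp))
  # reactions collide on id (reaction1 both) -> renamed
  expect_true("b_reaction1" %in%
                vapply(res$composed$reactions, `[[`, character(1), "id"))

  res2 <- compose(a, b, config = fuse_config(prefix_all = TRUE))
  sp2 <- vapply(res2$composed$species, `[[`, character(1), "id")
  expect_true(all(c("b_A1", "b_A2") %in% sp2))
})

test_that("namespace union keeps both URIs and resolves prefix clashes", {
  a <- scheme_to_model("S1 -> S2", "a")
  b <- scheme_to_model("S1 -> S2", "b")
  a$namespaces <- c(m = "http://example.org/A")
  b$namespaces <- c(q = "http://example.org/B")
  u <- union_namespaces(a, b)
  expect_setequal(unname(u), c("http://example.org/A",
                               "http://example.org/B"))
  b$namespaces <- c(m = "http://example.org/B")
  u2 <- union_namespaces(a, b)
  expect_equal(unname(u2[["m"]]), "http://example.org/A")
  expect_true("http://example.org/B" %in% u2)
  expect_false(anyDuplicated(names(u2)) > 0)
  # both URIs end up on the composed document's root element
  res <- compose(a, b)
  root <- regmatches(write_sbml(res$composed),
                     regexpr("<sbml[^>]*>", write_sbml(res$composed)))
  expect_match(root, "http://example.org/A", fixed = TRUE)
  expect_match(root, "http://example.org/B", fixed = TRUE)
})

test_that("carried opaque subtrees are renamed and references rewritten", {
  a <- parse_sbml(carried_subtree_xml("ua", "p1"))
  b <- parse_sbml(carried_subtree_xml("ub", "p2"))
  res <- compose(a, b)
  uids <- vapply(res$composed$unit_definitions, `[[`, character(1), "id")
  expect_setequal(uids, c("myunit", "ub_myunit"))
  # b's parameter survives (never merged) and its units ref is rewritten
  pb <- Filter(function(p) p$id == "p2", res$composed$parameters)[[1]]
  expect_equal(pb$units, "ub_myunit")
  sb <- Filter(function(s) s$id != "S1",
               res$composed$species)
  expect_length(sb, 0)  # S1 merged: same name and compartment
})

test_that("kinetic-law math identifiers are rewritten through the id map", {
  p <- worked_example_pair()
  res <- compose(p$m1, p$m2)
  expect_equal(unname(res$id_map2[c("k1", "k2")]),
               c("case00020_k1", "case00020_k2"))
  for (r in res$composed$reactions[3:4]) {
    ids <- sbmlfuse:::math_identifiers(r$kinetic_law$math)
    expect_true(all(ids %in% model_ids(res$composed)))
  }
})

test_that("id maps are total and idMap1 is the identity", {
  for (seed in c(2, 7, 11)) {
    pr <- random_pair(seed)
    res <- compose(pr$m1, pr$m2)
    expect_identical(res$id_map1, stats::setNames(model_ids(pr$m1),
                                                  model_ids(pr$m1)))
    m2_ids <- setdiff(model_ids(pr$m2), pr$m2$id)
    expect_true(all(m2_ids %in% names(res$id_map2)))
    expect_true(all(res$id_map2 %in% model_ids(res$composed)))
  }
})

test_that("every attribute-conflict warning chooses the model-1 value", {
  a <- scheme_to_model("S1 -> S2", "a", rate_constants = 1)
  b <- scheme_to_model("S1 -> S2", "b", rate_constants = 2)
  a$compartments[[1]]$size <- 1; b$compartments[[1]]$size <- 2
  b$species[[1]]$initial$value <- 0.25
  b$reactions[[1]]$reactants[[1]]$stoichiometry <- 3
  res <- compose(a, b)
  conflicts <- Filter(function(w) w$category == "attribute-conflict",
                      res$warnings)
  expect_gt(length(conflicts), 2)
  for (w in conflicts) expect_identical(w$chosen, w$value1)
})

test_that("composition is deterministic to the byte", {
  pr <- random_pair(5)
  t1 <- write_sbml(compose(pr$m1, pr$m2)$composed)
  t2 <- write_sbml(compose(pr$m1, pr$m2)$composed)
  expect_identical(t1, t2)
})

test_that("composed model metadata derives from both sources", {
  p <- worked_example_pair()
  res <- compose(p$m1, p$m2)
  expect_equal(res$composed$id, "case00015_case00020")
  expect_match(res$composed$name, "Composition of")
  res2 <- compose(p$m1, p$m2,
                  config = fuse_config(composed_id = "combo"))
  expect_equal(res2$composed$id, "combo")
})
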