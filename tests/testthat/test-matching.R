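test_that("similarity percentages follow the Dice formula", {
  m <- scheme_to_model("S1+S2 -> S3", "m")
  expect_equal(similarity_report(m, m)$species$percentage, 100)
  expect_equal(similarity_report(m, m)$compartments$percentage, 100)
  expect_equal(similarity_report(m, m)$reactions$percentage, 100)

  a <- scheme_to_model("S1 -> S2", "a")   # species S1, S2
  b <- scheme_to_model("S1 -> S3", "b")   # species S1, S3
  rep <- similarity_report(a, b)
  expect_equal(rep$species$percentage, 50)
  expect_equal(rep$species$matched_names, "S1")

  disj <- scheme_to_model("A1 -> A2", "d")
  expect_equal(similarity_report(a, disj)$species$percentage, 0)
  # empty class: percentage defined as 0
  expect_equal(similarity_report(empty_model("e1"),
                                 empty_model("e2"))$species$percentage, 0)
})

test_that("similarity percentage is symmetric and min-formula available", {
  for (seed in 1:10) {
    pr <- random_pair(seed)
    r12 <- similarity_report(pr$m1, pr$m2)
    r21 <- similarity_report(pr$m2, pr$m1)
    for (cl in c("compartments", "reactions", "species"))
      expect_equal(r12[[cl]]$percentage, r21[[cl]]$percentage)
  }
  a <- scheme_to_model("S1 -> S2", "a")
  b <- scheme_to_model("S1+S2 -> S3, S3 -> S1", "b")
  expect_equal(similarity_report(a, b, formula = "min")$species$percentage,
               100)  # both of a's species appear in b
})

test_that("compartments match by name, annotation, or not at all", {
  a <- scheme_to_model("S1 -> S2", "a")
  b <- scheme_to_model("S1 -> S2", "b")
  pairs <- auto_match_compartments(a, b)
  expect_equal(pairs$id1, "compartment")
  expect_equal(pairs$id2, "compartment")

  b2 <- b
  b2$compartments[[1]]$id <- "cytosol"
  b2$species <- lapply(b2$species, function(s) {
    s$compartment <- "cytosol"; s })
  expect_equal(nrow(auto_match_compartments(a, b2)), 0)

  # shared annotation overrides differing names
  a3 <- a; b3 <- b2
  a3$compartments[[1]]$annotation <- miriam_annotation(
    "http://identifiers.org/go/GO:0005829")
  b3$compartments[[1]]$annotation <- miriam_annotation(
    "urn:miriam:obo.go:GO%3A0005829")
  pairs3 <- auto_match_compartments(a3, b3)
  expect_equal(pairs3$provenance, "auto-annotation")
})

test_that("manual pairs win over automatic candidates", {
  a <- scheme_to_model("S1 -> S2", "a")
  b <- scheme_to_model("S1 -> S2", "b")
  manual <- match_table(species = list(c("S1", "S2")))
  tab <- auto_match(a, b, manual = manual)
  sp <- tab$species
  expect_true(any(sp$id1 == "S1" & sp$id2 == "S2" & sp$provenance == "manual"))
  # b's S1 is not claimed by a's S1 anymore; a's S2 pairs with b's... nothing
  expect_false(any(sp$id1 == "S1" & sp$id2 == "S1"))
})

test_that("species need name+corresponding compartment, or an annotation", {
  a <- scheme_to_model("S1 -> S2", "a")
  b <- scheme_to_model("S1 -> S2", "b")
  cp <- auto_match_compartments(a, b)
  sp <- auto_match_species(a, b, cp)
  expect_setequal(sp$id1, c("S1", "S2"))

  # same names but unmatched compartments: no pairing
  b2 <- b
  b2$compartments[[1]]$id <- "cytosol"
  b2$species <- lapply(b2$species, function(s) {
    s$compartment <- "cytosol"; s })
  cp2 <- auto_match_compartments(a, b2)
  expect_equal(nrow(auto_match_species(a, b2, cp2)), 0)

  # different names, shared annotation: paired
  a3 <- annotated_species_model("a3", "S1", chebi_url)
  b3 <- annotated_species_model("b3", "S2", chebi_urn)
  sp3 <- auto_match_species(a3, b3, auto_match_compartments(a3, b3))
  expect_true(any(sp3$id1 == "S1" & sp3$id2 == "S2" &
                    sp3$provenance == "auto-annotation"))
})

test_that("reactions require equal names AND equal reactant/product lists", {
  p <- worked_example_pair()
  tab <- auto_match(p$m1, p$m2)
  expect_equal(nrow(tab$reactions), 0)  # same names, different lists

  m <- scheme_to_model("S1+S2 -> S3, S3 -> S1+S2", "m")
  self <- auto_match(m, m)
  expect_equal(nrow(self$reactions), 2)

  # stoichiometry is not part of the equality test
  m2 <- m
  m2$reactions[[1]]$reactants[[1]]$stoichiometry <- 2
  tab2 <- auto_match(m, m2)
  expect_equal(nrow(tab2$reactions), 2)
})

test_that("match-table validation enforces one-to-one and id resolution", {
  a <- scheme_to_model("S1 -> S2", "a")
  b <- scheme_to_model("S1 -> S2", "b")
  expect_true(validate_match_table(match_table(), a, b))
  dup <- match_table(species = list(c("S1", "S1"), c("S1", "S2")))
  err <- expect_error(validate_match_table(dup, a, b),
                      class = "sbmlfuse_match_error")
  expect_match(conditionMessage(err), "S1")
  ghost <- match_table(species = list(c("Sx", "S1")))
  expect_error(validate_match_table(ghost, a, b),
               class = "sbmlfuse_match_error")
})

test_that("greedy matching attains the brute-force maximum on bijective graphs", {
  # on annotation-free generated models the eligibility graph for species
  # is a partial bijection (unique labels), so greedy must equal the
  # brute-force maximum matching over the same predicate
  for (seed in 1:15) {
    pr <- random_pair(seed)
    cp <- auto_match_compartments(pr$m1, pr$m2)
    sp <- auto_match_species(pr$m1, pr$m2, cp)
    l1 <- vapply(pr$m1$species, effective_name, character(1))
    l2 <- vapply(pr$m2$species, effective_name, character(1))
    elig <- outer(l1, l2, `==`)  # single compartment always corresponds
    bf <- brute_force_matching(elig)
    expect_equal(nrow(sp), bf$size, label = sprintf("seed %d", seed))
    got <- sort(paste(sp$id1, sp$id2))
    want <- sort(paste(l1[bf$pairs[, 1]], l2[bf$pairs[, 2]]))
    expect_equal(got, want)
  }
})

test_that("ambiguous graphs: greedy output is within some maximum matching", {
  # two model-1 species share one eligible partner via annotations
  a <- scheme_to_model("S1 -> S2", "amb1")
  a$species[[1]]$annotation <- miriam_annotation(chebi_url)
  a$species[[2]]$annotation <- miriam_annotation(chebi_url)
  b <- scheme_to_model("A1 -> A2", "amb2")
  b$species[[1]]$annotation <- miriam_annotation(chebi_urn)
  sp <- auto_match_species(a, b, auto_match_compartments(a, b))
  expect_equal(nrow(sp), 1)                     # maximum is 1
  expect_equal(sp$id1, "S1")                    # document order tie-break
  expect_equal(sp$id2, "A1")
})
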