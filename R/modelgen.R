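# Reaction-scheme model generator: builds SBML-Test-Suite-style fixture
# models from compact scheme strings ("S1+S2 -> S3+S4, 2S3+S4 -> S1+S2"),
# including the 40 reaction groups used for the composition stress tests
# and the case15/case20 worked-example pair.

TABLE2_GROUPS <- c(
  "S1 -> S2",
  "S1 -> S2, S2 -> S1",
  "S1 -> 2S2",
  "S1 -> 2S2, 2S2 -> S1",
  "S1+S2 -> S3, S3 -> S1+S2",
  "2S1+S2 -> S3, S3 -> 2S1+S2",
  "S1+S2 -> S3+S4, S3+S4 -> S1+S2",
  "S1+S2 -> S3+2S4, S3+S4 -> S1+S2",
  "S1 -> S2, S2 -> S1, S2 -> S3+S4, S3+S4 -> S2",
  "S1+S2 -> S3, S3 -> S1+S2, S3 -> S1+S4",
  "S1 -> S2, S2 -> S3, S3 -> S4",
  "S1 -> 0.3S2, 0.7S2 -> S1",
  "S1+S2 -> 2S2, S2 -> S3",
  "S1+S2 -> 2S2, S2 -> S3, S3+S4 -> 2S4",
  "S1 -> S3, S3 -> S1",
  "S1 -> S3, S3 -> S2",
  "S1+S2 -> S3, S3 -> 2S1+S2",
  "2S1 -> S2",
  "S1+2S2 -> S3, S3 -> S1+S2",
  "S1+S2 -> 2S3+S4, 2S3+S4 -> S1+S2",
  "S1+S2 -> S3+S4, 2S3+S4 -> S1+S2",
  "S1 -> S2, S2 -> S3, S3 -> S1",
  "S1+S2 -> 2S3, S3 -> S1+S2",
  "X0 -> T, T -> X1",
  "X0 -> 2T, T -> X1",
  "2X0 -> T, T -> X1",
  "S1+S2 -> S3, 2S3 -> S1+S2",
  "2S1 -> S3, S3 -> S1",
  "S1+S2 -> S3, S3 -> S1+2S2",
  "S1+S2+S3 -> S4",
  "S1 <-> S2",
  "S1+S2 <-> S3",
  "S1 <-> S2+S3",
  "S1 <-> 2S2",
  "S1+2S2 <-> S3",
  "S1 <-> S2+2S3",
  "S1 <-> S2, S3 <-> S4",
  "A4 <-> A2, A1+A2 <-> A3",
  "A4 -> A2, A1+A2 -> A3",
  "S1 -> S2, 2S2 -> S3, S3 -> S4")

BOUNDARY_LABELS <- c("X0", "X1")

#' The 40 reaction-scheme groups
#'
#' Canonical scheme strings for the 40 Test-Suite-style reaction groups
#' used by the composition stress tests. Labels `X0`/`X1` denote boundary
#' species (fixed source/sink).
#'
#' @return character vector of length 40.
#' @export
scheme_groups <- function() TABLE2_GROUPS

#' Parse a reaction-scheme string
#'
#' Grammar: comma-separated reactions; each side a `+`-separated list of
#' terms; a term is an optional positive (possibly fractional) coefficient
#' immediately followed by a species label; `->` marks an irreversible,
#' `<->` a reversible reaction.
#'
#' @param text scheme string, e.g. `"S1+S2 -> S3+S4, 2S3+S4 -> S1+S2"`.
#' @return a `reaction_scheme`: `reactions` (list with `reactants`,
#'   `products`, `reversible`), `species` (labels in order of first
#'   appearance) and `boundary` (subset treated as boundary species).
#' @export
parse_scheme <- function(text) {
  parts <- strsplit(text, ",", fixed = TRUE)[[1]]
  if (!length(parts) || !nzchar(trimws(text)))
    return(structure(list(reactions = list(), species = character(),
                          boundary = character()),
                     class = "reaction_scheme"))
  species <- character()
  parse_side <- function(side, rno, where) {
    side <- trimws(side)
    if (!nzchar(side) || grepl("^\\+|\\+\\s*\\+|\\+$", gsub(" ", "", side)))
      stop_sbml("sbmlfuse_scheme_error", sprintf(
        "reaction %d: empty term on %s side", rno, where))
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    lapply(terms, function(term) {
      m <- regmatches(term, regexec(
        "^([0-9]*\\.?[0-9]+)?\\s*([A-Za-z_][A-Za-z0-9_]*)$", term))[[1]]
      if (!length(m))
        stop_sbml("sbmlfuse_scheme_error", sprintf(
          "reaction %d (%s side): malformed term '%s'", rno, where, term))
      st <- if (nzchar(m[2])) as.numeric(m[2]) else 1
      if (st <= 0)
        stop_sbml("sbmlfuse_scheme_error", sprintf(
          "reaction %d: non-positive stoichiometry in '%s'", rno, term))
      species <<- union(species, m[3])
      list(label = m[3], stoichiometry = st)
    })
  }
  reactions <- lapply(seq_along(parts), function(rno) {
    p <- parts[[rno]]
    reversible <- grepl("<->", p, fixed = TRUE)
    sides <- strsplit(p, if (reversible) "<->" else "->", fixed = TRUE)[[1]]
    if (length(sides) != 2)
      stop_sbml("sbmlfuse_scheme_error", sprintf(
        "reaction %d: expected exactly one arrow in '%s'", rno, trimws(p)))
    list(reactants = parse_side(sides[1], rno, "reactant"),
         products = parse_side(sides[2], rno, "product"),
         reversible = reversible)
  })
  structure(list(reactions = reactions, species = species,
                 boundary = intersect(species, BOUNDARY_LABELS)),
            class = "reaction_scheme")
}

#' Render a scheme back to its canonical string
#'
#' Inverse of [parse_scheme()] on canonical strings.
#' @param scheme a `reaction_scheme`.
#' @return character scalar.
#' @export
render_scheme <- function(scheme) {
  side <- function(terms) paste(vapply(terms, function(tm)
    paste0(if (tm$stoichiometry != 1) fmt_num(tm$stoichiometry) else "",
           tm$label), character(1)), collapse = "+")
  paste(vapply(scheme$reactions, function(r)
    sprintf("%s %s %s", side(r$reactants),
            if (r$reversible) "<->" else "->", side(r$products)),
    character(1)), collapse = ", ")
}

mass_action_math <- function(compartment_id, k_id, terms) {
  args <- c(list(math_id(k_id), math_id(compartment_id)),
            lapply(terms, function(tm) {
              if (tm$stoichiometry == 1) math_id(tm$label)
              else math_op("power", math_id(tm$label),
                           math_num(tm$stoichiometry))
            }))
  list(k = "op", op = "times", args = args)
}

#' Generate an SBML model from a reaction scheme
#'
#' Produces a Test-Suite-style model: one compartment `"compartment"` of
#' size 1, every species at initial concentration 1 (labels `X0`/`X1`
#' flagged as boundary species), reactions `reaction1`, `reaction2`, ...
#' with mass-action kinetic laws `k_i * compartment * prod([R]^stoich)`
#' (reversible reactions get a forward-minus-reverse law and consume two
#' rate constants), and global parameters `k1`, `k2`, ....
#'
#' @param scheme a `reaction_scheme` or a scheme string.
#' @param model_id the SBML model id.
#' @param rate_constants numeric vector of rate constants (recycled when
#'   scalar); one per irreversible reaction, two per reversible one.
#'   When `NULL`: drawn uniformly from \[0.1, 10\] under `seed`, or all 1
#'   when `seed` is also `NULL`.
#' @param seed integer seed for drawn rate constants (RNG state is
#'   restored afterwards); identical seeds give byte-identical output.
#' @param initial initial concentration(s): scalar or named by label.
#' @param level,version SBML level/version of the emitted model.
#' @param name optional model name.
#' @return an `sbml_model`.
#' @export
scheme_to_model <- function(scheme, model_id, rate_constants = NULL,
                            seed = NULL, initial = 1, level = 2L,
                            version = 4L, name = NULL) {
  if (is.character(scheme)) scheme <- parse_scheme(scheme)
  n_k <- sum(vapply(scheme$reactions,
                    function(r) if (r$reversible) 2L else 1L, integer(1)))
  if (is.null(rate_constants)) {
    rate_constants <- if (is.null(seed)) rep(1, n_k)
    else with_seed(seed, stats::runif(n_k, 0.1, 10))
  }
  rate_constants <- rep_len(as.numeric(rate_constants), n_k)

  init_of <- function(lab) {
    if (!is.null(names(initial)) && lab %in% names(initial))
      initial[[lab]] else if (is.null(names(initial))) initial[[1]] else 1
  }
  species <- lapply(scheme$species, function(lab) sbml_species(
    id = lab, compartment = "compartment",
    initial_concentration = init_of(lab),
    boundary_condition = lab %in% scheme$boundary))

  params <- list()
  reactions <- list()
  ki <- 1L
  for (j in seq_along(scheme$reactions)) {
    rx <- scheme$reactions[[j]]
    kf_id <- paste0("k", ki)
    params[[ki]] <- sbml_parameter(kf_id, rate_constants[ki])
    ki <- ki + 1L
    math <- if (rx$reversible) {
      kr_id <- paste0("k", ki)
      params[[ki]] <- sbml_parameter(kr_id, rate_constants[ki])
      ki <- ki + 1L
      math_op("times", math_id("compartment"),
              math_op("minus",
                      mass_action_terms(kf_id, rx$reactants),
                      mass_action_terms(kr_id, rx$products)))
    } else {
      mass_action_math("compartment", kf_id, rx$reactants)
    }
    reactions[[j]] <- sbml_reaction(
      id = paste0("reaction", j),
      reactants = lapply(rx$reactants, function(tm)
        sbml_species_ref(tm$label, tm$stoichiometry)),
      products = lapply(rx$products, function(tm)
        sbml_species_ref(tm$label, tm$stoichiometry)),
      reversible = rx$reversible,
      kinetic_law = list(math = math, parameters = list()))
  }

  m <- sbml_model(
    id = model_id, name = name, level = level, version = version,
    compartments = list(sbml_compartment("compartment", size = 1)),
    species = species, reactions = reactions, parameters = params)
  validate_model(m)
  m
}

mass_action_terms <- function(k_id, terms) {
  args <- c(list(math_id(k_id)),
            lapply(terms, function(tm) {
              if (tm$stoichiometry == 1) math_id(tm$label)
              else math_op("power", math_id(tm$label),
                           math_num(tm$stoichiometry))
            }))
  list(k = "op", op = "times", args = args)
}

#' The worked-example fixture pair (case 15 / case 20)
#'
#' `case00015` carries the group-15 scheme `S1 -> S3, S3 -> S1`;
#' `case00020` a two-step chain `S1 -> S2, S2 -> S4`, so that the pair's
#' species-id union is S1-S4, the only shared species is S1, both models
#' name their reactions `reaction1`/`reaction2` with different substrate
#' and product lists (so no reaction merges), and both declare global
#' parameters `k1`/`k2` (which collide and get the `case00020_` prefix in
#' the composed model). Rate constants are fixed, documented values.
#'
#' @return `list(m1=, m2=)` of `sbml_model`s.
#' @export
worked_example_pair <- function() {
  list(m1 = scheme_to_model("S1 -> S3, S3 -> S1", "case00015",
                            rate_constants = c(1, 0.5)),
       m2 = scheme_to_model("S1 -> S2, S2 -> S4", "case00020",
                            rate_constants = c(0.8, 0.6)))
}

#' A seeded random pair of models from distinct reaction groups
#'
#' Draws two distinct groups from the 40 scheme groups and generates one
#' model per group with seeded rate constants. Identical seeds give
#' identical pairs.
#'
#' @param seed integer seed.
#' @return `list(m1=, m2=, groups=)`.
#' @export
random_pair <- function(seed) {
  with_seed(seed, {
    gs <- sample.int(40L, 2L)
    # draw constants inline so the whole pair depends only on `seed`
    s1 <- parse_scheme(TABLE2_GROUPS[gs[1]])
    s2 <- parse_scheme(TABLE2_GROUPS[gs[2]])
    nk1 <- sum(vapply(s1$reactions, function(r) if (r$reversible) 2L else 1L,
                      integer(1)))
    nk2 <- sum(vapply(s2$reactions, function(r) if (r$reversible) 2L else 1L,
                      integer(1)))
    m1 <- scheme_to_model(s1, sprintf("case_g%02d", gs[1]),
                          rate_constants = stats::runif(nk1, 0.1, 10))
    m2 <- scheme_to_model(s2, sprintf("case_g%02d", gs[2]),
                          rate_constants = stats::runif(nk2, 0.1, 10))
    list(m1 = m1, m2 = m2, groups = gs)
  })
}

#' Unireactant enzyme kinetics fixture
#'
#' The classic `E + S <-> ES -> E + P` mechanism as a mass-action model;
#' the linear moieties `[E]+[ES]` and `[S]+[ES]+[P]` are conserved along
#' any exact trajectory, which makes this the standard simulator
#' correctness fixture.
#'
#' @param rate_constants forward/backward binding and catalytic rate
#'   constants, in scheme order.
#' @return an `sbml_model`.
#' @export
enzyme_model <- function(rate_constants = c(1, 0.5, 1.5)) {
  scheme_to_model("E+S <-> ES, ES -> E+P", "enzyme",
                  rate_constants = rate_constants,
                  initial = c(E = 1, S = 1, ES = 0, P = 0))
}
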