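#' In-memory SBML model representation
#'
#' `sbml_model()` constructs the internal representation used by the whole
#' package: an ordered collection of compartments, species, reactions and
#' global parameters, plus opaquely carried subtrees (unit definitions,
#' function definitions, rules, events, ...) that are re-serialized verbatim.
#' Models are usually obtained from [parse_sbml()] or the generator
#' ([scheme_to_model()]) rather than built by hand.
#'
#' @param id model identifier (SId).
#' @param name optional human-readable name.
#' @param level,version SBML level/version the document is stamped with.
#' @param compartments,species,reactions,parameters ordered lists of the
#'   corresponding element constructors.
#' @param unit_definitions,other_elements opaque carried subtrees, each a
#'   `list(container=, id=, xml=)` entry.
#' @param namespaces named character vector of extra (non-core) namespace
#'   declarations, names are prefixes, values URIs.
#' @param notes,annotation raw XML strings carried verbatim (or `NULL`).
#' @return An object of class `sbml_model`.
#' @seealso [parse_sbml()], [write_sbml()], [validate_model()]
#' @export
sbml_model <- function(id, name = NULL, level = 2L, version = 4L,
                       compartments = list(), species = list(),
                       reactions = list(), parameters = list(),
                       unit_definitions = list(), other_elements = list(),
                       namespaces = character(), notes = NULL,
                       annotation = NULL) {
  namespaces <- stats::setNames(as.character(namespaces),
                                names(namespaces) %||% character())
  structure(list(
    id = as.character(id), name = name,
    level = as.integer(level), version = as.integer(version),
    namespaces = namespaces,
    compartments = compartments, species = species, reactions = reactions,
    parameters = parameters, unit_definitions = unit_definitions,
    other_elements = other_elements, notes = notes, annotation = annotation
  ), class = "sbml_model")
}

#' @rdname sbml_model
#' @param size compartment size in model units (finite when present).
#' @param units optional unit-definition id.
#' @param sbo_term optional SBO term string.
#' @param constant optional constancy flag.
#' @export
sbml_compartment <- function(id, name = NULL, size = NULL, units = NULL,
                             sbo_term = NULL, constant = NULL,
                             spatial_dimensions = NULL, annotation = NULL) {
  structure(list(id = as.character(id), name = name,
                 size = if (is.null(size)) NULL else as.numeric(size),
                 units = units, sbo_term = sbo_term, constant = constant,
                 spatial_dimensions = spatial_dimensions,
                 annotation = annotation),
            class = "sbml_compartment")
}

#' @rdname sbml_model
#' @param compartment id of the containing compartment.
#' @param initial_concentration,initial_amount exactly one of the two is
#'   carried; defaults to concentration 0 when neither is given.
#' @param boundary_condition species fixed by the environment: it enters
#'   kinetic laws but gets zero derivative.
#' @export
sbml_species <- function(id, compartment, initial_concentration = NULL,
                         initial_amount = NULL, name = NULL,
                         substance_units = NULL, boundary_condition = FALSE,
                         constant = FALSE, has_only_substance_units = FALSE,
                         sbo_term = NULL, annotation = NULL) {
  if (!is.null(initial_concentration) && !is.null(initial_amount))
    stop_sbml("sbmlfuse_validation_error", sprintf(
      "species '%s': carries both initialConcentration and initialAmount", id))
  init <- if (!is.null(initial_amount))
    list(type = "amount", value = as.numeric(initial_amount))
  else
    list(type = "concentration",
         value = as.numeric(initial_concentration %||% 0))
  structure(list(id = as.character(id), name = name,
                 compartment = as.character(compartment), initial = init,
                 substance_units = substance_units,
                 boundary_condition = isTRUE(boundary_condition),
                 constant = isTRUE(constant),
                 has_only_substance_units = isTRUE(has_only_substance_units),
                 sbo_term = sbo_term, annotation = annotation),
            class = "sbml_species")
}

#' @rdname sbml_model
#' @param species species id referenced.
#' @param stoichiometry positive stoichiometric coefficient (default 1).
#' @export
sbml_species_ref <- function(species, stoichiometry = 1) {
  structure(list(species = as.character(species),
                 stoichiometry = as.numeric(stoichiometry)),
            class = "sbml_species_ref")
}

#' @rdname sbml_model
#' @param reactants,products lists of [sbml_species_ref()].
#' @param modifiers character vector of modifier species ids.
#' @param reversible logical reversibility flag.
#' @param kinetic_law `NULL` or `list(math = <math AST>, parameters =
#'   <list of local sbml_parameter>)`.
#' @export
sbml_reaction <- function(id, reactants = list(), products = list(),
                          modifiers = character(), name = NULL,
                          reversible = FALSE, kinetic_law = NULL,
                          sbo_term = NULL, annotation = NULL) {
  structure(list(id = as.character(id), name = name,
                 reversible = isTRUE(reversible),
                 reactants = reactants, products = products,
                 modifiers = as.character(modifiers),
                 kinetic_law = kinetic_law, sbo_term = sbo_term,
                 annotation = annotation),
            class = "sbml_reaction")
}

#' @rdname sbml_model
#' @param value numeric parameter value (`NA` when absent in the document).
#' @export
sbml_parameter <- function(id, value = NA_real_, name = NULL, units = NULL,
                           constant = NULL) {
  structure(list(id = as.character(id), name = name,
                 value = as.numeric(value), units = units,
                 constant = constant),
            class = "sbml_parameter")
}

element_ids <- function(xs) vapply(xs, function(e) e$id %||% NA_character_,
                                   character(1))

#' All identifiers declared in a model
#'
#' Returns every id in the model's single SId namespace: the model id,
#' compartments, species, reactions, global parameters, local reaction
#' parameters are excluded (they are scoped to their kinetic law), unit
#' definitions and carried opaque elements that bear an id.
#' @param m an `sbml_model`.
#' @return character vector of ids.
#' @export
model_ids <- function(m) {
  other <- vapply(m$other_elements, function(e) e$id %||% NA_character_,
                  character(1))
  c(m$id,
    element_ids(m$compartments), element_ids(m$species),
    element_ids(m$reactions), element_ids(m$parameters),
    vapply(m$unit_definitions, function(e) e$id, character(1)),
    other[!is.na(other)])
}

#' Validate an SBML model's structural invariants
#'
#' Enforces id uniqueness across all id-bearing element classes, resolution
#' of every species' compartment reference and of every species reference in
#' every reaction, positivity of stoichiometries, finiteness of compartment
#' sizes and parameter values, and non-negative initial values.
#'
#' @param m an `sbml_model`.
#' @return `m`, invisibly; signals a classed `sbmlfuse_validation_error`
#'   otherwise.
#' @export
validate_model <- function(m) {
  ids <- model_ids(m)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop_sbml("sbmlfuse_validation_error",
              sprintf("duplicate id(s): %s", paste(unique(dup), collapse = ", ")))
  cids <- element_ids(m$compartments)
  sids <- element_ids(m$species)
  for (s in m$species) {
    if (!s$compartment %in% cids)
      stop_sbml("sbmlfuse_validation_error", sprintf(
        "species '%s' references unknown compartment '%s'", s$id, s$compartment))
    if (!is.na(s$initial$value) && s$initial$value < 0)
      stop_sbml("sbmlfuse_validation_error", sprintf(
        "species '%s': negative initial value", s$id))
  }
  for (cp in m$compartments)
    if (!is.null(cp$size) && !is.finite(cp$size))
      stop_sbml("sbmlfuse_validation_error", sprintf(
        "compartment '%s': non-finite size", cp$id))
  for (p in m$parameters)
    if (!is.na(p$value) && !is.finite(p$value))
      stop_sbml("sbmlfuse_validation_error", sprintf(
        "parameter '%s': non-finite value", p$id))
  for (r in m$reactions) {
    for (ref in c(r$reactants, r$products)) {
      if (!ref$species %in% sids)
        stop_sbml("sbmlfuse_validation_error", sprintf(
          "reaction '%s' references unknown species '%s'", r$id, ref$species))
      if (!is.finite(ref$stoichiometry) || ref$stoichiometry <= 0)
        stop_sbml("sbmlfuse_validation_error", sprintf(
          "reaction '%s': non-positive stoichiometry on '%s'", r$id, ref$species))
    }
    for (mod in r$modifiers)
      if (!mod %in% sids)
        stop_sbml("sbmlfuse_validation_error", sprintf(
          "reaction '%s' references unknown modifier species '%s'", r$id, mod))
  }
  invisible(m)
}

#' Effective name of an element
#'
#' Matching and similarity compare on the `name` attribute when present,
#' falling back to the `id` otherwise (Test-Suite-style models typically
#' carry only ids).
#' @param el a compartment, species, reaction or parameter object.
#' @return character scalar.
#' @export
effective_name <- function(el) {
  if (!is.null(el$name) && nzchar(el$name)) el$name else el$id
}

#' Structural equality of two models
#'
#' Field-by-field comparison of the internal representation: element counts,
#' ids, attributes, stoichiometries and math ASTs. Used by the round-trip
#' tests (`parse_sbml(write_sbml(m))` must equal `m`).
#' @param a,b `sbml_model` objects.
#' @return logical scalar.
#' @export
model_equal <- function(a, b) identical(strip_model(a), strip_model(b))

strip_model <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_model)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' @export
print.sbml_model <- function(x, ...) {
  cat(sprintf("<sbml_model> %s (L%dV%d)\n", x$id, x$level, x$version))
  cat(sprintf("  compartments: %d, species: %d, reactions: %d, parameters: %d\n",
              length(x$compartments), length(x$species), length(x$reactions),
              length(x$parameters)))
  if (length(x$unit_definitions) || length(x$other_elements))
    cat(sprintf("  carried subtrees: %d unit definition(s), %d other\n",
                length(x$unit_definitions), length(x$other_elements)))
  invisible(x)
}

#' JSON dump of the internal model representation
#'
#' Debugging aid behind the CLI's `--dump-json`; not an exchange format.
#' @param m an `sbml_model`.
#' @param path optional file to write to.
#' @return JSON string, invisibly when `path` is given.
#' @export
model_to_json <- function(m, path = NULL) {
  js <- jsonlite::toJSON(strip_model(m), auto_unbox = TRUE, null = "null",
                         digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
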