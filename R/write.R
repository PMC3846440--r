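# SBML document writing. Documents are assembled as text (carried opaque
# subtrees are spliced in verbatim) and the result is re-parsed once as a
# well-formedness check.

attr_str <- function(name, value) {
  if (is.null(value) || (length(value) == 1 && is.na(value))) return("")
  if (is.logical(value)) value <- bool_attr(value)
  if (is.numeric(value)) value <- fmt_num(value)
  sprintf(" %s=\"%s\"", name, xml_escape_attr(as.character(value)))
}

render_compartment <- function(cp) {
  attrs <- paste0(attr_str("id", cp$id), attr_str("name", cp$name),
                  attr_str("spatialDimensions", cp$spatial_dimensions),
                  attr_str("size", cp$size), attr_str("units", cp$units),
                  attr_str("constant", cp$constant),
                  attr_str("sboTerm", cp$sbo_term))
  if (is.null(cp$annotation))
    sprintf("      <compartment%s/>", attrs)
  else sprintf("      <compartment%s>%s</compartment>", attrs, cp$annotation)
}

render_species <- function(s, level) {
  init_attr <- if (s$initial$type == "amount")
    attr_str("initialAmount", s$initial$value)
  else attr_str("initialConcentration", s$initial$value)
  attrs <- paste0(
    attr_str("id", s$id), attr_str("name", s$name),
    attr_str("compartment", s$compartment), init_attr,
    attr_str("substanceUnits", s$substance_units),
    attr_str("hasOnlySubstanceUnits",
             if (level >= 3 || s$has_only_substance_units)
               s$has_only_substance_units else NULL),
    attr_str("boundaryCondition",
             if (level >= 3 || s$boundary_condition)
               s$boundary_condition else NULL),
    attr_str("constant", if (level >= 3 || s$constant) s$constant else NULL),
    attr_str("sboTerm", s$sbo_term))
  if (is.null(s$annotation)) sprintf("      <species%s/>", attrs)
  else sprintf("      <species%s>%s</species>", attrs, s$annotation)
}

render_parameter <- function(p, tag = "parameter") {
  sprintf("<%s%s/>", tag, paste0(
    attr_str("id", p$id), attr_str("name", p$name),
    attr_str("value", if (is.na(p$value)) NULL else p$value),
    attr_str("units", p$units), attr_str("constant", p$constant)))
}

render_refs <- function(refs, listname, indent) {
  if (!length(refs)) return(character())
  body <- vapply(refs, function(r) sprintf(
    "%s  <speciesReference%s%s/>", indent,
    attr_str("species", r$species),
    attr_str("stoichiometry", if (r$stoichiometry != 1) r$stoichiometry
             else NULL)), character(1))
  c(sprintf("%s<%s>", indent, listname), body,
    sprintf("%s</%s>", indent, listname))
}

render_reaction <- function(r, level) {
  ind <- "        "
  lines <- sprintf("      <reaction%s>", paste0(
    attr_str("id", r$id), attr_str("name", r$name),
    attr_str("reversible", r$reversible),
    attr_str("sboTerm", r$sbo_term)))
  if (!is.null(r$annotation)) lines <- c(lines, paste0(ind, r$annotation))
  lines <- c(lines,
             render_refs(r$reactants, "listOfReactants", ind),
             render_refs(r$products, "listOfProducts", ind))
  if (length(r$modifiers))
    lines <- c(lines, paste0(ind, "<listOfModifiers>"),
               vapply(r$modifiers, function(mm) sprintf(
                 "%s  <modifierSpeciesReference species=\"%s\"/>", ind, mm),
                 character(1)),
               paste0(ind, "</listOfModifiers>"))
  if (!is.null(r$kinetic_law)) {
    kl <- r$kinetic_law
    lines <- c(lines, paste0(ind, "<kineticLaw>"))
    if (!is.null(kl$math))
      lines <- c(lines, paste0(ind, "  ", write_mathml(kl$math)))
    if (length(kl$parameters)) {
      listname <- if (level >= 3) "listOfLocalParameters" else "listOfParameters"
      tag <- if (level >= 3) "localParameter" else "parameter"
      lines <- c(lines, sprintf("%s  <%s>", ind, listname),
                 vapply(kl$parameters, function(p)
                   paste0(ind, "    ", render_parameter(p, tag)),
                   character(1)),
                 sprintf("%s  </%s>", ind, listname))
    }
    lines <- c(lines, paste0(ind, "</kineticLaw>"))
  }
  c(lines, "      </reaction>")
}

render_container <- function(items, listname, renderer) {
  if (!length(items)) return(character())
  c(sprintf("    <%s>", listname),
    unlist(lapply(items, renderer)),
    sprintf("    </%s>", listname))
}

#' Serialize a model to an SBML document
#'
#' Emits the document at the model's stored level/version. Carried opaque
#' subtrees are written back verbatim in the canonical SBML container
#' order. The model is validated first and the produced text is re-parsed
#' as a well-formedness check, so `parse_sbml(write_sbml(m))` is
#' structurally equal to `m`.
#'
#' @param m an `sbml_model`.
#' @param file optional path to write to.
#' @return the XML text, invisibly when `file` is given.
#' @export
write_sbml <- function(m, file = NULL) {
  validate_model(m)
  core <- sbml_core_ns(m$level, m$version)
  ns_extra <- if (length(m$namespaces))
    paste0(vapply(seq_along(m$namespaces), function(i) sprintf(
      " xmlns:%s=\"%s\"", names(m$namespaces)[i],
      xml_escape_attr(m$namespaces[[i]])), character(1)), collapse = "")
  else ""

  carried <- function(container)
    lapply(Filter(function(e) e$container == container, m$other_elements),
           function(e) paste0("      ", e$xml))

  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf("<sbml xmlns=\"%s\"%s level=\"%d\" version=\"%d\">",
            core, ns_extra, m$level, m$version),
    sprintf("  <model%s%s>", attr_str("id", m$id), attr_str("name", m$name)))
  if (!is.null(m$notes)) lines <- c(lines, paste0("    ", m$notes))
  if (!is.null(m$annotation)) lines <- c(lines, paste0("    ", m$annotation))
  lines <- c(lines,
    render_container(carried("listOfFunctionDefinitions"),
                     "listOfFunctionDefinitions", identity),
    render_container(lapply(m$unit_definitions,
                            function(u) paste0("      ", u$xml)),
                     "listOfUnitDefinitions", identity),
    render_container(carried("listOfCompartmentTypes"),
                     "listOfCompartmentTypes", identity),
    render_container(carried("listOfSpeciesTypes"),
                     "listOfSpeciesTypes", identity),
    render_container(m$compartments, "listOfCompartments", render_compartment),
    render_container(m$species, "listOfSpecies",
                     function(s) render_species(s, m$level)),
    render_container(m$parameters, "listOfParameters", render_parameter_line),
    render_container(carried("listOfInitialAssignments"),
                     "listOfInitialAssignments", identity),
    render_container(carried("listOfRules"), "listOfRules", identity),
    render_container(carried("listOfConstraints"),
                     "listOfConstraints", identity),
    render_container(m$reactions, "listOfReactions",
                     function(r) render_reaction(r, m$level)),
    render_container(carried("listOfEvents"), "listOfEvents", identity),
    "  </model>",
    "</sbml>")
  text <- paste(unlist(lines), collapse = "\n")
  tryCatch(xml2::read_xml(text), error = function(e) stop_sbml(
    "sbmlfuse_write_error",
    paste0("serialization produced malformed XML: ", conditionMessage(e))))
  if (!is.null(file)) {
    writeLines(text, file)
    return(invisible(text))
  }
  text
}

render_parameter_line <- function(p) paste0("      ", render_parameter(p))
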