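# SBML document reading.
#
# Navigation uses local-name() XPath so files with or without explicit
# prefixes on the core namespace parse identically. Subtrees the package
# does not model (function definitions, unit definitions, rules, events,
# initial assignments, constraints, compartment/species types) are carried
# as verbatim XML strings; libxml2 adds the in-scope namespace declarations
# when serializing a subtree, so the carried strings are self-contained.

sbml_core_ns <- function(level, version) {
  if (level == 2) {
    if (version == 1) "http://www.sbml.org/sbml/level2"
    else sprintf("http://www.sbml.org/sbml/level2/version%d", version)
  } else if (level == 3) {
    sprintf("http://www.sbml.org/sbml/level3/version%d/core", version)
  } else {
    stop_sbml("sbmlfuse_parse_error",
              sprintf("SBML Level %d is not supported", level))
  }
}

OPAQUE_CONTAINERS <- c("listOfFunctionDefinitions", "listOfCompartmentTypes",
                       "listOfSpeciesTypes", "listOfInitialAssignments",
                       "listOfRules", "listOfConstraints", "listOfEvents")

ln_xpath <- function(...) {
  paste(vapply(c(...), function(x) sprintf("*[local-name()='%s']", x),
               character(1)), collapse = "/")
}

first_child <- function(node, name) {
  xml2::xml_find_first(node, paste0("./", ln_xpath(name)))
}

# Canonical form for carried fragments, so that captured subtrees are
# byte-stable across parse/write cycles: the inherited SBML core default
# namespace (redundant, re-established by the writer at the root) is
# stripped, and whitespace-only text nodes are normalized by a NOBLANKS
# re-parse and deterministic re-dump.
canon_fragment <- function(x) {
  x <- gsub(' xmlns="http://www\\.sbml\\.org/sbml/level[^"]*"', "", x)
  out <- tryCatch(
    as.character(xml2::read_xml(x, options = c("NOBLANKS"))),
    error = function(e) x)
  out <- sub("^<\\?xml[^>]*\\?>\\n?", "", out)
  sub("\\n$", "", out)
}

child_xml <- function(node, name) {
  n <- first_child(node, name)
  if (inherits(n, "xml_missing")) NULL else canon_fragment(as.character(n))
}

opt_attr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) NULL else v
}

opt_num_attr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) NULL else as.numeric(v)
}

opt_bool_attr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) NULL else identical(v, "true") || identical(v, "1")
}

# xmlns declarations on the root element's open tag, minus the SBML core
# and MathML namespaces (which the writer manages itself); libxml2 does not
# expose namespace declarations as attributes, hence the textual scan
collect_namespaces <- function(text) {
  root_tag <- regmatches(text, regexpr("<[A-Za-z][^>]*>", text))
  text <- if (length(root_tag)) root_tag else text
  m <- gregexpr("xmlns(:[A-Za-z_][A-Za-z0-9_.-]*)?\\s*=\\s*\"([^\"]*)\"",
                text, perl = TRUE)[[1]]
  if (m[1] == -1) return(character())
  decls <- regmatches(text, list(m))[[1]]
  prefixes <- sub("^xmlns:?([A-Za-z0-9_.-]*)\\s*=.*$", "\\1", decls)
  uris <- sub("^[^\"]*\"([^\"]*)\"$", "\\1", decls)
  keep <- !grepl("^http://www\\.sbml\\.org/sbml/level", uris) &
    uris != MATHML_NS & nzchar(prefixes)
  prefixes <- prefixes[keep]; uris <- uris[keep]
  out <- character(); out_p <- character()
  for (i in seq_along(uris)) {
    if (uris[i] %in% out) next          # union keyed by URI, first prefix wins
    p <- prefixes[i]
    while (p %in% out_p) p <- paste0(p, "_2")
    out <- c(out, uris[i]); out_p <- c(out_p, p)
  }
  stats::setNames(out, out_p)
}

#' Parse an SBML document
#'
#' Reads an SBML Level 2 or Level 3 document into the internal
#' [sbml_model()] representation. Compartments, species, reactions (with
#' kinetic-law math parsed into an AST) and global parameters are fully
#' modeled; everything else is carried opaquely and re-serialized verbatim
#' by [write_sbml()]. Structural invariants (unique ids, resolvable
#' references) are validated on every parse.
#'
#' @param x file path, or a character scalar holding the XML text.
#' @return an `sbml_model`.
#' @export
parse_sbml <- function(x) {
  text <- if (length(x) == 1 && !grepl("<", x, fixed = TRUE)) {
    if (!file.exists(x))
      stop_sbml("sbmlfuse_parse_error", sprintf("no such file: '%s'", x))
    paste(readLines(x, warn = FALSE), collapse = "\n")
  } else paste(x, collapse = "\n")

  doc <- tryCatch(xml2::read_xml(text),
                  error = function(e) stop_sbml(
                    "sbmlfuse_parse_error",
                    paste0("malformed XML: ", conditionMessage(e))))
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "sbml")
    stop_sbml("sbmlfuse_parse_error", "root element is not <sbml>")
  level <- as.integer(xml2::xml_attr(root, "level"))
  version <- as.integer(xml2::xml_attr(root, "version"))
  if (is.na(level) || is.na(version))
    stop_sbml("sbmlfuse_parse_error", "missing level/version attributes")
  sbml_core_ns(level, version)  # errors on unsupported levels

  mnode <- first_child(root, "model")
  if (inherits(mnode, "xml_missing"))
    stop_sbml("sbmlfuse_parse_error", "document has no <model> element")

  compartments <- lapply(
    xml2::xml_find_all(mnode, paste0("./", ln_xpath("listOfCompartments",
                                                    "compartment"))),
    function(n) sbml_compartment(
      id = xml2::xml_attr(n, "id"), name = opt_attr(n, "name"),
      size = opt_num_attr(n, "size"), units = opt_attr(n, "units"),
      sbo_term = opt_attr(n, "sboTerm"),
      constant = opt_bool_attr(n, "constant"),
      spatial_dimensions = opt_attr(n, "spatialDimensions"),
      annotation = child_xml(n, "annotation")))

  species <- lapply(
    xml2::xml_find_all(mnode, paste0("./", ln_xpath("listOfSpecies",
                                                    "species"))),
    function(n) sbml_species(
      id = xml2::xml_attr(n, "id"), name = opt_attr(n, "name"),
      compartment = xml2::xml_attr(n, "compartment"),
      initial_concentration = opt_num_attr(n, "initialConcentration"),
      initial_amount = opt_num_attr(n, "initialAmount"),
      substance_units = opt_attr(n, "substanceUnits"),
      boundary_condition = isTRUE(opt_bool_attr(n, "boundaryCondition")),
      constant = isTRUE(opt_bool_attr(n, "constant")),
      has_only_substance_units =
        isTRUE(opt_bool_attr(n, "hasOnlySubstanceUnits")),
      sbo_term = opt_attr(n, "sboTerm"),
      annotation = child_xml(n, "annotation")))

  parse_param <- function(n) sbml_parameter(
    id = xml2::xml_attr(n, "id"), name = opt_attr(n, "name"),
    value = opt_num_attr(n, "value") %||% NA_real_,
    units = opt_attr(n, "units"), constant = opt_bool_attr(n, "constant"))

  parameters <- lapply(
    xml2::xml_find_all(mnode, paste0("./", ln_xpath("listOfParameters",
                                                    "parameter"))),
    parse_param)

  parse_refs <- function(rnode, listname) lapply(
    xml2::xml_find_all(rnode, paste0("./", ln_xpath(listname,
                                                    "speciesReference"))),
    function(n) sbml_species_ref(
      species = xml2::xml_attr(n, "species"),
      stoichiometry = opt_num_attr(n, "stoichiometry") %||% 1))

  reactions <- lapply(
    xml2::xml_find_all(mnode, paste0("./", ln_xpath("listOfReactions",
                                                    "reaction"))),
    function(n) {
      kl_node <- first_child(n, "kineticLaw")
      kl <- NULL
      if (!inherits(kl_node, "xml_missing")) {
        math_node <- first_child(kl_node, "math")
        locals <- lapply(
          xml2::xml_find_all(kl_node, paste0(
            "./*[local-name()='listOfParameters' or ",
            "local-name()='listOfLocalParameters']/",
            "*[local-name()='parameter' or local-name()='localParameter']")),
          parse_param)
        kl <- list(
          math = if (inherits(math_node, "xml_missing")) NULL
                 else parse_mathml(math_node),
          parameters = locals)
      }
      rev_attr <- opt_bool_attr(n, "reversible")
      sbml_reaction(
        id = xml2::xml_attr(n, "id"), name = opt_attr(n, "name"),
        reversible = if (is.null(rev_attr)) level == 2 else rev_attr,
        reactants = parse_refs(n, "listOfReactants"),
        products = parse_refs(n, "listOfProducts"),
        modifiers = vapply(
          xml2::xml_find_all(n, paste0("./", ln_xpath(
            "listOfModifiers", "modifierSpeciesReference"))),
          function(x) xml2::xml_attr(x, "species"), character(1)),
        kinetic_law = kl, sbo_term = opt_attr(n, "sboTerm"),
        annotation = child_xml(n, "annotation"))
    })

  unit_definitions <- lapply(
    xml2::xml_find_all(mnode, paste0("./", ln_xpath("listOfUnitDefinitions",
                                                    "unitDefinition"))),
    function(n) list(id = xml2::xml_attr(n, "id"),
                     xml = canon_fragment(as.character(n))))

  other <- list()
  for (container in OPAQUE_CONTAINERS) {
    for (n in xml2::xml_find_all(mnode, paste0("./", ln_xpath(container),
                                               "/*"))) {
      other[[length(other) + 1L]] <- list(
        container = container, id = opt_attr(n, "id"),
        tag = xml2::xml_name(n), xml = canon_fragment(as.character(n)))
    }
  }

  m <- sbml_model(
    id = xml2::xml_attr(mnode, "id") %||% "model",
    name = opt_attr(mnode, "name"),
    level = level, version = version,
    namespaces = collect_namespaces(text),
    compartments = compartments, species = species,
    reactions = reactions, parameters = parameters,
    unit_definitions = unit_definitions, other_elements = other,
    notes = child_xml(mnode, "notes"),
    annotation = child_xml(mnode, "annotation"))
  validate_model(m)
  m
}

#' Check SBML level/version compatibility of two models
#'
#' Models can only be composed element-by-element when they share the same
#' SBML level and version; element structure differs across levels.
#'
#' @param m1,m2 `sbml_model` objects.
#' @param on_mismatch `"error"` (default) stops with a classed
#'   `sbmlfuse_compat_error`; `"warn"` passes and returns a `level-note`
#'   warning record instead.
#' @return list with `ok` (logical) and `warnings` (possibly empty list of
#'   [merge_warning()] records), invisibly on pass.
#' @export
check_compatibility <- function(m1, m2, on_mismatch = c("error", "warn")) {
  on_mismatch <- match.arg(on_mismatch)
  if (m1$level == m2$level && m1$version == m2$version)
    return(invisible(list(ok = TRUE, warnings = list())))
  msg <- sprintf("SBML level/version mismatch: L%dV%d vs L%dV%d",
                 m1$level, m1$version, m2$level, m2$version)
  if (on_mismatch == "error") stop_sbml("sbmlfuse_compat_error", msg)
  invisible(list(ok = TRUE, warnings = list(
    merge_warning("level-note", "other", c(m1$id, m2$id, ""),
                  attribute = "level",
                  value1 = sprintf("L%dV%d", m1$level, m1$version),
                  value2 = sprintf("L%dV%d", m2$level, m2$version),
                  chosen = sprintf("L%dV%d", m1$level, m1$version)))))
}
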