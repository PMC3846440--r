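# Fixture builders; everything is generated in code, no stored files.

minimal_sbml_xml <- function() {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="mini"><listOfCompartments><compartment id="c" size="1"/>',
    '</listOfCompartments><listOfSpecies>',
    '<species id="S1" compartment="c" initialConcentration="1"/>',
    '</listOfSpecies></model></sbml>')
}

duplicate_id_xml <- function() {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="dup"><listOfCompartments><compartment id="c" size="1"/>',
    '</listOfCompartments><listOfSpecies>',
    '<species id="S1" compartment="c" initialConcentration="1"/>',
    '<species id="S1" compartment="c" initialConcentration="2"/>',
    '</listOfSpecies></model></sbml>')
}

# model with a carried unit definition and an extra root namespace
carried_subtree_xml <- function(model_id = "withunits", param = "p1") {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" ',
    'xmlns:q="http://example.org/q" level="2" version="4">',
    '<model id="', model_id, '">',
    '<listOfUnitDefinitions><unitDefinition id="myunit"><listOfUnits>',
    '<unit kind="mole" scale="-3"/></listOfUnits></unitDefinition>',
    '</listOfUnitDefinitions>',
    '<listOfCompartments><compartment id="c" size="1"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="S1" compartment="c" initialConcentration="1" ',
    'substanceUnits="myunit"/></listOfSpecies>',
    '<listOfParameters><parameter id="', param,
    '" value="2" units="myunit"/></listOfParameters>',
    '</model></sbml>')
}

event_model_xml <- function() {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="ev"><listOfCompartments><compartment id="c" size="1"/>',
    '</listOfCompartments><listOfSpecies>',
    '<species id="S1" compartment="c" initialConcentration="1"/>',
    '</listOfSpecies>',
    '<listOfEvents><event id="e1"><trigger>',
    '<math xmlns="http://www.w3.org/1998/Math/MathML"><true/></math>',
    '</trigger></event></listOfEvents>',
    '</model></sbml>')
}

chebi_url <- "http://identifiers.org/chebi/CHEBI:17234"
chebi_urn <- "urn:miriam:obo.chebi:CHEBI%3A17234"

# two-species model where one species carries a MIRIAM annotation
annotated_species_model <- function(model_id, species_id, uri,
                                    qualifier = "is") {
  m <- scheme_to_model("S1 -> S2", model_id, rate_constants = 1)
  idx <- which(vapply(m$species, `[[`, character(1), "id") == species_id)
  m$species[[idx]]$annotation <- miriam_annotation(uri, qualifier)
  m$species[[idx]]$name <- paste0(species_id, "_of_", model_id)
  m
}

empty_model <- function(id = "empty") sbml_model(id)

# brute-force maximum bipartite matching over an eligibility matrix
# (logical n1 x n2); returns the maximum matching size and one witness
brute_force_matching <- function(elig) {
  n1 <- nrow(elig); n2 <- ncol(elig)
  best <- list(size = 0L, pairs = cbind(integer(), integer()))
  recurse <- function(i, used2, pairs) {
    if (i > n1) {
      if (nrow(pairs) > best$size)
        best <<- list(size = nrow(pairs), pairs = pairs)
      return(invisible())
    }
    recurse(i + 1L, used2, pairs)  # leave element i unmatched
    for (j in seq_len(n2)) {
      if (elig[i, j] && !used2[j]) {
        used2[j] <- TRUE
        recurse(i + 1L, used2, rbind(pairs, c(i, j)))
        used2[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, n2), cbind(integer(), integer()))
  best
}
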