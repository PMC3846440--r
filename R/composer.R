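# Model fusion: model 1 pivots, matched elements appear once with model-1
# attributes, unmatched model-2 elements are carried over with
# deterministic id-collision renaming, and every overridden difference or
# rename is recorded as an ordered warning.

#' Composition warning record
#'
#' @param category one of `attribute-conflict`, `id-renamed`,
#'   `name-conflict`, `level-note`.
#' @param element_class `compartment`, `species`, `reaction`, `parameter`
#'   or `other`.
#' @param ids character triple `(model1-id, model2-id, composed-id)`.
#' @param attribute conflicting attribute name (empty for renames).
#' @param value1,value2,chosen stringified values; for attribute conflicts
#'   `chosen` always equals `value1` (pivot rule).
#' @return a `merge_warning` list.
#' @export
merge_warning <- function(category, element_class, ids, attribute = "",
                          value1 = "", value2 = "", chosen = "") {
  structure(list(category = category, element_class = element_class,
                 ids = stats::setNames(as.character(ids),
                                       c("model1", "model2", "composed")),
                 attribute = attribute, value1 = as.character(value1),
                 value2 = as.character(value2), chosen = as.character(chosen)),
            class = "merge_warning")
}

#' @export
format.merge_warning <- function(x, ...) {
  if (x$category == "attribute-conflict")
    sprintf("[%s] %s %s/%s: %s differs (%s vs %s); kept %s",
            x$category, x$element_class, x$ids[["model1"]],
            x$ids[["model2"]], x$attribute, x$value1, x$value2, x$chosen)
  else if (x$category == "id-renamed")
    sprintf("[%s] %s '%s' renamed to '%s'", x$category, x$element_class,
            x$ids[["model2"]], x$ids[["composed"]])
  else sprintf("[%s] %s %s/%s: %s vs %s", x$category, x$element_class,
               x$ids[["model1"]], x$ids[["model2"]], x$value1, x$value2)
}

#' @export
print.merge_warning <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

warn_str <- function(v) {
  if (is.null(v)) return("")
  if (is.logical(v)) return(bool_attr(v))
  if (is.numeric(v)) return(fmt_num(v))
  as.character(v)
}

# one attribute-conflict warning per attribute present in both elements
# with different values; absence is not a conflict
conflict_warnings <- function(e1, e2, fields, element_class, composed_id) {
  out <- list()
  for (f in names(fields)) {
    v1 <- e1[[f]]; v2 <- e2[[f]]
    if (is.null(v1) || is.null(v2)) next
    if (identical(v1, v2)) next
    out[[length(out) + 1L]] <- merge_warning(
      "attribute-conflict", element_class, c(e1$id, e2$id, composed_id),
      attribute = fields[[f]], value1 = warn_str(v1), value2 = warn_str(v2),
      chosen = warn_str(v1))
  }
  out
}

#' Merge a matched pair of compartments
#'
#' Model-1 attributes win wholesale; a warning is emitted for each of
#' name, units, size, sboTerm and constant where both sides carry a value
#' and the values differ.
#'
#' @param c1,c2 `sbml_compartment` objects (a matched pair).
#' @return `list(merged=, warnings=)`.
#' @export
merge_compartments <- function(c1, c2) {
  list(merged = c1,
       warnings = conflict_warnings(
         c1, c2, c(name = "name", units = "units", size = "size",
                   sbo_term = "sboTerm", constant = "constant"),
         "compartment", c1$id))
}

#' Merge a matched pair of species
#'
#' Model-1 attributes win; conflicts on the initial value (including a
#' concentration-vs-amount form difference), substanceUnits,
#' boundaryCondition, constant and sboTerm are warned.
#'
#' @param s1,s2 `sbml_species` objects (a matched pair).
#' @return `list(merged=, warnings=)`.
#' @export
merge_species <- function(s1, s2) {
  warnings <- list()
  if (!identical(s1$initial, s2$initial)) {
    fmt_init <- function(i) {
      v <- fmt_num(i$value)
      if (s1$initial$type != s2$initial$type) paste(i$type, v) else v
    }
    warnings[[1L]] <- merge_warning(
      "attribute-conflict", "species", c(s1$id, s2$id, s1$id),
      attribute = "initialValue", value1 = fmt_init(s1$initial),
      value2 = fmt_init(s2$initial), chosen = fmt_init(s1$initial))
  }
  warnings <- c(warnings, conflict_warnings(
    s1, s2, c(substance_units = "substanceUnits",
              boundary_condition = "boundaryCondition",
              constant = "constant", sbo_term = "sboTerm"),
    "species", s1$id))
  list(merged = s1, warnings = warnings)
}

#' Merge a matched pair of reactions
#'
#' The model-1 reaction is kept (kinetic law, local parameters,
#' reversibility, sboTerm); modifier lists are unioned (model-2 modifiers
#' mapped through the species id map). Stoichiometry differences on
#' corresponding species references and a differing kinetic law are
#' warned, never silently dropped.
#'
#' @param r1,r2 `sbml_reaction` objects (a matched pair).
#' @param species_map named character vector mapping model-2 species ids
#'   to composed ids.
#' @return `list(merged=, warnings=)`.
#' @export
merge_reactions <- function(r1, r2, species_map = character()) {
  smap <- as.list(species_map)
  map_id <- function(i) if (!is.null(smap[[i]])) smap[[i]] else i
  warnings <- conflict_warnings(
    r1, r2, c(name = "name", reversible = "reversible",
              sbo_term = "sboTerm"),
    "reaction", r1$id)

  stoich_warnings <- function(refs1, refs2, side) {
    w <- list()
    for (ref1 in refs1) {
      for (ref2 in refs2) {
        if (identical(ref1$species, map_id(ref2$species)) &&
            ref1$stoichiometry != ref2$stoichiometry) {
          w[[length(w) + 1L]] <- merge_warning(
            "attribute-conflict", "reaction", c(r1$id, r2$id, r1$id),
            attribute = sprintf("stoichiometry(%s:%s)", side, ref1$species),
            value1 = fmt_num(ref1$stoichiometry),
            value2 = fmt_num(ref2$stoichiometry),
            chosen = fmt_num(ref1$stoichiometry))
          break
        }
      }
    }
    w
  }
  warnings <- c(warnings,
                stoich_warnings(r1$reactants, r2$reactants, "reactant"),
                stoich_warnings(r1$products, r2$products, "product"))

  m1_math <- if (!is.null(r1$kinetic_law)) r1$kinetic_law$math
  m2_math <- if (!is.null(r2$kinetic_law)) r2$kinetic_law$math
  if (!is.null(m1_math) && !is.null(m2_math)) {
    locals2 <- if (!is.null(r2$kinetic_law))
      element_ids(r2$kinetic_law$parameters) else character()
    mapped2 <- rename_math_ids(m2_math, smap, shadow = locals2)
    if (!identical(strip_model(m1_math), strip_model(mapped2)))
      warnings[[length(warnings) + 1L]] <- merge_warning(
        "attribute-conflict", "reaction", c(r1$id, r2$id, r1$id),
        attribute = "kineticLaw", value1 = math_to_string(m1_math),
        value2 = math_to_string(m2_math), chosen = math_to_string(m1_math))
  }

  merged <- r1
  mods2 <- vapply(r2$modifiers, map_id, character(1), USE.NAMES = FALSE)
  merged$modifiers <- union(r1$modifiers, mods2)
  list(merged = merged, warnings = warnings)
}

#' Collision-free prefixed identifier
#'
#' Returns `"<m2_id>_<element_id>"`; when that is itself taken, numeric
#' suffixes `_2`, `_3`, ... are appended until free.
#'
#' @param element_id the model-2 element id.
#' @param m2_id the model-2 model id used as prefix.
#' @param taken character vector of ids already in use.
#' @return the new identifier.
#' @export
rename_with_prefix <- function(element_id, m2_id, taken) {
  cand <- paste0(m2_id, "_", element_id)
  if (!cand %in% taken) return(cand)
  i <- 2L
  while (paste0(cand, "_", i) %in% taken) i <- i + 1L
  paste0(cand, "_", i)
}

#' Union of two models' namespace sets
#'
#' Keyed by URI; when the two models bind the same prefix to different
#' URIs the model-2 binding is re-prefixed. Carried subtrees self-declare
#' the namespaces they use, so re-prefixing the root-level declaration
#' never breaks a fragment.
#'
#' @param m1,m2 `sbml_model` objects.
#' @return named character vector (names are prefixes, values URIs).
#' @export
union_namespaces <- function(m1, m2) {
  out <- m1$namespaces
  for (i in seq_along(m2$namespaces)) {
    uri <- m2$namespaces[[i]]
    if (uri %in% out) next
    p <- names(m2$namespaces)[i]
    while (p %in% names(out)) p <- paste0(p, "2")
    out[p] <- uri
  }
  out
}

# textual id rewrite inside carried opaque subtrees: whole-identifier
# occurrences only (SId charset boundaries)
rewrite_opaque_ids <- function(xml, map) {
  for (old in names(map)) {
    if (identical(map[[old]], old)) next
    xml <- gsub(paste0("(?<![A-Za-z0-9_])", old, "(?![A-Za-z0-9_])"),
                map[[old]], xml, perl = TRUE)
  }
  xml
}

#' Compose two SBML models
#'
#' Executes the fusion: the composed model contains all of model 1
#' verbatim (model 1 pivots) plus every unmatched model-2 element, with
#' model-2 ids renamed on collision using the `"<model2-id>_"` prefix.
#' Matched elements appear once with model-1 attributes; differing
#' attribute values and every rename are recorded as ordered warnings.
#' Global parameters, unit definitions and carried constructs are never
#' merged. Namespaces are unioned. All identifier references in carried
#' model-2 fragments (species references, modifiers, kinetic-law math,
#' units attributes, opaque subtrees) are rewritten through the id map.
#'
#' @param m1,m2 `sbml_model` objects with equal SBML level/version (see
#'   `level_mismatch` in [fuse_config()]).
#' @param table a [match_table()]; `NULL` (default) runs [auto_match()]
#'   ("Automatic" for every element).
#' @param config a [fuse_config()].
#' @return a `merge_result`: `composed` (`sbml_model`), `id_map1` and
#'   `id_map2` (named character vectors old id -> composed id), and
#'   `warnings` (ordered list of [merge_warning()] records).
#' @export
compose <- function(m1, m2, table = NULL, config = fuse_config()) {
  compat <- check_compatibility(m1, m2, config$level_mismatch)
  warnings <- compat$warnings
  if (is.null(table)) table <- auto_match(m1, m2, config = config)
  validate_match_table(table, m1, m2)

  composed <- m1
  composed$id <- config$composed_id %||% paste0(m1$id, "_", m2$id)
  composed$name <- config$composed_name %||%
    sprintf("Composition of %s and %s", effective_name(m1),
            effective_name(m2))
  composed$namespaces <- union_namespaces(m1, m2)

  m1_ids <- model_ids(m1)
  taken <- unique(c(m1_ids, composed$id))
  id_map1 <- stats::setNames(m1_ids, m1_ids)
  id_map2 <- character()

  assign_id <- function(old_id, element_class) {
    if (config$prefix_all || old_id %in% taken) {
      new_id <- rename_with_prefix(old_id, m2$id, taken)
      warnings[[length(warnings) + 1L]] <<- merge_warning(
        "id-renamed", element_class, c("", old_id, new_id))
      new_id
    } else old_id
  }

  matched2 <- function(cl) stats::setNames(table[[cl]]$id1, table[[cl]]$id2)

  # --- compartments ---
  cmap <- matched2("compartments")
  added_compartments <- integer()
  for (c2 in m2$compartments) {
    if (c2$id %in% names(cmap)) {
      c1 <- m1$compartments[[which(element_ids(m1$compartments) ==
                                     cmap[[c2$id]])]]
      res <- merge_compartments(c1, c2)
      warnings <- c(warnings, res$warnings)
      id_map2[c2$id] <- c1$id
    } else {
      new_id <- assign_id(c2$id, "compartment")
      id_map2[c2$id] <- new_id
      c2$id <- new_id
      composed$compartments[[length(composed$compartments) + 1L]] <- c2
      added_compartments <- c(added_compartments,
                              length(composed$compartments))
      taken <- c(taken, new_id)
    }
  }

  # --- species ---
  smap <- matched2("species")
  added_species <- integer()
  for (s2 in m2$species) {
    if (s2$id %in% names(smap)) {
      s1 <- m1$species[[which(element_ids(m1$species) == smap[[s2$id]])]]
      res <- merge_species(s1, s2)
      warnings <- c(warnings, res$warnings)
      id_map2[s2$id] <- s1$id
    } else {
      new_id <- assign_id(s2$id, "species")
      id_map2[s2$id] <- new_id
      s2$id <- new_id
      composed$species[[length(composed$species) + 1L]] <- s2
      added_species <- c(added_species, length(composed$species))
      taken <- c(taken, new_id)
    }
  }

  # --- reactions ---
  rmap <- matched2("reactions")
  added_reactions <- integer()
  species_map_for_merge <- id_map2[element_ids(m2$species)]
  for (r2 in m2$reactions) {
    if (r2$id %in% names(rmap)) {
      idx1 <- which(element_ids(m1$reactions) == rmap[[r2$id]])
      r1 <- m1$reactions[[idx1]]
      res <- merge_reactions(r1, r2, species_map_for_merge)
      warnings <- c(warnings, res$warnings)
      composed$reactions[[idx1]] <- res$merged
      id_map2[r2$id] <- r1$id
    } else {
      new_id <- assign_id(r2$id, "reaction")
      id_map2[r2$id] <- new_id
      r2$id <- new_id
      composed$reactions[[length(composed$reactions) + 1L]] <- r2
      added_reactions <- c(added_reactions, length(composed$reactions))
      taken <- c(taken, new_id)
    }
  }

  # --- global parameters: never merged ---
  added_parameters <- integer()
  for (p2 in m2$parameters) {
    new_id <- assign_id(p2$id, "parameter")
    id_map2[p2$id] <- new_id
    p2$id <- new_id
    composed$parameters[[length(composed$parameters) + 1L]] <- p2
    added_parameters <- c(added_parameters, length(composed$parameters))
    taken <- c(taken, new_id)
  }

  # --- unit definitions and carried constructs: never merged ---
  added_units <- integer()
  for (u2 in m2$unit_definitions) {
    new_id <- assign_id(u2$id, "other")
    id_map2[u2$id] <- new_id
    u2$id <- new_id
    composed$unit_definitions[[length(composed$unit_definitions) + 1L]] <- u2
    added_units <- c(added_units, length(composed$unit_definitions))
    taken <- c(taken, new_id)
  }
  added_other <- integer()
  for (o2 in m2$other_elements) {
    if (!is.null(o2$id)) {
      new_id <- assign_id(o2$id, "other")
      id_map2[o2$id] <- new_id
      o2$id <- new_id
    }
    composed$other_elements[[length(composed$other_elements) + 1L]] <- o2
    added_other <- c(added_other, length(composed$other_elements))
    if (!is.null(o2$id)) taken <- c(taken, o2$id)
  }

  # --- rewrite references in everything carried over from model 2 ---
  map_ref <- function(i) {
    if (is.null(i)) return(NULL)
    if (i %in% names(id_map2)) id_map2[[i]] else i
  }
  composed_ids <- model_ids(composed)
  for (i in added_compartments) {
    u <- composed$compartments[[i]]$units
    if (!is.null(u)) composed$compartments[[i]]$units <- map_ref(u)
  }
  for (i in added_parameters) {
    u <- composed$parameters[[i]]$units
    if (!is.null(u)) composed$parameters[[i]]$units <- map_ref(u)
  }
  for (i in added_species) {
    s <- composed$species[[i]]
    s$compartment <- map_ref(s$compartment)
    if (!is.null(s$substance_units))
      s$substance_units <- map_ref(s$substance_units)
    composed$species[[i]] <- s
  }
  idmap_list <- as.list(id_map2)
  for (i in added_reactions) {
    r <- composed$reactions[[i]]
    r$reactants <- lapply(r$reactants, function(ref) {
      ref$species <- map_ref(ref$species); ref })
    r$products <- lapply(r$products, function(ref) {
      ref$species <- map_ref(ref$species); ref })
    r$modifiers <- vapply(r$modifiers, map_ref, character(1),
                          USE.NAMES = FALSE)
    if (!is.null(r$kinetic_law) && !is.null(r$kinetic_law$math)) {
      locals <- element_ids(r$kinetic_law$parameters)
      r$kinetic_law$math <- rename_math_ids(r$kinetic_law$math, idmap_list,
                                            shadow = locals)
      for (ident in math_identifiers(r$kinetic_law$math)) {
        if (!ident %in% c(composed_ids, locals, "time"))
          stop_sbml("sbmlfuse_consistency_error", sprintf(
            "reaction '%s': identifier '%s' has no mapping and no declaration in the composed model",
            r$id, ident))
      }
    }
    composed$reactions[[i]] <- r
  }
  changed <- id_map2[names(id_map2) != id_map2]
  if (length(changed)) {
    for (i in added_units)
      composed$unit_definitions[[i]]$xml <-
        rewrite_opaque_ids(composed$unit_definitions[[i]]$xml,
                           as.list(changed))
    for (i in added_other)
      composed$other_elements[[i]]$xml <-
        rewrite_opaque_ids(composed$other_elements[[i]]$xml,
                           as.list(changed))
  }

  tryCatch(validate_model(composed), error = function(e) stop_sbml(
    "sbmlfuse_consistency_error",
    paste0("composed model failed validation: ", conditionMessage(e))))

  structure(list(composed = composed, id_map1 = id_map1, id_map2 = id_map2,
                 warnings = warnings, match_table = table),
            class = "merge_result")
}

#' @export
print.merge_result <- function(x, ...) {
  cat(sprintf("<merge_result> composed model '%s'\n", x$composed$id))
  print(x$composed)
  cat(sprintf("  warnings: %d\n", length(x$warnings)))
  for (w in x$warnings) cat("   ", format(w), "\n")
  invisible(x)
}

#' Serialize a composition report (warnings + id maps) to JSON
#'
#' @param result a `merge_result` from [compose()].
#' @param path optional file to write to.
#' @return JSON string, invisibly when `path` is given.
#' @export
merge_report_json <- function(result, path = NULL) {
  rep <- list(
    composed_id = result$composed$id,
    warnings = lapply(result$warnings, function(w)
      list(category = w$category, element_class = w$element_class,
           model1_id = w$ids[["model1"]], model2_id = w$ids[["model2"]],
           composed_id = w$ids[["composed"]], attribute = w$attribute,
           value1 = w$value1, value2 = w$value2, chosen = w$chosen)),
    id_map1 = as.list(result$id_map1),
    id_map2 = as.list(result$id_map2))
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
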