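# Similarity indices and the one-to-one match table driving composition.
#
# Matching order is fixed: compartments -> species -> reactions, because
# species eligibility depends on the compartment pairing and reaction
# eligibility on the species pairing. Automatic matching is greedy and
# deterministic: model-1 document order, first unclaimed model-2 candidate
# in document order; manual pairs always win.

#' Composition configuration
#'
#' @param match_mode which MIRIAM qualifiers certify identity:
#'   `"strict"` (only `is`) or `"lenient"` (also `isVersionOf`/`hasVersion`).
#' @param prefix_all prefix every surviving model-2 element id with the
#'   model-2 id, not just colliding ones.
#' @param level_mismatch `"error"` or `"warn"` on SBML level/version
#'   mismatch.
#' @param similarity similarity percentage formula: Dice
#'   `100*2|M|/(|A|+|B|)` or `"min"` `100*|M|/min(|A|,|B|)`.
#' @param composed_id,composed_name override the composed model's metadata
#'   (defaults: `"<id1>_<id2>"` and `"Composition of <name1> and <name2>"`).
#' @return a `fuse_config` list.
#' @export
fuse_config <- function(match_mode = c("strict", "lenient"),
                        prefix_all = FALSE,
                        level_mismatch = c("error", "warn"),
                        similarity = c("dice", "min"),
                        composed_id = NULL, composed_name = NULL) {
  structure(list(match_mode = match.arg(match_mode),
                 prefix_all = isTRUE(prefix_all),
                 level_mismatch = match.arg(level_mismatch),
                 similarity = match.arg(similarity),
                 composed_id = composed_id, composed_name = composed_name),
            class = "fuse_config")
}

pair_df <- function(id1 = character(), id2 = character(),
                    provenance = character()) {
  data.frame(id1 = as.character(id1), id2 = as.character(id2),
             provenance = if (length(provenance)) as.character(provenance)
                          else rep("manual", length(id1)),
             stringsAsFactors = FALSE)
}

as_pair_df <- function(x) {
  if (is.null(x)) return(pair_df())
  if (is.data.frame(x)) {
    if (!nrow(x)) return(pair_df())
    return(pair_df(x[[1]], x[[2]],
                   if (ncol(x) >= 3) x[[3]] else character()))
  }
  if (is.matrix(x)) return(pair_df(x[, 1], x[, 2]))
  if (is.list(x)) {
    if (!length(x)) return(pair_df())
    return(pair_df(vapply(x, `[[`, character(1), 1),
                   vapply(x, `[[`, character(1), 2)))
  }
  stop_sbml("sbmlfuse_match_error", "cannot interpret match pairs")
}

#' One-to-one element correspondences between two models
#'
#' A validated table of `(model1-id, model2-id)` pairs per element class,
#' with per-pair provenance (`manual`, `auto-name`, `auto-annotation`).
#' Usually produced by [auto_match()]; manual pairs can be supplied as
#' two-column data frames / matrices / lists of length-2 vectors.
#'
#' @param compartments,species,reactions pair specifications.
#' @return a `match_table`.
#' @export
match_table <- function(compartments = NULL, species = NULL,
                        reactions = NULL) {
  structure(list(compartments = as_pair_df(compartments),
                 species = as_pair_df(species),
                 reactions = as_pair_df(reactions)),
            class = "match_table")
}

#' @export
print.match_table <- function(x, ...) {
  cat("<match_table>\n")
  for (cl in c("compartments", "species", "reactions")) {
    df <- x[[cl]]
    cat(sprintf("  %s: %d pair(s)\n", cl, nrow(df)))
    if (nrow(df))
      cat(sprintf("    %s <-> %s  [%s]\n", df$id1, df$id2, df$provenance),
          sep = "")
  }
  invisible(x)
}

#' Validate a match table against two models
#'
#' Passes iff, within each element class, every model-1 id and every
#' model-2 id is used at most once (one-to-one) and all ids resolve in
#' their respective models.
#'
#' @param table a [match_table()].
#' @param m1,m2 `sbml_model` objects.
#' @return `TRUE` invisibly, or a classed `sbmlfuse_match_error`.
#' @export
validate_match_table <- function(table, m1, m2) {
  class_ids <- function(m, cl) element_ids(m[[cl]])
  for (cl in c("compartments", "species", "reactions")) {
    df <- table[[cl]]
    if (!nrow(df)) next
    for (side in 1:2) {
      ids <- df[[side]]
      known <- class_ids(if (side == 1) m1 else m2, cl)
      bad <- setdiff(ids, known)
      if (length(bad))
        stop_sbml("sbmlfuse_match_error", sprintf(
          "%s pair references unknown model-%d id '%s'", cl, side, bad[1]))
      dup <- ids[duplicated(ids)]
      if (length(dup)) {
        rows <- df[ids == dup[1], , drop = FALSE]
        stop_sbml("sbmlfuse_match_error", sprintf(
          "one-to-one violation in %s: model-%d id '%s' used in pairs (%s)",
          cl, side, dup[1],
          paste(sprintf("%s<->%s", rows$id1, rows$id2), collapse = ", ")))
      }
    }
  }
  invisible(TRUE)
}

#' Exact-name similarity report between two models
#'
#' For each element class (compartments, reactions, species) reports the
#' effective names present in both models (exact, case-sensitive match) and
#' a percentage similarity; by default the Dice coefficient
#' `100 * 2 n_matched / (n1 + n2)` (0 when both models are empty in the
#' class). Symmetric in its inputs.
#'
#' @param m1,m2 `sbml_model` objects.
#' @param formula `"dice"` (default) or `"min"` (`100*|M|/min(n1,n2)`).
#' @return a `similarity_report`: per class, `percentage`,
#'   `matched_names`, and counts `n1`, `n2`, `n_matched`.
#' @export
similarity_report <- function(m1, m2, formula = c("dice", "min")) {
  formula <- match.arg(formula)
  one <- function(cl) {
    e1 <- m1[[cl]]; e2 <- m2[[cl]]
    names1 <- unique(vapply(e1, effective_name, character(1)))
    names2 <- unique(vapply(e2, effective_name, character(1)))
    matched <- intersect(names1, names2)
    n1 <- length(e1); n2 <- length(e2); nm <- length(matched)
    pct <- if (formula == "dice") {
      if (n1 + n2 == 0) 0 else 100 * 2 * nm / (n1 + n2)
    } else {
      if (min(n1, n2) == 0) 0 else 100 * nm / min(n1, n2)
    }
    list(percentage = pct, matched_names = matched,
         counts = c(n1 = n1, n2 = n2, n_matched = nm))
  }
  structure(list(compartments = one("compartments"),
                 reactions = one("reactions"),
                 species = one("species"),
                 formula = formula),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, details = FALSE, ...) {
  for (cl in c("compartments", "reactions", "species")) {
    s <- x[[cl]]
    cat(sprintf("%-12s %6.1f%%  (%d vs %d, %d matched)\n", cl,
                s$percentage, s$counts[["n1"]], s$counts[["n2"]],
                s$counts[["n_matched"]]))
    if (details && length(s$matched_names))
      cat(paste0("  ", s$matched_names, collapse = "\n"), "\n")
  }
  invisible(x)
}

# greedy one-to-one matcher shared by the three element classes
greedy_match <- function(e1, e2, manual_df, eligible) {
  out <- manual_df
  used1 <- out$id1; used2 <- out$id2
  for (a in e1) {
    if (a$id %in% used1) next
    for (b in e2) {
      if (b$id %in% used2) next
      elig <- eligible(a, b)
      if (isTRUE(elig) || is.character(elig)) {
        prov <- if (is.character(elig)) elig else "auto-name"
        out <- rbind(out, pair_df(a$id, b$id, prov))
        used1 <- c(used1, a$id); used2 <- c(used2, b$id)
        break
      }
    }
  }
  out
}

# eligibility result: FALSE, or provenance string
name_or_annotation <- function(a, b, mode) {
  if (shared_annotation(a$annotation, b$annotation, mode))
    return("auto-annotation")
  if (identical(effective_name(a), effective_name(b))) return("auto-name")
  FALSE
}

#' Automatic compartment matching
#'
#' Keeps `manual` pairs verbatim; remaining compartments are paired when
#' their effective names are equal or they share a MIRIAM annotation.
#'
#' @param m1,m2 `sbml_model` objects.
#' @param manual a [match_table()] of manual pairs.
#' @param config a [fuse_config()].
#' @return data frame of compartment pairs (`id1`, `id2`, `provenance`).
#' @export
auto_match_compartments <- function(m1, m2, manual = match_table(),
                                    config = fuse_config()) {
  validate_match_table(manual, m1, m2)
  greedy_match(m1$compartments, m2$compartments, manual$compartments,
               function(a, b) name_or_annotation(a, b, config$match_mode))
}

#' Automatic species matching
#'
#' Species pair when they share a MIRIAM annotation, or when their
#' effective names are equal and their compartments correspond (equal ids
#' after mapping the model-2 compartment through `compartment_pairs`).
#'
#' @param compartment_pairs pair data frame from
#'   [auto_match_compartments()].
#' @inheritParams auto_match_compartments
#' @return data frame of species pairs.
#' @export
auto_match_species <- function(m1, m2, compartment_pairs,
                               manual = match_table(),
                               config = fuse_config()) {
  validate_match_table(manual, m1, m2)
  cmap <- stats::setNames(compartment_pairs$id1, compartment_pairs$id2)
  map2 <- function(cid) if (cid %in% names(cmap)) cmap[[cid]] else cid
  greedy_match(m1$species, m2$species, manual$species, function(a, b) {
    if (shared_annotation(a$annotation, b$annotation, config$match_mode))
      return("auto-annotation")
    if (identical(effective_name(a), effective_name(b)) &&
        identical(a$compartment, map2(b$compartment))) return("auto-name")
    FALSE
  })
}

ref_multiset <- function(refs, map) {
  ids <- vapply(refs, function(r) r$species, character(1))
  sort(vapply(ids, function(i) if (i %in% names(map)) map[[i]] else i,
              character(1), USE.NAMES = FALSE))
}

#' Automatic reaction matching
#'
#' Reactions pair when they share a MIRIAM annotation or have equal
#' effective names, AND their reactant species-id multisets and product
#' species-id multisets are equal after mapping model-2 species ids
#' through `species_pairs`. Stoichiometry values do not take part in the
#' equality test (differences surface as composition warnings).
#'
#' @param species_pairs pair data frame from [auto_match_species()].
#' @inheritParams auto_match_compartments
#' @return data frame of reaction pairs.
#' @export
auto_match_reactions <- function(m1, m2, species_pairs,
                                 manual = match_table(),
                                 config = fuse_config()) {
  validate_match_table(manual, m1, m2)
  smap <- stats::setNames(species_pairs$id1, species_pairs$id2)
  greedy_match(m1$reactions, m2$reactions, manual$reactions, function(a, b) {
    named <- name_or_annotation(a, b, config$match_mode)
    if (isFALSE(named)) return(FALSE)
    if (!identical(ref_multiset(a$reactants, NULL),
                   ref_multiset(b$reactants, smap))) return(FALSE)
    if (!identical(ref_multiset(a$products, NULL),
                   ref_multiset(b$products, smap))) return(FALSE)
    named
  })
}

#' Full automatic matching
#'
#' Runs compartment, species and reaction matching in their mandatory
#' order and returns the combined validated match table.
#'
#' @inheritParams auto_match_compartments
#' @return a [match_table()].
#' @export
auto_match <- function(m1, m2, manual = match_table(),
                       config = fuse_config()) {
  cp <- auto_match_compartments(m1, m2, manual, config)
  sp <- auto_match_species(m1, m2, cp, manual, config)
  rp <- auto_match_reactions(m1, m2, sp, manual, config)
  tab <- structure(list(compartments = cp, species = sp, reactions = rp),
                   class = "match_table")
  validate_match_table(tab, m1, m2)
  tab
}

#' Read a manual match table from JSON
#'
#' Format: `{"compartments": [["c1","cx"]], "species": [["S1","S1"]],
#' "reactions": []}` (any key may be absent).
#'
#' @param path JSON file path.
#' @return a [match_table()].
#' @export
read_match_json <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  get_pairs <- function(x) {
    if (is.null(x) || !length(x)) return(NULL)
    if (is.matrix(x)) x else do.call(rbind, x)
  }
  match_table(compartments = get_pairs(js$compartments),
              species = get_pairs(js$species),
              reactions = get_pairs(js$reactions))
}
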