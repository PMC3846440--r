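# MIRIAM annotation handling: RDF-in-annotation parsing, URI/URN
# normalization, and annotation-based identity.

BIO_QUAL_NS <- "http://biomodels.net/biology-qualifiers/"
MODEL_QUAL_NS <- "http://biomodels.net/model-qualifiers/"

# legacy registry names seen in older BioModels exports
COLLECTION_ALIASES <- c(
  "obo.chebi" = "chebi", "obo.go" = "go", "obo.sbo" = "sbo",
  "obo.fma" = "fma", "obo.pw" = "pw", "ec-code" = "ec-code",
  "kegg.compound" = "kegg.compound")

normalize_collection <- function(x) {
  x <- tolower(x)
  ifelse(x %in% names(COLLECTION_ALIASES), COLLECTION_ALIASES[x], x)
}

#' Normalize one MIRIAM resource URI
#'
#' Handles both the legacy URN form (`urn:miriam:obo.chebi:CHEBI%3A17234`)
#' and identifiers.org URLs (`http://identifiers.org/chebi/CHEBI:17234`,
#' including the compact-identifier form `/CHEBI:17234`). Collections are
#' lowercased and mapped through a small legacy alias table; identifiers
#' are percent-decoded with case preserved. Normalization is idempotent.
#'
#' @param uri character scalar.
#' @return `list(collection=, identifier=)` or `NULL` when the URI is not a
#'   recognizable MIRIAM resource.
#' @export
normalize_miriam_uri <- function(uri) {
  uri <- trimws(uri)
  if (grepl("^urn:miriam:", uri)) {
    rest <- sub("^urn:miriam:", "", uri)
    parts <- strsplit(rest, ":", fixed = TRUE)[[1]]
    if (length(parts) < 2) return(NULL)
    return(list(collection = normalize_collection(parts[1]),
                identifier = utils::URLdecode(
                  paste(parts[-1], collapse = ":"))))
  }
  if (grepl("^https?://(www\\.)?identifiers\\.org/", uri)) {
    path <- sub("^https?://(www\\.)?identifiers\\.org/", "", uri)
    segs <- strsplit(path, "/", fixed = TRUE)[[1]]
    segs <- segs[nzchar(segs)]
    if (!length(segs)) return(NULL)
    if (length(segs) == 1) {
      # compact identifier: collection embedded in the CURIE prefix
      curie <- utils::URLdecode(segs[1])
      if (!grepl(":", curie, fixed = TRUE)) return(NULL)
      pre <- sub(":.*$", "", curie)
      return(list(collection = normalize_collection(pre), identifier = curie))
    }
    return(list(collection = normalize_collection(segs[1]),
                identifier = utils::URLdecode(
                  paste(segs[-1], collapse = "/"))))
  }
  NULL
}

miriam_df <- function(qualifier = character(), collection = character(),
                      identifier = character()) {
  structure(data.frame(qualifier = qualifier, collection = collection,
                       identifier = identifier, stringsAsFactors = FALSE),
            class = c("miriam_keys", "data.frame"))
}

#' Extract normalized MIRIAM keys from an annotation block
#'
#' Scans the RDF embedded in an SBML annotation for BioModels biology- and
#' model-qualifier elements and returns every resource as a normalized
#' `(qualifier, collection, identifier)` key. Unparseable RDF degrades to
#' an empty set with a logged warning, never an error.
#'
#' @param block raw annotation XML as a character scalar, or `NULL`.
#' @return a `miriam_keys` data frame (possibly zero rows).
#' @export
extract_miriam <- function(block) {
  if (is.null(block) || !nzchar(block)) return(miriam_df())
  doc <- tryCatch(xml2::read_xml(block), error = function(e) NULL)
  if (is.null(doc)) {
    warning("unparseable RDF inside annotation; treated as unannotated",
            call. = FALSE)
    return(miriam_df())
  }
  quals <- xml2::xml_find_all(doc, sprintf(
    ".//*[namespace-uri()='%s' or namespace-uri()='%s']",
    BIO_QUAL_NS, MODEL_QUAL_NS))
  out <- miriam_df()
  for (q in quals) {
    qualifier <- xml2::xml_name(q)
    lis <- xml2::xml_find_all(q, ".//*[local-name()='li']")
    for (li in lis) {
      at <- xml2::xml_attrs(li)
      res <- at[grepl("(^|:)resource$", names(at))]
      if (!length(res)) next
      key <- normalize_miriam_uri(res[[1]])
      if (is.null(key)) next
      out <- rbind(out, miriam_df(qualifier, key$collection, key$identifier))
    }
  }
  unique(out)
}

identity_qualifiers <- function(mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  if (mode == "strict") "is" else c("is", "isVersionOf", "hasVersion")
}

#' Do two annotation blocks certify the same entity?
#'
#' True iff the two blocks share at least one normalized MIRIAM key under
#' an identity qualifier. In strict mode (default) only `is` certifies
#' identity; lenient mode also accepts `isVersionOf`/`hasVersion`. Two
#' unannotated elements never match (absence of evidence).
#'
#' @param a,b raw annotation XML strings or `NULL`.
#' @param mode `"strict"` or `"lenient"`.
#' @return logical scalar; symmetric in its arguments.
#' @export
shared_annotation <- function(a, b, mode = c("strict", "lenient")) {
  quals <- identity_qualifiers(match.arg(mode))
  ka <- extract_miriam(a); kb <- extract_miriam(b)
  ka <- ka[ka$qualifier %in% quals, , drop = FALSE]
  kb <- kb[kb$qualifier %in% quals, , drop = FALSE]
  if (!nrow(ka) || !nrow(kb)) return(FALSE)
  any(paste(ka$collection, ka$identifier, sep = "\r") %in%
        paste(kb$collection, kb$identifier, sep = "\r"))
}

#' Build a MIRIAM RDF annotation block
#'
#' Convenience constructor (used by tests and the generator) producing the
#' standard RDF-in-annotation markup for a set of resource URIs under one
#' qualifier.
#'
#' @param uris character vector of resource URIs.
#' @param qualifier BioModels qualifier name, e.g. `"is"`.
#' @param about value of the `rdf:about` attribute.
#' @return annotation XML as a character scalar.
#' @export
miriam_annotation <- function(uris, qualifier = "is", about = "#meta") {
  lis <- paste(sprintf("<rdf:li rdf:resource=\"%s\"/>",
                       vapply(uris, xml_escape_attr, character(1))),
               collapse = "")
  canon_fragment(sprintf(paste0(
    "<annotation><rdf:RDF ",
    "xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\" ",
    "xmlns:bqbiol=\"%s\"><rdf:Description rdf:about=\"%s\">",
    "<bqbiol:%s><rdf:Bag>%s</rdf:Bag></bqbiol:%s>",
    "</rdf:Description></rdf:RDF></annotation>"),
    BIO_QUAL_NS, about, qualifier, lis, qualifier))
}
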