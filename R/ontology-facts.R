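# Fact extraction from loaded ontology documents.

#' Retrieve license annotations from an ontology document
#'
#' Collects the values of the canonical `dcterms:license` ontology annotation
#' (the agreed convention for stating the license inside the ontology file),
#' and separately any license-like values found under near-miss legacy
#' properties (`dc:license`, `dc:rights`, `dcterms:rights`) so the openness
#' check can flag that the correct property should be used.
#'
#' @param doc An `obo_ontology` document.
#' @return A list with `candidates` (character vector of values under
#'   `dcterms:license`) and `wrong_property_uses` (character vector of the
#'   near-miss property IRIs that carried a value).
#' @export
get_license_annotations <- function(doc) {
  stopifnot(inherits(doc, "obo_ontology"))
  ann <- doc$annotations
  candidates <- ann[[IRI_LICENSE]] %||% character(0)
  near <- license_near_miss_properties()
  used <- near[vapply(near, function(p) length(ann[[p]] %||% character(0)) > 0L,
                      logical(1))]
  list(candidates = candidates, wrong_property_uses = unname(used))
}

#' Extract a release date from a version IRI
#'
#' OBO version IRIs conventionally embed the release date as a
#' `YYYY-MM-DD` path segment
#' (`http://purl.obolibrary.org/obo/<id>/2021-04-06/<id>.owl`). Returns that
#' date when a path segment matches the pattern *and* is a real calendar
#' date; otherwise `NULL`. `"2021-02-30"` is rejected.
#'
#' @param version_iri The version IRI string.
#' @return A `Date`, or `NULL` when no valid date segment exists.
#' @examples
#' parse_version_date("http://purl.obolibrary.org/obo/exf/2021-04-06/exf.owl")
#' parse_version_date("http://purl.obolibrary.org/obo/exf/v1.2/exf.owl") # NULL
#' @export
parse_version_date <- function(version_iri) {
  if (is.null(version_iri) || !is_scalar_chr(version_iri)) {
    return(NULL)
  }
  segments <- strsplit(version_iri, "/", fixed = TRUE)[[1]]
  hits <- segments[grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", segments)]
  for (h in hits) {
    d <- as.Date(h, format = "%Y-%m-%d")
    # as.Date normalizes some impossible dates on certain platforms; require
    # the round-trip to reproduce the segment exactly
    if (!is.na(d) && format(d, "%Y-%m-%d") == h) {
      return(d)
    }
  }
  NULL
}
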