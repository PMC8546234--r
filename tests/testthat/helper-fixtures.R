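# Shared helpers: the canonical OBI example record, small Turtle documents
# built as text (so tests exercise the public loader, not the serializer),
# and a status rank for monotonicity assertions.

obi_entry <- function() {
  registry_entry(
    id = "obi",
    title = "Ontology for Biomedical Investigations",
    homepage = "http://obi-ontology.org/",
    contact = list(label = "Bjoern Peters", email = "bpeters@lji.org"),
    description = paste("An integrated ontology for the description of life",
                        "science and clinical investigations"),
    license = list(label = "CC-BY 4.0",
                   url = "https://creativecommons.org/licenses/by/4.0/"),
    products = list(list(id = "obi.owl")),
    activity_status = "active",
    is_obsolete = FALSE,
    domain = "investigations",
    usages = list(list(user = "https://example.org/immport")),
    tracker = "https://github.com/obi-ontology/obi/issues"
  )
}

ttl_prefixes <- paste(
  "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
  "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
  "@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .",
  "@prefix dcterms: <http://purl.org/dc/terms/> .",
  "@prefix dc: <http://purl.org/dc/elements/1.1/> .",
  "@prefix obo: <http://purl.obolibrary.org/obo/> .",
  sep = "\n"
)

# one Turtle frame per entity description: list(iri, type, label, def, deprecated)
ttl_doc <- function(..., ontology_iri = "http://purl.obolibrary.org/obo/exf.owl",
                    version_iri = NULL, license = NULL,
                    license_property = "dcterms:license") {
  frames <- list(...)
  header <- sprintf("<%s> a owl:Ontology", ontology_iri)
  if (!is.null(version_iri)) {
    header <- c(header, sprintf("    owl:versionIRI <%s>", version_iri))
  }
  if (!is.null(license)) {
    header <- c(header, sprintf("    %s <%s>", license_property, license))
  }
  body <- vapply(frames, function(f) {
    lines <- sprintf("<%s> a %s", f$iri, f$type %||% "owl:Class")
    for (l in f$label %||% character()) {
      lines <- c(lines, sprintf("    rdfs:label \"%s\"", l))
    }
    for (d in f$def %||% character()) {
      lines <- c(lines, sprintf("    obo:IAO_0000115 \"%s\"", d))
    }
    if (isTRUE(f$deprecated)) {
      lines <- c(lines, "    owl:deprecated \"true\"^^xsd:boolean")
    }
    paste0(paste(lines, collapse = " ;\n"), " .")
  }, character(1))
  paste(c(ttl_prefixes, "", paste0(paste(header, collapse = " ;\n"), " ."),
          "", body), collapse = "\n")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

status_rank <- c(PASS = 1L, INFO = 2L, WARN = 3L, ERROR = 4L)

row_status_vec <- function(row) {
  vapply(row$results, function(r) r$status, character(1))
}

# independent calendar oracle: month-length table with the Gregorian
# leap-year rule, no date classes involved
is_real_calendar_date <- function(y, m, d) {
  if (m < 1 || m > 12 || d < 1) return(FALSE)
  leap <- (y %% 4 == 0 && y %% 100 != 0) || y %% 400 == 0
  lengths <- c(31L, if (leap) 29L else 28L, 31L, 30L, 31L, 30L, 31L, 31L,
               30L, 31L, 30L, 31L)
  d <= lengths[m]
}
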