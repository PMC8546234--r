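# Serializers for ontology documents. Used by the fixture generator and for
# the fact-level round-trip guarantee (write then load preserves entity
# count, categories, labels, definitions and the version IRI). Output is a
# pure function of the document: no timestamps, fixed prefix table, entities
# in document order.

ttl_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

.ttl_category_terms <- c(
  class = "owl:Class", object_property = "owl:ObjectProperty",
  data_property = "owl:DatatypeProperty",
  annotation_property = "owl:AnnotationProperty",
  named_individual = "owl:NamedIndividual"
)

serialize_turtle <- function(doc) {
  out <- c(
    "@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .",
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .",
    "@prefix dcterms: <http://purl.org/dc/terms/> .",
    "@prefix dc: <http://purl.org/dc/elements/1.1/> .",
    "@prefix obo: <http://purl.obolibrary.org/obo/> .",
    ""
  )
  if (!is.null(doc$ontology_iri)) {
    lines <- sprintf("<%s> a owl:Ontology", doc$ontology_iri)
    if (!is.null(doc$version_iri)) {
      lines <- c(lines, sprintf("    owl:versionIRI <%s>", doc$version_iri))
    }
    for (p in names(doc$annotations)) {
      for (v in doc$annotations[[p]]) {
        val <- if (is_url_string(v)) sprintf("<%s>", v)
               else sprintf("\"%s\"", ttl_escape(v))
        lines <- c(lines, sprintf("    <%s> %s", p, val))
      }
    }
    out <- c(out, paste0(paste(lines, collapse = " ;\n"), " ."), "")
  }
  for (e in doc$entities) {
    lines <- sprintf("<%s> a %s", e$iri, .ttl_category_terms[[e$category]])
    for (l in e$labels) {
      lines <- c(lines, sprintf("    rdfs:label \"%s\"", ttl_escape(l)))
    }
    for (d in e$definitions) {
      lines <- c(lines, sprintf("    obo:IAO_0000115 \"%s\"", ttl_escape(d)))
    }
    if (isTRUE(e$deprecated)) {
      lines <- c(lines,
                 "    owl:deprecated \"true\"^^xsd:boolean")
    }
    out <- c(out, paste0(paste(lines, collapse = " ;\n"), " ."), "")
  }
  paste(out, collapse = "\n")
}

.xml_category_terms <- c(
  class = "owl:Class", object_property = "owl:ObjectProperty",
  data_property = "owl:DatatypeProperty",
  annotation_property = "owl:AnnotationProperty",
  named_individual = "owl:NamedIndividual"
)

serialize_rdfxml <- function(doc) {
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<rdf:RDF xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\"",
    "         xmlns:rdfs=\"http://www.w3.org/2000/01/rdf-schema#\"",
    "         xmlns:owl=\"http://www.w3.org/2002/07/owl#\"",
    "         xmlns:xsd=\"http://www.w3.org/2001/XMLSchema#\"",
    "         xmlns:dcterms=\"http://purl.org/dc/terms/\"",
    "         xmlns:dc=\"http://purl.org/dc/elements/1.1/\"",
    "         xmlns:obo=\"http://purl.obolibrary.org/obo/\">"
  )
  if (!is.null(doc$ontology_iri)) {
    out <- c(out, sprintf("  <owl:Ontology rdf:about=\"%s\">",
                          xml_escape(doc$ontology_iri)))
    if (!is.null(doc$version_iri)) {
      out <- c(out, sprintf("    <owl:versionIRI rdf:resource=\"%s\"/>",
                            xml_escape(doc$version_iri)))
    }
    for (p in names(doc$annotations)) {
      qn <- rdfxml_qname(p)
      for (v in doc$annotations[[p]]) {
        if (is_url_string(v)) {
          out <- c(out, sprintf("    <%s rdf:resource=\"%s\"/>", qn,
                                xml_escape(v)))
        } else {
          out <- c(out, sprintf("    <%s>%s</%s>", qn, xml_escape(v), qn))
        }
      }
    }
    out <- c(out, "  </owl:Ontology>")
  }
  for (e in doc$entities) {
    tag <- .xml_category_terms[[e$category]]
    out <- c(out, sprintf("  <%s rdf:about=\"%s\">", tag, xml_escape(e$iri)))
    for (l in e$labels) {
      out <- c(out, sprintf("    <rdfs:label>%s</rdfs:label>", xml_escape(l)))
    }
    for (d in e$definitions) {
      out <- c(out, sprintf("    <obo:IAO_0000115>%s</obo:IAO_0000115>",
                            xml_escape(d)))
    }
    if (isTRUE(e$deprecated)) {
      out <- c(out, paste0("    <owl:deprecated rdf:datatype=",
                           "\"http://www.w3.org/2001/XMLSchema#boolean\">",
                           "true</owl:deprecated>"))
    }
    out <- c(out, sprintf("  </%s>", tag))
  }
  out <- c(out, "</rdf:RDF>", "")
  paste(out, collapse = "\n")
}

# map a full property IRI onto the fixed prefix table for RDF/XML elements
rdfxml_qname <- function(iri) {
  table <- c(rdf = NS_RDF, rdfs = NS_RDFS, owl = NS_OWL, xsd = NS_XSD,
             dcterms = NS_DCTERMS, dc = NS_DC, obo = NS_OBO)
  for (p in names(table)) {
    if (startsWith(iri, table[[p]])) {
      local <- substring(iri, nchar(table[[p]]) + 1L)
      if (grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", local)) {
        return(paste0(p, ":", local))
      }
    }
  }
  stop("cannot express property as a QName for RDF/XML: ", iri)
}

#' Serialize an ontology document
#'
#' Writes the fact model back out as Turtle or RDF/XML. Loading the output
#' reproduces the document's facts (entity set, categories, labels,
#' definitions, deprecation, version IRI, ontology annotations). Output is
#' deterministic: the same document always yields the same bytes.
#'
#' @param doc An `obo_ontology` document.
#' @param path Output file path; when `NULL` the serialization is returned
#'   as a string.
#' @param format `"turtle"` or `"rdfxml"`.
#' @return The serialized text, invisibly when written to `path`.
#' @export
write_ontology <- function(doc, path = NULL, format = c("turtle", "rdfxml")) {
  stopifnot(inherits(doc, "obo_ontology"))
  format <- match.arg(format)
  text <- switch(format, turtle = serialize_turtle(doc),
                 rdfxml = serialize_rdfxml(doc))
  if (!is.null(path)) {
    writeLines(text, path, useBytes = TRUE)
    return(invisible(text))
  }
  text
}
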