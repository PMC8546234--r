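minimal_rdfxml <- paste(
  '<?xml version="1.0"?>',
  '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
  '         xmlns:owl="http://www.w3.org/2002/07/owl#">',
  '  <owl:Class rdf:about="http://purl.obolibrary.org/obo/EXF_0000001"/>',
  '</rdf:RDF>', sep = "\n")

test_that("a minimal RDF/XML document loads with one class", {
  doc <- load_ontology(minimal_rdfxml, text = TRUE, format = "rdfxml")
  expect_s3_class(doc, "obo_ontology")
  expect_length(doc$entities, 1)
  expect_identical(doc$entities[[1]]$category, "class")
})

test_that("truncated documents yield a format error, not an R error", {
  broken <- substr(minimal_rdfxml, 1, nchar(minimal_rdfxml) - 30)
  res <- load_ontology(broken, text = TRUE, format = "rdfxml")
  expect_true(is_format_error(res))
  expect_match(res$message, ".")
  # same for Turtle cut inside an IRI
  ttl <- ttl_doc(list(iri = "http://purl.obolibrary.org/obo/EXF_0000001"))
  res2 <- load_ontology(substr(ttl, 1, nchar(ttl) - 20), text = TRUE,
                        format = "turtle")
  expect_true(is_format_error(res2))
  # an unreadable path is an I/O error, distinct from a format error
  expect_error(load_ontology(file.path(tempdir(), "nope.owl")),
               "no such file")
})

test_that("the 5-term fixture loads with hand-enumerated facts", {
  # 3 classes (third deprecated), 1 object property, 1 annotation property
  fx <- generate_fixture(fixture_spec(n_classes = 3, n_object_properties = 1,
                                      n_annotation_properties = 1,
                                      n_deprecated = 1))
  doc <- load_ontology(fx$ontology_text, text = TRUE, format = "turtle")
  expect_length(doc$entities, 5)
  cats <- sort(vapply(doc$entities, `[[`, character(1), "category"))
  expect_identical(unname(cats),
                   c("annotation_property", "class", "class", "class",
                     "object_property"))
  dep <- vapply(doc$entities, `[[`, logical(1), "deprecated")
  expect_identical(sum(dep), 1L)
  expect_true(doc$entities[["http://purl.obolibrary.org/obo/EXF_0000003"]]$deprecated)
  expect_identical(doc$version_iri,
                   "http://purl.obolibrary.org/obo/exf/2021-03-02/exf.owl")
})

test_that("loading the same bytes twice is deterministic", {
  fx <- generate_fixture(fixture_spec())
  d1 <- load_ontology(fx$ontology_text, text = TRUE, format = "turtle")
  d2 <- load_ontology(fx$ontology_text, text = TRUE, format = "turtle")
  expect_identical(d1, d2)
})

test_that("serialize-then-load preserves facts in both formats", {
  fx <- generate_fixture(fixture_spec(n_classes = 4, n_object_properties = 2))
  doc <- fx$document
  for (fmt in c("turtle", "rdfxml")) {
    back <- load_ontology(write_ontology(doc, format = fmt), text = TRUE,
                          format = fmt)
    expect_setequal(names(back$entities), names(doc$entities))
    expect_identical(back$version_iri, doc$version_iri)
    for (iri in names(doc$entities)) {
      a <- doc$entities[[iri]]
      b <- back$entities[[iri]]
      expect_identical(b$category, a$category, label = iri)
      expect_identical(b$labels, a$labels, label = iri)
      expect_identical(b$definitions, a$definitions, label = iri)
      expect_identical(b$deprecated, a$deprecated, label = iri)
    }
  }
})

test_that("format sniffing distinguishes RDF/XML from Turtle content", {
  expect_s3_class(load_ontology(minimal_rdfxml, text = TRUE), "obo_ontology")
  ttl <- ttl_doc(list(iri = "http://purl.obolibrary.org/obo/EXF_0000001"))
  expect_s3_class(load_ontology(ttl, text = TRUE), "obo_ontology")
})

test_that("turtle reader handles escapes, language tags and comment lines", {
  ttl <- paste(
    ttl_prefixes,
    "# a comment with a \" quote and <angle>",
    '<http://purl.obolibrary.org/obo/exf.owl> a owl:Ontology .',
    '<http://purl.obolibrary.org/obo/EXF_0000001> a owl:Class ;',
    '    rdfs:label "said \\"hi\\"@home"@en ;',
    '    obo:IAO_0000115 "line one\\nline two" .',
    sep = "\n")
  doc <- load_ontology(ttl, text = TRUE, format = "turtle")
  e <- doc$entities[["http://purl.obolibrary.org/obo/EXF_0000001"]]
  expect_identical(e$labels, 'said "hi"@home')
  expect_identical(e$definitions, "line one\nline two")
})

test_that("license annotations split canonical and near-miss properties", {
  url <- "https://creativecommons.org/licenses/by/4.0/"
  good <- load_ontology(ttl_doc(license = url), text = TRUE)
  ann <- get_license_annotations(good)
  expect_identical(ann$candidates, url)
  expect_length(ann$wrong_property_uses, 0)

  legacy <- load_ontology(ttl_doc(license = url,
                                  license_property = "dc:license"),
                          text = TRUE)
  ann2 <- get_license_annotations(legacy)
  expect_length(ann2$candidates, 0)
  expect_identical(ann2$wrong_property_uses,
                   "http://purl.org/dc/elements/1.1/license")

  bare <- load_ontology(ttl_doc(), text = TRUE)
  ann3 <- get_license_annotations(bare)
  expect_length(ann3$candidates, 0)
  expect_length(ann3$wrong_property_uses, 0)
})

test_that("version dates parse only for real calendar date segments", {
  expect_identical(
    parse_version_date("http://purl.obolibrary.org/obo/exf/2021-04-06/exf.owl"),
    as.Date("2021-04-06"))
  expect_null(
    parse_version_date("http://purl.obolibrary.org/obo/exf/v1.2/exf.owl"))
  # impossible dates are rejected in agreement with the calendar oracle
  for (seg in c("2021-02-30", "2021-13-01", "2020-02-29", "2019-02-29",
                "2021-04-31", "2000-02-29", "1900-02-29")) {
    iri <- sprintf("http://purl.obolibrary.org/obo/exf/%s/exf.owl", seg)
    parts <- as.integer(strsplit(seg, "-")[[1]])
    real <- is_real_calendar_date(parts[1], parts[2], parts[3])
    got <- parse_version_date(iri)
    if (real) {
      expect_identical(got, as.Date(seg), label = seg)
    } else {
      expect_null(got, label = seg)
    }
  }
})

test_that("IRIs without a dated segment never yield a date", {
  set.seed(20210406)
  pools <- c(letters, LETTERS, as.character(0:9), "-", "_", ".", "/")
  for (i in 1:200) {
    seg <- paste(sample(pools, sample(1:12, 1), replace = TRUE),
                 collapse = "")
    if (grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", seg)) next
    iri <- sprintf("http://purl.obolibrary.org/obo/x/%s/x.owl", seg)
    expect_null(parse_version_date(iri), label = iri)
  }
})
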