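cc_by <- "https://creativecommons.org/licenses/by/4.0/"
cc0 <- "https://creativecommons.org/publicdomain/zero/1.0/"

test_that("openness requires an accepted license stated identically on both sides", {
  e <- obi_entry()
  doc <- load_ontology(ttl_doc(license = cc_by), text = TRUE)
  expect_identical(check_open(e, doc)$status, "PASS")

  # registry and ontology disagree
  doc0 <- load_ontology(ttl_doc(license = cc0), text = TRUE)
  r <- check_open(e, doc0)
  expect_identical(r$status, "ERROR")
  expect_match(paste(r$messages, collapse = " "), "same")

  # non-CC license in the registry
  e2 <- obi_entry()
  e2$license <- list(label = "GPL-3.0",
                     url = "https://www.gnu.org/licenses/gpl-3.0.en.html")
  expect_identical(check_open(e2, doc)$status, "ERROR")

  # scheme/trailing-slash spelling differences are not mismatches
  doc_http <- load_ontology(
    ttl_doc(license = "http://creativecommons.org/licenses/by/4.0"),
    text = TRUE)
  expect_identical(check_open(e, doc_http)$status, "PASS")

  # wrong property: the license exists but not under dcterms:license
  legacy <- load_ontology(ttl_doc(license = cc_by,
                                  license_property = "dc:license"),
                          text = TRUE)
  r2 <- check_open(e, legacy)
  expect_identical(r2$status, "ERROR")
  expect_match(paste(r2$messages, collapse = " "), "dcterms:license")

  # no document at all: registry side checked, ontology side is the error
  r3 <- check_open(e, NULL)
  expect_identical(r3$status, "ERROR")
  expect_match(paste(r3$messages, collapse = " "), "not found")
})

test_that("common format equals loadability", {
  fx <- generate_fixture(fixture_spec())
  doc <- load_ontology(fx$ontology_text, text = TRUE, format = "turtle")
  expect_identical(check_format(doc)$status, "PASS")
  bad <- load_ontology("not turtle at all {{{", text = TRUE,
                       format = "turtle")
  r <- check_format(bad)
  expect_identical(r$status, "ERROR")
  # an empty-but-well-formed ontology still passes: loadability only
  empty <- load_ontology(ttl_doc(), text = TRUE)
  expect_identical(check_format(empty)$status, "PASS")
})

test_that("entity IRIs must be prefix + underscore + numeric local id", {
  base <- "http://purl.obolibrary.org/obo/"
  doc <- load_ontology(ttl_doc(
    list(iri = paste0(base, "EXF_0000001")),
    list(iri = paste0(base, "EXF_0000002"))), text = TRUE)
  r <- check_uris(doc, "EXF")
  expect_identical(r$status, "PASS")
  expect_identical(r$metrics$checked, 2L)

  doc2 <- load_ontology(ttl_doc(
    list(iri = paste0(base, "EXF0000003"))), text = TRUE)
  r2 <- check_uris(doc2, "EXF")
  expect_identical(r2$status, "ERROR")
  expect_identical(r2$metrics$missing_underscore, 1L)

  doc3 <- load_ontology(ttl_doc(
    list(iri = paste0(base, "EXF_abc"))), text = TRUE)
  r3 <- check_uris(doc3, "EXF")
  expect_identical(r3$status, "ERROR")
  expect_identical(r3$metrics$nonnumeric_local_id, 1L)

  # foreign term reuse is skipped, annotation properties are excluded
  doc4 <- load_ontology(ttl_doc(
    list(iri = paste0(base, "GO_0008150")),
    list(iri = paste0(base, "exf#note"), type = "owl:AnnotationProperty"),
    list(iri = paste0(base, "EXF_0000001"))), text = TRUE)
  r4 <- check_uris(doc4, "EXF")
  expect_identical(r4$status, "PASS")
  expect_identical(r4$metrics$checked, 1L)
  expect_identical(r4$metrics$skipped_foreign, 1L)

  # a case-insensitive near-miss of the canonical prefix is reported
  doc5 <- load_ontology(ttl_doc(
    list(iri = paste0(base, "exf_0000009"))), text = TRUE)
  r5 <- check_uris(doc5, "EXF")
  expect_identical(r5$status, "ERROR")
  expect_identical(r5$metrics$case_mismatch, 1L)
})

test_that("versioning grades dated, undated and absent version IRIs", {
  dated <- load_ontology(ttl_doc(
    version_iri = "http://purl.obolibrary.org/obo/exf/2021-04-06/exf.owl"),
    text = TRUE)
  expect_identical(check_versioning(dated)$status, "PASS")
  undated <- load_ontology(ttl_doc(
    version_iri = "http://purl.obolibrary.org/obo/exf/v1.2/exf.owl"),
    text = TRUE)
  expect_identical(check_versioning(undated)$status, "INFO")
  absent <- load_ontology(ttl_doc(), text = TRUE)
  expect_identical(check_versioning(absent)$status, "ERROR")
})

test_that("scope compares domains across active, non-obsolete peers", {
  peers <- list(
    registry_entry(id = "aao", domain = "anatomy"),
    registry_entry(id = "hlo", domain = "health")
  )
  e <- obi_entry()
  e$domain <- "anatomy"
  r <- check_scope(e, peers)
  expect_identical(r$status, "INFO")
  expect_match(r$messages, "aao")

  e$domain <- "phenotype"
  expect_identical(check_scope(e, peers)$status, "PASS")

  e$domain <- NULL
  expect_identical(check_scope(e, peers)$status, "ERROR")

  # inactive or obsolete peers never count as sharing
  e$domain <- "anatomy"
  peers[[1]]$activity_status <- "inactive"
  expect_identical(check_scope(e, peers)$status, "PASS")
  peers[[1]]$activity_status <- "active"
  peers[[1]]$is_obsolete <- TRUE
  expect_identical(check_scope(e, peers)$status, "PASS")

  # matching is case-insensitive
  peers[[1]]$is_obsolete <- FALSE
  peers[[1]]$domain <- "Anatomy"
  expect_identical(check_scope(e, peers)$status, "INFO")
})

test_that("definition tallies match the hand-counted four-class fixture", {
  base <- "http://purl.obolibrary.org/obo/EXF_000000"
  doc <- load_ontology(ttl_doc(
    list(iri = paste0(base, "1"), label = "a"),                  # missing
    list(iri = paste0(base, "2"), label = "b", def = "shared"),  # duplicate
    list(iri = paste0(base, "3"), label = "c", def = "shared"),  # duplicate
    list(iri = paste0(base, "4"), label = "d", def = "unique")),
    text = TRUE)
  r <- check_definitions(doc)
  expect_identical(r$metrics$missing_definition, 1L)
  expect_identical(r$metrics$duplicate_definition, 2L)
  expect_identical(r$metrics$multiple_definitions, 0L)
  expect_identical(r$status, "ERROR")
  # duplicates list the offending IRIs in the findings
  expect_match(paste(r$messages, collapse = " "), paste0(base, "2"))
})

test_that("definition edge cases: empty ontology, multiple values, deprecation exemption", {
  empty <- load_ontology(ttl_doc(), text = TRUE)
  r0 <- check_definitions(empty)
  expect_identical(r0$status, "PASS")
  expect_true(all(unlist(r0$metrics) == 0L))

  base <- "http://purl.obolibrary.org/obo/EXF_000000"
  multi <- load_ontology(ttl_doc(
    list(iri = paste0(base, "1"), label = "a", def = c("one", "two"))),
    text = TRUE)
  r1 <- check_definitions(multi)
  expect_identical(r1$metrics$multiple_definitions, 1L)
  expect_identical(r1$metrics$duplicate_definition, 0L)
  expect_identical(r1$status, "ERROR")

  # a deprecated term without a definition is exempt from the missing count
  dep <- load_ontology(ttl_doc(
    list(iri = paste0(base, "1"), label = "a", deprecated = TRUE)),
    text = TRUE)
  expect_identical(check_definitions(dep)$status, "PASS")

  # severities follow the profile
  soft <- check_config(definition_severity = c(missing = "INFO",
                                               multiple = "ERROR",
                                               duplicate = "ERROR"))
  missing_only <- load_ontology(ttl_doc(
    list(iri = paste0(base, "1"), label = "a")), text = TRUE)
  expect_identical(check_definitions(missing_only, soft)$status, "INFO")
})

test_that("naming conventions reuse the engine over labels with ERROR defaults", {
  base <- "http://purl.obolibrary.org/obo/EXF_000000"
  doc <- load_ontology(ttl_doc(
    list(iri = paste0(base, "1"), def = "d1"),                        # no label
    list(iri = paste0(base, "2"), label = "same", def = "d2"),
    list(iri = paste0(base, "3"), label = "same", def = "d3"),
    list(iri = paste0(base, "4"), label = c("x", "y"), def = "d4")),
    text = TRUE)
  r <- check_naming(doc)
  expect_identical(r$metrics$missing_label, 1L)
  expect_identical(r$metrics$duplicate_label, 2L)
  expect_identical(r$metrics$multiple_labels, 1L)
  expect_identical(r$status, "ERROR")
})

test_that("relations classify RO reuse, local properties and foreign properties", {
  ro <- load_ro_index()
  base <- "http://purl.obolibrary.org/obo/"
  reused <- load_ontology(ttl_doc(
    list(iri = paste0(base, "RO_0002202"), type = "owl:ObjectProperty",
         label = "develops from", def = "d")), text = TRUE)
  r <- check_relations(reused, ro, "EXF")
  expect_identical(r$status, "PASS")
  expect_identical(r$metrics$reused, 1L)

  # a local property shadowing an RO label gets the RO IRI suggested
  shadow <- load_ontology(ttl_doc(
    list(iri = paste0(base, "EXF_8000001"), type = "owl:ObjectProperty",
         label = "part of", def = "d")), text = TRUE)
  r2 <- check_relations(shadow, ro, "EXF")
  expect_identical(r2$status, "WARN")
  expect_identical(r2$metrics$label_shadowed, 1L)
  expect_match(r2$messages, "BFO_0000050")

  # a local property with its own label is fine
  local <- load_ontology(ttl_doc(
    list(iri = paste0(base, "EXF_8000002"), type = "owl:ObjectProperty",
         label = "exf linked to", def = "d")), text = TRUE)
  expect_identical(check_relations(local, ro, "EXF")$status, "PASS")

  foreign <- load_ontology(ttl_doc(
    list(iri = "http://example.com/vocab/related_to",
         type = "owl:ObjectProperty", label = "related to", def = "d")),
    text = TRUE)
  r3 <- check_relations(foreign, ro, "EXF")
  expect_identical(r3$status, "WARN")
  expect_identical(r3$metrics$foreign_non_ro, 1L)

  # vacuous pass without properties; empty index is a configuration error
  none <- load_ontology(ttl_doc(
    list(iri = paste0(base, "EXF_0000001"), label = "c", def = "d")),
    text = TRUE)
  expect_identical(check_relations(none, ro, "EXF")$status, "PASS")
  expect_error(check_relations(none, list(), "EXF"), "configuration|index")
})

test_that("documentation checks homepage/description presence and resolution", {
  e <- obi_entry()
  offline <- check_context(offline = TRUE)
  expect_identical(check_documentation(e, offline)$status, "INFO")

  ok200 <- check_context(offline = FALSE, http_prober = function(url) 200L)
  expect_identical(check_documentation(e, ok200)$status, "PASS")

  nf404 <- check_context(offline = FALSE, http_prober = function(url) 404L)
  r <- check_documentation(e, nf404)
  expect_identical(r$status, "ERROR")
  expect_match(r$messages, "404")

  # 399 is still a pass; 400 is the first failing status
  expect_identical(check_documentation(
    e, check_context(offline = FALSE, http_prober = function(url) 399L)
  )$status, "PASS")
  expect_identical(check_documentation(
    e, check_context(offline = FALSE, http_prober = function(url) 400L)
  )$status, "ERROR")

  # transport failure counts as non-resolution
  boom <- check_context(offline = FALSE,
                        http_prober = function(url) stop("timeout"))
  r2 <- check_documentation(e, boom)
  expect_identical(r2$status, "ERROR")
  expect_match(r2$messages, "timeout")

  e$homepage <- NULL
  expect_identical(check_documentation(e, offline)$status, "ERROR")
  e <- obi_entry()
  e$description <- NULL
  expect_identical(check_documentation(e, offline)$status, "ERROR")
})

test_that("registry-presence principles check usages, contact and tracker", {
  e <- obi_entry()
  expect_identical(check_registry_presence(e, "FP9")$status, "PASS")
  expect_identical(check_registry_presence(e, "FP11")$status, "PASS")
  expect_identical(check_registry_presence(e, "FP20")$status, "PASS")

  e$usages <- list()
  expect_identical(check_registry_presence(e, "FP9")$status, "ERROR")

  e <- obi_entry()
  e$contact$label <- "bpeters@lji.org"
  expect_identical(check_registry_presence(e, "FP11")$status, "ERROR")

  e <- obi_entry()
  e$tracker <- NULL
  expect_identical(check_registry_presence(e, "FP20")$status, "ERROR")

  expect_error(check_registry_presence(obi_entry(), "FP6"), "FP9")
})

test_that("maintenance transitions occur exactly at the year boundaries", {
  today <- as.Date("2021-05-01")
  make_doc <- function(date_str) {
    load_ontology(ttl_doc(version_iri = sprintf(
      "http://purl.obolibrary.org/obo/exf/%s/exf.owl", date_str)),
      text = TRUE)
  }
  st <- function(d) check_maintenance(make_doc(d), today)$status
  expect_identical(st("2021-03-02"), "PASS")    # 60 days old
  expect_identical(st("2019-05-01"), "PASS")    # exactly 2 years: boundary
  expect_identical(st("2019-04-30"), "WARN")    # one day past the boundary
  expect_identical(st("2018-05-01"), "WARN")    # exactly 3 years
  expect_identical(st("2018-04-30"), "ERROR")   # one day past
  expect_identical(st("2017-05-01"), "ERROR")   # 4 years old
  expect_identical(st("2021-06-01"), "WARN")    # future date

  undated <- load_ontology(ttl_doc(
    version_iri = "http://purl.obolibrary.org/obo/exf/v1.2/exf.owl"),
    text = TRUE)
  expect_identical(check_maintenance(undated, today)$status, "WARN")

  # custom thresholds move the boundaries with them
  cfg <- check_config(warn_years = 1, error_years = 2)
  expect_identical(check_maintenance(make_doc("2020-05-01"), today, cfg)$status,
                   "PASS")
  expect_identical(check_maintenance(make_doc("2020-04-30"), today, cfg)$status,
                   "WARN")
  expect_identical(check_maintenance(make_doc("2019-04-30"), today, cfg)$status,
                   "ERROR")
})

test_that("worst-of aggregation follows the status order and skips NA", {
  expect_identical(worst_status(c("PASS", "PASS")), "PASS")
  expect_identical(worst_status(c("PASS", "INFO")), "INFO")
  expect_identical(worst_status(c("INFO", "WARN", "PASS")), "WARN")
  expect_identical(worst_status(c("WARN", "ERROR")), "ERROR")
  expect_identical(worst_status(c("NA", "PASS")), "PASS")
  expect_identical(worst_status(c("NA", "NA")), "NA")
  expect_error(worst_status("BOGUS"), "unknown")
})

test_that("a full evaluation run covers all 13 principles in order", {
  fx <- generate_fixture(fixture_spec())
  row <- evaluate_fixture(fx)
  expect_identical(names(row$results), principles()$id)
  expect_identical(row$summary, "INFO")
  expect_false("FP10" %in% names(row$results))

  # registry-only checks still run when the ontology is unloadable
  ctx <- check_context(today = fx$today, peers = fx$peers)
  bad <- load_ontology("garbage {{{", text = TRUE, format = "turtle")
  row2 <- evaluate_ontology(fx$entry, bad, ctx)
  st <- row_status_vec(row2)
  expect_identical(unname(st["FP9"]), "PASS")
  expect_identical(unname(st["FP2"]), "ERROR")
  expect_identical(unname(st["FP6"]), "ERROR")
  expect_match(row2$results$FP6$messages, "not loadable")
})

test_that("seeding a violation never improves any cell (monotonicity)", {
  clean <- row_status_vec(evaluate_fixture(generate_fixture(fixture_spec())))
  for (k in violation_catalog()$kind) {
    fx <- generate_fixture(fixture_spec(violations = k))
    st <- row_status_vec(evaluate_fixture(fx))
    expect_true(all(status_rank[st] >= status_rank[clean]), label = k)
  }
})
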