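test_that("the canonical OBI record parses into its modeled fields", {
  yml <- serialize_registry(obi_entry())
  entries <- parse_registry(text = yml)
  expect_length(entries, 1)
  e <- entries[[1]]
  expect_identical(e$id, "obi")
  expect_identical(e$title, "Ontology for Biomedical Investigations")
  expect_identical(e$contact$label, "Bjoern Peters")
  expect_identical(e$contact$email, "bpeters@lji.org")
  expect_identical(e$license$label, "CC-BY 4.0")
  expect_identical(e$license$url,
                   "https://creativecommons.org/licenses/by/4.0/")
  expect_identical(e$activity_status, "active")
  expect_false(e$is_obsolete)
})

test_that("empty documents and duplicate ids are handled per contract", {
  expect_identical(parse_registry(text = ""), list())
  expect_identical(parse_registry(text = "   \n"), list())
  two <- paste(
    "ontologies:",
    "  - id: obi",
    "    title: one",
    "  - id: obi",
    "    title: two", sep = "\n")
  expect_error(parse_registry(text = two), "duplicate")
  expect_error(parse_registry(text = "a: [unclosed"), "malformed")
})

test_that("unknown fields are preserved, never rejected", {
  yml <- paste(
    "id: exo",
    "title: T",
    "custom_tag: kept",
    "another: [1, 2]", sep = "\n")
  e <- parse_registry(text = yml)[[1]]
  expect_identical(e$extra$custom_tag, "kept")
  expect_length(e$extra$another, 2)
  # and they survive serialization
  e2 <- parse_registry(text = serialize_registry(e))[[1]]
  expect_identical(e2$extra$custom_tag, "kept")
})

test_that("parse/serialize round-trips the modeled fields", {
  e <- obi_entry()
  e2 <- parse_registry(text = serialize_registry(e))[[1]]
  for (f in setdiff(names(e), "extra")) {
    expect_identical(e2[[f]], e[[f]], label = paste("field", f))
  }
  # multi-record listing keeps order and round-trips too
  fleet <- list(e, registry_entry(id = "zzz", title = "Z",
                                  activity_status = "inactive"))
  back <- parse_registry(text = serialize_registry(fleet))
  expect_identical(vapply(back, `[[`, character(1), "id"), c("obi", "zzz"))
})

test_that("the full OBI example validates with zero violations", {
  expect_length(validate_entry(obi_entry()), 0)
})

test_that("each single-rule mutation yields exactly one matching violation", {
  mutations <- list(
    title_present = function(e) { e$title <- NULL; e },
    id_lowercase = function(e) { e$id <- "Obi"; e },
    id_characters = function(e) { e$id <- "ob i"; e },
    homepage_url = function(e) { e$homepage <- "not a url"; e },
    contact_label = function(e) { e$contact$label <- "bpeters@lji.org"; e },
    contact_email = function(e) { e$contact$email <- "bpeters-at-lji"; e },
    products_format = function(e) { e$products <- list(); e },
    description_present = function(e) { e$description <- "  "; e },
    license_label_consistent = function(e) { e$license$label <- "CC0 1.0"; e },
    license_url_format = function(e) { e$license$url <- "creativecommons"; e },
    activity_status_enum = function(e) { e$activity_status <- "retired"; e },
    obsolete_boolean = function(e) { e$is_obsolete <- "false"; e }
  )
  expect_setequal(names(mutations), registry_rules()$rule_id)
  for (rule in names(mutations)) {
    v <- validate_entry(mutations[[rule]](obi_entry()))
    expect_length(v, 1)
    expect_identical(v[[1]]$rule_id, rule)
  }
})

test_that("an id breaking two rules at once reports both", {
  # hand audit of 'OBI 2': uppercase letters break the lowercase rule, the
  # space breaks the character rule
  e <- obi_entry()
  e$id <- "OBI 2"
  v <- validate_entry(e)
  expect_setequal(vapply(v, `[[`, character(1), "rule_id"),
                  c("id_lowercase", "id_characters"))
})

test_that("bad product id formats are violations", {
  e <- obi_entry()
  e$products <- list(list(id = "no extension"))
  v <- validate_entry(e)
  expect_length(v, 1)
  expect_identical(v[[1]]$rule_id, "products_format")
  # subpath products are fine
  e$products <- list(list(id = "obi/obi_core.owl"))
  expect_length(validate_entry(e), 0)
})

test_that("license URL canonicalization normalizes scheme/host/slash and is idempotent", {
  expect_identical(
    canonicalize_license_url("http://creativecommons.org/licenses/by/4.0/"),
    "https://creativecommons.org/licenses/by/4.0")
  expect_identical(
    canonicalize_license_url("https://creativecommons.org/publicdomain/zero/1.0/"),
    "https://creativecommons.org/publicdomain/zero/1.0")
  expect_identical(
    canonicalize_license_url("HTTP://WWW.creativecommons.org/licenses/by/3.0"),
    "https://creativecommons.org/licenses/by/3.0")
  # idempotence over a mixed batch
  urls <- c("http://creativecommons.org/licenses/by/4.0/",
            "https://example.org/license/", "ftp://host.example/x")
  once <- vapply(urls, canonicalize_license_url, character(1))
  twice <- vapply(once, canonicalize_license_url, character(1))
  expect_identical(unname(twice), unname(once))
  expect_error(canonicalize_license_url("not a url"), "not a URL")
})

test_that("label/url correspondence tolerates hyphen and case variants", {
  url <- "https://creativecommons.org/licenses/by/4.0/"
  for (lab in c("CC-BY 4.0", "CC BY 4.0", "cc by 4.0")) {
    e <- obi_entry()
    e$license$label <- lab
    expect_length(validate_entry(e), 0)
  }
})

test_that("clean generated entries always validate clean", {
  for (seed in c(1, 7, 99)) {
    fx <- generate_fixture(fixture_spec(seed = seed))
    expect_length(validate_entry(fx$entry), 0)
  }
})
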