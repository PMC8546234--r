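# The thirteen automatable principle checks. Each maps a registry entry
# and/or a loaded ontology document (plus the run context) to a check result;
# failures are always statuses, never R errors.

#' Openness check (FP1)
#'
#' An ontology is considered open when it is in the public domain (CC0 1.0)
#' or under a Creative Commons Attribution license, 3.0 or later. The check
#' requires (a) a registry license with label and URL, (b) that the
#' canonicalized registry URL is one of the accepted licenses, (c) exactly
#' one `dcterms:license` annotation in the ontology file and (d) agreement
#' between the two after URL canonicalization. A license found under a
#' near-miss property (`dc:license`, `dc:rights`, `dcterms:rights`) adds a
#' WARN finding suggesting `dcterms:license`.
#'
#' @param entry A [registry_entry()].
#' @param doc An `obo_ontology`, or `NULL` when the ontology could not be
#'   loaded (then only the registry side is evaluated and the ontology side
#'   is an ERROR finding).
#' @return An `obo_check_result` for FP1.
#' @export
check_open <- function(entry, doc = NULL) {
  msgs <- character()
  sevs <- character()
  add <- function(sev, msg) {
    msgs <<- c(msgs, msg)
    sevs <<- c(sevs, sev)
  }
  accepted <- accepted_license_urls()

  reg_canon <- NA_character_
  lic <- entry$license
  if (!is_scalar_chr(lic$label %||% NULL) || !is_scalar_chr(lic$url %||% NULL)) {
    add("ERROR",
        "registry license entry missing or incomplete; add license.label and license.url")
  } else {
    reg_canon <- canonicalize_license_url_or_na(lic$url)
    if (is.na(reg_canon)) {
      add("ERROR", sprintf("registry license.url is not a URL: '%s'", lic$url))
    } else if (!reg_canon %in% accepted) {
      add("ERROR", sprintf(
        "registry license '%s' (%s) is not one of the accepted CC0/CC-BY licenses",
        lic$label, lic$url))
    }
  }

  n_candidates <- 0L
  n_wrong <- 0L
  if (is.null(doc)) {
    add("ERROR", "license annotation not found: ontology not loadable")
  } else {
    ann <- get_license_annotations(doc)
    n_candidates <- length(ann$candidates)
    n_wrong <- length(ann$wrong_property_uses)
    if (n_candidates == 0L) {
      add("ERROR",
          "license annotation not found: add a dcterms:license annotation to the ontology")
    } else if (n_candidates > 1L) {
      add("ERROR", sprintf(
        "ontology carries %d dcterms:license annotations; exactly one is required",
        n_candidates))
    } else {
      doc_canon <- canonicalize_license_url_or_na(ann$candidates[[1]])
      if (is.na(doc_canon)) {
        add("ERROR", sprintf(
          "ontology dcterms:license value is not a URL: '%s'",
          ann$candidates[[1]]))
      } else if (!is.na(reg_canon) && reg_canon %in% accepted &&
                 doc_canon != reg_canon) {
        add("ERROR", sprintf(
          "ontology license (%s) and registry license (%s) must be the same",
          doc_canon, reg_canon))
      }
    }
    if (n_wrong > 0L) {
      add("WARN", paste0(
        "license-like annotation under the wrong property (",
        paste(ann$wrong_property_uses, collapse = ", "),
        "); use the dcterms:license property"))
    }
  }

  check_result("FP1", status_from_findings(sevs), msgs,
               metrics = list(license_candidates = n_candidates,
                              wrong_property_uses = n_wrong))
}

#' Common format check (FP2)
#'
#' The ontology must be available in an accepted concrete syntax. The
#' operational rule is loadability: if the document loaded, it is assumed to
#' be in a good format; a loader failure is the failure.
#'
#' @param load_result The value returned by [load_ontology()]: either a
#'   document or a format error.
#' @return An `obo_check_result` for FP2.
#' @export
check_format <- function(load_result) {
  if (is_format_error(load_result)) {
    check_result("FP2", "ERROR",
                 paste0("ontology could not be loaded: ", load_result$message))
  } else if (inherits(load_result, "obo_ontology")) {
    check_result("FP2", "PASS")
  } else {
    stop("load_result must be an ontology document or a format error")
  }
}

#' URI/identifier space check (FP3)
#'
#' Every class and relation must use an IRI of the form OBO PURL base +
#' Foundry-unique prefix + underscore + numeric local identifier. Annotation
#' properties are excluded (legacy OBO conversions use words and hashtags
#' there). IRIs outside the ontology's own namespace are skipped — term
#' reuse is legal. Within the namespace, the character after the prefix must
#' be an underscore and the local id after the underscore must be numeric; a
#' prefix matching only case-insensitively is reported too.
#'
#' @param doc An `obo_ontology`.
#' @param canonical_prefix The ontology's canonical IRI prefix (normally the
#'   uppercased registry id).
#' @return An `obo_check_result` for FP3 with metrics `checked`,
#'   `missing_underscore`, `nonnumeric_local_id`, `case_mismatch`,
#'   `skipped_foreign`.
#' @export
check_uris <- function(doc, canonical_prefix) {
  stopifnot(inherits(doc, "obo_ontology"), is_scalar_chr(canonical_prefix))
  msgs <- character()
  checked <- 0L
  missing_underscore <- 0L
  nonnumeric <- 0L
  case_mismatch <- 0L
  skipped <- 0L
  for (e in doc$entities) {
    if (e$category == "annotation_property") next
    iri <- e$iri
    if (!startsWith(iri, NS_OBO)) {
      skipped <- skipped + 1L
      next
    }
    rest <- substring(iri, nchar(NS_OBO) + 1L)
    if (startsWith(rest, canonical_prefix)) {
      checked <- checked + 1L
      tail <- substring(rest, nchar(canonical_prefix) + 1L)
      if (!startsWith(tail, "_")) {
        missing_underscore <- missing_underscore + 1L
        msgs <- c(msgs, sprintf(
          "%s: character after the prefix must be an underscore", iri))
      } else if (!grepl("^[0-9]+$", substring(tail, 2L))) {
        nonnumeric <- nonnumeric + 1L
        msgs <- c(msgs, sprintf(
          "%s: local ID after the underscore must be numeric", iri))
      }
    } else if (startsWith(toupper(rest), toupper(canonical_prefix)) &&
               grepl("^[_]", substring(rest, nchar(canonical_prefix) + 1L))) {
      checked <- checked + 1L
      case_mismatch <- case_mismatch + 1L
      msgs <- c(msgs, sprintf(
        "%s: prefix differs from the canonical '%s' only by case",
        iri, canonical_prefix))
    } else {
      skipped <- skipped + 1L
    }
  }
  n_bad <- missing_underscore + nonnumeric + case_mismatch
  check_result("FP3", if (n_bad > 0L) "ERROR" else "PASS", msgs,
               metrics = list(checked = checked,
                              missing_underscore = missing_underscore,
                              nonnumeric_local_id = nonnumeric,
                              case_mismatch = case_mismatch,
                              skipped_foreign = skipped))
}

#' Versioning check (FP4)
#'
#' A version IRI must be present in the ontology header. If it embeds a
#' dated path segment the release is identifiable and the check passes; a
#' version IRI without a date format is INFO (versioned, but recency cannot
#' be assessed); no version IRI at all is an ERROR.
#'
#' @param doc An `obo_ontology`.
#' @return An `obo_check_result` for FP4.
#' @export
check_versioning <- function(doc) {
  stopifnot(inherits(doc, "obo_ontology"))
  if (is.null(doc$version_iri)) {
    return(check_result("FP4", "ERROR",
                        "no version IRI found in the ontology header"))
  }
  d <- parse_version_date(doc$version_iri)
  if (is.null(d)) {
    check_result("FP4", "INFO", sprintf(
      "version IRI '%s' is not in date format; release recency cannot be assessed",
      doc$version_iri))
  } else {
    check_result("FP4", "PASS")
  }
}

#' Scope check (FP5)
#'
#' The registry entry must carry a `domain` tag. The domain is compared
#' (case-insensitive exact string match) to the domains of all other active,
#' non-obsolete registry entries; sharing a domain is not a failure but the
#' list of sharing ontologies is returned as an INFO finding.
#'
#' @param entry A [registry_entry()].
#' @param peers List of peer [registry_entry()] objects (the entry itself is
#'   excluded automatically).
#' @return An `obo_check_result` for FP5.
#' @export
check_scope <- function(entry, peers = list()) {
  if (!is_scalar_chr(entry$domain %||% NULL) || !nzchar(trimws(entry$domain))) {
    return(check_result("FP5", "ERROR",
                        "no 'domain' tag in the registry entry; state the ontology's scope"))
  }
  peers <- Filter(function(p) {
    !identical(p$id, entry$id) &&
      identical(p$activity_status %||% "active", "active") &&
      !isTRUE(p$is_obsolete)
  }, peers)
  sharing <- vapply(peers, function(p) {
    is_scalar_chr(p$domain %||% NULL) &&
      tolower(trimws(p$domain)) == tolower(trimws(entry$domain))
  }, logical(1))
  ids <- vapply(peers[sharing], function(p) p$id, character(1))
  if (length(ids) > 0L) {
    check_result("FP5", "INFO",
                 sprintf("domain '%s' is shared with: %s", entry$domain,
                         paste(sort(ids), collapse = ", ")),
                 metrics = list(shared_with = length(ids)))
  } else {
    check_result("FP5", "PASS", metrics = list(shared_with = 0L))
  }
}

# ---------------------------------------------------------------------------
# Shared annotation-completeness engine (definitions: FP6; labels: FP12).
# Scope: all entities except annotation properties. Deprecated entities are
# exempt from the missing counter (historical artifacts) but still
# participate in multiple/duplicate counting.

tally_annotation_faults <- function(doc, field) {
  ents <- Filter(function(e) e$category != "annotation_property",
                 doc$entities)
  missing_iris <- character()
  multiple_iris <- character()
  value_owner_iri <- character()
  value_owner_val <- character()
  for (e in ents) {
    vals <- e[[field]]
    if (length(vals) == 0L && !isTRUE(e$deprecated)) {
      missing_iris <- c(missing_iris, e$iri)
    }
    if (length(vals) >= 2L) {
      multiple_iris <- c(multiple_iris, e$iri)
    }
    for (v in unique(vals)) {
      value_owner_iri <- c(value_owner_iri, e$iri)
      value_owner_val <- c(value_owner_val, v)
    }
  }
  shared_vals <- unique(value_owner_val[duplicated(value_owner_val)])
  duplicate_iris <- unique(value_owner_iri[value_owner_val %in% shared_vals])
  list(missing = missing_iris, multiple = multiple_iris,
       duplicate = duplicate_iris)
}

annotation_check <- function(doc, field, principle_id, counter_names,
                             severity, noun) {
  stopifnot(inherits(doc, "obo_ontology"))
  tally <- tally_annotation_faults(doc, field)
  msgs <- character()
  sevs <- character()
  if (length(tally$missing) > 0L) {
    msgs <- c(msgs, sprintf("missing %s (%d): %s; add a %s to each term",
                            noun, length(tally$missing),
                            paste(tally$missing, collapse = ", "), noun))
    sevs <- c(sevs, severity[["missing"]])
  }
  if (length(tally$multiple) > 0L) {
    msgs <- c(msgs, sprintf("multiple %ss (%d): %s; keep exactly one %s",
                            noun, length(tally$multiple),
                            paste(tally$multiple, collapse = ", "), noun))
    sevs <- c(sevs, severity[["multiple"]])
  }
  if (length(tally$duplicate) > 0L) {
    msgs <- c(msgs, sprintf("duplicate %s (%d): %s; make each %s distinct",
                            noun, length(tally$duplicate),
                            paste(tally$duplicate, collapse = ", "), noun))
    sevs <- c(sevs, severity[["duplicate"]])
  }
  metrics <- stats::setNames(
    list(length(tally$missing), length(tally$multiple),
         length(tally$duplicate)),
    counter_names
  )
  check_result(principle_id, status_from_findings(sevs), msgs, metrics)
}

#' Textual definitions check (FP6)
#'
#' All terms must have distinct textual definitions (carried by the OBO
#' definition annotation property). Counts missing definitions (live terms
#' with none), multiple definitions (two or more values on one term) and
#' duplicate definitions (identical definition text shared across terms;
#' every sharing term is counted). Deprecated terms are exempt from the
#' missing counter only.
#'
#' @param doc An `obo_ontology`.
#' @param config An [check_config()]; its `definition_severity` maps each
#'   nonzero counter to a status (defaults: missing WARN, multiple ERROR,
#'   duplicate ERROR).
#' @return An `obo_check_result` for FP6 with metrics `missing_definition`,
#'   `multiple_definitions`, `duplicate_definition`.
#' @export
check_definitions <- function(doc, config = check_config()) {
  annotation_check(doc, "definitions", "FP6",
                   c("missing_definition", "multiple_definitions",
                     "duplicate_definition"),
                   config$definition_severity, "definition")
}

#' Naming conventions check (FP12)
#'
#' Every entity must have exactly one unique `rdfs:label`. Same engine and
#' scope as [check_definitions()], over label values, with counters
#' `missing_label`, `multiple_labels`, `duplicate_label` (all ERROR by
#' default).
#'
#' @inheritParams check_definitions
#' @return An `obo_check_result` for FP12.
#' @export
check_naming <- function(doc, config = check_config()) {
  annotation_check(doc, "labels", "FP12",
                   c("missing_label", "multiple_labels", "duplicate_label"),
                   config$label_severity, "label")
}

#' Relations reuse check (FP7)
#'
#' Object and data properties should be reused from the Relations Ontology
#' (RO). Each property is classified: an IRI present in the RO index is a
#' reuse (fine); a property in the ontology's own namespace is local and
#' only flagged when its lowercase label exactly shadows an RO label (the
#' message suggests the RO IRI); any other property is a foreign non-RO
#' property and is flagged. Findings are WARN-only.
#'
#' @param doc An `obo_ontology`.
#' @param ro_index An `obo_ro_index` from [load_ro_index()].
#' @param own_prefix The ontology's canonical IRI prefix.
#' @return An `obo_check_result` for FP7 with metrics `reused`, `local`,
#'   `label_shadowed`, `foreign_non_ro`.
#' @export
check_relations <- function(doc, ro_index = load_ro_index(), own_prefix) {
  stopifnot(inherits(doc, "obo_ontology"))
  if (!inherits(ro_index, "obo_ro_index") || length(ro_index$iris) == 0L) {
    stop("configuration error: the RO property index is empty")
  }
  msgs <- character()
  reused <- 0L
  local <- 0L
  shadowed <- 0L
  foreign <- 0L
  own_ns <- paste0(NS_OBO, own_prefix, "_")
  props <- Filter(function(e)
    e$category %in% c("object_property", "data_property"), doc$entities)
  for (e in props) {
    if (e$iri %in% ro_index$iris) {
      reused <- reused + 1L
    } else if (startsWith(e$iri, own_ns)) {
      local <- local + 1L
      hit <- intersect(tolower(e$labels), names(ro_index$labels))
      if (length(hit) > 0L) {
        shadowed <- shadowed + 1L
        msgs <- c(msgs, sprintf(
          "local property %s is labeled '%s', which matches an existing RO property; reuse %s instead",
          e$iri, hit[[1]], ro_index$labels[[hit[[1]]]]))
      }
    } else {
      foreign <- foreign + 1L
      msgs <- c(msgs, sprintf(
        "property %s is neither an RO property nor in the ontology's own namespace; prefer an RO relation",
        e$iri))
    }
  }
  check_result("FP7", if (length(msgs) > 0L) "WARN" else "PASS", msgs,
               metrics = list(reused = reused, local = local,
                              label_shadowed = shadowed,
                              foreign_non_ro = foreign))
}

#' Documentation check (FP8)
#'
#' The registry entry must carry `homepage` and `description`. When both are
#' present and the run is online, the homepage is probed and must not return
#' an HTTP status of 400 or greater; a transport failure counts as
#' non-resolution. Offline runs report INFO (resolution not probed).
#'
#' @param entry A [registry_entry()].
#' @param ctx An [check_context()]; uses `offline` and `http_prober`.
#' @return An `obo_check_result` for FP8.
#' @export
check_documentation <- function(entry, ctx = check_context()) {
  msgs <- character()
  if (!is_scalar_chr(entry$homepage %||% NULL)) {
    msgs <- c(msgs, "no 'homepage' entry in the registry data")
  }
  if (!is_scalar_chr(entry$description %||% NULL) ||
      !nzchar(trimws(entry$description))) {
    msgs <- c(msgs, "no 'description' entry in the registry data")
  }
  if (length(msgs) > 0L) {
    return(check_result("FP8", "ERROR", msgs))
  }
  if (isTRUE(ctx$offline)) {
    return(check_result("FP8", "INFO",
                        "offline run: homepage resolution not probed"))
  }
  prober <- ctx$http_prober %||% default_http_prober
  status <- tryCatch(prober(entry$homepage), error = identity)
  if (inherits(status, "error")) {
    return(check_result("FP8", "ERROR", sprintf(
      "homepage %s did not resolve: %s", entry$homepage,
      conditionMessage(status))))
  }
  if (status >= 400L) {
    check_result("FP8", "ERROR",
                 sprintf("homepage %s returned HTTP status %d",
                         entry$homepage, as.integer(status)),
                 metrics = list(http_status = status))
  } else {
    check_result("FP8", "PASS", metrics = list(http_status = status))
  }
}

#' Registry-presence checks (FP9, FP11, FP20)
#'
#' Three principles reduce to the presence and well-formedness of a registry
#' field: FP9 (documented plurality of users) requires a non-empty `usages`
#' list; FP11 (locus of authority) requires a contact with a well-formed name
#' and email; FP20 (responsiveness) requires a URL-shaped `tracker`.
#'
#' @param entry A [registry_entry()].
#' @param principle_id `"FP9"`, `"FP11"` or `"FP20"`.
#' @return An `obo_check_result`.
#' @export
check_registry_presence <- function(entry, principle_id) {
  if (!principle_id %in% c("FP9", "FP11", "FP20")) {
    stop("check_registry_presence handles FP9, FP11 and FP20 only, got ",
         principle_id)
  }
  if (principle_id == "FP9") {
    users <- Filter(function(u) is_scalar_chr(u$user %||% NULL) &&
                      nzchar(trimws(u$user)), entry$usages)
    if (length(users) > 0L) {
      return(check_result("FP9", "PASS",
                          metrics = list(usages = length(users))))
    }
    return(check_result("FP9", "ERROR",
                        "no 'usages' entries in the registry data; document at least one independent user",
                        metrics = list(usages = 0L)))
  }
  if (principle_id == "FP11") {
    label <- entry$contact$label
    email <- entry$contact$email
    ok <- !is.null(label) && length(label) == 1L && is_scalar_chr(label[[1]]) &&
      nzchar(trimws(label[[1]])) && !grepl("@", label[[1]], fixed = TRUE) &&
      !is.null(email) && length(email) == 1L && is_email_string(email[[1]])
    if (ok) {
      return(check_result("FP11", "PASS"))
    }
    return(check_result("FP11", "ERROR",
                        "registry contact must have a single well-formed name (no '@') and email address"))
  }
  if (is_url_string(entry$tracker %||% NULL)) {
    check_result("FP20", "PASS")
  } else {
    check_result("FP20", "ERROR",
                 "no URL-shaped 'tracker' entry in the registry data; provide an issue tracker")
  }
}

# same calendar day n years earlier; Feb 29 maps to Feb 28
years_before <- function(date, n) {
  y <- as.integer(format(date, "%Y")) - n
  md <- format(date, "-%m-%d")
  out <- as.Date(paste0(y, md), format = "%Y-%m-%d")
  if (is.na(out)) {
    out <- as.Date(paste0(y, "-02-28"))
  }
  out
}

#' Maintenance check (FP16)
#'
#' The ontology must be updated in a timely manner. The release date is the
#' dated segment of the version IRI; with the default cutoffs a release
#' within the last 2 years passes, between 2 and 3 years warns, and older
#' than 3 years is an error. Transitions occur exactly at the calendar-year
#' boundaries. A version IRI without a parseable date (or a date in the
#' future) is WARN: recency cannot be assessed.
#'
#' @param doc An `obo_ontology`.
#' @param today Reference date.
#' @param config An [check_config()]; uses `warn_years` and `error_years`.
#' @return An `obo_check_result` for FP16 with metric `age_days` when a date
#'   is available.
#' @export
check_maintenance <- function(doc, today = Sys.Date(),
                              config = check_config()) {
  stopifnot(inherits(doc, "obo_ontology"))
  today <- as.Date(today)
  d <- parse_version_date(doc$version_iri)
  if (is.null(d)) {
    return(check_result("FP16", "WARN",
                        "no dated version IRI: release recency cannot be assessed"))
  }
  if (d > today) {
    return(check_result("FP16", "WARN", sprintf(
      "version date %s is in the future of %s (clock skew or pre-release?)",
      format(d), format(today))))
  }
  age_days <- as.integer(today - d)
  if (d >= years_before(today, config$warn_years)) {
    check_result("FP16", "PASS", metrics = list(age_days = age_days))
  } else if (d >= years_before(today, config$error_years)) {
    check_result("FP16", "WARN", sprintf(
      "last release %s is more than %g years old; release more frequently",
      format(d), config$warn_years), metrics = list(age_days = age_days))
  } else {
    check_result("FP16", "ERROR", sprintf(
      "last release %s is more than %g years old; the ontology looks unmaintained",
      format(d), config$error_years), metrics = list(age_days = age_days))
  }
}

# ERROR result used for every ontology-dependent check when the load failed
not_loadable_result <- function(principle_id, load_result) {
  msg <- if (is_format_error(load_result)) load_result$message else "no document"
  check_result(principle_id, "ERROR",
               paste0("ontology not loadable: ", msg))
}

#' Run all principle checks for one ontology
#'
#' Executes the 13 automatable checks in fixed principle order and assembles
#' a dashboard row. Registry-only checks (FP5, FP8, FP9, FP11, FP20) run even
#' when the ontology failed to load; ontology-dependent checks then report
#' ERROR with the loader message. The row summary is the worst status over
#' all non-NA cells.
#'
#' @param entry A [registry_entry()].
#' @param load_result Result of [load_ontology()] for the entry's canonical
#'   product (document or format error).
#' @param ctx An [check_context()].
#' @return An `obo_dashboard_row` (see [dashboard_row()]).
#' @export
evaluate_ontology <- function(entry, load_result, ctx = check_context()) {
  doc <- if (inherits(load_result, "obo_ontology")) load_result else NULL
  prefix <- canonical_prefix(entry, ctx$config)
  with_doc <- function(id, fun) {
    if (is.null(doc)) not_loadable_result(id, load_result) else fun(doc)
  }
  results <- list(
    FP1 = check_open(entry, doc),
    FP2 = check_format(load_result),
    FP3 = with_doc("FP3", function(d) check_uris(d, prefix)),
    FP4 = with_doc("FP4", check_versioning),
    FP5 = check_scope(entry, ctx$peers),
    FP6 = with_doc("FP6", function(d) check_definitions(d, ctx$config)),
    FP7 = with_doc("FP7", function(d) check_relations(d, ctx$ro_index, prefix)),
    FP8 = check_documentation(entry, ctx),
    FP9 = check_registry_presence(entry, "FP9"),
    FP11 = check_registry_presence(entry, "FP11"),
    FP12 = with_doc("FP12", function(d) check_naming(d, ctx$config)),
    FP16 = with_doc("FP16", function(d)
      check_maintenance(d, ctx$today, ctx$config)),
    FP20 = check_registry_presence(entry, "FP20")
  )
  dashboard_row(entry$id, results)
}
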