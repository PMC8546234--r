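# Deterministic fixture generator: registry records and ontology documents
# that are clean by construction, or carry exactly one named seeded fault,
# together with the expected per-principle outcome map. The same spec always
# produces the same bytes; the seed varies wording only, through an integer
# mixer rather than R's global RNG.

.fixture_adjectives <- c("membranous", "cortical", "distal", "proximal",
                         "vesicular", "ciliated", "basal", "apical",
                         "fibrous", "granular")
.fixture_nouns <- c("structure", "compartment", "process", "assembly",
                    "region", "layer", "filament", "junction", "matrix",
                    "lumen")

# deterministic index mixer (32-bit safe): seed and position -> small int
det_index <- function(seed, i, n) {
  x <- (as.numeric(seed) * 69069 + i * 2654435) %% 2147483647
  as.integer(x %% n) + 1L
}

#' Describe a fixture to generate
#'
#' @param idspace Foundry-style idspace for the fixture ontology (e.g.
#'   `"EXF"`).
#' @param n_classes Number of classes (including deprecated ones).
#' @param n_object_properties Number of object properties; the first is a
#'   reused Relations Ontology property, any further ones are local.
#' @param n_annotation_properties Number of annotation properties.
#' @param n_deprecated Number of classes marked deprecated (at most
#'   `n_classes`).
#' @param seed Integer seed; fully determines the output bytes.
#' @param violations Character vector of seeded fault kinds from
#'   [violation_catalog()]; empty for a clean fixture. `"malformed_file"`
#'   is exclusive and cannot be combined with other kinds.
#' @return A list of class `obo_fixture_spec`.
#' @export
fixture_spec <- function(idspace = "EXF", n_classes = 5,
                         n_object_properties = 1,
                         n_annotation_properties = 1, n_deprecated = 1,
                         seed = 42, violations = character()) {
  stopifnot(n_deprecated <= n_classes, n_classes >= 1)
  known <- violation_catalog()$kind
  bad <- setdiff(violations, known)
  if (length(bad) > 0L) {
    stop("unknown violation kind(s): ", paste(bad, collapse = ", "))
  }
  if ("malformed_file" %in% violations && length(violations) > 1L) {
    stop("malformed_file is exclusive: a truncated file cannot carry other seeded faults")
  }
  structure(
    list(idspace = idspace, n_classes = as.integer(n_classes),
         n_object_properties = as.integer(n_object_properties),
         n_annotation_properties = as.integer(n_annotation_properties),
         n_deprecated = as.integer(n_deprecated), seed = as.integer(seed),
         violations = violations),
    class = "obo_fixture_spec"
  )
}

#' The seeded-violation catalogue
#'
#' Every detectable fault kind the generator can seed, the principle whose
#' cell it targets, and a short description. Each kind maps to exactly one
#' target principle; no kind targets FP10, which is excluded from automation
#' by design. Used to auto-generate the isolation test matrix.
#'
#' @return A data.frame with columns `kind`, `principle`, `description`.
#' @export
violation_catalog <- function() {
  rows <- list(
    c("license_missing", "FP1", "registry license entry removed"),
    c("license_not_accepted", "FP1", "registry license set to a non-CC license (GPL-3.0)"),
    c("license_mismatch", "FP1", "ontology dcterms:license disagrees with the registry license"),
    c("wrong_license_property", "FP1", "license stated under legacy dc:license instead of dcterms:license"),
    c("malformed_file", "FP2", "ontology file truncated mid-document"),
    c("iri_no_underscore", "FP3", "class IRI lacks the underscore after the prefix"),
    c("iri_nonnumeric", "FP3", "class IRI has a non-numeric local id"),
    c("version_iri_absent", "FP4", "ontology header carries no version IRI"),
    c("version_iri_nondate", "FP4", "version IRI without a dated path segment"),
    c("domain_missing", "FP5", "registry domain tag removed"),
    c("domain_shared", "FP5", "registry domain set equal to a peer ontology's domain"),
    c("def_missing", "FP6", "one live class has no textual definition"),
    c("def_duplicate", "FP6", "two classes share an identical definition"),
    c("def_multiple", "FP6", "one class carries two distinct definitions"),
    c("nonro_property", "FP7", "object property outside both RO and the ontology's namespace"),
    c("homepage_missing", "FP8", "registry homepage removed"),
    c("homepage_404", "FP8", "homepage resolves with HTTP status 404"),
    c("usages_empty", "FP9", "registry usages list emptied"),
    c("contact_malformed", "FP11", "contact label replaced by an email address"),
    c("label_missing", "FP12", "one live class has no rdfs:label"),
    c("label_duplicate", "FP12", "two classes share an identical label"),
    c("label_multiple", "FP12", "one class carries two labels"),
    c("stale_version_date", "FP16", "dated release four years before the reference date"),
    c("tracker_missing", "FP20", "registry tracker entry removed")
  )
  data.frame(kind = vapply(rows, `[`, character(1), 1L),
             principle = vapply(rows, `[`, character(1), 2L),
             description = vapply(rows, `[`, character(1), 3L),
             stringsAsFactors = FALSE)
}

fixture_entity <- function(iri, category, labels = character(),
                           definitions = character(), deprecated = FALSE) {
  list(iri = iri, category = category, labels = labels,
       definitions = definitions, deprecated = deprecated)
}

make_fixture_document <- function(ontology_iri, version_iri, annotations,
                                  entities) {
  names(entities) <- vapply(entities, `[[`, character(1), "iri")
  structure(list(ontology_iri = ontology_iri, version_iri = version_iri,
                 annotations = annotations, entities = entities,
                 warnings = character()),
            class = "obo_ontology")
}

#' Generate a registry/ontology fixture
#'
#' Produces a registry record, an ontology document and the expected outcome
#' of every principle check, either clean or with the named seeded faults.
#' The clean fixture passes every check except FP8, which is INFO under the
#' default offline context (homepage resolution not probed). Most seeded
#' kinds perturb exactly their target principle's cell; the three kinds with
#' intrinsically coupled cells are encoded in the expected map
#' (`malformed_file` fails every ontology-dependent check;
#' `version_iri_absent`/`version_iri_nondate` also degrade FP16 because
#' Versioning and Maintenance share the version IRI).
#'
#' @param spec An [fixture_spec()].
#' @param format Ontology serialization, `"turtle"` or `"rdfxml"`.
#' @param today Reference date the fixture is built against; the clean
#'   release date is 60 days earlier.
#' @param dir Optional output directory; when given, `registry.yml` and the
#'   ontology file are written there.
#' @return A list with elements `spec`, `entry`, `registry_yaml`, `document`
#'   (NULL for `malformed_file`), `ontology_text`, `format`, `peers`,
#'   `context` (list with `offline`, `http_status`), `today`, `expected`
#'   (named status vector over the 13 principles) and, when `dir` is given,
#'   `paths`.
#' @export
generate_fixture <- function(spec = fixture_spec(),
                             format = c("turtle", "rdfxml"),
                             today = as.Date("2021-05-01"), dir = NULL) {
  stopifnot(inherits(spec, "obo_fixture_spec"))
  format <- match.arg(format)
  today <- as.Date(today)
  v <- spec$violations
  id <- tolower(spec$idspace)
  prefix <- toupper(spec$idspace)
  seed <- spec$seed

  word <- function(i, pool) pool[det_index(seed, i, length(pool))]
  class_label <- function(i) {
    sprintf("%s %s %d", id, word(i, .fixture_nouns), i)
  }
  class_def <- function(i) {
    sprintf("A %s %s of the %s fixture, number %d.",
            word(i * 3L + 1L, .fixture_adjectives),
            word(i * 3L + 2L, .fixture_nouns), id, i)
  }

  # --- ontology document -------------------------------------------------
  release_date <- today - 60L
  if ("stale_version_date" %in% v) {
    release_date <- years_before(today, 4)
  }
  version_iri <- sprintf("%s%s/%s/%s.owl", NS_OBO, id,
                         format(release_date, "%Y-%m-%d"), id)
  if ("version_iri_absent" %in% v) version_iri <- NULL
  if ("version_iri_nondate" %in% v) {
    version_iri <- sprintf("%s%s/v1.2/%s.owl", NS_OBO, id, id)
  }

  doc_license <- "https://creativecommons.org/licenses/by/4.0/"
  annotations <- stats::setNames(list(doc_license), IRI_LICENSE)
  if ("license_mismatch" %in% v) {
    annotations[[IRI_LICENSE]] <-
      "https://creativecommons.org/publicdomain/zero/1.0/"
  }
  if ("wrong_license_property" %in% v) {
    annotations <- stats::setNames(list(doc_license), paste0(NS_DC, "license"))
  }

  entities <- list()
  for (i in seq_len(spec$n_classes)) {
    deprecated <- i > spec$n_classes - spec$n_deprecated
    entities[[length(entities) + 1L]] <- fixture_entity(
      iri = sprintf("%s%s_%07d", NS_OBO, prefix, i),
      category = "class",
      labels = class_label(i),
      # deprecated classes keep their label but carry no definition; they
      # are exempt from the missing-definition count
      definitions = if (deprecated) character() else class_def(i),
      deprecated = deprecated
    )
  }
  if (spec$n_object_properties >= 1L) {
    entities[[length(entities) + 1L]] <- fixture_entity(
      iri = paste0(NS_OBO, "RO_0002202"), category = "object_property",
      labels = "develops from",
      definitions = "x develops from y if x is the product of developmental transformation of y."
    )
  }
  if (spec$n_object_properties >= 2L) {
    for (i in seq_len(spec$n_object_properties - 1L)) {
      entities[[length(entities) + 1L]] <- fixture_entity(
        iri = sprintf("%s%s_%07d", NS_OBO, prefix, 8000000L + i),
        category = "object_property",
        labels = sprintf("%s linked to %d", id, i),
        definitions = sprintf("A local relation of the %s fixture, number %d.",
                              id, i)
      )
    }
  }
  for (i in seq_len(spec$n_annotation_properties)) {
    entities[[length(entities) + 1L]] <- fixture_entity(
      iri = sprintf("%s%s#annotation_%d", NS_OBO, id, i),
      category = "annotation_property",
      labels = sprintf("%s note %d", id, i)
    )
  }

  # ontology-side seeded faults (class 1 and 2 are always live: the
  # deprecated block sits at the tail and n_classes >= n_deprecated + 2 is
  # required whenever a class-level fault is seeded)
  class_faults <- c("iri_no_underscore", "iri_nonnumeric", "def_missing",
                    "def_duplicate", "def_multiple", "label_missing",
                    "label_duplicate", "label_multiple")
  if (any(class_faults %in% v) &&
      spec$n_classes - spec$n_deprecated < 2L) {
    stop("class-level faults need at least two live classes")
  }
  if ("iri_no_underscore" %in% v) {
    entities[[1]]$iri <- sprintf("%s%s%07d", NS_OBO, prefix, 1L)
  }
  if ("iri_nonnumeric" %in% v) {
    entities[[1]]$iri <- sprintf("%s%s_abc", NS_OBO, prefix)
  }
  if ("def_missing" %in% v) entities[[1]]$definitions <- character()
  if ("def_duplicate" %in% v) {
    entities[[2]]$definitions <- entities[[1]]$definitions
  }
  if ("def_multiple" %in% v) {
    entities[[1]]$definitions <- c(entities[[1]]$definitions,
                                   "An alternative, conflicting definition.")
  }
  if ("label_missing" %in% v) entities[[1]]$labels <- character()
  if ("label_duplicate" %in% v) entities[[2]]$labels <- entities[[1]]$labels
  if ("label_multiple" %in% v) {
    entities[[1]]$labels <- c(entities[[1]]$labels, "an alternative label")
  }
  if ("nonro_property" %in% v) {
    entities[[length(entities) + 1L]] <- fixture_entity(
      iri = "http://example.com/vocab/related_to",
      category = "object_property", labels = "related to",
      definitions = "A vague association relation outside RO."
    )
  }

  document <- make_fixture_document(
    ontology_iri = paste0(NS_OBO, id, ".owl"),
    version_iri = version_iri,
    annotations = annotations,
    entities = entities
  )
  ontology_text <- write_ontology(document, format = format)
  if ("malformed_file" %in% v) {
    # cut just after an opening '<' near the middle: leaves an unterminated
    # IRI (Turtle) or unclosed tag (RDF/XML) whatever the half-way point is
    half <- floor(nchar(ontology_text) / 2)
    opens <- gregexpr("<", ontology_text, fixed = TRUE)[[1]]
    cut <- max(opens[opens <= half])
    ontology_text <- substr(ontology_text, 1L, cut)
    document <- NULL
  }

  # --- registry record ---------------------------------------------------
  entry <- registry_entry(
    id = id,
    title = sprintf("%s fixture ontology", toupper(id)),
    homepage = sprintf("https://example.org/%s", id),
    contact = list(label = "Alex Curator",
                   email = sprintf("%s-admin@example.org", id)),
    description = sprintf(
      "A generated ontology covering %s %s entities, used to exercise the principle checks.",
      word(1L, .fixture_adjectives), word(2L, .fixture_nouns)),
    license = list(label = "CC-BY 4.0",
                   url = "https://creativecommons.org/licenses/by/4.0/"),
    products = list(list(id = sprintf("%s.owl", id))),
    activity_status = "active", is_obsolete = FALSE,
    domain = "simulated anatomy",
    usages = list(list(user = "https://example.org/atlas-project",
                       description = "annotates atlas images")),
    tracker = sprintf("https://example.org/%s/issues", id)
  )
  if ("license_missing" %in% v) entry$license <- NULL
  if ("license_not_accepted" %in% v) {
    entry$license <- list(label = "GPL-3.0",
                          url = "https://www.gnu.org/licenses/gpl-3.0.en.html")
  }
  if ("domain_missing" %in% v) entry$domain <- NULL
  if ("domain_shared" %in% v) entry$domain <- "anatomy"
  if ("homepage_missing" %in% v) entry$homepage <- NULL
  if ("usages_empty" %in% v) entry$usages <- list()
  if ("contact_malformed" %in% v) {
    entry$contact$label <- sprintf("%s-admin@example.org", id)
  }
  if ("tracker_missing" %in% v) entry$tracker <- NULL

  peers <- list(
    registry_entry(id = "aao", title = "Peer anatomy ontology",
                   domain = "anatomy", activity_status = "active",
                   is_obsolete = FALSE),
    registry_entry(id = "hlo", title = "Peer health ontology",
                   domain = "health", activity_status = "active",
                   is_obsolete = FALSE)
  )

  context <- list(offline = !("homepage_404" %in% v),
                  http_status = if ("homepage_404" %in% v) 404L else 200L)

  # --- expected outcome map ----------------------------------------------
  expected <- stats::setNames(rep("PASS", length(principle_ids())),
                              principle_ids())
  expected[["FP8"]] <- if (context$offline) "INFO" else "PASS"
  overrides <- list(
    license_missing = c(FP1 = "ERROR"),
    license_not_accepted = c(FP1 = "ERROR"),
    license_mismatch = c(FP1 = "ERROR"),
    wrong_license_property = c(FP1 = "ERROR"),
    malformed_file = c(FP1 = "ERROR", FP2 = "ERROR", FP3 = "ERROR",
                       FP4 = "ERROR", FP6 = "ERROR", FP7 = "ERROR",
                       FP12 = "ERROR", FP16 = "ERROR"),
    iri_no_underscore = c(FP3 = "ERROR"),
    iri_nonnumeric = c(FP3 = "ERROR"),
    version_iri_absent = c(FP4 = "ERROR", FP16 = "WARN"),
    version_iri_nondate = c(FP4 = "INFO", FP16 = "WARN"),
    domain_missing = c(FP5 = "ERROR"),
    domain_shared = c(FP5 = "INFO"),
    def_missing = c(FP6 = "WARN"),
    def_duplicate = c(FP6 = "ERROR"),
    def_multiple = c(FP6 = "ERROR"),
    nonro_property = c(FP7 = "WARN"),
    homepage_missing = c(FP8 = "ERROR"),
    homepage_404 = c(FP8 = "ERROR"),
    usages_empty = c(FP9 = "ERROR"),
    contact_malformed = c(FP11 = "ERROR"),
    label_missing = c(FP12 = "ERROR"),
    label_duplicate = c(FP12 = "ERROR"),
    label_multiple = c(FP12 = "ERROR"),
    stale_version_date = c(FP16 = "ERROR"),
    tracker_missing = c(FP20 = "ERROR")
  )
  for (kind in v) {
    ov <- overrides[[kind]]
    expected[names(ov)] <- ov
  }

  out <- list(spec = spec, entry = entry,
              registry_yaml = serialize_registry(entry),
              document = document, ontology_text = ontology_text,
              format = format, peers = peers, context = context,
              today = today, expected = expected)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ext <- if (format == "turtle") "ttl" else "owl"
    reg_path <- file.path(dir, "registry.yml")
    onto_path <- file.path(dir, sprintf("%s.%s", id, ext))
    writeLines(out$registry_yaml, reg_path, sep = "", useBytes = TRUE)
    writeLines(out$ontology_text, onto_path, sep = "", useBytes = TRUE)
    out$paths <- c(registry = reg_path, ontology = onto_path)
  }
  out
}

#' Evaluate a generated fixture
#'
#' Runs the full check suite on a fixture under the context the fixture was
#' built for (its reference date, peers, offline flag and stubbed HTTP
#' prober) and returns the dashboard row. Comparing the row's statuses to
#' the fixture's `expected` map is the suite's central self-consistency
#' oracle.
#'
#' @param fx Output of [generate_fixture()].
#' @param config An [check_config()].
#' @return An `obo_dashboard_row`.
#' @export
evaluate_fixture <- function(fx, config = check_config()) {
  status <- fx$context$http_status
  ctx <- check_context(
    today = fx$today, peers = fx$peers, ro_index = load_ro_index(),
    http_prober = function(url) status,
    offline = fx$context$offline, config = config
  )
  load_result <- load_ontology(fx$ontology_text, format = fx$format,
                               text = TRUE)
  evaluate_ontology(fx$entry, load_result, ctx)
}
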