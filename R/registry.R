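# Registry metadata records: the curated per-ontology entries (title, id,
# homepage, contact, description, license, products, activity status,
# obsoletion status, plus the optional domain/usages/tracker tags) stored as
# YAML under version control alongside the ontologies.

.registry_fields <- c(
  "id", "title", "homepage", "contact", "description", "license", "products",
  "activity_status", "is_obsolete", "domain", "usages", "tracker"
)

#' Construct a registry entry
#'
#' Builds the in-memory record for one ontology's curated registry metadata.
#' `contact` is a list with `label` and `email`, `license` a list with `label`
#' and `url`, `products` a list of lists each carrying an `id`, and `usages` a
#' list of lists each carrying a `user` (and optionally a `description`).
#' Fields outside the minimal model are preserved under `extra`, never
#' rejected: real registry files carry many optional tags.
#'
#' @param id Ontology idspace (e.g. `"obi"`).
#' @param title Full ontology name.
#' @param homepage Project homepage URL.
#' @param contact List with `label` (person name) and `email`.
#' @param description Free-text scope description.
#' @param license List with `label` and `url`.
#' @param products List of product records (`list(id = "obi.owl")`, ...).
#' @param activity_status One of `"active"`, `"inactive"`, `"orphaned"`.
#' @param is_obsolete Logical obsoletion flag.
#' @param domain Optional free-text domain tag.
#' @param usages Optional list of usage records.
#' @param tracker Optional issue-tracker URL.
#' @param extra Named list of fields outside the minimal model, kept verbatim.
#' @return An object of class `obo_registry_entry`.
#' @export
registry_entry <- function(id, title = NULL, homepage = NULL, contact = NULL,
                           description = NULL, license = NULL,
                           products = list(), activity_status = "active",
                           is_obsolete = FALSE, domain = NULL, usages = list(),
                           tracker = NULL, extra = list()) {
  structure(
    list(
      id = id, title = title, homepage = homepage, contact = contact,
      description = description, license = license, products = products,
      activity_status = activity_status, is_obsolete = is_obsolete,
      domain = domain, usages = usages, tracker = tracker, extra = extra
    ),
    class = "obo_registry_entry"
  )
}

#' @export
print.obo_registry_entry <- function(x, ...) {
  cat("<registry entry>", x$id %||% "<no id>", "-", x$title %||% "<untitled>", "\n")
  cat("  status:", x$activity_status %||% "<unset>",
      if (isTRUE(x$is_obsolete)) "(obsolete)" else "", "\n")
  if (!is.null(x$license$label)) cat("  license:", x$license$label, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_registry_entry <- function(rec) {
  if (!is.list(rec)) {
    stop("registry record must be a mapping, got ", class(rec)[1])
  }
  known <- rec[intersect(names(rec), .registry_fields)]
  extra <- rec[setdiff(names(rec), .registry_fields)]
  # products/usages may arrive as a bare string or a flat map for one element
  norm_list <- function(x, key) {
    if (is.null(x)) return(list())
    if (!is.list(x) || !is.null(names(x))) x <- list(x)
    lapply(x, function(el) {
      if (is.character(el)) stats::setNames(list(el), key) else el
    })
  }
  registry_entry(
    id = known$id,
    title = known$title,
    homepage = known$homepage,
    contact = known$contact,
    description = known$description,
    license = known$license,
    products = norm_list(known$products, "id"),
    activity_status = known$activity_status %||% "active",
    is_obsolete = known$is_obsolete %||% FALSE,
    domain = known$domain,
    usages = norm_list(known$usages, "user"),
    tracker = known$tracker,
    extra = extra
  )
}

#' Parse registry metadata records
#'
#' Reads curated registry metadata from its structured YAML form. Both shapes
#' used in practice are supported: a single-record file (one mapping) and a
#' combined listing with an `ontologies` key holding one mapping per
#' ontology. Unknown fields are preserved under each entry's `extra` element.
#'
#' @param text Registry YAML as a single string (or character vector of lines).
#' @param file Path to a registry YAML file (alternative to `text`).
#' @return A list of [registry_entry()] objects.
#' @seealso [validate_entry()], [serialize_registry()]
#' @export
parse_registry <- function(text = NULL, file = NULL) {
  if (is.null(text) && is.null(file)) {
    stop("supply either `text` or `file`")
  }
  if (is.null(text)) {
    text <- paste(readLines(file, warn = FALSE), collapse = "\n")
  } else if (length(text) > 1L) {
    text <- paste(text, collapse = "\n")
  }
  if (!nzchar(trimws(text))) {
    return(list())
  }
  doc <- tryCatch(
    yaml::yaml.load(text),
    error = function(e) {
      stop("malformed registry document: ", conditionMessage(e), call. = FALSE)
    }
  )
  if (is.null(doc)) {
    return(list())
  }
  recs <- if (is.list(doc) && "ontologies" %in% names(doc)) {
    doc$ontologies %||% list()
  } else {
    list(doc)
  }
  entries <- lapply(recs, as_registry_entry)
  ids <- vapply(entries, function(e) e$id %||% NA_character_, character(1))
  dup <- unique(ids[!is.na(ids) & duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate ontology id(s) in registry listing: ",
         paste(dup, collapse = ", "))
  }
  entries
}

#' Serialize registry entries back to YAML
#'
#' Inverse of [parse_registry()] on the modeled fields: parsing the output
#' reproduces the entries (round-trip). Single entries are written as one
#' record; several entries as an `ontologies` listing.
#'
#' @param entries A list of [registry_entry()] objects (or a single entry).
#' @return A YAML string.
#' @export
serialize_registry <- function(entries) {
  if (inherits(entries, "obo_registry_entry")) {
    entries <- list(entries)
  }
  strip <- function(e) {
    rec <- e[.registry_fields]
    rec <- rec[!vapply(rec, is.null, logical(1))]
    rec <- rec[!vapply(rec, function(x) is.list(x) && length(x) == 0L, logical(1))]
    c(rec, e$extra)
  }
  recs <- lapply(entries, strip)
  if (length(recs) == 1L) {
    yaml::as.yaml(recs[[1]])
  } else {
    yaml::as.yaml(list(ontologies = recs))
  }
}

# ---------------------------------------------------------------------------
# Validation against the minimal registry model

#' The registry rule catalogue
#'
#' The fixed catalogue of the 12 automated registry validation rules. The
#' ontology id row of the minimal model carries two independent assertions
#' (lowercase; alphanumeric without spaces), so it contributes two rule ids.
#'
#' @return A data.frame with columns `rule_id`, `field`, `severity`,
#'   `description`.
#' @export
registry_rules <- function() {
  data.frame(
    rule_id = c(
      "title_present", "id_lowercase", "id_characters", "homepage_url",
      "contact_label", "contact_email", "products_format",
      "description_present", "license_label_consistent", "license_url_format",
      "activity_status_enum", "obsolete_boolean"
    ),
    field = c(
      "title", "id", "id", "homepage", "contact.label", "contact.email",
      "products", "description", "license.label", "license.url",
      "activity_status", "is_obsolete"
    ),
    severity = "ERROR",
    description = c(
      "title must be present",
      "id must be lowercase",
      "id must be alphanumeric with no spaces",
      "homepage must be in a URL format",
      "contact label must be a single name without '@'",
      "contact email must be a single address in email format",
      "products must list at least one canonical file in id.ext form",
      "description must be present",
      "license label must correspond to the title of the license URL",
      "license URL must be in a URL format",
      "activity status must be one of 'active', 'inactive' or 'orphaned'",
      "obsoletion status must be a boolean"
    ),
    stringsAsFactors = FALSE
  )
}

violation <- function(field_path, rule_id, message, severity = "ERROR") {
  structure(
    list(field_path = field_path, rule_id = rule_id, message = message,
         severity = severity),
    class = "obo_violation"
  )
}

#' @export
print.obo_violation <- function(x, ...) {
  cat(sprintf("[%s] %s (%s): %s\n", x$severity, x$rule_id, x$field_path,
              x$message))
  invisible(x)
}

is_scalar_chr <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' Validate a registry entry against the minimal model
#'
#' Applies the 12 automated registry rules (see [registry_rules()]) to one
#' entry. Violations are returned as data, never raised: each broken rule
#' yields one violation record carrying its stable `rule_id`. A fully
#' conformant record — such as the canonical OBI example — yields an empty
#' list.
#'
#' @param entry A [registry_entry()].
#' @return A list of violation records (class `obo_violation`), possibly empty.
#' @examples
#' e <- registry_entry(
#'   id = "obi", title = "Ontology for Biomedical Investigations",
#'   homepage = "http://obi-ontology.org/",
#'   contact = list(label = "Bjoern Peters", email = "bpeters@lji.org"),
#'   description = "An integrated ontology for the description of
#'     life science and clinical investigations",
#'   license = list(label = "CC-BY 4.0",
#'                  url = "https://creativecommons.org/licenses/by/4.0/"),
#'   products = list(list(id = "obi.owl")),
#'   activity_status = "active", is_obsolete = FALSE
#' )
#' validate_entry(e) # empty list
#' @export
validate_entry <- function(entry) {
  stopifnot(inherits(entry, "obo_registry_entry"))
  v <- list()
  add <- function(field, rule, msg) {
    v[[length(v) + 1L]] <<- violation(field, rule, msg)
  }

  if (!is_scalar_chr(entry$title) || !nzchar(trimws(entry$title))) {
    add("title", "title_present", "title must be present")
  }

  id <- entry$id
  if (!is_scalar_chr(id) || !nzchar(id)) {
    add("id", "id_characters", "id must be present and non-empty")
  } else {
    if (grepl("[A-Z]", id)) {
      add("id", "id_lowercase",
          sprintf("id '%s' must be lowercase", id))
    }
    if (grepl("[^A-Za-z0-9]", id)) {
      add("id", "id_characters",
          sprintf("id '%s' must be alphanumeric with no spaces", id))
    }
  }

  if (!is_url_string(entry$homepage)) {
    add("homepage", "homepage_url", "homepage must be in a URL format")
  }

  labels <- entry$contact$label
  if (is.null(labels) || length(labels) != 1L || !is_scalar_chr(labels[[1]]) ||
      grepl("@", labels[[1]], fixed = TRUE)) {
    add("contact.label", "contact_label",
        "contact must have exactly one label, not containing '@'")
  }
  emails <- entry$contact$email
  if (is.null(emails) || length(emails) != 1L || !is_email_string(emails[[1]])) {
    add("contact.email", "contact_email",
        "contact must have exactly one email address in email format")
  }

  prods <- entry$products
  if (length(prods) == 0L) {
    add("products", "products_format",
        "at least the canonical product (id.owl) must be listed")
  } else {
    ok <- vapply(prods, function(p) {
      is_scalar_chr(p$id) &&
        grepl("^[A-Za-z0-9_-]+(\\.[A-Za-z0-9.]+|/.+)$", p$id)
    }, logical(1))
    if (any(!ok)) {
      add("products", "products_format",
          paste0("product id(s) not in id.ext or id/subpath form: ",
                 paste(vapply(prods[!ok], function(p)
                   if (is_scalar_chr(p$id)) p$id else "<missing>",
                   character(1)), collapse = ", ")))
    }
  }

  if (!is_scalar_chr(entry$description) || !nzchar(trimws(entry$description))) {
    add("description", "description_present", "description must be present")
  }

  lic_url <- entry$license$url
  lic_label <- entry$license$label
  if (!is_url_string(lic_url)) {
    add("license.url", "license_url_format",
        "license URL must be present and in a URL format")
  } else if (is_scalar_chr(lic_label)) {
    # correspondence is only testable when the URL is a recognized license
    if (isFALSE(license_label_matches_url(lic_label, lic_url))) {
      add("license.label", "license_label_consistent",
          sprintf("license label '%s' does not correspond to %s",
                  lic_label, lic_url))
    }
  } else {
    add("license.label", "license_label_consistent",
        "license label must be present")
  }

  status <- entry$activity_status
  if (!is_scalar_chr(status) ||
      !status %in% c("active", "inactive", "orphaned")) {
    add("activity_status", "activity_status_enum",
        "activity status must be one of 'active', 'inactive' or 'orphaned'")
  }

  if (!is.logical(entry$is_obsolete) || length(entry$is_obsolete) != 1L ||
      is.na(entry$is_obsolete)) {
    add("is_obsolete", "obsolete_boolean",
        "obsoletion status must be a boolean ('true' or 'false')")
  }

  v
}

#' Validate a list of registry entries
#'
#' @param entries List of [registry_entry()] objects.
#' @return Named list (by ontology id) of violation lists.
#' @export
validate_registry <- function(entries) {
  out <- lapply(entries, validate_entry)
  names(out) <- vapply(entries, function(e) e$id %||% "", character(1))
  out
}

# JSON-lines rendering of violations, one object per line (stable field order)
violations_to_jsonl <- function(violations, id = NULL) {
  lines <- vapply(violations, function(v) {
    obj <- c(if (!is.null(id)) list(id = id),
             v[c("field_path", "rule_id", "severity", "message")])
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE))
  }, character(1))
  paste(lines, collapse = "\n")
}

violations_to_text <- function(violations, id = NULL) {
  if (length(violations) == 0L) {
    return(sprintf("%s: no violations", id %||% "registry entry"))
  }
  hdr <- sprintf("%s: %d violation(s)", id %||% "registry entry",
                 length(violations))
  body <- vapply(violations, function(v) {
    sprintf("  [%s] %s (%s): %s", v$severity, v$rule_id, v$field_path,
            v$message)
  }, character(1))
  paste(c(hdr, body), collapse = "\n")
}
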