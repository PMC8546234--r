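# CheckResult / CheckContext plumbing shared by all principle checks.

#' Construct a check result
#'
#' The outcome of one principle check: a status, human-readable findings with
#' fix suggestions, and named metric counts. A `WARN` or `ERROR` status must
#' carry at least one message.
#'
#' @param principle_id Principle identifier (`"FP1"` ... `"FP20"`, see
#'   [principles()]).
#' @param status One of [check_statuses()].
#' @param messages Character vector of findings.
#' @param metrics Named list of integer counts.
#' @return An object of class `obo_check_result`.
#' @export
check_result <- function(principle_id, status, messages = character(),
                         metrics = list()) {
  if (!principle_id %in% principle_ids()) {
    stop("unknown principle id: ", principle_id)
  }
  if (!status %in% check_statuses()) {
    stop("unknown status: ", status)
  }
  if (status %in% c("WARN", "ERROR") && length(messages) == 0L) {
    stop("a ", status, " result must carry at least one message")
  }
  metrics <- lapply(metrics, as.integer)
  structure(
    list(principle_id = principle_id, status = status,
         messages = as.character(messages), metrics = metrics),
    class = "obo_check_result"
  )
}

#' @export
print.obo_check_result <- function(x, ...) {
  cat(sprintf("[%s] %s (%s)\n", x$status, x$principle_id,
              principle_name(x$principle_id)))
  for (m in x$messages) cat("  -", m, "\n")
  if (length(x$metrics) > 0L) {
    cat("  metrics:", paste(names(x$metrics), unlist(x$metrics), sep = "=",
                            collapse = ", "), "\n")
  }
  invisible(x)
}

# worst-of over a set of per-finding severities; PASS when none
status_from_findings <- function(severities) {
  if (length(severities) == 0L) "PASS" else worst_status(severities)
}

#' Check configuration profile
#'
#' Tunable severities and thresholds for the principle checks. Definition
#' faults default to ERROR for duplicate and multiple definitions and WARN
#' for missing definitions; label faults all default to ERROR. Maintenance
#' recency cutoffs default to 2 years (WARN) and 3 years (ERROR); these
#' cutoffs are non-normative and fully overridable.
#'
#' @param definition_severity Named character vector with elements `missing`,
#'   `multiple`, `duplicate`.
#' @param label_severity Same shape, for label faults.
#' @param warn_years,error_years Maintenance recency cutoffs in years;
#'   `warn_years` must be smaller than `error_years`.
#' @param preferred_prefix Override for the canonical IRI prefix when it is
#'   not simply the uppercased registry id (mixed-case idspaces exist).
#' @return A list of class `obo_check_config`.
#' @export
check_config <- function(definition_severity = c(missing = "WARN",
                                                 multiple = "ERROR",
                                                 duplicate = "ERROR"),
                         label_severity = c(missing = "ERROR",
                                            multiple = "ERROR",
                                            duplicate = "ERROR"),
                         warn_years = 2, error_years = 3,
                         preferred_prefix = NULL) {
  stopifnot(warn_years < error_years)
  stopifnot(all(c("missing", "multiple", "duplicate") %in%
                  names(definition_severity)))
  stopifnot(all(c("missing", "multiple", "duplicate") %in%
                  names(label_severity)))
  structure(
    list(definition_severity = definition_severity,
         label_severity = label_severity,
         warn_years = warn_years, error_years = error_years,
         preferred_prefix = preferred_prefix),
    class = "obo_check_config"
  )
}

#' Read a severity/threshold profile file
#'
#' Flat `key = value` lines; `#` starts a comment. Recognized keys:
#' `definitions.missing`, `definitions.multiple`, `definitions.duplicate`,
#' `labels.missing`, `labels.multiple`, `labels.duplicate` (status values),
#' `maintenance.warn_years`, `maintenance.error_years` (numbers),
#' `preferred_prefix` (string).
#'
#' @param path Path to the profile file.
#' @return An `obo_check_config`.
#' @export
read_check_profile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- regmatches(lines, regexec("^([A-Za-z_.]+)[[:space:]]*=[[:space:]]*(.*)$",
                                  lines))
  bad <- lines[vapply(kv, length, integer(1)) == 0L]
  if (length(bad) > 0L) {
    stop("malformed profile line(s): ", paste(bad, collapse = "; "))
  }
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- trimws(vapply(kv, `[`, character(1), 3L))
  cfg <- check_config()
  pick <- function(key, default) if (key %in% keys) vals[match(key, keys)] else default
  for (slot in c("missing", "multiple", "duplicate")) {
    cfg$definition_severity[[slot]] <-
      pick(paste0("definitions.", slot), cfg$definition_severity[[slot]])
    cfg$label_severity[[slot]] <-
      pick(paste0("labels.", slot), cfg$label_severity[[slot]])
  }
  cfg$warn_years <- as.numeric(pick("maintenance.warn_years", cfg$warn_years))
  cfg$error_years <- as.numeric(pick("maintenance.error_years", cfg$error_years))
  if ("preferred_prefix" %in% keys) {
    cfg$preferred_prefix <- vals[match("preferred_prefix", keys)]
  }
  stopifnot(cfg$warn_years < cfg$error_years)
  cfg
}

#' Load a Relations Ontology property index
#'
#' Two-column tab-separated file (property IRI, label). The package ships a
#' small reference index under `inst/extdata/ro_index.tsv`; a fuller index
#' can be substituted without code changes.
#'
#' @param path Path to the TSV; defaults to the shipped index.
#' @return An object of class `obo_ro_index` with elements `iris` (character
#'   set) and `labels` (named map, lowercase label to IRI).
#' @export
load_ro_index <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ro_index.tsv", package = "obodash",
                        mustWork = TRUE)
  }
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           col.names = c("iri", "label"),
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#")
  labels <- stats::setNames(tab$iri, tolower(trimws(tab$label)))
  structure(list(iris = unique(tab$iri), labels = labels),
            class = "obo_ro_index")
}

#' Construct a check context
#'
#' Bundles the run-wide inputs the principle checks consume: the reference
#' date for maintenance checks, the peer registry entries for scope
#' comparison, the Relations Ontology property index, the HTTP prober (a
#' function `url -> integer status code`, stubbable for tests), the severity
#' profile, and the offline flag. Offline is the default: no network access
#' ever happens unless `offline = FALSE` and a prober is available.
#'
#' @param today Reference date (`Date`).
#' @param peers List of [registry_entry()] objects for scope comparison.
#' @param ro_index An `obo_ro_index`; defaults to the shipped index.
#' @param http_prober Function mapping a URL to an HTTP status code.
#' @param offline If `TRUE`, homepage resolution is not probed.
#' @param config An [check_config()] profile.
#' @return A list of class `obo_check_context`.
#' @export
check_context <- function(today = Sys.Date(), peers = list(),
                          ro_index = NULL, http_prober = NULL,
                          offline = TRUE, config = check_config()) {
  if (is.null(ro_index)) {
    ro_index <- load_ro_index()
  }
  structure(
    list(today = as.Date(today), peers = peers, ro_index = ro_index,
         http_prober = http_prober, offline = offline, config = config),
    class = "obo_check_context"
  )
}

# canonical IRI prefix for an ontology: uppercased registry id unless the
# profile overrides it
canonical_prefix <- function(entry, config = check_config()) {
  config$preferred_prefix %||% toupper(entry$id)
}

#' Live HTTP prober
#'
#' Resolves a URL with a HEAD request (GET fallback), following at most five
#' redirects with a ten-second timeout, and returns the final HTTP status
#' code. Requires the curl package; only used when a context is built with
#' `offline = FALSE` and no stub prober.
#'
#' @param url URL to probe.
#' @return Integer HTTP status code.
#' @export
default_http_prober <- function(url) {
  if (!requireNamespace("curl", quietly = TRUE)) {
    stop("live homepage probing needs the curl package; run offline instead")
  }
  h <- curl::new_handle(nobody = TRUE, followlocation = TRUE, maxredirs = 5,
                        timeout = 10)
  res <- tryCatch(curl::curl_fetch_memory(url, handle = h), error = identity)
  if (inherits(res, "error")) {
    h2 <- curl::new_handle(followlocation = TRUE, maxredirs = 5, timeout = 10)
    res <- curl::curl_fetch_memory(url, handle = h2)
  }
  as.integer(res$status_code)
}
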