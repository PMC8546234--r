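#' Check status vocabulary
#'
#' Per-cell outcomes of a principle check, ordered for worst-of aggregation:
#' `PASS < INFO < WARN < ERROR`. `"NA"` marks a cell that was not evaluated
#' (e.g. an inactive ontology) and is excluded from aggregation.
#'
#' @return Character vector of the five status values in aggregation order.
#' @export
check_statuses <- function() {
  c("PASS", "INFO", "WARN", "ERROR", "NA")
}

# ranks for worst-of; "NA" deliberately absent
.status_rank <- c(PASS = 1L, INFO = 2L, WARN = 3L, ERROR = 4L)

#' Worst-of status aggregation
#'
#' Summary status of a set of check outcomes: the maximum in the order
#' `PASS < INFO < WARN < ERROR`. `"NA"` cells are ignored; if every cell is
#' `"NA"` the summary is `"NA"`.
#'
#' @param statuses Character vector of status values.
#' @return A single status string.
#' @examples
#' worst_status(c("PASS", "WARN", "PASS")) # "WARN"
#' worst_status(c("NA", "NA"))             # "NA"
#' @export
worst_status <- function(statuses) {
  statuses <- statuses[!is.na(statuses)]
  statuses <- statuses[statuses != "NA"]
  if (length(statuses) == 0L) {
    return("NA")
  }
  bad <- setdiff(statuses, names(.status_rank))
  if (length(bad) > 0L) {
    stop("unknown status value(s): ", paste(bad, collapse = ", "))
  }
  names(.status_rank)[max(.status_rank[statuses])]
}

#' The thirteen automatable OBO Foundry principles
#'
#' Principle identifiers, display names and documentation links, in the fixed
#' dashboard column order (ascending FP number). FP10 (Commitment to
#' Collaboration) cannot be automated and never appears here or in any result.
#'
#' @return A data.frame with columns `id`, `name`, `url`.
#' @export
principles <- function() {
  data.frame(
    id = c("FP1", "FP2", "FP3", "FP4", "FP5", "FP6", "FP7", "FP8", "FP9",
           "FP11", "FP12", "FP16", "FP20"),
    name = c("Open", "Common Format", "URI/Identifier Space", "Versioning",
             "Scope", "Textual Definitions", "Relations", "Documentation",
             "Documented Plurality of Users", "Locus of Authority",
             "Naming Conventions", "Maintenance", "Responsiveness"),
    url = c(
      "http://obofoundry.org/principles/fp-001-open.html",
      "http://obofoundry.org/principles/fp-002-format.html",
      "http://obofoundry.org/principles/fp-003-uris.html",
      "http://obofoundry.org/principles/fp-004-versioning.html",
      "http://obofoundry.org/principles/fp-005-delineated-content.html",
      "http://obofoundry.org/principles/fp-006-textual-definitions.html",
      "http://obofoundry.org/principles/fp-007-relations.html",
      "http://obofoundry.org/principles/fp-008-documented.html",
      "http://obofoundry.org/principles/fp-009-users.html",
      "http://obofoundry.org/principles/fp-011-locus-of-authority.html",
      "http://obofoundry.org/principles/fp-012-naming-conventions.html",
      "http://obofoundry.org/principles/fp-016-maintenance.html",
      "http://obofoundry.org/principles/fp-020-responsiveness.html"
    ),
    stringsAsFactors = FALSE
  )
}

principle_ids <- function() principles()$id

principle_name <- function(id) {
  p <- principles()
  p$name[match(id, p$id)]
}

principle_url <- function(id) {
  p <- principles()
  p$url[match(id, p$id)]
}
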