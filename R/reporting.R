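# Dashboard assembly and rendering: ontologies as rows, principles as
# columns, a final worst-of Summary column, and per-ontology detail pages.
# All renderings are pure functions of (rows, metadata): with fixed metadata
# repeated rendering is byte-identical.

#' Construct a dashboard row
#'
#' One ontology's results across the 13 principles. The summary is always
#' recomputed as the worst-of over non-NA cells, never taken on trust.
#'
#' @param ontology_id Registry id of the ontology.
#' @param results Named list of `obo_check_result` objects covering every
#'   principle id exactly once (any order; stored in fixed principle order).
#' @return An object of class `obo_dashboard_row`.
#' @export
dashboard_row <- function(ontology_id, results) {
  ids <- principle_ids()
  if (!setequal(names(results), ids) || length(results) != length(ids)) {
    stop("results must contain each of the 13 principle ids exactly once")
  }
  results <- results[ids]
  for (id in ids) {
    r <- results[[id]]
    if (!inherits(r, "obo_check_result") || r$principle_id != id) {
      stop("results[['", id, "']] is not a check result for ", id)
    }
  }
  summary <- worst_status(vapply(results, `[[`, character(1), "status"))
  structure(list(ontology_id = ontology_id, results = results,
                 summary = summary),
            class = "obo_dashboard_row")
}

# an all-NA row for entries that are listed but not checked (inactive/obsolete)
na_dashboard_row <- function(ontology_id, reason) {
  results <- lapply(principle_ids(), function(id)
    check_result(id, "NA", messages = reason))
  names(results) <- principle_ids()
  dashboard_row(ontology_id, results)
}

row_statuses <- function(row) {
  vapply(row$results, `[[`, character(1), "status")
}

#' @export
print.obo_dashboard_row <- function(x, ...) {
  cat("<dashboard row>", x$ontology_id, "summary:", x$summary, "\n")
  st <- row_statuses(x)
  cat(" ", paste(names(st), st, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Run metadata for a dashboard
#'
#' Timestamps live only here so tests and reproducible runs can pin them.
#'
#' @param timestamp ISO-8601 UTC timestamp string.
#' @param tool_version Version string of the generating tool.
#' @param config_fingerprint Short fingerprint of the active profile.
#' @return A named list.
#' @export
run_metadata <- function(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                            tz = "UTC"),
                         tool_version =
                           as.character(utils::packageVersion("obodash")),
                         config_fingerprint = "default") {
  list(timestamp = timestamp, tool_version = tool_version,
       config_fingerprint = config_fingerprint)
}

#' Assemble the dashboard grid
#'
#' Sorts rows alphabetically by ontology id, recomputes every summary and
#' rejects duplicate ids.
#'
#' @param rows List of [dashboard_row()] objects.
#' @param meta [run_metadata()] for the run.
#' @return An object of class `obo_dashboard_grid`.
#' @export
assemble_grid <- function(rows, meta = run_metadata()) {
  ids <- vapply(rows, `[[`, character(1), "ontology_id")
  if (anyDuplicated(ids)) {
    stop("duplicate ontology id(s) in grid: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  rows <- rows[order(ids, method = "radix")]
  # dashboard_row() recomputes the summary; re-wrap to never trust input
  rows <- lapply(rows, function(r) dashboard_row(r$ontology_id, r$results))
  structure(list(rows = rows, run_metadata = meta),
            class = "obo_dashboard_grid")
}

#' @export
print.obo_dashboard_grid <- function(x, ...) {
  cat("<dashboard grid>", length(x$rows), "ontologies x",
      length(principle_ids()), "principles\n")
  for (r in x$rows) {
    cat(sprintf("  %-12s %s\n", r$ontology_id, r$summary))
  }
  invisible(x)
}

#' @export
summary.obo_dashboard_grid <- function(object, ...) {
  st <- t(vapply(object$rows, row_statuses,
                 character(length(principle_ids()))))
  rownames(st) <- vapply(object$rows, `[[`, character(1), "ontology_id")
  structure(st, class = c("obo_grid_summary", class(st)))
}

html_escape <- xml_escape

grid_header_names <- function() {
  p <- principles()
  c("Ontology", paste(p$id, p$name), "Summary")
}

render_grid_html <- function(grid) {
  p <- principles()
  head <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"/><title>Ontology principle dashboard</title>",
    "<style>",
    "table{border-collapse:collapse;font-family:sans-serif}",
    "td,th{border:1px solid #999;padding:4px 8px;text-align:center}",
    ".PASS{background:#c8e6c9}.INFO{background:#bbdefb}",
    ".WARN{background:#ffe0b2}.ERROR{background:#ffcdd2}.NA{background:#eee}",
    "</style></head><body>",
    "<h1>Ontology principle dashboard</h1>",
    sprintf("<p>Generated %s by obodash %s (profile %s)</p>",
            html_escape(grid$run_metadata$timestamp),
            html_escape(grid$run_metadata$tool_version),
            html_escape(grid$run_metadata$config_fingerprint)),
    "<table>",
    paste0("<tr><th>Ontology</th>",
           paste0(sprintf("<th><a href=\"%s\">%s</a></th>",
                          html_escape(p$url), html_escape(p$id)),
                  collapse = ""),
           "<th>Summary</th></tr>")
  )
  body <- vapply(grid$rows, function(r) {
    st <- row_statuses(r)
    cells <- paste0(sprintf("<td class=\"%s\">%s</td>", st, st),
                    collapse = "")
    paste0(
      sprintf("<tr><td><a href=\"reports/%s.html\">%s</a></td>",
              html_escape(r$ontology_id), html_escape(r$ontology_id)),
      cells,
      sprintf("<td class=\"%s\">%s</td></tr>", r$summary, r$summary)
    )
  }, character(1))
  paste(c(head, body, "</table></body></html>", ""), collapse = "\n")
}

grid_to_list <- function(grid) {
  list(
    run_metadata = grid$run_metadata,
    principles = principles(),
    rows = lapply(grid$rows, function(r) {
      list(
        ontology_id = r$ontology_id,
        summary = r$summary,
        results = lapply(r$results, function(cr) {
          list(status = cr$status,
               messages = as.list(cr$messages),
               metrics = cr$metrics)
        })
      )
    })
  )
}

render_grid_json <- function(grid) {
  as.character(jsonlite::toJSON(grid_to_list(grid), auto_unbox = TRUE,
                                pretty = TRUE, digits = NA, null = "null"))
}

#' Parse a JSON dashboard rendering back into a grid
#'
#' Inverse of the JSON rendering: statuses, messages and metrics are
#' reproduced exactly, making the JSON format lossless.
#'
#' @param json JSON string produced by [render_grid()] with
#'   `format = "json"`.
#' @return An `obo_dashboard_grid`.
#' @export
parse_grid_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  rows <- lapply(x$rows, function(r) {
    results <- lapply(names(r$results), function(id) {
      cr <- r$results[[id]]
      check_result(id, cr$status,
                   messages = vapply(cr$messages, identity, character(1)),
                   metrics = lapply(cr$metrics, as.integer))
    })
    names(results) <- names(r$results)
    dashboard_row(r$ontology_id, results)
  })
  assemble_grid(rows, meta = x$run_metadata)
}

render_grid_tsv <- function(grid) {
  ids <- principle_ids()
  header <- paste(c("ontology", ids, "summary"), collapse = "\t")
  lines <- vapply(grid$rows, function(r) {
    paste(c(r$ontology_id, unname(row_statuses(r)), r$summary),
          collapse = "\t")
  }, character(1))
  paste(c(header, lines, ""), collapse = "\n")
}

#' Render the dashboard grid
#'
#' Renders an assembled grid as a standalone HTML page (one row per
#' ontology, 13 principle columns plus a final Summary column, the ontology
#' id linking to its detail page), as lossless JSON (every result with
#' messages and metrics; see [parse_grid_json()]), or as a statuses-only
#' TSV. All renderings are byte-deterministic given fixed run metadata.
#'
#' @param grid An `obo_dashboard_grid` from [assemble_grid()].
#' @param format `"html"`, `"json"` or `"tsv"`.
#' @return A single string containing the rendered document.
#' @export
render_grid <- function(grid, format = c("html", "json", "tsv")) {
  stopifnot(inherits(grid, "obo_dashboard_grid"))
  format <- match.arg(format)
  switch(format,
         html = render_grid_html(grid),
         json = render_grid_json(grid),
         tsv = render_grid_tsv(grid))
}

#' Render a per-ontology detail report
#'
#' A standalone static HTML page: one section per non-PASS check with its
#' findings, metrics and a link to the principle's documentation; passing
#' checks are listed compactly at the end.
#'
#' @param row An `obo_dashboard_row`.
#' @return A single HTML string.
#' @export
render_detail <- function(row) {
  stopifnot(inherits(row, "obo_dashboard_row"))
  out <- c(
    "<!DOCTYPE html>",
    sprintf("<html><head><meta charset=\"utf-8\"/><title>%s report</title></head><body>",
            html_escape(row$ontology_id)),
    sprintf("<h1>Report for %s</h1>", html_escape(row$ontology_id)),
    sprintf("<p>Summary: <strong>%s</strong></p>", row$summary)
  )
  passing <- character()
  for (id in principle_ids()) {
    r <- row$results[[id]]
    if (r$status == "PASS") {
      passing <- c(passing, id)
      next
    }
    out <- c(out,
             sprintf("<h2>%s %s &mdash; %s</h2>", id,
                     html_escape(principle_name(id)), r$status),
             sprintf("<p><a href=\"%s\">Principle documentation</a></p>",
                     html_escape(principle_url(id))))
    if (length(r$messages) > 0L) {
      out <- c(out, "<ul>",
               sprintf("<li>%s</li>", html_escape(r$messages)), "</ul>")
    }
    if (length(r$metrics) > 0L) {
      out <- c(out, sprintf("<p>Metrics: %s</p>", html_escape(
        paste(names(r$metrics), unlist(r$metrics), sep = " = ",
              collapse = ", "))))
    }
  }
  if (length(passing) > 0L) {
    out <- c(out, "<h2>Passing checks</h2>",
             sprintf("<p>%s</p>", paste(passing, collapse = ", ")))
  }
  paste(c(out, "</body></html>", ""), collapse = "\n")
}

#' Write all dashboard outputs
#'
#' Writes `dashboard.html`, `dashboard.json` and `dashboard.tsv` (per
#' `formats`) plus `reports/<id>.html` for every row.
#'
#' @param grid An `obo_dashboard_grid`.
#' @param out_dir Output directory (created if missing).
#' @param formats Subset of `c("html", "json", "tsv")`.
#' @return Invisibly, the paths written.
#' @export
write_dashboard <- function(grid, out_dir,
                            formats = c("html", "json", "tsv")) {
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (f in formats) {
    p <- file.path(out_dir, paste0("dashboard.", f))
    writeLines(render_grid(grid, f), p, sep = "", useBytes = TRUE)
    paths <- c(paths, p)
  }
  rep_dir <- file.path(out_dir, "reports")
  dir.create(rep_dir, showWarnings = FALSE)
  for (r in grid$rows) {
    p <- file.path(rep_dir, paste0(r$ontology_id, ".html"))
    writeLines(render_detail(r), p, sep = "", useBytes = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
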