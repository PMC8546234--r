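# License handling shared by registry validation and the openness check.

# Canonical URLs of the licenses accepted as "open" for Foundry membership:
# public-domain CC0 1.0 and Creative Commons Attribution 3.0 or 4.0.
accepted_license_urls <- function() {
  c(
    cc0_1.0  = "https://creativecommons.org/publicdomain/zero/1.0",
    cc_by_3.0 = "https://creativecommons.org/licenses/by/3.0",
    cc_by_4.0 = "https://creativecommons.org/licenses/by/4.0"
  )
}

# Tolerated label spellings per canonical URL, after normalize_license_label().
accepted_license_labels <- function() {
  list(
    "https://creativecommons.org/publicdomain/zero/1.0" =
      c("CC0", "CC0 1.0", "CC0 1.0 UNIVERSAL", "CC 0", "CC 0 1.0"),
    "https://creativecommons.org/licenses/by/3.0" =
      c("CC BY 3.0", "CC BY 3.0 UNPORTED"),
    "https://creativecommons.org/licenses/by/4.0" =
      c("CC BY", "CC BY 4.0", "CC BY 4.0 INTERNATIONAL")
  )
}

# Case-, hyphen- and whitespace-insensitive label form ("CC-BY 4.0" -> "CC BY 4.0").
normalize_license_label <- function(label) {
  x <- toupper(trimws(label))
  x <- gsub("-", " ", x, fixed = TRUE)
  gsub("[[:space:]]+", " ", x)
}

is_url_string <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) &&
    grepl("^[A-Za-z][A-Za-z0-9+.-]*://[^[:space:]]+$", x)
}

# Syntactic only: exactly one '@', non-empty local part, dotted domain.
is_email_string <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) &&
    grepl("^[^@[:space:]]+@[^@[:space:]]+\\.[^@[:space:]]+$", x)
}

#' Canonicalize a license URL
#'
#' Normalizes a license URL so registry and ontology license declarations can
#' be compared robustly: the scheme and host are lowercased, `http` is
#' upgraded to `https` for `creativecommons.org` hosts, a `www.` host prefix
#' is dropped for the same hosts, and trailing slashes are stripped. The
#' function is idempotent.
#'
#' @param url A single URL string.
#' @return The canonical form of `url`.
#' @examples
#' canonicalize_license_url("http://creativecommons.org/licenses/by/4.0/")
#' @export
canonicalize_license_url <- function(url) {
  if (!is_url_string(url)) {
    stop("not a URL: ", deparse(substitute(url)), " = ",
         if (is.character(url) && length(url) == 1L) sQuote(url) else class(url))
  }
  m <- regmatches(url, regexec("^([A-Za-z][A-Za-z0-9+.-]*)://([^/]+)(.*)$", url))[[1]]
  scheme <- tolower(m[2])
  host <- tolower(m[3])
  rest <- m[4]
  if (grepl("(^|\\.)creativecommons\\.org$", host)) {
    scheme <- "https"
    host <- sub("^www\\.", "", host)
  }
  rest <- sub("/+$", "", rest)
  paste0(scheme, "://", host, rest)
}

# canonical URL if url-shaped, NA otherwise (annotation values may be plain text)
canonicalize_license_url_or_na <- function(x) {
  if (is_url_string(x)) canonicalize_license_url(x) else NA_character_
}

# TRUE/FALSE/NA: does the label correspond to the (canonicalized) url?
# NA when the url is not in the accepted table, i.e. correspondence untestable.
license_label_matches_url <- function(label, url) {
  canon <- canonicalize_license_url_or_na(url)
  if (is.na(canon)) {
    return(NA)
  }
  tab <- accepted_license_labels()
  if (!canon %in% names(tab)) {
    return(NA)
  }
  normalize_license_label(label) %in% tab[[canon]]
}
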