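# Ontology document loading. OWL documents are consumed at the RDF level:
# both readers produce a triple table (subject, predicate, object,
# is_literal) from which the same builder assembles the fact model the
# principle checks consume. Blank nodes never become entities.

NS_RDF     <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
NS_RDFS    <- "http://www.w3.org/2000/01/rdf-schema#"
NS_OWL     <- "http://www.w3.org/2002/07/owl#"
NS_XSD     <- "http://www.w3.org/2001/XMLSchema#"
NS_DCTERMS <- "http://purl.org/dc/terms/"
NS_DC      <- "http://purl.org/dc/elements/1.1/"
NS_OBO     <- "http://purl.obolibrary.org/obo/"

IRI_TYPE       <- paste0(NS_RDF, "type")
IRI_LABEL      <- paste0(NS_RDFS, "label")
IRI_DEFINITION <- paste0(NS_OBO, "IAO_0000115")  # OBO textual-definition property
IRI_DEPRECATED <- paste0(NS_OWL, "deprecated")
IRI_VERSION    <- paste0(NS_OWL, "versionIRI")
IRI_LICENSE    <- paste0(NS_DCTERMS, "license")

# Properties whose values look like licenses but use the wrong vocabulary;
# reported so the openness check can suggest dcterms:license instead.
license_near_miss_properties <- function() {
  c(paste0(NS_DC, "license"),
    paste0(NS_DC, "rights"),
    paste0(NS_DCTERMS, "rights"))
}

.category_iris <- c(
  "class" = paste0(NS_OWL, "Class"),
  "object_property" = paste0(NS_OWL, "ObjectProperty"),
  "data_property" = paste0(NS_OWL, "DatatypeProperty"),
  "annotation_property" = paste0(NS_OWL, "AnnotationProperty"),
  "named_individual" = paste0(NS_OWL, "NamedIndividual")
)

format_error <- function(message, line = NULL) {
  structure(list(message = message, line = line), class = "obo_format_error")
}

#' @export
print.obo_format_error <- function(x, ...) {
  cat("<format error>", x$message,
      if (!is.null(x$line)) sprintf("(line %s)", x$line) else "", "\n")
  invisible(x)
}

#' Test for a loader format error
#'
#' @param x Object returned by [load_ontology()].
#' @return `TRUE` if `x` is a format error rather than a loaded document.
#' @export
is_format_error <- function(x) inherits(x, "obo_format_error")

empty_triples <- function() {
  data.frame(subject = character(), predicate = character(),
             object = character(), is_literal = logical(),
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# RDF/XML

read_rdfxml_triples <- function(text) {
  doc <- xml2::read_xml(text)
  ns <- xml2::xml_ns(doc)
  ns <- c(ns, xml = "http://www.w3.org/XML/1998/namespace")
  expand <- function(qname) {
    parts <- strsplit(qname, ":", fixed = TRUE)[[1]]
    if (length(parts) == 1L) {
      return(parts[1])
    }
    uri <- ns[[parts[1]]]
    if (is.null(uri) || is.na(uri)) {
      stop("unknown namespace prefix: ", parts[1])
    }
    paste0(uri, paste(parts[-1], collapse = ":"))
  }
  subj <- character(); pred <- character(); obj <- character(); lit <- logical()
  emit <- function(s, p, o, is_lit) {
    subj[[length(subj) + 1L]] <<- s
    pred[[length(pred) + 1L]] <<- p
    obj[[length(obj) + 1L]] <<- o
    lit[[length(lit) + 1L]] <<- is_lit
  }
  getattr <- function(attrs, name) {
    if (name %in% names(attrs)) attrs[[name]] else NULL
  }
  resource_node <- function(node) {
    attrs <- xml2::xml_attrs(node, ns)
    about <- getattr(attrs, "rdf:about")
    if (is.null(about)) {
      return(NULL)  # rdf:nodeID / anonymous: blank node, never an entity
    }
    name <- expand(xml2::xml_name(node, ns))
    if (name != paste0(NS_RDF, "Description")) {
      emit(about, IRI_TYPE, name, FALSE)
    }
    for (child in xml2::xml_children(node)) {
      p <- expand(xml2::xml_name(child, ns))
      cattrs <- xml2::xml_attrs(child, ns)
      res <- getattr(cattrs, "rdf:resource")
      if (!is.null(res)) {
        emit(about, p, res, FALSE)
      } else if (length(xml2::xml_children(child)) > 0L) {
        for (nested in xml2::xml_children(child)) {
          nested_about <- resource_node(nested)
          if (!is.null(nested_about)) {
            emit(about, p, nested_about, FALSE)
          }
        }
      } else {
        emit(about, p, xml2::xml_text(child), TRUE)
      }
    }
    about
  }
  root_name <- expand(xml2::xml_name(xml2::xml_root(doc), ns))
  if (root_name != paste0(NS_RDF, "RDF")) {
    stop("not an RDF/XML document (root is not rdf:RDF)")
  }
  for (node in xml2::xml_children(doc)) {
    resource_node(node)
  }
  data.frame(subject = subj, predicate = pred, object = obj, is_literal = lit,
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Turtle. A compact purpose-built reader covering the constructs OBO release
# files use in their headers and term frames: @prefix/@base, IRIs, prefixed
# names, 'a', string literals with escapes, language tags and datatypes,
# booleans/numbers, and ';'/',' continuation lists. Blank-node property
# lists '[...]' and collections '(...)' are out of its subset and raise a
# parse error, which load_ontology() surfaces as a format error.

turtle_tokenize <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L
  line <- 1L
  tokens <- vector("list", 0L)
  push <- function(type, value) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value,
                                           line = line)
  }
  err <- function(msg) stop(sprintf("turtle parse error at line %d: %s",
                                    line, msg), call. = FALSE)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "\n") { line <- line + 1L; i <- i + 1L; next }
    if (grepl("^[[:space:]]$", ch)) { i <- i + 1L; next }
    if (ch == "#") {
      while (i <= n && chars[i] != "\n") i <- i + 1L
      next
    }
    if (ch == "<") {
      j <- i + 1L
      while (j <= n && chars[j] != ">") {
        if (chars[j] == "\n") err("newline inside IRI")
        j <- j + 1L
      }
      if (j > n) err("unterminated IRI")
      push("iri", paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + 1L
      next
    }
    if (ch == "\"") {
      # long (triple-quoted) or plain string
      long <- i + 2L <= n && chars[i + 1L] == "\"" && chars[i + 2L] == "\""
      j <- if (long) i + 3L else i + 1L
      buf <- character(0)
      repeat {
        if (j > n) err("unterminated string")
        cj <- chars[j]
        if (cj == "\\") {
          if (j + 1L > n) err("dangling escape")
          esc <- chars[j + 1L]
          val <- switch(esc,
            "n" = "\n", "t" = "\t", "r" = "\r", "\"" = "\"", "\\" = "\\",
            "u" = {
              if (j + 5L > n) err("truncated \\u escape")
              code <- paste(chars[(j + 2L):(j + 5L)], collapse = "")
              j <- j + 4L
              intToUtf8(strtoi(code, 16L))
            },
            err(paste0("unsupported escape \\", esc))
          )
          buf <- c(buf, val)
          j <- j + 2L
          next
        }
        if (!long && cj == "\"") break
        if (long && cj == "\"" && j + 2L <= n && chars[j + 1L] == "\"" &&
            chars[j + 2L] == "\"") break
        if (cj == "\n") {
          if (!long) err("newline in plain string")
          line <- line + 1L
        }
        buf <- c(buf, cj)
        j <- j + 1L
      }
      push("string", paste(buf, collapse = ""))
      i <- if (long) j + 3L else j + 1L
      # optional language tag or datatype
      if (i <= n && chars[i] == "@") {
        j <- i + 1L
        while (j <= n && grepl("^[A-Za-z0-9-]$", chars[j])) j <- j + 1L
        push("langtag", paste(chars[(i + 1L):(j - 1L)], collapse = ""))
        i <- j
      } else if (i + 1L <= n && chars[i] == "^" && chars[i + 1L] == "^") {
        push("datatype_marker", "^^")
        i <- i + 2L
      }
      next
    }
    if (ch %in% c(".", ";", ",")) {
      # '.' may also start a decimal; inside our subset a bare '.' is a
      # statement terminator
      push(switch(ch, "." = "dot", ";" = "semicolon", "," = "comma"), ch)
      i <- i + 1L
      next
    }
    if (ch %in% c("[", "]", "(", ")")) {
      err(sprintf("'%s' (blank-node property lists and collections are not supported)", ch))
    }
    # bare token: pname, keyword, number, boolean, '@prefix'
    j <- i
    while (j <= n && !grepl("^[[:space:]]$", chars[j]) &&
           !chars[j] %in% c(";", ",", "\"", "<", "[", "]", "(", ")", "#")) {
      j <- j + 1L
    }
    tok <- paste(chars[i:(j - 1L)], collapse = "")
    # a trailing '.' ends the statement unless part of a number/pname-internal
    while (grepl("\\.$", tok) && !grepl("^[0-9.+-]+$", tok)) {
      tok <- substr(tok, 1L, nchar(tok) - 1L)
      j <- j - 1L
    }
    if (nzchar(tok)) {
      push("word", tok)
    }
    i <- j
    next
  }
  tokens
}

read_turtle_triples <- function(text) {
  tokens <- turtle_tokenize(text)
  prefixes <- list()
  base <- ""
  k <- 1L
  ntok <- length(tokens)
  peek <- function() if (k <= ntok) tokens[[k]] else NULL
  take <- function() {
    if (k > ntok) stop("turtle parse error: unexpected end of input",
                       call. = FALSE)
    t <- tokens[[k]]
    k <<- k + 1L
    t
  }
  expect <- function(type) {
    t <- take()
    if (t$type != type) {
      stop(sprintf("turtle parse error at line %d: expected %s, got %s '%s'",
                   t$line, type, t$type, t$value), call. = FALSE)
    }
    t
  }
  resolve <- function(tok) {
    # returns list(value, is_literal)
    if (tok$type == "iri") {
      v <- tok$value
      if (!grepl("^[A-Za-z][A-Za-z0-9+.-]*:", v)) v <- paste0(base, v)
      return(list(value = v, is_literal = FALSE))
    }
    if (tok$type == "string") {
      # swallow decorations
      if (!is.null(peek()) && peek()$type == "langtag") take()
      if (!is.null(peek()) && peek()$type == "datatype_marker") {
        take()
        dt <- take()
        if (!dt$type %in% c("iri", "word")) {
          stop(sprintf("turtle parse error at line %d: bad datatype", dt$line),
               call. = FALSE)
        }
      }
      return(list(value = tok$value, is_literal = TRUE))
    }
    if (tok$type == "word") {
      v <- tok$value
      if (v == "a") {
        return(list(value = IRI_TYPE, is_literal = FALSE))
      }
      if (v %in% c("true", "false")) {
        return(list(value = v, is_literal = TRUE))
      }
      if (grepl("^[+-]?[0-9]", v)) {
        return(list(value = v, is_literal = TRUE))
      }
      if (grepl("^_:", v)) {
        return(list(value = v, is_literal = FALSE))
      }
      m <- regmatches(v, regexec("^([A-Za-z0-9_.-]*):(.*)$", v))[[1]]
      if (length(m) == 0L) {
        stop(sprintf("turtle parse error at line %d: unexpected token '%s'",
                     tok$line, v), call. = FALSE)
      }
      pfx <- m[2]
      local <- m[3]
      uri <- prefixes[[pfx]]
      if (is.null(uri)) {
        stop(sprintf("turtle parse error at line %d: undeclared prefix '%s:'",
                     tok$line, pfx), call. = FALSE)
      }
      return(list(value = paste0(uri, local), is_literal = FALSE))
    }
    stop(sprintf("turtle parse error at line %d: unexpected %s",
                 tok$line, tok$type), call. = FALSE)
  }

  subj <- character(); pred <- character(); obj <- character(); lit <- logical()
  emit <- function(s, p, o, is_lit) {
    subj[[length(subj) + 1L]] <<- s
    pred[[length(pred) + 1L]] <<- p
    obj[[length(obj) + 1L]] <<- o
    lit[[length(lit) + 1L]] <<- is_lit
  }

  while (!is.null(peek())) {
    tok <- take()
    if (tok$type == "word" &&
        tolower(tok$value) %in% c("@prefix", "prefix")) {
      p <- expect("word")$value
      if (!grepl(":$", p)) {
        stop(sprintf("turtle parse error at line %d: bad prefix declaration",
                     tok$line), call. = FALSE)
      }
      u <- expect("iri")$value
      prefixes[[sub(":$", "", p)]] <- u
      if (!is.null(peek()) && peek()$type == "dot") take()
      next
    }
    if (tok$type == "word" && tolower(tok$value) %in% c("@base", "base")) {
      base <- expect("iri")$value
      if (!is.null(peek()) && peek()$type == "dot") take()
      next
    }
    s <- resolve(tok)
    if (s$is_literal) {
      stop(sprintf("turtle parse error at line %d: literal subject",
                   tok$line), call. = FALSE)
    }
    repeat {
      p <- resolve(take())
      if (p$is_literal) {
        stop("turtle parse error: literal predicate", call. = FALSE)
      }
      repeat {
        o <- resolve(take())
        emit(s$value, p$value, o$value, o$is_literal)
        nxt <- take()
        if (nxt$type == "comma") next
        if (nxt$type == "semicolon") break
        if (nxt$type == "dot") break
        stop(sprintf("turtle parse error at line %d: expected '.', ';' or ','",
                     nxt$line), call. = FALSE)
      }
      if (nxt$type == "dot") break
      # after ';' the statement may still end with '.'
      if (!is.null(peek()) && peek()$type == "dot") { take(); break }
    }
  }
  data.frame(subject = subj, predicate = pred, object = obj, is_literal = lit,
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Fact-model builder shared by both readers

build_ontology_document <- function(triples, warnings = character()) {
  tp <- triples
  is_blank <- function(x) startsWith(x, "_:")

  onto_subjects <- unique(tp$subject[tp$predicate == IRI_TYPE &
                                       tp$object == paste0(NS_OWL, "Ontology") &
                                       !tp$is_literal])
  onto_subjects <- onto_subjects[!is_blank(onto_subjects)]
  ontology_iri <- if (length(onto_subjects) > 0L) onto_subjects[[1]] else NULL
  if (length(onto_subjects) > 1L) {
    warnings <- c(warnings, "multiple ontology headers; keeping the first")
  }

  version_iri <- NULL
  if (!is.null(ontology_iri)) {
    vr <- tp$object[tp$subject == ontology_iri & tp$predicate == IRI_VERSION]
    if (length(vr) > 1L) {
      warnings <- c(warnings,
                    "multiple version IRIs; keeping the first in document order")
    }
    if (length(vr) > 0L) version_iri <- vr[[1]]
  }

  annotations <- list()
  if (!is.null(ontology_iri)) {
    hdr <- tp[tp$subject == ontology_iri &
                !tp$predicate %in% c(IRI_TYPE, IRI_VERSION), , drop = FALSE]
    for (p in unique(hdr$predicate)) {
      vals <- hdr$object[hdr$predicate == p]
      if (length(vals) > 0L) annotations[[p]] <- vals
    }
  }

  # declared entities
  decl <- tp[tp$predicate == IRI_TYPE & tp$object %in% .category_iris &
               !is_blank(tp$subject), , drop = FALSE]
  cat_of <- stats::setNames(names(.category_iris), .category_iris)
  entity_iris <- unique(decl$subject)
  categories <- stats::setNames(
    cat_of[decl$object[match(entity_iris, decl$subject)]], entity_iris
  )
  # subjects of label/definition annotations without a declaration are still
  # entities (sloppy but real inputs); defaulted to class
  used <- unique(tp$subject[tp$predicate %in% c(IRI_LABEL, IRI_DEFINITION) &
                              !is_blank(tp$subject)])
  used <- setdiff(used, c(entity_iris, ontology_iri))
  if (length(used) > 0L) {
    categories[used] <- "class"
    entity_iris <- c(entity_iris, used)
  }

  entities <- lapply(entity_iris, function(iri) {
    mine <- tp[tp$subject == iri, , drop = FALSE]
    dep_vals <- mine$object[mine$predicate == IRI_DEPRECATED & mine$is_literal]
    list(
      iri = iri,
      category = unname(categories[[iri]]),
      labels = mine$object[mine$predicate == IRI_LABEL & mine$is_literal],
      definitions = mine$object[mine$predicate == IRI_DEFINITION &
                                  mine$is_literal],
      deprecated = any(tolower(dep_vals) == "true")
    )
  })
  names(entities) <- entity_iris

  structure(
    list(ontology_iri = ontology_iri, version_iri = version_iri,
         annotations = annotations, entities = entities,
         warnings = warnings),
    class = "obo_ontology"
  )
}

#' @export
print.obo_ontology <- function(x, ...) {
  cats <- table(vapply(x$entities, `[[`, character(1), "category"))
  cat("<ontology>", x$ontology_iri %||% "<no ontology IRI>", "\n")
  if (!is.null(x$version_iri)) cat("  version IRI:", x$version_iri, "\n")
  cat("  entities:", length(x$entities),
      if (length(cats)) paste0("(", paste(names(cats), cats, sep = ": ",
                                          collapse = ", "), ")") else "", "\n")
  invisible(x)
}

sniff_format <- function(text) {
  head <- substr(trimws(text), 1L, 2000L)
  if (grepl("^<\\?xml", head) || grepl("<rdf:RDF", head, fixed = TRUE) ||
      grepl("^<", head)) {
    "rdfxml"
  } else {
    "turtle"
  }
}

#' Load an ontology document
#'
#' Reads an OWL document serialized as RDF/XML (`.owl`) or Turtle (`.ttl`)
#' and extracts the facts the principle checks consume: ontology IRI, version
#' IRI, ontology-level annotations, and one record per declared entity (IRI,
#' category, labels, textual definitions, deprecation flag). A document that
#' cannot be parsed yields a format-error object rather than an R error —
#' that outcome feeds the Common Format check directly. An unreadable path,
#' by contrast, is a genuine I/O error.
#'
#' @param source Path to the document, or the document text itself when
#'   `text = TRUE`.
#' @param format One of `"auto"` (content sniffing), `"rdfxml"`, `"turtle"`.
#' @param text If `TRUE`, `source` is the serialized document itself.
#' @return An `obo_ontology` document, or an `obo_format_error` (test with
#'   [is_format_error()]).
#' @examples
#' ttl <- '
#' @prefix owl: <http://www.w3.org/2002/07/owl#> .
#' @prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
#' <http://purl.obolibrary.org/obo/exf.owl> a owl:Ontology .
#' <http://purl.obolibrary.org/obo/EXF_0000001> a owl:Class ;
#'     rdfs:label "sample" .
#' '
#' doc <- load_ontology(ttl, text = TRUE)
#' @export
load_ontology <- function(source, format = c("auto", "rdfxml", "turtle"),
                          text = FALSE) {
  format <- match.arg(format)
  if (text) {
    content <- paste(source, collapse = "\n")
  } else {
    if (!file.exists(source)) {
      stop("cannot read ontology source: no such file: ", source)
    }
    content <- paste(readLines(source, warn = FALSE, encoding = "UTF-8"),
                     collapse = "\n")
    if (format == "auto") {
      ext <- tolower(tools::file_ext(source))
      if (ext == "ttl") format <- "turtle"
      if (ext %in% c("owl", "rdf", "xml")) format <- "rdfxml"
    }
  }
  if (format == "auto") {
    format <- sniff_format(content)
  }
  triples <- tryCatch(
    switch(format,
           rdfxml = read_rdfxml_triples(content),
           turtle = read_turtle_triples(content)),
    error = function(e) format_error(conditionMessage(e))
  )
  if (is_format_error(triples)) {
    return(triples)
  }
  build_ontology_document(triples)
}
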