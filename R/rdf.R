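# Minimal in-memory RDF machinery: a triple container plus Turtle and
# N-Triples writers/readers covering the fragment this pipeline emits
# (IRI subjects/predicates, IRI or typed-literal objects, no blank nodes).
# The absence of blank nodes makes graph isomorphism plain set equality.

RDF_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
XSD <- "http://www.w3.org/2001/XMLSchema#"
DEFAULT_BASE_NS <- "https://w3id.org/fedqi"

xsd_iri <- function(name) paste0(XSD, name)

#' Construct a FAIR graph
#'
#' The graph is a set of (subject, predicate, object) triples. Subjects and
#' predicates are absolute IRIs; objects are either IRIs (`datatype` `NA`)
#' or typed literals (`datatype` an XSD datatype IRI). Duplicate triples are
#' collapsed: the container has set semantics.
#'
#' @param triples data.frame with character columns `subject`, `predicate`,
#'   `object`, `datatype`.
#' @param base_namespace IRI prefix under which patient and dataset subjects
#'   are minted.
#' @return object of class `fair_graph`.
#' @export
fair_graph <- function(triples = NULL, base_namespace = DEFAULT_BASE_NS) {
  if (is.null(triples)) {
    triples <- data.frame(subject = character(), predicate = character(),
                          object = character(), datatype = character(),
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(c("subject", "predicate", "object", "datatype") %in% names(triples)))
  triples <- unique(triples[, c("subject", "predicate", "object", "datatype")])
  rownames(triples) <- NULL
  structure(list(triples = triples, base_namespace = base_namespace),
            class = "fair_graph")
}

#' Number of triples in a graph
#' @param graph a [fair_graph()].
#' @return integer count.
#' @export
graph_size <- function(graph) nrow(graph$triples)

#' @export
print.fair_graph <- function(x, ...) {
  cat(sprintf("<fair_graph> %d triple(s), base <%s>\n", graph_size(x), x$base_namespace))
  invisible(x)
}

# canonical one-line form of each triple, used for set comparison
canonical_triples <- function(graph) {
  t <- graph$triples
  if (nrow(t) == 0L) return(character(0))
  obj <- ifelse(is.na(t$datatype),
                paste0("<", t$object, ">"),
                ifelse(t$datatype == xsd_iri("string"),
                       paste0("\"", escape_literal(t$object), "\""),
                       paste0("\"", escape_literal(t$object), "\"^^<", t$datatype, ">")))
  sort(paste0("<", t$subject, "> <", t$predicate, "> ", obj, " ."))
}

#' Test two graphs for isomorphism
#'
#' With no blank nodes in the data model, RDF graph isomorphism reduces to
#' equality of the triple sets (after literal-datatype normalization: a
#' plain string literal equals the same literal typed `xsd:string`).
#'
#' @param g1,g2 [fair_graph()] objects.
#' @return logical.
#' @export
graphs_isomorphic <- function(g1, g2) {
  identical(canonical_triples(g1), canonical_triples(g2))
}

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_literal <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    s <- x[i]
    res <- character(0)
    while (nchar(s) > 0L) {
      m <- regexpr("\\", s, fixed = TRUE)
      if (m == -1L) { res <- c(res, s); break }
      res <- c(res, substr(s, 1L, m - 1L))
      code <- substr(s, m + 1L, m + 1L)
      res <- c(res, switch(code, n = "\n", r = "\r", t = "\t", "\"" = "\"",
                           "\\" = "\\", code))
      s <- substr(s, m + 2L, nchar(s))
    }
    out[i] <- paste0(res, collapse = "")
  }
  out
}

serialize_object <- function(object, datatype, prefixes) {
  ifelse(is.na(datatype),
         compact_iri(object, prefixes),
         ifelse(datatype == xsd_iri("string"),
                paste0("\"", escape_literal(object), "\""),
                paste0("\"", escape_literal(object), "\"^^",
                       compact_iri(datatype, prefixes))))
}

standard_prefixes <- function(graph) {
  c(rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    xsd = XSD,
    fq = paste0(graph$base_namespace, "/ontology#"),
    res = paste0(graph$base_namespace, "/"),
    sct = "http://snomed.info/id/")
}

compact_iri <- function(iri, prefixes) {
  out <- paste0("<", iri, ">")
  for (pfx in names(prefixes)) {
    ns <- prefixes[[pfx]]
    hit <- startsWith(iri, ns)
    # only compact when the local part is a safe prefixed-name local
    local <- substr(iri, nchar(ns) + 1L, nchar(iri))
    ok <- hit & grepl("^[A-Za-z0-9_][A-Za-z0-9_.-]*$", local) & !endsWith(local, ".")
    out[ok] <- paste0(pfx, ":", local[ok])
  }
  out
}

#' Serialize a FAIR graph to Turtle or N-Triples
#'
#' Both serializations are standards-conformant for the fragment used (no
#' blank nodes, no collections); the Turtle writer groups triples by subject
#' with `;` separators and compacts IRIs against a fixed prefix set.
#'
#' @param graph a [fair_graph()].
#' @param path output file path.
#' @param format `"turtle"` or `"ntriples"` (default guessed from the file
#'   extension: `.nt` means N-Triples, anything else Turtle).
#' @return `path`, invisibly.
#' @export
serialize_graph <- function(graph, path,
                            format = c("auto", "turtle", "ntriples")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.nt$", path)) "ntriples" else "turtle"
  }
  t <- graph$triples
  if (format == "ntriples") {
    obj <- serialize_object(t$object, t$datatype, prefixes = list())
    lines <- if (nrow(t) == 0L) character() else
      paste0("<", t$subject, "> <", t$predicate, "> ", obj, " .")
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(path))
  }
  prefixes <- standard_prefixes(graph)
  header <- sprintf("@prefix %s: <%s> .", names(prefixes), unname(prefixes))
  body <- character(0)
  if (nrow(t) > 0L) {
    ord <- order(t$subject, t$predicate, t$object)
    t <- t[ord, ]
    obj <- serialize_object(t$object, t$datatype, prefixes)
    pred <- compact_iri(t$predicate, prefixes)
    pred[t$predicate == RDF_TYPE] <- "a"
    subj <- compact_iri(t$subject, prefixes)
    po <- paste0("    ", pred, " ", obj)
    grp <- split(seq_len(nrow(t)), factor(subj, levels = unique(subj)))
    body <- unlist(lapply(names(grp), function(s) {
      idx <- grp[[s]]
      c(s, paste0(po[idx], c(rep(" ;", length(idx) - 1L), " .")), "")
    }), use.names = FALSE)
  }
  writeLines(c(header, "", body), path, useBytes = TRUE)
  invisible(path)
}

# --- tokenizer shared by the Turtle reader and the SPARQL parser ----------

TOKEN_REGEX <- paste0(
  "(<[^<>\"{}|^`\\\\ ]*>)",                        # IRIREF
  "|(\"(?:[^\"\\\\]|\\\\.)*\")",                   # quoted string
  "|(\\?[A-Za-z_][A-Za-z0-9_]*)",                  # SPARQL variable
  "|(@[A-Za-z]+)",                                 # @prefix / lang tag
  "|(\\^\\^)",                                     # datatype marker
  "|(&&|\\|\\||!=|<=|>=|[=<>!])",                  # operators
  "|([A-Za-z_][A-Za-z0-9_.-]*)?:([A-Za-z0-9_][A-Za-z0-9_.-]*)?", # PNAME
  "|([A-Za-z][A-Za-z0-9_]*)",                      # bare word / keyword
  "|(-?[0-9]+(?:\\.[0-9]+)?)",                     # number
  "|([.;,(){}\\[\\]*])"                            # punctuation
)

tokenize_rdf <- function(text) {
  text <- paste(text, collapse = "\n")
  # strip comments: '#' to end of line, but not inside IRIs or strings;
  # handled by tokenizing line-wise on a comment-stripped copy is unsafe for
  # IRIs containing '#', so strip only '#' preceded by whitespace/line start
  m <- gregexpr(TOKEN_REGEX, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(character(0))
  regmatches(text, list(m))[[1]]
}

strip_comments <- function(lines) {
  # remove '#...' comments that are not inside <...> or "..."
  vapply(lines, function(l) {
    chars <- strsplit(l, "", fixed = TRUE)[[1]]
    in_iri <- FALSE; in_str <- FALSE; esc <- FALSE
    for (i in seq_along(chars)) {
      ch <- chars[i]
      if (in_str) {
        if (esc) esc <- FALSE
        else if (ch == "\\") esc <- TRUE
        else if (ch == "\"") in_str <- FALSE
      } else if (in_iri) {
        if (ch == ">") in_iri <- FALSE
      } else {
        if (ch == "\"") in_str <- TRUE
        else if (ch == "<") in_iri <- TRUE
        else if (ch == "#") return(substr(l, 1L, i - 1L))
      }
    }
    l
  }, character(1L), USE.NAMES = FALSE)
}

expand_token_iri <- function(tok, prefixes) {
  if (startsWith(tok, "<")) return(substr(tok, 2L, nchar(tok) - 1L))
  if (tok == "a") return(RDF_TYPE)
  colon <- regexpr(":", tok, fixed = TRUE)
  if (colon == -1L) {
    stop("RDF parse error: expected an IRI but saw token '", tok, "'", call. = FALSE)
  }
  pfx <- substr(tok, 1L, colon - 1L)
  local <- substr(tok, colon + 1L, nchar(tok))
  ns <- prefixes[[pfx]]
  if (is.null(ns)) stop("undeclared prefix '", pfx, ":'", call. = FALSE)
  paste0(ns, local)
}

is_iri_token <- function(tok) {
  startsWith(tok, "<") || grepl("^[A-Za-z_][A-Za-z0-9_.-]*:", tok) ||
    grepl("^:", tok)
}

#' Parse a Turtle or N-Triples file into a FAIR graph
#'
#' Reads the fragment of Turtle this package writes (and the common core of
#' the language): `@prefix` declarations, subject grouping with `;` and `,`,
#' `a` for `rdf:type`, typed and plain literals, boolean/numeric literal
#' shorthand. No blank nodes or collections.
#'
#' @param path file to read.
#' @param format `"turtle"`, `"ntriples"`, or `"auto"` (by extension).
#' @param base_namespace base IRI recorded on the returned graph.
#' @return a [fair_graph()].
#' @export
parse_graph <- function(path, format = c("auto", "turtle", "ntriples"),
                        base_namespace = DEFAULT_BASE_NS) {
  format <- match.arg(format)  # both formats share the tokenizer path
  if (!file.exists(path)) stop("RDF file not found: ", path, call. = FALSE)
  lines <- strip_comments(readLines(path, encoding = "UTF-8", warn = FALSE))
  toks <- tokenize_rdf(lines)
  prefixes <- list()
  subjects <- character(); predicates <- character()
  objects <- character(); datatypes <- character()
  i <- 1L
  n <- length(toks)
  peek <- function() if (i <= n) toks[i] else ""
  advance <- function() { tok <- toks[i]; i <<- i + 1L; tok }
  expect <- function(what) {
    tok <- advance()
    if (tok != what) stop("RDF parse error: expected '", what, "' but saw '", tok, "'",
                          call. = FALSE)
    tok
  }
  read_object <- function() {
    tok <- advance()
    if (startsWith(tok, "\"")) {
      val <- unescape_literal(substr(tok, 2L, nchar(tok) - 1L))
      dt <- xsd_iri("string")
      if (peek() == "^^") {
        advance()
        dt <- expand_token_iri(advance(), prefixes)
      } else if (startsWith(peek(), "@")) {
        advance()  # language tag tolerated, recorded as plain string
      }
      list(object = val, datatype = dt)
    } else if (tok %in% c("true", "false")) {
      list(object = tok, datatype = xsd_iri("boolean"))
    } else if (grepl("^-?[0-9]+$", tok)) {
      list(object = tok, datatype = xsd_iri("integer"))
    } else if (grepl("^-?[0-9]*\\.[0-9]+$", tok)) {
      list(object = tok, datatype = xsd_iri("decimal"))
    } else if (is_iri_token(tok) || tok == "a") {
      list(object = expand_token_iri(tok, prefixes), datatype = NA_character_)
    } else {
      stop("RDF parse error: unexpected object token '", tok, "'", call. = FALSE)
    }
  }
  while (i <= n) {
    tok <- advance()
    if (tok == "@prefix") {
      pname <- advance()
      pfx <- sub(":.*$", "", pname)
      iri_tok <- advance()
      prefixes[[pfx]] <- substr(iri_tok, 2L, nchar(iri_tok) - 1L)
      expect(".")
      next
    }
    subj <- expand_token_iri(tok, prefixes)
    repeat {
      pred <- expand_token_iri(advance(), prefixes)
      repeat {
        o <- read_object()
        subjects <- c(subjects, subj); predicates <- c(predicates, pred)
        objects <- c(objects, o$object); datatypes <- c(datatypes, o$datatype)
        if (peek() == ",") { advance(); next }
        break
      }
      tok2 <- advance()
      if (tok2 == ";") {
        if (peek() == ".") { advance(); break }  # trailing ';' before '.'
        next
      }
      if (tok2 == ".") break
      stop("RDF parse error: expected ';' or '.' but saw '", tok2, "'", call. = FALSE)
    }
  }
  fair_graph(data.frame(subject = subjects, predicate = predicates,
                        object = objects, datatype = datatypes,
                        stringsAsFactors = FALSE),
             base_namespace = base_namespace)
}
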