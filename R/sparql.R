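# Embedded SPARQL 1.1 SELECT engine over a fair_graph: the subset needed by
# the shipped cohort-retrieval queries (PREFIX prologue, SELECT var-list or
# *, basic graph patterns with ';'/',' abbreviation, OPTIONAL groups, FILTER
# with comparisons on typed literals, && || ! and BOUND). Solutions are
# computed by relational joins over per-pattern binding tables.

sparql_parse <- function(query) {
  toks <- tokenize_rdf(strip_comments(strsplit(query, "\n", fixed = TRUE)[[1]]))
  n <- length(toks)
  i <- 1L
  peek <- function() if (i <= n) toks[i] else ""
  advance <- function() {
    if (i > n) stop("SPARQL parse error: unexpected end of query at token ", i,
                    call. = FALSE)
    tok <- toks[i]; i <<- i + 1L; tok
  }
  expect <- function(what) {
    tok <- advance()
    if (toupper(tok) != toupper(what)) {
      stop("SPARQL parse error at token ", i - 1L, ": expected '", what,
           "' but saw '", tok, "'", call. = FALSE)
    }
  }
  prefixes <- list()
  while (toupper(peek()) == "PREFIX") {
    advance()
    pname <- advance()
    pfx <- sub(":.*$", "", pname)
    iri_tok <- advance()
    prefixes[[pfx]] <- substr(iri_tok, 2L, nchar(iri_tok) - 1L)
  }
  expect("SELECT")
  vars <- character(0)
  star <- FALSE
  if (peek() == "*") { advance(); star <- TRUE }
  while (startsWith(peek(), "?")) vars <- c(vars, substring(advance(), 2L))
  if (!star && length(vars) == 0L) {
    stop("SPARQL parse error: SELECT needs variables or *", call. = FALSE)
  }
  expect("WHERE")

  term <- function(tok) {
    if (startsWith(tok, "?")) {
      list(kind = "var", value = substring(tok, 2L))
    } else if (startsWith(tok, "\"")) {
      val <- unescape_literal(substr(tok, 2L, nchar(tok) - 1L))
      dt <- xsd_iri("string")
      if (peek() == "^^") { advance(); dt <- expand_token_iri(advance(), prefixes) }
      list(kind = "literal", value = val, datatype = dt)
    } else if (tok %in% c("true", "false")) {
      list(kind = "literal", value = tok, datatype = xsd_iri("boolean"))
    } else if (grepl("^-?[0-9]+$", tok)) {
      list(kind = "literal", value = tok, datatype = xsd_iri("integer"))
    } else if (grepl("^-?[0-9]*\\.[0-9]+$", tok)) {
      list(kind = "literal", value = tok, datatype = xsd_iri("decimal"))
    } else {
      list(kind = "iri", value = expand_token_iri(tok, prefixes))
    }
  }

  parse_filter_expr <- function() {
    # precedence: || < && < comparison < unary ! < primary
    parse_or <- function() {
      left <- parse_and()
      while (peek() == "||") { advance(); left <- list(op = "||", left = left, right = parse_and()) }
      left
    }
    parse_and <- function() {
      left <- parse_cmp()
      while (peek() == "&&") { advance(); left <- list(op = "&&", left = left, right = parse_cmp()) }
      left
    }
    parse_cmp <- function() {
      left <- parse_unary()
      if (peek() %in% c("=", "!=", "<", ">", "<=", ">=")) {
        op <- advance()
        return(list(op = op, left = left, right = parse_unary()))
      }
      left
    }
    parse_unary <- function() {
      if (peek() == "!") { advance(); return(list(op = "!", left = parse_unary())) }
      parse_primary()
    }
    parse_primary <- function() {
      if (peek() == "(") { advance(); e <- parse_or(); expect(")"); return(e) }
      if (toupper(peek()) == "BOUND") {
        advance(); expect("(")
        v <- advance(); expect(")")
        return(list(op = "bound", var = substring(v, 2L)))
      }
      list(op = "term", term = term(advance()))
    }
    parse_or()
  }

  parse_group <- function() {
    expect("{")
    patterns <- list(); optionals <- list(); filters <- list()
    repeat {
      tok <- peek()
      if (tok == "}") { advance(); break }
      if (toupper(tok) == "OPTIONAL") {
        advance()
        optionals[[length(optionals) + 1L]] <- parse_group()
        next
      }
      if (toupper(tok) == "FILTER") {
        advance(); expect("(")
        filters[[length(filters) + 1L]] <- parse_filter_expr()
        expect(")")
        next
      }
      # triples block: subject (pred obj (',' obj)*) (';' pred obj...)* '.'
      subj <- term(advance())
      repeat {
        ptok <- advance()
        pred <- if (startsWith(ptok, "?")) list(kind = "var", value = substring(ptok, 2L))
                else list(kind = "iri", value = expand_token_iri(ptok, prefixes))
        repeat {
          obj <- term(advance())
          patterns[[length(patterns) + 1L]] <- list(s = subj, p = pred, o = obj)
          if (peek() == ",") { advance(); next }
          break
        }
        sep <- advance()
        if (sep == ";") {
          if (peek() %in% c(".", "}")) { if (peek() == ".") advance(); break }
          next
        }
        if (sep == ".") break
        if (sep == "}") { i <<- i - 1L; break }
        stop("SPARQL parse error at token ", i - 1L,
             ": expected '.', ';' or '}' but saw '", sep, "'", call. = FALSE)
      }
    }
    list(patterns = patterns, optionals = optionals, filters = filters)
  }

  group <- parse_group()
  if (i <= n) {
    stop("SPARQL parse error at token ", i, ": trailing content '", peek(), "'",
         call. = FALSE)
  }
  list(vars = vars, star = star, group = group, prefixes = prefixes)
}

# one binding table column per variable; cells hold encoded terms:
# "I<iri>" for IRIs, "L<datatype>\x1f<lexical>" for literals, NA unbound
encode_terms <- function(object, datatype) {
  ifelse(is.na(datatype), paste0("I", object),
         paste0("L", datatype, "\x1f", object))
}

decode_lexical <- function(enc) {
  ifelse(is.na(enc), NA_character_,
         ifelse(startsWith(enc, "I"), substring(enc, 2L),
                sub("^L[^\x1f]*\x1f", "", enc)))
}

decode_datatype <- function(enc) {
  out <- rep(NA_character_, length(enc))
  lit <- !is.na(enc) & startsWith(enc, "L")
  out[lit] <- sub("^L([^\x1f]*)\x1f.*$", "\\1", enc[lit])
  out
}

match_pattern <- function(triples, pat) {
  if (nrow(triples) == 0L) {
    vars <- unique(unlist(lapply(c("s", "p", "o"), function(pos) {
      if (pat[[pos]]$kind == "var") pat[[pos]]$value else NULL
    })))
    out <- data.frame(row.names = integer(0))[, FALSE, drop = FALSE]
    for (v in vars) out[[v]] <- character(0)
    return(out)
  }
  s_enc <- paste0("I", triples$subject)
  p_enc <- paste0("I", triples$predicate)
  o_enc <- encode_terms(triples$object, triples$datatype)
  keep <- rep(TRUE, nrow(triples))
  cols <- list()
  for (pos in c("s", "p", "o")) {
    tm <- pat[[pos]]
    enc <- switch(pos, s = s_enc, p = p_enc, o = o_enc)
    if (tm$kind == "var") {
      cols[[tm$value]] <- enc
    } else {
      want <- if (tm$kind == "iri") paste0("I", tm$value)
              else paste0("L", tm$datatype, "\x1f", tm$value)
      keep <- keep & enc == want
    }
  }
  if (length(cols) == 0L) {
    return(data.frame(row.names = seq_len(sum(keep)))[, FALSE, drop = FALSE])
  }
  # a variable repeated inside one pattern must bind consistently
  while (anyDuplicated(names(cols))) {
    j <- which(duplicated(names(cols)))[1L]
    first <- which(names(cols) == names(cols)[j])[1L]
    keep <- keep & cols[[first]] == cols[[j]]
    cols[[j]] <- NULL
  }
  out <- as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

join_bindings <- function(a, b, left = FALSE) {
  common <- intersect(names(a), names(b))
  if (nrow(a) == 0L && !left) {
    empty <- a
    for (v in setdiff(names(b), names(a))) empty[[v]] <- character(0)
    return(empty)
  }
  if (length(common) == 0L) {
    if (nrow(b) == 0L) {
      if (left) { for (v in names(b)) a[[v]] <- NA_character_; return(a) }
      return(cbind(a[0, , drop = FALSE],
                   b[0, , drop = FALSE]))
    }
    idx <- expand.grid(ia = seq_len(nrow(a)), ib = seq_len(nrow(b)))
    out <- cbind(a[idx$ia, , drop = FALSE], b[idx$ib, , drop = FALSE])
    rownames(out) <- NULL
    return(out)
  }
  merged <- merge(a, b, by = common, all.x = left, sort = FALSE)
  rownames(merged) <- NULL
  merged
}

sparql_typed_value <- function(enc) {
  # scalar: decode an encoded term for filter evaluation
  if (is.na(enc)) return(NULL)
  if (startsWith(enc, "I")) return(substring(enc, 2L))
  dt <- sub("^L([^\x1f]*)\x1f.*$", "\\1", enc)
  lex <- sub("^L[^\x1f]*\x1f", "", enc)
  typed_scalar(lex, dt)
}

typed_scalar <- function(lex, dt) {
  if (dt == xsd_iri("date")) return(as.Date(lex))
  if (dt %in% c(xsd_iri("integer"), xsd_iri("decimal"), xsd_iri("double"))) {
    return(as.numeric(lex))
  }
  if (dt == xsd_iri("boolean")) return(lex == "true")
  lex
}

eval_filter <- function(expr, bindings) {
  n <- nrow(bindings)
  eval_node <- function(node) {
    if (node$op == "term") {
      tm <- node$term
      if (tm$kind == "var") {
        if (!tm$value %in% names(bindings)) return(rep(list(NULL), n))
        return(lapply(bindings[[tm$value]], sparql_typed_value))
      }
      v <- if (tm$kind == "iri") tm$value else typed_scalar(tm$value, tm$datatype)
      return(rep(list(v), n))
    }
    if (node$op == "bound") {
      if (!node$var %in% names(bindings)) return(as.list(rep(FALSE, n)))
      return(as.list(!is.na(bindings[[node$var]])))
    }
    if (node$op == "!") {
      l <- eval_node(node$left)
      return(lapply(l, function(x) if (is.logical(x)) !x else NA))
    }
    l <- eval_node(node$left)
    r <- eval_node(node$right)
    mapply(function(x, y) {
      if (is.null(x) || is.null(y)) return(NA)
      res <- switch(node$op,
                    "=" = isTRUE(x == y), "!=" = isTRUE(x != y),
                    "<" = isTRUE(x < y), ">" = isTRUE(x > y),
                    "<=" = isTRUE(x <= y), ">=" = isTRUE(x >= y),
                    "&&" = isTRUE(x) && isTRUE(y),
                    "||" = isTRUE(x) || isTRUE(y))
      res
    }, l, r, SIMPLIFY = FALSE)
  }
  res <- eval_node(expr)
  vapply(res, isTRUE, logical(1L))
}

eval_group <- function(group, triples) {
  bindings <- data.frame(row.names = "1")[, FALSE, drop = FALSE]  # one empty solution
  first <- TRUE
  for (pat in group$patterns) {
    tbl <- match_pattern(triples, pat)
    bindings <- if (first) tbl else join_bindings(bindings, tbl)
    first <- FALSE
  }
  for (opt in group$optionals) {
    opt_bind <- eval_group(opt, triples)
    bindings <- join_bindings(bindings, opt_bind, left = TRUE)
  }
  for (f in group$filters) {
    if (nrow(bindings) > 0L) bindings <- bindings[eval_filter(f, bindings), , drop = FALSE]
  }
  rownames(bindings) <- NULL
  bindings
}

#' Run a SPARQL SELECT query against a FAIR graph
#'
#' Supports the query subset the shipped indicator queries use: PREFIX,
#' SELECT with a variable list or `*`, basic graph patterns (including
#' `;`/`,` abbreviations and `a`), OPTIONAL groups and FILTER expressions
#' (comparisons on typed literals, `&&`, `||`, `!`, `BOUND`). Literals are
#' returned typed: dates as `Date`, integers/decimals as numeric, booleans
#' as logical, so downstream indicator code never touches serialization.
#' A query referencing predicates absent from the graph yields zero rows;
#' a malformed query raises a parse error with the offending token position.
#'
#' @param graph a [fair_graph()].
#' @param query SPARQL SELECT text.
#' @return data.frame, one column per selected variable, typed as above;
#'   unbound OPTIONAL cells are `NA`.
#' @export
sparql_select <- function(graph, query) {
  q <- sparql_parse(query)
  bindings <- eval_group(q$group, graph$triples)
  vars <- if (q$star) names(bindings) else q$vars
  out <- list()
  for (v in vars) {
    enc <- if (v %in% names(bindings)) bindings[[v]] else rep(NA_character_, nrow(bindings))
    dts <- decode_datatype(enc)
    lex <- decode_lexical(enc)
    dt <- unique(dts[!is.na(dts)])
    col <- if (length(dt) == 1L) {
      if (dt == xsd_iri("date")) as.Date(lex)
      else if (dt %in% c(xsd_iri("integer"))) as.integer(lex)
      else if (dt %in% c(xsd_iri("decimal"), xsd_iri("double"))) as.numeric(lex)
      else if (dt == xsd_iri("boolean")) lex == "true"
      else lex
    } else lex
    out[[v]] <- col
  }
  res <- as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
  if (length(vars) > 0L && nrow(bindings) == 0L) res <- res[0, , drop = FALSE]
  res
}
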