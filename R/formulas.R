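#' Boolean search formulas over annotation records
#'
#' Cofactor objects and enzyme groups are defined by small boolean formulas
#' evaluated over a UniProt-style annotation catalog. A formula is a tree of
#' AND/OR/NOT nodes over field predicates. Three match modes exist per leaf:
#'
#' * `substring` — case-insensitive fixed substring of the whole cell,
#' * `regex` — case-insensitive regular expression,
#' * `tag` — exact membership in a semicolon-separated tag set (e.g. keyword
#'   ids `KW-0520` or ChEBI ids `CHEBI:57540`).
#'
#' The text syntax accepted by [parse_search_formula()] is
#' `field:"pattern"` (substring), `field~"pattern"` (regex) and
#' `field="TAG"` (exact tag), combined with `AND`, `OR`, `NOT` and
#' parentheses, e.g.
#' `(chebi="CHEBI:57540" OR chebi="CHEBI:58349") AND NOT keyword="KW-9999"`.
#' Recognized fields: `accession`, `entry_name`, `ec`, `catalytic`,
#' `nucleotide`, `keyword`, `chebi`.
#'
#' @param field Field name (see above).
#' @param pattern Pattern or tag to match.
#' @param mode One of `"substring"`, `"regex"`, `"tag"`.
#' @return A `search_formula` tree node.
#' @export
#' @examples
#' f <- ff_and(ff_leaf("ec", "1.1.1.", "substring"),
#'             ff_not(ff_leaf("keyword", "KW-0000", "tag")))
#' identical(f, parse_search_formula('ec:"1.1.1." AND NOT keyword="KW-0000"'))
ff_leaf <- function(field, pattern, mode = c("substring", "regex", "tag")) {
  mode <- match.arg(mode)
  field <- normalize_field(field)
  if (mode == "regex") {
    ok <- tryCatch({ grepl(pattern, "", perl = TRUE); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("invalid regex in leaf (", field, " ~ \"", pattern, "\")")
  }
  structure(list(op = "leaf", field = field, pattern = pattern, mode = mode),
            class = "search_formula")
}

#' @rdname ff_leaf
#' @param ... `search_formula` children.
#' @export
ff_and <- function(...) ff_node("and", list(...))

#' @rdname ff_leaf
#' @export
ff_or <- function(...) ff_node("or", list(...))

#' @rdname ff_leaf
#' @param x A `search_formula`.
#' @export
ff_not <- function(x) ff_node("not", list(x))

ff_node <- function(op, children) {
  stopifnot(length(children) >= 1)
  ok <- vapply(children, inherits, logical(1), "search_formula")
  if (!all(ok)) stop("all children of ", toupper(op), " must be search formulas")
  if (op == "not" && length(children) != 1) stop("NOT takes exactly one child")
  structure(list(op = op, children = children), class = "search_formula")
}

#' @export
print.search_formula <- function(x, ...) {
  cat(deparse_formula(x), "\n")
  invisible(x)
}

deparse_formula <- function(f) {
  if (f$op == "leaf") {
    op <- c(substring = ":", regex = "~", tag = "=")[[f$mode]]
    return(sprintf('%s%s"%s"', f$field, op, f$pattern))
  }
  if (f$op == "not") return(paste0("NOT ", wrap_child(f$children[[1]])))
  paste(vapply(f$children, wrap_child, character(1)),
        collapse = paste0(" ", toupper(f$op), " "))
}

wrap_child <- function(f) {
  if (f$op == "leaf") deparse_formula(f) else paste0("(", deparse_formula(f), ")")
}

catalog_fields <- function() {
  c(accession = "accession", entry_name = "entry_name", ec = "ec_number",
    catalytic = "catalytic_activity", nucleotide = "nucleotide_binding",
    keyword = "keyword_id", chebi = "chebi_id")
}

normalize_field <- function(field) {
  fields <- catalog_fields()
  if (field %in% names(fields)) return(field)
  hit <- names(fields)[fields == field]
  if (length(hit) == 1) return(hit)
  stop("unknown formula field '", field, "'; use one of ",
       paste(names(fields), collapse = ", "))
}

#' Parse a search formula from text
#'
#' @param text Formula text (syntax under [ff_leaf()]).
#' @return A `search_formula`.
#' @export
parse_search_formula <- function(text) {
  toks <- tokenize_formula(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$i <- 1L
  out <- parse_or(st)
  if (st$i <= length(st$toks)) {
    stop("trailing input in formula near '", st$toks[[st$i]]$text, "'")
  }
  out
}

tokenize_formula <- function(text) {
  toks <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    rest <- substr(text, i, n)
    if (grepl("^\\s", rest)) { i <- i + 1L; next }
    m <- regmatches(rest, regexpr("^(AND|OR|NOT)\\b", rest, ignore.case = TRUE))
    if (length(m) == 1) {
      toks[[length(toks) + 1L]] <- list(type = tolower(m), text = m)
      i <- i + nchar(m); next
    }
    ch <- substr(rest, 1, 1)
    if (ch %in% c("(", ")")) {
      toks[[length(toks) + 1L]] <- list(type = ch, text = ch)
      i <- i + 1L; next
    }
    m <- regmatches(rest, regexpr('^([A-Za-z_]+)\\s*([:~=])\\s*"([^"]*)"', rest, perl = TRUE))
    if (length(m) == 1) {
      parts <- regmatches(m, regexec('^([A-Za-z_]+)\\s*([:~=])\\s*"([^"]*)"', m, perl = TRUE))[[1]]
      mode <- c(":" = "substring", "~" = "regex", "=" = "tag")[[parts[3]]]
      toks[[length(toks) + 1L]] <- list(type = "leaf", text = m,
                                        field = parts[2], pattern = parts[4],
                                        mode = mode)
      i <- i + nchar(m); next
    }
    stop("cannot tokenize formula at: '", substr(rest, 1, 30), "'")
  }
  toks
}

peek <- function(st) if (st$i <= length(st$toks)) st$toks[[st$i]] else NULL
advance <- function(st) { st$i <- st$i + 1L; invisible(NULL) }

parse_or <- function(st) {
  parts <- list(parse_and(st))
  while (!is.null(tk <- peek(st)) && tk$type == "or") {
    advance(st)
    parts[[length(parts) + 1L]] <- parse_and(st)
  }
  if (length(parts) == 1) parts[[1]] else ff_node("or", parts)
}

parse_and <- function(st) {
  parts <- list(parse_factor(st))
  while (!is.null(tk <- peek(st)) && tk$type == "and") {
    advance(st)
    parts[[length(parts) + 1L]] <- parse_factor(st)
  }
  if (length(parts) == 1) parts[[1]] else ff_node("and", parts)
}

parse_factor <- function(st) {
  tk <- peek(st)
  if (is.null(tk)) stop("formula ends unexpectedly")
  if (tk$type == "not") { advance(st); return(ff_not(parse_factor(st))) }
  if (tk$type == "(") {
    advance(st)
    out <- parse_or(st)
    tk <- peek(st)
    if (is.null(tk) || tk$type != ")") stop("unbalanced parentheses in formula")
    advance(st)
    return(out)
  }
  if (tk$type == "leaf") {
    advance(st)
    return(ff_leaf(tk$field, tk$pattern, tk$mode))
  }
  stop("unexpected token '", tk$text, "' in formula")
}

#' Evaluate a search formula over a catalog
#'
#' @param catalog Annotation catalog tibble (see [read_annotation_catalog()]).
#' @param formula A `search_formula` or formula text.
#' @return Character vector of matching accessions (possibly empty).
#' @export
evaluate_search_formula <- function(catalog, formula) {
  if (is.character(formula)) formula <- parse_search_formula(formula)
  catalog$accession[formula_mask(catalog, formula)]
}

formula_mask <- function(catalog, f) {
  if (f$op == "leaf") {
    col <- catalog[[catalog_fields()[[f$field]]]]
    col[is.na(col)] <- ""
    return(switch(f$mode,
      substring = stringr::str_detect(tolower(col),
                                      stringr::fixed(tolower(f$pattern))),
      regex = grepl(f$pattern, col, ignore.case = TRUE, perl = TRUE),
      tag = vapply(strsplit(col, ";", fixed = TRUE), function(tags) {
        f$pattern %in% trimws(tags)
      }, logical(1))
    ))
  }
  masks <- lapply(f$children, function(ch) formula_mask(catalog, ch))
  switch(f$op,
         and = Reduce(`&`, masks),
         or = Reduce(`|`, masks),
         not = !masks[[1]])
}

#' Read a named formula file
#'
#' The file is YAML: each top-level name is an object; its value is either a
#' single formula string (evaluated against the protein catalog) or a mapping
#' with `enzymes` and `metabolites` formula strings. A scalar `reconstructed:
#' true` flag is tolerated and ignored during evaluation.
#'
#' @param path YAML file path.
#' @return Named list; each element has parsed `enzymes` and (optionally)
#'   `metabolites` formulas.
#' @export
read_formula_file <- function(path) {
  raw <- yaml::read_yaml(path)
  purrr::imap(raw, function(entry, name) {
    if (is.character(entry)) {
      list(enzymes = parse_search_formula(entry), metabolites = NULL)
    } else {
      list(
        enzymes = if (!is.null(entry$enzymes)) parse_search_formula(entry$enzymes),
        metabolites = if (!is.null(entry$metabolites)) parse_search_formula(entry$metabolites)
      )
    }
  })
}
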