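#' Gene-protein-reaction (GPR) rules
#'
#' A GPR rule is a boolean expression over gene identifiers that states
#' which gene products a reaction requires: `and` joins subunits of a
#' complex (all required), `or` joins isozymes (any suffices). Rules are
#' held as expression trees with node kinds `"all"`, `"any"`, `"leaf"`,
#' and the empty-rule sentinel `"none"` (no gene association).
#'
#' `parse_gpr()` parses BiGG-style rule strings (`and`/`or`,
#' case-insensitive, parentheses; `and` binds tighter than `or`).
#' `gpr_to_string()` serializes a tree back to a canonical string;
#' parsing a canonical string is the identity up to tree equality.
#' `gpr_genes()` lists the distinct gene identifiers in a rule.
#'
#' @param text Rule string, e.g. `"(G1 and G2) or G3"`. Empty or
#'   whitespace-only strings give the empty rule.
#' @param gpr A GPR tree as returned by `parse_gpr()`.
#' @return `parse_gpr()` a `gpr_rule` tree; `gpr_to_string()` a string
#'   (empty string for the empty rule); `gpr_genes()` a character vector.
#' @examples
#' r <- parse_gpr("G1 and G2 or G3")
#' gpr_to_string(r)
#' gpr_genes(r)
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0 || is.na(text) ||
      !nzchar(trimws(text))) {
    return(gpr_none())
  }
  toks <- gpr_tokenize(text)
  st <- list(tokens = toks, pos = 1L, text = text)
  res <- gpr_parse_or(st)
  if (res$state$pos <= length(toks)) {
    tok <- toks[[res$state$pos]]
    abort(sprintf("GPR parse error in %s: unexpected '%s' at token %d",
                  dQuote(text), tok$value, res$state$pos))
  }
  res$node
}

gpr_none <- function() structure(list(kind = "none"), class = "gpr_rule")
gpr_leaf <- function(gene) {
  structure(list(kind = "leaf", gene = gene), class = "gpr_rule")
}
gpr_node <- function(kind, children) {
  # flatten nested nodes of the same kind so "(a or b) or c" == "a or b or c"
  flat <- list()
  for (ch in children) {
    if (ch$kind == kind) flat <- c(flat, ch$children) else flat <- c(flat, list(ch))
  }
  if (length(flat) == 1L) return(flat[[1L]])
  structure(list(kind = kind, children = flat), class = "gpr_rule")
}

gpr_tokenize <- function(text) {
  chars <- strsplit(text, "")[[1]]
  toks <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) {
      i <- i + 1L
    } else if (ch == "(" || ch == ")") {
      toks[[length(toks) + 1L]] <- list(type = ch, value = ch, pos = i)
      i <- i + 1L
    } else {
      j <- i
      while (j <= n && !grepl("^[\\s()]$", chars[j], perl = TRUE)) j <- j + 1L
      word <- paste(chars[i:(j - 1L)], collapse = "")
      lw <- tolower(word)
      type <- if (lw == "and") "and" else if (lw == "or") "or" else "gene"
      toks[[length(toks) + 1L]] <- list(type = type, value = word, pos = i)
      i <- j
    }
  }
  toks
}

gpr_peek <- function(st) {
  if (st$pos > length(st$tokens)) NULL else st$tokens[[st$pos]]
}

gpr_parse_or <- function(st) {
  res <- gpr_parse_and(st)
  st <- res$state
  children <- list(res$node)
  repeat {
    tok <- gpr_peek(st)
    if (is.null(tok) || tok$type != "or") break
    st$pos <- st$pos + 1L
    res <- gpr_parse_and(st)
    st <- res$state
    children <- c(children, list(res$node))
  }
  list(node = gpr_node("any", children), state = st)
}

gpr_parse_and <- function(st) {
  res <- gpr_parse_atom(st)
  st <- res$state
  children <- list(res$node)
  repeat {
    tok <- gpr_peek(st)
    if (is.null(tok) || tok$type != "and") break
    st$pos <- st$pos + 1L
    res <- gpr_parse_atom(st)
    st <- res$state
    children <- c(children, list(res$node))
  }
  list(node = gpr_node("all", children), state = st)
}

gpr_parse_atom <- function(st) {
  tok <- gpr_peek(st)
  if (is.null(tok)) {
    abort(sprintf("GPR parse error in %s: unexpected end of rule",
                  dQuote(st$text)))
  }
  if (tok$type == "(") {
    st$pos <- st$pos + 1L
    res <- gpr_parse_or(st)
    st <- res$state
    closing <- gpr_peek(st)
    if (is.null(closing) || closing$type != ")") {
      abort(sprintf(
        "GPR parse error in %s: unbalanced parenthesis opened at position %d",
        dQuote(st$text), tok$pos))
    }
    st$pos <- st$pos + 1L
    return(list(node = res$node, state = st))
  }
  if (tok$type == "gene") {
    st$pos <- st$pos + 1L
    return(list(node = gpr_leaf(tok$value), state = st))
  }
  abort(sprintf("GPR parse error in %s: dangling operator '%s' at position %d",
                dQuote(st$text), tok$value, tok$pos))
}

#' @rdname parse_gpr
#' @export
gpr_to_string <- function(gpr) {
  stopifnot(inherits(gpr, "gpr_rule"))
  gpr_str_rec(gpr, parent = "any")
}

gpr_str_rec <- function(node, parent) {
  switch(node$kind,
    none = "",
    leaf = node$gene,
    all = {
      s <- paste(vapply(node$children, gpr_str_rec, "", parent = "all"),
                 collapse = " and ")
      s
    },
    any = {
      s <- paste(vapply(node$children, gpr_str_rec, "", parent = "any"),
                 collapse = " or ")
      if (parent == "all") paste0("(", s, ")") else s
    }
  )
}

#' @rdname parse_gpr
#' @export
gpr_genes <- function(gpr) {
  stopifnot(inherits(gpr, "gpr_rule"))
  switch(gpr$kind,
    none = character(),
    leaf = gpr$gene,
    unique(unlist(lapply(gpr$children, gpr_genes)))
  )
}

#' @export
print.gpr_rule <- function(x, ...) {
  if (x$kind == "none") cat("<gpr_rule: (none)>\n")
  else cat("<gpr_rule:", gpr_to_string(x), ">\n")
  invisible(x)
}

#' @export
format.gpr_rule <- function(x, ...) gpr_to_string(x)

gpr_is_empty <- function(gpr) gpr$kind == "none"
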