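#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules link genes to the reaction they catalyze: `or` separates
#' isozymes (either gene product suffices), `and` joins subunits of a
#' complex (all are required). The dialect is the usual one: gene
#' identifiers, `and`, `or` (case-insensitive) and parentheses. `and` binds
#' tighter than `or`, so `"a and b or c"` parses as `(a and b) or c`;
#' genome-scale model files in practice parenthesize fully.
#'
#' @param text rule string; the empty string (or `NA`) yields the empty
#'   rule, meaning the reaction is not gene-associated.
#' @return an object of class `gpr_rule`: either `NULL` (empty rule) or a
#'   nested list with elements `op` (`"and"`, `"or"`, or `"gene"`), `args`
#'   (sub-rules, for boolean nodes) or `gene` (identifier, for leaves).
#' @export
#' @examples
#' r <- parse_gpr("(g1 and g2) or g3")
#' gpr_genes(r)
#' gpr_to_string(r)
parse_gpr <- function(text) {
  if (length(text) != 1L || is.na(text)) text <- ""
  tokens <- .gpr_tokenize(text)
  if (length(tokens$type) == 0L) {
    return(structure(list(), class = "gpr_rule", empty = TRUE))
  }
  st <- new.env(parent = emptyenv())
  st$pos <- 1L
  tree <- .gpr_expr(tokens, st)
  if (st$pos <= length(tokens$type)) {
    stop("GPR parse error at position ", tokens$at[st$pos],
         ": unexpected '", tokens$text[st$pos], "'")
  }
  structure(tree, class = "gpr_rule", empty = FALSE)
}

.gpr_tokenize <- function(text) {
  type <- character(); txt <- character(); at <- integer()
  i <- 1L; n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "(") { type <- c(type, "("); txt <- c(txt, "("); at <- c(at, i); i <- i + 1L; next }
    if (ch == ")") { type <- c(type, ")"); txt <- c(txt, ")"); at <- c(at, i); i <- i + 1L; next }
    m <- regmatches(substr(text, i, n),
                    regexpr("^[^()[:space:]]+", substr(text, i, n)))
    word <- m[1]
    lw <- tolower(word)
    type <- c(type, if (lw %in% c("and", "or")) lw else "gene")
    txt <- c(txt, word); at <- c(at, i)
    i <- i + nchar(word)
  }
  list(type = type, text = txt, at = at)
}

.gpr_expr <- function(tk, st) {            # term ("or" term)*
  args <- list(.gpr_term(tk, st))
  while (st$pos <= length(tk$type) && tk$type[st$pos] == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(.gpr_term(tk, st)))
  }
  if (length(args) == 1L) args[[1]] else .gpr_flatten("or", args)
}

.gpr_term <- function(tk, st) {            # factor ("and" factor)*
  args <- list(.gpr_factor(tk, st))
  while (st$pos <= length(tk$type) && tk$type[st$pos] == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(.gpr_factor(tk, st)))
  }
  if (length(args) == 1L) args[[1]] else .gpr_flatten("and", args)
}

.gpr_factor <- function(tk, st) {
  if (st$pos > length(tk$type)) {
    stop("GPR parse error: unexpected end of rule")
  }
  ty <- tk$type[st$pos]
  if (ty == "(") {
    open_at <- tk$at[st$pos]
    st$pos <- st$pos + 1L
    e <- .gpr_expr(tk, st)
    if (st$pos > length(tk$type) || tk$type[st$pos] != ")") {
      stop("GPR parse error at position ", open_at, ": unbalanced '('")
    }
    st$pos <- st$pos + 1L
    return(e)
  }
  if (ty == "gene") {
    g <- tk$text[st$pos]
    st$pos <- st$pos + 1L
    return(list(op = "gene", gene = g))
  }
  stop("GPR parse error at position ", tk$at[st$pos],
       ": unexpected '", tk$text[st$pos], "'")
}

# merge children that repeat the parent operator so internal nodes
# always have >= 2 distinct children
.gpr_flatten <- function(op, args) {
  out <- list()
  for (a in args) {
    if (!is.null(a$op) && a$op == op) out <- c(out, a$args)
    else out <- c(out, list(a))
  }
  list(op = op, args = out)
}

#' @export
print.gpr_rule <- function(x, ...) {
  cat("<gpr_rule> ", gpr_to_string(x), "\n", sep = "")
  invisible(x)
}

#' Serialize a GPR rule back to text
#'
#' Fully parenthesized, so `parse_gpr(gpr_to_string(r))` is equivalent to
#' `r` for any rule.
#' @param rule a `gpr_rule`.
#' @return a string; `""` for the empty rule.
#' @export
gpr_to_string <- function(rule) {
  if (gpr_is_empty(rule)) return("")
  .gpr_str <- function(node) {
    if (node$op == "gene") return(node$gene)
    inner <- vapply(node$args, .gpr_str, character(1))
    paste0("(", paste(inner, collapse = paste0(" ", node$op, " ")), ")")
  }
  s <- .gpr_str(unclass(rule))
  sub("^\\((.*)\\)$", "\\1", s)
}

#' @rdname gpr_to_string
#' @export
gpr_is_empty <- function(rule) {
  is.null(rule) || isTRUE(attr(rule, "empty")) || length(rule) == 0L
}

#' List the genes referenced by a GPR rule
#' @param rule a `gpr_rule`.
#' @return character vector of unique gene ids (empty for the empty rule).
#' @export
gpr_genes <- function(rule) {
  if (gpr_is_empty(rule)) return(character())
  out <- character()
  walk <- function(node) {
    if (node$op == "gene") out <<- c(out, node$gene)
    else for (a in node$args) walk(a)
  }
  walk(unclass(rule))
  unique(out)
}

# structural equivalence up to child order
gpr_equal <- function(a, b) {
  if (gpr_is_empty(a) || gpr_is_empty(b)) {
    return(gpr_is_empty(a) && gpr_is_empty(b))
  }
  key <- function(node) {
    if (node$op == "gene") return(paste0("g:", node$gene))
    ks <- sort(vapply(node$args, key, character(1)))
    paste0(node$op, "(", paste(ks, collapse = ","), ")")
  }
  identical(key(unclass(a)), key(unclass(b)))
}
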