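# Mini selection language over a topology table.
#
# Grammar:  expr    := term ("or" term)*
#           term    := factor ("and" factor)*
#           factor  := ["not"] ( "(" expr ")" | primary )
#           primary := keyword value+ | "all" | "protein" | "hydrogen" |
#                      "heavy"
# Keywords: name, resname, resid, chain, element, serial.
# resid/serial values may be integers or "a:b" ranges; other values are
# literal strings. Matching is case-sensitive for names, as in PDB files.

.SEL_KEYWORDS <- c("name", "resname", "resid", "chain", "element", "serial")
.SEL_BARE <- c("all", "protein", "hydrogen", "heavy")
.SEL_OPS <- c("and", "or", "not", "(", ")")

.sel_tokenize <- function(expr) {
  expr <- gsub("([()])", " \\1 ", expr)
  tok <- strsplit(trimws(expr), "[[:space:]]+")[[1]]
  tok[nzchar(tok)]
}

.sel_values <- function(tokens, pos) {
  vals <- character(0)
  while (pos <= length(tokens) &&
         !(tolower(tokens[pos]) %in% c(.SEL_KEYWORDS, .SEL_BARE, .SEL_OPS))) {
    vals <- c(vals, tokens[pos])
    pos <- pos + 1L
  }
  list(values = vals, pos = pos)
}

.sel_int_set <- function(vals, tok) {
  out <- integer(0)
  for (v in vals) {
    if (grepl("^-?[0-9]+:-?[0-9]+$", v)) {
      ab <- as.integer(strsplit(v, ":")[[1]])
      out <- c(out, ab[1]:ab[2])
    } else {
      i <- suppressWarnings(as.integer(v))
      if (is.na(i)) stop("selection syntax error: non-integer value '", v,
                         "' after '", tok, "'")
      out <- c(out, i)
    }
  }
  out
}

.sel_parse <- function(tokens, pos, top) {
  res <- .sel_parse_term(tokens, pos, top)
  while (res$pos <= length(tokens) && tolower(tokens[res$pos]) == "or") {
    rhs <- .sel_parse_term(tokens, res$pos + 1L, top)
    res <- list(mask = res$mask | rhs$mask, pos = rhs$pos)
  }
  res
}

.sel_parse_term <- function(tokens, pos, top) {
  res <- .sel_parse_factor(tokens, pos, top)
  while (res$pos <= length(tokens) && tolower(tokens[res$pos]) == "and") {
    rhs <- .sel_parse_factor(tokens, res$pos + 1L, top)
    res <- list(mask = res$mask & rhs$mask, pos = rhs$pos)
  }
  res
}

.sel_parse_factor <- function(tokens, pos, top) {
  if (pos > length(tokens)) stop("selection syntax error: unexpected end")
  tok <- tokens[pos]; ltok <- tolower(tok)
  if (ltok == "not") {
    res <- .sel_parse_factor(tokens, pos + 1L, top)
    return(list(mask = !res$mask, pos = res$pos))
  }
  if (tok == "(") {
    res <- .sel_parse(tokens, pos + 1L, top)
    if (res$pos > length(tokens) || tokens[res$pos] != ")")
      stop("selection syntax error: missing ')'")
    return(list(mask = res$mask, pos = res$pos + 1L))
  }
  if (ltok %in% .SEL_BARE) {
    mask <- switch(ltok,
      all = rep(TRUE, nrow(top)),
      protein = top$resname %in% .AMINO3,
      hydrogen = top$element == "H",
      heavy = top$element != "H")
    return(list(mask = mask, pos = pos + 1L))
  }
  if (ltok %in% .SEL_KEYWORDS) {
    vr <- .sel_values(tokens, pos + 1L)
    if (length(vr$values) == 0)
      stop("selection syntax error: '", tok, "' needs at least one value")
    mask <- switch(ltok,
      name = top$name %in% vr$values,
      resname = top$resname %in% vr$values,
      chain = top$chain %in% vr$values,
      element = top$element %in% toupper(vr$values),
      resid = top$resid %in% .sel_int_set(vr$values, tok),
      serial = top$serial %in% .sel_int_set(vr$values, tok))
    return(list(mask = mask, pos = vr$pos))
  }
  stop("selection syntax error: unexpected token '", tok, "'")
}

#' Resolve a selection expression against a topology
#'
#' Deterministic, pure resolution of a textual atom selection to an ordered
#' index set (ascending serial). An empty result is allowed and returned as
#' `integer(0)`.
#'
#' @param expr selection string, e.g. `"resid 156 and name SG"`,
#'   `"resname POPC and name P"`, `"resid 29 185 217"`.
#' @param top a [topology()] (or a trajectory, whose topology is used).
#' @return integer vector of row indices into the topology, ordered by
#'   ascending atom serial.
#' @export
resolve_selection <- function(expr, top) {
  if (inherits(top, "traj")) top <- top$topology
  if (is.numeric(expr)) return(as.integer(expr))  # already indices
  stopifnot(is.character(expr), length(expr) == 1L)
  tokens <- .sel_tokenize(expr)
  if (length(tokens) == 0) stop("empty selection expression")
  res <- .sel_parse(tokens, 1L, top)
  if (res$pos <= length(tokens))
    stop("selection syntax error: unexpected token '", tokens[res$pos], "'")
  idx <- which(res$mask)
  idx[order(top$serial[idx])]
}

.resolve1 <- function(expr, top, what) {
  idx <- resolve_selection(expr, top)
  if (length(idx) != 1L)
    stop(what, " selection must resolve to exactly 1 atom (got ",
         length(idx), "): '", if (is.character(expr)) expr else "<indices>",
         "'")
  idx
}
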