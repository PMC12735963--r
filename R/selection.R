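# Atom-selection mini-language.
#
# Grammar:
#   expr    := term ("or" term)*
#   term    := factor ("and" factor)*
#   factor  := "not" factor | "(" expr ")" | primary
#   primary := "calpha" | "backbone" | "ligand" | "water" | "protein"
#            | "all" | "resid" RANGE ("," RANGE)*     RANGE := N | N-M
#
# "calpha" and "backbone" exclude ligand and water by construction (see
# infer_roles); "protein" is every non-ligand, non-water atom.

.SEL_KEYWORDS <- c("calpha", "backbone", "ligand", "water", "protein", "all")

.tokenize_selection <- function(expression) {
  pat <- "\\(|\\)|[A-Za-z_]+|[0-9]+\\s*-\\s*[0-9]+|[0-9]+|,|\\S"
  m <- gregexpr(pat, expression, perl = TRUE)[[1]]
  if (m[1] == -1) return(data.frame(text = character(), pos = integer()))
  data.frame(text = regmatches(expression, list(m))[[1]],
             pos = as.integer(m), stringsAsFactors = FALSE)
}

#' Select atoms with a small selection language
#'
#' Evaluates a selection expression against a topology and returns the
#' matching atom indices as a strictly increasing integer vector
#' (a selection mask). Supported primaries: role keywords `calpha`,
#' `backbone`, `ligand`, `water`, `protein`, `all` and residue ranges such as
#' `resid 339-480` or `resid 125, 451`; combine with `and`, `or`, `not` and
#' parentheses. Selections are deterministic and the result is always sorted,
#' so commutative operators are order-independent.
#'
#' @param topology a [topology()].
#' @param expression selection string, e.g. `"resid 339-480 and calpha"`.
#' @return Sorted integer vector of 1-based atom indices.
#' @examples
#' \dontrun{select_atoms(top, "calpha or ligand")}
#' @export
select_atoms <- function(topology, expression) {
  stopifnot(inherits(topology, "topology"), is.character(expression))
  toks <- .tokenize_selection(expression)
  st <- new.env(parent = emptyenv())
  st$i <- 1L
  st$toks <- toks
  peek <- function() if (st$i <= nrow(st$toks)) st$toks$text[st$i] else NA_character_
  advance <- function() { t <- peek(); st$i <- st$i + 1L; t }
  perr <- function(msg) {
    pos <- if (st$i <= nrow(st$toks)) st$toks$pos[st$i]
           else nchar(expression) + 1L
    stop(sprintf("selection parse error at position %d: %s (in '%s')",
                 pos, msg, expression), call. = FALSE)
  }

  parse_primary <- function() {
    t <- peek()
    if (is.na(t)) perr("unexpected end of expression")
    if (t == "(") {
      advance()
      v <- parse_expr()
      if (!identical(peek(), ")")) perr("expected ')'")
      advance()
      return(v)
    }
    tl <- tolower(t)
    if (tl %in% .SEL_KEYWORDS) {
      advance()
      return(switch(tl,
        calpha   = topology$calpha,
        backbone = topology$backbone,
        ligand   = topology$ligand,
        water    = topology$water,
        protein  = !topology$ligand & !topology$water,
        all      = rep(TRUE, nrow(topology))))
    }
    if (tl == "resid") {
      advance()
      mask <- rep(FALSE, nrow(topology))
      repeat {
        r <- peek()
        if (is.na(r) || !grepl("^[0-9]+(\\s*-\\s*[0-9]+)?$", r))
          perr("expected residue number or range after 'resid'")
        advance()
        bounds <- as.integer(strsplit(gsub("\\s", "", r), "-")[[1]])
        lo <- bounds[1]; hi <- if (length(bounds) > 1) bounds[2] else bounds[1]
        if (hi < lo) perr(sprintf("empty residue range %d-%d", lo, hi))
        mask <- mask | (topology$resno >= lo & topology$resno <= hi)
        if (identical(peek(), ",")) advance() else break
      }
      return(mask)
    }
    perr(sprintf("unknown token '%s'", t))
  }
  parse_factor <- function() {
    if (identical(tolower(peek()), "not")) {
      advance()
      return(!parse_factor())
    }
    parse_primary()
  }
  parse_term <- function() {
    v <- parse_factor()
    while (identical(tolower(peek()), "and")) {
      advance()
      v <- v & parse_factor()
    }
    v
  }
  parse_expr <- function() {
    v <- parse_term()
    while (identical(tolower(peek()), "or")) {
      advance()
      v <- v | parse_term()
    }
    v
  }

  mask <- parse_expr()
  if (!is.na(peek())) perr(sprintf("unexpected trailing token '%s'", peek()))
  idx <- which(mask)
  if (length(idx) == 0L)
    stop("empty selection: '", expression, "' matches no atoms", call. = FALSE)
  idx
}
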