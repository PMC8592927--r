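## A small MDAnalysis/VMD-flavoured atom selection language:
##   keyword selectors : name, element, resname, resid, chain
##   values            : one or more tokens after a keyword (OR-ed);
##                       resid accepts ranges "169:173" or "169-173"
##   combinators       : and, or, not, parentheses; "all" matches all atoms
## Examples: "name CA and resid 210", "element O and resname TIP3",
##           "name CA and resid 169:173 and chain B", "not element H"

.sel_tokenize <- function(expr) {
  expr <- gsub("\\(", " ( ", expr)
  expr <- gsub("\\)", " ) ", expr)
  toks <- strsplit(trimws(expr), "\\s+")[[1]]
  toks[nzchar(toks)]
}

.sel_keywords <- c("name", "element", "resname", "resid", "chain")
.sel_reserved <- c(.sel_keywords, "and", "or", "not", "(", ")", "all")

# recursive descent: expr := term ("or" term)*
#                    term := factor ("and" factor)*
#                    factor := "not" factor | "(" expr ")" | primitive
.sel_parse <- function(toks, atoms) {
  pos <- 1L
  n <- length(toks)
  peek <- function() if (pos <= n) toks[pos] else NA_character_
  take <- function() { t <- toks[pos]; pos <<- pos + 1L; t }

  primitive <- function() {
    kw <- take()
    if (identical(kw, "all")) return(rep(TRUE, nrow(atoms)))
    if (!kw %in% .sel_keywords)
      stop("selection parse error: unexpected token '", kw, "'")
    vals <- character()
    while (!is.na(peek()) && !(peek() %in% .sel_reserved)) vals <- c(vals, take())
    if (!length(vals))
      stop("selection parse error: keyword '", kw, "' needs a value")
    if (kw == "resid") {
      hit <- rep(FALSE, nrow(atoms))
      for (v in vals) {
        if (grepl("^[0-9]+[:-][0-9]+$", v)) {
          ab <- as.integer(strsplit(v, "[:-]")[[1]])
          hit <- hit | (atoms$resno >= ab[1] & atoms$resno <= ab[2])
        } else if (grepl("^[0-9]+$", v)) {
          hit <- hit | atoms$resno == as.integer(v)
        } else stop("selection parse error: bad resid value '", v, "'")
      }
      hit
    } else {
      col <- switch(kw, name = atoms$name, element = atoms$element,
                    resname = atoms$resname, chain = atoms$chain)
      toupper(trimws(col)) %in% toupper(vals)
    }
  }
  factor_ <- function() {
    t <- peek()
    if (is.na(t)) stop("selection parse error: unexpected end of expression")
    if (t == "not") { take(); return(!factor_()) }
    if (t == "(") {
      take()
      v <- expr_()
      if (!identical(peek(), ")"))
        stop("selection parse error: missing ')'")
      take()
      return(v)
    }
    primitive()
  }
  term_ <- function() {
    v <- factor_()
    while (identical(peek(), "and")) { take(); v <- v & factor_() }
    v
  }
  expr_ <- function() {
    v <- term_()
    while (identical(peek(), "or")) { take(); v <- v | term_() }
    v
  }
  out <- expr_()
  if (pos <= n)
    stop("selection parse error: trailing tokens from '", toks[pos], "'")
  out
}

#' Resolve a selection expression into atom indices
#'
#' Resolution is deterministic: the same expression on the same topology
#' always yields the identical ascending 1-based index set. An empty
#' result is allowed.
#'
#' @param topology a \linkS4class{ChannelTopology}.
#' @param selection selection string, e.g. \code{"name CA and resid 210"}.
#' @return sorted integer vector of atom indices (may be empty).
#' @export
resolveSelection <- function(topology, selection) {
  toks <- .sel_tokenize(selection)
  if (!length(toks)) stop("selection parse error: empty expression")
  mask <- .sel_parse(toks, topology@atoms)
  which(mask)
}
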