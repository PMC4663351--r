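#' Select atoms with a small selection language
#'
#' The expression vocabulary covers the selections the analyses need:
#' \itemize{
#'   \item molecule kinds: `peptide`, `lipid`, `solvent`, `ion`, `all`
#'   \item `name P CA ...` — atom names
#'   \item `resname POPC ...` — residue names
#'   \item `element H ...` — chemical elements
#'   \item `resid 20-37` (also `20~37`, single numbers, or lists) — residue
#'     index ranges
#'   \item combinators `and`, `or`, `not` and parentheses; `not` binds
#'     tightest, then `and`, then `or`.
#' }
#' Selections are deterministic and order-preserving: atoms come out in
#' topology order.
#'
#' @param top a `topology`.
#' @param expression selection string, e.g. `"peptide and resid 20-37"`,
#'   `"lipid and name P"`, `"not element H"`.
#' @param label label for the resulting group (defaults to the expression).
#' @return an `atom_group`.
#' @export
select_atoms <- function(top, expression, label = expression) {
  toks <- sel_tokenize(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  mask <- sel_or(st, top)
  if (st$pos <= length(st$toks))
    stop("trailing tokens in selection: ",
         paste(st$toks[st$pos:length(st$toks)], collapse = " "))
  atom_group(top, which(mask), label = label)
}

sel_tokenize <- function(s) {
  s <- gsub("([()])", " \\1 ", s)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  if (!length(toks)) stop("empty selection expression")
  toks
}

sel_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_
sel_next <- function(st) { t <- sel_peek(st); st$pos <- st$pos + 1L; t }

.sel_keywords <- c("and", "or", "not", "(", ")")

sel_or <- function(st, top) {
  m <- sel_and(st, top)
  while (!is.na(sel_peek(st)) && sel_peek(st) == "or") {
    sel_next(st)
    m <- m | sel_and(st, top)
  }
  m
}

sel_and <- function(st, top) {
  m <- sel_not(st, top)
  while (!is.na(sel_peek(st)) && sel_peek(st) == "and") {
    sel_next(st)
    m <- m & sel_not(st, top)
  }
  m
}

sel_not <- function(st, top) {
  if (!is.na(sel_peek(st)) && sel_peek(st) == "not") {
    sel_next(st)
    return(!sel_not(st, top))
  }
  sel_primary(st, top)
}

sel_values <- function(st) {
  vals <- character(0)
  while (!is.na(sel_peek(st)) && !(sel_peek(st) %in% .sel_keywords)) {
    vals <- c(vals, sel_next(st))
  }
  if (!length(vals)) stop("selection keyword needs at least one value")
  vals
}

sel_resid_set <- function(vals) {
  out <- integer(0)
  for (v in vals) {
    if (grepl("^[0-9]+[-~][0-9]+$", v)) {
      ab <- as.integer(strsplit(v, "[-~]")[[1]])
      out <- c(out, ab[1]:ab[2])
    } else if (grepl("^[0-9]+$", v)) {
      out <- c(out, as.integer(v))
    } else stop("bad resid token: ", v)
  }
  out
}

sel_primary <- function(st, top) {
  at <- top$atoms
  t <- sel_next(st)
  if (is.na(t)) stop("selection ended unexpectedly")
  switch(t,
    "(" = {
      m <- sel_or(st, top)
      if (is.na(sel_peek(st)) || sel_next(st) != ")")
        stop("unbalanced parenthesis in selection")
      m
    },
    "all" = rep(TRUE, nrow(at)),
    "peptide" = at$moltype == "peptide",
    "lipid" = at$moltype == "lipid",
    "solvent" = at$moltype == "solvent",
    "ion" = at$moltype == "ion",
    "name" = at$name %in% sel_values(st),
    "resname" = at$resname %in% sel_values(st),
    "element" = toupper(at$element) %in% toupper(sel_values(st)),
    "resid" = at$resid %in% sel_resid_set(sel_values(st)),
    stop("unknown selection keyword: ", t)
  )
}
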