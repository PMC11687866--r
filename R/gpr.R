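# Gene-protein-reaction (GPR) rules: boolean expressions over gene ids with
# `and` (enzyme complexes) and `or` (isoenzymes). Parsed by recursive descent
# into nested lists; a leaf is a gene id, an inner node is
# list(op = "and"/"or", args = list(...)).

#' Parse a GPR expression
#'
#' @param text a GPR string, e.g. `"g1 and (g2 or g3)"`. Operators are
#'   case-insensitive; gene ids are any non-operator tokens.
#' @return a parse tree (nested list), or `NULL` for an empty rule.
#' @export
gpr_parse <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(NULL)
  toks <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  st$text <- text
  tree <- gpr_parse_or(st)
  if (st$pos <= length(st$toks)) {
    stop("malformed GPR expression '", text, "': unexpected token '",
         st$toks[st$pos], "'")
  }
  tree
}

gpr_tokenize <- function(text) {
  text <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks[nzchar(toks)]
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_and(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_atom(st))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_atom(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(st) {
  tok <- gpr_peek(st)
  if (is.na(tok)) stop("malformed GPR expression '", st$text,
                       "': unexpected end of input")
  if (tok == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    if (is.na(gpr_peek(st)) || gpr_peek(st) != ")") {
      stop("malformed GPR expression '", st$text, "': missing ')'")
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tolower(tok) %in% c("and", "or", ")")) {
    stop("malformed GPR expression '", st$text, "': unexpected '", tok, "'")
  }
  st$pos <- st$pos + 1L
  tok
}

#' Format a GPR parse tree back to canonical text
#'
#' `or` children of an `and` node (and vice versa) are parenthesised, so
#' parse -> format -> parse is the identity.
#'
#' @param tree a parse tree from [gpr_parse()], or `NULL`.
#' @return a single string (empty for `NULL`).
#' @export
gpr_format <- function(tree) {
  if (is.null(tree)) return("")
  if (is.character(tree)) return(tree)
  parts <- vapply(tree$args, function(a) {
    s <- gpr_format(a)
    if (!is.character(a) && a$op != tree$op) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", tree$op, " "))
}

#' Genes referenced by a GPR tree
#' @param tree a parse tree or `NULL`.
#' @return character vector of gene ids.
#' @export
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character(0))
  if (is.character(tree)) return(tree)
  unique(unlist(lapply(tree$args, gpr_genes)))
}

# Expression-confidence ordering used when GPRs combine gene categories.
.conf_levels <- c("NOT_PRESENT", "LOW", "MEDIUM", "HIGH", "UNKNOWN")
.conf_rank <- c(NOT_PRESENT = 1, LOW = 2, MEDIUM = 3, HIGH = 4)

# Evaluate a GPR tree against per-gene confidence categories.
# AND: a complex with a NOT_PRESENT member is NOT_PRESENT; otherwise a member
#      of unknown confidence makes the complex UNKNOWN (it cannot be claimed
#      functional); otherwise the minimum of the members.
# OR:  the maximum over members of known confidence; UNKNOWN isoenzymes are
#      ignored when any sibling is known, and only an all-UNKNOWN node stays
#      UNKNOWN. Genes absent from `conf` count as UNKNOWN.
gpr_eval_confidence <- function(tree, conf) {
  if (is.null(tree)) return("UNKNOWN")
  if (is.character(tree)) {
    val <- conf[tree]
    if (is.na(val) || !val %in% names(.conf_rank)) return("UNKNOWN")
    return(unname(val))
  }
  vals <- vapply(tree$args, gpr_eval_confidence, character(1), conf = conf)
  known <- vals[vals != "UNKNOWN"]
  if (tree$op == "and") {
    if (any(vals == "NOT_PRESENT")) return("NOT_PRESENT")
    if (any(vals == "UNKNOWN")) return("UNKNOWN")
    return(names(.conf_rank)[min(.conf_rank[vals])])
  }
  if (!length(known)) return("UNKNOWN")
  names(.conf_rank)[max(.conf_rank[known])]
}
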