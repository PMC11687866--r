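#' Construct an expression profile for one cell type
#'
#' @param cell_type one of `"RPE"`, `"rod"`, `"cone"` (other labels are
#'   accepted for synthetic data).
#' @param values named numeric vector of expression values (gene id ->
#'   non-negative value); `NA` marks a missing measurement.
#' @return an `expression_profile`.
#' @export
expression_profile <- function(cell_type, values) {
  stopifnot(is.character(cell_type), length(cell_type) == 1L)
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    stop("values must be named by gene id")
  }
  if (any(values < 0, na.rm = TRUE)) stop("expression values must be non-negative")
  structure(list(cell_type = cell_type, values = values),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat("<expression_profile> ", x$cell_type, ": ", length(x$values),
      " genes (", sum(is.na(x$values)), " missing)\n", sep = "")
  invisible(x)
}

#' Read an expression profile from a TSV file
#'
#' Expects columns `gene_id` and `value`; a blank value is treated as
#' missing. An optional two-column mapping table (symbol -> model gene id)
#' translates identifiers; unmapped symbols are dropped with a message and
#' treated as missing data.
#'
#' @param path TSV file with columns `gene_id`, `value`.
#' @param cell_type label for the profile.
#' @param mapping optional data.frame (or TSV path) with columns `symbol`,
#'   `gene_id` used to translate `gene_id` entries.
#' @return an `expression_profile`.
#' @export
read_expression_tsv <- function(path, cell_type, mapping = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("", "NA"))
  if (!all(c("gene_id", "value") %in% names(tab))) {
    stop("expression TSV needs columns gene_id, value")
  }
  if (!is.null(mapping)) {
    if (is.character(mapping)) {
      mapping <- utils::read.delim(mapping, stringsAsFactors = FALSE)
    }
    if (!all(c("symbol", "gene_id") %in% names(mapping))) {
      stop("mapping needs columns symbol, gene_id")
    }
    idx <- match(tab$gene_id, mapping$symbol)
    unmapped <- tab$gene_id[is.na(idx)]
    if (length(unmapped)) {
      message(length(unmapped), " symbols not in mapping table (treated as missing): ",
              paste(utils::head(unmapped, 5), collapse = ", "),
              if (length(unmapped) > 5) ", ..." else "")
    }
    tab <- tab[!is.na(idx), , drop = FALSE]
    tab$gene_id <- mapping$gene_id[idx[!is.na(idx)]]
  }
  expression_profile(cell_type, stats::setNames(tab$value, tab$gene_id))
}

#' Discretize expression values into five confidence categories
#'
#' Values below the detection threshold are NOT_PRESENT; among the present
#' (above-threshold) values, those up to the first quartile are LOW, those
#' between the first and third quartiles MEDIUM, those above the third
#' quartile HIGH; missing values are UNKNOWN. Quartiles are
#' linear-interpolation quantiles over the present values only.
#'
#' @param profile an `expression_profile`.
#' @param threshold detection threshold separating NOT_PRESENT from LOW
#'   (default `1e-5`).
#' @return a `confidence_assignment` with element `gene_conf`: named factor
#'   with levels NOT_PRESENT, LOW, MEDIUM, HIGH, UNKNOWN.
#' @export
discretize <- function(profile, threshold = 1e-5) {
  stopifnot(inherits(profile, "expression_profile"))
  v <- profile$values
  if (length(v) == 0L || all(is.na(v))) stop("no expressed genes")
  present <- v[!is.na(v) & v >= threshold]
  if (length(present) == 0L) stop("no expressed genes")
  q <- stats::quantile(present, c(0.25, 0.75), names = FALSE, type = 7)
  cat <- rep("UNKNOWN", length(v))
  known <- !is.na(v)
  cat[known & v < threshold] <- "NOT_PRESENT"
  cat[known & v >= threshold & v <= q[1]] <- "LOW"
  cat[known & v > q[1] & v <= q[2]] <- "MEDIUM"
  cat[known & v > q[2]] <- "HIGH"
  structure(list(
    gene_conf = factor(stats::setNames(cat, names(v)), levels = .conf_levels),
    rxn_conf = NULL,
    quartiles = stats::setNames(q, c("Q1", "Q3")),
    threshold = threshold,
    cell_type = profile$cell_type
  ), class = "confidence_assignment")
}

#' @export
print.confidence_assignment <- function(x, ...) {
  cat("<confidence_assignment>", if (!is.null(x$cell_type)) x$cell_type, "\n")
  cat("  genes:     ", paste(names(table(x$gene_conf)),
                             table(x$gene_conf), sep = "=", collapse = " "), "\n")
  if (!is.null(x$rxn_conf)) {
    cat("  reactions: ", paste(names(table(x$rxn_conf)),
                               table(x$rxn_conf), sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Map gene confidences onto reactions through GPR rules
#'
#' Enzyme complexes (`and`) take the weakest member's category, with a
#' NOT_PRESENT member silencing the complex and an unknown member making the
#' complex unknown; isoenzyme alternatives (`or`) take the strongest known
#' member. Reactions without a GPR, or whose genes are all unresolvable,
#' get UNKNOWN.
#'
#' @param model a `metabolic_model`.
#' @param conf a `confidence_assignment` from [discretize()].
#' @return `conf` with `rxn_conf` filled in: a named factor over reaction
#'   ids with the same five levels.
#' @export
score_reactions <- function(model, conf) {
  stopifnot(inherits(conf, "confidence_assignment"))
  gmap <- stats::setNames(as.character(conf$gene_conf), names(conf$gene_conf))
  rc <- vapply(seq_len(nrow(model$rxns)), function(j) {
    g <- model$rxns$gpr[j]
    if (!nzchar(g)) return("UNKNOWN")
    tree <- tryCatch(gpr_parse(g), error = function(e) {
      stop("reaction '", model$rxns$id[j], "': ", conditionMessage(e),
           call. = FALSE)
    })
    gpr_eval_confidence(tree, gmap)
  }, character(1))
  conf$rxn_conf <- factor(stats::setNames(rc, model$rxns$id),
                          levels = .conf_levels)
  conf
}
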