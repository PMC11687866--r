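# SBML Level 3 + FBC v2 input/output, built on xml2. Covers the subset a
# constraint-based pipeline needs: compartments, species, reactions with
# bounds stored as parameters, gene-product-association trees, and the
# active objective. Identifiers are encoded to valid SBML SIds with the
# usual M_/R_/G_ prefixes and "__<ascii>__" escapes for characters outside
# [A-Za-z0-9_] (the convention COBRA tools use), so arbitrary ids survive a
# round trip.

.sbml_ns <- c(
  sbml = "http://www.sbml.org/sbml/level3/version1/core",
  fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2"
)

# read an fbc-namespaced attribute, tolerating unprefixed writers
fbc_attr <- function(node, name) {
  v <- xml2::xml_attr(node, paste0("fbc:", name), ns = .sbml_ns)
  miss <- is.na(v)
  if (any(miss)) v[miss] <- xml2::xml_attr(node, name)[miss]
  v
}

encode_sid <- function(x, prefix = "") {
  enc <- vapply(x, function(s) {
    ch <- strsplit(s, "")[[1]]
    bad <- !grepl("[A-Za-z0-9_]", ch)
    ch[bad] <- vapply(ch[bad], function(c) {
      sprintf("__%d__", utf8ToInt(c))
    }, character(1))
    paste0(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  paste0(prefix, enc)
}

decode_sid <- function(x, prefix = "") {
  if (nzchar(prefix)) x <- sub(paste0("^", prefix), "", x)
  vapply(x, function(s) {
    m <- gregexpr("__([0-9]+)__", s)
    regmatches(s, m) <- lapply(regmatches(s, m), function(ms) {
      vapply(ms, function(t) intToUtf8(as.integer(gsub("\\D", "", t))),
             character(1), USE.NAMES = FALSE)
    })
    s
  }, character(1), USE.NAMES = FALSE)
}

#' Write a model as SBML Level 3 with the FBC extension
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_sbml()]
#' @export
write_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = .sbml_ns[["sbml"]], "xmlns:fbc" = .sbml_ns[["fbc"]],
    level = "3", version = "1", "fbc:required" = "false"
  )
  mnode <- xml2::xml_add_child(doc, "model", id = encode_sid(model$id),
                               "fbc:strict" = "false")

  comps <- unique(model$mets$compartment)
  lc <- xml2::xml_add_child(mnode, "listOfCompartments")
  for (cp in comps) {
    xml2::xml_add_child(lc, "compartment", id = encode_sid(cp), name = cp,
                        constant = "true")
  }

  ls <- xml2::xml_add_child(mnode, "listOfSpecies")
  for (i in seq_len(nrow(model$mets))) {
    xml2::xml_add_child(
      ls, "species",
      id = encode_sid(model$mets$id[i], "M_"),
      name = model$mets$name[i],
      compartment = encode_sid(model$mets$compartment[i]),
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
  }

  lp <- xml2::xml_add_child(mnode, "listOfParameters")
  rid_enc <- encode_sid(model$rxns$id, "R_")
  for (j in seq_len(nrow(model$rxns))) {
    xml2::xml_add_child(lp, "parameter", id = paste0(rid_enc[j], "_lb"),
                        value = format(model$rxns$lower_bound[j], digits = 17),
                        constant = "true")
    xml2::xml_add_child(lp, "parameter", id = paste0(rid_enc[j], "_ub"),
                        value = format(model$rxns$upper_bound[j], digits = 17),
                        constant = "true")
  }

  genes <- sort(unique(unlist(lapply(model$rxns$gpr, function(g) {
    gpr_genes(gpr_parse(g))
  }))))

  lr <- xml2::xml_add_child(mnode, "listOfReactions")
  for (j in seq_len(nrow(model$rxns))) {
    rnode <- xml2::xml_add_child(
      lr, "reaction", id = rid_enc[j],
      reversible = tolower(model$rxns$lower_bound[j] < 0),
      fast = "false",
      "fbc:lowerFluxBound" = paste0(rid_enc[j], "_lb"),
      "fbc:upperFluxBound" = paste0(rid_enc[j], "_ub"))
    if (nzchar(model$rxns$subsystem[j])) {
      xml2::xml_set_attr(rnode, "name", model$rxns$subsystem[j])
    }
    col <- model$S[, j]
    nzi <- which(col != 0)
    reac <- nzi[col[nzi] < 0]
    prod <- nzi[col[nzi] > 0]
    if (length(reac)) {
      lrt <- xml2::xml_add_child(rnode, "listOfReactants")
      for (i in reac) {
        xml2::xml_add_child(lrt, "speciesReference",
                            species = encode_sid(model$mets$id[i], "M_"),
                            stoichiometry = format(-col[i], digits = 17),
                            constant = "true")
      }
    }
    if (length(prod)) {
      lpr <- xml2::xml_add_child(rnode, "listOfProducts")
      for (i in prod) {
        xml2::xml_add_child(lpr, "speciesReference",
                            species = encode_sid(model$mets$id[i], "M_"),
                            stoichiometry = format(col[i], digits = 17),
                            constant = "true")
      }
    }
    if (nzchar(model$rxns$gpr[j])) {
      gpa <- xml2::xml_add_child(rnode, "fbc:geneProductAssociation")
      sbml_write_gpr(gpa, gpr_parse(model$rxns$gpr[j]))
    }
  }

  if (!is.null(model$objective)) {
    lo <- xml2::xml_add_child(mnode, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(
      lo, "fbc:objective", "fbc:id" = "obj",
      "fbc:type" = if (model$objective$direction == "max") "maximize" else "minimize")
    lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lfo, "fbc:fluxObjective",
                        "fbc:reaction" = encode_sid(model$objective$reaction, "R_"),
                        "fbc:coefficient" = "1")
  }

  if (length(genes)) {
    lg <- xml2::xml_add_child(mnode, "fbc:listOfGeneProducts")
    for (g in genes) {
      xml2::xml_add_child(lg, "fbc:geneProduct",
                          "fbc:id" = encode_sid(g, "G_"),
                          "fbc:label" = g)
    }
  }

  xml2::write_xml(doc, path)
  invisible(path)
}

sbml_write_gpr <- function(parent, tree) {
  if (is.character(tree)) {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = encode_sid(tree, "G_"))
    return(invisible(NULL))
  }
  node <- xml2::xml_add_child(parent, paste0("fbc:", tree$op))
  for (a in tree$args) sbml_write_gpr(node, a)
  invisible(NULL)
}

#' Read a model from SBML Level 3 with the FBC extension
#'
#' Requires FBC flux-bound attributes on every reaction; a reaction without
#' them is rejected by id. Malformed XML raises a parse error.
#'
#' @param path an SBML file.
#' @return a `metabolic_model`.
#' @seealso [write_sbml()]
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("SBML parse error in '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  ns <- .sbml_ns
  mnode <- xml2::xml_find_first(doc, "./sbml:model", ns)
  if (inherits(mnode, "xml_missing")) stop("SBML parse error: no <model> element")
  model_id <- decode_sid(xml2::xml_attr(mnode, "id"))
  if (is.na(model_id)) model_id <- "model"

  comp_nodes <- xml2::xml_find_all(mnode, ".//sbml:listOfCompartments/sbml:compartment", ns)
  comp_map <- stats::setNames(
    decode_sid(xml2::xml_attr(comp_nodes, "id")),
    xml2::xml_attr(comp_nodes, "id"))

  sp_nodes <- xml2::xml_find_all(mnode, ".//sbml:listOfSpecies/sbml:species", ns)
  if (!length(sp_nodes)) stop("SBML parse error: no <species> elements")
  sp_sid <- xml2::xml_attr(sp_nodes, "id")
  mets <- data.frame(
    id = decode_sid(sp_sid, "M_"),
    name = ifelse(is.na(xml2::xml_attr(sp_nodes, "name")),
                  decode_sid(sp_sid, "M_"), xml2::xml_attr(sp_nodes, "name")),
    compartment = unname(comp_map[xml2::xml_attr(sp_nodes, "compartment")]),
    stringsAsFactors = FALSE)
  met_by_sid <- stats::setNames(mets$id, sp_sid)

  par_nodes <- xml2::xml_find_all(mnode, ".//sbml:listOfParameters/sbml:parameter", ns)
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                             xml2::xml_attr(par_nodes, "id"))

  gp_nodes <- xml2::xml_find_all(mnode, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gp_label <- stats::setNames(fbc_attr(gp_nodes, "label"),
                              fbc_attr(gp_nodes, "id"))
  gp_label[is.na(gp_label)] <- decode_sid(names(gp_label)[is.na(gp_label)], "G_")

  rx_nodes <- xml2::xml_find_all(mnode, ".//sbml:listOfReactions/sbml:reaction", ns)
  if (!length(rx_nodes)) stop("SBML parse error: no <reaction> elements")
  reactions <- lapply(rx_nodes, function(rn) {
    sid <- xml2::xml_attr(rn, "id")
    rid <- decode_sid(sid, "R_")
    lb_ref <- fbc_attr(rn, "lowerFluxBound")
    ub_ref <- fbc_attr(rn, "upperFluxBound")
    if (is.na(lb_ref) || is.na(ub_ref)) {
      stop("reaction '", rid, "' lacks FBC flux bounds", call. = FALSE)
    }
    lb <- par_val[lb_ref]; ub <- par_val[ub_ref]
    if (is.na(lb) || is.na(ub)) {
      stop("reaction '", rid, "' references undefined bound parameters",
           call. = FALSE)
    }
    st <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(rn, paste0("./sbml:", side, "/sbml:speciesReference"), ns)
      if (!length(refs)) next
      sp <- met_by_sid[xml2::xml_attr(refs, "species")]
      if (anyNA(sp)) stop("reaction '", rid, "' references unknown species",
                          call. = FALSE)
      coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      coef[is.na(coef)] <- 1
      if (side == "listOfReactants") coef <- -coef
      add <- stats::setNames(coef, sp)
      for (k in seq_along(add)) {
        st[names(add)[k]] <- (if (names(add)[k] %in% names(st)) st[[names(add)[k]]] else 0) + add[k]
      }
    }
    gpa <- xml2::xml_find_first(rn, "./fbc:geneProductAssociation/*", ns)
    gpr <- if (inherits(gpa, "xml_missing")) "" else
      gpr_format(sbml_read_gpr(gpa, gp_label))
    name <- xml2::xml_attr(rn, "name")
    list(id = rid, stoich = st, lower_bound = unname(lb),
         upper_bound = unname(ub), gpr = gpr,
         subsystem = if (is.na(name)) "" else name)
  })

  objective <- NULL
  obj_node <- xml2::xml_find_first(
    mnode, ".//fbc:listOfObjectives/fbc:objective", ns)
  if (!inherits(obj_node, "xml_missing")) {
    fo <- xml2::xml_find_first(obj_node, ".//fbc:fluxObjective", ns)
    if (!inherits(fo, "xml_missing")) {
      objective <- list(
        reaction = decode_sid(fbc_attr(fo, "reaction"), "R_"),
        direction = if (identical(fbc_attr(obj_node, "type"),
                                  "minimize")) "min" else "max")
    }
  }

  metabolic_model(model_id, mets, reactions, objective = objective)
}

sbml_read_gpr <- function(node, gp_label) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- fbc_attr(node, "geneProduct")
    lbl <- gp_label[ref]
    return(if (is.na(lbl)) decode_sid(ref, "G_") else unname(lbl))
  }
  if (!nm %in% c("and", "or")) {
    stop("SBML parse error: unsupported GPR node <", nm, ">", call. = FALSE)
  }
  kids <- xml2::xml_children(node)
  list(op = nm, args = lapply(kids, sbml_read_gpr, gp_label = gp_label))
}
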