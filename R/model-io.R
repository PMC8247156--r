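#' Write a model to disk
#'
#' Two formats: \code{"json"}, the canonical lossless dialect (all fields,
#' including metabolite/reaction kind tags and the protein map, survive a
#' round trip), and \code{"sbml"}, SBML Level 3 with the fbc package (flux
#' bounds, objective, gene associations; kind tags are carried in per-element
#' annotations).
#'
#' @param model an \code{ec_model}.
#' @param path output file.
#' @param format "json" (default) or "sbml".
#' @return \code{path}, invisibly.
#' @export
write_model <- function(model, path, format = c("json", "sbml")) {
  format <- match.arg(format)
  validate_model(model)
  if (format == "json") write_model_json(model, path) else write_sbml(model, path)
  invisible(path)
}

#' Read a model written by \code{\link{write_model}}
#'
#' @param path file path; format inferred from extension (".xml"/".sbml" =>
#'   SBML, otherwise JSON).
#' @return an \code{ec_model}.
#' @export
read_model <- function(path) {
  if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) read_sbml(path)
  else read_model_json(path)
}

num_out <- function(v) ifelse(is.finite(v), v, ifelse(v > 0, "inf", "-inf"))
num_in <- function(v) {
  if (is.numeric(v)) return(as.numeric(v))
  out <- suppressWarnings(as.numeric(v))
  out[v %in% c("inf", "Inf")] <- Inf
  out[v %in% c("-inf", "-Inf")] <- -Inf
  out
}

write_model_json <- function(model, path) {
  rx <- lapply(unname(model$reactions), function(r) {
    list(id = r$id, stoich = as.list(r$stoich),
         lb = num_out(r$lb), ub = num_out(r$ub),
         gpr = gpr_to_string(r$gpr), kind = r$kind)
  })
  obj <- list(metabolites = model$metabolites,
              reactions = rx,
              genes = model$genes,
              objective = model$objective,
              protein_map = as.list(model$protein_map))
  extra <- list()
  if (!is.null(model$parent_map)) extra$parent_map <- as.list(model$parent_map)
  jsonlite::write_json(c(obj, extra), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
}

read_model_json <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = FALSE)
  mets <- do.call(rbind, lapply(d$metabolites, function(m)
    data.frame(id = m$id, name = m$name, compartment = m$compartment,
               kind = m$kind, stringsAsFactors = FALSE)))
  rx <- lapply(d$reactions, function(r) {
    st <- vapply(r$stoich, as.numeric, 0)
    reaction(r$id, st, lb = num_in(r$lb), ub = num_in(r$ub),
             gpr = if (nzchar(r$gpr)) parse_gpr(r$gpr) else NULL,
             kind = r$kind)
  })
  m <- metabolic_model(mets, rx,
                       genes = as.character(unlist(d$genes)),
                       objective = d$objective,
                       protein_map = unlist(d$protein_map) %||% character())
  if (!is.null(d$parent_map)) m$parent_map <- unlist(d$parent_map)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# SBML Level 3 + fbc (subset)
# ---------------------------------------------------------------------------

NS_SBML <- "http://www.sbml.org/sbml/level3/version1/core"
NS_FBC  <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Sanitize an id for SBML (SId grammar)
#'
#' Non-alphanumeric characters map to "_"; a leading digit gains an "x"
#' prefix. Deterministic, so the same input id always yields the same SId;
#' the original ids are persisted in a translation table attribute.
#'
#' @param id character vector.
#' @return sanitized ids.
#' @export
sanitize_id <- function(id) {
  out <- gsub("[^A-Za-z0-9_]", "_", id)
  ifelse(grepl("^[0-9]", out), paste0("x", out), out)
}

write_sbml <- function(model, path) {
  sid <- function(x) sanitize_id(x)
  doc <- xml2::xml_new_root("sbml",
    xmlns = NS_SBML, "xmlns:fbc" = NS_FBC,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = "model",
                             "fbc:strict" = "false")

  comps <- unique(model$metabolites$compartment)
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in comps)
    xml2::xml_add_child(lc, "compartment", id = sid(cp), constant = "true")

  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    mt <- model$metabolites[i, ]
    sp <- xml2::xml_add_child(ls, "species",
      id = sid(mt$id), name = mt$name, compartment = sid(mt$compartment),
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
    an <- xml2::xml_add_child(sp, "annotation")
    xml2::xml_add_child(an, "kind", kind = mt$kind, originalId = mt$id)
  }

  # flux-bound parameters, deduplicated by value
  bounds <- unique(c(vapply(model$reactions, `[[`, 0, "lb"),
                     vapply(model$reactions, `[[`, 0, "ub")))
  bname <- function(v) {
    if (!is.finite(v)) return(if (v > 0) "bnd_inf" else "bnd_minus_inf")
    paste0("bnd_", gsub("[^A-Za-z0-9]", "_", format(v, digits = 17)))
  }
  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  for (v in bounds)
    xml2::xml_add_child(lp, "parameter", id = bname(v),
                        value = format(if (is.finite(v)) v else sign(v) * Inf,
                                       digits = 17),
                        constant = "true")

  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in model$reactions) {
    rn <- xml2::xml_add_child(lr, "reaction",
      id = sid(r$id), reversible = if (r$lb < 0) "true" else "false",
      fast = "false",
      "fbc:lowerFluxBound" = bname(r$lb), "fbc:upperFluxBound" = bname(r$ub))
    an <- xml2::xml_add_child(rn, "annotation")
    xml2::xml_add_child(an, "kind", kind = r$kind, originalId = r$id)
    subs <- r$stoich[r$stoich < 0]; prods <- r$stoich[r$stoich > 0]
    if (length(subs)) {
      lre <- xml2::xml_add_child(rn, "listOfReactants")
      for (mid in names(subs))
        xml2::xml_add_child(lre, "speciesReference", species = sid(mid),
                            stoichiometry = format(-subs[[mid]], digits = 17),
                            constant = "true")
    }
    if (length(prods)) {
      lpr <- xml2::xml_add_child(rn, "listOfProducts")
      for (mid in names(prods))
        xml2::xml_add_child(lpr, "speciesReference", species = sid(mid),
                            stoichiometry = format(prods[[mid]], digits = 17),
                            constant = "true")
    }
    if (!is.null(r$gpr)) {
      ga <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
      sbml_gpr_node(ga, r$gpr)
    }
  }

  lg <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
  for (g in model$genes) {
    pr <- unname(model$protein_map[g])
    xml2::xml_add_child(lg, "fbc:geneProduct", "fbc:id" = sid(g),
                        "fbc:label" = g,
                        "fbc:name" = if (!is.null(pr) && !is.na(pr)) pr else g)
  }

  lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                            "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lf, "fbc:fluxObjective",
                      "fbc:reaction" = sid(model$objective),
                      "fbc:coefficient" = "1")
  xml2::write_xml(doc, path)
}

sbml_gpr_node <- function(parent, node) {
  if (node$op == "LEAF") {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = sanitize_id(node$gene))
  } else {
    el <- xml2::xml_add_child(parent,
                              if (node$op == "AND") "fbc:and" else "fbc:or")
    for (ch in node$children) sbml_gpr_node(el, ch)
  }
}

#' Read an SBML Level 3 + fbc model
#'
#' Supports the subset this package writes plus plain fbc exports from other
#' tools: species, compartments, reactions with fbc flux-bound parameters,
#' gene-product associations and the active fbc objective.
#'
#' @param path SBML file.
#' @return an \code{ec_model}.
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse error in <sbml>: ",
                                           conditionMessage(e)))
  xml2::xml_ns_strip(doc)  # work on local names; fbc attrs keep prefixes
  mdl <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mdl, "xml_missing")) stop("SBML parse error: no <model> element")

  att <- function(nd, a) xml2::xml_attr(nd, a)
  params <- xml2::xml_find_all(mdl, ".//listOfParameters/parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  sp <- xml2::xml_find_all(mdl, ".//listOfSpecies/species")
  if (!length(sp)) stop("SBML parse error: no <species>")
  kind_of <- function(nd, default) {
    k <- xml2::xml_find_first(nd, "./annotation/kind")
    if (inherits(k, "xml_missing")) default else att(k, "kind")
  }
  orig_of <- function(nd, fallback) {
    k <- xml2::xml_find_first(nd, "./annotation/kind")
    o <- if (inherits(k, "xml_missing")) NA_character_ else att(k, "originalId")
    if (is.na(o)) fallback else o
  }
  met_sid <- xml2::xml_attr(sp, "id")
  mets <- data.frame(
    id = vapply(seq_along(sp), function(i) orig_of(sp[[i]], met_sid[i]), ""),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")), met_sid,
                  xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    kind = vapply(sp, kind_of, "", default = "chemical"),
    stringsAsFactors = FALSE)
  sid2id <- stats::setNames(mets$id, met_sid)

  gp <- xml2::xml_find_all(mdl, ".//*[local-name()='geneProduct']")
  glabel <- xml2::xml_attr(gp, "label"); gid <- xml2::xml_attr(gp, "id")
  gname <- xml2::xml_attr(gp, "name")
  gid2gene <- stats::setNames(ifelse(is.na(glabel), gid, glabel), gid)
  protein_map <- stats::setNames(gname, ifelse(is.na(glabel), gid, glabel))
  protein_map <- protein_map[!is.na(protein_map) &
                             protein_map != names(protein_map)]

  rx_nodes <- xml2::xml_find_all(mdl, ".//listOfReactions/reaction")
  if (!length(rx_nodes)) stop("model has no reactions")
  rx <- lapply(rx_nodes, function(nd) {
    rid <- orig_of(nd, att(nd, "id"))
    lbp <- att(nd, "lowerFluxBound"); ubp <- att(nd, "upperFluxBound")
    if (is.na(lbp) || is.na(ubp) || is.na(pval[lbp]) || is.na(pval[ubp]))
      stop("no flux bounds for reaction ", rid)
    st <- numeric()
    for (sr in xml2::xml_find_all(nd, "./listOfReactants/speciesReference")) {
      mid <- sid2id[[att(sr, "species")]]
      st[mid] <- -as.numeric(att(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(nd, "./listOfProducts/speciesReference")) {
      mid <- sid2id[[att(sr, "species")]]
      st[mid] <- as.numeric(att(sr, "stoichiometry")) + (st[mid] %||na% 0)
    }
    ga <- xml2::xml_find_first(nd, "./*[local-name()='geneProductAssociation']")
    gpr <- if (inherits(ga, "xml_missing")) NULL
           else sbml_gpr_read(xml2::xml_children(ga)[[1]], gid2gene)
    reaction(rid, st, lb = pval[[lbp]], ub = pval[[ubp]], gpr = gpr,
             kind = kind_of(nd, "metabolic"))
  })

  obj_nd <- xml2::xml_find_first(mdl, ".//*[local-name()='fluxObjective']")
  if (inherits(obj_nd, "xml_missing"))
    stop("SBML validation error: no active objective")
  obj_sid <- att(obj_nd, "reaction")
  rid_by_sid <- stats::setNames(vapply(rx, `[[`, "", "id"),
                                xml2::xml_attr(rx_nodes, "id"))
  objective <- rid_by_sid[[obj_sid]] %||% obj_sid

  genes <- unname(gid2gene)
  if (!length(genes))
    genes <- unique(unlist(lapply(rx, function(r) gpr_genes(r$gpr))))
  metabolic_model(mets, rx, genes = genes, objective = objective,
                  protein_map = protein_map)
}

`%||na%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

sbml_gpr_read <- function(nd, gid2gene) {
  nm <- xml2::xml_name(nd)
  if (nm == "geneProductRef") {
    g <- xml2::xml_attr(nd, "geneProduct")
    return(list(op = "LEAF", gene = gid2gene[[g]] %||% g))
  }
  kids <- lapply(xml2::xml_children(nd), sbml_gpr_read, gid2gene = gid2gene)
  list(op = if (nm == "and") "AND" else "OR", children = kids)
}
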