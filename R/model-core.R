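#' Construct a metabolic model
#'
#' The central container of the package: a stoichiometric network with
#' reaction bounds, gene-protein-reaction (GPR) rules and a biomass (or other)
#' objective. Metabolite \code{kind} distinguishes ordinary chemicals from
#' enzyme species and isozyme arm pseudo-metabolites introduced by
#' \code{\link{expand_ec}}.
#'
#' @param metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment}, \code{kind} (one of "chemical", "enzyme", "arm").
#' @param reactions named list; each element a list with \code{id},
#'   \code{stoich} (named numeric, metabolite id -> signed coefficient),
#'   \code{lb}, \code{ub} (mmol/gDW/h), \code{gpr} (a GPR node or NULL) and
#'   \code{kind} (one of "metabolic", "exchange", "arm", "usage").
#' @param genes character vector of gene ids.
#' @param objective reaction id of the objective (typically biomass).
#' @param protein_map named character vector, gene id -> protein id.
#' @return object of class \code{ec_model}.
#' @export
metabolic_model <- function(metabolites, reactions, genes = character(),
                            objective, protein_map = character()) {
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  m <- structure(list(metabolites = metabolites, reactions = reactions,
                      genes = genes, objective = objective,
                      protein_map = protein_map),
                 class = "ec_model")
  validate_model(m)
  m
}

#' Create a reaction record
#'
#' @param id reaction id.
#' @param stoich named numeric vector of signed stoichiometric coefficients.
#' @param lb,ub flux bounds, mmol/gDW/h.
#' @param gpr GPR node (see \code{\link{parse_gpr}}) or NULL.
#' @param kind reaction kind.
#' @return list usable inside \code{\link{metabolic_model}}.
#' @export
reaction <- function(id, stoich, lb = 0, ub = 1000, gpr = NULL,
                     kind = "metabolic") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  list(id = id, stoich = stoich, lb = lb, ub = ub, gpr = gpr, kind = kind)
}

#' Validate a model's structural invariants
#'
#' Checks id uniqueness, bound ordering, stoichiometry references and the
#' objective. Called by constructors and after every structural edit.
#'
#' @param model an \code{ec_model}.
#' @return the model, invisibly; stops on violation.
#' @export
validate_model <- function(model) {
  met <- model$metabolites
  stopifnot(is.data.frame(met),
            all(c("id", "name", "compartment", "kind") %in% names(met)))
  if (anyDuplicated(met$id)) stop("duplicate metabolite ids")
  if (any(!nzchar(met$compartment))) stop("empty compartment")
  if (!all(met$kind %in% c("chemical", "enzyme", "arm")))
    stop("unknown metabolite kind")
  if (length(model$reactions) == 0L) stop("model has no reactions")
  rids <- vapply(model$reactions, `[[`, "", "id")
  if (anyDuplicated(rids)) stop("duplicate reaction ids")
  for (r in model$reactions) {
    if (r$lb > r$ub) stop("reaction ", r$id, ": lb > ub")
    if (r$kind %in% c("metabolic", "arm") && length(r$stoich) == 0L)
      stop("reaction ", r$id, ": empty stoichiometry")
    bad <- setdiff(names(r$stoich), met$id)
    if (length(bad)) stop("reaction ", r$id, ": unknown metabolite ", bad[1])
    if (r$kind == "usage") {
      prod <- names(r$stoich)[r$stoich > 0]
      if (length(prod) != 1L ||
          met$kind[match(prod, met$id)] != "enzyme")
        stop("usage reaction ", r$id, " must produce exactly one enzyme")
    }
  }
  if (!model$objective %in% rids) stop("objective not a reaction id")
  invisible(model)
}

#' @export
print.ec_model <- function(x, ...) {
  k <- table(factor(x$metabolites$kind, c("chemical", "enzyme", "arm")))
  cat("<ec_model> ", length(x$reactions), " reactions, ",
      nrow(x$metabolites), " metabolites (",
      k[["enzyme"]], " enzymes, ", k[["arm"]], " arm), ",
      length(x$genes), " genes; objective: ", x$objective, "\n", sep = "")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model an \code{ec_model}.
#' @return dense numeric matrix S, rows = metabolites, columns = reactions,
#'   with dimnames.
#' @export
stoich_matrix <- function(model) {
  mets <- model$metabolites$id
  rids <- names(model$reactions)
  S <- matrix(0, length(mets), length(rids), dimnames = list(mets, rids))
  for (r in model$reactions) S[names(r$stoich), r$id] <- r$stoich
  S
}

#' Reaction bound vectors
#' @param model an \code{ec_model}.
#' @return list with numeric \code{lb} and \code{ub}, named by reaction.
#' @export
model_bounds <- function(model) {
  list(lb = vapply(model$reactions, `[[`, 0, "lb"),
       ub = vapply(model$reactions, `[[`, 0, "ub"))
}

# ---------------------------------------------------------------------------
# GPR rules
# ---------------------------------------------------------------------------

#' Parse a gene-protein-reaction rule
#'
#' Parses a boolean expression over gene ids ("g1 and g2", "g1 or (g2 and
#' g3)", case-insensitive operators) into a normalized tree. OR encodes
#' isozymes, AND encodes enzyme complexes.
#'
#' @param text the rule; NULL yields NULL (no gene association), an empty or
#'   whitespace-only string is an error.
#' @return a GPR node: list with \code{op} ("AND", "OR" or "LEAF"),
#'   \code{children} (for AND/OR) or \code{gene} (for LEAF); or NULL.
#' @export
parse_gpr <- function(text) {
  if (is.null(text)) return(NULL)
  if (is.na(text) || !nzchar(trimws(text))) stop("empty GPR expression")
  toks <- gpr_tokens(text)
  st <- gpr_parse_or(toks, 1L)
  if (st$pos <= length(toks))
    stop("GPR parse error near '", toks[st$pos], "'")
  st$node
}

gpr_tokens <- function(text) {
  text <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  if (!length(toks)) stop("empty GPR expression")
  toks
}

gpr_parse_or <- function(toks, pos) {
  st <- gpr_parse_and(toks, pos)
  kids <- list(st$node); pos <- st$pos
  while (pos <= length(toks) && tolower(toks[pos]) == "or") {
    st <- gpr_parse_and(toks, pos + 1L)
    kids <- c(kids, list(st$node)); pos <- st$pos
  }
  node <- if (length(kids) == 1L) kids[[1]] else list(op = "OR", children = kids)
  list(node = node, pos = pos)
}

gpr_parse_and <- function(toks, pos) {
  st <- gpr_parse_atom(toks, pos)
  kids <- list(st$node); pos <- st$pos
  while (pos <= length(toks) && tolower(toks[pos]) == "and") {
    st <- gpr_parse_atom(toks, pos + 1L)
    kids <- c(kids, list(st$node)); pos <- st$pos
  }
  node <- if (length(kids) == 1L) kids[[1]] else list(op = "AND", children = kids)
  list(node = node, pos = pos)
}

gpr_parse_atom <- function(toks, pos) {
  if (pos > length(toks)) stop("GPR expression ends unexpectedly")
  tk <- toks[pos]
  if (tk == "(") {
    st <- gpr_parse_or(toks, pos + 1L)
    if (st$pos > length(toks) || toks[st$pos] != ")")
      stop("unbalanced parentheses in GPR")
    return(list(node = st$node, pos = st$pos + 1L))
  }
  if (tk == ")" || tolower(tk) %in% c("and", "or"))
    stop("GPR parse error near '", tk, "'")
  list(node = list(op = "LEAF", gene = tk), pos = pos + 1L)
}

#' Serialize a GPR tree back to text
#' @param node a GPR node or NULL.
#' @return character rule ("" for NULL).
#' @export
gpr_to_string <- function(node) {
  if (is.null(node)) return("")
  if (node$op == "LEAF") return(node$gene)
  parts <- vapply(node$children, function(ch) {
    s <- gpr_to_string(ch)
    if (ch$op != "LEAF") paste0("(", s, ")") else s
  }, "")
  paste(parts, collapse = if (node$op == "AND") " and " else " or ")
}

#' Evaluate a GPR tree under gene deletions
#' @param node GPR node or NULL (NULL evaluates TRUE: no gene dependency).
#' @param knocked character vector of deleted genes.
#' @return logical: can the reaction still be catalyzed?
#' @export
gpr_eval <- function(node, knocked) {
  if (is.null(node)) return(TRUE)
  switch(node$op,
         LEAF = !(node$gene %in% knocked),
         AND  = all(vapply(node$children, gpr_eval, TRUE, knocked = knocked)),
         OR   = any(vapply(node$children, gpr_eval, TRUE, knocked = knocked)))
}

#' Genes referenced by a GPR tree
#' @param node GPR node or NULL.
#' @return character vector of gene ids.
#' @export
gpr_genes <- function(node) {
  if (is.null(node)) return(character())
  if (node$op == "LEAF") return(node$gene)
  unique(unlist(lapply(node$children, gpr_genes)))
}

# OR-branches of a GPR: a list of character vectors, each the genes of one
# isozyme branch (an AND-complex contributes all its subunits to one branch).
gpr_branches <- function(node) {
  if (is.null(node)) return(list())
  if (node$op == "LEAF") return(list(node$gene))
  if (node$op == "AND") return(list(gpr_genes(node)))
  out <- list()
  for (ch in node$children) out <- c(out, gpr_branches(ch))
  out
}

# ---------------------------------------------------------------------------
# Irreversible conversion
# ---------------------------------------------------------------------------

#' Convert a model to irreversible form
#'
#' Every reaction with \code{lb < 0 < ub} is split into a forward copy
#' ("_fwd", original stoichiometry, bounds [0, ub]) and a backward copy
#' ("_rev", negated stoichiometry, bounds [0, -lb]). Reactions running only
#' backwards (\code{ub <= 0}) are negated and renamed "_rev". A
#' parent-reaction map is attached for later flux-variability pairing. For an
#' exchange reaction, the "_rev" copy is the uptake direction.
#'
#' @param model an \code{ec_model}.
#' @return irreversible \code{ec_model} with attribute-free field
#'   \code{parent_map} (named character: new id -> original id).
#' @export
to_irreversible <- function(model) {
  new <- list(); parent <- character()
  for (r in model$reactions) {
    if (r$lb < 0 && r$ub > 0) {
      fwd <- r; fwd$id <- paste0(r$id, "_fwd"); fwd$lb <- 0
      rev <- r; rev$id <- paste0(r$id, "_rev")
      rev$stoich <- -r$stoich; rev$lb <- 0; rev$ub <- -r$lb
      new <- c(new, list(fwd), list(rev))
      parent[c(fwd$id, rev$id)] <- r$id
    } else if (r$ub <= 0) {
      rev <- r; rev$id <- paste0(r$id, "_rev")
      rev$stoich <- -r$stoich; rev$lb <- -r$ub; rev$ub <- -r$lb
      new <- c(new, list(rev))
      parent[rev$id] <- r$id
    } else {
      new <- c(new, list(r))
      parent[r$id] <- r$id
    }
  }
  ids <- vapply(new, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("id collision after irreversible split: ", ids[duplicated(ids)][1])
  obj <- model$objective
  if (!obj %in% ids) obj <- paste0(model$objective, "_fwd")
  out <- metabolic_model(model$metabolites, new, model$genes, obj,
                         model$protein_map)
  out$parent_map <- parent
  out
}

#' Resolve an uptake bound to the right reaction of an irreversible model
#'
#' Condition specifications give uptake magnitudes by exchange-reaction base
#' id. In a reversible model uptake is negative flux on the exchange; after
#' splitting, the "_rev" copy carries uptake. This helper applies one uptake
#' bound either way.
#'
#' @param model an \code{ec_model}.
#' @param rxn exchange reaction base id.
#' @param uptake uptake magnitude (>= 0), mmol/gDW/h; \code{Inf} lifts the
#'   limit.
#' @return modified model.
#' @export
set_uptake_bound <- function(model, rxn, uptake) {
  if (uptake < 0) stop("uptake magnitude must be >= 0")
  rev_id <- paste0(rxn, "_rev")
  if (rev_id %in% names(model$reactions)) {
    model$reactions[[rev_id]]$ub <- uptake
  } else if (rxn %in% names(model$reactions)) {
    model$reactions[[rxn]]$lb <- -uptake
  } else {
    stop("no exchange reaction '", rxn, "' in model")
  }
  model
}
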