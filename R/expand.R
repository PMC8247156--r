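#' Expand an irreversible model into an enzyme-constrained model
#'
#' Implements the stoichiometric-expansion recipe: (i) enzymes become
#' pseudo-metabolites consumed with coefficient 1/kcat by the reactions they
#' catalyze; (ii) a reaction with n >= 2 matched isozyme branches is replaced
#' by one arm reaction (substrates -> arm pseudo-metabolite) plus one branch
#' reaction per isozyme, each carrying its own enzyme cost; (iii) every
#' enzyme gains a usage (enzyme-exchange) reaction whose upper bound is the
#' matched protein abundance (infinite when no abundance matched, i.e. the
#' constraint is removed rather than imputed). Reactions without GPR or
#' without kinetic evidence are left untouched.
#'
#' An AND complex contributes all its subunits to one branch, each with
#' coefficient 1/kcat of the whole reaction (the minimum of the subunit
#' kcats; subunit stoichiometry 1). A multifunctional enzyme keeps one enzyme
#' species and one usage reaction shared by all reactions it catalyzes, so
#' its abundance bound couples those fluxes. A reversible enzyme split over
#' "_fwd"/"_rev" copies may carry two kcats but shares one usage bound.
#'
#' @param model an irreversible \code{ec_model} (all lb >= 0).
#' @param kinetics a \code{kcat_table}.
#' @param abundances an \code{abundance_table}, or NULL for none.
#' @return an \code{ec_ecmodel}: the expanded model plus \code{proteins}
#'   (registry data.frame), \code{usage_reactions}, \code{arm_metabolites},
#'   \code{parent_map} (expanded id -> pre-expansion id) and
#'   \code{build_report}.
#' @export
expand_ec <- function(model, kinetics, abundances = NULL) {
  lbs <- vapply(model$reactions, `[[`, 0, "lb")
  if (any(lbs < 0)) stop("expand_ec needs an irreversible model; run to_irreversible() first")

  pm <- model$protein_map
  lookup_kcat <- function(protein, rid) {
    hit <- select_kcat(kinetics, protein, rid)
    if (is.null(hit) && !is.null(model$parent_map)) {
      base <- model$parent_map[[rid]] %||% rid
      if (!identical(base, rid)) hit <- select_kcat(kinetics, protein, base)
    }
    hit
  }

  proteins <- new.env(parent = emptyenv())   # protein -> entry
  note_protein <- function(p, genes, rid, kcat, rule) {
    e <- get0(p, envir = proteins)
    if (is.null(e)) e <- list(protein = p, genes = character(),
                              kcat_by_reaction = numeric(), rules = character())
    e$genes <- unique(c(e$genes, genes))
    e$kcat_by_reaction[rid] <- kcat
    e$rules[rid] <- rule
    assign(p, e, envir = proteins)
  }

  new_rx <- list()
  new_mets <- model$metabolites
  arm_mets <- character()
  parent <- character()
  report_rows <- list()

  for (r in model$reactions) {
    branches <- gpr_branches(r$gpr)
    if (!length(branches) || r$kind != "metabolic") {
      new_rx <- c(new_rx, list(r)); parent[r$id] <- r$id
      if (length(branches))
        report_rows[[length(report_rows) + 1L]] <-
          data.frame(reaction = r$id, status = "non_metabolic_gpr",
                     n_branches = length(branches), n_matched = 0L)
      next
    }
    # resolve each branch to proteins + kcats
    binfo <- lapply(branches, function(genes) {
      prots <- unname(pm[genes])
      if (any(is.na(prots))) return(list(ok = FALSE, genes = genes))
      hits <- lapply(prots, lookup_kcat, rid = r$id)
      if (any(vapply(hits, is.null, TRUE)))
        return(list(ok = FALSE, genes = genes, proteins = prots))
      kc <- vapply(hits, `[[`, 0, "kcat")
      list(ok = TRUE, genes = genes, proteins = prots,
           kcat = min(kc), rules = vapply(hits, `[[`, "", "rule"))
    })
    matched <- vapply(binfo, `[[`, TRUE, "ok")
    n_m <- sum(matched)
    report_rows[[length(report_rows) + 1L]] <-
      data.frame(reaction = r$id,
                 status = if (n_m == 0L) "no_kinetics"
                          else if (length(branches) >= 2L && n_m < 2L) "partial_kinetics"
                          else "expanded",
                 n_branches = length(branches), n_matched = n_m)

    if (n_m == 0L || (length(branches) >= 2L && n_m < 2L)) {
      # no (usable) kinetic evidence: constraint removed, reaction untouched
      if (n_m < length(branches))
        warning("reaction ", r$id, ": kinetic evidence incomplete; left unconstrained",
                call. = FALSE)
      new_rx <- c(new_rx, list(r)); parent[r$id] <- r$id
      next
    }

    if (length(branches) == 1L) {
      bi <- binfo[[1]]
      r2 <- r
      for (p in bi$proteins) {
        emet <- paste0("prot_", p)
        r2$stoich[emet] <- (r2$stoich[emet] %||na% 0) - 1 / bi$kcat
        note_protein(p, bi$genes, r$id, bi$kcat, bi$rules[1])
      }
      new_rx <- c(new_rx, list(r2)); parent[r2$id] <- r$id
    } else {
      amet <- paste0("pmet_", r$id)
      arm_mets <- c(arm_mets, amet)
      subs <- r$stoich[r$stoich < 0]; prods <- r$stoich[r$stoich >= 0]
      arm <- reaction(paste0("arm_", r$id),
                      c(subs, stats::setNames(1, amet)),
                      lb = 0, ub = r$ub, gpr = NULL, kind = "arm")
      new_rx <- c(new_rx, list(arm)); parent[arm$id] <- r$id
      for (i in seq_along(binfo)) {
        bi <- binfo[[i]]
        st <- c(stats::setNames(-1, amet), prods)
        if (bi$ok) {
          for (p in bi$proteins) {
            emet <- paste0("prot_", p)
            st[emet] <- (st[emet] %||na% 0) - 1 / bi$kcat
            note_protein(p, bi$genes, paste0(r$id, "No", i), bi$kcat, bi$rules[1])
          }
        }
        gtxt <- if (length(bi$genes) > 1L)
          paste(bi$genes, collapse = " and ") else bi$genes
        br <- reaction(paste0(r$id, "No", i), st, lb = 0, ub = r$ub,
                       gpr = parse_gpr(gtxt), kind = "metabolic")
        new_rx <- c(new_rx, list(br)); parent[br$id] <- r$id
      }
    }
  }

  # enzyme species + usage reactions, abundance-bounded
  plist <- mget(ls(proteins), envir = proteins)
  usage <- character()
  prot_rows <- list()
  for (p in names(plist)) {
    e <- plist[[p]]
    emet <- paste0("prot_", p)
    new_mets <- rbind(new_mets,
                      data.frame(id = emet, name = p, compartment = "enz",
                                 kind = "enzyme", stringsAsFactors = FALSE))
    ab <- if (!is.null(abundances)) match_abundance(abundances, p) else NULL
    bound <- if (is.null(ab)) Inf else ab$abundance
    uid <- paste0("usage_", p)
    new_rx <- c(new_rx, list(reaction(uid, stats::setNames(1, emet),
                                      lb = 0, ub = bound, kind = "usage")))
    parent[uid] <- uid
    usage[p] <- uid
    prot_rows[[p]] <- data.frame(
      protein = p, genes = paste(e$genes, collapse = ";"),
      mw = protein_mw(kinetics, p),
      n_reactions = length(e$kcat_by_reaction),
      abundance_bound = bound,
      abundance_taxon = if (is.null(ab)) NA_character_ else ab$taxon,
      abundance_rank = if (is.null(ab)) NA_character_ else ab$rank,
      kcat_rules = paste(unique(e$rules), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  if (length(arm_mets))
    new_mets <- rbind(new_mets,
                      data.frame(id = arm_mets, name = arm_mets,
                                 compartment = "c", kind = "arm",
                                 stringsAsFactors = FALSE))

  out <- metabolic_model(new_mets, new_rx, model$genes, model$objective, pm)
  class(out) <- c("ec_ecmodel", class(out))
  out$proteins <- if (length(prot_rows)) do.call(rbind, unname(prot_rows))
                  else data.frame()
  out$protein_entries <- plist
  out$usage_reactions <- usage
  out$arm_metabolites <- arm_mets
  out$parent_map <- parent
  out$base_parent_map <- model$parent_map
  out$build_report <- if (length(report_rows)) do.call(rbind, report_rows)
                      else data.frame()
  out
}

#' Set the abundance (usage) bound of one protein
#'
#' @param ecmodel an \code{ec_ecmodel}.
#' @param protein protein id.
#' @param bound new upper bound, mmol/gDW (may be \code{Inf}).
#' @return modified model.
#' @export
set_usage_bound <- function(ecmodel, protein, bound) {
  if (bound < 0) stop("usage bound must be >= 0")
  if (!protein %in% names(ecmodel$usage_reactions))
    stop("unknown protein: ", protein)
  uid <- ecmodel$usage_reactions[[protein]]
  ecmodel$reactions[[uid]]$ub <- bound
  ecmodel$proteins$abundance_bound[ecmodel$proteins$protein == protein] <- bound
  ecmodel
}

#' Add a shared protein-pool constraint
#'
#' Couples all enzyme usages through a common pool: a pool pseudo-species is
#' drawn MW/1000 g per mmol of each usage and supplied by a pool-exchange
#' reaction bounded by \code{sigma * ptot} g protein/gDW. Proteins without a
#' known molecular weight are excluded with a warning. Disabled by default in
#' the pipeline; with a generous pool the constraint is slack and the optimum
#' unchanged.
#'
#' @param ecmodel an \code{ec_ecmodel}.
#' @param ptot total protein content, g protein/gDW.
#' @param sigma fraction of the proteome available to metabolism (0..1).
#' @return modified model with pool species \code{prot_pool} and reaction
#'   \code{usage_pool}.
#' @export
add_protein_pool <- function(ecmodel, ptot, sigma = 0.5) {
  ecmodel$metabolites <- rbind(ecmodel$metabolites,
    data.frame(id = "prot_pool", name = "protein pool", compartment = "enz",
               kind = "enzyme", stringsAsFactors = FALSE))
  pooled <- 0L
  for (p in names(ecmodel$usage_reactions)) {
    mw <- ecmodel$proteins$mw[ecmodel$proteins$protein == p]
    if (!length(mw) || is.na(mw)) {
      warning("protein ", p, " has no molecular weight; excluded from pool",
              call. = FALSE)
      next
    }
    uid <- ecmodel$usage_reactions[[p]]
    ecmodel$reactions[[uid]]$stoich["prot_pool"] <- -mw / 1000
    pooled <- pooled + 1L
  }
  ecmodel$reactions[["usage_pool"]] <-
    reaction("usage_pool", stats::setNames(1, "prot_pool"),
             lb = 0, ub = sigma * ptot, kind = "usage")
  ecmodel$parent_map["usage_pool"] <- "usage_pool"
  validate_model(ecmodel)
  ecmodel
}

#' Lift every usage bound (remove all enzyme-abundance constraints)
#' @param ecmodel an \code{ec_ecmodel}.
#' @return model with all usage upper bounds set to \code{Inf}.
#' @export
relax_usage_bounds <- function(ecmodel) {
  for (uid in ecmodel$usage_reactions)
    ecmodel$reactions[[uid]]$ub <- Inf
  ecmodel
}
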