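#' Create a condition specification
#'
#' A condition names uptake magnitudes (mmol/gDW/h) for exchange reactions
#' and, optionally, reactions fixed to a value (e.g. growth fixed to a
#' chemostat dilution rate).
#'
#' @param uptake named numeric vector, exchange base id -> uptake magnitude
#'   (>= 0; \code{Inf} lifts the limit).
#' @param fixed named numeric vector, reaction id -> fixed flux value.
#' @param label condition label.
#' @return list of class \code{ec_condition}.
#' @export
condition_spec <- function(uptake = numeric(), fixed = numeric(),
                           label = "condition") {
  if (any(uptake < 0)) stop("uptake bounds are magnitudes and must be >= 0")
  structure(list(uptake = uptake, fixed = fixed, label = label),
            class = "ec_condition")
}

#' Read a condition specification from YAML
#'
#' Schema: \code{uptake:} mapping of exchange id to magnitude (the string
#' "inf" lifts a limit); \code{fixed:} mapping of reaction id to value;
#' \code{label:} optional.
#'
#' @param path YAML file.
#' @return an \code{ec_condition}.
#' @export
read_condition <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read condition files")
  d <- yaml::read_yaml(path)
  as_num <- function(v) {
    out <- vapply(v, function(x)
      if (is.character(x) && tolower(x) == "inf") Inf else as.numeric(x), 0)
    out
  }
  condition_spec(uptake = if (length(d$uptake)) as_num(d$uptake) else numeric(),
                 fixed = if (length(d$fixed)) as_num(d$fixed) else numeric(),
                 label = d$label %||% basename(path))
}

apply_condition <- function(model, condition) {
  if (is.null(condition)) return(model)
  for (rxn in names(condition$uptake))
    model <- set_uptake_bound(model, rxn, condition$uptake[[rxn]])
  for (rxn in names(condition$fixed)) {
    rid <- if (rxn %in% names(model$reactions)) rxn else paste0(rxn, "_fwd")
    if (!rid %in% names(model$reactions)) stop("unknown reaction in condition: ", rxn)
    v <- condition$fixed[[rxn]]
    model$reactions[[rid]]$lb <- v
    model$reactions[[rid]]$ub <- v
  }
  model
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux of an objective reaction subject to
#' steady state (S v = 0) and the model's flux bounds, optionally under a
#' condition specification. With \code{pfba = TRUE} the flux vector is
#' stabilized by parsimonious FBA: the objective is fixed at its optimum and
#' total absolute flux is minimized, which resolves alternate optima
#' deterministically.
#'
#' @param model an \code{ec_model} or \code{ec_ecmodel}.
#' @param objective reaction id; defaults to the model objective.
#' @param condition an \code{ec_condition} or NULL.
#' @param maximize direction (default TRUE).
#' @param pfba stabilize fluxes by parsimonious FBA (default FALSE).
#' @return list of class \code{ec_flux}: \code{objective_value},
#'   \code{fluxes} (named), \code{status}.
#' @export
fba <- function(model, objective = NULL, condition = NULL, maximize = TRUE,
                pfba = FALSE) {
  objective <- objective %||% model$objective
  model <- apply_condition(model, condition)
  if (!objective %in% names(model$reactions))
    stop("objective reaction not in model: ", objective)
  S <- stoich_matrix(model)
  bb <- model_bounds(model)
  obj <- as.numeric(names(model$reactions) == objective)
  sol <- solve_lp(obj, S, rep(0, nrow(S)), bb$lb, bb$ub, maximize = maximize)
  if (sol$status != "optimal") {
    return(structure(list(objective_value = NA_real_, fluxes = NULL,
                          status = sol$status), class = "ec_flux"))
  }
  fluxes <- stats::setNames(sol$x, names(model$reactions))
  if (pfba) {
    fluxes <- pfba_fluxes(model, objective, sol$objective, S, bb)
  }
  structure(list(objective_value = sol$objective, fluxes = fluxes,
                 status = "optimal"), class = "ec_flux")
}

# minimize total |v| at fixed objective value; reversible columns are split
# internally so the l1 objective stays linear.
pfba_fluxes <- function(model, objective, zstar, S, bb) {
  lb <- bb$lb; ub <- bb$ub
  i_obj <- match(objective, names(model$reactions))
  lb[i_obj] <- zstar; ub[i_obj] <- zstar
  n <- ncol(S)
  negs <- which(lb < 0)
  if (length(negs)) {
    S2 <- cbind(S, -S[, negs, drop = FALSE])
    lb2 <- c(pmax(lb, 0), rep(0, length(negs)))
    ub2 <- c(pmax(ub, 0), ifelse(is.finite(lb[negs]), -lb[negs], Inf))
    sol <- solve_lp(rep(1, ncol(S2)), S2, rep(0, nrow(S2)), lb2, ub2,
                    maximize = FALSE)
    if (sol$status != "optimal") stop("pFBA subproblem ", sol$status)
    v <- sol$x[seq_len(n)]
    v[negs] <- v[negs] - sol$x[n + seq_along(negs)]
  } else {
    sol <- solve_lp(rep(1, n), S, rep(0, nrow(S)), lb, ub, maximize = FALSE)
    if (sol$status != "optimal") stop("pFBA subproblem ", sol$status)
    v <- sol$x
  }
  stats::setNames(v, names(model$reactions))
}

#' Growth robustness surface over two exchange fluxes
#'
#' Runs max-growth FBA on a grid of uptake bounds for two exchange reactions
#' (typically glucose and oxygen, 0-5 mmol/gDW/h) and reports the growth
#' optimum at each point. An enzyme-constrained model saturates (plateaus)
#' when enzyme capacity, not supply, limits growth; an unconstrained model
#' keeps climbing with supply.
#'
#' @param model an \code{ec_model}.
#' @param rxn_a,rxn_b exchange base ids of the two varied uptakes.
#' @param max_a,max_b upper ends of the ranges (mmol/gDW/h).
#' @param steps grid points per axis (range is 0..max inclusive).
#' @param condition baseline condition applied before the sweep.
#' @return list: \code{growth} (steps x steps matrix, rows = rxn_a values),
#'   \code{a_values}, \code{b_values}, \code{saturated} (logical: growth at
#'   the grid corner stops responding to either supply), \code{infeasible}
#'   (logical matrix; infeasible points carry growth 0).
#' @export
robustness_surface <- function(model, rxn_a, rxn_b, max_a = 5, max_b = 5,
                               steps = 11, condition = NULL) {
  model <- apply_condition(model, condition)
  av <- seq(0, max_a, length.out = steps)
  bv <- seq(0, max_b, length.out = steps)
  gr <- matrix(0, steps, steps, dimnames = list(signif(av, 6), signif(bv, 6)))
  inf <- matrix(FALSE, steps, steps)
  for (i in seq_along(av)) for (j in seq_along(bv)) {
    m <- set_uptake_bound(model, rxn_a, av[i])
    m <- set_uptake_bound(m, rxn_b, bv[j])
    s <- fba(m)
    if (s$status == "optimal") gr[i, j] <- s$objective_value else inf[i, j] <- TRUE
  }
  sat <- steps >= 2 &&
    abs(gr[steps, steps] - gr[steps - 1, steps]) <= 1e-9 &&
    abs(gr[steps, steps] - gr[steps, steps - 1]) <= 1e-9
  list(growth = gr, a_values = av, b_values = bv, saturated = sat,
       infeasible = inf)
}

#' Flux variability analysis
#'
#' Constrains the objective to at least \code{fraction} of its FBA optimum
#' and solves a min and a max LP per reaction. FV = max - min per reaction.
#'
#' @param model an \code{ec_model}.
#' @param fraction fraction of the optimum retained (default 0.999, i.e. a
#'   99.9\% confidence level on the biomass flux).
#' @param condition optional \code{ec_condition}.
#' @param reactions subset of reaction ids (default: all).
#' @return data.frame: \code{reaction}, \code{min_flux}, \code{max_flux},
#'   \code{fv}; unbounded directions yield infinite entries.
#' @export
fva <- function(model, fraction = 0.999, condition = NULL, reactions = NULL) {
  model <- apply_condition(model, condition)
  base <- fba(model)
  if (base$status != "optimal") stop("FVA: baseline FBA is ", base$status)
  S <- stoich_matrix(model)
  bb <- model_bounds(model)
  i_obj <- match(model$objective, names(model$reactions))
  bb$lb[i_obj] <- max(bb$lb[i_obj], fraction * base$objective_value)
  rids <- reactions %||% names(model$reactions)
  zero <- rep(0, nrow(S))
  out <- data.frame(reaction = rids, min_flux = NA_real_, max_flux = NA_real_)
  for (k in seq_along(rids)) {
    j <- match(rids[k], names(model$reactions))
    obj <- numeric(ncol(S)); obj[j] <- 1
    lo <- solve_lp(obj, S, zero, bb$lb, bb$ub, maximize = FALSE)
    hi <- solve_lp(obj, S, zero, bb$lb, bb$ub, maximize = TRUE)
    out$min_flux[k] <- if (lo$status == "optimal") lo$objective
                       else if (lo$status == "unbounded") -Inf else NA
    out$max_flux[k] <- if (hi$status == "optimal") hi$objective
                       else if (hi$status == "unbounded") Inf else NA
  }
  out$fv <- out$max_flux - out$min_flux
  out$fv[out$fv < 0 & out$fv > -1e-9] <- 0
  out
}

#' Flux-variability reduction of an enzyme-constrained model vs its base
#'
#' Per base reaction j: reduction_j = (1 - FV_ec_j / FV_base_j) x 100.
#' Reactions with zero base FV get reduction 0 (the ratio is undefined
#' there); reactions with infinite FV on either side are excluded and
#' counted. The model-level figure is the arithmetic mean over compared
#' reactions; a total-FV ratio (1 - sum FV_ec / sum FV_base) is reported
#' alongside.
#'
#' @param fva_base FVA table of the (irreversible) base model.
#' @param fva_ec FVA table of the expanded model.
#' @param parent_map named character, expanded reaction id -> base id (from
#'   \code{\link{expand_ec}}); for an arm-split reaction the arm reaction
#'   carries the comparable total flux.
#' @return list of class \code{ec_fv_reduction}: \code{per_reaction}
#'   (data.frame), \code{model_reduction} (mean percent),
#'   \code{total_fv_reduction} (percent), \code{n_reduced},
#'   \code{n_reduced_75}, \code{n_compared}, \code{n_excluded}.
#' @export
fv_reduction <- function(fva_base, fva_ec, parent_map) {
  ec_for_base <- function(base_id) {
    arm <- paste0("arm_", base_id)
    if (arm %in% fva_ec$reaction) return(arm)
    kids <- names(parent_map)[parent_map == base_id]
    kids <- setdiff(intersect(kids, fva_ec$reaction), character())
    if (base_id %in% kids) return(base_id)
    if (length(kids) == 1L) return(kids)
    NA_character_
  }
  rows <- list(); excluded <- 0L
  for (k in seq_len(nrow(fva_base))) {
    bid <- fva_base$reaction[k]
    eid <- ec_for_base(bid)
    if (is.na(eid)) { excluded <- excluded + 1L; next }
    fvb <- fva_base$fv[k]
    fve <- fva_ec$fv[match(eid, fva_ec$reaction)]
    if (!is.finite(fvb) || !is.finite(fve)) { excluded <- excluded + 1L; next }
    red <- if (fvb <= 1e-12) 0 else (1 - fve / fvb) * 100
    rows[[length(rows) + 1L]] <-
      data.frame(reaction = bid, ec_reaction = eid, fv_base = fvb,
                 fv_ec = fve, reduction = red)
  }
  per <- do.call(rbind, rows)
  tot_b <- sum(per$fv_base); tot_e <- sum(per$fv_ec)
  structure(list(
    per_reaction = per,
    model_reduction = mean(per$reduction),
    total_fv_reduction = if (tot_b > 0) (1 - tot_e / tot_b) * 100 else 0,
    n_reduced = sum(per$reduction > 1e-9),
    n_reduced_75 = sum(per$reduction > 75),
    n_compared = nrow(per), n_excluded = excluded),
    class = "ec_fv_reduction")
}

#' Single-gene knockout screen
#'
#' For each gene, the GPR of every reaction is evaluated with that gene
#' deleted; reactions that can no longer be catalyzed get bounds [0, 0], and
#' in an enzyme-constrained model the usage bound of any protein left with
#' no supporting gene is zeroed (isozyme branches keep rerouting through
#' their own usage reactions). grRatio = mu_mutant / mu_wild.
#'
#' @param model an \code{ec_model} or \code{ec_ecmodel}.
#' @param genes genes to screen (default: all model genes).
#' @param condition optional \code{ec_condition} shared by wild type and
#'   mutants.
#' @param eps classification tolerance: lethal when grRatio <= eps, neutral
#'   when |grRatio - 1| <= eps, otherwise limiting.
#' @return data.frame: \code{gene}, \code{mu_mutant}, \code{grRatio},
#'   \code{class}.
#' @export
single_gene_knockout <- function(model, genes = NULL, condition = NULL,
                                 eps = 1e-6) {
  genes <- genes %||% model$genes
  missing <- setdiff(genes, model$genes)
  if (length(missing))
    stop("genes absent from model: ", paste(missing, collapse = ", "))
  model <- apply_condition(model, condition)
  wt <- fba(model)
  if (wt$status != "optimal") stop("wild-type FBA is ", wt$status)
  mu_w <- wt$objective_value
  is_ec <- inherits(model, "ec_ecmodel")
  out <- data.frame(gene = genes, mu_mutant = NA_real_, grRatio = NA_real_,
                    class = NA_character_)
  for (k in seq_along(genes)) {
    g <- genes[k]
    m <- model
    for (r in m$reactions) {
      if (!is.null(r$gpr) && !gpr_eval(r$gpr, g)) {
        m$reactions[[r$id]]$lb <- 0
        m$reactions[[r$id]]$ub <- 0
      }
    }
    if (is_ec) {
      for (p in names(m$usage_reactions)) {
        pg <- m$protein_entries[[p]]$genes
        if (g %in% pg && all(pg %in% g)) {
          m$reactions[[m$usage_reactions[[p]]]]$ub <- 0
        }
      }
    }
    s <- fba(m)
    mu <- if (s$status == "optimal") s$objective_value else 0
    gr <- if (mu_w > 0) mu / mu_w else NA_real_
    out$mu_mutant[k] <- mu
    out$grRatio[k] <- gr
    out$class[k] <- if (is.na(gr)) NA_character_
                    else if (gr <= eps) "lethal"
                    else if (abs(gr - 1) <= eps) "neutral"
                    else "limiting"
  }
  out
}

#' Differential enzyme usage across carbon sources
#'
#' Runs max-growth parsimonious FBA under a reference condition (e.g.
#' glucose at 1.0 mmol/gDW/h, oxygen unlimited) and each alternate carbon
#' source (e.g. xylose at 1.2 or maltose at 0.5 mmol/gDW/h, chosen so the
#' carbon-mole supply matches), reads the flux of every enzyme-usage
#' reaction, and reports fold changes of alternate vs reference usage.
#' Usages induced from a zero baseline are flagged rather than divided by
#' zero (denominator floored at \code{eps}).
#'
#' @param ecmodel an \code{ec_ecmodel}.
#' @param reference \code{ec_condition} of the reference carbon source.
#' @param alternates list of \code{ec_condition}s.
#' @param eps denominator floor for fold changes.
#' @return data.frame: \code{condition}, \code{protein}, \code{usage_ref},
#'   \code{usage}, \code{fold_change}, \code{induced_from_zero}; ordered by
#'   condition then descending fold change.
#' @export
differential_usage <- function(ecmodel, reference, alternates, eps = 1e-8) {
  ref <- fba(ecmodel, condition = reference, pfba = TRUE)
  if (ref$status != "optimal")
    stop("reference condition '", reference$label, "' is ", ref$status)
  uids <- ecmodel$usage_reactions
  u_ref <- ref$fluxes[uids]
  rows <- list()
  for (cond in alternates) {
    alt <- fba(ecmodel, condition = cond, pfba = TRUE)
    if (alt$status != "optimal")
      stop("condition '", cond$label, "' is ", alt$status)
    u_alt <- alt$fluxes[uids]
    fc <- u_alt / pmax(u_ref, eps)
    d <- data.frame(condition = cond$label, protein = names(uids),
                    usage_ref = unname(u_ref), usage = unname(u_alt),
                    fold_change = unname(fc),
                    induced_from_zero = unname(u_ref <= eps & u_alt > eps))
    rows[[cond$label]] <- d[order(-d$fold_change), ]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
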