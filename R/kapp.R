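#' Build a substrate x oxygen condition grid
#'
#' Cartesian grid of uptake conditions for two exchange reactions, used for
#' the apparent-catalytic-rate (kapp) sweep. The default 20 x 20 grid over
#' (0.25, 5.0] mmol/gDW/h on each axis yields 400 conditions, glc-major
#' ordered.
#'
#' @param glc_rxn,o2_rxn exchange base ids (defaults "EX_glc", "EX_o2").
#' @param glc_range,o2_range numeric length-2 ranges (mmol/gDW/h), inclusive.
#' @param steps grid points per axis (>= 1).
#' @return list of \code{ec_condition}s, length steps^2.
#' @export
condition_grid <- function(glc_rxn = "EX_glc", o2_rxn = "EX_o2",
                           glc_range = c(0.25, 5), o2_range = c(0.25, 5),
                           steps = 20) {
  if (steps < 1) stop("steps must be >= 1")
  if (diff(glc_range) < 0 || diff(o2_range) < 0) stop("ranges must be increasing")
  gv <- if (steps == 1) glc_range[2] else seq(glc_range[1], glc_range[2], length.out = steps)
  ov <- if (steps == 1) o2_range[2] else seq(o2_range[1], o2_range[2], length.out = steps)
  out <- vector("list", steps * steps)
  k <- 0L
  for (g in gv) for (o in ov) {
    k <- k + 1L
    out[[k]] <- condition_spec(
      uptake = stats::setNames(c(g, o), c(glc_rxn, o2_rxn)),
      label = sprintf("glc=%.4g,o2=%.4g", g, o))
  }
  out
}

#' Estimate apparent catalytic rates over a condition grid
#'
#' For each condition, a max-growth (parsimonious) FBA is run and
#' kapp = v_j / E_j computed per (protein, reaction) pair, with E_j the
#' protein's fixed abundance bound -- abundances are not condition-specific.
#' With \code{flux_source = "relaxed"} (default) the usage bounds are lifted
#' before simulating, so fluxes are not capped by the possibly
#' over-constraining kcat * E products; \code{"constrained"} keeps the
#' bounds, in which case kapp <= kcat holds by construction. Pairs with zero
#' flux in every condition yield no estimate; infeasible conditions are
#' skipped and recorded.
#'
#' @param ecmodel an \code{ec_ecmodel} whose scored proteins have finite
#'   abundance bounds.
#' @param conditions list of \code{ec_condition}s (see
#'   \code{\link{condition_grid}}).
#' @param flux_source "relaxed" or "constrained".
#' @return list of class \code{ec_kapp}: \code{estimates} (data.frame:
#'   protein, reaction, kcat_db, kapp_max, eta_max, n_conditions),
#'   \code{by_condition} (long data.frame of per-condition kapp),
#'   \code{skipped} (labels of infeasible conditions).
#' @export
estimate_kapp <- function(ecmodel, conditions,
                          flux_source = c("relaxed", "constrained")) {
  flux_source <- match.arg(flux_source)
  sim_model <- if (flux_source == "relaxed") relax_usage_bounds(ecmodel)
               else ecmodel
  pairs <- kcat_pairs(ecmodel)
  if (!nrow(pairs)) stop("model has no enzyme-costed reactions")
  E <- stats::setNames(ecmodel$proteins$abundance_bound,
                       ecmodel$proteins$protein)
  if (any(!is.finite(E[pairs$protein])))
    stop("kapp estimation needs a finite abundance bound for every scored protein")
  skipped <- character()
  long <- list()
  for (cond in conditions) {
    s <- fba(sim_model, condition = cond, pfba = TRUE)
    if (s$status != "optimal") { skipped <- c(skipped, cond$label); next }
    v <- s$fluxes[pairs$reaction]
    long[[cond$label]] <- data.frame(
      protein = pairs$protein, reaction = pairs$reaction,
      condition = cond$label, v = unname(v),
      kapp = unname(v) / unname(E[pairs$protein]))
  }
  if (!length(long)) stop("all conditions infeasible")
  bc <- do.call(rbind, long); rownames(bc) <- NULL
  key <- paste(bc$protein, bc$reaction, sep = "\r")
  agg <- stats::aggregate(bc$kapp, list(key = key), max)
  nonzero <- stats::setNames(agg$x, agg$key)
  est <- pairs
  k2 <- paste(est$protein, est$reaction, sep = "\r")
  est$kapp_max <- unname(nonzero[k2])
  est$eta_max <- est$kapp_max / est$kcat_db
  est$n_conditions <- as.integer(table(key)[k2])
  est <- est[est$kapp_max > 1e-12, , drop = FALSE]   # all-zero-flux pairs drop out
  structure(list(estimates = est, by_condition = bc, skipped = skipped),
            class = "ec_kapp")
}

# (protein, reaction, kcat_db) pairs of every enzyme-costed reaction
kcat_pairs <- function(ecmodel) {
  rows <- list()
  for (p in names(ecmodel$protein_entries)) {
    e <- ecmodel$protein_entries[[p]]
    for (rid in names(e$kcat_by_reaction)) {
      rows[[length(rows) + 1L]] <-
        data.frame(protein = p, reaction = rid,
                   kcat_db = unname(e$kcat_by_reaction[[rid]]))
    }
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}

#' Replace kcat values by kapp-derived estimates
#'
#' For every (protein, reaction) with an estimate, the enzyme's
#' stoichiometric coefficient in that reaction becomes -1/kcat_new. The
#' default policy \code{"replace_if_larger"} takes
#' kcat_new = max(kcat_db, kapp_max), so the correction can only relax the
#' model (the growth optimum cannot decrease, and a second pass changes
#' nothing); \code{"always_replace"} takes kapp_max unconditionally.
#'
#' @param ecmodel the \code{ec_ecmodel} the estimates were computed on.
#' @param kapp an \code{ec_kapp} from \code{\link{estimate_kapp}}.
#' @param policy "replace_if_larger" (default) or "always_replace".
#' @return the corrected model, with a \code{kcat_changes} data.frame
#'   (protein, reaction, kcat_old, kcat_new, ratio) attached.
#' @export
correct_kcats <- function(ecmodel, kapp,
                          policy = c("replace_if_larger", "always_replace")) {
  policy <- match.arg(policy)
  est <- kapp$estimates
  changes <- list()
  for (k in seq_len(nrow(est))) {
    p <- est$protein[k]; rid <- est$reaction[k]
    emet <- paste0("prot_", p)
    rxn <- ecmodel$reactions[[rid]]
    if (is.null(rxn) || is.na(rxn$stoich[emet]) || rxn$stoich[emet] >= 0)
      stop("no enzyme coefficient for ", p, " in reaction ", rid)
    old <- ecmodel$protein_entries[[p]]$kcat_by_reaction[[rid]]
    new <- if (policy == "replace_if_larger") max(old, est$kapp_max[k])
           else est$kapp_max[k]
    ecmodel$reactions[[rid]]$stoich[emet] <- -1 / new
    ecmodel$protein_entries[[p]]$kcat_by_reaction[[rid]] <- new
    changes[[length(changes) + 1L]] <-
      data.frame(protein = p, reaction = rid, kcat_old = old, kcat_new = new,
                 ratio = new / old)
  }
  ecmodel$kcat_changes <- do.call(rbind, changes)
  ecmodel
}

#' Detect enzyme over-constraint
#'
#' Flags a model whose max-growth optimum stays below \code{threshold}
#' across an entire condition grid -- the signature of database kcat values
#' too small for any growth. For a flagged model the report lists the
#' binding capacities: (protein, reaction) pairs whose kcat * E ceiling lies
#' below the flux the relaxed model would carry at the most permissive grid
#' point.
#'
#' @param ecmodel an \code{ec_ecmodel}.
#' @param conditions list of \code{ec_condition}s.
#' @param threshold growth-rate floor, 1/h (default 1e-6).
#' @return list of class \code{ec_overconstraint}: \code{flagged},
#'   \code{max_growth}, \code{threshold}, \code{binding} (data.frame of
#'   undersized capacities).
#' @export
detect_overconstraint <- function(ecmodel, conditions, threshold = 1e-6) {
  best <- 0; best_cond <- NULL
  for (cond in conditions) {
    s <- fba(ecmodel, condition = cond)
    if (s$status == "optimal" && s$objective_value > best) {
      best <- s$objective_value; best_cond <- cond
    }
    if (is.null(best_cond)) best_cond <- cond
  }
  flagged <- best < threshold
  binding <- data.frame()
  if (flagged) {
    ref <- fba(relax_usage_bounds(ecmodel), condition = best_cond, pfba = TRUE)
    if (ref$status == "optimal") {
      pairs <- kcat_pairs(ecmodel)
      E <- stats::setNames(ecmodel$proteins$abundance_bound,
                           ecmodel$proteins$protein)
      cap <- pairs$kcat_db * unname(E[pairs$protein])
      need <- unname(ref$fluxes[pairs$reaction])
      sel <- need > cap + 1e-12
      binding <- cbind(pairs[sel, , drop = FALSE],
                       capacity = cap[sel], required_flux = need[sel])
    }
  }
  structure(list(flagged = flagged, max_growth = best, threshold = threshold,
                 binding = binding), class = "ec_overconstraint")
}
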