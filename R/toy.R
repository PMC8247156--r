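#' Specification for a synthetic toy model
#'
#' Toy models are substrate-exchange -> linear-chain -> biomass networks with
#' the requested enzyme patterns, built so the max-growth optimum has a
#' closed form: the minimum of the uptake bound and every enzyme capacity
#' along the chain. Topology is deterministic from the counts; randomness
#' (seeded) touches only the kcat/abundance draws and reversibility choices.
#'
#' @param n_linear_steps chain length (>= 1).
#' @param isozyme_reactions steps catalyzed by an OR pair of isozymes.
#' @param complex_reactions steps catalyzed by an AND two-subunit complex.
#' @param reversible_fraction fraction of chain steps made reversible.
#' @param kcat_range kcat draw range, 1/h.
#' @param abundance_range abundance draw range, mmol/gDW.
#' @param uptake_bound substrate uptake bound, mmol/gDW/h.
#' @param multifunctional share one enzyme between two plain steps when
#'   possible (default TRUE).
#' @param seed RNG seed; same seed, same fixtures.
#' @return list of class \code{ec_toy_spec}.
#' @export
toy_spec <- function(n_linear_steps = 4, isozyme_reactions = 1,
                     complex_reactions = 1, reversible_fraction = 0.25,
                     kcat_range = c(50, 500), abundance_range = c(0.001, 0.05),
                     uptake_bound = 10, multifunctional = TRUE, seed = 1) {
  stopifnot(n_linear_steps >= 1, isozyme_reactions >= 0, complex_reactions >= 0,
            isozyme_reactions + complex_reactions <= n_linear_steps,
            all(kcat_range > 0), all(abundance_range > 0), uptake_bound > 0)
  structure(list(n_linear_steps = n_linear_steps,
                 isozyme_reactions = isozyme_reactions,
                 complex_reactions = complex_reactions,
                 reversible_fraction = reversible_fraction,
                 kcat_range = kcat_range, abundance_range = abundance_range,
                 uptake_bound = uptake_bound,
                 multifunctional = multifunctional, seed = seed),
            class = "ec_toy_spec")
}

#' Generate a toy model with known analytic optima
#'
#' Builds \code{EX_S} (substrate exchange, uptake bound), chain steps
#' \code{r1..rn} converting \code{S[e] -> M1[c] -> ... -> Mn[c]}, and the
#' biomass drain \code{r_bio} (the objective) consuming \code{Mn}; every
#' chain step therefore carries the growth flux. Steps are assigned in
#' order: isozyme (OR) steps first, then complex (AND) steps, then -- when
#' two plain steps remain and \code{multifunctional} -- one enzyme shared by
#' the next two steps, and single enzymes for the rest. Every enzyme has a
#' kcat record and a species-rank abundance record.
#'
#' The analytic max-growth optimum is min(uptake, min over step
#' capacities), with step capacity: kcat*E for a single enzyme, sum of
#' kcat_i*E_i for an isozyme pair, kcat*min(E_subunit) for a complex, and
#' E/(1/kcat_a + 1/kcat_b) shared across the two multifunctional steps.
#' Without enzyme constraints the optimum is the uptake bound.
#'
#' @param spec an \code{ec_toy_spec}.
#' @return list: \code{model} (reversible form), \code{kinetics}
#'   (\code{kcat_table}), \code{abundances} (\code{abundance_table}),
#'   \code{analytic} (optimum_unconstrained, optimum_constrained,
#'   step_capacities).
#' @export
make_toy <- function(spec) {
  stopifnot(inherits(spec, "ec_toy_spec"))
  set.seed(spec$seed)
  n <- spec$n_linear_steps
  rkc <- function(k) stats::runif(k, spec$kcat_range[1], spec$kcat_range[2])
  rab <- function(k) stats::runif(k, spec$abundance_range[1],
                                  spec$abundance_range[2])

  kinds <- rep("single", n)
  if (spec$isozyme_reactions > 0)
    kinds[seq_len(spec$isozyme_reactions)] <- "iso"
  if (spec$complex_reactions > 0)
    kinds[spec$isozyme_reactions + seq_len(spec$complex_reactions)] <- "complex"
  plain <- which(kinds == "single")
  if (spec$multifunctional && length(plain) >= 2) kinds[plain[1:2]] <- "multi"
  n_rev <- floor(spec$reversible_fraction * n)
  rev_steps <- if (n_rev > 0) sort(sample(seq_len(n), n_rev)) else integer()

  nodes <- c("S[e]", paste0("M", seq_len(n), "[c]"))
  mets <- data.frame(id = nodes,
                     name = c("S", paste0("M", seq_len(n))),
                     compartment = c("e", rep("c", n)),
                     kind = "chemical", stringsAsFactors = FALSE)

  add_kcat <- function(p, rid, kcat)
    data.frame(protein = p, reaction = rid, kcat_per_h = kcat, sa = NA_real_,
               mw_da = 5e4, source = "synthetic", stringsAsFactors = FALSE)
  add_ab <- function(p, E)
    data.frame(protein = p, abundance = E, unit = "mmol_gDW",
               taxon = "target_sp", rank = "species", stringsAsFactors = FALSE)

  rx <- list(reaction("EX_S", stats::setNames(-1, "S[e]"),
                      lb = -spec$uptake_bound, ub = 0, kind = "exchange"))
  krec <- list(); arec <- list(); pmap <- character(); genes <- character()
  caps <- stats::setNames(rep(Inf, n), paste0("r", seq_len(n)))
  multi <- list(protein = NULL, gene = NULL, E = NA_real_, kcats = numeric())

  for (i in seq_len(n)) {
    rid <- paste0("r", i)
    st <- stats::setNames(c(-1, 1), nodes[c(i, i + 1)])
    lb <- if (i %in% rev_steps) -1000 else 0
    kind <- kinds[i]
    if (kind == "iso") {
      g <- paste0("g", i, c("a", "b")); p <- paste0("P", i, c("a", "b"))
      kc <- rkc(2); E <- rab(2)
      gpr <- parse_gpr(paste(g, collapse = " or "))
      krec <- c(krec, list(add_kcat(p[1], rid, kc[1]),
                           add_kcat(p[2], rid, kc[2])))
      arec <- c(arec, list(add_ab(p[1], E[1]), add_ab(p[2], E[2])))
      caps[rid] <- sum(kc * E)
      pmap[g] <- p
    } else if (kind == "complex") {
      g <- paste0("g", i, c("a", "b")); p <- paste0("P", i, c("a", "b"))
      kc <- rkc(1); E <- rab(2)
      gpr <- parse_gpr(paste(g, collapse = " and "))
      krec <- c(krec, list(add_kcat(p[1], rid, kc), add_kcat(p[2], rid, kc)))
      arec <- c(arec, list(add_ab(p[1], E[1]), add_ab(p[2], E[2])))
      caps[rid] <- kc * min(E)
      pmap[g] <- p
    } else if (kind == "multi") {
      if (is.null(multi$protein)) {
        multi$protein <- paste0("P", i, "mf")
        multi$gene <- paste0("g", i)
        multi$E <- rab(1)
        arec <- c(arec, list(add_ab(multi$protein, multi$E)))
      }
      g <- multi$gene; p <- multi$protein
      kc <- rkc(1)
      gpr <- parse_gpr(g)
      krec <- c(krec, list(add_kcat(p, rid, kc)))
      multi$kcats <- c(multi$kcats, kc)
      pmap[g] <- p
    } else {
      g <- paste0("g", i); p <- paste0("P", i)
      kc <- rkc(1); E <- rab(1)
      gpr <- parse_gpr(g)
      krec <- c(krec, list(add_kcat(p, rid, kc)))
      arec <- c(arec, list(add_ab(p, E)))
      caps[rid] <- kc * E
      pmap[g] <- p
    }
    genes <- unique(c(genes, gpr_genes(gpr)))
    rx <- c(rx, list(reaction(rid, st, lb = lb, ub = 1000, gpr = gpr)))
  }
  if (length(multi$kcats) == 2) {
    midx <- which(kinds == "multi")
    caps[paste0("r", midx[1])] <- multi$E / sum(1 / multi$kcats)
    # the shared-enzyme constraint is one coupling over both steps; count once
    caps[paste0("r", midx[2])] <- Inf
  }
  rx <- c(rx, list(reaction("r_bio", stats::setNames(-1, nodes[n + 1]),
                            lb = 0, ub = 1000, kind = "metabolic")))

  model <- metabolic_model(mets, rx, genes = genes, objective = "r_bio",
                           protein_map = pmap)
  list(model = model,
       kinetics = as_kcat_table(do.call(rbind, krec)),
       abundances = as_abundance_table(do.call(rbind, arec)),
       analytic = list(
         optimum_unconstrained = spec$uptake_bound,
         optimum_constrained = min(spec$uptake_bound, min(caps)),
         step_capacities = caps))
}

#' Build the enzyme-constrained form of a toy in one call
#' @param toy result of \code{\link{make_toy}}.
#' @return an \code{ec_ecmodel}.
#' @export
toy_ecmodel <- function(toy) {
  expand_ec(to_irreversible(toy$model), toy$kinetics, toy$abundances)
}

#' Generate an over-constrained toy fixture
#'
#' Multiplies the kcat records of one essential single-enzyme step by
#' \code{shrink}, dropping its capacity below any useful growth -- the
#' signature the kapp correction workflow must detect and repair. The
#' unshrunk analytic optimum is retained for the restoration check.
#'
#' @param spec an \code{ec_toy_spec}; needs at least one single-enzyme step.
#' @param shrink multiplicative factor (< 1 to over-constrain; 1 leaves the
#'   fixtures unchanged).
#' @return as \code{\link{make_toy}}, plus \code{shrunk} (protein/reaction
#'   hit) and \code{analytic$optimum_shrunk}.
#' @export
make_overconstrained <- function(spec, shrink = 1e-4) {
  if (shrink > 1) stop("shrink must be <= 1")
  toy <- make_toy(spec)
  kt <- toy$kinetics
  singles <- grep("^P[0-9]+$", kt$protein, value = TRUE)
  if (!length(singles)) stop("spec has no single-enzyme step to shrink")
  p <- singles[1]
  sel <- kt$protein == p
  kt$kcat_per_h[sel] <- kt$kcat_per_h[sel] * shrink
  rid <- kt$reaction[sel][1]
  toy$kinetics <- kt
  toy$shrunk <- list(protein = p, reaction = rid, factor = shrink)
  toy$analytic$optimum_shrunk <-
    min(toy$analytic$optimum_constrained,
        shrink * toy$analytic$step_capacities[[rid]])
  toy
}

#' Generate the carbon-source-switch toy
#'
#' Two alternative carbon-entry pathways feed a common carbon pool: a
#' 6-carbon source (glucose-like, uptake 1.0 mmol/gDW/h) and a 5-carbon
#' source (xylose-like, uptake 1.2 mmol/gDW/h), each gated by a dedicated
#' enzyme, so both conditions supply the same 6 C-mmol/gDW/h and switching
#' carbon source must up-regulate exactly the active pathway's enzyme usage.
#'
#' @param kcat gate-enzyme kcat, 1/h.
#' @param abundance gate-enzyme abundance, mmol/gDW (ample by default).
#' @return list: \code{model}, \code{kinetics}, \code{abundances},
#'   \code{conditions} (glucose reference + xylose alternate),
#'   \code{analytic} (growth 1.0 under both; 6 C-mmol/gDW/h supply).
#' @export
make_carbon_switch_toy <- function(kcat = 1e4, abundance = 1) {
  mets <- data.frame(
    id = c("GLC[e]", "XYL[e]", "C[c]"),
    name = c("GLC", "XYL", "C"),
    compartment = c("e", "e", "c"),
    kind = "chemical", stringsAsFactors = FALSE)
  rx <- list(
    reaction("EX_glc", stats::setNames(-1, "GLC[e]"), lb = -1, ub = 0,
             kind = "exchange"),
    reaction("EX_xyl", stats::setNames(-1, "XYL[e]"), lb = 0, ub = 0,
             kind = "exchange"),
    reaction("GLCt", c("GLC[e]" = -1, "C[c]" = 6), gpr = parse_gpr("gGLC")),
    reaction("XYLt", c("XYL[e]" = -1, "C[c]" = 5), gpr = parse_gpr("gXYL")),
    reaction("r_bio", c("C[c]" = -6), lb = 0, ub = 1000))
  model <- metabolic_model(mets, rx, genes = c("gGLC", "gXYL"),
                           objective = "r_bio",
                           protein_map = c(gGLC = "PGLC", gXYL = "PXYL"))
  kinetics <- as_kcat_table(rbind(
    data.frame(protein = "PGLC", reaction = "GLCt", kcat_per_h = kcat,
               sa = NA_real_, mw_da = 5e4, source = "synthetic"),
    data.frame(protein = "PXYL", reaction = "XYLt", kcat_per_h = kcat,
               sa = NA_real_, mw_da = 5e4, source = "synthetic")))
  abundances <- as_abundance_table(rbind(
    data.frame(protein = "PGLC", abundance = abundance, unit = "mmol_gDW",
               taxon = "target_sp", rank = "species"),
    data.frame(protein = "PXYL", abundance = abundance, unit = "mmol_gDW",
               taxon = "target_sp", rank = "species")))
  conditions <- list(
    glucose = condition_spec(uptake = c(EX_glc = 1.0, EX_xyl = 0),
                             label = "glucose"),
    xylose = condition_spec(uptake = c(EX_glc = 0, EX_xyl = 1.2),
                            label = "xylose"))
  list(model = model, kinetics = kinetics, abundances = abundances,
       conditions = conditions,
       analytic = list(growth = 1.0, carbon_mmol_per_h = 6))
}
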