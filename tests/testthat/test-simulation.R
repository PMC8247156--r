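test_that("FBA solves analytic chains and reports status faithfully", {
  fx <- linear_fixture(uptake = 10)
  irr <- to_irreversible(fx$model)
  expect_equal(fba(irr)$objective_value, 10)
  ec <- expand_ec(irr, fx$kinetics, fx$abundances)
  expect_equal(fba(ec)$objective_value, 1)      # enzyme cap kcat*E = 1
  # fixed-growth mode with an alternative objective: minimize uptake
  m <- apply_fixed <- fba(irr, objective = "EX_S_rev",
                          condition = condition_spec(fixed = c(r_bio = 0.4)),
                          maximize = FALSE)
  expect_equal(apply_fixed$objective_value, 0.4)
  # infeasible: demand above supply
  bad <- fba(irr, condition = condition_spec(uptake = c(EX_S = 1),
                                             fixed = c(r_bio = 5)))
  expect_identical(bad$status, "infeasible")
  expect_true(is.na(bad$objective_value))
})

test_that("FBA matches the brute-force LP oracle on toy fixtures", {
  for (s in c(2, 4, 6)) {
    toy <- make_toy(toy_spec(n_linear_steps = 3, isozyme_reactions = 1,
                             complex_reactions = 0, reversible_fraction = 0,
                             multifunctional = FALSE, seed = s,
                             uptake_bound = 5))
    ec <- toy_ecmodel(toy)
    S <- stoich_matrix(ec)
    bb <- model_bounds(ec)
    ub <- pmin(bb$ub, 1e4)                  # oracle needs finite bounds
    obj <- as.numeric(names(ec$reactions) == ec$objective)
    ref <- lp_bruteforce(obj, S, rep(0, nrow(S)), bb$lb, ub)
    expect_equal(fba(ec)$objective_value, ref, tolerance = 1e-7)
  }
})

test_that("pFBA keeps the optimum and minimizes total flux", {
  # two parallel equivalent paths: plain FBA may split; pFBA must not cycle
  mets <- data.frame(id = c("A[c]", "B[c]"), name = c("A", "B"),
                     compartment = "c", kind = "chemical")
  rx <- list(reaction("EX_A", c("A[c]" = -1), lb = -2, ub = 0, kind = "exchange"),
             reaction("p1", c("A[c]" = -1, "B[c]" = 1)),
             reaction("p2", c("A[c]" = -1, "B[c]" = 1)),
             reaction("loop", c("B[c]" = -1, "A[c]" = 1)),
             reaction("r_bio", c("B[c]" = -1)))
  m <- metabolic_model(mets, rx, objective = "r_bio")
  sol <- fba(m, pfba = TRUE)
  expect_equal(sol$objective_value, 2)
  expect_equal(sol$fluxes[["loop"]], 0)     # futile cycle suppressed
  expect_equal(sum(abs(sol$fluxes)), 2 + 2 + 2)  # |uptake| + paths + biomass
})

test_that("robustness surface plateaus iff the model is enzyme-capped", {
  fx <- linear_fixture(kcat = 100, abundance = 0.01, uptake = 10)
  irr <- to_irreversible(fx$model)
  ec <- expand_ec(irr, fx$kinetics, fx$abundances)
  rs_ec <- robustness_surface(ec, "EX_S", "EX_S", max_a = 5, max_b = 5,
                              steps = 6)
  expect_true(rs_ec$saturated)
  expect_equal(max(rs_ec$growth), 1)        # plateau at vmax = kcat*E
  expect_equal(rs_ec$growth[1, 1], 0)       # zero uptake, zero growth
  rs_base <- robustness_surface(irr, "EX_S", "EX_S", max_a = 5, max_b = 5,
                                steps = 6)
  expect_false(rs_base$saturated)           # supply-limited: keeps climbing
  expect_equal(max(rs_base$growth), 5)
  # monotone non-decreasing along each axis
  expect_true(all(apply(rs_ec$growth, 1, function(x) all(diff(x) >= -1e-9))))
  expect_true(all(apply(rs_base$growth, 2, function(x) all(diff(x) >= -1e-9))))
})

test_that("FVA: single path pins fluxes; parallel paths swing by the window", {
  fx <- linear_fixture(uptake = 10)
  irr <- to_irreversible(fx$model)
  v <- fva(irr, fraction = 1.0)
  expect_true(all(v$fv < 1e-9))             # no degrees of freedom
  # parallel equivalent branches with total flux 1:
  mets <- data.frame(id = c("A[c]", "B[c]"), name = c("A", "B"),
                     compartment = "c", kind = "chemical")
  rx <- list(reaction("EX_A", c("A[c]" = -1), lb = -1, ub = 0, kind = "exchange"),
             reaction("p1", c("A[c]" = -1, "B[c]" = 1)),
             reaction("p2", c("A[c]" = -1, "B[c]" = 1)),
             reaction("r_bio", c("B[c]" = -1)))
  m <- metabolic_model(mets, rx, objective = "r_bio")
  v2 <- fva(to_irreversible(m), fraction = 0.999)
  for (p in c("p1", "p2")) {
    rec <- v2[v2$reaction == p, ]
    expect_equal(rec$min_flux, 0, tolerance = 1e-6)
    expect_equal(rec$max_flux, 1, tolerance = 1e-6)
  }
  # nested windows: fv at fraction 1.0 never exceeds fv at 0.999
  v3 <- fva(to_irreversible(m), fraction = 1.0)
  expect_true(all(v3$fv <= v2$fv + 1e-9))
  # FBA flux lies within [min, max] per reaction
  sol <- fba(to_irreversible(m))
  for (k in seq_len(nrow(v2)))
    expect_true(sol$fluxes[[v2$reaction[k]]] >= v2$min_flux[k] - 1e-7 &&
                sol$fluxes[[v2$reaction[k]]] <= v2$max_flux[k] + 1e-7)
})

test_that("flux-variability reduction follows its defining arithmetic", {
  fb <- data.frame(reaction = c("a", "b", "c"), min_flux = 0,
                   max_flux = c(2, 4, 0), fv = c(2, 4, 0))
  fe <- data.frame(reaction = c("a", "b", "c"), min_flux = 0,
                   max_flux = c(2, 2, 0), fv = c(2, 2, 0))
  pm <- stats::setNames(c("a", "b", "c"), c("a", "b", "c"))
  red <- fv_reduction(fb, fe, pm)
  expect_equal(red$per_reaction$reduction, c(0, 50, 0))  # zero-base -> 0
  expect_equal(red$model_reduction, mean(c(0, 50, 0)))
  expect_equal(red$total_fv_reduction, (1 - 4 / 6) * 100)
  expect_equal(red$n_reduced, 1)
  expect_equal(red$n_reduced_75, 0)
  # a model against itself reduces nothing
  self <- fv_reduction(fb, fb, pm)
  expect_true(all(self$per_reaction$reduction == 0))
})

test_that("enzyme constraints shrink the feasible flux space (FVA nesting)", {
  for (s in c(3, 8, 15)) {
    toy <- make_toy(toy_spec(n_linear_steps = 4, isozyme_reactions = 1,
                             seed = s))
    irr <- to_irreversible(toy$model)
    ec <- toy_ecmodel(toy)
    fb <- fva(irr, fraction = 0.999)
    fe <- fva(ec, fraction = 0.999)
    red <- fv_reduction(fb, fe, ec$parent_map)
    expect_lte(sum(red$per_reaction$fv_ec), sum(red$per_reaction$fv_base) + 1e-9)
    expect_true(all(red$per_reaction$reduction <= 100 + 1e-9))
  }
})

test_that("gene knockouts: neutral, lethal, and isozyme compensation", {
  mets <- data.frame(id = c("S[e]", "M[c]"), name = c("S", "M"),
                     compartment = c("e", "c"), kind = "chemical")
  rx <- list(reaction("EX_S", c("S[e]" = -1), lb = -10, ub = 0, kind = "exchange"),
             reaction("r1", c("S[e]" = -1, "M[c]" = 1), gpr = parse_gpr("ga or gb")),
             reaction("r_bio", c("M[c]" = -1)))
  m <- metabolic_model(mets, rx, genes = c("ga", "gb", "gz"),
                       objective = "r_bio", protein_map = c(ga = "Pa", gb = "Pb"))
  kt <- as_kcat_table(rbind(
    data.frame(protein = "Pa", reaction = "r1", kcat_per_h = 100, sa = NA,
               mw_da = 5e4, source = "s"),
    data.frame(protein = "Pb", reaction = "r1", kcat_per_h = 100, sa = NA,
               mw_da = 5e4, source = "s")))
  ab <- as_abundance_table(rbind(
    data.frame(protein = "Pa", abundance = 0.01, unit = "mmol_gDW",
               taxon = "t", rank = "species"),
    data.frame(protein = "Pb", abundance = 0.01, unit = "mmol_gDW",
               taxon = "t", rank = "species")))
  ec <- expand_ec(to_irreversible(m), kt, ab)
  ko <- single_gene_knockout(ec)
  expect_equal(ko$grRatio[ko$gene == "gz"], 1)      # gene in no GPR
  expect_identical(ko$class[ko$gene == "gz"], "neutral")
  # symmetric isozymes, each cap 1, demand 2: losing one halves growth
  expect_equal(ko$grRatio[ko$gene == "ga"], 0.5)
  expect_identical(ko$class[ko$gene == "ga"], "limiting")
  # sole-path gene is lethal
  m2 <- m; m2$reactions[["r1"]]$gpr <- parse_gpr("ga")
  ec2 <- expand_ec(to_irreversible(m2), kt, ab)
  ko2 <- single_gene_knockout(ec2, genes = "ga")
  expect_equal(ko2$grRatio, 0)
  expect_identical(ko2$class, "lethal")
  # knocking out never helps
  expect_true(all(ko$grRatio <= 1 + 1e-6))
  expect_error(single_gene_knockout(ec, genes = "gq"), "absent")
})

test_that("differential usage up-regulates exactly the active pathway", {
  cs <- make_carbon_switch_toy()
  ec <- expand_ec(to_irreversible(cs$model), cs$kinetics, cs$abundances)
  du <- differential_usage(ec, cs$conditions$glucose,
                           list(cs$conditions$xylose))
  xyl <- du[du$protein == "PXYL", ]
  glc <- du[du$protein == "PGLC", ]
  expect_true(xyl$induced_from_zero)
  expect_gt(xyl$usage, 0)
  expect_equal(glc$usage, 0)
  expect_false(glc$induced_from_zero)
  # identical conditions: all fold changes 1
  du2 <- differential_usage(ec, cs$conditions$glucose,
                            list(cs$conditions$glucose))
  active <- du2[du2$usage_ref > 1e-8, ]
  expect_equal(active$fold_change, rep(1, nrow(active)))
  # carbon-mole parity: 6 C-mmol/gDW/h under both conditions
  for (cond in cs$conditions) {
    sol <- fba(ec, condition = cond, pfba = TRUE)
    cmol <- 6 * sol$fluxes[["EX_glc_rev"]] + 5 * sol$fluxes[["EX_xyl_rev"]]
    expect_equal(unname(cmol), 6)
    expect_equal(sol$objective_value, cs$analytic$growth)
  }
})
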