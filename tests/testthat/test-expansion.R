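test_that("isozyme reaction becomes arm + one branch per isozyme", {
  mets <- data.frame(id = c("A[c]", "B[c]"), name = c("A", "B"),
                     compartment = "c", kind = "chemical")
  rx <- list(reaction("EX_A", c("A[c]" = -1), lb = -10, ub = 0, kind = "exchange"),
             reaction("r1", c("A[c]" = -1, "B[c]" = 1), gpr = parse_gpr("g1 or g2")),
             reaction("r_bio", c("B[c]" = -1)))
  m <- metabolic_model(mets, rx, genes = c("g1", "g2"), objective = "r_bio",
                       protein_map = c(g1 = "E1", g2 = "E2"))
  kt <- as_kcat_table(rbind(
    data.frame(protein = "E1", reaction = "r1", kcat_per_h = 100, sa = NA,
               mw_da = 5e4, source = "s"),
    data.frame(protein = "E2", reaction = "r1", kcat_per_h = 200, sa = NA,
               mw_da = 5e4, source = "s")))
  ec <- expand_ec(to_irreversible(m), kt, NULL)
  # A -> pm ; pm + E1/kcat1 -> B ; pm + E2/kcat2 -> B
  expect_true("arm_r1" %in% names(ec$reactions))
  expect_setequal(grep("^r1No", names(ec$reactions), value = TRUE),
                  c("r1No1", "r1No2"))
  expect_equal(ec$reactions[["arm_r1"]]$stoich,
               c("A[c]" = -1, "pmet_r1" = 1))
  expect_equal(ec$reactions[["r1No1"]]$stoich,
               c("pmet_r1" = -1, "B[c]" = 1, "prot_E1" = -1 / 100))
  expect_equal(ec$reactions[["r1No2"]]$stoich,
               c("pmet_r1" = -1, "B[c]" = 1, "prot_E2" = -1 / 200))
  expect_setequal(unname(ec$usage_reactions), c("usage_E1", "usage_E2"))
  # arm metabolite produced by exactly one arm reaction, consumed by branches
  S <- stoich_matrix(ec)
  arm_row <- S["pmet_r1", ]
  expect_identical(names(arm_row[arm_row > 0]), "arm_r1")
  expect_setequal(names(arm_row[arm_row < 0]), c("r1No1", "r1No2"))
})

test_that("expansion bookkeeping: column and metabolite count arithmetic", {
  for (s in c(3, 7, 19)) {
    toy <- make_toy(toy_spec(n_linear_steps = 5, isozyme_reactions = 2,
                             complex_reactions = 1, seed = s))
    irr <- to_irreversible(toy$model)
    ec <- toy_ecmodel(toy)
    n_arm <- length(ec$arm_metabolites)
    extra_branches <- sum(ec$build_report$n_branches[
      ec$build_report$status == "expanded" & ec$build_report$n_branches >= 2] - 1)
    n_usage <- length(ec$usage_reactions)
    expect_length(ec$reactions,
                  length(irr$reactions) + n_arm + extra_branches + n_usage)
    expect_equal(nrow(ec$metabolites),
                 nrow(irr$metabolites) + n_usage + n_arm)
    # every enzyme metabolite produced by exactly one usage reaction
    S <- stoich_matrix(ec)
    for (emet in ec$metabolites$id[ec$metabolites$kind == "enzyme"]) {
      prod <- names(which(S[emet, ] > 0))
      expect_length(prod, 1)
      expect_match(prod, "^usage_")
    }
  }
})

test_that("enzyme capacity bounds the flux: vmax = kcat * E", {
  fx <- linear_fixture(kcat = 100, abundance = 0.01, uptake = 10)
  ec <- expand_ec(to_irreversible(fx$model), fx$kinetics, fx$abundances)
  expect_equal(fba(ec)$objective_value, 1)   # 100 * 0.01
  # halving the binding bound halves the optimum
  ec2 <- set_usage_bound(ec, "P1", 0.005)
  expect_equal(fba(ec2)$objective_value, 0.5)
  # zero bound blocks the reaction entirely
  ec0 <- set_usage_bound(ec, "P1", 0)
  expect_equal(fba(ec0)$objective_value, 0)
  # infinite bound restores the base optimum
  ecI <- set_usage_bound(ec, "P1", Inf)
  expect_equal(fba(ecI)$objective_value, 10)
  expect_error(set_usage_bound(ec, "P1", -1), ">= 0")
  expect_error(set_usage_bound(ec, "nope", 1), "unknown protein")
})

test_that("every flux solution respects v <= kcat * usage by construction", {
  for (s in 1:10) {
    toy <- make_toy(toy_spec(n_linear_steps = 4, isozyme_reactions = 1,
                             seed = s))
    ec <- toy_ecmodel(toy)
    sol <- fba(ec)
    expect_lt(max(abs(stoich_matrix(ec) %*% sol$fluxes)), 1e-6)
    for (p in names(ec$protein_entries)) {
      e <- ec$protein_entries[[p]]
      usage <- sol$fluxes[[ec$usage_reactions[[p]]]]
      for (rid in names(e$kcat_by_reaction))
        expect_lte(sol$fluxes[[rid]],
                   e$kcat_by_reaction[[rid]] * usage + 1e-7)
    }
  }
})

test_that("reactions without GPR or kinetics are left unconstrained", {
  fx <- linear_fixture()
  empty_kt <- as_kcat_table(data.frame(protein = "Px", reaction = "rx",
                                       kcat_per_h = 1, sa = NA, mw_da = 5e4,
                                       source = "s"))
  expect_warning(
    expand_ec(to_irreversible(fx$model), empty_kt, fx$abundances),
    "unconstrained")
  ec <- suppressWarnings(
    expand_ec(to_irreversible(fx$model), empty_kt, fx$abundances))
  expect_equal(fba(ec)$objective_value, fx$uptake)
  expect_identical(
    ec$build_report$status[ec$build_report$reaction == "r1"], "no_kinetics")
})

test_that("reversible enzymes share one usage bound across _fwd/_rev", {
  fx <- linear_fixture(kcat = 100, abundance = 0.01)
  m <- fx$model
  m$reactions[["r1"]]$lb <- -5
  ec <- expand_ec(to_irreversible(m), fx$kinetics, fx$abundances)
  expect_length(ec$usage_reactions, 1)
  S <- stoich_matrix(ec)
  consumers <- names(which(S["prot_P1", ] < 0))
  expect_setequal(consumers, c("r1_fwd", "r1_rev"))
  expect_equal(fba(ec)$objective_value, 1)  # rev direction carries nothing
})

test_that("protein pool couples usages stoichiometrically", {
  fx <- linear_fixture(kcat = 100, abundance = 0.01, uptake = 10)
  ec <- expand_ec(to_irreversible(fx$model), fx$kinetics, fx$abundances)
  # generous pool: slack, optimum unchanged
  big <- add_protein_pool(ec, ptot = 1000, sigma = 1)
  expect_equal(fba(big)$objective_value, fba(ec)$objective_value)
  # empty pool: no enzyme, no growth
  none <- add_protein_pool(ec, ptot = 0)
  expect_equal(fba(none)$objective_value, 0)
  # binding pool on a single enzyme: usage = pool/(MW/1000), v = kcat * usage
  # pool 0.1 g/gDW, MW 5e4 -> usage 0.002 mmol/gDW -> v = 0.2 (< kcat*E = 1)
  tight <- add_protein_pool(relax_usage_bounds(ec), ptot = 0.2, sigma = 0.5)
  expect_equal(fba(tight)$objective_value, 100 * (0.2 * 0.5) / (5e4 / 1000))
})

test_that("binding two-enzyme pool matches the analytic pool-simplex LP", {
  # two sequential steps, enzymes with kcats k1, k2 and MWs w1, w2 share a
  # pool P: max v s.t. v/k1*w1 + v/k2*w2 <= P  =>  v = P / (w1/k1 + w2/k2)
  mets <- data.frame(id = c("A[c]", "B[c]", "C[c]"),
                     name = c("A", "B", "C"), compartment = "c",
                     kind = "chemical")
  rx <- list(reaction("EX_A", c("A[c]" = -1), lb = -100, ub = 0, kind = "exchange"),
             reaction("r1", c("A[c]" = -1, "B[c]" = 1), gpr = parse_gpr("g1")),
             reaction("r2", c("B[c]" = -1, "C[c]" = 1), gpr = parse_gpr("g2")),
             reaction("r_bio", c("C[c]" = -1)))
  m <- metabolic_model(mets, rx, genes = c("g1", "g2"), objective = "r_bio",
                       protein_map = c(g1 = "P1", g2 = "P2"))
  kt <- as_kcat_table(rbind(
    data.frame(protein = "P1", reaction = "r1", kcat_per_h = 50, sa = NA,
               mw_da = 3e4, source = "s"),
    data.frame(protein = "P2", reaction = "r2", kcat_per_h = 200, sa = NA,
               mw_da = 8e4, source = "s")))
  ec <- expand_ec(to_irreversible(m), kt, NULL)
  ec <- add_protein_pool(ec, ptot = 0.4, sigma = 0.5)
  expected <- (0.4 * 0.5) / (30 / 50 + 80 / 200)
  expect_equal(fba(ec)$objective_value, expected, tolerance = 1e-9)
})
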