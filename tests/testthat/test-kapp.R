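test_that("condition grid is a deterministic glc-major Cartesian product", {
  g <- condition_grid(steps = 20)
  expect_length(g, 400)
  g2 <- condition_grid(glc_range = c(1, 2), o2_range = c(3, 4), steps = 2)
  ups <- t(vapply(g2, function(cs) cs$uptake, c(EX_glc = 0, EX_o2 = 0)))
  expect_equal(unname(ups),
               rbind(c(1, 3), c(1, 4), c(2, 3), c(2, 4)))
  expect_identical(g2, condition_grid(glc_range = c(1, 2), o2_range = c(3, 4),
                                      steps = 2))
  expect_error(condition_grid(steps = 0), "steps")
  expect_error(condition_grid(glc_range = c(5, 1)), "increasing")
})

test_that("kapp arithmetic: kapp = v / E with fixed abundances", {
  fx <- linear_fixture(kcat = 100, abundance = 0.01, uptake = 10)
  ec <- expand_ec(to_irreversible(fx$model), fx$kinetics, fx$abundances)
  # one condition, uptake 0.5 below the capacity: v = 0.5, kapp = 50
  est <- estimate_kapp(ec, list(condition_spec(uptake = c(EX_S = 0.5),
                                               label = "c1")))
  expect_equal(est$estimates$kapp_max[est$estimates$protein == "P1"], 50)
})

test_that("a saturating condition recovers the true kcat (constrained sweep)", {
  fx <- linear_fixture(kcat = 100, abundance = 0.01, uptake = 50)
  ec <- expand_ec(to_irreversible(fx$model), fx$kinetics, fx$abundances)
  conds <- lapply(seq(0.25, 5, by = 0.25), function(u)
    condition_spec(uptake = c(EX_S = u), label = paste0("u", u)))
  est <- estimate_kapp(ec, conds, flux_source = "constrained")
  k <- est$estimates$kapp_max[est$estimates$protein == "P1"]
  expect_equal(k, 100, tolerance = 1e-6)   # cap kcat*E = 1 is crossed by grid
  # constrained sweep never exceeds the database kcat
  expect_true(all(est$estimates$kapp_max <= est$estimates$kcat_db + 1e-9))
  expect_true(all(est$estimates$eta_max <= 1 + 1e-9))
})

test_that("all-zero-flux reactions yield no kapp estimate", {
  cs <- make_carbon_switch_toy()
  ec <- expand_ec(to_irreversible(cs$model), cs$kinetics, cs$abundances)
  est <- estimate_kapp(ec, list(cs$conditions$glucose))
  expect_false("PXYL" %in% est$estimates$protein)   # xylose path is idle
  expect_true("PGLC" %in% est$estimates$protein)
})

test_that("kcat correction replaces coefficients and cannot lower the optimum", {
  spec <- toy_spec(n_linear_steps = 4, isozyme_reactions = 1,
                   complex_reactions = 0, reversible_fraction = 0,
                   multifunctional = FALSE, seed = 5,
                   kcat_range = c(2000, 4000), uptake_bound = 5)
  toy <- make_overconstrained(spec, shrink = 1e-4)
  ec <- toy_ecmodel(toy)
  before <- fba(ec)$objective_value
  conds <- lapply(seq(0.25, 5, by = 0.25), function(u)
    condition_spec(uptake = c(EX_S = u), label = paste0("u", u)))
  est <- estimate_kapp(ec, conds, flux_source = "relaxed")
  ec2 <- correct_kcats(ec, est, policy = "replace_if_larger")
  after <- fba(ec2)$objective_value
  expect_gte(after, before - 1e-9)
  ch <- ec2$kcat_changes
  hit <- ch[ch$protein == toy$shrunk$protein, ]
  expect_gt(hit$kcat_new, hit$kcat_old)
  expect_equal(ec2$reactions[[hit$reaction]]$stoich[[paste0("prot_", hit$protein)]],
               -1 / hit$kcat_new)
  # idempotence: a second pass with the same estimates changes nothing
  ec3 <- correct_kcats(ec2, est, policy = "replace_if_larger")
  expect_equal(ec3$kcat_changes$ratio, rep(1, nrow(ec3$kcat_changes)))
  expect_equal(fba(ec3)$objective_value, after)
  # smaller kapp under replace_if_larger leaves the coefficient alone
  expect_true(all(ec2$kcat_changes$kcat_new >= ec2$kcat_changes$kcat_old))
})

test_that("over-constraint detection flags, correction un-flags, growth restored", {
  spec <- toy_spec(n_linear_steps = 4, isozyme_reactions = 1,
                   complex_reactions = 0, reversible_fraction = 0,
                   multifunctional = FALSE, seed = 5,
                   kcat_range = c(2000, 4000), uptake_bound = 5)
  toy <- make_overconstrained(spec, shrink = 1e-9)
  ec <- toy_ecmodel(toy)
  conds <- lapply(seq(0.25, 5, by = 0.25), function(u)
    condition_spec(uptake = c(EX_S = u), label = paste0("u", u)))
  oc <- detect_overconstraint(ec, conds)
  expect_true(oc$flagged)
  expect_lt(oc$max_growth, 1e-6)
  expect_true(toy$shrunk$protein %in% oc$binding$protein)
  est <- estimate_kapp(ec, conds, flux_source = "relaxed")
  ec2 <- correct_kcats(ec, est)
  expect_false(detect_overconstraint(ec2, conds)$flagged)
  expect_equal(fba(ec2)$objective_value, toy$analytic$optimum_constrained,
               tolerance = 1e-8)
  # an unconstrained model is never flagged
  expect_false(detect_overconstraint(relax_usage_bounds(ec), conds)$flagged)
})

test_that("growth is monotone over the uptake grid (relaxed or not)", {
  toy <- make_toy(toy_spec(seed = 13))
  ec <- toy_ecmodel(toy)
  vals <- vapply(seq(0.5, 5, by = 0.5), function(u)
    fba(ec, condition = condition_spec(uptake = c(EX_S = u)))$objective_value, 0)
  expect_true(all(diff(vals) >= -1e-9))
})
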