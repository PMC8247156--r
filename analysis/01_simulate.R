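#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study fixtures.
#
# Three fixture sets, all with closed-form answers:
#   * a linear-chain toy with isozyme, complex and shared (multifunctional)
#     enzymes -- the workhorse for every downstream stage;
#   * its over-constrained variant (one kcat shrunk 1e9-fold), which stage 3
#     must detect and repair;
#   * the carbon-source-switch toy (6-C vs 5-C entry pathways at matched
#     carbon-mole supply) for the differential-usage stage.
#
# Everything is written under results/fixtures/ as the JSON model dialect and
# TSV evidence tables, exactly the files a real run would start from.

library(ecgem)

out <- "results/fixtures"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
tsv <- function(d, name) utils::write.table(
  d, file.path(out, paste0(name, ".tsv")), sep = "\t", quote = FALSE,
  row.names = FALSE)

spec <- toy_spec(n_linear_steps = 6, isozyme_reactions = 2,
                 complex_reactions = 1, reversible_fraction = 0.25,
                 uptake_bound = 10, seed = 20240101)
toy <- make_toy(spec)
write_model(toy$model, file.path(out, "toy_model.json"))
write_model(toy$model, file.path(out, "toy_model.xml"), format = "sbml")
tsv(toy$kinetics, "toy_kcat")
tsv(toy$abundances, "toy_abundance")
jsonlite::write_json(toy$analytic, file.path(out, "toy_analytic.json"),
                     auto_unbox = TRUE, digits = NA)

# The over-constrained fixture uses its own spec: generous database kcats
# (capacities above the uptake bound) and an uptake bound inside the kapp
# sweep range, so the correction can restore the analytic optimum exactly.
oc_spec <- toy_spec(n_linear_steps = 4, isozyme_reactions = 1,
                    complex_reactions = 0, reversible_fraction = 0,
                    multifunctional = FALSE, kcat_range = c(2000, 4000),
                    uptake_bound = 5, seed = 20240102)
oc <- make_overconstrained(oc_spec, shrink = 1e-9)
write_model(oc$model, file.path(out, "toy_oc_model.json"))
tsv(oc$kinetics, "toy_kcat_overconstrained")
tsv(oc$abundances, "toy_abundance_overconstrained")
jsonlite::write_json(c(oc$analytic, oc$shrunk),
                     file.path(out, "toy_overconstrained_analytic.json"),
                     auto_unbox = TRUE, digits = NA)

cs <- make_carbon_switch_toy()
write_model(cs$model, file.path(out, "carbon_switch_model.json"))
tsv(cs$kinetics, "carbon_switch_kcat")
tsv(cs$abundances, "carbon_switch_abundance")

cat("Fixture summary\n")
cat("  chain toy:", length(toy$model$reactions), "reactions,",
    nrow(toy$kinetics), "kcat records,", nrow(toy$abundances),
    "abundance records\n")
cat("  analytic optimum (unconstrained):",
    toy$analytic$optimum_unconstrained, "mmol/gDW/h\n")
cat("  analytic optimum (enzyme-constrained):",
    signif(toy$analytic$optimum_constrained, 6), "mmol/gDW/h\n")
cat("  over-constrained variant: kcat of", oc$shrunk$protein, "on",
    oc$shrunk$reaction, "shrunk by", oc$shrunk$factor, "\n")
cat("  carbon-switch toy: glucose 1.0 vs xylose 1.2 mmol/gDW/h (both 6 C-mmol)\n")
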