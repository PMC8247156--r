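#' Run the full enzyme-constraint workflow
#'
#' Wires the stages together in dependency order: read (or receive) a base
#' model, convert to irreversible form, expand with kinetic and abundance
#' evidence, optionally correct kcats by a kapp sweep, then run the
#' requested analyses (FBA, robustness, FVA + variability reduction,
#' knockouts, differential usage, network metrics). Every artifact is
#' written under \code{out_dir} as TSV/JSON together with a manifest of
#' parameters and input digests; inputs on disk are never modified.
#'
#' @param config list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{model}{path to a model file, or an \code{ec_model}.}
#'     \item{kinetics}{path to a kcat TSV, or a \code{kcat_table}.}
#'     \item{abundances}{path to an abundance TSV, or an
#'       \code{abundance_table} (optional).}
#'     \item{out_dir}{output directory (created).}
#'     \item{correct_kcats}{logical: run the kapp sweep + correction.}
#'     \item{grid}{list(glc_rxn, o2_rxn, glc_range, o2_range, steps) for the
#'       sweep and robustness stages.}
#'     \item{fva_fraction}{FVA fraction of optimum (default 0.999).}
#'     \item{condition}{\code{ec_condition} applied to the analyses
#'       (optional).}
#'     \item{stages}{character subset of c("fba", "robustness", "fva",
#'       "knockout", "network"); default all.}
#'   }
#' @return invisible list with the stage results and the output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read config files")
    config <- yaml::read_yaml(config)
  }
  cfg <- config
  out_dir <- cfg$out_dir %||% stop("config needs an out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- cfg$stages %||% c("fba", "robustness", "fva", "knockout", "network")
  tsv <- function(d, name) {
    p <- file.path(out_dir, paste0(name, ".tsv"))
    utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }

  model <- if (is.character(cfg$model)) read_model(cfg$model) else cfg$model
  kinetics <- if (is.character(cfg$kinetics)) read_kcat_table(cfg$kinetics)
              else cfg$kinetics
  abundances <- if (is.null(cfg$abundances)) NULL
                else if (is.character(cfg$abundances))
                  read_abundance_table(cfg$abundances)
                else cfg$abundances

  message("stage irreversible: ", length(model$reactions), " reactions in")
  irr <- to_irreversible(model)
  message("  -> ", length(irr$reactions), " irreversible reactions")

  ec <- expand_ec(irr, kinetics, abundances)
  message("stage expand: ", length(ec$reactions), " reactions, ",
          nrow(ec$metabolites), " metabolites, ",
          length(ec$usage_reactions), " enzyme usages, ",
          length(ec$arm_metabolites), " arm metabolites")
  tsv(ec$build_report, "build_report")
  tsv(ec$proteins, "proteins")

  grid_cfg <- cfg$grid %||% list()
  grid <- do.call(condition_grid, grid_cfg)
  results <- list(ec = ec)

  if (isTRUE(cfg$correct_kcats)) {
    oc <- detect_overconstraint(ec, grid)
    message("stage kapp: over-constraint flagged = ", oc$flagged)
    kapp <- estimate_kapp(ec, grid, flux_source = "relaxed")
    tsv(kapp$estimates, "kapp_estimates")
    ec <- correct_kcats(ec, kapp, policy = "replace_if_larger")
    tsv(ec$kcat_changes, "kcat_changes")
    results$overconstraint <- oc
    results$kapp <- kapp
    results$ec <- ec
  }

  cond <- cfg$condition
  if ("fba" %in% stages) {
    sol <- fba(ec, condition = cond)
    message("stage fba: status ", sol$status, ", objective ",
            format(sol$objective_value, digits = 6))
    tsv(data.frame(reaction = names(sol$fluxes), flux = unname(sol$fluxes)),
        "fba_fluxes")
    results$fba <- sol
  }
  if ("robustness" %in% stages) {
    g <- grid_cfg
    rs <- robustness_surface(ec, g$glc_rxn %||% "EX_glc", g$o2_rxn %||% "EX_o2",
                             max(g$glc_range %||% c(0, 5)),
                             max(g$o2_range %||% c(0, 5)),
                             steps = 11, condition = cond)
    message("stage robustness: saturated = ", rs$saturated)
    utils::write.table(rs$growth, file.path(out_dir, "robustness.tsv"),
                       sep = "\t", quote = FALSE)
    results$robustness <- rs
  }
  if ("fva" %in% stages) {
    frac <- cfg$fva_fraction %||% 0.999
    fva_base <- fva(irr, fraction = frac, condition = cond)
    fva_ec <- fva(ec, fraction = frac, condition = cond)
    red <- fv_reduction(fva_base, fva_ec, ec$parent_map)
    message("stage fva: mean reduction ",
            format(red$model_reduction, digits = 4), "% over ",
            red$n_compared, " reactions")
    tsv(fva_base, "fva_base"); tsv(fva_ec, "fva_ec")
    tsv(red$per_reaction, "fv_reduction")
    results$fva <- list(base = fva_base, ec = fva_ec, reduction = red)
  }
  if ("knockout" %in% stages) {
    ko <- single_gene_knockout(ec, condition = cond)
    message("stage knockout: ", sum(ko$class == "lethal"), " lethal / ",
            nrow(ko), " genes")
    tsv(ko, "knockouts")
    results$knockout <- ko
  }
  if ("network" %in% stages) {
    g_all <- build_graph(ec)
    g_cur <- build_graph(ec, exclude_currency = CURRENCY_METABOLITES)
    met_all <- network_metrics(g_all)
    met_cur <- if (igraph::vcount(g_cur) > 0) network_metrics(g_cur) else NULL
    message("stage network: ", met_all$n_nodes, " nodes, clustering ",
            format(met_all$clustering, digits = 4))
    mdf <- data.frame(metric = names(met_all),
                      with_currency = unlist(met_all),
                      without_currency = if (is.null(met_cur)) NA
                                         else unlist(met_cur))
    tsv(mdf, "network_metrics")
    results$network <- list(with_currency = met_all,
                            without_currency = met_cur)
  }

  manifest <- list(
    package = as.character(utils::packageVersion("ecgem")),
    stages = stages,
    parameters = cfg[setdiff(names(cfg), c("model", "kinetics", "abundances",
                                           "condition"))],
    inputs = lapply(cfg[c("model", "kinetics", "abundances")], function(x)
      if (is.character(x)) unname(tools::md5sum(x)) else "in-memory"),
    counts = list(base_reactions = length(model$reactions),
                  irreversible_reactions = length(irr$reactions),
                  ec_reactions = length(ec$reactions),
                  ec_metabolites = nrow(ec$metabolites),
                  enzymes = length(ec$usage_reactions),
                  arm_metabolites = length(ec$arm_metabolites)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}
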