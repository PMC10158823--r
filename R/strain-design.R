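# Knockout scenario definition, evaluation by FBA + flux sampling, and
# ranking of candidate 2-KIV overproducer designs.

#' Define a knockout design scenario
#'
#' @param name Scenario name (used for deterministic tie-breaking when
#'   ranking).
#' @param deletions Character vector of gene ids to delete.
#' @param target_reactions Reactions whose sampled flux the report
#'   summarises (e.g. the acetolactate synthase, dihydroxy-acid
#'   dehydratase, 2-KIV exchange and acetate exchange reactions).
#' @param augmentations Character vector of cytosolic metabolite ids for
#'   which a secretion route should be added (via
#'   [add_secretion_pathway()]) before evaluation, skipped when the route
#'   already exists.
#' @return A `design_scenario` object.
#' @export
design_scenario <- function(name, deletions = character(),
                            target_reactions = character(),
                            augmentations = character()) {
  structure(
    list(name = name, deletions = unique(as.character(deletions)),
         target_reactions = as.character(target_reactions),
         augmentations = as.character(augmentations)),
    class = "design_scenario"
  )
}

#' @export
print.design_scenario <- function(x, ...) {
  cat(sprintf("<design_scenario> %s: delete {%s}; targets {%s}\n",
              x$name, paste(x$deletions, collapse = ", "),
              paste(x$target_reactions, collapse = ", ")))
  invisible(x)
}

#' Default knockout map: canonical gene names to model gene ids
#'
#' Gene names used in the literature (aceF, mdh, ppc, ldhA, pflB, adhE)
#' rarely match the locus tags genome-scale models use; this editable map
#' translates them.  The identity default suits models (like the bundled
#' toy network) that label reactions with gene names directly.
#'
#' @return A named character vector, canonical name -> model gene id.
#' @export
default_gene_map <- function() {
  c(aceF = "aceF", mdh = "mdh", ppc = "ppc",
    ldhA = "ldhA", pflB = "pflB", adhE = "adhE")
}

#' The studied knockout scenarios plus a wild-type baseline
#'
#' Builds the three candidate 2-KIV overproducer genotypes examined in
#' silico -- the aceF-mdh and ppc-mdh double mutants and the
#' ldhA-pflB-adhE triple mutant -- plus the wild-type baseline, each
#' carrying the same target-reaction list for sampling summaries.
#'
#' @param model A [metabolic_model()]; every mapped gene must exist in
#'   it.
#' @param gene_map Named character vector translating canonical gene
#'   names to the model's gene ids (see [default_gene_map()]).
#' @param target_reactions Reactions to summarise per scenario.
#' @return A list of four [design_scenario()] objects (WT first).
#' @export
build_default_scenarios <- function(model, gene_map = default_gene_map(),
                                    target_reactions =
                                      c("ACLS", "DHAD", "EX_kiv", "EX_ac")) {
  if (!length(gene_map)) stop("empty gene map", call. = FALSE)
  sets <- list(
    WT = character(),
    `aceF-mdh` = c("aceF", "mdh"),
    `ppc-mdh` = c("ppc", "mdh"),
    `ldhA-pflB-adhE` = c("ldhA", "pflB", "adhE")
  )
  purrr::imap(sets, function(genes, nm) {
    unmapped <- setdiff(genes, names(gene_map))
    if (length(unmapped)) {
      stop("scenario '", nm, "': gene name(s) not in map: ",
           paste(unmapped, collapse = ", "), call. = FALSE)
    }
    ids <- unname(gene_map[genes])
    absent <- setdiff(ids, model$genes)
    if (length(absent)) {
      stop("scenario '", nm, "': mapped gene(s) absent from model: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    design_scenario(nm, deletions = ids,
                    target_reactions = target_reactions)
  })
}

#' Evaluate one design scenario by FBA and flux sampling
#'
#' Applies the scenario's augmentations and gene knockouts, solves FBA
#' for both the biomass objective and the product exchange, samples the
#' knocked-out flux polytope with [sample_achr()], and summarises the
#' target reactions.  A scenario whose deletions abolish growth simply
#' reports a biomass optimum of 0.
#'
#' @param model A [metabolic_model()] (pre-augmentation).
#' @param scenario A [design_scenario()].
#' @param product_reaction Exchange reaction treated as the product
#'   objective (default `"EX_kiv"`).
#' @param n_points,seed,thinning Sampling parameters (see
#'   [sample_achr()]).
#' @param n_bins Histogram bins for the summaries.
#' @return A one-row tibble: `scenario`, `n_deletions`,
#'   `disabled_reactions` (list), `biomass_opt`, `product_opt`, `summary`
#'   (list column holding the [summarize_reaction_flux()] table).
#' @export
evaluate_scenario <- function(model, scenario,
                              product_reaction = "EX_kiv",
                              n_points = 1000, seed, thinning = 10,
                              n_bins = 50) {
  stopifnot(inherits(scenario, "design_scenario"))
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  for (met in scenario$augmentations) {
    model <- tryCatch(add_secretion_pathway(model, met),
                      error = function(e) {
                        if (grepl("secretion route exists",
                                  conditionMessage(e))) model else stop(e)
                      })
  }
  missing_t <- setdiff(scenario$target_reactions, model$reactions$id)
  if (length(missing_t)) {
    stop("scenario '", scenario$name, "': target reaction(s) not in ",
         "model: ", paste(missing_t, collapse = ", "), call. = FALSE)
  }
  ko <- apply_gene_knockouts(model, scenario$deletions)
  biomass <- solve_fba(ko$model)
  product <- solve_fba(ko$model, objective = product_reaction)
  samples <- sample_achr(ko$model, n_points = n_points, seed = seed,
                         thinning = thinning)
  summ <- summarize_reaction_flux(samples, scenario$target_reactions,
                                  n_bins = n_bins)
  scenario_name <- scenario$name
  n_del <- length(scenario$deletions)
  tibble::tibble(
    scenario = scenario_name,
    n_deletions = n_del,
    disabled_reactions = list(ko$knockouts$disabled_reactions),
    biomass_opt = if (biomass$status == "optimal")
      biomass$objective_value else NA_real_,
    product_opt = if (product$status == "optimal")
      product$objective_value else NA_real_,
    summary = list(summ)
  )
}

#' Evaluate a list of scenarios into a design report
#'
#' @param model A [metabolic_model()].
#' @param scenarios List of [design_scenario()] objects.
#' @param ... Passed to [evaluate_scenario()] (all scenarios share the
#'   same seed and sampling parameters, keeping rows comparable).
#' @return A `design_report` tibble, one row per scenario.
#' @export
evaluate_scenarios <- function(model, scenarios, ...) {
  out <- purrr::map_dfr(scenarios, evaluate_scenario, model = model, ...)
  class(out) <- c("design_report", class(out))
  out
}

#' Rank design scenarios by a sampled flux statistic
#'
#' Orders scenarios by `statistic(target_reaction) - penalty_weight *
#' statistic(penalty_reaction)`, descending; ties break deterministically
#' by scenario name.  The default (mean 2-KIV exchange flux, no penalty)
#' reproduces a pure frequency-plot style comparison; a positive penalty
#' weight on e.g. the acetate exchange credits designs with lower
#' byproduct secretion.
#'
#' @param report A `design_report` from [evaluate_scenarios()].
#' @param statistic One of `"mean"`, `"median"`, `"p95"`.
#' @param target Target reaction id (must be among the summarised
#'   targets).
#' @param penalty_reaction Optional byproduct reaction id.
#' @param penalty_weight Non-negative weight on the penalty term
#'   (default 0).
#' @return A tibble ordered by decreasing score: `rank`, `scenario`,
#'   `score`, `target_value`, `penalty_value`, `biomass_opt`,
#'   `product_opt`.
#' @export
rank_scenarios <- function(report, statistic = c("mean", "median", "p95"),
                           target = "EX_kiv", penalty_reaction = NULL,
                           penalty_weight = 0) {
  statistic <- match.arg(statistic)
  stopifnot(penalty_weight >= 0)
  pull_stat <- function(summ, rid) {
    row <- summ[summ$reaction == rid, ]
    if (nrow(row) != 1L) {
      stop("statistic for reaction '", rid,
           "' unavailable in the report", call. = FALSE)
    }
    row[[statistic]]
  }
  scored <- report |>
    dplyr::mutate(
      target_value = purrr::map_dbl(summary, pull_stat, rid = target),
      penalty_value = if (is.null(penalty_reaction)) 0 else
        purrr::map_dbl(summary, pull_stat, rid = penalty_reaction),
      score = target_value - penalty_weight * penalty_value
    ) |>
    dplyr::arrange(dplyr::desc(score), scenario) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select(rank, scenario, score, target_value, penalty_value,
                  biomass_opt, product_opt)
  tibble::as_tibble(scored)
}
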