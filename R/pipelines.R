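# Orchestration of the two workflows -- strain design and kinetics --
# from a structured YAML config, with logging sufficient to reproduce
# every output (seed, model hash, parameters).

#' Default configuration for the strain-design pipeline
#'
#' @return A nested list of documented defaults: toy model, the standard
#'   knockout scenarios, 35000 sample points, thinning 100, single
#'   carbon-source medium with uptake 10 mmol/gDCW/h.
#' @export
default_design_config <- function() {
  list(
    model = "toy",
    gene_map = as.list(default_gene_map()),
    target_reactions = c("ACLS", "DHAD", "EX_kiv", "EX_ac"),
    product_reaction = "EX_kiv",
    sampling = list(n_points = 35000, seed = 1, thinning = 100),
    medium = list(carbon_exchange = "EX_glc", uptake = 10),
    ranking = list(statistic = "mean", target = "EX_kiv",
                   penalty_reaction = NULL, penalty_weight = 0),
    output_dir = "design_output"
  )
}

#' Default configuration for the kinetics pipeline
#'
#' @return A list of documented defaults (alpha 0.05, automatic
#'   exponential-phase windows of at least 4 points).
#' @export
default_kinetics_config <- function() {
  list(
    input = NULL,
    alpha = 0.05,
    min_points = 4,
    od_factor = 0.452,
    output_dir = "kinetics_output"
  )
}

read_pipeline_config <- function(config, defaults) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  utils::modifyList(defaults, config)
}

#' Constrain the in-silico growth medium
#'
#' Applies the single-carbon-source convention: the named carbon exchange
#' gets uptake capacity `-uptake` as its lower bound and every other
#' exchange reaction's lower bound is raised to 0 (secretion stays open).
#'
#' @param model A [metabolic_model()].
#' @param carbon_exchange Exchange reaction id of the carbon source.
#' @param uptake Maximum uptake rate, mmol/gDCW/h (default 10).
#' @return The constrained model.
#' @export
apply_medium <- function(model, carbon_exchange, uptake = 10) {
  if (!carbon_exchange %in% model$reactions$id) {
    stop("carbon exchange '", carbon_exchange, "' not in model",
         call. = FALSE)
  }
  ex <- model$reactions$is_exchange
  model$reactions$lb[ex] <- pmax(model$reactions$lb[ex], 0)
  idx <- match(carbon_exchange, model$reactions$id)
  model$reactions$lb[idx] <- -abs(uptake)
  model
}

pipeline_log <- function(path, lines) {
  stamp <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  cat(paste0("[", stamp, "] ", lines, "\n"), file = path, append = TRUE,
      sep = "")
}

load_pipeline_model <- function(spec) {
  if (identical(spec, "toy")) return(make_toy_network())
  if (!file.exists(spec)) stop("model file not found: ", spec, call. = FALSE)
  if (grepl("\\.xml$", spec, ignore.case = TRUE)) read_sbml_fbc(spec)
  else read_native_model(spec)
}

#' Run the strain-design workflow end to end
#'
#' Loads the model, applies the medium constraint, ensures a 2-KIV
#' secretion route exists, builds the default knockout scenarios (or
#' reads them from a YAML file), evaluates each by FBA plus flux
#' sampling, ranks them, and writes `design_report.csv`, `ranking.txt`
#' and `pipeline.log` (seed, model hash and per-stage status) under the
#' configured output directory.  Identical config and seed give
#' byte-identical report CSVs.
#'
#' @param config A nested list or a YAML file path; see
#'   [default_design_config()] for the recognised fields.  A `scenarios`
#'   field may name a YAML file with entries `name`, `deletions`,
#'   `target_reactions`.
#' @return Invisibly, a list with `report`, `ranking` and `paths`.
#' @export
run_design_pipeline <- function(config = default_design_config()) {
  cfg <- read_pipeline_config(config, default_design_config())
  if (!is.null(cfg$scenarios) && is.character(cfg$scenarios) &&
      !file.exists(cfg$scenarios)) {
    stop("scenario file not found: ", cfg$scenarios, call. = FALSE)
  }
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$output_dir, "pipeline.log")
  if (file.exists(log_path)) file.remove(log_path)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      pipeline_log(log_path, sprintf("stage %s failed: %s", name,
                                     conditionMessage(e)))
      stop("design pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }

  model <- stage("load_model", load_pipeline_model(cfg$model))
  pipeline_log(log_path, c(
    sprintf("config hash %s", rlang::hash(cfg)),
    sprintf("model %s: %d reactions, %d metabolites, %d genes (hash %s)",
            model$name, nrow(model$reactions), nrow(model$metabolites),
            length(model$genes), rlang::hash(model)),
    sprintf("sampling seed %d, n_points %d, thinning %d",
            cfg$sampling$seed, cfg$sampling$n_points, cfg$sampling$thinning)
  ))
  model <- stage("medium", apply_medium(model, cfg$medium$carbon_exchange,
                                        cfg$medium$uptake))
  model <- stage("augment", {
    kiv_c <- if (!is.null(cfg$secretion_metabolite)) cfg$secretion_metabolite
             else "kiv_c"
    tryCatch(add_secretion_pathway(model, kiv_c),
             error = function(e) {
               if (grepl("secretion route exists", conditionMessage(e))) {
                 pipeline_log(log_path, "secretion route already present")
                 model
               } else stop(e)
             })
  })
  scenarios <- stage("scenarios", {
    if (is.null(cfg$scenarios)) {
      build_default_scenarios(model,
                              gene_map = unlist(cfg$gene_map),
                              target_reactions = cfg$target_reactions)
    } else {
      raw <- yaml::read_yaml(cfg$scenarios)
      purrr::map(raw, function(s) {
        design_scenario(s$name, deletions = unlist(s$deletions),
                        target_reactions =
                          unlist(s$target_reactions %||NULL%
                                   cfg$target_reactions))
      })
    }
  })
  report <- stage("evaluate", evaluate_scenarios(
    model, scenarios, product_reaction = cfg$product_reaction,
    n_points = cfg$sampling$n_points, seed = cfg$sampling$seed,
    thinning = cfg$sampling$thinning))
  pipeline_log(log_path, sprintf(
    "evaluated %d scenarios (biomass optima: %s)",
    nrow(report), paste(signif(report$biomass_opt, 6), collapse = ", ")))
  ranking <- stage("rank", rank_scenarios(
    report, statistic = cfg$ranking$statistic, target = cfg$ranking$target,
    penalty_reaction = cfg$ranking$penalty_reaction,
    penalty_weight = cfg$ranking$penalty_weight))

  report_flat <- report |>
    dplyr::select(-summary) |>
    dplyr::mutate(disabled_reactions =
                    purrr::map_chr(disabled_reactions, paste,
                                   collapse = ";"))
  stats_flat <- report |>
    dplyr::mutate(s = purrr::map(summary, ~ dplyr::select(.x, -histogram))) |>
    dplyr::select(scenario, s) |>
    tidyr::unnest(s)
  paths <- list(
    report = file.path(cfg$output_dir, "design_report.csv"),
    target_stats = file.path(cfg$output_dir, "target_flux_stats.csv"),
    ranking = file.path(cfg$output_dir, "ranking.txt"),
    log = log_path
  )
  utils::write.csv(report_flat, paths$report, row.names = FALSE)
  utils::write.csv(stats_flat, paths$target_stats, row.names = FALSE)
  writeLines(c(
    sprintf("scenario ranking by %s(%s) - %g * %s(%s)",
            cfg$ranking$statistic, cfg$ranking$target,
            cfg$ranking$penalty_weight, cfg$ranking$statistic,
            if (is.null(cfg$ranking$penalty_reaction)) "none"
            else cfg$ranking$penalty_reaction),
    sprintf("%d. %s (score %.6g)", ranking$rank, ranking$scenario,
            ranking$score)
  ), paths$ranking)
  pipeline_log(log_path, "design pipeline complete")
  invisible(list(report = report, ranking = ranking, paths = paths))
}

`%||NULL%` <- function(a, b) if (is.null(a)) b else a

#' Run the batch-kinetics workflow end to end
#'
#' Reads a tidy culture CSV (`time_h`, `od600` or `dcw_g_l`,
#' `substrate_g_l`, `product_g_l`, `replicate`, `condition`), converts OD
#' to dry cell weight when needed, estimates per-replicate kinetic
#' parameters (growth rate and yields), summarises each condition as
#' mean ± sd, compares conditions' growth rates with Duncan's multiple
#' range test, and writes `kinetic_params.csv`,
#' `condition_summary.csv`, `duncan_letters.txt` and `pipeline.log`.
#'
#' @param config A list or YAML file path; see
#'   [default_kinetics_config()].  `input` (the CSV path) is required.
#' @return Invisibly, a list with `params`, `summary`, `duncan`, `paths`.
#' @export
run_kinetics_pipeline <- function(config) {
  cfg <- read_pipeline_config(config, default_kinetics_config())
  if (is.null(cfg$input)) stop("config lacks 'input' CSV path", call. = FALSE)
  if (!file.exists(cfg$input)) {
    stop("input file not found: ", cfg$input, call. = FALSE)
  }
  raw <- utils::read.csv(cfg$input, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("input CSV is empty: ", cfg$input, call. = FALSE)
  need <- c("time_h", "substrate_g_l", "product_g_l", "replicate",
            "condition")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("input CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"dcw_g_l" %in% names(raw)) {
    if (!"od600" %in% names(raw)) {
      stop("input CSV needs either 'dcw_g_l' or 'od600'", call. = FALSE)
    }
    raw$dcw_g_l <- od_to_dcw(raw$od600, factor = cfg$od_factor)
  }
  for (col in c("time_h", "dcw_g_l", "substrate_g_l", "product_g_l")) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (length(bad)) {
      stop("non-numeric value in column '", col, "' at data row ",
           bad[1], call. = FALSE)
    }
    raw[[col]] <- vals
  }

  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$output_dir, "pipeline.log")
  if (file.exists(log_path)) file.remove(log_path)
  pipeline_log(log_path, c(
    sprintf("input %s (hash %s): %d rows, %d conditions", cfg$input,
            rlang::hash(raw), nrow(raw),
            length(unique(raw$condition))),
    sprintf("alpha %g, min_points %d", cfg$alpha, cfg$min_points)
  ))

  params <- raw |>
    dplyr::group_by(condition, replicate) |>
    dplyr::arrange(time_h, .by_group = TRUE) |>
    dplyr::group_modify(~ estimate_kinetics(.x,
                                            min_points = cfg$min_points)) |>
    dplyr::ungroup()
  summary_tbl <- params |>
    dplyr::group_by(condition) |>
    dplyr::summarise(dplyr::across(c(mu_max, yxs, yps, ypx),
                                   list(mean = ~ mean(.x, na.rm = TRUE),
                                        sd = ~ stats::sd(.x, na.rm = TRUE))),
                     n = dplyr::n(), .groups = "drop")
  dmrt <- if (length(unique(params$condition)) >= 2L &&
              all(table(params$condition) >= 2L)) {
    duncan_mrt(params, value = "mu_max", group = "condition",
               alpha = cfg$alpha)
  } else NULL

  paths <- list(
    params = file.path(cfg$output_dir, "kinetic_params.csv"),
    summary = file.path(cfg$output_dir, "condition_summary.csv"),
    letters = file.path(cfg$output_dir, "duncan_letters.txt"),
    log = log_path
  )
  utils::write.csv(params, paths$params, row.names = FALSE)
  utils::write.csv(summary_tbl, paths$summary, row.names = FALSE)
  if (!is.null(dmrt)) {
    g <- dmrt$groups
    writeLines(c(
      sprintf("Duncan's multiple range test on mu_max (alpha = %g)",
              cfg$alpha),
      "groups sharing a letter are not significantly different",
      sprintf("%-20s %10s %8s  %s", "condition", "mean mu_max", "n",
              "letters"),
      sprintf("%-20s %10.5f %8d  %s", g$group, g$mean, g$n, g$letters)
    ), paths$letters)
  } else {
    writeLines("Duncan comparison skipped: need >=2 conditions with >=2 replicates each",
               paths$letters)
  }
  pipeline_log(log_path, "kinetics pipeline complete")
  invisible(list(params = params, summary = summary_tbl, duncan = dmrt,
                 paths = paths))
}
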