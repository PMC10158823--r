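#' Flux balance analysis
#'
#' Solves the steady-state flux problem: choose the flux vector `v`
#' maximising (or minimising) the objective reaction's flux subject to
#' `S v = 0` and the box bounds `lb <= v <= ub`, where `S` is the
#' stoichiometric matrix.  Exchange fluxes follow the usual sign
#' convention (negative = uptake).  Alternate optima are not resolved:
#' the solver returns whichever optimal vertex it lands on; use
#' [run_fva()] for uniqueness questions.
#'
#' @param model A [metabolic_model()].
#' @param objective Reaction id to optimise; defaults to the model's
#'   objective reaction.
#' @param sense `"max"` (default) or `"min"`.
#' @param extra_bounds Optional bounds overriding the model's, in the form
#'   accepted by [set_bounds()].
#' @param zero_tol Fluxes smaller than this in magnitude are reported as
#'   exact zeros (default 1e-9).
#'
#' @return An object of class `fba_solution`: a list with `fluxes` (tibble
#'   of `reaction`, `flux`), `objective_value`, `objective_id`, `sense`
#'   and `status` (`"optimal"`, `"infeasible"` or `"unbounded"`; fluxes
#'   are `NULL` unless optimal).
#' @examples
#' toy <- make_toy_network()
#' sol <- solve_fba(toy)                      # biomass objective
#' sol$objective_value                        # 20 at glucose uptake 10
#' solve_fba(toy, objective = "EX_kiv")$objective_value  # 10
#' @export
solve_fba <- function(model, objective = NULL, sense = c("max", "min"),
                      extra_bounds = NULL, zero_tol = 1e-9) {
  sense <- match.arg(sense)
  if (is.null(objective)) objective <- model$objective_id
  if (!objective %in% model$reactions$id) {
    stop("objective reaction '", objective, "' not in model", call. = FALSE)
  }
  if (!is.null(extra_bounds)) model <- set_bounds(model, extra_bounds)
  S <- stoich_matrix(model)
  n <- ncol(S)
  cvec <- numeric(n)
  cvec[match(objective, model$reactions$id)] <- if (sense == "max") 1 else -1
  res <- lp_solve_bounded(S, rep(0, nrow(S)), cvec,
                          model$reactions$lb, model$reactions$ub)
  if (res$status != "optimal") {
    return(structure(list(fluxes = NULL, objective_value = NA_real_,
                          objective_id = objective, sense = sense,
                          status = res$status),
                     class = "fba_solution"))
  }
  v <- res$x
  v[abs(v) < zero_tol] <- 0
  obj <- v[match(objective, model$reactions$id)]
  structure(
    list(fluxes = tibble::tibble(reaction = model$reactions$id, flux = v),
         objective_value = obj, objective_id = objective, sense = sense,
         status = "optimal"),
    class = "fba_solution"
  )
}

#' @export
print.fba_solution <- function(x, ...) {
  cat(sprintf("<fba_solution> %s %s: status %s, objective %s\n",
              x$sense, x$objective_id, x$status,
              format(x$objective_value)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a flux solution into a reaction/flux tibble
#'
#' @param x An `fba_solution`.
#' @param ... Unused.
#' @method tidy fba_solution
#' @export
tidy.fba_solution <- function(x, ...) {
  if (is.null(x$fluxes)) {
    return(tibble::tibble(reaction = character(), flux = double()))
  }
  x$fluxes
}

#' One-row summary of a flux solution
#'
#' @param x An `fba_solution`.
#' @param ... Unused.
#' @method glance fba_solution
#' @export
glance.fba_solution <- function(x, ...) {
  tibble::tibble(status = x$status, objective_id = x$objective_id,
                 sense = x$sense, objective_value = x$objective_value,
                 n_reactions = if (is.null(x$fluxes)) 0L else nrow(x$fluxes))
}

#' Apply gene knockouts to a model through its GPR rules
#'
#' Deletes the given genes and disables (bounds set to `[0, 0]`) exactly
#' those reactions whose gene-protein-reaction rule evaluates to `FALSE`
#' under the deletion.  Reactions are never removed, so the stoichiometric
#' matrix keeps its shape across knockout scenarios.  The input model is
#' left unmodified.
#'
#' @param model A [metabolic_model()].
#' @param genes Character vector of gene ids to delete; every id must
#'   exist in `model$genes` (unknown ids raise an error rather than
#'   silently doing nothing).
#' @return A list with `model` (the knocked-out model) and `knockouts`, a
#'   `knockout_set` holding `genes` and the derived `disabled_reactions`.
#' @examples
#' toy <- make_toy_network()
#' ko <- apply_gene_knockouts(toy, "aceF")
#' ko$knockouts$disabled_reactions        # "PDH"
#' solve_fba(ko$model)$objective_value    # 0: no acetyl-CoA for biomass
#' @export
apply_gene_knockouts <- function(model, genes) {
  genes <- unique(as.character(genes))
  unknown <- setdiff(genes, model$genes)
  if (length(unknown)) {
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  disabled <- model$reactions$id[
    !purrr::map_lgl(model$reactions$gene_rule, evaluate_gene_rule,
                    deleted = genes)
  ]
  idx <- match(disabled, model$reactions$id)
  model$reactions$lb[idx] <- 0
  model$reactions$ub[idx] <- 0
  list(
    model = model,
    knockouts = structure(list(genes = genes,
                               disabled_reactions = disabled),
                          class = "knockout_set")
  )
}

#' @export
print.knockout_set <- function(x, ...) {
  cat(sprintf("<knockout_set> genes: %s; disabled reactions: %s\n",
              paste(x$genes, collapse = ", "),
              if (length(x$disabled_reactions))
                paste(x$disabled_reactions, collapse = ", ") else "none"))
  invisible(x)
}

#' Add a secretion route for a cytosolic metabolite
#'
#' Gives a model the ability to secrete a metabolite by appending one
#' transport reaction per compartment hop along the chain plus a terminal
#' irreversible exchange, creating compartment-specific metabolite copies
#' as needed.  On a three-compartment model (cytosol, periplasm,
#' extracellular) this adds exactly three reactions; pre-existing
#' reactions are untouched.  Transport steps are outward-only (lower bound
#' 0) since only secretion is being granted.
#'
#' @param model A [metabolic_model()].
#' @param metabolite_id Id of the metabolite in the innermost compartment
#'   of the chain (e.g. `"kiv_c"`).
#' @param compartment_chain Ordered compartments from the metabolite's own
#'   compartment to the extracellular one; defaults to the model's chain.
#' @return The augmented model.  Transport reactions are named
#'   `"<MET>t<from><to>"` and the exchange `"EX_<met>_<outer>"`.
#' @export
add_secretion_pathway <- function(model, metabolite_id,
                                  compartment_chain = model$compartments) {
  if (length(compartment_chain) < 2L) {
    stop("compartment chain must have at least two compartments",
         call. = FALSE)
  }
  mets <- model$metabolites
  if (!metabolite_id %in% mets$id) {
    stop("metabolite '", metabolite_id, "' not in model", call. = FALSE)
  }
  inner <- compartment_chain[1]
  if (mets$compartment[match(metabolite_id, mets$id)] != inner) {
    stop("metabolite '", metabolite_id,
         "' is not in the innermost compartment '", inner, "'",
         call. = FALSE)
  }
  base <- sub(paste0("_", inner, "$"), "", metabolite_id)
  outer <- compartment_chain[length(compartment_chain)]
  outer_id <- paste0(base, "_", outer)
  # refuse if a secretion route (an exchange touching the outer copy of
  # this metabolite) already exists
  has_route <- purrr::map2_lgl(
    model$reactions$stoichiometry, model$reactions$is_exchange,
    function(st, ex) isTRUE(ex) && outer_id %in% names(st)
  )
  if (any(has_route)) stop("secretion route exists", call. = FALSE)

  met_name <- mets$name[match(metabolite_id, mets$id)]
  new_mets <- list()
  new_rxns <- list()
  comp_id <- function(comp) if (comp == inner) metabolite_id
                            else paste0(base, "_", comp)
  for (k in seq_len(length(compartment_chain) - 1L)) {
    from <- compartment_chain[k]
    to <- compartment_chain[k + 1L]
    to_id <- comp_id(to)
    if (!to_id %in% c(mets$id, purrr::map_chr(new_mets, "id"))) {
      new_mets[[length(new_mets) + 1L]] <-
        tibble::tibble(id = to_id, name = met_name, compartment = to)
    }
    st <- stats::setNames(c(-1, 1), c(comp_id(from), to_id))
    new_rxns[[length(new_rxns) + 1L]] <- tibble::tibble(
      id = paste0(toupper(base), "t", from, to),
      name = paste0(met_name, " transport ", from, " -> ", to),
      stoichiometry = list(st), lb = 0, ub = 1000,
      gene_rule = "", is_exchange = FALSE
    )
  }
  new_rxns[[length(new_rxns) + 1L]] <- tibble::tibble(
    id = paste0("EX_", base, "_", outer),
    name = paste0(met_name, " exchange"),
    stoichiometry = list(stats::setNames(-1, outer_id)),
    lb = 0, ub = 1000, gene_rule = "", is_exchange = TRUE
  )
  if (length(new_mets)) {
    model$metabolites <- dplyr::bind_rows(mets, new_mets)
  }
  model$reactions <- dplyr::bind_rows(model$reactions, new_rxns)
  model
}

#' Flux variability analysis
#'
#' Computes, for each reaction, the minimum and maximum flux attainable
#' while the objective reaction is held at at least `objective_fraction`
#' of its optimum (for a maximisation objective).  This costs two LP
#' solves per reaction.
#'
#' @param model A [metabolic_model()].
#' @param objective_fraction Number in `[0, 1]`; fraction of the FBA
#'   optimum imposed as a lower bound on the objective reaction.
#' @param reactions Reactions to scan (default: all).
#' @param zero_tol Magnitude below which fluxes are reported as 0.
#' @return A tibble with columns `reaction`, `min_flux`, `max_flux`.
#' @export
run_fva <- function(model, objective_fraction = 0, reactions = NULL,
                    zero_tol = 1e-9) {
  stopifnot(objective_fraction >= 0, objective_fraction <= 1)
  base_sol <- solve_fba(model)
  if (base_sol$status != "optimal") {
    stop("FBA on the input model is ", base_sol$status, call. = FALSE)
  }
  opt <- base_sol$objective_value
  obj_idx <- match(model$objective_id, model$reactions$id)
  target <- objective_fraction * opt
  # tiny backoff keeps the constraint numerically feasible at fraction 1
  model$reactions$lb[obj_idx] <- max(model$reactions$lb[obj_idx],
                                     target - 1e-9 * max(1, abs(target)))
  if (is.null(reactions)) reactions <- model$reactions$id
  unknown <- setdiff(reactions, model$reactions$id)
  if (length(unknown)) {
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  rows <- purrr::map(reactions, function(rid) {
    lo <- solve_fba(model, objective = rid, sense = "min",
                    zero_tol = zero_tol)
    hi <- solve_fba(model, objective = rid, sense = "max",
                    zero_tol = zero_tol)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA subproblem for '", rid, "' is ",
           if (lo$status != "optimal") lo$status else hi$status,
           call. = FALSE)
    }
    tibble::tibble(reaction = rid,
                   min_flux = min(lo$objective_value, hi$objective_value),
                   max_flux = max(lo$objective_value, hi$objective_value))
  })
  dplyr::bind_rows(rows)
}

#' Write a flux solution or FVA table to CSV
#'
#' @param x An `fba_solution` or a tibble such as [run_fva()]'s result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_flux_csv <- function(x, path) {
  df <- if (inherits(x, "fba_solution")) tidy(x) else as.data.frame(x)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
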