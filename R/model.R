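#' Construct a constraint-based metabolic model
#'
#' A `metabolic_model` bundles the stoichiometric network used by flux
#' balance analysis: an ordered metabolite table, an ordered reaction table
#' (with flux bounds and gene-protein-reaction rules), the gene set implied
#' by those rules, the objective reaction, and the ordered compartment
#' chain from innermost to extracellular.  Column order of the implied
#' stoichiometric matrix is reaction order; row order is metabolite order.
#'
#' @param metabolites A data frame with columns `id`, `name`,
#'   `compartment`, one row per metabolite, in matrix row order.
#' @param reactions A data frame with columns `id`, `name`,
#'   `stoichiometry` (a list column of named numeric vectors, names are
#'   metabolite ids, values signed coefficients), `lb`, `ub` (flux bounds
#'   in mmol/gDCW/h; the biomass reaction in 1/h), `gene_rule` (boolean
#'   expression over gene ids with AND/OR/parentheses, `""` meaning
#'   unconditionally present) and `is_exchange`.
#' @param objective_id Reaction id of the objective (typically biomass).
#' @param compartments Character vector of compartment tags ordered from
#'   innermost (cytosol) to extracellular.
#' @param name Optional model name.
#'
#' @return An object of class `metabolic_model`.
#' @seealso [validate_model()], [stoich_matrix()], [solve_fba()]
#' @export
metabolic_model <- function(metabolites, reactions, objective_id,
                            compartments = c("c", "e"), name = "model") {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  stopifnot(
    all(c("id", "compartment") %in% names(metabolites)),
    all(c("id", "stoichiometry", "lb", "ub") %in% names(reactions))
  )
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"name" %in% names(reactions)) reactions$name <- reactions$id
  if (!"gene_rule" %in% names(reactions)) reactions$gene_rule <- ""
  if (!"is_exchange" %in% names(reactions)) {
    reactions$is_exchange <- purrr::map_lgl(reactions$stoichiometry,
                                            ~ length(.x) == 1L)
  }
  reactions$gene_rule[is.na(reactions$gene_rule)] <- ""
  genes <- sort(unique(unlist(purrr::map(reactions$gene_rule, gpr_genes))))
  model <- structure(
    list(
      name = name,
      metabolites = metabolites[, c("id", "name", "compartment")],
      reactions = reactions[, c("id", "name", "stoichiometry", "lb", "ub",
                                "gene_rule", "is_exchange")],
      genes = genes,
      objective_id = objective_id,
      compartments = compartments
    ),
    class = "metabolic_model"
  )
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf(
    "<metabolic_model> %s: %d reactions, %d metabolites, %d genes\n",
    x$name, nrow(x$reactions), nrow(x$metabolites), length(x$genes)
  ))
  cat(sprintf("  objective: %s; compartments: %s\n",
              x$objective_id, paste(x$compartments, collapse = " > ")))
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' Builds the dense metabolites-by-reactions matrix S whose column order is
#' the model's reaction order and row order its metabolite order, so that
#' steady state reads `S %*% v = 0`.
#'
#' @param model A [metabolic_model()].
#' @return A numeric matrix with dimnames (metabolite ids, reaction ids).
#' @export
stoich_matrix <- function(model) {
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  S <- matrix(0, nrow = length(met_ids), ncol = length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (j in seq_along(rxn_ids)) {
    st <- model$reactions$stoichiometry[[j]]
    if (length(st)) S[names(st), j] <- unname(st)
  }
  S
}

#' Validate a metabolic model
#'
#' Checks the structural invariants of a [metabolic_model()] and returns
#' findings instead of raising conditions, so a model can be audited in one
#' pass.  Checked: non-empty network; unique non-empty metabolite and
#' reaction ids; compartments of metabolites listed in the compartment
#' chain; every stoichiometry entry resolving to a metabolite; ordered
#' bounds (lb <= ub); non-empty stoichiometry for non-exchange reactions;
#' a resolvable objective reaction; gene rules that parse; metabolites
#' referenced by no reaction (dangling) are reported too.
#'
#' @param model A [metabolic_model()].
#' @return A tibble with columns `check` and `message`, zero rows when all
#'   invariants hold.  Idempotent and side-effect free.
#' @export
validate_model <- function(model) {
  f <- list()
  add <- function(check, message) {
    f[[length(f) + 1L]] <<- tibble::tibble(check = check, message = message)
  }
  mets <- model$metabolites
  rxns <- model$reactions
  if (nrow(rxns) == 0L) add("empty_network", "model has no reactions")
  if (nrow(mets) == 0L) add("empty_network", "model has no metabolites")
  dup <- unique(mets$id[duplicated(mets$id)])
  for (d in dup) add("duplicate_metabolite", sprintf("duplicate metabolite id '%s'", d))
  dup <- unique(rxns$id[duplicated(rxns$id)])
  for (d in dup) add("duplicate_reaction", sprintf("duplicate reaction id '%s'", d))
  if (any(!nzchar(mets$id))) add("empty_id", "metabolite with empty id")
  if (any(!nzchar(rxns$id))) add("empty_id", "reaction with empty id")
  bad <- mets$id[!mets$compartment %in% model$compartments]
  for (b in bad) {
    add("unknown_compartment",
        sprintf("metabolite '%s' has compartment outside the chain", b))
  }
  for (j in seq_len(nrow(rxns))) {
    st <- rxns$stoichiometry[[j]]
    missing <- setdiff(names(st), mets$id)
    for (m in missing) {
      add("unknown_metabolite",
          sprintf("reaction '%s' references unknown metabolite '%s'",
                  rxns$id[j], m))
    }
    if (length(st) == 0L && !isTRUE(rxns$is_exchange[j])) {
      add("empty_stoichiometry",
          sprintf("non-exchange reaction '%s' has empty stoichiometry",
                  rxns$id[j]))
    }
    if (rxns$lb[j] > rxns$ub[j]) {
      add("bound_order",
          sprintf("reaction '%s' has lb %g > ub %g",
                  rxns$id[j], rxns$lb[j], rxns$ub[j]))
    }
    ok <- tryCatch({ gpr_genes(rxns$gene_rule[j]); TRUE },
                   error = function(e) FALSE)
    if (!ok) {
      add("bad_gene_rule",
          sprintf("reaction '%s' has unparsable gene rule", rxns$id[j]))
    }
  }
  if (!model$objective_id %in% rxns$id) {
    add("missing_objective",
        sprintf("objective reaction '%s' absent from model", model$objective_id))
  }
  used <- unique(unlist(purrr::map(rxns$stoichiometry, names)))
  for (m in setdiff(mets$id, used)) {
    add("dangling_metabolite",
        sprintf("metabolite '%s' participates in no reaction", m))
  }
  if (length(f)) dplyr::bind_rows(f) else {
    tibble::tibble(check = character(), message = character())
  }
}

#' Flux bounds of a model as a tibble
#'
#' @param model A [metabolic_model()].
#' @return A tibble with columns `reaction`, `lb`, `ub`.
#' @export
reaction_bounds <- function(model) {
  tibble::tibble(reaction = model$reactions$id,
                 lb = model$reactions$lb, ub = model$reactions$ub)
}

#' Set flux bounds on named reactions
#'
#' @param model A [metabolic_model()].
#' @param bounds A named list or data frame: either a named list of
#'   `c(lb, ub)` pairs keyed by reaction id, or a data frame with columns
#'   `reaction`, `lb`, `ub`.
#' @return The modified model (the input is left untouched).
#' @export
set_bounds <- function(model, bounds) {
  if (is.data.frame(bounds)) {
    ids <- bounds$reaction
    lb <- bounds$lb
    ub <- bounds$ub
  } else {
    ids <- names(bounds)
    lb <- purrr::map_dbl(bounds, 1)
    ub <- purrr::map_dbl(bounds, 2)
  }
  unknown <- setdiff(ids, model$reactions$id)
  if (length(unknown)) {
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(ids, model$reactions$id)
  model$reactions$lb[idx] <- lb
  model$reactions$ub[idx] <- ub
  model
}
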