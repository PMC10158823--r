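# Synthetic inputs: an analytically solvable toy central-carbon network,
# batch growth curves with known generative parameters, and the published
# batch-endpoint records used for yield arithmetic.

#' Analytically solvable toy central-carbon network
#'
#' Builds a 15-reaction, single-compartment (+ extracellular) model that
#' mirrors the topology relevant to 2-ketoisovalerate (2-KIV)
#' overproduction in central carbon metabolism: glycolysis lumped to
#' pyruvate, the pyruvate dehydrogenase / TCA branch, the branched-chain
#' keto acid branch (acetolactate synthase -> ketol-acid reductoisomerase
#' -> dihydroxy-acid dehydratase -> 2-KIV export), an acetate overflow
#' drain from acetyl-CoA, a transhydrogenase coupling NADH and NADPH, a
#' respiration lump oxidising NADH to ATP, a biomass drain and an ATP
#' maintenance reaction.  Cofactors (NAD(H), NADP(H), ATP/ADP) are
#' explicitly balanced so the NADPH demand of the reductoisomerase is a
#' real constraint, and key reactions carry gene rules so knockouts can be
#' simulated (PDH: aceF, ACLS: alsS, KARA: ilvC, DHAD: ilvD, TCA: gltA).
#'
#' The optima are known in closed form: with a glucose uptake cap `u`,
#' each glucose yields two pyruvate, biomass drains one pyruvate
#' equivalent per unit (half directly, half via acetyl-CoA) and 2-KIV
#' condenses two pyruvate, so max biomass = `2u` and max 2-KIV export =
#' `u`, both scaling linearly in `u`.
#'
#' @param glucose_uptake Uptake cap in mmol/gDCW/h on the glucose
#'   exchange (default 10; the exchange lower bound is `-glucose_uptake`).
#' @param include_kiv_branch If `FALSE`, the acetolactate synthase step is
#'   disabled (bounds `[0, 0]`), making the 2-KIV export optimum 0.  The
#'   reaction set is unchanged.
#' @param include_kiv_export If `FALSE`, the 2-KIV transport and exchange
#'   reactions are omitted (13 reactions), e.g. to exercise
#'   [add_secretion_pathway()].
#' @param gene_labels Named character vector overriding the default gene
#'   labels per reaction id.
#' @return A [metabolic_model()] that passes [validate_model()] cleanly.
#' @examples
#' toy <- make_toy_network()
#' nrow(toy$reactions)                       # 15
#' solve_fba(toy)$objective_value            # 20
#' solve_fba(toy, "EX_kiv")$objective_value  # 10
#' @export
make_toy_network <- function(glucose_uptake = 10,
                             include_kiv_branch = TRUE,
                             include_kiv_export = TRUE,
                             gene_labels = c(PDH = "aceF", ACLS = "alsS",
                                             KARA = "ilvC", DHAD = "ilvD",
                                             TCA = "gltA")) {
  stopifnot(glucose_uptake >= 0)
  mets <- tibble::tribble(
    ~id,       ~name,                          ~compartment,
    "glc_e",   "D-glucose (extracellular)",    "e",
    "glc_c",   "D-glucose",                    "c",
    "pyr_c",   "pyruvate",                     "c",
    "accoa_c", "acetyl-CoA",                   "c",
    "alac_c",  "2-acetolactate",               "c",
    "dhiv_c",  "2,3-dihydroxy-3-methylbutanoate", "c",
    "kiv_c",   "2-ketoisovalerate",            "c",
    "kiv_e",   "2-ketoisovalerate (extracellular)", "e",
    "nad_c",   "NAD+",                         "c",
    "nadh_c",  "NADH",                         "c",
    "nadp_c",  "NADP+",                        "c",
    "nadph_c", "NADPH",                        "c",
    "atp_c",   "ATP",                          "c",
    "adp_c",   "ADP",                          "c"
  )
  g <- function(id) if (id %in% names(gene_labels)) gene_labels[[id]] else ""
  st <- function(...) {
    x <- c(...)
    stats::setNames(as.numeric(x), names(x))
  }
  rxn <- function(id, name, stoich, lb, ub, gene = g(id), exch = FALSE) {
    tibble::tibble(id = id, name = name, stoichiometry = list(stoich),
                   lb = lb, ub = ub, gene_rule = gene, is_exchange = exch)
  }
  acls_ub <- if (include_kiv_branch) 1000 else 0
  rxns <- list(
    rxn("EX_glc", "glucose exchange", st(glc_e = -1),
        -glucose_uptake, 1000, exch = TRUE),
    rxn("GLCt", "glucose transport", st(glc_e = -1, glc_c = 1), 0, 1000),
    rxn("EMP", "glycolysis (lumped)",
        st(glc_c = -1, adp_c = -2, nad_c = -2,
           pyr_c = 2, atp_c = 2, nadh_c = 2), 0, 1000),
    rxn("PDH", "pyruvate dehydrogenase",
        st(pyr_c = -1, nad_c = -1, accoa_c = 1, nadh_c = 1), 0, 1000),
    rxn("TCA", "TCA cycle (lumped)",
        st(accoa_c = -1, nad_c = -3, adp_c = -1,
           nadh_c = 3, atp_c = 1), 0, 1000),
    rxn("ACLS", "acetolactate synthase",
        st(pyr_c = -2, alac_c = 1), 0, acls_ub),
    rxn("KARA", "ketol-acid reductoisomerase",
        st(alac_c = -1, nadph_c = -1, dhiv_c = 1, nadp_c = 1), 0, 1000),
    rxn("DHAD", "dihydroxy-acid dehydratase",
        st(dhiv_c = -1, kiv_c = 1), 0, 1000),
    rxn("THD", "transhydrogenase",
        st(nadh_c = -1, nadp_c = -1, nad_c = 1, nadph_c = 1), -1000, 1000),
    rxn("NADHOX", "NADH oxidation / respiration (lumped)",
        st(nadh_c = -1, adp_c = -1, nad_c = 1, atp_c = 1), 0, 1000),
    rxn("BIOMASS", "biomass drain",
        st(pyr_c = -0.5, accoa_c = -0.5, atp_c = -1, adp_c = 1), 0, 1000),
    rxn("ATPM", "ATP maintenance", st(atp_c = -1, adp_c = 1), 0, 1000),
    rxn("EX_ac", "acetate overflow (lumped secretion)",
        st(accoa_c = -1), 0, 1000, exch = TRUE)
  )
  if (include_kiv_export) {
    rxns <- append(rxns, list(
      rxn("KIVt", "2-KIV transport", st(kiv_c = -1, kiv_e = 1), 0, 1000),
      rxn("EX_kiv", "2-KIV exchange", st(kiv_e = -1), 0, 1000, exch = TRUE)
    ), after = 8L)
  } else {
    mets <- mets[mets$id != "kiv_e", ]
  }
  metabolic_model(mets, dplyr::bind_rows(rxns), objective_id = "BIOMASS",
                  compartments = c("c", "e"), name = "toy_kiv")
}

#' Simulate a batch culture with known kinetic parameters
#'
#' Generates biomass/substrate/product time series under the textbook
#' batch model the kinetics estimators assume: exponential growth
#' `X(t) = X0 exp(mu t)` until the substrate is exhausted, then constant
#' biomass; yield-coupled substrate depletion
#' `S(t) = max(0, S0 - (X - X0)/Yxs)`; growth-coupled product formation
#' `P(t) = Yps (S0 - S(t))`.  Measurement error is multiplicative
#' lognormal (concentrations are positive), with `noise_sd` interpreted on
#' the log scale.  With `noise_sd = 0` the curves satisfy the generative
#' equations exactly, so [fit_mu_max()] and [compute_yields()] recover the
#' parameters in closed loop.
#'
#' @param mu Specific growth rate, 1/h.
#' @param yxs Biomass yield on substrate, g DCW per g.
#' @param yps Product yield on substrate, g per g.
#' @param x0 Inoculum biomass, g DCW/L.
#' @param s0 Initial substrate, g/L.
#' @param times Sampling times in hours (strictly increasing).
#' @param noise_sd Log-scale standard deviation of the multiplicative
#'   measurement noise (0 = noiseless).
#' @param n_replicates Number of replicate cultures.
#' @param condition Condition label attached to the curves.
#' @param seed Integer seed; identical seeds give identical curves.
#' @return A `growth_curve` tibble with columns `time_h`, `dcw_g_l`,
#'   `substrate_g_l`, `product_g_l`, `replicate`, `condition`.
#' @export
simulate_batch_culture <- function(mu = 0.5, yxs = 0.4, yps = 0.2,
                                   x0 = 0.452, s0 = 10,
                                   times = seq(0, 24, by = 1),
                                   noise_sd = 0.02, n_replicates = 2,
                                   condition = "synthetic", seed) {
  stopifnot(mu > 0, yps >= 0, x0 > 0, s0 > 0, noise_sd >= 0,
            n_replicates >= 1, all(diff(times) > 0))
  if (yxs <= 0) stop("yxs must be positive", call. = FALSE)
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  x_max <- x0 + yxs * s0                 # biomass at substrate exhaustion
  truth <- function(t) {
    x <- pmin(x0 * exp(mu * t), x_max)
    s <- pmax(0, s0 - (x - x0) / yxs)
    p <- yps * (s0 - s)
    list(x = x, s = s, p = p)
  }
  local_seed(seed, {
    purrr::map_dfr(seq_len(n_replicates), function(rep) {
      tr <- truth(times)
      jitter <- function(v) v * exp(stats::rnorm(length(v), 0, noise_sd))
      tibble::tibble(
        time_h = times,
        dcw_g_l = jitter(tr$x),
        substrate_g_l = jitter(tr$s),
        product_g_l = jitter(tr$p),
        replicate = rep,
        condition = condition
      )
    }) |> as_growth_curve()
  })
}

as_growth_curve <- function(df) {
  structure(df, class = c("growth_curve", class(tibble::as_tibble(df))))
}

#' Published batch-endpoint records for the W1262 producer strain
#'
#' Returns the 24 h shake-flask endpoints of the engineered 2-KIV
#' producer on its three carbon sources -- glucose, lactose and whey
#' lactose -- as tidy pipeline input records: total substrate uptake,
#' 2-KIV titer, the whey-culture L-valine titer, and the published yield
#' coefficients for cross-checking.  These feed [compute_yields()]
#' directly (`yps = kiv_g_l / substrate_uptake_g_l`).
#'
#' @return A tibble with one row per carbon source.
#' @examples
#' fx <- make_table2_fixture()
#' fx$kiv_g_l / fx$substrate_uptake_g_l   # 0.214, 0.268, 0.826
#' @export
make_table2_fixture <- function() {
  tibble::tribble(
    ~strain,  ~condition,     ~time_h, ~substrate_uptake_g_l, ~kiv_g_l,
      ~valine_g_l, ~yxs_printed, ~yps_printed, ~ypx_printed,
    "W1262",  "glucose",      24, 10.2, 2.18, NA,   0.04, 0.21, 5.17,
    "W1262",  "lactose",      24,  9.0, 2.41, NA,   0.05, 0.27, 5.15,
    "W1262",  "whey_lactose", 24,  3.9, 3.22, 1.40, 0.08, 0.81, 9.71
  )
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
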