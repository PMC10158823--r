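test_that("toy network FBA reproduces the hand-derived optima", {
  toy <- make_toy_network()
  sol <- solve_fba(toy)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, 20, tolerance = 1e-9)
  expect_equal(solve_fba(toy, objective = "EX_kiv")$objective_value, 10,
               tolerance = 1e-9)
  # solution satisfies steady state and bounds
  v <- sol$fluxes$flux
  S <- stoich_matrix(toy)
  expect_lt(max(abs(S %*% v)), 1e-6 * max(1, max(abs(v))))
  expect_true(all(v >= toy$reactions$lb - 1e-9 &
                  v <= toy$reactions$ub + 1e-9))
  # closed system: zero everywhere
  closed <- solve_fba(toy, extra_bounds = list(EX_glc = c(0, 0),
                                               EX_kiv = c(0, 0),
                                               EX_ac = c(0, 0)))
  expect_equal(closed$objective_value, 0)
})

test_that("FBA statuses cover infeasible and unbounded problems", {
  toy <- make_toy_network()
  # forcing glucose *production* against an irreversible importer
  inf <- solve_fba(toy, extra_bounds = list(EX_glc = c(5, 5)))
  expect_identical(inf$status, "infeasible")
  expect_null(inf$fluxes)
  # a two-reaction open chain with infinite bounds has no finite optimum
  mets <- tibble::tibble(id = "a_c", name = "a", compartment = "c")
  rxns <- tibble::tibble(
    id = c("IN", "OUT"), name = c("IN", "OUT"),
    stoichiometry = list(c(a_c = 1), c(a_c = -1)),
    lb = c(0, 0), ub = c(Inf, Inf),
    gene_rule = "", is_exchange = TRUE
  )
  chain <- metabolic_model(mets, rxns, objective_id = "OUT",
                           compartments = "c")
  expect_identical(solve_fba(chain)$status, "unbounded")
})

test_that("FBA objective matches the independent HiGHS oracle", {
  withr::local_seed(421)
  instances <- replicate(25, random_network(sample(5:20, 1),
                                            sample(2:10, 1)),
                         simplify = FALSE)
  oracle <- lp_oracle_batch(instances)
  for (k in seq_along(instances)) {
    inst <- instances[[k]]
    mine <- kivflux:::lp_solve_bounded(inst$S, rep(0, nrow(inst$S)),
                                       inst$c, inst$lb, inst$ub)
    expect_identical(mine$status, oracle$status[k])
    if (mine$status == "optimal") {
      expect_equal(mine$objective, oracle$objective[k],
                   tolerance = 1e-6,
                   label = sprintf("network %d objective", k))
    }
  }
})

test_that("gene knockouts disable exactly the GPR-false reactions", {
  toy <- make_toy_network()
  ko <- apply_gene_knockouts(toy, "aceF")
  expect_identical(ko$knockouts$disabled_reactions, "PDH")
  idx <- match("PDH", ko$model$reactions$id)
  expect_equal(ko$model$reactions$lb[idx], 0)
  expect_equal(ko$model$reactions$ub[idx], 0)
  # all other reactions untouched; input model unmodified
  expect_identical(as.data.frame(ko$model$reactions[-idx, ]),
                   as.data.frame(toy$reactions[-idx, ]))
  expect_equal(toy$reactions$ub[idx], 1000)
  # growth collapses without acetyl-CoA
  expect_equal(solve_fba(ko$model)$objective_value, 0)
  # empty deletion is the identity
  none <- apply_gene_knockouts(toy, character())
  expect_identical(as.data.frame(none$model$reactions),
                   as.data.frame(toy$reactions))
  expect_length(none$knockouts$disabled_reactions, 0)
  expect_error(apply_gene_knockouts(toy, "not_a_gene"),
               "unknown gene id.*not_a_gene")
})

test_that("knockouts are monotone: more deletions never help", {
  toy <- make_toy_network()
  sets <- list(character(), "aceF", c("aceF", "gltA"),
               c("aceF", "gltA", "ilvC"))
  for (obj in c("BIOMASS", "EX_kiv")) {
    opts <- vapply(sets, function(g) {
      solve_fba(apply_gene_knockouts(toy, g)$model,
                objective = obj)$objective_value
    }, numeric(1))
    expect_true(all(diff(opts) <= 1e-9),
                label = sprintf("%s optima non-increasing", obj))
  }
})

test_that("FVA brackets fluxes at the stated objective fraction", {
  toy <- make_toy_network()
  fva0 <- run_fva(toy, objective_fraction = 0)
  expect_equal(fva0$min_flux[fva0$reaction == "EX_kiv"], 0)
  expect_equal(fva0$max_flux[fva0$reaction == "EX_kiv"], 10,
               tolerance = 1e-9)
  expect_true(all(fva0$min_flux <= fva0$max_flux + 1e-12))
  expect_true(all(fva0$min_flux >= toy$reactions$lb - 1e-9 &
                  fva0$max_flux <= toy$reactions$ub + 1e-9))
  # a fixed reaction collapses to its bound value
  pinned <- set_bounds(toy, list(ATPM = c(3, 3)))
  fvap <- run_fva(pinned, objective_fraction = 0, reactions = "ATPM")
  expect_equal(fvap$min_flux, 3)
  expect_equal(fvap$max_flux, 3)
  # at full optimum the objective range collapses to the optimum
  fva1 <- run_fva(toy, objective_fraction = 1, reactions = "BIOMASS")
  expect_equal(fva1$min_flux, 20, tolerance = 1e-6)
  expect_equal(fva1$max_flux, 20, tolerance = 1e-6)
})

test_that("flux solutions export tidily", {
  toy <- make_toy_network()
  sol <- solve_fba(toy)
  td <- generics::tidy(sol)
  expect_identical(names(td), c("reaction", "flux"))
  expect_identical(nrow(td), nrow(toy$reactions))
  gl <- generics::glance(sol)
  expect_identical(gl$status, "optimal")
  path <- withr::local_tempfile(fileext = ".csv")
  write_flux_csv(sol, path)
  back <- utils::read.csv(path)
  expect_equal(back$flux, td$flux)
})
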