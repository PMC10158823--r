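test_that("native dialect write/read round-trips a model exactly", {
  toy <- make_toy_network()
  path <- withr::local_tempfile(fileext = ".txt")
  write_native_model(toy, path)
  back <- read_native_model(path)
  expect_identical(as.data.frame(back$reactions),
                   as.data.frame(toy$reactions))
  expect_identical(as.data.frame(back$metabolites),
                   as.data.frame(toy$metabolites))
  expect_identical(back$objective_id, toy$objective_id)
  expect_identical(back$compartments, toy$compartments)
  expect_identical(back$genes, toy$genes)
  # second round trip is byte-stable
  path2 <- withr::local_tempfile(fileext = ".txt")
  write_native_model(back, path2)
  expect_identical(readLines(path2), readLines(path))
})

test_that("native dialect applies arrow defaults and flags bad bounds", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "MODEL arrows",
    "COMPARTMENTS c",
    "OBJECTIVE R1",
    "METABOLITE a_c c",
    "METABOLITE b_c c",
    "REACTION R1 : a_c <=> b_c",
    "REACTION R2 : a_c --> b_c"
  ), path)
  m <- read_native_model(path)
  expect_equal(m$reactions$lb, c(-1000, 0))
  expect_equal(m$reactions$ub, c(1000, 1000))

  writeLines(c(
    "MODEL bad", "COMPARTMENTS c", "OBJECTIVE R1",
    "METABOLITE a_c c",
    "REACTION R1 : a_c --> [5, 2]"
  ), path)
  expect_error(read_native_model(path), ":5: .*lower bound 5 exceeds")
  writeLines(c("MODEL bad", "WHAT is this"), path)
  expect_error(read_native_model(path), ":2: unknown directive")
})

test_that("validate_model reports one finding per violation", {
  toy <- make_toy_network()
  expect_identical(nrow(validate_model(toy)), 0L)
  # broken objective
  broke <- toy
  broke$objective_id <- "NOPE"
  f <- validate_model(broke)
  expect_identical(f$check, "missing_objective")
  # unknown metabolite named in the finding
  broke <- toy
  broke$reactions$stoichiometry[[3]] <- c(ghost_c = -1, pyr_c = 2)
  f <- validate_model(broke)
  expect_true(any(grepl("EMP", f$message) & grepl("ghost_c", f$message)))
  # lb > ub
  broke <- toy
  broke$reactions$lb[1] <- 5
  broke$reactions$ub[1] <- -5
  expect_true("bound_order" %in% validate_model(broke)$check)
  # dangling metabolite
  broke <- toy
  broke$metabolites <- dplyr::bind_rows(
    broke$metabolites,
    tibble::tibble(id = "lonely_c", name = "lonely", compartment = "c"))
  expect_true("dangling_metabolite" %in% validate_model(broke)$check)
  # idempotent, side-effect free
  expect_identical(validate_model(toy), validate_model(toy))
})

test_that("SBML-FBC reader recovers network, bounds, GPR and objective", {
  path <- system.file("extdata", "synthetic_mini_fbc.xml",
                      package = "kivflux")
  m <- read_sbml_fbc(path)
  expect_identical(nrow(m$reactions), 6L)
  expect_identical(nrow(m$metabolites), 5L)
  expect_identical(length(m$genes), 3L)
  expect_identical(m$objective_id, "BIOMASS_synth")
  expect_identical(m$compartments, c("c", "p", "e"))
  expect_equal(m$reactions$lb[m$reactions$id == "EX_glc"], -10)
  # explicit INF maps to the conventional 1000
  expect_equal(m$reactions$ub[m$reactions$id == "BIOMASS_synth"], 1000)
  expect_identical(m$reactions$gene_rule[m$reactions$id == "GLY"],
                   "((gapA and alsS) or pykF)")
  expect_false(evaluate_gene_rule(
    m$reactions$gene_rule[m$reactions$id == "GLY"], c("gapA", "pykF")))
  expect_identical(nrow(validate_model(m)), 0L)
  expect_equal(solve_fba(m)$objective_value, 20)
})

test_that("SBML to native round trip preserves counts, bounds and rules", {
  m <- read_sbml_fbc(system.file("extdata", "synthetic_mini_fbc.xml",
                                 package = "kivflux"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_native_model(m, path)
  back <- read_native_model(path)
  expect_identical(nrow(back$reactions), nrow(m$reactions))
  expect_identical(back$reactions$lb, m$reactions$lb)
  expect_identical(back$reactions$ub, m$reactions$ub)
  norm_ws <- function(x) gsub("\\s+", " ", x)
  expect_identical(norm_ws(back$reactions$gene_rule),
                   norm_ws(m$reactions$gene_rule))
})

test_that("SBML reader rejects broken files with descriptive errors", {
  src <- readLines(system.file("extdata", "synthetic_mini_fbc.xml",
                               package = "kivflux"))
  path <- withr::local_tempfile(fileext = ".xml")

  dup <- sub('id="GLCtpp"', 'id="GLCtex"', src)
  writeLines(dup, path)
  expect_error(read_sbml_fbc(path), "duplicate reaction.*GLCtex")

  nolb <- sub(' fbc:lowerFluxBound="lb_0"', "",
              src[grep('id="GLY"', src)])
  tmp <- src
  tmp[grep('id="GLY"', src)] <- nolb
  writeLines(tmp, path)
  expect_error(read_sbml_fbc(path), "GLY.*lowerFluxBound")

  lvl2 <- sub('level="3"', 'level="2"', src)
  writeLines(lvl2, path)
  expect_error(read_sbml_fbc(path), "Level 3")

  other <- sub('fbc:required="false"',
               'fbc:required="false" comp:required="true" xmlns:comp="http://www.sbml.org/sbml/level3/version1/comp/version1"',
               src)
  writeLines(other, path)
  expect_error(read_sbml_fbc(path), "unsupported required SBML package")
})

test_that("secretion augmentation adds one reaction per chain element", {
  # three-compartment model: two transports + exchange = +3 reactions
  m <- read_sbml_fbc(system.file("extdata", "synthetic_mini_fbc.xml",
                                 package = "kivflux"))
  m2 <- add_secretion_pathway(m, "kiv_c", c("c", "p", "e"))
  expect_identical(nrow(m2$reactions), nrow(m$reactions) + 3L)
  expect_setequal(setdiff(m2$reactions$id, m$reactions$id),
                  c("KIVtcp", "KIVtpe", "EX_kiv_e"))
  # pre-existing reactions untouched
  expect_identical(as.data.frame(m2$reactions[seq_len(nrow(m$reactions)), ]),
                   as.data.frame(m$reactions))
  expect_equal(solve_fba(m2, "EX_kiv_e")$objective_value, 10)

  # two-compartment toy without export: +2 reactions
  toy <- make_toy_network(include_kiv_export = FALSE)
  toy2 <- add_secretion_pathway(toy, "kiv_c", c("c", "e"))
  expect_identical(nrow(toy2$reactions), nrow(toy$reactions) + 2L)
  expect_equal(solve_fba(toy2, "EX_kiv_e")$objective_value, 10)

  # errors: absent metabolite; route already present
  expect_error(add_secretion_pathway(toy, "ghost_c"), "not in model")
  expect_error(add_secretion_pathway(make_toy_network(), "kiv_c"),
               "secretion route exists")
  expect_error(add_secretion_pathway(toy2, "kiv_c", c("c", "e")),
               "secretion route exists")
})
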