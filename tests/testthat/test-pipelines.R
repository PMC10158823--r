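test_that("the design pipeline runs end to end on the toy network", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  scen_file <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    list(name = "WT", deletions = list()),
    list(name = "dAceF", deletions = list("aceF"))
  ), scen_file)
  cfg <- list(
    model = "toy", scenarios = scen_file,
    sampling = list(n_points = 400, seed = 1, thinning = 5),
    output_dir = out1
  )
  res <- run_design_pipeline(cfg)
  expect_true(all(file.exists(unlist(res$paths))))
  # the PDH knockout outranks wild type on mean 2-KIV flux
  expect_identical(res$ranking$scenario[1], "dAceF")
  expect_lt(res$ranking$score[2], res$ranking$score[1])
  # log records seed and model hash
  log <- readLines(res$paths$log)
  expect_true(any(grepl("seed 1", log)))
  expect_true(any(grepl("hash", log)))
  # identical config + seed -> byte-identical reports
  cfg$output_dir <- out2
  res2 <- run_design_pipeline(cfg)
  expect_identical(readLines(res2$paths$report),
                   readLines(res$paths$report))
  expect_identical(readLines(res2$paths$target_stats),
                   readLines(res$paths$target_stats))
})

test_that("the design pipeline fails fast on a missing scenario file", {
  cfg <- list(model = "toy", scenarios = "/nonexistent/scenarios.yaml",
              output_dir = withr::local_tempdir())
  expect_error(run_design_pipeline(cfg), "scenario file not found")
})

test_that("the kinetics pipeline estimates, summarises and letters", {
  out <- withr::local_tempdir()
  curves <- dplyr::bind_rows(
    simulate_batch_culture(mu = 0.30, noise_sd = 0.01, n_replicates = 3,
                           condition = "glucose", seed = 5),
    simulate_batch_culture(mu = 0.55, noise_sd = 0.01, n_replicates = 3,
                           condition = "lactose", seed = 6)
  )
  input <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(curves, input, row.names = FALSE)
  res <- run_kinetics_pipeline(list(input = input, output_dir = out))
  expect_true(all(file.exists(unlist(res$paths))))
  expect_identical(nrow(res$params), 6L)
  # recovered rates sit near their generative values
  means <- res$summary$mu_max_mean[match(c("glucose", "lactose"),
                                         res$summary$condition)]
  expect_equal(means, c(0.30, 0.55), tolerance = 0.05)
  # distinct growth rates earn distinct letters
  expect_identical(length(unique(res$duncan$groups$letters)), 2L)

  # OD input is converted through the correlation before fitting
  od_curves <- curves |>
    dplyr::mutate(od600 = dcw_g_l / 0.452) |>
    dplyr::select(-dcw_g_l)
  input_od <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(od_curves, input_od, row.names = FALSE)
  res_od <- run_kinetics_pipeline(list(input = input_od, output_dir = out))
  expect_equal(res_od$params$mu_max, res$params$mu_max, tolerance = 1e-9)
})

test_that("equal true growth rates usually share a letter", {
  out <- withr::local_tempdir()
  curves <- dplyr::bind_rows(lapply(1:3, function(i) {
    simulate_batch_culture(mu = 0.4, noise_sd = 0.02, n_replicates = 3,
                           condition = paste0("cond", i), seed = 40 + i)
  }))
  input <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(curves, input, row.names = FALSE)
  res <- run_kinetics_pipeline(list(input = input, output_dir = out))
  expect_identical(length(unique(res$duncan$groups$letters)), 1L)
})

test_that("malformed kinetics input is rejected with its location", {
  out <- withr::local_tempdir()
  input <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_h,dcw_g_l,substrate_g_l,product_g_l,replicate,condition",
               "0,0.4,10,0,1,glc",
               "2,oops,9,0.1,1,glc"), input)
  expect_error(run_kinetics_pipeline(list(input = input, output_dir = out)),
               "dcw_g_l.*row 2")
  writeLines("time_h,dcw_g_l,substrate_g_l,product_g_l,replicate,condition",
             input)
  expect_error(run_kinetics_pipeline(list(input = input, output_dir = out)),
               "empty")
  expect_error(run_kinetics_pipeline(list(input = "/nope.csv",
                                          output_dir = out)),
               "not found")
})

test_that("autoplot methods return ggplot objects", {
  curves <- simulate_batch_culture(noise_sd = 0.01, n_replicates = 2,
                                   seed = 3)
  expect_s3_class(ggplot2::autoplot(curves), "ggplot")
  toy <- make_toy_network()
  s <- sample_achr(toy, n_points = 100, seed = 1, thinning = 2)
  expect_s3_class(ggplot2::autoplot(summarize_reaction_flux(s, "EX_kiv")),
                  "ggplot")
  d <- data.frame(value = c(rnorm(4), rnorm(4, 5)),
                  group = rep(c("a", "b"), each = 4))
  expect_s3_class(ggplot2::autoplot(duncan_mrt(d)), "ggplot")
})
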