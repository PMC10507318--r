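test_that("experiment presets pin the study coordinates", {
  sp <- experiment_spec("mislabels")
  expect_equal(c(sp$L_train, sp$L_test), c(8, 8))
  expect_equal(sp$mu, 0.2)
  expect_equal(sp$alpha_grid, 0.5)
  sp2 <- experiment_spec("combined")
  expect_equal(c(sp2$L_train, sp2$L_test), c(6, 8))
  expect_equal(c(sp2$mu, sp2$alpha_grid), c(0.2, 0.4))
  sp3 <- experiment_spec("alpha_sweep")
  expect_equal(sp3$N_grid, 500)
  expect_true(all(sp3$alpha_grid > 0 & sp3$alpha_grid < 1))
  expect_error(experiment_spec("length_extrapolation", L_train = 8), "length 5 or 6")
})

test_that("run_experiment fills the grid with the expected row count", {
  sp <- experiment_spec("mislabels", families = "MLP", capacity_levels = 2.70,
                        N_grid = c(60, 120), repetitions = 2, test_size = 200)
  gr <- run_experiment(sp, scale = "full", config = quick_config())
  expect_s3_class(gr, "grid_result")
  expect_equal(nrow(gr$long), 2 * 2) # 2 N values x 2 repetitions
  expect_equal(nrow(gr$summary), 2)
  # aggregation is reproducible from the long form
  expect_equal(summarize_simulations(gr$long), gr$summary)
  gr2 <- run_experiment(sp, scale = "full", config = quick_config())
  expect_identical(gr$long, gr2$long)
})

test_that("interrupted experiments resume from the long-form CSV", {
  sp <- experiment_spec("mislabels", families = "MLP", capacity_levels = 2.70,
                        N_grid = 60, repetitions = 2, test_size = 100)
  dir <- withr::local_tempdir()
  gr <- run_experiment(sp, scale = "full", out_dir = dir, config = quick_config())
  path <- file.path(dir, "mislabels_long.csv")
  expect_true(file.exists(path))
  before <- file.mtime(path)
  gr2 <- run_experiment(sp, scale = "full", out_dir = dir, config = quick_config())
  expect_equal(nrow(gr2$long), nrow(gr$long)) # skipped, not duplicated
  expect_equal(gr2$summary$mean_test, gr$summary$mean_test)
})

test_that("crossover_curve orders by N and rejects missing slices", {
  sp <- experiment_spec("mislabels", families = "MLP", capacity_levels = 2.70,
                        N_grid = c(120, 60), repetitions = 2, test_size = 100)
  gr <- run_experiment(sp, scale = "full", config = quick_config())
  cc <- crossover_curve(gr, "MLP", 2.70)
  expect_equal(cc$N, c(60, 120))
  expect_equal(cc$repetitions, c(2, 2))
  expect_error(crossover_curve(gr, "CNN", 2.70), "no rows")
})

test_that("alpha_sweep_curve aggregates one curve per family and level", {
  sp <- experiment_spec("alpha_sweep", families = "MLP", capacity_levels = 2.70,
                        alpha_grid = c(0.3, 0.6), repetitions = 2, test_size = 100)
  gr <- run_experiment(sp, scale = "full", config = quick_config())
  curve <- alpha_sweep_curve(gr)
  expect_equal(curve$alpha, c(0.3, 0.6))
  expect_true(all(curve$repetitions == 2))
  expect_error(alpha_sweep_curve(gr$long[0, ]), "empty")
})

test_that("plot helpers return ggplot objects", {
  sp <- experiment_spec("mislabels", families = "MLP", capacity_levels = 2.70,
                        N_grid = 60, repetitions = 2, test_size = 100)
  gr <- run_experiment(sp, scale = "full", config = quick_config())
  expect_s3_class(autoplot(gr), "ggplot")
  expect_s3_class(plot_crossover(crossover_curve(gr, "MLP", 2.70)), "ggplot")
  m <- build_model(architecture_spec("MLP", 2.70), seed = 1)
  expect_s3_class(plot_probe_scores(probe_scores(list(m))), "ggplot")
})
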