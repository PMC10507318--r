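test_that("the oracle applies the Watson-Crick predicate position by position", {
  expect_equal(oracle_classifier(tibble::tibble(s = "AGUCAG", s_bar = "CUGACU")), 1L)
  # last pair A-C is not Watson-Crick
  expect_equal(oracle_classifier(tibble::tibble(s = "AGUCAG", s_bar = "CUGACC")), 0L)
  expect_error(oracle_classifier(tibble::tibble(s = "AGUCAG", s_bar = "CUG")),
               "equal lengths")
  # mixed stem lengths take the per-row path
  mixed <- tibble::tibble(s = c("AU", "AGUCAG"), s_bar = c("AU", "CUGACU"))
  expect_equal(oracle_classifier(mixed), c(1L, 1L))
})

test_that("oracle and generator agree on 1e5 generated examples", {
  ds <- generate_dataset(all_strands(6), 1e5, alpha = 0.37, role = "train", seed = 31)
  expect_identical(oracle_classifier(ds), ds$true_label)
})

test_that("accuracy implements the thresholded decision rule", {
  te <- generate_dataset(all_strands(5), 400, role = "test", seed = 2)
  # a perfect scorer
  expect_equal(accuracy(as.numeric(te$true_label), te)$accuracy, 1)
  # constant high score predicts everything positive: 0.5 on a balanced set
  expect_equal(accuracy(rep(0.99, 400), te)$accuracy, 0.5)
  # ties at theta count as negative
  expect_equal(accuracy(rep(0.5, 400), te, theta = 0.5)$accuracy, 0.5)
  expect_error(accuracy(rep(0.5, 0), te[0, ]), "empty")
})

test_that("oracle accuracy against observed labels equals the unflipped fraction", {
  ds <- generate_dataset(all_strands(6), 10000, alpha = 0.5, mu = 0.2,
                         role = "train", seed = 17)
  acc <- accuracy(as.numeric(oracle_classifier(ds)), ds)$accuracy
  expect_lt(abs(acc - 0.8), 3 * sqrt(0.2 * 0.8 / 10000))
})

test_that("score complementation mirrors accuracy around 1/2", {
  te <- generate_dataset(all_strands(4), 300, role = "test", seed = 9)
  set.seed(1)
  scores <- runif(300) # no score ties theta exactly, almost surely
  a1 <- accuracy(scores, te)$accuracy
  a2 <- accuracy(1 - scores, te)$accuracy
  expect_equal(a1 + a2, 1)
})

test_that("run_simulation is deterministic end to end and robust at tiny N", {
  r1 <- run_simulation("MLP", 2.70, N = 100, L_train = 4, mu = 0.1,
                       rep_seed = 6, test_size = 200, config = quick_config())
  r2 <- run_simulation("MLP", 2.70, N = 100, L_train = 4, mu = 0.1,
                       rep_seed = 6, test_size = 200, config = quick_config())
  expect_identical(r1, r2)
  r3 <- run_simulation("MLP", 2.70, N = 8, L_train = 4, rep_seed = 1,
                       test_size = 50, config = quick_config())
  expect_true(r3$train_accuracy >= 0 && r3$train_accuracy <= 1)
  expect_true(r3$test_accuracy >= 0 && r3$test_accuracy <= 1)
})

test_that("simulation summaries are consistent with their repetitions", {
  res <- run_simulations("MLP", repetitions = 3, base_seed = 1, level = 2.70,
                         N = 80, L_train = 3, test_size = 100,
                         config = quick_config())
  expect_equal(nrow(res), 3)
  expect_equal(res$repetition_seed, c(1, 2, 3))
  sm <- summarize_simulations(res)
  expect_equal(sm$repetitions, 3)
  expect_true(sm$min_test <= sm$mean_test && sm$mean_test <= sm$max_test)
  expect_equal(sm$mean_test, mean(res$test_accuracy))
  same <- summarize_simulations(res[c(1, 1, 1), ])
  expect_equal(same$sd_test, 0)
})

test_that("the probe set encodes the printed diagnostic sequences", {
  pr <- probe_examples()
  expect_equal(pr$true_label, c(1L, 0L, 0L))
  expect_equal(paste0(pr$s[2], pr$loop[2], pr$s_bar[2]), "ACGUACGUGAAAACGUAGCA")
  # mismatched positions can never pair: complement-substitution guarantees it
  expect_equal(oracle_classifier(pr), pr$true_label)
  m <- build_model(architecture_spec("MLP", 2.70), seed = 1)
  ps <- probe_scores(list(m), pr)
  expect_equal(nrow(ps), 3)
  expect_true(all(ps$score > 0 & ps$score < 1))
})

test_that("every family learns the clean within-length task at some capacity", {
  # high-N regime, no label noise: one moderate-capacity model per family
  accs <- vapply(c("MLP", "Att", "LSTM", "CNN"), function(fam) {
    run_simulation(fam, 3.50, N = 8000, L_train = 8, mu = 0, rep_seed = 1,
                   test_size = 2000)$test_accuracy
  }, numeric(1))
  expect_true(all(accs > 0.95))
})
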