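test_that("capacity_lookup returns the ledger pairs and rejects unknown levels", {
  expect_equal(capacity_lookup("MLP", 3.50), list(H = 30, U = 30))
  expect_equal(capacity_lookup("CNN", 5.50), list(H = 20, U = 36))
  expect_equal(capacity_lookup("LSTM", 2.70), list(H = 2, U = 5))
  expect_equal(capacity_lookup("Att", 4.15), list(H = 12, U = 60))
  expect_error(capacity_lookup("MLP", 3.25), "unknown capacity level")
})

test_that("parameter counts match the ledger's order of magnitude for every cell", {
  tab <- capacity_table()
  expect_equal(nrow(tab), 24)
  lg <- vapply(seq_len(nrow(tab)), function(i) {
    m <- build_model(architecture_spec(tab$family[i], H = tab$H[i], U = tab$U[i]),
                     seed = 1)
    log10(count_parameters(m))
  }, numeric(1))
  expect_true(all(abs(lg - tab$level) <= 0.25))
  # counts increase strictly with the ledger column within each family
  for (fam in unique(tab$family)) {
    expect_true(all(diff(lg[tab$family == fam]) > 0))
  }
})

test_that("the closed-form MLP count at (500, 500) is reproduced", {
  m <- build_model(architecture_spec("MLP", H = 500, U = 500), seed = 1)
  manual <- 16 + (96 * 500 + 500) + 2 * 500 + (500 * 500 + 500) + 2 * 500 + 501
  expect_equal(count_parameters(m), manual)
  expect_equal(log10(manual), 5.48, tolerance = 0.01)
})

test_that("model construction is deterministic in the seed", {
  a <- build_model(architecture_spec("Att", 2.70), seed = 11)
  b <- build_model(architecture_spec("Att", 2.70), seed = 11)
  expect_identical(a$params, b$params)
  c <- build_model(architecture_spec("Att", 2.70), seed = 12)
  expect_false(identical(a$params, c$params))
})

test_that("scores are strictly inside (0,1) and independent of batch company", {
  ds <- generate_dataset(all_strands(8), 256, alpha = 0.5, role = "train", seed = 2)
  tok <- encode_dataset(ds)
  for (fam in c("MLP", "Att", "LSTM", "CNN")) {
    m <- build_model(architecture_spec(fam, 2.70), seed = 3)
    s_all <- predict_scores(m, tok)
    expect_true(all(s_all > 0 & s_all < 1))
    # evaluation mode: one example alone scores the same as inside a batch
    s_one <- predict_scores(m, tok[7, , drop = FALSE])
    expect_equal(s_one, s_all[7], tolerance = 1e-12)
  }
})

test_that("untrained models sit at chance on a balanced test set", {
  te <- generate_dataset(all_strands(6), 1000, role = "test", seed = 4)
  accs <- vapply(1:10, function(s) {
    m <- build_model(architecture_spec("MLP", 3.00), seed = s)
    accuracy(m, te)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("the PAD token embeds to the zero vector", {
  m <- build_model(architecture_spec("MLP", 2.70), seed = 5)
  expect_equal(m$params$embedding[1, ], rep(0, 4))
})

test_that("forward refuses token layouts of the wrong length", {
  m <- build_model(architecture_spec("MLP", 2.70), seed = 1)
  expect_error(predict_scores(m, matrix(0L, 2, 23)), "input length")
})

test_that("checkpoints round-trip parameters and running statistics", {
  m <- build_model(architecture_spec("LSTM", 2.70), seed = 9)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m2$params, m$params)
  tok <- encode_dataset(generate_dataset(all_strands(4), 32, role = "test", seed = 1))
  expect_equal(predict_scores(m2, tok), predict_scores(m, tok))
})
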