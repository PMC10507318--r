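test_that("weighted_bce reproduces the defining arithmetic", {
  expect_equal(weighted_bce(0.5, 1, 0.5), log(2))
  # with twice as many negatives as positives the positive loss doubles
  y <- c(0.1, 0.4, 0.7, 0.9)
  expect_equal(weighted_bce(y, 1, 1 / 3), 2 * weighted_bce(y, 1, 0.5))
  # the negative branch carries no class weight
  for (a in c(0.1, 0.3, 0.5, 0.9)) {
    expect_equal(weighted_bce(y, 0, a), -log(1 - y))
  }
  # clamping keeps the loss finite at the boundary
  expect_true(is.finite(weighted_bce(0, 1, 0.5)))
  expect_true(is.finite(weighted_bce(1, 0, 0.5)))
})

test_that("alpha = 1/2 recovers the standard binary cross-entropy on a grid", {
  grid <- expand.grid(y = seq(0.05, 0.95, by = 0.1), t = c(0, 1))
  std <- -(grid$t * log(grid$y) + (1 - grid$t) * log(1 - grid$y))
  expect_equal(weighted_bce(grid$y, grid$t, 0.5), std)
})

test_that("the epoch rule divides a fixed example budget by N", {
  expect_equal(epochs_for(4000), 20L)
  expect_equal(epochs_for(500), 160L)
  expect_equal(epochs_for(100000), 1L) # floor of one epoch
  expect_equal(epochs_for(8e4), 1L)
})

test_that("total gradient steps are constant across the N grid", {
  # 8e4 examples / batches of 256 is about 312 updates; the ceiling on
  # partial batches makes the realised count exactly 320 for every grid size
  steps <- vapply(c(250, 500, 1000, 2000, 4000, 8000), planned_steps, integer(1))
  expect_true(all(steps == steps[1]))
  expect_lt(abs(steps[1] - 8e4 / 256) / (8e4 / 256), 0.03)
})

test_that("training is deterministic and respects its contracts", {
  ds <- tiny_train_set(L = 4, N = 120, mu = 0.1, seed = 7)
  m <- build_model(architecture_spec("MLP", 2.70), seed = 2)
  f1 <- train_model(m, ds, quick_config(epochs = 3, seed = 5))
  f2 <- train_model(m, ds, quick_config(epochs = 3, seed = 5))
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$record, f2$record)
  expect_true(all(is.finite(f1$record$loss)))
  expect_equal(nrow(f1$record), 3)
  # the input model is untouched
  expect_identical(m$params, build_model(architecture_spec("MLP", 2.70), seed = 2)$params)
  # the frozen PAD embedding row survives optimisation
  expect_equal(f1$model$params$embedding[1, ], rep(0, 4))
  te <- generate_dataset(all_strands(4), 100, role = "test", seed = 3)
  expect_error(train_model(m, te), "train-role")
})

test_that("the trace length follows the epoch rule when no override is given", {
  ds <- tiny_train_set(L = 4, N = 20000, seed = 11)
  m <- build_model(architecture_spec("MLP", 2.70), seed = 1)
  fit <- train_model(m, ds, train_config(seed = 1))
  expect_equal(nrow(fit$record), epochs_for(20000)) # 4 epochs
  expect_equal(fit$steps, planned_steps(20000))
})

test_that("a moderate-capacity MLP learns the within-length task", {
  ds <- generate_dataset(pool_strands(partition_sequence_space(8, seed = 1), "train"),
                         8000, alpha = 0.5, role = "train", seed = 2)
  m <- build_model(architecture_spec("MLP", 3.50), seed = 3)
  fit <- train_model(m, ds, train_config(seed = 4))
  expect_gte(fit$final_train_accuracy, 0.95)
})

test_that("tidy and glance expose the training record", {
  ds <- tiny_train_set(L = 3, N = 60, seed = 1)
  fit <- train_model(build_model(architecture_spec("MLP", 2.70), seed = 1),
                     ds, quick_config())
  expect_equal(tidy(fit)$loss, fit$record$loss)
  g <- glance(fit)
  expect_equal(g$family, "MLP")
  expect_equal(g$steps, fit$steps)
})
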