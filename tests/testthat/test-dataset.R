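test_that("partition_sequence_space gives disjoint exhaustive deterministic pools", {
  p <- partition_sequence_space(2, seed = 3)
  trn <- pool_strands(p, "train")
  tst <- pool_strands(p, "test")
  expect_length(c(trn, tst), 16)
  expect_length(intersect(trn, tst), 0)
  expect_equal(sort(c(trn, tst)), all_strands(2))
  p2 <- partition_sequence_space(2, seed = 3)
  expect_identical(pool_strands(p2, "train"), trn)
  p8 <- partition_sequence_space(8, seed = 1)
  expect_equal(length(p8$train_ids) + length(p8$test_ids), 65536)
  expect_equal(length(p8$train_ids), 32768)
  expect_error(partition_sequence_space(11, seed = 1), "must be in")
})

test_that("make_example builds complementary positives and never-complementary negatives", {
  pos <- make_example("AGUCAG", positive = TRUE, seed = 1)
  expect_equal(pos$s_bar, "CUGACU")
  expect_equal(pos$true_label, 1L)
  expect_equal(nchar(pos$loop), 4L)
  # L = 1 negatives: s_bar drawn from the three strands that are not s*
  draws <- vapply(1:200, function(i) {
    make_example("A", positive = FALSE, seed = i)$s_bar
  }, character(1))
  expect_true(all(draws %in% c("A", "C", "G")))
  expect_false(any(draws == "U"))
  # every generated negative is rejected by the oracle
  neg <- dplyr::bind_rows(lapply(1:50, function(i) {
    make_example("ACGU", positive = FALSE, seed = i)
  }))
  expect_true(all(oracle_classifier(neg) == 0L))
})

test_that("test-role datasets are exactly balanced and correctly labelled", {
  ds <- generate_dataset(all_strands(4), 1000, role = "test", seed = 5)
  expect_equal(sum(ds$true_label == 1), 500)
  expect_equal(sum(ds$true_label == 0), 500)
  expect_identical(ds$observed_label, ds$true_label)
  expect_false(any(ds$is_mislabelled))
  expect_error(generate_dataset(all_strands(4), 100, mu = 0.1, role = "test"),
               "mu = 0")
})

test_that("the positivity rate is controlled exactly before mislabelling", {
  ds <- generate_dataset(all_strands(6), 500, alpha = 0.4, role = "train", seed = 2)
  expect_equal(sum(ds$true_label), 200)
  expect_error(generate_dataset(all_strands(4), 100, alpha = 0, role = "train"),
               "alpha")
})

test_that("mislabelling flips the observed labels at the requested rate", {
  ds <- generate_dataset(all_strands(6), 10000, alpha = 0.5, role = "train", seed = 9)
  expect_identical(apply_mislabelling(ds, 0, seed = 1)$observed_label,
                   ds$observed_label)
  mis <- apply_mislabelling(ds, 0.2, seed = 1)
  # empirical flip fraction within 3 binomial standard deviations
  expect_lt(abs(mean(mis$is_mislabelled) - 0.2), 3 * sqrt(0.2 * 0.8 / 10000))
  expect_identical(mis$true_label, ds$true_label)
  expect_identical(mis$is_mislabelled, mis$observed_label != mis$true_label)
  te <- generate_dataset(all_strands(4), 100, role = "test", seed = 1)
  expect_error(apply_mislabelling(te, 0.1), "train-role")
})

test_that("at mu = 1/2 observed labels carry no information about true labels", {
  ds <- generate_dataset(all_strands(6), 20000, alpha = 0.5, role = "train", seed = 4)
  mis <- apply_mislabelling(ds, 0.5, seed = 2)
  agree <- mean(mis$observed_label == mis$true_label)
  expect_lt(abs(agree - 0.5), 3 * sqrt(0.25 / 20000))
  tab <- table(mis$observed_label, mis$true_label)
  expect_gt(suppressWarnings(stats::chisq.test(tab)$p.value), 0.001)
})

test_that("negative partners are uniform over the 4^L - 1 non-complements", {
  # fix one stem; 10000 negative draws over the 63 admissible partners
  ds <- generate_dataset("ACG", 10000, alpha = 1e-6, role = "train", seed = 8)
  expect_equal(sum(ds$true_label), 0)
  sstar <- exact_complement("ACG")
  expect_false(any(ds$s_bar == sstar))
  counts <- table(factor(ds$s_bar, levels = setdiff(all_strands(3), sstar)))
  expect_length(counts, 63)
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("identical seeds reproduce identical datasets, disjoint pools never share stems", {
  a <- generate_dataset(all_strands(5), 500, alpha = 0.3, mu = 0.2,
                        role = "train", seed = 42)
  b <- generate_dataset(all_strands(5), 500, alpha = 0.3, mu = 0.2,
                        role = "train", seed = 42)
  expect_identical(a, b)
  p <- partition_sequence_space(4, seed = 6)
  trn <- generate_dataset(pool_strands(p, "train"), 300, role = "train", seed = 1)
  tst <- generate_dataset(pool_strands(p, "test"), 300, role = "test", seed = 2)
  expect_length(intersect(unique(trn$s), unique(tst$s)), 0)
})

test_that("full_balanced_test_set enumerates one positive and one negative per stem", {
  ds <- full_balanced_test_set(3, seed = 1)
  expect_equal(nrow(ds), 2 * 64)
  expect_equal(sum(ds$true_label), 64)
  expect_equal(sort(unique(ds$s)), all_strands(3))
  expect_identical(oracle_classifier(ds), ds$true_label)
})

test_that("generated positives satisfy the pairwise complementarity condition", {
  ds <- generate_dataset(all_strands(5), 400, alpha = 0.5, role = "train", seed = 3)
  expect_identical(oracle_classifier(ds), ds$true_label)
})
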