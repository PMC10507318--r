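#' Ground-truth oracle classifier
#'
#' Brute-force Watson-Crick check: an example is positive iff every position
#' `i` of `s` is the complement of position `L + 1 - i` of `s_bar`. This is
#' the defining predicate of the task, implemented character-by-character and
#' independently of the integer arithmetic the generator uses, so it doubles
#' as a verification oracle for generated datasets and as a perfect reference
#' classifier.
#'
#' @param ds A `hairpin_dataset` or data frame with `s` and `s_bar` columns.
#' @return Integer vector of ground-truth labels in `{0, 1}`.
#' @examples
#' oracle_classifier(tibble::tibble(s = "AGUCAG", s_bar = "CUGACU")) # 1
#' @export
oracle_classifier <- function(ds) {
  L <- nchar(ds$s)
  if (any(nchar(ds$s_bar) != L)) {
    stop("s and s_bar must have equal lengths", call. = FALSE)
  }
  if (length(unique(L)) != 1L) {
    sm <- strsplit(ds$s, "", fixed = TRUE)
    bm <- strsplit(ds$s_bar, "", fixed = TRUE)
    return(vapply(seq_along(sm), function(r) {
      as.integer(all(sm[[r]] == complement_base(rev(bm[[r]]))))
    }, integer(1)))
  }
  L <- L[1]
  sm <- matrix(unlist(strsplit(ds$s, "", fixed = TRUE)), ncol = L, byrow = TRUE)
  bm <- matrix(unlist(strsplit(ds$s_bar, "", fixed = TRUE)), ncol = L, byrow = TRUE)
  ok <- rep(TRUE, nrow(sm))
  for (i in seq_len(L)) {
    ok <- ok & (sm[, i] == complement_base(bm[, L + 1 - i]))
  }
  as.integer(ok)
}

#' Thresholded classification accuracy
#'
#' The fraction of examples on which the thresholded score agrees with the
#' observed label: a score strictly above `theta` predicts class 1, a score
#' at or below `theta` predicts class 0 (ties count as negative).
#'
#' @param object A `hairpin_model`, `hairpin_fit`, or a numeric vector of
#'   scores aligned with the rows of `ds`.
#' @param ds A `hairpin_dataset`.
#' @param theta Classification threshold in `(0, 1)` (default 0.5).
#' @return A one-row tibble with `accuracy`, `theta`, `n_examples`, `role`.
#' @export
accuracy <- function(object, ds, theta = 0.5) {
  if (nrow(ds) == 0L) stop("empty dataset", call. = FALSE)
  stopifnot(theta > 0, theta < 1)
  scores <- if (is.numeric(object)) object else predict(object, ds)
  stopifnot(length(scores) == nrow(ds))
  tibble::tibble(
    accuracy = mean(as.integer(scores > theta) == ds$observed_label),
    theta = theta, n_examples = nrow(ds),
    role = attr(ds, "role") %||% NA_character_)
}

#' Run one end-to-end simulation
#'
#' One repetition of an experiment cell: generate datasets, build and train a
#' model, and evaluate train and test accuracy. All randomness derives from
#' `rep_seed`, so identical calls reproduce identical accuracies.
#'
#' Within-length runs (`L_train == L_test`) first partition the `4^L`
#' sequence space into disjoint train/test pools and sample a balanced,
#' correctly labelled test set of `test_size` examples from the test pool.
#' Length-extrapolation runs (`L_train != L_test`) train on stems drawn from
#' the full length-`L_train` space and evaluate on the exhaustive balanced
#' set of all `4^L_test` stems ([full_balanced_test_set()]).
#'
#' @param family Architecture family or an [architecture_spec()].
#' @param level Capacity level (ignored if `family` is already a spec).
#' @param N Training-set size.
#' @param L_train,L_test Stem lengths for training and testing.
#' @param alpha Training positivity rate.
#' @param mu Training mislabelling probability.
#' @param loop_length Apical loop length (default 4).
#' @param rep_seed Integer seed for this repetition.
#' @param theta Classification threshold (default 0.5).
#' @param test_size Test-set size for within-length runs (default 10000).
#' @param train_fraction Train share of the sequence-space partition.
#' @param config Optional [train_config()]; its seed is overridden by the
#'   seed derived from `rep_seed`.
#' @param keep_fit Keep the fitted model in the result (attribute `"fit"`)?
#' @return A one-row tibble with the experiment coordinates and train/test
#'   accuracies; when `keep_fit = TRUE` the `hairpin_fit` is attached as
#'   attribute `"fit"`.
#' @export
run_simulation <- function(family, level = NULL, N = 500, L_train = 8,
                           L_test = L_train, alpha = 0.5, mu = 0,
                           loop_length = 4, rep_seed = 1, theta = 0.5,
                           test_size = 10000, train_fraction = 0.5,
                           config = NULL, keep_fit = FALSE) {
  spec <- if (inherits(family, "architecture_spec")) family
          else architecture_spec(family, level = level, loop_length = loop_length)
  if (L_train == L_test) {
    part <- partition_sequence_space(L_train, seed = rep_seed, train_fraction)
    train_pool <- pool_strands(part, "train")
    test_ds <- generate_dataset(pool_strands(part, "test"), test_size,
                                role = "test", loop_length = loop_length,
                                seed = rep_seed + 2)
  } else {
    train_pool <- all_strands(L_train)
    test_ds <- full_balanced_test_set(L_test, loop_length, seed = rep_seed + 2)
  }
  train_ds <- generate_dataset(train_pool, N, alpha = alpha, mu = mu,
                               loop_length = loop_length, role = "train",
                               seed = rep_seed + 1)
  model <- build_model(spec, seed = rep_seed + 3)
  cfg <- config %||% train_config()
  cfg$seed <- rep_seed + 4
  fit <- train_model(model, train_ds, cfg, theta = theta)
  test_acc <- accuracy(fit, test_ds, theta)$accuracy
  out <- tibble::tibble(
    family = spec$family, level = spec$level %||% NA_real_,
    H = spec$H, U = spec$U, N = N, L_train = L_train, L_test = L_test,
    alpha = alpha, mu = mu, repetition_seed = rep_seed,
    train_accuracy = fit$final_train_accuracy, test_accuracy = test_acc)
  if (keep_fit) attr(out, "fit") <- fit
  out
}

#' Repeat a simulation over seeds
#'
#' Runs [run_simulation()] (or [run_baseline_simulation()] when `family` is a
#' baseline method name) for `repetitions` seeds `base_seed, base_seed + 1,
#' ...` and binds the per-repetition rows.
#'
#' @inheritParams run_simulation
#' @param repetitions Number of repetitions (the headline results in this
#'   package default to 10; increase for tighter means).
#' @param base_seed First repetition seed.
#' @param keep_fits Keep the fitted models (attribute `"fits"`)?
#' @param ... Passed to [run_simulation()] / [run_baseline_simulation()].
#' @return A tibble with one row per repetition.
#' @export
run_simulations <- function(family, repetitions = 10, base_seed = 1,
                            keep_fits = FALSE, ...) {
  is_baseline <- is.character(family) &&
    family %in% c("KNN", "SVM", "TREE", "FOREST")
  fits <- vector("list", repetitions)
  rows <- purrr::map(seq_len(repetitions), function(r) {
    seed <- base_seed + r - 1
    if (is_baseline) {
      run_baseline_simulation(family, rep_seed = seed, ...)
    } else {
      res <- run_simulation(family, rep_seed = seed, keep_fit = keep_fits, ...)
      if (keep_fits) fits[[r]] <<- attr(res, "fit")
      res
    }
  })
  out <- dplyr::bind_rows(rows)
  if (keep_fits && !is_baseline) attr(out, "fits") <- fits
  out
}

#' Aggregate repeated simulations
#'
#' @param results A tibble of per-repetition rows from [run_simulations()] or
#'   [run_experiment()].
#' @return A tibble with one row per experiment cell carrying mean, standard
#'   deviation, minimum and maximum of the train and test accuracies and the
#'   repetition count.
#' @export
summarize_simulations <- function(results) {
  dplyr::summarise(
    dplyr::group_by(results, .data$family, .data$level, .data$H, .data$U,
                    .data$N, .data$L_train, .data$L_test, .data$alpha,
                    .data$mu),
    repetitions = dplyr::n(),
    mean_train = mean(.data$train_accuracy), sd_train = sd(.data$train_accuracy),
    min_train = min(.data$train_accuracy), max_train = max(.data$train_accuracy),
    mean_test = mean(.data$test_accuracy), sd_test = sd(.data$test_accuracy),
    min_test = min(.data$test_accuracy), max_test = max(.data$test_accuracy),
    .groups = "drop")
}

#' Diagnostic probe sequences
#'
#' Three fixed length-8 probes built on the stem `s = ACGUACGU` (its own
#' exact complement) with loop `GAAA`:
#' the fully complementary positive, a negative with mismatches at base-pair
#' positions 6-8 (second-strand positions 6-8, the region adjacent to the
#' padding when models are trained on shorter stems), and a negative with
#' mismatches at positions 2-4. Mismatches replace the correct base by its
#' Watson-Crick complement, which can never pair (a base cannot pair with
#' itself), so the full second strand of the upper-mismatch probe reads
#' `ACGUAGCA` and the probe sequence is `ACGUACGUGAAAACGUAGCA`.
#'
#' @return A `hairpin_dataset` of the three probes with a `probe` descriptor
#'   column.
#' @export
probe_examples <- function() {
  s <- "ACGUACGU"
  sstar <- exact_complement(s) # ACGUACGU: self-complementary
  mismatch <- function(pos) {
    ch <- strsplit(sstar, "", fixed = TRUE)[[1]]
    ch[pos] <- complement_base(ch[pos])
    paste(ch, collapse = "")
  }
  tbl <- tibble::tibble(
    id = 1:3,
    probe = c("positive", "mismatch_pairs_6_8", "mismatch_pairs_2_4"),
    s = s, loop = "GAAA",
    s_bar = c(sstar, mismatch(6:8), mismatch(2:4)))
  tbl$true_label <- oracle_classifier(tbl)
  tbl$observed_label <- tbl$true_label
  tbl$is_mislabelled <- FALSE
  new_hairpin_dataset(tbl, 8L, 0.5, 0, "test", 4L, NA_integer_)
}

#' Score probe sequences with trained models
#'
#' @param fits A list of `hairpin_fit` (or `hairpin_model`) objects.
#' @param probes A probe dataset (default [probe_examples()]).
#' @param theta Classification threshold (default 0.5).
#' @return A tibble with one row per (model, probe): positivity score,
#'   thresholded prediction and ground truth.
#' @export
probe_scores <- function(fits, probes = probe_examples(), theta = 0.5) {
  purrr::map_dfr(seq_along(fits), function(k) {
    scores <- predict(fits[[k]], probes)
    tibble::tibble(
      model_id = k,
      probe = if (!is.null(probes$probe)) probes$probe else as.character(probes$id),
      score = scores, theta = theta,
      predicted = as.integer(scores > theta),
      true_label = probes$true_label)
  })
}
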