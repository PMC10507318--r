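#' Partition the sequence space of length-L strands
#'
#' Randomly splits the set of all `4^L` strands of length `L` into disjoint
#' train and test pools, so that no stem sequence `s` used for training can
#' appear in a test set built from the same partition. The split is a shuffled
#' exact split: pool sizes are deterministic, `round(train_fraction * 4^L)`
#' strands go to the train pool.
#'
#' @param L Strand length, `1 <= L <= 10`.
#' @param seed Integer seed; the same `(L, seed, train_fraction)` always gives
#'   the same partition.
#' @param train_fraction Fraction of the space assigned to the train pool
#'   (default 0.5).
#' @return An object of class `sequence_partition`: a list with `L`, `seed`,
#'   `train_fraction` and the two id pools.
#' @examples
#' p <- partition_sequence_space(4, seed = 1)
#' length(pool_strands(p, "train")) + length(pool_strands(p, "test")) == 4^4
#' @export
partition_sequence_space <- function(L, seed, train_fraction = 0.5) {
  if (L < 1 || L > max_strand_length()) {
    stop("L must be in [1, ", max_strand_length(), "]", call. = FALSE)
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  n <- 4^L
  n_train <- round(train_fraction * n)
  if (n_train < 1 || n_train >= n) stop("degenerate split", call. = FALSE)
  set.seed(seed)
  perm <- sample.int(n) - 1 # strand ids are 0-based
  structure(
    list(L = as.integer(L), seed = as.integer(seed),
         train_fraction = train_fraction,
         train_ids = perm[seq_len(n_train)],
         test_ids = perm[(n_train + 1):n]),
    class = "sequence_partition"
  )
}

#' @export
print.sequence_partition <- function(x, ...) {
  cat(sprintf(
    "<sequence_partition> L = %d, 4^L = %d strands: %d train / %d test (seed %d)\n",
    x$L, 4^x$L, length(x$train_ids), length(x$test_ids), x$seed))
  invisible(x)
}

#' Extract a pool of strands from a partition
#'
#' @param partition A [partition_sequence_space()] result.
#' @param role `"train"` or `"test"`.
#' @return Character vector of strands.
#' @export
pool_strands <- function(partition, role = c("train", "test")) {
  role <- match.arg(role)
  ids <- if (role == "train") partition$train_ids else partition$test_ids
  int_to_strands(ids_to_int(ids, partition$L))
}

new_hairpin_dataset <- function(tbl, L, alpha, mu, role, loop_length, seed) {
  structure(
    tbl,
    L = as.integer(L), alpha = alpha, mu = mu, role = role,
    loop_length = as.integer(loop_length), seed = seed,
    class = c("hairpin_dataset", class(tibble::tibble())))
}

#' @export
print.hairpin_dataset <- function(x, ...) {
  cat(sprintf(
    "<hairpin_dataset> role = %s, N = %d, L = %d, loop = %d, alpha = %.3g, mu = %.3g\n",
    attr(x, "role"), nrow(x), attr(x, "L"), attr(x, "loop_length"),
    attr(x, "alpha"), attr(x, "mu")))
  NextMethod()
}

## vectorised core: builds the example table for given stem ids and signs
build_examples <- function(s_ids, L, positive, loop_length) {
  n <- length(s_ids)
  s_int <- ids_to_int(s_ids, L)
  sstar_int <- int_complement(s_int)
  sstar_ids <- int_to_ids(sstar_int)
  sbar_int <- sstar_int
  neg <- which(!positive)
  if (length(neg)) {
    # uniform over the 4^L - 1 strands different from s*: draw from a space
    # with the complement removed, then shift ids at or above it up by one
    r <- sample.int(4^L - 1, length(neg), replace = TRUE) - 1
    r <- r + (r >= sstar_ids[neg])
    sbar_int[neg, ] <- ids_to_int(r, L)
  }
  loop_int <- matrix(sample.int(4L, n * loop_length, replace = TRUE),
                     nrow = n, ncol = loop_length)
  tibble::tibble(
    id = seq_len(n),
    s = int_to_strands(s_int),
    loop = int_to_strands(loop_int),
    s_bar = int_to_strands(sbar_int),
    true_label = as.integer(positive),
    observed_label = as.integer(positive),
    is_mislabelled = FALSE
  )
}

#' Build a single hairpin example
#'
#' Draws a random apical loop and, for a positive example, sets the second
#' strand to the exact complement `s*`; for a negative example draws the second
#' strand uniformly among the `4^L - 1` strands different from `s*`.
#'
#' @param s A single strand (string over `{A, C, G, U}`).
#' @param loop_length Apical loop length, 3 to 7 (default 4).
#' @param positive Logical; build a fully complementary (positive) example?
#' @param seed Optional integer seed; if `NULL` the current RNG stream is used.
#' @return A one-row tibble with columns `s`, `loop`, `s_bar`, `true_label`,
#'   `observed_label`, `is_mislabelled`.
#' @export
make_example <- function(s, loop_length = 4, positive = TRUE, seed = NULL) {
  validate_strands(s)
  stopifnot(length(s) == 1L, loop_length >= 3, loop_length <= 7)
  if (!is.null(seed)) set.seed(seed)
  L <- nchar(s)
  build_examples(int_to_ids(strands_to_int(s)), L, positive, loop_length)
}

#' Flip training labels at random
#'
#' Each example's observed label is flipped independently with probability
#' `mu`; ground-truth labels are untouched. Test datasets are refused: test
#' sets are always correctly labelled.
#'
#' @param ds A `hairpin_dataset` with role `"train"`.
#' @param mu Mislabelling probability in `[0, 1/2]`.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is used.
#' @return The dataset with flipped `observed_label` and updated
#'   `is_mislabelled`, and the `mu` attribute set.
#' @export
apply_mislabelling <- function(ds, mu, seed = NULL) {
  if (!identical(attr(ds, "role"), "train")) {
    stop("mislabelling may only be applied to train-role datasets", call. = FALSE)
  }
  if (mu < 0 || mu > 0.5) stop("mu must be in [0, 1/2]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  flip <- runif(nrow(ds)) < mu
  ds$observed_label <- ifelse(flip, 1L - ds$true_label, ds$true_label)
  ds$is_mislabelled <- ds$observed_label != ds$true_label
  attr(ds, "mu") <- mu
  ds
}

#' Generate a labelled hairpin dataset
#'
#' Draws stem sequences `s` from a pool (with replacement, so `N` may exceed
#' the pool size), builds one hairpin example per draw with
#' `round(alpha * N)` positives, and -- for train-role datasets -- flips each
#' observed label independently with probability `mu`. Test-role datasets are
#' forced to `alpha = 1/2` (equal counts of true positives and negatives,
#' `N` must be even) and `mu = 0`.
#'
#' @param pool Character vector of candidate stem strands (all the same
#'   length), e.g. from [pool_strands()] or [all_strands()].
#' @param N Number of examples.
#' @param alpha Positive-example ratio in `(0, 1)` (by true label, before any
#'   mislabelling). Ignored (forced to 1/2) for test-role datasets.
#' @param mu Mislabelling probability in `[0, 1/2]`; must be 0 for test role.
#' @param loop_length Apical loop length, 3 to 7 (default 4).
#' @param role `"train"` or `"test"`.
#' @param seed Integer seed; datasets are byte-identical for identical inputs.
#' @return A `hairpin_dataset` tibble.
#' @export
generate_dataset <- function(pool, N, alpha = 0.5, mu = 0, loop_length = 4,
                             role = c("train", "test"), seed = 1) {
  role <- match.arg(role)
  if (length(pool) == 0L) stop("empty strand pool", call. = FALSE)
  validate_strands(pool[1])
  stopifnot(N >= 1, loop_length >= 3, loop_length <= 7)
  L <- nchar(pool[1])
  if (role == "test") {
    if (mu != 0) stop("test datasets must have mu = 0", call. = FALSE)
    if (N %% 2 != 0) stop("test datasets need even N for exact balance", call. = FALSE)
    alpha <- 0.5
  } else if (alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  set.seed(seed)
  pool_ids <- int_to_ids(strands_to_int(pool))
  n_pos <- round(alpha * N)
  positive <- sample(c(rep(TRUE, n_pos), rep(FALSE, N - n_pos)))
  s_ids <- pool_ids[sample.int(length(pool_ids), N, replace = TRUE)]
  tbl <- build_examples(s_ids, L, positive, loop_length)
  ds <- new_hairpin_dataset(tbl, L, alpha, 0, role, loop_length, seed)
  if (role == "train" && mu > 0) ds <- apply_mislabelling(ds, mu)
  attr(ds, "mu") <- mu
  ds
}

#' Balanced test set over the full sequence space
#'
#' Builds the exhaustive balanced test set used for length-wise extrapolation:
#' one positive and one negative example for every one of the `4^L` strands of
#' length `L` (so `N = 2 * 4^L`), all correctly labelled.
#'
#' @param L Strand length of the test examples.
#' @param loop_length Apical loop length (default 4).
#' @param seed Integer seed for the loops and the negative partners.
#' @return A test-role `hairpin_dataset` with `2 * 4^L` rows.
#' @export
full_balanced_test_set <- function(L, loop_length = 4, seed = 1) {
  stopifnot(L >= 1, L <= max_strand_length())
  set.seed(seed)
  ids <- 0:(4^L - 1)
  s_ids <- c(ids, ids)
  positive <- rep(c(TRUE, FALSE), each = 4^L)
  tbl <- build_examples(s_ids, L, positive, loop_length)
  new_hairpin_dataset(tbl, L, 0.5, 0, "test", loop_length, seed)
}

#' One-row summary of a hairpin dataset
#'
#' @param x A `hairpin_dataset`.
#' @param ... Unused.
#' @return A one-row tibble with the dataset's generation parameters and the
#'   empirical positive and mislabelled fractions.
#' @export
glance.hairpin_dataset <- function(x, ...) {
  tibble::tibble(
    role = attr(x, "role"), n = nrow(x), L = attr(x, "L"),
    loop_length = attr(x, "loop_length"),
    alpha = attr(x, "alpha"), mu = attr(x, "mu"),
    frac_true_positive = mean(x$true_label),
    frac_observed_positive = mean(x$observed_label),
    frac_mislabelled = mean(x$is_mislabelled),
    seed = attr(x, "seed")
  )
}
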