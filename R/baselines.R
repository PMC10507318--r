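#' One-hot featurisation for classical baselines
#'
#' Position-wise one-hot encoding over `{A, C, G, U}` of the fixed-size token
#' layout: `4 * (2 * max_len + loop_length)` features (96 by default), with
#' padding positions all-zero -- mirroring the networks' zero-padding so that
#' baselines and networks see the same information.
#'
#' @param ds A `hairpin_dataset` (or data frame with `s`, `loop`, `s_bar`).
#' @param max_len Maximum stem length (default 10).
#' @return A numeric matrix with one row per example.
#' @export
featurize <- function(ds, max_len = max_strand_length()) {
  tok <- encode_dataset(ds, max_len)
  n <- nrow(tok)
  Tlen <- ncol(tok)
  X <- matrix(0, n, 4L * Tlen)
  for (b in 1:4) {
    hit <- which(tok == b, arr.ind = TRUE)
    X[cbind(hit[, 1], (hit[, 2] - 1L) * 4L + b)] <- 1
  }
  X
}

#' Fit a classical baseline classifier
#'
#' The four comparator methods, with the three stated overrides and otherwise
#' plain defaults:
#' * `KNN`: 35 nearest neighbours, Euclidean distance, uniform vote
#'   (lazy -- the "fit" stores the training data).
#' * `SVM`: radial-basis kernel, cost 1, kernel width
#'   `1 / (n_features * var(X))`, hard labels.
#' * `TREE`: decision tree, Gini impurity, maximum depth 12, no other pruning.
#' * `FOREST`: random forest of 400 trees, Gini, unlimited depth, bootstrap
#'   resampling, square-root feature subsampling.
#'
#' Baselines use no class weighting: the alpha-correction applies only to the
#' networks' loss.
#'
#' @param method One of `"KNN"`, `"SVM"`, `"TREE"`, `"FOREST"`.
#' @param ds A train-role `hairpin_dataset`; models fit the observed
#'   (possibly flipped) labels.
#' @param seed Integer seed for the randomised methods.
#' @param knn_neighbors,tree_max_depth,forest_trees The stated overrides.
#' @return A `hairpin_baseline` object.
#' @export
fit_baseline <- function(method = c("KNN", "SVM", "TREE", "FOREST"), ds,
                         seed = 1, knn_neighbors = 35, tree_max_depth = 12,
                         forest_trees = 400) {
  method <- match.arg(method)
  if (!identical(attr(ds, "role"), "train")) {
    stop("fit_baseline() requires a train-role dataset", call. = FALSE)
  }
  if (nrow(ds) == 0L) stop("empty dataset", call. = FALSE)
  X <- featurize(ds)
  y <- factor(ds$observed_label, levels = c(0, 1))
  set.seed(seed)
  fit <- switch(method,
    KNN = list(X = X, y = y, k = knn_neighbors),
    SVM = e1071::svm(X, y, type = "C-classification", kernel = "radial",
                     cost = 1, gamma = 1 / (ncol(X) * var(as.vector(X))),
                     scale = FALSE),
    TREE = {
      df <- data.frame(y = y, X)
      rpart::rpart(y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     maxdepth = tree_max_depth, cp = 0, minsplit = 2,
                     minbucket = 1, xval = 0))
    },
    FOREST = randomForest::randomForest(X, y, ntree = forest_trees))
  structure(list(method = method, fit = fit, n_features = ncol(X)),
            class = "hairpin_baseline")
}

#' @export
print.hairpin_baseline <- function(x, ...) {
  cat(sprintf("<hairpin_baseline> %s on %d one-hot features\n",
              x$method, x$n_features))
  invisible(x)
}

#' @export
predict.hairpin_baseline <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else featurize(newdata)
  if (ncol(X) != object$n_features) {
    stop("feature length mismatch: expected ", object$n_features, call. = FALSE)
  }
  pred <- switch(object$method,
    KNN = class::knn(object$fit$X, X, object$fit$y, k = object$fit$k),
    SVM = predict(object$fit, X),
    TREE = predict(object$fit, data.frame(X), type = "class"),
    FOREST = predict(object$fit, X))
  as.integer(as.character(pred))
}

#' Accuracy of a fitted baseline
#'
#' Hard 0/1 predictions scored with the same thresholded-accuracy measure as
#' the networks, against the dataset's observed labels.
#'
#' @param baseline A `hairpin_baseline` from [fit_baseline()].
#' @param ds A `hairpin_dataset`.
#' @return A one-row tibble as from [accuracy()].
#' @export
baseline_accuracy <- function(baseline, ds) {
  if (nrow(ds) == 0L) stop("empty dataset", call. = FALSE)
  pred <- predict(baseline, ds)
  tibble::tibble(
    accuracy = mean(pred == ds$observed_label),
    theta = 0.5, n_examples = nrow(ds),
    role = attr(ds, "role") %||% NA_character_)
}

#' One end-to-end baseline simulation
#'
#' Mirrors [run_simulation()] -- identical dataset construction from the same
#' seeds, so a baseline row and a network row with equal seeds differ only in
#' the classifier -- with `family` set to the method name in the output.
#'
#' @inheritParams run_simulation
#' @param method Baseline method name.
#' @param level Ignored (baselines have no capacity ledger); accepted so
#'   network and baseline runs can share a calling convention.
#' @param keep_fit Keep the fitted baseline (attribute `"fit"`)?
#' @param ... Passed to [fit_baseline()].
#' @return A one-row tibble with the experiment coordinates and accuracies.
#' @export
run_baseline_simulation <- function(method, level = NULL, N = 500, L_train = 8,
                                    L_test = L_train, alpha = 0.5, mu = 0,
                                    loop_length = 4, rep_seed = 1,
                                    test_size = 10000, train_fraction = 0.5,
                                    keep_fit = FALSE, ...) {
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
  fit <- fit_baseline(method, train_ds, seed = rep_seed + 3, ...)
  out <- tibble::tibble(
    family = method, level = NA_real_, H = NA_integer_, U = NA_integer_,
    N = N, L_train = L_train, L_test = L_test, alpha = alpha, mu = mu,
    repetition_seed = rep_seed,
    train_accuracy = baseline_accuracy(fit, train_ds)$accuracy,
    test_accuracy = baseline_accuracy(fit, test_ds)$accuracy)
  if (keep_fit) attr(out, "fit") <- fit
  out
}
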