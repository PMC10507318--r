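#' Describe an experiment grid
#'
#' The named presets pin the coordinates each study holds fixed:
#' * `mislabels`: within-length learning under label noise,
#'   `L = 8`, `mu = 0.2`, `alpha = 0.5`.
#' * `length_extrapolation`: train short / test long, `L_train` 5 or 6,
#'   `L_test = 8`, `mu = 0`.
#' * `alpha_sweep`: positivity-rate sensitivity at
#'   `(N, L, mu) = (500, 6, 0)`, `alpha` over a grid in `(0, 1)`.
#' * `combined`: extrapolation with mislabels, `L_train = 6`, `L_test = 8`,
#'   `mu = 0.2`, `alpha = 0.4`.
#' * `baselines`: classical methods on any of the above coordinates.
#'
#' @param name Experiment name (see above).
#' @param families Architecture families (or baseline methods for
#'   `"baselines"`) to run.
#' @param capacity_levels Capacity levels from [capacity_table()].
#' @param N_grid Training-set sizes.
#' @param L_train,L_test Stem lengths.
#' @param alpha_grid Positivity rates (length > 1 only for `alpha_sweep`).
#' @param mu Mislabelling probability.
#' @param repetitions Repetitions per cell (default 50; reduced-scale runs
#'   override this).
#' @param base_seed First repetition seed.
#' @param test_size Within-length test-set size.
#' @param loop_length Apical loop length.
#' @return An `experiment_spec` list.
#' @export
experiment_spec <- function(name = c("mislabels", "length_extrapolation",
                                     "alpha_sweep", "combined", "baselines"),
                            families = c("MLP", "Att", "LSTM", "CNN"),
                            capacity_levels = c(2.70, 3.00, 3.50, 4.15, 4.75, 5.50),
                            N_grid = c(125, 250, 500, 1000, 2000, 4000, 8000),
                            L_train = NULL, L_test = NULL, alpha_grid = NULL,
                            mu = NULL, repetitions = 50, base_seed = 1,
                            test_size = 10000, loop_length = 4) {
  name <- match.arg(name)
  defaults <- switch(name,
    mislabels = list(L_train = 8, L_test = 8, alpha_grid = 0.5, mu = 0.2),
    length_extrapolation = list(L_train = 6, L_test = 8, alpha_grid = 0.5, mu = 0),
    alpha_sweep = list(L_train = 6, L_test = 6,
                       alpha_grid = c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5,
                                      0.6, 0.7, 0.8, 0.9, 0.95),
                       mu = 0, N_grid = 500),
    combined = list(L_train = 6, L_test = 8, alpha_grid = 0.4, mu = 0.2),
    baselines = list(L_train = 8, L_test = 8, alpha_grid = 0.5, mu = 0.2))
  if (name == "alpha_sweep") N_grid <- defaults$N_grid
  spec <- list(
    name = name, families = families,
    capacity_levels = if (name == "baselines") NA_real_ else capacity_levels,
    N_grid = N_grid,
    L_train = L_train %||% defaults$L_train,
    L_test = L_test %||% defaults$L_test,
    alpha_grid = alpha_grid %||% defaults$alpha_grid,
    mu = mu %||% defaults$mu,
    repetitions = repetitions, base_seed = base_seed,
    test_size = test_size, loop_length = loop_length)
  if (name == "length_extrapolation" && !spec$L_train %in% c(5, 6)) {
    stop("length_extrapolation trains on stems of length 5 or 6", call. = FALSE)
  }
  structure(spec, class = "experiment_spec")
}

#' Run an experiment grid
#'
#' Executes every (family, capacity level, N, alpha) cell of the grid through
#' [run_simulation()] (or [run_baseline_simulation()] for baseline methods)
#' for the requested repetitions, and aggregates the long-form rows. At
#' `scale = "reduced"` repetitions default to 10. When `out_dir` is given the
#' long-form table is written to `<name>_long.csv` after every cell and
#' already-present cells are skipped on restart, so interrupted grids resume;
#' a cell that errors is recorded with `NA` accuracies and the run continues.
#'
#' @param spec An [experiment_spec()].
#' @param scale `"full"` (the spec's repetitions) or `"reduced"` (10).
#' @param out_dir Optional output directory for the long-form and aggregated
#'   CSV tables.
#' @param config Optional [train_config()] forwarded to every network run
#'   (e.g. to shorten training in exploratory sweeps).
#' @return A `grid_result`: list with `long` (one row per repetition) and
#'   `summary` (one row per cell, from [summarize_simulations()]).
#' @export
run_experiment <- function(spec, scale = c("full", "reduced"), out_dir = NULL,
                           config = NULL) {
  stopifnot(inherits(spec, "experiment_spec"))
  scale <- match.arg(scale)
  reps <- if (scale == "reduced") min(10, spec$repetitions) else spec$repetitions
  cells <- expand.grid(family = spec$families, level = spec$capacity_levels,
                       N = spec$N_grid, alpha = spec$alpha_grid,
                       stringsAsFactors = FALSE)
  long_path <- if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    file.path(out_dir, paste0(spec$name, "_long.csv"))
  }
  done <- if (!is.null(long_path) && file.exists(long_path)) {
    readr::read_csv(long_path, show_col_types = FALSE)
  } else NULL
  rows <- if (is.null(done)) list() else list(done)
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    if (!is.null(done) &&
        nrow(dplyr::filter(done, .data$family == cell$family,
                           (is.na(.data$level) & is.na(cell$level)) |
                             .data$level %in% cell$level,
                           .data$N == cell$N, .data$alpha == cell$alpha)) >= reps) {
      next
    }
    is_baseline <- cell$family %in% c("KNN", "SVM", "TREE", "FOREST")
    extra <- if (is_baseline) list() else list(config = config)
    res <- tryCatch(
      do.call(run_simulations, c(list(
        cell$family, repetitions = reps, base_seed = spec$base_seed,
        level = if (is.na(cell$level)) NULL else cell$level,
        N = cell$N, L_train = spec$L_train, L_test = spec$L_test,
        alpha = cell$alpha, mu = spec$mu, loop_length = spec$loop_length,
        test_size = spec$test_size), extra)),
      error = function(e) {
        warning("cell ", ci, " failed: ", conditionMessage(e), call. = FALSE)
        tibble::tibble(
          family = cell$family, level = cell$level, H = NA_integer_,
          U = NA_integer_, N = cell$N, L_train = spec$L_train,
          L_test = spec$L_test, alpha = cell$alpha, mu = spec$mu,
          repetition_seed = NA_real_, train_accuracy = NA_real_,
          test_accuracy = NA_real_)
      })
    rows <- c(rows, list(res))
    if (!is.null(long_path)) {
      readr::write_csv(dplyr::bind_rows(rows), long_path)
    }
  }
  long <- dplyr::bind_rows(rows)
  summary <- summarize_simulations(long[!is.na(long$train_accuracy), ])
  if (!is.null(out_dir)) {
    readr::write_csv(summary, file.path(out_dir, paste0(spec$name, "_summary.csv")))
  }
  structure(list(long = long, summary = summary, spec = spec),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("<grid_result> %s: %d repetition rows over %d cells\n",
              x$spec$name, nrow(x$long), nrow(x$summary)))
  invisible(x)
}

#' @export
tidy.grid_result <- function(x, ...) x$long

#' @export
glance.grid_result <- function(x, ...) x$summary

#' Train/test accuracy as a function of training-set size
#'
#' Extracts the mean train and test accuracy per `N` for one (family, level)
#' slice, sorted by `N` -- the view in which the cross-over of the two curves
#' under label noise is located.
#'
#' @param results A `grid_result` or its long-form tibble.
#' @param family Architecture family or baseline method.
#' @param level Capacity level (`NULL` for baselines).
#' @return A tibble `(N, mean_train, mean_test, repetitions)` sorted by `N`.
#' @export
crossover_curve <- function(results, family, level = NULL) {
  long <- if (inherits(results, "grid_result")) results$long else results
  slice <- long[long$family == family &
                  (if (is.null(level)) is.na(long$level)
                   else !is.na(long$level) & long$level == level), ]
  if (nrow(slice) == 0L) {
    stop("no rows for family ", family,
         if (!is.null(level)) paste0(" at level ", level), call. = FALSE)
  }
  dplyr::arrange(
    dplyr::summarise(dplyr::group_by(slice, .data$N),
                     mean_train = mean(.data$train_accuracy),
                     mean_test = mean(.data$test_accuracy),
                     repetitions = dplyr::n(), .groups = "drop"),
    .data$N)
}

#' Test accuracy as a function of training positivity rate
#'
#' @param results A `grid_result` (or long tibble) from an `alpha_sweep`
#'   experiment.
#' @return A tibble `(family, level, alpha, mean_train, mean_test,
#'   repetitions)` sorted by `alpha` within each (family, level).
#' @export
alpha_sweep_curve <- function(results) {
  long <- if (inherits(results, "grid_result")) results$long else results
  if (nrow(long) == 0L) stop("empty results", call. = FALSE)
  dplyr::arrange(
    dplyr::summarise(dplyr::group_by(long, .data$family, .data$level, .data$alpha),
                     mean_train = mean(.data$train_accuracy),
                     mean_test = mean(.data$test_accuracy),
                     repetitions = dplyr::n(), .groups = "drop"),
    .data$family, .data$level, .data$alpha)
}
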