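# Observed-vs-simulated evaluation: k-fold plans, per-trait Welch t-tests,
# Bonferroni family-wise adjustment, misclassification counting and the
# confusion-matrix sensitivity rate.

#' Plan a k-fold split with all train/test fold permutations
#'
#' Randomly partitions sample ids into `k` near-equal folds (sizes differ by
#' at most 1) and enumerates every choice of `k_train` training folds, the
#' remaining folds forming the test set — C(5, 3) = 10 permutations for the
#' default 5-fold / 3-train design.
#'
#' @param sample_ids Vector of sample identifiers (plants/images).
#' @param k Number of folds.
#' @param k_train Number of training folds per permutation.
#' @return A `fold_plan`: tibble `assignment` (`sample_id`, `fold`) and
#'   tibble `permutations` (`permutation`, list-columns `train_folds`,
#'   `test_folds`).
#' @export
kfold_split <- function(sample_ids, k = 5, k_train = 3) {
  n <- length(sample_ids)
  if (n < k) stop("fewer samples (", n, ") than folds (", k, ")",
                  call. = FALSE)
  folds <- sample(rep(seq_len(k), length.out = n))
  combos <- utils::combn(k, k_train)
  perms <- tibble::tibble(
    permutation = seq_len(ncol(combos)),
    train_folds = lapply(seq_len(ncol(combos)), function(j) combos[, j]),
    test_folds = lapply(seq_len(ncol(combos)), function(j) {
      setdiff(seq_len(k), combos[, j])
    })
  )
  structure(list(
    assignment = tibble::tibble(sample_id = sample_ids, fold = folds),
    permutations = perms, k = k, k_train = k_train
  ), class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("fold_plan: %d samples in %d folds, %d train/test permutations\n",
              nrow(x$assignment), x$k, nrow(x$permutations)))
  invisible(x)
}

#' Two-sample t-test p-value for one trait
#'
#' Welch (unequal-variance) two-sided t-test by default; set
#' `var_equal = TRUE` for the pooled-variance variant. Degenerate inputs are
#' resolved without exceptions: both groups constant and equal means gives
#' p = 1; constant groups with unequal means gives p = 0.
#'
#' @param observed,simulated Numeric vectors (>= 2 values each).
#' @param var_equal Pooled-variance t-test instead of Welch.
#' @return Raw two-sided p-value.
#' @export
trait_ttest <- function(observed, simulated, var_equal = FALSE) {
  if (length(observed) < 2 || length(simulated) < 2) {
    stop("need at least 2 values per group", call. = FALSE)
  }
  if (stats::var(observed) == 0 && stats::var(simulated) == 0) {
    return(if (isTRUE(all.equal(mean(observed), mean(simulated)))) 1 else 0)
  }
  stats::t.test(observed, simulated, var.equal = var_equal)$p.value
}

#' Bonferroni adjustment
#'
#' `adjusted_i = min(1, p_i * m)` with `m = length(p_values)`; delegated to
#' [stats::p.adjust()].
#'
#' @param p_values Raw p-values in [0, 1].
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "bonferroni")
}

#' Sensitivity rate from a misclassification count
#'
#' Percentage of correctly predicted traits,
#' `100 * (n_traits - n_misclassified) / n_traits`, as read off a confusion
#' matrix whose positives are the traits with no significant
#' observed-vs-simulated difference.
#'
#' @param n_traits Number of traits compared (> 0).
#' @param n_misclassified Number with significant differences.
#' @return Percentage in [0, 100].
#' @export
#' @examples
#' sensitivity_rate(39, 20)
#' sensitivity_rate(39, 24)
sensitivity_rate <- function(n_traits, n_misclassified) {
  if (n_traits <= 0) stop("n_traits must be > 0", call. = FALSE)
  if (n_misclassified < 0 || n_misclassified > n_traits) {
    stop("n_misclassified must lie in [0, n_traits]", call. = FALSE)
  }
  100 * (n_traits - n_misclassified) / n_traits
}

#' Compare observed and simulated trait tables
#'
#' Per shared numeric trait: Welch t-test, Bonferroni adjustment over the
#' shared-trait family, misclassification where the adjusted p falls below
#' `alpha`, and the resulting sensitivity rate.
#'
#' @param observed,simulated Data frames of trait records (rows = samples).
#' @param alpha Significance level on adjusted p-values.
#' @param var_equal Passed to [trait_ttest()].
#' @return An `evaluation_report`: tibble `traits` (`trait`, `raw_p`,
#'   `adjusted_p`, `misclassified`) plus `n_traits`, `n_misclassified`,
#'   `sensitivity_rate`.
#' @export
evaluate_traits <- function(observed, simulated, alpha = 0.05,
                            var_equal = FALSE) {
  num_obs <- dplyr::select(tibble::as_tibble(observed),
                           dplyr::where(is.numeric))
  num_sim <- dplyr::select(tibble::as_tibble(simulated),
                           dplyr::where(is.numeric))
  shared <- intersect(names(num_obs), names(num_sim))
  if (length(shared) == 0) stop("no shared trait columns", call. = FALSE)
  raw <- vapply(shared, function(tr) {
    trait_ttest(num_obs[[tr]], num_sim[[tr]], var_equal = var_equal)
  }, numeric(1))
  adj <- bonferroni_adjust(raw)
  mis <- adj < alpha
  traits <- tibble::tibble(trait = shared, raw_p = unname(raw),
                           adjusted_p = unname(adj),
                           misclassified = unname(mis))
  structure(list(traits = traits, n_traits = length(shared),
                 n_misclassified = sum(mis),
                 sensitivity_rate = sensitivity_rate(length(shared),
                                                     sum(mis)),
                 alpha = alpha),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "evaluation_report: %d/%d traits misclassified, sensitivity %.1f%%\n",
    x$n_misclassified, x$n_traits, x$sensitivity_rate))
  invisible(x)
}

#' @export
tidy.evaluation_report <- function(x, ...) x$traits

#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(n_traits = x$n_traits, n_misclassified = x$n_misclassified,
                 sensitivity_rate = x$sensitivity_rate, alpha = x$alpha)
}

#' @export
autoplot.evaluation_report <- function(object, ...) {
  ggplot2::ggplot(object$traits,
                  ggplot2::aes(x = stats::reorder(.data$trait,
                                                  .data$adjusted_p),
                               y = .data$adjusted_p,
                               fill = .data$misclassified)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$alpha, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Bonferroni-adjusted p") +
    ggplot2::theme_minimal()
}

#' Cross-validated evaluation of the parameterize-simulate-extract loop
#'
#' Runs the full evaluation workflow on an observed trait table: one random
#' k-fold split of the samples; for every train/test fold permutation the
#' training-fold records are summarized and converted to growth-model
#' parameters, one root system is simulated, rendered and re-extracted per
#' test-fold sample, and the simulated trait table is compared to the
#' test-fold observations ([evaluate_traits()]). Fold permutations that fail
#' in the pipeline are flagged and reported, never silently dropped.
#'
#' @param observed Trait table, one row per sample (plant/image).
#' @param config A `simulation_config` for the simulated outputs; its seed
#'   also drives the fold split.
#' @param t_days Observation-window length handed to [summarize_traits()].
#' @param orders Root orders to parameterize.
#' @param k,k_train Fold design.
#' @param alpha Significance level.
#' @param render_scale_mm_per_px Rendering resolution of simulated outputs.
#' @return A `cv_report`: tibble `iterations` (per permutation: counts,
#'   sensitivity, ok flag), `mean_misclassified`, `mean_sensitivity`, the
#'   fold plan and the per-permutation `evaluation_report`s.
#' @export
cross_validate <- function(observed, config, t_days, orders = 1:2,
                           k = 5, k_train = 3, alpha = 0.05,
                           render_scale_mm_per_px = 0.5) {
  observed <- tibble::as_tibble(observed)
  if (nrow(observed) == 0) stop("empty observed table", call. = FALSE)
  set.seed(config$seed)
  plan <- kfold_split(seq_len(nrow(observed)), k = k, k_train = k_train)
  reports <- vector("list", nrow(plan$permutations))
  rows <- vector("list", nrow(plan$permutations))
  for (j in seq_len(nrow(plan$permutations))) {
    train_ids <- plan$assignment$sample_id[
      plan$assignment$fold %in% plan$permutations$train_folds[[j]]]
    test_ids <- plan$assignment$sample_id[
      plan$assignment$fold %in% plan$permutations$test_folds[[j]]]
    res <- tryCatch({
      summ <- summarize_traits(observed[train_ids, ], t = t_days)
      params <- derive_parameter_table(summ, orders)
      sims <- lapply(seq_along(test_ids), function(s) {
        cfg <- config
        cfg$seed <- derive_seed(config$seed, j, s)
        sys <- simulate_root_system(params, cfg)
        measure_root_image(render_projection(
          sys, "xz", scale_mm_per_px = render_scale_mm_per_px))
      })
      sim_tbl <- dplyr::bind_rows(sims)
      evaluate_traits(observed[test_ids, ], sim_tbl, alpha = alpha)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      reports[[j]] <- NULL
      rows[[j]] <- tibble::tibble(permutation = j, ok = FALSE,
                                  n_traits = NA_integer_,
                                  n_misclassified = NA_integer_,
                                  sensitivity_rate = NA_real_,
                                  error = conditionMessage(res))
    } else {
      reports[[j]] <- res
      rows[[j]] <- tibble::tibble(permutation = j, ok = TRUE,
                                  n_traits = res$n_traits,
                                  n_misclassified = res$n_misclassified,
                                  sensitivity_rate = res$sensitivity_rate,
                                  error = NA_character_)
    }
  }
  iterations <- dplyr::bind_rows(rows)
  ok <- iterations$ok
  structure(list(
    iterations = iterations,
    mean_misclassified = mean(iterations$n_misclassified[ok]),
    mean_sensitivity = mean(iterations$sensitivity_rate[ok]),
    plan = plan, reports = reports, alpha = alpha
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "cv_report: %d permutations (%d ok), mean %.1f misclassified, mean sensitivity %.1f%%\n",
    nrow(x$iterations), sum(x$iterations$ok), x$mean_misclassified,
    x$mean_sensitivity))
  invisible(x)
}

#' @export
tidy.cv_report <- function(x, ...) x$iterations

#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(n_permutations = nrow(x$iterations),
                 n_ok = sum(x$iterations$ok),
                 mean_misclassified = x$mean_misclassified,
                 mean_sensitivity = x$mean_sensitivity,
                 alpha = x$alpha)
}

#' Write an evaluation report to CSV + JSON summary
#'
#' @param report An `evaluation_report`.
#' @param csv_path Per-trait CSV (trait, raw_p, adjusted_p, misclassified).
#' @param json_path Optional JSON summary path.
#' @export
write_evaluation_report <- function(report, csv_path, json_path = NULL) {
  readr::write_csv(report$traits, csv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(n_traits = report$n_traits,
           n_misclassified = report$n_misclassified,
           sensitivity_rate = report$sensitivity_rate,
           alpha = report$alpha),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
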