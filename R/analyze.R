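#' Run the full behavioral measurement pipeline
#'
#' Applies the complete analysis chain to a trial/trajectory/ratings dataset
#' (real or synthetic): derive difficulty and correctness, exclude
#' over-6-s outlier trials, compute per-trial trajectory conflict areas,
#' accuracy by group and by response-time category, cumulative
#' response-time distributions, irritation scores, and the group-level
#' statistics (one-way ANOVA with eta-squared and Holm-adjusted pairwise
#' comparisons for accuracy; rank-sum with Cliff's delta for irritation).
#'
#' @param trials Trial table (`participant_id`, `group`, `proportion`,
#'   `response`, `rt_s`, and `trial_id` if trajectories are supplied).
#' @param trajectories Optional long trajectory table (`participant_id`,
#'   `trial_id`, `t_s`, `x_px`, `y_px`).
#' @param ratings Optional ratings table (`participant_id`, `block`,
#'   `rating`).
#' @param rt_max Outlier threshold in seconds.
#' @return A list of class `rrsat_analysis`:
#'   \describe{
#'     \item{trials}{prepared, filtered trial tibble (with `rt_category`,
#'       and `auc_px2` when trajectories were supplied)}
#'     \item{accuracy_by_group}{per-participant accuracy by difficulty}
#'     \item{accuracy_by_category}{mean accuracy by group, difficulty and
#'       response-time category}
#'     \item{auc_by_category}{mean conflict area by group, difficulty and
#'       response-time category (or `NULL`)}
#'     \item{rt_cdf}{cumulative response-time distributions by group,
#'       difficulty and correctness}
#'     \item{irritation}{per-participant irritation scores (or `NULL`)}
#'     \item{stats}{list of `rrsat_group_test` objects: accuracy ANOVA per
#'       difficulty, and the irritation rank-sum when two waiting groups
#'       rated}
#'     \item{excluded_fraction}{fraction of trials dropped by the outlier
#'       rule}
#'   }
#' @export
analyze_dataset <- function(trials, trajectories = NULL, ratings = NULL,
                            rt_max = 6) {
  tr <- prepare_trials(trials)
  tr <- filter_trials(tr, rt_max = rt_max)
  excl <- excluded_fraction(tr)
  tr <- dplyr::mutate(tr, rt_category = rt_category(.data$rt_s))

  auc_tab <- NULL
  if (!is.null(trajectories)) {
    stopifnot("trial_id" %in% names(tr))
    aucs <- auc_by_trial(trajectories)
    tr <- dplyr::left_join(tr, aucs, by = c("participant_id", "trial_id"))
    auc_tab <- dplyr::summarise(
      dplyr::group_by(tr, .data$group, .data$difficulty, .data$rt_category),
      n = dplyr::n(),
      mean_auc = mean(.data$auc_px2, na.rm = TRUE),
      .groups = "drop"
    )
  }

  acc_group <- participant_accuracy(tr, .data$difficulty)
  # observed cells only: waiting-time lockout makes early response-time
  # categories structurally empty in the 1 s / 2.5 s groups
  acc_cat <- accuracy_by(tr, .data$group, .data$difficulty, .data$rt_category)
  cdf <- rt_cdf(tr, .data$group, .data$difficulty, .data$correct,
                rt_max = rt_max)

  stats <- list()
  for (d in levels(tr$difficulty)) {
    sub <- dplyr::filter(acc_group, .data$difficulty == d)
    if (dplyr::n_distinct(sub$group) >= 2 && all(table(sub$group) >= 2)) {
      stats[[paste0("accuracy_", d)]] <-
        group_compare(sub, .data$accuracy, .data$group, method = "anova")
    }
  }

  irr <- NULL
  if (!is.null(ratings) && nrow(ratings) > 0) {
    irr <- irritation_scores(ratings,
                             n_blocks = dplyr::n_distinct(ratings$block))
    rated <- dplyr::filter(irr, !.data$excluded)
    if ("group" %in% names(rated) && dplyr::n_distinct(rated$group) == 2 &&
        all(table(rated$group) >= 2)) {
      stats$irritation <-
        group_compare(rated, .data$irritation, .data$group, method = "ranksum")
    }
  }

  structure(
    list(
      trials = tr,
      accuracy_by_group = acc_group,
      accuracy_by_category = acc_cat,
      auc_by_category = auc_tab,
      rt_cdf = cdf,
      irritation = irr,
      stats = stats,
      excluded_fraction = excl
    ),
    class = "rrsat_analysis"
  )
}

#' @export
print.rrsat_analysis <- function(x, ...) {
  cat(sprintf("Grid-task analysis: %d trials kept (%.1f%% excluded as > 6 s)\n",
              nrow(x$trials), 100 * x$excluded_fraction))
  grp <- dplyr::summarise(
    dplyr::group_by(x$accuracy_by_group, .data$group, .data$difficulty),
    accuracy = mean(.data$accuracy), .groups = "drop"
  )
  print(tidyr::pivot_wider(grp, names_from = "difficulty",
                           values_from = "accuracy"))
  for (nm in names(x$stats)) {
    cat("\n[", nm, "] ", sep = "")
    print(x$stats[[nm]])
  }
  invisible(x)
}
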