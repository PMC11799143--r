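#' Derive difficulty and correctness for a trial table
#'
#' Adds the analysis columns the measurement pipeline expects: `difficulty`
#' (`"difficult"` for stimulus proportions 0.45/0.55, `"easy"` for
#' 0.35/0.65) and `correct` (`response == "yes"` iff the black proportion
#' exceeds 0.5).
#'
#' @param trials A data frame with columns `participant_id`, `group`,
#'   `proportion`, `response`, `rt_s`.
#' @return The trials as a tibble with `difficulty` (factor) and `correct`
#'   (logical) added.
#' @export
prepare_trials <- function(trials) {
  required <- c("participant_id", "group", "proportion", "response", "rt_s")
  missing <- setdiff(required, names(trials))
  if (length(missing) > 0) {
    stop("trials table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!all(trials$response %in% c("yes", "no"))) {
    stop("`response` must be \"yes\" or \"no\"")
  }
  if (any(trials$rt_s < 0)) stop("`rt_s` must be non-negative")
  dplyr::mutate(
    tibble::as_tibble(trials),
    difficulty = factor(
      ifelse(abs(.data$proportion - 0.5) < 0.075, "difficult", "easy"),
      levels = c("difficult", "easy")
    ),
    correct = (.data$response == "yes") == (.data$proportion > 0.5)
  )
}

#' Exclude slow-response outlier trials
#'
#' Drops trials whose response time is strictly over `rt_max` seconds and
#' records the excluded fraction as the `"excluded_fraction"` attribute
#' (retrievable with [excluded_fraction()]).
#'
#' @param trials A trial tibble with an `rt_s` column.
#' @param rt_max Exclusion threshold in seconds; trials with `rt_s > rt_max`
#'   are removed (exactly `rt_max` is kept).
#' @return The kept trials.
#' @examples
#' tr <- tibble::tibble(rt_s = c(5.9, 6, 6.1))
#' kept <- filter_trials(tr)
#' excluded_fraction(kept) # 1/3
#' @export
filter_trials <- function(trials, rt_max = 6) {
  stopifnot("rt_s" %in% names(trials), rt_max > 0)
  if (nrow(trials) == 0) {
    warning("empty trial table: excluded fraction is undefined")
    out <- tibble::as_tibble(trials)
    attr(out, "excluded_fraction") <- NA_real_
    return(out)
  }
  keep <- trials$rt_s <= rt_max
  out <- tibble::as_tibble(trials)[keep, , drop = FALSE]
  attr(out, "excluded_fraction") <- mean(!keep)
  out
}

#' @rdname filter_trials
#' @param x A tibble returned by [filter_trials()].
#' @export
excluded_fraction <- function(x) attr(x, "excluded_fraction")

#' Time-normalize one mouse trajectory
#'
#' Resamples a recorded cursor path to `n_points` positions at equal
#' fractions of the trial duration, interpolating x and y linearly and
#' independently. This puts trials of different durations on a common time
#' base; endpoints are preserved exactly.
#'
#' @param traj A data frame with columns `t_s`, `x_px`, `y_px`; at least two
#'   samples with strictly positive duration. Duplicate time stamps are
#'   averaged before interpolation.
#' @param n_points Number of output points (101 gives 100 equal time steps).
#' @return A tibble with columns `fraction`, `t_s`, `x_px`, `y_px` and
#'   `n_points` rows.
#' @export
time_normalize <- function(traj, n_points = 101) {
  stopifnot(all(c("t_s", "x_px", "y_px") %in% names(traj)), n_points >= 2)
  if (nrow(traj) < 2) stop("trajectory needs at least 2 samples")
  o <- order(traj$t_s)
  t <- traj$t_s[o]; x <- traj$x_px[o]; y <- traj$y_px[o]
  if (anyDuplicated(t)) {
    x <- tapply(x, t, mean); y <- tapply(y, t, mean); t <- unique(t)
  }
  if (length(t) < 2 || t[length(t)] <= t[1]) {
    stop("trajectory has zero duration")
  }
  fr <- seq(0, 1, length.out = n_points)
  tt <- t[1] + fr * (t[length(t)] - t[1])
  xn <- stats::approx(t, x, xout = tt)$y
  yn <- stats::approx(t, y, xout = tt)$y
  # pin endpoints against floating-point drift in tt
  xn[1] <- x[1]; yn[1] <- y[1]
  xn[n_points] <- x[length(x)]; yn[n_points] <- y[length(y)]
  tibble::tibble(fraction = fr, t_s = tt, x_px = xn, y_px = yn)
}

#' Signed area between a trajectory and the direct path
#'
#' Measures cognitive conflict as the area between the recorded cursor path
#' and the straight line from its first to its last point. The coordinates
#' are projected onto that line; the area is the trapezoidal integral of the
#' perpendicular deviation along the line, so excursions on one side and
#' overshoots on the other carry opposite signs and cancel.
#'
#' By default the counter-clockwise side of the start-to-end direction is
#' positive. Supplying `positive_toward` (e.g. the location of the button
#' that was *not* chosen) orients the sign so deviation toward that point is
#' positive, the usual mouse-tracking convention.
#'
#' @param traj A data frame with columns `x_px`, `y_px` (typically the
#'   output of [time_normalize()]); endpoints must be distinct.
#' @param positive_toward Optional `c(x, y)` point defining the positive
#'   side.
#' @return Signed area in squared pixels.
#' @examples
#' tri <- tibble::tibble(x_px = c(0, 1, 2), y_px = c(0, 1, 0))
#' traj_auc(tri) # 1
#' @export
traj_auc <- function(traj, positive_toward = NULL) {
  stopifnot(all(c("x_px", "y_px") %in% names(traj)))
  x <- traj$x_px; y <- traj$y_px
  n <- length(x)
  stopifnot(n >= 2)
  dx <- x[n] - x[1]; dy <- y[n] - y[1]
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) stop("start and end points coincide: direct path undefined")
  ux <- dx / len; uy <- dy / len
  s <- (x - x[1]) * ux + (y - y[1]) * uy      # along the direct path
  h <- -(x - x[1]) * uy + (y - y[1]) * ux     # perpendicular deviation
  area <- sum(diff(s) * (h[-n] + h[-1]) / 2)
  if (!is.null(positive_toward)) {
    side <- -(positive_toward[1] - x[1]) * uy + (positive_toward[2] - y[1]) * ux
    if (side < 0) area <- -area
  }
  area
}

#' Per-trial trajectory areas for a long trajectory table
#'
#' Time-normalizes every trial's trajectory and computes its signed area
#' ([traj_auc()]). The positive side is oriented toward the mirror image of
#' the trajectory endpoint across the vertical line through its start, i.e.
#' toward the unchosen button in a symmetric two-button layout.
#'
#' @param trajectories Long table with columns `participant_id`, `trial_id`,
#'   `t_s`, `x_px`, `y_px`.
#' @param n_points Points for time normalization.
#' @return A tibble with one row per (participant_id, trial_id): `auc_px2`.
#' @export
auc_by_trial <- function(trajectories, n_points = 101) {
  required <- c("participant_id", "trial_id", "t_s", "x_px", "y_px")
  missing <- setdiff(required, names(trajectories))
  if (length(missing) > 0) {
    stop("trajectories table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  key <- paste(trajectories$participant_id, trajectories$trial_id, sep = "\r")
  idx <- split(seq_len(nrow(trajectories)), key)
  t_all <- trajectories$t_s; x_all <- trajectories$x_px; y_all <- trajectories$y_px
  fr <- seq(0, 1, length.out = n_points)
  auc <- vapply(idx, function(ii) {
    t <- t_all[ii]; x <- x_all[ii]; y <- y_all[ii]
    m <- length(ii)
    tt <- t[1] + fr * (t[m] - t[1])
    xn <- stats::approx(t, x, xout = tt, ties = "ordered")$y
    yn <- stats::approx(t, y, xout = tt, ties = "ordered")$y
    xn[1] <- x[1]; yn[1] <- y[1]; xn[n_points] <- x[m]; yn[n_points] <- y[m]
    mirror <- c(2 * xn[1] - xn[n_points], yn[n_points])
    traj_auc(list(x_px = xn, y_px = yn), positive_toward = mirror)
  }, numeric(1))
  first <- vapply(idx, `[`, integer(1), 1L)
  tibble::tibble(
    participant_id = trajectories$participant_id[first],
    trial_id = trajectories$trial_id[first],
    auc_px2 = unname(auc)
  )
}

rt_category_labels <- c("~1.0 s", "1.0-2.5 s", "2.5-4.0 s", "4.0 s ~")

#' Categorize response times
#'
#' Bins post-filter response times into the four analysis categories:
#' \[0, 1.0), \[1.0, 2.5), \[2.5, 4.0) and \[4.0, 6.0\] seconds.
#'
#' @param rt Response times in seconds, each in (0, 6\]; apply
#'   [filter_trials()] first.
#' @return An ordered factor with levels `r paste(rt_category_labels,
#'   collapse = ", ")`.
#' @examples
#' rt_category(c(0.8, 2.5, 6))
#' @export
rt_category <- function(rt) {
  if (any(rt > 6)) {
    stop("response times over 6 s present: filter outlier trials first")
  }
  if (any(rt <= 0)) stop("response times must be positive")
  i <- findInterval(rt, c(1.0, 2.5, 4.0)) + 1L
  factor(rt_category_labels[i], levels = rt_category_labels, ordered = TRUE)
}

#' Mean accuracy by grouping variables
#'
#' Per-cell trial counts and mean correctness for any grouping of the trial
#' table (e.g. group, difficulty, response-time category, participant).
#'
#' @param trials A prepared, filtered trial tibble with a logical `correct`
#'   column.
#' @param ... Grouping columns (tidy-select style, unquoted).
#' @param complete If `TRUE`, include every crossing of the grouping
#'   variables' observed levels; empty cells get `n = 0`, `accuracy = NA`,
#'   with a warning.
#' @return A tibble with the grouping columns plus `n` and `accuracy`.
#' @export
accuracy_by <- function(trials, ..., complete = FALSE) {
  stopifnot("correct" %in% names(trials))
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(trials), ...),
    n = dplyr::n(),
    accuracy = mean(.data$correct),
    .groups = "drop"
  )
  if (complete) {
    keys <- setdiff(names(out), c("n", "accuracy"))
    out <- tidyr::complete(
      out, !!!rlang::syms(keys),
      fill = list(n = 0L, accuracy = NA_real_)
    )
    if (any(out$n == 0)) {
      warning(sum(out$n == 0), " empty cell(s): accuracy undefined there")
    }
  }
  out
}

#' Per-participant judgment accuracy
#'
#' The rate of correct judgments for each participant, optionally split by
#' further variables (usually `difficulty`); the unit of analysis for group
#' comparisons.
#'
#' @inheritParams accuracy_by
#' @return A tibble with `participant_id`, `group`, any extra grouping
#'   columns, `n` and `accuracy`.
#' @export
participant_accuracy <- function(trials, ...) {
  accuracy_by(trials, .data$participant_id, .data$group, ...)
}

#' Cumulative response-time distributions
#'
#' Cumulative fraction of trials with `rt_s` at or below each bin edge,
#' separately within each stratum. Bins are `(k*bin, (k+1)*bin]` over
#' (0, `rt_max`\]; the curve is non-decreasing and ends at 1 in every
#' non-empty stratum.
#'
#' @param trials A prepared, filtered trial tibble.
#' @param ... Stratifying columns (default behavior-analysis strata are
#'   `group`, `difficulty`, `correct`; pass them explicitly).
#' @param bin Bin width in seconds.
#' @param rt_max Upper end of the binning range.
#' @return A tibble with the strata columns plus `edge` (bin upper edge) and
#'   `cum_prob`.
#' @examples
#' tr <- tibble::tibble(g = "a", rt_s = c(0.05, 0.15, 0.15))
#' rt_cdf(tr, g)[1:2, ]
#' @export
rt_cdf <- function(trials, ..., bin = 0.1, rt_max = 6) {
  stopifnot("rt_s" %in% names(trials), bin > 0)
  if (any(trials$rt_s > rt_max)) {
    stop("response times over ", rt_max, " s present: filter first")
  }
  edges <- seq(bin, rt_max, by = bin)
  grouped <- dplyr::group_by(tibble::as_tibble(trials), ...)
  dplyr::reframe(
    grouped,
    edge = edges,
    cum_prob = vapply(edges, function(e) mean(.data$rt_s <= e), numeric(1))
  )
}

#' Irritation scores from per-block ratings
#'
#' A participant's irritation is the maximum of their nine per-block
#' visual-analog ratings (0-100). Participants who rated 0 in every block
#' are flagged as excluded (treated as non-responses).
#'
#' @param ratings Long table with columns `participant_id`, `block`,
#'   `rating` (and optionally `group`, carried through).
#' @param n_blocks Required number of ratings per participant.
#' @return A tibble with one row per participant: `irritation` and a logical
#'   `excluded` flag.
#' @examples
#' r <- tibble::tibble(participant_id = "p1", block = 1:9,
#'                     rating = c(10, 50, 20, 0, 0, 0, 0, 0, 30))
#' irritation_scores(r)
#' @export
irritation_scores <- function(ratings, n_blocks = 9) {
  required <- c("participant_id", "block", "rating")
  missing <- setdiff(required, names(ratings))
  if (length(missing) > 0) {
    stop("ratings table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (any(ratings$rating < 0 | ratings$rating > 100)) {
    stop("ratings must lie in [0, 100]")
  }
  keys <- intersect(c("participant_id", "group"), names(ratings))
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(ratings),
                    dplyr::across(dplyr::all_of(keys))),
    n_blocks_seen = dplyr::n(),
    irritation = max(.data$rating),
    .groups = "drop"
  )
  if (any(out$n_blocks_seen != n_blocks)) {
    bad <- out$participant_id[out$n_blocks_seen != n_blocks]
    stop("participant(s) without exactly ", n_blocks, " ratings: ",
         paste(bad, collapse = ", "))
  }
  dplyr::mutate(dplyr::select(out, -"n_blocks_seen"),
                excluded = .data$irritation == 0)
}

#' Cliff's delta effect size
#'
#' Dominance effect size for two samples: the probability that a value from
#' `x` exceeds one from `y`, minus the reverse, over all pairs.
#'
#' @param x,y Non-empty numeric samples.
#' @return A number in \[-1, 1\].
#' @examples
#' cliffs_delta(c(3, 4, 5), c(1, 2)) # 1
#' cliffs_delta(c(1, 3), c(2, 4)) # -0.5
#' @export
cliffs_delta <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("samples must be non-empty")
  d <- sign(outer(x, y, `-`))
  mean(d)
}

#' Holm step-down p-value adjustment
#'
#' The step-down multiple-comparison correction: sort the p-values, multiply
#' the i-th smallest of m by (m - i + 1), enforce monotonicity with a running
#' maximum, cap at 1, and return in the original order.
#'
#' @param p P-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03)) # 0.03 0.06 0.06
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- pmin(1, cummax(p[o] * (m - seq_len(m) + 1)))
  adj[order(o)]
}

#' Compare per-participant values between groups
#'
#' Group comparison used for both thinking-benefit and thinking-cost
#' analyses. `method = "anova"` runs a one-way ANOVA (delegated to
#' [stats::aov()]) with eta-squared (between-group over total sum of
#' squares) and Holm-adjusted pairwise pooled-SD t-tests. `method =
#' "ranksum"` (two groups) runs a Mann-Whitney/Wilcoxon rank-sum test
#' (delegated to [stats::wilcox.test()]) with Cliff's delta.
#'
#' @param data A data frame of per-participant values.
#' @param value,group Unquoted column names of the response and the grouping
#'   factor.
#' @param method `"anova"` or `"ranksum"`.
#' @return An object of class `rrsat_group_test`; see [tidy.rrsat_group_test()]
#'   and [glance.rrsat_group_test()].
#' @examples
#' d <- tibble::tibble(g = rep(c("a", "b"), each = 2), v = c(1, 2, 3, 4))
#' glance(group_compare(d, v, g))
#' @export
group_compare <- function(data, value, group, method = c("anova", "ranksum")) {
  method <- match.arg(method)
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs at least 2 values")
  lev <- levels(g)
  if (method == "anova") {
    fit <- stats::aov(v ~ g)
    an <- stats::anova(fit)
    ss_between <- an$`Sum Sq`[1]
    ss_total <- sum(an$`Sum Sq`)
    pairs <- utils::combn(lev, 2, simplify = FALSE)
    sd_pooled <- sqrt(an$`Mean Sq`[2])
    df_resid <- an$Df[2]
    raw_p <- vapply(pairs, function(pr) {
      m <- tapply(v, g, mean)[pr]
      n <- table(g)[pr]
      tstat <- (m[1] - m[2]) / (sd_pooled * sqrt(1 / n[1] + 1 / n[2]))
      2 * stats::pt(-abs(tstat), df_resid)
    }, numeric(1))
    pairwise <- tibble::tibble(
      group1 = vapply(pairs, `[`, character(1), 1),
      group2 = vapply(pairs, `[`, character(1), 2),
      p_value = raw_p,
      p_adjusted = holm_adjust(raw_p)
    )
    out <- list(
      method = "anova",
      statistic = an$`F value`[1],
      df = c(an$Df[1], an$Df[2]),
      p_value = an$`Pr(>F)`[1],
      effect_size = ss_between / ss_total,
      effect_size_type = "eta_squared",
      pairwise = pairwise,
      groups = lev
    )
  } else {
    if (nlevels(g) != 2) stop("ranksum comparison needs exactly 2 groups")
    x <- v[g == lev[1]]; y <- v[g == lev[2]]
    wt <- stats::wilcox.test(x, y, exact = FALSE)
    out <- list(
      method = "ranksum",
      statistic = unname(wt$statistic),
      df = NULL,
      p_value = wt$p.value,
      effect_size = cliffs_delta(x, y),
      effect_size_type = "cliffs_delta",
      pairwise = NULL,
      groups = lev
    )
  }
  structure(out, class = "rrsat_group_test")
}

#' @export
print.rrsat_group_test <- function(x, ...) {
  if (x$method == "anova") {
    cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g, eta^2 = %.3f\n",
                x$df[1], x$df[2], x$statistic, x$p_value, x$effect_size))
    cat("Holm-adjusted pairwise comparisons:\n")
    print(x$pairwise)
  } else {
    cat(sprintf(
      "Mann-Whitney rank-sum (%s vs %s): W = %.1f, p = %.4g, Cliff's delta = %.3f\n",
      x$groups[1], x$groups[2], x$statistic, x$p_value, x$effect_size))
  }
  invisible(x)
}

#' Tidy a group comparison
#'
#' @param x An `rrsat_group_test`.
#' @param ... Unused.
#' @return For ANOVA, the Holm-adjusted pairwise table; for rank-sum, a
#'   one-row tibble with the test statistic.
#' @export
tidy.rrsat_group_test <- function(x, ...) {
  if (x$method == "anova") {
    x$pairwise
  } else {
    tibble::tibble(group1 = x$groups[1], group2 = x$groups[2],
                   statistic = x$statistic, p_value = x$p_value,
                   cliffs_delta = x$effect_size)
  }
}

#' Glance at a group comparison
#'
#' @param x An `rrsat_group_test`.
#' @param ... Unused.
#' @return A one-row tibble with the omnibus statistic, p-value and effect
#'   size.
#' @export
glance.rrsat_group_test <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    statistic = x$statistic,
    df1 = if (is.null(x$df)) NA_integer_ else x$df[1],
    df2 = if (is.null(x$df)) NA_integer_ else x$df[2],
    p_value = x$p_value,
    effect_size = x$effect_size,
    effect_size_type = x$effect_size_type
  )
}
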