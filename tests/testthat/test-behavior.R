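test_that("outlier filtering is strict at 6 s and reports the excluded fraction", {
  kept <- filter_trials(make_trials(c(5.9, 6.0, 6.1)))
  expect_equal(kept$rt_s, c(5.9, 6.0))
  expect_equal(excluded_fraction(kept), 1 / 3)

  all_in <- filter_trials(make_trials(c(0.5, 2, 6)))
  expect_identical(nrow(all_in), 3L)
  expect_equal(excluded_fraction(all_in), 0)

  set.seed(8)
  rts <- c(runif(979, 0.2, 5.8), runif(21, 6.01, 9))
  big <- filter_trials(make_trials(sample(rts)))
  expect_equal(excluded_fraction(big), 0.021)

  expect_warning(empty <- filter_trials(make_trials(numeric(0))), "empty")
  expect_true(is.na(excluded_fraction(empty)))
})

test_that("trial preparation derives difficulty and correctness", {
  tr <- tibble::tibble(
    participant_id = "p", group = "0s",
    proportion = c(0.35, 0.45, 0.55, 0.65),
    response = c("no", "yes", "yes", "no"),
    rt_s = 1
  )
  out <- prepare_trials(tr)
  expect_equal(as.character(out$difficulty),
               c("easy", "difficult", "difficult", "easy"))
  expect_equal(out$correct, c(TRUE, FALSE, TRUE, FALSE))
  expect_error(prepare_trials(dplyr::select(tr, -"response")), "response")
})

test_that("time normalization interpolates linearly and preserves endpoints", {
  seg <- tibble::tibble(t_s = c(0, 1), x_px = c(0, 100), y_px = c(0, 200))
  out <- time_normalize(seg)
  expect_identical(nrow(out), 101L)
  expect_equal(out$x_px, seq(0, 100, by = 1))
  expect_equal(out$y_px, 2 * out$x_px)

  # already-normalized input is a fixed point
  again <- time_normalize(out)
  expect_equal(again$x_px, out$x_px)
  expect_equal(again$y_px, out$y_px)

  # piecewise-linear case checked by hand: x holds 10 after t = 0.2
  pw <- tibble::tibble(t_s = c(0, 0.2, 1), x_px = c(0, 10, 10), y_px = 0)
  n <- time_normalize(pw)
  expect_equal(n$x_px[abs(n$fraction - 0.5) < 1e-9], 10)
  expect_equal(n$x_px[abs(n$fraction - 0.1) < 1e-9], 5)

  expect_error(time_normalize(seg[1, ]), "2 samples")
  expect_error(
    time_normalize(tibble::tibble(t_s = c(1, 1), x_px = 0:1, y_px = 0:1)),
    "duration"
  )
})

test_that("trajectory area matches hand geometry and signed conventions", {
  # straight path deviates nowhere
  straight <- tibble::tibble(x_px = seq(0, 10, length.out = 101),
                             y_px = seq(0, -5, length.out = 101))
  expect_equal(traj_auc(straight), 0, tolerance = 1e-12)

  # unit-height triangle over a base of 2 has area 1
  u <- seq(0, 1, length.out = 101)
  tri <- tibble::tibble(x_px = 2 * u, y_px = 1 - abs(2 * u - 1))
  expect_equal(traj_auc(tri), 1, tolerance = 1e-12)

  # mirror-symmetric halves cancel exactly
  sym <- tibble::tibble(x_px = 2 * u, y_px = sin(2 * pi * u))
  expect_equal(traj_auc(sym), 0, tolerance = 1e-12)

  # the positive side can be oriented toward a reference point
  expect_equal(traj_auc(tri, positive_toward = c(1, -5)), -1,
               tolerance = 1e-12)
  expect_error(traj_auc(tibble::tibble(x_px = c(1, 1), y_px = c(2, 2))),
               "coincide")
})

test_that("trajectory area agrees with the shoelace polygon oracle", {
  set.seed(14)
  for (i in 1:100) {
    tr <- random_trajectory(sample(5:50, 1))
    # the closed path returns to the start along the direct line, so the
    # enclosed shoelace area equals minus the deviation integral
    expect_equal(traj_auc(tr), -shoelace_area(tr$x_px, tr$y_px),
                 tolerance = 1e-6)
  }
})

test_that("trajectory area is rigid-motion invariant and scales quadratically", {
  set.seed(15)
  tr <- random_trajectory(40)
  a0 <- traj_auc(tr)
  for (theta in c(0.3, 1.7, -2.5)) {
    moved <- rotate_translate(tr, theta, dx = 123.4, dy = -56.7)
    expect_equal(traj_auc(moved), a0, tolerance = 1e-9)
  }
  scaled <- tibble::tibble(x_px = 3 * tr$x_px, y_px = 3 * tr$y_px)
  expect_equal(traj_auc(scaled), 9 * a0, tolerance = 1e-9)
})

test_that("response-time categories use right-open bins with a closed top", {
  expect_equal(as.character(rt_category(c(0.8, 1.0, 2.5, 4.0, 6.0))),
               c("~1.0 s", "1.0-2.5 s", "2.5-4.0 s", "4.0 s ~", "4.0 s ~"))
  expect_true(is.ordered(rt_category(1)))
  expect_error(rt_category(6.1), "filter")
  expect_error(rt_category(0), "positive")
})

test_that("accuracy tables count and average correctly, flagging empty cells", {
  tr <- prepare_trials(make_trials(
    rt_s = rep(1, 4), proportion = 0.55,
    response = c("yes", "yes", "yes", "no")
  ))
  out <- accuracy_by(tr, group)
  expect_equal(out$n, 4L)
  expect_equal(out$accuracy, 0.75)

  easy <- prepare_trials(make_trials(rep(1, 10), proportion = 0.65,
                                     response = "yes"))
  expect_equal(accuracy_by(easy, group)$accuracy, 1)

  # a requested crossing with no trials is completed and flagged
  two <- prepare_trials(tibble::tibble(
    participant_id = "p", group = c("0s", "1s"),
    proportion = c(0.55, 0.65), response = "yes", rt_s = 1
  ))
  expect_warning(full <- accuracy_by(two, group, difficulty, complete = TRUE),
                 "empty")
  expect_identical(nrow(full), 4L)
  expect_true(any(full$n == 0 & is.na(full$accuracy)))
})

test_that("cumulative RT distributions match hand counts and normalize", {
  tr <- make_trials(c(0.05, 0.15, 0.15))
  cdf <- rt_cdf(tr, group)
  expect_equal(cdf$cum_prob[cdf$edge == 0.1], 1 / 3)
  expect_equal(cdf$cum_prob[abs(cdf$edge - 0.2) < 1e-9], 1)

  set.seed(21)
  many <- make_trials(runif(500, 0.1, 5.9),
                      participant_id = sample(c("a", "b"), 500, TRUE))
  cdf2 <- rt_cdf(many, participant_id)
  for (p in c("a", "b")) {
    v <- cdf2$cum_prob[cdf2$participant_id == p]
    expect_true(all(diff(v) >= 0))
    expect_equal(v[length(v)], 1)
  }
  expect_error(rt_cdf(make_trials(7), group), "over 6")
})

test_that("irritation is the maximum block rating; all-zero raters are flagged", {
  r <- tibble::tibble(
    participant_id = rep(c("p1", "p2", "p3"), each = 9),
    block = rep(1:9, 3),
    rating = c(
      c(10, 50, 20, 0, 0, 0, 0, 0, 30),
      rep(0, 9),
      rep(100, 9)
    )
  )
  out <- irritation_scores(r)
  expect_equal(out$irritation[out$participant_id == "p1"], 50)
  expect_true(out$excluded[out$participant_id == "p2"])
  expect_equal(out$irritation[out$participant_id == "p3"], 100)
  expect_error(irritation_scores(r[1:8, ]), "exactly 9")
  r$rating[1] <- 101
  expect_error(irritation_scores(r), "0, 100")
})

test_that("Cliff's delta matches enumerated pairs and is antisymmetric", {
  expect_identical(cliffs_delta(c(3, 4, 5), c(1, 2)), 1)
  expect_identical(cliffs_delta(1:3, 1:3), 0)
  expect_identical(cliffs_delta(c(1, 3), c(2, 4)), -0.5)
  expect_error(cliffs_delta(numeric(0), 1), "non-empty")
  set.seed(4)
  for (i in 1:20) {
    x <- sample(0:10, 7, replace = TRUE)
    y <- sample(0:10, 5, replace = TRUE)
    d <- cliffs_delta(x, y)
    expect_identical(d, -cliffs_delta(y, x))
    expect_true(d >= -1 && d <= 1)
  }
})

test_that("Holm adjustment matches the hand-computed step-down procedure", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(0.5, 0.9)), c(1, 1))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # cross-check against the reference routine on random inputs
  set.seed(9)
  for (i in 1:25) {
    p <- runif(sample(1:8, 1))
    expect_equal(holm_adjust(p), p.adjust(p, method = "holm"))
    expect_true(all(holm_adjust(p) >= p))
  }
})

test_that("group comparison reproduces hand sums of squares and delegates tests", {
  d <- tibble::tibble(g = rep(c("a", "b"), each = 2), v = c(1, 2, 3, 4))
  res <- group_compare(d, v, g)
  # SS_between = 4, SS_total = 5
  expect_equal(res$effect_size, 0.8)
  fit <- anova(aov(v ~ g, data = d))
  expect_equal(res$statistic, fit$`F value`[1])
  expect_equal(res$p_value, fit$`Pr(>F)`[1])
  expect_equal(glance(res)$effect_size, 0.8)

  # identical groups carry no between-group variance
  same <- tibble::tibble(g = rep(c("a", "b", "c"), each = 4),
                         v = rep(c(1, 2, 3, 4), 3))
  res0 <- group_compare(same, v, g)
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  expect_equal(res0$effect_size, 0, tolerance = 1e-12)
  expect_true(all(res0$pairwise$p_adjusted == 1))

  # rank-sum route: complete separation gives |delta| = 1 and the W of the
  # reference implementation
  sep <- tibble::tibble(g = rep(c("lo", "hi"), each = 3),
                        v = c(1, 2, 3, 4, 5, 6))
  rs <- group_compare(sep, v, g, method = "ranksum")
  wt <- wilcox.test(c(4, 5, 6), c(1, 2, 3), exact = FALSE)
  expect_equal(abs(rs$effect_size), 1)
  expect_equal(rs$statistic, unname(wt$statistic))
  expect_identical(nrow(tidy(rs)), 1L)

  expect_error(group_compare(d[1:2, ], v, g), "2 groups")
})

test_that("pairwise comparisons use pooled-SD t tests with Holm ordering", {
  set.seed(33)
  d <- tibble::tibble(
    g = rep(c("a", "b", "c"), each = 10),
    v = rnorm(30) + rep(c(0, 0.8, 1), each = 10)
  )
  res <- group_compare(d, v, g)
  ref <- pairwise.t.test(d$v, d$g, p.adjust.method = "none")$p.value
  expect_equal(res$pairwise$p_value[1], ref["b", "a"])
  expect_equal(res$pairwise$p_value[2], ref["c", "a"])
  expect_equal(res$pairwise$p_value[3], ref["c", "b"])
  expect_equal(res$pairwise$p_adjusted,
               unname(p.adjust(res$pairwise$p_value, "holm")))
})
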