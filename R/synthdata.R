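#' Configure the synthetic behavioral dataset generator
#'
#' Parameters of a simulated three-group waiting-time experiment on the grid
#' task: three between-participant groups (0 s, 1 s, 2.5 s enforced waiting
#' before the response buttons appear), four stimulus proportions presented
#' equally often over 9 blocks of 40 trials, group- and difficulty-dependent
#' accuracy, response times shifted by the waiting time, cursor trajectories
#' whose conflict area grows with response time, and 9 per-block irritation
#' ratings per participant in the waiting groups.
#'
#' Default accuracy targets are the group means observed in the behavioral
#' experiment the generator emulates (difficult: 0.67/0.75/0.78; easy:
#' 0.91/0.99/0.99 for the 0 s/1 s/2.5 s groups), and the default irritation
#' locations (29 vs 42) match the reported 1 s and 2.5 s group means.
#'
#' @param n_per_group Participants per group.
#' @param blocks,trials_per_block Block structure (9 x 40 = 360 trials per
#'   participant).
#' @param proportions Stimulus black proportions, cycled equally often.
#' @param group_wait Named waiting times (s) defining the groups.
#' @param accuracy_difficult,accuracy_easy Named per-group probabilities of
#'   a correct response for difficult (0.45/0.55) and easy (0.35/0.65)
#'   stimuli.
#' @param rt_meanlog,rt_sdlog Log-normal parameters of the decision time
#'   added to the group's waiting time.
#' @param outlier_rate Fraction of trials given a response time over 6 s
#'   (slow outliers the analysis pipeline must exclude).
#' @param auc_slope Trajectory conflict area per second of response time
#'   (px^2/s).
#' @param auc_noise_sd SD of trial-level noise on the conflict area (px^2).
#' @param irritation_mean,irritation_sd Location/scale of the per-participant
#'   latent irritation (0-100 visual-analog scale) in the waiting groups.
#' @param p_zero_rater Probability a waiting-group participant rates 0 in
#'   every block (an inappropriate responder the pipeline must drop).
#' @param jitter_sd Gaussian positional jitter on interior trajectory
#'   samples (px).
#' @param sample_rate Cursor sampling rate (samples/s).
#' @param button_x,button_y Button locations at (+-`button_x`, `button_y`)
#'   px relative to the screen-centre start.
#' @param seed Integer seed; the whole dataset is a pure function of the
#'   config.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_per_group = 40L,
                         blocks = 9L,
                         trials_per_block = 40L,
                         proportions = c(0.35, 0.45, 0.55, 0.65),
                         group_wait = c("0s" = 0, "1s" = 1, "2.5s" = 2.5),
                         accuracy_difficult = c("0s" = 0.67, "1s" = 0.75, "2.5s" = 0.78),
                         accuracy_easy = c("0s" = 0.91, "1s" = 0.99, "2.5s" = 0.99),
                         rt_meanlog = log(0.9),
                         rt_sdlog = 0.55,
                         outlier_rate = 0.021,
                         auc_slope = 30,
                         auc_noise_sd = 15,
                         irritation_mean = c("1s" = 29, "2.5s" = 42),
                         irritation_sd = 20,
                         p_zero_rater = 0.05,
                         jitter_sd = 2,
                         sample_rate = 60,
                         button_x = 300,
                         button_y = -200,
                         seed = 1L) {
  stopifnot(
    n_per_group >= 1, blocks >= 1, trials_per_block >= 1,
    all(proportions > 0 & proportions < 1),
    (blocks * trials_per_block) %% length(proportions) == 0,
    all(group_wait >= 0), !is.null(names(group_wait)),
    all(accuracy_difficult >= 0 & accuracy_difficult <= 1),
    all(accuracy_easy >= 0 & accuracy_easy <= 1),
    setequal(names(accuracy_difficult), names(group_wait)),
    setequal(names(accuracy_easy), names(group_wait)),
    rt_sdlog > 0, outlier_rate >= 0, outlier_rate < 1,
    auc_slope >= 0, auc_noise_sd >= 0,
    all(irritation_mean >= 0 & irritation_mean <= 100), irritation_sd > 0,
    p_zero_rater >= 0, p_zero_rater < 1,
    jitter_sd >= 0, sample_rate > 0, button_x != 0,
    is.numeric(seed), length(seed) == 1
  )
  structure(
    list(
      n_per_group = as.integer(n_per_group), blocks = as.integer(blocks),
      trials_per_block = as.integer(trials_per_block),
      proportions = proportions, group_wait = group_wait,
      accuracy_difficult = accuracy_difficult, accuracy_easy = accuracy_easy,
      rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
      outlier_rate = outlier_rate, auc_slope = auc_slope,
      auc_noise_sd = auc_noise_sd, irritation_mean = irritation_mean,
      irritation_sd = irritation_sd, p_zero_rater = p_zero_rater,
      jitter_sd = jitter_sd, sample_rate = sample_rate,
      button_x = button_x, button_y = button_y, seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' Generate one cursor trajectory with a known conflict area
#'
#' Builds a path from the screen centre to the chosen button as the straight
#' line plus a half-sine perpendicular excursion toward the unchosen button,
#' scaled so the signed area between path and direct line equals `conflict`
#' (up to sampling discretization and jitter). This gives the tests an
#' analytically known area oracle rather than a cognitively realistic
#' movement model.
#'
#' @param rt Trial duration in seconds (> 0).
#' @param conflict Target area in px^2 (>= 0).
#' @param chosen_side `"left"` or `"right"` button.
#' @param sample_rate Samples per second.
#' @param jitter_sd Positional jitter SD on interior samples (px); endpoints
#'   stay exact.
#' @param button_x,button_y Button geometry as in [synth_config()].
#' @return A tibble with columns `t_s`, `x_px`, `y_px` starting at (0, 0)
#'   and ending at the chosen button.
#' @export
generate_trajectory <- function(rt, conflict, chosen_side = c("right", "left"),
                                sample_rate = 60, jitter_sd = 0,
                                button_x = 300, button_y = -200) {
  chosen_side <- match.arg(chosen_side)
  stopifnot(rt > 0, conflict >= 0)
  sx <- if (chosen_side == "right") 1 else -1
  ex <- sx * button_x; ey <- button_y
  len <- sqrt(ex^2 + ey^2)
  # unit normal (counter-clockwise of travel direction)
  nx <- -ey / len; ny <- ex / len
  # side of the unchosen button relative to the direct path
  side <- sign((-ex - 0) * nx + (ey - 0) * ny)
  if (side == 0) side <- 1
  amp <- side * conflict * pi / (2 * len)
  n <- max(2L, as.integer(ceiling(rt * sample_rate)) + 1L)
  u <- seq(0, 1, length.out = n)
  x <- u * ex + amp * sin(pi * u) * nx
  y <- u * ey + amp * sin(pi * u) * ny
  if (jitter_sd > 0 && n > 2) {
    mid <- 2:(n - 1)
    x[mid] <- x[mid] + stats::rnorm(n - 2, 0, jitter_sd)
    y[mid] <- y[mid] + stats::rnorm(n - 2, 0, jitter_sd)
  }
  tibble::tibble(t_s = u * rt, x_px = x, y_px = y)
}

#' Generate a black-and-white grid stimulus
#'
#' A `rows` x `cols` binary matrix with exactly `round(proportion * rows *
#' cols)` black (1) tiles placed uniformly at random.
#'
#' @param proportion Black-tile proportion in \[0, 1\].
#' @param rows,cols Grid dimensions.
#' @return An integer matrix of 0s and 1s.
#' @examples
#' sum(generate_grid_stimulus(0.55)) # 1375 of 2500
#' @export
generate_grid_stimulus <- function(proportion, rows = 50, cols = 50) {
  stopifnot(proportion >= 0, proportion <= 1, rows >= 1, cols >= 1)
  n <- rows * cols
  k <- round(proportion * n)
  g <- integer(n)
  g[sample.int(n, k)] <- 1L
  matrix(g, nrow = rows, ncol = cols)
}

#' Generate a synthetic behavioral dataset
#'
#' Produces the three tables the measurement pipeline consumes: `trials`
#' (one row per response), `trajectories` (long cursor samples) and
#' `ratings` (9 per-block irritation ratings per waiting-group participant).
#' Response times are the group's waiting time plus a log-normal decision
#' time, with a small fraction inflated past 6 s as slow outliers;
#' correctness is Bernoulli at the group x difficulty accuracy target;
#' trajectory conflict area grows linearly with response time. The output is
#' a pure function of the config (per-participant seeds are derived from
#' `config$seed` by a counter scheme).
#'
#' @param config A [synth_config()].
#' @return A list of class `rrsat_synth` with tibbles `trials`,
#'   `trajectories`, `ratings`; the config is attached as an attribute.
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  groups <- names(config$group_wait)
  n_trials <- config$blocks * config$trials_per_block
  reps <- n_trials / length(config$proportions)
  pid_width <- nchar(as.character(config$n_per_group * length(groups)))
  trial_list <- list()
  traj_list <- list()
  rating_list <- list()
  pnum <- 0L
  for (gi in seq_along(groups)) {
    grp <- groups[gi]
    wait <- config$group_wait[[grp]]
    for (j in seq_len(config$n_per_group)) {
      pnum <- pnum + 1L
      pid <- sprintf(paste0("P%0", pid_width, "d"), pnum)
      set.seed(individual_seed(config$seed, pnum))
      prop <- sample(rep(config$proportions, reps))
      difficult <- abs(prop - 0.5) < 0.075
      acc <- ifelse(difficult,
                    config$accuracy_difficult[[grp]],
                    config$accuracy_easy[[grp]])
      correct <- stats::runif(n_trials) < acc
      response <- ifelse((prop > 0.5) == correct, "yes", "no")
      rt <- wait + stats::rlnorm(n_trials, config$rt_meanlog, config$rt_sdlog)
      slow <- stats::runif(n_trials) < config$outlier_rate
      rt[slow] <- 6 + 0.05 + stats::rexp(sum(slow), rate = 2)
      conflict <- pmax(0, config$auc_slope * rt +
                         stats::rnorm(n_trials, 0, config$auc_noise_sd))
      side <- ifelse(response == "yes", "right", "left")
      trial_list[[pnum]] <- tibble::tibble(
        participant_id = pid, group = grp,
        block = rep(seq_len(config$blocks), each = config$trials_per_block),
        trial_id = seq_len(n_trials), proportion = prop,
        response = response, rt_s = rt
      )
      trajs <- vector("list", n_trials)
      for (k in seq_len(n_trials)) {
        tr <- generate_trajectory(
          rt[k], conflict[k], side[k],
          sample_rate = config$sample_rate, jitter_sd = config$jitter_sd,
          button_x = config$button_x, button_y = config$button_y
        )
        trajs[[k]] <- list(n = nrow(tr), t = tr$t_s, x = tr$x_px, y = tr$y_px)
      }
      lens <- vapply(trajs, `[[`, integer(1), "n")
      traj_list[[pnum]] <- tibble::tibble(
        participant_id = pid,
        trial_id = rep(seq_len(n_trials), lens),
        t_s = unlist(lapply(trajs, `[[`, "t")),
        x_px = unlist(lapply(trajs, `[[`, "x")),
        y_px = unlist(lapply(trajs, `[[`, "y"))
      )
      if (grp %in% names(config$irritation_mean)) {
        if (stats::runif(1) < config$p_zero_rater) {
          r <- rep(0, config$blocks)
        } else {
          latent <- round(rtnorm(1, config$irritation_mean[[grp]],
                                 config$irritation_sd, lo = 1, hi = 100))
          r <- round(latent * stats::runif(config$blocks, 0.2, 0.95))
          r[sample.int(config$blocks, 1)] <- latent
        }
        rating_list[[length(rating_list) + 1L]] <- tibble::tibble(
          participant_id = pid, group = grp,
          block = seq_len(config$blocks), rating = r
        )
      }
    }
  }
  out <- list(
    trials = dplyr::bind_rows(trial_list),
    trajectories = dplyr::bind_rows(traj_list),
    ratings = dplyr::bind_rows(rating_list)
  )
  attr(out, "config") <- config
  class(out) <- "rrsat_synth"
  out
}

#' @export
print.rrsat_synth <- function(x, ...) {
  cat(sprintf(
    "Synthetic grid-task dataset: %d participants, %d trials, %d trajectory samples, %d ratings\n",
    dplyr::n_distinct(x$trials$participant_id), nrow(x$trials),
    nrow(x$trajectories), nrow(x$ratings)))
  invisible(x)
}
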