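#' Configure a grid-task adjustment simulation
#'
#' Builds the parameter set for the anchoring-and-adjustment account of the
#' grid task: an observer judges whether black tiles exceed 50% of a
#' black-and-white grid by starting from an anchor near 0.5 and repeatedly
#' proposing small adjustments that are accepted or rejected by a
#' Metropolis-Hastings rule against a truncated-normal belief about the true
#' proportion.
#'
#' @param c_prop True proportion of black tiles, in (0, 1). 0.55 plays the
#'   role of a difficult stimulus, 0.65 of an easy one.
#' @param belief_sd Standard deviation of both the prior around the 0.5
#'   anchor and the belief (target) distribution around `c_prop`; the
#'   observer's strength of belief.
#' @param proposal_sd Standard deviation of the zero-mean Gaussian adjustment
#'   proposals.
#' @param n_steps Number of adjustment steps per chain (estimates are indexed
#'   t = 0, ..., `n_steps`).
#' @param n_iterations Number of independent chains per simulated individual.
#' @param n_individuals Number of simulated individuals in a population run.
#' @param max_cost Thinking cost at the final step; the cost schedule rises
#'   linearly from 0 to `max_cost`. 0 recovers the pure speed-accuracy
#'   trade-off (SAT) regime; positive values give the resource-rational
#'   regime.
#' @param prior `"unimodal"` for a truncated N(0.5, `belief_sd`) anchor, or
#'   `"bimodal"` for an equal-weight mixture of truncated normals at
#'   `bimodal_means`.
#' @param bimodal_means Component means of the bimodal prior.
#' @param bimodal_sd Component standard deviation of the bimodal prior.
#' @param seed Integer seed; every random draw in a population run is derived
#'   from it.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(c_prop = 0.55, n_individuals = 10)
#' @export
sim_config <- function(c_prop = 0.55,
                       belief_sd = 0.1,
                       proposal_sd = 0.05,
                       n_steps = 150L,
                       n_iterations = 1000L,
                       n_individuals = 500L,
                       max_cost = 0.5,
                       prior = c("unimodal", "bimodal"),
                       bimodal_means = c(0.4, 0.6),
                       bimodal_sd = 0.05,
                       seed = 1L) {
  prior <- match.arg(prior)
  stopifnot(
    is.numeric(c_prop), length(c_prop) == 1, c_prop > 0, c_prop < 1,
    is.numeric(belief_sd), belief_sd > 0,
    is.numeric(proposal_sd), proposal_sd > 0,
    n_steps >= 1, n_iterations >= 1, n_individuals >= 1,
    is.numeric(max_cost), all(max_cost >= 0),
    length(bimodal_means) == 2, all(bimodal_means > 0 & bimodal_means < 1),
    bimodal_sd > 0,
    is.numeric(seed), length(seed) == 1
  )
  structure(
    list(
      c_prop = c_prop, belief_sd = belief_sd, proposal_sd = proposal_sd,
      n_steps = as.integer(n_steps), n_iterations = as.integer(n_iterations),
      n_individuals = as.integer(n_individuals), max_cost = max_cost,
      prior = prior, bimodal_means = bimodal_means, bimodal_sd = bimodal_sd,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Truncated-normal density
#'
#' Density of a normal distribution truncated to `[lo, hi]`: the Gaussian
#' density renormalized over the interval, and exactly 0 outside it. All
#' belief distributions in the simulator live on the proportion scale and are
#' truncated to \[0, 1\].
#'
#' @param x Quantiles.
#' @param mean,sd Mean and standard deviation of the parent normal.
#' @param lo,hi Truncation bounds, `lo < hi`.
#' @return Densities, same length as `x`.
#' @examples
#' dtnorm(0.5, mean = 0.5, sd = 0.1) # ~ dnorm(0, sd = 0.1)
#' dtnorm(-0.1, mean = 0.5, sd = 0.1) # 0, outside the support
#' @export
dtnorm <- function(x, mean, sd, lo = 0, hi = 1) {
  if (!is.numeric(sd) || any(sd <= 0)) stop("`sd` must be positive")
  if (lo >= hi) stop("`lo` must be less than `hi`")
  z <- stats::pnorm(hi, mean, sd) - stats::pnorm(lo, mean, sd)
  out <- stats::dnorm(x, mean, sd) / z
  out[x < lo | x > hi] <- 0
  out
}

#' Truncated-normal random draws
#'
#' Inverse-CDF sampler for a normal truncated to `[lo, hi]`; consumes exactly
#' one uniform draw per sample, so streams are reproducible.
#'
#' @inheritParams dtnorm
#' @param n Number of draws.
#' @return Numeric vector of length `n` in `[lo, hi]`.
#' @export
rtnorm <- function(n, mean, sd, lo = 0, hi = 1) {
  if (!is.numeric(sd) || any(sd <= 0)) stop("`sd` must be positive")
  if (lo >= hi) stop("`lo` must be less than `hi`")
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  pmin(hi, pmax(lo, stats::qnorm(p, mean, sd)))
}

#' Draw initial estimates from the prior
#'
#' The first estimate is anchored at the decision criterion: a truncated
#' N(0.5, `belief_sd`) draw under the unimodal prior, or an equal-weight
#' mixture of truncated normals centred at `bimodal_means` under the bimodal
#' prior (for observers who start convinced the answer is one side or the
#' other).
#'
#' @param n Number of draws.
#' @param config A [sim_config()].
#' @return Numeric vector of proportions in \[0, 1\].
#' @export
sample_prior <- function(n, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$prior == "unimodal") {
    rtnorm(n, 0.5, config$belief_sd)
  } else {
    pick <- stats::runif(n) < 0.5
    v <- numeric(n)
    v[pick] <- rtnorm(sum(pick), config$bimodal_means[1], config$bimodal_sd)
    v[!pick] <- rtnorm(sum(!pick), config$bimodal_means[2], config$bimodal_sd)
    v
  }
}

#' Metropolis-Hastings acceptance probability for one adjustment
#'
#' Probability of accepting a move from `v_prev` to `v_prop` under the
#' truncated-normal belief N(`c_prop`, `belief_sd`) on \[0, 1\]. The
#' truncation constants cancel inside the interval, so the ratio reduces to a
#' Gaussian density ratio; proposals outside \[0, 1\] have density 0 and are
#' never accepted.
#'
#' @param v_prev Current estimate in \[0, 1\].
#' @param v_prop Proposed estimate (any real).
#' @param c_prop Belief mean (true proportion).
#' @param belief_sd Belief standard deviation.
#' @return Acceptance probabilities in \[0, 1\].
#' @examples
#' mh_acceptance(0.55, 0.45, c_prop = 0.55, belief_sd = 0.1) # exp(-0.5)
#' @export
mh_acceptance <- function(v_prev, v_prop, c_prop, belief_sd) {
  stopifnot(all(v_prev >= 0 & v_prev <= 1), belief_sd > 0)
  ratio <- ifelse(
    v_prop >= 0 & v_prop <= 1,
    exp(((v_prev - c_prop)^2 - (v_prop - c_prop)^2) / (2 * belief_sd^2)),
    0
  )
  pmin(1, ratio)
}

#' Advance one estimate by one Metropolis-Hastings adjustment
#'
#' Draws an adjustment `delta ~ N(0, proposal_sd)`, accepts the adjusted
#' value whenever it is at least as probable as the current one under the
#' truncated-normal belief, otherwise accepts it with probability equal to
#' the density ratio, and returns the (possibly unchanged) estimate.
#'
#' @inheritParams mh_acceptance
#' @param proposal_sd Proposal standard deviation.
#' @param delta Optional fixed adjustment (bypasses the proposal draw); used
#'   for deterministic checks.
#' @return The next estimate, in \[0, 1\].
#' @export
mh_step <- function(v_prev, c_prop, belief_sd = 0.1, proposal_sd = 0.05,
                    delta = NULL) {
  stopifnot(length(v_prev) == 1, v_prev >= 0, v_prev <= 1)
  if (is.null(delta)) delta <- stats::rnorm(1, 0, proposal_sd)
  u <- stats::runif(1)
  v_prop <- v_prev + delta
  if (u < mh_acceptance(v_prev, v_prop, c_prop, belief_sd)) v_prop else v_prev
}

# Vectorized chain advance: one column per time step, one row per chain.
# Draw order per step (proposals then uniforms) matches mh_step for a single
# chain, so a 1-row run is bit-identical to stepping mh_step by hand.
advance_chains <- function(v, n_steps, c_prop, belief_sd, proposal_sd) {
  n <- length(v)
  out <- matrix(NA_real_, nrow = n, ncol = n_steps + 1)
  out[, 1] <- v
  two_b2 <- 2 * belief_sd^2
  for (t in seq_len(n_steps)) {
    delta <- stats::rnorm(n, 0, proposal_sd)
    u <- stats::runif(n)
    v_prop <- v + delta
    inside <- v_prop >= 0 & v_prop <= 1
    ratio <- numeric(n)
    ratio[inside] <- exp(((v[inside] - c_prop)^2 -
                            (v_prop[inside] - c_prop)^2) / two_b2)
    accept <- u < ratio
    v[accept] <- v_prop[accept]
    out[, t + 1] <- v
  }
  out
}

#' Run the adjustment chains for one simulated individual
#'
#' Initializes `n_iterations` independent chains from the prior and advances
#' each through `n_steps` Metropolis-Hastings adjustments. Uses the current
#' RNG state; see [simulate_population()] for seeded population runs.
#'
#' @param config A [sim_config()].
#' @return A numeric matrix of shape `n_iterations` x (`n_steps` + 1); entry
#'   (i, t+1) is chain i's estimate after t adjustments, in \[0, 1\].
#' @export
run_chains <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  v0 <- sample_prior(config$n_iterations, config)
  advance_chains(v0, config$n_steps, config$c_prop, config$belief_sd,
                 config$proposal_sd)
}

#' Benefit, cost and total-benefit curves for one individual
#'
#' The thinking benefit at step t is the fraction of chains whose estimate
#' exceeds the 0.5 criterion (the rate of correct judgments, since the true
#' proportion is above 0.5), rescaled so its maximum is 1. The thinking cost
#' rises linearly from 0 at step 0 to `max_cost` at the final step, and the
#' total benefit is their difference.
#'
#' @param chains An estimate matrix from [run_chains()].
#' @param config The [sim_config()] that produced it (supplies `max_cost`).
#' @param max_cost Optional override of `config$max_cost` (scalar).
#' @return A tibble of class `rrsat_curves` with columns `t`,
#'   `think_benefit_raw`, `think_benefit`, `think_cost`, `total_benefit`.
#' @export
benefit_curves <- function(chains, config, max_cost = NULL) {
  stopifnot(is.matrix(chains), nrow(chains) >= 1)
  if (is.null(max_cost)) max_cost <- config$max_cost
  stopifnot(length(max_cost) == 1, max_cost >= 0)
  n_steps <- ncol(chains) - 1
  raw <- colMeans(chains > 0.5)
  if (max(raw) == 0) {
    stop("degenerate benefit curve: no chain ever crossed the 0.5 criterion")
  }
  t <- 0:n_steps
  cost <- max_cost * t / n_steps
  benefit <- raw / max(raw)
  tibble::new_tibble(
    list(
      t = t,
      think_benefit_raw = raw,
      think_benefit = benefit,
      think_cost = cost,
      total_benefit = benefit - cost
    ),
    class = "rrsat_curves"
  )
}

#' Peak time of a total-benefit curve
#'
#' The earliest adjustment step t in 1..n_steps at which the total benefit is
#' maximal; step 0 (no adjustment at all) is not an admissible recommendation
#' and ties go to the earliest step.
#'
#' @param curves An `rrsat_curves` tibble from [benefit_curves()], or any
#'   data frame with columns `t` and `total_benefit` including t = 0.
#' @return An integer step.
#' @examples
#' cfg <- sim_config(n_iterations = 50, n_steps = 30)
#' set.seed(1)
#' peak_time(benefit_curves(run_chains(cfg), cfg))
#' @export
peak_time <- function(curves) {
  stopifnot(all(c("t", "total_benefit") %in% names(curves)))
  tb <- curves$total_benefit[curves$t >= 1]
  tt <- curves$t[curves$t >= 1]
  as.integer(tt[which.max(tb)])
}

# Per-individual RNG seed: a fixed-stride counter scheme on the config seed,
# so individual i's stream is stable when n_individuals changes.
individual_seed <- function(seed, i) {
  as.integer((as.double(seed %% 2147483647L) + i * 48271) %% 2147483647)
}

#' Simulate a population of individuals and their peak times
#'
#' For each simulated individual: run the adjustment chains, form the
#' benefit/cost curves, and record the step at which total benefit peaks.
#' Several cost regimes can be evaluated on the identical chains by passing a
#' vector `max_cost`, which is how the SAT (zero-cost) and resource-rational
#' regimes are compared like-for-like.
#'
#' @param config A [sim_config()].
#' @param max_cost Cost ceiling(s) to evaluate; defaults to
#'   `config$max_cost`.
#' @param keep_curves If `TRUE`, attach every individual's curves as the
#'   `"curves"` attribute (a long tibble).
#' @return A tibble of class `rrsat_peaks` with columns `individual`,
#'   `c_prop`, `prior`, `max_cost`, `peak_time`; one row per individual per
#'   cost regime. Deterministic given `config$seed`.
#' @examples
#' cfg <- sim_config(n_individuals = 5, n_iterations = 100, seed = 42)
#' simulate_population(cfg, max_cost = c(0, 0.5))
#' @export
simulate_population <- function(config, max_cost = NULL, keep_curves = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(max_cost)) max_cost <- config$max_cost
  stopifnot(all(max_cost >= 0))
  n <- config$n_individuals
  res <- vector("list", n)
  curves_out <- if (keep_curves) vector("list", n) else NULL
  for (i in seq_len(n)) {
    set.seed(individual_seed(config$seed, i))
    chains <- run_chains(config)
    rows <- lapply(max_cost, function(mc) {
      cur <- benefit_curves(chains, config, max_cost = mc)
      tibble::tibble(
        individual = i, c_prop = config$c_prop, prior = config$prior,
        max_cost = mc, peak_time = peak_time(cur)
      )
    })
    if (keep_curves) {
      curves_out[[i]] <- dplyr::bind_rows(lapply(max_cost, function(mc) {
        dplyr::mutate(benefit_curves(chains, config, max_cost = mc),
                      individual = i, max_cost = mc, .before = 1)
      }))
    }
    res[[i]] <- dplyr::bind_rows(rows)
  }
  out <- dplyr::bind_rows(res)
  out <- tibble::new_tibble(out, class = "rrsat_peaks")
  attr(out, "config") <- config
  if (keep_curves) attr(out, "curves") <- dplyr::bind_rows(curves_out)
  out
}

#' Summarize peak times per condition
#'
#' @param peaks An `rrsat_peaks` tibble from [simulate_population()] (rows
#'   from several runs may be bound together).
#' @return A tibble with one row per (c_prop, prior, max_cost) condition:
#'   `n`, `mean`, `min`, `max` of the peak times.
#' @export
peak_summary <- function(peaks) {
  stopifnot(all(c("c_prop", "prior", "max_cost", "peak_time") %in% names(peaks)))
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(peaks), .data$c_prop, .data$prior,
                    .data$max_cost),
    n = dplyr::n(),
    mean = mean(.data$peak_time),
    min = min(.data$peak_time),
    max = max(.data$peak_time),
    .groups = "drop"
  )
}

#' @export
tidy.rrsat_peaks <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.rrsat_peaks <- function(x, ...) peak_summary(x)
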