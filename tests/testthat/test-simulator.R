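test_that("truncated-normal density is renormalized, zero outside support, symmetric", {
  # closed form: phi(0)/0.1 divided by the [0,1] normalizing mass
  z <- pnorm(5) - pnorm(-5)
  expect_equal(dtnorm(0.5, 0.5, 0.1), dnorm(0, sd = 0.1) / z)
  expect_equal(dtnorm(0.5, 0.5, 0.1), 3.98942, tolerance = 1e-5)
  expect_identical(dtnorm(-0.1, 0.5, 0.1), 0)
  expect_identical(dtnorm(1.2, 0.5, 0.1), 0)
  expect_equal(dtnorm(0.4, 0.5, 0.1), dtnorm(0.6, 0.5, 0.1))
  # integrates to 1 over the support (independent quadrature oracle)
  total <- integrate(dtnorm, 0, 1, mean = 0.3, sd = 0.2)$value
  expect_equal(total, 1, tolerance = 1e-6)
  expect_error(dtnorm(0.5, 0.5, -1), "sd")
  expect_error(dtnorm(0.5, 0.5, 0.1, lo = 1, hi = 0), "lo")
})

test_that("prior draws respect truncation and their stated means", {
  cfg <- sim_config()
  set.seed(123)
  v <- sample_prior(1e5, cfg)
  expect_true(all(v >= 0 & v <= 1))
  # symmetric truncation about 0.5 leaves the mean at exactly 0.5
  se <- 0.1 / sqrt(1e5)
  expect_lt(abs(mean(v) - 0.5), 3 * se)

  cfgb <- sim_config(prior = "bimodal")
  set.seed(123)
  vb <- sample_prior(1e5, cfgb)
  expect_true(all(vb >= 0 & vb <= 1))
  d <- density(vb, bw = 0.01)
  # local maxima of the mixture density sit near 0.4 and 0.6
  peaks <- d$x[which(diff(sign(diff(d$y))) == -2) + 1]
  expect_true(any(abs(peaks - 0.4) < 0.02))
  expect_true(any(abs(peaks - 0.6) < 0.02))
})

test_that("MH acceptance follows the truncated-density ratio rule", {
  # uphill moves are certain
  expect_equal(mh_acceptance(0.50, 0.55, 0.55, 0.1), 1)
  # downhill: analytic Gaussian ratio exp(-(0.10)^2 / (2 * 0.1^2))
  expect_equal(mh_acceptance(0.55, 0.45, 0.55, 0.1), exp(-0.5))
  # proposals outside [0, 1] are never accepted
  expect_equal(mh_acceptance(0.99, 1.04, 0.55, 0.1), 0)
  expect_equal(mh_acceptance(0.01, -0.04, 0.55, 0.1), 0)
})

test_that("mh_step with forced adjustments reproduces the accept/reject rule", {
  set.seed(1)
  expect_equal(mh_step(0.50, 0.55, delta = 0.05), 0.55)
  expect_equal(mh_step(0.99, 0.55, delta = 0.05), 0.99)
  # downhill acceptance rate converges to the analytic ratio
  set.seed(42)
  moved <- replicate(4000, mh_step(0.55, 0.55, delta = -0.10) != 0.55)
  expect_equal(mean(moved), exp(-0.5), tolerance = 0.03)
})

test_that("run_chains has the shape contract and stays in [0, 1]", {
  cfg <- sim_config(n_iterations = 3, n_steps = 150)
  set.seed(5)
  ch <- run_chains(cfg)
  expect_identical(dim(ch), c(3L, 151L))
  expect_true(all(ch >= 0 & ch <= 1))
})

test_that("a single chain equals stepping mh_step by hand under the same seed", {
  cfg <- sim_config(n_iterations = 1, n_steps = 50)
  set.seed(99)
  ch <- run_chains(cfg)
  set.seed(99)
  v <- sample_prior(1, cfg)
  manual <- v
  for (t in 1:50) {
    v <- mh_step(v, cfg$c_prop, cfg$belief_sd, cfg$proposal_sd)
    manual <- c(manual, v)
  }
  expect_equal(drop(ch), manual)
})

test_that("benefit curves rescale to max 1 and cost is linear", {
  cfg <- sim_config(n_iterations = 200, n_steps = 150, max_cost = 0.5)
  set.seed(2)
  ch <- run_chains(cfg)
  cur <- benefit_curves(ch, cfg)
  expect_equal(max(cur$think_benefit), 1)
  expect_true(all(cur$think_benefit_raw >= 0 & cur$think_benefit_raw <= 1))
  expect_equal(cur$think_cost[cur$t == 0], 0)
  expect_equal(cur$think_cost[cur$t == 150], 0.5)
  expect_equal(diff(cur$think_cost), rep(0.5 / 150, 150))
  expect_equal(cur$total_benefit, cur$think_benefit - cur$think_cost)
  # zero-cost regime: total benefit is the thinking benefit (SAT identity)
  cur0 <- benefit_curves(ch, cfg, max_cost = 0)
  expect_equal(cur0$total_benefit, cur0$think_benefit)
  # degenerate all-zero curve is reported, not silently rescaled
  expect_error(
    benefit_curves(matrix(0.2, nrow = 4, ncol = 11), cfg),
    "degenerate"
  )
})

test_that("rescaling divides by the curve maximum", {
  # 10 chains engineered so the raw accuracy curve is [0.5, 0.6, 0.8]
  ch <- cbind(
    c(rep(0.6, 5), rep(0.4, 5)),
    c(rep(0.6, 6), rep(0.4, 4)),
    c(rep(0.6, 8), rep(0.4, 2))
  )
  cfg <- sim_config(max_cost = 0)
  cur <- benefit_curves(ch, cfg)
  expect_equal(cur$think_benefit_raw, c(0.5, 0.6, 0.8))
  expect_equal(cur$think_benefit, c(0.625, 0.75, 1.0))
})

test_that("peak_time takes the earliest maximizing step and excludes step 0", {
  mk <- function(tb) tibble::tibble(t = seq_along(tb) - 1, total_benefit = tb)
  # strictly increasing curve peaks at the last step
  expect_identical(peak_time(mk(seq(0, 1, length.out = 151))), 150L)
  # constant curve: tie broken at the first admissible step
  expect_identical(peak_time(mk(rep(0.3, 151))), 1L)
  expect_identical(peak_time(mk(c(0, 0.2, 0.9, 0.7, 0.9))), 2L)
  # agrees with the brute-force argmax oracle on random curves
  set.seed(31)
  for (i in 1:50) {
    tb <- round(runif(21), 2)
    expect_identical(peak_time(mk(tb)), argmax_first(tb))
  }
})

test_that("simulate_population is deterministic, stable in n_individuals, singleton-safe", {
  cfg <- sim_config(n_individuals = 4, n_iterations = 100, n_steps = 60,
                    seed = 7)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$peak_time, b$peak_time)
  # first individuals unchanged when the population grows
  cfg6 <- sim_config(n_individuals = 6, n_iterations = 100, n_steps = 60,
                     seed = 7)
  c6 <- simulate_population(cfg6)
  expect_identical(a$peak_time, c6$peak_time[1:4])

  one <- sim_config(n_individuals = 1, n_iterations = 100, n_steps = 60)
  s <- peak_summary(simulate_population(one))
  expect_equal(s$mean, s$min)
  expect_equal(s$min, s$max)
})

test_that("tidy and glance methods work on population results", {
  cfg <- sim_config(n_individuals = 3, n_iterations = 50, n_steps = 40)
  pk <- simulate_population(cfg, max_cost = c(0, 0.5))
  expect_s3_class(tidy(pk), "tbl_df")
  g <- glance(pk)
  expect_identical(nrow(g), 2L)
  expect_true(all(g$min <= g$mean & g$mean <= g$max))
})
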