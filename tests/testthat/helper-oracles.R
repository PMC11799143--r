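# Independent oracles the implementation is checked against.

# Shoelace signed area of the closed polygon through (x, y) (closing edge
# from the last vertex back to the first); counter-clockwise positive.
shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

# Brute-force first-maximum search over steps 1..n (excluding step 0).
argmax_first <- function(total_benefit, t = seq_along(total_benefit) - 1) {
  best <- -Inf
  best_t <- NA_integer_
  for (i in seq_along(total_benefit)) {
    if (t[i] >= 1 && total_benefit[i] > best) {
      best <- total_benefit[i]
      best_t <- as.integer(t[i])
    }
  }
  best_t
}

# Tail probability P(X > 0.5) of a normal truncated to [0, 1].
tnorm_tail_above_half <- function(mean, sd) {
  (pnorm((1 - mean) / sd) - pnorm((0.5 - mean) / sd)) /
    (pnorm((1 - mean) / sd) - pnorm((0 - mean) / sd))
}

# Random piecewise-linear trajectory with distinct endpoints.
random_trajectory <- function(n_points, scale = 100) {
  repeat {
    x <- cumsum(rnorm(n_points, sd = scale / sqrt(n_points)))
    y <- cumsum(rnorm(n_points, sd = scale / sqrt(n_points)))
    if ((x[n_points] - x[1])^2 + (y[n_points] - y[1])^2 > 1e-6) break
  }
  tibble::tibble(x_px = x, y_px = y)
}

# Apply a rigid motion (rotation by theta + translation) to a trajectory.
rotate_translate <- function(traj, theta, dx = 0, dy = 0) {
  tibble::tibble(
    x_px = cos(theta) * traj$x_px - sin(theta) * traj$y_px + dx,
    y_px = sin(theta) * traj$x_px + cos(theta) * traj$y_px + dy
  )
}

# Minimal valid trial table builder.
make_trials <- function(rt_s, proportion = 0.55, response = "yes",
                        participant_id = "p1", group = "0s") {
  tibble::tibble(
    participant_id = participant_id, group = group,
    proportion = proportion, response = response, rt_s = rt_s
  )
}
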