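# Shared fixtures: random rotations, perturbed duplexes, small planted
# ensembles. Everything is generated in code under fixed seeds.

rand_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# Apply a rigid transform to a structure model.
transform_model <- function(model, R, t) {
  xyz <- cbind(model$x, model$y, model$z) %*% t(R)
  model$x <- xyz[, 1] + t[1]
  model$y <- xyz[, 2] + t[2]
  model$z <- xyz[, 3] + t[3]
  model
}

# Random in-range helical parameter set for an n-pair duplex.
random_params <- function(n, angle_max = 60, trans_max = 3) {
  p <- bform_params(n)
  p$pair[, 1:3] <- matrix(stats::runif(3 * n, -trans_max, trans_max), n)
  p$pair[, 4:6] <- matrix(stats::runif(3 * n, -angle_max, angle_max), n)
  p$step[, 1:3] <- matrix(stats::runif(3 * (n - 1), -trans_max, trans_max),
                          n - 1)
  p$step[, 3] <- abs(p$step[, 3]) + 2  # keep rise positive and stacked
  p$step[, 4:6] <- matrix(stats::runif(3 * (n - 1), -angle_max, angle_max),
                          n - 1)
  p
}

# One-model ensemble over the fixture duplex.
fixture_ensemble <- function(model, platinated = NULL) {
  duplex_ensemble(list(model),
                  topology = fixture_topology(
                    platinated_residues = platinated))
}

expect_all_close <- function(x, y, tol) {
  expect_lt(max(abs(x - y)), tol)
}
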