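# Build a synthetic long-format trajectory from per-frame positions.
make_traj <- function(times, pos_fn, n) {
  dplyr::bind_rows(lapply(seq_along(times), function(k) {
    p <- pos_fn(times[k])
    tibble::tibble(t = times[k], cell = seq_len(n),
                   x = p[, 1], y = p[, 2], px = 0, py = 0)
  }))
}

test_that("cluster velocity is displacement over time", {
  base <- init_hexagonal_cluster(7, angle = 0)
  tt <- seq(0, 10, by = 0.5)
  still <- make_traj(tt, function(t) base, 7)
  expect_equal(unlist(cluster_velocity(still)), c(vx = 0, vy = 0))
  moving <- make_traj(tt, function(t) sweep(base, 2, c(0.3 * t, 0), "+"), 7)
  expect_equal(cluster_velocity(moving)$vx, 0.3)
  expect_equal(cluster_velocity(moving, window = c(2, 8))$vx, 0.3)
})

test_that("velocity estimator recovers a known drift from noisy ensembles", {
  set.seed(61)
  base <- init_hexagonal_cluster(7, angle = 0)
  tt <- seq(0, 20, by = 0.2)
  vxs <- replicate(30, {
    wob <- cumsum(rnorm(length(tt), sd = 0.05))
    tr <- make_traj(tt, function(t) {
      k <- which.min(abs(tt - t))
      sweep(base, 2, c(0.25 * t + wob[k], 0), "+")
    }, 7)
    cluster_velocity(tr)$vx
  })
  se <- sd(vxs) / sqrt(length(vxs))
  expect_lt(abs(mean(vxs) - 0.25), 3 * se + 1e-12)
})

test_that("chemotactic index handles pure drift and isotropy", {
  expect_equal(chemotactic_index(tibble::tibble(vx = c(2, 2, 2), vy = 0)), 1)
  th <- 2 * pi * (0:99) / 100
  expect_lt(abs(chemotactic_index(cbind(cos(th), sin(th)))), 1e-10)
})

test_that("chemotactic index of a Gaussian ensemble matches quadrature", {
  mu <- 0.8; s <- 0.5
  # oracle: E[Vx]/E[|V|] with E|V| from the Rice mean by 2-D quadrature
  f <- function(r) r^2 / s^2 * exp(-(r^2 + mu^2) / (2 * s^2)) *
    besselI(r * mu / s^2, 0, expon.scaled = TRUE) * exp(r * mu / s^2 - 0)
  e_absv <- integrate(function(r) {
    z <- r * mu / s^2
    r^2 / s^2 * exp(-(r^2 + mu^2) / (2 * s^2) + z) *
      besselI(z, 0, expon.scaled = TRUE)
  }, 0, mu + 12 * s, rel.tol = 1e-10)$value
  oracle_ci <- mu / e_absv
  set.seed(62)
  v <- cbind(rnorm(2e5, mu, s), rnorm(2e5, 0, s))
  expect_equal(chemotactic_index(v), oracle_ci, tolerance = 0.01)
})

test_that("angular speed is exact for rigid rotation and Galilean invariant", {
  base <- init_hexagonal_cluster(7, angle = 0)
  tt <- seq(0, 5, by = 0.05)
  w0 <- 0.7
  rot <- function(t, drift = c(0, 0)) {
    a <- w0 * t
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    sweep(base %*% t(R), 2, drift * t, "+")
  }
  pure <- make_traj(tt, function(t) rot(t), 7)
  # finite differences carry an O((w dt)^2) chord bias, here ~8e-4 relative
  expect_equal(angular_speed(pure)$omega, w0, tolerance = 1e-3)
  # translation alone has no rotation
  trans <- make_traj(tt, function(t) sweep(base, 2, c(0.4 * t, -0.2 * t), "+"), 7)
  expect_equal(angular_speed(trans)$omega, 0, tolerance = 1e-12)
  # superposed translation leaves the rotation rate unchanged (exactly)
  both <- make_traj(tt, function(t) rot(t, drift = c(0.4, -0.2)), 7)
  expect_equal(angular_speed(both)$omega, angular_speed(pure)$omega,
               tolerance = 1e-10)
})

test_that("fragmentation counts connected components at the contact cutoff", {
  hex <- init_hexagonal_cluster(7, angle = 0)
  expect_equal(fragmentation_count(hex), 1L)
  two <- rbind(hex, sweep(hex, 2, c(10, 0), "+"))
  expect_equal(fragmentation_count(two), 2L)
  chain <- cbind(c(0, 1, 2, 3.5, 4.5), 0)
  expect_equal(fragmentation_count(chain, D0 = 1.2), 2L)
})

test_that("rigid predictor gives zero drift without a gradient", {
  p <- model_params(beta_bar = 20, response_mode = "minimal")
  pred <- rigid_steady_prediction(init_hexagonal_cluster(19, angle = 0), p,
                                  signal_field("uniform", S0 = 2),
                                  n_orientations = 8)
  expect_lt(abs(pred$mean_vx), 1e-12)
  expect_lt(abs(pred$ci), 1e-10)
})

test_that("predictor CI grows monotonically with the velocity scale", {
  f <- signal_field("exponential", S0 = 1, S1 = 0.025)
  pos <- init_hexagonal_cluster(19, angle = 0)
  cis <- vapply(c(5, 10, 20, 40), function(bb) {
    rigid_steady_prediction(pos, model_params(beta_bar = bb), f,
                            n_orientations = 16)$ci
  }, numeric(1))
  expect_true(all(diff(cis) > 0))
})

test_that("orientation averaging is converged at the default resolution", {
  f <- signal_field("exponential", S0 = 1, S1 = 0.025)
  p <- model_params(beta_bar = 20, response_mode = "legi_linear")
  pos <- init_hexagonal_cluster(19, angle = 0)
  a <- rigid_steady_prediction(pos, p, f, n_orientations = 64)
  b <- rigid_steady_prediction(pos, p, f, n_orientations = 128)
  expect_lt(abs(a$mean_vx - b$mean_vx) / abs(b$mean_vx), 1e-3)
})

test_that("rigid predictor agrees with full stochastic simulation", {
  # strongly adherent 7-cell cluster, minimal response, shallow gradient
  f <- signal_field("exponential", S0 = 1, S1 = 0.025)
  p <- model_params(beta_bar = 20, v_r = 500, v_a = 500,
                    response_mode = "minimal", dt = 1e-4)
  pred <- rigid_steady_prediction(init_hexagonal_cluster(7, angle = 0), p, f)
  ens <- run_ensemble(p, f, N = 7, T = 6, n_traj = 50, seed = 63,
                      window = c(1, 6), snapshot_dt = 0.5)
  se <- sd(ens$vx) / sqrt(nrow(ens))
  expect_lt(abs(mean(ens$vx) - pred$mean_vx),
            max(3 * se, 0.1 * pred$mean_vx))
})

test_that("chirality-drift pairing recovers a constructed coupling", {
  set.seed(64)
  om <- c(rnorm(40, 1, 0.2), rnorm(40, -1, 0.2))
  cc <- 0.3
  ens <- tibble::tibble(omega = om, vy = cc * om + rnorm(80, 0, 0.05))
  cd <- chirality_drift(ens)
  bm <- cd$branch_means
  up <- bm$mean_vy[bm$branch == "ccw"]
  dn <- bm$mean_vy[bm$branch == "cw"]
  expect_equal(up, cc * mean(om[om > 0]), tolerance = 0.1)
  expect_equal(dn, cc * mean(om[om < 0]), tolerance = 0.1)
  # symmetric, uncoupled ensemble: both branch means near zero
  ens0 <- tibble::tibble(omega = c(1, -1, 2, -2), vy = 0)
  expect_equal(chirality_drift(ens0)$branch_means$mean_vy, c(0, 0))
})

test_that("mirror reflection negates omega and vy, preserves vx", {
  p <- model_params(beta_bar = 35, chi = 50)
  tr <- run_trajectory(p, signal_field("uniform"), N = 12, T = 3, seed = 65)
  refl <- dplyr::mutate(tr, y = -y, py = -py)
  v <- cluster_velocity(tr); vr <- cluster_velocity(refl)
  expect_equal(vr$vx, v$vx)
  expect_equal(vr$vy, -v$vy)
  expect_equal(angular_speed(refl)$omega, -angular_speed(tr)$omega)
})
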