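test_that("hexagonal initialization builds closed shells", {
  expect_equal(init_hexagonal_cluster(1, angle = 0), matrix(0, 1, 2))
  p7 <- init_hexagonal_cluster(7, angle = 0)
  d7 <- sqrt(rowSums(sweep(p7, 2, colMeans(p7))^2))
  expect_equal(sort(round(d7, 9)), c(0, rep(1, 6)))
  p19 <- init_hexagonal_cluster(19, angle = 0)
  d19 <- sqrt(rowSums(sweep(p19, 2, colMeans(p19))^2))
  expect_equal(max(d19), 2, tolerance = 1e-9)
  expect_equal(sum(abs(d19) < 1e-9), 1L)       # 1 centre
  expect_equal(sum(abs(d19 - 1) < 1e-9), 6L)   # 6 in first shell
  # non-shell N: correct count, centred
  p10 <- init_hexagonal_cluster(10, angle = 0)
  expect_equal(nrow(p10), 10L)
  expect_equal(colMeans(p10), c(0, 0), tolerance = 1e-12)
  expect_error(init_hexagonal_cluster(0), "positive")
})

test_that("random orientation rotates the cluster rigidly", {
  set.seed(51)
  p <- init_hexagonal_cluster(19)
  d <- sort(round(as.vector(dist(p)), 9))
  d0 <- sort(round(as.vector(dist(init_hexagonal_cluster(19, angle = 0))), 9))
  expect_equal(d, d0)
})

test_that("polarity rate decomposes into decay, CIL, and co-attraction", {
  f <- signal_field("uniform")
  # isolated cell: pure Ornstein-Uhlenbeck drift
  pr <- polarity_rate(matrix(0, 1, 2), matrix(c(2, -1), 1, 2),
                      model_params(chi = 0), f)
  expect_equal(c(pr$dpx, pr$dpy), c(-2, 1))
  # contacting pair, minimal mode: outward bias of magnitude beta_bar * S
  p2 <- model_params(beta_bar = 20, chi = 0)
  pr2 <- polarity_rate(rbind(c(0.55, 0), c(-0.55, 0)), matrix(0, 2, 2), p2, f)
  expect_equal(pr2$dpx, c(20, -20))
  # symmetric hexagon interior cell: q = 0, decay only
  pos <- init_hexagonal_cluster(7, angle = 0)
  pol <- matrix(rnorm(14), 7, 2)
  pr7 <- polarity_rate(pos, pol, p2, f)
  centre <- which(contact_graph(pos)$n_contacts == 6L)
  expect_equal(pr7$dpx[centre], -pol[centre, 1], tolerance = 1e-9)
})

test_that("deterministic Euler step is exact for pure polarity decay", {
  p <- model_params(sigma = 0, chi = 0, dt = 1e-3)
  st <- coguide:::new_sim_state(matrix(0, 1, 2), matrix(c(1, 0), 1, 2))
  st2 <- sim_step(st, p, signal_field("uniform"))
  expect_equal(st2$polarities[1, 1], 1 - 1e-3 / 1)
  expect_equal(st2$positions[1, 1], 1e-3) # moved with polarity 1
})

test_that("deterministic observables converge first order in dt", {
  f <- signal_field("uniform")
  run_to <- function(dt) {
    p <- model_params(sigma = 0, beta_bar = 20, chi = 0, v_r = 100,
                      v_a = 0, dt = dt)
    st <- coguide:::new_sim_state(rbind(c(0.7, 0), c(-0.7, 0)),
                                  rbind(c(-1, 0), c(1, 0)))
    sim_step(st, p, f, n_steps = round(0.5 / dt))$positions
  }
  ref <- run_to(1e-5 / 4)
  errs <- vapply(c(4e-4, 2e-4, 1e-4),
                 function(dt) max(abs(run_to(dt) - ref)), numeric(1))
  expect_true(all(diff(errs) < 0))
  ratio <- errs[1] / errs[2]
  expect_gt(ratio, 1.5); expect_lt(ratio, 3)
})

test_that("trajectories are reproducible under a fixed seed", {
  p <- model_params(beta_bar = 35, chi = 20)
  f <- signal_field("uniform")
  t1 <- run_trajectory(p, f, N = 7, T = 1, seed = 99)
  t2 <- run_trajectory(p, f, N = 7, T = 1, seed = 99)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  t3 <- run_trajectory(p, f, N = 7, T = 1, seed = 100)
  expect_false(identical(t3$x, t1$x))
})

test_that("polarity statistics match the Ornstein-Uhlenbeck closed form", {
  p <- model_params(beta_bar = 0, chi = 0, dt = 1e-3)
  tr <- run_trajectory(p, signal_field("uniform"), N = 1, T = 500, seed = 5,
                       snapshot_dt = 0.1)
  st <- attr(tr, "stats")
  # stationary <|p|^2> = 2 sigma^2 tau; ~500 correlation times sampled,
  # so allow 3 standard errors of the variance estimate (~19%)
  expect_equal(st$mean_speed2, 2, tolerance = 0.2)
  # velocity autocorrelation decays as exp(-t/tau)
  ac <- acf(dplyr::filter(tr, t > 1)$px, lag.max = 15, plot = FALSE)$acf
  lags <- (seq_along(ac) - 1) * 0.1
  fit <- lm(log(ac[ac > 0.05]) ~ lags[ac > 0.05])
  tau_fit <- -1 / coef(fit)[2]
  expect_equal(unname(tau_fit), 1, tolerance = 0.1)
})

test_that("internal forces never move the centroid", {
  # noiseless crowded cluster: centroid displacement per step equals the
  # mean polarity exactly, because pair forces cancel
  p <- model_params(sigma = 0, beta_bar = 30, chi = 10, v_r = 100, dt = 1e-3)
  set.seed(52)
  pos <- init_hexagonal_cluster(12, angle = 0) * 0.95 # compressed: forces active
  pol <- matrix(rnorm(24), 12, 2)
  st <- coguide:::new_sim_state(pos, pol)
  st2 <- sim_step(st, p, signal_field("uniform"))
  drift <- colMeans(st2$positions) - colMeans(st$positions)
  expect_equal(drift, p$dt * colMeans(pol), tolerance = 1e-12)
})

test_that("uniform-signal ensembles are isotropic", {
  p <- model_params(beta_bar = 20, chi = 15)
  ens <- run_ensemble(p, signal_field("uniform"), N = 7, T = 6,
                      n_traj = 16, seed = 53)
  se <- stats::sd(ens$vx) / sqrt(nrow(ens))
  expect_lt(abs(mean(ens$vx)), 3 * se)
  se_y <- stats::sd(ens$vy) / sqrt(nrow(ens))
  expect_lt(abs(mean(ens$vy)), 3 * se_y)
})

test_that("an unstable step size raises an instability error", {
  # dt > 2 tau makes the explicit polarity-decay update oscillate and
  # diverge; the integrator must detect the non-finite state
  p <- model_params(sigma = 0, chi = 0, dt = 5)
  st <- coguide:::new_sim_state(matrix(0, 1, 2), matrix(c(1, 0), 1, 2))
  expect_error(sim_step(st, p, signal_field("uniform"), n_steps = 5000),
               "non-finite")
})
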