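test_that("LEGI right-hand sides evaluate term by term", {
  rates <- legi_rates(kA = 1, k_mA = 1, kI = 1, k_mI = 1, kD = 4)
  # isolated cell: dI = kI S - k_mI I = 1 - 0.5
  g1 <- contact_graph(matrix(0, 1, 2))
  d1 <- legi_rhs(list(A = 1, I = 0.5, R = 0.1), S_i = 1, g1, rates)
  expect_equal(d1$dI, 0.5)
  # A at its steady state: dA = 0
  expect_equal(d1$dA, 0)
  # uniform I across a connected cluster: transfer terms cancel exactly
  pos <- init_hexagonal_cluster(7, angle = 0)
  g7 <- contact_graph(pos)
  d7 <- legi_rhs(list(A = rep(2, 7), I = rep(0.8, 7), R = rep(0.3, 7)),
                 S_i = rep(1, 7), g7, rates)
  expect_equal(d7$dI, rep(1 - 0.8, 7))
})

test_that("negative concentrations are rejected", {
  g1 <- contact_graph(matrix(0, 1, 2))
  expect_error(legi_rhs(list(A = -1, I = 0, R = 0), 1, g1, legi_rates()),
               "non-negative")
})

test_that("inhibitor transfer conserves the total inhibitor exactly", {
  set.seed(41)
  pos <- random_connected_cluster(12)
  g <- contact_graph(pos)
  st <- list(A = runif(12), I = runif(12), R = runif(12))
  S_i <- runif(12, 0.5, 2)
  rates <- legi_rates()
  d <- legi_rhs(st, S_i, g, rates)
  # d(sum I)/dt must equal production minus decay alone
  expect_lt(abs(sum(d$dI) - sum(rates$kI * S_i - rates$k_mI * st$I)), 1e-10)
})

test_that("steady-state solver matches the ODE-relaxation oracle", {
  set.seed(42)
  rates <- legi_rates()
  for (k in 1:5) {
    n <- sample(c(5, 9, 19, 37), 1)
    pos <- random_connected_cluster(n)
    g <- contact_graph(pos)
    S_i <- signal_at(signal_field("exponential", S0 = 1, S1 = 0.05), pos)
    ss <- legi_steady_state(S_i, g, rates)
    orc <- legi_relax_oracle(S_i, g, rates)
    expect_lt(max(abs(ss$I - orc$I) / orc$I), 1e-6)
    expect_lt(max(abs(ss$R - orc$R) / orc$R), 1e-6)
  }
})

test_that("uniform signal gives signal-independent uniform response", {
  pos <- init_hexagonal_cluster(19, angle = 0)
  g <- contact_graph(pos)
  rates <- legi_rates()
  s1 <- legi_steady_state(rep(1, 19), g, rates)
  s2 <- legi_steady_state(rep(3.7, 19), g, rates)
  expect_equal(s1$I, rep(rates$kI / rates$k_mI, 19))
  expect_equal(s1$R, s2$R, tolerance = 1e-12)
})

test_that("fast intercellular diffusion recovers cluster-mean sensing", {
  pos <- init_hexagonal_cluster(7, angle = 0)
  g <- contact_graph(pos)
  lin <- signal_field("linear", S0 = 1, S1 = 0.025)
  S_i <- signal_at(lin, pos)
  rates <- legi_rates(kD = 1e6)
  ss <- legi_steady_state(S_i, g, rates)
  expect_equal(ss$I, rep((rates$kI / rates$k_mI) * mean(S_i), 7),
               tolerance = 1e-4)
  # convergence to the ideal profile is monotone in kD
  dev <- vapply(c(4, 40, 400, 4000), function(kd) {
    r <- legi_rates(kD = kd)
    s <- legi_steady_state(S_i, g, r)
    max(abs(s$R - legi_r0(r) * S_i / mean(S_i)) / s$R)
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
})

test_that("k_mI = 0 on a disconnected graph is singular", {
  pos <- rbind(c(0, 0), c(10, 0))
  g <- contact_graph(pos)
  expect_error(legi_steady_state(c(1, 2), g, legi_rates(k_mI = 0)),
               "singular")
})

test_that("a uniform signal step produces a transient pulse that adapts away", {
  pos <- init_hexagonal_cluster(7, angle = 0)
  fld <- signal_field("step_in_time", S0 = 1, t_step = 1, S0_after = 2)
  rates <- legi_rates()
  out <- legi_integrate(fld, pos, rates,
                        times = seq(0, 1 + 20 / rates$k_mI, by = 0.05))
  r1 <- dplyr::filter(out, cell == 1)
  r_pre <- r1$R[r1$time == 1]
  expect_gt(max(r1$R / r_pre - 1), 0.10)          # a genuine pulse
  expect_lt(abs(r1$R[nrow(r1)] / r_pre - 1), 1e-3) # perfect adaptation
  # all cells identical under a uniform signal
  fin <- dplyr::filter(out, time == max(time))
  expect_lt(diff(range(fin$R)), 1e-12)
})
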