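test_that("pair force follows the piecewise spring law", {
  # repulsive branch: v_r * (1 - d)
  expect_equal(pair_force(0.9, v_r = 100, v_a = 0), 10)
  # equilibrium: both branches vanish
  expect_equal(pair_force(1, v_r = 123, v_a = 456, D0 = 2), 0)
  # attractive branch: -v_a (d - 1)/(D0 - 1)
  expect_equal(pair_force(1.5, v_r = 100, v_a = 100, D0 = 2), -50)
  # beyond interaction range
  expect_equal(pair_force(2.1, v_r = 100, v_a = 100, D0 = 2), 0)
  expect_equal(pair_force(1.3, v_r = 100, v_a = 100, D0 = 1.2), 0)
})

test_that("pair force is continuous at d = 1 and jumps at d = D0", {
  eps <- 1e-9
  expect_lt(abs(pair_force(1 - eps, 500, 500) - pair_force(1 + eps, 500, 500)),
            1e-5)
  expect_lt(abs(pair_force(1, 500, 500)), 1e-12)
  # documented discontinuity at D0: -v_a just below, 0 at and above
  expect_equal(pair_force(1.2 - 1e-12, v_r = 0, v_a = 80, D0 = 1.2), -80,
               tolerance = 1e-6)
  expect_equal(pair_force(1.2, v_r = 0, v_a = 80, D0 = 1.2), 0)
})

test_that("coincident cells raise a degenerate-overlap error", {
  expect_error(pair_force(0, 100, 0), "coincide")
  expect_error(net_forces(rbind(c(0, 0), c(0, 0))), "coincide")
})

test_that("net forces obey Newton's third law on random configurations", {
  set.seed(11)
  for (k in 1:5) {
    n <- sample(3:20, 1)
    pos <- matrix(runif(2 * n, 0, 4), n, 2)
    f <- net_forces(pos, v_r = 100, v_a = 50, D0 = 1.5)
    expect_lt(abs(sum(f$fx)), 1e-10)
    expect_lt(abs(sum(f$fy)), 1e-10)
  }
})

test_that("two-cell forces are equal, opposite, and push apart below d = 1", {
  pos <- rbind(c(0.9, 0), c(0, 0))
  f <- net_forces(pos, v_r = 100, v_a = 0)
  expect_equal(f$fx, c(10, -10))
  expect_equal(f$fy, c(0, 0))
})

test_that("equilibrium hexagon has zero net forces", {
  pos <- init_hexagonal_cluster(7, angle = 0)
  f <- net_forces(pos, v_r = 500, v_a = 500, D0 = 1.2)
  expect_lt(max(abs(c(f$fx, f$fy))), 1e-10)
})

test_that("contact graph edges are exactly the pairs within the cutoff", {
  expect_equal(sum(contact_graph(rbind(c(0, 0), c(0.9, 0)), 1.2)$n_contacts), 2)
  expect_equal(sum(contact_graph(rbind(c(0, 0), c(1.3, 0)), 1.2)$n_contacts), 0)
  # 7-cell hexagon: centre has 6 neighbours, edge cells 3 (brute-force check)
  pos <- init_hexagonal_cluster(7, angle = 0)
  g <- contact_graph(pos, cutoff = 1.2)
  d <- as.matrix(dist(pos))
  brute <- rowSums(d < 1.2) - 1
  expect_equal(g$n_contacts, as.integer(brute))
  centre <- which.min(rowSums(sweep(pos, 2, colMeans(pos))^2))
  expect_equal(g$n_contacts[centre], 6L)
  expect_equal(sort(g$n_contacts[-centre]), rep(3L, 6))
})

test_that("CIL bias vanishes for isolated and symmetric-interior cells", {
  expect_equal(unlist(cil_bias(matrix(c(0, 0), 1, 2))[, c("qx", "qy")]),
               c(qx = 0, qy = 0))
  # pair along x: right cell pushed right, left cell pushed left
  q <- cil_bias(rbind(c(0.5, 0), c(-0.5, 0)))
  expect_equal(q$qx, c(1, -1))
  expect_equal(q$qy, c(0, 0))
  # centre of a hexagon: six unit vectors cancel
  pos <- init_hexagonal_cluster(7, angle = 0)
  q7 <- cil_bias(pos)
  centre <- which(contact_graph(pos)$n_contacts == 6L)
  expect_lt(abs(q7$qx[centre]) + abs(q7$qy[centre]), 1e-12)
})

test_that("closed-shell clusters have zero interior and outward edge bias", {
  pos <- init_hexagonal_cluster(19, angle = 0)
  g <- contact_graph(pos)
  q <- cil_bias(pos, g)
  qn <- sqrt(q$qx^2 + q$qy^2)
  interior <- g$n_contacts == 6L
  expect_equal(sum(interior), 7L)
  expect_lt(max(qn[interior]), 1e-12)
  expect_gt(min(qn[!interior]), 0.5)
  # edge bias points outward: positive projection on the radial direction
  rad <- sweep(pos, 2, colMeans(pos))
  proj <- q$qx * rad[, 1] + q$qy * rad[, 2]
  expect_true(all(proj[!interior] > 0))
})

test_that("mirror-symmetric clusters have mirror-symmetric total CIL bias", {
  set.seed(21)
  half <- cbind(runif(6, 0, 3), runif(6, 0.2, 2))
  pos <- rbind(half, cbind(half[, 1], -half[, 2])) # symmetric about x axis
  q <- cil_bias(pos)
  expect_lt(abs(sum(q$qy)), 1e-12)
  # and the total bias always vanishes by pairwise antisymmetry
  expect_lt(abs(sum(q$qx)), 1e-12)
})
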