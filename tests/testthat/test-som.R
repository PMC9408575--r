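test_that("find_bmu matches an exhaustive brute-force oracle", {
  g <- random_grid(1, 1, 3, seed = 1)
  expect_equal(find_bmu(g, c(100, -5, 2)), c(1L, 1L))

  g <- random_grid(5, 5, 4, seed = 2)
  x <- g$W[17, ]
  co <- moodmap:::unit_coords(17L, 5L)
  expect_equal(find_bmu(g, x), as.integer(co[1, ]))

  for (s in 1:100) {
    set.seed(s)
    J <- sample(2:6, 1); K <- sample(2:6, 1); I <- sample(1:5, 1)
    g <- random_grid(J, K, I, seed = s + 1000)
    x <- rnorm(I)
    expect_equal(find_bmu(g, x), as.integer(oracle_bmu(g$W, J, K, x)))
  }
  expect_error(find_bmu(random_grid(2, 2, 3, 1), c(1, 2)), "length")
})

test_that("neighborhood_extent follows the linear shrink schedule", {
  cfg <- train_config(psi0 = 40, O = 200)
  expect_identical(neighborhood_extent(cfg, 0), 40L)
  expect_identical(neighborhood_extent(cfg, 200), 0L)
  expect_identical(neighborhood_extent(cfg, 100), 20L)
  psis <- vapply(0:200, function(t) neighborhood_extent(cfg, t), integer(1))
  expect_true(all(diff(psis) <= 0))
  expect_error(neighborhood_extent(cfg, 201), "outside")
  expect_error(neighborhood_extent(cfg, -1), "outside")
})

test_that("update_weights moves exactly the clipped square neighborhood", {
  g <- random_grid(4, 4, 2, seed = 3)
  x <- c(2, 4)
  # full step: every neighborhood unit lands exactly on x
  g1 <- update_weights(g, x, c(2L, 2L), alpha_t = 1, psi_t = 1)
  for (j in 1:3) for (k in 1:3) {
    expect_equal(g1$W[(j - 1) * 4 + k, ], x)
  }
  expect_equal(g1$W[16, ], g$W[16, ])  # far corner untouched
  # degenerate neighborhood: only the BMU moves
  g2 <- update_weights(g, x, c(3L, 3L), alpha_t = 0.5, psi_t = 0)
  moved <- which(rowSums(abs(g2$W - g$W)) > 0)
  expect_identical(moved, 11L)
  # half-step arithmetic
  g3 <- g; g3$W[11, ] <- c(0, 0)
  g3 <- update_weights(g3, x, c(3L, 3L), alpha_t = 0.5, psi_t = 0)
  expect_equal(g3$W[11, ], c(1, 2))
  # convex-hull bound per dimension
  for (s in 1:20) {
    set.seed(s)
    g0 <- random_grid(3, 3, 3, seed = s)
    xs <- rnorm(3)
    a <- runif(1, 0.05, 1)
    gn <- update_weights(g0, xs, find_bmu(g0, xs), a, sample(0:2, 1))
    lo <- pmin(apply(g0$W, 2, min), xs) - 1e-12
    hi <- pmax(apply(g0$W, 2, max), xs) + 1e-12
    expect_true(all(sweep(gn$W, 2, lo, `>=`)))
    expect_true(all(sweep(gn$W, 2, hi, `<=`)))
  }
})

test_that("som_train converges, separates clusters and is deterministic", {
  # fixed point: all units in the terminal neighborhood reach the sample
  x <- matrix(c(0.3, -0.7), 1)
  cfg <- train_config(alpha0 = 0.5, psi0 = 2, O = 300, J = 3, K = 3,
                      seed = 1)
  g <- som_train(rbind(x, x), cfg)
  u <- moodmap:::unit_index(find_bmu(g, x[1, ])[1], find_bmu(g, x[1, ])[2],
                            3L)
  expect_lt(sqrt(sum((g$W[u, ] - x[1, ])^2)), 1e-3)

  # two well-separated clusters end on distinct units
  set.seed(7)
  d <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
             matrix(rnorm(40, 5, 0.1), 20, 2))
  cfg <- train_config(psi0 = 5, O = 60, J = 10, K = 10, seed = 2)
  g <- som_train(d, cfg)
  b1 <- find_bmu(g, c(0, 0)); b2 <- find_bmu(g, c(5, 5))
  expect_false(all(b1 == b2))

  # determinism: identical seed => bitwise-identical weights
  g2 <- som_train(d, cfg)
  expect_identical(g$W, g2$W)
  g3 <- som_train(d, train_config(psi0 = 5, O = 60, J = 10, K = 10,
                                  seed = 3))
  expect_false(identical(g$W, g3$W))
  expect_error(som_train(matrix(numeric(0), 0, 2), cfg), "empty")
})

test_that("training reduces quantization error on 2-cluster data", {
  ok <- 0
  for (s in 1:100) {
    set.seed(s)
    d <- rbind(matrix(rnorm(30, 0, 0.3), 15, 2),
               matrix(rnorm(30, 4, 0.3), 15, 2))
    cfg <- train_config(psi0 = 4, O = 30, J = 8, K = 8, seed = s)
    W0 <- withr::with_seed(s, moodmap:::init_weights_uniform(d, 64))
    g0 <- moodmap:::new_som_grid(W0, 8L, 8L)
    g <- som_train(d, cfg)
    if (quantization_error(g, d) < quantization_error(g0, d)) ok <- ok + 1
  }
  expect_gte(ok, 95)
})

test_that("C++ training loop agrees with the composed R operations", {
  set.seed(11)
  d <- matrix(rnorm(12), 6, 2)
  cfg <- train_config(alpha0 = 0.3, psi0 = 1, O = 4, J = 3, K = 3, seed = 4)
  orders <- withr::with_seed(99, moodmap:::make_orders(6, 4))
  W0 <- withr::with_seed(4, moodmap:::init_weights_uniform(d, 9))
  got <- som_train(d, cfg, init_weights = W0, orders = orders)
  # replay with the granular exported R ops
  g <- moodmap:::new_som_grid(W0, 3L, 3L)
  for (t in 0:3) {
    a <- cfg$alpha0 * (1 - t / cfg$O)
    p <- neighborhood_extent(cfg, t)
    for (srow in orders[t + 1, ]) {
      b <- find_bmu(g, d[srow, ])
      g <- update_weights(g, d[srow, ], b, a, p)
    }
  }
  expect_equal(got$W, g$W, tolerance = 1e-12)
})

test_that("grid serialization round-trips", {
  g <- random_grid(3, 4, 2, seed = 12)
  base <- file.path(withr::local_tempdir(), "grid")
  som_save(g, base)
  g2 <- som_load(base)
  expect_equal(g2$W, g$W, tolerance = 1e-12)
  expect_identical(c(g2$J, g2$K, g2$I), c(g$J, g$K, g$I))
})
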