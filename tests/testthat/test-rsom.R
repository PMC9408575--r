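fresh_map <- function(W, betas = c(0.5, 0.2, 0.3), update = "gated") {
  cfg <- rsom_config(n_units = nrow(W), betas = betas, update = update)
  moodmap:::new_rsom_map(W, cfg)
}

test_that("rsom_step implements the two-step leaky recursion", {
  W <- matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)
  # beta = (0,0,1): degenerates to the static distance rule
  m <- fresh_map(W, betas = c(0, 0, 1))
  st <- rsom_step(m, c(0.4, 0.4))
  expect_identical(st$bmu, 1L)
  expect_equal(st$map$y1[1, ], c(0.4, 0.4))

  # input equal to a unit's weight with zero history: that unit wins with
  # zero activation
  m <- fresh_map(W)
  st <- rsom_step(m, c(5, 5))
  expect_identical(st$bmu, 2L)
  expect_equal(st$map$y1[2, ], c(0, 0))

  # three constant steps, defaults (0.5, 0.2, 0.3): hand-unrolled factors
  # y1 = 0.3 d; y2 = 0.5*0.3 d + 0.3 d = 0.45 d;
  # y3 = 0.5*0.45 d + 0.2*0.3 d + 0.3 d = 0.585 d
  d <- c(1, -2) - W[1, ]
  m <- fresh_map(W)
  for (expected in c(0.3, 0.45, 0.585)) {
    st <- rsom_step(m, c(1, -2))
    expect_equal(st$map$y1[1, ], expected * d)
    m <- st$map
  }
  expect_error(rsom_step(m, c(1, 2, 3)), "length")
})

test_that("rsom_update gates the step by activation magnitude", {
  W <- matrix(c(0, 0), 1, 2)
  m <- fresh_map(W)
  # zero activation: no movement even with large gamma
  m$y1[] <- 0
  expect_equal(rsom_update(m, c(3, 3), 1L, gamma_t = 1)$W, W)
  # gamma -> 0: no movement
  m$y1[1, ] <- c(1, 1)
  expect_equal(rsom_update(m, c(3, 3), 1L, gamma_t = 0)$W, W)
  # gated half step: gain = gamma * ||y||/(1+||y||)
  nrm <- sqrt(2)
  got <- rsom_update(m, c(3, 3), 1L, gamma_t = 0.5)$W
  expect_equal(got[1, ], 0.5 * nrm / (1 + nrm) * c(3, 3))

  # single unit converges onto a repeated constant input
  cfg <- rsom_config(n_units = 1L, gamma0 = 0.5, O = 200, seed = 1)
  seqm <- matrix(rep(c(2, -1), each = 200), 200, 2)
  map <- rsom_train(seqm, cfg)
  expect_lt(sqrt(sum((map$W[1, ] - c(2, -1))^2)), 1e-2)
})

test_that("activations remain bounded for bounded inputs", {
  set.seed(8)
  seqm <- matrix(runif(400, -1, 1), 200, 2)
  cfg <- rsom_config(n_units = 5L, seed = 2)
  map <- rsom_train(seqm, cfg)
  m <- map; m$y1[] <- 0; m$y2[] <- 0
  maxw <- max(sqrt(rowSums(m$W^2)))
  bound <- (0.5 + 0.2) * 10 + 0.3 * (sqrt(2) + maxw)  # loose a-priori bound
  for (s in seq_len(nrow(seqm))) {
    st <- rsom_step(m, seqm[s, ])
    m <- st$map
    expect_lt(max(sqrt(rowSums(m$y1^2))), bound)
  }
})

test_that("rsom with beta3-only and the som rule reproduces som_core", {
  set.seed(42)
  seqm <- matrix(rnorm(240), 60, 4)
  O <- 40L
  rc <- rsom_config(n_units = 15L, betas = c(0, 0, 1), gamma0 = 0.1,
                    O = O, psi0 = 1L, update = "som", seed = 7)
  sc <- train_config(alpha0 = 0.1, psi0 = 1L, O = O, J = 15L, K = 1L,
                     seed = 7)
  m <- rsom_train(seqm, rc)
  g <- som_train(seqm, sc,
                 orders = matrix(rep(seq_len(60), O), O, byrow = TRUE))
  expect_equal(max(abs(m$W - g$W)), 0, tolerance = 1e-9)
})

test_that("extract_smiles separates frame types and is scale-invariant", {
  # alternating two-frame-type sequence partitions exactly by type
  a <- c(0, 0, 0, 0); b <- c(4, 4, 4, 4)
  seqm <- do.call(rbind, rep(list(a, b), 30))
  cfg <- rsom_config(n_units = 4L, O = 80, seed = 3)
  map <- rsom_train(seqm, cfg)
  sm <- extract_smiles(seqm, map)
  types <- rep(c(1, 2), 30)
  in_smile <- seq_len(60) %in% sm$smile_frames
  expect_true(all(tapply(in_smile, types, function(v) all(v) || !any(v))))
  expect_true(any(in_smile) && !all(in_smile))

  # degenerate constant sequence is flagged
  cseq <- matrix(1, 10, 3)
  cmap <- rsom_train(cseq, rsom_config(n_units = 3L, O = 10, seed = 4))
  csm <- extract_smiles(cseq, cmap)
  expect_true(csm$degenerate)
  expect_true(csm$R %in% c(0L, 10L))

  # uniform scaling of all frames leaves the extraction invariant
  sq <- generate_smile_sequence(smile_spec(n_cycles = 3,
                                           frames_per_cycle = 45, seed = 5))
  cfg <- rsom_config(O = 60, seed = 6)
  m1 <- rsom_train(sq$features, cfg)
  s1 <- extract_smiles(sq$features, m1)
  m2 <- m1; m2$W <- 3 * m1$W
  s2 <- extract_smiles(3 * sq$features, m2)
  expect_identical(s1$smile_frames, s2$smile_frames)
  expect_error(extract_smiles(sq$features[1:2, ], m1), "3 frames")
})

test_that("a neutral calibration frame rescues smile-dominated footage", {
  # smiles dominate the cycle, so the median anchor points the wrong way;
  # a supplied expressionless frame restores the correct orientation
  sq <- generate_smile_sequence(smile_spec(plateau_frac = 0.6,
                                           neutral_frac = 0.2, seed = 21))
  map <- rsom_train(sq$features, rsom_config(O = 100, seed = 22))
  ref <- sq$features[which.min(sq$intensity), ]
  sm <- extract_smiles(sq$features, map, neutral_ref = ref)
  pred <- seq_len(nrow(sq$features)) %in% sm$smile_frames
  expect_gt(mean(pred == sq$gt), 0.85)
  sm0 <- extract_smiles(sq$features, map)
  pred0 <- seq_len(nrow(sq$features)) %in% sm0$smile_frames
  expect_lt(mean(pred0 == sq$gt), 0.5)
  expect_error(extract_smiles(sq$features, map, neutral_ref = c(1, 2)),
               "length")
})

test_that("smile extraction on default tempo cycles beats 90% accuracy", {
  sq <- generate_smile_sequence(smile_spec(seed = 11))
  map <- rsom_train(sq$features, rsom_config(seed = 12))
  sm <- extract_smiles(sq$features, map)
  pred <- seq_len(nrow(sq$features)) %in% sm$smile_frames
  expect_gte(mean(pred == sq$gt), 0.9)
})
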