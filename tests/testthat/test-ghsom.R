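test_that("mean_deviation matches the brute-force oracle", {
  # single unit at 0, single input (3,4): deviation 5
  g <- moodmap:::new_som_grid(matrix(0, 1, 2), 1L, 1L)
  expect_equal(mean_deviation(g, matrix(c(3, 4), 1)), 5)
  # inputs equal to their BMU weights: zero
  g <- random_grid(2, 2, 3, seed = 1)
  expect_equal(mean_deviation(g, g$W), 0)
  for (s in 1:25) {
    set.seed(s)
    g <- random_grid(sample(1:3, 1), sample(1:3, 1), 2, seed = s + 300)
    d <- matrix(rnorm(10), 5, 2)
    expect_equal(mean_deviation(g, d), oracle_mean_deviation(g$W, d),
                 tolerance = 1e-12)
  }
  expect_error(mean_deviation(g, matrix(numeric(0), 0, 2)), "empty")
})

test_that("should_grow applies the breadth-threshold ratio", {
  expect_false(should_grow(0, 1, 0.08))
  expect_true(should_grow(1, 1, 0.08))     # ratio 1 > 0.08
  expect_false(should_grow(0.05, 1, 0.08)) # ratio 0.05 < 0.08
  expect_true(should_grow(0.09, 1, 0.08))
  expect_false(should_grow(0.5, 0, 0.08))  # perfectly quantized parent
  expect_error(should_grow(0.5, 1, 1.5), "T_m")
})

test_that("grow_step enlarges the lattice and reduces quantization error", {
  set.seed(5)
  d <- rbind(matrix(rnorm(20, 0, 0.2), 10, 2),
             matrix(rnorm(20, 6, 0.2), 10, 2),
             matrix(rnorm(20, c(0, 6), 0.2), 10, 2))
  cfg <- moodmap:::ghsom_subcfg(2L, 2L, 60L, 3L)
  g <- som_train(d, cfg)
  g2 <- grow_step(g, d, epochs = 60, seed = 4)
  expect_true((g2$J == 3 && g2$K == 2) || (g2$J == 2 && g2$K == 3))
  expect_lt(mean_deviation(g2, d), mean_deviation(g, d))
})

test_that("build_tree handles degenerate and planted-group inputs", {
  # identical inputs: single leaf, G = 1
  tr <- build_tree(matrix(1, 7, 3), seed = 1)
  expect_identical(tr$G, 1L)
  expect_identical(sort(unlist(tr$leaves)), 1:7)

  # 15 prototypes in 4 planted groups: exact recovery on most seeds
  hits <- 0
  for (s in 1:10) {
    protos <- planted_prototypes(c(4, 4, 4, 3), seed = s)
    tr <- build_tree(protos, seed = s + 40)
    truth <- rep(1:4, c(4, 4, 4, 3))
    got <- integer(15)
    for (l in seq_along(tr$leaves)) got[tr$leaves[[l]]] <- l
    if (adjusted_rand(truth, got) == 1) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("leaves always partition the inputs and the tree is bounded", {
  for (s in 1:10) {
    set.seed(s)
    n <- sample(5:20, 1)
    x <- matrix(rnorm(n * 3) * sample(1:5, 1), n, 3)
    tr <- build_tree(x, epochs = 30, seed = s)
    expect_identical(sort(unlist(tr$leaves)), seq_len(n))
    expect_identical(tr$G, length(tr$leaves))
    # depth bound
    maxd <- 0
    walk <- function(node) {
      if (is.null(node)) return(invisible())
      maxd <<- max(maxd, node$depth)
      for (ch in node$children) walk(ch)
    }
    walk(tr$root)
    expect_lte(maxd, 5)
  }
})

test_that("child maps never increase the assignment deviation", {
  for (s in 1:8) {
    protos <- planted_prototypes(c(5, 5, 5), dim = 4, noise = 0.8,
                                 seed = s + 7)
    tr <- build_tree(protos, epochs = 60, seed = s)
    check <- function(node) {
      if (is.null(node)) return(invisible())
      for (u in names(node$children)) {
        ui <- as.integer(u)
        m <- node$assignment == ui
        sub <- protos[node$input_idx[m], , drop = FALSE]
        v_parent <- moodmap:::mean_deviation_point(node$map$W[ui, ], sub)
        expect_lte(node$children[[u]]$v_m, v_parent + 1e-9)
        check(node$children[[u]])
      }
    }
    check(tr$root)
  }
})

test_that("a two-level structure is representable and serializes stably", {
  # five first-layer groups, the fourth splitting into two at depth 2
  set.seed(33)
  centers <- rbind(c(0, 0), c(20, 0), c(0, 20), c(20, 20), c(40, 40))
  sizes <- c(3, 3, 3, 4, 2)
  xs <- do.call(rbind, lapply(1:5, function(g) {
    base <- matrix(rnorm(sizes[g] * 2, 0, 0.05), sizes[g], 2) +
      rep(centers[g, ], each = sizes[g])
    if (g == 4) base + cbind(rep(c(0, 2.5), each = 2), 0) else base
  }))
  tr <- build_tree(xs, epochs = 80, seed = 10)
  depths <- integer(0)
  walk <- function(node) {
    if (is.null(node)) return(invisible())
    depths <<- c(depths, node$depth)
    for (ch in node$children) walk(ch)
  }
  walk(tr$root)
  expect_gte(max(depths), 2)       # a second layer exists
  expect_gte(tr$G, 5)
  # every spawned layer map starts as 2x2
  shapes <- list()
  walk2 <- function(node) {
    if (is.null(node)) return(invisible())
    shapes[[length(shapes) + 1L]] <<- node$initial_shape
    for (ch in node$children) walk2(ch)
  }
  walk2(tr$root)
  expect_true(all(vapply(shapes, function(sp) all(sp == c(2L, 2L)),
                         logical(1))))

  # byte-stable serialization under a fixed seed
  f1 <- file.path(withr::local_tempdir(), "t1.json")
  f2 <- file.path(withr::local_tempdir(), "t2.json")
  ghsom_to_json(build_tree(xs, epochs = 80, seed = 10), f1)
  ghsom_to_json(build_tree(xs, epochs = 80, seed = 10), f2)
  expect_identical(readLines(f1), readLines(f2))
  txt <- format(tr)
  expect_true(any(grepl("depth 2", txt)))
})
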