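#' Mean deviation (quantization error) of a map over assigned inputs
#'
#' Mean Euclidean distance between each input and the weight of its BMU on
#' the map. This is the growth statistic `v_m` of the hierarchy: a map (or a
#' single prototype) quantizing its inputs well has small mean deviation.
#'
#' @param grid a `som_grid` (or, for a single prototype, a 1-row weight
#'   matrix wrapped via [new_som_grid()] is unnecessary -- see
#'   `mean_deviation_point()`).
#' @param data matrix of assigned inputs (>= 1 row).
#' @return non-negative scalar `v_m`.
#' @export
mean_deviation <- function(grid, data) {
  data <- as.matrix(data)
  if (nrow(data) == 0L) stop_mm("mean_deviation: empty assignment")
  u <- bmu_assign(grid, data)
  mean(sqrt(rowSums((data - grid$W[u, , drop = FALSE])^2)))
}

# Deviation of inputs around a single reference vector (the root w0, or one
# unit's weight).
mean_deviation_point <- function(w, data) {
  data <- as.matrix(data)
  if (nrow(data) == 0L) stop_mm("mean_deviation_point: empty assignment")
  mean(sqrt(rowSums((data - rep(w, each = nrow(data)))^2)))
}

#' Hierarchical growth decision
#'
#' A map keeps growing (and a unit spawns a child map) while the ratio of
#' its mean deviation to the parent deviation exceeds the breadth threshold
#' `T_m` (default 0.08). A perfectly quantized parent (`v_parent = 0`)
#' never grows.
#'
#' @param v_m mean deviation of the candidate map/unit.
#' @param v_parent mean deviation of the parent assignment.
#' @param T_m breadth threshold in (0, 1).
#' @return logical.
#' @export
should_grow <- function(v_m, v_parent, T_m = 0.08) {
  check_number(v_m, "v_m"); check_number(v_parent, "v_parent")
  if (!(T_m > 0 && T_m < 1)) stop_mm("T_m must be in (0, 1)")
  if (v_parent <= 0) return(FALSE)
  v_m / v_parent > T_m
}

# Per-unit mean deviation over assigned inputs; units without inputs get 0.
unit_deviations <- function(grid, data, assign_u) {
  dev <- numeric(grid$J * grid$K)
  for (u in unique(assign_u)) {
    m <- assign_u == u
    dev[u] <- mean(sqrt(rowSums(
      (as.matrix(data)[m, , drop = FALSE] -
         rep(grid$W[u, ], each = sum(m)))^2)))
  }
  dev
}

lateral_neighbors <- function(j, k, J, K) {
  out <- NULL
  if (j > 1) out <- rbind(out, c(j - 1L, k))
  if (j < J) out <- rbind(out, c(j + 1L, k))
  if (k > 1) out <- rbind(out, c(j, k - 1L))
  if (k < K) out <- rbind(out, c(j, k + 1L))
  out
}

ghsom_subcfg <- function(J, K, epochs, seed) {
  train_config(alpha0 = 0.1, psi0 = 1L, O = epochs, J = J, K = K, seed = seed)
}

#' One lateral growth step of a layer map
#'
#' The four-step unit insertion: (1) find the error unit `u_e` with the
#' largest mean deviation over its assigned inputs; (2) pick the dissimilar
#' unit `u_d` among the lateral neighbors of `u_e` -- by default, per the
#' source's literal rule, the neighbor with the *minimum* deviation
#' (`ud_rule = "min_deviation"`); the standard-GHSOM alternative, the
#' neighbor with the most dissimilar weight, is available as
#' `ud_rule = "max_weight_distance"`; (3) insert a full row or column of new
#' units between them, with weights interpolated as the mean of the flanking
#' units; (4) retrain the enlarged map with the SOM rule and reassign inputs.
#' Ties break to the smallest `(j, k)`.
#'
#' @param grid a `som_grid` layer map.
#' @param data assigned inputs of this map.
#' @param epochs retraining epochs.
#' @param seed retraining seed (presentation order).
#' @param ud_rule dissimilar-unit selection rule (see above).
#' @return the retrained, enlarged `som_grid`.
#' @export
grow_step <- function(grid, data, epochs = 50L, seed = 1L,
                      ud_rule = c("min_deviation", "max_weight_distance")) {
  ud_rule <- match.arg(ud_rule)
  data <- as.matrix(data)
  au <- bmu_assign(grid, data)
  dev <- unit_deviations(grid, data, au)
  ue <- which.max(dev)  # first maximum = smallest (j, k)
  co <- unit_coords(ue, grid$K)
  nb <- lateral_neighbors(co[1], co[2], grid$J, grid$K)
  nb_u <- unit_index(nb[, 1], nb[, 2], grid$K)
  ud <- if (ud_rule == "min_deviation") {
    nb_u[which.min(dev[nb_u])]
  } else {
    d2 <- rowSums((grid$W[nb_u, , drop = FALSE] -
                     rep(grid$W[ue, ], each = length(nb_u)))^2)
    nb_u[which.max(d2)]
  }
  cd <- unit_coords(ud, grid$K)
  A <- array(0, dim = c(grid$J, grid$K, grid$I))
  allco <- unit_coords(seq_len(grid$J * grid$K), grid$K)
  for (i in seq_len(grid$I)) A[cbind(allco, i)] <- grid$W[, i]
  if (co[1] != cd[1]) {
    # insert a row of units between rows j_e and j_d
    jlo <- min(co[1], cd[1])
    newrow <- (A[jlo, , , drop = FALSE] + A[jlo + 1, , , drop = FALSE]) / 2
    A2 <- array(0, dim = c(grid$J + 1, grid$K, grid$I))
    A2[1:jlo, , ] <- A[1:jlo, , ]
    A2[jlo + 1, , ] <- newrow
    A2[(jlo + 2):(grid$J + 1), , ] <- A[(jlo + 1):grid$J, , ]
    J2 <- grid$J + 1L; K2 <- grid$K
  } else {
    klo <- min(co[2], cd[2])
    newcol <- (A[, klo, , drop = FALSE] + A[, klo + 1, , drop = FALSE]) / 2
    A2 <- array(0, dim = c(grid$J, grid$K + 1, grid$I))
    A2[, 1:klo, ] <- A[, 1:klo, ]
    A2[, klo + 1, ] <- newcol
    A2[, (klo + 2):(grid$K + 1), ] <- A[, (klo + 1):grid$K, ]
    J2 <- grid$J; K2 <- grid$K + 1L
  }
  W2 <- matrix(0, J2 * K2, grid$I)
  co2 <- unit_coords(seq_len(J2 * K2), K2)
  for (i in seq_len(grid$I)) W2[, i] <- A2[cbind(co2, i)]
  cfg <- ghsom_subcfg(J2, K2, epochs, seed)
  som_train(data, cfg, init_weights = W2)
}

# Build one layer map (2x2, grown laterally) plus its children, recursively.
ghsom_layer <- function(data, v_parent, depth, T_m, max_per_layer, max_depth,
                        max_units, epochs, seed, ud_rule, counter_env) {
  nstream <- function() {
    counter_env$n <- counter_env$n + 1L
    derive_seed(seed, counter_env$n)
  }
  idx <- attr(data, "idx")
  data <- as.matrix(data)
  cfg <- ghsom_subcfg(2L, 2L, epochs, nstream())
  map <- som_train(data, cfg)
  steps <- 0L
  repeat {
    v_m <- mean_deviation(map, data)
    if (!should_grow(v_m, v_parent, T_m)) break
    if (steps >= max_per_layer || map$J * map$K >= max_units) break
    map <- grow_step(map, data, epochs = epochs, seed = nstream(),
                     ud_rule = ud_rule)
    steps <- steps + 1L
  }
  au <- bmu_assign(map, data)
  children <- list()
  occupied <- sort(unique(au))
  for (u in occupied) {
    m <- au == u
    sub <- data[m, , drop = FALSE]
    v_u <- mean_deviation_point(map$W[u, ], sub)
    if (depth < max_depth && sum(m) >= 2L &&
        nrow(unique(sub)) >= 2L && should_grow(v_u, v_parent, T_m)) {
      attr(sub, "idx") <- idx[m]
      children[[as.character(u)]] <-
        ghsom_layer(sub, v_u, depth + 1L, T_m, max_per_layer, max_depth,
                    max_units, epochs, seed, ud_rule, counter_env)
      children[[as.character(u)]]$parent_unit <- u
    }
  }
  list(map = map, depth = depth, n = nrow(data),
       initial_shape = c(2L, 2L),
       v_m = mean_deviation(map, data), assignment = au,
       input_idx = idx, children = children)
}

#' Build a growing hierarchical SOM tree
#'
#' The top layer is a single virtual unit with weight `w0 =` the mean of all
#' inputs and deviation `v_0` around it. One 2x2 layer-1 map is trained on
#' all inputs and grown laterally with [grow_step()] while
#' `v_m / v_0 > T_m`, up to `max_per_layer` insertions (and at most
#' `max_units` units per map). Any unit whose own assignment deviation still
#' exceeds `T_m` relative to this map's parent deviation spawns a fresh 2x2
#' child map on its assigned inputs, recursively, down to `max_depth`.
#' Leaves (occupied units without children) enumerate the `G` clusters.
#'
#' @param inputs numeric matrix (vectors x dimensions), e.g. the 15 RSOM
#'   prototypes.
#' @param T_m breadth threshold in (0, 1); default 0.08.
#' @param max_per_layer maximum lateral growth insertions per layer map
#'   (default 4, giving at most 4x4 maps from a 2x2 start).
#' @param max_depth maximum hierarchy depth (default 5).
#' @param max_units hard cap on units per map (default 16).
#' @param epochs SOM training epochs per (re)training (default 200).
#' @param seed integer seed; the whole tree is deterministic given it.
#' @param ud_rule dissimilar-unit rule, see [grow_step()].
#' @return object of class `ghsom_tree`: list with `w0`, `v0`, `root`
#'   (recursive node structure), `leaves` (list of input-index vectors),
#'   and `G` (leaf count).
#' @export
build_tree <- function(inputs, T_m = 0.08, max_per_layer = 4L,
                       max_depth = 5L, max_units = 16L, epochs = 200L,
                       seed = 1L, ud_rule = "min_deviation") {
  inputs <- as.matrix(inputs)
  if (nrow(inputs) < 1L) stop_mm("build_tree: need at least one input")
  if (any(!is.finite(inputs))) stop_mm("build_tree: non-finite inputs")
  if (!(T_m > 0 && T_m < 1)) stop_mm("T_m must be in (0, 1)")
  attr(inputs, "idx") <- seq_len(nrow(inputs))
  w0 <- colMeans(inputs)
  v0 <- mean_deviation_point(w0, inputs)
  counter_env <- new.env(parent = emptyenv())
  counter_env$n <- 0L
  root <- if (v0 > 0) {
    ghsom_layer(inputs, v0, 1L, T_m, max_per_layer, max_depth, max_units,
                epochs, seed, ud_rule, counter_env)
  } else {
    NULL
  }
  leaves <- list()
  collect <- function(node) {
    for (u in sort(unique(node$assignment))) {
      ch <- node$children[[as.character(u)]]
      idx <- node$input_idx[node$assignment == u]
      if (is.null(ch)) {
        leaves[[length(leaves) + 1L]] <<- idx
      } else {
        collect(ch)
      }
    }
  }
  if (is.null(root)) {
    leaves <- list(seq_len(nrow(inputs)))
  } else {
    collect(root)
  }
  structure(list(w0 = w0, v0 = v0, root = root, leaves = leaves,
                 G = length(leaves), seed = as.integer(seed), T_m = T_m),
            class = "ghsom_tree")
}

#' @export
print.ghsom_tree <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Indented text rendering of a GHSOM tree
#'
#' @param x a `ghsom_tree`.
#' @param ... unused.
#' @return character vector of lines.
#' @export
format.ghsom_tree <- function(x, ...) {
  lines <- c(sprintf("ghsom_tree: %d inputs, G = %d leaf clusters, v0 = %.4g",
                     if (is.null(x$root)) length(x$leaves[[1]]) else x$root$n,
                     x$G, x$v0))
  walk <- function(node, indent) {
    pre <- strrep("  ", indent)
    lines <<- c(lines, sprintf("%s[depth %d] %dx%d map, %d inputs, v=%.4g",
                               pre, node$depth, node$map$J, node$map$K,
                               node$n, node$v_m))
    for (u in sort(unique(node$assignment))) {
      idx <- node$input_idx[node$assignment == u]
      ch <- node$children[[as.character(u)]]
      if (is.null(ch)) {
        lines <<- c(lines, sprintf("%s  unit %d: leaf {%s}", pre, u,
                                   paste(idx, collapse = ",")))
      } else {
        lines <<- c(lines, sprintf("%s  unit %d:", pre, u))
        walk(ch, indent + 2L)
      }
    }
  }
  if (!is.null(x$root)) walk(x$root, 1L)
  lines
}

#' Serialize a GHSOM tree to JSON
#'
#' @param tree a `ghsom_tree`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
ghsom_to_json <- function(tree, path) {
  strip <- function(node) {
    if (is.null(node)) return(NULL)
    list(depth = node$depth,
         shape = c(node$map$J, node$map$K),
         n_inputs = node$n,
         v_m = node$v_m,
         units = lapply(sort(unique(node$assignment)), function(u) {
           list(unit = u,
                inputs = node$input_idx[node$assignment == u],
                child = strip(node$children[[as.character(u)]]))
         }))
  }
  obj <- list(G = tree$G, v0 = tree$v0, seed = tree$seed, T_m = tree$T_m,
              leaves = tree$leaves, root = strip(tree$root))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10,
                       null = "null")
  invisible(path)
}
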