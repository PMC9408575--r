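#' SOM training configuration
#'
#' Meta-parameters of the online SOM, with the study's defaults: a 50x50
#' rectangular lattice, initial learning coefficient `alpha0 = 0.1`, initial
#' square-neighborhood radius `psi0 = 40`, and `O = 200` learning epochs.
#' The learning rate decays linearly, `alpha_t = alpha0 * (1 - t/O)`, and the
#' neighborhood radius as `psi_t = floor(psi0 * (1 - t/O) + 0.5)`, reaching 0
#' at the final epoch.
#'
#' @param alpha0 initial learning coefficient in (0, 1].
#' @param psi0 initial neighborhood radius (non-negative integer, Chebyshev).
#' @param O maximum number of learning epochs (>= 1).
#' @param J,K lattice width and height in units.
#' @param seed integer RNG seed for weight initialization and presentation
#'   order.
#' @return an object of class `train_config`.
#' @export
train_config <- function(alpha0 = 0.1, psi0 = 40, O = 200,
                         J = 50, K = 50, seed = 1L) {
  if (!(alpha0 > 0 && alpha0 <= 1)) stop_mm("alpha0 must be in (0, 1]")
  if (psi0 < 0 || psi0 != floor(psi0)) {
    stop_mm("psi0 must be a non-negative integer")
  }
  if (O < 1) stop_mm("O must be >= 1")
  if (J < 1 || K < 1) stop_mm("J and K must be >= 1")
  structure(list(alpha0 = alpha0, psi0 = as.integer(psi0), O = as.integer(O),
                 J = as.integer(J), K = as.integer(K),
                 seed = as.integer(seed)),
            class = "train_config")
}

# Linear (1-based) unit index from lattice coordinates; u = (j-1)*K + k so
# increasing u is lexicographic in (j, k).
unit_index <- function(j, k, K) (j - 1L) * K + k

unit_coords <- function(u, K) {
  cbind(j = ((u - 1L) %/% K) + 1L, k = ((u - 1L) %% K) + 1L)
}

new_som_grid <- function(W, J, K, epoch = 0L, seed = NA_integer_) {
  stopifnot(nrow(W) == J * K)
  seed <- if (is.null(seed) || length(seed) != 1L) {
    NA_integer_
  } else {
    suppressWarnings(as.integer(seed))
  }
  structure(list(W = W, J = as.integer(J), K = as.integer(K),
                 I = ncol(W), epoch = as.integer(epoch),
                 seed = seed),
            class = "som_grid")
}

#' @export
print.som_grid <- function(x, ...) {
  cat(sprintf("som_grid: %d x %d lattice, input dim %d, epoch %d\n",
              x$J, x$K, x$I, x$epoch))
  invisible(x)
}

#' Best-matching unit of an input vector
#'
#' Returns the lattice unit whose weight vector minimizes the squared
#' Euclidean distance to `x`. Ties break deterministically to the smallest
#' `j`, then smallest `k`.
#'
#' @param grid a `som_grid`.
#' @param x numeric vector of length `grid$I`.
#' @return integer vector `c(j, k)` (1-based lattice coordinates).
#' @export
find_bmu <- function(grid, x) {
  if (length(x) != grid$I) {
    stop_mm("find_bmu: input has length %d, grid expects %d",
            length(x), grid$I)
  }
  d <- colSums((t(grid$W) - x)^2)
  u <- which.min(d)  # first minimum = smallest (j, k)
  as.integer(unit_coords(u, grid$K)[1, ])
}

#' Neighborhood radius schedule
#'
#' `psi_t = floor(psi0 * (1 - t/O) + 0.5)`: linear shrinkage of the square
#' neighborhood from `psi0` at epoch 0 to 0 at epoch `O`.
#'
#' @param cfg a [train_config()].
#' @param t epoch, `0 <= t <= O`.
#' @return integer radius.
#' @export
neighborhood_extent <- function(cfg, t) {
  check_number(t, "t")
  if (t < 0 || t > cfg$O) stop_mm("epoch t=%g outside [0, %d]", t, cfg$O)
  as.integer(floor(cfg$psi0 * (1 - t / cfg$O) + 0.5))
}

#' Single SOM weight update
#'
#' Moves every unit within the square (Chebyshev) neighborhood of radius
#' `psi_t` around the BMU, clipped at the lattice edges, by
#' `w <- w + alpha_t * (x - w)`. All other units are unchanged.
#'
#' @param grid a `som_grid`.
#' @param x input vector.
#' @param bmu `c(j, k)` as returned by [find_bmu()].
#' @param alpha_t learning rate in (0, 1].
#' @param psi_t neighborhood radius (>= 0).
#' @return the updated `som_grid`.
#' @export
update_weights <- function(grid, x, bmu, alpha_t, psi_t) {
  if (!(alpha_t > 0 && alpha_t <= 1)) stop_mm("alpha_t must be in (0, 1]")
  if (psi_t < 0) stop_mm("psi_t must be >= 0")
  jr <- max(1L, bmu[1] - psi_t):min(grid$J, bmu[1] + psi_t)
  kr <- max(1L, bmu[2] - psi_t):min(grid$K, bmu[2] + psi_t)
  idx <- as.vector(outer(jr, kr, function(j, k) unit_index(j, k, grid$K)))
  W <- grid$W
  W[idx, ] <- W[idx, ] + alpha_t * (rep(x, each = length(idx)) - W[idx, ])
  grid$W <- W
  grid
}

# Seeded uniform weight initialization in the per-dimension data range.
init_weights_uniform <- function(data, n_units) {
  lo <- apply(data, 2, min)
  hi <- apply(data, 2, max)
  U <- matrix(runif(n_units * ncol(data)), n_units, ncol(data))
  sweep(sweep(U, 2, hi - lo, `*`), 2, lo, `+`)
}

# One shuffled presentation order per epoch, O x n.
make_orders <- function(n, O) {
  t(vapply(seq_len(O), function(t) sample.int(n), integer(n)))
}

#' Train a SOM
#'
#' Online training: `O` epochs, each presenting every sample once in a
#' seeded shuffled order, with linearly decaying learning rate and shrinking
#' square neighborhood (see [train_config()]). Identical seed and data give
#' bitwise-identical weights.
#'
#' @param data numeric matrix (samples x dimensions) or data.frame.
#' @param cfg a [train_config()].
#' @param init_weights optional initial weight matrix `(J*K) x I`; default
#'   seeded uniform in the per-dimension data range.
#' @param orders optional `O x n` presentation-order matrix (1-based sample
#'   indices); default seeded per-epoch shuffles. Mainly for tests.
#' @return a trained `som_grid`.
#' @export
som_train <- function(data, cfg = train_config(), init_weights = NULL,
                      orders = NULL) {
  data <- as.matrix(data)
  if (nrow(data) == 0L) stop_mm("som_train: empty data")
  if (any(!is.finite(data))) stop_mm("som_train: non-finite values in data")
  n_units <- cfg$J * cfg$K
  with_seed(cfg$seed, {
    if (is.null(init_weights)) {
      init_weights <- init_weights_uniform(data, n_units)
    }
    if (is.null(orders)) orders <- make_orders(nrow(data), cfg$O)
  })
  stopifnot(nrow(init_weights) == n_units, ncol(init_weights) == ncol(data),
            nrow(orders) == cfg$O, ncol(orders) == nrow(data))
  ts <- seq_len(cfg$O) - 1
  alpha <- cfg$alpha0 * (1 - ts / cfg$O)
  psi <- vapply(ts, function(t) neighborhood_extent(cfg, t), integer(1))
  W <- .som_train_cpp(data, init_weights, cfg$J, cfg$K,
                      orders, alpha, psi)
  new_som_grid(W, cfg$J, cfg$K, epoch = cfg$O, seed = cfg$seed)
}

#' BMU assignment of a whole dataset
#'
#' @param grid a `som_grid`.
#' @param data matrix of samples.
#' @return integer vector of 1-based linear unit indices (`u = (j-1)*K + k`).
#' @export
bmu_assign <- function(grid, data) {
  data <- as.matrix(data)
  if (ncol(data) != grid$I) stop_mm("bmu_assign: dimension mismatch")
  .bmu_all_cpp(data, grid$W) + 1L
}

#' Mean quantization error
#'
#' Mean squared Euclidean distance between samples and their BMU weights.
#'
#' @inheritParams bmu_assign
#' @return non-negative scalar.
#' @export
quantization_error <- function(grid, data) {
  data <- as.matrix(data)
  u <- bmu_assign(grid, data)
  mean(rowSums((data - grid$W[u, , drop = FALSE])^2))
}

#' Serialize / load a SOM grid
#'
#' Writes shape and schedule metadata as JSON and the weight matrix as CSV
#' next to it, so a trained map can be reloaded for U-Matrix computation.
#'
#' @param grid a `som_grid`.
#' @param path base path; `<path>.json` and `<path>_weights.csv` are written.
#' @return `som_save` returns `path` invisibly; `som_load` the `som_grid`.
#' @export
som_save <- function(grid, path) {
  meta <- list(J = grid$J, K = grid$K, I = grid$I,
               epoch = grid$epoch, seed = grid$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  write.csv(as.data.frame(grid$W), paste0(path, "_weights.csv"),
            row.names = FALSE)
  invisible(path)
}

#' @rdname som_save
#' @export
som_load <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  W <- as.matrix(read.csv(paste0(path, "_weights.csv")))
  dimnames(W) <- NULL
  new_som_grid(W, meta$J, meta$K, epoch = meta$epoch, seed = meta$seed)
}
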