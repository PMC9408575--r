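#' Recurrent SOM for facial time series
#'
#' A 15-unit recurrent SOM (RSOM) whose unit activations carry a leaky,
#' two-step memory of past inputs:
#' `y(t) = beta1*y(t-1) + beta2*y(t-2) + beta3*(x_t - w)`, with the BMU the
#' unit minimizing `||y(t)||^2`. Defaults follow the study: 15 units (the
#' prototype count fixed by the expression-chart representation), learning
#' coefficients `betas = (0.5, 0.2, 0.3)`, `gamma = 0.1`, 200 epochs. The
#' units form a 1-D chain with neighborhood radius 1; activation histories
#' are zero at sequence start.
#'
#' @param n_units number of mapping units (default 15).
#' @param betas numeric length-3 `(beta1, beta2, beta3)`.
#' @param gamma0 initial weight-update coefficient (decays linearly to 0).
#' @param O training epochs over the sequence.
#' @param psi0 initial chain neighborhood radius (default 1), shrinking
#'   linearly to 0 over the epochs like the static SOM's schedule.
#' @param update `"gated"` (default; step size modulated by activation
#'   magnitude `||y||/(1+||y||)`) or `"som"` (plain SOM rule, which makes the
#'   model degenerate to a static SOM when `betas = c(0, 0, 1)`).
#' @param seed RNG seed for weight initialization.
#' @return an `rsom_config` object.
#' @export
rsom_config <- function(n_units = 15L, betas = c(0.5, 0.2, 0.3),
                        gamma0 = 0.1, O = 200L, psi0 = 1L,
                        update = c("gated", "som"), seed = 1L) {
  update <- match.arg(update)
  if (length(betas) != 3L || any(!is.finite(betas))) {
    stop_mm("betas must be three finite numbers")
  }
  sb <- sum(betas)
  if (!(sb > 0 && sb <= 1.5)) stop_mm("sum(betas) must lie in (0, 1.5]")
  if (!(gamma0 > 0 && gamma0 <= 1)) stop_mm("gamma0 must be in (0, 1]")
  structure(list(n_units = as.integer(n_units), betas = betas,
                 gamma0 = gamma0, O = as.integer(O),
                 psi0 = as.integer(psi0), update = update,
                 seed = as.integer(seed)),
            class = "rsom_config")
}

new_rsom_map <- function(W, cfg) {
  structure(list(W = W, n_units = nrow(W), I = ncol(W),
                 betas = cfg$betas, update = cfg$update,
                 y1 = matrix(0, nrow(W), ncol(W)),
                 y2 = matrix(0, nrow(W), ncol(W)),
                 seed = cfg$seed),
            class = "rsom_map")
}

#' @export
print.rsom_map <- function(x, ...) {
  cat(sprintf("rsom_map: %d units, input dim %d, betas (%s)\n",
              x$n_units, x$I, paste(x$betas, collapse = ", ")))
  invisible(x)
}

#' One recurrent activation step
#'
#' Computes the new activations `y = beta1*y1 + beta2*y2 + beta3*(x - W)`,
#' picks the BMU minimizing `||y||^2` (ties to the smallest unit index),
#' and shifts the activation history by one step.
#'
#' @param map an `rsom_map`.
#' @param x_t input vector for this frame.
#' @return list with `bmu` (1-based unit index) and the updated `map`.
#' @export
rsom_step <- function(map, x_t) {
  if (length(x_t) != map$I) {
    stop_mm("rsom_step: input has length %d, map expects %d",
            length(x_t), map$I)
  }
  b <- map$betas
  y <- b[1] * map$y1 + b[2] * map$y2 +
    b[3] * (rep(x_t, each = map$n_units) - map$W)
  bmu <- which.min(rowSums(y^2))
  map$y2 <- map$y1
  map$y1 <- y
  list(bmu = bmu, map = map)
}

#' One RSOM weight update
#'
#' Moves the BMU and its chain neighbors within radius `psi` toward `x_t`.
#' Under the gated rule the step is scaled per unit by
#' `||y||/(1 + ||y||)`, bounding the activation-driven gain; under the
#' `"som"` rule the step is plain `gamma_t * (x - w)`.
#'
#' @param map an `rsom_map` (activations `y1` holding the current step's
#'   activations, i.e. call after [rsom_step()]).
#' @param x_t input vector.
#' @param bmu BMU unit index from [rsom_step()].
#' @param gamma_t learning coefficient in (0, 1].
#' @param psi chain neighborhood radius (default 1).
#' @return the updated `rsom_map`.
#' @export
rsom_update <- function(map, x_t, bmu, gamma_t, psi = 1L) {
  if (!(gamma_t >= 0 && gamma_t <= 1)) stop_mm("gamma_t must be in [0, 1]")
  idx <- max(1L, bmu - psi):min(map$n_units, bmu + psi)
  for (u in idx) {
    gain <- if (map$update == "gated") {
      nrm <- sqrt(sum(map$y1[u, ]^2))
      gamma_t * nrm / (1 + nrm)
    } else {
      gamma_t
    }
    map$W[u, ] <- map$W[u, ] + gain * (x_t - map$W[u, ])
  }
  map
}

#' Train an RSOM on an ordered frame sequence
#'
#' Presents the sequence in temporal order for `cfg$O` epochs with
#' `gamma_t = gamma0 * (1 - t/O)`; activation histories reset to zero at
#' each epoch start. The hot loop runs in compiled code; identical seed and
#' sequence give bitwise-identical weights.
#'
#' @param seq_mat numeric matrix, frames x dimensions (>= 3 frames).
#' @param cfg an [rsom_config()].
#' @param init_weights optional initial weights (`n_units x I`); default
#'   seeded uniform in the per-dimension data range.
#' @return a trained `rsom_map`.
#' @export
rsom_train <- function(seq_mat, cfg = rsom_config(), init_weights = NULL) {
  seq_mat <- as.matrix(seq_mat)
  if (nrow(seq_mat) < 3L) stop_mm("rsom_train: need at least 3 frames")
  if (any(!is.finite(seq_mat))) stop_mm("rsom_train: non-finite values")
  if (is.null(init_weights)) {
    init_weights <- with_seed(cfg$seed,
                              init_weights_uniform(seq_mat, cfg$n_units))
  }
  ts <- seq_len(cfg$O) - 1
  gamma <- cfg$gamma0 * (1 - ts / cfg$O)
  # same linear shrink as the static SOM so that betas = (0,0,1) with the
  # "som" update rule reproduces som_train trajectories exactly
  psi <- as.integer(floor(cfg$psi0 * (1 - ts / cfg$O) + 0.5))
  W <- .rsom_train_cpp(seq_mat, init_weights,
                       cfg$betas[1], cfg$betas[2], cfg$betas[3],
                       gamma, as.integer(psi), cfg$update == "gated")
  new_rsom_map(W, cfg)
}

# Forward pass without weight updates: BMU per frame with fresh history.
rsom_assign <- function(map, seq_mat) {
  seq_mat <- as.matrix(seq_mat)
  m <- map
  m$y1[] <- 0; m$y2[] <- 0
  out <- integer(nrow(seq_mat))
  for (s in seq_len(nrow(seq_mat))) {
    st <- rsom_step(m, seq_mat[s, ])
    out[s] <- st$bmu
    m <- st$map
  }
  out
}

#' Extract smile-expression frames from a sequence
#'
#' Assigns every frame to its BMU on a trained RSOM, splits the unit
#' prototypes into two groups by 2-means (deterministically initialized at
#' the most distant prototype pair), and takes as the smile group the one
#' whose prototypes lie farther, on average, from the sequence's
#' per-dimension median frame (the neutral pole). Frames mapped to
#' smile-group units are the extracted smiles; their count is the
#' per-session feature `R`.
#'
#' @param seq_mat numeric matrix, frames x dimensions (>= 3 frames).
#' @param map a trained `rsom_map`.
#' @param neutral_ref optional calibration vector: a known expressionless
#'   frame to use as the neutral anchor instead of the sequence's
#'   per-dimension median (use when smiles dominate the recording).
#' @return list with `smile_frames` (frame indices), `assignment` (per-frame
#'   unit), `smile_units`, `R` (number of smile frames), and `degenerate`
#'   (TRUE when the prototypes carry no spread to split on).
#' @export
extract_smiles <- function(seq_mat, map, neutral_ref = NULL) {
  seq_mat <- as.matrix(seq_mat)
  if (nrow(seq_mat) < 3L) stop_mm("extract_smiles: need at least 3 frames")
  assignment <- rsom_assign(map, seq_mat)
  W <- map$W
  D <- as.matrix(stats::dist(W))
  degenerate <- max(D) == 0
  if (degenerate) {
    smile_units <- integer(0)
  } else {
    far <- which(D == max(D), arr.ind = TRUE)[1, ]
    km <- suppressWarnings(
      kmeans(W, centers = W[c(far[1], far[2]), , drop = FALSE])
    )
    med <- if (is.null(neutral_ref)) {
      apply(seq_mat, 2, median)
    } else {
      if (length(neutral_ref) != map$I) {
        stop_mm("extract_smiles: neutral_ref has length %d, map expects %d",
                length(neutral_ref), map$I)
      }
      as.numeric(neutral_ref)
    }
    dmed <- sqrt(rowSums((W - rep(med, each = nrow(W)))^2))
    g1 <- mean(dmed[km$cluster == 1])
    g2 <- mean(dmed[km$cluster == 2])
    smile_cluster <- if (g1 >= g2) 1L else 2L
    smile_units <- which(km$cluster == smile_cluster)
  }
  smile_frames <- which(assignment %in% smile_units)
  list(smile_frames = smile_frames, assignment = assignment,
       smile_units = smile_units, R = length(smile_frames),
       degenerate = degenerate)
}
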