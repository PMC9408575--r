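#' Gaze trace container
#'
#' Time-stamped screen-coordinate samples from an eye tracker (emulating a
#' 60 Hz head-and-eye tracking device). Invalid samples (blinks, dropouts)
#' are flagged rather than removed.
#'
#' @param t sample times in seconds, strictly increasing.
#' @param x,y screen coordinates in pixels.
#' @param valid logical/0-1 validity flags (default all valid).
#' @param rate nominal sampling rate in Hz (default 60).
#' @param screen `c(width, height)` in pixels (default 1920 x 1080).
#' @return object of class `gaze_trace`.
#' @export
gaze_trace <- function(t, x, y, valid = rep(TRUE, length(t)),
                       rate = 60, screen = c(1920, 1080)) {
  if (any(diff(t) <= 0)) stop_mm("gaze_trace: times must strictly increase")
  if (length(x) != length(t) || length(y) != length(t)) {
    stop_mm("gaze_trace: x/y/t length mismatch")
  }
  structure(list(t = t, x = x, y = y, valid = as.logical(valid),
                 rate = rate, screen = screen),
            class = "gaze_trace")
}

#' Read a gaze trace from CSV
#'
#' Columns: `t_s, x_px, y_px, valid` (0/1).
#'
#' @param path CSV path.
#' @inheritParams gaze_trace
#' @return a `gaze_trace`.
#' @export
load_gaze_csv <- function(path, rate = 60, screen = c(1920, 1080)) {
  df <- read.csv(path)
  req <- c("t_s", "x_px", "y_px", "valid")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop_mm("gaze CSV '%s' missing column(s): %s", path,
            paste(missing, collapse = ", "))
  }
  gaze_trace(df$t_s, df$x_px, df$y_px, df$valid == 1, rate, screen)
}

#' @rdname load_gaze_csv
#' @param trace a `gaze_trace`.
#' @export
write_gaze_csv <- function(trace, path) {
  write.csv(data.frame(t_s = trace$t, x_px = trace$x, y_px = trace$y,
                       valid = as.integer(trace$valid)),
            path, row.names = FALSE)
  invisible(path)
}

#' Velocity-threshold saccade detection
#'
#' Point-to-point speeds are computed between consecutive valid samples.
#' Maximal runs of speed above `velocity_threshold`, bounded by
#' below-threshold (fixation) samples on both sides, count as one saccade
#' each; above-threshold runs separated by a fixation shorter than
#' `min_fixation_ms` are merged into a single saccade. This mirrors how
#' saccades -- rapid eye movements between fixation points -- are counted by
#' tracker software, which the study delegated to its device.
#'
#' @param trace a `gaze_trace`.
#' @param velocity_threshold speed threshold in px/s (default 1000 at the
#'   default synthetic screen geometry).
#' @param min_fixation_ms minimum fixation duration separating saccades.
#' @return list with `S` (saccade count) and `intervals` (data.frame of
#'   start/end times of each saccade).
#' @export
detect_saccades <- function(trace, velocity_threshold = 1000,
                            min_fixation_ms = 100) {
  keep <- trace$valid
  if (sum(keep) < 2L) stop_mm("detect_saccades: fewer than 2 valid samples")
  t <- trace$t[keep]; x <- trace$x[keep]; y <- trace$y[keep]
  dt <- diff(t)
  sp <- sqrt(diff(x)^2 + diff(y)^2) / dt
  above <- sp > velocity_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  # runs must be bounded by fixation samples on both sides
  idx <- idx[idx > 1L & idx < length(r$values)]
  if (!length(idx)) {
    return(list(S = 0L,
                intervals = data.frame(t_start = numeric(0),
                                       t_end = numeric(0))))
  }
  t_start <- t[starts[idx]]
  t_end <- t[ends[idx] + 1L]
  # merge saccades separated by too-short fixations
  if (length(idx) > 1L) {
    gap <- t_start[-1] - t_end[-length(t_end)]
    keep_new <- c(TRUE, gap >= min_fixation_ms / 1000)
    grp <- cumsum(keep_new)
    t_start <- tapply(t_start, grp, min)
    t_end <- tapply(t_end, grp, max)
  }
  list(S = length(t_start),
       intervals = data.frame(t_start = as.numeric(t_start),
                              t_end = as.numeric(t_end)))
}

# Mass-preserving 1-D Gaussian spread matrix: column b spreads a unit mass
# at cell b over rows.
blur_matrix <- function(n, sigma_cells) {
  if (sigma_cells <= 0) return(diag(n))
  G <- outer(seq_len(n), seq_len(n),
             function(a, b) dnorm(a - b, sd = sigma_cells))
  sweep(G, 2, colSums(G), `/`)
}

#' Gaze concentration-density heatmap
#'
#' Valid samples are binned on a cell grid over the screen and blurred with
#' a separable, mass-preserving Gaussian kernel; the result is the sum of
#' (discretized) isotropic Gaussian kernels, one per valid sample, so total
#' mass equals the number of valid samples.
#'
#' @param trace a `gaze_trace`.
#' @param kernel_sigma kernel standard deviation in screen pixels
#'   (default 20).
#' @param grid `c(ncol, nrow)` heatmap cells (default `c(192, 108)`, i.e.
#'   10-px cells at the default screen).
#' @return matrix (nrow x ncol) of class `gaze_heatmap` with attributes
#'   `cell` (pixel size of a cell) and `n_samples`.
#' @export
gaze_heatmap <- function(trace, kernel_sigma = 20, grid = c(192, 108)) {
  if (any(grid < 1)) stop_mm("gaze_heatmap: zero-size grid")
  keep <- trace$valid
  if (!any(keep)) stop_mm("gaze_heatmap: no valid samples")
  cw <- trace$screen[1] / grid[1]
  ch <- trace$screen[2] / grid[2]
  cx <- pmin(pmax(ceiling(trace$x[keep] / cw), 1L), grid[1])
  cy <- pmin(pmax(ceiling(trace$y[keep] / ch), 1L), grid[2])
  C <- matrix(0, grid[2], grid[1])
  for (s in seq_along(cx)) C[cy[s], cx[s]] <- C[cy[s], cx[s]] + 1
  Gr <- blur_matrix(grid[2], kernel_sigma / ch)
  Gc <- blur_matrix(grid[1], kernel_sigma / cw)
  H <- Gr %*% C %*% t(Gc)
  structure(H, class = c("gaze_heatmap", "matrix"),
            cell = c(cw, ch), n_samples = sum(keep))
}

#' Gaze-extent pixel count E
#'
#' `E` is the number of heatmap cells whose density exceeds the given
#' quantile of the nonzero densities: an operational measure of how widely
#' the gaze was distributed. Scale-invariant (doubling all densities leaves
#' `E` unchanged).
#'
#' @param heatmap a `gaze_heatmap` (or plain matrix).
#' @param density_quantile quantile in (0, 1); default 0.90.
#' @return integer `E`.
#' @export
gaze_extent <- function(heatmap, density_quantile = 0.90) {
  h <- as.vector(unclass(heatmap))
  if (!length(h)) stop_mm("gaze_extent: empty heatmap")
  nz <- h[h > 0]
  if (!length(nz)) return(0L)
  thr <- quantile(nz, density_quantile, names = FALSE)
  # ">=" so that a field with all mass in one cell yields E = 1
  as.integer(sum(h >= thr))
}

# Complex Gabor kernel, zero-DC even part, unit L2 norm.
gabor_kernel <- function(wavelength, theta, sigma, size) {
  r <- (size - 1) / 2
  g <- expand.grid(x = -r:r, y = -r:r)
  xr <- g$x * cos(theta) + g$y * sin(theta)
  yr <- -g$x * sin(theta) + g$y * cos(theta)
  env <- exp(-(xr^2 + yr^2) / (2 * sigma^2))
  even <- env * cos(2 * pi * xr / wavelength)
  odd <- env * sin(2 * pi * xr / wavelength)
  even <- even - mean(even)  # remove DC so flat images give ~zero response
  nrm <- sqrt(sum(even^2) + sum(odd^2))
  matrix(complex(real = even / nrm, imaginary = odd / nrm), size, size)
}

fft_convolve <- function(img, kern) {
  n <- nrow(img); m <- ncol(img)
  K <- matrix(0 + 0i, n, m)
  ks <- nrow(kern)
  K[1:ks, 1:ks] <- kern
  # center the kernel so the response is spatially aligned
  shift <- floor(ks / 2)
  K <- K[c((shift + 1):n, 1:shift), c((shift + 1):m, 1:shift)]
  stats::fft(stats::fft(img) * stats::fft(K), inverse = TRUE) / (n * m)
}

#' Gabor-wavelet frame features
#'
#' Applies a bank of complex Gabor filters (default 4 orientations x 2
#' scales) to a 160 x 160 grayscale image and summarizes each filter's
#' response magnitude over an 8 x 8 block grid, concatenated into one
#' deterministic feature vector (length `orientations * scales * blocks^2`).
#'
#' @param image numeric 160 x 160 matrix (grayscale, any fixed intensity
#'   scale).
#' @param orientations number of filter orientations (default 4).
#' @param scales number of filter scales (default 2; wavelengths 8 and 16
#'   px).
#' @param blocks pooling grid per side (default 8).
#' @return numeric feature vector.
#' @export
gabor_frame_features <- function(image, orientations = 4L, scales = 2L,
                                 blocks = 8L) {
  if (!is.matrix(image) || nrow(image) != 160L || ncol(image) != 160L) {
    stop_mm("gabor_frame_features: image must be a 160x160 matrix")
  }
  if (any(!is.finite(image))) stop_mm("gabor_frame_features: non-finite image")
  thetas <- (seq_len(orientations) - 1) * pi / orientations
  waves <- 8 * 2^(seq_len(scales) - 1)
  bs <- nrow(image) / blocks
  feats <- numeric(0)
  for (w in waves) {
    kern <- NULL
    for (th in thetas) {
      k <- gabor_kernel(w, th, sigma = w * 0.6, size = 2 * floor(w) + 1)
      resp <- Mod(fft_convolve(image, k))
      pooled <- matrix(0, blocks, blocks)
      for (bi in seq_len(blocks)) {
        for (bj in seq_len(blocks)) {
          rows <- ((bi - 1) * bs + 1):(bi * bs)
          cols <- ((bj - 1) * bs + 1):(bj * bs)
          pooled[bi, bj] <- mean(resp[rows, cols])
        }
      }
      feats <- c(feats, as.vector(pooled))
    }
  }
  feats
}

#' Load a grayscale face image from PNG
#'
#' Reads a PNG, averages channels to grayscale if needed, and center-crops /
#' bilinearly resizes to 160 x 160 (a 320 x 320 region of interest is simply
#' downscaled). Requires the `png` package.
#'
#' @param path PNG file path.
#' @return 160 x 160 numeric matrix in [0, 1].
#' @export
load_face_png <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop_mm("load_face_png requires the 'png' package")
  }
  a <- png::readPNG(path)
  img <- if (length(dim(a)) == 3L) apply(a[, , 1:3, drop = FALSE], c(1, 2),
                                         mean) else a
  resize_bilinear(img, 160L, 160L)
}

resize_bilinear <- function(img, nr, nc) {
  sr <- nrow(img); sc <- ncol(img)
  if (sr == nr && sc == nc) return(img)
  ri <- (seq_len(nr) - 0.5) * sr / nr + 0.5
  ci <- (seq_len(nc) - 0.5) * sc / nc + 0.5
  r0 <- pmin(pmax(floor(ri), 1), sr); r1 <- pmin(r0 + 1, sr)
  c0 <- pmin(pmax(floor(ci), 1), sc); c1 <- pmin(c0 + 1, sc)
  fr <- ri - r0; fc <- ci - c0
  out <- (1 - fr) %o% (1 - fc) * img[r0, c0] +
    (1 - fr) %o% fc * img[r0, c1] +
    fr %o% (1 - fc) * img[r1, c0] +
    fr %o% fc * img[r1, c1]
  out
}

#' Gabor features for a whole image sequence
#'
#' @param images list of 160 x 160 grayscale matrices.
#' @return matrix, one feature row per image.
#' @export
face_sequence_features <- function(images) {
  t(vapply(images, gabor_frame_features, numeric(4 * 2 * 64)))
}
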