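#' U-Matrix boundary-depth field of a trained SOM
#'
#' For every lattice unit the squared Euclidean distances to its available
#' neighbors are aggregated into a single boundary-depth value. Lateral
#' components are plain squared distances to the four edge-sharing neighbors.
#' Each diagonal component is the average of the two distinct cross-pair
#' squared distances spanning that diagonal,
#' `0.5*||w(j,k) - w(j+dj,k+dk)||^2 + 0.5*||w(j+dj,k) - w(j,k+dk)||^2`.
#' The per-unit value `U` is the mean of the components that exist (interior
#' units have 8, edges and corners fewer). High `U` marks deep category
#' boundaries; in the study's rendering convention deep boundaries are drawn
#' dark (low brightness), so display uses inverted `U` by default.
#'
#' @param grid a trained `som_grid`.
#' @return object of class `umatrix_field`: list with `U` (J x K matrix),
#'   and the grid shape.
#' @export
compute_umatrix <- function(grid) {
  if (!inherits(grid, "som_grid")) stop_mm("compute_umatrix: need a som_grid")
  J <- grid$J; K <- grid$K; I <- grid$I
  if (J * K < 1 || is.null(grid$W)) stop_mm("compute_umatrix: empty grid")
  # W as array A[j, k, i]
  A <- array(0, dim = c(J, K, I))
  co <- unit_coords(seq_len(J * K), K)
  for (i in seq_len(I)) A[cbind(co, i)] <- grid$W[, i]

  dist2 <- function(a, b) {
    # a, b: index lists (j-range, k-range); squared distance field
    d <- (A[a[[1]], a[[2]], , drop = FALSE] -
            A[b[[1]], b[[2]], , drop = FALSE])^2
    array(rowSums(matrix(d, ncol = I)), dim = dim(d)[1:2])
  }

  comp_sum <- matrix(0, J, K)
  comp_n <- matrix(0L, J, K)
  add <- function(jr, kr, val) {
    comp_sum[jr, kr] <<- comp_sum[jr, kr] + val
    comp_n[jr, kr] <<- comp_n[jr, kr] + 1L
  }

  if (J > 1) {
    h <- dist2(list(1:(J - 1), 1:K), list(2:J, 1:K))  # between j and j+1
    add(1:(J - 1), 1:K, h)   # Uh+ of unit j
    add(2:J, 1:K, h)         # Uh- of unit j+1
  }
  if (K > 1) {
    v <- dist2(list(1:J, 1:(K - 1)), list(1:J, 2:K))
    add(1:J, 1:(K - 1), v)
    add(1:J, 2:K, v)
  }
  if (J > 1 && K > 1) {
    jr <- 1:(J - 1); kr <- 1:(K - 1)
    main <- dist2(list(jr, kr), list(jr + 1, kr + 1))        # (j,k)-(j+1,k+1)
    anti <- dist2(list(jr + 1, kr), list(jr, kr + 1))        # (j+1,k)-(j,k+1)
    d <- 0.5 * main + 0.5 * anti
    add(jr, kr, d)           # Ud++ of (j,k)
    add(jr + 1, kr + 1, d)   # Ud-- of (j+1,k+1)
    add(jr + 1, kr, d)       # Ud-+ of (j+1,k)
    add(jr, kr + 1, d)       # Ud+- of (j,k+1)
  }
  U <- ifelse(comp_n > 0, comp_sum / pmax(comp_n, 1L), 0)
  structure(list(U = U, J = J, K = K), class = "umatrix_field")
}

#' Segment a U-Matrix field into categories
#'
#' Units whose boundary depth exceeds the `threshold_quantile` quantile of
#' all `U` values are marked as boundary walls; the remaining units are
#' grouped into 4-connected components, and boundary units are then absorbed
#' into the adjacent component whose nearest member weight is closest. The
#' number of categories is the number of components. (The study drew category
#' boundaries by hand; this algorithmic rule replaces that for
#' reproducibility.)
#'
#' @param field a `umatrix_field` from [compute_umatrix()].
#' @param grid the `som_grid` the field was computed from (used for weight
#'   distances when absorbing boundary units).
#' @param threshold_quantile boundary quantile in (0, 1); default 0.80.
#' @return object of class `category_segmentation`: list with `labels`
#'   (J x K integer matrix of category ids), `n_categories`, `boundary`
#'   (logical J x K), and `categories` (list of per-category unit indices).
#' @export
segment_categories <- function(field, grid, threshold_quantile = 0.80) {
  if (!(threshold_quantile > 0 && threshold_quantile < 1)) {
    stop_mm("threshold_quantile must be in (0, 1)")
  }
  U <- field$U; J <- field$J; K <- field$K
  thr <- quantile(U, threshold_quantile, names = FALSE)
  boundary <- U > thr
  labels <- matrix(0L, J, K)
  # flood fill 4-connected components of non-boundary units
  comp <- 0L
  stack_j <- integer(J * K); stack_k <- integer(J * K)
  for (j0 in seq_len(J)) {
    for (k0 in seq_len(K)) {
      if (boundary[j0, k0] || labels[j0, k0] != 0L) next
      comp <- comp + 1L
      top <- 1L
      stack_j[1] <- j0; stack_k[1] <- k0
      labels[j0, k0] <- comp
      while (top > 0L) {
        j <- stack_j[top]; k <- stack_k[top]; top <- top - 1L
        for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
          jj <- j + d[1]; kk <- k + d[2]
          if (jj >= 1 && jj <= J && kk >= 1 && kk <= K &&
              !boundary[jj, kk] && labels[jj, kk] == 0L) {
            labels[jj, kk] <- comp
            top <- top + 1L
            stack_j[top] <- jj; stack_k[top] <- kk
          }
        }
      }
    }
  }
  if (comp == 0L) {
    # every unit above threshold (degenerate); one category covers the map
    labels[] <- 1L
    comp <- 1L
  } else {
    # absorb boundary units into the adjacent component with the closest
    # member weight; iterate so enclosed boundary regions drain outward
    repeat {
      todo <- which(labels == 0L, arr.ind = TRUE)
      if (nrow(todo) == 0) break
      assigned <- FALSE
      newlab <- labels
      for (r in seq_len(nrow(todo))) {
        j <- todo[r, 1]; k <- todo[r, 2]
        u <- unit_index(j, k, K)
        best <- NA_integer_; bestd <- Inf
        for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
          jj <- j + d[1]; kk <- k + d[2]
          if (jj < 1 || jj > J || kk < 1 || kk > K) next
          lab <- labels[jj, kk]
          if (lab == 0L) next
          un <- unit_index(jj, kk, K)
          dd <- sum((grid$W[u, ] - grid$W[un, ])^2)
          if (dd < bestd) { bestd <- dd; best <- lab }
        }
        if (!is.na(best)) { newlab[j, k] <- best; assigned <- TRUE }
      }
      labels <- newlab
      if (!assigned) { labels[labels == 0L] <- 1L; break }
    }
  }
  cats <- lapply(seq_len(comp), function(cc) which(t(labels) == cc))
  # which(t(labels)) gives linear index over (k fastest) = unit_index order
  structure(list(labels = labels, n_categories = comp, boundary = boundary,
                 threshold_quantile = threshold_quantile,
                 categories = cats),
            class = "category_segmentation")
}

#' Attach positive/neutral/negative semantic labels to categories
#'
#' Per category the mean member TMD and F scores are computed from the
#' sessions mapped into it. A category is tagged `negative` when its mean
#' TMD exceeds `tmd_ref`; among the rest, `positive` when mean F exceeds
#' `f_ref`, else `neutral`. The study located the TMD decision boundary
#' around 51 T-score points (below the normative mean of 55) and the F
#' boundary near 52 points (above the normative mean of 49); both are
#' configurable.
#'
#' @param seg a `category_segmentation`.
#' @param points data.frame of mood points (columns `TMD`, `F`).
#' @param bmu_units integer vector: linear unit index of each point's BMU
#'   (as from [bmu_assign()]).
#' @param tmd_ref,f_ref decision boundaries in T-score units.
#' @return `seg` with an added `summary` data.frame (category id, n members,
#'   mean TMD, mean F, semantic tag) and `point_category` (per-point id).
#' @export
assign_semantic_labels <- function(seg, points, bmu_units,
                                   tmd_ref = 51, f_ref = 52) {
  K <- ncol(seg$labels)
  co <- unit_coords(bmu_units, K)
  pc <- seg$labels[co]
  tags <- character(seg$n_categories)
  mt <- mf <- nn <- numeric(seg$n_categories)
  for (cc in seq_len(seg$n_categories)) {
    m <- pc == cc
    nn[cc] <- sum(m)
    if (!any(m)) {
      warning(sprintf("category %d has no member sessions; tagged neutral",
                      cc))
      tags[cc] <- "neutral"; mt[cc] <- NA_real_; mf[cc] <- NA_real_
      next
    }
    mt[cc] <- mean(points$TMD[m])
    mf[cc] <- mean(points$F[m])
    tags[cc] <- if (mt[cc] > tmd_ref) {
      "negative"
    } else if (mf[cc] > f_ref) {
      "positive"
    } else {
      "neutral"
    }
  }
  seg$summary <- data.frame(category = seq_len(seg$n_categories),
                            n = nn, mean_TMD = mt, mean_F = mf,
                            tag = tags, stringsAsFactors = FALSE)
  seg$point_category <- pc
  seg
}

#' Render a U-Matrix to an image file
#'
#' Grayscale rendering; by default deep boundaries (high `U`) are dark, as in
#' the study's figures. Writes PNG via the grDevices device when available,
#' otherwise a plain-text PGM with the same base name.
#'
#' @param field a `umatrix_field`.
#' @param path output path (extension replaced as needed).
#' @param invert if `TRUE` (default) high `U` maps to low brightness.
#' @return the path actually written, invisibly.
#' @export
render_umatrix <- function(field, path, invert = TRUE) {
  U <- field$U
  rng <- range(U)
  B <- if (diff(rng) > 0) (U - rng[1]) / diff(rng) else U * 0
  if (invert) B <- 1 - B
  ok <- FALSE
  if (isTRUE(capabilities("png")[[1]])) {
    ok <- tryCatch({
      grDevices::png(path, width = 64 + 8 * field$J,
                     height = 64 + 8 * field$K)
      graphics::image(seq_len(field$J), seq_len(field$K), B,
                      col = grDevices::gray.colors(256, 0, 1),
                      xlab = "j", ylab = "k", useRaster = TRUE)
      grDevices::dev.off()
      TRUE
    }, error = function(e) FALSE)
  }
  if (!ok) {
    path <- sub("\\.png$", ".pgm", path)
    g <- round(t(B[, rev(seq_len(field$K)), drop = FALSE]) * 255)
    con <- file(path, "w")
    writeLines(c("P2", paste(field$J, field$K), "255"), con)
    write(t(g), con, ncolumns = field$J)
    close(con)
  }
  invisible(path)
}
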