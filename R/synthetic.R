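#' Synthetic five-cluster mood layout
#'
#' Package constants (synthetic, not measured values) placing five mood
#' clusters in the TMD-F T-score plane the way the study's category layout
#' reads semantically: two positive clusters (low TMD / high F), one neutral
#' near the center, two negative (high TMD / low F). The mixture is centered
#' near (50, 50) with overall spread near 10 so that self-normalized
#' T-scoring approximately preserves the planted coordinates.
#'
#' @format matrix with rows A-E and columns `TMD`, `F`.
#' @export
mood_cluster_layout <- function() {
  m <- rbind(A = c(38, 62), B = c(46, 57), C = c(50, 49),
             D = c(56, 43), E = c(64, 37))
  colnames(m) <- c("TMD", "F")
  m
}

# Per-cluster behavioral tendencies (synthetic stand-ins): positive moods get
# concentrated gaze, fewer saccades and longer/steadier smiles; negative the
# opposite. Used by generate_study().
cluster_behavior <- function() {
  data.frame(cluster = 1:5,
             dispersion = c(70, 100, 150, 220, 300),
             n_saccades = c(4L, 7L, 10L, 13L, 16L),
             n_cycles = c(6L, 5L, 4L, 3L, 2L),
             plateau = c(0.35, 0.30, 0.25, 0.20, 0.15))
}

#' Cohort specification for the synthetic POMS2 generator
#'
#' Defaults emulate the study's dataset shape: 20 subjects measured weekly,
#' 10 for four weeks and 10 for eight weeks (120 session records), with
#' session-level (TMD, F) targets drawn from five Gaussian mood clusters.
#'
#' @param n_subjects number of subjects (default 20).
#' @param sessions_per_subject integer vector recycled over subjects; the
#'   default `NULL` uses the study's manifest pattern (blocks of five
#'   subjects alternating 4- and 8-week terms).
#' @param cluster_means 5 x 2 matrix of (TMD, F) cluster centers in T-score
#'   units; default [mood_cluster_layout()].
#' @param cluster_sd within-cluster standard deviation in T-score units
#'   (default 2, so adjacent cluster centers -- 8.5 to 10 T-points apart --
#'   sit at least 4 within-cluster sd apart: well-separated categories).
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 20L, sessions_per_subject = NULL,
                        cluster_means = mood_cluster_layout(),
                        cluster_sd = 2, seed = 1L) {
  if (n_subjects < 1) stop_mm("cohort_spec: need >= 1 subject")
  if (is.null(sessions_per_subject)) {
    # Table-1 pattern: five 4-week subjects, five 8-week, repeated
    base <- rep(c(4L, 8L), each = 5)
    sessions_per_subject <- rep(base, length.out = n_subjects)
  } else {
    sessions_per_subject <- rep(as.integer(sessions_per_subject),
                                length.out = n_subjects)
  }
  if (cluster_sd < 0) stop_mm("cohort_spec: cluster_sd must be >= 0")
  structure(list(n_subjects = as.integer(n_subjects),
                 sessions_per_subject = sessions_per_subject,
                 cluster_means = cluster_means,
                 cluster_sd = cluster_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Map a planted T-score target to the raw-score scale the component
# decomposition works on.
raw_tmd_from_t <- function(z) (z - 50) / 10 * 15 + 20
raw_f_from_t <- function(z) pmax((z - 50) / 10 * 4 + 12, 0)

#' Generate a synthetic POMS2 cohort
#'
#' Each subject is assigned a home mood cluster (cycling through the five
#' clusters so each has both 4- and 8-week subjects). Per session a (TMD, F)
#' target is drawn around the cluster center, converted to a raw-score
#' scale, and decomposed into the seven components: the five TMD-positive
#' components are drawn near `(raw_TMD + 25) / 5` (truncated at 0) and VA is
#' solved last as `sum(five) - raw_TMD`, so the identity
#' `TMD = AH+CB+DD+FI+TA-VA` holds exactly. Sessions where VA would come out
#' negative are resampled (error after 100 attempts).
#'
#' @param spec a [cohort_spec()].
#' @return list with `scores` (component table as from [load_poms_csv()]),
#'   `cluster` (per-session ground-truth cluster id), and `target`
#'   (per-session planted (TMD, F) T-score targets).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  nclust <- nrow(spec$cluster_means)
  subj_ids <- make.unique(rep(LETTERS, length.out = spec$n_subjects),
                          sep = "")
  rows <- list(); cl <- integer(0); tg <- NULL
  with_seed(spec$seed, {
    for (si in seq_len(spec$n_subjects)) {
      home <- ((si - 1L) %% nclust) + 1L
      for (se in seq_len(spec$sessions_per_subject[si])) {
        z <- spec$cluster_means[home, ] + rnorm(2, 0, spec$cluster_sd)
        t_raw <- raw_tmd_from_t(z[1])
        f_raw <- raw_f_from_t(z[2])
        ok <- FALSE
        for (attempt in seq_len(100)) {
          five <- pmax(rnorm(5, (t_raw + 25) / 5, 2), 0)
          va <- sum(five) - t_raw
          if (va >= 0) { ok <- TRUE; break }
        }
        if (!ok) {
          stop_mm("generate_cohort: no non-negative decomposition for %s/%d",
                  subj_ids[si], se)
        }
        rows[[length(rows) + 1L]] <-
          data.frame(subject_id = subj_ids[si], session = se,
                     AH = five[1], CB = five[2], DD = five[3],
                     FI = five[4], TA = five[5], VA = va, F = f_raw,
                     stringsAsFactors = FALSE)
        cl <- c(cl, home)
        tg <- rbind(tg, z)
      }
    }
  })
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  dimnames(tg) <- list(NULL, c("TMD", "F"))
  list(scores = scores, cluster = cl, target = tg)
}

#' Gaze-trace generator specification
#'
#' Emulates tracker output: alternating fixations (Gaussian jitter around a
#' fixation point) and instantaneous saccadic jumps to a new fixation point.
#'
#' @param duration trace length in seconds (default 30).
#' @param rate sampling rate in Hz (default 60).
#' @param n_saccades number of planted saccades (default 10).
#' @param fixation_jitter within-fixation jitter sd in px (default 2).
#'   Jitter is white per-sample noise, so at 60 Hz its implied
#'   point-to-point speeds (~`jitter * sqrt(2) * 60` px/s) must stay well
#'   below the saccade velocity threshold; 2 px keeps the tail under
#'   1/10^6 per sample at the 1000 px/s default.
#' @param dispersion sd of fixation-point spread around screen center in px
#'   (default 150); larger = more dispersed gaze.
#' @param min_amplitude minimum planted jump amplitude in px (default 60,
#'   i.e. 3600 px/s at one 60 Hz sample -- far above the jitter speeds).
#' @param ballistic if `TRUE` saccades take 3 samples instead of 1.
#' @param screen screen size `c(w, h)` px.
#' @param seed integer seed.
#' @return object of class `gaze_spec`.
#' @export
gaze_spec <- function(duration = 30, rate = 60, n_saccades = 10L,
                      fixation_jitter = 2, dispersion = 150,
                      min_amplitude = 60, ballistic = FALSE,
                      screen = c(1920, 1080), seed = 1L) {
  if (duration <= 0 || rate <= 0) stop_mm("gaze_spec: need positive duration/rate")
  if (n_saccades < 0) stop_mm("gaze_spec: n_saccades must be >= 0")
  structure(list(duration = duration, rate = rate,
                 n_saccades = as.integer(n_saccades),
                 fixation_jitter = fixation_jitter,
                 dispersion = dispersion, min_amplitude = min_amplitude,
                 ballistic = isTRUE(ballistic), screen = screen,
                 seed = as.integer(seed)),
            class = "gaze_spec")
}

#' Generate a synthetic gaze trace with known saccades
#'
#' @param spec a [gaze_spec()].
#' @return list with `trace` (a [gaze_trace()]), `S_true` (planted saccade
#'   count) and `jump_times` (sample times at which fixation points switch).
#' @export
generate_gaze <- function(spec = gaze_spec()) {
  n <- round(spec$duration * spec$rate)
  k <- spec$n_saccades
  with_seed(spec$seed, {
    center <- spec$screen / 2
    margin <- 0.1 * spec$screen
    draw_point <- function(prev = NULL) {
      for (i in seq_len(200)) {
        p <- center + rnorm(2, 0, spec$dispersion)
        p <- pmin(pmax(p, margin), spec$screen - margin)
        if (is.null(prev) ||
            sqrt(sum((p - prev)^2)) >= spec$min_amplitude) {
          return(p)
        }
      }
      # force a jump of at least min_amplitude in a random direction
      ang <- runif(1, 0, 2 * pi)
      pmin(pmax(prev + spec$min_amplitude * 1.5 * c(cos(ang), sin(ang)),
                margin), spec$screen - margin)
    }
    pts <- matrix(0, k + 1, 2)
    pts[1, ] <- draw_point()
    if (k > 0) for (i in seq_len(k)) pts[i + 1, ] <- draw_point(pts[i, ])
    # segment lengths: at least 0.2 s per fixation
    minlen <- max(2L, round(0.2 * spec$rate))
    w <- runif(k + 1, 0.5, 1.5)
    lens <- pmax(minlen, floor(w / sum(w) * n))
    lens[k + 1] <- max(minlen, n - sum(lens[-(k + 1)]))
    n_tot <- sum(lens)
    fix_id <- rep(seq_len(k + 1), lens)
    xy <- pts[fix_id, , drop = FALSE] +
      matrix(rnorm(2 * n_tot, 0, spec$fixation_jitter), n_tot, 2)
    if (spec$ballistic && k > 0) {
      # spread each jump over 3 samples
      starts <- cumsum(lens)[seq_len(k)]
      for (s in starts) {
        if (s + 2 <= n_tot) {
          a <- xy[s, ]; b <- xy[s + 2, ]
          xy[s + 1, ] <- (a + b) / 2
        }
      }
    }
    t <- (seq_len(n_tot) - 1) / spec$rate
    jump_times <- t[cumsum(lens)[seq_len(k)]]
    list(trace = gaze_trace(t, xy[, 1], xy[, 2], rate = spec$rate,
                            screen = spec$screen),
         S_true = k, jump_times = jump_times)
  })
}

#' Smile-sequence generator specification
#'
#' Emulates intentional-smile "tempo" cycles: each cycle runs from an
#' expressionless state through a smile plateau back to expressionless, so
#' per-frame intensity follows a trapezoid (neutral - rise - plateau -
#' fall). Ground truth flags frames with intensity above 0.5 as smiles.
#'
#' @param n_cycles number of tempo cycles (default 8).
#' @param frames_per_cycle frames per cycle (default 90, i.e. 1.5 s at
#'   60 fps).
#' @param plateau_frac fraction of a cycle at full smile (default 0.25).
#' @param neutral_frac fraction at rest (default 0.45; the remainder splits
#'   evenly into rise and fall ramps). Rest dominates the cycle, as in
#'   repeated intentional-smile recordings, so the per-dimension median
#'   frame is a neutral face -- the anchor [extract_smiles()] relies on.
#' @param noise_sigma feature/pixel noise sd (default 0.05).
#' @param mode `"vectors"` (fast default: feature = base + intensity *
#'   direction + noise) or `"images"` (parametric 160x160 face renders).
#' @param dim feature dimension in vector mode (default 40).
#' @param rate frame rate in Hz (default 60).
#' @param seed integer seed.
#' @return object of class `smile_spec`.
#' @export
smile_spec <- function(n_cycles = 8L, frames_per_cycle = 90L,
                       plateau_frac = 0.25, neutral_frac = 0.45,
                       noise_sigma = 0.05, mode = c("vectors", "images"),
                       dim = 40L, rate = 60, seed = 1L) {
  mode <- match.arg(mode)
  if (n_cycles < 0) stop_mm("smile_spec: n_cycles must be >= 0")
  if (!(plateau_frac > 0 && plateau_frac < 1)) {
    stop_mm("smile_spec: plateau_frac must be in (0, 1)")
  }
  if (plateau_frac + neutral_frac >= 1) {
    stop_mm("smile_spec: plateau_frac + neutral_frac must be < 1")
  }
  structure(list(n_cycles = as.integer(n_cycles),
                 frames_per_cycle = as.integer(frames_per_cycle),
                 plateau_frac = plateau_frac, neutral_frac = neutral_frac,
                 noise_sigma = noise_sigma, mode = mode,
                 dim = as.integer(dim), rate = rate,
                 seed = as.integer(seed)),
            class = "smile_spec")
}

# Trapezoidal intensity profile of one cycle (neutral, rise, plateau, fall),
# evaluated at frame midpoints so the vector length is exact.
tempo_cycle <- function(frames, plateau_frac, neutral_frac) {
  ramp <- (1 - plateau_frac - neutral_frac) / 2
  pos <- (seq_len(frames) - 0.5) / frames
  b1 <- neutral_frac
  b2 <- b1 + ramp
  b3 <- b2 + plateau_frac
  ifelse(pos < b1, 0,
         ifelse(pos < b2, (pos - b1) / ramp,
                ifelse(pos < b3, 1, pmax(0, 1 - (pos - b3) / ramp))))
}

# Parametric face render: ellipse head, two eyes, mouth whose curvature
# tracks smile intensity. Values in [0, 1].
render_face <- function(intensity, size = 160L) {
  g <- expand.grid(x = seq_len(size), y = seq_len(size))
  img <- matrix(0, size, size)
  cx <- size / 2; cy <- size / 2
  head <- ((g$x - cx) / (0.42 * size))^2 + ((g$y - cy) / (0.48 * size))^2 <= 1
  img[cbind(g$x[head], g$y[head])] <- 0.6
  for (ex in c(cx - 0.15 * size, cx + 0.15 * size)) {
    eye <- ((g$x - ex)^2 + (g$y - (cy - 0.12 * size))^2) <= (0.04 * size)^2
    img[cbind(g$x[eye], g$y[eye])] <- 0.15
  }
  # mouth: parabola opening upward with intensity; widens when smiling
  mw <- (0.16 + 0.08 * intensity) * size
  my <- cy + 0.22 * size
  curv <- 0.5 * intensity / (0.5 * mw)
  mx <- g$x - cx
  in_mouth <- abs(mx) <= mw / 2 &
    abs(g$y - (my - curv * (mx^2 - (mw / 2)^2) / (mw / 2))) <= 2.2
  img[cbind(g$x[in_mouth], g$y[in_mouth])] <- 0.1
  img
}

#' Generate a synthetic smile sequence with ground truth
#'
#' @param spec a [smile_spec()].
#' @return list with `features` (frames x dim matrix; in image mode the
#'   Gabor features of each render), `images` (image-mode only: list of
#'   160x160 matrices), `intensity` (per-frame planted intensity), `gt`
#'   (logical smile flags, intensity > 0.5), and `rate`.
#' @export
generate_smile_sequence <- function(spec = smile_spec()) {
  cyc <- tempo_cycle(spec$frames_per_cycle, spec$plateau_frac,
                     spec$neutral_frac)
  intensity <- if (spec$n_cycles > 0) {
    rep(cyc, spec$n_cycles)
  } else {
    rep(0, spec$frames_per_cycle)
  }
  gt <- intensity > 0.5
  with_seed(spec$seed, {
    if (spec$mode == "vectors") {
      base <- rnorm(spec$dim)
      base <- base / sqrt(sum(base^2))
      dirv <- rnorm(spec$dim)
      dirv <- dirv - sum(dirv * base) * base
      dirv <- dirv / sqrt(sum(dirv^2))
      Tn <- length(intensity)
      feats <- matrix(rep(base, each = Tn), Tn, spec$dim) +
        intensity %o% dirv +
        matrix(rnorm(Tn * spec$dim, 0, spec$noise_sigma), Tn, spec$dim)
      list(features = feats, images = NULL, intensity = intensity,
           gt = gt, rate = spec$rate)
    } else {
      imgs <- lapply(intensity, function(v) {
        img <- render_face(v)
        img + matrix(rnorm(length(img), 0, spec$noise_sigma),
                     nrow(img), ncol(img))
      })
      feats <- t(vapply(imgs, gabor_frame_features,
                        numeric(4 * 2 * 64)))
      list(features = feats, images = imgs, intensity = intensity,
           gt = gt, rate = spec$rate)
    }
  })
}

#' Subject manifest of the emulated cohort
#'
#' The 20-subject weekly-measurement manifest (10 four-week and 10
#' eight-week subjects; 120 session records in total), shipped as a small
#' CSV under `extdata`.
#'
#' @param path optional alternative manifest CSV (columns `subject_id`,
#'   `sex`, `age`, `n_sessions`).
#' @return data.frame with one row per subject.
#' @export
subject_manifest <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "subject_manifest.csv",
                        package = "moodmap")
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "n_sessions")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop_mm("manifest '%s' missing column(s): %s", path,
            paste(missing, collapse = ", "))
  }
  df
}
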