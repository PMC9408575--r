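pattern_columns <- function(pattern) {
  switch(pattern,
         TMD_F = c("TMD", "F"),
         I = c("TMD", "F", "E", "S"),
         II = c("TMD", "F", "R", "G"),
         III = c("TMD", "F", "E", "S", "R", "G"),
         stop_mm("unknown input pattern '%s'", pattern))
}

#' Assemble the fusion feature matrix for a SOM input pattern
#'
#' The study combines the two mood indicators with behavioral features in
#' three patterns: Input I = TMD, F, E, S (gaze); Input II = TMD, F, R, G
#' (expression); Input III = all six. Column order is fixed as
#' TMD, F, E, S, R, G (as applicable). Because the raw features live on very
#' different scales (T-scores vs pixel counts), each column is z-scored over
#' sessions before SOM input by default; min-max scaling to [0, 1] is the
#' alternative.
#'
#' @param records data.frame with one row per session, columns `subject_id`,
#'   `session`, `TMD`, `F` and, as the pattern requires, `E`, `S`, `R`, `G`.
#' @param pattern `"TMD_F"`, `"I"`, `"II"` or `"III"`.
#' @param normalization `"zscore"` (default) or `"minmax"`.
#' @return numeric matrix, sessions x features, rows in input order.
#' @export
assemble_features <- function(records, pattern = "TMD_F",
                              normalization = c("zscore", "minmax")) {
  normalization <- match.arg(normalization)
  cols <- pattern_columns(pattern)
  for (cc in cols) {
    if (is.null(records[[cc]]) || all(is.na(records[[cc]]))) {
      stop_mm("pattern %s requires feature '%s', absent from the records",
              pattern, cc)
    }
    bad <- which(!is.finite(records[[cc]]))
    if (length(bad)) {
      stop_mm("pattern %s: feature '%s' missing for session(s): %s",
              pattern, cc,
              paste(paste0(records$subject_id[bad], "/",
                           records$session[bad]), collapse = ", "))
    }
  }
  X <- as.matrix(records[cols])
  norm_col <- function(v) {
    if (normalization == "zscore") {
      s <- sd(v)
      if (s == 0) return(v - mean(v))
      (v - mean(v)) / s
    } else {
      r <- range(v)
      if (diff(r) == 0) return(v * 0)
      (v - r[1]) / diff(r)
    }
  }
  X <- apply(X, 2, norm_col)
  rownames(X) <- paste(records$subject_id, records$session, sep = "/")
  X
}

#' Pipeline run configuration
#'
#' @param pattern SOM input pattern (see [assemble_features()]).
#' @param som a [train_config()] (Table-of-defaults: 50x50 map, alpha 0.1,
#'   psi0 40, 200 epochs).
#' @param rsom an [rsom_config()] for the smile stage.
#' @param threshold_quantile U-Matrix boundary quantile (default 0.80).
#' @param tmd_ref,f_ref semantic-label decision boundaries (T-score units).
#' @param T_m GHSOM breadth threshold (default 0.08).
#' @param normalization feature scaling mode.
#' @param seed master seed; stage seeds derive from it.
#' @param out_dir output directory (created if needed); `NULL` = no files.
#' @return a `run_config` object.
#' @export
run_config <- function(pattern = "TMD_F", som = NULL, rsom = NULL,
                       threshold_quantile = 0.80, tmd_ref = 51, f_ref = 52,
                       T_m = 0.08, normalization = "zscore",
                       seed = 1L, out_dir = NULL) {
  pattern_columns(pattern)  # validates
  if (is.null(som)) som <- train_config(seed = derive_seed(seed, 1L))
  if (is.null(rsom)) rsom <- rsom_config(seed = derive_seed(seed, 2L))
  structure(list(pattern = pattern, som = som, rsom = rsom,
                 threshold_quantile = threshold_quantile,
                 tmd_ref = tmd_ref, f_ref = f_ref, T_m = T_m,
                 normalization = normalization,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Recognized top-level keys: `pattern`, `seed`, `out_dir`,
#' `threshold_quantile`, `tmd_ref`, `f_ref`, `T_m`, `normalization`, and
#' nested `som:` (`alpha0`, `psi0`, `O`, `J`, `K`) and `rsom:` (`n_units`,
#' `betas`, `gamma0`, `O`) blocks mirroring the study's meta-parameter
#' table.
#'
#' @param path YAML file path.
#' @return a [run_config()].
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- if (is.null(y$seed)) 1L else as.integer(y$seed)
  som <- do.call(train_config,
                 c(y$som, list(seed = derive_seed(seed, 1L))))
  rsom <- do.call(rsom_config,
                  c(y$rsom, list(seed = derive_seed(seed, 2L))))
  args <- y[intersect(names(y), c("pattern", "threshold_quantile",
                                  "tmd_ref", "f_ref", "T_m",
                                  "normalization", "out_dir"))]
  do.call(run_config, c(args, list(som = som, rsom = rsom, seed = seed)))
}

#' Simulate a full study: cohort scores plus per-session behavioral signals
#'
#' Generates the POMS2 component table from a [cohort_spec()] and, for every
#' session, a gaze trace and a smile sequence whose generator parameters
#' depend on the session's mood cluster: positive clusters get concentrated
#' gaze, few saccades and long, steady smile plateaus; negative clusters
#' dispersed gaze, many saccades and short, variable smiles (synthetic
#' stand-ins mirroring the study's qualitative findings).
#'
#' @param spec a [cohort_spec()].
#' @param gaze_duration seconds of gaze per session (default 30).
#' @param frames_per_cycle smile-cycle length in frames (default 90).
#' @param feature_dim smile feature dimension (default 40).
#' @param seed master seed (defaults to `spec$seed`).
#' @return list with `scores`, `cluster`, `gaze` (list of
#'   [generate_gaze()] results) and `smiles` (list of
#'   [generate_smile_sequence()] results), one element per session row.
#' @export
simulate_study <- function(spec = cohort_spec(), gaze_duration = 30,
                           frames_per_cycle = 90L, feature_dim = 40L,
                           seed = spec$seed) {
  cohort <- generate_cohort(spec)
  beh <- cluster_behavior()
  n <- nrow(cohort$scores)
  gaze <- vector("list", n)
  smiles <- vector("list", n)
  for (r in seq_len(n)) {
    b <- beh[cohort$cluster[r], ]
    gaze[[r]] <- generate_gaze(gaze_spec(
      duration = gaze_duration,
      n_saccades = b$n_saccades,
      dispersion = b$dispersion,
      seed = derive_seed(seed, 1000L + r)))
    smiles[[r]] <- generate_smile_sequence(smile_spec(
      n_cycles = b$n_cycles,
      frames_per_cycle = frames_per_cycle,
      plateau_frac = b$plateau,
      dim = feature_dim,
      seed = derive_seed(seed, 2000L + r)))
  }
  c(cohort, list(gaze = gaze, smiles = smiles))
}

#' Compute per-session behavioral features E, S, R, G
#'
#' E = gaze-extent cell count, S = saccade count, R = smile-frame count from
#' the RSOM stage, G = leaf-cluster count of the GHSOM built on the
#' session's 15 RSOM prototypes.
#'
#' @param study a [simulate_study()] result (or an equivalently shaped list).
#' @param cfg a [run_config()].
#' @param need_gaze,need_face which feature families to compute (both
#'   default TRUE).
#' @param ghsom_epochs SOM epochs inside the GHSOM stage (default 50; the
#'   maps are tiny so this is plenty).
#' @return data.frame with `subject_id`, `session` and the requested of
#'   `E`, `S`, `R`, `G`.
#' @export
session_features <- function(study, cfg = run_config(),
                             need_gaze = TRUE, need_face = TRUE,
                             ghsom_epochs = 50L) {
  n <- nrow(study$scores)
  out <- study$scores[c("subject_id", "session")]
  if (need_gaze) {
    out$E <- NA_real_; out$S <- NA_real_
    for (r in seq_len(n)) {
      tr <- study$gaze[[r]]$trace
      out$S[r] <- detect_saccades(tr)$S
      out$E[r] <- gaze_extent(gaze_heatmap(tr))
    }
  }
  if (need_face) {
    out$R <- NA_real_; out$G <- NA_real_
    for (r in seq_len(n)) {
      feats <- study$smiles[[r]]$features
      rc <- cfg$rsom
      rc$seed <- derive_seed(cfg$seed, 3000L + r)
      map <- rsom_train(feats, rc)
      out$R[r] <- extract_smiles(feats, map)$R
      tree <- build_tree(map$W, T_m = cfg$T_m, epochs = ghsom_epochs,
                         seed = derive_seed(cfg$seed, 4000L + r))
      out$G[r] <- tree$G
    }
  }
  out
}

#' Run the end-to-end mood-map pipeline
#'
#' psychometrics -> behavioral features (as the pattern requires) ->
#' fusion matrix -> SOM -> U-Matrix -> category segmentation -> semantic
#' labels. When `out_dir` is set in the config, writes the fusion matrix
#' (CSV), the U-Matrix (CSV and PNG/PGM), the segmentation and per-category
#' report (JSON) and a run manifest (JSON: config, seed, input hash);
#' re-running with the same seed and inputs reproduces identical JSON
#' artifacts.
#'
#' @param cfg a [run_config()].
#' @param study data source: a [simulate_study()] result, or `NULL` to
#'   simulate one with defaults seeded from `cfg$seed`.
#' @return list with `records` (sessions + features), `X` (fusion matrix),
#'   `grid`, `field`, `seg` (labeled segmentation), and `paths` of written
#'   artifacts (if any).
#' @export
run_pipeline <- function(cfg = run_config(), study = NULL) {
  if (is.null(study)) {
    study <- simulate_study(cohort_spec(seed = derive_seed(cfg$seed, 99L)),
                            seed = derive_seed(cfg$seed, 99L))
  }
  points <- mood_points(study$scores)
  cols <- pattern_columns(cfg$pattern)
  need_gaze <- any(c("E", "S") %in% cols)
  need_face <- any(c("R", "G") %in% cols)
  records <- points
  if (need_gaze || need_face) {
    sf <- session_features(study, cfg, need_gaze = need_gaze,
                           need_face = need_face)
    records <- cbind(points, sf[setdiff(names(sf),
                                        c("subject_id", "session"))])
  }
  X <- assemble_features(records, cfg$pattern, cfg$normalization)
  grid <- som_train(X, cfg$som)
  field <- compute_umatrix(grid)
  seg <- segment_categories(field, grid, cfg$threshold_quantile)
  bmu <- bmu_assign(grid, X)
  seg <- assign_semantic_labels(seg, records, bmu,
                                tmd_ref = cfg$tmd_ref, f_ref = cfg$f_ref)
  paths <- list()
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(cfg$out_dir, f)
    write.csv(data.frame(records, X, check.names = FALSE),
              p("fusion.csv"), row.names = FALSE)
    write.csv(as.data.frame(field$U), p("umatrix.csv"), row.names = FALSE)
    paths$umatrix_png <- render_umatrix(field, p("umatrix.png"))
    members <- lapply(seq_len(seg$n_categories), function(cc) {
      rownames(X)[seg$point_category == cc]
    })
    jsonlite::write_json(
      list(n_categories = seg$n_categories,
           threshold_quantile = seg$threshold_quantile,
           summary = seg$summary,
           members = members,
           labels = seg$labels),
      p("segmentation.json"), auto_unbox = TRUE, digits = 10)
    jsonlite::write_json(
      list(pattern = cfg$pattern, seed = cfg$seed,
           som = unclass(cfg$som),
           threshold_quantile = cfg$threshold_quantile,
           tmd_ref = cfg$tmd_ref, f_ref = cfg$f_ref,
           normalization = cfg$normalization,
           input_hash = unname(tools::md5sum(p("fusion.csv")))),
      p("manifest.json"), auto_unbox = TRUE, digits = 10)
    paths$fusion <- p("fusion.csv")
    paths$umatrix <- p("umatrix.csv")
    paths$segmentation <- p("segmentation.json")
    paths$manifest <- p("manifest.json")
  }
  list(records = records, X = X, grid = grid, field = field, seg = seg,
       paths = paths)
}

#' Write a simulated study to a cohort directory
#'
#' Layout consumed by the command-line interface: `poms.csv`,
#' `gaze/<subject>_<session>.csv`, `faces/<subject>_<session>.csv`
#' (frame-feature matrices) and `gt.json` (planted clusters, saccade counts
#' and smile flags).
#'
#' @param study a [simulate_study()] result.
#' @param out_dir target directory.
#' @return `out_dir`, invisibly.
#' @export
write_study_dir <- function(study, out_dir) {
  dir.create(file.path(out_dir, "gaze"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "faces"), showWarnings = FALSE)
  write.csv(study$scores, file.path(out_dir, "poms.csv"), row.names = FALSE)
  key <- paste0(study$scores$subject_id, "_", study$scores$session)
  for (r in seq_len(nrow(study$scores))) {
    write_gaze_csv(study$gaze[[r]]$trace,
                   file.path(out_dir, "gaze", paste0(key[r], ".csv")))
    write.csv(as.data.frame(study$smiles[[r]]$features),
              file.path(out_dir, "faces", paste0(key[r], ".csv")),
              row.names = FALSE)
  }
  jsonlite::write_json(
    list(cluster = study$cluster,
         S_true = vapply(study$gaze, function(g) g$S_true, numeric(1)),
         smile_gt = lapply(study$smiles, function(s) as.integer(s$gt))),
    file.path(out_dir, "gt.json"), auto_unbox = TRUE)
  invisible(out_dir)
}

#' Read a cohort directory written by [write_study_dir()]
#'
#' @param dir cohort directory.
#' @return a study list shaped like [simulate_study()]'s result (without
#'   ground-truth fields unless `gt.json` is present).
#' @export
read_study_dir <- function(dir) {
  scores <- load_poms_csv(file.path(dir, "poms.csv"))
  key <- paste0(scores$subject_id, "_", scores$session)
  gaze <- lapply(key, function(k) {
    f <- file.path(dir, "gaze", paste0(k, ".csv"))
    if (file.exists(f)) list(trace = load_gaze_csv(f)) else NULL
  })
  smiles <- lapply(key, function(k) {
    f <- file.path(dir, "faces", paste0(k, ".csv"))
    if (file.exists(f)) list(features = as.matrix(read.csv(f))) else NULL
  })
  out <- list(scores = scores, gaze = gaze, smiles = smiles)
  gtf <- file.path(dir, "gt.json")
  if (file.exists(gtf)) {
    out$gt <- jsonlite::read_json(gtf, simplifyVector = TRUE)
    out$cluster <- out$gt$cluster
  }
  out
}
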