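#' POMS2 mood components and pipeline indicators
#'
#' The POMS2 instrument yields seven mood-component scores per session:
#' anger--hostility (AH), confusion--bewilderment (CB), depression--dejection
#' (DD), fatigue--inertia (FI), tension--anxiety (TA), vigor--activity (VA)
#' and friendliness (F). The pipeline reduces these to two indicators: total
#' mood disturbance, `TMD = AH + CB + DD + FI + TA - VA` (VA enters inverted),
#' and F, which is independent of TMD. Higher TMD means a more negative mood;
#' higher F a more positive one.
#'
#' @param scores a data.frame of component scores as returned by
#'   [load_poms_csv()]: one row per session with columns `subject_id`,
#'   `session`, `AH`, `CB`, `DD`, `FI`, `TA`, `VA`, `F`, all scores finite
#'   and non-negative.
#' @return `compute_tmd()` returns a numeric vector of TMD values, one per row.
#' @examples
#' s <- data.frame(subject_id = "A", session = 1,
#'                 AH = 3, CB = 5, DD = 2, FI = 7, TA = 4, VA = 6, F = 10)
#' compute_tmd(s)  # 21 - 6 = 15
#' @export
compute_tmd <- function(scores) {
  comps <- c("AH", "CB", "DD", "FI", "TA", "VA")
  missing <- setdiff(comps, names(scores))
  if (length(missing)) {
    stop_mm("component column(s) missing: %s", paste(missing, collapse = ", "))
  }
  for (cc in comps) {
    v <- scores[[cc]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      stop_mm("component '%s' contains non-finite or non-numeric values", cc)
    }
  }
  scores$AH + scores$CB + scores$DD + scores$FI + scores$TA - scores$VA
}

#' Linear T-score standardization
#'
#' Standardizes a raw-score vector to T-scores with sample mean 50 and sample
#' standard deviation 10: `50 + 10 * (x - mean(x)) / sd(x)`. The sample sd
#' uses the n-1 denominator. Alternatively a fixed external norm `(mean, sd)`
#' pair can be supplied for norm-referenced scoring.
#'
#' @param raw numeric vector of raw scores, length >= 2 unless `norm` is given.
#' @param norm optional `c(mean, sd)` reference; when supplied the sample
#'   statistics are not used and any input length is accepted.
#' @return numeric vector of T-scores.
#' @export
t_score <- function(raw, norm = NULL) {
  if (!is.numeric(raw) || any(!is.finite(raw))) {
    stop_mm("t_score: input must be finite numeric")
  }
  if (!is.null(norm)) {
    if (length(norm) != 2L || !all(is.finite(norm)) || norm[2] <= 0) {
      stop_mm("t_score: 'norm' must be c(mean, sd) with sd > 0")
    }
    return(50 + 10 * (raw - norm[1]) / norm[2])
  }
  if (length(raw) < 2L) stop_mm("t_score: need at least 2 values")
  s <- sd(raw)
  if (s == 0) stop_mm("t_score: input is constant (sd = 0)")
  50 + 10 * (raw - mean(raw)) / s
}

#' Read POMS2 component scores from CSV
#'
#' Expects a UTF-8, comma-separated file with a header row containing at least
#' `subject_id, session, AH, CB, DD, FI, TA, VA, F`. Row order is preserved;
#' `(subject_id, session)` pairs must be unique.
#'
#' @param path path to the CSV file.
#' @return data.frame with one row per session record.
#' @export
load_poms_csv <- function(path) {
  if (!file.exists(path)) stop_mm("POMS file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "session", "AH", "CB", "DD", "FI", "TA", "VA", "F")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop_mm("POMS CSV '%s' is missing column(s): %s", path,
            paste(missing, collapse = ", "))
  }
  for (cc in setdiff(req, "subject_id")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop_mm("POMS CSV '%s': non-numeric value in column '%s' at data row %d",
              path, cc, bad[1])
    }
    df[[cc]] <- v
  }
  neg <- which(as.matrix(df[c("AH", "CB", "DD", "FI", "TA", "VA", "F")]) < 0,
               arr.ind = TRUE)
  if (nrow(neg)) {
    stop_mm("POMS CSV '%s': negative score at data row %d", path, neg[1, 1])
  }
  key <- paste(df$subject_id, df$session, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop_mm("POMS CSV '%s': duplicate (subject_id, session) at data row %d",
            path, dup[1])
  }
  df[req]
}

#' Compute per-session mood points (TMD, F) in T-score units
#'
#' Applies [compute_tmd()] and [t_score()] to a component-score table. By
#' default TMD is computed from raw component scores and then T-scored over
#' the dataset (`order = "raw_then_t"`); the alternative T-scores each
#' component first and sums the standardized components
#' (`order = "t_then_sum"`). F is T-scored directly.
#'
#' @param scores data.frame from [load_poms_csv()].
#' @param order `"raw_then_t"` (default) or `"t_then_sum"`.
#' @param tmd_norm,f_norm optional external `c(mean, sd)` norms passed to
#'   [t_score()]; default self-normalization over the dataset.
#' @return data.frame with columns `subject_id`, `session`, `TMD`, `F`.
#' @export
mood_points <- function(scores, order = c("raw_then_t", "t_then_sum"),
                        tmd_norm = NULL, f_norm = NULL) {
  order <- match.arg(order)
  if (order == "raw_then_t") {
    tmd <- t_score(compute_tmd(scores), norm = tmd_norm)
  } else {
    comps <- lapply(c("AH", "CB", "DD", "FI", "TA"),
                    function(cc) t_score(scores[[cc]]))
    tmd0 <- Reduce(`+`, comps) - t_score(scores$VA)
    tmd <- t_score(tmd0, norm = tmd_norm)
  }
  data.frame(subject_id = scores$subject_id,
             session = scores$session,
             TMD = tmd,
             F = t_score(scores$F, norm = f_norm),
             stringsAsFactors = FALSE)
}
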