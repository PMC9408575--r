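#' @keywords internal
"_PACKAGE"

#' @useDynLib moodmap, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rnorm quantile kmeans median sd dnorm
#' @importFrom utils read.csv write.csv
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a reproducible child seed from a parent seed and a stream index.
# Kept below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(stream)) %% 2147483629)
}

stop_mm <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop_mm("'%s' must be a single finite number (got %s)", name,
            paste(format(x), collapse = ","))
  }
  invisible(x)
}
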