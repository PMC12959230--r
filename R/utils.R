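## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state, so
#' generator functions are reproducible without clobbering the session RNG.
#' @noRd
with_seed <- function(seed, expr) {
  seed <- as.integer(seed %% 2147483647L)
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
  set.seed(seed)
  expr
}

#' Deterministic non-negative integer hash of a label
#'
#' Used to key order-insensitive RNG substreams by genotype label.
#' @noRd
label_hash <- function(label) {
  h <- 0
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 31 + ch) %% 1000003
  }
  as.integer(h)
}

#' @noRd
stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

#' Normalize genotype/batch labels: trimmed, lower-case
#' @noRd
norm_label <- function(x) {
  tolower(trimws(as.character(x)))
}

#' Draw gamma variates parameterized by mean and squared coefficient of
#' variation
#'
#' The gamma family is the package's stand-in law for strictly positive
#' measurements: `shape = 1/cv2`, `scale = mean * cv2` reproduces the two
#' moments the analysis uses exactly. A `cv2` of zero returns the mean
#' repeated.
#'
#' @param n number of draws.
#' @param mean positive target mean.
#' @param cv2 non-negative target squared coefficient of variation,
#'   `(sd/mean)^2`.
#' @return numeric vector of length `n`.
#' @examples
#' x <- rgamma_meancv2(1e4, mean = 100, cv2 = 0.04)
#' c(mean(x), (sd(x) / mean(x))^2)
#' @export
rgamma_meancv2 <- function(n, mean, cv2) {
  if (any(mean <= 0)) stop_invalid("'mean' must be positive")
  if (any(cv2 < 0)) stop_invalid("'cv2' must be non-negative")
  if (all(cv2 == 0)) return(rep_len(mean, n))
  stats::rgamma(n, shape = 1 / cv2, scale = mean * cv2)
}
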