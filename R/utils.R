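#' Evaluate code with a temporary RNG state
#'
#' Seeds the generator, runs `code`, and restores the caller's RNG state so
#' that seeded internals do not perturb the session stream.
#'
#' @param seed integer seed, or `NULL` to run unseeded.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  force(code)
}

#' Principal angles between two subspaces
#'
#' Angles (degrees) between the column spans of `a` and `b`, computed from the
#' singular values of the product of their orthonormal bases.
#'
#' @param a,b matrices whose columns span the two subspaces.
#' @return numeric vector of angles in degrees, one per dimension of the
#'   smaller subspace.
#' @export
principal_angles <- function(a, b) {
  qa <- qr.Q(qr(as.matrix(a)))
  qb <- qr.Q(qr(as.matrix(b)))
  s <- svd(crossprod(qa, qb))$d
  acos(pmin(pmax(s, -1), 1)) * 180 / pi
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Variance of a signal within a frequency band
#'
#' Band-limited variance from the discrete Fourier transform (Parseval),
#' used to calibrate generator signal-to-noise ratios inside the analysis
#' band that survives preprocessing.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param band length-2 numeric, band edges in Hz.
#' @return variance of the band-limited component of `x`.
#' @export
band_variance <- function(x, fs, band = c(0.1, 1)) {
  n <- length(x)
  xf <- fft(x - mean(x))
  freqs <- (seq_len(n) - 1) * fs / n
  half <- 2:(floor(n / 2) + 1)
  keep <- half[freqs[half] >= band[1] & freqs[half] <= band[2]]
  2 * sum(Mod(xf[keep])^2) / n^2
}
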