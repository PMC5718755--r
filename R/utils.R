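# Small numerical helpers shared across modules.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

#' Wrap angles into (-180, 180] degrees
#' @param a numeric vector of angles in degrees.
#' @return wrapped angles.
#' @keywords internal
wrap_angle <- function(a) {
  w <- (a + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

# Signed in-plane angle (degrees) of the projection of v onto span(e1, e2),
# measured from e1 towards e2.
plane_angle <- function(v, e1, e2) {
  deg(atan2(sum(v * e2), sum(v * e1)))
}

#' Centered rolling mean, truncated at the edges
#'
#' NA values are dropped within each window; a window with no finite value
#' yields NA. `width` is the nominal window length in samples.
#'
#' @param x numeric vector (may contain NA).
#' @param width window length in samples (>= 1).
#' @return numeric vector of `length(x)`.
#' @keywords internal
rolling_mean <- function(x, width) {
  n <- length(x)
  if (width < 1) stop("width must be >= 1")
  half_lo <- floor((width - 1) / 2)
  half_hi <- ceiling((width - 1) / 2)
  ok <- !is.na(x)
  cs <- cumsum(ifelse(ok, x, 0))
  cn <- cumsum(ok)
  lo <- pmax(seq_len(n) - half_lo, 1L)
  hi <- pmin(seq_len(n) + half_hi, n)
  s <- cs[hi] - ifelse(lo > 1L, cs[lo - 1L], 0)
  k <- cn[hi] - ifelse(lo > 1L, cn[lo - 1L], 0)
  out <- s / k
  out[k == 0] <- NA_real_
  out
}
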