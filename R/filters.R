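# Zero-phase low-pass filtering and spline differentiation.
# Hand-rolled 2nd-order Butterworth + forward-backward pass (no signal
# package available); matches standard gait-lab practice (effective 4th
# order, zero lag).

butter2 <- function(cutoff_hz, fs) {
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stop("cutoff must be in (0, fs/2)")
  wc <- tan(pi * cutoff_hz / fs)
  k <- wc^2
  den <- 1 + sqrt(2) * wc + k
  list(b = c(k, 2 * k, k) / den,
       a = c(1, (2 * k - 2) / den, (1 - sqrt(2) * wc + k) / den))
}

# Direct-form II transposed IIR with initial state.
iir_filter <- function(b, a, x, zi = NULL) {
  n <- length(x)
  y <- numeric(n)
  z1 <- if (is.null(zi)) 0 else zi[1L]
  z2 <- if (is.null(zi)) 0 else zi[2L]
  for (i in seq_len(n)) {
    y[i] <- b[1L] * x[i] + z1
    z1 <- b[2L] * x[i] - a[2L] * y[i] + z2
    z2 <- b[3L] * x[i] - a[3L] * y[i]
  }
  y
}

# Steady-state initial conditions for a unit step (scipy lfilter_zi).
filter_zi <- function(b, a) {
  # state-space of DF2T: solve (I - A') zi = B'
  A <- matrix(c(-a[2L], 1, -a[3L], 0), 2L, 2L, byrow = TRUE)
  Bv <- c(b[2L] - b[1L] * a[2L], b[3L] - b[1L] * a[3L])
  as.numeric(solve(diag(2L) - A, Bv))
}

#' Zero-phase Butterworth low-pass filter
#'
#' Second-order Butterworth applied forward and backward (zero phase,
#' effective fourth order) with odd-reflection edge padding and steady-state
#' initial conditions; a constant series passes through unchanged.
#'
#' @param x numeric series (uniformly sampled)
#' @param cutoff_hz -3 dB cutoff (Hz); `Inf` returns `x` unchanged
#' @param fs sampling rate (Hz)
#' @return filtered series, same length
#' @export
filtfilt_butter <- function(x, cutoff_hz, fs) {
  if (!is.finite(cutoff_hz)) return(x)
  co <- butter2(cutoff_hz, fs)
  npad <- max(12L, ceiling(3 * fs / cutoff_hz))
  if (length(x) <= npad)
    stop("series shorter than the filter warm-up (", npad, " samples)")
  pre <- 2 * x[1L] - x[seq(npad + 1L, 2L)]
  post <- 2 * x[length(x)] - x[seq(length(x) - 1L, length(x) - npad)]
  xx <- c(pre, x, post)
  zi <- filter_zi(co$b, co$a)
  y <- iir_filter(co$b, co$a, xx, zi * xx[1L])
  y <- rev(iir_filter(co$b, co$a, rev(y), zi * y[length(y)]))
  y[(npad + 1L):(npad + length(x))]
}

#' Smooth and differentiate coordinate trajectories
#'
#' Zero-phase low-pass filtering (default 6 Hz, standard for gait marker
#' data) followed by cubic-spline differentiation of each coordinate.
#'
#' @param time time grid (s), uniform sampling
#' @param q matrix of coordinates (frames x DOF)
#' @param cutoff_hz filter cutoff (Hz); `Inf` disables filtering
#' @return list with smoothed `q`, `qd`, `qdd` matrices
#' @examples
#' t <- seq(0, 1, by = 0.01)
#' s <- smooth_differentiate(t, cbind(sin(2 * pi * t)), cutoff_hz = Inf)
#' max(abs(s$qdd + (2 * pi)^2 * sin(2 * pi * t)))  # ~0
#' @export
smooth_differentiate <- function(time, q, cutoff_hz = 6) {
  q <- as.matrix(q)
  dt <- diff(time)
  if (max(abs(dt - dt[1L])) > 1e-9 * dt[1L])
    stop("smooth_differentiate requires uniform sampling")
  fs <- 1 / dt[1L]
  qs <- q; qd <- q; qdd <- q
  for (j in seq_len(ncol(q))) {
    xs <- filtfilt_butter(q[, j], cutoff_hz, fs)
    sf <- stats::splinefun(time, xs, method = "fmm")
    qs[, j] <- xs
    qd[, j] <- sf(time, deriv = 1L)
    qdd[, j] <- sf(time, deriv = 2L)
  }
  list(q = qs, qd = qd, qdd = qdd)
}
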