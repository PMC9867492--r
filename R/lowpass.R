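#' Design the first-order discrete low-pass filter
#'
#' Starts from the continuous first-order low-pass prototype
#' \deqn{H(s) = \omega_l / (s + \omega_l)}
#' and discretizes it with the bilinear substitution
#' \eqn{s = 2 f_s (z - 1)/(z + 1)} (no pre-warping: at a 0.16 Hz cut-off and
#' 5 Hz sampling the warping error is below 0.1 %).  The resulting recursion
#' is
#' \deqn{y[k] = b_0 x[k] + b_1 x[k-1] - a_1 y[k-1]}
#' with \eqn{b_0 = b_1 = \omega_l/(\omega_l + 2 f_s)} and
#' \eqn{a_1 = (\omega_l - 2 f_s)/(\omega_l + 2 f_s)}.  The design has unity
#' DC gain (\eqn{b_0 + b_1 = 1 + a_1}) and is stable (\eqn{|a_1| < 1}) for
#' every positive sampling rate.
#'
#' @param omega_l Cut-off angular frequency in rad/s (default 1, i.e. a
#'   cut-off frequency of \eqn{1/2\pi \approx 0.16} Hz -- temperature
#'   changes slowly).
#' @param fs Sampling rate in Hz (default 5).
#' @return An object of class `lpf_coefficients` with fields `b0`, `b1`,
#'   `a1`, `omega_l`, `fs` and the continuous cut-off `cutoff_hz`.
#' @examples
#' co <- design_lpf(omega_l = 1, fs = 5)
#' co$b0          # 1/11
#' co$cutoff_hz   # 0.159... ~ 0.16 Hz
#' @export
design_lpf <- function(omega_l = 1, fs = 5) {
  if (!is.numeric(omega_l) || omega_l <= 0)
    stop("`omega_l` must be a positive cut-off in rad/s", call. = FALSE)
  if (!is.numeric(fs) || fs <= 0)
    stop("`fs` must be a positive sampling rate in Hz", call. = FALSE)
  structure(
    list(b0 = omega_l / (omega_l + 2 * fs),
         b1 = omega_l / (omega_l + 2 * fs),
         a1 = (omega_l - 2 * fs) / (omega_l + 2 * fs),
         omega_l = omega_l, fs = fs,
         cutoff_hz = omega_l / (2 * pi)),
    class = "lpf_coefficients"
  )
}

#' @export
print.lpf_coefficients <- function(x, ...) {
  cat(sprintf(
    "<lpf_coefficients> b0 = b1 = %.6g, a1 = %.6g (cut-off %.4g Hz @ fs = %g Hz)\n",
    x$b0, x$a1, x$cutoff_hz, x$fs))
  invisible(x)
}

#' Filter a single sample series
#'
#' Applies the designed recursion to one numeric series.  The filter memory
#' is initialized to the first sample (`x_prev = y_prev = x[1]`), which
#' removes the startup transient: a constant series passes through
#' unchanged from the very first sample.
#'
#' @param x Numeric vector.
#' @param coeffs An `lpf_coefficients` object.
#' @return Filtered numeric vector of the same length.
#' @export
filter_series <- function(x, coeffs) {
  stopifnot(inherits(coeffs, "lpf_coefficients"))
  n <- length(x)
  if (n == 0) return(x)
  # y[k] = b0 x[k] + b1 x[k-1] - a1 y[k-1]; feed-forward part first, then
  # the recursive pole via stats::filter.
  u <- coeffs$b0 * x + coeffs$b1 * c(x[1], x[-n])
  as.numeric(stats::filter(u, -coeffs$a1, method = "recursive",
                           init = x[1]))
}

#' Frequency response magnitude of the discrete filter
#'
#' Evaluates \eqn{|H(e^{j 2\pi f / f_s})|} for the designed recursion; used
#' to verify the -3 dB point at the cut-off.
#'
#' @param coeffs An `lpf_coefficients` object.
#' @param f_hz Frequencies in Hz.
#' @return Magnitude gains (linear, not dB).
#' @export
lpf_gain <- function(coeffs, f_hz) {
  z1 <- exp(-1i * 2 * pi * f_hz / coeffs$fs)   # z^-1
  Mod((coeffs$b0 + coeffs$b1 * z1) / (1 + coeffs$a1 * z1))
}

#' Low-pass filter a frame stream pixel-wise
#'
#' Every one of the 1024 pixel series is filtered independently by the
#' recursion of [design_lpf()]; ambient, PIR and timestamps pass through
#' unchanged.  Output length equals input length.
#'
#' @param stream A non-empty `frame_stream` of raw frames.
#' @param coeffs Filter design, default `design_lpf(1, stream$fs)`.
#' @return A `frame_stream` of filtered frames.
#' @export
filter_stream <- function(stream, coeffs = design_lpf(1, stream$fs)) {
  if (!inherits(stream, "frame_stream") || !length(stream$frames))
    stop("`stream` must be a non-empty frame_stream", call. = FALSE)
  n <- length(stream$frames)
  b0 <- coeffs$b0; b1 <- coeffs$b1; a1 <- coeffs$a1
  prev_x <- as.vector(stream$frames[[1]]$grid)
  prev_y <- prev_x
  out <- vector("list", n)
  for (k in seq_len(n)) {
    f <- stream$frames[[k]]
    xk <- as.vector(f$grid)
    yk <- b0 * xk + b1 * prev_x - a1 * prev_y
    prev_x <- xk
    prev_y <- yk
    out[[k]] <- thermal_frame(matrix(yk, GRID_DIM, GRID_DIM),
                              ambient = f$ambient,
                              timestamp = f$timestamp, pir = f$pir)
  }
  frame_stream(out, fs = stream$fs, label = stream$label,
               scenario_meta = stream$scenario_meta)
}
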