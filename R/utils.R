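#' @keywords internal
"_PACKAGE"

# Input-validation helper: stop with a classed condition so callers and tests
# can distinguish user-input errors from internal failures.
stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("dce_input_error", "error")))
}

stop_estimation <- function(...) {
  stop(errorCondition(paste0(...), class = c("dce_estimation_error", "error")))
}

#' Round half away from zero
#'
#' Decimal rounding where ties go away from zero (so 0.03125 renders as
#' 0.0313), unlike [round()]'s round-half-even. Used for all displayed
#' statistics; full precision is always kept in CSV output.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# Trapezoidal integral of y over (possibly nonuniform) grid t.
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) * diff(t)) / 2
}

# Trapezoidal quadrature weights for grid t (w such that sum(w*y) = trapz).
trapz_weights <- function(t) {
  n <- length(t)
  if (n == 1) return(0)
  dt <- diff(t)
  w <- numeric(n)
  w[1] <- dt[1] / 2
  w[n] <- dt[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dt[-(n - 1)] + dt[-1]) / 2
  w
}

# Discrete causal convolution y_i = int_0^{t_i} cp(tau) k(t_i - tau) dtau
# by trapezoid on the sample grid. `kernel` is a vectorised function of the
# lag s >= 0. O(n^2), fine at clinical frame counts.
kernel_conv <- function(cp, t, kernel) {
  n <- length(t)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (i == 1) { out[1] <- 0; next }
    ti <- t[seq_len(i)]
    integrand <- cp[seq_len(i)] * kernel(t[i] - ti)
    out[i] <- trapz(ti, integrand)
  }
  out
}

# Precomputed-grid variant used in the fitting hot path: W is the
# lower-triangular matrix of trapezoid weights, DT the lag matrix t_i - t_j.
conv_grid <- function(t) {
  n <- length(t)
  W <- matrix(0, n, n)
  for (i in 2:n) W[i, seq_len(i)] <- trapz_weights(t[seq_len(i)])
  DT <- outer(t, t, "-")
  DT[DT < 0] <- 0
  list(W = W, DT = DT, n = n)
}

kernel_conv_fast <- function(cp, grid, kernel_of_lag) {
  K <- kernel_of_lag(grid$DT)
  as.vector((grid$W * K) %*% cp)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
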