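`%||%` <- function(a, b) if (is.null(a)) b else a

## trapezoidal integral of y over x (same length)
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

## central-difference gradient with one-sided endpoints
num_gradient <- function(y, dx = 1) {
  n <- length(y)
  if (n < 3L) stop("need at least 3 samples to differentiate", call. = FALSE)
  g <- numeric(n)
  g[1] <- (y[2] - y[1]) / dx
  g[n] <- (y[n] - y[n - 1]) / dx
  g[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * dx)
  g
}

## indices i such that y crosses zero between i and i+1 in the stated direction
zero_crossings <- function(y, direction = c("down", "up")) {
  direction <- match.arg(direction)
  n <- length(y)
  if (n < 2L) return(integer(0))
  a <- y[-n]
  b <- y[-1]
  # exact zeros attach to the left interval
  if (direction == "down") which(a > 0 & b <= 0) else which(a < 0 & b >= 0)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid parameter '%s': %s", field, msg), call. = FALSE)
}

## linear resampling of y (arbitrary length) onto n_out points spanning the
## same normalized [0, 1] support
resample_to <- function(y, n_out) {
  n <- length(y)
  if (n == n_out) return(y)
  stats::approx(seq(0, 1, length.out = n), y, xout = seq(0, 1, length.out = n_out))$y
}
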