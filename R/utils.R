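# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
# seed = NULL means "use the current RNG stream" so that callers holding an
# outer with_seed() scope stay fully reproducible without nested reseeding.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer or NULL", call. = FALSE)
  }
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# von Mises sampler (Best & Fisher 1979 rejection method).
# kappa = 0 falls back to the uniform circle; kappa = Inf is degenerate at mu.
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0)
  if (n == 0L) return(numeric(0))
  if (is.infinite(kappa)) return(rep(wrap_angle(mu), n))
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(m)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k > 0L) {
      u3 <- stats::runif(k)
      theta <- sign(u3 - 0.5) * acos(f[ok])
      out[(got + 1L):(got + k)] <- theta
      got <- got + k
    }
  }
  wrap_angle(out + mu)
}

# Wrap angles into (-pi, pi].
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# Mean resultant length of a von Mises distribution, I1(kappa)/I0(kappa).
vm_resultant <- function(kappa) {
  if (is.infinite(kappa)) return(1)
  if (kappa == 0) return(0)
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

# Extend rows to a 2-3-5-smooth FFT length (mirror continuation, then zeros
# if the mirror cannot cover the gap); R's mixed-radix FFT degrades to
# O(n^2) on lengths with large prime factors.
fft_length_pad <- function(xm) {
  n <- ncol(xm)
  n2 <- stats::nextn(n, c(2, 3, 5))
  if (n2 == n) return(list(x = xm, n = n))
  gap <- n2 - n
  mir <- min(gap, n - 1L)
  ext <- xm[, n - seq_len(mir), drop = FALSE]
  if (gap > mir) ext <- cbind(ext, matrix(0, nrow(xm), gap - mir))
  list(x = cbind(xm, ext), n = n)
}

# Analytic signal by frequency-domain Hilbert multiplier; x is a numeric
# vector or a matrix whose *rows* are signals.
analytic_signal <- function(x) {
  one_d <- is.null(dim(x))
  xm <- if (one_d) matrix(x, nrow = 1L) else x
  n0 <- ncol(xm)
  padded <- fft_length_pad(xm)
  xm <- padded$x
  n <- ncol(xm)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1
    h[2L:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2)] <- 2
  }
  X <- t(stats::mvfft(t(xm)))
  X <- X * rep(h, each = nrow(xm))
  a <- t(stats::mvfft(t(X), inverse = TRUE))[, seq_len(n0), drop = FALSE] / n
  if (one_d) a[1L, ] else a
}

# Mirror-pad rows of a matrix (or a vector) by `pad` samples each side.
mirror_pad <- function(x, pad) {
  one_d <- is.null(dim(x))
  xm <- if (one_d) matrix(x, nrow = 1L) else x
  n <- ncol(xm)
  pad <- min(pad, n - 1L)
  if (pad <= 0L) return(x)
  left <- xm[, pad:1L, drop = FALSE]
  right <- xm[, n:(n - pad + 1L), drop = FALSE]
  out <- cbind(left, xm, right)
  if (one_d) out[1L, ] else out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
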