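# Internal numeric helpers shared across modules.

#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  force(code)
}

# Derive a child seed from a parent seed and a stream index, kept < 2^31.
#' @noRd
derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + as.double(stream) * 16807) %% 2147483629
}

# Population (1/n) standard deviation; the motion metrics use this throughout.
#' @noRd
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

# Analytic-signal envelope along the first dimension of a vector or matrix.
#' @noRd
envelope <- function(x) {
  if (is.matrix(x)) {
    n <- nrow(x)
    h <- hilbert_weights(n)
    return(abs(stats::mvfft(stats::mvfft(x) * h, inverse = TRUE) / n))
  }
  n <- length(x)
  h <- hilbert_weights(n)
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

#' @noRd
hilbert_weights <- function(n) {
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  h
}

# Refine an integer argmax by fitting a parabola through its neighbours.
# Returns the fractional offset in [-0.5, 0.5].
#' @noRd
parabolic_offset <- function(ym1, y0, yp1) {
  denom <- ym1 - 2 * y0 + yp1
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps * (abs(y0) + 1)) {
    return(0)
  }
  delta <- 0.5 * (ym1 - yp1) / denom
  max(-0.5, min(0.5, delta))
}

# Sub-sample refinement of an envelope peak: least-squares quadratic fit to
# log(envelope) over peak +- 3 samples (exact for a Gaussian envelope).
# Falls back to the 3-point parabola near edges; returns offset in samples.
#' @noRd
refine_peak_log <- function(env, k) {
  n <- length(env)
  r <- 3L
  if (k - r >= 1L && k + r <= n && all(env[(k - r):(k + r)] > 0)) {
    u <- (-r):r
    y <- log(env[(k - r):(k + r)])
    # quadratic fit y ~ a + b u + c u^2 on the symmetric stencil
    s2 <- sum(u^2)
    s4 <- sum(u^4)
    m <- length(u)
    b <- sum(u * y) / s2
    c2 <- (m * sum(u^2 * y) - s2 * sum(y)) / (m * s4 - s2^2)
    if (is.finite(b) && is.finite(c2) && c2 < 0) {
      return(max(-1, min(1, -b / (2 * c2))))
    }
  }
  if (k > 1L && k < n && env[k - 1L] > 0 && env[k + 1L] > 0) {
    return(parabolic_offset(log(env[k - 1L]), log(env[k]), log(env[k + 1L])))
  }
  0
}

# Reflected ("symmetric") index padding: maps any integer onto 1..n.
#' @noRd
reflect_index <- function(i, n) {
  if (n == 1L) {
    return(rep(1L, length(i)))
  }
  period <- 2L * (n - 1L)
  j <- (i - 1L) %% period
  j <- ifelse(j < 0, j + period, j)
  as.integer(ifelse(j >= n, period - j, j) + 1L)
}

# Pad a vector by r samples each side with odd ("antisymmetric") reflection
# about the edge value: linear ramps continue through the border unchanged,
# so border smoothing does not flatten an anatomical slope.
#' @noRd
pad_odd <- function(v, r) {
  n <- length(v)
  if (r == 0L) {
    return(v)
  }
  li <- reflect_index(seq.int(1L + r, 2L, by = -1L), n)
  ri <- reflect_index(seq.int(n - 1L, n - r, by = -1L), n)
  c(2 * v[1L] - v[li], v, 2 * v[n] - v[ri])
}

# 1-D convolution with odd-reflected edges (kernel normalized, odd length).
#' @noRd
conv1_reflect <- function(v, kernel) {
  n <- length(v)
  r <- (length(kernel) - 1L) %/% 2L
  padded <- pad_odd(v, r)
  out <- stats::filter(padded, kernel, method = "convolution", sides = 2L)
  as.numeric(out[(r + 1L):(r + n)])
}

#' @noRd
gaussian_kernel <- function(sigma) {
  if (sigma <= 0) {
    return(1)
  }
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# 2-D median filter with odd-reflected edges; window = c(n_fast, n_slow).
#' @noRd
median_filter2 <- function(m, window) {
  window <- as.integer(window)
  if (any(window < 1L)) stop("median window entries must be >= 1")
  if (any(window > dim(m))) {
    stop("median window larger than the surface map in at least one axis")
  }
  rf <- (window[1L] - 1L) %/% 2L
  rs <- (window[2L] - 1L) %/% 2L
  nr <- nrow(m)
  nc <- ncol(m)
  padded <- apply(m, 2L, pad_odd, r = rf)
  if (!is.matrix(padded)) padded <- matrix(padded, nrow = nr + 2L * rf)
  padded <- t(apply(padded, 1L, pad_odd, r = rs))
  if (!is.matrix(padded) || nrow(padded) == 1L && nr + 2L * rf > 1L) {
    padded <- matrix(as.vector(padded), nrow = nr + 2L * rf)
  }
  out <- m
  for (j in seq_len(nc)) {
    cols <- j:(j + 2L * rs)
    for (i in seq_len(nr)) {
      out[i, j] <- stats::median(padded[i:(i + 2L * rf), cols])
    }
  }
  out
}

# Separable 2-D Gaussian smoothing with reflected edges; sigma = c(fast, slow).
#' @noRd
gaussian_filter2 <- function(m, sigma) {
  kf <- gaussian_kernel(sigma[1L])
  ks <- gaussian_kernel(sigma[2L])
  if (length(kf) > 1L) {
    m <- apply(m, 2L, conv1_reflect, kernel = kf)
    if (!is.matrix(m)) m <- matrix(m, nrow = 1L)
  }
  if (length(ks) > 1L) {
    m <- t(apply(m, 1L, conv1_reflect, kernel = ks))
    if (!is.matrix(m)) m <- matrix(m, ncol = 1L)
  }
  m
}

# Sample a vector at fractional positions; out-of-range positions give 0.
# method "cubic" is Catmull-Rom (local, no edge ringing), "linear" is two-point.
#' @noRd
resample_at <- function(x, pos, method = c("cubic", "linear")) {
  method <- match.arg(method)
  n <- length(x)
  out <- numeric(length(pos))
  inside <- pos >= 1 & pos <= n
  if (!any(inside)) {
    return(out)
  }
  p <- pos[inside]
  i0 <- floor(p)
  u <- p - i0
  xe <- c(x[1L], x, x[n], x[n])  # clamp one point each side for the cubic stencil
  # xe index k corresponds to x index k - 1
  if (method == "linear") {
    v0 <- xe[i0 + 1L]
    v1 <- xe[i0 + 2L]
    out[inside] <- v0 * (1 - u) + v1 * u
  } else {
    pm1 <- xe[i0]
    p0 <- xe[i0 + 1L]
    p1 <- xe[i0 + 2L]
    p2 <- xe[i0 + 3L]
    out[inside] <- 0.5 * ((2 * p0) +
      (-pm1 + p1) * u +
      (2 * pm1 - 5 * p0 + 4 * p1 - p2) * u^2 +
      (-pm1 + 3 * p0 - 3 * p1 + p2) * u^3)
  }
  out
}

# Spearman rank correlation with a normal-approximation p-value (one- or
# two-sided); avoids cor.test's exact-tie warnings on small ladders.
#' @noRd
spearman_trend <- function(x, y) {
  n <- length(x)
  rho <- stats::cor(rank(x), rank(y))
  # t-approximation
  tval <- rho * sqrt((n - 2) / max(1e-12, 1 - rho^2))
  p_less <- stats::pt(tval, df = n - 2)
  list(rho = rho, p_less = p_less)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
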