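# Low-level signal-processing primitives shared across modules.

next_pow2 <- function(n) 2^ceiling(log2(max(n, 2)))

# Smallest 7-smooth integer >= n (sizes the mixed-radix FFT handles fast).
next_fast_len <- function(n) {
  if (n <= 6) return(as.integer(n))
  best <- next_pow2(n)
  p5 <- 1
  while (p5 < best) {
    p35 <- p5
    while (p35 < best) {
      p357 <- p35
      while (p357 < best) {
        m <- p357
        while (m < n) m <- m * 2
        if (m < best) best <- m
        p357 <- p357 * 7
      }
      p35 <- p35 * 3
    }
    p5 <- p5 * 5
  }
  as.integer(best)
}

#' Zero-phase Butterworth bandpass filter
#'
#' Filters forwards and backwards (\code{signal::filtfilt}) so the output has
#' no phase distortion, as required when envelopes from different channels are
#' compared in time.
#'
#' @param x numeric signal vector.
#' @param fs sampling rate in Hz.
#' @param low,high band edges in Hz; `high` must be below the Nyquist rate.
#' @param order filter order of the underlying one-pass Butterworth design.
#' @return filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, low, high, order = 4L) {
  nyq <- fs / 2
  if (high >= nyq) stop("upper band edge ", high, " Hz is at or above Nyquist (",
                        nyq, " Hz)")
  if (low <= 0 || low >= high) stop("invalid band [", low, ", ", high, "]")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

lowpass_filter <- function(x, fs, cutoff, order = 6L) {
  nyq <- fs / 2
  if (cutoff >= nyq) stop("cutoff at or above Nyquist")
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

#' Analytic signal via the frequency domain
#'
#' Returns the complex analytic signal whose modulus is the instantaneous
#' amplitude envelope of `x` (the discrete Hilbert-transform construction).
#'
#' @param x real signal vector.
#' @return complex vector, same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Centered moving average with edge shrinkage (window truncated at the ends).
moving_average <- function(x, n) {
  n <- max(1L, as.integer(n))
  if (n == 1L) return(x)
  cs <- cumsum(c(0, x))
  half <- n %/% 2
  i <- seq_along(x)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, length(x))
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Trapezoidal integral with uniform spacing dx.
trapz_uniform <- function(y, dx) {
  n <- length(y)
  if (n < 2) return(0)
  dx * (sum(y) - (y[1] + y[n]) / 2)
}

#' Decimate a signal to a lower sampling rate
#'
#' Applies a zero-phase Butterworth anti-alias lowpass at 0.4 times the target
#' rate, then keeps every `fs/target_fs`-th sample.  The source rate must be
#' an integer multiple of the target rate.
#'
#' @param x signal vector.
#' @param fs original sampling rate (Hz).
#' @param target_fs desired rate (Hz).
#' @param cutoff_frac anti-alias cutoff as a fraction of `target_fs`; raise
#'   toward 0.5 when band content close to the new Nyquist must survive.
#' @param order anti-alias filter order.
#' @return list with `x` (decimated signal) and `fs` (the target rate).
#' @export
decimate_to <- function(x, fs, target_fs, cutoff_frac = 0.4, order = 6L,
                        method = c("iir", "fft")) {
  method <- match.arg(method)
  if (fs == target_fs) return(list(x = x, fs = fs))
  q <- fs / target_fs
  if (abs(q - round(q)) > 1e-9) stop("fs must be an integer multiple of target_fs")
  q <- as.integer(round(q))
  if (method == "fft") {
    # zero-phase spectral lowpass (raised-cosine rolloff into the new
    # Nyquist), then subsample
    n <- length(x)
    X <- stats::fft(x)
    f <- seq(0, fs, length.out = n + 1)[1:n]
    f <- pmin(f, fs - f)
    g <- rep(1, n)
    f1 <- cutoff_frac * target_fs; f2 <- 0.5 * target_fs
    roll <- f > f1 & f < f2
    g[roll] <- 0.5 * (1 + cos(pi * (f[roll] - f1) / (f2 - f1)))
    g[f >= f2] <- 0
    y <- Re(stats::fft(X * g, inverse = TRUE) / n)
  } else {
    y <- lowpass_filter(x, fs, cutoff = cutoff_frac * target_fs, order = order)
  }
  list(x = y[seq(1L, length(y), by = q)], fs = target_fs)
}

# Band-limited unit-variance Gaussian noise synthesised in the frequency
# domain (flat spectrum on [low, high] Hz), one inverse FFT.
bandlimited_noise <- function(n, fs, low, high) {
  nh <- n %/% 2
  f <- (1:nh) * fs / n
  g <- as.numeric(f >= low & f <= high)
  Z <- complex(real = stats::rnorm(nh), imaginary = stats::rnorm(nh)) * g
  X <- complex(real = numeric(n))
  X[2:(nh + 1)] <- Z
  if (n %% 2 == 0) {
    X[nh + 1] <- complex(real = Re(Z[nh]))
    X[(nh + 2):n] <- Conj(Z[(nh - 1):1])
  } else {
    X[(nh + 2):n] <- Conj(Z[nh:1])
  }
  y <- Re(stats::fft(X, inverse = TRUE) / n)
  y / stats::sd(y)
}

# 1/f^a coloured Gaussian noise, unit variance.  The spectrum is drawn
# directly (complex Gaussian bins scaled by f^(-a/2), Hermitian-symmetrised)
# so only one inverse FFT is needed.
one_over_f_noise <- function(n, fs, exponent) {
  if (exponent <= 0) return(stats::rnorm(n))
  nh <- n %/% 2
  f <- (1:nh) * fs / n
  g <- pmax(f, 0.5)^(-exponent / 2)            # flatten below 0.5 Hz
  Z <- complex(real = stats::rnorm(nh), imaginary = stats::rnorm(nh)) * g
  X <- complex(real = numeric(n))
  X[2:(nh + 1)] <- Z
  if (n %% 2 == 0) {
    X[nh + 1] <- complex(real = Re(Z[nh]))     # real Nyquist bin
    X[(nh + 2):n] <- Conj(Z[(nh - 1):1])
  } else {
    X[(nh + 2):n] <- Conj(Z[nh:1])
  }
  y <- Re(stats::fft(X, inverse = TRUE) / n)
  y / stats::sd(y)
}

# --- Welch auto/cross spectra -------------------------------------------------

# Segment a signal into Hann-windowed half-overlapping pieces and return the
# one-sided DFT of each (matrix: nfft/2+1 rows x nseg cols).
welch_segments <- function(x, nfft, overlap = 0.5) {
  n <- length(x)
  step <- as.integer(nfft * (1 - overlap))
  starts <- seq(1L, n - nfft + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nfft - 1) / (nfft - 1))  # Hann
  out <- matrix(0 + 0i, nrow = nfft %/% 2 + 1, ncol = length(starts))
  for (k in seq_along(starts)) {
    seg <- x[starts[k]:(starts[k] + nfft - 1L)] * w
    F <- stats::fft(seg)
    out[, k] <- F[1:(nfft %/% 2 + 1)]
  }
  out
}

welch_freqs <- function(fs, nfft) seq(0, fs / 2, length.out = nfft %/% 2 + 1)
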