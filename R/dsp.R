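# Internal DSP primitives: Butterworth design, zero-phase filtering,
# Hilbert transform, Welch PSD. Kept dependency-free on purpose.

# Analog Butterworth lowpass prototype poles (unit cutoff), order n.
butter_prototype <- function(n) {
  k <- seq_len(n)
  exp(1i * pi * (2 * k + n - 1) / (2 * n))
}

# Digital Butterworth bandpass, prototype order n (final order 2n).
# lo, hi are band edges in Hz; fs the sampling rate. Returns list(b, a).
butter_bandpass <- function(n, lo, hi, fs) {
  stopifnot(lo > 0, hi > lo, hi < fs / 2)
  # pre-warp edges for the bilinear transform
  w1 <- 2 * fs * tan(pi * lo / fs)
  w2 <- 2 * fs * tan(pi * hi / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  p <- butter_prototype(n)
  # lowpass -> bandpass: each pole maps to a conjugate pair
  pl <- p * bw / 2
  pb <- c(pl + sqrt(pl^2 - w0^2), pl - sqrt(pl^2 - w0^2))
  zb <- rep(0 + 0i, n)                 # n zeros at s = 0
  kb <- bw^n                           # analog gain
  # bilinear transform s = 2*fs*(z-1)/(z+1)
  fs2 <- 2 * fs
  zd <- (fs2 + zb) / (fs2 - zb)
  pd <- (fs2 + pb) / (fs2 - pb)
  kd <- kb * Re(prod(fs2 - zb) / prod(fs2 - pb))
  # zeros at z = -1 complete the numerator (degree match)
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))
  b <- Re(kd * poly_from_roots(zd))
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

# Direct-form II transposed IIR filter.
iir_filter <- function(b, a, x, zi = NULL) {
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf - length(b))) / a[1]
  a <- c(a, rep(0, nf - length(a))) / a[1]
  z <- if (is.null(zi)) rep(0, nf - 1) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (nf > 2) {
      for (j in seq_len(nf - 2)) z[j] <- b[j + 1] * xi + z[j + 1] - a[j + 1] * yi
    }
    z[nf - 1] <- b[nf] * xi - a[nf] * yi
    y[i] <- yi
  }
  y
}

# Steady-state initial conditions so a step input produces a step output
# (Gustafsson / scipy lfilter_zi construction).
filter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf - length(b))) / a[1]
  a <- c(a, rep(0, nf - length(a))) / a[1]
  n <- nf - 1
  if (n == 0) return(numeric(0))
  A <- diag(n)
  # companion-form state transition for DF2T
  M <- matrix(0, n, n)
  M[, 1] <- -a[2:nf]
  if (n > 1) M[seq_len(n - 1), 2:n] <- diag(n - 1)
  B <- b[2:nf] - a[2:nf] * b[1]
  solve(A - M, B)
}

# Zero-phase filtering with odd extension padding (scipy filtfilt default).
filtfilt_bw <- function(b, a, x) {
  nf <- max(length(a), length(b))
  padlen <- 3 * nf
  if (length(x) <= padlen)
    stop("signal too short for zero-phase filtering (need > ", padlen, " samples)")
  pre <- 2 * x[1] - x[(padlen + 1):2]
  post <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - padlen)]
  ext <- c(pre, x, post)
  zi <- filter_zi(b, a)
  y <- iir_filter(b, a, ext, zi * ext[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + length(x))]
}

# Analytic signal via the frequency-domain Hilbert transformer.
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

# Welch PSD, one-sided density. Hann window, linear detrend per segment.
# Returns freqs (Hz) and psd in input-units^2 / Hz.
welch_psd <- function(x, fs, nperseg, overlap = 0.5) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1, floor(nperseg * (1 - overlap)))
  starts <- seq(1, n - nperseg + 1, by = step)
  # keep the record fully covered: final segment flush with the end
  if (starts[length(starts)] < n - nperseg + 1)
    starts <- c(starts, n - nperseg + 1)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nperseg - 1) / nperseg)  # periodic Hann
  scale <- 1 / (fs * sum(w^2))
  nfreq <- floor(nperseg / 2) + 1
  acc <- numeric(nfreq)
  tt <- seq_len(nperseg)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1)]
    fit <- stats::lm.fit(cbind(1, tt), seg)        # linear detrend
    seg <- fit$residuals
    X <- stats::fft(seg * w)[1:nfreq]
    p <- (Mod(X)^2) * scale
    # one-sided: double everything except DC (and Nyquist when even)
    if (nperseg %% 2 == 0) p[2:(nfreq - 1)] <- 2 * p[2:(nfreq - 1)]
    else p[2:nfreq] <- 2 * p[2:nfreq]
    acc <- acc + p
  }
  list(freqs = (seq_len(nfreq) - 1) * fs / nperseg,
       psd = acc / length(starts),
       n_segments = length(starts))
}

# Trapezoidal integral of y over x restricted to the half-open band [lo, hi).
band_power <- function(freqs, psd, lo, hi) {
  idx <- which(freqs >= lo & freqs < hi)
  if (length(idx) < 2) return(0)
  f <- freqs[idx]; p <- psd[idx]
  sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
}
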