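# Morlet time-frequency frontend. The Gaussian envelope is fixed across
# frequencies (32 ms full width at half maximum by default), so the analysis
# is effectively a short-term Fourier transform evaluated at log-spaced
# centre frequencies. The inverse resynthesizes per-bin cosines with
# accumulated analytic phase and overlap-added amplitude envelopes.

#' Morlet time-frequency transform
#'
#' @param waveform numeric vector (mono).
#' @param sr sample rate in Hz.
#' @param fMin,fMax frequency range; \code{fMax} must not exceed Nyquist.
#' @param nBins number of log-spaced frequency bins.
#' @param envelopeMs Gaussian envelope width (FWHM) in milliseconds, fixed
#'   across frequencies.
#' @param hopMs spacing of time bins in milliseconds.
#' @return list with \code{mag} (nBins x nT magnitude matrix), \code{freqs},
#'   \code{sr}, \code{hop} (samples), \code{n} (original length).
#' @export
audioToTF <- function(waveform, sr, fMin = 40, fMax = 4000, nBins = 64,
                      envelopeMs = 32, hopMs = envelopeMs / 4) {
  if (fMax > sr / 2) stop("fMax exceeds the Nyquist frequency")
  if (fMin >= fMax) stop("fMin must be below fMax")
  n <- length(waveform)
  freqs <- exp(seq(log(fMin), log(fMax), length.out = nBins))
  sigma <- envelopeMs / 1000 / (2 * sqrt(2 * log(2))) * sr  # FWHM -> sd, samples
  hop <- max(1L, as.integer(round(hopMs / 1000 * sr)))
  centers <- seq(1L, n, by = hop)
  half <- as.integer(ceiling(4 * sigma))
  tt <- seq(-half, half)
  env <- exp(-tt^2 / (2 * sigma^2))
  env <- env / sum(env)
  nf <- stats::nextn(n + 2L * half + 1L, 2L)
  xf <- stats::fft(c(waveform, rep(0, nf - n)))
  mag <- matrix(0, nBins, length(centers))
  for (b in seq_len(nBins)) {
    kern <- env * exp(1i * 2 * pi * freqs[b] * tt / sr)
    kf <- stats::fft(c(kern, rep(0, nf - length(kern))))
    conv <- stats::fft(xf * kf, inverse = TRUE) / nf
    # kernel is centred at sample 'half + 1'
    analytic <- conv[centers + half]
    mag[b, ] <- Mod(analytic)
  }
  list(mag = mag, freqs = freqs, sr = sr, hop = hop, n = n,
       envelopeMs = envelopeMs)
}

#' Inverse time-frequency transform
#'
#' Resynthesizes a waveform whose re-analysis approximates the given
#' magnitudes: each bin contributes a cosine at its centre frequency with
#' phase accumulated analytically and an amplitude envelope linearly
#' interpolated between time bins.
#'
#' @param tf list as returned by \code{\link{audioToTF}}.
#' @return numeric waveform of the original length.
#' @export
tfToAudio <- function(tf) {
  n <- tf$n
  out <- numeric(n)
  ts <- seq_len(n)
  centers <- seq(1L, n, by = tf$hop)
  for (b in seq_len(nrow(tf$mag))) {
    a <- tf$mag[b, ]
    if (max(a) == 0) next
    amp <- stats::approx(centers, a, xout = ts, rule = 2)$y
    phase <- 2 * pi * tf$freqs[b] * (ts - 1L) / tf$sr
    out <- out + amp * cos(phase)
  }
  out
}
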