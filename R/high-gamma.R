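#' High-gamma filter bank specification
#'
#' Describes the chain that converts raw multi-channel field potentials into
#' high-gamma analytic-amplitude features: a bank of linear-phase FIR
#' band-pass filters with geometrically spaced center frequencies spanning the
#' high-gamma range, an FIR Hilbert approximator for the analytic amplitude,
#' decimation to the feature frame rate, band averaging, and a sliding-window
#' z-score.
#'
#' @param n_bands Number of band-pass filters (default 8).
#' @param f_low,f_high First and last center frequencies in Hz (defaults 72
#'   and 144, spanning the high-gamma band).
#' @param bp_order Band-pass FIR filter order (default 150, i.e. 151 taps).
#' @param hilbert_order FIR Hilbert approximator order (default 80); the real
#'   component is the input delayed by `hilbert_order/2` samples.
#' @param input_rate Sampling rate of the raw input in Hz (default 381.47).
#' @param decimation Integer decimation factor applied after the Hilbert
#'   stage (default 4), giving feature frame rate `input_rate/decimation`.
#'
#' @return A `filter_bank_spec` list.
#' @export
filter_bank_spec <- function(n_bands = 8, f_low = 72, f_high = 144,
                             bp_order = 150, hilbert_order = 80,
                             input_rate = 381.47, decimation = 4) {
  if (n_bands < 1) abort("n_bands must be >= 1")
  if (!(f_low > 0 && f_high > f_low && f_high < input_rate / 2)) {
    abort("need 0 < f_low < f_high < input_rate/2")
  }
  if (decimation < 1 || decimation != round(decimation)) {
    abort("decimation must be a positive integer")
  }
  if (hilbert_order %% 2 != 0) abort("hilbert_order must be even")
  structure(list(n_bands = as.integer(n_bands), f_low = f_low, f_high = f_high,
                 bp_order = as.integer(bp_order),
                 hilbert_order = as.integer(hilbert_order),
                 input_rate = input_rate, decimation = as.integer(decimation)),
            class = "filter_bank_spec")
}

#' Center frequencies of the band-pass filter bank
#'
#' Centers are geometrically (logarithmically) spaced with endpoints
#' `f_low` and `f_high`: `c_k = f_low * (f_high/f_low)^((k-1)/(n-1))`.
#'
#' @param spec A [filter_bank_spec()].
#' @return Numeric vector of Hz, length `n_bands`.
#' @examples
#' round(band_centers(filter_bank_spec()), 1)
#' @export
band_centers <- function(spec) {
  n <- spec$n_bands
  if (n == 1) return(spec$f_low)
  spec$f_low * (spec$f_high / spec$f_low)^((seq_len(n) - 1) / (n - 1))
}

#' Design the band-pass FIR filter bank
#'
#' Linear-phase band-pass filters designed with the Parks-McClellan algorithm
#' (`signal::remez`). Passband edges sit at the geometric half-spacing around
#' each center, `c_k * 2^(+/- 1/(2(n-1)))`, with transition bands of
#' `0.15 * c_k` on each side.
#'
#' @param spec A [filter_bank_spec()].
#' @return List of `n_bands` numeric coefficient vectors (`bp_order + 1` taps
#'   each), in center-frequency order.
#' @export
design_band_filters <- function(spec) {
  centers <- band_centers(spec)
  nyq <- spec$input_rate / 2
  half <- if (spec$n_bands > 1) 2^(1 / (2 * (spec$n_bands - 1))) else 2^(1 / 14)
  lapply(centers, function(ck) {
    p_lo <- ck / half
    p_hi <- ck * half
    if (p_lo - 0.15 * ck <= 0 || p_hi + 0.15 * ck >= nyq) {
      abort("infeasible band-pass design: edges beyond [0, Nyquist]")
    }
    # The Remez exchange can fail to converge (or converge to a useless
    # solution) for particular edge grids; retry over a deterministic ladder
    # of grid densities and marginally narrower transition bands, accepting
    # the first design whose response is sane (unit passband at the center,
    # no blow-up, suppressed DC).
    check <- function(b) {
      probe <- c(ck, 1, ck / 2)
      resp <- abs(vapply(probe, function(fr) {
        sum(b * exp(-2i * pi * fr / spec$input_rate * (seq_along(b) - 1)))
      }, 0i))
      abs(resp[1] - 1) < 0.05 && resp[2] < 0.1 && resp[3] < 0.1 &&
        max(abs(b)) < 1
    }
    for (trans in c(0.15, 0.14, 0.13, 0.12, 0.11, 0.10, 0.09, 0.08)) {
      for (dens in c(16, 20, 24, 32)) {
        s_lo <- p_lo - trans * ck
        s_hi <- p_hi + trans * ck
        if (s_lo <= 0 || s_hi >= 0.995 * nyq) next
        f <- c(0, s_lo, p_lo, p_hi, s_hi, nyq) / nyq
        b <- tryCatch(
          signal::remez(spec$bp_order, f, c(0, 0, 1, 1, 0, 0),
                        density = dens),
          error = function(e) NULL
        )
        if (!is.null(b) && all(is.finite(b)) && check(b)) {
          return(as.numeric(b))
        }
      }
    }
    abort(sprintf("band-pass design failed to converge at %.1f Hz", ck))
  })
}

# Windowed ideal (type III) FIR Hilbert transformer: antisymmetric impulse
# response h[k] = 2/(pi k) for odd lags, Hamming-windowed, odd tap count
# order + 1.
fir_hilbert <- function(order) {
  k <- seq(-order / 2, order / 2)
  h <- ifelse(k %% 2 != 0, 2 / (pi * k), 0)
  n <- order + 1
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  h * w
}

# Causal FIR filtering with zero initial state, column-wise on a matrix.
fir_filter <- function(b, x) {
  x <- as.matrix(x)
  apply(x, 2, function(col) as.numeric(signal::filter(b, 1, col)))
}

#' Analytic amplitude via an FIR Hilbert approximator
#'
#' Forms the analytic signal whose real part is the input delayed by
#' `hilbert_order/2` samples and whose imaginary part is the FIR Hilbert
#' approximation of the input, and returns its magnitude, evaluated at every
#' `decimation`-th sample.
#'
#' @param band_signal Numeric vector or samples-by-channels matrix (one band).
#' @param hilbert_order Even FIR Hilbert order (default 80).
#' @param decimation Keep every `decimation`-th sample (default 1).
#' @return Matrix of analytic amplitudes, `floor(samples/decimation)` frames by
#'   channels (a plain vector input yields a 1-column matrix).
#' @export
analytic_amplitude <- function(band_signal, hilbert_order = 80, decimation = 1) {
  x <- as.matrix(band_signal)
  if (nrow(x) <= hilbert_order) abort("signal must be longer than hilbert_order")
  h <- fir_hilbert(hilbert_order)
  d <- hilbert_order / 2
  im <- fir_filter(h, x)
  re <- rbind(matrix(0, d, ncol(x)), x[seq_len(nrow(x) - d), , drop = FALSE])
  env <- sqrt(re^2 + im^2)
  keep <- seq(decimation, nrow(env), by = decimation)
  env[keep, , drop = FALSE]
}

#' Average analytic amplitudes across bands
#'
#' @param envelopes 3-d array, bands x frames x electrodes, or a list of
#'   frames-by-electrodes matrices (one per band).
#' @return Frames-by-electrodes matrix: arithmetic mean over the band axis.
#' @export
average_bands <- function(envelopes) {
  if (is.list(envelopes)) {
    dims <- vapply(envelopes, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
      abort("band envelopes must share dimensions")
    }
    return(Reduce(`+`, envelopes) / length(envelopes))
  }
  if (length(dim(envelopes)) != 3) abort("expected bands x frames x electrodes array")
  apply(envelopes, c(2, 3), mean)
}

#' Sliding-window z-score with clipping
#'
#' Standardizes each electrode by the mean and standard deviation of a
#' trailing window (running single-pass updates of the window sums, in the
#' spirit of Welford's online method), then clips to `[-clip, clip]`. Frames
#' seen before one full window use expanding-window statistics; a
#' zero-variance window yields z = 0.
#'
#' @param signal Frames-by-electrodes numeric matrix (band-averaged analytic
#'   amplitudes).
#' @param frame_rate Frames per second.
#' @param window_s Trailing window length in seconds (default 30).
#' @param clip Clip bound in z-score units (default 3.5).
#' @param t0 Time origin passed through to the result.
#' @return A [feature_stream()].
#' @export
sliding_zscore <- function(signal, frame_rate, window_s = 30, clip = 3.5, t0 = 0) {
  x <- as.matrix(signal)
  if (nrow(x) == 0) abort("empty input")
  if (window_s <= 0) abort("window_s must be positive")
  w <- max(2L, as.integer(round(window_s * frame_rate)))
  n <- nrow(x)
  z <- matrix(0, n, ncol(x))
  s1 <- rep(0, ncol(x))
  s2 <- rep(0, ncol(x))
  for (t in seq_len(n)) {
    xt <- x[t, ]
    s1 <- s1 + xt
    s2 <- s2 + xt^2
    if (t > w) {
      xo <- x[t - w, ]
      s1 <- s1 - xo
      s2 <- s2 - xo^2
    }
    k <- min(t, w)
    mu <- s1 / k
    v <- pmax(0, (s2 - k * mu^2) / max(1, k - 1))
    sd <- sqrt(v)
    zt <- ifelse(sd > 0, (xt - mu) / sd, 0)
    z[t, ] <- pmin(clip, pmax(-clip, zt))
  }
  feature_stream(z, frame_rate = frame_rate, t0 = t0, clip = clip)
}

#' Extract high-gamma z-score features from raw multichannel signals
#'
#' Runs the full feature chain: band-pass filter bank, per-band analytic
#' amplitude with decimation, band averaging, and sliding-window z-score with
#' clipping.
#'
#' @param raw Samples-by-channels numeric matrix of raw field potentials
#'   (line-noise filtering and anti-aliasing assumed done upstream).
#' @param spec A [filter_bank_spec()]; its `input_rate` must match the raw
#'   sampling rate.
#' @param window_s,clip Sliding z-score parameters (see [sliding_zscore()]).
#' @return A [feature_stream()] at `input_rate/decimation` Hz.
#' @export
extract_high_gamma <- function(raw, spec = filter_bank_spec(), window_s = 30,
                               clip = 3.5) {
  raw <- as.matrix(raw)
  filters <- design_band_filters(spec)
  envs <- lapply(filters, function(b) {
    analytic_amplitude(fir_filter(b, raw), spec$hilbert_order, spec$decimation)
  })
  hg <- average_bands(envs)
  sliding_zscore(hg, frame_rate = spec$input_rate / spec$decimation,
                 window_s = window_s, clip = clip)
}
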