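#' Filter chain specification
#'
#' The pre-processing chain applied to every recording: a zero-phase
#' (forward-backward) IIR notch at the power-line frequency, a causal
#' (forward-only) Butterworth IIR bandpass, and decimation. Defaults match
#' the standard P300 speller chain: 60 Hz notch with quality factor 30,
#' 1-20 Hz bandpass of order 5 (10 poles after the band transform), and
#' downsampling by 2.
#'
#' @param notch_freq Notch center frequency, Hz (default 60).
#' @param notch_q Quality factor: center frequency / bandwidth (default 30).
#' @param band_low,band_high Bandpass edges, Hz (defaults 1 and 20); each edge
#'   sits at -3 dB.
#' @param butter_order Butterworth prototype order (default 5); the band
#'   transform doubles the pole count.
#' @param downsample_factor Decimation factor (default 2), applied by keeping
#'   every `downsample_factor`-th sample starting at the first.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(notch_freq = 60, notch_q = 30,
                        band_low = 1, band_high = 20,
                        butter_order = 5, downsample_factor = 2) {
  if (notch_q <= 0 || notch_freq <= 0) stop("notch parameters must be > 0")
  if (band_low <= 0 || band_high <= band_low) {
    stop("need 0 < band_low < band_high")
  }
  if (butter_order < 1 || downsample_factor < 1) {
    stop("order and downsample factor must be >= 1")
  }
  structure(
    list(notch_freq = notch_freq, notch_q = notch_q,
         band_low = band_low, band_high = band_high,
         butter_order = as.integer(butter_order),
         downsample_factor = as.integer(downsample_factor),
         notch_mode = "zero_phase", bandpass_mode = "causal"),
    class = "filter_spec"
  )
}

# 2nd-order IIR notch (constrained biquad with zeros on the unit circle at
# +/- the notch frequency and -3 dB bandwidth notch_freq/Q)
.design_notch <- function(f0, q, fs) {
  w0 <- f0 / (fs / 2)
  bw <- w0 / q
  beta <- tan(bw * pi / 2)
  gain <- 1 / (1 + beta)
  list(b = gain * c(1, -2 * cos(pi * w0), 1),
       a = c(1, -2 * gain * cos(pi * w0), 2 * gain - 1))
}

# Butterworth bandpass in zero-pole-gain form: textbook analog prototype
# poles, band transform and bilinear mapping via the signal package. The
# zpk form keeps the band-edge response accurate to machine precision where
# the expanded order-2n polynomial coefficients do not.
.design_butter_zpk <- function(order, low, high, fs) {
  if (high >= fs / 2) stop("band edge at or above Nyquist")
  k <- seq_len(order)
  proto <- signal::Zpg(zero = numeric(0),
                       pole = exp(1i * pi * (2 * k + order - 1) / (2 * order)),
                       gain = 1)
  T <- 2
  warped <- (2 / T) * tan(pi * c(low, high) / fs)
  bp <- signal::sftrans(proto, W = warped, stop = FALSE)
  dig <- signal::bilinear(bp, T = T)
  list(zero = dig$zero, pole = dig$pole, gain = Re(dig$gain))
}

# split a bandpass zpk (zeros at +/-1) into second-order sections
.zpk_to_sos <- function(zpk) {
  p <- zpk$pole
  cplx <- p[Im(p) > 1e-12]
  realp <- Re(p[abs(Im(p)) <= 1e-12])
  sections <- list()
  for (pp in cplx) {
    sections[[length(sections) + 1L]] <-
      list(b = c(1, 0, -1), a = c(1, -2 * Re(pp), Mod(pp)^2))
  }
  realp <- sort(realp)
  while (length(realp) >= 2) {
    p1 <- realp[1]; p2 <- realp[length(realp)]
    realp <- realp[-c(1, length(realp))]
    sections[[length(sections) + 1L]] <-
      list(b = c(1, 0, -1), a = c(1, -(p1 + p2), p1 * p2))
  }
  if (length(realp) == 1) {
    sections[[length(sections) + 1L]] <-
      list(b = c(1, -1), a = c(1, -realp[1]))
  }
  # most resonant sections last
  ord <- order(vapply(sections, function(s) max(Mod(polyroot(rev(s$a)))), 1))
  sections[ord]
}

#' Design the notch + bandpass filter chain for a sampling rate
#'
#' @param spec A [filter_spec()].
#' @param fs Sampling rate of the data the chain will be applied to, Hz.
#' @return A `designed_filters` object holding the notch biquad, the
#'   bandpass in zero-pole-gain and second-order-section form, `spec` and
#'   `fs`. Use [filter_response()] to evaluate magnitude responses.
#' @examples
#' fl <- design_filter_chain(filter_spec(), fs = 300)
#' filter_response(fl, c(1, 20), "bandpass")   # both ~ 1/sqrt(2)
#' @export
design_filter_chain <- function(spec, fs) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$band_high >= (fs / spec$downsample_factor) / 2) {
    stop("band_high must stay below the post-downsample Nyquist frequency")
  }
  if (spec$notch_freq >= fs / 2) stop("notch frequency at or above Nyquist")
  zpk <- .design_butter_zpk(spec$butter_order, spec$band_low, spec$band_high, fs)
  structure(
    list(notch = .design_notch(spec$notch_freq, spec$notch_q, fs),
         bandpass = list(zpk = zpk, sos = .zpk_to_sos(zpk)),
         spec = spec, fs = fs),
    class = "designed_filters"
  )
}

#' Magnitude response of a designed filter chain
#'
#' @param filters A `designed_filters`.
#' @param f Frequencies (Hz) at which to evaluate.
#' @param component One of `"bandpass"` (single causal pass),
#'   `"notch"` (single pass), `"notch_zero_phase"` (forward-backward, i.e.
#'   the squared single-pass magnitude), or `"chain"` (zero-phase notch
#'   followed by the causal bandpass; decimation excluded).
#' @return Numeric vector of magnitudes `|H(f)|`.
#' @export
filter_response <- function(filters, f,
                            component = c("bandpass", "notch",
                                          "notch_zero_phase", "chain")) {
  stopifnot(inherits(filters, "designed_filters"))
  component <- match.arg(component)
  fs <- filters$fs
  z <- exp(1i * 2 * pi * f / fs)
  bp_mag <- function() {
    zpk <- filters$bandpass$zpk
    vapply(z, function(zz) {
      Mod(zpk$gain * prod(zz - zpk$zero) / prod(zz - zpk$pole))
    }, 1)
  }
  notch_mag <- function() {
    n <- filters$notch
    vapply(z, function(zz) {
      Mod(sum(n$b * zz^-(0:2)) / sum(n$a * zz^-(0:2)))
    }, 1)
  }
  switch(component,
         bandpass = bp_mag(),
         notch = notch_mag(),
         notch_zero_phase = notch_mag()^2,
         chain = notch_mag()^2 * bp_mag())
}

.filter_1d <- function(b, a, x) {
  as.numeric(signal::filter(b, a, x))
}

# forward-backward pass: zero net phase, squared magnitude response.
# Odd-reflection padding at both ends lets the filter transients decay in
# the padding instead of corrupting the segment edges.
.zero_phase <- function(b, a, x) {
  n <- length(x)
  p <- min(n - 1L, 300L)
  xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- rev(.filter_1d(b, a, rev(.filter_1d(b, a, xp))))
  y[(p + 1):(p + n)]
}

.causal_sos <- function(bandpass, x) {
  for (s in bandpass$sos) x <- .filter_1d(s$b, s$a, x)
  x * bandpass$zpk$gain
}

#' Apply the filter chain to a continuous segment
#'
#' Runs, in order: the zero-phase notch (forward-backward), the causal
#' Butterworth bandpass (forward only, zero initial conditions), then
#' decimation keeping every `downsample_factor`-th sample starting at the
#' first. Each channel (row) is processed independently.
#'
#' @param segment Numeric channels x samples matrix.
#' @param filters A `designed_filters` from [design_filter_chain()].
#' @return Filtered channels x `floor(samples / downsample_factor)` matrix
#'   (one extra column when `samples %% factor > 0`, i.e.
#'   `ceiling(samples / factor)` columns).
#' @export
apply_filter_chain <- function(segment, filters) {
  stopifnot(inherits(filters, "designed_filters"), is.matrix(segment))
  spec <- filters$spec
  min_len <- 3 * (2 * spec$butter_order + 1)
  if (ncol(segment) <= min_len) {
    stop(sprintf("segment too short: %d samples, need more than %d",
                 ncol(segment), min_len))
  }
  keep <- seq(1, ncol(segment), by = spec$downsample_factor)
  out <- matrix(0, nrow(segment), length(keep),
                dimnames = list(rownames(segment), NULL))
  for (c in seq_len(nrow(segment))) {
    y <- .zero_phase(filters$notch$b, filters$notch$a, segment[c, ])
    y <- .causal_sos(filters$bandpass, y)
    out[c, ] <- y[keep]
  }
  out
}
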