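## 4-pole low-pass Bessel filter, the standard patch-clamp amplifier
## output stage. Built from the order-4 analog Bessel prototype poles
## (normalized to a -3 dB frequency of 1 rad/s), frequency-scaled with
## bilinear prewarping, and discretized with signal::bilinear().

.bessel4_prototype_poles <- c(
  complex(real = -0.65721173, imaginary =  0.83016155),
  complex(real = -0.65721173, imaginary = -0.83016155),
  complex(real = -0.90476203, imaginary =  0.27091873),
  complex(real = -0.90476203, imaginary = -0.27091873))

#' Digital 4-pole Bessel low-pass filter
#'
#' Returns a zero/pole/gain digital filter approximating a 4-pole analog
#' Bessel low-pass with -3 dB cutoff `cutoff_hz`, discretized at
#' `sampling_hz` via the bilinear transform with frequency prewarping.
#' Used to emulate the 2 kHz amplifier filtering of recorded sweeps.
#'
#' @param cutoff_hz -3 dB cutoff frequency (Hz).
#' @param sampling_hz Sampling rate (Hz); must be at least `2 * cutoff_hz`.
#' @return A `signal::Zpg` filter object.
#' @export
bessel_lowpass <- function(cutoff_hz, sampling_hz) {
  if (sampling_hz < 2 * cutoff_hz)
    stop("sampling rate below Nyquist limit for requested cutoff")
  wc <- 2 * sampling_hz * tan(pi * cutoff_hz / sampling_hz)  # prewarped rad/s
  poles <- .bessel4_prototype_poles * wc
  gain <- Re(prod(-poles))  # unit DC gain
  zp <- signal::bilinear(Sz = numeric(0), Sp = poles, Sg = gain,
                         T = 1 / sampling_hz)
  signal::Zpg(zp$z, zp$p, zp$g)
}

#' Apply low-pass filtering to a current trace
#'
#' The filter state is initialized at the trace's first sample (the trace
#' starts at a steady holding level), so no start-up step transient is
#' introduced: the trace is filtered relative to its initial value and the
#' unit-DC-gain offset is restored afterwards.
#'
#' @param x Numeric trace.
#' @param filt Filter from [bessel_lowpass()].
#' @return Filtered trace of the same length.
#' @export
filter_trace <- function(x, filt) {
  as.numeric(signal::filter(filt, x - x[1])) + x[1]
}
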