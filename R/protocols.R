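#' Voltage-clamp protocols
#'
#' Constructors for the three whole-cell protocols used to characterise a
#' T-type current. Each returns a `voltage_protocol`: an ordered list of
#' constant-voltage segments (one of which varies sweep to sweep), the
#' sweep-varying values, and the acquisition settings (10 kHz digitization,
#' 2 kHz low-pass filtering).
#'
#' * `make_activation_protocol()`: from a -100 mV holding potential, a
#'   200 ms hyperpolarizing prepulse to -110 mV followed by 140 ms test
#'   steps from -80 to +20 mV in 5 mV increments (21 sweeps).
#' * `make_ssi_protocol()`: 1 s conditioning prepulses from -110 to
#'   -15 mV in 5 mV increments (20 sweeps), each followed by a 50 ms test
#'   step to -30 mV.
#' * `make_recovery_protocol()`: a double-pulse design -- 2 s inactivating
#'   pulse at -20 mV, a -110 mV interpulse of sweep-varying duration
#'   (default 10 log-spaced values spanning 1 ms to 8 s), then a 150 ms
#'   test pulse at -20 mV; preceded by a 50 ms prepulse to -110 mV from
#'   the -100 mV holding potential.
#'
#' Every protocol opens with a short segment at the holding potential so
#' downstream analysis has a zero-current baseline window.
#'
#' @param interpulses Interpulse durations (ms), strictly increasing,
#'   within \[1, 8000\].
#' @param sampling_rate Digitization rate in Hz.
#' @param filter_cutoff Low-pass cutoff in Hz; must be at most half the
#'   sampling rate.
#' @return A `voltage_protocol` object.
#' @examples
#' p <- make_activation_protocol()
#' length(p$sweep_values)  # 21 test voltages
#' @name protocols
NULL

voltage_protocol <- function(name, holding, segments, sweep_values,
                             varying, sampling_rate = 10000,
                             filter_cutoff = 2000) {
  stopifnot(is.data.frame(segments),
            all(c("label", "voltage", "duration") %in% names(segments)))
  if (any(!is.na(segments$duration) & segments$duration <= 0))
    stop("segment durations must be positive")
  if (length(sweep_values) > 1 && !all(diff(sweep_values) > 0) &&
      !all(diff(sweep_values) < 0))
    stop("sweep_values must be strictly monotone")
  if (sampling_rate < 2 * filter_cutoff)
    stop("sampling_rate must be at least twice filter_cutoff (Nyquist)")
  structure(list(name = name, holding = holding, segments = segments,
                 sweep_values = sweep_values, varying = varying,
                 sampling_rate = sampling_rate,
                 filter_cutoff = filter_cutoff),
            class = "voltage_protocol")
}

#' @rdname protocols
#' @export
make_activation_protocol <- function(sampling_rate = 10000,
                                     filter_cutoff = 2000) {
  voltage_protocol(
    name = "activation", holding = -100,
    segments = data.frame(
      label = c("holding", "prepulse", "test"),
      voltage = c(-100, -110, NA),
      duration = c(50, 200, 140)),
    sweep_values = seq(-80, 20, by = 5), varying = "test",
    sampling_rate = sampling_rate, filter_cutoff = filter_cutoff)
}

#' @rdname protocols
#' @export
make_ssi_protocol <- function(sampling_rate = 10000,
                              filter_cutoff = 2000) {
  voltage_protocol(
    name = "ssi", holding = -100,
    segments = data.frame(
      label = c("holding", "prepulse", "test"),
      voltage = c(-100, NA, -30),
      duration = c(50, 1000, 50)),
    sweep_values = seq(-110, -15, by = 5), varying = "prepulse",
    sampling_rate = sampling_rate, filter_cutoff = filter_cutoff)
}

#' @rdname protocols
#' @export
make_recovery_protocol <- function(interpulses = default_interpulses(),
                                   sampling_rate = 10000,
                                   filter_cutoff = 2000) {
  if (any(interpulses < 1 | interpulses > 8000))
    stop("interpulses must lie within [1, 8000] ms")
  if (length(interpulses) > 1 && any(diff(interpulses) <= 0))
    stop("interpulses must be strictly increasing")
  voltage_protocol(
    name = "recovery", holding = -100,
    segments = data.frame(
      label = c("holding", "prepulse", "inactivating", "interpulse", "test"),
      voltage = c(-100, -110, -20, -110, -20),
      duration = c(50, 50, 2000, NA, 150)),
    sweep_values = interpulses, varying = "interpulse",
    sampling_rate = sampling_rate, filter_cutoff = filter_cutoff)
}

#' @rdname protocols
#' @export
default_interpulses <- function() {
  round(exp(seq(log(1), log(8000), length.out = 10)), 1)
}

#' Resolve the segment table of one sweep
#'
#' Expands a protocol into the concrete (voltage, duration) segment list
#' of sweep `i`, substituting that sweep's value of the varying quantity.
#'
#' @param protocol A `voltage_protocol`.
#' @param i Sweep index.
#' @return A data.frame with columns `label`, `voltage`, `duration`.
#' @export
sweep_segments <- function(protocol, i) {
  stopifnot(inherits(protocol, "voltage_protocol"),
            i >= 1, i <= length(protocol$sweep_values))
  segs <- protocol$segments
  val <- protocol$sweep_values[i]
  j <- which(segs$label == protocol$varying)
  if (protocol$name == "recovery") segs$duration[j] <- val
  else segs$voltage[j] <- val
  segs
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf("Voltage protocol '%s': %d sweeps, holding %g mV, %g kHz / %g kHz filter\n",
              x$name, length(x$sweep_values), x$holding,
              x$sampling_rate / 1000, x$filter_cutoff / 1000))
  print(x$segments, row.names = FALSE)
  invisible(x)
}
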