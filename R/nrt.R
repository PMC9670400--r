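#' Reference nRT neuron parameters
#'
#' Loads the pinned parameter set of the three-compartment reticular-
#' thalamic neuron (geometry, passive properties, spike-current and
#' T-current densities, calcium concentrations) from the versioned
#' parameter file bundled with the package, and derives compartment
#' areas and axial coupling conductances from the geometry.
#'
#' @return A list of model constants (areas in cm^2, couplings in nS,
#'   densities in S/cm^2 or cm/s).
#' @export
nrt_reference <- function() {
  path <- system.file("extdata", "nrt_reference_model.json",
                      package = "cavgate", mustWork = TRUE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  geo <- j$geometry
  area <- function(g) pi * g$diam_um * g$L_um * 1e-8      # cm^2
  rhalf <- function(g) {                                   # ohm
    r_cm <- g$diam_um / 2 * 1e-4
    j$Ra_ohm_cm * (g$L_um / 2 * 1e-4) / (pi * r_cm^2)
  }
  gc <- function(a, b) 1e9 / (rhalf(a) + rhalf(b))         # nS
  list(area = c(soma = area(geo$soma), dend1 = area(geo$dend1),
                dend2 = area(geo$dend2)),
       gc01 = gc(geo$soma, geo$dend1), gc12 = gc(geo$dend1, geo$dend2),
       cm = j$cm_uF_cm2, g_pas = j$g_pas_S_cm2, e_pas = j$e_pas_mV,
       g_na = j$g_na_S_cm2, g_k = j$g_k_S_cm2, e_na = j$e_na_mV,
       e_k = j$e_k_mV, vtraub = j$vtraub_mV,
       pcat = c(soma = j$pcat_cm_s$soma, dend1 = j$pcat_cm_s$dend1,
                dend2 = j$pcat_cm_s$dend2),
       cai = j$cai_mM, cao = j$cao_mM, celsius = j$celsius,
       pexp = j$t_gate_exponent, version = j$version)
}

#' Build an nRT model carrying a fraction of variant T conductance
#'
#' Clones the reference three-compartment neuron and splits the T-type
#' permeability of every compartment into `(1 - f)` with reference
#' kinetics and `f` with the supplied variant kinetics (independent gate
#' states; total density preserved). `f = 0.2` reflects roughly 40%
#' Cav3.2 contribution to the native nRT T conductance combined with
#' heterozygosity of the variants. With `f = 0` the model is the
#' reference cell, bit for bit.
#'
#' @param variant A [t_gating_model()] built by [build_gating_model()]
#'   (must carry a parametric `pars` description).
#' @param f Variant fraction of the T conductance, in \[0, 1\].
#' @param reference Constants from [nrt_reference()].
#' @return An object of class `nrt_model`.
#' @examples
#' wt <- variant_params("WT")
#' m <- build_nrt_model(build_gating_model(wt$act, wt$inact, wt$rec,
#'                                         label = "WT"))
#' @export
build_nrt_model <- function(variant, f = 0.2, reference = nrt_reference()) {
  stopifnot(inherits(variant, "t_gating_model"))
  if (is.null(variant$pars))
    stop("variant model lacks a parametric description; build it with ",
         "build_gating_model()")
  if (!is.numeric(f) || length(f) != 1 || is.na(f) || f < 0 || f > 1)
    stop("f must be a single value in [0, 1]")
  if (any(!is.finite(variant$pars))) stop("non-finite variant parameters")
  structure(list(reference = reference, variant = variant$pars,
                 label = variant$label, f = f, cache = new.env()),
            class = "nrt_model")
}

#' @export
print.nrt_model <- function(x, ...) {
  cat(sprintf("nRT model: variant '%s' at fraction f = %g of T conductance\n",
              x$label, x$f))
  invisible(x)
}

## flat parameter vector for the C++ core
.nrt_pack <- function(model) {
  r <- model$reference; v <- model$variant
  c(r$area, r$gc01, r$gc12, r$cm, r$g_pas, r$e_pas,
    r$g_na, r$g_k, r$e_na, r$e_k, r$vtraub,
    r$pcat, model$f, r$cai, r$cao, r$celsius,
    -52, 7.4, -80, 5,                       # reference T steady states
    v[["vha"]], v[["ka"]], v[["vhi"]], v[["ki"]],
    v[["dm"]], v[["dh"]], v[["s_rec"]], r$pexp)
}

#' Solve the holding bias current and resting state
#'
#' Finds the constant somatic bias current that holds the resting somatic
#' membrane potential at `holding` (current-clamp holding, not a voltage
#' clamp): the cell is relaxed for `settle_ms` under a candidate bias and
#' the end-point somatic voltage drives a secant iteration. The solved
#' bias and relaxed full state are cached on the model.
#'
#' @param model An `nrt_model`.
#' @param holding Target somatic resting potential (mV).
#' @param settle_ms Relaxation time per candidate (default 3000 ms,
#'   several times the slowest T-gate time constant).
#' @param dt Integration step (ms).
#' @param tol Voltage tolerance (mV).
#' @return List with `bias_pA` and `state` (the relaxed state vector).
#' @export
nrt_steady_state <- function(model, holding = -70, settle_ms = 3000,
                             dt = 0.0125, tol = 1e-4) {
  key <- sprintf("ss_%g_%g", holding, dt)
  if (!is.null(model$cache[[key]])) return(model$cache[[key]])
  par <- .nrt_pack(model)
  y0 <- .nrt_init_state_cpp(par, holding)
  relax <- function(bias) {
    r <- .nrt_run_cpp(par, y0, dt, settle_ms, bias, 4000L)
    list(v = r$state_end[1], state = r$state_end)
  }
  ## initial bracket from the passive input conductance
  g_in <- sum(model$reference$area * model$reference$g_pas) * 1e9  # nS
  b0 <- 0; r0 <- relax(b0)
  b1 <- b0 + (holding - r0$v) * g_in; r1 <- relax(b1)
  for (i in 1:30) {
    if (abs(r1$v - holding) < tol) break
    if (abs(r1$v - r0$v) < 1e-12)
      stop("bias solve stalled; resting point may be unstable")
    b2 <- b1 + (holding - r1$v) * (b1 - b0) / (r1$v - r0$v)
    b0 <- b1; r0 <- r1; b1 <- b2; r1 <- relax(b2)
  }
  if (abs(r1$v - holding) >= max(tol, 0.01))
    stop(sprintf("holding solve did not converge (reached %.3f mV)", r1$v))
  res <- list(bias_pA = b1, state = r1$state)
  model$cache[[key]] <- res
  res
}

#' Somatic current-clamp simulation
#'
#' Integrates the full compartmental system through a pre-pulse /
#' pulse / post-pulse current injection schedule from the solved holding
#' state, and detects somatic action potentials (upward 0 mV crossings
#' with a 2 ms refractory time).
#'
#' @param model An `nrt_model`.
#' @param amplitude Injected current during the pulse, in nA (negative =
#'   hyperpolarizing).
#' @param pulse_ms Pulse duration (default 200 ms).
#' @param pre_ms,post_ms Time before and after the pulse.
#' @param holding Holding potential (mV), maintained by a solved bias.
#' @param dt Integration step (ms); 12.5 us default. The fixed step
#'   makes runs bit-reproducible; halving `dt` is the accuracy
#'   cross-check.
#' @param record_dt Sampling interval of the returned traces (ms).
#' @return A `current_clamp_result`: `time` (ms), `v_m` (matrix, one
#'   column per compartment, soma first), `injected_nA`, `spike_times`
#'   (ms), `phases` (pre/pulse/post boundaries), `bias_pA`.
#' @examples
#' \donttest{
#' wt <- variant_params("WT")
#' m <- build_nrt_model(build_gating_model(wt$act, wt$inact, wt$rec))
#' r <- run_current_clamp(m, -0.65)
#' length(r$spike_times)
#' }
#' @export
run_current_clamp <- function(model, amplitude, pulse_ms = 200,
                              pre_ms = 200, post_ms = 400,
                              holding = -70, dt = 0.0125,
                              record_dt = 0.1) {
  stopifnot(inherits(model, "nrt_model"))
  ss <- nrt_steady_state(model, holding, dt = dt)
  par <- .nrt_pack(model)
  rec_every <- max(1L, as.integer(round(record_dt / dt)))
  r <- .nrt_run_cpp(par, ss$state, dt,
                    c(pre_ms, pulse_ms, post_ms),
                    ss$bias_pA + c(0, amplitude * 1000, 0),
                    rec_every)
  spikes <- detect_spikes(r$time, r$v[, 1])
  structure(list(time = r$time, v_m = r$v, injected_nA = amplitude,
                 spike_times = spikes,
                 phases = c(pre = pre_ms, pulse = pulse_ms,
                            post = post_ms),
                 bias_pA = ss$bias_pA, holding = holding),
            class = "current_clamp_result")
}

#' Detect action potentials in a voltage trace
#'
#' Upward threshold crossings with a refractory time to deduplicate.
#'
#' @param t Time vector (ms).
#' @param v Voltage trace (mV).
#' @param threshold Crossing threshold (mV), default 0.
#' @param refractory Minimum spacing between detected spikes (ms).
#' @return Spike times (ms).
#' @export
detect_spikes <- function(t, v, threshold = 0, refractory = 2) {
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  if (!length(up)) return(numeric(0))
  st <- t[up]
  keep <- c(TRUE, diff(st) >= refractory)
  while (!all(keep)) {        # successive dedup for dense crossings
    st <- st[keep]
    keep <- c(TRUE, diff(st) >= refractory)
  }
  st
}

## spikes within [from, to) ms
.spikes_in <- function(result, from, to) {
  sum(result$spike_times >= from & result$spike_times < to)
}

#' Count rebound spikes over a grid of hyperpolarizing amplitudes
#'
#' Runs the current clamp at every amplitude and counts spikes in the
#' rebound window (pulse offset to `rebound_ms` after offset).
#'
#' @param model An `nrt_model`.
#' @param amplitudes Negative injection amplitudes (nA), ordered.
#' @param rebound_ms Rebound analysis window after pulse offset.
#' @param ... Passed to [run_current_clamp()].
#' @return data.frame with `amplitude_nA` and `rebound_spikes`.
#' @export
rebound_scan <- function(model, amplitudes, rebound_ms = 300, ...) {
  if (any(amplitudes >= 0))
    stop("rebound scan needs hyperpolarizing (negative) amplitudes")
  counts <- vapply(amplitudes, function(a) {
    r <- run_current_clamp(model, a, ...)
    off <- r$phases[["pre"]] + r$phases[["pulse"]]
    .spikes_in(r, off, off + rebound_ms)
  }, numeric(1))
  data.frame(amplitude_nA = amplitudes, rebound_spikes = counts)
}

#' Rheobase by bisection
#'
#' Minimal injected current magnitude that elicits at least one spike:
#' in the rebound window after a hyperpolarizing pulse
#' (`direction = "rebound"`) or during a depolarizing pulse
#' (`direction = "tonic"`). The search magnitude interval must bracket
#' the flip between 0 and >= 1 spikes; bisection proceeds to the
#' requested resolution.
#'
#' @param model An `nrt_model`.
#' @param direction `"rebound"` or `"tonic"`.
#' @param resolution Current resolution in nA (defaults: 0.001 rebound,
#'   0.0001 tonic).
#' @param bracket Magnitude interval (nA) to search, `c(lo, hi)`.
#' @param rebound_ms Rebound window (ms).
#' @param ... Passed to [run_current_clamp()].
#' @return Signed rheobase current in nA (negative for rebound).
#' @export
find_rheobase <- function(model, direction = c("rebound", "tonic"),
                          resolution = NULL, bracket = NULL,
                          rebound_ms = 300, ...) {
  direction <- match.arg(direction)
  if (is.null(resolution))
    resolution <- if (direction == "rebound") 0.001 else 0.0001
  if (is.null(bracket))
    bracket <- if (direction == "rebound") c(0.05, 1.5) else c(0.001, 0.5)
  sgn <- if (direction == "rebound") -1 else 1
  n_spikes <- function(mag) {
    r <- run_current_clamp(model, sgn * mag, ...)
    off <- r$phases[["pre"]] + r$phases[["pulse"]]
    if (direction == "rebound") .spikes_in(r, off, off + rebound_ms)
    else .spikes_in(r, r$phases[["pre"]], off)
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (n_spikes(lo) > 0 || n_spikes(hi) == 0)
    stop("no rheobase bracket in [", lo, ", ", hi, "] nA (",
         direction, ")")
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (n_spikes(mid) > 0) hi <- mid else lo <- mid
  }
  sgn * hi
}

#' Firing frequency of a current-clamp result
#'
#' Spike count in the analysis window divided by the conventional 200 ms
#' analysis duration (so 3 rebound spikes report 15 Hz).
#'
#' @param result A `current_clamp_result`.
#' @param window `"pulse"` (tonic firing during the pulse) or
#'   `"rebound"` (after pulse offset).
#' @param rebound_ms Rebound window length (ms).
#' @param denominator_ms Duration used as the frequency denominator.
#' @return Frequency in Hz.
#' @export
firing_frequency <- function(result, window = c("pulse", "rebound"),
                             rebound_ms = 300, denominator_ms = 200) {
  window <- match.arg(window)
  stopifnot(inherits(result, "current_clamp_result"))
  off <- result$phases[["pre"]] + result$phases[["pulse"]]
  n <- if (window == "pulse")
    .spikes_in(result, result$phases[["pre"]], off)
  else .spikes_in(result, off, off + rebound_ms)
  if (denominator_ms <= 0) stop("empty analysis window")
  n / (denominator_ms / 1000)
}

#' @export
print.current_clamp_result <- function(x, ...) {
  cat(sprintf("Current clamp: %+.3f nA x %g ms from %g mV; %d spikes\n",
              x$injected_nA, x$phases[["pulse"]], x$holding,
              length(x$spike_times)))
  invisible(x)
}
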