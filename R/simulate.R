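#' Synthesize whole-cell current sweeps under a voltage protocol
#'
#' Forward-simulates the family of current traces a voltage-clamp protocol
#' would record from a cell expressing the given two-gate T-channel model,
#' standing in for unavailable raw recordings. Within each constant-
#' voltage segment the gate equations
#' \eqn{dm/dt = (m_\infty(V) - m)/\tau_m(V)},
#' \eqn{dh/dt = (h_\infty(V) - h)/\tau_h(V)}
#' are integrated with the exact exponential update (V is piecewise
#' constant, so no solver tolerance enters). The T current is
#' \eqn{g_{bar} C_m m^p h (V - V_{rev})} (pA; inward negative), to which
#' an ohmic leak \eqn{g_{leak}(V - E_{leak})} and i.i.d. Gaussian noise
#' are added. Traces are digitized at the protocol's sampling rate and
#' low-pass filtered with a 4-pole Bessel stage at the protocol's cutoff.
#'
#' Gates start each sweep at their steady state for the holding potential.
#' Results are bit-reproducible for a fixed `seed`.
#'
#' @param model A [t_gating_model()] with linear driving force (see
#'   [recording_model()]).
#' @param protocol A protocol from [make_activation_protocol()],
#'   [make_ssi_protocol()] or [make_recovery_protocol()].
#' @param capacitance Cell capacitance in pF.
#' @param leak_conductance Linear leak conductance in nS.
#' @param e_leak Leak reversal potential in mV.
#' @param noise_sd Gaussian current-noise SD in pA (before filtering).
#' @param seed Integer RNG seed; required when `noise_sd > 0`.
#' @param filter Apply the Bessel stage (TRUE, default) or return the
#'   unfiltered digitized trace.
#' @return A `sweep_set`: time base `time_ms`, matrices `command` and
#'   `current` (rows = samples, columns = sweeps; sweeps shorter than the
#'   longest are NA-padded), plus the protocol and recording metadata.
#' @examples
#' wt <- variant_params("WT")
#' mod <- recording_model(wt$act, wt$inact, wt$rec, label = "WT")
#' sw <- simulate_sweeps(mod, make_activation_protocol(), noise_sd = 0)
#' dim(sw$current)
#' @export
simulate_sweeps <- function(model, protocol, capacitance = 15,
                            leak_conductance = 2, e_leak = 0,
                            noise_sd = 5, seed = 1, filter = TRUE) {
  stopifnot(inherits(model, "t_gating_model"),
            inherits(protocol, "voltage_protocol"))
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (model$driving != "linear")
    stop("sweep synthesis uses the linear driving force; build the model ",
         "with driving = 'linear' (see recording_model())")
  dt <- 1000 / protocol$sampling_rate
  n_sweeps <- length(protocol$sweep_values)
  filt <- if (filter) bessel_lowpass(protocol$filter_cutoff,
                                     protocol$sampling_rate)

  sw <- vector("list", n_sweeps)
  for (i in seq_len(n_sweeps)) {
    segs <- sweep_segments(protocol, i)
    n_seg <- round(segs$duration / dt)
    v_cmd <- rep(segs$voltage, n_seg)
    m <- model$m_inf(protocol$holding)
    h <- model$h_inf(protocol$holding)
    cur <- numeric(sum(n_seg))
    pos <- 0L
    for (s in seq_len(nrow(segs))) {
      v <- segs$voltage[s]; n <- n_seg[s]
      if (n == 0L) next
      tt <- dt * seq_len(n)
      mi <- model$m_inf(v); hi <- model$h_inf(v)
      mm <- mi + (m - mi) * exp(-tt / model$tau_m(v))
      hh <- hi + (h - hi) * exp(-tt / model$tau_h(v))
      if (any(mm < 0 | mm > 1 | hh < 0 | hh > 1))
        stop("gate variable left [0, 1]: unstable segment update")
      cur[pos + seq_len(n)] <-
        model$g_bar * capacitance * mm^model$p * hh * (v - model$v_rev)
      m <- mm[n]; h <- hh[n]; pos <- pos + n
    }
    cur <- cur + leak_conductance * (v_cmd - e_leak)
    sw[[i]] <- list(v = v_cmd, i = cur)
  }

  n_max <- max(vapply(sw, function(s) length(s$i), integer(1)))
  command <- current <- matrix(NA_real_, n_max, n_sweeps)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("a seed is required when noise_sd > 0")
    set.seed(seed)
  }
  for (i in seq_len(n_sweeps)) {
    n <- length(sw[[i]]$i)
    cur <- sw[[i]]$i
    if (noise_sd > 0) cur <- cur + stats::rnorm(n, sd = noise_sd)
    if (filter) cur <- filter_trace(cur, filt)
    command[seq_len(n), i] <- sw[[i]]$v
    current[seq_len(n), i] <- cur
  }
  structure(list(protocol = protocol, time_ms = dt * seq_len(n_max),
                 command = command, current = current,
                 capacitance = capacitance,
                 leak_conductance = leak_conductance, e_leak = e_leak,
                 noise_sd = noise_sd, seed = seed, filtered = filter,
                 leak_included = leak_conductance != 0),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("Sweep set: protocol '%s', %d sweeps x %d samples, C %g pF, leak %g nS, noise %g pA\n",
              x$protocol$name, ncol(x$current), nrow(x$current),
              x$capacitance, x$leak_conductance, x$noise_sd))
  invisible(x)
}

#' P/4 leak subtraction
#'
#' Removes the linear leak from a sweep set the way an acquisition system
#' does online: for every sweep, four quarter-amplitude leak-only
#' subsweeps are synthesized from the holding potential, their summed
#' deviation from the holding level estimates the leak response to the
#' full command, and that estimate -- together with the holding-level
#' current itself -- is subtracted from the recorded trace. For a purely
#' linear leak the cancellation is exact up to noise.
#'
#' Subsweep noise is generated from the sweep set's seed (offset so it is
#' independent of the recording noise) and passed through the same Bessel
#' stage, matching the noise cost of real P/4 correction.
#'
#' @param raw A `sweep_set` whose `leak_conductance` metadata is present.
#' @return A `sweep_set` with the leak removed (`leak_included = FALSE`).
#' @export
p4_subtract <- function(raw) {
  stopifnot(inherits(raw, "sweep_set"))
  if (is.null(raw$leak_conductance))
    stop("sweep set lacks leak metadata; cannot build P/4 subsweeps")
  prot <- raw$protocol
  filt <- if (raw$filtered) bessel_lowpass(prot$filter_cutoff,
                                           prot$sampling_rate)
  hold_n <- round(prot$segments$duration[1] * prot$sampling_rate / 1000)
  base_win <- seq(max(1, hold_n - round(hold_n / 2)), hold_n - 1)
  if (raw$noise_sd > 0) set.seed(raw$seed + 1000003L)
  out <- raw
  for (i in seq_len(ncol(raw$current))) {
    ok <- !is.na(raw$current[, i])
    v_cmd <- raw$command[ok, i]
    sub_total <- numeric(sum(ok))
    for (k in 1:4) {
      v_sub <- prot$holding + (v_cmd - prot$holding) / 4
      i_sub <- raw$leak_conductance * (v_sub - raw$e_leak)
      if (raw$noise_sd > 0)
        i_sub <- i_sub + stats::rnorm(length(i_sub), sd = raw$noise_sd)
      if (raw$filtered) i_sub <- filter_trace(i_sub, filt)
      sub_total <- sub_total + i_sub
    }
    leak_step <- sub_total - mean(sub_total[base_win])
    corrected <- raw$current[ok, i] - leak_step -
      mean(raw$current[base_win, i])
    out$current[ok, i] <- corrected
  }
  out$leak_included <- FALSE
  out
}
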