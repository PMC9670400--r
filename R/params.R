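#' Fitted gating-parameter sets
#'
#' Constructors for the three parameter sets recovered from whole-cell
#' voltage-clamp analysis of a T-type calcium current: the modified
#' Boltzmann describing the peak current--voltage relationship, the
#' two-state Boltzmann describing steady-state inactivation, and the
#' single-exponential recovery from inactivation.
#'
#' Sign convention: the inactivation slope factor is stored positive
#' together with the decreasing form of the availability curve. Report
#' writers re-emit the conventional negative sign (see
#' [variant_summary_table()]).
#'
#' @param v_half Half-(in)activation voltage in mV.
#' @param slope_k Slope factor in mV, stored positive.
#' @param g_max Maximal conductance density in nS/pF.
#' @param v_rev Reversal potential in mV; must lie above `v_half`.
#' @param i_max Maximal normalized current amplitude (dimensionless,
#'   at most 1.05 to tolerate noisy normalized fits).
#' @param tau Recovery time constant in ms.
#' @param amplitude_A Recovery amplitude (dimensionless, at most 1.05).
#' @return An object of class `activation_params`, `inactivation_params`
#'   or `recovery_params`: a named list of the validated fields.
#' @examples
#' wt_act <- activation_params(g_max = 0.84, v_half = -38.17,
#'                             slope_k = 6.38, v_rev = 40)
#' wt_inact <- inactivation_params(v_half = -61.61, slope_k = 4.48)
#' wt_rec <- recovery_params(tau = 644)
#' @name gating_params
NULL

#' @rdname gating_params
#' @export
activation_params <- function(g_max, v_half, slope_k, v_rev = 40) {
  stopifnot(is.numeric(g_max), is.numeric(v_half), is.numeric(slope_k),
            is.numeric(v_rev), length(g_max) == 1L, length(v_half) == 1L,
            length(slope_k) == 1L, length(v_rev) == 1L)
  if (!all(is.finite(c(g_max, v_half, slope_k, v_rev))))
    stop("activation parameters must be finite")
  if (slope_k <= 0) stop("slope_k must be positive (stored-positive convention)")
  if (g_max < 0) stop("g_max must be non-negative")
  if (v_rev <= v_half) stop("v_rev must exceed v_half")
  structure(list(g_max = g_max, v_half = v_half, slope_k = slope_k,
                 v_rev = v_rev),
            class = "activation_params")
}

#' @rdname gating_params
#' @export
inactivation_params <- function(v_half, slope_k, i_max = 1) {
  stopifnot(is.numeric(v_half), is.numeric(slope_k), is.numeric(i_max),
            length(v_half) == 1L, length(slope_k) == 1L, length(i_max) == 1L)
  if (!all(is.finite(c(v_half, slope_k, i_max))))
    stop("inactivation parameters must be finite")
  if (slope_k <= 0) stop("slope_k must be positive (stored-positive convention)")
  if (i_max <= 0 || i_max > 1.05) stop("i_max must lie in (0, 1.05]")
  structure(list(v_half = v_half, slope_k = slope_k, i_max = i_max),
            class = "inactivation_params")
}

#' @rdname gating_params
#' @export
recovery_params <- function(tau, amplitude_A = 1) {
  stopifnot(is.numeric(tau), is.numeric(amplitude_A),
            length(tau) == 1L, length(amplitude_A) == 1L)
  if (!all(is.finite(c(tau, amplitude_A))))
    stop("recovery parameters must be finite")
  if (tau <= 0) stop("tau must be positive")
  if (amplitude_A <= 0 || amplitude_A > 1.05)
    stop("amplitude_A must lie in (0, 1.05]")
  structure(list(tau = tau, amplitude_A = amplitude_A),
            class = "recovery_params")
}

#' @export
print.activation_params <- function(x, ...) {
  cat(sprintf("Activation (I/V Boltzmann): Gmax %.3f nS/pF, V1/2 %.2f mV, k %.2f mV, Vrev %.1f mV\n",
              x$g_max, x$v_half, x$slope_k, x$v_rev))
  invisible(x)
}

#' @export
print.inactivation_params <- function(x, ...) {
  cat(sprintf("Steady-state inactivation: V1/2 %.2f mV, k %.2f mV (reported %.2f), Imax %.3f\n",
              x$v_half, x$slope_k, -x$slope_k, x$i_max))
  invisible(x)
}

#' @export
print.recovery_params <- function(x, ...) {
  cat(sprintf("Recovery from inactivation: tau %.0f ms, A %.3f\n",
              x$tau, x$amplitude_A))
  invisible(x)
}

#' Serialize a variant's gating parameters to and from JSON
#'
#' A flat schema carrying the variant label, the three parameter sets and
#' an optional provenance note, so fitted parameters can move between
#' pipeline stages and sessions as plain text.
#'
#' @param label Variant label (e.g. `"WT"`).
#' @param act,inact,rec Parameter objects from [activation_params()],
#'   [inactivation_params()], [recovery_params()].
#' @param provenance Optional free-text provenance note.
#' @param path File path to write to / read from.
#' @return `write_gating_json()` returns `path` invisibly;
#'   `read_gating_json()` returns a list with elements `label`, `act`,
#'   `inact`, `rec`, `provenance`.
#' @export
write_gating_json <- function(label, act, inact, rec, path,
                              provenance = NULL) {
  stopifnot(inherits(act, "activation_params"),
            inherits(inact, "inactivation_params"),
            inherits(rec, "recovery_params"))
  x <- list(label = label,
            act = unclass(act), inact = unclass(inact), rec = unclass(rec),
            provenance = if (is.null(provenance)) "" else provenance)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gating_json
#' @export
read_gating_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(label = x$label,
       act = do.call(activation_params, as.list(x$act)),
       inact = do.call(inactivation_params, as.list(x$inact)),
       rec = do.call(recovery_params, as.list(x$rec)),
       provenance = x$provenance)
}
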