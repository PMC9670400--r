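#' Forward gating equations
#'
#' The four forward models fitted to whole-cell T-type current data:
#'
#' * `eval_iv()` -- peak current density versus step voltage, a Boltzmann
#'   activation term multiplied by a linear driving force:
#'   \deqn{I(V) = G_{max} (V - V_{rev}) / (1 + e^{(V_{0.5}-V)/k})}
#' * `eval_conductance()` -- the corresponding conductance curve
#'   \eqn{G(V) = G_{max} / (1 + e^{(V_{0.5}-V)/k})}; with
#'   `normalized = TRUE` the curve is divided by \eqn{G_{max}}.
#' * `eval_ssi()` -- steady-state availability after long conditioning
#'   prepulses, the decreasing two-state Boltzmann
#'   \eqn{I(V) = I_{max} / (1 + e^{(V-V_{0.5})/k})} (slope stored
#'   positive).
#' * `eval_recovery()` -- fractional recovery from inactivation after an
#'   interpulse of duration t at strongly hyperpolarized potential,
#'   \eqn{I/I_{max} = A (1 - e^{-t/\tau})}.
#'
#' All four are total functions of their voltage/time argument and are
#' vectorised over it.
#'
#' @param v Voltage(s) in mV.
#' @param t Time(s) in ms, non-negative.
#' @param p The matching parameter object ([activation_params()],
#'   [inactivation_params()] or [recovery_params()]).
#' @param normalized For `eval_conductance()`, divide by `g_max`.
#' @return Numeric vector: current density (pA/pF) for `eval_iv()`,
#'   conductance (nS/pF or normalized) for `eval_conductance()`,
#'   normalized current for `eval_ssi()` and `eval_recovery()`.
#' @examples
#' wt <- activation_params(0.84, -38.17, 6.38, v_rev = 40)
#' eval_iv(-30, wt)
#' eval_conductance(seq(-80, 20, 5), wt, normalized = TRUE)
#' @name gating_equations
NULL

#' @rdname gating_equations
#' @export
eval_iv <- function(v, p) {
  stopifnot(inherits(p, "activation_params"))
  p$g_max * (v - p$v_rev) / (1 + exp((p$v_half - v) / p$slope_k))
}

#' @rdname gating_equations
#' @export
eval_conductance <- function(v, p, normalized = FALSE) {
  stopifnot(inherits(p, "activation_params"))
  g <- p$g_max / (1 + exp((p$v_half - v) / p$slope_k))
  if (normalized) g / p$g_max else g
}

#' @rdname gating_equations
#' @export
eval_ssi <- function(v, p) {
  stopifnot(inherits(p, "inactivation_params"))
  p$i_max / (1 + exp((v - p$v_half) / p$slope_k))
}

#' @rdname gating_equations
#' @export
eval_recovery <- function(t, p) {
  stopifnot(inherits(p, "recovery_params"))
  if (any(t < 0)) stop("recovery time t must be non-negative")
  p$amplitude_A * (1 - exp(-t / p$tau))
}
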