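#' Two-gate Hodgkin-Huxley T-channel models
#'
#' A `t_gating_model` bundles the voltage-dependent steady states and time
#' constants of a two-gate (activation m, availability h) T-type channel
#' with its conductance parameterization: open fraction
#' \eqn{m(V,t)^p h(V,t)}, gate exponent `p`, maximal conductance density
#' `g_bar` (nS/pF), and either a linear driving force `(V - v_rev)` or the
#' constant-field (GHK) flux form.
#'
#' @param m_inf,h_inf Functions of voltage (mV) returning gate steady
#'   states in \[0, 1\]; `m_inf` non-decreasing, `h_inf` non-increasing.
#' @param tau_m,tau_h Functions of voltage returning strictly positive
#'   time constants (ms) over \[-120, 40\] mV.
#' @param g_bar Maximal conductance density (nS/pF).
#' @param p Activation-gate exponent (reference convention: 2).
#' @param v_rev Reversal potential (mV) for the linear driving force.
#' @param driving `"linear"` or `"ghk"`.
#' @param label Variant name.
#' @param pars Optional named numeric vector of the parametric description
#'   (used by the compartmental simulator).
#' @return An object of class `t_gating_model`.
#' @seealso [build_gating_model()], [recording_model()],
#'   [reference_t_kinetics()]
#' @export
t_gating_model <- function(m_inf, tau_m, h_inf, tau_h, g_bar, p = 2,
                           v_rev = 40, driving = c("linear", "ghk"),
                           label = "unnamed", pars = NULL) {
  stopifnot(is.function(m_inf), is.function(tau_m),
            is.function(h_inf), is.function(tau_h),
            is.numeric(g_bar), g_bar >= 0)
  driving <- match.arg(driving)
  m <- structure(list(m_inf = m_inf, tau_m = tau_m, h_inf = h_inf,
                      tau_h = tau_h, g_bar = g_bar, p = p, v_rev = v_rev,
                      driving = driving, label = label, pars = pars),
                 class = "t_gating_model")
  validate_gating_model(m)
  m
}

#' Check a gating model's invariants on a voltage grid
#'
#' Scans \[-120, +40\] mV at 0.1 mV: both steady states bounded in
#' \[0, 1\], `m_inf` non-decreasing, `h_inf` non-increasing, both time
#' constants finite and strictly positive.
#'
#' @param model A [t_gating_model()].
#' @param grid Voltage grid for the scan.
#' @return `model`, invisibly; errors if an invariant fails.
#' @export
validate_gating_model <- function(model, grid = seq(-120, 40, by = 0.1)) {
  m <- model$m_inf(grid); h <- model$h_inf(grid)
  tm <- model$tau_m(grid); th <- model$tau_h(grid)
  tol <- 1e-9
  if (any(!is.finite(c(m, h, tm, th))))
    stop("gating model: non-finite steady state or time constant")
  if (any(m < -tol | m > 1 + tol) || any(h < -tol | h > 1 + tol))
    stop("gating model: steady states must lie in [0, 1]")
  if (any(diff(m) < -tol))
    stop("gating model: m_inf must be non-decreasing in V")
  if (any(diff(h) > tol))
    stop("gating model: h_inf must be non-increasing in V")
  if (any(tm <= 0) || any(th <= 0))
    stop("gating model: time constants must be strictly positive")
  invisible(model)
}

#' @export
print.t_gating_model <- function(x, ...) {
  cat(sprintf("T-channel gating model '%s': m^%d h, g_bar %.3f nS/pF, %s driving\n",
              x$label, x$p, x$g_bar, x$driving))
  invisible(x)
}

## Reference reticular-thalamic T-current kinetics (reduced nRT cell model
## of Destexhe et al. 1996, J Neurophysiol 76:2049; rate constants at
## 24 degC so the Q10 factors are unity).  All voltages mV, times ms.
.ref_kin <- list(vm_half = -52, km = 7.4, vh_half = -80, kh = 5)

.ref_tau_m <- function(v) 3 + 1 / (exp((v + 27) / 10) + exp(-(v + 102) / 15))
.ref_tau_h <- function(v) 85 + 1 / (exp((v + 48) / 4) + exp(-(v + 407) / 50))

#' Reference nRT T-current kinetics
#'
#' The baseline wild-type T-current of the reduced three-compartment
#' reticular-thalamic-neuron model (Destexhe et al. 1996): steady states
#' \eqn{m_\infty = 1/(1+e^{-(V+52)/7.4})},
#' \eqn{h_\infty = 1/(1+e^{(V+80)/5})}, the published bi-exponential
#' time-constant curves, gate exponent 2, and constant-field driving.
#' Rates are taken at 24 degC (temperature factors unity) and inherited
#' unchanged by every derived model.
#'
#' @param g_bar Conductance density placeholder (the compartmental model
#'   sets per-compartment densities itself).
#' @return A [t_gating_model()] labelled `"reference"`.
#' @export
reference_t_kinetics <- function(g_bar = 1) {
  k <- .ref_kin
  t_gating_model(
    m_inf = function(v) 1 / (1 + exp((k$vm_half - v) / k$km)),
    tau_m = .ref_tau_m,
    h_inf = function(v) 1 / (1 + exp((v - k$vh_half) / k$kh)),
    tau_h = .ref_tau_h,
    g_bar = g_bar, p = 2, driving = "ghk", label = "reference",
    pars = c(vha = k$vm_half, ka = k$km, vhi = k$vh_half, ki = k$kh,
             dm = 0, dh = 0, s_rec = 1))
}

#' Build a variant T-channel model from fitted gating parameters
#'
#' Maps a variant's fitted Boltzmann/exponential parameters onto the
#' two-gate reference kinetics:
#'
#' * `m_inf` and `h_inf` are the normalized fitted activation and
#'   availability curves;
#' * `tau_m(V)` and `tau_h(V)` are the reference model's time-constant
#'   curves voltage-shifted, per gate, by the variant's half-voltage shift
#'   relative to the reference steady state;
#' * the hyperpolarized (recovery) limb of `tau_h` is additionally scaled
#'   so that `tau_h` at -110 mV equals the variant's fitted recovery time
#'   constant -- consequently the ratio of two built models' recovery
#'   limbs equals the ratio of their fitted recovery taus. The scale
#'   blends into the unscaled depolarized limb through a sigmoid centred
#'   on the inactivation midpoint (5 mV width).
#'
#' The fitted time course of recovery is the only kinetic quantity the
#' voltage-clamp analysis yields, so it anchors the hyperpolarized limb;
#' all remaining dynamics are inherited from the reference model.
#'
#' @param act,inact,rec Fitted parameter objects.
#' @param reference Reference kinetics, normally
#'   [reference_t_kinetics()]; must carry a `pars` vector.
#' @param label Variant name for the model.
#' @return A [t_gating_model()] with constant-field driving and the
#'   reference gate exponent.
#' @examples
#' wt <- variant_params("WT")
#' m <- build_gating_model(wt$act, wt$inact, wt$rec, label = "WT")
#' m$tau_h(-110)  # equals the fitted recovery tau
#' @export
build_gating_model <- function(act, inact, rec,
                               reference = reference_t_kinetics(),
                               label = "variant") {
  stopifnot(inherits(act, "activation_params"),
            inherits(inact, "inactivation_params"),
            inherits(rec, "recovery_params"))
  if (is.null(reference) || !inherits(reference, "t_gating_model") ||
      is.null(reference$pars))
    stop("a parametric reference model is required")
  rp <- reference$pars
  dm <- act$v_half - rp[["vha"]]
  dh <- inact$v_half - rp[["vhi"]]
  s <- rec$tau / .ref_tau_h(-110 - dh)
  vhi <- inact$v_half
  t_gating_model(
    m_inf = function(v) 1 / (1 + exp((act$v_half - v) / act$slope_k)),
    tau_m = function(v) .ref_tau_m(v - dm),
    h_inf = function(v) 1 / (1 + exp((v - vhi) / inact$slope_k)),
    tau_h = function(v) .ref_tau_h(v - dh) *
      (1 + (s - 1) / (1 + exp((v - vhi) / 5))),
    g_bar = act$g_max, p = reference$p, v_rev = act$v_rev,
    driving = reference$driving, label = label,
    pars = c(vha = act$v_half, ka = act$slope_k, vhi = vhi,
             ki = inact$slope_k, dm = unname(dm), dh = unname(dh),
             s_rec = unname(s)))
}

#' Idealized-instrument T-channel model for synthetic recordings
#'
#' Builds the gating model used to synthesize voltage-clamp sweep
#' families. Its steady states are the fitted Boltzmann curves (the
#' activation gate is raised to `1/p` so the macroscopic conductance
#' equals the fitted curve exactly), and its time constants separate the
#' protocol timescales: a fast, voltage-independent activation time
#' constant, and an inactivation time constant that follows the fitted
#' recovery tau at strongly hyperpolarized potentials and relaxes to a
#' fast depolarized value through a sigmoid placed below the physiological
#' range (-95 mV, 3 mV width). This separation makes transient peak
#' measurements quasi-stationary, so the generating Boltzmann parameters
#' are recoverable from the synthesized protocols; see the methods
#' vignette for the fidelity analysis.
#'
#' @inheritParams build_gating_model
#' @param tau_act Activation time constant (ms), default 0.25.
#' @param tau_inact_dep Depolarized-limb inactivation time constant (ms),
#'   default 150 (fast enough to equilibrate within the 1 s conditioning
#'   prepulse of the steady-state-inactivation protocol).
#' @param p Gate exponent.
#' @return A [t_gating_model()] with linear driving force.
#' @export
recording_model <- function(act, inact, rec, tau_act = 0.25,
                            tau_inact_dep = 150, p = 2, label = "variant") {
  stopifnot(inherits(act, "activation_params"),
            inherits(inact, "inactivation_params"),
            inherits(rec, "recovery_params"))
  t_gating_model(
    m_inf = function(v) (1 / (1 + exp((act$v_half - v) / act$slope_k)))^(1 / p),
    tau_m = function(v) rep_len(tau_act, length(v)),
    h_inf = function(v) 1 / (1 + exp((v - inact$v_half) / inact$slope_k)),
    tau_h = function(v) tau_inact_dep +
      (rec$tau - tau_inact_dep) / (1 + exp((v + 95) / 3)),
    g_bar = act$g_max, p = p, v_rev = act$v_rev, driving = "linear",
    label = label)
}
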