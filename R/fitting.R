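#' Liquid-junction-potential correction
#'
#' Shifts command voltages by the calculated liquid junction potential
#' (default -2.6 mV for the CsCl-based solutions used to isolate T-type
#' currents): `corrected = v - ljp`. Applied uniformly, once, to all
#' protocol voltages; `reverse = TRUE` undoes the correction.
#'
#' For a `voltage_protocol` the correction is applied to every segment
#' voltage, the holding potential, and to the sweep values when they are
#' voltages (not interpulse durations).
#'
#' @param v Voltage(s) in mV, or a `voltage_protocol`.
#' @param ljp Junction potential in mV.
#' @param reverse Undo rather than apply the correction.
#' @return Corrected voltages, or the corrected protocol.
#' @export
apply_ljp_correction <- function(v, ljp = -2.6, reverse = FALSE) {
  UseMethod("apply_ljp_correction")
}

#' @export
apply_ljp_correction.default <- function(v, ljp = -2.6, reverse = FALSE) {
  if (reverse) v + ljp else v - ljp
}

#' @export
apply_ljp_correction.voltage_protocol <- function(v, ljp = -2.6,
                                                  reverse = FALSE) {
  v$holding <- apply_ljp_correction(v$holding, ljp, reverse)
  v$segments$voltage <- apply_ljp_correction(v$segments$voltage, ljp, reverse)
  if (v$name != "recovery")
    v$sweep_values <- apply_ljp_correction(v$sweep_values, ljp, reverse)
  v
}

## sample-index range of a named segment within sweep i
.segment_window <- function(sweeps, i, label) {
  prot <- sweeps$protocol
  segs <- sweep_segments(prot, i)
  j <- match(label, segs$label)
  if (is.na(j)) stop("segment '", label, "' not found in protocol '",
                     prot$name, "'")
  n_seg <- round(segs$duration * prot$sampling_rate / 1000)
  lo <- if (j > 1) sum(n_seg[seq_len(j - 1)]) else 0L
  list(idx = lo + seq_len(n_seg[j]), segs = segs, j = j, n_seg = n_seg)
}

#' Measure per-sweep peak currents
#'
#' Extracts, for each sweep, the extremal inward (most negative) current
#' within a named protocol segment, after baseline subtraction and
#' normalization by the cell capacitance.
#'
#' Baseline options: `"pre"` subtracts the mean over the last
#' `baseline_ms` of the segment preceding the window (the classical
#' pre-step baseline, appropriate for the activation protocol whose
#' prepulse carries no T current); `"holding"` subtracts the mean over
#' the second half of the sweep's initial holding segment, appropriate
#' for conditioning-pulse protocols where steady window current flows
#' immediately before the test step. A constant offset added to a sweep
#' leaves its peak unchanged under either choice.
#'
#' @param sweeps A leak-subtracted `sweep_set` (see [p4_subtract()]).
#' @param window Segment label to search, default `"test"`.
#' @param baseline `"pre"`, `"holding"`, or `NULL` to choose by protocol
#'   (`"pre"` for the activation protocol, `"holding"` otherwise).
#' @param baseline_ms Averaging window for the `"pre"` baseline.
#' @return A data.frame with one row per sweep: `sweep`, `sweep_value`
#'   (test voltage, prepulse voltage or interpulse duration), `test_v`
#'   (command voltage of the measured segment) and `peak_i` (pA/pF,
#'   inward negative).
#' @export
measure_peaks <- function(sweeps, window = "test", baseline = NULL,
                          baseline_ms = 5) {
  stopifnot(inherits(sweeps, "sweep_set"))
  prot <- sweeps$protocol
  if (is.null(baseline))
    baseline <- if (prot$name == "activation") "pre" else "holding"
  baseline <- match.arg(baseline, c("pre", "holding"))
  n_sweeps <- ncol(sweeps$current)
  out <- data.frame(sweep = seq_len(n_sweeps),
                    sweep_value = prot$sweep_values,
                    test_v = NA_real_, peak_i = NA_real_)
  n_base <- round(baseline_ms * prot$sampling_rate / 1000)
  for (i in seq_len(n_sweeps)) {
    w <- .segment_window(sweeps, i, window)
    trace <- sweeps$current[, i]
    base <- if (baseline == "pre") {
      if (w$j == 1) stop("no pre-segment before window '", window, "'")
      lo <- sum(w$n_seg[seq_len(w$j - 1)])
      mean(trace[(lo - n_base + 1):lo])
    } else {
      n_hold <- w$n_seg[1]
      mean(trace[max(1, round(n_hold / 2)):(n_hold - 1)])
    }
    out$test_v[i] <- w$segs$voltage[w$j]
    out$peak_i[i] <- min(trace[w$idx] - base) / sweeps$capacitance
  }
  out
}

#' Normalized steady-state-inactivation points
#'
#' Test-pulse peak per conditioning prepulse voltage, normalized to the
#' largest-magnitude peak of the family.
#'
#' @param sweeps A leak-subtracted `sweep_set` from the SSI protocol.
#' @return data.frame with `v` (prepulse mV) and `rel_i` (0..1).
#' @export
ssi_points <- function(sweeps) {
  pk <- measure_peaks(sweeps, window = "test", baseline = "holding")
  ref <- pk$peak_i[which.max(abs(pk$peak_i))]
  data.frame(v = pk$sweep_value, rel_i = pk$peak_i / ref)
}

#' Normalized recovery-from-inactivation points
#'
#' Test-pulse peak as a fraction of the same sweep's inactivating-
#' prepulse peak, per interpulse duration.
#'
#' @param sweeps A leak-subtracted `sweep_set` from the recovery protocol.
#' @return data.frame with `t` (interpulse ms) and `rel_i` (0..1).
#' @export
recovery_points <- function(sweeps) {
  tst <- measure_peaks(sweeps, window = "test", baseline = "holding")
  pre <- measure_peaks(sweeps, window = "inactivating",
                       baseline = "holding")
  data.frame(t = tst$sweep_value, rel_i = tst$peak_i / pre$peak_i)
}

## Shared bounded Levenberg-Marquardt wrapper with diagnostics.
.lm_fit <- function(start, lower, upper, resid_fn, par_names) {
  fit <- minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                         ptol = 1e-12))
  est <- stats::setNames(coef(fit), par_names)
  converged <- fit$info %in% 1:4
  if (!converged)
    stop("fit did not converge (nls.lm info ", fit$info, ": ",
         fit$message, ")")
  tol <- 1e-6 * pmax(1, abs(est))
  at_bound <- par_names[(est - lower) < tol | (upper - est) < tol]
  se <- tryCatch(sqrt(diag(solve(fit$hessian)) * fit$deviance /
                        max(1, length(fit$fvec) - length(est))),
                 error = function(e) rep(NA_real_, length(est)))
  list(estimate = est, se = stats::setNames(se, par_names),
       resid_norm = sqrt(fit$deviance), converged = converged,
       at_bound = at_bound, n_points = length(fit$fvec))
}

#' Fit the gating equations to measured points
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) with
#' deterministic, data-driven starting values:
#'
#' * `fit_iv()` fits the modified Boltzmann I/V (activation times linear
#'   driving force) over (`g_max`, `v_rev`, `v_half`, `slope_k`) to peak
#'   current densities versus step voltage. Starts: `v_half` at the
#'   half-maximal normalized conductance, slope from a two-point logit,
#'   `v_rev` at +40 mV. Bounds: `slope_k` in \[0.5, 30\], `v_half` in
#'   \[-90, 0\], `v_rev` in \[10, 80\] mV (physiological ranges that
#'   prevent limb swapping).
#' * `fit_ssi()` fits the decreasing two-state Boltzmann over (`i_max`,
#'   `v_half`, `slope_k`) to normalized availability versus prepulse
#'   voltage, and refuses data whose availability increases with voltage
#'   rather than report a sign-flipped curve.
#' * `fit_recovery()` fits \eqn{A(1 - e^{-t/\tau})} over (`A`, `tau`) to
#'   normalized recovery versus interpulse duration.
#'
#' Non-convergence is an error; estimates that land on a bound are
#' reported in the `at_bound` field of the result. Fits are invariant to
#' the ordering of the input points.
#'
#' @param points For `fit_iv()`, a data.frame with `test_v` and `peak_i`
#'   (as from [measure_peaks()]); for `fit_ssi()` columns `v`, `rel_i`;
#'   for `fit_recovery()` columns `t`, `rel_i`.
#' @return A list of class `gating_fit` with elements `params` (the
#'   fitted parameter object), `se`, `resid_norm`, `at_bound`,
#'   `n_points`.
#' @examples
#' wt <- variant_params("WT")
#' v <- seq(-80, 20, 5)
#' f <- fit_iv(data.frame(test_v = v, peak_i = eval_iv(v, wt$act)))
#' f$params
#' @name gating_fits
NULL

#' @rdname gating_fits
#' @export
fit_iv <- function(points) {
  stopifnot(all(c("test_v", "peak_i") %in% names(points)))
  points <- points[order(points$test_v), ]
  v <- points$test_v; y <- points$peak_i
  if (length(v) < 6) stop("fit_iv needs at least 6 points")
  if (all(abs(y) < 1e-12))
    stop("degenerate I/V data: all peaks are zero")
  vrev0 <- 40
  g <- y / (v - vrev0)
  g_n <- g / max(g)
  vh0 <- .half_crossing(v, g_n, 0.5)
  k0 <- .logit_slope(v, g_n)
  f <- .lm_fit(
    start = c(max(g), vrev0, vh0, k0),
    lower = c(0, 10, -90, 0.5), upper = c(100, 80, 0, 30),
    resid_fn = function(p)
      p[1] * (v - p[2]) / (1 + exp((p[3] - v) / p[4])) - y,
    par_names = c("g_max", "v_rev", "v_half", "slope_k"))
  e <- f$estimate
  f$params <- activation_params(g_max = e[["g_max"]],
                                v_half = e[["v_half"]],
                                slope_k = e[["slope_k"]],
                                v_rev = e[["v_rev"]])
  class(f) <- "gating_fit"
  f
}

#' @rdname gating_fits
#' @export
fit_ssi <- function(points) {
  stopifnot(all(c("v", "rel_i") %in% names(points)))
  points <- points[order(points$v), ]
  v <- points$v; y <- points$rel_i
  if (length(v) < 6) stop("fit_ssi needs at least 6 points")
  if (all(abs(y) < 1e-12)) stop("degenerate SSI data: all points zero")
  lo_m <- mean(y[seq_len(3)]); hi_m <- mean(y[length(y) - 2:0])
  if (hi_m > lo_m)
    stop("availability increases with voltage: not a steady-state ",
         "inactivation curve (would need a negative slope factor)")
  yn <- y / max(y)
  vh0 <- .half_crossing(v, yn, 0.5)
  k0 <- .logit_slope(v, 1 - yn)
  f <- .lm_fit(
    start = c(max(y), vh0, k0),
    lower = c(0.2, -90, 0.5), upper = c(1.05, 0, 30),
    resid_fn = function(p) p[1] / (1 + exp((v - p[2]) / p[3])) - y,
    par_names = c("i_max", "v_half", "slope_k"))
  e <- f$estimate
  f$params <- inactivation_params(v_half = e[["v_half"]],
                                  slope_k = e[["slope_k"]],
                                  i_max = e[["i_max"]])
  class(f) <- "gating_fit"
  f
}

#' @rdname gating_fits
#' @export
fit_recovery <- function(points) {
  stopifnot(all(c("t", "rel_i") %in% names(points)))
  points <- points[order(points$t), ]
  t <- points$t; y <- points$rel_i
  if (length(t) < 3)
    stop("fit_recovery is under-determined with fewer than 3 points")
  tau0 <- .half_crossing(t, y / max(y), 1 - exp(-1))
  if (!is.finite(tau0)) tau0 <- stats::median(t)
  f <- .lm_fit(
    start = c(max(y), tau0),
    lower = c(0.2, 1), upper = c(1.05, 30000),
    resid_fn = function(p) p[1] * (1 - exp(-t / p[2])) - y,
    par_names = c("amplitude_A", "tau"))
  e <- f$estimate
  f$params <- recovery_params(tau = e[["tau"]],
                              amplitude_A = e[["amplitude_A"]])
  class(f) <- "gating_fit"
  f
}

#' @export
print.gating_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("  residual norm %.3g over %d points%s\n", x$resid_norm,
              x$n_points,
              if (length(x$at_bound))
                paste0("; AT BOUND: ", paste(x$at_bound, collapse = ", "))
              else ""))
  invisible(x)
}

## linear-interpolated crossing of a normalized monotone-ish curve
.half_crossing <- function(x, y_n, level) {
  dir <- if (stats::cor(x, y_n) >= 0) 1 else -1
  y_u <- if (dir > 0) y_n else 1 - y_n
  lv <- if (dir > 0) level else 1 - level
  i <- which(y_u >= lv)[1]
  if (is.na(i) || i == 1) return(stats::median(x))
  x0 <- x[i - 1]; x1 <- x[i]; y0 <- y_u[i - 1]; y1 <- y_u[i]
  x0 + (lv - y0) / (y1 - y0) * (x1 - x0)
}

## two-point logit slope estimate between the 25% and 75% levels
.logit_slope <- function(x, y_n) {
  x25 <- .half_crossing(x, y_n, 0.25)
  x75 <- .half_crossing(x, y_n, 0.75)
  k <- abs(x75 - x25) / (2 * log(3))
  if (!is.finite(k) || k < 0.5) 5 else min(k, 30)
}
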