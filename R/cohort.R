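#' Synthesize and fit a cohort of virtual cells
#'
#' Emulates the per-cell analysis workflow on a cohort of `n_cells`
#' virtual cells expressing one variant: each cell's sweep families are
#' synthesized under the requested protocols (activation, steady-state
#' inactivation, recovery), P/4 leak-subtracted, peak-measured and fitted
#' per cell; group statistics are then taken over the per-cell fits
#' (mean +/- SEM over cells, matching how patch-clamp cohorts are
#' reported).
#'
#' With `jitter = TRUE` every cell draws its generating parameters from
#' Gaussians centred on the variant's mean values with SDs reconstructed
#' from the published dispersion (SEM x sqrt(n)), emulating biological
#' cell-to-cell variability on top of recording noise; with
#' `jitter = FALSE` all cells share the table's mean parameters and only
#' recording noise differs. The jitter model is a stand-in for the
#' unavailable per-cell data, not a claim about the real cohort.
#'
#' @param label Variant label in `table`.
#' @param n_cells Number of virtual cells.
#' @param table Parameter table, defaults to [cav32_variants()].
#' @param seed Integer seed; cell `c` uses `seed + c` internally.
#' @param noise_sd Recording noise SD in pA.
#' @param jitter Draw per-cell generating parameters (see above).
#' @param protocols Which protocols to run and fit.
#' @param interpulses Interpulse grid for the recovery protocol.
#' @param capacitance,leak_conductance Recording conditions.
#' @return `cohort_fits()`: data.frame of per-cell fitted parameters
#'   (one row per cell). `cohort_summary()`: data.frame of mean, SD and
#'   SEM per fitted parameter.
#' @examples
#' \donttest{
#' fits <- cohort_fits("WT", n_cells = 3, seed = 7,
#'                     protocols = "activation")
#' cohort_summary(fits)
#' }
#' @export
cohort_fits <- function(label, n_cells = 10, table = cav32_variants(),
                        seed = 1, noise_sd = 5, jitter = FALSE,
                        protocols = c("activation", "ssi", "recovery"),
                        interpulses = default_interpulses(),
                        capacitance = 15, leak_conductance = 2) {
  protocols <- match.arg(protocols, several.ok = TRUE)
  row <- table[match(label, table$label), ]
  if (is.na(row$label[1])) stop("unknown variant label: ", label)
  prot_act <- make_activation_protocol()
  prot_ssi <- make_ssi_protocol()
  prot_rec <- make_recovery_protocol(interpulses)
  out <- vector("list", n_cells)
  for (cc in seq_len(n_cells)) {
    cell_seed <- seed + cc
    par <- .cell_params(row, jitter, cell_seed)
    mod <- recording_model(par$act, par$inact, par$rec, label = label)
    rowres <- list(cell = cc)
    if ("activation" %in% protocols) {
      sw <- p4_subtract(simulate_sweeps(mod, prot_act, capacitance,
                                        leak_conductance,
                                        noise_sd = noise_sd,
                                        seed = cell_seed))
      f <- fit_iv(measure_peaks(sw))
      rowres <- c(rowres, list(gmax = f$params$g_max,
                               v_rev = f$params$v_rev,
                               vh_act = f$params$v_half,
                               k_act = f$params$slope_k))
    }
    if ("ssi" %in% protocols) {
      sw <- p4_subtract(simulate_sweeps(mod, prot_ssi, capacitance,
                                        leak_conductance,
                                        noise_sd = noise_sd,
                                        seed = cell_seed + 500000L))
      f <- fit_ssi(ssi_points(sw))
      rowres <- c(rowres, list(vh_inact = f$params$v_half,
                               k_inact = f$params$slope_k,
                               i_max = f$params$i_max))
    }
    if ("recovery" %in% protocols) {
      sw <- p4_subtract(simulate_sweeps(mod, prot_rec, capacitance,
                                        leak_conductance,
                                        noise_sd = noise_sd,
                                        seed = cell_seed + 900000L))
      f <- fit_recovery(recovery_points(sw))
      rowres <- c(rowres, list(tau_rec = f$params$tau,
                               amplitude_A = f$params$amplitude_A))
    }
    out[[cc]] <- as.data.frame(rowres)
  }
  res <- do.call(rbind, out)
  attr(res, "label") <- label
  attr(res, "generating") <- row
  res
}

## per-cell generating parameters, optionally jittered with SD = SEM*sqrt(n)
.cell_params <- function(row, jitter, cell_seed) {
  g <- row$gmax; vha <- row$vh_act; ka <- row$k_act
  vhi <- row$vh_inact; ki <- row$k_inact; tau <- row$tau_rec
  if (jitter) {
    set.seed(cell_seed)
    g <- max(0.05, stats::rnorm(1, g, row$gmax_sem * sqrt(row$n_act)))
    vha <- stats::rnorm(1, vha, row$vh_act_sem * sqrt(row$n_act))
    ka <- max(0.6, stats::rnorm(1, ka, row$k_act_sem * sqrt(row$n_act)))
    vhi <- stats::rnorm(1, vhi, row$vh_inact_sem * sqrt(row$n_inact))
    ki <- max(0.6, stats::rnorm(1, ki,
                                row$k_inact_sem * sqrt(row$n_inact)))
    tau <- max(20, stats::rnorm(1, tau,
                                row$tau_rec_sem * sqrt(row$n_rec)))
    vha <- min(vha, row$v_rev - 20)
  }
  list(act = activation_params(g, vha, ka, v_rev = row$v_rev),
       inact = inactivation_params(vhi, ki),
       rec = recovery_params(tau))
}

#' @rdname cohort_fits
#' @param fits A data.frame from `cohort_fits()`.
#' @export
cohort_summary <- function(fits) {
  num <- fits[setdiff(names(fits), "cell")]
  data.frame(parameter = names(num),
             mean = vapply(num, mean, numeric(1)),
             sd = vapply(num, stats::sd, numeric(1)),
             sem = vapply(num, function(x)
               stats::sd(x) / sqrt(length(x)), numeric(1)),
             n = nrow(fits), row.names = NULL)
}
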