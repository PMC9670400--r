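#' Published Cav3.2 variant gating parameters
#'
#' Loads the bundled table of mean +/- SEM gating parameters for wild-type
#' Cav3.2 and 13 trigeminal-neuralgia-associated missense variants
#' characterised in tsA-201 cells: maximal conductance density, half-
#' activation voltage and slope, half-inactivation voltage and slope, and
#' the recovery-from-inactivation time constant, together with the number
#' of cells behind each mean.
#'
#' Inactivation slope factors are printed negative in the source table;
#' they are re-signed on load to the package's stored-positive convention
#' (the decreasing Boltzmann form).
#'
#' @return A data.frame with one row per variant and columns `label`,
#'   `gmax`, `gmax_sem`, `vh_act`, `vh_act_sem`, `k_act`, `k_act_sem`,
#'   `n_act`, `vh_inact`, `vh_inact_sem`, `k_inact`, `k_inact_sem`,
#'   `n_inact`, `tau_rec`, `tau_rec_sem`, `n_rec`, `v_rev`.
#' @examples
#' head(cav32_variants())
#' @export
cav32_variants <- function() {
  path <- system.file("extdata", "cav32_gating_params.json",
                      package = "cavgate", mustWork = TRUE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tab <- x$variants
  tab$k_inact <- abs(tab$k_inact)  # stored-positive convention
  tab$v_rev <- x$v_rev_mV
  tab
}

#' Gating-parameter objects for one variant
#'
#' Convenience accessor turning one row of [cav32_variants()] (or any
#' data.frame with the same columns) into the three parameter objects used
#' throughout the package.
#'
#' @param label Variant label, e.g. `"WT"` or `"P2280H"`.
#' @param table Parameter table; defaults to the bundled variant table.
#' @return A list with elements `label`, `act`, `inact`, `rec`.
#' @examples
#' wt <- variant_params("WT")
#' eval_iv(-30, wt$act)
#' @export
variant_params <- function(label, table = cav32_variants()) {
  i <- match(label, table$label)
  if (is.na(i)) stop("unknown variant label: ", label)
  r <- table[i, ]
  list(label = label,
       act = activation_params(g_max = r$gmax, v_half = r$vh_act,
                               slope_k = r$k_act, v_rev = r$v_rev),
       inact = inactivation_params(v_half = r$vh_inact, slope_k = r$k_inact),
       rec = recovery_params(tau = r$tau_rec))
}
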