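## shared fixtures built in code

wt_act <- function() activation_params(g_max = 0.84, v_half = -38.17,
                                       slope_k = 6.38, v_rev = 40)
wt_inact <- function() inactivation_params(v_half = -61.61,
                                           slope_k = 4.48)
wt_rec <- function() recovery_params(tau = 644)

## a quick recording model for one variant label
rec_model <- function(label = "WT", table = cav32_variants()) {
  p <- variant_params(label, table)
  recording_model(p$act, p$inact, p$rec, label = label)
}

## the reference T kinetics expressed as a variant (for the nRT
## conductance-splitting identity checks)
reference_as_variant <- function() {
  t_gating_model(
    m_inf = function(v) 1 / (1 + exp((-52 - v) / 7.4)),
    tau_m = function(v) 3 + 1 / (exp((v + 27) / 10) +
                                   exp(-(v + 102) / 15)),
    h_inf = function(v) 1 / (1 + exp((v + 80) / 5)),
    tau_h = function(v) 85 + 1 / (exp((v + 48) / 4) +
                                    exp(-(v + 407) / 50)),
    g_bar = 1, p = 2, driving = "ghk", label = "reference",
    pars = c(vha = -52, ka = 7.4, vhi = -80, ki = 5,
             dm = 0, dh = 0, s_rec = 1))
}

nrt_for <- function(label, f = 0.2, table = cav32_variants()) {
  p <- variant_params(label, table)
  build_nrt_model(build_gating_model(p$act, p$inact, p$rec,
                                     label = label), f = f)
}

## brute-force tie-corrected Kruskal-Wallis H (independent of the
## package implementation)
oracle_kw_H <- function(groups) {
  x <- unlist(groups); g <- rep(seq_along(groups), lengths(groups))
  N <- length(x); r <- rank(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / lengths(groups)) - 3 * (N + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr <= 0) 0 else H / corr
}

## exact permutation p-value for H via recursive enumeration (combn),
## a different code path from the package's iterator
oracle_perm_p <- function(groups) {
  x <- unlist(groups); sizes <- lengths(groups)
  H_obs <- oracle_kw_H(groups)
  N <- length(x)
  count <- 0L; total <- 0L
  recurse <- function(avail, gi, assignment) {
    if (gi > length(sizes)) {
      total <<- total + 1L
      gr <- split(x[order(assignment)], sort(assignment))
      gr <- lapply(seq_along(sizes), function(j) x[assignment == j])
      if (oracle_kw_H(gr) >= H_obs - 1e-12) count <<- count + 1L
      return(invisible())
    }
    ch <- utils::combn(avail, sizes[gi])
    for (k in seq_len(ncol(ch))) {
      a2 <- assignment; a2[ch[, k]] <- gi
      recurse(setdiff(avail, ch[, k]), gi + 1L, a2)
    }
  }
  recurse(seq_len(N), 1L, integer(N))
  count / total
}
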