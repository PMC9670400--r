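#' Variant-versus-wild-type summary
#'
#' Derived comparison statistics for one variant against wild type:
#' half-voltage shifts (`variant - WT`, mV), activation-slope change,
#' recovery acceleration (`WT tau / variant tau`, so values above 1 are
#' faster recovery), relative maximal-conductance change (%), and a
#' functional classification.
#'
#' The classification rule is explicit package policy (configurable via
#' `thresholds`), not a published algorithm: gain-of-function (GoF) when
#' the activation midpoint is hyperpolarized by at least 5 mV or recovery
#' is accelerated at least 2-fold (each significant at `alpha`);
#' loss-of-function (LoF) when `g_max` falls by at least 40%
#' (significant) or the inactivation midpoint is hyperpolarized by at
#' least 10 mV without an accompanying activation shift; otherwise
#' neutral. Per-feature flags are returned alongside the label.
#'
#' @param variant,wt Lists with elements `act`, `inact`, `rec` (as from
#'   [variant_params()] or the `params` of fits), plus optional `label`.
#' @param pvals Named numeric vector of per-feature p-values
#'   (`act_vhalf`, `inact_vhalf`, `gmax`, `rec`); features without a
#'   p-value are judged on effect size alone.
#' @param thresholds Named list: `gof_act_shift` (-5 mV),
#'   `gof_rec_fold` (2), `lof_gmax_pct` (-40), `lof_inact_shift`
#'   (-10 mV), `alpha` (0.05).
#' @return A list of class `variant_summary`: `label`,
#'   `delta_v_half_act`, `delta_v_half_inact`, `delta_slope_act`,
#'   `recovery_fold`, `g_max_change_pct`, `flags`, `classification`.
#' @examples
#' wt <- variant_params("WT")
#' summarize_variant(variant_params("P2280H"), wt)
#' @export
summarize_variant <- function(variant, wt, pvals = NULL,
                              thresholds = list()) {
  for (x in list(variant, wt))
    if (!all(c("act", "inact", "rec") %in% names(x)))
      stop("variant and wt must carry act, inact and rec parameter sets")
  th <- utils::modifyList(
    list(gof_act_shift = -5, gof_rec_fold = 2, lof_gmax_pct = -40,
         lof_inact_shift = -10, alpha = 0.05), thresholds)
  pv <- function(name) {
    if (is.null(pvals) || is.na(pvals[name])) 0 else pvals[[name]]
  }
  d_act <- variant$act$v_half - wt$act$v_half
  d_inact <- variant$inact$v_half - wt$inact$v_half
  d_slope <- variant$act$slope_k - wt$act$slope_k
  fold <- wt$rec$tau / variant$rec$tau
  d_gmax <- 100 * (variant$act$g_max - wt$act$g_max) / wt$act$g_max
  flags <- c(
    act_hyperpolarized = d_act <= th$gof_act_shift &&
      pv("act_vhalf") <= th$alpha,
    recovery_accelerated = fold >= th$gof_rec_fold &&
      pv("rec") <= th$alpha,
    gmax_reduced = d_gmax <= th$lof_gmax_pct && pv("gmax") <= th$alpha,
    inact_hyperpolarized_alone = d_inact <= th$lof_inact_shift &&
      !(d_act <= th$gof_act_shift))
  classification <-
    if (flags[["act_hyperpolarized"]] || flags[["recovery_accelerated"]])
      "GoF"
    else if (flags[["gmax_reduced"]] ||
             flags[["inact_hyperpolarized_alone"]]) "LoF"
    else "neutral"
  structure(list(label = if (!is.null(variant$label)) variant$label else "variant",
                 delta_v_half_act = d_act, delta_v_half_inact = d_inact,
                 delta_slope_act = d_slope, recovery_fold = fold,
                 g_max_change_pct = d_gmax, flags = flags,
                 classification = classification),
            class = "variant_summary")
}

#' @export
print.variant_summary <- function(x, ...) {
  cat(sprintf("%s vs WT: dV1/2(act) %+.1f mV, dV1/2(inact) %+.1f mV, recovery x%.1f, Gmax %+.0f%% -> %s\n",
              x$label, x$delta_v_half_act, x$delta_v_half_inact,
              x$recovery_fold, x$g_max_change_pct, x$classification))
  invisible(x)
}

#' Variant summary table with report rounding
#'
#' Applies [summarize_variant()] to every non-WT row of a parameter
#' table and rounds the derived quantities to reporting precision:
#' voltage shifts and slope changes to 1 decimal (the precision used for
#' derived shifts in figures/text), recovery folds to 1 decimal,
#' conductance changes to whole percent.
#'
#' @param table Parameter table in the layout of [cav32_variants()].
#' @param rounded Apply report rounding (default TRUE).
#' @return data.frame keyed by variant label.
#' @export
variant_summary_table <- function(table = cav32_variants(),
                                  rounded = TRUE) {
  wt <- variant_params("WT", table)
  labs <- setdiff(table$label, "WT")
  if (!length(labs))
    return(data.frame(label = character(), delta_v_half_act = numeric(),
                      delta_v_half_inact = numeric(),
                      delta_slope_act = numeric(),
                      recovery_fold = numeric(),
                      g_max_change_pct = numeric(),
                      classification = character()))
  rows <- lapply(labs, function(l) {
    s <- summarize_variant(variant_params(l, table), wt)
    data.frame(label = l,
               delta_v_half_act = s$delta_v_half_act,
               delta_v_half_inact = s$delta_v_half_inact,
               delta_slope_act = s$delta_slope_act,
               recovery_fold = s$recovery_fold,
               g_max_change_pct = s$g_max_change_pct,
               classification = s$classification)
  })
  out <- do.call(rbind, rows)
  if (rounded) {
    out$delta_v_half_act <- report_round(out$delta_v_half_act, 1)
    out$delta_v_half_inact <- report_round(out$delta_v_half_inact, 1)
    out$delta_slope_act <- report_round(out$delta_slope_act, 1)
    out$recovery_fold <- report_round(out$recovery_fold, 1)
    out$g_max_change_pct <- report_round(out$g_max_change_pct, 0)
  }
  out
}

#' Report rounding at table precision
#'
#' Rounds derived quantities the way the source tables do: the value is
#' first snapped to the 2-decimal fixed-point grid of the published
#' parameters (so differences of 2-decimal numbers are exact), then
#' rounded half away from zero to `digits` decimals. Plain [round()]
#' would turn a difference like -14.95 (stored as -14.9499...) into
#' -14.9 instead of the printed -15.0.
#'
#' @param x Numeric vector.
#' @param digits Decimals to keep (0 or 1 in the report tables).
#' @return Rounded numeric vector.
#' @export
report_round <- function(x, digits = 1) {
  xi <- round(x * 100)           # exact integer grid of 2-dp inputs
  den <- 10^(2 - digits)
  sign(xi) * floor((abs(xi) + den / 2) / den) / 10^digits
}

#' Kruskal-Wallis test with Dunn's post test versus a control group
#'
#' Computes the tie-corrected Kruskal-Wallis H over all groups and Dunn's
#' pairwise z statistics of every group against the control, with a
#' multiplicity adjustment across those comparisons (default Bonferroni,
#' the conventional Dunn adjustment; `"holm"`, `"BH"` and `"none"` are
#' available).
#'
#' With `p_method = "permutation"` the p-values are computed by exact
#' enumeration of all distinct assignments of the pooled observations to
#' the groups (feasible for small groups; an error is raised beyond
#' `max_perm` arrangements): the Kruskal-Wallis p is the fraction of
#' arrangements with H at least the observed, and each Dunn p the
#' fraction with a pairwise mean-rank difference at least as extreme.
#'
#' @param groups Named list of numeric vectors, one per group; each
#'   non-empty. The control group must be present.
#' @param control Name of the control group (default `"WT"`).
#' @param p_adjust Multiplicity adjustment across the control
#'   comparisons.
#' @param p_method `"asymptotic"` (default) or `"permutation"`.
#' @param max_perm Enumeration guard for the permutation method.
#' @return List with `H`, `df`, `p_kw`, `comparisons` (data.frame:
#'   `group`, `n`, `mean_rank`, `z`, `p_unadj`, `p_adj`), `method`.
#' @examples
#' set.seed(1)
#' g <- list(WT = rnorm(8), A = rnorm(8, 2), B = rnorm(8))
#' kruskal_dunn(g)$comparisons
#' @export
kruskal_dunn <- function(groups, control = "WT",
                         p_adjust = c("bonferroni", "holm", "BH", "none"),
                         p_method = c("asymptotic", "permutation"),
                         max_perm = 2e5) {
  p_adjust <- match.arg(p_adjust)
  p_method <- match.arg(p_method)
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) == 0)) stop("empty group")
  if (!control %in% names(groups))
    stop("control group '", control, "' not found")
  x <- unlist(groups, use.names = FALSE)
  gidx <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  kw <- .kw_stats(x, gidx, length(groups))
  others <- setdiff(seq_along(groups), match(control, names(groups)))
  ci <- match(control, names(groups))
  z <- vapply(others, function(j)
    .dunn_z(kw$mean_rank[ci], kw$mean_rank[j], kw$n[ci], kw$n[j],
            N, kw$tie_sum), numeric(1))
  if (p_method == "asymptotic") {
    p_kw <- if (kw$all_tied) 1 else
      stats::pchisq(kw$H, df = length(groups) - 1, lower.tail = FALSE)
    p_un <- if (kw$all_tied) rep(1, length(z)) else
      2 * stats::pnorm(-abs(z))
  } else {
    perm <- .kw_dunn_permutation(x, lengths(groups), ci, others, max_perm)
    p_kw <- mean(perm$H >= kw$H - 1e-12)
    obs_d <- abs(kw$mean_rank[ci] - kw$mean_rank[others])
    p_un <- vapply(seq_along(others), function(k)
      mean(perm$rankdiff[, k] >= obs_d[k] - 1e-12), numeric(1))
  }
  p_adj_v <- pmin(1, stats::p.adjust(p_un, method =
    switch(p_adjust, bonferroni = "bonferroni", holm = "holm",
           BH = "BH", none = "none")))
  list(H = kw$H, df = length(groups) - 1, p_kw = min(1, p_kw),
       comparisons = data.frame(
         group = names(groups)[others], n = kw$n[others],
         mean_rank = kw$mean_rank[others], z = z,
         p_unadj = pmin(1, p_un), p_adj = p_adj_v),
       method = paste(p_method, p_adjust, sep = "/"))
}

## tie-corrected Kruskal-Wallis pieces from pooled data
.kw_stats <- function(x, gidx, k) {
  N <- length(x)
  r <- rank(x)
  n <- tabulate(gidx, nbins = k)
  mean_rank <- vapply(seq_len(k), function(j) mean(r[gidx == j]),
                      numeric(1))
  H <- 12 / (N * (N + 1)) * sum(n * mean_rank^2) - 3 * (N + 1)
  ties <- table(x)
  tie_sum <- sum(ties^3 - ties)
  all_tied <- length(ties) == 1
  corr <- 1 - tie_sum / (N^3 - N)
  H <- if (all_tied || corr <= 0) 0 else H / corr
  list(H = H, n = n, mean_rank = mean_rank, tie_sum = tie_sum,
       all_tied = all_tied)
}

.dunn_z <- function(rb1, rb2, n1, n2, N, tie_sum) {
  s2 <- (N * (N + 1) / 12 - tie_sum / (12 * (N - 1))) * (1 / n1 + 1 / n2)
  if (s2 <= 0) return(0)
  (rb1 - rb2) / sqrt(s2)
}

## exhaustive enumeration of group assignments (multiset permutations of
## the group labels), returning H and the control-vs-other mean-rank
## differences for every arrangement
.kw_dunn_permutation <- function(x, sizes, ci, others, max_perm) {
  k <- length(sizes)
  n_arr <- factorial(sum(sizes)) / prod(factorial(sizes))
  ## identical values collapse arrangements; bound is still the safe guard
  if (n_arr > max_perm)
    stop("permutation enumeration too large (", format(n_arr),
         " arrangements); use p_method = 'asymptotic'")
  r <- rank(x)
  ties <- table(x); tie_sum <- sum(ties^3 - ties)
  N <- length(x)
  assigns <- .group_assignments(N, sizes)
  H <- numeric(nrow(assigns))
  rankdiff <- matrix(0, nrow(assigns), length(others))
  for (a in seq_len(nrow(assigns))) {
    gidx <- assigns[a, ]
    mr <- vapply(seq_len(k), function(j) mean(r[gidx == j]), numeric(1))
    h <- 12 / (N * (N + 1)) * sum(sizes * mr^2) - 3 * (N + 1)
    corr <- 1 - tie_sum / (N^3 - N)
    H[a] <- if (corr <= 0) 0 else h / corr
    rankdiff[a, ] <- abs(mr[ci] - mr[others])
  }
  list(H = H, rankdiff = rankdiff)
}

## all assignments of indices 1..N into ordered groups of given sizes
.group_assignments <- function(N, sizes) {
  build <- function(avail, si) {
    if (si == length(sizes)) {
      m <- matrix(0L, 1, N)
      m[1, avail] <- si
      return(m)
    }
    ch <- utils::combn(avail, sizes[si])
    out <- vector("list", ncol(ch))
    for (j in seq_len(ncol(ch))) {
      sel <- ch[, j]
      sub <- build(setdiff(avail, sel), si + 1L)
      sub[, sel] <- si
      out[[j]] <- sub
    }
    do.call(rbind, out)
  }
  build(seq_len(N), 1L)
}
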