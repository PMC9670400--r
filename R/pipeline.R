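#' End-to-end analysis pipeline
#'
#' Orchestrates the package's stages on a variant parameter table:
#' window-current analysis, variant-versus-WT summary statistics,
#' optional synthetic-cohort simulation with per-cell re-fitting, and the
#' optional nRT excitability simulation. Results are returned as data
#' frames and, when `out_dir` is given, written as CSV together with a
#' JSON provenance manifest (configuration, its MD5 hash, package
#' version). Runs are deterministic for a fixed seed, so repeated runs
#' write byte-identical tables.
#'
#' @param variants Variant labels to process (default: every label in
#'   `table`). `"WT"` is always included as the comparator.
#' @param table Parameter table in the layout of [cav32_variants()].
#' @param stages Subset of `c("window", "summary", "cohort", "nrt")`.
#' @param seed Integer seed for the cohort stage.
#' @param n_cells,noise_sd,jitter Cohort options (see [cohort_fits()]).
#' @param f Variant fraction of T conductance for the nRT stage.
#' @param nrt_amplitudes Named list with `rebound_test` and `tonic_test`
#'   injection amplitudes (nA) for the frequency read-outs.
#' @param rheobase_resolution Bisection resolution (nA) for the nRT
#'   stage.
#' @param out_dir Output directory (created if missing); `NULL` for no
#'   file output.
#' @return A list of class `cavgate_report` with elements `window`,
#'   `summary`, `cohort`, `nrt` (those requested) and `manifest`.
#' @examples
#' rep <- run_pipeline(variants = c("WT", "P2280H"),
#'                     stages = c("window", "summary"))
#' rep$summary
#' @export
run_pipeline <- function(variants = NULL, table = cav32_variants(),
                         stages = c("window", "summary"),
                         seed = 1, n_cells = 5, noise_sd = 5,
                         jitter = FALSE, f = 0.2,
                         nrt_amplitudes = list(rebound_test = -0.65,
                                               tonic_test = 0.2),
                         rheobase_resolution = 0.001,
                         out_dir = NULL) {
  stages <- match.arg(stages, c("window", "summary", "cohort", "nrt"),
                      several.ok = TRUE)
  if (is.null(variants)) variants <- table$label
  variants <- union("WT", variants)
  bad <- setdiff(variants, table$label)
  if (length(bad)) stop("unknown variants: ", paste(bad, collapse = ", "))
  out <- list()

  if ("window" %in% stages) {
    wt_p <- variant_params("WT", table)
    wt_w <- window_curve(wt_p$act, wt_p$inact)
    rows <- lapply(variants, function(l) {
      p <- variant_params(l, table)
      w <- window_curve(p$act, p$inact)
      sf <- window_shift_and_fold(w, wt_w)
      data.frame(label = l, peak_v = w$peak_v, crossing_v = w$crossing_v,
                 area = w$area, delta_peak_v = sf$delta_peak_v,
                 area_ratio = sf$area_ratio)
    })
    out$window <- do.call(rbind, rows)
  }

  if ("summary" %in% stages)
    out$summary <- variant_summary_table(
      table[table$label %in% variants, ])

  if ("cohort" %in% stages) {
    rows <- lapply(seq_along(variants), function(i) {
      fits <- cohort_fits(variants[i], n_cells = n_cells, table = table,
                          seed = seed + 10000L * (i - 1L),
                          noise_sd = noise_sd, jitter = jitter)
      s <- cohort_summary(fits)
      s$label <- variants[i]
      s
    })
    out$cohort <- do.call(rbind, rows)
  }

  if ("nrt" %in% stages) {
    rows <- lapply(variants, function(l) {
      p <- variant_params(l, table)
      m <- build_nrt_model(build_gating_model(p$act, p$inact, p$rec,
                                              label = l), f = f)
      reb <- run_current_clamp(m, nrt_amplitudes$rebound_test)
      ton <- run_current_clamp(m, nrt_amplitudes$tonic_test)
      data.frame(
        label = l,
        rebound_rheobase_nA = find_rheobase(
          m, "rebound", resolution = rheobase_resolution,
          rebound_ms = 400),
        rebound_freq_hz = firing_frequency(reb, "rebound",
                                           rebound_ms = 400),
        tonic_rheobase_nA = find_rheobase(m, "tonic"),
        tonic_freq_hz = firing_frequency(ton, "pulse"))
    })
    out$nrt <- do.call(rbind, rows)
  }

  cfg <- list(variants = variants, stages = stages, seed = seed,
              n_cells = n_cells, noise_sd = noise_sd, jitter = jitter,
              f = f, nrt_amplitudes = nrt_amplitudes,
              rheobase_resolution = rheobase_resolution)
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  out$manifest <- list(
    config = cfg, config_md5 = unname(tools::md5sum(tmp)),
    package_version = as.character(utils::packageVersion("cavgate")))
  unlink(tmp)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in intersect(names(out), c("window", "summary", "cohort",
                                       "nrt")))
      utils::write.csv(out[[nm]], file.path(out_dir,
                                            paste0(nm, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(out$manifest, file.path(out_dir,
                                                 "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  class(out) <- "cavgate_report"
  out
}

#' @export
print.cavgate_report <- function(x, ...) {
  cat("cavgate report with stages:",
      paste(intersect(names(x), c("window", "summary", "cohort", "nrt")),
            collapse = ", "), "\n")
  invisible(x)
}

#' Compare a report against expected values
#'
#' Machine-readable per-target comparison of computed report fields with
#' a fixture of expected values, each at its own tolerance.
#'
#' @param report A `cavgate_report` (or any nested list of data frames).
#' @param fixture data.frame with columns `stage`, `label`, `field`,
#'   `expected`, `tol` (absolute tolerance).
#' @return The fixture with added columns `value` and `pass`; attribute
#'   `all_pass`.
#' @export
validate_report <- function(report, fixture) {
  need <- c("stage", "label", "field", "expected", "tol")
  if (!all(need %in% names(fixture)))
    stop("fixture must have columns ", paste(need, collapse = ", "))
  fixture$value <- NA_real_
  for (i in seq_len(nrow(fixture))) {
    st <- report[[fixture$stage[i]]]
    if (is.null(st) || !fixture$field[i] %in% names(st))
      stop("report is missing field '", fixture$field[i],
           "' of stage '", fixture$stage[i], "'")
    j <- match(fixture$label[i], st$label)
    if (is.na(j)) stop("report stage '", fixture$stage[i],
                       "' lacks label '", fixture$label[i], "'")
    fixture$value[i] <- st[[fixture$field[i]]][j]
  }
  fixture$pass <- abs(fixture$value - fixture$expected) <= fixture$tol
  attr(fixture, "all_pass") <- all(fixture$pass)
  fixture
}
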