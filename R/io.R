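#' Read and write sweep sets as tidy CSV
#'
#' Sweeps are stored long-format with columns `sweep_id`, `time_ms`,
#' `command_mV`, `current_pA`, plus a JSON sidecar (`<path>.json`)
#' carrying the protocol definition and recording metadata so a sweep set
#' round-trips losslessly through plain text.
#'
#' @param sweeps A `sweep_set`.
#' @param path CSV path; the sidecar is written next to it.
#' @return `write_sweep_csv()` returns `path` invisibly;
#'   `read_sweep_csv()` returns a `sweep_set`.
#' @export
write_sweep_csv <- function(sweeps, path) {
  stopifnot(inherits(sweeps, "sweep_set"))
  n_sweeps <- ncol(sweeps$current)
  rows <- lapply(seq_len(n_sweeps), function(i) {
    ok <- !is.na(sweeps$current[, i])
    data.frame(sweep_id = i, time_ms = sweeps$time_ms[ok],
               command_mV = sweeps$command[ok, i],
               current_pA = sweeps$current[ok, i])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  prot <- sweeps$protocol
  side <- list(
    protocol = list(name = prot$name, holding = prot$holding,
                    segments = prot$segments,
                    sweep_values = prot$sweep_values,
                    varying = prot$varying,
                    sampling_rate = prot$sampling_rate,
                    filter_cutoff = prot$filter_cutoff),
    capacitance = sweeps$capacitance,
    leak_conductance = sweeps$leak_conductance, e_leak = sweeps$e_leak,
    noise_sd = sweeps$noise_sd, seed = sweeps$seed,
    filtered = sweeps$filtered, leak_included = sweeps$leak_included)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  p <- side$protocol
  prot <- voltage_protocol(p$name, p$holding,
                           as.data.frame(p$segments), p$sweep_values,
                           p$varying, p$sampling_rate, p$filter_cutoff)
  tab <- utils::read.csv(path)
  ids <- sort(unique(tab$sweep_id))
  n_max <- max(tabulate(tab$sweep_id))
  command <- current <- matrix(NA_real_, n_max, length(ids))
  for (i in seq_along(ids)) {
    s <- tab[tab$sweep_id == ids[i], ]
    command[seq_len(nrow(s)), i] <- s$command_mV
    current[seq_len(nrow(s)), i] <- s$current_pA
  }
  dt <- 1000 / prot$sampling_rate
  structure(list(protocol = prot, time_ms = dt * seq_len(n_max),
                 command = command, current = current,
                 capacitance = side$capacitance,
                 leak_conductance = side$leak_conductance,
                 e_leak = side$e_leak, noise_sd = side$noise_sd,
                 seed = side$seed, filtered = side$filtered,
                 leak_included = side$leak_included),
            class = "sweep_set")
}
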