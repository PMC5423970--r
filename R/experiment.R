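#' Experiment configuration
#'
#' Bundles every block needed to run a (sweep of) simulation experiment(s):
#' grid and kernel, neuron/synapse/afferent parameters, analysis settings,
#' sweep axes, and a master seed from which per-component child seeds are
#' spawned so each component is independently reproducible.
#'
#' @param grid A [grid_spec()].
#' @param kernel A [kernel_spec()] (base values; sweep axes override).
#' @param neuron,synapse,afferent Parameter objects.
#' @param sweep Named list of vectors to cross (recognised names:
#'   `g_EE`, `g_IE`, `sigma_E`, `sigma_I`, `nu_max`); `NULL` for a single
#'   run.
#' @param duration Simulated seconds per run (after warm-up).
#' @param warmup Warm-up (s).
#' @param max_distance Near-pair distance cutoff (px) for the r_SC summary.
#' @param n_pairs Pair subsample for the correlation summary.
#' @param dt Integration step (ms).
#' @param seed Master seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(grid = grid_spec(50),
                              kernel = kernel_spec(),
                              neuron = neuron_params(),
                              synapse = synapse_params(),
                              afferent = afferent_config(),
                              sweep = NULL, duration = 10, warmup = 1,
                              max_distance = 13.3, n_pairs = 2000,
                              dt = 0.05, seed = 1) {
  allowed <- c("g_EE", "g_IE", "sigma_E", "sigma_I", "nu_max")
  if (!is.null(sweep)) {
    bad <- setdiff(names(sweep), allowed)
    if (length(bad))
      abort(sprintf("unknown sweep axes: %s", paste(bad, collapse = ", ")))
  }
  structure(list(grid = grid, kernel = kernel, neuron = neuron,
                 synapse = synapse, afferent = afferent, sweep = sweep,
                 duration = duration, warmup = warmup,
                 max_distance = max_distance, n_pairs = n_pairs,
                 dt = dt, seed = seed),
            class = "experiment_config")
}

#' Run a (swept) correlation experiment
#'
#' For every point of the sweep grid: build the topology, test for
#' self-sustained activity, and - only if the network is not self-sustained
#' (self-sustained networks are excluded from all analyses and recorded in
#' the boundary mask) - simulate and compute the mean near-pair noise
#' correlation from sliding-window counts.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory; results and per-run configs are
#'   written there as TSV/DCF text files.
#' @param window Sliding-window length (s) for the correlation summary.
#' @return A tibble with one row per grid point: the swept parameters,
#'   `profile`, `self_sustained`, `mean_r_sc` (NA when excluded),
#'   `mean_rate_hz`, and the child `seed` used.
#' @export
run_experiment <- function(config, out_dir = NULL, window = 1) {
  sweep <- config$sweep
  pts <- if (is.null(sweep)) tibble(.row = 1L)
         else as_tibble(expand.grid(sweep, KEEP.OUT.ATTRS = FALSE))
  message(sprintf("sweep grid: %d point(s)", nrow(pts)))
  seeds <- child_seeds(config$seed, nrow(pts) * 3)
  rows <- vector("list", nrow(pts))
  for (k in seq_len(nrow(pts))) {
    kern <- config$kernel; syn <- config$synapse; aff <- config$afferent
    if (!is.null(pts[["sigma_E"]])) kern <- kernel_spec(pts[["sigma_E"]][k],
      kern$sigma_I, kern$K_E, kern$K_I, kern$D)
    if (!is.null(pts[["sigma_I"]])) kern <- kernel_spec(kern$sigma_E,
      pts[["sigma_I"]][k], kern$K_E, kern$K_I, kern$D)
    if (!is.null(pts[["g_EE"]])) syn$g_EE <- pts[["g_EE"]][k]
    if (!is.null(pts[["g_IE"]])) syn$g_IE <- pts[["g_IE"]][k]
    if (!is.null(pts[["nu_max"]])) { aff$nu_max <- pts[["nu_max"]][k]
                                     aff$nu_base <- pts[["nu_max"]][k] / 10 }
    s_topo <- seeds[[3 * k - 2]]; s_cls <- seeds[[3 * k - 1]]
    s_run <- seeds[[3 * k]]
    topo <- build_topology(config$grid, kern, seed = s_topo)
    ss <- classify_self_sustained(topo, config$neuron, syn, aff,
                                  dt = config$dt, seed = s_cls)
    if (ss) {
      rows[[k]] <- tibble(profile = kern$profile, self_sustained = TRUE,
                          mean_r_sc = NA_real_, mean_rate_hz = NA_real_,
                          seed = s_run)
      next
    }
    sp <- run_simulation(topo, config$neuron, syn, aff,
                         duration = config$warmup + config$duration,
                         dt = config$dt, warmup = config$warmup,
                         seed = s_run)
    cm <- sliding_window_counts(sp, T = window, stride = window / 2)
    r <- mean_near_correlation(cm, max_distance = config$max_distance,
                               n_pairs = config$n_pairs, seed = s_run)
    nE <- sum(topo$positions$pop == "E")
    rate <- sum(sp$time > config$warmup &
                  sp$neuron <= nE) / nE / config$duration
    rows[[k]] <- tibble(profile = kern$profile, self_sustained = FALSE,
                        mean_r_sc = r, mean_rate_hz = rate, seed = s_run)
  }
  res <- dplyr::bind_cols(pts[setdiff(names(pts), ".row")],
                          dplyr::bind_rows(rows))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results(res, file.path(out_dir, "results.tsv"),
                  config = list(seed = config$seed,
                                sigma_E = config$kernel$sigma_E,
                                sigma_I = config$kernel$sigma_I,
                                duration = config$duration))
  }
  res
}

# ---------------------------------------------------------------------------
# text IO: TSV with '#key: value' header lines
# ---------------------------------------------------------------------------

write_header <- function(con, config) {
  writeLines(sprintf("#%s: %s", names(config),
                     vapply(config, function(v) paste(format(v), collapse = ","),
                            character(1))), con)
}

read_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  if (length(hdr) == 0) return(list(header = list(), skip = 0L))
  kv <- strsplit(sub("^#", "", hdr), ": ", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2
  if (any(bad))
    abort(sprintf("malformed header line: '%s'", hdr[which(bad)[1]]))
  out <- stats::setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`, 1, FUN.VALUE = ""))
  list(header = out, skip = length(hdr))
}

#' Write / read spike data as TSV
#'
#' Columnar text format `trial`, `neuron_id`, `t_s` with `#key: value`
#' header lines carrying units and provenance (duration, warm-up, grid
#' side, neuron count). Round-trips exactly through [read_spike_data()].
#'
#' @param spikes A `spike_data`.
#' @param path Output file.
#' @param config Extra header fields (named list).
#' @return `path`, invisibly.
#' @export
write_spike_data <- function(spikes, path, config = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, c(list(format = "mexhat/spikes-v1",
                           units = "neuron_id:index,t_s:seconds",
                           n_neurons = attr(spikes, "n_neurons"),
                           duration = attr(spikes, "duration"),
                           warmup = attr(spikes, "warmup"),
                           L = attr(spikes, "L") %||% NA), config))
  write.table(as.data.frame(spikes)[, c("trial", "neuron", "time")],
              con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_data
#' @export
read_spike_data <- function(path) {
  h <- read_header(path)
  fmt <- h$header$format
  if (is.null(fmt) || !startsWith(fmt, "mexhat/spikes"))
    abort("not a mexhat spike file (missing 'format: mexhat/spikes-v1' header)")
  if (fmt != "mexhat/spikes-v1")
    abort(sprintf("unsupported spike file schema '%s'; expected v1", fmt))
  df <- read.delim(path, skip = h$skip, sep = "\t")
  if (!all(c("trial", "neuron", "time") %in% names(df)))
    abort("truncated or malformed spike table")
  L <- suppressWarnings(as.numeric(h$header$L))
  new_spike_data(df,
                 n_neurons = as.integer(h$header$n_neurons),
                 duration = as.numeric(h$header$duration),
                 warmup = as.numeric(h$header$warmup),
                 L = if (is.na(L)) NULL else L)
}

#' Write / read a count matrix as TSV
#'
#' Wide text format (neurons in rows) with a `#` header carrying the window
#' kind and length, neuron ids, positions, and stimulus labels.
#'
#' @param counts A [count_matrix].
#' @param path File path.
#' @param config Extra header fields.
#' @return `path` invisibly; [read_counts()] returns the `count_matrix`.
#' @export
write_counts <- function(counts, path, config = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- list(format = "mexhat/counts-v1",
              kind = attr(counts, "kind"), T_s = attr(counts, "T"),
              L = attr(counts, "L") %||% NA,
              neurons = paste(attr(counts, "neurons"), collapse = ","),
              x = paste(attr(counts, "x"), collapse = ","),
              y = paste(attr(counts, "y"), collapse = ","))
  stim <- attr(counts, "stimulus")
  if (!is.null(stim)) hdr$stimulus <- paste(stim, collapse = ",")
  write_header(con, c(hdr, config))
  write.table(unclass(counts), con, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  h <- read_header(path)
  fmt <- h$header$format
  if (is.null(fmt) || fmt != "mexhat/counts-v1")
    abort("not a mexhat counts file (v1)")
  m <- as.matrix(read.delim(path, skip = h$skip, header = FALSE))
  dimnames(m) <- NULL
  num <- function(k) if (is.null(h$header[[k]])) NULL
                     else as.numeric(strsplit(h$header[[k]], ",")[[1]])
  L <- suppressWarnings(as.numeric(h$header$L))
  new_count_matrix(m, kind = h$header$kind,
                   T = suppressWarnings(as.numeric(h$header$T_s)),
                   neurons = num("neurons"), x = num("x"), y = num("y"),
                   L = if (is.na(L)) NULL else L, stimulus = num("stimulus"))
}

#' Write a results table with a config header
#'
#' @param results A data frame / tibble.
#' @param path File path.
#' @param config Named list written as `#key: value` header lines.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, config = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, c(list(format = "mexhat/results-v1"), config))
  write.table(as.data.frame(results), con, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  h <- read_header(path)
  if (is.null(h$header$format) || h$header$format != "mexhat/results-v1")
    abort("not a mexhat results file (v1)")
  as_tibble(read.delim(path, skip = h$skip, sep = "\t"))
}
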