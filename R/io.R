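# Readers/writers for the package's file formats. The canonical container is
# a plain-text bundle: a directory with JSON metadata plus full-precision CSV
# matrices. Writing is deterministic, so save -> load -> save is
# byte-identical.

.fmt_num <- function(x) sprintf("%.17g", x)

.write_matrix_csv <- function(m, path) {
  lines <- apply(m, 1L, function(r) paste(.fmt_num(r), collapse = ","))
  writeLines(lines, path)
}

.read_matrix_csv <- function(path) {
  lines <- readLines(path)
  do.call(rbind, lapply(strsplit(lines, ",", fixed = TRUE), function(x) {
    x[x == "NA"] <- NA_character_   # literal NA cells (e.g. warm-up samples)
    as.numeric(x)
  }))
}

#' Save a trajectory library as a plain-text bundle
#'
#' Writes `meta.json` (tau, delta_ms, sampling rate, behavior names,
#' circular flags, neuron ids, version) plus per-condition
#' `rates_<c>.csv` (N x Kc, spikes/s) and `behavior_<c>.csv` (M x Kc)
#' at full double precision.
#'
#' @param library a `trajectory_library`
#' @param path directory to create/overwrite
#' @return `path`, invisibly
#' @export
save_library <- function(library, path) {
  stopifnot(inherits(library, "trajectory_library"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format = "mint_library", version = library$version,
               tau = library$tau, delta_ms = library$delta_ms,
               sampling_rate_hz = library$sampling_rate_hz,
               n_conditions = library$n_conditions,
               n_neurons = library$n_neurons, n_behaviors = library$n_behaviors,
               Kc = library$Kc, circular = library$circular,
               neuron_ids = library$neuron_ids,
               behavior_names = library$behavior_names)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (c in seq_len(library$n_conditions)) {
    .write_matrix_csv(library$rates[[c]], file.path(path, sprintf("rates_%d.csv", c)))
    .write_matrix_csv(library$behavior[[c]], file.path(path, sprintf("behavior_%d.csv", c)))
  }
  invisible(path)
}

#' Load a trajectory library bundle
#'
#' Strict: a missing or mismatched field (including `circular`) is an error,
#' not a silent default; a version other than the writer's is an explicit
#' error with no silent migration.
#'
#' @param path bundle directory written by [save_library()]
#' @return a `trajectory_library`
#' @export
load_library <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) .stopf("no meta.json under '%s'", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$format, "mint_library"))
    .stopf("'%s' is not a trajectory library bundle", path)
  if (!identical(as.integer(meta$version), 1L))
    .stopf("library bundle version %s is not supported (expected 1)", meta$version)
  req <- c("tau", "delta_ms", "n_conditions", "circular", "behavior_names",
           "neuron_ids")
  missing <- setdiff(req, names(meta))
  if (length(missing))
    .stopf("library bundle is missing field(s): %s", paste(missing, collapse = ", "))
  C <- meta$n_conditions
  rates <- lapply(seq_len(C), function(c)
    .read_matrix_csv(file.path(path, sprintf("rates_%d.csv", c))))
  behavior <- lapply(seq_len(C), function(c)
    .read_matrix_csv(file.path(path, sprintf("behavior_%d.csv", c))))
  assemble_library(rates, behavior, tau = meta$tau, delta_ms = meta$delta_ms,
                   circular = meta$circular, neuron_ids = meta$neuron_ids,
                   behavior_names = meta$behavior_names)
}

#' Save trial-structured spike/behavior data as CSV tables
#'
#' Writes `spikes.csv` (unit_id, trial_id, time_ms), `behavior.csv`
#' (trial_id, time_ms, var1..varM), and `trials.csv` (trial_id, condition,
#' duration_ms, one column per event).
#'
#' @param trials a [trial_set()]
#' @param path directory to create/overwrite
#' @return `path`, invisibly
#' @export
save_spike_data <- function(trials, path) {
  stopifnot(inherits(trials, "trial_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  sp <- list()
  for (i in seq_len(trials$n_trials)) {
    hits <- which(trials$spikes[[i]] > 0, arr.ind = TRUE)
    if (nrow(hits)) {
      reps <- trials$spikes[[i]][hits]
      sp[[i]] <- data.frame(unit_id = rep(hits[, 1L], reps),
                            trial_id = i,
                            time_ms = rep(hits[, 2L] - 1L, reps))
    }
  }
  sp <- do.call(rbind, sp) %||% data.frame(unit_id = integer(), trial_id = integer(),
                                           time_ms = integer())
  sp <- sp[order(sp$trial_id, sp$unit_id, sp$time_ms), ]
  utils::write.csv(sp, file.path(path, "spikes.csv"), row.names = FALSE, quote = FALSE)
  beh <- do.call(rbind, lapply(seq_len(trials$n_trials), function(i) {
    B <- t(trials$behavior[[i]])
    colnames(B) <- trials$behavior_names
    data.frame(trial_id = i, time_ms = seq_len(nrow(B)) - 1L, B, check.names = FALSE)
  }))
  utils::write.csv(beh, file.path(path, "behavior.csv"), row.names = FALSE, quote = FALSE)
  ev_names <- names(trials$events[[1L]])
  tr <- data.frame(trial_id = seq_len(trials$n_trials),
                   condition = trials$condition,
                   duration_ms = vapply(trials$spikes, ncol, integer(1)))
  for (e in ev_names)
    tr[[e]] <- vapply(trials$events, function(ev) ev[[e]], numeric(1))
  utils::write.csv(tr, file.path(path, "trials.csv"), row.names = FALSE, quote = FALSE)
  meta <- list(format = "mint_trials", version = 1L,
               n_neurons = trials$n_neurons, n_behaviors = trials$n_behaviors,
               behavior_names = trials$behavior_names, circular = trials$circular,
               events = ev_names)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load trial-structured spike/behavior data
#'
#' Reads the CSV-table bundle written by [save_spike_data()]. Unsorted spike
#' timestamps are sorted with a warning.
#'
#' @param path bundle directory
#' @return a [trial_set()]
#' @export
load_spike_data <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) .stopf("no meta.json under '%s'", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$format, "mint_trials"))
    .stopf("'%s' is not a spike-data bundle (format '%s')", path, meta$format)
  sp <- utils::read.csv(file.path(path, "spikes.csv"))
  beh <- utils::read.csv(file.path(path, "behavior.csv"), check.names = FALSE)
  tr <- utils::read.csv(file.path(path, "trials.csv"))
  if (is.unsorted(order(sp$trial_id, sp$unit_id, sp$time_ms)))
    .warnf("spike table not sorted; sorting")
  N <- meta$n_neurons
  spikes <- list(); behavior <- list(); events <- list()
  for (i in tr$trial_id) {
    Tlen <- tr$duration_ms[tr$trial_id == i]
    s <- matrix(0L, N, Tlen)
    rows <- sp[sp$trial_id == i, ]
    if (nrow(rows)) {
      for (j in seq_len(nrow(rows)))
        s[rows$unit_id[j], rows$time_ms[j] + 1L] <- s[rows$unit_id[j], rows$time_ms[j] + 1L] + 1L
    }
    spikes[[i]] <- s
    b <- beh[beh$trial_id == i, meta$behavior_names, drop = FALSE]
    behavior[[i]] <- unname(t(as.matrix(b)))
    ev <- tr[tr$trial_id == i, meta$events, drop = FALSE]
    events[[i]] <- stats::setNames(as.numeric(ev), meta$events)
  }
  trial_set(spikes, behavior, tr$condition, events,
            behavior_names = meta$behavior_names, circular = meta$circular)
}

#' Save / load a spike stream as CSV
#' @param stream N x T count matrix
#' @param path file path
#' @return `path` / the stream matrix
#' @export
save_stream <- function(stream, path) {
  .write_matrix_csv(as.matrix(stream), path)
  invisible(path)
}

#' @rdname save_stream
#' @export
load_stream <- function(path) .read_matrix_csv(path)

#' Load and validate a JSON run configuration
#'
#' Unknown keys are rejected so typos fail loudly before any computation.
#'
#' @param path JSON file
#' @param allowed character vector of permitted keys
#' @return named list
#' @export
load_config <- function(path, allowed = c("sigma_ms", "window_start", "window_end",
                                          "align_event", "end_event",
                                          "averaging_mode", "d_neural",
                                          "d_condition", "soft_norm_constant",
                                          "warp_mode", "delta_ms", "window_ms",
                                          "interp", "n_candidates",
                                          "min_separation_ms", "causal",
                                          "lag_ms", "seed", "tau")) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    .stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg
}
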