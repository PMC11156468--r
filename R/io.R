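# CSV/JSON interchange for trial tables and spike sets, plus the optional
# NWB-like session container.

serialize_licks <- function(licks) {
  vapply(licks, function(lk) {
    if (!nrow(lk)) return("")
    paste(sprintf("%.6f:%s", lk$time, lk$port), collapse = ";")
  }, character(1))
}

deserialize_licks <- function(s) {
  lapply(s, function(x) {
    if (is.na(x) || !nzchar(x))
      return(data.frame(time = numeric(0), port = character(0),
                        stringsAsFactors = FALSE))
    parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], ":",
                      fixed = TRUE)
    data.frame(time = as.numeric(vapply(parts, `[`, "", 1)),
               port = vapply(parts, `[`, "", 2),
               stringsAsFactors = FALSE)
  })
}

#' Write / read a trial table as CSV
#'
#' One row per trial; the lick list-column is serialized as
#' semicolon-joined `time:port` tokens.
#'
#' @param trials Trial table.
#' @param path CSV file path.
#' @return `write_trial_table` the path invisibly; `read_trial_table` the
#'   trial table.
#' @export
write_trial_table <- function(trials, path) {
  df <- trials
  df$licks <- serialize_licks(trials$licks)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$licks <- I(deserialize_licks(df$licks))
  df$cue <- as.logical(df$cue)
  if (!is.null(df$outcome)) df$outcome <- as.character(df$outcome)
  df
}

#' Write / read a spike set as CSV plus a JSON metadata sidecar
#'
#' Spike times go to a long CSV of `(unit_id, spike_time)`; unit metadata
#' and the session end time go to `<path>.meta.json`.
#'
#' @param spikes A `spike_set`.
#' @param path CSV file path.
#' @return `write_spike_set` the path invisibly; `read_spike_set` the
#'   `spike_set`.
#' @export
write_spike_set <- function(spikes, path) {
  long <- data.frame(
    unit_id = rep(names(spikes$spikes),
                  vapply(spikes$spikes, length, integer(1))),
    spike_time = unlist(spikes$spikes, use.names = FALSE))
  utils::write.csv(long, path, row.names = FALSE)
  jsonlite::write_json(list(units = spikes$units, t_end = spikes$t_end),
                       paste0(path, ".meta.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spike_set
#' @export
read_spike_set <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  units <- as.data.frame(meta$units, stringsAsFactors = FALSE)
  spikes <- lapply(units$unit_id, function(u)
    sort(long$spike_time[long$unit_id == u]))
  names(spikes) <- units$unit_id
  structure(list(units = units, spikes = spikes, t_end = meta$t_end),
            class = "spike_set")
}

#' Convert a session to / from an NWB-like container
#'
#' A plain-list stand-in for an NWB session file: a `trials` table and a
#' `units` table with per-unit spike times, serializable to JSON. True
#' HDF5-backed NWB files are not supported in this offline build; the
#' container mirrors the trials-table/units-table layout so a round trip
#' is exact.
#'
#' @param trials Trial table.
#' @param spikes A `spike_set` (or `NULL`).
#' @return An `nwb_like` list with `trials` and `units` elements.
#' @export
as_nwb_like <- function(trials, spikes = NULL) {
  tr <- trials
  tr$licks <- serialize_licks(trials$licks)
  units <- if (!is.null(spikes)) {
    u <- spikes$units
    u$spike_times <- I(unname(spikes$spikes))
    list(table = u, t_end = spikes$t_end)
  }
  structure(list(trials = tr, units = units), class = "nwb_like")
}

#' Read a session from an NWB-like container
#'
#' Accepts an `nwb_like` list or the path of a JSON file holding one.
#' Column aliases (e.g. `list(stim_onset = "start_time")`) map foreign
#' names onto the package's trial-table fields; unmapped extra columns are
#' kept. Missing required structures raise a descriptive ingestion error.
#'
#' @param x An `nwb_like` object or JSON path.
#' @param aliases Named list: package field -> source column name.
#' @return List with `trials` and `spikes` (`NULL` when no units table).
#' @export
read_nwb_session <- function(x, aliases = list()) {
  if (is.character(x)) {
    obj <- jsonlite::read_json(x, simplifyVector = TRUE)
  } else obj <- unclass(x)
  if (is.null(obj$trials))
    structural_error("NWB-like ingestion error: missing 'trials' table")
  tr <- as.data.frame(obj$trials, stringsAsFactors = FALSE)
  for (field in names(aliases)) {
    src <- aliases[[field]]
    if (!is.null(tr[[src]]) && is.null(tr[[field]])) {
      tr[[field]] <- tr[[src]]
      tr[[src]] <- NULL
    }
  }
  required <- c("block_index", "block_rule", "trial_index",
                "trial_in_block", "modality", "stim_onset", "licks")
  miss <- setdiff(required, names(tr))
  if (length(miss))
    structural_error(paste("NWB-like ingestion error: trials table lacks",
                           paste(miss, collapse = ", ")))
  tr$licks <- I(deserialize_licks(as.character(tr$licks)))
  spikes <- NULL
  if (!is.null(obj$units)) {
    ut_raw <- obj$units$table
    st <- ut_raw$spike_times
    if (is.null(st))
      structural_error(
        "NWB-like ingestion error: 'units' table lacks spike_times")
    ut_raw$spike_times <- NULL   # ragged; rebuilt as a plain list below
    ut <- as.data.frame(ut_raw, stringsAsFactors = FALSE)
    sp <- lapply(st, function(v) sort(as.numeric(v)))
    names(sp) <- ut$unit_id
    spikes <- structure(list(units = ut, spikes = sp,
                             t_end = obj$units$t_end %||%
                               max(unlist(sp), 0)),
                        class = "spike_set")
  } else {
    structural_error("NWB-like ingestion error: missing 'units' table")
  }
  list(trials = tr, spikes = spikes)
}

#' Write an NWB-like container to JSON
#' @param x An `nwb_like` object.
#' @param path JSON file path.
#' @return The path, invisibly.
#' @export
write_nwb_like <- function(x, path) {
  jsonlite::write_json(unclass(x), path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
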