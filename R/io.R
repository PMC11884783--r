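# Recording container and event-table I/O. The container is a
# directory with meta.json (schema version, per-signal sampling rate,
# units, role, seed and parameter hash), one TSV per signal and one TSV
# per event kind; numeric values are written with 9 significant digits
# and locale-independent decimal points.

.somnet_schema <- 1L

#' Create a recording object
#'
#' @param signals named list of numeric vectors.
#' @param fs sampling rate(s), Hz: scalar or named vector per signal.
#' @param units units per signal (scalar or named vector), default "mV".
#' @param roles channel roles (e.g. "lfp", "emg", "eog",
#'   "intracellular", "model"), scalar or named vector.
#' @param events named list of event tables (see [events_table()]).
#' @param meta list of free-form metadata (seed, parameter hash, ...).
#' @return object of class `recording`.
#' @export
recording <- function(signals, fs, units = "mV", roles = "lfp",
                      events = list(), meta = list()) {
  stopifnot(is.list(signals), length(names(signals)) == length(signals))
  expand <- function(v) {
    if (length(v) == 1) stats::setNames(rep(v, length(signals)),
                                        names(signals))
    else v[names(signals)]
  }
  fs <- expand(fs); units <- expand(units); roles <- expand(roles)
  if (anyNA(fs)) stop("every signal needs a sampling rate")
  dur <- vapply(names(signals), function(nm)
    length(signals[[nm]]) / fs[[nm]], numeric(1))
  for (kind in names(events)) {
    ev <- events[[kind]]
    if (nrow(ev) && any(ev$offset_s > max(dur) + 1e-9))
      stop("event beyond signal end in '", kind, "'")
  }
  structure(list(signals = signals, fs = fs, units = units,
                 roles = roles, events = events, meta = meta),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat("<recording>\n")
  for (nm in names(x$signals))
    cat(sprintf("  %s: %d samples @ %g Hz [%s, %s]\n", nm,
                length(x$signals[[nm]]), x$fs[[nm]], x$units[[nm]],
                x$roles[[nm]]))
  for (k in names(x$events))
    cat(sprintf("  events/%s: %d\n", k, nrow(x$events[[k]])))
  invisible(x)
}

#' Write / read a recording container
#'
#' The container is a directory holding `meta.json`, `signals/<name>.tsv`
#' and `events/<kind>.tsv`; the round trip is lossless to the stored
#' precision (full double precision for signals).
#'
#' @param rec a `recording`.
#' @param path container directory (created if needed).
#' @return `path` (write) / a `recording` (read).
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  dir.create(file.path(path, "signals"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(path, "events"), showWarnings = FALSE)
  meta <- list(schema = .somnet_schema,
               signals = lapply(names(rec$signals), function(nm)
                 list(name = nm, fs = rec$fs[[nm]],
                      units = rec$units[[nm]], role = rec$roles[[nm]],
                      n = length(rec$signals[[nm]]))),
               meta = rec$meta)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(rec$signals))
    data.table::fwrite(data.table::data.table(value = rec$signals[[nm]]),
                       file.path(path, "signals", paste0(nm, ".tsv")),
                       sep = "\t")
  for (k in names(rec$events))
    write_events_tsv(rec$events[[k]],
                     file.path(path, "events", paste0(k, ".tsv")))
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stop("not a recording container: missing ", mf)
  meta <- jsonlite::read_json(mf)
  if (is.null(meta$schema) || meta$schema > .somnet_schema)
    stop("unsupported container schema version: ",
         meta$schema %||% "<missing>")
  signals <- list(); fs <- c(); units <- c(); roles <- c()
  for (s in meta$signals) {
    if (is.null(s$fs) || is.null(s$units))
      stop("schema error: signal '", s$name, "' lacks fs/units")
    v <- data.table::fread(file.path(path, "signals",
                                     paste0(s$name, ".tsv")))$value
    signals[[s$name]] <- v
    fs[s$name] <- s$fs; units[s$name] <- s$units
    roles[s$name] <- s$role %||% "lfp"
  }
  events <- list()
  for (f in list.files(file.path(path, "events"), pattern = "\\.tsv$")) {
    events[[sub("\\.tsv$", "", f)]] <-
      read_events_tsv(file.path(path, "events", f))
  }
  recording(signals, fs, units, roles, events,
            meta = meta$meta %||% list())
}

#' Write / read an event table as TSV
#'
#' Fixed leading header (kind, channel, onset_s, peak_s, offset_s,
#' amplitude; further columns preserved); numbers with 9 significant
#' digits, locale-independent decimal point.
#'
#' @param events event table.
#' @param path file path.
#' @export
write_events_tsv <- function(events, path) {
  lead <- c("kind", "channel", "onset_s", "peak_s", "offset_s",
            "amplitude")
  stopifnot(all(lead %in% names(events)))
  df <- events[, c(lead, setdiff(names(events), lead)), drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.9g", v))
  old <- Sys.getlocale("LC_NUMERIC")
  on.exit(Sys.setlocale("LC_NUMERIC", old), add = TRUE)
  Sys.setlocale("LC_NUMERIC", "C")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, colClasses = NA),
    error = function(e) stop("malformed event file ", path, ": ",
                             conditionMessage(e)))
  need <- c("kind", "channel", "onset_s", "peak_s", "offset_s",
            "amplitude")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("event file ", path, " lacks column(s): ",
                         paste(miss, collapse = ", "))
  for (cc in setdiff(names(df), c("kind", "channel")))
    df[[cc]] <- as.numeric(df[[cc]])
  df$kind <- as.character(df$kind); df$channel <- as.character(df$channel)
  df
}

#' Convert a simulation trace to a recording
#'
#' Excitatory membrane potentials (and the TRN inhibitory potential)
#' become channels of a 1 kHz recording with role "model".
#'
#' @param trace a `sim_trace`.
#' @return a `recording`.
#' @export
as_recording <- function(trace) {
  stopifnot(inherits(trace, "sim_trace"))
  chans <- c(cx = "Ve_CX", cxp = "Ve_CXp", reu = "Ve_REU",
             ca1 = "Ve_CA1", ca3 = "Ve_CA3", md = "Ve_MD",
             trn = "Vi_TRN")
  signals <- lapply(chans, function(v) as.numeric(trace$states[, v]))
  names(signals) <- names(chans)
  ph <- substr(digest_params(trace$params), 1, 12)
  recording(signals, fs = trace$fs, units = "mV", roles = "model",
            meta = list(seed = trace$seed, burn_in = trace$burn_in,
                        noise_sd = trace$noise_sd, param_hash = ph,
                        t0 = trace$time[1]))
}

# small stable hash of the parameter list (sum of char codes of the
# serialized key=value text; enough to fingerprint a configuration)
digest_params <- function(p) {
  s <- paste(names(p), vapply(p, function(v) sprintf("%.10g", v), ""),
             sep = "=", collapse = ";")
  raw <- utils::head(serialize(s, NULL), 10000)
  sprintf("%08x%08x",
          sum(as.integer(raw) * seq_along(raw)) %% .Machine$integer.max,
          (sum(as.integer(raw)^2) + length(raw)) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
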