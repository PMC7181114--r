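# Readers and writers for the portable recording container, plus dataset
# dialect conventions.
#
# The GENERIC container is a JSON text file. Signal samples and the sampling
# rate are serialized as "%.17g" strings: 17 significant digits round-trip
# IEEE doubles exactly, which plain JSON number emission does not guarantee.
# Trial labels are stored in ordinal valence form (-1/0/+1) so the same
# container is readable under any dialect convention.
#
# Dialect conventions (applied on load):
#   GENERIC  scheme read from the file; fs from the file.
#   SEED     ordinal labels in {-1, 0, 1} -> POS_NEU_NEG; default fs 200 Hz.
#   DEAP     per-trial valence ratings in [1, 9], binarized at 4.5 -> POS_NEG;
#            default fs 128 Hz.
#   LUMED    ordinal labels in {-1, 1} -> POS_NEG; default fs 500 Hz.
#
# The original SEED/DEAP distributions ship as MATLAB/pickle containers; those
# are converted to this container externally (one scipy.io/h5py call) and then
# loaded with the matching dialect.

.dialect_fs <- c(SEED = 200, DEAP = 128, LUMED = 500)

#' Write a recording to the portable GENERIC container
#'
#' Serializes an [eeg_recording] to a JSON container that
#' [load_recording()] reads back bit-exactly (data, fs, names, trials).
#' Recordings containing non-finite samples are rejected before writing.
#'
#' @param rec an `eeg_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  obj <- list(
    format = "eeg-recording",
    version = 1L,
    fs = sprintf("%.17g", rec$fs),
    subject_id = rec$subject_id,
    session_id = rec$session_id,
    scheme = rec$scheme,
    channels = rec$channel_names,
    trials = list(
      start = as.integer(rec$trials$start),
      end = as.integer(rec$trials$end),
      ordinal_label = as.integer(label_to_ordinal(rec$trials$label, rec$scheme))
    ),
    n_channels = nrow(rec$data),
    n_samples = ncol(rec$data),
    # flat, channel-major (row 1's samples, then row 2's, ...): immune to the
    # row/vector ambiguity of nested JSON arrays
    data = sprintf("%.17g", as.vector(t(rec$data)))
  )
  if (!is.null(rec$valence)) obj$valence <- sprintf("%.17g", rec$valence)
  ok <- tryCatch({
    jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stopf("I/O error writing '%s': %s", path, conditionMessage(ok))
  invisible(path)
}

#' Load a recording from a container file
#'
#' Reads a GENERIC JSON container and applies the label/sampling-rate
#' conventions of the requested dataset dialect (see the dialect table in the
#' package vignette). For the DEAP dialect, per-trial valence ratings are
#' binarized at 4.5 via [binarize_valence()].
#'
#' @param path container file path.
#' @param dialect one of `"GENERIC"`, `"SEED"`, `"DEAP"`, `"LUMED"`.
#' @param fs optional sampling-rate override (Hz).
#' @return an `eeg_recording`.
#' @export
load_recording <- function(path, dialect = c("GENERIC", "SEED", "DEAP", "LUMED"),
                           fs = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("I/O error: file not found: %s", path)
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e)
                    stopf("format error: cannot parse container '%s': %s",
                          path, conditionMessage(e)))
  for (key in c("channels", "data", "trials")) {
    if (is.null(obj[[key]]))
      stopf("format error: container is missing key '%s'", key)
  }
  if (is.null(fs)) {
    fs <- if (!is.null(obj$fs)) as.numeric(obj$fs) else unname(.dialect_fs[dialect])
    if (is.null(fs) || is.na(fs))
      stopf("format error: container is missing key 'fs' and dialect %s has no default",
            dialect)
  }
  for (key in c("n_channels", "n_samples")) {
    if (is.null(obj[[key]]))
      stopf("format error: container is missing key '%s'", key)
  }
  nc <- as.integer(obj$n_channels); ns <- as.integer(obj$n_samples)
  vals <- as.numeric(unlist(obj$data, use.names = FALSE))
  if (length(vals) != nc * ns)
    stopf("format error: 'data' has %d values but n_channels x n_samples = %d x %d",
          length(vals), nc, ns)
  if (nc != length(obj$channels))
    stopf("format error: %d channel names but %d data rows",
          length(obj$channels), nc)
  data <- matrix(vals, nrow = nc, ncol = ns, byrow = TRUE)

  tr <- obj$trials
  start <- as.integer(tr$start); end <- as.integer(tr$end)
  ords <- as.integer(tr$ordinal_label)
  n_tr <- length(start)

  scheme <- switch(dialect,
    GENERIC = {
      if (is.null(obj$scheme))
        stopf("format error: container is missing key 'scheme'")
      obj$scheme
    },
    SEED = "POS_NEU_NEG",
    DEAP = "POS_NEG",
    LUMED = "POS_NEG")

  labels <- if (dialect == "DEAP") {
    ratings <- as.numeric(if (!is.null(obj$valence)) obj$valence else ords)
    if (length(ratings) != n_tr)
      stopf("format error: %d valence ratings for %d trials", length(ratings), n_tr)
    if (any(ratings < 1 | ratings > 9))
      stopf("label error: valence rating outside [1, 9]")
    binarize_valence(ratings)
  } else {
    if (n_tr > 0 && length(ords) != n_tr)
      stopf("format error: container is missing key 'trials$ordinal_label'")
    allowed <- .scheme_info(scheme)$ordinals
    if (n_tr > 0 && !all(ords %in% allowed))
      stopf("label error: ordinal label(s) %s outside dialect %s range {%s}",
            paste(unique(ords[!ords %in% allowed]), collapse = ","),
            dialect, paste(allowed, collapse = ","))
    if (n_tr > 0) ordinal_to_label(ords, scheme) else integer(0)
  }

  eeg_recording(
    data = data, fs = fs, channel_names = as.character(obj$channels),
    subject_id = if (!is.null(obj$subject_id)) obj$subject_id else "s1",
    session_id = if (!is.null(obj$session_id)) obj$session_id else "1",
    trials = data.frame(start = start, end = end, label = labels),
    scheme = scheme)
}

#' Export a recording's trial table as CSV
#'
#' Writes one row per trial: start/end sample, start/end seconds, class code,
#' ordinal valence and class name, for quick inspection outside R.
#'
#' @param rec an `eeg_recording`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_trials_csv <- function(rec, path) {
  validate_recording(rec)
  tr <- rec$trials
  ords <- label_to_ordinal(tr$label, rec$scheme)
  out <- data.frame(
    subject_id = rec$subject_id, session_id = rec$session_id,
    trial = seq_len(nrow(tr)) - 1L,
    start_sample = tr$start, end_sample = tr$end,
    start_s = tr$start / rec$fs, end_s = tr$end / rec$fs,
    label = tr$label, ordinal = ords,
    class = scheme_class_names(rec$scheme)[match(tr$label, scheme_codes(rec$scheme))])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
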