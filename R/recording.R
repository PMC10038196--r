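#' Single-subject fNIRS recording
#'
#' A recording holds the concentration-change time series of one subject as an
#' `m x n` matrix, where `n = 3 * c` for `c` channels: each channel contributes
#' three interleaved attribute columns (oxygenated, deoxygenated and total
#' hemoglobin, in channel-major order `ch1_HbO2, ch1_Hb, ch1_HbT, ch2_HbO2,
#' ...`). Total hemoglobin is the sum of the other two by definition.
#'
#' @param values Numeric `m x n` matrix, `n = 3 * n_channels`.
#' @param label Class label: 1 (ASD) or 0 (TD).
#' @param subject_id Character scalar identifier.
#' @param sampling_interval_s Sampling interval in seconds (default 0.07).
#' @param check_hbt If `TRUE`, require `HbT = HbO2 + Hb` within `1e-9` per
#'   entry (enforced for synthetic recordings; raw readers do not enforce it).
#' @return An object of class `"subject_recording"`.
#' @export
subject_recording <- function(values, label, subject_id,
                              sampling_interval_s = 0.07, check_hbt = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("`values` must be a numeric matrix")
  }
  if (nrow(values) < 1L) stopf("recording must contain at least one sample")
  if (ncol(values) %% 3L != 0L) {
    stopf("recording has %d columns; expected 3 attribute columns per channel",
          ncol(values))
  }
  if (anyNA(values)) stopf("recording contains missing values")
  if (!label %in% c(0, 1)) stopf("label must be 0 (TD) or 1 (ASD)")
  if (!is.numeric(sampling_interval_s) || sampling_interval_s <= 0) {
    stopf("sampling interval must be a positive number of seconds")
  }
  n_channels <- ncol(values) %/% 3L
  if (isTRUE(check_hbt)) {
    dev <- max(abs(values[, attr_cols(n_channels, "HbT"), drop = FALSE] -
                   values[, attr_cols(n_channels, "HbO2"), drop = FALSE] -
                   values[, attr_cols(n_channels, "Hb"), drop = FALSE]))
    if (dev > 1e-9) stopf("HbT != HbO2 + Hb (max deviation %.3g)", dev)
  }
  structure(list(subject_id = as.character(subject_id),
                 values = values,
                 label = as.integer(label),
                 n_channels = n_channels,
                 sampling_interval_s = sampling_interval_s),
            class = "subject_recording")
}

#' @export
print.subject_recording <- function(x, ...) {
  cat(sprintf("<subject_recording> %s: %d samples x %d channels x 3 attributes, label %d (%s), dt %.3g s\n",
              x$subject_id, nrow(x$values), x$n_channels, x$label,
              if (x$label == 1L) "ASD" else "TD", x$sampling_interval_s))
  invisible(x)
}

# Column indices of one attribute in the channel-major interleaved layout.
attr_cols <- function(n_channels, attribute) {
  offset <- match(attribute, c("HbO2", "Hb", "HbT"))
  if (is.na(offset)) stopf("unknown attribute '%s' (use HbO2, Hb or HbT)", attribute)
  3L * (seq_len(n_channels) - 1L) + offset
}

#' Extract one hemoglobin attribute from a recording
#'
#' @param rec A [subject_recording()].
#' @param attribute One of `"HbO2"`, `"Hb"`, `"HbT"`.
#' @return An `m x c` numeric matrix, channel order preserved, with column
#'   names `ch1..chc`.
#' @export
select_attribute <- function(rec, attribute = c("HbO2", "Hb", "HbT")) {
  if (!inherits(rec, "subject_recording")) stopf("`rec` must be a subject_recording")
  if (length(attribute) == 1L && !attribute %in% c("HbO2", "Hb", "HbT")) {
    stopf("unknown attribute '%s' (use HbO2, Hb or HbT)", attribute)
  }
  attribute <- match.arg(attribute)
  out <- rec$values[, attr_cols(rec$n_channels, attribute), drop = FALSE]
  colnames(out) <- paste0("ch", seq_len(rec$n_channels))
  out
}

csv_header <- function(n_channels) {
  as.vector(t(outer(paste0("ch", seq_len(n_channels)),
                    c("HbO2", "Hb", "HbT"), paste, sep = "_")))
}

#' Read and write per-subject recordings
#'
#' Recordings are stored as delimited tables with one row per time sample and
#' `3 * c` columns named `ch{k}_{HbO2,Hb,HbT}` in channel-major order. Labels
#' travel in a sidecar manifest (see [read_cohort()]).
#'
#' @param path File path of a CSV/TSV table.
#' @param label Class label 0/1 supplied from the manifest.
#' @param subject_id Identifier; defaults to the file name.
#' @param n_channels Declared channel count; checked against the table width.
#' @param sampling_interval_s Sampling interval metadata in seconds.
#' @param sep Field separator (`","` or `"\t"`).
#' @return `read_subject()` returns a [subject_recording()].
#' @export
read_subject <- function(path, label, subject_id = NULL, n_channels = NULL,
                         sampling_interval_s = 0.07, sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "numeric")
  values <- as.matrix(tab)
  if (!is.numeric(values)) stopf("non-numeric cell in %s", path)
  if (!is.null(n_channels)) {
    if (ncol(values) != 3L * n_channels) {
      stopf("%s has %d columns but %d channels were declared (expected %d)",
            path, ncol(values), n_channels, 3L * n_channels)
    }
  }
  subject_recording(values, label = label,
                    subject_id = subject_id %||% sub("\\.[^.]+$", "", basename(path)),
                    sampling_interval_s = sampling_interval_s)
}

#' @rdname read_subject
#' @param rec A [subject_recording()] to write.
#' @export
write_subject <- function(rec, path) {
  values <- rec$values
  colnames(values) <- csv_header(rec$n_channels)
  utils::write.csv(as.data.frame(values), path, row.names = FALSE)
  invisible(path)
}

#' Read and write cohorts as manifest + per-subject CSV files
#'
#' A cohort directory contains one CSV per subject plus `manifest.csv` with
#' columns `subject_id`, `path` (relative to the manifest), `label`.
#'
#' @param manifest Path to the manifest CSV.
#' @return `read_cohort()` returns a list of [subject_recording()] objects.
#' @export
read_cohort <- function(manifest) {
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("subject_id", "path", "label")
  if (!all(need %in% names(man))) {
    stopf("manifest must have columns %s", paste(need, collapse = ", "))
  }
  if (!all(man$label %in% c(0, 1))) stopf("manifest labels must be 0 or 1")
  base <- dirname(manifest)
  lapply(seq_len(nrow(man)), function(i) {
    read_subject(file.path(base, man$path[i]), label = man$label[i],
                 subject_id = man$subject_id[i])
  })
}

#' @rdname read_cohort
#' @param subjects List of [subject_recording()] objects.
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(subjects, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(subjects, function(s) {
    file <- paste0(s$subject_id, ".csv")
    write_subject(s, file.path(dir, file))
    data.frame(subject_id = s$subject_id, path = file, label = s$label,
               stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, rows)
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}
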