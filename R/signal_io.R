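#' hrvscd: early sudden-cardiac-death detection from heart rate variability
#'
#' End-to-end pipeline from raw ECG (or RR-interval series) to a k-NN
#' classifier separating normal from SCD-prone subjects: preprocessing,
#' ensemble empirical mode decomposition, entropy and classical linear HRV
#' features, feature ranking and cross-validated classification.
#'
#' @keywords internal
"_PACKAGE"

#' Canonical 27-feature column order
#'
#' Fixed order of the feature vector produced by [extract_features()]:
#' three time-domain indices, four frequency-domain indices, then the five
#' entropy estimators on each of the first four intrinsic mode functions.
#' `FuEn1` denotes fuzzy entropy computed on IMF1, and so on for the other
#' estimators.
#'
#' @format Character vector of length 27.
#' @export
hrv_feature_names <- c(
  "RMSSD", "SDNN", "pNN50",
  "VLF", "LF", "HF", "LF_HF",
  paste0("FuEn",   1:4),
  paste0("DisEn",  1:4),
  paste0("IMPE",   1:4),
  paste0("RdisEn", 1:4),
  paste0("RenEn",  1:4)
)

#' ECG signal container
#'
#' @param samples Numeric vector of voltage samples (mV).
#' @param fs Sampling rate in Hz (> 0).
#' @param lead Lead label, e.g. `"I"`.
#' @param subject_id Subject/record identifier.
#' @param group One of `"normal"`, `"scd"`, `"unknown"`.
#' @return An object of class `ecg_signal`.
#' @export
ecg_signal <- function(samples, fs, lead = "", subject_id = "",
                       group = c("unknown", "normal", "scd")) {
  group <- match.arg(group)
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("non-positive sampling rate")
  if (length(samples) < 2L) stop("ECG signal must have at least 2 samples")
  if (!all(is.finite(samples))) stop("ECG samples must all be finite")
  structure(
    list(samples = samples, fs = fs, lead = lead,
         subject_id = subject_id, group = group),
    class = "ecg_signal"
  )
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal> %d samples @ %g Hz (%.1f s)  lead=%s  subject=%s  group=%s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              if (nzchar(x$lead)) x$lead else "?",
              if (nzchar(x$subject_id)) x$subject_id else "?", x$group))
  invisible(x)
}

#' RR-interval series container
#'
#' Intervals are stored in milliseconds. `beat_times` holds cumulative beat
#' times in seconds with the length-plus-one convention: `beat_times[1]` is
#' the time of the beat opening the first interval and
#' `beat_times[i + 1] = beat_times[i] + rr[i] / 1000`.
#'
#' @param rr Numeric vector of RR intervals in ms (all finite, > 0).
#' @param beat_times Optional numeric vector of beat times (s),
#'   `length(rr) + 1` long and strictly increasing; defaults to
#'   `c(0, cumsum(rr) / 1000)`.
#' @param subject_id Subject identifier.
#' @param group One of `"unknown"`, `"normal"`, `"scd"`.
#' @param corrected Logical; has the ectopic filter been applied?
#' @return An object of class `rr_series`.
#' @export
rr_series <- function(rr, beat_times = NULL, subject_id = "",
                      group = c("unknown", "normal", "scd"),
                      corrected = FALSE) {
  group <- match.arg(group)
  rr <- as.numeric(rr)
  if (length(rr) < 1L) stop("empty RR series")
  if (!all(is.finite(rr)) || any(rr <= 0))
    stop("RR intervals must be finite and positive")
  if (is.null(beat_times)) beat_times <- c(0, cumsum(rr) / 1000)
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) != length(rr) + 1L)
    stop("beat_times must have length(rr) + 1 entries")
  if (any(diff(beat_times) <= 0)) stop("beat_times must be strictly increasing")
  structure(
    list(rr = rr, beat_times = beat_times, subject_id = subject_id,
         group = group, corrected = corrected),
    class = "rr_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d intervals, %.1f s, mean RR %.0f ms  subject=%s  group=%s  corrected=%s\n",
              length(x$rr), sum(x$rr) / 1000, mean(x$rr),
              if (nzchar(x$subject_id)) x$subject_id else "?",
              x$group, x$corrected))
  invisible(x)
}

#' Duration of an RR series in seconds
#' @param rr An `rr_series`.
#' @return Total duration (s), i.e. the span of `beat_times`.
#' @export
rr_duration <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  diff(range(rr$beat_times))
}

#' Read an ECG record
#'
#' CSV records carry their metadata in leading comment lines of the form
#' `# key: value` (`fs` mandatory; `lead`, `subject_id`, `group` optional)
#' followed by a mandatory header row and one sample value per row.
#' WFDB records are read from the text `.hea` header plus the binary `.dat`
#' file (formats 16 and 212 supported); one lead is selected.
#'
#' @param path Path to the CSV file or to the WFDB record (with or without
#'   the `.hea` extension).
#' @param format `"csv"` or `"wfdb"`.
#' @param lead For WFDB, the signal description or index of the lead to
#'   extract (default: first lead).
#' @param group Optional class label overriding any stored metadata.
#' @return An [ecg_signal()].
#' @export
read_ecg <- function(path, format = c("csv", "wfdb"), lead = NULL,
                     group = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    meta_idx <- grep("^\\s*#", lines)
    meta <- list()
    for (ln in lines[meta_idx]) {
      m <- regmatches(ln, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*[:=]\\s*(.*)$", ln))[[1]]
      if (length(m) == 3L) meta[[m[2]]] <- trimws(m[3])
    }
    if (is.null(meta$fs)) stop("CSV header must declare fs")
    fs <- suppressWarnings(as.numeric(meta$fs))
    if (is.na(fs) || fs <= 0) stop("non-positive sampling rate")
    body <- lines[setdiff(seq_along(lines), meta_idx)]
    body <- body[nzchar(trimws(body))]
    if (length(body) < 2L) stop("no samples in ", path)
    samples <- suppressWarnings(as.numeric(body[-1L]))  # first body line = header
    if (anyNA(samples)) stop("non-numeric samples in ", path)
    grp <- if (!is.null(group)) group else if (!is.null(meta$group)) meta$group else "unknown"
    ecg_signal(samples, fs,
               lead = if (!is.null(meta$lead)) meta$lead else "",
               subject_id = if (!is.null(meta$subject_id)) meta$subject_id else
                 sub("\\.[^.]*$", "", basename(path)),
               group = grp)
  } else {
    read_wfdb(path, lead = lead, group = group)
  }
}

# Minimal read-only WFDB support: .hea header + .dat in format 16 or 212.
read_wfdb <- function(record, lead = NULL, group = NULL) {
  hea <- if (grepl("\\.hea$", record)) record else paste0(record, ".hea")
  if (!file.exists(hea)) stop("file not found: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(rec[2])
  fs <- if (length(rec) >= 3) as.numeric(sub("/.*", "", rec[3])) else 250
  nsamp <- if (length(rec) >= 4) as.integer(rec[4]) else NA_integer_
  if (is.na(fs) || fs <= 0) stop("non-positive sampling rate")
  sig <- lapply(lines[1 + seq_len(nsig)], function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    gain <- 200; baseline <- 0
    if (length(f) >= 3) {
      gm <- regmatches(f[3], regexec("^([-0-9.eE+]+)(\\(([-0-9]+)\\))?", f[3]))[[1]]
      if (nzchar(gm[2])) gain <- as.numeric(gm[2])
      if (length(gm) >= 4 && nzchar(gm[4])) baseline <- as.numeric(gm[4])
    }
    if (gain == 0) gain <- 200
    list(file = f[1], fmt = sub("x.*|:.*|\\+.*", "", f[2]),
         gain = gain, baseline = baseline,
         desc = if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else "")
  })
  fmts <- unique(vapply(sig, `[[`, "", "fmt"))
  if (length(fmts) != 1L || !fmts %in% c("16", "212"))
    stop("unsupported WFDB signal format: ", paste(fmts, collapse = ","))
  datfile <- file.path(dirname(hea), sig[[1]]$file)
  if (!file.exists(datfile)) stop("file not found: ", datfile)
  raw <- readBin(datfile, "raw", n = file.info(datfile)$size)
  if (fmts == "16") {
    adc <- readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
                   signed = TRUE, endian = "little")
    mat <- matrix(adc[seq_len((length(adc) %/% nsig) * nsig)], nrow = nsig)
  } else {
    n3 <- (length(raw) %/% 3L) * 3L
    b <- as.integer(raw[seq_len(n3)])
    b1 <- b[seq(1, n3, 3)]; b2 <- b[seq(2, n3, 3)]; b3 <- b[seq(3, n3, 3)]
    s1 <- b1 + bitwAnd(b2, 15L) * 256L
    s2 <- b3 + bitwAnd(b2 %/% 16L, 15L) * 256L
    s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
    s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
    adc <- as.vector(rbind(s1, s2))
    mat <- matrix(adc[seq_len((length(adc) %/% nsig) * nsig)], nrow = nsig)
  }
  if (!is.na(nsamp) && ncol(mat) > nsamp) mat <- mat[, seq_len(nsamp), drop = FALSE]
  descs <- vapply(sig, `[[`, "", "desc")
  idx <- if (is.null(lead)) 1L
         else if (is.numeric(lead)) as.integer(lead)
         else match(lead, descs)
  if (is.na(idx) || idx < 1L || idx > nsig) stop("lead not found: ", lead)
  mv <- (mat[idx, ] - sig[[idx]]$baseline) / sig[[idx]]$gain
  ecg_signal(mv, fs, lead = descs[idx],
             subject_id = sub("\\.hea$", "", basename(hea)),
             group = if (is.null(group)) "unknown" else group)
}

#' Read an RR-interval series from CSV
#'
#' One interval per row under a mandatory header line; values in seconds or
#' milliseconds. Intervals are stored in ms.
#'
#' @param path CSV file path.
#' @param units `"ms"` or `"s"`.
#' @param subject_id,group,corrected Metadata forwarded to [rr_series()].
#' @return An [rr_series()].
#' @export
read_rr <- function(path, units = c("ms", "s"), subject_id = "",
                    group = "unknown", corrected = FALSE) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (length(lines) < 2L) stop("empty RR file: ", path)
  vals <- suppressWarnings(as.numeric(lines[-1L]))
  if (anyNA(vals)) stop("non-numeric RR values in ", path)
  if (any(vals <= 0)) stop("RR intervals must be positive")
  if (units == "s") vals <- vals * 1000
  rr_series(vals, subject_id = if (nzchar(subject_id)) subject_id else
              sub("\\.[^.]*$", "", basename(path)),
            group = group, corrected = corrected)
}

#' Write an RR-interval series to CSV
#' @param rr An `rr_series`.
#' @param path Output path; intervals written in ms under header `rr`.
#' @return `path`, invisibly.
#' @export
write_rr <- function(rr, path) {
  stopifnot(inherits(rr, "rr_series"))
  writeLines(c("rr", format(rr$rr, digits = 15, scientific = FALSE,
                            trim = TRUE)), path)
  invisible(path)
}

#' Feature table container
#'
#' One row per (subject, segment); columns are the 27 features in
#' [hrv_feature_names] order plus `label` and `interval_index`.
#'
#' @param features Numeric matrix or data frame of feature values whose
#'   column names must match `feature_names`.
#' @param labels Character/factor vector of class labels, one per row.
#' @param interval_index Integer vector, the 2-min interval (1-based) each
#'   row was extracted from.
#' @param feature_names Ordered feature names; defaults to
#'   [hrv_feature_names].
#' @return A `feature_table`: a data frame with attribute `feature_names`.
#' @export
feature_table <- function(features, labels, interval_index = 1L,
                          feature_names = hrv_feature_names) {
  features <- as.data.frame(features)
  if (anyDuplicated(feature_names)) stop("feature names must be unique")
  if (!identical(colnames(features), feature_names))
    stop("feature columns must match feature_names in order")
  n <- nrow(features)
  if (n < 1L) stop("empty feature table")
  labels <- as.character(labels)
  if (length(labels) != n) stop("one label per row required")
  interval_index <- as.integer(rep_len(interval_index, n))
  out <- cbind(features,
               data.frame(label = labels, interval_index = interval_index,
                          stringsAsFactors = FALSE))
  structure(out, feature_names = feature_names,
            class = c("feature_table", "data.frame"))
}

#' @export
print.feature_table <- function(x, ...) {
  fn <- attr(x, "feature_names")
  cat(sprintf("<feature_table> %d rows x %d features  labels: %s\n",
              nrow(x), length(fn),
              paste(sprintf("%s=%d", names(table(x$label)), table(x$label)),
                    collapse = ", ")))
  invisible(x)
}

#' Write a feature table to CSV
#'
#' Columns: the feature names, then `label` and `interval_index`. Values are
#' written with enough digits to round-trip within 1e-12 relative error.
#'
#' @param table A [feature_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  if (!inherits(table, "feature_table")) stop("not a feature_table")
  if (nrow(table) < 1L) stop("empty feature table")
  df <- as.data.frame(table)
  fn <- attr(table, "feature_names")
  for (col in fn) df[[col]] <- format(df[[col]], digits = 17, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("label", "interval_index") %in% colnames(df)))
    stop("not a feature table: missing label/interval_index columns")
  fn <- setdiff(colnames(df), c("label", "interval_index"))
  feature_table(df[fn], df$label, df$interval_index, feature_names = fn)
}

#' Read a run configuration (YAML or JSON)
#'
#' Keys mirror the configuration constructors ([preprocess_config()],
#' [eemd_config()], [entropy_config()], [linear_config()]); unknown keys are
#' ignored by the consumers.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}

# Stage-tagged log line used across the pipeline.
hrv_log <- function(stage, subject_id = "", interval_index = NA, ...) {
  msg <- paste0(...)
  message(sprintf("[%s]%s%s %s", stage,
                  if (nzchar(subject_id)) paste0(" subject=", subject_id) else "",
                  if (!is.na(interval_index)) paste0(" interval=", interval_index) else "",
                  msg))
  invisible(NULL)
}
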