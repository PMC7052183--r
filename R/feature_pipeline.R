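#' Extract the 27-feature vector of one 2-min RR segment
#'
#' Time-domain (SDNN, RMSSD, pNN50) and frequency-domain (VLF, LF, HF,
#' LF/HF) indices from the RR series, then EEMD of the series, and the
#' five entropy estimators (FuEn, DisEn, IMPE, RdisEn, RenEn) on each of
#' the first four IMFs. The EEMD/entropy stage works on RR expressed in
#' seconds: every estimator except FuEn is amplitude-invariant, and the
#' fuzzy membership `exp(-d^p / r)` keeps FuEn on its conventional
#' magnitude scale only for seconds-valued intervals. The fuzzy-entropy
#' tolerance tracks each IMF's own SD. Missing IMF slots (degenerate
#' segments) produce zero entropy
#' features and a warning; the result is always 27 finite values in
#' [hrv_feature_names] order. Deterministic for a fixed EEMD seed.
#'
#' @param segment A corrected [rr_series()] of duration >= 60 s.
#' @param eemd_cfg An [eemd_config()].
#' @param ent_cfg An [entropy_config()].
#' @param lin_cfg A [linear_config()].
#' @return Named numeric vector of length 27 with attributes `subject_id`,
#'   `group`, `interval_index` and `missing_imfs`.
#' @export
extract_features <- function(segment, eemd_cfg = eemd_config(),
                             ent_cfg = entropy_config(),
                             lin_cfg = linear_config()) {
  stopifnot(inherits(segment, "rr_series"))
  td <- tryCatch(time_domain(segment, lin_cfg$pnn_threshold),
                 error = function(e) stop("time_domain: ", conditionMessage(e)))
  fd <- tryCatch(frequency_domain(segment, lin_cfg),
                 error = function(e) stop("frequency_domain: ", conditionMessage(e)))
  if (is.na(fd$LF_HF)) {
    warning("HF power is zero; LF/HF set to 0 for subject ",
            segment$subject_id)
    fd$LF_HF <- 0
  }
  dec <- tryCatch(eemd(segment$rr / 1000, eemd_cfg),
                  error = function(e) stop("eemd: ", conditionMessage(e)))
  dec4 <- first_k_imfs(dec, 4L)
  missing <- attr(dec4, "missing_slots")
  if (missing > 0L)
    warning(sprintf("only %d IMFs available; %d entropy slots set to 0 (subject %s)",
                    length(dec4$imfs), missing, segment$subject_id))
  ent <- matrix(0, nrow = 5L, ncol = 4L,
                dimnames = list(c("FuEn", "DisEn", "IMPE", "RdisEn", "RenEn"),
                                NULL))
  for (k in seq_along(dec4$imfs)) {
    imf <- dec4$imfs[[k]]
    if (stats::sd(imf) == 0) next  # degenerate slot stays 0
    ent["FuEn", k]   <- fuzzy_entropy(imf, ent_cfg$fuen_a, ent_cfg$fuen_r,
                                      ent_cfg$fuen_p)
    ent["DisEn", k]  <- dispersion_entropy(imf, ent_cfg$disen_m,
                                           ent_cfg$disen_c, ent_cfg$disen_d)
    ent["IMPE", k]   <- impe(imf, ent_cfg$impe_m, ent_cfg$impe_s)
    ent["RdisEn", k] <- rdis_entropy(imf, ent_cfg$rdisen_a, ent_cfg$rdisen_M,
                                     ent_cfg$rdisen_q)
    ent["RenEn", k]  <- renyi_entropy(imf, ent_cfg$renen_q)
  }
  v <- c(td$RMSSD, td$SDNN, td$pNN50, fd$VLF, fd$LF, fd$HF, fd$LF_HF,
         ent["FuEn", ], ent["DisEn", ], ent["IMPE", ], ent["RdisEn", ],
         ent["RenEn", ])
  names(v) <- hrv_feature_names
  attr(v, "subject_id") <- segment$subject_id
  attr(v, "group") <- segment$group
  attr(v, "interval_index") <- attr(segment, "interval_index")
  attr(v, "missing_imfs") <- missing
  v
}

#' Build a feature table from labelled RR segments
#'
#' @param segments List of [rr_series()] objects carrying `group` labels
#'   (and optionally `interval_index` attributes).
#' @param eemd_cfg,ent_cfg,lin_cfg Stage configurations, see
#'   [extract_features()].
#' @return A [feature_table()] with one row per segment.
#' @export
build_feature_table <- function(segments, eemd_cfg = eemd_config(),
                                ent_cfg = entropy_config(),
                                lin_cfg = linear_config()) {
  vecs <- lapply(segments, extract_features, eemd_cfg = eemd_cfg,
                 ent_cfg = ent_cfg, lin_cfg = lin_cfg)
  mat <- do.call(rbind, vecs)
  labels <- vapply(segments, function(s) s$group, character(1))
  idx <- vapply(segments, function(s) {
    ii <- attr(s, "interval_index"); if (is.null(ii)) 1L else as.integer(ii)
  }, integer(1))
  feature_table(as.data.frame(mat), labels, idx)
}

#' Entropy-parameter sweep over a labelled segment set
#'
#' Recomputes one tunable estimator (the Renyi order `q` of RdisEn or the
#' scale `s` of IMPE) on the first four IMFs of every segment for each
#' grid value, and reports the two-sample pooled t-test p-value per
#' (IMF, value) cell — the grid used to pick `q = 2` and `s = 2`.
#' Decompositions are computed once and reused across the grid.
#'
#' @param segments List of labelled [rr_series()] objects; both classes
#'   must be present.
#' @param param `"rdisen_q"` or `"impe_s"`.
#' @param grid Numeric vector of parameter values.
#' @param eemd_cfg An [eemd_config()].
#' @param ent_cfg An [entropy_config()] supplying the fixed parameters.
#' @return Data frame with columns `imf`, `param`, `value`, `p`.
#' @export
parameter_sweep <- function(segments, param = c("rdisen_q", "impe_s"), grid,
                            eemd_cfg = eemd_config(),
                            ent_cfg = entropy_config()) {
  param <- match.arg(param)
  stopifnot(length(grid) >= 1L)
  labels <- vapply(segments, function(s) s$group, character(1))
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  decs <- lapply(segments, function(s) first_k_imfs(eemd(s$rr / 1000, eemd_cfg), 4L))
  rows <- list()
  for (val in grid) {
    feat <- vapply(decs, function(d) {
      out <- numeric(4L)
      for (k in seq_along(d$imfs)) {
        imf <- d$imfs[[k]]
        if (stats::sd(imf) == 0) next
        out[k] <- if (param == "rdisen_q")
          rdis_entropy(imf, ent_cfg$rdisen_a, ent_cfg$rdisen_M, val)
        else
          impe(imf, ent_cfg$impe_m, as.integer(val))
      }
      out
    }, numeric(4L))
    for (k in 1:4) {
      a <- feat[k, labels == unique(labels)[1]]
      b <- feat[k, labels == unique(labels)[2]]
      rows[[length(rows) + 1L]] <- data.frame(
        imf = k, param = param, value = val, p = feature_pvalue(a, b))
    }
  }
  do.call(rbind, rows)
}
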