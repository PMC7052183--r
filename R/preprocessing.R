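#' Preprocessing configuration
#'
#' Defaults follow short-term HRV practice for 360-Hz ECG: denoising zeroes
#' the first two wavelet detail bands (45-180 Hz, power-line interference)
#' and the level-8 approximation (< 0.7 Hz, baseline wander); ectopic
#' intervals deviating more than 20% from the median of their ten
#' neighbours are deleted; the corrected series is cut into seven 2-min
#' segments.
#'
#' @param target_fs Resampling target in Hz.
#' @param wavelet Wavelet basis; only `"db6"` is provided.
#' @param dwt_level Decomposition depth. `NA` scales it with the sampling
#'   rate as `ceiling(log2(fs / 0.7)) - 2` (8 at 360 Hz).
#' @param zeroed_details How many of the finest detail bands to zero.
#' @param ectopic_tolerance Relative deviation from the neighbourhood
#'   median above which an interval is removed.
#' @param ectopic_window Neighbours per side entering the median.
#' @param segment_len Segment length in seconds.
#' @param n_segments Number of consecutive segments.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(target_fs = 360, wavelet = "db6",
                              dwt_level = NA, zeroed_details = 2L,
                              ectopic_tolerance = 0.20, ectopic_window = 5L,
                              segment_len = 120, n_segments = 7L) {
  stopifnot(target_fs > 0, ectopic_tolerance > 0, ectopic_tolerance < 1,
            ectopic_window >= 1, segment_len > 0, n_segments >= 1)
  if (wavelet != "db6") stop("only the db6 wavelet is provided")
  structure(list(target_fs = target_fs, wavelet = wavelet,
                 dwt_level = dwt_level, zeroed_details = as.integer(zeroed_details),
                 ectopic_tolerance = ectopic_tolerance,
                 ectopic_window = as.integer(ectopic_window),
                 segment_len = segment_len, n_segments = as.integer(n_segments)),
            class = "preprocess_config")
}

# Depth such that the zeroed approximation band (f < fs / 2^(level + 1))
# reaches up to ~0.7 Hz, keeping the < 0.5 Hz baseline wander well inside
# the stop band: 8 at 360 Hz.
dwt_level_for_fs <- function(fs) max(1L, as.integer(ceiling(log2(fs / 0.7)) - 2))

#' Resample an ECG signal
#'
#' Rational-factor polyphase resampling; duration is preserved to within
#' one sample period and content below the original Nyquist is retained.
#'
#' @param ecg An [ecg_signal()].
#' @param target_fs Target sampling rate in Hz (> 0).
#' @return A resampled [ecg_signal()].
#' @export
resample_ecg <- function(ecg, target_fs) {
  stopifnot(inherits(ecg, "ecg_signal"))
  if (!is.numeric(target_fs) || target_fs <= 0) stop("non-positive sampling rate")
  if (isTRUE(all.equal(target_fs, ecg$fs))) {
    out <- ecg
    out$fs <- target_fs
    return(out)
  }
  frac <- rational_approx(target_fs / ecg$fs)
  y <- signal::resample(ecg$samples, frac[1], frac[2])
  n_target <- round(length(ecg$samples) * target_fs / ecg$fs)
  if (length(y) > n_target) y <- y[seq_len(n_target)]
  ecg_signal(y, target_fs, lead = ecg$lead, subject_id = ecg$subject_id,
             group = ecg$group)
}

# Small-denominator rational approximation p/q of a positive ratio.
rational_approx <- function(r, max_den = 4096L) {
  best <- c(round(r), 1L); err <- abs(r - best[1])
  for (q in seq_len(max_den)) {
    p <- round(r * q)
    e <- abs(r - p / q)
    if (e < err - 1e-15) { best <- c(p, q); err <- e }
    if (err < 1e-12) break
  }
  as.integer(best)
}

# db6 analysis filters (Daubechies extremal-phase, 12 taps).
db6_lo <- c(-1.077301085308479591e-03,  4.777257510945510759e-03,
             5.538422011614961256e-04, -3.158203931748602977e-02,
             2.752286553030572694e-02,  9.750160558732304250e-02,
            -1.297668675672619398e-01, -2.262646939654398281e-01,
             3.152503517091976293e-01,  7.511339080210953645e-01,
             4.946238903984530588e-01,  1.115407433501094669e-01)
db6_hi <- rev(db6_lo) * rep_len(c(1, -1), 12L)

# Circular filtering y_t = sum_l f_l v_{(t - s*l) mod N} via FFT; `conj = TRUE`
# gives the adjoint (correlation) used by the inverse transform.
circ_filt <- function(v, f, stride, conj = FALSE) {
  n <- length(v)
  fu <- numeric(n)
  idx <- (stride * (seq_along(f) - 1L)) %% n
  for (k in seq_along(f)) fu[idx[k] + 1L] <- fu[idx[k] + 1L] + f[k]
  F <- stats::fft(fu)
  if (conj) F <- Conj(F)
  Re(stats::fft(stats::fft(v) * F, inverse = TRUE)) / n
}

# Undecimated (maximal-overlap) db6 DWT to `level`; returns list of detail
# coefficient vectors W[[1..level]] and the approximation V.
modwt_db6 <- function(x, level) {
  g <- db6_lo / sqrt(2); h <- db6_hi / sqrt(2)
  v <- x; W <- vector("list", level)
  for (j in seq_len(level)) {
    s <- 2^(j - 1L)
    W[[j]] <- circ_filt(v, h, s)
    v <- circ_filt(v, g, s)
  }
  list(W = W, V = v)
}

imodwt_db6 <- function(dec) {
  g <- db6_lo / sqrt(2); h <- db6_hi / sqrt(2)
  level <- length(dec$W)
  v <- dec$V
  for (j in rev(seq_len(level))) {
    s <- 2^(j - 1L)
    v <- circ_filt(v, g, s, conj = TRUE) + circ_filt(dec$W[[j]], h, s, conj = TRUE)
  }
  v
}

#' Wavelet denoising of an ECG signal
#'
#' Undecimated db6 wavelet decomposition to `dwt_level`; the finest
#' `zeroed_details` detail bands (power-line interference) and the
#' deepest-level approximation (baseline wander) are zeroed before
#' reconstruction at the original length.
#'
#' @param ecg An [ecg_signal()].
#' @param cfg A [preprocess_config()].
#' @return The denoised [ecg_signal()].
#' @export
denoise_dwt <- function(ecg, cfg = preprocess_config()) {
  stopifnot(inherits(ecg, "ecg_signal"))
  level <- if (is.na(cfg$dwt_level)) dwt_level_for_fs(ecg$fs) else cfg$dwt_level
  n <- length(ecg$samples)
  span <- (2^level - 1L) * (length(db6_lo) - 1L) + 1L
  if (n < span)
    stop(sprintf("signal too short for level-%d decomposition (need >= %d samples)",
                 level, span))
  dec <- modwt_db6(ecg$samples, level)
  for (j in seq_len(min(cfg$zeroed_details, level)))
    dec$W[[j]] <- numeric(n)
  dec$V <- numeric(n)
  out <- ecg
  out$samples <- imodwt_db6(dec)
  out
}

#' Pan-Tompkins QRS detection
#'
#' Classic stage sequence: 5-15 Hz band-pass, five-point derivative,
#' squaring, 150-ms moving-window integration, adaptive dual thresholds
#' with search-back, 200-ms refractory period and T-wave discrimination by
#' slope within 360 ms. Detected peaks are refined to the local maximum of
#' the band-passed signal.
#'
#' @param ecg An [ecg_signal()] with `fs >= 100` Hz and duration >= 10 s.
#' @return A list of class `beat_annotations` with `r_peaks` (1-based
#'   sample indices) and `fs`.
#' @export
detect_qrs <- function(ecg) {
  stopifnot(inherits(ecg, "ecg_signal"))
  fs <- ecg$fs
  if (fs < 100) stop("sampling rate must be >= 100 Hz for QRS detection")
  x <- ecg$samples
  n <- length(x)
  if (n / fs < 10) stop("record shorter than 10 s")
  if (stats::sd(x) == 0) stop("no QRS detected: flat signal")

  bp <- signal::filtfilt(signal::butter(3, c(5, 15) / (fs / 2), "pass"), x)
  dv <- as.numeric(signal::filter(c(1, 2, 0, -2, -1) * fs / 8, 1, bp))
  sq <- dv^2
  w <- max(1L, round(0.150 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 1))
  mwi[is.na(mwi)] <- 0

  # candidate peaks of the integrated signal
  pk <- which(diff(sign(diff(mwi))) < 0) + 1L
  if (length(pk) == 0L) stop("no QRS detected")
  # group delay: derivative (2 samples) + half the integration window
  delay <- as.integer(round(w / 2)) + 2L

  init <- mwi[seq_len(min(n, round(2 * fs)))]
  spki <- max(init) * 0.5
  npki <- mean(init) * 0.5
  thr1 <- npki + 0.25 * (spki - npki)
  refr <- round(0.200 * fs)
  twin <- round(0.360 * fs)

  beats <- integer(0)
  slopes <- numeric(0)
  rr_hist <- numeric(0)
  last_beat <- -refr
  i <- 1L
  while (i <= length(pk)) {
    p <- pk[i]
    a <- mwi[p]
    accept <- FALSE
    if (a > thr1 && (p - last_beat) > refr) {
      accept <- TRUE
      # T-wave test: close to the previous beat and with a shallower upslope
      if (length(beats) && (p - last_beat) <= twin) {
        sl <- max(dv[max(1L, p - w):p])
        if (sl < 0.5 * slopes[length(slopes)]) accept <- FALSE
      }
    }
    if (accept) {
      beats <- c(beats, p)
      slopes <- c(slopes, max(dv[max(1L, p - w):p]))
      if (length(beats) >= 2L)
        rr_hist <- utils::tail(c(rr_hist, diff(utils::tail(beats, 2L))), 8L)
      last_beat <- p
      spki <- 0.125 * a + 0.875 * spki
    } else {
      npki <- 0.125 * a + 0.875 * npki
    }
    thr1 <- npki + 0.25 * (spki - npki)

    # search-back when a beat seems missed
    if (length(rr_hist) >= 2L) {
      rr_avg <- mean(rr_hist)
      nxt <- if (i < length(pk)) pk[i + 1L] else n
      if ((nxt - last_beat) > 1.66 * rr_avg) {
        cand <- pk[pk > last_beat + refr & pk < nxt]
        cand <- cand[mwi[cand] > 0.5 * thr1]
        if (length(cand)) {
          p2 <- cand[which.max(mwi[cand])]
          beats <- sort(c(beats, p2))
          slopes <- c(slopes, max(dv[max(1L, p2 - w):p2]))
          last_beat <- max(beats)
          rr_hist <- utils::tail(diff(beats), 8L)
          spki <- 0.25 * mwi[p2] + 0.75 * spki
          thr1 <- npki + 0.25 * (spki - npki)
        }
      }
    }
    i <- i + 1L
  }
  if (length(beats) == 0L) stop("no QRS detected")

  # refine: local maximum of the band-passed signal preceding the MWI peak
  half <- as.integer(round(0.075 * fs))
  refined <- vapply(beats, function(p) {
    lo <- max(1L, as.integer(p) - delay - half)
    hi <- min(n, as.integer(p) - delay + half)
    lo + which.max(bp[lo:hi]) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  structure(list(r_peaks = refined, fs = fs), class = "beat_annotations")
}

#' @export
print.beat_annotations <- function(x, ...) {
  cat(sprintf("<beat_annotations> %d R peaks @ %g Hz\n", length(x$r_peaks), x$fs))
  invisible(x)
}

#' RR intervals from beat annotations
#'
#' @param ann A `beat_annotations` object from [detect_qrs()].
#' @param subject_id,group Metadata forwarded to [rr_series()].
#' @return An uncorrected [rr_series()]; `rr[i]` is
#'   `(r_peaks[i+1] - r_peaks[i]) / fs * 1000` ms.
#' @export
extract_rr <- function(ann, subject_id = "", group = "unknown") {
  stopifnot(inherits(ann, "beat_annotations"))
  if (length(ann$r_peaks) < 2L) stop("need at least 2 beats")
  rr <- diff(ann$r_peaks) / ann$fs * 1000
  rr_series(rr, beat_times = (ann$r_peaks - ann$r_peaks[1]) / ann$fs,
            subject_id = subject_id, group = group, corrected = FALSE)
}

#' Ectopic-interval correction
#'
#' Median filter of width five per side: an interval deviating from the
#' median of its up-to-five previous and five next neighbours (itself
#' excluded) by more than `ectopic_tolerance` (relative) is deleted. At the
#' series edges whatever neighbours exist (at least 3) are used. Beat times
#' are recomputed from the surviving intervals.
#'
#' @param rr An [rr_series()] of length >= 3.
#' @param cfg A [preprocess_config()].
#' @return The corrected [rr_series()] (`corrected = TRUE`).
#' @export
correct_ectopic <- function(rr, cfg = preprocess_config()) {
  stopifnot(inherits(rr, "rr_series"))
  x <- rr$rr
  n <- length(x)
  if (n < 3L) stop("need at least 3 intervals")
  w <- cfg$ectopic_window
  keep <- vapply(seq_len(n), function(i) {
    prev <- if (i > 1L) x[max(1L, i - w):(i - 1L)] else numeric(0)
    nxt <- if (i < n) x[(i + 1L):min(n, i + w)] else numeric(0)
    nb <- c(prev, nxt)
    if (length(nb) < 3L) return(TRUE)  # too short an edge context to judge
    abs(x[i] - stats::median(nb)) / stats::median(nb) <= cfg$ectopic_tolerance
  }, logical(1))
  if (!any(keep)) stop("all intervals removed by ectopic filter")
  rr_series(x[keep], subject_id = rr$subject_id, group = rr$group,
            corrected = TRUE)
}

#' Select the analysis window of an RR series
#'
#' For SCD records the window is the `segment_len * n_segments` seconds
#' immediately preceding the supplied event time (VF onset); for normal
#' records the window start is drawn uniformly at random (seeded).
#'
#' @param rr An [rr_series()].
#' @param cfg A [preprocess_config()].
#' @param event_time Event time in seconds (relative to `beat_times`), or
#'   `NULL` for a random window.
#' @param seed RNG seed used when `event_time` is `NULL`.
#' @return The windowed [rr_series()].
#' @export
select_window <- function(rr, cfg = preprocess_config(), event_time = NULL,
                          seed = 1L) {
  stopifnot(inherits(rr, "rr_series"))
  span <- cfg$segment_len * cfg$n_segments
  t <- rr$beat_times
  total <- t[length(t)] - t[1]
  if (total < span)
    stop(sprintf("record shorter than %g min", span / 60))
  if (is.null(event_time)) {
    start <- t[1] + with_seed(seed, stats::runif(1, 0, total - span))
  } else {
    start <- event_time - span
    if (start < t[1]) stop("event time leaves less than the analysis span")
  }
  endt <- start + span
  sel <- which(t[-1] > start & t[-1] <= endt + 1e-9)
  rr_series(rr$rr[sel], beat_times = c(t[sel[1]], t[sel + 1L]),
            subject_id = rr$subject_id, group = rr$group,
            corrected = rr$corrected)
}

#' Split an RR series into consecutive fixed-length segments
#'
#' The first `n_segments * segment_len` seconds of the series are cut into
#' `n_segments` equal segments; each interval is assigned to the segment
#' containing its ending beat time. `interval_index` 1 is the earliest
#' segment.
#'
#' @param rr An [rr_series()].
#' @param cfg A [preprocess_config()].
#' @return A list of `n_segments` [rr_series()] objects, each with an
#'   `interval_index` attribute.
#' @export
segment_rr <- function(rr, cfg = preprocess_config()) {
  stopifnot(inherits(rr, "rr_series"))
  t <- rr$beat_times - rr$beat_times[1]
  span <- cfg$segment_len * cfg$n_segments
  if (t[length(t)] < span - 1e-9)
    stop(sprintf("record shorter than %g min", span / 60))
  ends <- t[-1]
  out <- vector("list", cfg$n_segments)
  for (s in seq_len(cfg$n_segments)) {
    lo <- (s - 1) * cfg$segment_len
    hi <- s * cfg$segment_len
    sel <- which(ends > lo & ends <= hi + 1e-9)
    if (!length(sel)) stop("empty segment ", s)
    seg <- rr_series(rr$rr[sel], beat_times = c(t[sel[1]], ends[sel]),
                     subject_id = rr$subject_id, group = rr$group,
                     corrected = rr$corrected)
    attr(seg, "interval_index") <- s
    out[[s]] <- seg
  }
  out
}

#' Full ECG-to-segments preprocessing chain
#'
#' Resample to `target_fs`, wavelet-denoise, detect QRS, extract and
#' correct RR intervals, window (event-anchored or random) and segment.
#'
#' @param ecg An [ecg_signal()].
#' @param cfg A [preprocess_config()].
#' @param event_time VF-onset time in seconds for SCD records, else `NULL`.
#' @param seed Seed for the random window of normal records.
#' @return List of segment [rr_series()] objects.
#' @export
preprocess_ecg <- function(ecg, cfg = preprocess_config(), event_time = NULL,
                           seed = 1L) {
  ecg <- resample_ecg(ecg, cfg$target_fs)
  ecg <- denoise_dwt(ecg, cfg)
  ann <- detect_qrs(ecg)
  hrv_log("qrs", ecg$subject_id, NA, length(ann$r_peaks), " beats detected")
  rr <- extract_rr(ann, subject_id = ecg$subject_id, group = ecg$group)
  n0 <- length(rr$rr)
  rr <- correct_ectopic(rr, cfg)
  hrv_log("ectopic", ecg$subject_id, NA, n0 - length(rr$rr),
          " intervals removed")
  rr <- select_window(rr, cfg, event_time = event_time, seed = seed)
  segment_rr(rr, cfg)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
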