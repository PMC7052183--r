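#' Classical linear HRV feature configuration
#'
#' Standard short-term HRV bands: VLF 0.003-0.04 Hz, LF 0.04-0.15 Hz,
#' HF 0.15-0.4 Hz. The RR tachogram is cubic-interpolated to an even
#' `resample_hz` grid before spectral estimation.
#'
#' @param vlf_band,lf_band,hf_band Two-element Hz vectors, ascending and
#'   non-overlapping.
#' @param resample_hz Tachogram resampling rate (Hz).
#' @param pnn_threshold pNN threshold in ms (strict `>`).
#' @return A list of class `linear_config`.
#' @export
linear_config <- function(vlf_band = c(0.003, 0.04), lf_band = c(0.04, 0.15),
                          hf_band = c(0.15, 0.4), resample_hz = 4,
                          pnn_threshold = 50) {
  bands <- c(vlf_band, lf_band, hf_band)
  stopifnot(length(bands) == 6L, all(diff(c(vlf_band[1], vlf_band[2],
                                            lf_band[2], hf_band[2])) > 0),
            vlf_band[2] <= lf_band[1], lf_band[2] <= hf_band[1],
            resample_hz > 0, pnn_threshold > 0)
  structure(list(vlf_band = vlf_band, lf_band = lf_band, hf_band = hf_band,
                 resample_hz = resample_hz, pnn_threshold = pnn_threshold),
            class = "linear_config")
}

#' Time-domain HRV indices
#'
#' @param rr An [rr_series()] (or bare numeric ms vector) of length >= 3.
#' @param pnn_threshold Threshold in ms for pNN (default 50, strict `>`).
#' @return List with `SDNN` (ms), `RMSSD` (ms) and `pNN50` (%).
#' @export
time_domain <- function(rr, pnn_threshold = 50) {
  x <- if (inherits(rr, "rr_series")) rr$rr else as.numeric(rr)
  if (length(x) < 3L) stop("need at least 3 intervals")
  dx <- diff(x)
  list(SDNN = stats::sd(x),
       RMSSD = sqrt(mean(dx^2)),
       pNN50 = 100 * mean(abs(dx) > pnn_threshold))
}

# Welch PSD: Hann-windowed segments with 50% overlap, one-sided density in
# units^2/Hz. Returns freq + psd such that sum(psd) * df ~= signal variance.
welch_psd <- function(x, fs, seg_len = min(length(x), 256L)) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1L, seg_len %/% 2L)
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  U <- sum(w^2)
  nf <- seg_len %/% 2L
  acc <- numeric(nf + 1L)
  for (s0 in starts) {
    seg <- x[s0:(s0 + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(stats::fft(seg))^2 / (fs * U)
    half <- P[1:(nf + 1L)]
    if (seg_len %% 2L == 0L) half[2:nf] <- 2 * half[2:nf]
    else half[2:(nf + 1L)] <- 2 * half[2:(nf + 1L)]
    acc <- acc + half
  }
  list(freq = (0:nf) * fs / seg_len, psd = acc / length(starts))
}

#' Frequency-domain HRV indices
#'
#' The RR tachogram (interval value at its ending beat time) is
#' cubic-spline interpolated to an even `resample_hz` grid, mean-removed,
#' and a Welch periodogram (64-s Hann segments, 50% overlap) is integrated
#' over the VLF, LF and HF bands. Powers are in absolute ms^2.
#'
#' @param rr An [rr_series()] of duration >= 60 s.
#' @param cfg A [linear_config()].
#' @return List with `VLF`, `LF`, `HF` (ms^2) and `LF_HF` (`NA` when HF
#'   power is zero).
#' @export
frequency_domain <- function(rr, cfg = linear_config()) {
  stopifnot(inherits(rr, "rr_series"))
  dur <- rr_duration(rr)
  if (dur < 60) stop("need at least 60 s of RR data")
  t <- rr$beat_times[-1L]
  fs <- cfg$resample_hz
  grid <- seq(t[1], t[length(t)], by = 1 / fs)
  if (stats::sd(rr$rr) == 0) {
    return(list(VLF = 0, LF = 0, HF = 0, LF_HF = NA_real_))
  }
  y <- stats::spline(t, rr$rr, xout = grid, method = "fmm")$y
  y <- y - mean(y)
  sp <- welch_psd(y, fs, seg_len = min(length(y), 64L * fs))
  df <- sp$freq[2] - sp$freq[1]
  band_power <- function(b) sum(sp$psd[sp$freq > b[1] & sp$freq <= b[2]]) * df
  vlf <- band_power(cfg$vlf_band)
  lf <- band_power(cfg$lf_band)
  hf <- band_power(cfg$hf_band)
  list(VLF = vlf, LF = lf, HF = hf,
       LF_HF = if (hf > 0) lf / hf else NA_real_)
}
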