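#' EMD sifting configuration
#'
#' @param sift_threshold Cauchy-type stopping statistic
#'   `D = sum((b_prev - b)^2) / sum(b_prev^2)`; sifting of one IMF stops
#'   when `D < sift_threshold`.
#' @param max_siftings Hard cap on sifting iterations per IMF.
#' @param max_imfs Hard cap on extracted IMFs.
#' @param boundary Envelope boundary handling; only `"mirror"` (reflect the
#'   extrema nearest each end) is provided.
#' @return A list of class `emd_config`.
#' @export
emd_config <- function(sift_threshold = 0.2, max_siftings = 100L,
                       max_imfs = 10L, boundary = "mirror") {
  stopifnot(sift_threshold > 0, max_siftings >= 1, max_imfs >= 1)
  if (boundary != "mirror") stop("only mirror boundary handling is provided")
  structure(list(sift_threshold = sift_threshold,
                 max_siftings = as.integer(max_siftings),
                 max_imfs = as.integer(max_imfs), boundary = boundary),
            class = "emd_config")
}

#' EEMD configuration
#'
#' @param noise_ratio SD of the added white Gaussian noise as a fraction of
#'   the signal SD.
#' @param ensemble_size Number of noise-perturbed EMD trials averaged.
#' @param seed Integer seed making the ensemble reproducible.
#' @param emd An [emd_config()].
#' @return A list of class `eemd_config`.
#' @export
eemd_config <- function(noise_ratio = 0.2, ensemble_size = 100L, seed = 1L,
                        emd = emd_config()) {
  stopifnot(noise_ratio >= 0, ensemble_size >= 1)
  structure(list(noise_ratio = noise_ratio,
                 ensemble_size = as.integer(ensemble_size),
                 seed = as.integer(seed), emd = emd),
            class = "eemd_config")
}

# Strict local maxima indices; plateaus contribute their first sample.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  # carry the previous non-zero slope through flats so plateau edges count once
  s <- sign(d)
  for (i in seq_along(s)) if (s[i] == 0 && i > 1L) s[i] <- s[i - 1L]
  which(s[-length(s)] > 0 & s[-1L] < 0) + 1L
}

local_minima <- function(x) local_maxima(-x)

# Cubic-spline envelope through extrema, mirrored at both ends.
spline_envelope <- function(x, idx) {
  n <- length(x)
  k <- length(idx)
  ti <- idx; vi <- x[idx]
  # mirror up to two extrema about each endpoint
  nl <- min(2L, k)
  tl <- 2 * 1 - ti[seq_len(nl)]
  vl <- vi[seq_len(nl)]
  tr <- 2 * n - ti[k - seq_len(nl) + 1L]
  vr <- vi[k - seq_len(nl) + 1L]
  tt <- c(rev(tl), ti, rev(tr))
  vv <- c(rev(vl), vi, rev(vr))
  keep <- !duplicated(tt)
  stats::splinefun(tt[keep], vv[keep], method = "fmm")(seq_len(n))
}

#' Empirical mode decomposition
#'
#' Iterative sifting: upper/lower cubic-spline envelopes through the local
#' maxima/minima (mirror-extended at the ends), subtraction of the envelope
#' mean, stopping one IMF when the relative squared change between
#' consecutive sifts falls below `sift_threshold`. Extraction stops when
#' the residue has fewer than two extrema or `max_imfs` is reached.
#'
#' @param x Numeric vector (length >= 8, all finite).
#' @param cfg An [emd_config()].
#' @return A list of class `imf_set`: `imfs` (list of components, input
#'   length each), `residue`, `source = "emd"`.
#' @export
emd <- function(x, cfg = emd_config()) {
  x <- as.numeric(x)
  if (length(x) < 8L) stop("signal too short for EMD (need >= 8 samples)")
  if (!all(is.finite(x))) stop("signal must be finite")
  r <- x
  imfs <- list()
  while (length(imfs) < cfg$max_imfs) {
    mx <- local_maxima(r); mn <- local_minima(r)
    if (length(mx) + length(mn) < 2L || length(mx) < 1L || length(mn) < 1L)
      break
    b_prev <- r
    for (it in seq_len(cfg$max_siftings)) {
      emax <- spline_envelope(b_prev, local_maxima(b_prev))
      emin <- spline_envelope(b_prev, local_minima(b_prev))
      b <- b_prev - (emax + emin) / 2
      denom <- sum(b_prev^2)
      D <- if (denom > 0) sum((b_prev - b)^2) / denom else 0
      b_prev <- b
      if (D < cfg$sift_threshold) break
      if (length(local_maxima(b_prev)) < 1L || length(local_minima(b_prev)) < 1L)
        break
    }
    imfs[[length(imfs) + 1L]] <- b_prev
    r <- r - b_prev
  }
  structure(list(imfs = imfs, residue = r, source = "emd"), class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs + residue (%s), length %d\n",
              length(x$imfs), x$source,
              if (length(x$imfs)) length(x$imfs[[1]]) else length(x$residue)))
  invisible(x)
}

#' Ensemble empirical mode decomposition
#'
#' `ensemble_size` EMD trials on copies of the signal perturbed with
#' zero-mean white Gaussian noise of SD `noise_ratio * sd(x)`; the k-th
#' IMFs are averaged across trials (trials yielding fewer IMFs contribute
#' zeros, the divisor staying at the ensemble size). The residue is
#' recomputed as input minus the summed averaged IMFs, preserving
#' completeness. Fully reproducible for a fixed seed.
#'
#' @param x Numeric vector (length >= 8, all finite).
#' @param cfg An [eemd_config()].
#' @return An `imf_set` with `source = "eemd"`.
#' @export
eemd <- function(x, cfg = eemd_config()) {
  x <- as.numeric(x)
  if (length(x) < 8L) stop("signal too short for EMD (need >= 8 samples)")
  if (!all(is.finite(x))) stop("signal must be finite")
  L <- cfg$ensemble_size
  sdx <- stats::sd(x)
  if (cfg$noise_ratio == 0 && L == 1L) {
    dec <- emd(x, cfg$emd)
    dec$source <- "eemd"
    return(dec)
  }
  n <- length(x)
  acc <- NULL
  with_seed(cfg$seed, {
    for (i in seq_len(L)) {
      noise <- stats::rnorm(n, 0, cfg$noise_ratio * sdx)
      dec <- emd(x + noise, cfg$emd)
      k <- length(dec$imfs)
      if (is.null(acc)) acc <- matrix(0, n, 0)
      if (k > ncol(acc)) acc <- cbind(acc, matrix(0, n, k - ncol(acc)))
      for (j in seq_len(k)) acc[, j] <- acc[, j] + dec$imfs[[j]]
    }
  })
  avg <- acc / L
  imfs <- lapply(seq_len(ncol(avg)), function(j) avg[, j])
  residue <- x
  for (im in imfs) residue <- residue - im
  structure(list(imfs = imfs, residue = residue, source = "eemd"),
            class = "imf_set")
}

#' Keep the first k IMFs
#'
#' If fewer than `k` IMFs are available the missing slots are flagged so
#' downstream feature extraction can emit zero features with a warning
#' instead of dropping the segment.
#'
#' @param decomp An `imf_set`.
#' @param k Number of IMFs wanted (>= 1).
#' @return An `imf_set` with at most `k` IMFs and attribute
#'   `missing_slots` (integer, how many slots could not be filled).
#' @export
first_k_imfs <- function(decomp, k) {
  stopifnot(inherits(decomp, "imf_set"), k >= 1)
  avail <- length(decomp$imfs)
  keep <- min(k, avail)
  out <- decomp
  out$imfs <- decomp$imfs[seq_len(keep)]
  attr(out, "missing_slots") <- as.integer(max(0L, k - avail))
  out
}

#' Write an IMF set to a wide CSV (one column per IMF plus residue)
#' @param decomp An `imf_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_imf_set <- function(decomp, path) {
  stopifnot(inherits(decomp, "imf_set"))
  df <- as.data.frame(decomp$imfs)
  names(df) <- paste0("IMF", seq_along(decomp$imfs))
  df$residue <- decomp$residue
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
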