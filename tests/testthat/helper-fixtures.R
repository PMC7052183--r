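# Shared fixtures, generated in code at test time.

two_tone <- function(n = 512) {
  t <- 0:(n - 1)
  list(fast = sin(2 * pi * 0.2 * t), slow = sin(2 * pi * 0.02 * t),
       signal = sin(2 * pi * 0.2 * t) + sin(2 * pi * 0.02 * t))
}

# iid RR-like fixture on the seconds scale used by the entropy stage.
rr_iid <- function(n) 0.8 + 0.05 * rnorm(n)

# Matching surviving intervals back to original indices (order-preserving
# exact-value subsequence alignment); returns the removed original indices.
removed_indices <- function(original, surviving) {
  j <- 1L
  removed <- integer(0)
  for (i in seq_along(original)) {
    if (j <= length(surviving) && original[i] == surviving[j]) j <- j + 1L
    else removed <- c(removed, i)
  }
  removed
}

# Small two-class feature table with `n_inf` informative features out of
# `n_feat`; the rest are pure noise.
toy_feature_table <- function(n_a = 20, n_b = 20, n_feat = 27, n_inf = 3,
                              sep = 3, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm((n_a + n_b) * n_feat), n_a + n_b, n_feat)
    X[(n_a + 1):(n_a + n_b), seq_len(n_inf)] <-
      X[(n_a + 1):(n_a + n_b), seq_len(n_inf)] + sep
    colnames(X) <- hrv_feature_names[seq_len(n_feat)]
    feature_table(as.data.frame(X),
                  c(rep("normal", n_a), rep("scd", n_b)),
                  feature_names = colnames(X))
  })
}
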