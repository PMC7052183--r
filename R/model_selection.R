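#' Two-sample pooled t-test p-value
#'
#' Two-sided Student t-test with pooled variance. When both classes have
#' zero variance the p-value is defined as 1 for equal means and 0
#' otherwise.
#'
#' @param x,y Numeric vectors (>= 2 values each).
#' @return p-value in `[0, 1]`.
#' @export
feature_pvalue <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("need at least 2 values per class")
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  dm <- mean(x) - mean(y)
  if (sp2 == 0) return(if (dm == 0) 1 else 0)
  t <- dm / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * stats::pt(-abs(t), df = nx + ny - 2)
}

# |t| statistic used by the t-test ranking criterion; finite by convention.
feature_tstat <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  dm <- mean(x) - mean(y)
  if (sp2 == 0) return(if (dm == 0) 0 else .Machine$double.xmax)
  abs(dm / sqrt(sp2 * (1 / nx + 1 / ny)))
}

#' ROC area under the curve
#'
#' Rank-statistic AUC (ties counted half): the probability that a value
#' from `pos` exceeds one from `neg`. With SCD as the positive class an
#' AUC of 1 means complete separation. `feature_auc(x, y) +
#' feature_auc(y, x) = 1` exactly.
#'
#' @param pos Values of the positive (SCD) class.
#' @param neg Values of the negative (normal) class.
#' @return AUC in `[0, 1]`.
#' @export
feature_auc <- function(pos, neg) {
  np <- length(pos); nn <- length(neg)
  if (np < 1L || nn < 1L) stop("need at least 1 value per class")
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

# Standardised Wilcoxon rank-sum z with tie correction.
wilcoxon_z <- function(x, y) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y), ties.method = "average")
  W <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  ties <- table(r)
  sig2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sig2 <= 0) return(0)
  (W - mu) / sqrt(sig2)
}

# Symmetric Kullback-Leibler divergence between per-class Gaussian fits.
gaussian_kl_sym <- function(x, y) {
  eps <- .Machine$double.eps
  v1 <- max(stats::var(x), eps); v2 <- max(stats::var(y), eps)
  dm2 <- (mean(x) - mean(y))^2
  (v1 + dm2) / (2 * v2) + (v2 + dm2) / (2 * v1) - 1
}

# Bhattacharyya distance between per-class Gaussian fits.
gaussian_bhattacharyya <- function(x, y) {
  eps <- .Machine$double.eps
  v1 <- max(stats::var(x), eps); v2 <- max(stats::var(y), eps)
  (mean(x) - mean(y))^2 / (4 * (v1 + v2)) + 0.5 * log((v1 + v2) / (2 * sqrt(v1 * v2)))
}

#' Rank features by class-separation criterion
#'
#' Criteria: `ttest` — absolute pooled t statistic; `roc` — `|AUC - 0.5|`;
#' `wilcoxon` — absolute standardised rank-sum z; `entropy` — symmetric
#' Kullback-Leibler divergence between per-class Gaussian fits;
#' `bhattacharyya` — Gaussian Bhattacharyya distance. Features are sorted
#' by decreasing score; ties keep the original column order.
#'
#' @param table A [feature_table()] with both classes present.
#' @param method One of `"ttest"`, `"entropy"`, `"roc"`, `"wilcoxon"`,
#'   `"bhattacharyya"`.
#' @param positive Label of the positive (SCD) class; default the
#'   lexicographically later label, which makes `"scd"` positive against
#'   `"normal"`.
#' @return A list of class `ranking_result`: `method`, `order` (feature
#'   indices, best first), `scores` (per feature, original order).
#' @export
rank_features <- function(table, method = c("ttest", "entropy", "roc",
                                            "wilcoxon", "bhattacharyya"),
                          positive = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(table, "feature_table"))
  fn <- attr(table, "feature_names")
  labs <- table$label
  classes <- sort(unique(labs))
  if (length(classes) != 2L) stop("exactly two classes required")
  if (is.null(positive)) positive <- classes[2L]
  pos <- labs == positive
  if (sum(pos) < 2L || sum(!pos) < 2L) stop("need >= 2 rows per class")
  scores <- vapply(fn, function(f) {
    a <- table[[f]][pos]; b <- table[[f]][!pos]
    switch(method,
           ttest = feature_tstat(a, b),
           roc = abs(feature_auc(a, b) - 0.5),
           wilcoxon = abs(wilcoxon_z(a, b)),
           entropy = gaussian_kl_sym(a, b),
           bhattacharyya = gaussian_bhattacharyya(a, b))
  }, numeric(1))
  ord <- order(-scores, seq_along(scores))
  structure(list(method = method, order = ord, scores = scores,
                 feature_names = fn, positive = positive),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf("<ranking_result> method=%s  top 5: %s\n", x$method,
              paste(x$feature_names[x$order[1:min(5, length(x$order))]],
                    collapse = ", ")))
  invisible(x)
}

# Seeded stratified fold assignment: per class, shuffled indices dealt
# round-robin into `folds` folds.
stratified_folds <- function(labels, folds, seed) {
  assign <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' k-NN classification with stratified 10-fold cross-validation
#'
#' Folds are stratified by class (seeded). Within each fold the selected
#' features are z-scored with training-fold statistics and classified by
#' Euclidean k-NN majority vote; a tied vote is resolved by the single
#' nearest neighbour's class. Accuracy, sensitivity and specificity
#' (SCD positive) are averaged over folds, in percent.
#'
#' @param table A [feature_table()] with >= 20 rows.
#' @param order A `ranking_result` (or an integer permutation of feature
#'   indices).
#' @param n_features How many top-ranked features to use.
#' @param k Neighbour count (1 or 10 in the study design).
#' @param folds Number of folds.
#' @param seed Fold-assignment seed.
#' @param positive Positive-class label (default `"scd"` when present,
#'   else the later label).
#' @param standardize z-score features on training statistics (default
#'   TRUE; feature magnitudes differ by orders).
#' @return A list of class `cv_report`: `k`, `n_features`, `per_fold`
#'   (TP/TN/FP/FN per fold), `accuracy`, `sensitivity`, `specificity`
#'   (percent), `seed`.
#' @export
knn_cross_validate <- function(table, order, n_features, k = 1L,
                               folds = 10L, seed = 1L, positive = NULL,
                               standardize = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  fn <- attr(table, "feature_names")
  ord <- if (inherits(order, "ranking_result")) order$order else as.integer(order)
  stopifnot(n_features >= 1L, n_features <= length(fn))
  if (nrow(table) < 20L) stop("need at least 20 rows")
  labs <- table$label
  classes <- sort(unique(labs))
  if (length(classes) != 2L) stop("exactly two classes required")
  if (is.null(positive))
    positive <- if ("scd" %in% classes) "scd" else classes[2L]
  X <- as.matrix(as.data.frame(table)[, fn[ord[seq_len(n_features)]], drop = FALSE])
  fold_of <- stratified_folds(labs, folds, seed)
  per_fold <- data.frame(fold = seq_len(folds), TP = 0L, TN = 0L,
                         FP = 0L, FN = 0L)
  for (f in seq_len(folds)) {
    tr <- fold_of != f; te <- !tr
    if (length(unique(labs[tr])) < 2L) stop("class absent from training fold ", f)
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(Xtr)
      sg <- apply(Xtr, 2L, stats::sd)
      sg[sg == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2L, mu), 2L, sg, "/")
      Xte <- sweep(sweep(Xte, 2L, mu), 2L, sg, "/")
    }
    ytr <- labs[tr]
    kk <- min(k, nrow(Xtr))
    pred <- apply(Xte, 1L, function(row) {
      d2 <- colSums((t(Xtr) - row)^2)
      nb <- order(d2)[seq_len(kk)]
      votes <- table(ytr[nb])
      win <- names(votes)[votes == max(votes)]
      if (length(win) > 1L) ytr[nb[1L]] else win
    })
    yte <- labs[te]
    per_fold$TP[f] <- sum(pred == positive & yte == positive)
    per_fold$TN[f] <- sum(pred != positive & yte != positive)
    per_fold$FP[f] <- sum(pred == positive & yte != positive)
    per_fold$FN[f] <- sum(pred != positive & yte == positive)
  }
  acc <- with(per_fold, (TP + TN) / (TP + TN + FP + FN))
  sens <- with(per_fold, ifelse(TP + FN > 0, TP / (TP + FN), NA_real_))
  spec <- with(per_fold, ifelse(TN + FP > 0, TN / (TN + FP), NA_real_))
  structure(list(k = k, n_features = n_features, per_fold = per_fold,
                 accuracy = 100 * mean(acc),
                 sensitivity = 100 * mean(sens, na.rm = TRUE),
                 specificity = 100 * mean(spec, na.rm = TRUE),
                 positive = positive, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> k=%d  n_features=%d  acc=%.1f%%  sens=%.1f%%  spec=%.1f%%\n",
              x$k, x$n_features, x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

#' Incremental-feature accuracy sweep
#'
#' Feeds the ranked features one by one into k-NN classifiers and records
#' the cross-validated accuracy curve per `k`, plus the best setting
#' (ties resolved towards fewer features, then smaller `k`).
#'
#' @param table A [feature_table()].
#' @param order A `ranking_result` or index permutation.
#' @param k_values Neighbour counts to sweep (default `c(1, 10)`).
#' @param max_features Upper end of the feature-count sweep (default all).
#' @param folds,seed,positive Passed to [knn_cross_validate()].
#' @return List of class `incremental_sweep`: `curves` (data frame `k`,
#'   `n_features`, `accuracy`, `sensitivity`, `specificity`) and `best`
#'   (the winning `cv_report`).
#' @export
incremental_sweep <- function(table, order, k_values = c(1L, 10L),
                              max_features = NULL, folds = 10L, seed = 1L,
                              positive = NULL) {
  fn <- attr(table, "feature_names")
  if (is.null(max_features)) max_features <- length(fn)
  rows <- list()
  reports <- list()
  for (k in k_values) {
    for (n in seq_len(max_features)) {
      rep <- knn_cross_validate(table, order, n_features = n, k = k,
                                folds = folds, seed = seed,
                                positive = positive)
      rows[[length(rows) + 1L]] <- data.frame(
        k = k, n_features = n, accuracy = rep$accuracy,
        sensitivity = rep$sensitivity, specificity = rep$specificity)
      reports[[length(reports) + 1L]] <- rep
    }
  }
  curves <- do.call(rbind, rows)
  best_i <- order(-curves$accuracy, curves$n_features, curves$k)[1L]
  structure(list(curves = curves, best = reports[[best_i]]),
            class = "incremental_sweep")
}

#' @export
print.incremental_sweep <- function(x, ...) {
  cat(sprintf("<incremental_sweep> %d settings; best: k=%d, n=%d, acc=%.1f%%\n",
              nrow(x$curves), x$best$k, x$best$n_features, x$best$accuracy))
  invisible(x)
}
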