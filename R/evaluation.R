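# Agreement and diagnostic-accuracy statistics: squared errors, Spearman
# correlation, Bland-Altman with fixed/proportional bias tests, Friedman +
# Holm, rank tests, ROC/AUC with the DeLong comparison, and
# lower-limit-of-normal screening rates.

#' Per-observation squared errors for one or more estimators
#'
#' @param measured measured vital capacities (L).
#' @param estimates named list (or data.frame) of estimate vectors, each
#'   the same length as `measured`.
#' @return a list with `errors` (long data.frame: `method`, `observation`,
#'   `squared_error`) and `summary` (per-method mean and median squared
#'   error, in L^2).
#' @export
squared_error_table <- function(measured, estimates) {
  if (is.data.frame(estimates)) estimates <- as.list(estimates)
  stopifnot(is.list(estimates), length(estimates) >= 1,
            !is.null(names(estimates)))
  n <- length(measured)
  for (nm in names(estimates))
    if (length(estimates[[nm]]) != n)
      stop("length mismatch for method '", nm, "'")
  long <- do.call(rbind, lapply(names(estimates), function(nm) {
    data.frame(method = nm, observation = seq_len(n),
               squared_error = (estimates[[nm]] - measured)^2,
               stringsAsFactors = FALSE)
  }))
  summ <- do.call(rbind, lapply(names(estimates), function(nm) {
    se <- (estimates[[nm]] - measured)^2
    data.frame(method = nm, mean_se = mean(se), median_se = median(se),
               stringsAsFactors = FALSE)
  }))
  list(errors = long, summary = summ)
}

midrank <- function(x) rank(x, ties.method = "average")

# all permutations of 1..n (n <= 8)
perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  p <- perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    q <- p + (p >= k)
    cbind(rep(k, nrow(q)), q)
  }))
}

#' Spearman rank correlation with tie-aware p-value
#'
#' Midranks handle ties; the p-value comes from the exact permutation
#' distribution for n <= 8 and the t-approximation
#' `t = rho sqrt((n-2)/(1-rho^2))` otherwise.
#'
#' @param x,y numeric vectors of equal length, n >= 3, neither constant.
#' @return list with `rho`, `p`, `n`, `method`.
#' @export
spearman <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  if (sd(x) == 0 || sd(y) == 0)
    stop("Spearman correlation undefined for a constant vector")
  rx <- midrank(x); ry <- midrank(y)
  rho <- cor(rx, ry)
  if (n <= 8) {
    pm <- perms(n)
    rhos <- apply(pm, 1, function(idx) cor(rx, ry[idx]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-300))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

#' Bland-Altman agreement analysis
#'
#' Differences are `measured - estimated` (orientation recorded in the
#' output); means are `(measured + estimated)/2`. Limits of agreement are
#' `mean_diff +/- k * sd_diff` with k = 2 by default (the 2-SD
#' convention). Fixed bias is the one-sample t test of the differences
#' against zero; proportional bias is the Pearson correlation of
#' differences against means.
#'
#' @param measured,estimated numeric vectors, n >= 3.
#' @param limit_k multiplier for the limits of agreement (default 2).
#' @return an object of class `coughvc_bland_altman`.
#' @export
bland_altman <- function(measured, estimated, limit_k = 2) {
  n <- length(measured)
  stopifnot(length(estimated) == n, n >= 3)
  d <- measured - estimated
  m <- (measured + estimated) / 2
  md <- mean(d); sdd <- sd(d)
  if (sdd > 0) {
    tstat <- md / (sdd / sqrt(n))
    t_p <- 2 * pt(-abs(tstat), df = n - 1)
  } else {
    tstat <- NA_real_; t_p <- NA_real_
  }
  if (sdd > 0 && sd(m) > 0) {
    r <- cor(d, m)
    rt <- r * sqrt((n - 2) / max(1 - r^2, 1e-300))
    r_p <- 2 * pt(-abs(rt), df = n - 2)
  } else {
    r <- NA_real_; r_p <- NA_real_
  }
  structure(list(mean_diff = md, sd_diff = sdd,
                 limits = c(lower = md - limit_k * sdd,
                            upper = md + limit_k * sdd),
                 limit_k = limit_k,
                 fixed_bias_t = list(statistic = tstat, p = t_p, df = n - 1),
                 proportional_bias_r = list(r = r, p = r_p),
                 orientation = "measured - estimated",
                 diffs = d, means = m, n = n),
            class = "coughvc_bland_altman")
}

#' @export
print.coughvc_bland_altman <- function(x, ...) {
  cat(sprintf("<Bland-Altman (%s): mean diff %.4f, LoA [%.4f, %.4f] (+/- %g SD)>\n",
              x$orientation, x$mean_diff, x$limits[1], x$limits[2],
              x$limit_k))
  invisible(x)
}

#' Friedman rank test across k related methods
#'
#' Midranks within each subject row; the tie-corrected statistic
#' `chi2 = (k-1) * sum_j (R_j - n(k+1)/2)^2 / (sum_ij r_ij^2 - n k (k+1)^2 / 4)`
#' is referred to a chi-square with k-1 degrees of freedom. Reduces to the
#' classical `12/(nk(k+1)) sum R_j^2 - 3n(k+1)` without ties.
#'
#' @param mat n subjects x k methods numeric matrix (k >= 3, n >= 2).
#' @return list with `statistic`, `p`, `df`, `rank_sums`.
#' @export
friedman <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (k < 3) stop("Friedman test needs k >= 3 methods; use a paired test")
  stopifnot(n >= 2)
  r <- t(apply(mat, 1, midrank))
  Rj <- colSums(r)
  num <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2)
  den <- sum(r^2) - n * k * (k + 1)^2 / 4
  stat <- if (den == 0) 0 else num / den
  list(statistic = stat, p = pchisq(stat, df = k - 1, lower.tail = FALSE),
       df = k - 1, rank_sums = Rj)
}

#' Holm step-down multiplicity adjustment
#'
#' Sorts p-values ascending, multiplies the i-th by `m - i + 1`, enforces
#' monotone non-decrease, caps at 1, and returns values in input order.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1 | !is.finite(p))) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax(p[o] * (m - seq_len(m) + 1)))
  out <- numeric(m)
  out[o] <- adj
  out
}

two_sided_from_counts <- function(p_le, p_ge) min(1, 2 * min(p_le, p_ge))

#' Wilcoxon signed-rank test (paired)
#'
#' Zero differences are dropped (documented convention). For n <= 12
#' non-zero pairs the p-value is exact, by enumerating all 2^n sign
#' assignments over the midranks of |d| (so ties are handled exactly);
#' otherwise a normal approximation with tie and continuity correction is
#' used.
#'
#' @param x,y paired numeric vectors of equal length.
#' @return list with `statistic` (V, the positive-rank sum), `p`,
#'   `n_used`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all pairs tied: signed-rank test undefined")
  r <- midrank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 12) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vall <- as.vector(signs %*% r)
    p <- two_sided_from_counts(mean(vall <= v + 1e-12),
                               mean(vall >= v - 1e-12))
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = v, p = p, n_used = n, method = method)
}

#' Mann-Whitney U test (unpaired)
#'
#' For group sizes both <= 8 the p-value is exact, by enumerating all
#' group assignments over the pooled midranks (ties handled exactly);
#' otherwise a normal approximation with tie and continuity correction is
#' used.
#'
#' @param x,y numeric samples.
#' @return list with `statistic` (U for `x`), `p`, `method`.
#' @export
mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- midrank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= 8 && n2 <= 8) {
    combos <- utils::combn(n1 + n2, n1)
    uall <- apply(combos, 2, function(idx) sum(r[idx])) -
      n1 * (n1 + 1) / 2
    p <- two_sided_from_counts(mean(uall <= u + 1e-12),
                               mean(uall >= u - 1e-12))
    method <- "exact enumeration"
  } else {
    mu <- n1 * n2 / 2
    nn <- n1 + n2
    tie_tab <- table(r)
    sig2 <- n1 * n2 / 12 *
      (nn + 1 - sum(tie_tab^3 - tie_tab) / (nn * (nn - 1)))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = u, p = p, method = method)
}

#' ROC curve and AUC for abnormality screening
#'
#' AUC is the Mann-Whitney probability: over all positive-negative pairs,
#' the fraction where the positive scores higher, ties counted 1/2.
#' For vital-capacity screening the score convention is
#' `lln - estimate` (higher = more abnormal; threshold 0 reproduces the
#' "estimate below LLN" decision rule) and the positive label is
#' `measured < lln`; see [screening_roc()].
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels logical (or 0/1) true class labels; both classes present.
#' @return an object of class `coughvc_roc` with `auc`, `thresholds`,
#'   `tpr`, `fpr`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present to compute a ROC curve")
  r <- midrank(scores)
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1))
  structure(list(auc = auc, thresholds = thr, tpr = tpr, fpr = fpr,
                 n_pos = n_pos, n_neg = n_neg,
                 score_convention = "higher score = more abnormal"),
            class = "coughvc_roc")
}

#' @export
print.coughvc_roc <- function(x, ...) {
  cat(sprintf("<ROC: AUC %.3f (%d positive / %d negative)>\n", x$auc,
              x$n_pos, x$n_neg))
  invisible(x)
}

delong_components <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  v10 <- vapply(pos, function(s) mean((s > neg) + 0.5 * (s == neg)),
                numeric(1))
  v01 <- vapply(neg, function(s) mean((pos > s) + 0.5 * (pos == s)),
                numeric(1))
  list(auc = mean(v10), v10 = v10, v01 = v01)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two scores measured on the same subjects using the
#' placement-value covariance estimator; the AUC difference is referred to
#' a standard normal.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels common true labels; both classes present.
#' @return list with `auc_a`, `auc_b`, `auc_diff`, `var_diff`, `z`, `p`
#'   (two-sided) and `degenerate` (TRUE when the difference has zero
#'   variance, in which case p = 1).
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores_a) == length(scores_b),
            length(labels) == length(scores_a))
  if (sum(labels) == 0 || sum(!labels) == 0)
    stop("both classes must be present")
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  m <- sum(labels); n <- sum(!labels)
  s10 <- stats::var(ca$v10 - cb$v10)
  s01 <- stats::var(ca$v01 - cb$v01)
  var_diff <- s10 / m + s01 / n
  diff <- ca$auc - cb$auc
  if (var_diff <= 0) {
    return(list(auc_a = ca$auc, auc_b = cb$auc, auc_diff = diff,
                var_diff = 0, z = NA_real_, p = 1, degenerate = TRUE))
  }
  z <- diff / sqrt(var_diff)
  list(auc_a = ca$auc, auc_b = cb$auc, auc_diff = diff,
       var_diff = var_diff, z = z, p = 2 * pnorm(-abs(z)),
       degenerate = FALSE)
}

#' Screening confusion rates at the lower limit of normal
#'
#' Predicted positive means estimate < LLN; true positive means measured
#' VC < LLN. `TPR + FNR = 1` and `FPR + TNR = 1` by construction.
#'
#' @param estimates estimated vital capacities (L).
#' @param measured measured vital capacities (L).
#' @param lln_values per-subject lower limits of normal (L).
#' @return list with `tpr`, `fnr`, `fpr`, `tnr` and the counts.
#' @export
screening_confusion <- function(estimates, measured, lln_values) {
  n <- length(measured)
  stopifnot(length(estimates) == n, length(lln_values) == n)
  truth <- measured < lln_values
  pred <- estimates < lln_values
  if (sum(truth) == 0) stop("no positive-class (below-LLN) subjects")
  tp <- sum(pred & truth); fn <- sum(!pred & truth)
  fp <- sum(pred & !truth); tn <- sum(!pred & !truth)
  list(tpr = tp / (tp + fn), fnr = fn / (tp + fn),
       fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
       tnr = if (fp + tn > 0) tn / (fp + tn) else NA_real_,
       counts = c(tp = tp, fn = fn, fp = fp, tn = tn))
}

#' ROC for vital-capacity screening from estimates and LLN
#'
#' Convenience wrapper applying the package's screening score convention
#' (`score = lln - estimate`, positive = `measured < lln`) to [roc_auc()].
#'
#' @inheritParams screening_confusion
#' @return a `coughvc_roc`.
#' @export
screening_roc <- function(estimates, measured, lln_values) {
  roc_auc(lln_values - estimates, measured < lln_values)
}

#' Partial correlation of two variables controlling for others
#'
#' Pearson correlation of the residuals of `x` and `y` after linear
#' regression on the control variables, with the t-approximation p-value
#' at n - k - 2 degrees of freedom. Provided for pipeline parity with the
#' variable-selection step; its values on synthetic cohorts are
#' generator-specific.
#'
#' @param x,y numeric vectors.
#' @param controls data.frame/matrix of control variables (may be empty).
#' @return list with `r`, `p`, `df`.
#' @export
partial_correlation <- function(x, y, controls = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(controls) || NCOL(controls) == 0) {
    rx <- x; ry <- y; k <- 0
  } else {
    Z <- as.matrix(controls)
    k <- ncol(Z)
    rx <- residuals(lm(x ~ Z))
    ry <- residuals(lm(y ~ Z))
  }
  r <- cor(rx, ry)
  df <- n - k - 2
  tstat <- r * sqrt(df / max(1 - r^2, 1e-300))
  list(r = r, p = 2 * pt(-abs(tstat), df = df), df = df)
}
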