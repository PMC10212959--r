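test_that("squared error table matches hand arithmetic", {
  r <- squared_error_table(c(4, 3), list(m = c(3, 5)))
  expect_equal(r$errors$squared_error, c(1, 4))
  expect_equal(r$summary$mean_se, 2.5)
  expect_equal(r$summary$median_se, 2.5)
  r0 <- squared_error_table(1:5, list(id = 1:5))
  expect_true(all(r0$errors$squared_error == 0))
  # brute-force check of the constant-shift pattern
  set.seed(1)
  meas <- rnorm(7); est <- rnorm(7); cshift <- 0.3
  r1 <- squared_error_table(meas, list(a = est, b = est + cshift))
  expect_equal(r1$errors$squared_error[r1$errors$method == "b"],
               ((est - meas) + cshift)^2)
  expect_error(squared_error_table(1:3, list(a = 1:4)), "length mismatch")
})

test_that("Spearman: exact small-n p matches exhaustive enumeration", {
  expect_equal(spearman(1:5, c(2, 4, 6, 7, 9))$rho, 1)
  expect_equal(spearman(1:5, 5:1)$rho, -1)
  set.seed(2)
  x <- rnorm(6); y <- rnorm(6)
  s <- spearman(x, y)
  rx <- rank(x); ry <- rank(y)
  rhos <- vapply(all_perms(6), function(p) cor(rx, ry[p]), numeric(1))
  expect_equal(s$p, mean(abs(rhos) >= abs(s$rho) - 1e-12))
  # t-approximation branch agrees with the closed form
  set.seed(3)
  x <- rnorm(20); y <- x + rnorm(20)
  s2 <- spearman(x, y)
  tstat <- s2$rho * sqrt((20 - 2) / (1 - s2$rho^2))
  expect_equal(s2$p, 2 * pt(-abs(tstat), 18), tolerance = 1e-12)
  expect_error(spearman(rep(1, 5), rnorm(5)), "constant")
})

test_that("Bland-Altman statistics and conventions", {
  x <- c(3.1, 4.0, 2.5, 3.8, 4.4, 2.9, 3.3, 4.1, 3.6, 2.7)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(unname(ba0$limits), c(0, 0))
  expect_true(is.na(ba0$proportional_bias_r$r))
  set.seed(4)
  est <- x + rnorm(10, 0.2, 0.15)
  ba <- bland_altman(x, est)
  d <- x - est
  expect_equal(ba$mean_diff, mean(d))
  # limits are mean +/- 2 SD exactly (the 2-SD convention, not 1.96)
  expect_equal(unname(ba$limits), mean(d) + c(-2, 2) * sd(d),
               tolerance = 1e-12)
  expect_equal(ba$fixed_bias_t$statistic, mean(d) / (sd(d) / sqrt(10)),
               tolerance = 1e-12)
  expect_equal(ba$fixed_bias_t$p, t.test(d)$p.value, tolerance = 1e-12)
  expect_equal(ba$proportional_bias_r$r, cor(d, (x + est) / 2),
               tolerance = 1e-12)
  # perfect proportional bias
  meas <- seq(2, 5, length.out = 8)
  bap <- bland_altman(meas, meas * 0.5)
  expect_equal(abs(bap$proportional_bias_r$r), 1, tolerance = 1e-12)
})

test_that("Friedman statistic: fixture, invariances, oracle", {
  mat <- rbind(c(1, 2, 3), c(10, 20, 30), c(0.1, 0.2, 0.3))
  fr <- friedman(mat)
  expect_equal(fr$statistic, 6.0)
  expect_equal(fr$p, pchisq(6, 2, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(friedman(mat[, c(3, 1, 2)])$statistic, 6.0)
  expect_equal(friedman(matrix(5, 4, 3))$statistic, 0)
  expect_error(friedman(matrix(1, 3, 2)), "paired")
  set.seed(5)
  m2 <- matrix(rnorm(10 * 4), 10, 4)   # continuous: tie-free
  expect_equal(friedman(m2)$statistic,
               unname(stats::friedman.test(m2)$statistic),
               tolerance = 1e-12)
})

test_that("Holm adjustment: fixture, order, dominance", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(0.2, 3)), rep(0.6, 3))
  set.seed(6)
  for (i in 1:10) {
    p <- runif(sample(2:6, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, p.adjust(p, "holm"), tolerance = 1e-12)
    expect_true(all(adj >= p))
  }
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("signed-rank test: exact enumeration and edge rules", {
  y <- c(2.0, 3.1, 1.4, 4.2, 2.8, 3.6)
  w <- wilcoxon_signed_rank(y + 1, y)
  expect_equal(w$p, 2 / 2^6)   # uniform shift: smallest attainable p
  # oracle: enumerate all sign assignments of the ranked |d|
  set.seed(7)
  x2 <- rnorm(8); y2 <- x2 + rnorm(8)
  w2 <- wilcoxon_signed_rank(x2, y2)
  d <- x2 - y2; r <- rank(abs(d))
  vobs <- sum(r[d > 0])
  n <- 8
  signs <- as.matrix(expand.grid(rep(list(0:1), n)))
  vall <- signs %*% r
  p_exact <- mean(pmin(2 * pmin(mean(vall <= vobs), mean(vall >= vobs)), 1))
  expect_equal(w2$p, p_exact, tolerance = 1e-12)
  expect_error(wilcoxon_signed_rank(y, y), "tied")
  # symmetry: swapping arguments mirrors the statistic
  ws <- wilcoxon_signed_rank(y2, x2)
  expect_equal(ws$statistic, sum(r) - w2$statistic)
})

test_that("Mann-Whitney: exact enumeration oracle and symmetry", {
  set.seed(8)
  x <- rnorm(5); y <- rnorm(6) + 0.5
  mw <- mann_whitney(x, y)
  # oracle: U distribution by enumerating all group assignments
  pooled <- c(x, y); r <- rank(pooled)
  uobs <- sum(r[1:5]) - 5 * 6 / 2
  combos <- combn(11, 5)
  uall <- apply(combos, 2, function(idx) sum(r[idx]) - 15)
  p_exact <- min(1, 2 * min(mean(uall <= uobs), mean(uall >= uobs)))
  expect_equal(mw$p, p_exact, tolerance = 1e-12)
  mw2 <- mann_whitney(y, x)
  expect_equal(mw2$statistic, 5 * 6 - mw$statistic)
  expect_equal(mw2$p, mw$p, tolerance = 1e-12)
})

test_that("AUC equals brute-force pair counting (property)", {
  expect_equal(roc_auc(c(5, 4, 1, 2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(c(0.9, 0.2, 0.8, 0.1), c(1, 1, 0, 0))$auc, 0.75)
  expect_equal(roc_auc(rep(1, 6), c(1, 1, 0, 0, 0, 1))$auc, 0.5)
  set.seed(9)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    labels <- c(1, 0, sample(0:1, n - 2, TRUE))
    scores <- sample(seq(0, 1, 0.1), n, TRUE)   # forces ties
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, auc_brute(scores, labels), tolerance = 1e-12)
    expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("DeLong test: degeneracy, antisymmetry, jackknife oracle", {
  lab <- c(rep(TRUE, 4), rep(FALSE, 6))
  s <- rnorm(10)
  dg <- delong_test(s, s, lab)
  expect_true(dg$degenerate)
  expect_equal(dg$p, 1)
  expect_equal(dg$auc_diff, 0)
  set.seed(10)
  sa <- rnorm(10); sb <- sa + rnorm(10, 0, 0.5)
  dl <- delong_test(sa, sb, lab)
  expect_equal(dl$auc_a, roc_auc(sa, lab)$auc, tolerance = 1e-12)
  expect_equal(dl$auc_b, roc_auc(sb, lab)$auc, tolerance = 1e-12)
  ds <- delong_test(sb, sa, lab)
  expect_equal(ds$z, -dl$z, tolerance = 1e-12)
  # delete-one jackknife variance oracle
  pos <- which(lab); neg <- which(!lab)
  jack <- function(idx) vapply(idx, function(i)
    auc_brute(sa[-i], lab[-i]) - auc_brute(sb[-i], lab[-i]), numeric(1))
  jp <- jack(pos); jn <- jack(neg)
  vjack <- (length(pos) - 1) / length(pos) * sum((jp - mean(jp))^2) +
    (length(neg) - 1) / length(neg) * sum((jn - mean(jn))^2)
  expect_lt(abs(dl$var_diff - vjack), 1e-10)
})

test_that("screening confusion rates at the LLN", {
  lln_v <- rep(3, 6)
  meas <- c(2.5, 2.8, 3.5, 3.2, 2.9, 3.8)   # 3 true positives
  expect_equal(screening_confusion(meas, meas, lln_v)$tpr, 1)
  expect_equal(screening_confusion(meas, meas, lln_v)$fpr, 0)
  expect_equal(screening_confusion(lln_v + 0.01, meas, lln_v)$tpr, 0)
  est <- c(2.7, 3.1, 2.9, 3.4, 2.6, 3.9)
  cc <- screening_confusion(est, meas, lln_v)
  # hand tally: positives are obs 1,2,5 -> predicted positive 1,5 (est<3)
  expect_equal(unname(cc$counts), c(2, 1, 1, 2))
  expect_equal(cc$tpr + cc$fnr, 1)
  expect_equal(cc$fpr + cc$tnr, 1)
  expect_error(screening_confusion(est, lln_v + 1, lln_v), "positive-class")
  # screening_roc applies the documented score convention
  r <- screening_roc(est, meas, lln_v)
  expect_equal(r$auc, auc_brute(lln_v - est, meas < lln_v),
               tolerance = 1e-12)
})

test_that("partial correlation matches the residual-regression oracle", {
  set.seed(11)
  z <- rnorm(30); x <- z + rnorm(30); y <- -z + rnorm(30)
  pc <- partial_correlation(x, y, data.frame(z = z))
  rx <- residuals(lm(x ~ z)); ry <- residuals(lm(y ~ z))
  expect_equal(pc$r, cor(rx, ry), tolerance = 1e-12)
  expect_equal(pc$df, 27)
  pc0 <- partial_correlation(x, y)
  expect_equal(pc0$r, cor(x, y), tolerance = 1e-12)
})
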