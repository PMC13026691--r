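# mortality-association stage

# the published group-level mortality counts (deaths / totals per A, B, C, D)
published_table <- function() contingency_from_counts(c(3, 4, 3, 48), c(18, 62, 128, 467))

# expand a contingency table into per-patient label/outcome vectors
expand_table <- function(tab) {
  list(labels = rep(tab$label, tab$total),
       death30 = unlist(mapply(function(d, t) c(rep(1L, d), rep(0L, t - d)),
                               tab$deaths, tab$total, SIMPLIFY = FALSE)))
}

test_that("contingency counts deaths and survivors per label", {
  tab <- published_table()
  expect_equal(sum(tab$deaths), 58L)
  expect_equal(sum(tab$total), 675L)
  ep <- expand_table(tab)
  tab2 <- contingency(ep$labels, ep$death30)
  expect_equal(as.data.frame(tab2), as.data.frame(tab))
  # unit case
  one <- contingency("D", 1L, all_labels = c("A", "B", "C", "D"))
  expect_equal(one$deaths, c(0L, 0L, 0L, 1L))
  expect_equal(attr(one, "empty_labels"), c("A", "B", "C"))
  # empty cohort: all-zero, flagged
  empty <- contingency(character(0), integer(0), all_labels = c("A", "B"))
  expect_equal(empty$total, c(0L, 0L))
  expect_equal(attr(empty, "empty_labels"), c("A", "B"))
})

test_that("chi-square tests: independence, expected-count rule, G2 oracle", {
  flat <- contingency_from_counts(c(10, 10), c(20, 20), labels = c("x", "y"))
  res <- chi2_tests(flat)
  expect_equal(res$pearson$statistic, 0)
  expect_equal(res$pearson$p, 1)
  # the published table triggers the expected-count rule: 18*58/675 ~ 1.55
  res2 <- chi2_tests(published_table())
  expect_equal(res2$min_expected, 18 * 58 / 675, tolerance = 1e-12)
  expect_true(res2$use_likelihood_ratio)
  expect_equal(res2$pearson$df, 3L)
  # G2 matches the naive direct formula on a random 2x4 table
  set.seed(42)
  for (i in 1:5) {
    d <- rbinom(4, 50, 0.3); t <- 50 + rbinom(4, 30, 0.5)
    tab <- contingency_from_counts(d, t)
    O <- cbind(tab$deaths, tab$survivors)
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    g2 <- 2 * sum(O[O > 0] * log(O[O > 0] / E[O > 0]))
    expect_equal(chi2_tests(tab)$lr$statistic, g2, tolerance = 1e-10)
  }
  # degenerate marginals are fatal
  expect_error(chi2_tests(contingency_from_counts(c(0, 0), c(10, 10), c("x", "y"))),
               "degenerate")
})

test_that("Pearson and G2 agree within 15% on well-populated tables", {
  set.seed(7)
  for (i in 1:10) {
    d <- 20 + rbinom(3, 40, 0.5); t <- d + 30 + rbinom(3, 60, 0.5)
    tab <- contingency_from_counts(d, t, labels = c("x", "y", "z"))
    res <- chi2_tests(tab)
    if (res$min_expected < 10 || res$pearson$statistic < 0.5) next
    expect_lt(abs(res$pearson$statistic - res$lr$statistic) /
                res$pearson$statistic, 0.15)
  }
})

test_that("Monte-Carlo conditional p-values are seeded and sane", {
  tab <- published_table()
  r1 <- chi2_tests(tab, mc_exact = TRUE, mc_draws = 2000, seed = 9)
  r2 <- chi2_tests(tab, mc_exact = TRUE, mc_draws = 2000, seed = 9)
  expect_identical(r1$mc, r2$mc)
  expect_true(r1$mc$p_pearson > 0 && r1$mc$p_pearson < 1)
  # MC and asymptotic agree loosely on a healthy table
  big <- contingency_from_counts(c(30, 60), c(100, 130), labels = c("x", "y"))
  rb <- chi2_tests(big, mc_exact = TRUE, mc_draws = 5000, seed = 1)
  expect_lt(abs(rb$mc$p_pearson - rb$pearson$p), 0.05)
})

test_that("odds ratios reproduce the published regression-table rows exactly", {
  ors <- odds_ratios(published_table(), reference = "C")
  rA <- ors[ors$label == "A", ]
  expect_equal(rA$log_or, 2.120, tolerance = 5e-4)
  expect_equal(rA$se, 0.861, tolerance = 5e-4)
  expect_equal(rA$or_value, 8.333, tolerance = 5e-4)
  expect_equal(rA$ci_low, 1.541, tolerance = 5e-4)
  expect_equal(rA$ci_high, 45.052, tolerance = 5e-3)
  expect_equal(round(rA$wald_p, 3), 0.014)  # printed "Sig." is rounded
  expect_equal(ors$or_value[ors$label == "B"], 2.874, tolerance = 5e-4)
  expect_equal(ors$or_value[ors$label == "D"], 4.773, tolerance = 5e-4)
  # self-comparison has OR 1
  same <- contingency_from_counts(c(3, 3), c(128, 128), labels = c("C", "X"))
  orx <- odds_ratios(same, reference = "C")
  expect_equal(orx$or_value, 1)
  expect_equal(orx$log_or, 0)
  # zero cell flagged
  zc <- contingency_from_counts(c(0, 3), c(10, 128), labels = c("Z", "C"))
  expect_true(odds_ratios(zc, reference = "C")$zero_cell)
})

test_that("logistic fit matches contingency log-ORs, the intercept, and glm", {
  ep <- expand_table(published_table())
  fit <- fit_logistic(ep$labels, ep$death30, reference = "C")
  expect_true(fit$converged)
  co <- fit$coefficients
  expect_equal(co$estimate[co$term == "(Intercept)"], log(3 / 125), tolerance = 1e-6)
  expect_equal(co$estimate[co$term == "(Intercept)"], -3.730, tolerance = 5e-4)
  expect_equal(co$se[co$term == "(Intercept)"], 0.584, tolerance = 5e-4)
  ors <- odds_ratios(published_table(), reference = "C")
  for (g in c("A", "B", "D")) {
    expect_equal(co$estimate[co$term == g], ors$log_or[ors$label == g],
                 tolerance = 1e-6)
    expect_equal(co$se[co$term == g], ors$se[ors$label == g], tolerance = 1e-4)
  }
  # independent oracle: stats::glm on the same design
  gl <- glm(ep$death30 ~ factor(ep$labels, levels = c("C", "A", "B", "D")),
            family = binomial())
  expect_equal(unname(co$estimate), unname(coef(gl)[c(1, 2, 3, 4)]), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(gl)), tolerance = 1e-6)
})

test_that("logistic edge cases: balanced intercept-only, separation flag", {
  fit <- fit_logistic(rep("C", 10), rep(c(0L, 1L), 5), reference = "C")
  expect_equal(fit$coefficients$estimate[1], 0, tolerance = 1e-8)
  # a non-reference group with all deaths triggers the separation diagnostic
  labels <- c(rep("C", 20), rep("A", 4))
  y <- c(rep(0L, 18), 1L, 1L, rep(1L, 4))
  fit2 <- fit_logistic(labels, y, reference = "C")
  expect_false(fit2$converged)
  expect_match(fit2$diagnostic, "separation")
})

test_that("ROC AUC: published value, brute-force oracle, edge cases", {
  tab <- published_table()
  ep <- expand_table(tab)
  scores <- rep(tab$mortality, tab$total)  # group-risk scores
  r <- roc_auc(scores, ep$death30)
  # brute force over all 58 x 617 pairs
  cs <- scores[ep$death30 == 1]; ns <- scores[ep$death30 == 0]
  cmp <- outer(cs, ns, `-`)
  brute <- (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / length(cmp)
  expect_equal(r$auc, brute, tolerance = 1e-12)
  expect_equal(r$auc, 21472 / 35786, tolerance = 1e-12)
  expect_equal(r$auc, 0.600, tolerance = 5e-4)
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  expect_lt(r$p_vs_half, 0.05)
  # monotone score transform leaves AUC unchanged (probabilities vs ranks)
  rank_scores <- match(ep$labels, c("C", "B", "D", "A"))
  expect_equal(roc_auc(rank_scores, ep$death30)$auc, r$auc, tolerance = 1e-12)
  # separation and all-ties
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(2, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  expect_error(roc_auc(1:4, rep(0, 4)), "both outcome classes")
})

test_that("random-instance AUC equals brute force exactly", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(20:80, 1)
    y <- rbinom(n, 1, 0.3)
    if (sum(y) == 0 || sum(y) == n) next
    sc <- sample(1:5, n, replace = TRUE)  # heavy ties
    cmp <- outer(sc[y == 1], sc[y == 0], `-`)
    brute <- (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / length(cmp)
    expect_equal(roc_auc(sc, y)$auc, brute, tolerance = 1e-12)
  }
})

test_that("roc_points runs from (0,0) to (1,1) and integrates to the AUC", {
  set.seed(3)
  y <- rbinom(60, 1, 0.4); y[1] <- 1; y[2] <- 0
  sc <- rnorm(60)
  pts <- roc_points(sc, y)
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
  # trapezoidal area equals the Mann-Whitney AUC
  area <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  expect_equal(area, roc_auc(sc, y)$auc, tolerance = 1e-10)
})

test_that("ANOVA with Bonferroni: trivial and arithmetic cases", {
  v <- c(rnorm(10), rnorm(10))
  g <- rep(c("a", "b"), each = 10)
  same <- anova_bonferroni(rep(c(1, 2, 3, 1, 2, 3), 2),
                           rep(c("a", "b"), each = 6))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  res <- anova_bonferroni(c(v, rnorm(10, 2)), c(g, rep("c", 10)))
  expect_equal(res$pairwise$p_bonferroni,
               pmin(1, res$pairwise$p_raw * 3))
  expect_warning(anova_bonferroni(c(v, 5), c(g, "tiny")), "tiny")
})

test_that("Bonferroni pairwise control is conservative under the null", {
  set.seed(99)
  reps <- 1000
  fwe <- mean(replicate(reps, {
    v <- rnorm(48)
    g <- rep(c("a", "b", "c", "d"), each = 12)
    any(anova_bonferroni(v, g)$pairwise$p_bonferroni < 0.05)
  }))
  expect_lte(fwe, 0.05 + 2 * sqrt(0.05 * 0.95 / reps))
})

test_that("analyze_mortality wires the full stage together", {
  ep <- expand_table(published_table())
  res <- analyze_mortality(ep$labels, ep$death30, reference = "C")
  expect_equal(nrow(res$odds_ratios), 3L)
  expect_equal(res$roc$auc, 0.600, tolerance = 5e-4)
  expect_true(res$chi2$use_likelihood_ratio)
})
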