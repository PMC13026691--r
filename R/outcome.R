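#' Mortality contingency table by subphenotype
#'
#' Counts 30-day deaths and survivors per group label. Labels with zero
#' patients are retained with zero counts and flagged.
#'
#' @param labels Character/factor vector of per-patient subphenotype labels.
#' @param death30 0/1 (or logical) vector of the same length.
#' @param all_labels Optional label universe; defaults to the labels present
#'   (sorted).
#' @return An object of class `contingency_table`: data frame
#'   `label, deaths, survivors, total, mortality`, with empty labels in
#'   `attr(, "empty_labels")`.
#' @export
contingency <- function(labels, death30, all_labels = NULL) {
  stopifnot(length(labels) == length(death30))
  death30 <- as.integer(death30)
  if (length(death30) && (any(is.na(death30)) || any(!death30 %in% c(0L, 1L)))) {
    stop("death30 must be 0/1 with no missing values", call. = FALSE)
  }
  if (is.null(all_labels)) all_labels <- sort(unique(as.character(labels)))
  labels <- factor(as.character(labels), levels = all_labels)
  deaths <- as.integer(tapply(death30, labels, sum, default = 0L))
  totals <- as.integer(table(labels))
  out <- data.frame(label = all_labels, deaths = deaths,
                    survivors = totals - deaths, total = totals,
                    mortality = ifelse(totals > 0, deaths / totals, NA_real_),
                    stringsAsFactors = FALSE)
  structure(out, class = c("contingency_table", "data.frame"),
            empty_labels = all_labels[totals == 0L])
}

#' Build a contingency table directly from printed counts
#'
#' Convenience constructor for validating against published group-level
#' death/total counts.
#'
#' @param deaths,totals Integer vectors per label.
#' @param labels Group labels.
#' @return A `contingency_table`.
#' @export
contingency_from_counts <- function(deaths, totals, labels = c("A", "B", "C", "D")) {
  stopifnot(length(deaths) == length(totals), length(labels) == length(deaths),
            all(deaths >= 0), all(totals >= deaths))
  out <- data.frame(label = labels, deaths = as.integer(deaths),
                    survivors = as.integer(totals - deaths),
                    total = as.integer(totals),
                    mortality = ifelse(totals > 0, deaths / totals, NA_real_),
                    stringsAsFactors = FALSE)
  structure(out, class = c("contingency_table", "data.frame"),
            empty_labels = labels[totals == 0L])
}

#' Chi-square and likelihood-ratio tests on a groups x outcome table
#'
#' Pearson `X^2 = sum (O-E)^2 / E` and the likelihood-ratio statistic
#' `G^2 = 2 sum O log(O/E)` (zero cells contribute 0), both on
#' `df = rows - 1` for a groups x 2 table. When any expected count is below
#' 5 the `use_likelihood_ratio` flag is raised (the expected-count rule).
#' Optionally a Monte-Carlo conditional "exact" p-value is computed for both
#' statistics by sampling tables with fixed margins (Patefield algorithm).
#'
#' @param table A `contingency_table`.
#' @param mc_exact If `TRUE`, add Monte-Carlo conditional p-values.
#' @param mc_draws Number of Monte-Carlo tables (default 1e5).
#' @param seed Seed for the Monte-Carlo draw.
#' @return List with `pearson` (`statistic, df, p`), `lr`
#'   (`statistic, df, p`), `expected` matrix, `min_expected`,
#'   `use_likelihood_ratio`, and optionally `mc` (`p_pearson, p_lr, draws`).
#' @export
chi2_tests <- function(table, mc_exact = FALSE, mc_draws = 1e5, seed = 0L) {
  stopifnot(inherits(table, "contingency_table"), nrow(table) >= 2L)
  O <- cbind(deaths = table$deaths, survivors = table$survivors)
  if (any(rowSums(O) == 0) || any(colSums(O) == 0)) {
    stop("degenerate table: zero marginal row or column", call. = FALSE)
  }
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  X2 <- sum((O - E)^2 / E)
  G2 <- 2 * sum(ifelse(O > 0, O * log(O / E), 0))
  df <- nrow(O) - 1L
  out <- list(
    pearson = list(statistic = X2, df = df,
                   p = stats::pchisq(X2, df, lower.tail = FALSE)),
    lr = list(statistic = G2, df = df,
              p = stats::pchisq(G2, df, lower.tail = FALSE)),
    expected = E, min_expected = min(E),
    use_likelihood_ratio = min(E) < 5
  )
  if (mc_exact) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    draws <- stats::r2dtable(mc_draws, rowSums(O), colSums(O))
    stat_of <- function(tab) {
      x2 <- sum((tab - E)^2 / E)
      g2 <- 2 * sum(ifelse(tab > 0, tab * log(tab / E), 0))
      c(x2, g2)
    }
    sims <- vapply(draws, stat_of, numeric(2))
    out$mc <- list(
      p_pearson = (1 + sum(sims[1, ] >= X2 - 1e-12)) / (mc_draws + 1),
      p_lr = (1 + sum(sims[2, ] >= G2 - 1e-12)) / (mc_draws + 1),
      draws = mc_draws
    )
  }
  out
}

#' Odds ratios vs a reference group with Woolf intervals
#'
#' For each non-reference group g: `b = log[(d_g/s_g) / (d_r/s_r)]`,
#' Woolf `se = sqrt(1/d_g + 1/s_g + 1/d_r + 1/s_r)`,
#' `CI = exp(b -+ 1.96 se)`, two-sided Wald p from `z = b/se`. Groups with a
#' zero cell are flagged; no continuity correction is applied.
#'
#' @param table A `contingency_table`.
#' @param reference Reference group label (default `"C"`).
#' @return Data frame of class `odds_ratio_result`: one row per
#'   non-reference group with `label, log_or, se, or_value, ci_low, ci_high,
#'   wald_p, zero_cell`.
#' @export
odds_ratios <- function(table, reference = "C") {
  stopifnot(inherits(table, "contingency_table"))
  ri <- match(reference, table$label)
  if (is.na(ri)) stop(sprintf("reference group '%s' not in table", reference), call. = FALSE)
  d_r <- table$deaths[ri]; s_r <- table$survivors[ri]
  if (d_r < 1 || s_r < 1) {
    stop("reference group must have at least one death and one survivor", call. = FALSE)
  }
  others <- setdiff(seq_len(nrow(table)), ri)
  rows <- lapply(others, function(i) {
    d <- table$deaths[i]; s <- table$survivors[i]
    zero <- d == 0 || s == 0
    b <- log((d / s) / (d_r / s_r))
    se <- sqrt(1 / d + 1 / s + 1 / d_r + 1 / s_r)
    data.frame(label = table$label[i], log_or = b, se = se,
               or_value = exp(b),
               ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
               wald_p = 2 * stats::pnorm(-abs(b / se)),
               zero_cell = zero, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("odds_ratio_result", "data.frame"),
            reference = reference)
}

#' Unconditional logistic regression by Newton-Raphson
#'
#' Maximum-likelihood logistic regression of a binary outcome on group dummy
#' variables (reference cell coding), fit by Newton-Raphson with convergence
#' declared when the largest absolute score component falls below 1e-8.
#' Standard errors come from the inverse observed information. For this
#' saturated dummy-only model the coefficients equal the contingency log
#' odds ratios and the intercept equals `log(d_ref / s_ref)`. Perfect
#' separation (a group with all deaths or all survivors) is flagged
#' non-converged with a diagnostic.
#'
#' @param labels Per-patient group labels.
#' @param death30 0/1 outcome vector.
#' @param reference Reference group label (default `"C"`).
#' @param max_iter Newton iteration cap (default 50).
#' @return Object of class `logistic_fit`: `coefficients` (data frame
#'   `term, estimate, se, z, wald_p`), `loglik`, `converged`, `n_iter`,
#'   `reference`, `diagnostic`.
#' @export
fit_logistic <- function(labels, death30, reference = "C", max_iter = 50L) {
  y <- as.integer(death30)
  stopifnot(length(labels) == length(y), all(y %in% c(0L, 1L)))
  if (sum(y) == 0L || sum(y) == length(y)) {
    stop("need at least one death and one survivor overall", call. = FALSE)
  }
  labels <- as.character(labels)
  levs <- c(reference, sort(setdiff(unique(labels), reference)))
  if (!reference %in% labels) stop(sprintf("reference group '%s' absent", reference), call. = FALSE)
  X <- cbind(1, vapply(levs[-1], function(l) as.numeric(labels == l),
                       numeric(length(labels))))
  X <- matrix(X, nrow = length(labels))
  colnames(X) <- c("(Intercept)", levs[-1])

  # separation screen: a non-reference group with all deaths or all survivors
  sep <- vapply(levs, function(l) {
    yy <- y[labels == l]
    length(yy) > 0 && (all(yy == 1L) || all(yy == 0L))
  }, TRUE)
  diagnostic <- if (any(sep)) {
    sprintf("separation: group(s) %s have all-deaths or all-survivors",
            paste(levs[sep], collapse = ", "))
  } else NA_character_

  beta <- rep(0, ncol(X))
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    score <- crossprod(X, y - p)
    if (max(abs(score)) < 1e-8) { converged <- TRUE; break }
    W <- p * (1 - p)
    info <- crossprod(X * W, X)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) break
    # dampen huge steps (separation sends coefficients to infinity)
    if (max(abs(step)) > 10) step <- step * 10 / max(abs(step))
    beta <- beta + drop(step)
  }
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  info <- crossprod(X * (p * (1 - p)), X)
  vc <- tryCatch(solve(info), error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  se <- sqrt(diag(vc))
  z <- beta / se
  coefs <- data.frame(term = colnames(X), estimate = beta, se = se, z = z,
                      wald_p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  loglik <- sum(y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300)))
  structure(
    list(coefficients = coefs, loglik = loglik,
         converged = converged && !any(sep), n_iter = it,
         reference = reference, diagnostic = diagnostic,
         fitted = p),
    class = "logistic_fit"
  )
}

#' Tie-corrected ROC AUC with Hanley-McNeil standard error
#'
#' AUC by the Mann-Whitney construction with ties counted one-half:
#' `AUC = (# pairs where the case's score exceeds the control's +
#' 0.5 * # tied pairs) / (n_case * n_control)`, computed via midranks.
#' The SE is Hanley-McNeil; `CI = auc -+ 1.96 se` truncated to \[0, 1\];
#' `p_vs_half` is the two-sided Wald p for `AUC = 0.5`.
#'
#' @param scores Numeric risk scores (higher = more death-like).
#' @param death30 0/1 outcome vector.
#' @return Object of class `roc_result`: `auc, se, ci_low, ci_high,
#'   p_vs_half, n_case, n_control`.
#' @export
roc_auc <- function(scores, death30) {
  y <- as.integer(death30)
  stopifnot(length(scores) == length(y), all(y %in% c(0L, 1L)))
  n1 <- sum(y); n0 <- sum(1L - y)
  if (n1 == 0L || n0 == 0L) stop("both outcome classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) + (n0 - 1) * (q2 - auc^2)) /
               (n1 * n0))
  z <- (auc - 0.5) / se
  structure(
    list(auc = auc, se = se,
         ci_low = max(0, auc - 1.96 * se), ci_high = min(1, auc + 1.96 * se),
         p_vs_half = 2 * stats::pnorm(-abs(z)),
         n_case = n1, n_control = n0),
    class = "roc_result"
  )
}

#' Empirical ROC curve coordinates
#'
#' One (FPR, TPR) point per distinct score threshold, from (0,0) to (1,1),
#' suitable for plotting or CSV export.
#'
#' @inheritParams roc_auc
#' @return Data frame `threshold, fpr, tpr`.
#' @export
roc_points <- function(scores, death30) {
  y <- as.integer(death30)
  n1 <- sum(y); n0 <- sum(1L - y)
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(thr, function(th) {
    c(fpr = sum(scores >= th & y == 0L) / n0,
      tpr = sum(scores >= th & y == 1L) / n1)
  }, c(fpr = 0, tpr = 0)))
  rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0),
        data.frame(threshold = thr, fpr = pts[, "fpr"], tpr = pts[, "tpr"]))
}

#' One-way ANOVA with Bonferroni-corrected pairwise comparisons
#'
#' Classic one-way ANOVA F test across groups, followed by all pairwise
#' Welch two-sample t comparisons whose p-values are multiplied by the family
#' size (number of pairwise comparisons, or `family_size` if given) and
#' capped at 1. Groups with fewer than 2 values are excluded with a warning.
#'
#' @param values Numeric vector of the continuous covariate (e.g. the
#'   per-patient maximum laboratory value over the first 24 h).
#' @param groups Group label per value.
#' @param family_size Optional multiplier for the Bonferroni correction;
#'   defaults to the number of pairwise comparisons performed.
#' @return List with `F`, `df` (c(between, within)), `p`, `group_means`,
#'   and `pairwise` (data frame `group1, group2, mean_diff, t, df, p_raw,
#'   p_bonferroni`).
#' @export
anova_bonferroni <- function(values, groups, family_size = NULL) {
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups[keep])
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning(sprintf("excluding group(s) with <2 values: %s", paste(small, collapse = ", ")))
    keep <- !groups %in% small
    values <- values[keep]; groups <- groups[keep]
  }
  levs <- sort(unique(groups))
  if (length(levs) < 2L) stop("need at least 2 groups with >=2 values each", call. = FALSE)
  n <- length(values)
  k <- length(levs)
  gm <- tapply(values, groups, mean)
  grand <- mean(values)
  ss_b <- sum(tapply(values, groups, length) * (gm - grand)^2)
  ss_w <- sum((values - gm[groups])^2)
  df_b <- k - 1L; df_w <- n - k
  Fstat <- if (ss_w == 0) {
    if (ss_b == 0) 0 else Inf
  } else (ss_b / df_b) / (ss_w / df_w)
  p <- if (is.infinite(Fstat)) 0 else stats::pf(Fstat, df_b, df_w, lower.tail = FALSE)
  if (Fstat == 0) p <- 1

  pairs <- utils::combn(levs, 2L, simplify = FALSE)
  n_fam <- if (is.null(family_size)) length(pairs) else family_size
  pairwise <- do.call(rbind, lapply(pairs, function(pr) {
    x1 <- values[groups == pr[1]]; x2 <- values[groups == pr[2]]
    tt <- tryCatch(stats::t.test(x1, x2), error = function(e) NULL)
    if (is.null(tt)) {  # zero variance in both groups
      eq <- mean(x1) == mean(x2)
      data.frame(group1 = pr[1], group2 = pr[2], mean_diff = mean(x1) - mean(x2),
                 t = if (eq) 0 else Inf, df = NA_real_,
                 p_raw = if (eq) 1 else 0,
                 p_bonferroni = if (eq) 1 else 0, stringsAsFactors = FALSE)
    } else {
      data.frame(group1 = pr[1], group2 = pr[2], mean_diff = mean(x1) - mean(x2),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_raw = tt$p.value,
                 p_bonferroni = min(1, tt$p.value * n_fam), stringsAsFactors = FALSE)
    }
  }))
  list(F = Fstat, df = c(between = df_b, within = df_w), p = p,
       group_means = gm, pairwise = pairwise, family_size = n_fam)
}

#' Full mortality-association analysis for an assigned cohort
#'
#' Convenience wrapper running [contingency()], [chi2_tests()],
#' [odds_ratios()], [fit_logistic()] and [roc_auc()] (scores are the
#' logistic predicted probabilities, i.e. the group mortality rates) in one
#' call.
#'
#' @param labels Per-patient subphenotype labels.
#' @param death30 0/1 outcome vector.
#' @param reference Reference group (default `"C"`, the control).
#' @param mc_exact Forwarded to [chi2_tests()].
#' @param seed Seed for the Monte-Carlo exact test.
#' @return List with `table`, `chi2`, `odds_ratios`, `logistic`, `roc`.
#' @export
analyze_mortality <- function(labels, death30, reference = "C",
                              mc_exact = FALSE, seed = 0L) {
  tab <- contingency(labels, death30)
  chi <- chi2_tests(tab, mc_exact = mc_exact, seed = seed)
  ors <- odds_ratios(tab, reference = reference)
  lg <- fit_logistic(labels, death30, reference = reference)
  roc <- roc_auc(lg$fitted, death30)
  list(table = tab, chi2 = chi, odds_ratios = ors, logistic = lg, roc = roc)
}
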