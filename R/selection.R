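#' Choose linear vs quadratic trajectory for one channel
#'
#' Before mixture fitting, a one-group polynomial is fit to the channel
#' (Gaussian maximum likelihood) at orders 1 and 2 and compared by likelihood
#' ratio test: `2 * (loglik_quadratic - loglik_linear) ~ chi-square(1)`.
#' Quadratic is selected iff `p < alpha`.
#'
#' @param series_set A `patient_series_set`.
#' @param channel One of [vs_channels()].
#' @param alpha Significance level (default 0.05).
#' @return List with `order` (1 or 2), `statistic`, `df`, `p`,
#'   `loglik_linear`, `loglik_quadratic`.
#' @export
select_polynomial_order <- function(series_set, channel, alpha = 0.05) {
  channel <- match.arg(channel, vs_channels())
  long <- series_long(series_set)
  v <- match(channel, vs_channels())
  idx <- long$ch == v
  t <- long$time[idx]
  y <- long$value[idx]
  if (length(unique(t)) < 3L) {
    stop(sprintf("channel %s has fewer than 3 distinct measurement times; quadratic term unidentifiable",
                 channel), call. = FALSE)
  }
  n <- length(y)
  # Gaussian profile log-likelihood of an OLS fit: -n/2 (log(2 pi RSS/n) + 1)
  ll_of <- function(X) {
    b <- solve(crossprod(X), crossprod(X, y))
    rss <- sum((y - drop(X %*% b))^2)
    rss <- max(rss, .Machine$double.xmin)
    -n / 2 * (log(2 * pi * rss / n) + 1)
  }
  ll1 <- ll_of(cbind(1, t))
  ll2 <- ll_of(cbind(1, t, t^2))
  stat <- max(0, 2 * (ll2 - ll1))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(order = if (p < alpha) 2L else 1L, statistic = stat, df = 1L, p = p,
       loglik_linear = ll1, loglik_quadratic = ll2)
}

#' Sweep over 1--4 group models and select by BIC with adequacy screens
#'
#' Fits G = 1..4 models at the given polynomial orders, then screens each
#' candidate: a candidate fails if any modal group share is below
#' `min_share` (default 5% of the cohort) or if any populated group's
#' average posterior probability is not strictly above `app_threshold`
#' (default 0.70). Among survivors the lowest-BIC model is selected; when no
#' candidate survives, `selected_G` is `NA` and the report carries the
#' failure reasons. Failure to select is a reportable outcome, not an error.
#'
#' @param series_set A `patient_series_set`.
#' @param orders Named per-channel polynomial orders (e.g. from
#'   [select_polynomial_order()]); default all linear.
#' @param seed,n_starts,max_iter,tol Passed to [fit_gbtm()].
#' @param G_max Largest number of groups tried (default 4).
#' @param min_share Minimum admissible modal group share (default 0.05).
#' @param app_threshold APP adequacy threshold, strict (default 0.70).
#' @param variance Variance mode for [gbtm_spec()].
#' @return An object of class `model_selection_report`: `candidates` (one
#'   entry per G with `model`, `assignments`, `bic`, `loglik`, `shares`,
#'   `app`, `pass`, `reasons`), `selected_G`, `selected_model`,
#'   `assignments`, `label_map`, `orders`.
#' @export
sweep_groups <- function(series_set, orders = stats::setNames(rep(1L, 5L), vs_channels()),
                         seed = 0L, n_starts = 10L, max_iter = 500L, tol = 1e-6,
                         G_max = 4L, min_share = 0.05, app_threshold = 0.70,
                         variance = "group") {
  stopifnot(inherits(series_set, "patient_series_set"), length(series_set) > 0)
  n <- length(series_set)
  candidates <- vector("list", G_max)
  for (G in seq_len(G_max)) {
    spec <- gbtm_spec(G, orders, variance)
    model <- tryCatch(
      fit_gbtm(series_set, spec, n_starts = n_starts, max_iter = max_iter,
               tol = tol, seed = seed + G),
      error = function(e) e
    )
    if (inherits(model, "error")) {
      candidates[[G]] <- list(G = G, model = NULL, assignments = NULL,
                              bic = NA_real_, loglik = NA_real_,
                              shares = rep(NA_real_, G), app = rep(NA_real_, G),
                              pass = FALSE,
                              reasons = sprintf("fit failed: %s", conditionMessage(model)))
      next
    }
    asg <- e_step(model, series_set)
    shares <- tabulate(asg$modal_group, nbins = G) / n
    app <- average_posterior_probability(asg, G)
    reasons <- character(0)
    if (any(shares < min_share)) {
      reasons <- c(reasons, sprintf("min share < %g%%", 100 * min_share))
    }
    populated <- !is.na(app)
    if (any(app[populated] <= app_threshold)) {
      reasons <- c(reasons, sprintf("APP <= %g for some group", app_threshold))
    }
    candidates[[G]] <- list(G = G, model = model, assignments = asg,
                            bic = bic(model), loglik = model$loglik,
                            shares = shares, app = app,
                            pass = length(reasons) == 0L, reasons = reasons)
  }
  bics <- vapply(candidates, function(cd) if (isTRUE(cd$pass)) cd$bic else NA_real_, 0)
  selected_G <- if (all(is.na(bics))) NA_integer_ else which.min(bics)
  selected_model <- if (!is.na(selected_G)) candidates[[selected_G]]$model else NULL
  assignments <- if (!is.na(selected_G)) candidates[[selected_G]]$assignments else NULL
  label_map <- if (!is.na(selected_G)) {
    label_groups(selected_model, assignments, series_set)
  } else NULL
  structure(
    list(candidates = candidates, selected_G = selected_G,
         selected_model = selected_model, assignments = assignments,
         label_map = label_map, orders = orders,
         min_share = min_share, app_threshold = app_threshold),
    class = "model_selection_report"
  )
}

# Per-group derangement profile in natural units: whether the fitted 24-h
# time-averaged mean crosses each clinical cut-off.
.derangement_profile <- function(model) {
  G <- model$spec$n_groups
  chans <- vs_channels()
  means <- matrix(NA_real_, G, length(chans), dimnames = list(NULL, chans))
  for (g in seq_len(G)) {
    for (v in seq_along(chans)) {
      b <- model$beta[[g]][[v]]
      if (!is.null(model$scaling)) {
        b <- .beta_natural(b, model$sigma[g, v], model$scaling[v, ])$beta
      }
      # time-average of beta0 + beta1 t + beta2 t^2 over [0, 24]
      means[g, v] <- b[1] + b[2] * 12 + if (length(b) == 3L) b[3] * 192 else 0
    }
  }
  data.frame(
    group = seq_len(G),
    fever = means[, "TEMP"] >= 38.0,
    tachycardia = means[, "HR"] >= 100,
    tachypnea = means[, "RR"] >= 22,
    hypertension = means[, "SBP"] >= 140,
    hypotension = means[, "SBP"] < 100,
    mean_TEMP = means[, "TEMP"], mean_HR = means[, "HR"], mean_RR = means[, "RR"],
    mean_SBP = means[, "SBP"], mean_DBP = means[, "DBP"]
  )
}

#' Assign clinical subphenotype labels A--D to fitted groups
#'
#' Each group's fitted 24-h mean per channel (natural units) is thresholded
#' into a derangement profile (fever TEMP >= 38, tachycardia HR >= 100,
#' tachypnea RR >= 22, hypertension SBP >= 140, hypotension SBP < 100), and
#' labels are assigned so that A = most channels deranged, B = hypertensive
#' pattern, C = fewest derangements, D = hypotension-only. The best injective
#' group-to-label map is found by exact enumeration of a pattern-match score;
#' ties break deterministically with larger groups taking earlier labels.
#' With fewer than four groups, labels come from the best-matching subset of
#' \{A, B, C, D\}.
#'
#' @param model A fitted `gbtm_model`.
#' @param assignments Its `posterior_assignment` (for group sizes).
#' @param series_set The fitted `patient_series_set` (unused except for
#'   validation; profiles come from the model's fitted curves).
#' @return Character vector, one label per group index, with the derangement
#'   profile attached as `attr(, "profiles")`.
#' @export
label_groups <- function(model, assignments, series_set) {
  G <- model$spec$n_groups
  stopifnot(G <= 4L)
  prof <- .derangement_profile(model)
  cnt <- rowSums(prof[, c("fever", "tachycardia", "tachypnea", "hypertension",
                          "hypotension")])
  score <- cbind(
    A = cnt,
    B = 4 * prof$hypertension + 0.5 * (cnt == 1),
    C = 4 - cnt,
    D = 4 * (prof$hypotension & cnt == 1)
  )
  sizes <- tabulate(assignments$modal_group, nbins = G)
  ord <- order(sizes, decreasing = TRUE)  # larger groups pick first on ties
  labels4 <- c("A", "B", "C", "D")
  best <- NULL
  best_total <- -Inf
  assign_rec <- function(i, used, acc, total) {
    if (i > G) {
      if (total > best_total) { best_total <<- total; best <<- acc }
      return(invisible())
    }
    g <- ord[i]
    for (lab in labels4[!used]) {
      u <- used; u[match(lab, labels4)] <- TRUE
      a <- acc; a[g] <- lab
      assign_rec(i + 1L, u, a, total + score[g, lab])
    }
  }
  assign_rec(1L, rep(FALSE, 4L), character(G), 0)
  structure(best, profiles = prof)
}

#' @export
print.model_selection_report <- function(x, ...) {
  cat("GBTM model selection report\n")
  for (cd in x$candidates) {
    cat(sprintf("  G=%d  BIC=%s  min share=%s  min APP=%s  %s%s\n",
                cd$G,
                ifelse(is.na(cd$bic), "NA", sprintf("%.1f", cd$bic)),
                ifelse(all(is.na(cd$shares)), "NA", sprintf("%.3f", min(cd$shares))),
                ifelse(all(is.na(cd$app)), "NA", sprintf("%.3f", min(cd$app, na.rm = TRUE))),
                if (isTRUE(cd$pass)) "PASS" else "FAIL",
                if (length(cd$reasons)) paste0(" [", paste(cd$reasons, collapse = "; "), "]") else ""))
  }
  if (is.na(x$selected_G)) {
    cat("  selected: none (no candidate survived the screens)\n")
  } else {
    cat(sprintf("  selected: G=%d, labels: %s\n", x$selected_G,
                paste(x$label_map, collapse = " ")))
  }
  invisible(x)
}

#' Serialize a selection report to JSON
#'
#' @param report A `model_selection_report`.
#' @param path Optional output file path.
#' @return JSON string (invisibly when written to file).
#' @export
report_to_json <- function(report, path = NULL) {
  doc <- list(
    format = "vstraj-selection", version = 1L,
    orders = as.list(report$orders),
    min_share = report$min_share,
    app_threshold = report$app_threshold,
    candidates = lapply(report$candidates, function(cd) {
      list(G = cd$G, bic = cd$bic, loglik = cd$loglik,
           shares = cd$shares, app = cd$app,
           pass = cd$pass, reasons = as.list(cd$reasons))
    }),
    selected_G = if (is.na(report$selected_G)) NULL else report$selected_G,
    label_map = if (is.null(report$label_map)) NULL else as.list(report$label_map)
  )
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
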