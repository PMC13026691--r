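#' GBTM model specification
#'
#' Structural choices for the group-based trajectory model: the number of
#' latent groups, the polynomial order of each channel's mean trajectory
#' (1 = linear, 2 = quadratic in time), and whether residual SDs are shared
#' across groups within a channel or group-specific.
#'
#' @param n_groups Number of latent groups G, 1 to 4.
#' @param orders Named integer vector over [vs_channels()], each 1 or 2.
#' @param variance `"group"` (group-specific residual SD per channel, the
#'   default) or `"shared"` (one SD per channel pooled over groups).
#' @return An object of class `gbtm_spec`.
#' @export
gbtm_spec <- function(n_groups,
                      orders = stats::setNames(rep(1L, 5L), vs_channels()),
                      variance = c("group", "shared")) {
  variance <- match.arg(variance)
  if (!is.numeric(n_groups) || length(n_groups) != 1L || n_groups < 1 || n_groups > 4) {
    stop("invalid 'n_groups': must be 1..4", call. = FALSE)
  }
  if (is.null(names(orders))) names(orders) <- vs_channels()
  orders <- orders[vs_channels()]
  if (any(is.na(orders)) || !all(orders %in% c(1L, 2L))) {
    stop("invalid 'orders': need one order in {1,2} per channel", call. = FALSE)
  }
  structure(list(n_groups = as.integer(n_groups),
                 orders = stats::setNames(as.integer(orders), vs_channels()),
                 variance = variance),
            class = "gbtm_spec")
}

# residual-SD floor (standardized units): the finite-mixture likelihood is
# unbounded without it
.sigma_floor <- 1e-3

# Precompute the flat fitting representation: per channel, the rows, the
# polynomial design matrix, the responses and the patient index.
.fit_data <- function(series_set, spec) {
  long <- series_long(series_set)
  n <- length(series_set)
  chans <- vs_channels()
  per_channel <- lapply(seq_along(chans), function(v) {
    idx <- which(long$ch == v)
    if (!length(idx)) return(NULL)
    t <- long$time[idx]
    ord <- spec$orders[[v]]
    X <- cbind(1, t, if (ord == 2L) t^2)
    list(X = X, y = long$value[idx], pid = long$pid[idx])
  })
  list(n = n, per_channel = per_channel, chans = chans)
}

# n x G matrix of per-patient component log-densities
.component_loglik <- function(fd, beta, sigma, G) {
  L <- matrix(0, fd$n, G)
  for (g in seq_len(G)) {
    acc <- numeric(fd$n)
    for (v in seq_along(fd$per_channel)) {
      pc <- fd$per_channel[[v]]
      if (is.null(pc)) next
      mu <- drop(pc$X %*% beta[[g]][[v]])
      ll <- stats::dnorm(pc$y, mu, sigma[g, v], log = TRUE)
      tab <- rowsum(ll, pc$pid)
      acc[as.integer(rownames(tab))] <- acc[as.integer(rownames(tab))] + drop(tab)
    }
    L[, g] <- acc
  }
  L
}

# stable log(sum(exp())) by row
.row_lse <- function(a) {
  mx <- apply(a, 1L, max)
  mx + log(rowSums(exp(a - mx)))
}

#' Per-patient mixture log-likelihood
#'
#' Evaluates, for a single patient series, each group's component log-density
#' (the product over observed (channel, time) cells of
#' Normal(value; group mean, residual SD)) and the total log mixture density
#' `log(sum_g pi_g * component_g)` via log-sum-exp; unobserved cells
#' contribute nothing (missingness is handled in the likelihood, never
#' imputed).
#'
#' @param model A fitted `gbtm_model` (or any list with `spec`, `mixing`,
#'   `beta`, `sigma`).
#' @param series A single `patient_series`.
#' @return List with `component_loglik` (length-G vector) and `total`.
#' @export
patient_loglik <- function(model, series) {
  stopifnot(inherits(series, "patient_series"))
  one <- structure(list(series), class = "patient_series_set")
  fd <- .fit_data(one, model$spec)
  G <- model$spec$n_groups
  L <- .component_loglik(fd, model$beta, model$sigma, G)
  a <- L[1, ] + log(model$mixing)
  list(component_loglik = drop(L[1, ]), total = .row_lse(matrix(a, 1)))
}

#' E-step: posterior group membership
#'
#' Computes, per patient, `posterior_g` proportional to
#' `pi_g * component_g`, normalised, plus the modal group and its
#' probability.
#'
#' @param model A `gbtm_model`.
#' @param series_set A `patient_series_set`.
#' @return An object of class `posterior_assignment`: list with
#'   `patient_id`, `posterior` (n x G matrix), `modal_group`,
#'   `max_posterior`.
#' @export
e_step <- function(model, series_set) {
  fd <- .fit_data(series_set, model$spec)
  G <- model$spec$n_groups
  L <- .component_loglik(fd, model$beta, model$sigma, G)
  a <- sweep(L, 2L, log(model$mixing), `+`)
  post <- exp(a - .row_lse(a))
  post <- post / rowSums(post)
  modal <- max.col(post, ties.method = "first")
  structure(
    list(patient_id = vapply(series_set, `[[`, "", "patient_id"),
         posterior = post,
         modal_group = modal,
         max_posterior = post[cbind(seq_len(nrow(post)), modal)]),
    class = "posterior_assignment"
  )
}

#' M-step: update mixture parameters from posteriors
#'
#' Trajectory coefficients are posterior-weighted least squares of each
#' channel's observations on the time polynomial basis; residual variances
#' are posterior-weighted mean squared residuals (pooled over groups in
#' shared-variance mode); mixing proportions are mean posteriors. Residual
#' SDs are floored at 1e-3 (standardized units).
#'
#' @param series_set A `patient_series_set`.
#' @param posteriors n x G matrix of membership probabilities (or a
#'   `posterior_assignment`).
#' @param spec A `gbtm_spec`.
#' @return List with `mixing`, `beta` (per group, per channel coefficient
#'   vectors) and `sigma` (G x 5 matrix).
#' @export
m_step <- function(series_set, posteriors, spec) {
  if (inherits(posteriors, "posterior_assignment")) posteriors <- posteriors$posterior
  posteriors <- as.matrix(posteriors)
  fd <- .fit_data(series_set, spec)
  .m_step_fd(fd, posteriors, spec)
}

.m_step_fd <- function(fd, post, spec) {
  G <- spec$n_groups
  V <- length(fd$per_channel)
  beta <- vector("list", G)
  sigma <- matrix(NA_real_, G, V)
  ss <- matrix(0, G, V)     # weighted residual sums of squares
  sw <- matrix(0, G, V)     # weight totals
  for (g in seq_len(G)) {
    beta[[g]] <- vector("list", V)
    names(beta[[g]]) <- fd$chans
    for (v in seq_len(V)) {
      pc <- fd$per_channel[[v]]
      if (is.null(pc)) next
      w <- post[pc$pid, g]
      Xw <- pc$X * w
      XtWX <- crossprod(Xw, pc$X)
      b <- tryCatch(solve(XtWX, crossprod(Xw, pc$y)),
                    error = function(e) stop(sprintf(
                      "singular design for group %d, channel %s", g, fd$chans[v]),
                      call. = FALSE))
      b <- drop(b)
      beta[[g]][[v]] <- b
      r <- pc$y - drop(pc$X %*% b)
      ss[g, v] <- sum(w * r^2)
      sw[g, v] <- sum(w)
    }
  }
  if (spec$variance == "group") {
    sigma <- sqrt(ss / pmax(sw, .Machine$double.eps))
  } else {
    pooled <- sqrt(colSums(ss) / pmax(colSums(sw), .Machine$double.eps))
    sigma <- matrix(pooled, G, V, byrow = TRUE)
  }
  sigma <- pmax(sigma, .sigma_floor)
  list(mixing = colMeans(post), beta = beta, sigma = sigma)
}

# free-parameter count: (G-1) mixing + G * sum(order_v + 1) coefficients +
# residual-SD parameters
.n_params <- function(spec) {
  G <- spec$n_groups
  (G - 1L) + G * sum(spec$orders + 1L) +
    if (spec$variance == "group") G * length(spec$orders) else length(spec$orders)
}

# one EM run from an initial posterior matrix; returns NULL if the start is
# degenerate (a group's mixing share collapses below 1/(2n))
.em_run <- function(fd, post0, spec, max_iter, tol) {
  G <- spec$n_groups
  n <- fd$n
  post <- post0
  prev <- -Inf
  trace <- numeric(0)
  params <- NULL
  for (it in seq_len(max_iter)) {
    params <- .m_step_fd(fd, post, spec)
    if (G > 1L && any(params$mixing < 1 / (2 * n))) {
      return(list(degenerate = TRUE))
    }
    L <- .component_loglik(fd, params$beta, params$sigma, G)
    a <- sweep(L, 2L, log(params$mixing), `+`)
    lse <- .row_lse(a)
    ll <- sum(lse)
    trace <- c(trace, ll)
    post <- exp(a - lse)
    post <- post / rowSums(post)
    if (is.finite(prev) && abs(ll - prev) < tol) {
      return(list(degenerate = FALSE, converged = TRUE, params = params,
                  loglik = ll, n_iter = it, trace = trace, post = post))
    }
    prev <- ll
  }
  list(degenerate = FALSE, converged = FALSE, params = params,
       loglik = prev, n_iter = max_iter, trace = trace, post = post)
}

#' Fit a group-based trajectory model by EM
#'
#' Runs expectation-maximisation from `n_starts` initialisations: start 1 is
#' a k-means split on per-patient channel means (missing channels filled with
#' the cohort mean for initialisation only), the remaining starts draw random
#' Dirichlet(1) posteriors. Each run iterates until the absolute
#' log-likelihood change is below `tol` or `max_iter` is reached; the
#' highest-log-likelihood converged, non-degenerate run wins. Deterministic
#' given `seed`.
#'
#' @param series_set A `patient_series_set` (typically standardized; if the
#'   set carries a scaling record it is propagated to the model).
#' @param spec A `gbtm_spec`.
#' @param n_starts Number of EM initialisations (default 10).
#' @param max_iter Maximum EM iterations per start (default 500).
#' @param tol Convergence tolerance on the absolute log-likelihood change
#'   (default 1e-6).
#' @param seed Integer seed controlling all initialisation randomness.
#' @return An object of class `gbtm_model`: `spec`, `mixing`, `beta`,
#'   `sigma`, `loglik`, `n_params`, `n_patients`, `converged`, `n_iter`,
#'   `loglik_trace` (of the winning start), `start_used`, `scaling`.
#' @export
fit_gbtm <- function(series_set, spec, n_starts = 10L, max_iter = 500L,
                     tol = 1e-6, seed = 0L) {
  stopifnot(inherits(series_set, "patient_series_set"), length(series_set) > 0,
            inherits(spec, "gbtm_spec"), n_starts >= 1L)
  fd <- .fit_data(series_set, spec)
  G <- spec$n_groups
  n <- fd$n

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)

  starts <- vector("list", if (G == 1L) 1L else n_starts)
  if (G == 1L) {
    starts[[1L]] <- matrix(1, n, 1L)
  } else {
    # start 1: k-means on per-patient channel means
    M <- matrix(NA_real_, n, length(fd$chans))
    for (v in seq_along(fd$per_channel)) {
      pc <- fd$per_channel[[v]]
      if (is.null(pc)) next
      mv <- rowsum(pc$y, pc$pid) / rowsum(rep(1, length(pc$y)), pc$pid)
      M[as.integer(rownames(mv)), v] <- drop(mv)
    }
    for (v in seq_len(ncol(M))) M[is.na(M[, v]), v] <- mean(M[, v], na.rm = TRUE)
    km <- tryCatch(stats::kmeans(M, centers = G, nstart = 5, iter.max = 50),
                   error = function(e) NULL)
    if (!is.null(km)) {
      p1 <- matrix(0, n, G)
      p1[cbind(seq_len(n), km$cluster)] <- 1
      starts[[1L]] <- p1
    }
    for (k in seq_len(n_starts)) {
      if (k == 1L && !is.null(starts[[1L]])) next
      p <- matrix(stats::rgamma(n * G, 1), n, G)
      starts[[k]] <- p / rowSums(p)
    }
  }

  best <- NULL
  diag_msgs <- character(0)
  for (k in seq_along(starts)) {
    run <- tryCatch(.em_run(fd, starts[[k]], spec, max_iter, tol),
                    error = function(e) list(error = conditionMessage(e)))
    if (!is.null(run$error)) {
      diag_msgs <- c(diag_msgs, sprintf("start %d: %s", k, run$error)); next
    }
    if (isTRUE(run$degenerate)) {
      diag_msgs <- c(diag_msgs, sprintf("start %d: degenerate (empty group)", k)); next
    }
    if (!isTRUE(run$converged)) {
      # only converged runs compete; if none converges the fit is fatal
      diag_msgs <- c(diag_msgs, sprintf("start %d: no convergence in %d iterations", k, max_iter))
      next
    }
    if (is.null(best) || run$loglik > best$loglik) {
      run$start_used <- k
      best <- run
    }
  }
  if (is.null(best)) {
    stop(paste(c("GBTM fit failed: no usable EM start.", diag_msgs), collapse = "\n"),
         call. = FALSE)
  }
  structure(
    list(spec = spec,
         mixing = best$params$mixing,
         beta = best$params$beta,
         sigma = best$params$sigma,
         loglik = best$loglik,
         n_params = .n_params(spec),
         n_patients = n,
         converged = isTRUE(best$converged),
         n_iter = best$n_iter,
         loglik_trace = best$trace,
         start_used = best$start_used,
         seed = as.integer(seed),
         scaling = attr(series_set, "scaling")),
    class = "gbtm_model"
  )
}

#' Bayesian information criterion
#'
#' `BIC = -2 * loglik + n_params * log(n_patients)`; lower is better.
#'
#' @param model A `gbtm_model` (or a list with `loglik` and `n_params`).
#' @param n_patients Number of patients; defaults to the model's.
#' @return The BIC value.
#' @export
bic <- function(model, n_patients = model$n_patients) {
  -2 * model$loglik + model$n_params * log(n_patients)
}

#' Average posterior probability of assignment
#'
#' The assignment-adequacy diagnostic: for each group g, the mean of
#' `max_posterior` over patients modally assigned to g. Groups with no
#' modally assigned patients get `NA` (flagged as unpopulated).
#'
#' @param assignments A `posterior_assignment`.
#' @param G Number of groups.
#' @return Numeric length-G vector of APPs (NA for empty groups).
#' @export
average_posterior_probability <- function(assignments, G) {
  stopifnot(inherits(assignments, "posterior_assignment"))
  vapply(seq_len(G), function(g) {
    in_g <- assignments$modal_group == g
    if (!any(in_g)) return(NA_real_)
    mean(assignments$max_posterior[in_g])
  }, 0)
}

# convert standardized-scale coefficients/SD back to natural units
.beta_natural <- function(beta_v, sigma_v, scale_row) {
  b <- beta_v * scale_row$sd
  b[1] <- b[1] + scale_row$mean
  list(beta = b, sigma = sigma_v * scale_row$sd)
}

#' Serialize a fitted model to JSON
#'
#' Writes a versioned document with the spec, mixing proportions, per-group
#' per-channel coefficients and residual SDs (in standardized and, when a
#' scaling record is attached, natural units), the log-likelihood, BIC and
#' convergence metadata.
#'
#' @param model A `gbtm_model`.
#' @param path Optional file path; when given the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
gbtm_to_json <- function(model, path = NULL) {
  G <- model$spec$n_groups
  chans <- vs_channels()
  groups <- lapply(seq_len(G), function(g) {
    per_ch <- lapply(seq_along(chans), function(v) {
      entry <- list(coefficients = model$beta[[g]][[v]],
                    residual_sd = model$sigma[g, v])
      if (!is.null(model$scaling)) {
        nat <- .beta_natural(model$beta[[g]][[v]], model$sigma[g, v],
                             model$scaling[v, ])
        entry$coefficients_natural <- nat$beta
        entry$residual_sd_natural <- nat$sigma
      }
      entry
    })
    names(per_ch) <- chans
    list(mixing = model$mixing[g], channels = per_ch)
  })
  doc <- list(
    format = "vstraj-gbtm", version = 1L,
    spec = list(n_groups = G, orders = as.list(model$spec$orders),
                variance = model$spec$variance),
    groups = groups,
    loglik = model$loglik,
    n_params = model$n_params,
    n_patients = model$n_patients,
    bic = bic(model),
    converged = model$converged,
    n_iter = model$n_iter,
    seed = model$seed
  )
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @export
print.gbtm_model <- function(x, ...) {
  cat(sprintf("GBTM model: G=%d, variance=%s, loglik=%.3f, BIC=%.3f (%s)\n",
              x$spec$n_groups, x$spec$variance, x$loglik, bic(x),
              if (x$converged) sprintf("converged in %d iter", x$n_iter) else "NOT converged"))
  cat("mixing:", paste(sprintf("%.3f", x$mixing), collapse = " "), "\n")
  invisible(x)
}
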