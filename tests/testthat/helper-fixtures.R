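# Fixture builders shared across the suite. Everything is generated in code;
# no stored binary data.

# one patient_series from a named list of data.frame(time, value)
make_series <- function(id, observed, death30 = 0L, age = NA_real_, sex = NA_character_) {
  obs <- stats::setNames(vector("list", 5L), vs_channels())
  for (ch in names(observed)) obs[[ch]] <- observed[[ch]]
  structure(list(patient_id = id, observed = obs, death30 = as.integer(death30),
                 age = age, sex = sex),
            class = "patient_series")
}

make_set <- function(...) {
  structure(list(...), class = "patient_series_set",
            exclusions = data.frame(patient_id = character(), reason = character()))
}

# random small mixture instance for property tests: `channels` of the five
# channels observed, linear group trajectories, occasional missing cells
rand_instance <- function(seed, n = 12L, G = 2L, channels = 2L, times = c(0, 6, 12, 18, 24)) {
  set.seed(seed)
  chans <- vs_channels()[seq_len(channels)]
  beta <- lapply(seq_len(G), function(g) {
    b <- lapply(chans, function(ch) c(rnorm(1, 0, 2), rnorm(1, 0, 0.1)))
    names(b) <- chans
    b
  })
  sigma <- matrix(runif(G * channels, 0.3, 1.2), G, channels)
  mixing <- as.numeric(rmultinom(1, 20, rep(1, G)) + 1)
  mixing <- mixing / sum(mixing)
  grp <- sample.int(G, n, replace = TRUE, prob = mixing)
  series <- lapply(seq_len(n), function(i) {
    obs <- list()
    for (v in seq_along(chans)) {
      keep <- runif(length(times)) > 0.15
      if (!any(keep)) keep[1] <- TRUE
      t <- times[keep]
      mu <- group_mean(beta[[grp[i]]][[v]], t)
      obs[[chans[v]]] <- data.frame(time = t, value = mu + rnorm(length(t), 0, sigma[grp[i], v]))
    }
    make_series(sprintf("S%03d", i), obs)
  })
  set <- do.call(make_set, series)
  spec <- gbtm_spec(G, orders = stats::setNames(rep(1L, 5L), vs_channels()))
  list(set = set, spec = spec, truth = grp,
       params = list(mixing = mixing, beta = beta, sigma = sigma))
}

# naive direct-summation mixture log-likelihood (the independent oracle):
# plain sums and exp(), no log-sum-exp
oracle_loglik <- function(set, mixing, beta, sigma) {
  tot <- 0
  for (s in set) {
    comp <- numeric(length(mixing))
    for (g in seq_along(mixing)) {
      lg <- 0
      for (v in seq_along(vs_channels())) {
        ch <- vs_channels()[v]
        ob <- s$observed[[ch]]
        if (is.null(ob) || !nrow(ob) || is.null(beta[[g]][[ch]])) next
        mu <- group_mean(beta[[g]][[ch]], ob$time)
        lg <- lg + sum(dnorm(ob$value, mu, sigma[g, v], log = TRUE))
      }
      comp[g] <- lg
    }
    tot <- tot + log(sum(mixing * exp(comp)))
  }
  tot
}

# total mixture loglik of a model object on a set, via per-patient evaluation
model_loglik_on <- function(model, set) {
  sum(vapply(set, function(s) patient_loglik(model, s)$total, 0))
}

# wrap raw params into something patient_loglik/e_step accept
as_model <- function(spec, mixing, beta, sigma) {
  # index beta lists by the full channel universe
  G <- spec$n_groups
  beta_full <- lapply(seq_len(G), function(g) {
    b <- stats::setNames(vector("list", 5L), vs_channels())
    for (ch in names(beta[[g]])) b[[ch]] <- beta[[g]][[ch]]
    b
  })
  sig_full <- matrix(.Machine$double.eps, G, 5L)
  sig_full[, seq_len(ncol(sigma))] <- sigma
  structure(list(spec = spec, mixing = mixing, beta = beta_full, sigma = sig_full,
                 loglik = NA_real_, n_params = NA_integer_, n_patients = length(mixing)),
            class = "gbtm_model")
}

# best-permutation agreement between modal assignments and latent truth
best_label_agreement <- function(modal, truth_int, G) {
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  best <- 0
  for (p in perms(seq_len(G))) {
    best <- max(best, mean(p[modal] == truth_int))
  }
  best
}

# a small complete-case observation table: 3 patients, full 7 x 5 grid
complete_obs_fixture <- function() {
  sched <- seq(0, 24, by = 4)
  base <- list(TEMP = 36.8, HR = 84, RR = 17, SBP = 122, DBP = 74)
  rows <- expand.grid(patient_id = c("p1", "p2", "p3"), channel = vs_channels(),
                      time_hours = sched, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  rows$value <- unlist(base[rows$channel]) + 0.1
  rows[order(rows$patient_id, rows$channel, rows$time_hours), ]
}
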