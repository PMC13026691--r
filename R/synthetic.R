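#' Channel trajectory template
#'
#' A polynomial mean trajectory plus Gaussian residual SD for one vital-sign
#' channel of one synthetic archetype.
#'
#' @param channel One of [vs_channels()].
#' @param coefficients Numeric length 2 or 3: intercept, slope per hour,
#'   optional curvature per hour^2, in the channel's natural units.
#' @param residual_sd Positive measurement noise SD, same units as the channel.
#' @return An object of class `channel_template`.
#' @export
channel_template <- function(channel, coefficients, residual_sd) {
  channel <- match.arg(channel, vs_channels())
  if (!is.numeric(coefficients) || !length(coefficients) %in% c(2L, 3L)) {
    stop("invalid 'coefficients': must be numeric of length 2 or 3", call. = FALSE)
  }
  # zero is admitted so the noiseless sanity world (observation == template
  # mean exactly) can be generated
  if (!is.numeric(residual_sd) || length(residual_sd) != 1L || residual_sd < 0) {
    stop("invalid 'residual_sd': must be a single non-negative number", call. = FALSE)
  }
  b <- vs_bounds(channel)
  mu <- group_mean(coefficients, seq(0, 24, by = 0.5))
  if (any(mu < b[1]) || any(mu > b[2])) {
    stop(sprintf(
      "invalid 'coefficients': %s mean leaves physiologic bounds [%g, %g] on [0, 24] h",
      channel, b[1], b[2]
    ), call. = FALSE)
  }
  structure(
    list(channel = channel, coefficients = as.numeric(coefficients),
         residual_sd = as.numeric(residual_sd)),
    class = "channel_template"
  )
}

#' Synthetic emergency-department cohort configuration
#'
#' Describes the latent world the generator draws from: four trajectory
#' archetypes with fixed cohort shares and per-archetype 30-day mortality
#' probabilities, a measurement schedule on \[0, 24\] hours, and the two
#' data-quality corruptions the preprocessing stage must survive
#' (missing-completely-at-random dropout and duplicate same-time recordings).
#'
#' @param n_patients Number of patients to simulate.
#' @param group_shares Probability vector over the 4 archetypes (A, B, C, D);
#'   renormalised, must sum to 1 within 1e-9 after renormalisation.
#' @param group_templates List of 4 archetypes, each a list of 5
#'   [channel_template()] objects named by channel.
#' @param mortality_probs Death probability per archetype, each in \[0, 1\].
#' @param schedule_hours Strictly increasing measurement times within \[0, 24\].
#' @param missing_rate Probability an individual observation is dropped.
#' @param duplicate_rate Probability an observation is recorded twice at the
#'   same time (with an independent noise draw), exercising duplicate
#'   averaging downstream.
#' @param seed Integer RNG seed; identical configs give byte-identical output.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients, group_shares, group_templates,
                             mortality_probs, schedule_hours = seq(0, 24, by = 4),
                             missing_rate = 0.1, duplicate_rate = 0.03, seed = 0L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 1) {
    stop("invalid 'n_patients': must be a single count >= 1", call. = FALSE)
  }
  if (!is.numeric(group_shares) || length(group_shares) != 4L ||
      any(group_shares < 0) || sum(group_shares) <= 0) {
    stop("invalid 'group_shares': must be 4 non-negative values", call. = FALSE)
  }
  group_shares <- group_shares / sum(group_shares)
  if (abs(sum(group_shares) - 1) > 1e-9) {
    stop("invalid 'group_shares': do not sum to 1 after renormalization", call. = FALSE)
  }
  if (!is.numeric(mortality_probs) || length(mortality_probs) != 4L ||
      any(mortality_probs < 0) || any(mortality_probs > 1)) {
    stop("invalid 'mortality_probs': must be 4 probabilities in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(schedule_hours) || length(schedule_hours) < 1L ||
      any(schedule_hours < 0) || any(schedule_hours > 24) ||
      any(diff(schedule_hours) <= 0)) {
    stop("invalid 'schedule_hours': must be strictly increasing within [0, 24]",
         call. = FALSE)
  }
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 1) {
    stop("invalid 'missing_rate': must be in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(duplicate_rate) || duplicate_rate < 0 || duplicate_rate >= 1) {
    stop("invalid 'duplicate_rate': must be in [0, 1)", call. = FALSE)
  }
  if (!is.list(group_templates) || length(group_templates) != 4L) {
    stop("invalid 'group_templates': must be a list of 4 archetypes", call. = FALSE)
  }
  for (g in seq_along(group_templates)) {
    tm <- group_templates[[g]]
    if (!is.list(tm) || !setequal(names(tm), vs_channels())) {
      stop(sprintf("invalid 'group_templates': archetype %d must have one template per channel", g),
           call. = FALSE)
    }
    for (ch in vs_channels()) {
      if (!inherits(tm[[ch]], "channel_template")) {
        stop(sprintf("invalid 'group_templates': archetype %d channel %s is not a channel_template", g, ch),
             call. = FALSE)
      }
    }
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      group_shares = group_shares,
      group_templates = group_templates,
      mortality_probs = mortality_probs,
      schedule_hours = as.numeric(schedule_hours),
      missing_rate = missing_rate,
      duplicate_rate = duplicate_rate,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# Build one archetype's template set from named mean/slope/sd vectors.
.make_templates <- function(means, slopes, sds) {
  out <- lapply(vs_channels(), function(ch) {
    channel_template(ch, c(means[[ch]], slopes[[ch]]), sds[[ch]])
  })
  names(out) <- vs_channels()
  out
}

#' Default synthetic cohort configuration
#'
#' The stated world the downstream analysis is validated on: four archetypes
#' with cohort shares 2.66 / 9.2 / 19 / 69.2 % and per-archetype 30-day
#' mortality 3/18, 4/62, 3/128, 48/467, sampled every 4 h over 0--24 h.
#' Archetype patterns: A = fever + tachycardia + tachypnea + hypotension
#' (all channels deranged, drifting mildly toward normal); B = hypertension
#' only; C = all channels normal; D = hypotension only.
#'
#' Deranged starting means are TEMP 38.8 degC, HR 118 bpm, RR 26 /min,
#' SBP 88 mmHg, DBP 52 mmHg; normal means TEMP 36.8, HR 84, RR 17, SBP 122
#' (B: 162), DBP 74. Deranged channels drift linearly about halfway back to
#' normal over 24 h. Residual SDs are typical clinical measurement noise:
#' TEMP 0.4, HR 9, RR 3, SBP 11, DBP 8.
#'
#' @param n_patients Cohort size (default 675, the study's sample size).
#' @param seed Integer RNG seed.
#' @param missing_rate,duplicate_rate Data-corruption rates, see
#'   [synthetic_config()].
#' @return A `synthetic_config` with archetypes named A--D.
#' @export
default_config <- function(n_patients = 675L, seed = 0L,
                           missing_rate = 0.1, duplicate_rate = 0.03) {
  sds <- list(TEMP = 0.4, HR = 9, RR = 3, SBP = 11, DBP = 8)
  normal <- list(TEMP = 36.8, HR = 84, RR = 17, SBP = 122, DBP = 74)
  flat <- list(TEMP = 0, HR = 0, RR = 0, SBP = 0, DBP = 0)
  templates <- list(
    # A: all channels deranged, drifting toward normal
    A = .make_templates(
      list(TEMP = 38.8, HR = 118, RR = 26, SBP = 88, DBP = 52),
      list(TEMP = -0.042, HR = -0.7, RR = -0.19, SBP = 0.7, DBP = 0.45),
      sds
    ),
    # B: hypertension only
    B = .make_templates(
      list(TEMP = 36.8, HR = 84, RR = 17, SBP = 162, DBP = 74),
      list(TEMP = 0, HR = 0, RR = 0, SBP = -0.8, DBP = 0),
      sds
    ),
    # C: all normal (control)
    C = .make_templates(normal, flat, sds),
    # D: arterial hypotension only
    D = .make_templates(
      list(TEMP = 36.8, HR = 84, RR = 17, SBP = 88, DBP = 74),
      list(TEMP = 0, HR = 0, RR = 0, SBP = 0.7, DBP = 0),
      sds
    )
  )
  synthetic_config(
    n_patients = n_patients,
    group_shares = c(A = 0.0266, B = 0.092, C = 0.19, D = 0.692),
    group_templates = templates,
    mortality_probs = c(A = 3 / 18, B = 4 / 62, C = 3 / 128, D = 48 / 467),
    schedule_hours = seq(0, 24, by = 4),
    missing_rate = missing_rate,
    duplicate_rate = duplicate_rate,
    seed = seed
  )
}

#' Generate a synthetic cohort
#'
#' Draws one latent archetype per patient from the configured shares, emits
#' each scheduled observation as template mean plus Gaussian noise (dropped
#' with `missing_rate`, recorded twice at the same time with
#' `duplicate_rate`), and draws the 30-day death flag from the archetype's
#' mortality probability. The latent archetype never appears in the
#' observation or outcome tables; it is returned in a separate truth table
#' keyed only by patient id.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_cohort` with data frames
#'   `observations` (`patient_id, channel, time_hours, value`),
#'   `outcomes` (`patient_id, death30, age, sex`) and
#'   `truth` (`patient_id, archetype`).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop("invalid 'config': not a synthetic_config", call. = FALSE)
  }
  # run under a private RNG state so generation is deterministic and does not
  # disturb the caller's stream
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(config$seed)

  n <- config$n_patients
  labels <- names(config$group_templates)
  if (is.null(labels)) labels <- as.character(seq_along(config$group_templates))
  arch <- sample.int(4L, n, replace = TRUE, prob = config$group_shares)
  pid <- sprintf("P%05d", seq_len(n))

  sched <- config$schedule_hours
  n_t <- length(sched)
  chans <- vs_channels()

  # fully vectorised draw over the (patient x channel x time) grid
  grid <- expand.grid(ti = seq_len(n_t), v = seq_along(chans), i = seq_len(n),
                      KEEP.OUT.ATTRS = FALSE)
  mu_tab <- array(NA_real_, dim = c(4L, length(chans), n_t))
  sd_tab <- matrix(NA_real_, 4L, length(chans))
  for (g in 1:4) for (v in seq_along(chans)) {
    tm <- config$group_templates[[g]][[chans[v]]]
    mu_tab[g, v, ] <- group_mean(tm$coefficients, sched)
    sd_tab[g, v] <- tm$residual_sd
  }
  gi <- arch[grid$i]
  mu <- mu_tab[cbind(gi, grid$v, grid$ti)]
  sdv <- sd_tab[cbind(gi, grid$v)]
  m <- nrow(grid)
  val <- mu + stats::rnorm(m, 0, sdv)
  keep <- stats::runif(m) >= config$missing_rate
  dup <- keep & (stats::runif(m) < config$duplicate_rate)
  # duplicates share the recorded time but carry an independent noise draw
  dup_val <- mu[dup] + stats::rnorm(sum(dup), 0, sdv[dup])
  observations <- data.frame(
    patient_id = pid[c(grid$i[keep], grid$i[dup])],
    channel = chans[c(grid$v[keep], grid$v[dup])],
    time_hours = sched[c(grid$ti[keep], grid$ti[dup])],
    value = c(val[keep], dup_val),
    stringsAsFactors = FALSE
  )
  observations <- observations[order(observations$patient_id,
                                     observations$channel,
                                     observations$time_hours), , drop = FALSE]
  rownames(observations) <- NULL

  death30 <- stats::rbinom(n, 1L, config$mortality_probs[arch])
  age <- round(pmin(96, pmax(18, stats::rnorm(n, 59.2, 19.3))))
  sex <- ifelse(stats::runif(n) < 0.5, "F", "M")

  structure(
    list(
      observations = observations,
      outcomes = data.frame(patient_id = pid, death30 = death30,
                            age = age, sex = sex, stringsAsFactors = FALSE),
      truth = data.frame(patient_id = pid, archetype = labels[arch],
                         stringsAsFactors = FALSE)
    ),
    class = "synthetic_cohort"
  )
}

#' Write a synthetic cohort to CSV
#'
#' Emits `observations.csv`, `outcomes.csv` and `truth.csv` (UTF-8, dot
#' decimal separator) into `dir`.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory, created if absent.
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("observations.csv", "outcomes.csv", "truth.csv"))
  utils::write.csv(cohort$observations, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$outcomes, paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$truth, paths[3], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
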