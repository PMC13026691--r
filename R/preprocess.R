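#' Load long-format vital-sign observations
#'
#' Reads a CSV with columns `patient_id, channel, time_hours, value`,
#' validates each row (known channel, parseable numerics, time within the
#' 0--24 h window, value within physiologic bounds) and returns the accepted
#' rows together with a rejection log carrying one reason per rejected row.
#' Invalid rows are never silently dropped.
#'
#' @param path CSV file path.
#' @return List with `observations` (accepted rows, columns as above) and
#'   `rejections` (data frame `row, reason`).
#' @export
load_observations <- function(path) {
  if (!file.exists(path)) stop(sprintf("observation file not found: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  required <- c("patient_id", "channel", "time_hours", "value")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("observation file is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (!nrow(raw)) {
    warning("observation file contains a header only; no observations loaded")
    return(list(
      observations = data.frame(patient_id = character(), channel = character(),
                                time_hours = numeric(), value = numeric(),
                                stringsAsFactors = FALSE),
      rejections = data.frame(row = integer(), reason = character(),
                              stringsAsFactors = FALSE)
    ))
  }
  tt <- suppressWarnings(as.numeric(raw$time_hours))
  vv <- suppressWarnings(as.numeric(raw$value))
  reason <- rep(NA_character_, nrow(raw))
  bad_chan <- !(raw$channel %in% vs_channels())
  reason[bad_chan] <- sprintf("unknown channel '%s'", raw$channel[bad_chan])
  nonnum <- is.na(tt) | is.na(vv)
  reason[is.na(reason) & nonnum] <- "unparseable numeric time_hours/value"
  out_t <- !nonnum & (tt < 0 | tt > 24)
  reason[is.na(reason) & out_t] <- "time outside 0-24 h window"
  lo <- rep(NA_real_, nrow(raw)); hi <- rep(NA_real_, nrow(raw))
  ok_chan <- !bad_chan
  lo[ok_chan] <- vapply(raw$channel[ok_chan], function(ch) .vs_bounds[[ch]][1], 0)
  hi[ok_chan] <- vapply(raw$channel[ok_chan], function(ch) .vs_bounds[[ch]][2], 0)
  out_v <- ok_chan & !nonnum & (vv < lo | vv > hi)
  reason[is.na(reason) & out_v] <- sprintf(
    "value outside physiologic bounds for %s", raw$channel[is.na(reason) & out_v])
  keep <- is.na(reason)
  observations <- data.frame(
    patient_id = raw$patient_id[keep],
    channel = raw$channel[keep],
    time_hours = tt[keep],
    value = vv[keep],
    stringsAsFactors = FALSE
  )
  rejections <- data.frame(row = which(!keep), reason = reason[!keep],
                           stringsAsFactors = FALSE)
  list(observations = observations, rejections = rejections)
}

#' Average duplicate same-time measurements
#'
#' For each (patient, channel, time) group the output holds a single row whose
#' value is the arithmetic mean of the group's values; this implements the
#' rule that when multiple measurements exist at the same time the average
#' measurement is used. "Same time" means identical `time_hours` after
#' rounding to 2 decimals. Output order is stable by (patient, channel, time).
#'
#' @param observations Data frame `patient_id, channel, time_hours, value`.
#' @return Data frame with duplicates collapsed.
#' @export
collapse_duplicates <- function(observations) {
  stopifnot(all(c("patient_id", "channel", "time_hours", "value") %in% names(observations)))
  if (!nrow(observations)) return(observations)
  tt <- round(observations$time_hours, 2)
  key <- interaction(observations$patient_id, observations$channel, tt, drop = TRUE)
  agg <- tapply(observations$value, key, mean)
  first <- !duplicated(key)
  out <- data.frame(
    patient_id = observations$patient_id[first],
    channel = observations$channel[first],
    time_hours = tt[first],
    value = as.numeric(agg[as.character(key[first])]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$patient_id, out$channel, out$time_hours), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble per-patient time series
#'
#' Joins deduplicated observations with the per-patient outcomes table into
#' one `patient_series` per patient. Patients present in the outcomes table
#' with zero valid observations are excluded (and logged); patients with
#' observations but no outcome row are a fatal referential-integrity error.
#' Missing (channel, time) cells are simply absent — nothing is imputed.
#'
#' @param observations Deduplicated observation data frame.
#' @param outcomes Data frame with `patient_id`, `death30`, optional `age`, `sex`.
#' @return A `patient_series_set`: list of `patient_series`, each holding
#'   `patient_id`, `observed` (per channel, a data frame `time, value`
#'   strictly increasing in time), `death30`, `age`, `sex`. Exclusions are in
#'   `attr(, "exclusions")`.
#' @export
assemble_series <- function(observations, outcomes) {
  stopifnot(all(c("patient_id", "death30") %in% names(outcomes)))
  if (anyDuplicated(outcomes$patient_id)) {
    stop("outcomes table has duplicated patient_id rows", call. = FALSE)
  }
  obs_ids <- unique(observations$patient_id)
  orphan <- setdiff(obs_ids, outcomes$patient_id)
  if (length(orphan)) {
    stop(sprintf("missing outcome for patient(s): %s",
                 paste(orphan, collapse = ", ")), call. = FALSE)
  }
  split_obs <- split(observations, observations$patient_id)
  excluded <- setdiff(outcomes$patient_id, obs_ids)
  keep_ids <- outcomes$patient_id[outcomes$patient_id %in% obs_ids]
  series <- lapply(keep_ids, function(id) {
    po <- split_obs[[id]]
    observed <- lapply(vs_channels(), function(ch) {
      pc <- po[po$channel == ch, , drop = FALSE]
      if (!nrow(pc)) return(NULL)
      pc <- pc[order(pc$time_hours), , drop = FALSE]
      if (anyDuplicated(pc$time_hours)) {
        stop(sprintf("duplicate times remain for patient %s channel %s; run collapse_duplicates first",
                     id, ch), call. = FALSE)
      }
      data.frame(time = pc$time_hours, value = pc$value)
    })
    names(observed) <- vs_channels()
    orow <- outcomes[match(id, outcomes$patient_id), , drop = FALSE]
    structure(
      list(patient_id = id, observed = observed,
           death30 = as.integer(orow$death30),
           age = if ("age" %in% names(orow)) orow$age else NA_real_,
           sex = if ("sex" %in% names(orow)) orow$sex else NA_character_),
      class = "patient_series"
    )
  })
  structure(series, class = "patient_series_set",
            exclusions = data.frame(
              patient_id = excluded,
              reason = rep("no valid observations", length(excluded)),
              stringsAsFactors = FALSE))
}

# Flatten a series set to one long table with integer patient / channel codes;
# the internal representation every fitting routine works from.
series_long <- function(series_set) {
  stopifnot(inherits(series_set, "patient_series_set"))
  chans <- vs_channels()
  rows <- lapply(seq_along(series_set), function(i) {
    s <- series_set[[i]]
    per <- lapply(seq_along(chans), function(v) {
      ob <- s$observed[[chans[v]]]
      if (is.null(ob) || !nrow(ob)) return(NULL)
      data.frame(pid = i, ch = v, time = ob$time, value = ob$value)
    })
    do.call(rbind, per)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("series set contains no observations", call. = FALSE)
  out
}

#' Z-score a series set per channel
#'
#' Standardises each channel with the cohort's pooled observation mean and SD
#' (population SD computed with denominator n), keeping the scaling record so
#' fitted trajectories can be reported back in natural units.
#'
#' @param series_set A `patient_series_set`.
#' @return List with `series` (the standardized set; the scaling record is
#'   also attached as `attr(, "scaling")`) and `scaling` (data frame
#'   `channel, mean, sd`).
#' @export
standardize <- function(series_set) {
  stopifnot(inherits(series_set, "patient_series_set"), length(series_set) > 0)
  long <- series_long(series_set)
  chans <- vs_channels()
  scaling <- do.call(rbind, lapply(seq_along(chans), function(v) {
    x <- long$value[long$ch == v]
    if (!length(x)) return(data.frame(channel = chans[v], mean = NA_real_, sd = NA_real_))
    m <- mean(x)
    s <- sqrt(mean((x - m)^2))
    if (!is.na(s) && s == 0) {
      stop(sprintf("channel %s has zero variance; cannot standardize", chans[v]),
           call. = FALSE)
    }
    data.frame(channel = chans[v], mean = m, sd = s, stringsAsFactors = FALSE)
  }))
  out <- lapply(series_set, function(s) {
    for (v in seq_along(chans)) {
      ob <- s$observed[[chans[v]]]
      if (is.null(ob) || !nrow(ob)) next
      s$observed[[chans[v]]]$value <- (ob$value - scaling$mean[v]) / scaling$sd[v]
    }
    s
  })
  out <- structure(out, class = "patient_series_set",
                   exclusions = attr(series_set, "exclusions"),
                   scaling = scaling)
  list(series = out, scaling = scaling)
}

#' Invert the standardization of a series set
#'
#' @param series_set A standardized `patient_series_set`.
#' @param scaling The scaling record from [standardize()].
#' @return The series set in natural units.
#' @export
unstandardize <- function(series_set, scaling) {
  chans <- vs_channels()
  out <- lapply(series_set, function(s) {
    for (v in seq_along(chans)) {
      ob <- s$observed[[chans[v]]]
      if (is.null(ob) || !nrow(ob)) next
      s$observed[[chans[v]]]$value <- ob$value * scaling$sd[v] + scaling$mean[v]
    }
    s
  })
  structure(out, class = "patient_series_set",
            exclusions = attr(series_set, "exclusions"))
}
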