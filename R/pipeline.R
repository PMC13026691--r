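#' Pipeline configuration
#'
#' Bundles everything one run needs: either a synthetic-cohort config or
#' paths to observation/outcome CSVs (exactly one of the two), the
#' standardize flag, model-selection settings, and the run seed.
#'
#' @param outdir Output directory for all artifacts.
#' @param synthetic_config A [synthetic_config()] to simulate from, or `NULL`.
#' @param input_observations,input_outcomes CSV paths for a real cohort, or
#'   `NULL` when simulating.
#' @param standardize Z-score channels before fitting (default `TRUE`).
#' @param orders Named per-channel polynomial orders; `NULL` selects them by
#'   the per-channel likelihood-ratio test.
#' @param alpha LRT significance level for order selection (default 0.05).
#' @param n_starts,max_iter,tol EM settings, see [fit_gbtm()].
#' @param min_share,app_threshold Selection screens, see [sweep_groups()].
#' @param variance Variance mode, see [gbtm_spec()].
#' @param reference Reference subphenotype for the mortality stage.
#' @param seed Run seed (default 0; every random draw derives from it).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir,
                            synthetic_config = NULL,
                            input_observations = NULL,
                            input_outcomes = NULL,
                            standardize = TRUE,
                            orders = NULL,
                            alpha = 0.05,
                            n_starts = 10L, max_iter = 500L, tol = 1e-6,
                            min_share = 0.05, app_threshold = 0.70,
                            variance = "group",
                            reference = "C",
                            seed = 0L) {
  synthetic <- !is.null(synthetic_config)
  has_inputs <- !is.null(input_observations) || !is.null(input_outcomes)
  if (synthetic == has_inputs) {
    stop("exactly one of 'synthetic_config' or input CSV paths must be given",
         call. = FALSE)
  }
  if (!synthetic && (is.null(input_observations) || is.null(input_outcomes))) {
    stop("both 'input_observations' and 'input_outcomes' are required", call. = FALSE)
  }
  structure(
    list(outdir = outdir, synthetic = synthetic,
         synthetic_config = synthetic_config,
         input_observations = input_observations,
         input_outcomes = input_outcomes,
         standardize = isTRUE(standardize), orders = orders, alpha = alpha,
         n_starts = as.integer(n_starts), max_iter = as.integer(max_iter),
         tol = tol, min_share = min_share, app_threshold = app_threshold,
         variance = variance, reference = reference, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full trajectory-subphenotyping pipeline
#'
#' Executes simulate (optional) -> preprocess -> fit/select -> assign ->
#' analyze, writing every intermediate artifact into `config$outdir`
#' (deduplicated observations, standardization record, selection report,
#' model JSON, assignments CSV, outcome tables, ROC coordinates) plus a run
#' manifest with the seed, package version and per-artifact MD5 checksums.
#' Re-running the same config reproduces identical artifacts.
#'
#' When the selection screens reject every candidate the analyze stage falls
#' back to the lowest-BIC fitted candidate and the manifest records the
#' fallback.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest list (also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  artifacts <- character(0)
  notes <- character(0)

  # -- simulate ---------------------------------------------------------------
  if (config$synthetic) {
    .stage("simulate", {
      cohort <- generate_cohort(config$synthetic_config)
      artifacts <- c(artifacts, write_cohort(cohort, outdir))
    })
    obs_path <- file.path(outdir, "observations.csv")
    out_path <- file.path(outdir, "outcomes.csv")
  } else {
    obs_path <- config$input_observations
    out_path <- config$input_outcomes
  }

  # -- preprocess -------------------------------------------------------------
  env <- new.env()
  .stage("preprocess", {
    loaded <- load_observations(obs_path)
    if (!file.exists(out_path)) stop(sprintf("outcome file not found: %s", out_path))
    outcomes <- utils::read.csv(out_path, stringsAsFactors = FALSE)
    dedup <- collapse_duplicates(loaded$observations)
    dedup_path <- file.path(outdir, "observations_dedup.csv")
    utils::write.csv(dedup, dedup_path, row.names = FALSE, quote = FALSE)
    rej_path <- file.path(outdir, "rejections.log")
    writeLines(
      if (nrow(loaded$rejections)) {
        sprintf("row %d: %s", loaded$rejections$row, loaded$rejections$reason)
      } else character(0), rej_path)
    series <- assemble_series(dedup, outcomes)
    excl <- attr(series, "exclusions")
    excl_path <- file.path(outdir, "exclusions.log")
    writeLines(
      if (nrow(excl)) sprintf("%s: %s", excl$patient_id, excl$reason) else character(0),
      excl_path)
    if (config$standardize) {
      std <- standardize(series)
      scaling_path <- file.path(outdir, "scaling.csv")
      utils::write.csv(std$scaling, scaling_path, row.names = FALSE, quote = FALSE)
      env$series <- std$series
      artifacts <- c(artifacts, dedup_path, rej_path, excl_path, scaling_path)
    } else {
      env$series <- series
      artifacts <- c(artifacts, dedup_path, rej_path, excl_path)
    }
    env$outcomes <- outcomes
  })

  # -- fit / select -----------------------------------------------------------
  .stage("fit", {
    orders <- config$orders
    lrt <- NULL
    if (is.null(orders)) {
      lrt <- lapply(vs_channels(), function(ch)
        select_polynomial_order(env$series, ch, alpha = config$alpha))
      names(lrt) <- vs_channels()
      orders <- vapply(lrt, `[[`, 0L, "order")
    }
    report <- sweep_groups(env$series, orders = orders, seed = config$seed,
                           n_starts = config$n_starts, max_iter = config$max_iter,
                           tol = config$tol, min_share = config$min_share,
                           app_threshold = config$app_threshold,
                           variance = config$variance)
    sel_path <- file.path(outdir, "selection_report.json")
    report_to_json(report, sel_path)
    env$report <- report
    if (is.na(report$selected_G)) {
      # fall back to the lowest-BIC fitted candidate so downstream stages run
      bics <- vapply(report$candidates,
                     function(cd) if (is.null(cd$model)) NA_real_ else cd$bic, 0)
      if (all(is.na(bics))) stop("no candidate model could be fitted")
      gi <- which.min(bics)
      notes <- c(notes, sprintf(
        "no candidate survived the selection screens; analyze uses G=%d (lowest BIC)", gi))
      env$model <- report$candidates[[gi]]$model
      env$assignments <- report$candidates[[gi]]$assignments
      env$label_map <- label_groups(env$model, env$assignments, env$series)
    } else {
      env$model <- report$selected_model
      env$assignments <- report$assignments
      env$label_map <- report$label_map
    }
    model_path <- file.path(outdir, "model.json")
    gbtm_to_json(env$model, model_path)
    artifacts <- c(artifacts, sel_path, model_path)
  })

  # -- assign -----------------------------------------------------------------
  .stage("assign", {
    asg <- env$assignments
    G <- env$model$spec$n_groups
    post <- as.data.frame(asg$posterior)
    names(post) <- sprintf("posterior_%s", env$label_map)
    adf <- cbind(
      data.frame(patient_id = asg$patient_id,
                 subphenotype = env$label_map[asg$modal_group],
                 max_posterior = asg$max_posterior,
                 stringsAsFactors = FALSE),
      post)
    asg_path <- file.path(outdir, "assignments.csv")
    utils::write.csv(adf, asg_path, row.names = FALSE, quote = FALSE)
    env$assign_df <- adf
    artifacts <- c(artifacts, asg_path)
  })

  # -- analyze ----------------------------------------------------------------
  .stage("analyze", {
    merged <- merge(env$assign_df[, c("patient_id", "subphenotype")],
                    env$outcomes[, c("patient_id", "death30")], by = "patient_id")
    ref <- config$reference
    if (!ref %in% merged$subphenotype) {
      # reference label may be absent for G<4 fits; use the largest group
      ref <- names(sort(table(merged$subphenotype), decreasing = TRUE))[1]
      notes <- c(notes, sprintf(
        "reference '%s' not among fitted labels; using largest group '%s'",
        config$reference, ref))
    }
    res <- analyze_mortality(merged$subphenotype, merged$death30,
                             reference = ref, seed = config$seed)
    ct_path <- file.path(outdir, "contingency.csv")
    utils::write.csv(as.data.frame(res$table), ct_path, row.names = FALSE, quote = FALSE)
    or_path <- file.path(outdir, "odds_ratios.csv")
    utils::write.csv(as.data.frame(res$odds_ratios), or_path, row.names = FALSE, quote = FALSE)
    roc_path <- file.path(outdir, "roc_points.csv")
    utils::write.csv(roc_points(res$logistic$fitted, merged$death30), roc_path,
                     row.names = FALSE, quote = FALSE)
    tests_path <- file.path(outdir, "analysis.json")
    jsonlite::write_json(
      list(
        chi2 = res$chi2[c("pearson", "lr", "min_expected", "use_likelihood_ratio")],
        logistic = list(coefficients = res$logistic$coefficients,
                        converged = res$logistic$converged,
                        reference = res$logistic$reference,
                        loglik = res$logistic$loglik),
        roc = res$roc[c("auc", "se", "ci_low", "ci_high", "p_vs_half")]
      ),
      tests_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    env$analysis <- res
    artifacts <- c(artifacts, ct_path, or_path, roc_path, tests_path)
  })

  # -- report -----------------------------------------------------------------
  manifest <- list(
    package = "vstraj",
    version = as.character(utils::packageVersion("vstraj")),
    seed = config$seed,
    standardize = config$standardize,
    stages = c(if (config$synthetic) "simulate", "preprocess", "fit", "assign",
               "analyze"),
    notes = notes,
    artifacts = lapply(artifacts, function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# minimal flag parser: --key value or --flag
.parse_flags <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop(sprintf("unexpected argument '%s'", a), call. = FALSE)
    key <- sub("^--", "", a)
    if (i < length(args) && !startsWith(args[i + 1L], "--")) {
      out[[key]] <- args[i + 1L]; i <- i + 2L
    } else {
      out[[key]] <- TRUE; i <- i + 1L
    }
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort), `all` (full
#' pipeline), `analyze` (mortality stage from an existing `assignments.csv`
#' + outcomes CSV). Global flags: `--outdir`, `--seed`, `--n`,
#' `--obs`/`--outcomes` (input CSVs), `--no-standardize`, `--min-share`,
#' `--config` (JSON file of [pipeline_config()] fields; explicit flags win).
#' Logs to stderr; returns 0 on success, 1 on failure naming the failed
#' stage.
#'
#' @param args Character vector, defaults to `commandArgs(trailingOnly=TRUE)`.
#' @return Integer exit status, invisibly.
#' @export
vstraj_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: vstraj <simulate|all|analyze> [--outdir DIR] [--seed N] [--n N] [--obs FILE --outcomes FILE] [--no-standardize] [--min-share X] [--config FILE]"
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  status <- tryCatch({
    flags <- .parse_flags(args[-1])
    if (!is.null(flags$config)) {
      cfgjs <- jsonlite::read_json(flags$config, simplifyVector = TRUE)
      for (k in names(cfgjs)) if (is.null(flags[[k]])) flags[[k]] <- cfgjs[[k]]
    }
    outdir <- if (is.null(flags$outdir)) "vstraj_out" else flags$outdir
    seed <- if (is.null(flags$seed)) 0L else as.integer(flags$seed)
    n <- if (is.null(flags$n)) 675L else as.integer(flags$n)
    if (cmd == "simulate") {
      cohort <- generate_cohort(default_config(n_patients = n, seed = seed))
      paths <- write_cohort(cohort, outdir)
      message(sprintf("wrote %s", paste(basename(paths), collapse = ", ")))
      0L
    } else if (cmd == "all") {
      cfg <- if (is.null(flags$obs)) {
        pipeline_config(outdir,
                        synthetic_config = default_config(n_patients = n, seed = seed),
                        standardize = is.null(flags[["no-standardize"]]),
                        min_share = if (is.null(flags[["min-share"]])) 0.05
                                    else as.numeric(flags[["min-share"]]),
                        seed = seed)
      } else {
        pipeline_config(outdir,
                        input_observations = flags$obs,
                        input_outcomes = flags$outcomes,
                        standardize = is.null(flags[["no-standardize"]]),
                        min_share = if (is.null(flags[["min-share"]])) 0.05
                                    else as.numeric(flags[["min-share"]]),
                        seed = seed)
      }
      run_pipeline(cfg)
      message(sprintf("pipeline complete; artifacts in %s", outdir))
      0L
    } else if (cmd == "analyze") {
      adf <- utils::read.csv(file.path(outdir, "assignments.csv"), stringsAsFactors = FALSE)
      outcomes <- utils::read.csv(
        if (is.null(flags$outcomes)) file.path(outdir, "outcomes.csv") else flags$outcomes,
        stringsAsFactors = FALSE)
      merged <- merge(adf[, c("patient_id", "subphenotype")],
                      outcomes[, c("patient_id", "death30")], by = "patient_id")
      res <- analyze_mortality(merged$subphenotype, merged$death30, seed = seed)
      utils::write.csv(as.data.frame(res$odds_ratios),
                       file.path(outdir, "odds_ratios.csv"),
                       row.names = FALSE, quote = FALSE)
      message(sprintf("AUC = %.3f", res$roc$auc))
      0L
    } else {
      message(usage)
      1L
    }
  }, error = function(e) {
    message(conditionMessage(e))
    1L
  })
  invisible(status)
}
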