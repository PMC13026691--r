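# finite-mixture trajectory model: likelihood, EM, BIC, posteriors

test_that("group_mean evaluates the trajectory polynomial", {
  expect_equal(group_mean(c(36.8, 0, 0), 12), 36.8)
  expect_equal(group_mean(c(1, 1, 1), 2), 7)
  expect_equal(group_mean(c(0, 2), 3), 6)
  expect_equal(group_mean(c(1, 2, 3), c(0, 1)), c(1, 6))
})

test_that("patient_loglik: degenerate mixture and standard-normal peak", {
  spec <- gbtm_spec(1L)
  m <- as_model(spec, 1, list(list(TEMP = c(36.8, 0))), matrix(1, 1, 1))
  s <- make_series("p", list(TEMP = data.frame(time = 12, value = 36.8)))
  pl <- patient_loglik(m, s)
  expect_equal(pl$total, -0.5 * log(2 * pi), tolerance = 1e-12)
  expect_equal(pl$total, pl$component_loglik[1], tolerance = 1e-12)
})

test_that("patient_loglik matches the direct-summation oracle to 1e-10", {
  for (seed in 1:20) {
    inst <- rand_instance(seed, n = 5L, G = sample(2:3, 1))
    m <- as_model(inst$spec, inst$params$mixing, inst$params$beta, inst$params$sigma)
    expect_equal(
      model_loglik_on(m, inst$set),
      oracle_loglik(inst$set, inst$params$mixing, inst$params$beta, inst$params$sigma),
      tolerance = 1e-10
    )
  }
})

test_that("log-sum-exp survives densities spanning hundreds of orders of magnitude", {
  spec <- gbtm_spec(2L)
  # two groups 60 residual SDs apart: per-observation density ratio ~ exp(-1800)
  beta <- list(list(TEMP = c(0, 0)), list(TEMP = c(60, 0)))
  m <- as_model(spec, c(0.5, 0.5), beta, matrix(1, 2, 1))
  s <- make_series("p", list(TEMP = data.frame(time = c(0, 6, 12), value = c(0, 0, 0))))
  pl <- patient_loglik(m, s)
  expect_true(is.finite(pl$total))
  expect_equal(pl$total, log(0.5) + 3 * dnorm(0, log = TRUE), tolerance = 1e-9)
})

test_that("e_step: symmetry, normalization, dominance", {
  spec <- gbtm_spec(2L)
  beta_same <- list(list(TEMP = c(0, 0)), list(TEMP = c(0, 0)))
  m_same <- as_model(spec, c(0.5, 0.5), beta_same, matrix(1, 2, 1))
  s <- make_series("p", list(TEMP = data.frame(time = c(0, 12), value = c(0.3, -0.2))))
  asg <- e_step(m_same, make_set(s))
  expect_equal(unname(asg$posterior[1, ]), c(0.5, 0.5), tolerance = 1e-12)

  beta_far <- list(list(TEMP = c(0, 0)), list(TEMP = c(30, 0)))
  m_far <- as_model(spec, c(0.5, 0.5), beta_far, matrix(1, 2, 1))
  on_curve <- make_series("q", list(TEMP = data.frame(time = c(0, 12), value = c(0, 0))))
  asg2 <- e_step(m_far, make_set(on_curve))
  expect_gte(asg2$posterior[1, 1], 1 - 1e-6)

  inst <- rand_instance(33, n = 30L, G = 3L)
  m3 <- as_model(inst$spec, inst$params$mixing, inst$params$beta, inst$params$sigma)
  asg3 <- e_step(m3, inst$set)
  expect_equal(rowSums(asg3$posterior), rep(1, 30), tolerance = 1e-12)
  expect_true(all(asg3$max_posterior >= 1 / 3 - 1e-12))
})

test_that("m_step reduces to OLS under unit weights and to per-subset OLS under 0/1 weights", {
  inst <- rand_instance(7, n = 16L, G = 2L, channels = 2L)
  spec1 <- gbtm_spec(1L)
  pars <- m_step(inst$set, matrix(1, 16, 1), spec1)
  long <- do.call(rbind, lapply(inst$set, function(s) {
    data.frame(time = s$observed$TEMP$time, value = s$observed$TEMP$value)
  }))
  ols <- unname(coef(lm(value ~ time, long)))
  expect_equal(unname(pars$beta[[1]]$TEMP), ols, tolerance = 1e-10)

  # hard 0/1 posteriors partition the cohort
  hard <- matrix(0, 16, 2)
  hard[cbind(1:16, inst$truth)] <- 1
  pars2 <- m_step(inst$set, hard, inst$spec)
  for (g in 1:2) {
    sub <- which(inst$truth == g)
    longg <- do.call(rbind, lapply(inst$set[sub], function(s) {
      data.frame(time = s$observed$HR$time, value = s$observed$HR$value)
    }))
    expect_equal(unname(pars2$beta[[g]]$HR),
                 unname(coef(lm(value ~ time, longg))), tolerance = 1e-10)
  }
})

test_that("singular design is fatal and names group and channel", {
  s1 <- make_series("p1", list(TEMP = data.frame(time = 4, value = 37)))
  s2 <- make_series("p2", list(TEMP = data.frame(time = 4, value = 38)))
  spec <- gbtm_spec(1L, orders = setNames(c(2L, 1L, 1L, 1L, 1L), vs_channels()))
  expect_error(m_step(make_set(s1, s2), matrix(1, 2, 1), spec),
               "group 1.*TEMP")
})

test_that("one EM cycle never decreases the log-likelihood", {
  for (seed in c(3, 14, 159)) {
    inst <- rand_instance(seed, n = 15L, G = 2L)
    # start from a perturbed model, run one e/m cycle by hand
    m0 <- as_model(inst$spec, c(0.4, 0.6),
                   lapply(inst$params$beta, lapply, function(b) b + 0.3),
                   inst$params$sigma + 0.2)
    ll0 <- model_loglik_on(m0, inst$set)
    asg <- e_step(m0, inst$set)
    pars <- m_step(inst$set, asg, inst$spec)
    m1 <- as_model(inst$spec, pars$mixing,
                   lapply(pars$beta, function(bg) bg[vs_channels()[1:2]]),
                   pars$sigma[, 1:2, drop = FALSE])
    expect_gte(model_loglik_on(m1, inst$set), ll0 - 1e-9)
  }
})

test_that("fit_gbtm with G=1 equals OLS and converges in <= 2 iterations", {
  inst <- rand_instance(21, n = 25L, G = 1L, channels = 2L)
  model <- fit_gbtm(inst$set, gbtm_spec(1L), n_starts = 1L, seed = 0)
  expect_true(model$converged)
  expect_lte(model$n_iter, 2L)
  long <- do.call(rbind, lapply(inst$set, function(s) {
    data.frame(time = s$observed$TEMP$time, value = s$observed$TEMP$value)
  }))
  expect_equal(unname(model$beta[[1]]$TEMP), unname(coef(lm(value ~ time, long))),
               tolerance = 1e-8)
})

test_that("fit_gbtm is deterministic given a seed", {
  inst <- rand_instance(5, n = 20L, G = 2L)
  m1 <- fit_gbtm(inst$set, inst$spec, n_starts = 3L, max_iter = 100L, seed = 17)
  m2 <- fit_gbtm(inst$set, inst$spec, n_starts = 3L, max_iter = 100L, seed = 17)
  expect_identical(m1, m2)
})

test_that("label permutation leaves loglik and BIC unchanged", {
  inst <- rand_instance(8, n = 5L, G = 2L)
  model <- fit_gbtm(inst$set, inst$spec, n_starts = 2L, max_iter = 100L, seed = 2)
  permuted <- model
  permuted$mixing <- model$mixing[c(2, 1)]
  permuted$beta <- model$beta[c(2, 1)]
  permuted$sigma <- model$sigma[c(2, 1), , drop = FALSE]
  expect_equal(model_loglik_on(permuted, inst$set), model_loglik_on(model, inst$set),
               tolerance = 1e-8)
  permuted$loglik <- model$loglik
  expect_equal(bic(permuted), bic(model))
})

test_that("bic arithmetic", {
  fake <- list(loglik = 0, n_params = 3L, n_patients = exp(2))
  expect_equal(bic(fake), 6)
  fake2 <- list(loglik = 0, n_params = 4L, n_patients = exp(2))
  expect_equal(bic(fake2) - bic(fake), log(exp(2)))
  expect_equal(bic(list(loglik = -10, n_params = 2L), n_patients = 100),
               20 + 2 * log(100))
})

test_that("average_posterior_probability: hard, symmetric and empty groups", {
  hard <- structure(list(
    patient_id = c("a", "b", "c"),
    posterior = rbind(c(1, 0), c(0, 1), c(1, 0)),
    modal_group = c(1L, 2L, 1L),
    max_posterior = c(1, 1, 1)), class = "posterior_assignment")
  expect_equal(average_posterior_probability(hard, 2L), c(1, 1))
  even <- structure(list(
    patient_id = c("a", "b"),
    posterior = rbind(c(0.5, 0.5), c(0.5, 0.5)),
    modal_group = c(1L, 1L),
    max_posterior = c(0.5, 0.5)), class = "posterior_assignment")
  app <- average_posterior_probability(even, 2L)
  expect_equal(app[1], 0.5)
  expect_true(is.na(app[2]))  # unpopulated group is flagged
})

test_that("well-separated two-group world: parameters recovered, APP high", {
  cfg <- default_config(n_patients = 400, seed = 31, missing_rate = 0.05,
                        duplicate_rate = 0)
  cfg$group_shares <- c(0, 0, 0.5, 0.5)  # C (normotensive) vs D (hypotensive)
  coh <- generate_cohort(cfg)
  series <- assemble_series(collapse_duplicates(coh$observations), coh$outcomes)
  model <- fit_gbtm(series, gbtm_spec(2L), n_starts = 3L, seed = 1)
  expect_true(model$converged)
  # mixing within 0.05 of the 50/50 truth
  expect_lt(abs(sort(model$mixing)[1] - 0.5), 0.05)
  # identify which fitted group is the hypotensive one via the SBP intercept
  gD <- which.min(vapply(1:2, function(g) model$beta[[g]]$SBP[1], 0))
  gC <- 3 - gD
  # coefficients within 3 OLS standard errors of the generating templates
  truth_lab <- coh$truth$archetype[match(
    vapply(series, `[[`, "", "patient_id"), coh$truth$patient_id)]
  for (ch in c("SBP", "TEMP", "HR")) {
    for (arc in c("C", "D")) {
      g <- if (arc == "D") gD else gC
      long <- do.call(rbind, lapply(series[truth_lab == arc], function(s) s$observed[[ch]]))
      fit <- lm(value ~ time, long)
      se <- sqrt(diag(vcov(fit)))
      expect_lt(max(abs(model$beta[[g]][[ch]] - cfg$group_templates[[arc]][[ch]]$coefficients) / se), 3)
    }
  }
  asg <- e_step(model, series)
  app <- average_posterior_probability(asg, 2L)
  expect_true(all(app > 0.70))
  # EM monotonicity on the winning trace
  expect_true(all(diff(model$loglik_trace) > -1e-7))
})

test_that("model JSON serialization carries the full parameter set", {
  inst <- rand_instance(2, n = 10L, G = 2L)
  model <- fit_gbtm(inst$set, inst$spec, n_starts = 2L, max_iter = 50L, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  gbtm_to_json(model, path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(doc$format, "vstraj-gbtm")
  expect_equal(doc$spec$n_groups, 2L)
  expect_equal(length(doc$groups), 2L)
  expect_equal(doc$loglik, model$loglik, tolerance = 1e-12)
  expect_equal(doc$bic, bic(model), tolerance = 1e-12)
})
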