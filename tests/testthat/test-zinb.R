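test_that("design bookkeeping matches the candidate-table df accounting", {
  tab <- bundle_model_table(study_bundle())
  specs <- table1_model_set()
  k_of <- function(s) build_design(s, tab)$k
  expect_equal(k_of(specs$conflict_int), 13) # with TD:HD interaction
  expect_equal(k_of(specs$conflict), 12)     # without
  expect_equal(k_of(specs$full_int), 16)
  expect_equal(k_of(specs$full), 15)
  expect_equal(k_of(specs$anthropogenic_int), 12)
  expect_equal(k_of(specs$anthropogenic), 11)
  expect_equal(k_of(specs$environmental), 8)
  expect_equal(k_of(specs$null), 4) # intercept + sigma + dispersion + zi

  t2 <- table2_model_set()
  expect_length(t2, 8)
  expect_equal(build_design(t2[["conflict x season"]]$nb1, tab)$k, 11)
  expect_equal(build_design(t2[["season"]]$nb1, tab)$k, 7)
  expect_true("null" %in% names(t2))
  # season enters as three contrasts against the spring reference
  X <- build_design(t2[["season"]]$nb2, tab)$X
  expect_equal(colnames(X),
               c("(Intercept)", "seasonsummer", "seasonautumn",
                 "seasonwinter"))
})

test_that("zero-effort rows are dropped with a message and missing covariates error", {
  tab <- bundle_model_table(study_bundle())
  tab$effort[1:3] <- 0
  expect_message(d <- build_design(model_spec(~EVI), tab), "3 rows")
  expect_equal(d$n, nrow(tab) - 3)
  expect_error(build_design(model_spec(~nonexistent), tab),
               "nonexistent")
})

test_that("quadrature likelihood matches brute-force integration", {
  d <- make_zinb_data(n_sites = 20, n_occ = 5, seed = 42)
  design <- build_design(model_spec(~x1), d)
  pars <- list(
    c(-2.8, 0.4, log(0.6), log(1.0), qlogis(0.25)),
    c(-3.2, 0.6, log(1.1), log(0.5), qlogis(0.1)),
    c(-2.5, 0.0, log(0.3), log(2.0), qlogis(0.4))
  )
  for (par in pars) {
    for (fam in c("nb2", "nb1")) {
      agq <- zinb_nll(par, design, family = fam, nagq = 15)
      oracle <- trapezoid_nll(par, design, family = fam)
      expect_equal(agq, oracle, tolerance = 1e-6)
    }
  }
})

test_that("likelihood reduces to plain NB regression when pi=0 and sigma->0", {
  d <- make_zinb_data(n_sites = 15, n_occ = 4, pi = 0, sigma = 0, seed = 7)
  design <- build_design(model_spec(~x1), d)
  beta <- c(-3, 0.5)
  theta <- 1.2
  par <- c(beta, log(1e-5), log(theta), qlogis(1e-12))
  agq <- zinb_nll(par, design, family = "nb2", nagq = 15)
  mu <- exp(as.vector(design$X %*% beta) + design$offset)
  oracle <- -sum(dnbinom(design$y, size = theta, mu = mu, log = TRUE))
  expect_equal(agq, oracle, tolerance = 1e-5)
})

test_that("nb2 likelihood approaches the Poisson limit for large theta", {
  d <- make_zinb_data(n_sites = 15, n_occ = 4, pi = 0, sigma = 0, seed = 8)
  design <- build_design(model_spec(~x1), d)
  beta <- c(-3, 0.5)
  par <- c(beta, log(1e-5), log(1e7), qlogis(1e-12))
  agq <- zinb_nll(par, design, family = "nb2", nagq = 15)
  mu <- exp(as.vector(design$X %*% beta) + design$offset)
  pois <- -sum(dpois(design$y, mu, log = TRUE))
  expect_equal(agq, pois, tolerance = 1e-4)
})

test_that("fitting is deterministic and recovers a moment check", {
  d <- make_zinb_data(n_sites = 40, n_occ = 8, beta = c(-3, 0), pi = 0,
                      sigma = 0, theta = 5, seed = 13)
  f1 <- fit_zinb(d, model_spec(~1), n_starts = 3, seed = 5)
  f2 <- fit_zinb(d, model_spec(~1), n_starts = 3, seed = 5)
  expect_identical(f1$par, f2$par)
  # intercept-only, near-Poisson data: intercept ~ log(total count / effort)
  expect_equal(f1$coefficients$estimate[1],
               log(sum(d$count) / sum(d$effort)), tolerance = 0.05)
})

test_that("fits agree with an independent mixed-model implementation", {
  skip_if_not_installed("glmmTMB")
  d <- make_zinb_data(n_sites = 30, n_occ = 8, pi = 0.25, seed = 42)
  ours <- fit_zinb(d, model_spec(~x1), n_starts = 3, seed = 1)
  tmb <- glmmTMB::glmmTMB(
    count ~ x1 + (1 | site_id), ziformula = ~1,
    family = glmmTMB::nbinom2, offset = log(d$effort), data = d)
  expect_equal(ours$coefficients$estimate,
               unname(glmmTMB::fixef(tmb)$cond), tolerance = 0.02)
  # AGQ integrates exactly what Laplace approximates: likelihoods are close
  # and quadrature can only do better
  expect_equal(ours$logLik, as.numeric(stats::logLik(tmb)), tolerance = 0.1)
  expect_gte(ours$logLik, as.numeric(stats::logLik(tmb)) - 1e-4)

  ours1 <- fit_zinb(d, model_spec(~x1, family = "nb1"), n_starts = 3,
                    seed = 1)
  tmb1 <- glmmTMB::glmmTMB(
    count ~ x1 + (1 | site_id), ziformula = ~1,
    family = glmmTMB::nbinom1, offset = log(d$effort), data = d)
  expect_equal(ours1$logLik, as.numeric(stats::logLik(tmb1)),
               tolerance = 0.1)
})

test_that("AICc formula, domain error and limits", {
  expect_equal(aicc(-5, 3, 10), 20) # 10 + 6 + 24/6
  expect_equal(aicc(-5, 0, 10), 10)
  expect_error(aicc(-5, 9, 10), "n must exceed")
  expect_equal(aicc(-5, 3, 1e9), -2 * (-5) + 6, tolerance = 1e-6)
})

test_that("Akaike weights are normalized relative likelihoods", {
  expect_equal(akaike_weights(c(100, 100)), c(0.5, 0.5))
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  withr::with_seed(2, {
    for (i in 1:10) {
      v <- runif(sample(2:8, 1), 50, 80)
      w <- akaike_weights(v)
      expect_equal(sum(w), 1)
      # ratio identity: w_i / w_j = exp((AICc_j - AICc_i) / 2)
      expect_equal(w[1] / w[2], exp((v[2] - v[1]) / 2))
    }
  })
})

test_that("model comparison reports within- and between-set deltas", {
  fake_fit <- function(name, set, aicc_val) {
    structure(list(
      spec = model_spec(~1, name = name, set = set),
      logLik = -aicc_val / 2, k = 4, n = 100, AICc = aicc_val,
      sigma_site = 1, dispersion = 1, zi_prob = 0.1, converged = TRUE
    ), class = "btk_zinb")
  }
  fits <- list(fake_fit("a1", "A", 100), fake_fit("a2", "A", 100.6),
               fake_fit("b1", "B", 104))
  cmp <- compare_models(fits)
  expect_equal(cmp$within_delta[cmp$model == "a2"], 0.6)
  expect_equal(cmp$between_delta[cmp$model == "b1"], 4)
  expect_equal(cmp$between_delta[cmp$set == "A"], c(0, 0))
  # weight ratio at delta 0.6 is exp(0.3)
  wa <- cmp$weight[cmp$model == "a1"] / cmp$weight[cmp$model == "a2"]
  expect_equal(wa, exp(0.3))
  # single-model set gets weight 1 and delta 0
  expect_equal(cmp$weight[cmp$model == "b1"], 1)
  # non-converged fits are excluded with a warning
  bad <- fake_fit("c1", "C", 90)
  bad$converged <- FALSE
  expect_warning(cmp2 <- compare_models(c(fits, list(bad))),
                 "non-converged")
  expect_false("c1" %in% cmp2$model)
})

test_that("parameter recovery on data simulated from a known spec", {
  # moderate-size single check; the replicated coverage study lives in the
  # acceptance suite
  truth_beta <- c(`(Intercept)` = -3.5, x1 = 0.6)
  d <- make_zinb_data(n_sites = 150, n_occ = 10, beta = truth_beta,
                      sigma = 0.6, theta = 1, pi = 0.25, seed = 31)
  f <- fit_zinb(d, model_spec(~x1), n_starts = 1, nagq = 7)
  expect_true(f$converged)
  est <- f$coefficients$estimate
  se <- f$coefficients$std_error
  expect_true(all(abs(est - truth_beta) < 3 * se))
  expect_equal(f$sigma_site, 0.6, tolerance = 0.35)
  expect_equal(f$zi_prob, 0.25, tolerance = 0.3)
})
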